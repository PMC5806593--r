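# Structural front end: parse PDB ATOM records, order residues by distance
# from a focal atom/residue/point, and turn a distinguished-residue list
# into the binary sequence the cluster test consumes.
#
# The parser reads only what this package needs from the fixed-column PDB
# format (ATOM/HETATM coordinate records, first model): chain, residue
# number + insertion code, atom name, alternate-location id, element and
# coordinates.

#' Read coordinate records from a PDB file
#'
#' Parses `ATOM`/`HETATM` records of the first model. Keeps the first
#' alternate location of each atom; drops hydrogens/deuteriums.
#'
#' @param path PDB file.
#' @return A data.frame with one row per atom: `record, atom, resname,
#'   chain, resseq, icode, x, y, z, element, residue_id` (id format
#'   `chain:resseq` with any insertion code appended).
#' @export
read_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end_model <- grep("^ENDMDL", lines)
  if (length(end_model)) lines <- lines[seq_len(end_model[1L] - 1L)]
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) stop("no ATOM/HETATM records parsed from ", path)
  fld <- function(a, b) trimws(substr(lines, a, b))
  coords <- suppressWarnings(cbind(as.numeric(substr(lines, 31, 38)),
                                   as.numeric(substr(lines, 39, 46)),
                                   as.numeric(substr(lines, 47, 54))))
  if (anyNA(coords)) stop("unparseable coordinates in ", path)
  atoms <- data.frame(
    record = trimws(substr(lines, 1, 6)),
    atom = fld(13, 16), altloc = fld(17, 17), resname = fld(18, 20),
    chain = fld(22, 22), resseq = as.integer(fld(23, 26)),
    icode = fld(27, 27),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    element = fld(77, 78)
  )
  if (anyNA(atoms$resseq)) stop("unparseable residue numbers in ", path)
  # element fallback from the atom name (digits stripped, first letter)
  blank <- !nzchar(atoms$element)
  atoms$element[blank] <-
    substr(gsub("[^A-Za-z]", "", atoms$atom[blank]), 1, 1)
  atoms <- atoms[!toupper(atoms$element) %in% c("H", "D"), , drop = FALSE]
  # first alternate location per (residue, atom name)
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$atom, sep = "\r")
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  atoms$residue_id <- paste0(atoms$chain, ":", atoms$resseq, atoms$icode)
  rownames(atoms) <- NULL
  atoms
}

#' Select residues from a structure
#'
#' @param path PDB file.
#' @param chains optional character vector of chain identifiers to keep.
#' @param residue_range optional `c(from, to)` residue-number window.
#' @param include_hetero keep `HETATM` groups other than water
#'   (default `FALSE`); water (`HOH`/`WAT`/`DOD`) is always dropped.
#' @return Atom data.frame as in [read_pdb_atoms()], restricted to the
#'   selection; errors name the selection when it is empty.
#' @export
load_structure <- function(path, chains = NULL, residue_range = NULL,
                           include_hetero = FALSE) {
  atoms <- read_pdb_atoms(path)
  atoms <- atoms[!atoms$resname %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  if (!include_hetero) atoms <- atoms[atoms$record == "ATOM", , drop = FALSE]
  if (!is.null(chains)) {
    atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
    if (!nrow(atoms))
      stop("no residues for chain selection: ", paste(chains, collapse = ", "))
  }
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2L)
    atoms <- atoms[atoms$resseq >= residue_range[1L] &
                     atoms$resseq <= residue_range[2L], , drop = FALSE]
    if (!nrow(atoms))
      stop("no residues in range ", residue_range[1L], "-", residue_range[2L])
  }
  rownames(atoms) <- NULL
  atoms
}

#' Resolve a focal specification to a point in space
#'
#' Accepted forms: `"x,y,z"` (literal coordinates), `"chain:resnum[:atom]"`
#' — a named atom of a residue, or the heavy-atom centroid of the residue
#' when no atom is given. `focal_atoms` may be a different selection than
#' the residues being ordered (e.g. a residue of the binding partner).
#'
#' @param spec focal specification string.
#' @param focal_atoms atom data.frame in which residue/atom focals resolve.
#' @return list with `point` (numeric xyz) and `residue_id` (`NA` for a
#'   literal point).
#' @export
parse_focal <- function(spec, focal_atoms = NULL) {
  stopifnot(is.character(spec), length(spec) == 1L)
  if (grepl("^\\s*-?[0-9.eE+-]+\\s*,", spec)) {
    xyz <- suppressWarnings(as.numeric(strsplit(spec, ",")[[1L]]))
    if (length(xyz) != 3L || anyNA(xyz))
      stop("literal focal point must be 'x,y,z': ", spec)
    return(list(point = xyz, residue_id = NA_character_))
  }
  parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
  if (!length(parts) %in% 2:3)
    stop("focal must be 'x,y,z', 'chain:resnum' or 'chain:resnum:atom': ", spec)
  if (is.null(focal_atoms)) stop("a structure is needed to resolve focal ", spec)
  rid <- paste0(parts[1L], ":", parts[2L])
  sel <- focal_atoms[focal_atoms$residue_id == rid, , drop = FALSE]
  if (!nrow(sel)) stop("focal residue not found in structure: ", rid)
  if (length(parts) == 3L) {
    sel <- sel[sel$atom == parts[3L], , drop = FALSE]
    if (!nrow(sel))
      stop("focal atom '", parts[3L], "' not found in residue ", rid)
    return(list(point = c(sel$x[1L], sel$y[1L], sel$z[1L]), residue_id = rid))
  }
  list(point = c(mean(sel$x), mean(sel$y), mean(sel$z)), residue_id = rid)
}

#' Order residues by distance from a focal point
#'
#' Each residue's distance to the focal point is the minimum over its
#' heavy atoms (`atom_mode = "min"`, default) or the C-alpha distance
#' (`"ca"`). Residues sort by ascending distance; distances are snapped to
#' 1e-6 Angstrom before sorting and ties break by (chain, residue number,
#' insertion code). If the focal specification names a residue of the
#' selection, that index residue is omitted from the track.
#'
#' @param atoms atom data.frame from [load_structure()].
#' @param focal focal specification string (see [parse_focal()]) or a
#'   numeric xyz vector.
#' @param atom_mode `"min"` (minimum heavy-atom distance) or `"ca"`.
#' @param focal_atoms atoms in which to resolve the focal (defaults to
#'   `atoms`; pass the full structure when the focal lies outside the
#'   ordered selection).
#' @return An `icl_track` data.frame: `rank, residue_id, distance,
#'   distinguished` (all `FALSE` until [make_binary()]), with attributes
#'   `focal` and `omitted_index`.
#' @export
order_by_distance <- function(atoms, focal, atom_mode = c("min", "ca"),
                              focal_atoms = atoms) {
  atom_mode <- match.arg(atom_mode)
  if (is.numeric(focal)) {
    stopifnot(length(focal) == 3L)
    focal <- list(point = as.numeric(focal), residue_id = NA_character_)
  } else {
    focal <- parse_focal(focal, focal_atoms)
  }
  work <- atoms
  if (atom_mode == "ca") {
    work <- work[work$atom == "CA", , drop = FALSE]
    if (!nrow(work)) stop("no C-alpha atoms in selection")
  }
  d2 <- (work$x - focal$point[1L])^2 + (work$y - focal$point[2L])^2 +
    (work$z - focal$point[3L])^2
  dist <- sqrt(d2)
  agg <- stats::aggregate(dist, by = list(residue_id = work$residue_id), min)
  names(agg)[2L] <- "distance"
  meta <- work[!duplicated(work$residue_id),
               c("residue_id", "chain", "resseq", "icode")]
  agg <- merge(agg, meta, by = "residue_id", sort = FALSE)
  omitted <- NA_character_
  if (!is.na(focal$residue_id) && focal$residue_id %in% agg$residue_id) {
    omitted <- focal$residue_id
    agg <- agg[agg$residue_id != omitted, , drop = FALSE]
  }
  snapped <- round(agg$distance / 1e-6) * 1e-6
  ord <- order(snapped, agg$chain, agg$resseq, agg$icode)
  track <- data.frame(rank = seq_along(ord),
                      residue_id = agg$residue_id[ord],
                      distance = agg$distance[ord],
                      distinguished = FALSE)
  structure(track, focal = focal, omitted_index = omitted,
            atom_mode = atom_mode,
            class = c("icl_track", "data.frame"))
}

#' Binary sequence from an ordered residue track
#'
#' Ones at the ranks of the distinguished residues. Identifiers that do
#' not match the track (including one equal to the omitted index residue)
#' are reported with a warning, never dropped silently.
#'
#' @param track an `icl_track` from [order_by_distance()].
#' @param distinguished character vector of residue identifiers
#'   (`chain:resnum[icode]`).
#' @return A [binary_sequence()] of length `nrow(track)` labelled with the
#'   residue identifiers; attribute `unmatched` lists identifiers that did
#'   not resolve.
#' @export
make_binary <- function(track, distinguished) {
  stopifnot(inherits(track, "icl_track"))
  distinguished <- unique(trimws(distinguished))
  distinguished <- distinguished[nzchar(distinguished)]
  hit <- match(distinguished, track$residue_id)
  unmatched <- distinguished[is.na(hit)]
  if (length(unmatched))
    warning("distinguished residues not in track: ",
            paste(unmatched, collapse = ", "))
  seq <- binary_sequence(nrow(track), track$rank[stats::na.omit(hit)],
                         labels = track$residue_id)
  attr(seq, "unmatched") <- unmatched
  seq
}

#' Read a distinguished-residue list
#'
#' One identifier per line (`chain:resnum[icode]`); blank lines and lines
#' starting with `#` are skipped.
#'
#' @param path text file.
#' @return character vector of identifiers.
#' @export
read_distinguished <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
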
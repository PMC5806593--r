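# Independent oracles: direct arithmetic (no logs, no package internals),
# feasible only at tiny L, used to pin down the log-space implementation.

# Two-segment maximum likelihood by direct powers, 0^0 = 1.
oracle_K <- function(x, y, d1, d2) {
  pw <- function(p, n) if (n == 0) 1 else p^n
  p1 <- d1 / x; p2 <- d2 / y
  pw(p1, d1) * pw(1 - p1, x - d1) * pw(p2, d2) * pw(1 - p2, y - d2)
}

# Z by brute-force enumeration of all C(L, D) arrangements.
oracle_Z_enumerate <- function(L, D, x) {
  if (D == 0 || D == L) return(oracle_K(x, L - x, min(D, x), max(0, D - x)))
  combos <- utils::combn(L, D)
  sum(apply(combos, 2, function(pos) {
    d1 <- sum(pos <= x)
    oracle_K(x, L - x, d1, D - d1)
  }))
}

# Optimal admissible cut by direct scan with enumerated Z; smallest-x ties.
oracle_best_cut <- function(bits, prior = "jeffreys") {
  L <- length(bits); D <- sum(bits)
  best <- NULL
  for (x in 1:(L - 1)) {
    y <- L - x
    d1 <- sum(bits[1:x]); d2 <- D - d1
    if (!(d1 / x > d2 / y)) next
    score <- oracle_K(x, y, d1, d2) / oracle_Z_enumerate(L, D, x)
    if (prior == "flattened") score <- score / sqrt(1 / x^2 + 1 / y^2)
    if (is.null(best) || score > best$score + 1e-12 * abs(best$score))
      best <- list(x = x, D1 = d1, score = score)
  }
  best
}

random_binseq <- function(L, D) binary_sequence(L, sample.int(L, D))

# Fixed-column PDB coordinate line.
pdb_line <- function(serial, name, resname, chain, resseq, xyz,
                     icode = " ", alt = " ", record = "ATOM  ",
                     element = substr(gsub("[^A-Za-z]", "", name), 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resname, chain, resseq, icode,
          xyz[1], xyz[2], xyz[3], 1, 0, element)
}

# Synthetic structure: n residues of chain `chain` on the x-axis at the
# given x-coordinates (one CA plus one CB 0.25 A further out per residue).
write_line_pdb <- function(path, xcoords, chain = "A", start_res = 1L) {
  lines <- character(0)
  serial <- 0L
  for (i in seq_along(xcoords)) {
    serial <- serial + 1L
    lines <- c(lines, pdb_line(serial, "CA", "ALA", chain,
                               start_res + i - 1L, c(xcoords[i], 0, 0)))
    serial <- serial + 1L
    lines <- c(lines, pdb_line(serial, "CB", "ALA", chain,
                               start_res + i - 1L, c(xcoords[i] + 0.25, 0, 0)))
  }
  writeLines(c(lines, "END"), path)
  path
}
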
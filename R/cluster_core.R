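# Core statistic: description lengths under H0/H1, NML normalization,
# model complexity under Jeffreys and flattened priors, optimal-cut search,
# and the logistic p-value conversion. All likelihood arithmetic is in
# base-2 log space (log-gamma + log-sum-exp); counts never materialize as
# binomial coefficients.

# x * log2(p) with the 0 * log2(0) = 0 convention (0^0 = 1 by continuity).
xlog2 <- function(n, p) {
  out <- numeric(length(n) * 0 + max(length(n), length(p)))
  n <- rep_len(n, length(out)); p <- rep_len(p, length(out))
  nz <- n != 0
  out[nz] <- n[nz] * log2(p[nz])
  out
}

# log2(sum(2^v)) guarding against -Inf-only input.
logsumexp2 <- function(v) {
  v <- v[v > -Inf]
  if (!length(v)) return(-Inf)
  m <- max(v)
  m + log2(sum(2^(v - m)))
}

#' Description length of the data under the null model
#'
#' The null model is a single Bernoulli theory with success probability
#' `D / L`; its description length is `L` times the Bernoulli entropy,
#' `D log2(L/D) + (L - D) log2(L/(L - D))` bits, with `0 log(0)` terms
#' taken as 0. The null contains one theory, so its complexity is 0 bits.
#'
#' @param L sequence length (positive integer).
#' @param D number of ones, `0 <= D <= L`.
#' @return Description length in bits (nonnegative).
#' @examples
#' null_description_length(2, 1)   # 2 bits
#' null_description_length(10, 0)  # 0 bits
#' @export
null_description_length <- function(L, D) {
  if (length(L) != 1L || L < 1 || L != floor(L))
    stop("L must be a positive integer")
  if (length(D) != 1L || D < 0 || D > L || D != floor(D))
    stop("D must be an integer in [0, L]")
  xlog2(D, L / max(D, 1)) + xlog2(L - D, L / max(L - D, 1))
}

#' Log2 maximum likelihood of a two-segment Bernoulli split
#'
#' For a cut producing an initial segment of length `x` with `D1` ones and
#' a terminal segment of length `y` with `D2` ones, returns the base-2 log
#' of `P1^D1 (1-P1)^(x-D1) P2^D2 (1-P2)^(y-D2)` where `P1 = D1/x` and
#' `P2 = D2/y` are the per-segment maximum-likelihood rates (`0^0 = 1`).
#' Vectorized over all four arguments.
#'
#' @param x,y segment lengths (each >= 1).
#' @param D1,D2 per-segment one-counts, `0 <= D1 <= x`, `0 <= D2 <= y`.
#' @return log2 likelihood, `<= 0`.
#' @export
cut_likelihood_log2 <- function(x, y, D1, D2) {
  n <- max(length(x), length(y), length(D1), length(D2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  D1 <- rep_len(D1, n); D2 <- rep_len(D2, n)
  if (any(x < 1 | y < 1)) stop("segment lengths must be >= 1")
  if (any(D1 < 0 | D1 > x | D2 < 0 | D2 > y))
    stop("segment counts must satisfy 0 <= D1 <= x and 0 <= D2 <= y")
  xlog2(D1, D1 / x) + xlog2(x - D1, (x - D1) / x) +
    xlog2(D2, D2 / y) + xlog2(y - D2, (y - D2) / y)
}

#' Log2 of the NML normalizer Z for a fixed cut
#'
#' `Z` is the sum of the two-segment maximum likelihood over all length-`L`
#' sequences with `D` ones. Grouping sequences by their initial-segment
#' count `D1` leaves at most `D + 1` terms:
#' `Z = sum_D1 C(x, D1) C(L-x, D-D1) K_x(D1)`, with `D1` restricted to
#' `[max(0, D-(L-x)), min(D, x)]` (binomial coefficients vanish outside).
#' No density restriction enters here; the restriction to 1-dense initial
#' segments is accounted for in the complexity term.
#'
#' @param L,D sequence length and one-count.
#' @param x cut position, `1 <= x <= L - 1`; vectorized.
#' @return log2 Z, same length as `x`.
#' @export
nml_normalizer_log2 <- function(L, D, x) {
  if (any(x < 1 | x > L - 1)) stop("x must lie in [1, L-1]")
  vapply(x, function(xx) {
    y <- L - xx
    d1 <- seq.int(max(0, D - y), min(D, xx))
    lg <- (lchoose(xx, d1) + lchoose(y, D - d1)) / log(2) +
      cut_likelihood_log2(xx, y, d1, D - d1)
    logsumexp2(lg)
  }, numeric(1))
}

# Log2 of the Jeffreys density factor sqrt(1/x^2 + 1/y^2).
log2_jeffreys_factor <- function(x, y) 0.5 * log2(1 / x^2 + 1 / y^2)

#' Evaluate every cut of a binary sequence
#'
#' Returns one row per cut `x = 1 .. L-1` with the per-segment counts and
#' rates, the log2 maximum likelihood `K_x`, the NML normalizer `Z`, the
#' NML score `log2 P_x = log2 K_x - log2 Z`, the flattened score
#' `log2 R_x = log2 P_x - log2 sqrt(1/x^2 + 1/y^2)`, and the admissibility
#' flag (initial density strictly greater than terminal density).
#'
#' @param seq a [binary_sequence()] with `L >= 2`.
#' @return A data.frame with columns `x, y, D1, D2, P1, P2, log2_Kx,
#'   log2_Z, log2_Px, log2_Rx, admissible`.
#' @export
cut_table <- function(seq) {
  stopifnot(inherits(seq, "binseq"))
  L <- seq$L; D <- seq$D
  if (L < 2L) stop("need L >= 2 to place a cut")
  x <- seq_len(L - 1L)
  y <- L - x
  D1 <- d1_prefix(seq, x)
  D2 <- D - D1
  lk <- cut_likelihood_log2(x, y, D1, D2)
  lz <- nml_normalizer_log2(L, D, x)
  lp <- lk - lz
  data.frame(
    x = x, y = y, D1 = D1, D2 = D2,
    P1 = D1 / x, P2 = D2 / y,
    log2_Kx = lk, log2_Z = lz, log2_Px = lp,
    log2_Rx = lp - log2_jeffreys_factor(x, y),
    admissible = D1 * y > D2 * x
  )
}

#' Score a single cut
#'
#' @param seq a [binary_sequence()].
#' @param x cut position in `[1, L-1]`.
#' @param prior `"jeffreys"` or `"flattened"` (affects only which score a
#'   caller would maximize; both are returned).
#' @return One-row data.frame as in [cut_table()].
#' @export
cut_score <- function(seq, x, prior = c("jeffreys", "flattened")) {
  prior <- match.arg(prior)
  tab <- cut_table(seq)
  if (length(x) != 1L || !(x %in% tab$x)) stop("x must lie in [1, L-1]")
  tab[tab$x == x, , drop = FALSE]
}

#' Fisher information for the cut location
#'
#' Under the continuous Poisson relaxation, the Fisher information of the
#' cut parameter at `X` is `J_X = (D/2) (1/X^2 + 1/Y^2)` with `Y = L - X`.
#'
#' @param X real cut location in `(0, L)`; vectorized.
#' @param L,D sequence length and one-count.
#' @return Nonnegative real, same length as `X`.
#' @export
fisher_information <- function(X, L, D) {
  if (any(X <= 0 | X >= L)) stop("X must lie in the open interval (0, L)")
  (D / 2) * (1 / X^2 + 1 / (L - X)^2)
}

#' Effective number of independent cut theories, Jeffreys prior
#'
#' The cut model holds `L - 1` theories, but neighbouring cuts are highly
#' correlated. The effective count is `(1/2) sqrt(D/pi) *
#' sum_{x=1}^{L-1} sqrt(1/x^2 + 1/y^2)` (exact sum over discrete cuts) or
#' the closed-form fit `sqrt(D/pi) ln(1.024 L)`. The exact sum is the
#' default: it is O(L) and carries no fitted constant.
#'
#' @param L sequence length, `>= 2`.
#' @param D one-count, `>= 1` (the test is undefined with no ones).
#' @param method `"sum"` (exact, default) or `"closed"`.
#' @return Positive real.
#' @export
independent_theories_jeffreys <- function(L, D, method = c("sum", "closed")) {
  method <- match.arg(method)
  if (L < 2) stop("L must be >= 2")
  if (D < 1) stop("D must be >= 1: test undefined with no ones")
  if (method == "closed") return(sqrt(D / pi) * log(1.024 * L))
  x <- seq_len(L - 1L)
  0.5 * sqrt(D / pi) * sum(sqrt(1 / x^2 + 1 / (L - x)^2))
}

#' Effective number of independent cut theories, flattened prior
#'
#' Dividing the NML score by the Jeffreys density makes the implied prior
#' over cut locations approximately uniform; the corresponding effective
#' theory count is `I* = sqrt(D/pi) (L - 1)`.
#'
#' @inheritParams independent_theories_jeffreys
#' @return Positive real.
#' @export
independent_theories_flattened <- function(L, D) {
  if (L < 2) stop("L must be >= 2")
  if (D < 1) stop("D must be >= 1: test undefined with no ones")
  sqrt(D / pi) * (L - 1)
}

#' Model complexity in bits
#'
#' `COMP = log2(I_eff / 2)`: the halving restricts the model to cuts whose
#' initial segment is the denser one (the terminal-dense half of the
#' theory space has no biological reading here). The optional finite-size
#' correction multiplies the effective count by `1 - D/L`, offsetting the
#' Poisson relaxation's inclusion of `(D1, X)` pairs with `D1 > X` or
#' `D2 > Y` that the discrete problem forbids.
#'
#' @param I positive effective theory count.
#' @param L,D sequence length and one-count (used by the correction).
#' @param apply_correction logical; multiply `I` by `1 - D/L` first.
#' @return Complexity in bits (may be negative for tiny `L`).
#' @export
complexity_bits <- function(I, L, D, apply_correction = FALSE) {
  if (I <= 0) stop("I must be positive")
  if (apply_correction) {
    if (D >= L) stop("correction factor 1 - D/L is zero for D = L")
    I <- I * (1 - D / L)
  }
  log2(I / 2)
}

#' Find the optimal admissible cut
#'
#' Scans `x = 1 .. L-1`, keeps cuts whose initial one-density strictly
#' exceeds the terminal density, and returns the admissible cut maximizing
#' `log2 P_x` (Jeffreys) or `log2 R_x` (flattened). Ties break toward the
#' smallest `x`. Returns `NULL` when no cut is admissible (e.g. `D = 0`,
#' all ones terminal, or `D = L`), never an error.
#'
#' @param seq a [binary_sequence()] with `L >= 2`.
#' @param prior `"jeffreys"` or `"flattened"`.
#' @return One-row data.frame (a [cut_table()] row) or `NULL`.
#' @export
best_cut <- function(seq, prior = c("jeffreys", "flattened")) {
  prior <- match.arg(prior)
  tab <- cut_table(seq)
  adm <- tab[tab$admissible, , drop = FALSE]
  if (!nrow(adm)) return(NULL)
  score <- if (prior == "jeffreys") adm$log2_Px else adm$log2_Rx
  adm[which.max(score), , drop = FALSE]
}

# Stable logistic: p = 1 / (1 + 2^delta).
logistic_pvalue <- function(delta_bits) {
  ifelse(delta_bits >= 0,
         2^(-delta_bits) / (1 + 2^(-delta_bits)),
         1 / (1 + 2^(delta_bits)))
}

#' Run the initial-cluster test
#'
#' Compares the one-theory Bernoulli null against the two-segment cut
#' model. The evidence is the description-length difference in bits,
#' `delta = DL(S|H0) - (DL(S|H1) + COMP(H1))`, converted to a p-value by
#' the logistic function `p = 1 / (1 + 2^delta)`, so the cut model is
#' preferred exactly when `p < 0.5`. With no admissible cut the result has
#' `X = NA` and `p = 1` by convention.
#'
#' @param seq a [binary_sequence()] with `L >= 2`.
#' @param prior `"jeffreys"` (maximize the NML score `P_x`, complexity from
#'   the Fisher-information sum) or `"flattened"` (maximize `R_x`,
#'   complexity `sqrt(D/pi)(L-1)/2`).
#' @param apply_correction logical; multiply the effective theory count by
#'   `1 - D/L`. Default `TRUE`, appropriate for observational tracks; the
#'   null-simulation experiments run uncorrected (see [sim_skew_recovery()]).
#' @param complexity_method `"sum"` or `"closed"`, Jeffreys prior only.
#' @return An `icl_result` list: `prior`, `correction`, `L`, `D`, `X`,
#'   `D1`, `dl_null_bits`, `dl_alt_bits`, `comp_bits`, `delta_bits`,
#'   `p_value`.
#' @examples
#' r <- cluster_test(parse_binary_string("1100"), prior = "jeffreys",
#'                   apply_correction = FALSE)
#' round(r$p_value, 3)  # 0.073
#' @export
cluster_test <- function(seq, prior = c("jeffreys", "flattened"),
                         apply_correction = TRUE,
                         complexity_method = c("sum", "closed")) {
  prior <- match.arg(prior)
  complexity_method <- match.arg(complexity_method)
  stopifnot(inherits(seq, "binseq"))
  L <- seq$L; D <- seq$D
  dl_null <- null_description_length(L, D)
  best <- best_cut(seq, prior)
  if (is.null(best)) {
    res <- list(prior = prior, correction = apply_correction, L = L, D = D,
                X = NA_integer_, D1 = NA_integer_, dl_null_bits = dl_null,
                dl_alt_bits = NA_real_, comp_bits = NA_real_,
                delta_bits = NA_real_, p_value = 1)
    class(res) <- "icl_result"
    return(res)
  }
  I <- switch(prior,
              jeffreys = independent_theories_jeffreys(L, D, complexity_method),
              flattened = independent_theories_flattened(L, D))
  comp <- complexity_bits(I, L, D, apply_correction)
  dl_alt <- -(if (prior == "jeffreys") best$log2_Px else best$log2_Rx)
  delta <- dl_null - (dl_alt + comp)
  res <- list(prior = prior, correction = apply_correction, L = L, D = D,
              X = best$x, D1 = best$D1, dl_null_bits = dl_null,
              dl_alt_bits = dl_alt, comp_bits = comp,
              delta_bits = delta, p_value = logistic_pvalue(delta))
  class(res) <- "icl_result"
  res
}

#' @export
print.icl_result <- function(x, ...) {
  cat(sprintf("initial-cluster test (%s prior%s)\n", x$prior,
              if (x$correction) ", finite-size correction" else ""))
  cat(sprintf("  L = %d, D = %d\n", x$L, x$D))
  if (is.na(x$X)) {
    cat("  no admissible cut; p = 1\n")
  } else {
    cat(sprintf("  optimal cut X = %d with D1 = %d ones before it\n",
                x$X, x$D1))
    cat(sprintf("  DL(H0) = %.3f bits, DL(H1) = %.3f + COMP %.3f bits\n",
                x$dl_null_bits, x$dl_alt_bits, x$comp_bits))
    cat(sprintf("  delta = %.3f bits, p = %.4g\n", x$delta_bits, x$p_value))
  }
  invisible(x)
}

#' Expected initial-segment count under the Poisson NML relaxation
#'
#' Evaluates the series `E[D1] = sum_i i * f(i)` where
#' `f(i) ~ i^i j^j / (i! j!)` with `j = D - i` and `0^0 = 1` — the NML
#' form of the two-Poisson model used to derive the Fisher information.
#' The series collapses to `D/2` by the `i <-> j` symmetry; this function
#' exists to verify that identity numerically, not for production use.
#'
#' @param D total one-count, `>= 0`.
#' @return `E[D1]`, equal to `D/2` up to floating point.
#' @export
poisson_expected_initial_count <- function(D) {
  if (D < 0 || D != floor(D)) stop("D must be a nonnegative integer")
  if (D == 0) return(0)
  i <- 0:D
  j <- D - i
  # log of i^i j^j / (i! j!); i^(i+1) adds one extra log(i) (zero term at i=0)
  base <- ifelse(i > 0, i * log(i), 0) + ifelse(j > 0, j * log(j), 0) -
    lgamma(i + 1) - lgamma(j + 1)
  m <- max(base)
  z <- sum(exp(base - m))
  num <- sum(i * exp(base - m))
  num / z
}
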
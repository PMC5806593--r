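test_that("null description length is L times the Bernoulli entropy", {
  expect_equal(null_description_length(2, 1), 2)
  expect_equal(null_description_length(10, 0), 0)
  expect_equal(null_description_length(10, 10), 0)
  # direct high-precision evaluation of the entropy formula
  expect_equal(null_description_length(601, 75),
               75 * log2(601 / 75) + 526 * log2(601 / 526))
  expect_equal(round(null_description_length(601, 75), 1), 326.3)
  expect_error(null_description_length(0, 0), "positive")
  expect_error(null_description_length(5, 6), "\\[0, L\\]")
})

test_that("two-segment likelihood honours 0^0 = 1 and its bounds", {
  expect_equal(cut_likelihood_log2(2, 2, 2, 0), 0)
  expect_equal(cut_likelihood_log2(2, 2, 1, 1), log2(1 / 16))
  expect_equal(cut_likelihood_log2(1, 3, 1, 1), log2(4 / 27))
  # vectorized, always <= 0
  set.seed(11)
  x <- sample(1:9, 50, TRUE); y <- sample(1:9, 50, TRUE)
  d1 <- vapply(x, function(k) sample(0:k, 1), integer(1))
  d2 <- vapply(y, function(k) sample(0:k, 1), integer(1))
  expect_true(all(cut_likelihood_log2(x, y, d1, d2) <= 1e-12))
  expect_error(cut_likelihood_log2(2, 2, 3, 0), "D1 <= x")
  expect_error(cut_likelihood_log2(0, 2, 0, 0), ">= 1")
})

test_that("NML normalizer matches brute-force enumeration and reflects", {
  expect_equal(nml_normalizer_log2(4, 2, 2), log2(2.25))
  expect_equal(nml_normalizer_log2(4, 2, 1), log2(8 / 9))
  expect_equal(nml_normalizer_log2(4, 2, 3), nml_normalizer_log2(4, 2, 1))
  # spot checks against enumeration (the exhaustive sweep is in acceptance)
  for (case in list(c(7, 3, 2), c(9, 4, 5), c(10, 1, 7), c(8, 7, 3))) {
    expect_equal(2^nml_normalizer_log2(case[1], case[2], case[3]),
                 oracle_Z_enumerate(case[1], case[2], case[3]),
                 tolerance = 1e-12)
  }
  # reflection symmetry in log space
  for (L in c(9, 12, 30)) {
    lz <- nml_normalizer_log2(L, 4, 1:(L - 1))
    expect_equal(lz, rev(lz), tolerance = 1e-12)
  }
  expect_error(nml_normalizer_log2(4, 2, 4), "\\[1, L-1\\]")
})

test_that("cut_table scores match hand computation for 1100", {
  tab <- cut_table(parse_binary_string("1100"))
  expect_equal(nrow(tab), 3L)
  expect_equal(2^tab$log2_Px[tab$x == 2], 4 / 9)
  expect_equal(2^tab$log2_Px[tab$x == 1], 1 / 6)
  expect_equal(tab$admissible, c(TRUE, TRUE, TRUE))  # even x=3: 2/3 > 0
  expect_equal(cut_table(parse_binary_string("0011"))$admissible,
               rep(FALSE, 3))
  expect_true(all(tab$log2_Px <= 1e-12))
  expect_equal(tab$D1 + tab$D2, rep(2L, 3))
  # midpoint: the Jeffreys density divisor is 2*sqrt(2)/L
  s <- random_binseq(20, 6)
  row <- cut_score(s, 10)
  expect_equal(row$log2_Rx - row$log2_Px, -log2(2 * sqrt(2) / 20))
})

test_that("Fisher information follows (D/2)(1/X^2 + 1/Y^2)", {
  expect_equal(fisher_information(50, 100, 50), 0.02)
  expect_equal(fisher_information(17.3, 100, 0), 0)
  expect_equal(fisher_information(200, 601, 75),
               37.5 * (1 / 40000 + 1 / 160801))
  expect_error(fisher_information(0, 10, 2), "open interval")
  expect_error(fisher_information(10, 10, 2), "open interval")
})

test_that("effective theory counts: values, scaling, sum vs closed form", {
  expect_equal(independent_theories_jeffreys(601, 75, "closed"),
               sqrt(75 / pi) * log(1.024 * 601))
  expect_equal(round(independent_theories_jeffreys(601, 75, "closed"), 1), 31.4)
  expect_equal(independent_theories_jeffreys(601, 75),
               independent_theories_jeffreys(601, 75, "closed"),
               tolerance = 0.01)
  # I scales as sqrt(D)
  expect_equal(independent_theories_jeffreys(601, 300),
               2 * independent_theories_jeffreys(601, 75))
  expect_equal(independent_theories_flattened(601, 300),
               2 * independent_theories_flattened(601, 75))
  expect_equal(independent_theories_flattened(601, 75), sqrt(75 / pi) * 600)
  expect_equal(round(independent_theories_flattened(601, 75), 1), 2931.6)
  expect_equal(independent_theories_flattened(2, 1), sqrt(1 / pi))
  expect_error(independent_theories_jeffreys(601, 0), "undefined")
  expect_error(independent_theories_flattened(601, 0), "undefined")
})

test_that("complexity halves the theory count and the correction shrinks it", {
  expect_equal(complexity_bits(2, 100, 10), 0)
  expect_equal(complexity_bits(2931.615, 601, 75, apply_correction = TRUE),
               log2(2931.615 * (526 / 601) / 2))
  for (D in c(1, 10, 99)) {
    expect_lt(complexity_bits(50, 100, D, apply_correction = TRUE),
              complexity_bits(50, 100, D))
  }
  expect_error(complexity_bits(0, 10, 2), "positive")
  expect_error(complexity_bits(5, 10, 10, apply_correction = TRUE), "zero")
})

test_that("best_cut matches the enumeration oracle on random sequences", {
  b <- best_cut(parse_binary_string("1100"))
  expect_equal(b$x, 2L)
  expect_equal(b$D1, 2L)
  expect_equal(2^b$log2_Px, 4 / 9)
  expect_null(best_cut(parse_binary_string("0011")))
  expect_null(best_cut(parse_binary_string("1111")))
  expect_null(best_cut(binary_sequence(6)))

  set.seed(202)
  for (i in 1:25) {
    L <- sample(4:11, 1)
    D <- sample(1:(L - 1), 1)
    s <- random_binseq(L, D)
    bits <- integer(L); bits[s$ones] <- 1L
    for (prior in c("jeffreys", "flattened")) {
      got <- best_cut(s, prior)
      want <- oracle_best_cut(bits, prior)
      if (is.null(want)) {
        expect_null(got, info = paste(format(s), prior))
        next
      }
      expect_equal(got$x, want$x, info = paste(format(s), prior))
      expect_equal(got$D1, want$D1)
      sc <- if (prior == "jeffreys") got$log2_Px else got$log2_Rx
      expect_equal(2^sc, want$score, tolerance = 1e-10)
    }
  }
})

test_that("cluster_test reproduces the worked 1100 chain and conventions", {
  r <- cluster_test(parse_binary_string("1100"), "jeffreys",
                    apply_correction = FALSE)
  expect_equal(r$dl_null_bits, 4)
  expect_equal(r$dl_alt_bits, log2(9 / 4))
  expect_equal(round(r$comp_bits, 3), -0.832)
  expect_equal(round(r$p_value, 4), 0.0732)
  # H1 preferred iff delta > 0 iff p < 0.5
  expect_true(r$delta_bits > 0 && r$p_value < 0.5)

  # degenerate inputs give p = 1, never errors
  for (s in c("0011", "11", "000")) {
    r0 <- cluster_test(parse_binary_string(s))
    expect_true(is.na(r0$X))
    expect_equal(r0$p_value, 1)
  }

  # logistic mapping in bits
  expect_equal(initclust:::logistic_pvalue(0), 0.5)
  expect_equal(initclust:::logistic_pvalue(10), 1 / 1025)
  expect_equal(initclust:::logistic_pvalue(5000), 0)
  expect_equal(initclust:::logistic_pvalue(-5000), 1)

  # correction strictly lowers the p-value when an admissible cut exists
  s <- parse_binary_string("110100100001000000000001")
  expect_lt(cluster_test(s, apply_correction = TRUE)$p_value,
            cluster_test(s, apply_correction = FALSE)$p_value)
})

test_that("moving a 1 into the initial segment never worsens the fit", {
  set.seed(303)
  for (i in 1:20) {
    L <- sample(8:16, 1)
    D <- sample(2:(L - 2), 1)
    s <- random_binseq(L, D)
    b <- best_cut(s)
    if (is.null(b)) next
    X <- b$x
    term_ones <- s$ones[s$ones > X]
    init_zeros <- setdiff(1:X, s$ones)
    if (!length(term_ones) || !length(init_zeros)) next
    ones2 <- sort(c(setdiff(s$ones, term_ones[1]), init_zeros[1]))
    b2 <- best_cut(binary_sequence(L, ones2))
    expect_lte(-b2$log2_Px, -b$log2_Px + 1e-10)
  }
})

test_that("Poisson NML series for E[D1] collapses to D/2", {
  expect_equal(poisson_expected_initial_count(2), 1)
  expect_equal(poisson_expected_initial_count(10), 5)
  for (D in c(1, 3, 17, 60, 200)) {
    expect_equal(poisson_expected_initial_count(D), D / 2,
                 tolerance = 1e-9)
  }
  expect_equal(poisson_expected_initial_count(0), 0)
})
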
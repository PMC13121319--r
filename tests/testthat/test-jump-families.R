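test_that("coefficient sequences honor the strict crossing inequality", {
  deg <- jump_family("degenerate", value = 1)
  cs <- coeff_sequence(deg, 17, 20)
  expect_equal(cs$values[17], 1)   # c_16: 16 < 17
  expect_equal(cs$values[18], 0)   # c_17: 17 is not < 17
  expect_equal(cs$n_max_zero, 17L)
  # strictness at integer thresholds, several values
  for (z in c(2, 5, 9)) {
    v <- coeff_sequence(deg, z, z + 1)$values
    expect_equal(v[z], 1)
    expect_equal(v[z + 1], 0)
  }
})

test_that("c_0 = 1 for every family (empty sum is below any threshold)", {
  fams <- list(jump_family("degenerate", value = 3),
               jump_family("bernoulli", prob = 0.36),
               jump_family("binomial", size = 4, prob = 0.2),
               jump_family("poisson", mean = 1.23),
               jump_family("exponential", rate = 0.71),
               jump_family("gamma", shape = 2, rate = 1.5),
               jump_family("discrete_lattice", support = c(0, 0.5, 2),
                           probs = c(0.2, 0.5, 0.3)))
  for (f in fams) expect_equal(coeff_sequence(f, 0.7, 5)$values[1], 1)
})

test_that("closed forms match independent oracles", {
  # single exponential jump below 14: quadrature of the density
  c1 <- coeff_sequence(jump_family("exponential", rate = 0.71), 14, 2)$values[2]
  oracle <- integrate(function(u) dexp(u, 0.71), 0, 14,
                      rel.tol = 1e-12)$value
  expect_equal(c1, oracle, tolerance = 1e-10)
  expect_equal(c1, 1 - exp(-9.94), tolerance = 1e-12)

  # ten bernoulli jumps below 7: exhaustive enumeration of 2^10 outcomes
  p <- 0.36
  outcomes <- 0:(2^10 - 1)
  bits <- vapply(outcomes, function(o) sum(bitwAnd(o, 2^(0:9)) > 0),
                 numeric(1))
  probs <- p^bits * (1 - p)^(10 - bits)
  oracle10 <- sum(probs[bits < 7])
  c10 <- coeff_sequence(jump_family("bernoulli", prob = p), 7, 10)$values[11]
  expect_equal(c10, oracle10, tolerance = 1e-10)
  expect_equal(c10, pbinom(6, 10, p), tolerance = 1e-12)
})

test_that("lattice closed forms agree with brute-force convolution to 1e-10", {
  cases <- list(
    list(fam = jump_family("bernoulli", prob = 0.36), pmf = c(0.64, 0.36),
         thr = 7),
    list(fam = jump_family("poisson", mean = 1.23),
         pmf = dpois(0:60, 1.23), thr = 19),
    list(fam = jump_family("binomial", size = 3, prob = 0.4),
         pmf = dbinom(0:3, 3, 0.4), thr = 5))
  for (cs in cases) {
    v <- coeff_sequence(cs$fam, cs$thr, 30)$values
    for (n in c(1, 2, 5, 12, 30)) {
      pmf_n <- conv_pmf(cs$pmf, n)
      expect_equal(v[n + 1], sum(pmf_n[seq_len(min(cs$thr, length(pmf_n)))]),
                   tolerance = 1e-10)
    }
  }
})

test_that("gamma-family coefficients agree with quadrature for n <= 30", {
  fam <- jump_family("gamma", shape = 1.7, rate = 0.9)
  v <- coeff_sequence(fam, 12, 30)$values
  for (n in c(1, 3, 10, 30)) {
    oracle <- integrate(function(u) dgamma(u, shape = 1.7 * n, rate = 0.9),
                        0, 12, rel.tol = 1e-12)$value
    expect_equal(v[n + 1], oracle, tolerance = 1e-10)
  }
})

test_that("discrete_lattice convolution matches hand-computed masses", {
  fam <- jump_family("discrete_lattice", support = c(0, 1, 3),
                     probs = c(0.5, 0.3, 0.2))
  v <- coeff_sequence(fam, 4, 3)$values
  # P(S_2 < 4) = 1 - P(S_2 >= 4): S_2 in {4, 6} has prob 2*.3*.2 + .2^2
  expect_equal(v[3], 1 - (2 * 0.3 * 0.2 + 0.04), tolerance = 1e-12)
  # P(S_3 < 4): complement of any sum >= 4
  pmf1 <- c(0.5, 0.3, 0, 0.2)
  pmf3 <- conv_pmf(pmf1, 3)
  expect_equal(v[4], sum(pmf3[1:4]), tolerance = 1e-12)
})

test_that("sequences are nonincreasing and within [0,1] over random draws", {
  set.seed(42)
  for (r in 1:20) {
    fam <- switch(sample(4, 1),
      jump_family("bernoulli", prob = runif(1, 0.05, 0.95)),
      jump_family("poisson", mean = runif(1, 0.2, 4)),
      jump_family("exponential", rate = runif(1, 0.2, 4)),
      jump_family("gamma", shape = runif(1, 0.3, 3),
                  rate = runif(1, 0.3, 3)))
    thr <- runif(1, 0.5, 20)
    v <- coeff_sequence(fam, thr, 40)$values
    expect_true(all(diff(v) <= 1e-15))
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("exponential coefficients are invariant under joint rescaling", {
  for (k in c(0.25, 2, 7.3)) {
    a <- coeff_sequence(jump_family("exponential", rate = 0.71), 14, 30)$values
    b <- coeff_sequence(jump_family("exponential", rate = 0.71 * k),
                        14 / k, 30)$values
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("families are classified into the identifiability taxonomy", {
  expect_equal(classify_family(jump_family("degenerate", value = 1)), "F1")
  expect_equal(classify_family(jump_family("exponential", rate = 0.71)), "F2")
  expect_equal(classify_family(jump_family("gamma", shape = 2, rate = 1)), "F2")
  expect_equal(classify_family(jump_family("poisson", mean = 1.23)), "F3")
  expect_equal(classify_family(jump_family("bernoulli", prob = 0.36)), "F3")
  expect_equal(classify_family(
    jump_family("discrete_lattice", support = c(1, 2), probs = c(.5, .5))),
    "F1")
  expect_equal(classify_family(
    jump_family("discrete_lattice", support = c(0, 2), probs = c(.5, .5))),
    "F3")
})

test_that("ratio diagnostic recovers the known tail limits", {
  # F2: ratio tends to 0
  d <- ratio_limit_diagnostic(
    coeff_sequence(jump_family("exponential", rate = 0.71), 14, 200))
  expect_lt(abs(d$limit), 1e-3)
  # F3: ratio tends to the mass at zero, O(1/n) discrepancy
  d3 <- ratio_limit_diagnostic(
    coeff_sequence(jump_family("poisson", mean = 1.23), 19, 400))
  expect_lt(abs(d3$limit - exp(-1.23)), 5e-2)
  expect_lt(abs(d3$last_ratio - exp(-1.23)), 5e-2)
  # F1: exact zero
  d1 <- ratio_limit_diagnostic(
    coeff_sequence(jump_family("degenerate", value = 1), 17, 30))
  expect_equal(d1$limit, 0)
  expect_equal(d1$n_zero, 17L)
  # too-short sequences are refused
  expect_error(ratio_limit_diagnostic(
    coeff_sequence(jump_family("exponential", rate = 1), 5, 5)),
    "too short")
})

test_that("assumption check routes the reference configurations correctly", {
  ka <- check_assumption(case_a$model$x_family, case_a$model$z_family, 7, 17)
  expect_equal(ka$assumption, "H1")
  expect_equal(ka$model_required, "I")
  expect_equal(ka$n_max, 17L)

  kb <- check_assumption(case_b$model$x_family, case_b$model$z_family, 14, 7)
  expect_equal(kb$assumption, "H2.i")
  expect_equal(kb$model_required, "I")

  kc <- check_assumption(case_c$model$x_family, case_c$model$z_family, 7, 19)
  expect_equal(kc$assumption, "H2.ii")
  expect_equal(kc$model_required, "II")
})

test_that("invalid family parameters are rejected", {
  expect_error(jump_family("bernoulli", prob = 1.2), "\\(0,1\\)")
  expect_error(jump_family("exponential", rate = -1), "positive")
  expect_error(jump_family("degenerate", value = 0), "positive")
  expect_error(jump_family("discrete_lattice", support = 0, probs = 1),
               "mass at 0")
  expect_error(coeff_sequence(jump_family("poisson", mean = 1), -2, 5),
               "positive")
})
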
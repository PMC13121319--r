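test_that("tie probability has the expected closed-form special cases", {
  # both margins cross at the second tick, always together
  m <- fht_model(jump_family("degenerate", value = 1),
                 jump_family("degenerate", value = 1), x = 2, z = 2)
  expect_equal(as.numeric(prob_equal(fht_theta(1), m)), 1)

  # Z crosses at the first tick: tie iff the first X jump crosses too
  m2 <- fht_model(jump_family("bernoulli", prob = 0.36),
                  jump_family("degenerate", value = 1), x = 1, z = 1)
  expect_equal(as.numeric(prob_equal(fht_theta(1.42, alpha = 0.36), m2)),
               0.36, tolerance = 1e-12)

  # case a: only the n = 16 term survives (Z degenerate, z = 17)
  pe <- prob_equal(case_a$theta, case_a$model)
  expect_equal(as.numeric(pe),
               pbinom(6, 16, 0.36) - pbinom(6, 17, 0.36), tolerance = 1e-12)
  expect_equal(attr(pe, "tail_bound"), 0)
})

test_that("tie probability vanishes iff one crossing a.s. precedes the other", {
  m <- fht_model(jump_family("degenerate", value = 1),
                 jump_family("degenerate", value = 1), x = 3, z = 1)
  expect_equal(as.numeric(prob_equal(fht_theta(1), m)), 0)
  p <- simulate_latent(fht_theta(1), m, 500, seed = 5)
  expect_true(all(p$nu_z < p$nu_x))
  expect_true(all(p$c_event < p$t_event))
})

test_that("singular density matches its closed form and integrates to the tie probability", {
  th <- erlang_toy$theta; m <- erlang_toy$model
  u <- c(0.1, 0.5, 1, 3, 10)
  expect_equal(singular_density(u, th, m),
               th$lambda^2 * u * exp(-th$lambda * u), tolerance = 1e-12)
  for (cs in list(case_a, case_b)) {
    q <- integrate(function(u) singular_density(u, cs$theta, cs$model),
                   0, Inf, rel.tol = 1e-10)$value
    expect_equal(q, as.numeric(prob_equal(cs$theta, cs$model)),
                 tolerance = 1e-8)
  }
})

test_that("outcome density reduces to Erlang(2) for the degenerate toy model", {
  th <- erlang_toy$theta; m <- erlang_toy$model
  t <- c(0.2, 1, 2.5, 7)
  expect_equal(outcome_density(t, 1, th, m),
               th$lambda^2 * t * exp(-th$lambda * t), tolerance = 1e-12)
  expect_equal(outcome_log_density(t, 0, th, m), rep(-Inf, length(t)))
  expect_equal(hazard_y(t, th, m), th$lambda^2 * t / (1 + th$lambda * t),
               tolerance = 1e-12)
  expect_equal(marginal_survival(t, th, m, "T"),
               exp(-th$lambda * t) * (1 + th$lambda * t), tolerance = 1e-12)
  expect_equal(marginal_survival(0, th, m, "T"), 1)
})

test_that("truncated evaluator matches a direct finite-sum oracle", {
  # case a terminates by n = 17, so the series is exact
  expect_equal(outcome_density(5, 0, case_a$theta, case_a$model),
               direct_density(5, 0, case_a$theta, case_a$model),
               tolerance = 1e-10)
  expect_equal(outcome_density(2.3, 1, case_a$theta, case_a$model),
               direct_density(2.3, 1, case_a$theta, case_a$model),
               tolerance = 1e-10)
  # moderate lambda*t keeps linear space safe for case b too
  for (d in 0:1)
    expect_equal(outcome_density(3, d, case_b$theta, case_b$model),
                 direct_density(3, d, case_b$theta, case_b$model),
                 tolerance = 1e-10)
})

test_that("Model II branches aggregate to Model I pointwise", {
  for (cs in list(case_a, case_b)) {
    m2 <- fht_model(cs$model$x_family, cs$model$z_family,
                    cs$model$x, cs$model$z, model_type = "II",
                    N = cs$model$N)
    t <- c(0, 0.5, 2, 8, 20)
    f1_event <- outcome_density(t, 1, cs$theta, cs$model)
    expect_equal(outcome_density(t, 1, cs$theta, m2) +
                   outcome_density(t, 2, cs$theta, m2),
                 f1_event, tolerance = 1e-12)
    expect_equal(outcome_density(t, 0, cs$theta, m2),
                 outcome_density(t, 0, cs$theta, cs$model),
                 tolerance = 1e-12)
  }
})

test_that("outcome densities are properly normalized", {
  for (cs in list(case_a, case_b, case_c)) {
    deltas <- if (cs$model$model_type == "I") 0:1 else 0:2
    total <- sum(vapply(deltas, function(d)
      integrate(function(t) outcome_density(t, d, cs$theta, cs$model),
                0, Inf, rel.tol = 1e-9)$value, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-4)
    # closed-form branch masses agree with the quadrature route
    expect_equal(sum(delta_mass(cs$theta, cs$model)), total,
                 tolerance = 1e-6)
  }
})

test_that("hazard is internally consistent and plateaus at lambda under F2 margins", {
  # h = f_Y / S_Y against densities summed over delta
  cs <- case_b
  t <- c(0.5, 1, 2, 5, 10)
  fy <- outcome_density(t, 1, cs$theta, cs$model) +
    outcome_density(t, 0, cs$theta, cs$model)
  expect_equal(hazard_y(t, cs$theta, cs$model),
               fy / survival_y(t, cs$theta, cs$model), tolerance = 1e-8)
  # large-time limit: the plateau lambda is approached, but slowly -- the
  # dominant series index grows like (alpha x * beta z * lambda t)^(1/3),
  # so the gap decays like t^(-2/3)
  gaps <- cs$theta$lambda - hazard_y(c(50, 400), cs$theta, cs$model)
  expect_true(all(gaps > 0))
  expect_lt(gaps[2], gaps[1])
  expect_equal(gaps[2] / gaps[1], 8^(-2/3), tolerance = 0.35)
  expect_true(all(hazard_y(t, cs$theta, cs$model) <= cs$theta$lambda))
})

test_that("off-diagonal joint density is symmetric under margin swap and normalized", {
  cs <- case_b
  swapped <- fht_model(cs$model$z_family, cs$model$x_family,
                       x = cs$model$z, z = cs$model$x, model_type = "I",
                       N = cs$model$N)
  th_sw <- fht_theta(cs$theta$lambda, alpha = cs$theta$beta,
                     beta = cs$theta$alpha)
  pts <- list(c(1, 2), c(0.3, 4), c(6, 2.5))
  for (p in pts) {
    expect_equal(joint_density_ac(p[1], p[2], cs$theta, cs$model),
                 joint_density_ac(p[2], p[1], th_sw, swapped),
                 tolerance = 1e-12)
  }
  expect_error(joint_density_ac(2, 2, cs$theta, cs$model), "diagonal")

  # case a: double integral off the diagonal plus the tie mass is 1
  # (inner integral split at the diagonal, where the ac part is undefined;
  # the box [0, 60]^2 carries all but a negligible sliver of mass since
  # both crossings happen by ~17/1.42 + slack)
  f_outer <- function(u) {
    vapply(u, function(ui) {
      f_inner <- function(v) joint_density_ac(rep(ui, length(v)), v,
                                              case_a$theta, case_a$model)
      integrate(f_inner, 0, ui, rel.tol = 1e-7)$value +
        integrate(f_inner, ui, 60, rel.tol = 1e-7)$value
    }, numeric(1))
  }
  off_diag <- integrate(f_outer, 0, 60, rel.tol = 1e-6)$value
  expect_equal(off_diag + as.numeric(prob_equal(case_a$theta, case_a$model)),
               1, tolerance = 1e-4)
})

test_that("outcome log-density is invariant under joint threshold/rate rescaling", {
  cs <- case_b
  t <- c(0.4, 1.7, 6)
  base <- outcome_log_density(t, c(1, 0, 1), cs$theta, cs$model)
  for (k in c(0.5, 3)) {
    m_k <- fht_model(cs$model$x_family, cs$model$z_family,
                     x = cs$model$x / k, z = cs$model$z / (2 * k),
                     model_type = "I", N = cs$model$N)
    th_k <- fht_theta(cs$theta$lambda, alpha = k * cs$theta$alpha,
                      beta = 2 * k * cs$theta$beta)
    expect_equal(outcome_log_density(t, c(1, 0, 1), th_k, m_k), base,
                 tolerance = 1e-10)
  }
})

test_that("truncation remainder bound behaves as the theory prescribes", {
  # case a: finite sum, no remainder at N >= 17
  ra <- remainder_bound(case_a$theta, case_a$model, lam_max = 2, tau = 20,
                        N = 17)
  expect_identical(ra$bound, 0)
  # nonincreasing in N, all else fixed (case b, N = 20..40)
  bounds <- vapply(seq(20, 40, by = 4), function(N)
    remainder_bound(case_b$theta, case_b$model, lam_max = 2, tau = 20,
                    N = N)$bound, numeric(1))
  expect_true(all(diff(bounds) <= 1e-12))
  # reference evaluation at N=25, j=18: finite and positive, and the
  # per-j entry matches an independent plain-arithmetic computation
  rb <- remainder_bound(case_b$theta, case_b$model, lam_max = 2, tau = 20,
                        N = 25)
  expect_true(is.finite(rb$bound) && rb$bound > 0)
  cx <- coeff_sequence(jump_family("exponential", rate = 0.71), 14, 426)$values
  cz <- coeff_sequence(jump_family("exponential", rate = 2.04), 7, 426)$values
  i <- 1:425
  num1 <- (cx[i] - cx[i + 1]) * cz[i]
  num2 <- (cz[i] - cz[i + 1]) * cx[i + 1]
  j <- 18
  b18 <- max(max(num1[27:425]) / num1[j + 1], max(num2[27:425]) / num2[j + 1])
  expect_equal(rb$per_j$b_j[rb$per_j$j == 18], b18, tolerance = 1e-10)
  lmt <- 40
  tail_exact <- exp(lmt) * ppois(25, lmt, lower.tail = FALSE)
  expect_equal(rb$per_j$bound_exact[rb$per_j$j == 18],
               factorial(18) / lmt^18 * b18 * tail_exact, tolerance = 1e-8)
  # the loose variant dominates the exact-tail variant
  expect_true(all(rb$per_j$bound_loose >= rb$per_j$bound_exact))
})

test_that("truncation order selection prefers exact finite sums", {
  expect_identical(choose_truncation(case_a$theta, case_a$model,
                                     lam_max = 2, tau = 20), 17L)
  Nb <- choose_truncation(case_b$theta, case_b$model, lam_max = 2, tau = 20)
  expect_true(Nb >= 25)  # no informative bound below tolerance at small N
})
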
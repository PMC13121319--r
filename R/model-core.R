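#' Parameter vector of the hitting-time model
#'
#' Bundles the Poisson clock intensity with the jump-law parameters of the
#' two margins. `alpha` and `beta` hold the estimated parameters of the X
#' and Z jump families in the order reported by the corresponding family
#' (empty for fixed families such as `degenerate`).
#'
#' @param lambda positive intensity of the shared Poisson clock (events per
#'   unit time).
#' @param alpha,beta numeric vectors of jump-law parameters (possibly empty).
#' @return object of class `cpfht_theta`.
#' @export
fht_theta <- function(lambda, alpha = numeric(0), beta = numeric(0)) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("'lambda' must be a single positive number", call. = FALSE)
  structure(list(lambda = lambda, alpha = as.numeric(alpha),
                 beta = as.numeric(beta)), class = "cpfht_theta")
}

#' @export
print.cpfht_theta <- function(x, ...) {
  cat(sprintf("theta: lambda = %.6g", x$lambda))
  if (length(x$alpha)) cat(", alpha = (", paste(signif(x$alpha, 6),
                                                collapse = ", "), ")")
  if (length(x$beta)) cat(", beta = (", paste(signif(x$beta, 6),
                                              collapse = ", "), ")")
  cat("\n")
  invisible(x)
}

#' Model configuration: jump families, thresholds, observation scheme
#'
#' Describes one instance of the dependent-censoring hitting-time model.
#' The event time T is the first time the X-margin compound Poisson process
#' reaches `x`; the censoring time C is the first time the Z-margin reaches
#' `z`; both margins jump at the ticks of one shared Poisson clock. Under
#' Model I the observation is `(min(T, C), 1{T <= C})`; under Model II the
#' indicator distinguishes `T > C` (0), `T < C` (1) and the tie `T = C` (2).
#'
#' The series order `N` controls truncation of all Poisson-mixture series.
#' When either coefficient sequence hits an exact zero the series is a
#' finite sum and `N` defaults to that order (the evaluation is then exact);
#' otherwise `N` must be supplied or chosen via [choose_truncation()].
#'
#' @param x_family,z_family [jump_family()] objects (their parameters act as
#'   defaults; model functions take the current values from a [fht_theta()]).
#' @param x,z positive thresholds.
#' @param model_type `"I"` or `"II"`.
#' @param N series truncation order (`NULL` to auto-detect a finite sum).
#' @param bounds optional named list of `c(lower, upper)` boxes for
#'   `lambda`, `alpha`, `beta` used by the fitter; defaults are wide.
#' @return object of class `cpfht_model`.
#' @examples
#' fht_model(jump_family("bernoulli", prob = 0.36),
#'           jump_family("degenerate", value = 1), x = 7, z = 17,
#'           model_type = "I")
#' @export
fht_model <- function(x_family, z_family, x, z, model_type = c("I", "II"),
                      N = NULL, bounds = NULL) {
  model_type <- match.arg(model_type)
  stopifnot(inherits(x_family, "cpfht_family"),
            inherits(z_family, "cpfht_family"))
  if (x <= 0 || z <= 0) stop("thresholds must be positive", call. = FALSE)
  chk <- check_assumption(x_family, z_family, x, z)
  if (identical(chk$assumption, "H2.ii") && model_type == "I")
    warning("both jump laws are discrete with an atom at 0 (H2.ii): ",
            "the intensity is not identifiable under Model I; use Model II",
            call. = FALSE)
  if (is.null(N)) {
    N <- finite_sum_order(x_family, z_family, x, z)
    if (is.na(N))
      stop("no finite-sum order available; supply 'N' ",
           "(see choose_truncation())", call. = FALSE)
  }
  m <- structure(list(x_family = x_family, z_family = z_family,
                      x = x, z = z, model_type = model_type,
                      N = as.integer(N), assumption = chk),
                 class = "cpfht_model")
  m$bounds <- default_bounds(m, bounds)
  m
}

#' @export
print.cpfht_model <- function(x, ...) {
  cat(sprintf("hitting-time model (Model %s), thresholds x = %.6g, z = %.6g, N = %d\n",
              x$model_type, x$x, x$z, x$N))
  cat("X margin: "); print(x$x_family)
  cat("Z margin: "); print(x$z_family)
  cat(sprintf("identifiability: %s\n", x$assumption$assumption))
  invisible(x)
}

## order at which every series branch terminates: once either coefficient
## sequence hits an exact zero all branch terms vanish (only F1 laws do)
finite_sum_order <- function(x_family, z_family, x, z) {
  cap <- function(fam, thr) {
    if (classify_family(fam) == "F1")
      as.integer(ceiling(thr / essential_min(fam)))
    else NA_integer_
  }
  caps <- c(cap(x_family, x), cap(z_family, z))
  if (all(is.na(caps))) NA_integer_ else min(caps, na.rm = TRUE)
}

## wide default parameter boxes (H3 compactness); user entries override
default_bounds <- function(model, bounds = NULL) {
  box1 <- function(fam) {
    switch(fam$family,
      bernoulli = , binomial = matrix(c(0.001, 0.999), 1),
      poisson = , exponential = matrix(c(0.01, 50), 1),
      gamma = matrix(rep(c(0.01, 50), each = 2), 2),
      matrix(numeric(0), 0, 2))
  }
  b <- list(lambda = c(0.01, 50),
            alpha = box1(model$x_family),
            beta = box1(model$z_family))
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  b
}

## families with the parameter values of theta substituted in
theta_families <- function(theta, model) {
  list(xf = family_set(model$x_family, theta$alpha),
       zf = family_set(model$z_family, theta$beta))
}

## coefficient cache: the likelihood re-evaluates c-sequences at every
## optimizer step; key on (family tag, params, threshold, N)
.coeff_cache <- new.env(parent = emptyenv())

cached_coeffs <- function(family, threshold, N) {
  key <- paste(family$family,
               paste(formatC(unlist(family[setdiff(names(family),
                                                   c("family", "zero_mass"))]),
                             digits = 17, format = "g"), collapse = ","),
               formatC(threshold, digits = 17, format = "g"), N, sep = "|")
  hit <- .coeff_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- coeff_sequence(family, threshold, N)$values
  if (length(ls(.coeff_cache)) > 4096) rm(list = ls(.coeff_cache),
                                          envir = .coeff_cache)
  assign(key, val, envir = .coeff_cache)
  val
}

## c_0..c_{N+1} for both margins at theta
model_coeffs <- function(theta, model, N = model$N) {
  tf <- theta_families(theta, model)
  list(cx = cached_coeffs(tf$xf, model$x, N + 1L),
       cz = cached_coeffs(tf$zf, model$z, N + 1L))
}

## log c_0..c_{N+1}, uncached (used by descriptive evaluators at large t
## where linear-space coefficients underflow)
model_coeffs_log <- function(theta, model, N = model$N) {
  tf <- theta_families(theta, model)
  list(lcx = coeff_sequence_log(tf$xf, model$x, N + 1L),
       lcz = coeff_sequence_log(tf$zf, model$z, N + 1L))
}

## series coefficients a_n, n = 0..N, of the requested outcome branch
branch_coefs <- function(delta, theta, model, cc = model_coeffs(theta, model)) {
  N <- model$N
  i <- seq_len(N + 1L)                       # n = 0..N
  dx <- cc$cx[i] - cc$cx[i + 1L]
  dz <- cc$cz[i] - cc$cz[i + 1L]
  if (model$model_type == "I") {
    switch(as.character(delta),
      "1" = dx * cc$cz[i],
      "0" = dz * cc$cx[i + 1L],
      stop("Model I admits delta in {0, 1}", call. = FALSE))
  } else {
    switch(as.character(delta),
      "0" = dz * cc$cx[i + 1L],
      "1" = dx * cc$cz[i + 1L],
      "2" = dx * dz,
      stop("Model II admits delta in {0, 1, 2}", call. = FALSE))
  }
}

## log-sum-exp over columns of log(a_n) + n log(lambda t) - lgamma(n+1),
## for a vector of times; zero coefficients are skipped, t = 0 handled
## through the n = 0 term only
poisson_mixture_log <- function(t, a, lambda) {
  poisson_mixture_log_la(t, log(a), lambda)
}

## same, from log coefficients (safe far below double underflow)
poisson_mixture_log_la <- function(t, la_full, lambda) {
  keep <- which(is.finite(la_full))
  if (!length(keep)) return(rep(-Inf, length(t)))
  la <- la_full[keep]; nn <- keep - 1L
  lt <- ifelse(t > 0, log(lambda * t), -Inf)
  M <- outer(lt, nn)                         # n * log(lambda t)
  M[is.nan(M)] <- 0                          # t = 0 with n = 0
  M <- sweep(M, 2L, la - lgamma(nn + 1L), `+`)
  mx <- apply(M, 1L, max)
  out <- mx + log(rowSums(exp(M - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

#' Log-density of the censored outcome (Y, Delta)
#'
#' Evaluates the log of the outcome density, a Poisson mixture of products
#' and differences of the two coefficient sequences, truncated at the model
#' order `N`. The accumulation is done in log space (log-sum-exp) so large
#' `lambda * t` does not overflow; zero coefficients are skipped. Branches
#' with zero mass return `-Inf`.
#'
#' @param t nonnegative times (vectorized).
#' @param delta outcome codes; `{0,1}` under Model I, `{0,1,2}` under
#'   Model II (recycled against `t`).
#' @param theta a [fht_theta()].
#' @param model a [fht_model()].
#' @return numeric vector of log-density values.
#' @export
outcome_log_density <- function(t, delta, theta, model) {
  if (any(t < 0)) stop("'t' must be nonnegative", call. = FALSE)
  n <- max(length(t), length(delta))
  t <- rep_len(t, n); delta <- rep_len(delta, n)
  cc <- model_coeffs(theta, model)
  out <- numeric(n)
  for (d in unique(delta)) {
    a <- branch_coefs(d, theta, model, cc)
    sel <- delta == d
    out[sel] <- log(theta$lambda) - theta$lambda * t[sel] +
      poisson_mixture_log(t[sel], a, theta$lambda)
  }
  out
}

#' @rdname outcome_log_density
#' @export
outcome_density <- function(t, delta, theta, model)
  exp(outcome_log_density(t, delta, theta, model))

#' Probability that the two hitting times coincide
#'
#' The shared clock gives the pair (T, C) an atom on the diagonal: both
#' processes can complete their crossings at the same tick. The tie
#' probability is the sum over n of the products of coefficient-sequence
#' differences; it does not involve the intensity. The series is truncated
#' at the model order (exact when either sequence hits zero at or before
#' `N`); the attribute `"tail_bound"` bounds the omitted mass.
#'
#' @param theta a [fht_theta()].
#' @param model a [fht_model()].
#' @param tol flag the result (attribute `"flagged"`) when the tail bound
#'   exceeds this tolerance.
#' @return tie probability in \[0, 1\] with attributes `"tail_bound"` and
#'   `"flagged"`.
#' @export
prob_equal <- function(theta, model, tol = 1e-6) {
  cc <- model_coeffs(theta, model)
  i <- seq_len(model$N + 1L)
  dx <- cc$cx[i] - cc$cx[i + 1L]
  dz <- cc$cz[i] - cc$cz[i + 1L]
  p <- sum(dx * dz)
  tail <- min(cc$cx[model$N + 2L], cc$cz[model$N + 2L])
  structure(min(max(p, 0), 1), tail_bound = tail, flagged = tail > tol)
}

#' Density of the diagonal (tie) component of (T, C)
#'
#' The singular part of the joint law of the event and censoring times
#' lives on the diagonal; its density integrates to [prob_equal()].
#'
#' @param u nonnegative times (vectorized).
#' @inheritParams prob_equal
#' @return density values along the diagonal.
#' @export
singular_density <- function(u, theta, model) {
  if (any(u < 0)) stop("'u' must be nonnegative", call. = FALSE)
  cc <- model_coeffs(theta, model)
  i <- seq_len(model$N + 1L)
  a <- (cc$cx[i] - cc$cx[i + 1L]) * (cc$cz[i] - cc$cz[i + 1L])
  exp(log(theta$lambda) - theta$lambda * u +
        poisson_mixture_log(u, a, theta$lambda))
}

## off-diagonal double series for s < t: margin A crosses at s (inner index),
## margin B at t (outer index); dA, dB are coefficient differences
joint_ac_core <- function(s, t, dA, dB, lambda, N) {
  terms <- -Inf
  ls <- if (s > 0) log(lambda * s) else -Inf
  ld <- log(lambda * (t - s))
  for (n in seq_len(N)) {
    if (dB[n + 1L] <= 0) next                # dB at outer index n
    j <- seq_len(n)
    keep <- dA[j] > 0                        # dA at j - 1
    if (!any(keep)) next
    j <- j[keep]
    lt <- log(dA[j]) + log(dB[n + 1L]) + 2 * log(lambda) - lambda * t +
      (n - j) * ld - lgamma(n - j + 1) +
      ifelse(j == 1L, 0, (j - 1L) * ls) - lgamma(j)
    terms <- c(terms, lt)
  }
  m <- max(terms)
  if (!is.finite(m)) return(0)
  exp(m + log(sum(exp(terms - m))))
}

#' Absolutely continuous part of the joint density of (T, C)
#'
#' Evaluates the off-diagonal density of the pair of hitting times,
#' truncated at the model order, with log-space accumulation. The diagonal
#' `u == v` is refused: the density there is the singular component
#' ([singular_density()]), not a value of the absolutely continuous part.
#'
#' @param u,v nonnegative times with `u != v` (vectorized in parallel).
#' @inheritParams prob_equal
#' @return density values.
#' @export
joint_density_ac <- function(u, v, theta, model) {
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  if (any(u < 0 | v < 0)) stop("times must be nonnegative", call. = FALSE)
  if (any(u == v))
    stop("u == v: the absolutely continuous density is not defined on the ",
         "diagonal (see singular_density())", call. = FALSE)
  # the outer index counts the later margin's jumps, whose Poisson weight
  # is centered at lambda * max(u, v): extend the order accordingly
  Nev <- eval_order(theta$lambda, max(u, v), model$N)
  cc <- model_coeffs(theta, model, N = Nev)
  i <- seq_len(Nev + 1L)
  dx <- cc$cx[i] - cc$cx[i + 1L]
  dz <- cc$cz[i] - cc$cz[i + 1L]
  vapply(seq_len(n), function(k) {
    if (u[k] < v[k]) joint_ac_core(u[k], v[k], dx, dz, theta$lambda, Nev)
    else joint_ac_core(v[k], u[k], dz, dx, theta$lambda, Nev)
  }, numeric(1))
}

## series order adequate for descriptive evaluation at times up to tmax:
## beyond qpois(1 - 1e-13, lambda * tmax) the Poisson weights are negligible.
## The likelihood keeps the frozen model order; hazard/survival evaluators
## extend it so their large-t limits are honest.
eval_order <- function(lambda, tmax, N_min) {
  max(N_min, stats::qpois(1e-13, lambda * max(tmax, 0), lower.tail = FALSE) + 5L)
}

#' Hazard function of the observed time Y
#'
#' The hazard of `Y = min(T, C)` is proportional to the clock intensity:
#' `h(t) = lambda * (1 - g(t))` where `g` is a ratio of two Poisson-weighted
#' series in the products of the coefficient sequences. As `t` grows, `g`
#' tends to the limit of the coefficient-product ratio, so the hazard
#' plateau identifies `lambda` whenever that limit is 0 (F1 or F2 jump
#' laws on at least one margin).
#'
#' @param t positive times (vectorized).
#' @inheritParams prob_equal
#' @return hazard values in \[0, lambda\].
#' @export
hazard_y <- function(t, theta, model) {
  if (any(t <= 0)) stop("'t' must be positive", call. = FALSE)
  Nev <- eval_order(theta$lambda, max(t), model$N)
  cc <- model_coeffs_log(theta, model, N = Nev)
  i <- seq_len(Nev + 1L)
  lnum <- poisson_mixture_log_la(t, cc$lcx[i + 1L] + cc$lcz[i + 1L],
                                 theta$lambda)
  lden <- poisson_mixture_log_la(t, cc$lcx[i] + cc$lcz[i], theta$lambda)
  if (any(!is.finite(lden)))
    stop("survival underflow: denominator series is zero", call. = FALSE)
  g <- exp(lnum - lden)
  theta$lambda * (1 - pmin(g, 1))
}

#' Marginal survival of the event or censoring time
#'
#' `S_T(t) = e^{-lambda t} sum_n c_{n,X} (lambda t)^n / n!` (and the same
#' with the Z coefficients for C): the process has not crossed by time `t`
#' iff the cumulative jumps after `N_t` ticks are still below the threshold.
#'
#' @param t nonnegative times (vectorized).
#' @param margin `"T"` (event) or `"C"` (censoring).
#' @inheritParams prob_equal
#' @return survival probabilities.
#' @export
marginal_survival <- function(t, theta, model, margin = c("T", "C")) {
  margin <- match.arg(margin)
  if (any(t < 0)) stop("'t' must be nonnegative", call. = FALSE)
  Nev <- eval_order(theta$lambda, max(t), model$N)
  cc <- model_coeffs_log(theta, model, N = Nev)
  cn <- if (margin == "T") cc$lcx else cc$lcz
  exp(-theta$lambda * t + poisson_mixture_log_la(t, cn, theta$lambda))
}

#' Survival function of the observed time Y
#'
#' `S_Y(t) = e^{-lambda t} sum_n c_{n,X} c_{n,Z} (lambda t)^n / n!`:
#' neither process has crossed after `N_t` ticks.
#'
#' @param t nonnegative times (vectorized).
#' @inheritParams prob_equal
#' @return survival probabilities of `Y = min(T, C)`.
#' @export
survival_y <- function(t, theta, model) {
  if (any(t < 0)) stop("'t' must be nonnegative", call. = FALSE)
  Nev <- eval_order(theta$lambda, max(t), model$N)
  cc <- model_coeffs_log(theta, model, N = Nev)
  i <- seq_len(Nev + 1L)
  exp(-theta$lambda * t +
        poisson_mixture_log_la(t, cc$lcx[i] + cc$lcz[i], theta$lambda))
}

#' Total mass of each outcome branch
#'
#' Integrating each branch of the outcome density over time leaves the sum
#' of its series coefficients, so the probability of each censoring code
#' has a closed form. Under Model II the three masses sum to 1 (up to
#' series truncation) and the `delta = 2` mass equals [prob_equal()].
#'
#' @inheritParams prob_equal
#' @return named vector of branch probabilities.
#' @export
delta_mass <- function(theta, model) {
  cc <- model_coeffs(theta, model)
  deltas <- if (model$model_type == "I") 0:1 else 0:2
  out <- vapply(deltas, function(d)
    sum(branch_coefs(d, theta, model, cc)), numeric(1))
  stats::setNames(out, as.character(deltas))
}

#' Uniform bound on the series-truncation error of the log-density
#'
#' Truncating the outcome-density series at order `N` perturbs the
#' log-density by a remainder `r_N(t, delta) >= 0`. For any `lambda_max`
#' bounding the intensity and any horizon `tau`, the remainder is bounded
#' uniformly on `[0, tau]` by
#' `min_j  j! / (lambda_max tau)^j * b_j * TAIL`, where `b_j` compares the
#' supremum of the post-`N` series coefficients to the coefficient at `j`,
#' and `TAIL` is either the exact tail sum of `(lambda_max tau)^n / n!`
#' or the cruder `exp(lambda_max tau)`. Both variants are returned. The
#' supremum over `n > N` is evaluated on a finite window with a
#' verified-decrease stopping rule.
#'
#' @param theta a [fht_theta()] at which the coefficient sequences are
#'   evaluated (typically the truth or a representative interior value).
#' @param model a [fht_model()].
#' @param lam_max upper bound on the intensities considered (`>= theta$lambda`).
#' @param tau positive time horizon.
#' @param N truncation order (defaults to the model's).
#' @param window number of post-`N` coefficients scanned for the supremum.
#' @return object of class `cpfht_remainder`: data frame `per_j` with the
#'   per-index bounds, the minimizing index `j_star`, `bound` (exact-tail
#'   variant) and `bound_loose` (`exp(lam_max tau)` variant).
#' @export
remainder_bound <- function(theta, model, lam_max, tau, N = model$N,
                            window = 400L) {
  if (lam_max < theta$lambda)
    stop("'lam_max' must dominate theta$lambda", call. = FALSE)
  if (tau <= 0 || N < 1) stop("need tau > 0 and N >= 1", call. = FALSE)
  cc <- model_coeffs(theta, model, N = N + window)
  i <- seq_len(N + window)                   # n = 0..N+window-1
  dx <- cc$cx[i] - cc$cx[i + 1L]
  dz <- cc$cz[i] - cc$cz[i + 1L]
  num1 <- dx * cc$cz[i]                      # uncensored-branch coefficients
  num2 <- dz * cc$cx[i + 1L]                 # censored-branch coefficients
  post <- (N + 2L):(N + window)              # indices with n > N
  sup1 <- max(num1[post]); sup2 <- max(num2[post])
  ## stopping rule: the scanned window must end on a decreasing stretch
  dec_ok <- function(v, s) {
    if (s == 0) return(TRUE)
    k <- which.max(v[post])
    k < length(post) && all(diff(v[post][seq(max(k, length(post) - 20L),
                                             length(post))]) <= 1e-15)
  }
  if (!dec_ok(num1, sup1) || !dec_ok(num2, sup2))
    warning("post-N coefficients not verifiably decreasing within the ",
            "window; enlarge 'window'", call. = FALSE)
  j <- 0:N
  den1 <- num1[j + 1L]; den2 <- num2[j + 1L]
  rat <- function(s, d) ifelse(d > 0, s / d, ifelse(s > 0, Inf, 0))
  bj <- pmax(rat(sup1, den1), rat(sup2, den2))
  lmt <- lam_max * tau
  log_tail <- lmt + stats::ppois(N, lmt, lower.tail = FALSE, log.p = TRUE)
  lead <- lgamma(j + 1) - j * log(lmt)
  bound_exact <- ifelse(bj == 0, 0, exp(lead + log(bj) + log_tail))
  bound_loose <- ifelse(bj == 0, 0, exp(lead + log(bj) + lmt))
  j_star <- j[which.min(bound_exact)]
  structure(list(per_j = data.frame(j = j, b_j = bj,
                                    bound_exact = bound_exact,
                                    bound_loose = bound_loose),
                 j_star = j_star,
                 bound = min(bound_exact),
                 bound_loose = min(bound_loose),
                 N = N, lam_max = lam_max, tau = tau),
            class = "cpfht_remainder")
}

#' @export
print.cpfht_remainder <- function(x, ...) {
  cat(sprintf("truncation remainder bound, N = %d, lambda_max = %.4g, tau = %.4g\n",
              x$N, x$lam_max, x$tau))
  cat(sprintf("  exact-tail variant: %.6g (at j = %d)\n", x$bound, x$j_star))
  cat(sprintf("  exp(lambda_max tau) variant: %.6g\n", x$bound_loose))
  invisible(x)
}

#' Choose a series truncation order
#'
#' Returns the exact finite-sum order when either coefficient sequence hits
#' zero (the series then terminates and no truncation error is incurred).
#' Otherwise scans orders upward until the [remainder_bound()] falls below
#' `tol`; if the bound never becomes informative, falls back to
#' `ceiling(lam_max * tau + 10 * sqrt(lam_max * tau))`, past which the
#' Poisson weights themselves are negligible on `[0, tau]`.
#'
#' @inheritParams remainder_bound
#' @param tol target bound on the log-density truncation error.
#' @param N_grid candidate orders to scan.
#' @return integer truncation order.
#' @export
choose_truncation <- function(theta, model, lam_max, tau, tol = 1e-3,
                              N_grid = c(10, 15, 20, 25, 30, 40, 60, 80)) {
  fso <- finite_sum_order(model$x_family, model$z_family, model$x, model$z)
  if (!is.na(fso)) return(fso)
  for (N in N_grid) {
    b <- suppressWarnings(remainder_bound(theta, model, lam_max, tau, N = N))
    if (is.finite(b$bound) && b$bound <= tol) return(as.integer(N))
  }
  as.integer(ceiling(lam_max * tau + 10 * sqrt(lam_max * tau)))
}
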
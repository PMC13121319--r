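#' Built-in study configurations
#'
#' Three reference configurations spanning the identifiability regimes,
#' used throughout the package's simulation experiments:
#' \describe{
#'   \item{a}{`lambda = 1.42`, X Bernoulli(0.36), Z degenerate at 1,
#'     thresholds `(x, z) = (7, 17)`; one margin is F1 (condition H1), the
#'     series is a finite sum and Model I suffices.}
#'   \item{b}{`lambda = 1.42`, X Exponential(0.71), Z Exponential(2.04),
#'     `(x, z) = (14, 7)`; F2 margins (H2.i), series order `N = 25`,
#'     Model I.}
#'   \item{c}{`lambda = 1.42`, X Bernoulli(0.36), Z Poisson(1.23),
#'     `(x, z) = (7, 19)`; both margins F3 (H2.ii), series order `N = 28`,
#'     Model II required.}
#' }
#'
#' @param case `"a"`, `"b"` or `"c"`.
#' @return list with elements `theta` ([fht_theta()]), `model`
#'   ([fht_model()]) and `label`.
#' @examples
#' study_case("b")$model
#' @export
study_case <- function(case = c("a", "b", "c")) {
  case <- match.arg(case)
  switch(case,
    a = list(theta = fht_theta(1.42, alpha = 0.36),
             model = fht_model(jump_family("bernoulli", prob = 0.36),
                               jump_family("degenerate", value = 1),
                               x = 7, z = 17, model_type = "I"),
             label = "a"),
    b = list(theta = fht_theta(1.42, alpha = 0.71, beta = 2.04),
             model = fht_model(jump_family("exponential", rate = 0.71),
                               jump_family("exponential", rate = 2.04),
                               x = 14, z = 7, model_type = "I", N = 25L),
             label = "b"),
    c = list(theta = fht_theta(1.42, alpha = 0.36, beta = 1.23),
             model = fht_model(jump_family("bernoulli", prob = 0.36),
                               jump_family("poisson", mean = 1.23),
                               x = 7, z = 19, model_type = "II", N = 28L),
             label = "c"))
}

#' Chi-square acceptance rates from a set of fitted parameter vectors
#'
#' For replicate estimates `theta_hat_k` of a true `theta0`, computes the
#' quadratic statistics `s_k = n (theta_hat_k - theta0)' A_k
#' (theta_hat_k - theta0)` and the fraction falling below chi-square
#' quantiles with `d` degrees of freedom. `A_k` is either the
#' score-outer-product matrix at the k-th estimate (`B_n`) or the inverse
#' of the empirical covariance `D` of the `sqrt(n)`-scaled estimates
#' (common to all replicates). Positive definiteness is checked by a
#' Cholesky factorization; replicates whose matrix fails are excluded and
#' counted.
#'
#' @param thetas `M x d` matrix of estimates (rows).
#' @param theta0 length-`d` true parameter vector.
#' @param n per-replicate sample size.
#' @param A_list list of `M` matrices (for the `B_n` choice) or a single
#'   matrix applied to all replicates (for `D^{-1}`).
#' @param levels nominal levels.
#' @return list with `rates` (named by level), `stats`, and `n_excluded`.
#' @export
coverage_rates <- function(thetas, theta0, n, A_list,
                           levels = c(0.90, 0.95, 0.99)) {
  M <- nrow(thetas)
  d <- length(theta0)
  if (is.matrix(A_list)) A_list <- rep(list(A_list), M)
  s <- rep(NA_real_, M)
  for (k in seq_len(M)) {
    A <- A_list[[k]]
    ok <- !is.null(A) && all(is.finite(A)) &&
      !inherits(try(chol(A), silent = TRUE), "try-error")
    if (!ok) next
    dk <- thetas[k, ] - theta0
    s[k] <- n * drop(t(dk) %*% A %*% dk)
  }
  used <- is.finite(s)
  q <- stats::qchisq(levels, df = d)
  rates <- vapply(q, function(qq) mean(s[used] <= qq), numeric(1))
  names(rates) <- sprintf("%g%%", 100 * levels)
  list(rates = rates, stats = s, n_excluded = sum(!used))
}

#' Coverage experiment for the asymptotic chi-square pivot
#'
#' Simulates `M` independent samples of size `n` from the model at
#' `theta_true`, fits each by maximum likelihood, and reports the fraction
#' of the quadratic statistics `||sqrt(n A)(theta_hat_k - theta0)||^2`
#' below chi-square quantiles with `1 + d1 + d2` degrees of freedom, where
#' `A` is the score matrix `B_n(theta_hat_k)` and/or the inverse of the
#' empirical covariance `D` of the scaled estimates (`D` is centered at
#' the empirical mean; centering at the truth is available via
#' `center = "truth"`). Replicate seeds are `base_seed + k`. Failed fits
#' and non-positive-definite matrices are excluded with a reported count.
#'
#' @param theta_true a [fht_theta()].
#' @param model a [fht_model()].
#' @param n sample size per replicate.
#' @param M number of replicates.
#' @param base_seed integer; replicate `k` uses seed `base_seed + k`.
#' @param levels nominal chi-square levels.
#' @param matrices subset of `c("Bn", "Dinv")`.
#' @param center centering of the empirical covariance `D`.
#' @param starts optimizer starts per fit.
#' @return object of class `cpfht_coverage`: data frame `rates`
#'   (`matrix`, `level`, `rate`), matrix `thetas`, `D`, counts of excluded
#'   replicates, and the seeds manifest.
#' @export
coverage_experiment <- function(theta_true, model, n, M, base_seed,
                                levels = c(0.90, 0.95, 0.99),
                                matrices = c("Bn", "Dinv"),
                                center = c("mean", "truth"),
                                starts = 2L) {
  matrices <- match.arg(matrices, several.ok = TRUE)
  center <- match.arg(center)
  theta0 <- theta_pack(theta_true, model)
  d <- length(theta0)
  seeds <- base_seed + seq_len(M)
  thetas <- matrix(NA_real_, M, d, dimnames = list(NULL, names(theta0)))
  B_list <- vector("list", M)
  n_fail <- 0L
  for (k in seq_len(M)) {
    fit <- tryCatch({
      s <- simulate_sample(theta_true, model, n, seed = seeds[k])
      fit_mle(s, model, starts = starts, seed = seeds[k] + 10000L)
    }, error = function(e) NULL)
    if (is.null(fit) || !fit$converged || is.null(fit$B)) {
      n_fail <- n_fail + 1L
      next
    }
    thetas[k, ] <- fit$par
    B_list[[k]] <- fit$B
  }
  ok <- stats::complete.cases(thetas)
  rates <- list()
  excluded <- c(fit = n_fail)
  Dm <- NULL
  if ("Bn" %in% matrices) {
    cr <- coverage_rates(thetas[ok, , drop = FALSE], theta0, n, B_list[ok],
                         levels)
    rates$Bn <- cr$rates
    excluded["Bn_nonpd"] <- cr$n_excluded
  }
  if ("Dinv" %in% matrices) {
    Zs <- sqrt(n) * thetas[ok, , drop = FALSE]
    Dm <- if (center == "mean") stats::cov(Zs)
          else crossprod(sweep(Zs, 2L, sqrt(n) * theta0)) / (sum(ok) - 1L)
    cr <- coverage_rates(thetas[ok, , drop = FALSE], theta0, n, solve(Dm),
                         levels)
    rates$Dinv <- cr$rates
    excluded["Dinv_nonpd"] <- cr$n_excluded
  }
  tab <- do.call(rbind, lapply(names(rates), function(m)
    data.frame(matrix = m, level = levels, rate = unname(rates[[m]]))))
  structure(list(rates = tab, thetas = thetas, D = Dm, n = n, M = M,
                 excluded = excluded, seeds = seeds, levels = levels),
            class = "cpfht_coverage")
}

#' @export
print.cpfht_coverage <- function(x, ...) {
  cat(sprintf("coverage experiment: n = %d, M = %d (%d fit failures)\n",
              x$n, x$M, x$excluded["fit"]))
  print(x$rates, row.names = FALSE)
  invisible(x)
}

#' Bias and mean-squared-error curves of the estimated marginal CDF
#'
#' Simulates `M` replicates, fits each, and evaluates the estimated
#' marginal distribution function of T (or C) on a time grid. Reports, per
#' grid point, the mean squared error (`nx`) and the mean absolute error
#' (`bias`) of the `M` estimated CDFs against the true one.
#'
#' @inheritParams coverage_experiment
#' @param grid time grid.
#' @param margin `"T"` or `"C"`.
#' @return data frame with columns `t`, `nx`, `bias`, plus attributes
#'   `n_fail` and `thetas`.
#' @export
bias_mse_curves <- function(theta_true, model, n, M, base_seed, grid,
                            margin = c("T", "C"), starts = 2L) {
  margin <- match.arg(margin)
  F_true <- 1 - marginal_survival(grid, theta_true, model, margin)
  seeds <- base_seed + seq_len(M)
  Fhat <- matrix(NA_real_, M, length(grid))
  thetas <- list()
  n_fail <- 0L
  for (k in seq_len(M)) {
    fit <- tryCatch({
      s <- simulate_sample(theta_true, model, n, seed = seeds[k])
      fit_mle(s, model, starts = starts, seed = seeds[k] + 10000L,
              compute_se = FALSE)
    }, error = function(e) NULL)
    if (is.null(fit)) { n_fail <- n_fail + 1L; next }
    thetas[[k]] <- fit$par
    Fhat[k, ] <- 1 - marginal_survival(grid, fit$theta_hat, model, margin)
  }
  ok <- stats::complete.cases(Fhat)
  dev <- sweep(Fhat[ok, , drop = FALSE], 2L, F_true)
  out <- data.frame(t = grid,
                    nx = colMeans(dev^2),
                    bias = colMeans(abs(dev)))
  attr(out, "n_fail") <- n_fail
  attr(out, "thetas") <- do.call(rbind, thetas)
  out
}

#' Two distinct Poisson-mixture parameterizations with identical densities
#'
#' Demonstrates why the outcome density alone cannot identify the
#' intensity without structural conditions on the coefficient sequences:
#' the mixtures `exp(-l t) sum_n r^n (l t)^n / n!` with `(l, r) = (1, 1/2)`
#' and `(2/3, 1/4)` are both equal to `exp(-t/2)` for every `t`. The
#' function evaluates both series numerically on a grid (truncated to a
#' machine-negligible tail) and returns the maximum absolute gap.
#'
#' @param grid positive evaluation times.
#' @param lambda1,ratio1 first intensity and geometric coefficient ratio.
#' @param lambda2,ratio2 second pair.
#' @param N series truncation (default covers `lambda * t` up to ~40).
#' @return list with `gap` (max absolute difference), and the two
#'   evaluated curves `f1`, `f2`.
#' @export
mixture_pair_gap <- function(grid = seq(0.1, 20, by = 0.1),
                             lambda1 = 1, ratio1 = 1/2,
                             lambda2 = 2/3, ratio2 = 1/4, N = 400L) {
  stopifnot(all(grid > 0))
  mix <- function(lam, r) {
    a <- r^(0:N)
    exp(-lam * grid + poisson_mixture_log(grid, a, lam))
  }
  f1 <- mix(lambda1, ratio1)
  f2 <- mix(lambda2, ratio2)
  list(gap = max(abs(f1 - f2)), f1 = f1, f2 = f2, grid = grid)
}

#' Matched binomial parameter giving an indistinguishable coefficient
#'
#' With one margin degenerate and binomial jump laws of different sizes on
#' the other, a single equation can link the two success probabilities:
#' `p^9 = P(Binomial(12, p') >= 9)`. For each `p` in (0, 1) there is a
#' unique `p'` solving it, producing two distinct jump laws whose single
#' relevant cumulative-jump coefficient coincides -- a designed
#' non-identifiable configuration. The root is found by bracketing.
#'
#' @param p probability in (0, 1).
#' @param tol root-finding tolerance.
#' @return the matching probability `p'` in (0, 1).
#' @export
matched_binomial_parameter <- function(p, tol = 1e-12) {
  stopifnot(p > 0, p < 1)
  f <- function(q) stats::pbinom(8, 12, q, lower.tail = FALSE) - p^9
  stats::uniroot(f, interval = c(1e-14, 1 - 1e-14), tol = tol)$root
}

#' Mardia's multivariate normality test
#'
#' Omnibus test based on multivariate skewness and kurtosis. The skewness
#' statistic `n b1 / 6` is referred to a chi-square with
#' `p(p+1)(p+2)/6` degrees of freedom; the kurtosis statistic
#' `(b2 - p(p+2)) / sqrt(8 p (p+2) / n)` to a standard normal. The
#' omnibus p-value is the Bonferroni combination of the two.
#'
#' @param Z `n x p` matrix of observations.
#' @return list with `p_skew`, `p_kurt`, `p_omnibus` and the statistics.
#' @export
mardia_test <- function(Z) {
  Z <- as.matrix(Z)
  n <- nrow(Z); p <- ncol(Z)
  Zc <- sweep(Z, 2L, colMeans(Z))
  S <- crossprod(Zc) / n
  Sinv <- solve(S)
  D <- Zc %*% Sinv %*% t(Zc)
  b1 <- mean(D^3)
  b2 <- mean(diag(D)^2)
  stat_skew <- n * b1 / 6
  df_skew <- p * (p + 1) * (p + 2) / 6
  p_skew <- stats::pchisq(stat_skew, df_skew, lower.tail = FALSE)
  stat_kurt <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  p_kurt <- 2 * stats::pnorm(abs(stat_kurt), lower.tail = FALSE)
  list(p_skew = p_skew, p_kurt = p_kurt,
       p_omnibus = min(1, 2 * min(p_skew, p_kurt)),
       b1 = b1, b2 = b2, stat_skew = stat_skew, stat_kurt = stat_kurt)
}
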
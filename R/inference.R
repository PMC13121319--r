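## ---- parameter packing ---------------------------------------------------

## theta <-> flat named vector (original scale)
theta_pack <- function(theta, model) {
  c(lambda = theta$lambda,
    stats::setNames(theta$alpha, family_par_names(model$x_family, "alpha")),
    stats::setNames(theta$beta, family_par_names(model$z_family, "beta")))
}

theta_unpack <- function(par, model) {
  d1 <- family_npar(model$x_family)
  d2 <- family_npar(model$z_family)
  fht_theta(par[1],
            alpha = if (d1) par[1 + seq_len(d1)] else numeric(0),
            beta = if (d2) par[1 + d1 + seq_len(d2)] else numeric(0))
}

## flat vector <-> unconstrained coordinates (log intensity/rates, logit probs)
par_to_unconstrained <- function(par, model) {
  d1 <- family_npar(model$x_family)
  d2 <- family_npar(model$z_family)
  c(log(par[1]),
    family_to_unconstrained(model$x_family,
                            if (d1) par[1 + seq_len(d1)] else numeric(0)),
    family_to_unconstrained(model$z_family,
                            if (d2) par[1 + d1 + seq_len(d2)] else numeric(0)))
}

par_from_unconstrained <- function(u, model) {
  d1 <- family_npar(model$x_family)
  d2 <- family_npar(model$z_family)
  c(exp(u[1]),
    family_from_unconstrained(model$x_family,
                              if (d1) u[1 + seq_len(d1)] else numeric(0)),
    family_from_unconstrained(model$z_family,
                              if (d2) u[1 + d1 + seq_len(d2)] else numeric(0)))
}

## bounds as flat lower/upper vectors on the original scale
bounds_matrix <- function(model) {
  b <- model$bounds
  lower <- c(b$lambda[1], b$alpha[, 1], b$beta[, 1])
  upper <- c(b$lambda[2], b$alpha[, 2], b$beta[, 2])
  rbind(lower = lower, upper = upper)
}

#' Mean log-likelihood of a censored sample
#'
#' Average of [outcome_log_density()] over the observations. Returns
#' `-Inf` when any observation has zero density under `theta`.
#'
#' @param theta a [fht_theta()].
#' @param sample a `cpfht_sample` (or any data frame with columns `y`,
#'   `delta`).
#' @param model a [fht_model()] whose `model_type` matches the sample codes.
#' @return mean log-likelihood (scalar).
#' @export
fht_loglik <- function(theta, sample, model) {
  if (!nrow(sample)) stop("empty sample", call. = FALSE)
  ok <- if (model$model_type == "I") c(0L, 1L) else c(0L, 1L, 2L)
  if (!all(sample$delta %in% ok))
    stop("sample codes incompatible with Model ", model$model_type,
         call. = FALSE)
  mean(outcome_log_density(sample$y, sample$delta, theta, model))
}

#' Maximum-likelihood fit of the hitting-time model
#'
#' Maximizes the mean log-likelihood over the model's compact parameter
#' box with a bounded quasi-Newton search (`L-BFGS-B`) on transformed
#' coordinates: log for the intensity and rate-type parameters, logit for
#' probabilities. The search is repeated from `starts` random
#' initializations (drawn in a moderate central range of the box) and the
#' best interior optimum is kept. The truncation order is frozen at the
#' model's `N` before optimization so the objective is smooth in the
#' parameters.
#'
#' @param sample a `cpfht_sample`.
#' @param model a [fht_model()].
#' @param starts number of random initializations.
#' @param seed optional seed for the start draws.
#' @param init optional [fht_theta()] used as the first start.
#' @param compute_se compute the score/Hessian matrices and sandwich
#'   standard errors at the optimum.
#' @return object of class `cpfht_fit`: `theta_hat`, `par` (named vector),
#'   `loglik` (mean log-likelihood at the optimum), `converged`, `N_used`,
#'   `A`, `B`, `C` (sandwich), `C_model` (`-A^{-1}`), `se`
#'   (`sqrt(diag(C)/n)`), and `starts` (per-start record).
#' @export
fit_mle <- function(sample, model, starts = 5L, seed = NULL, init = NULL,
                    compute_se = TRUE) {
  if (!nrow(sample)) stop("empty sample", call. = FALSE)
  chk <- model$assumption
  if (identical(chk$assumption, "none"))
    warning("configuration not known to be identifiable", call. = FALSE)
  bm <- bounds_matrix(model)
  lo <- par_to_unconstrained(bm["lower", ], model)
  up <- par_to_unconstrained(bm["upper", ], model)
  d <- length(lo)
  if (!is.null(seed)) set.seed(seed)
  ## start points: optional user start, then random draws in the central
  ## half of the transformed box
  mid <- (lo + up) / 2
  spread <- (up - lo) / 4
  start_pts <- lapply(seq_len(starts), function(k)
    mid + spread * stats::runif(d, -1, 1))
  if (!is.null(init))
    start_pts <- c(list(par_to_unconstrained(theta_pack(init, model), model)),
                   start_pts)
  negll <- function(u) {
    th <- theta_unpack(par_from_unconstrained(u, model), model)
    v <- tryCatch(fht_loglik(th, sample, model), error = function(e) -Inf)
    if (!is.finite(v)) 1e10 else -v
  }
  runs <- lapply(start_pts, function(u0) {
    tryCatch(stats::optim(u0, negll, method = "L-BFGS-B",
                          lower = lo, upper = up,
                          control = list(maxit = 300L, factr = 1e7)),
             error = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  runs <- Filter(function(r) is.finite(r$value) && r$value < 1e9, runs)
  if (!length(runs))
    stop("all optimizer starts failed to converge", call. = FALSE)
  vals <- vapply(runs, `[[`, numeric(1), "value")
  interior <- vapply(runs, function(r)
    all(r$par > lo + 1e-6 & r$par < up - 1e-6), logical(1))
  pick <- if (any(interior)) which(interior)[which.min(vals[interior])]
          else which.min(vals)
  best <- runs[[pick]]
  par_hat <- par_from_unconstrained(best$par, model)
  names(par_hat) <- colnames(bm)
  theta_hat <- theta_unpack(par_hat, model)
  names(par_hat) <- names(theta_pack(theta_hat, model))
  fit <- list(theta_hat = theta_hat, par = par_hat,
              loglik = -best$value,
              converged = best$convergence == 0 && interior[pick],
              optim_message = best$message,
              N_used = model$N, model = model,
              n = nrow(sample),
              starts = data.frame(value = -vals, interior = interior))
  if (compute_se) {
    ab <- tryCatch(info_matrices(theta_hat, sample, model),
                   error = function(e) NULL)
    if (!is.null(ab)) {
      fit$A <- ab$A; fit$B <- ab$B
      cv <- tryCatch(sandwich_cov(ab$A, ab$B), error = function(e) NULL)
      if (!is.null(cv)) {
        fit$C <- cv$robust; fit$C_model <- cv$model_based
        fit$se <- sqrt(pmax(diag(cv$robust), 0) / nrow(sample))
        names(fit$se) <- names(par_hat)
      }
    }
  }
  class(fit) <- "cpfht_fit"
  fit
}

#' @export
print.cpfht_fit <- function(x, ...) {
  cat(sprintf("hitting-time model fit (Model %s, n = %d, N = %d)\n",
              x$model$model_type, x$n, x$N_used))
  tab <- data.frame(estimate = x$par)
  if (!is.null(x$se)) tab$se <- x$se
  print(signif(as.matrix(tab), 5))
  cat(sprintf("mean log-likelihood %.6f, converged: %s\n",
              x$loglik, x$converged))
  invisible(x)
}

#' @export
logLik.cpfht_fit <- function(object, ...) {
  structure(object$loglik * object$n, df = length(object$par),
            class = "logLik")
}

#' @export
coef.cpfht_fit <- function(object, ...) object$par

#' Empirical Hessian and score-outer-product matrices
#'
#' Computes `A_n`, the averaged Hessian of the per-observation
#' log-densities, and `B_n`, the averaged outer product of per-observation
#' scores, at `theta`, by central finite differences with per-coordinate
#' steps scaled to the parameter magnitude. In a well-specified model the
#' information identity gives `A = -B` at the truth, so `A_n + B_n` being
#' small at the optimum is a useful specification check.
#'
#' @param theta a [fht_theta()] interior to the bounds.
#' @param sample a `cpfht_sample`.
#' @param model a [fht_model()].
#' @return list with matrices `A` and `B` (dimension `1 + d1 + d2`) and
#'   `scores`, the `n x d` matrix of per-observation score estimates.
#' @export
info_matrices <- function(theta, sample, model) {
  par <- theta_pack(theta, model)
  d <- length(par)
  n <- nrow(sample)
  f_obs <- function(p) {
    th <- theta_unpack(p, model)
    outcome_log_density(sample$y, sample$delta, th, model)
  }
  ## per-observation scores (central differences)
  hg <- 1e-5 * pmax(abs(par), 1)
  G <- matrix(NA_real_, n, d)
  for (j in seq_len(d)) {
    pj <- par; pj[j] <- par[j] + hg[j]
    mj <- par; mj[j] <- par[j] - hg[j]
    G[, j] <- (f_obs(pj) - f_obs(mj)) / (2 * hg[j])
  }
  if (any(!is.finite(G))) {
    bad <- which(!is.finite(G), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite score for observation %d, parameter '%s'",
                 bad[1], names(par)[bad[2]]), call. = FALSE)
  }
  ## Hessian of the mean log-likelihood
  hh <- (.Machine$double.eps)^(1/4) * pmax(abs(par), 1)
  m_fun <- function(p) mean(f_obs(p))
  H <- matrix(NA_real_, d, d)
  m0 <- m_fun(par)
  for (j in seq_len(d)) {
    pj <- par; pj[j] <- par[j] + hh[j]
    mj <- par; mj[j] <- par[j] - hh[j]
    H[j, j] <- (m_fun(pj) - 2 * m0 + m_fun(mj)) / hh[j]^2
    if (j > 1) for (k in seq_len(j - 1)) {
      pp <- par; pp[j] <- par[j] + hh[j]; pp[k] <- par[k] + hh[k]
      pm <- par; pm[j] <- par[j] + hh[j]; pm[k] <- par[k] - hh[k]
      mp <- par; mp[j] <- par[j] - hh[j]; mp[k] <- par[k] + hh[k]
      mm <- par; mm[j] <- par[j] - hh[j]; mm[k] <- par[k] - hh[k]
      H[j, k] <- H[k, j] <-
        (m_fun(pp) - m_fun(pm) - m_fun(mp) + m_fun(mm)) /
        (4 * hh[j] * hh[k])
    }
  }
  if (any(!is.finite(H)))
    stop("non-finite Hessian entry", call. = FALSE)
  dimnames(H) <- list(names(par), names(par))
  B <- crossprod(G) / n
  dimnames(B) <- dimnames(H)
  list(A = (H + t(H)) / 2, B = B, scores = G)
}

#' Sandwich and model-based covariance of the MLE
#'
#' Returns the robust sandwich `A^{-1} B A^{-1}` and the model-based
#' `-A^{-1}`; in a well-specified model the two agree asymptotically.
#' Symmetry is enforced by averaging with the transpose.
#'
#' @param A,B matrices from [info_matrices()].
#' @param kappa_max reciprocal-condition threshold below which `A` is
#'   treated as singular.
#' @return list with `robust` and `model_based` covariance matrices (these
#'   estimate the covariance of `sqrt(n) (theta_hat - theta)`).
#' @export
sandwich_cov <- function(A, B, kappa_max = 1e12) {
  if (!is.finite(rcond(A)) || rcond(A) < 1 / kappa_max)
    stop("A_n is numerically singular; the asymptotic-normality result ",
         "requires a non-singular Hessian", call. = FALSE)
  Ainv <- solve(A)
  robust <- Ainv %*% B %*% Ainv
  robust <- (robust + t(robust)) / 2
  model_based <- -(Ainv + t(Ainv)) / 2
  list(robust = robust, model_based = model_based)
}
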
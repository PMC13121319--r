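## one batch of jump draws from a family
draw_jumps <- function(family, n) {
  switch(family$family,
    degenerate = rep(family$value, n),
    bernoulli = stats::rbinom(n, 1L, family$prob),
    binomial = stats::rbinom(n, family$size, family$prob),
    poisson = stats::rpois(n, family$mean),
    exponential = stats::rexp(n, family$rate),
    gamma = stats::rgamma(n, shape = family$shape, rate = family$rate),
    discrete_lattice = sample(family$support, n, replace = TRUE,
                              prob = family$probs))
}

#' Exact simulation of the latent bivariate process and its hitting times
#'
#' Simulates, for each subject, one shared stream of exponential
#' inter-arrival times (the common Poisson clock) and, at every tick, one
#' jump for each margin. The event time T is the clock time at which the
#' cumulative X-jumps first reach `x`; the censoring time C is the clock
#' time at which the cumulative Z-jumps first reach `z`. Because both
#' margins ride the same clock, T and C coincide exactly when the two
#' crossings happen at the same tick -- the tie is a structural event
#' decided by jump-count equality, never by comparing floating-point times.
#'
#' @param theta a [fht_theta()].
#' @param model a [fht_model()] (thresholds and jump families; the
#'   observation scheme is irrelevant here).
#' @param n number of subjects.
#' @param seed optional integer seed (reproducible given
#'   `(seed, n, theta, model)`).
#' @param keep_jumps retain the per-subject inter-arrival and jump
#'   sequences (list attribute `"jumps"`; intended for small `n`).
#' @param max_jumps per-subject cap on clock ticks, guarding against
#'   nontermination when the jump laws put almost all mass at 0.
#' @return data frame of class `cpfht_paths` with columns `nu_x`, `nu_z`
#'   (jump counts at crossing), `t_event` (T) and `c_event` (C).
#' @export
simulate_latent <- function(theta, model, n, seed = NULL, keep_jumps = FALSE,
                            max_jumps = 1e6) {
  stopifnot(n >= 1)
  tf <- theta_families(theta, model)
  if ((tf$xf$zero_mass >= 1) || (tf$zf$zero_mass >= 1))
    stop("a jump law with all mass at 0 cannot cross its threshold",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tm <- numeric(n); sx <- numeric(n); sz <- numeric(n)
  nux <- rep(NA_integer_, n); nuz <- rep(NA_integer_, n)
  tt <- rep(NA_real_, n); ct <- rep(NA_real_, n)
  jrec <- if (keep_jumps) replicate(n, list(e = numeric(0), x = numeric(0),
                                            z = numeric(0)),
                                    simplify = FALSE)
  active <- seq_len(n)
  k <- 0L
  while (length(active)) {
    k <- k + 1L
    if (k > max_jumps) {
      stop(sprintf("subject %d exceeded the jump cap (%g ticks) without %s",
                   active[1], max_jumps, "crossing both thresholds"),
           call. = FALSE)
    }
    m <- length(active)
    e <- stats::rexp(m, theta$lambda)
    xj <- draw_jumps(tf$xf, m)
    zj <- draw_jumps(tf$zf, m)
    tm[active] <- tm[active] + e
    sx[active] <- sx[active] + xj
    sz[active] <- sz[active] + zj
    if (keep_jumps) {
      for (ii in seq_len(m)) {
        s <- active[ii]
        jrec[[s]]$e <- c(jrec[[s]]$e, e[ii])
        jrec[[s]]$x <- c(jrec[[s]]$x, xj[ii])
        jrec[[s]]$z <- c(jrec[[s]]$z, zj[ii])
      }
    }
    hit_x <- active[is.na(nux[active]) & sx[active] >= model$x]
    nux[hit_x] <- k; tt[hit_x] <- tm[hit_x]
    hit_z <- active[is.na(nuz[active]) & sz[active] >= model$z]
    nuz[hit_z] <- k; ct[hit_z] <- tm[hit_z]
    active <- active[is.na(nux[active]) | is.na(nuz[active])]
  }
  out <- data.frame(nu_x = nux, nu_z = nuz, t_event = tt, c_event = ct)
  class(out) <- c("cpfht_paths", "data.frame")
  if (keep_jumps) attr(out, "jumps") <- jrec
  out
}

#' Censored outcomes from latent paths
#'
#' Converts latent hitting-time pairs into the observed `(y, delta)` data.
#' Under Model I `delta = 1` iff `T <= C`; under Model II `delta` is 0 for
#' `T > C`, 1 for `T < C` and 2 for the tie `T = C`. Orderings and ties are
#' read off the jump counts (`nu_x` vs `nu_z`), so a tie is exact.
#'
#' @param paths a `cpfht_paths` data frame from [simulate_latent()].
#' @param model_type `"I"` or `"II"`.
#' @param latent keep the latent times as columns `t_latent`, `c_latent`.
#' @return data frame of class `cpfht_sample` with columns `y`, `delta`
#'   and attribute `model_type`.
#' @export
to_outcomes <- function(paths, model_type = c("I", "II"), latent = FALSE) {
  model_type <- match.arg(model_type)
  y <- pmin(paths$t_event, paths$c_event)
  delta <- if (model_type == "I") {
    as.integer(paths$nu_x <= paths$nu_z)
  } else {
    ifelse(paths$nu_x < paths$nu_z, 1L,
           ifelse(paths$nu_x > paths$nu_z, 0L, 2L))
  }
  out <- data.frame(y = y, delta = as.integer(delta))
  if (latent) {
    out$t_latent <- paths$t_event
    out$c_latent <- paths$c_event
  }
  class(out) <- c("cpfht_sample", "data.frame")
  attr(out, "model_type") <- model_type
  out
}

#' Simulate a censored sample in one call
#'
#' Convenience wrapper: [simulate_latent()] followed by [to_outcomes()]
#' with the model's observation scheme.
#'
#' @inheritParams simulate_latent
#' @param latent keep the latent times as extra columns.
#' @return a `cpfht_sample` data frame with provenance attributes
#'   (`seed`, `model_type`).
#' @examples
#' m <- fht_model(jump_family("bernoulli", prob = 0.36),
#'                jump_family("degenerate", value = 1), x = 7, z = 17)
#' s <- simulate_sample(fht_theta(1.42, alpha = 0.36), m, n = 20, seed = 1)
#' table(s$delta)
#' @export
simulate_sample <- function(theta, model, n, seed = NULL, latent = FALSE,
                            max_jumps = 1e6) {
  paths <- simulate_latent(theta, model, n, seed = seed,
                           max_jumps = max_jumps)
  out <- to_outcomes(paths, model$model_type, latent = latent)
  attr(out, "seed") <- seed
  out
}
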
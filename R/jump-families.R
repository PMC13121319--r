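#' Jump-size distribution of one margin of the latent process
#'
#' Constructs the law of a single jump of one of the two compound Poisson
#' processes. Both margins jump at the same Poisson clock ticks; each margin
#' has its own i.i.d. jump-size law, which must be supported on the
#' nonnegative half-line and must not be degenerate at zero.
#'
#' Available families and their parameters:
#' \describe{
#'   \item{degenerate}{`value > 0`: every jump equals `value`.}
#'   \item{bernoulli}{`prob` in (0,1): jumps are 0/1.}
#'   \item{binomial}{`size` (positive integer, fixed, not estimated) and
#'     `prob` in (0,1).}
#'   \item{poisson}{`mean > 0`: nonnegative integer jumps.}
#'   \item{exponential}{`rate > 0`.}
#'   \item{gamma}{`shape > 0`, `rate > 0`.}
#'   \item{discrete_lattice}{`support` (distinct nonnegative reals) and
#'     `probs` (matching probabilities summing to 1). Parameters are fixed,
#'     not estimated.}
#' }
#'
#' @param family character tag, one of the families above.
#' @param ... named family parameters, see Details.
#' @return an object of class `cpfht_family` with elements `family` (the tag),
#'   the parameters, and `zero_mass`, the probability that one jump equals 0.
#' @examples
#' jump_family("exponential", rate = 0.71)
#' jump_family("bernoulli", prob = 0.36)
#' @export
jump_family <- function(family = c("degenerate", "bernoulli", "binomial",
                                   "poisson", "exponential", "gamma",
                                   "discrete_lattice"), ...) {
  family <- match.arg(family)
  p <- list(...)
  need <- function(nms) {
    miss <- setdiff(nms, names(p))
    if (length(miss))
      stop(sprintf("family '%s' requires parameter(s): %s",
                   family, paste(miss, collapse = ", ")), call. = FALSE)
  }
  obj <- switch(family,
    degenerate = {
      need("value")
      if (!is.numeric(p$value) || length(p$value) != 1L || p$value <= 0)
        stop("degenerate jump value must be a single positive number",
             call. = FALSE)
      list(family = family, value = p$value, zero_mass = 0)
    },
    bernoulli = {
      need("prob")
      if (p$prob <= 0 || p$prob >= 1)
        stop("bernoulli 'prob' must lie in (0,1)", call. = FALSE)
      list(family = family, prob = p$prob, zero_mass = 1 - p$prob)
    },
    binomial = {
      need(c("size", "prob"))
      if (p$size < 1 || p$size != round(p$size))
        stop("binomial 'size' must be a positive integer", call. = FALSE)
      if (p$prob <= 0 || p$prob >= 1)
        stop("binomial 'prob' must lie in (0,1)", call. = FALSE)
      list(family = family, size = as.integer(p$size), prob = p$prob,
           zero_mass = (1 - p$prob)^p$size)
    },
    poisson = {
      need("mean")
      if (p$mean <= 0) stop("poisson 'mean' must be positive", call. = FALSE)
      list(family = family, mean = p$mean, zero_mass = exp(-p$mean))
    },
    exponential = {
      need("rate")
      if (p$rate <= 0) stop("exponential 'rate' must be positive", call. = FALSE)
      list(family = family, rate = p$rate, zero_mass = 0)
    },
    gamma = {
      need(c("shape", "rate"))
      if (p$shape <= 0 || p$rate <= 0)
        stop("gamma 'shape' and 'rate' must be positive", call. = FALSE)
      list(family = family, shape = p$shape, rate = p$rate, zero_mass = 0)
    },
    discrete_lattice = {
      need(c("support", "probs"))
      s <- p$support; w <- p$probs
      if (length(s) != length(w) || anyDuplicated(s) || any(s < 0))
        stop("'support' must be distinct nonnegative values matching 'probs'",
             call. = FALSE)
      if (any(w < 0) || abs(sum(w) - 1) > 1e-12)
        stop("'probs' must be nonnegative and sum to 1", call. = FALSE)
      o <- order(s)
      s <- s[o]; w <- w[o]
      zm <- if (s[1] == 0) w[1] else 0
      if (zm >= 1) stop("jump law cannot put all mass at 0", call. = FALSE)
      list(family = family, support = s, probs = w, zero_mass = zm)
    })
  structure(obj, class = "cpfht_family")
}

#' @export
print.cpfht_family <- function(x, ...) {
  pars <- x[setdiff(names(x), c("family", "zero_mass"))]
  pstr <- paste(vapply(names(pars), function(nm)
    paste0(nm, "=", paste(signif(pars[[nm]], 6), collapse = ",")),
    character(1)), collapse = ", ")
  cat(sprintf("jump family: %s(%s)  [P(jump = 0) = %.4g, class %s]\n",
              x$family, pstr, x$zero_mass, classify_family(x)))
  invisible(x)
}

## largest lattice point strictly below x, for unit-spaced integer support
strict_below_int <- function(x) {
  f <- floor(x)
  if (f < x) f else f - 1
}

#' Probabilities that cumulative jumps stay below the threshold
#'
#' Computes the coefficient sequence `c_n = P(S_n < threshold)` for
#' `S_n` the sum of `n` i.i.d. jumps, for `n = 0, ..., N`. These sequences
#' are the sufficient summaries of the jump laws: every model function
#' (joint density, tie probability, outcome densities, hazard) is a
#' Poisson mixture of their differences and products. The inequality is
#' strict, matching the up-crossing rule `L >= threshold`; on lattice
#' families strictness is honored exactly.
#'
#' Closed forms are used throughout: binomial/Poisson/gamma convolution
#' identities for the named families, and an exact truncated convolution
#' for `discrete_lattice`.
#'
#' @param family a [jump_family()].
#' @param threshold positive crossing level.
#' @param N largest number of jumps (sequence has `N + 1` entries).
#' @return an object of class `cpfht_coeffs`: list with `values` (numeric,
#'   `c_0..c_N`), `threshold`, `family`, and `n_max_zero` (smallest `n` with
#'   `c_n = 0`, or `NA` if none within `0..N`).
#' @examples
#' coeff_sequence(jump_family("exponential", rate = 0.71), 14, 25)
#' @export
coeff_sequence <- function(family, threshold, N) {
  stopifnot(inherits(family, "cpfht_family"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("'threshold' must be a single positive number", call. = FALSE)
  if (N < 0 || N != round(N)) stop("'N' must be a nonnegative integer",
                                   call. = FALSE)
  n <- 0:N
  vals <- switch(family$family,
    degenerate = as.numeric(n * family$value < threshold),
    bernoulli = stats::pbinom(strict_below_int(threshold), n, family$prob),
    binomial = stats::pbinom(strict_below_int(threshold), n * family$size,
                             family$prob),
    poisson = stats::ppois(strict_below_int(threshold), n * family$mean),
    exponential = stats::pgamma(threshold, shape = n, rate = family$rate),
    gamma = stats::pgamma(threshold, shape = n * family$shape,
                          rate = family$rate),
    discrete_lattice = lattice_coeffs(family, threshold, N))
  vals[1] <- 1  # empty sum is 0 < threshold
  zero <- which(vals == 0)
  structure(list(values = vals, threshold = threshold, family = family,
                 n_max_zero = if (length(zero)) n[zero[1]] else NA_integer_),
            class = "cpfht_coeffs")
}

## exact convolution of a finite nonnegative lattice law, mass at or past the
## threshold lumped into one absorbing cell (sums only grow)
lattice_coeffs <- function(family, threshold, N) {
  tol <- 1e-9 * max(1, threshold)
  s <- family$support; w <- family$probs
  cur_s <- 0; cur_w <- 1       # distribution of S_0
  out <- numeric(N + 1); out[1] <- 1
  if (N == 0) return(out)
  for (k in seq_len(N)) {
    ns <- as.vector(outer(cur_s, s, `+`))
    nw <- as.vector(outer(cur_w, w, `*`))
    ns[ns >= threshold - tol] <- threshold  # absorbing
    agg <- rowsum(nw, group = round(ns / tol))
    cur_s <- as.numeric(rownames(agg)) * tol
    cur_w <- as.vector(agg)
    out[k + 1] <- sum(cur_w[cur_s < threshold - tol])
  }
  out
}

#' @export
print.cpfht_coeffs <- function(x, ...) {
  cat(sprintf("coefficient sequence c_0..c_%d, threshold %.6g, family %s\n",
              length(x$values) - 1L, x$threshold, x$family$family))
  print(utils::head(x$values, 10))
  if (length(x$values) > 10) cat("...\n")
  if (!is.na(x$n_max_zero))
    cat(sprintf("first exact zero at n = %d\n", x$n_max_zero))
  invisible(x)
}

#' Classify a jump law into the identifiability taxonomy
#'
#' The identifiability analysis of the model sorts jump laws into three
#' classes: `F1` (jumps almost surely at least a positive constant, so the
#' coefficient sequence hits an exact zero), `F2` (absolutely continuous
#' with mass arbitrarily close to 0 and an eventually monotone convolution
#' power; the coefficient ratio `c_{n+1}/c_n` tends to 0), and `F3`
#' (discrete with an atom at 0 and a smallest positive atom; the ratio
#' tends to `P(jump = 0)`).
#'
#' @param family a [jump_family()].
#' @return one of `"F1"`, `"F2"`, `"F3"`, `"unclassified"`.
#' @export
classify_family <- function(family) {
  stopifnot(inherits(family, "cpfht_family"))
  switch(family$family,
    degenerate = "F1",
    exponential = ,
    gamma = "F2",
    bernoulli = ,
    binomial = ,
    poisson = "F3",
    discrete_lattice = {
      pos <- family$support[family$probs > 0]
      if (min(pos) > 0) "F1"
      else if (any(pos > 0)) "F3"
      else "unclassified"
    },
    "unclassified")
}

## smallest positive value a jump can take (Inf if mass arbitrarily near 0)
essential_min <- function(family) {
  switch(family$family,
    degenerate = family$value,
    bernoulli = ,
    binomial = ,
    poisson = 1,
    discrete_lattice = min(family$support[family$probs > 0 &
                                          family$support > 0]),
    0)
}

#' Tail-ratio diagnostic for a coefficient sequence
#'
#' Estimates the limit of the ratio `c_{n+1}/c_n`, which drives the
#' large-time hazard: the hazard tends to `lambda * (1 - a)` where `a` is
#' the limit of the product-sequence ratio. For an F1 family the sequence
#' hits an exact zero; for F2 the ratio tends to 0; for F3 it tends to the
#' family's mass at 0 with an O(1/n) discrepancy. The limit is estimated by
#' regressing the tail ratios on `1/n` and `1/n^2` and reporting the
#' intercept; the tail trend (the 1/n slope) is reported but the class is
#' never asserted from it.
#'
#' @param coeffs a [coeff_sequence()] with at least 10 strictly positive
#'   consecutive values (unless it hits an exact zero).
#' @return list of class `cpfht_ratio_diag` with `limit` (intercept
#'   estimate, or exactly 0 when the sequence hits zero), `last_ratio`,
#'   `slope` (1/n trend, `NA` for exact zeros), and `n_zero`.
#' @export
ratio_limit_diagnostic <- function(coeffs) {
  stopifnot(inherits(coeffs, "cpfht_coeffs"))
  v <- coeffs$values
  if (!is.na(coeffs$n_max_zero)) {
    return(structure(list(limit = 0, last_ratio = 0, slope = NA_real_,
                          n_zero = coeffs$n_max_zero),
                     class = "cpfht_ratio_diag"))
  }
  if (length(v) < 11 || any(v <= 0))
    stop("sequence too short (need >= 10 strictly positive consecutive values)",
         call. = FALSE)
  n <- seq_len(length(v) - 1L)          # ratio r_n = c_{n+1} / c_n, n >= 1
  r <- v[-1][-1] / v[-length(v)][-1]
  n <- n[-1]
  tail_idx <- n >= max(10, floor(max(n) / 2))
  fit <- stats::lm(r[tail_idx] ~ I(1 / n[tail_idx]) + I(1 / n[tail_idx]^2))
  structure(list(limit = unname(stats::coef(fit)[1]),
                 last_ratio = r[length(r)],
                 slope = unname(stats::coef(fit)[2]),
                 n_zero = NA_integer_),
            class = "cpfht_ratio_diag")
}

#' @export
print.cpfht_ratio_diag <- function(x, ...) {
  if (!is.na(x$n_zero))
    cat(sprintf("exact zero reached at n = %d (ratio limit 0)\n", x$n_zero))
  else
    cat(sprintf("ratio limit estimate %.6g (last ratio %.6g, 1/n slope %.4g)\n",
                x$limit, x$last_ratio, x$slope))
  invisible(x)
}

#' Which identifiability assumption a pair of jump laws satisfies
#'
#' Determines the structural condition met by the two jump laws and the
#' observation scheme it requires. If either law is of class F1 the
#' coefficient sequences terminate and Model I suffices (condition `H1`);
#' if either is F2, Model I still suffices (`H2.i`); if both are F3 the
#' large-time hazard only pins down `lambda * (1 - P[X=0] P[Z=0])` under
#' Model I, so the richer Model II (which records ties separately) is
#' required (`H2.ii`).
#'
#' @param x_family,z_family [jump_family()] objects for the two margins.
#' @param x,z optional thresholds; when given and `H1` holds, the smallest
#'   `n` at which either coefficient sequence vanishes (`n_max`) is returned.
#' @return list of class `cpfht_assumption` with `assumption` (one of
#'   `"H1"`, `"H2.i"`, `"H2.ii"`, `"none"`), `model_required` (`"I"` or
#'   `"II"`), the two classes, `n_max` (or `NA`), and `note`.
#' @export
check_assumption <- function(x_family, z_family, x = NULL, z = NULL) {
  cx <- classify_family(x_family)
  cz <- classify_family(z_family)
  if (cx == "unclassified" || cz == "unclassified") {
    return(structure(list(assumption = "none", model_required = NA_character_,
                          x_class = cx, z_class = cz, n_max = NA_integer_,
                          note = "one of the families is unclassified"),
                     class = "cpfht_assumption"))
  }
  tag <- if (cx == "F1" || cz == "F1") "H1"
         else if (cx == "F2" || cz == "F2") "H2.i"
         else "H2.ii"
  n_max <- NA_integer_
  if (tag == "H1" && !is.null(x) && !is.null(z)) {
    cap <- function(fam, thr) {
      # the sequence terminates only when jumps are a.s. >= a positive
      # constant (class F1): then c_n = 0 for n >= ceiling(threshold / min)
      if (classify_family(fam) == "F1")
        as.integer(ceiling(thr / essential_min(fam)))
      else NA_integer_
    }
    n_max <- min(cap(x_family, x), cap(z_family, z), na.rm = TRUE)
  }
  structure(list(assumption = tag,
                 model_required = if (tag == "H2.ii") "II" else "I",
                 x_class = cx, z_class = cz, n_max = n_max,
                 note = switch(tag,
                   H1 = "coefficient sequences terminate; Model I sufficient",
                   H2.i = "Model I sufficient",
                   H2.ii = "both laws discrete with an atom at 0; Model II required")),
            class = "cpfht_assumption")
}

#' @export
print.cpfht_assumption <- function(x, ...) {
  cat(sprintf("assumption %s (X: %s, Z: %s) -> Model %s\n",
              x$assumption, x$x_class, x$z_class, x$model_required))
  if (!is.na(x$n_max)) cat(sprintf("coefficient sequences vanish by n = %d\n",
                                   x$n_max))
  cat(x$note, "\n")
  invisible(x)
}

## log of the coefficient sequence, computed with log.p = TRUE closed forms
## so that coefficients far below the double underflow threshold remain
## usable (needed by survival/hazard evaluation at large lambda * t)
coeff_sequence_log <- function(family, threshold, N) {
  n <- 0:N
  lv <- switch(family$family,
    degenerate = ifelse(n * family$value < threshold, 0, -Inf),
    bernoulli = stats::pbinom(strict_below_int(threshold), n, family$prob,
                              log.p = TRUE),
    binomial = stats::pbinom(strict_below_int(threshold), n * family$size,
                             family$prob, log.p = TRUE),
    poisson = stats::ppois(strict_below_int(threshold), n * family$mean,
                           log.p = TRUE),
    exponential = stats::pgamma(threshold, shape = n, rate = family$rate,
                                log.p = TRUE),
    gamma = stats::pgamma(threshold, shape = n * family$shape,
                          rate = family$rate, log.p = TRUE),
    discrete_lattice = log(lattice_coeffs(family, threshold, N)))
  lv[1] <- 0
  lv
}

## ---- free-parameter plumbing used by inference --------------------------

## number of estimated parameters of a family
family_npar <- function(family) {
  switch(family$family,
    degenerate = 0L, discrete_lattice = 0L,
    bernoulli = 1L, binomial = 1L, poisson = 1L, exponential = 1L,
    gamma = 2L)
}

## current estimated-parameter values (original scale)
family_get <- function(family) {
  switch(family$family,
    degenerate = , discrete_lattice = numeric(0),
    bernoulli = family$prob, binomial = family$prob,
    poisson = family$mean, exponential = family$rate,
    gamma = c(family$shape, family$rate))
}

## names for reporting
family_par_names <- function(family, prefix) {
  nm <- switch(family$family,
    degenerate = , discrete_lattice = character(0),
    bernoulli = , binomial = "prob",
    poisson = "mean", exponential = "rate",
    gamma = c("shape", "rate"))
  if (length(nm)) paste(prefix, nm, sep = ".") else character(0)
}

## replace estimated parameters, keeping fixed structure (e.g. binomial size)
family_set <- function(family, par) {
  stopifnot(length(par) == family_npar(family))
  switch(family$family,
    degenerate = , discrete_lattice = family,
    bernoulli = jump_family("bernoulli", prob = par[1]),
    binomial = jump_family("binomial", size = family$size, prob = par[1]),
    poisson = jump_family("poisson", mean = par[1]),
    exponential = jump_family("exponential", rate = par[1]),
    gamma = jump_family("gamma", shape = par[1], rate = par[2]))
}

## map to/from unconstrained coordinates (log for rates, logit for probs)
family_to_unconstrained <- function(family, par) {
  switch(family$family,
    bernoulli = , binomial = stats::qlogis(par),
    degenerate = , discrete_lattice = numeric(0),
    log(par))
}

family_from_unconstrained <- function(family, u) {
  switch(family$family,
    bernoulli = , binomial = stats::plogis(u),
    degenerate = , discrete_lattice = numeric(0),
    exp(u))
}
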
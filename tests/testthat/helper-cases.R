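# shared fixtures: the three reference configurations and a toy
# degenerate model whose outcome law is Erlang(2)

case_a <- study_case("a")
case_b <- study_case("b")
case_c <- study_case("c")

erlang_toy <- list(
  theta = fht_theta(2),
  model = fht_model(jump_family("degenerate", value = 1),
                    jump_family("degenerate", value = 1),
                    x = 1.5, z = 1.5, model_type = "I"))

# brute-force n-fold pmf of an integer-valued jump law on 0..K, by repeated
# exact convolution (independent of the closed forms under test)
conv_pmf <- function(pmf1, n) {
  out <- 1
  for (i in seq_len(n)) {
    m <- outer(out, pmf1)
    out <- as.vector(tapply(as.vector(m),
                            as.vector(row(m) + col(m) - 2L), sum))
  }
  out
}

# direct linear-space evaluation of the truncated outcome density (no
# log-sum-exp), as an independent oracle for small lambda * t
direct_density <- function(t, delta, theta, model) {
  N <- model$N
  tf <- list(xf = do.call(jump_family,
                          c(list(model$x_family$family),
                            fam_args(model$x_family, theta$alpha))),
             zf = do.call(jump_family,
                          c(list(model$z_family$family),
                            fam_args(model$z_family, theta$beta))))
  cx <- coeff_sequence(tf$xf, model$x, N + 1)$values
  cz <- coeff_sequence(tf$zf, model$z, N + 1)$values
  i <- seq_len(N + 1)
  dx <- cx[i] - cx[i + 1]; dz <- cz[i] - cz[i + 1]
  a <- if (model$model_type == "I") {
    if (delta == 1) dx * cz[i] else dz * cx[i + 1]
  } else {
    switch(as.character(delta),
           "0" = dz * cx[i + 1], "1" = dx * cz[i + 1], "2" = dx * dz)
  }
  n <- 0:N
  sum(a * theta$lambda * exp(-theta$lambda * t) *
        (theta$lambda * t)^n / factorial(n))
}

# reconstruct family argument list with substituted estimated parameters
fam_args <- function(family, par) {
  switch(family$family,
    degenerate = list(value = family$value),
    discrete_lattice = list(support = family$support, probs = family$probs),
    bernoulli = list(prob = par[1]),
    binomial = list(size = family$size, prob = par[1]),
    poisson = list(mean = par[1]),
    exponential = list(rate = par[1]),
    gamma = list(shape = par[1], rate = par[2]))
}
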
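# Shared fixtures: small, fast synthetic participants.

# a quiet, well-identified participant for estimation tests
quiet_gen <- function(scale1 = 14, scale2 = 20) {
  generator_params(alpha_offset = 0.2, v = 20, b0 = log(0.6),
                   sigma1 = scale_to_sigma(scale1),
                   sigma2 = scale_to_sigma(scale2),
                   x0_base = 0, x0_conflict = 0.3)
}

# deterministic generator: no state noise
noise_free_gen <- function(effects = numeric(0), v = 30) {
  generator_params(alpha_offset = 0.2, v = v, b0 = log(0.6),
                   sigma1 = 0, sigma2 = 0, b_in_base = effects,
                   x0_base = 0, x0_conflict = 0.3)
}

# dense-grid posterior for a single conflict-free trial (1 latent state):
# prior N(m0, P0) on x_base, offset-gamma likelihood through the log link
grid_posterior_1d <- function(rt, gp, m0 = 0, P0 = 0.5,
                              lim = 6, n = 40001) {
  x <- seq(m0 - lim, m0 + lim, length.out = n)
  lp <- stats::dnorm(x, m0, sqrt(P0), log = TRUE) +
    stats::dgamma(rt - gp$alpha_offset, shape = gp$v,
                  rate = gp$v / exp(gp$b0 + gp$b1 * x), log = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  mu <- sum(w * x)
  list(mean = mu, var = sum(w * (x - mu)^2))
}
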
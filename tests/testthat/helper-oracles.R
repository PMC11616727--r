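# Independent oracles used to validate the closed-form implementation.

# Grid-based numerical Bayes update: normal prior x normal likelihood of the
# observed mean difference, normalized on a fine grid.
grid_posterior <- function(prior_mean, prior_var, xdiff, n, R, sigma2,
                           gridsize = 40001L) {
  lik_sd <- sqrt(sigma2 / (n * R * (1 - R)))
  lo <- min(prior_mean - 10 * sqrt(prior_var), xdiff - 10 * lik_sd)
  hi <- max(prior_mean + 10 * sqrt(prior_var), xdiff + 10 * lik_sd)
  th <- seq(lo, hi, length.out = gridsize)
  dens <- dnorm(th, prior_mean, sqrt(prior_var)) * dnorm(xdiff, th, lik_sd)
  dens <- dens / sum(dens)
  m <- sum(th * dens)
  list(mean = m, variance = sum((th - m)^2 * dens))
}

# Hellinger distance between two normals by numerical integration of the
# affinity integral(sqrt(f g)).
hellinger_numeric <- function(mu1, s1, mu2, s2) {
  aff <- integrate(function(x) sqrt(dnorm(x, mu1, s1) * dnorm(x, mu2, s2)),
                   -Inf, Inf, rel.tol = 1e-12)$value
  sqrt(1 - aff)
}

# Monte-Carlo variance of the marginalized commensurate prior: draw the
# precision from the Gamma mixture, then theta | nu ~ N(0, 1/nu).
mc_mixture_variance <- function(w, prior, ndraws = 1e6) {
  comp1 <- runif(ndraws) < w
  nu <- ifelse(comp1, rgamma(ndraws, prior$a1, prior$b1),
               rgamma(ndraws, prior$a2, prior$b2))
  th <- rnorm(ndraws, 0, 1 / sqrt(nu))
  v <- var(th)
  list(variance = v, se = sd((th - mean(th))^2) / sqrt(ndraws))
}

# Brute-force coordinate bisection iterated to a fixed point: for each
# subtrial in turn, bisect its size so its own constraint holds at the
# current complementary sizes.
bisection_solve <- function(design, tol = 1e-12, sweeps = 2000L) {
  K <- design$K
  target <- precision_target(design$delta, design$eta, design$zeta)
  n <- pmax(design$sigma2 / (design$R * (1 - design$R)) *
              (target - 1 / design$s02), 0)
  upper <- max(n) + 10
  for (s in seq_len(sweeps)) {
    n_old <- n
    for (k in seq_len(K)) {
      f <- function(nk) {
        m <- n; m[k] <- nk
        borrowing_constraint_lhs(m, design, k) - target[k]
      }
      n[k] <- if (f(0) >= 0) 0 else uniroot(f, c(0, upper), tol = tol)$root
    }
    if (max(abs(n - n_old)) < tol) break
  }
  n
}
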
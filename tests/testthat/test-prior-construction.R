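mix <- gamma_mixture_prior(1.1, 1.1, 54, 3)

test_that("moment-matched variance follows the mixture formula and its MC oracle", {
  expect_equal(moment_matched_variance(1, mix), 11)
  expect_equal(moment_matched_variance(0, mix), 3 / 53)
  # frozen from the Monte-Carlo oracle (draw nu from the mixture, then
  # theta | nu normal): the w = 0.5 value is the average of the extremes
  expect_equal(moment_matched_variance(0.5, mix), 5.528302, tolerance = 1e-6)
  # Monte-Carlo check of the moment matching. The sample variance of theta
  # only has a usable standard error when E[nu^-2] is finite, i.e. both
  # shapes exceed 2, so the 3-SE comparison uses a shape-3 discounting
  # component; the shape-1.1 component is covered by its exact mean above.
  mix_mc <- gamma_mixture_prior(3, 22, 54, 3)
  set.seed(42)
  for (w in c(0, 0.25, 0.5, 0.75, 1)) {
    mc <- mc_mixture_variance(w, mix_mc)
    expect_lt(abs(mc$variance - moment_matched_variance(w, mix_mc)),
              3 * mc$se)
  }
  # linear and increasing in w when component 1 dominates
  ws <- seq(0, 1, by = 0.1)
  v <- moment_matched_variance(ws, mix)
  expect_true(all(diff(v) > 0))
  expect_equal(diff(v), rep(diff(v)[1], 10))
})

test_that("gamma mixture prior rejects shapes <= 1 and reports inverted roles", {
  expect_error(gamma_mixture_prior(1, 1.1, 54, 3), "moment matching")
  expect_error(gamma_mixture_prior(1.1, 1.1, 0.9, 3), "moment matching")
  expect_error(gamma_mixture_prior(1.1, -1, 54, 3), "positive")
  expect_warning(gamma_mixture_prior(54, 3, 1.1, 1.1), "inverted")
  expect_error(moment_matched_variance(1.2, mix), "\\[0, 1\\]")
})

test_that("synthesis weights normalize, discriminate, and respect symmetry", {
  # equal w => equal p, regardless of the shared value or c0
  for (wv in c(0, 0.3, 1)) {
    p <- synthesis_weights(rep(wv, 5), c0 = 0.05)
    expect_equal(p, rep(1 / 5, 5))
  }
  # frozen from direct evaluation of the two exponentials
  p <- synthesis_weights(c(0.239, 0.417), c0 = 0.05)
  expect_equal(p, c(0.9117635, 0.0882365), tolerance = 1e-6)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # c0 -> 0+ concentrates on the smallest w
  p0 <- synthesis_weights(c(0.2, 0.4, 0.9), c0 = 1e-4)
  expect_equal(p0[1], 1, tolerance = 1e-10)
  # permutation equivariance and sum-to-one on random draws
  set.seed(7)
  for (i in 1:20) {
    w <- runif(4)
    perm <- sample(4)
    p <- synthesis_weights(w, 0.05)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(synthesis_weights(w[perm], 0.05), p[perm])
    # strictly decreasing in any single w holding others fixed
    w2 <- w; w2[2] <- min(1, w[2] + 0.05)
    expect_lt(synthesis_weights(w2, 0.05)[2], p[2])
  }
  expect_error(synthesis_weights(c(0.1, 0.2), c0 = -1), "positive")
})

test_that("Hellinger weight matches numerical integration and its invariants", {
  expect_equal(hellinger_weight(0.3, 1.2, 0.3, 1.2), 0)
  # equal means: exponential term is 1
  expect_equal(hellinger_weight(0, 1, 0, 2),
               sqrt(1 - sqrt(2 * 1 * 2 / (1 + 4))))
  # numeric-integration oracle on the two most different subtype distributions
  expect_equal(hellinger_weight(-0.489, 0.587, 0.226, 0.345),
               hellinger_numeric(-0.489, 0.587, 0.226, 0.345),
               tolerance = 1e-9)
  set.seed(11)
  for (i in 1:15) {
    mu <- rnorm(2); s <- rexp(2) + 0.2
    h <- hellinger_weight(mu[1], s[1], mu[2], s[2])
    expect_equal(h, hellinger_weight(mu[2], s[2], mu[1], s[1]))
    expect_gte(h, 0); expect_lte(h, 1)
    expect_equal(h, hellinger_numeric(mu[1], s[1], mu[2], s[2]),
                 tolerance = 1e-7)
    # widening the mean gap at fixed variances increases the distance
    expect_gt(hellinger_weight(mu[1] + sign(mu[1] - mu[2]) + 0.01, s[1],
                               mu[2], s[2]), h)
  }
  expect_error(hellinger_weight(0, -1, 0, 1), "positive")
})

test_that("operational posterior agrees with the grid-Bayes oracle", {
  pr <- operational_prior(0, 100)
  # no data: prior returned unchanged
  post0 <- operational_posterior(pr, subtrial_summary(NA, NA, 0, 0.5, 6.177))
  expect_equal(post0$mean, 0)
  expect_equal(post0$variance, 100)
  # flat-prior limit reduces to the sampling distribution of the difference
  flat <- operational_posterior(operational_prior(0, 1e12),
                                subtrial_summary(1.3, 0.3, 40, 0.5, 6.177))
  expect_equal(flat$mean, 1.0, tolerance = 1e-9)
  expect_equal(flat$variance, 6.177 / (40 * 0.25), tolerance = 1e-9)
  # frozen grid-oracle values for the worked example
  post <- operational_posterior(pr, subtrial_summary(1, 0, 40, 0.5, 6.177))
  expect_equal(post$variance, 0.6139079, tolerance = 1e-6)
  expect_equal(post$mean, 0.9938609, tolerance = 1e-6)
  set.seed(3)
  for (i in 1:10) {
    m0 <- rnorm(1); s02 <- rexp(1) * 10 + 0.5
    xE <- rnorm(1); xC <- rnorm(1); n <- sample(5:80, 1)
    R <- runif(1, 0.2, 0.8); s2 <- rexp(1) + 0.3
    post <- operational_posterior(operational_prior(m0, s02),
                                  subtrial_summary(xE, xC, n, R, s2))
    g <- grid_posterior(m0, s02, xE - xC, n, R, s2)
    expect_equal(post$mean, g$mean, tolerance = 1e-6)
    expect_equal(post$variance, g$variance, tolerance = 1e-6)
  }
  expect_error(subtrial_summary(0, 0, 10, 1.2, 1), "\\(0, 1\\)")
})

test_that("commensurate prior inflates the source variance by the mixture term", {
  src <- operational_posterior(
    operational_prior(0, 100), subtrial_summary(0.5, 0, 25, 0.6, 5.134))
  cp0 <- commensurate_prior(src, 0, mix)
  expect_equal(cp0$variance, src$variance + 3 / 53)
  cp <- commensurate_prior(src, 0.239, mix)
  expect_equal(cp$variance, 3.520485, tolerance = 1e-5) # composed oracle value
  expect_gt(cp$variance, src$variance)
  expect_equal(cp$mean, src$mean)
  # n_q -> infinity, w = 1: variance tends to the discounting component's 11
  src_inf <- operational_posterior(operational_prior(0, 100),
                                   subtrial_summary(0.5, 0, 1e9, 0.5, 5))
  expect_equal(commensurate_prior(src_inf, 1, mix)$variance, 11,
               tolerance = 1e-6)
})

test_that("collective prior convolution has the stated mean and variance", {
  one <- collective_prior(1, list(list(mean = 0.4, variance = 2)))
  expect_equal(one$mean, 0.4); expect_equal(one$variance, 2)
  # equal weights over identical components: variance shrinks by 1/(K-1)
  comps <- replicate(6, list(mean = 0.1, variance = 3.3), simplify = FALSE)
  cp <- collective_prior(rep(1 / 6, 6), comps)
  expect_equal(cp$variance, 3.3 / 6)
  expect_equal(cp$mean, 0.1)
  # direct arithmetic example
  cp2 <- collective_prior(c(0.912, 0.088),
                          list(list(mean = 0.2, variance = 3.52),
                               list(mean = -0.1, variance = 4)))
  expect_equal(cp2$mean, 0.912 * 0.2 + 0.088 * (-0.1))
  expect_equal(cp2$variance, 0.912^2 * 3.52 + 0.088^2 * 4)
  # invariance to component reordering
  set.seed(5)
  p <- synthesis_weights(runif(4), 0.05)
  comps <- lapply(1:4, function(i) list(mean = rnorm(1),
                                        variance = rexp(1) + 0.1))
  perm <- c(3, 1, 4, 2)
  expect_equal(collective_prior(p, comps)$variance,
               collective_prior(p[perm], comps[perm])$variance)
  expect_equal(collective_prior(p, comps)$mean,
               collective_prior(p[perm], comps[perm])$mean)
  expect_error(collective_prior(c(0.5, 0.4), comps[1:2]), "sum to 1")
})

test_that("commensurability matrix validation is strict", {
  w <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  expect_s3_class(commensurability_matrix(w), "commensurability_matrix")
  wa <- w; wa[1, 2] <- 0.3
  expect_error(commensurability_matrix(wa), "not symmetric.*w\\[1,2\\]")
  wd <- w; diag(wd) <- 0.1
  expect_error(commensurability_matrix(wd), "diagonal")
  wb <- matrix(c(0, 1.2, 1.2, 0), 2, 2)
  expect_error(commensurability_matrix(wb), "\\[0, 1\\]")
})
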
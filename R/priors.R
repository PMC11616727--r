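#' Two-component Gamma mixture prior on between-subtrial precision
#'
#' Constructs the mixture prior placed on the commensurate-prior precision
#' \eqn{\nu_{qk}}: with probability \eqn{w_{qk}} a Gamma(a1, b1) component
#' (density mass on small precisions, i.e. substantial discounting of the
#' complementary subtrial) and with probability \eqn{1 - w_{qk}} a
#' Gamma(a2, b2) component (large precisions, limited discounting). The
#' shape/rate parameterization is used throughout, so a component's mean is
#' shape/rate and its moment-matched variance contribution is
#' rate/(shape - 1).
#'
#' @param a1,b1 Shape and rate of the discounting component; `a1 > 1`.
#' @param a2,b2 Shape and rate of the borrowing component; `a2 > 1`.
#'
#' @return An object of class `gamma_mixture_prior`.
#'
#' @details Moment matching of the marginalized t mixture requires both
#'   shapes to exceed 1; inputs violating this are rejected. The first
#'   component is expected to imply the larger variance contribution
#'   (`b1/(a1-1) >= b2/(a2-1)`); if not, the components are kept as given and
#'   a warning reports the inversion rather than silently swapping them.
#'
#' @examples
#' gamma_mixture_prior(1.1, 1.1, 54, 3)
#' @export
gamma_mixture_prior <- function(a1 = 1.1, b1 = 1.1, a2 = 54, b2 = 3) {
  for (nm in c("a1", "b1", "a2", "b2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (a1 <= 1 || a2 <= 1)
    stop("moment matching of the marginal t mixture requires both Gamma ",
         "shapes > 1 (got a1 = ", a1, ", a2 = ", a2, ")", call. = FALSE)
  if (b1 <= 0 || b2 <= 0)
    stop("Gamma rates b1, b2 must be positive", call. = FALSE)
  if (b1 / (a1 - 1) < b2 / (a2 - 1))
    warning("component 1 implies a smaller variance contribution than ",
            "component 2 (b1/(a1-1) < b2/(a2-1)); the discounting and ",
            "borrowing roles of the two components appear inverted",
            call. = FALSE)
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2),
            class = "gamma_mixture_prior")
}

#' @export
print.gamma_mixture_prior <- function(x, ...) {
  cat("Gamma mixture precision prior\n")
  cat(sprintf("  component 1 (discounting): Gamma(%g, %g), mean %.3g, variance contribution %.4g\n",
              x$a1, x$b1, x$a1 / x$b1, x$b1 / (x$a1 - 1)))
  cat(sprintf("  component 2 (borrowing):   Gamma(%g, %g), mean %.3g, variance contribution %.4g\n",
              x$a2, x$b2, x$a2 / x$b2, x$b2 / (x$a2 - 1)))
  invisible(x)
}

#' Moment-matched variance of the marginal commensurate prior
#'
#' Integrating the precision out of the conditional commensurate prior leaves
#' a two-component t mixture centered at the complementary subtrial effect;
#' matching its first two moments gives a normal with variance
#' \deqn{w b_1/(a_1-1) + (1-w) b_2/(a_2-1).}
#'
#' @param w Incommensurability weight(s) in \[0, 1\]; vectorized.
#' @param prior A [gamma_mixture_prior()].
#'
#' @return Numeric vector of variances, linear and increasing in `w` when the
#'   discounting component dominates.
#' @examples
#' moment_matched_variance(c(0, 1), gamma_mixture_prior(1.1, 1.1, 54, 3))
#' @export
moment_matched_variance <- function(w, prior) {
  stopifnot(inherits(prior, "gamma_mixture_prior"))
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("incommensurability weights w must lie in [0, 1]", call. = FALSE)
  w * prior$b1 / (prior$a1 - 1) + (1 - w) * prior$b2 / (prior$a2 - 1)
}

#' Pairwise incommensurability matrix
#'
#' Validates a K x K matrix of pairwise incommensurability weights
#' \eqn{w_{qk}}: symmetric (the discrepancy between subtrials q and k does
#' not depend on orientation), zero diagonal, off-diagonal entries in
#' \[0, 1\]. Asymmetric input is an error, never repaired silently.
#'
#' @param w Numeric K x K matrix, `K >= 2`.
#' @return The matrix with class `commensurability_matrix`.
#' @export
commensurability_matrix <- function(w) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w) || nrow(w) < 2L)
    stop("w must be a square matrix with K >= 2 subtrials", call. = FALSE)
  if (any(!is.finite(w)))
    stop("w contains non-finite entries", call. = FALSE)
  asym <- which(abs(w - t(w)) > 1e-12, arr.ind = TRUE)
  if (nrow(asym) > 0L) {
    q <- asym[1, 1]; k <- asym[1, 2]
    stop(sprintf(
      "incommensurability matrix is not symmetric: w[%d,%d] = %g but w[%d,%d] = %g",
      q, k, w[q, k], k, q, w[k, q]), call. = FALSE)
  }
  if (any(abs(diag(w)) > 1e-12))
    stop("diagonal entries of w must be 0", call. = FALSE)
  diag(w) <- 0
  if (any(w < 0) || any(w > 1))
    stop("off-diagonal entries of w must lie in [0, 1]", call. = FALSE)
  structure(w, class = c("commensurability_matrix", "matrix"))
}

#' Synthesis weights from incommensurability weights
#'
#' Transforms the K-1 incommensurability weights for a target subtrial into
#' normalized synthesis weights
#' \deqn{p_{qk} = \exp(-w_{qk}^2/c_0) / \sum_q \exp(-w_{qk}^2/c_0),}
#' a decreasing function of \eqn{w_{qk}}: the most commensurate complementary
#' subtrial receives the largest share of the collective prior. As
#' \eqn{c_0 \to 0^+} the weights concentrate on the smallest w; equal w yield
#' equal weights regardless of `c0`.
#'
#' @param w_column Off-diagonal entries of column k of the
#'   incommensurability matrix (length K-1, values in \[0, 1\]).
#' @param c0 Concentration parameter, > 0. Should be substantially smaller
#'   than the typical magnitude of `w_column` to discriminate between
#'   complementary subtrials.
#' @return Numeric vector of weights summing to 1.
#' @examples
#' synthesis_weights(c(0.239, 0.417), c0 = 0.05)
#' @export
synthesis_weights <- function(w_column, c0 = 0.05) {
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0) || c0 <= 0)
    stop("concentration parameter c0 must be a positive finite number",
         call. = FALSE)
  if (any(!is.finite(w_column)) || any(w_column < 0) || any(w_column > 1))
    stop("incommensurability weights must lie in [0, 1]", call. = FALSE)
  # subtract the min exponent so c0 -> 0+ stays numerically stable
  e <- -(w_column^2) / c0
  e <- exp(e - max(e))
  e / sum(e)
}

#' Hellinger incommensurability between two normal outcome distributions
#'
#' Closed-form Hellinger distance between N(mu_q, sigma_q^2) and
#' N(mu_k, sigma_k^2), used to derive incommensurability weights from assumed
#' outcome distributions:
#' \deqn{w_{qk} = \left[1 - \sqrt{\frac{2\sigma_q\sigma_k}{\sigma_q^2+\sigma_k^2}}
#'   \exp\left(-\frac{(\mu_q-\mu_k)^2}{4(\sigma_q^2+\sigma_k^2)}\right)\right]^{1/2}.}
#' Symmetric, bounded in \[0, 1\], zero iff the distributions coincide.
#'
#' @param mu_q,sigma_q Mean and standard deviation of the first normal.
#' @param mu_k,sigma_k Mean and standard deviation of the second normal.
#' @return Hellinger distance in \[0, 1\]; vectorized.
#' @export
hellinger_weight <- function(mu_q, sigma_q, mu_k, sigma_k) {
  if (any(sigma_q <= 0) || any(sigma_k <= 0))
    stop("standard deviations must be positive", call. = FALSE)
  s2 <- sigma_q^2 + sigma_k^2
  aff <- sqrt(2 * sigma_q * sigma_k / s2) * exp(-(mu_q - mu_k)^2 / (4 * s2))
  sqrt(pmax(0, 1 - aff))
}

#' Hellinger-derived incommensurability matrix
#'
#' Builds the full K x K incommensurability matrix by applying
#' [hellinger_weight()] to every pair of assumed subtrial outcome
#' distributions (typically the experimental-arm distributions).
#'
#' @param mu Vector of K normal means.
#' @param sigma Vector of K normal standard deviations.
#' @return A [commensurability_matrix()].
#' @examples
#' hellinger_matrix(c(-0.489, 0.226), c(0.587, 0.345))
#' @export
hellinger_matrix <- function(mu, sigma) {
  K <- length(mu)
  if (length(sigma) != K)
    stop("mu and sigma must have the same length", call. = FALSE)
  w <- outer(seq_len(K), seq_len(K), function(q, k)
    hellinger_weight(mu[q], sigma[q], mu[k], sigma[k]))
  diag(w) <- 0
  commensurability_matrix(w)
}

#' Operational prior for a subtrial treatment effect
#'
#' The vague normal prior N(m0, s02) placed on a subtrial's own treatment
#' effect, used to form an interim ("operational") posterior from that
#' subtrial's data before it is discounted into a commensurate prior for the
#' others.
#'
#' @param m0 Prior mean (outcome units); default 0.
#' @param s02 Prior variance; default 100, effectively uninformative on the
#'   outcome scales considered here.
#' @return Object of class `operational_prior`.
#' @export
operational_prior <- function(m0 = 0, s02 = 100) {
  if (!is.finite(m0)) stop("m0 must be finite", call. = FALSE)
  if (!is.finite(s02) || s02 <= 0)
    stop("operational prior variance s02 must be positive", call. = FALSE)
  structure(list(m0 = m0, s02 = s02), class = "operational_prior")
}

#' Per-arm summary of one subtrial's data
#'
#' @param mean_E,mean_C Sample means in the experimental and control arm.
#' @param n Total subtrial sample size (may be the real-valued design size).
#' @param R Allocation probability to the experimental arm, in (0, 1).
#' @param sigma2 Known outcome variance.
#' @return Object of class `subtrial_summary`.
#' @export
subtrial_summary <- function(mean_E, mean_C, n, R, sigma2) {
  if (!is.finite(n) || n < 0) stop("n must be >= 0", call. = FALSE)
  if (!is.finite(R) || R <= 0 || R >= 1)
    stop("allocation probability R must lie strictly in (0, 1)", call. = FALSE)
  if (!is.finite(sigma2) || sigma2 <= 0)
    stop("outcome variance sigma2 must be positive", call. = FALSE)
  if (n > 0 && (!is.finite(mean_E) || !is.finite(mean_C)))
    stop("arm means must be finite when n > 0", call. = FALSE)
  structure(list(mean_E = mean_E, mean_C = mean_C, n = n, R = R,
                 sigma2 = sigma2),
            class = "subtrial_summary")
}

normal_summary <- function(mean, variance) {
  structure(list(mean = mean, variance = variance), class = "normal_summary")
}

#' Operational posterior for a subtrial treatment effect
#'
#' Conjugate normal update of the operational prior by the observed
#' difference in arm means, whose sampling distribution is
#' N(theta, sigma2 / (n R (1-R))):
#' posterior variance \eqn{(1/s_0^2 + nR(1-R)/\sigma^2)^{-1}} and mean
#' \deqn{\lambda = \frac{m_0}{1 + (s_0^2/\sigma^2)\, nR(1-R)}
#'   + \frac{\bar{x}_E - \bar{x}_C}{1 + (\sigma^2/s_0^2)/(nR(1-R))}.}
#' With `n = 0` the prior is returned unchanged.
#'
#' @param prior An [operational_prior()].
#' @param data A [subtrial_summary()].
#' @return A `normal_summary` with elements `mean` and `variance`.
#' @export
operational_posterior <- function(prior, data) {
  stopifnot(inherits(prior, "operational_prior"),
            inherits(data, "subtrial_summary"))
  if (data$n == 0)
    return(normal_summary(prior$m0, prior$s02))
  eff <- data$n * data$R * (1 - data$R) # effective sample size of the mean difference
  v <- 1 / (1 / prior$s02 + eff / data$sigma2)
  lambda <- prior$m0 / (1 + prior$s02 / data$sigma2 * eff) +
    (data$mean_E - data$mean_C) / (1 + (data$sigma2 / prior$s02) / eff)
  normal_summary(lambda, v)
}

#' Commensurate prior from one complementary subtrial
#'
#' Centers a prior for the target subtrial's effect at the complementary
#' subtrial's operational posterior mean and inflates its variance by the
#' moment-matched mixture variance, so the prior discounts the complementary
#' information according to the pairwise incommensurability w:
#' \eqn{\xi_{qk}^2 = \mathrm{Var}(\theta_q \mid x_q) + w b_1/(a_1-1) + (1-w) b_2/(a_2-1)}.
#'
#' @param source_posterior `normal_summary` from [operational_posterior()]
#'   applied to the complementary subtrial q.
#' @param w Incommensurability weight between the two subtrials.
#' @param prior A [gamma_mixture_prior()].
#' @return A `normal_summary` with mean \eqn{\lambda_q} and variance
#'   \eqn{\xi_{qk}^2} (always exceeding the source posterior variance).
#' @export
commensurate_prior <- function(source_posterior, w, prior) {
  stopifnot(inherits(source_posterior, "normal_summary"))
  normal_summary(source_posterior$mean,
                 source_posterior$variance + moment_matched_variance(w, prior))
}

#' Collective commensurate prior from all complementary subtrials
#'
#' Convolution of the K-1 single-source commensurate priors, scaled by the
#' synthesis weights: a normal prior with mean \eqn{\sum_q p_{qk}\lambda_q}
#' and variance \eqn{\sum_q p_{qk}^2 \xi_{qk}^2}.
#'
#' @param p Synthesis weights (must sum to 1 within 1e-10).
#' @param components List of `normal_summary` objects, one per complementary
#'   subtrial, aligned with `p`.
#' @return Object of class `collective_prior` with fields `p`,
#'   `component_means`, `component_variances`, `mean`, `variance`.
#' @export
collective_prior <- function(p, components) {
  if (length(p) != length(components))
    stop("p and components must have the same length", call. = FALSE)
  if (any(p < 0) || any(p > 1))
    stop("synthesis weights must lie in [0, 1]", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-10)
    stop("synthesis weights must sum to 1 (got ", format(sum(p), digits = 12),
         ")", call. = FALSE)
  mu <- vapply(components, function(x) x$mean, numeric(1))
  v <- vapply(components, function(x) x$variance, numeric(1))
  if (any(v <= 0)) stop("component variances must be positive", call. = FALSE)
  structure(list(p = p, component_means = mu, component_variances = v,
                 mean = sum(p * mu), variance = sum(p^2 * v)),
            class = "collective_prior")
}

#' @export
print.collective_prior <- function(x, ...) {
  cat(sprintf("Collective commensurate prior: N(%.4g, %.4g) from %d complementary subtrials\n",
              x$mean, x$variance, length(x$p)))
  cat("  synthesis weights:", paste(sprintf("%.3f", x$p), collapse = ", "), "\n")
  invisible(x)
}
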
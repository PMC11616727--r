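#' Posterior for a subtrial effect under borrowing
#'
#' Updates the collective commensurate prior with the subtrial's own data.
#' Posterior variance \eqn{(1/\mathrm{Var}_{prior} + nR(1-R)/\sigma^2)^{-1}}
#' and mean
#' \deqn{d_\theta = \frac{\sigma^2/(nR(1-R)) \cdot \mathrm{E}_{prior} +
#'   (\bar{x}_E-\bar{x}_C) \cdot \mathrm{Var}_{prior}}
#'   {\mathrm{Var}_{prior} + \sigma^2/(nR(1-R))},}
#' a convex combination of the prior mean and the observed mean difference.
#'
#' @param prior A [collective_prior()] (any object with `mean` and
#'   `variance` elements is accepted).
#' @param data A [subtrial_summary()] with `n > 0`.
#' @return Object of class `posterior_summary` with elements `mean` and
#'   `variance`.
#' @export
posterior_with_borrowing <- function(prior, data) {
  stopifnot(inherits(data, "subtrial_summary"))
  if (data$n <= 0)
    stop("analysis requires contemporary subtrial data (n > 0)",
         call. = FALSE)
  if (!is.numeric(prior$mean) || !is.numeric(prior$variance) ||
      prior$variance <= 0)
    stop("prior must carry a finite mean and positive variance",
         call. = FALSE)
  s2n <- data$sigma2 / (data$n * data$R * (1 - data$R))
  d <- (s2n * prior$mean + (data$mean_E - data$mean_C) * prior$variance) /
    (prior$variance + s2n)
  v <- 1 / (1 / prior$variance + 1 / s2n)
  structure(list(mean = d, variance = v),
            class = c("posterior_summary", "normal_summary"))
}

#' Stand-alone posterior for a subtrial effect (no borrowing)
#'
#' The subtrial's own data updating its operational prior only; identical
#' mathematics to [operational_posterior()], returned as a
#' `posterior_summary` for use with [decide()]. This is the true
#' no-borrowing analysis model.
#'
#' @param prior An [operational_prior()].
#' @param data A [subtrial_summary()] with `n > 0`.
#' @return Object of class `posterior_summary`.
#' @export
posterior_standalone <- function(prior, data) {
  stopifnot(inherits(prior, "operational_prior"),
            inherits(data, "subtrial_summary"))
  if (data$n <= 0)
    stop("analysis requires contemporary subtrial data (n > 0)",
         call. = FALSE)
  post <- operational_posterior(prior, data)
  structure(list(mean = post$mean, variance = post$variance),
            class = c("posterior_summary", "normal_summary"))
}

# Tail probabilities on the beneficial / non-beneficial side of 0 and delta.
# For delta > 0: P(theta > 0) and P(theta <= delta).
# For delta < 0 everything is mirrored: P(theta < 0) and P(theta >= delta).
posterior_tail_probs <- function(mean, variance, delta) {
  sd <- sqrt(variance)
  if (delta > 0) {
    list(prob_efficacy = stats::pnorm(mean / sd),
         prob_futility = stats::pnorm((delta - mean) / sd))
  } else {
    list(prob_efficacy = stats::pnorm(-mean / sd),
         prob_futility = stats::pnorm((mean - delta) / sd))
  }
}

#' Efficacy/futility decision from a posterior
#'
#' Applies the posterior decision rules. For delta > 0 the treatment is
#' declared efficacious if \eqn{P(\theta > 0 \mid data) \ge \eta} and futile
#' if \eqn{P(\theta \le \delta \mid data) \ge \zeta}; for delta < 0 (lower
#' outcomes beneficial) the rules are mirrored, implemented by negating the
#' posterior mean and delta and reusing the positive-delta rule. When the
#' posterior precision meets the design target the two declarations are
#' mutually exclusive; otherwise the result may be inconclusive.
#'
#' @param post A `posterior_summary` (or any list with `mean`, `variance`).
#' @param delta Clinically relevant difference (nonzero).
#' @param eta,zeta Probability thresholds.
#' @param bonferroni If `TRUE`, the efficacy threshold is sharpened to
#'   `1 - (1 - eta)/K` for strong familywise control across the K subtrials.
#' @param K Number of subtrials, used only for the Bonferroni adjustment.
#' @return Object of class `basket_decision`: `decision` (one of
#'   `"efficacious"`, `"futile"`, `"inconclusive"`), the two posterior
#'   probabilities, and the thresholds used.
#' @examples
#' post <- structure(list(mean = 1, variance = 0.25), class = "posterior_summary")
#' decide(post, delta = 2.3, eta = 0.95, zeta = 0.80)
#' @export
decide <- function(post, delta, eta, zeta, bonferroni = FALSE, K = 1L) {
  if (length(delta) != 1L || delta == 0)
    stop("delta must be a single nonzero number", call. = FALSE)
  if (bonferroni) eta <- 1 - (1 - eta) / K
  pr <- posterior_tail_probs(post$mean, post$variance, delta)
  decision <- if (pr$prob_efficacy >= eta) "efficacious"
  else if (pr$prob_futility >= zeta) "futile"
  else "inconclusive"
  structure(list(decision = decision,
                 prob_efficacy = pr$prob_efficacy,
                 prob_futility = pr$prob_futility,
                 eta = eta, zeta = zeta, delta = delta),
            class = "basket_decision")
}

#' @export
print.basket_decision <- function(x, ...) {
  cat(sprintf("Decision: %s  [P(efficacy side) = %.4f vs eta = %g; P(futility side) = %.4f vs zeta = %g]\n",
              x$decision, x$prob_efficacy, x$eta, x$prob_futility, x$zeta))
  invisible(x)
}

#' Analyze one realized basket trial under both models
#'
#' Convenience wrapper: given per-subtrial data summaries and the design,
#' builds each subtrial's collective commensurate prior from the observed
#' complementary data (operational posteriors with the design's operational
#' priors, synthesis weights and mixture variances fixed at their design
#' values), computes the borrowing and/or stand-alone posteriors, and
#' applies the decision rules.
#'
#' @param data List of K [subtrial_summary()] objects (or a data.frame with
#'   columns `mean_E`, `mean_C`, `n`, `R`, `sigma2`).
#' @param design A [basket_design()].
#' @param models Character vector, subset of `c("borrowing", "standalone")`.
#' @return A data.frame with one row per subtrial x model: posterior mean
#'   and variance, the two posterior probabilities, and the decision.
#' @export
analyze_basket <- function(data, design, models = c("borrowing", "standalone")) {
  stopifnot(inherits(design, "basket_design"))
  models <- match.arg(models, c("borrowing", "standalone"), several.ok = TRUE)
  if (is.data.frame(data))
    data <- lapply(seq_len(nrow(data)), function(i)
      subtrial_summary(data$mean_E[i], data$mean_C[i], data$n[i],
                       data$R[i], data$sigma2[i]))
  if (length(data) != design$K)
    stop("need one data summary per subtrial", call. = FALSE)
  op <- lapply(seq_len(design$K), function(q)
    operational_posterior(operational_prior(design$m0[q], design$s02[q]),
                          data[[q]]))
  P <- design_synthesis_weights(design)
  out <- list()
  for (k in seq_len(design$K)) {
    posts <- list()
    if ("borrowing" %in% models) {
      comp <- lapply(seq_len(design$K)[-k], function(q)
        commensurate_prior(op[[q]], design$w[q, k], design$mixture))
      cp <- collective_prior(P[-k, k], comp)
      posts$borrowing <- posterior_with_borrowing(cp, data[[k]])
    }
    if ("standalone" %in% models)
      posts$standalone <- posterior_standalone(
        operational_prior(design$m0[k], design$s02[k]), data[[k]])
    for (m in names(posts)) {
      dec <- decide(posts[[m]], design$delta[k], design$eta, design$zeta[k])
      out[[length(out) + 1L]] <- data.frame(
        subtrial = k, model = m, d = posts[[m]]$mean,
        sigma_theta2 = posts[[m]]$variance,
        prob_efficacy = dec$prob_efficacy,
        prob_futility = dec$prob_futility,
        decision = dec$decision)
    }
  }
  do.call(rbind, out)
}
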
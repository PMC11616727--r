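#' Scenario specification for simulating basket trials
#'
#' Describes the truth under which replicate trials are generated: per-arm
#' normal outcome means and common within-subtrial variance, the subtrial
#' sizes at which the trial is run (the solver's real-valued design sizes
#' may be passed directly; see Details), allocation probabilities, and the
#' incommensurability matrix (derived from the experimental-arm outcome
#' distributions via the Hellinger distance when not given).
#'
#' @details Patient-level outcomes are drawn for whole patients: the
#'   experimental arm enrolls `floor(n * R)` patients and the control arm
#'   `floor(n * (1 - R))`. The analysis model, however, evaluates posterior
#'   precisions at the nominal design size `n` — the quantity the design
#'   constraints were solved for — so fractional design sizes are honoured
#'   in the analysis exactly as planned.
#'
#' @param mu_E,mu_C True arm means (length K; `mu_C` recycled).
#' @param sigma2 True outcome variances (length K or scalar).
#' @param n Subtrial total sizes, real-valued allowed, each >= 1.
#' @param R Allocation probabilities (scalar or length K).
#' @param w Optional incommensurability matrix; if `NULL`, computed as the
#'   pairwise Hellinger distance between the `N(mu_E, sigma2)` distributions.
#' @param labels Optional subtrial labels.
#' @return Object of class `scenario_spec`.
#' @examples
#' scenario_spec(mu_E = rep(-0.4, 7), mu_C = 0, sigma2 = 0.3, n = rep(8.9, 7))
#' @export
scenario_spec <- function(mu_E, mu_C = 0, sigma2, n, R = 0.5, w = NULL,
                          labels = NULL) {
  K <- length(mu_E)
  if (K < 2L) stop("a scenario needs K >= 2 subtrials", call. = FALSE)
  rec <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, K)
    if (length(x) != K)
      stop("`", nm, "` must be a scalar or length-K vector", call. = FALSE)
    x
  }
  mu_C <- rec(mu_C, "mu_C"); sigma2 <- rec(sigma2, "sigma2")
  n <- rec(n, "n"); R <- rec(R, "R")
  if (any(sigma2 <= 0)) stop("true variances must be positive", call. = FALSE)
  if (any(n < 1)) stop("subtrial sizes must be >= 1", call. = FALSE)
  if (any(R <= 0) || any(R >= 1))
    stop("allocation probabilities R must lie strictly in (0, 1)",
         call. = FALSE)
  if (is.null(w)) w <- hellinger_matrix(mu_E, sqrt(sigma2))
  else w <- commensurability_matrix(w)
  if (nrow(w) != K)
    stop("incommensurability matrix dimension does not match K", call. = FALSE)
  if (is.null(labels)) labels <- paste0("subtrial_", seq_len(K))
  nE <- floor(n * R + 1e-9)
  nC <- floor(n * (1 - R) + 1e-9)
  if (any(nE < 1) || any(nC < 1))
    stop("every arm must enroll at least one patient; subtrial size(s) ",
         "too small for the allocation probabilities", call. = FALSE)
  structure(list(K = K, mu_E = mu_E, mu_C = mu_C, sigma2 = sigma2,
                 n = n, n_E = nE, n_C = nC, R = R, w = w,
                 theta = mu_E - mu_C, labels = labels),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Basket trial scenario: K = %d subtrials\n", x$K))
  print(data.frame(subtrial = x$labels, theta = x$theta, sigma2 = x$sigma2,
                   n = x$n, n_E = x$n_E, n_C = x$n_C, R = x$R),
        row.names = FALSE)
  invisible(x)
}

# Draw `reps` replicates of per-arm sample means; K x reps matrices.
# Subtrial by subtrial, experimental arm before control, so that a single
# replicate and a batch share the same stream layout.
simulate_summaries <- function(scenario, reps) {
  K <- scenario$K
  mE <- matrix(0, K, reps)
  mC <- matrix(0, K, reps)
  for (k in seq_len(K)) {
    sd_k <- sqrt(scenario$sigma2[k])
    mE[k, ] <- colMeans(matrix(
      stats::rnorm(scenario$n_E[k] * reps, scenario$mu_E[k], sd_k),
      scenario$n_E[k], reps))
    mC[k, ] <- colMeans(matrix(
      stats::rnorm(scenario$n_C[k] * reps, scenario$mu_C[k], sd_k),
      scenario$n_C[k], reps))
  }
  list(mean_E = mE, mean_C = mC)
}

#' Simulate one replicate basket trial
#'
#' Draws whole-patient normal outcomes per arm (see [scenario_spec()] for
#' the enrollment policy) and returns the per-subtrial summaries carrying
#' the nominal design size for analysis.
#'
#' @param scenario A [scenario_spec()].
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame with columns `subtrial`, `mean_E`, `mean_C`, `n`,
#'   `R`, `sigma2`, directly usable by [analyze_basket()].
#' @export
simulate_trial <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  s <- simulate_summaries(scenario, 1L)
  data.frame(subtrial = seq_len(scenario$K),
             mean_E = s$mean_E[, 1], mean_C = s$mean_C[, 1],
             n = scenario$n, R = scenario$R, sigma2 = scenario$sigma2)
}

#' Operating characteristics of a basket trial design
#'
#' Simulates replicate basket trials under a scenario, analyzes each with
#' the borrowing and/or stand-alone Bayesian models at the design's
#' thresholds, and summarizes per-subtrial rates of efficacy, futility and
#' inconclusive declarations together with the overall (familywise) false
#' positive rate — the fraction of replicates declaring efficacy in at
#' least one subtrial whose true effect is zero.
#'
#' The analysis is the closed-form normal machinery of [analyze_basket()]
#' vectorized across replicates: operational posteriors for each subtrial,
#' collective commensurate priors with synthesis weights and mixture
#' variances fixed at their design values, conjugate updates, and the
#' delta-signed decision rules.
#'
#' @param scenario A [scenario_spec()].
#' @param design A [basket_design()] with the same K.
#' @param reps Number of replicate trials.
#' @param seed Integer seed (recorded in the output).
#' @param models Subset of `c("borrowing", "standalone")`.
#' @param bonferroni If `TRUE`, Bonferroni-sharpen the efficacy threshold
#'   across the K subtrials.
#' @return Object of class `operating_characteristics`: `$rates` (one row
#'   per subtrial x model with the three rates and Monte Carlo standard
#'   errors), `$overall_fpr` (named per model; `NA` when the scenario has no
#'   null subtrials), `$reps`, `$seed`.
#' @examples
#' sc <- scenario_spec(mu_E = rep(0, 3), mu_C = 0, sigma2 = 1, n = rep(40, 3))
#' d <- basket_design(sigma2 = rep(1, 3), delta = 0.8, eta = 0.95, zeta = 0.8)
#' operating_characteristics(sc, d, reps = 200, seed = 1)
#' @export
operating_characteristics <- function(scenario, design, reps = 1e4,
                                      seed = NULL,
                                      models = c("borrowing", "standalone"),
                                      bonferroni = FALSE) {
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(design, "basket_design"))
  if (scenario$K != design$K)
    stop("scenario and design disagree on the number of subtrials",
         call. = FALSE)
  models <- match.arg(models, c("borrowing", "standalone"),
                      several.ok = TRUE)
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  K <- scenario$K
  s <- simulate_summaries(scenario, reps)
  xd <- s$mean_E - s$mean_C # K x reps observed mean differences
  eta <- if (bonferroni) 1 - (1 - design$eta) / K else design$eta

  # operational posteriors at the nominal design sizes (analysis model
  # assumes the planned allocation n R (1-R) and the known variances)
  eff_n <- scenario$n * scenario$R * (1 - scenario$R)
  v_op <- 1 / (1 / design$s02 + eff_n / scenario$sigma2)
  lam <- design$m0 / (1 + design$s02 / scenario$sigma2 * eff_n) +
    xd / (1 + (scenario$sigma2 / design$s02) / eff_n)

  decision_rates <- function(d_mat, v_vec) {
    eff <- fut <- matrix(FALSE, K, reps)
    for (k in seq_len(K)) {
      pr <- posterior_tail_probs(d_mat[k, ], v_vec[k], design$delta[k])
      eff[k, ] <- pr$prob_efficacy >= eta
      fut[k, ] <- !eff[k, ] & pr$prob_futility >= design$zeta[k]
    }
    list(eff = eff, fut = fut)
  }

  rates <- list(); fpr <- c(); fpr_se <- c()
  nulls <- which(scenario$theta == 0)
  for (m in models) {
    if (m == "borrowing") {
      P <- design_synthesis_weights(design)
      M <- moment_matched_variance(design$w, design$mixture)
      xi2 <- outer(v_op, rep(1, K)) + M        # xi2[q, k]
      pv_prior <- vapply(seq_len(K), function(k)
        sum(P[-k, k]^2 * xi2[-k, k]), numeric(1))
      pm_prior <- crossprod(P, lam)            # K x reps: sum_q p_qk lam_q
      s2n <- scenario$sigma2 / eff_n
      d <- (s2n * pm_prior + xd * pv_prior) / (pv_prior + s2n)
      v_post <- 1 / (1 / pv_prior + 1 / s2n)
    } else {
      d <- lam
      v_post <- v_op
    }
    dec <- decision_rates(d, v_post)
    r_eff <- rowMeans(dec$eff); r_fut <- rowMeans(dec$fut)
    rates[[m]] <- data.frame(
      subtrial = seq_len(K), model = m, theta_true = scenario$theta,
      n = scenario$n,
      rate_efficacy = r_eff, rate_futility = r_fut,
      rate_inconclusive = 1 - r_eff - r_fut,
      se_efficacy = sqrt(r_eff * (1 - r_eff) / reps),
      se_futility = sqrt(r_fut * (1 - r_fut) / reps))
    if (length(nulls) > 0L) {
      p <- mean(colSums(dec$eff[nulls, , drop = FALSE]) > 0)
      fpr[m] <- p
      fpr_se[m] <- sqrt(p * (1 - p) / reps)
    } else {
      fpr[m] <- NA_real_; fpr_se[m] <- NA_real_
    }
  }
  structure(list(rates = do.call(rbind, rates), overall_fpr = fpr,
                 overall_fpr_se = fpr_se, reps = reps, seed = seed,
                 models = models, bonferroni = bonferroni),
            class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf("Operating characteristics over %d replicates (seed %s)\n",
              x$reps, if (is.null(x$seed)) "none" else x$seed))
  print(x$rates, row.names = FALSE, digits = 4)
  for (m in x$models)
    if (!is.na(x$overall_fpr[m]))
      cat(sprintf("  overall false positive rate (%s): %.4f (MC SE %.4f)\n",
                  m, x$overall_fpr[m], x$overall_fpr_se[m]))
  invisible(x)
}

#' @export
plot.operating_characteristics <- function(x, ...) {
  r <- x$rates
  models <- unique(r$model)
  op <- graphics::par(mfrow = c(1, length(models)))
  on.exit(graphics::par(op))
  for (m in models) {
    rm_ <- r[r$model == m, ]
    graphics::barplot(t(as.matrix(rm_[, c("rate_efficacy", "rate_futility",
                                          "rate_inconclusive")])),
                      names.arg = rm_$subtrial, col = c("#2b8cbe", "#e34a33",
                                                        "grey80"),
                      main = m, xlab = "subtrial", ylab = "rate",
                      legend.text = c("efficacy", "futility", "inconclusive"),
                      args.legend = list(x = "topright", bty = "n",
                                         cex = 0.7), ...)
  }
  invisible(x)
}
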
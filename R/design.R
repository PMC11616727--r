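#' Declarative design configuration for a randomized basket trial
#'
#' Collects everything needed to solve for the subtrial sample sizes: the
#' clinically relevant difference delta (negative when lower outcomes mean
#' benefit), the posterior probability thresholds eta (efficacy) and zeta
#' (futility), per-subtrial allocation probabilities, known outcome
#' variances, operational priors, the pairwise incommensurability matrix
#' with its concentration parameter c0, and the Gamma mixture precision
#' prior. Scalars are broadcast across the K subtrials; delta and zeta may
#' be per-subtrial vectors.
#'
#' @param sigma2 Vector of K known outcome variances (K >= 2).
#' @param delta Clinically relevant difference(s); nonzero, scalar or
#'   length-K.
#' @param eta Efficacy threshold in (0.5, 1).
#' @param zeta Futility threshold(s) in (0.5, 1); scalar or length-K.
#' @param R Allocation probabilities in (0, 1); scalar or length-K.
#' @param w Incommensurability matrix (K x K, see
#'   [commensurability_matrix()]); defaults to all zero off-diagonals
#'   (perfect commensurability).
#' @param s02,m0 Operational prior variance(s) and mean(s); scalar or
#'   length-K.
#' @param c0 Concentration parameter for the synthesis weights.
#' @param mixture A [gamma_mixture_prior()].
#'
#' @return Object of class `basket_design`.
#' @examples
#' oacs <- basket_design(
#'   sigma2 = c(6.177, 5.134, 5.134), delta = 2.3, eta = 0.95,
#'   zeta = c(0.90, 0.80, 0.80), R = c(0.5, 0.6, 0.6),
#'   w = matrix(c(0, 0.239, 0.417, 0.239, 0, 0.145, 0.417, 0.145, 0), 3, 3))
#' @export
basket_design <- function(sigma2, delta, eta, zeta, R = 0.5, w = NULL,
                          s02 = 100, m0 = 0, c0 = 0.05,
                          mixture = gamma_mixture_prior(1.1, 1.1, 54, 3)) {
  K <- length(sigma2)
  if (K < 2L) stop("a basket design needs K >= 2 subtrials", call. = FALSE)
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0))
    stop("outcome variances sigma2 must be positive", call. = FALSE)
  bc <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, K)
    if (length(x) != K)
      stop("`", nm, "` must be a scalar or length-K vector", call. = FALSE)
    x
  }
  delta <- bc(delta, "delta"); zeta <- bc(zeta, "zeta")
  R <- bc(R, "R"); s02 <- bc(s02, "s02"); m0 <- bc(m0, "m0")
  if (any(delta == 0)) stop("delta must be nonzero", call. = FALSE)
  if (length(unique(sign(delta))) > 1L)
    stop("all elements of delta must share one sign", call. = FALSE)
  if (!is.finite(eta) || eta <= 0.5 || eta >= 1)
    stop("efficacy threshold eta must lie in (0.5, 1)", call. = FALSE)
  if (any(zeta <= 0.5) || any(zeta >= 1))
    stop("futility thresholds zeta must lie in (0.5, 1)", call. = FALSE)
  if (any(R <= 0) || any(R >= 1))
    stop("allocation probabilities R must lie strictly in (0, 1)",
         call. = FALSE)
  if (any(s02 <= 0)) stop("s02 must be positive", call. = FALSE)
  if (is.null(w)) w <- matrix(0, K, K)
  w <- commensurability_matrix(w)
  if (nrow(w) != K)
    stop("incommensurability matrix dimension (", nrow(w),
         ") does not match length(sigma2) = ", K, call. = FALSE)
  if (!is.finite(c0) || c0 <= 0) stop("c0 must be positive", call. = FALSE)
  off <- w[upper.tri(w)]
  if (any(off > 0) && c0 >= min(off[off > 0]))
    warning("c0 = ", c0, " is not substantially smaller than the smallest ",
            "positive incommensurability weight (", min(off[off > 0]),
            "); synthesis weights will barely discriminate between ",
            "complementary subtrials", call. = FALSE)
  stopifnot(inherits(mixture, "gamma_mixture_prior"))
  structure(list(K = K, sigma2 = sigma2, delta = delta, eta = eta,
                 zeta = zeta, R = R, s02 = s02, m0 = m0, c0 = c0,
                 w = w, mixture = mixture),
            class = "basket_design")
}

#' @export
print.basket_design <- function(x, ...) {
  cat(sprintf("Basket trial design: K = %d subtrials\n", x$K))
  cat(sprintf("  delta = %s, eta = %g, zeta = %s\n",
              paste(unique(x$delta), collapse = "/"), x$eta,
              paste(x$zeta, collapse = ", ")))
  cat(sprintf("  R = %s, sigma2 = %s\n", paste(x$R, collapse = ", "),
              paste(signif(x$sigma2, 4), collapse = ", ")))
  cat(sprintf("  c0 = %g, mean off-diagonal w = %.3f\n", x$c0,
              mean(x$w[upper.tri(x$w)])))
  invisible(x)
}

# K x K matrix of synthesis weights; column k holds p_{qk} with zero diagonal
design_synthesis_weights <- function(design) {
  K <- design$K
  P <- matrix(0, K, K)
  for (k in seq_len(K)) P[-k, k] <- synthesis_weights(design$w[-k, k], design$c0)
  P
}

#' Target posterior precision for a decisive conclusion
#'
#' For the efficacy and futility rules to be simultaneously satisfiable the
#' posterior standard deviation must satisfy
#' \eqn{|\delta|/\sigma_\theta \ge z_\eta + z_\zeta}, i.e. the posterior
#' precision must reach \eqn{((z_\eta + z_\zeta)/\delta)^2}. The sign of
#' delta is immaterial here; it only reorients the decision rules.
#'
#' @param delta Clinically relevant difference (nonzero).
#' @param eta,zeta Probability thresholds in (0, 1).
#' @return The required posterior precision; vectorized over all arguments.
#' @export
precision_target <- function(delta, eta, zeta) {
  if (any(delta == 0)) stop("delta must be nonzero", call. = FALSE)
  ((stats::qnorm(eta) + stats::qnorm(zeta)) / abs(delta))^2
}

sample_size_result <- function(design, n_real, achieved, target, mode,
                               converged = TRUE, iterations = 0L,
                               solver = NA_character_) {
  structure(list(K = design$K, n_real = n_real, n_int = ceiling(n_real),
                 achieved_precision = achieved, target_precision = target,
                 mode = mode, converged = converged,
                 iterations = iterations, solver = solver,
                 design = design),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf("Subtrial sample sizes (%s)%s\n",
              gsub("_", " ", x$mode),
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(as.data.frame(x), row.names = FALSE, digits = 6)
  cat(sprintf("  total: %.1f patients\n", sum(x$n_real)))
  invisible(x)
}

#' @export
as.data.frame.sample_size_result <- function(x, ...) {
  data.frame(subtrial = seq_len(x$K), mode = x$mode,
             n_real = round(x$n_real, 4), n_int = x$n_int,
             achieved_precision = x$achieved_precision,
             target_precision = x$target_precision)
}

#' Subtrial sample sizes without borrowing
#'
#' Closed-form sizes when each subtrial is analyzed on its own with its
#' operational prior: the posterior precision is
#' \eqn{1/s_{0k}^2 + n_k R_k(1-R_k)/\sigma_k^2}, so
#' \deqn{n_k^0 = \frac{\sigma_k^2}{R_k(1-R_k)}
#'   \left[\left(\frac{z_\eta+z_\zeta}{\delta}\right)^2 - \frac{1}{s_{0k}^2}\right],}
#' independently across subtrials. A size is clamped at 0 (with a warning)
#' when the prior alone already meets the precision target.
#'
#' @param design A [basket_design()].
#' @return A `sample_size_result` with mode `"no_borrowing"`.
#' @export
sample_size_no_borrowing <- function(design) {
  stopifnot(inherits(design, "basket_design"))
  target <- precision_target(design$delta, design$eta, design$zeta)
  n0 <- design$sigma2 / (design$R * (1 - design$R)) * (target - 1 / design$s02)
  if (any(n0 <= 0)) {
    warning("operational prior precision alone meets the target for ",
            "subtrial(s) ", paste(which(n0 <= 0), collapse = ", "),
            "; sample size clamped at 0 - such a subtrial cannot ",
            "meaningfully be run", call. = FALSE)
    n0 <- pmax(n0, 0)
  }
  achieved <- 1 / design$s02 + n0 * design$R * (1 - design$R) / design$sigma2
  sample_size_result(design, n0, achieved, target, "no_borrowing",
                     solver = "closed_form")
}

#' Posterior-precision constraint under borrowing
#'
#' Left-hand side of the design constraint for subtrial k at candidate sizes
#' `n`: the data precision plus the collective-prior precision,
#' \deqn{\frac{n_k R_k(1-R_k)}{\sigma_k^2} + \left[\sum_{q\ne k} p_{qk}^2
#'   \left(\left(\frac{1}{s_{0q}^2}+\frac{n_q R_q(1-R_q)}{\sigma_q^2}\right)^{-1}
#'   + \frac{w_{qk}b_1}{a_1-1}+\frac{(1-w_{qk})b_2}{a_2-1}\right)\right]^{-1},}
#' strictly increasing in every element of `n`.
#'
#' @param n Candidate K-vector of (real-valued) sample sizes, >= 0.
#' @param design A [basket_design()].
#' @param k Subtrial index.
#' @return The achieved posterior precision for subtrial k.
#' @export
borrowing_constraint_lhs <- function(n, design, k) {
  stopifnot(inherits(design, "basket_design"))
  if (length(n) != design$K || any(n < 0))
    stop("n must be a nonnegative vector of length K", call. = FALSE)
  if (length(k) != 1L || !(k %in% seq_len(design$K)))
    stop("k must be a single subtrial index in 1..K", call. = FALSE)
  P <- design_synthesis_weights(design)
  A <- design$R * (1 - design$R) / design$sigma2
  v <- 1 / (1 / design$s02 + n * A)
  M <- moment_matched_variance(design$w[-k, k], design$mixture)
  n[k] * A[k] + 1 / sum(P[-k, k]^2 * (v[-k] + M))
}

#' Simultaneous subtrial sample sizes under borrowing
#'
#' Solves the K coupled constraints
#' `borrowing_constraint_lhs(n, design, k) = precision_target_k` as a system
#' of nonlinear equations (equalities give the minimal sizes meeting the
#' design inequalities). Newton's method with the analytic Jacobian is
#' started at the no-borrowing solution, a feasible upper starting point;
#' steps are halved whenever an iterate turns negative or fails to reduce
#' the residual norm, and a damped fixed-point iteration
#' \eqn{n_k \leftarrow \sigma_k^2/(R_k(1-R_k)) [T_k - 1/\sum_q p_{qk}^2 \xi_{qk}^2(n_q)]}
#' serves as fallback if Newton stalls.
#'
#' @param design A [basket_design()].
#' @param tol Maximum absolute constraint residual accepted at the solution.
#' @param max_iter Iteration cap (per solver) before failure is reported.
#' @param jacobian `"analytic"` (closed-form partial derivatives, default)
#'   or `"numeric"` (central finite differences, for debugging).
#' @return A `sample_size_result` with mode `"borrowing"`; each `n_real` is
#'   no larger than its no-borrowing counterpart whenever any borrowing is
#'   possible.
#' @examples
#' d <- basket_design(sigma2 = rep(0.3, 7), delta = -0.4, eta = 0.95,
#'                    zeta = 0.80)
#' solve_sample_sizes(d)$n_real
#' @export
solve_sample_sizes <- function(design, tol = 1e-8, max_iter = 500L,
                               jacobian = c("analytic", "numeric")) {
  stopifnot(inherits(design, "basket_design"))
  jacobian <- match.arg(jacobian)
  K <- design$K
  target <- precision_target(design$delta, design$eta, design$zeta)
  A <- design$R * (1 - design$R) / design$sigma2
  P <- design_synthesis_weights(design)
  M <- moment_matched_variance(design$w, design$mixture) # K x K, diag unused
  Ssum <- function(n) {
    v <- 1 / (1 / design$s02 + n * A)
    vapply(seq_len(K),
           function(k) sum(P[-k, k]^2 * (v[-k] + M[-k, k])), numeric(1))
  }
  Fres <- function(n) n * A + 1 / Ssum(n) - target
  Jac <- function(n) {
    v <- 1 / (1 / design$s02 + n * A)
    S <- Ssum(n)
    J <- diag(A, K)
    for (k in seq_len(K))
      for (q in seq_len(K)[-k])
        J[k, q] <- P[q, k]^2 * A[q] * v[q]^2 / S[k]^2
    J
  }
  JacNum <- function(n) {
    h <- pmax(1e-6, 1e-6 * n)
    J <- matrix(0, K, K)
    for (q in seq_len(K)) {
      e <- replace(numeric(K), q, h[q])
      J[, q] <- (Fres(pmax(n + e, 0)) - Fres(pmax(n - e, 0))) / (2 * h[q])
    }
    J
  }
  n <- pmax(design$sigma2 / (design$R * (1 - design$R)) *
              (target - 1 / design$s02), 0)
  res <- Fres(n)
  iter <- 0L
  converged <- FALSE
  solver <- "newton"
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- if (jacobian == "analytic") Jac(n) else JacNum(n)
    step <- tryCatch(solve(J, res), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (half in 1:30) {
      cand <- n - lambda * step
      if (all(cand >= 0)) {
        rc <- Fres(cand)
        if (max(abs(rc)) < max(abs(res))) {
          n <- cand; res <- rc; improved <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved) break
    if (max(abs(res)) <= tol * 1e-4 || max(abs(res)) == 0) break
  }
  if (max(abs(res)) > tol) {
    # fixed-point fallback: n_k from its own constraint at the current n_q
    solver <- "fixed_point"
    for (i in seq_len(max_iter)) {
      iter <- iter + 1L
      n_new <- pmax(design$sigma2 / (design$R * (1 - design$R)) *
                      (target - 1 / Ssum(n)), 0)
      if (max(abs(n_new - n)) < 1e-12) { n <- n_new; break }
      n <- n_new
    }
    res <- Fres(n)
  }
  converged <- max(abs(res)) <= tol
  if (!converged)
    warning("sample-size solver did not converge after ", iter,
            " iterations; max residual ", format(max(abs(res))),
            " exceeds tol = ", tol, call. = FALSE)
  if (any(n == 0))
    warning("complementary information alone meets the precision target ",
            "for subtrial(s) ", paste(which(n == 0), collapse = ", "),
            "; n clamped at 0 - a subtrial enrolling no patients cannot ",
            "practically or ethically be run", call. = FALSE)
  achieved <- n * A + 1 / Ssum(n)
  sample_size_result(design, n, achieved, target, "borrowing",
                     converged = converged, iterations = iter,
                     solver = solver)
}
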
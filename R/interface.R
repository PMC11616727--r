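#' Load a design or scenario configuration from a YAML file
#'
#' Configuration keys mirror the model notation: a design file carries
#' `sigma2`, `delta`, `eta`, `zeta`, `R`, `s02`, `m0`, `c0`,
#' `gamma_mixture: {a1, b1, a2, b2}` and either `w_matrix` (list of rows) or
#' `distributions: {mu, sigma}` from which the incommensurability matrix is
#' derived via the Hellinger distance. A scenario file is recognized by the
#' presence of `mu_E` and additionally carries `mu_C`, `n` (optional — can
#' be filled from a solved design downstream) and optionally its own
#' `w_matrix`/`labels`. Every invariant of the constructed object is
#' validated; violations raise named errors.
#'
#' @param path Path to a YAML configuration file.
#' @return A [basket_design()] or [scenario_spec()].
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg))
    stop("configuration file is not a YAML mapping: ", path, call. = FALSE)
  if (!is.null(cfg$mu_E)) config_to_scenario(cfg, path)
  else config_to_design(cfg, path)
}

need <- function(cfg, field, path) {
  if (is.null(cfg[[field]]))
    stop("missing required field `", field, "` in ", path, call. = FALSE)
  cfg[[field]]
}

config_w <- function(cfg, K) {
  if (!is.null(cfg$w_matrix)) {
    w <- do.call(rbind, lapply(cfg$w_matrix, as.numeric))
    commensurability_matrix(w)
  } else if (!is.null(cfg$distributions)) {
    hellinger_matrix(as.numeric(cfg$distributions$mu),
                     as.numeric(cfg$distributions$sigma))
  } else NULL
}

config_to_design <- function(cfg, path) {
  sigma2 <- as.numeric(need(cfg, "sigma2", path))
  mix <- if (!is.null(cfg$gamma_mixture))
    do.call(gamma_mixture_prior, cfg$gamma_mixture)
  else gamma_mixture_prior()
  basket_design(
    sigma2 = sigma2,
    delta = as.numeric(need(cfg, "delta", path)),
    eta = as.numeric(need(cfg, "eta", path)),
    zeta = as.numeric(need(cfg, "zeta", path)),
    R = as.numeric(cfg$R %||% 0.5),
    w = config_w(cfg, length(sigma2)),
    s02 = as.numeric(cfg$s02 %||% 100),
    m0 = as.numeric(cfg$m0 %||% 0),
    c0 = as.numeric(cfg$c0 %||% 0.05),
    mixture = mix)
}

config_to_scenario <- function(cfg, path) {
  mu_E <- as.numeric(need(cfg, "mu_E", path))
  scenario_spec(
    mu_E = mu_E,
    mu_C = as.numeric(cfg$mu_C %||% 0),
    sigma2 = as.numeric(need(cfg, "sigma2", path)),
    n = as.numeric(need(cfg, "n", path)),
    R = as.numeric(cfg$R %||% 0.5),
    w = config_w(cfg, length(mu_E)),
    labels = cfg$labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a design or scenario back to a YAML configuration
#'
#' Inverse of [load_config()] up to normalization (scalars broadcast to
#' vectors, the incommensurability matrix written explicitly).
#'
#' @param x A `basket_design` or `scenario_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) {
  if (inherits(x, "basket_design")) {
    cfg <- list(sigma2 = x$sigma2, delta = x$delta, eta = x$eta,
                zeta = x$zeta, R = x$R, s02 = x$s02, m0 = x$m0, c0 = x$c0,
                w_matrix = lapply(seq_len(x$K), function(q) unname(x$w[q, ])),
                gamma_mixture = list(a1 = x$mixture$a1, b1 = x$mixture$b1,
                                     a2 = x$mixture$a2, b2 = x$mixture$b2))
  } else if (inherits(x, "scenario_spec")) {
    cfg <- list(mu_E = x$mu_E, mu_C = x$mu_C, sigma2 = x$sigma2, n = x$n,
                R = x$R,
                w_matrix = lapply(seq_len(x$K), function(q) unname(x$w[q, ])),
                labels = x$labels)
  } else stop("cannot serialize objects of class ", class(x)[1],
              call. = FALSE)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

config_hash <- function(x) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(x, tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, command, objects, seed = NULL,
                           outputs = character()) {
  lines <- c(
    paste0("tool: basketssd ", as.character(utils::packageVersion("basketssd"))),
    paste0("command: ", command),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    if (!is.null(seed)) paste0("seed: ", seed),
    vapply(names(objects), function(nm)
      paste0("config_hash_", nm, ": ", config_hash(objects[[nm]])),
      character(1)),
    vapply(outputs, function(f) paste0("output: ", f), character(1)))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
  invisible(file.path(out_dir, "manifest.txt"))
}

#' Run the sample-size determination for a design
#'
#' Dispatches to [sample_size_no_borrowing()] and/or
#' [solve_sample_sizes()] and, when `out_dir` is given, writes the tidy
#' sizes table (`sizes.csv`) and a run manifest.
#'
#' @param config A `basket_design` or path to a design YAML file.
#' @param mode One of `"both"`, `"borrowing"`, `"no_borrowing"`.
#' @param out_dir Optional output directory (created if needed).
#' @return A data.frame with one row per subtrial x mode.
#' @export
run_design <- function(config, mode = c("both", "borrowing", "no_borrowing"),
                       out_dir = NULL) {
  mode <- match.arg(mode)
  design <- if (is.character(config)) load_config(config) else config
  stopifnot(inherits(design, "basket_design"))
  res <- list()
  if (mode %in% c("both", "no_borrowing"))
    res$no_borrowing <- sample_size_no_borrowing(design)
  if (mode %in% c("both", "borrowing")) {
    res$borrowing <- solve_sample_sizes(design)
    if (!res$borrowing$converged)
      stop("sample-size solver failed to converge; see warnings for ",
           "residual diagnostics", call. = FALSE)
  }
  tab <- do.call(rbind, lapply(res, as.data.frame))
  rownames(tab) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(out_dir, "sizes.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    write_manifest(out_dir, paste0("design mode=", mode),
                   list(design = design), outputs = f)
  }
  tab
}

#' Run an operating-characteristics simulation
#'
#' Dispatches to [operating_characteristics()]; when the scenario carries
#' no sample sizes they are filled with the solved (real-valued) borrowing
#' sizes of the design. When `out_dir` is given, writes the tidy rates
#' table (`rates.csv`, one row per subtrial x model plus overall rows) and
#' a run manifest.
#'
#' @param scenario A `scenario_spec` or path to a scenario YAML file.
#' @param design A `basket_design` or path to a design YAML file.
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @param models Subset of `c("borrowing", "standalone")`.
#' @return The `operating_characteristics` object, invisibly when writing.
#' @export
run_simulate <- function(scenario, design, reps = 1e4, seed = 1,
                         out_dir = NULL,
                         models = c("borrowing", "standalone")) {
  design <- if (is.character(design)) load_config(design) else design
  if (is.character(scenario)) {
    cfg <- yaml::read_yaml(scenario)
    if (is.null(cfg$n)) {
      sizes <- solve_sample_sizes(design)
      cfg$n <- sizes$n_real
      scenario <- config_to_scenario(cfg, scenario)
    } else scenario <- load_config(scenario)
  }
  stopifnot(inherits(scenario, "scenario_spec"))
  oc <- operating_characteristics(scenario, design, reps = reps,
                                  seed = seed, models = models)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(out_dir, "rates.csv")
    long <- oc$rates
    overall <- data.frame(subtrial = NA_integer_, model = names(oc$overall_fpr),
                          theta_true = NA_real_, n = NA_real_,
                          rate_efficacy = NA_real_, rate_futility = NA_real_,
                          rate_inconclusive = NA_real_,
                          se_efficacy = oc$overall_fpr_se,
                          se_futility = NA_real_)
    overall$rate_efficacy <- oc$overall_fpr
    long <- rbind(cbind(long, statistic = "per_subtrial"),
                  cbind(overall, statistic = "overall_false_positive"))
    utils::write.csv(long, f, row.names = FALSE)
    write_manifest(out_dir, paste0("simulate reps=", reps),
                   list(scenario = scenario, design = design), seed = seed,
                   outputs = f)
    return(invisible(oc))
  }
  oc
}
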
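#' Cohort scenario: proportional-hazards simulation parameters
#'
#' Patients carry clinicopathological covariates and slide-level indicator
#' values; breast-cancer-specific death times are drawn from an exponential
#' proportional-hazards model and administratively censored (default 120
#' months, i.e. follow-up restricted to ten years after surgery).
#'
#' Log-hazard coefficients act on standardized (z-scored) continuous
#' covariates and on binary covariates as given, so effect sizes are
#' comparable across indicators. The exponential baseline rate is either
#' supplied or calibrated so the expected event fraction under censoring
#' matches `target_event_rate` (default 0.13, the ballpark of 33 deaths per
#' 252 patients in an ER+HER2- cohort).
#'
#' @param n number of patients (>= 1).
#' @param coefficients named numeric vector of log-hazard ratios; names must
#'   be covariate names (see [generate_cohort()] for the defaults produced).
#' @param baseline_rate exponential baseline hazard (events/month); if `NULL`
#'   it is calibrated to `target_event_rate`.
#' @param target_event_rate expected fraction of patients with an observed
#'   event, used only when `baseline_rate` is `NULL`.
#' @param censor_months administrative censoring time (months).
#' @param seed integer seed.
#' @return an object of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n,
                            coefficients = c(Ki67_entropy = 0.6,
                                             CD8_m_T = -0.6,
                                             CD8_ID = 0.5,
                                             pN_pos = 0.7),
                            baseline_rate = NULL,
                            target_event_rate = 0.13,
                            censor_months = 120,
                            seed = 1L) {
  if (n < 1) stop("`n` must be >= 1")
  if (censor_months <= 0) stop("`censor_months` must be > 0")
  if (any(!is.finite(coefficients))) stop("coefficients must be finite")
  structure(list(n = as.integer(n), coefficients = coefficients,
                 baseline_rate = baseline_rate,
                 target_event_rate = target_event_rate,
                 censor_months = censor_months, seed = as.integer(seed)),
            class = "cohort_scenario")
}

# Covariate distributions loosely shaped like an ER+HER2- cohort:
# right-skewed densities (lognormal), near-normal entropy, binary stage/node.
simulate_covariates <- function(n) {
  data.frame(
    id = seq_len(n),
    age = round(stats::rnorm(n, 61, 11)),
    grade3 = stats::rbinom(n, 1, 0.3),
    pT2 = stats::rbinom(n, 1, 0.4),
    pN_pos = stats::rbinom(n, 1, 0.35),
    Ki67_pct = pmin(100, stats::rlnorm(n, log(12), 0.8)),
    Ki67_entropy = pmin(log(100), pmax(0, stats::rnorm(n, 2.2, 1.2))),
    CD8_m_S = stats::rlnorm(n, log(180), 1.0),
    CD8_m_T = stats::rlnorm(n, log(60), 1.1),
    CD8_ID = stats::rlnorm(n, log(2.7), 0.9))
}

# z-score continuous covariates, leave binaries (0/1) as-is
standardize_design <- function(df, vars) {
  X <- sapply(vars, function(v) {
    x <- df[[v]]
    if (all(x %in% c(0, 1))) return(x)
    (x - mean(x)) / stats::sd(x)
  })
  matrix(X, nrow = nrow(df), dimnames = list(NULL, vars))
}

#' Generate a survival cohort from a proportional-hazards scenario
#'
#' Event times are exponential with rate `baseline_rate * exp(lp)` where
#' `lp` is the linear predictor from the scenario's coefficients; observed
#' time is the minimum of the event time and the administrative censoring
#' time.
#'
#' @param scenario a [cohort_scenario()].
#' @return data.frame with covariates plus `time_months`, `event` and an
#'   attribute `baseline_rate` (the calibrated rate actually used).
#' @export
generate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(scenario$seed)

  df <- simulate_covariates(scenario$n)
  vars <- names(scenario$coefficients)
  missing_vars <- setdiff(vars, names(df))
  if (length(missing_vars))
    stop("unknown covariates in coefficients: ",
         paste(missing_vars, collapse = ", "))
  X <- standardize_design(df, vars)
  lp <- drop(X %*% scenario$coefficients)

  rate0 <- scenario$baseline_rate
  if (is.null(rate0)) {
    cm <- scenario$censor_months
    target <- scenario$target_event_rate
    f <- function(r) mean(1 - exp(-r * exp(lp) * cm)) - target
    rate0 <- stats::uniroot(f, c(1e-8, 10), tol = 1e-10)$root
  }
  t_event <- stats::rexp(scenario$n, rate = rate0 * exp(lp))
  df$time_months <- pmin(t_event, scenario$censor_months)
  df$event <- as.integer(t_event <= scenario$censor_months)
  attr(df, "baseline_rate") <- rate0
  attr(df, "linear_predictor") <- lp
  df
}

#' Write / read a cohort table CSV
#' @param cohort a cohort data.frame with `time_months` and `event`.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_months", "event") %in% names(df)))
    stop("cohort table must have `time_months` and `event` columns")
  df
}
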
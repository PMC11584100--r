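#' Optimal cutoff dichotomization by log-rank scan
#'
#' Scans every midpoint between consecutive sorted distinct values whose
#' split leaves at least `min_group_fraction` of the cohort in each group,
#' and returns the cutoff minimizing the log-rank p-value, together with the
#' hazard ratio (high vs low) of the dichotomy. This mirrors optimal-cutpoint
#' tools for survival dichotomization; note that scanning many candidate
#' splits inflates the type-I error of the reported p-value, which is not
#' corrected here (the screen reports raw p-values).
#'
#' @param values numeric indicator values.
#' @param times follow-up times.
#' @param events event flags (1 = event).
#' @param min_group_fraction minimum fraction of subjects per group.
#' @return list of class `cutoff_result`: `cutoff`, `chisq`, `p`, `hr`,
#'   `ci_lower`, `ci_upper`, `n_low`, `n_high`.
#' @export
optimal_cutoff <- function(values, times, events, min_group_fraction = 0.1) {
  n <- length(values)
  stopifnot(length(times) == n, length(events) == n)
  if (sum(events) < 1) stop("at least one event is required")
  sv <- sort(unique(values))
  if (length(sv) < 2) stop("all values identical: no split exists")
  cand <- (sv[-1] + sv[-length(sv)]) / 2
  n_min <- ceiling(min_group_fraction * n)
  admissible <- vapply(cand, function(cc) {
    nl <- sum(values <= cc); nl >= n_min && (n - nl) >= n_min
  }, logical(1))
  cand <- cand[admissible]
  if (length(cand) == 0) stop("no admissible split under min_group_fraction")
  scan <- vapply(cand, function(cc) {
    g <- values > cc
    sd1 <- survival::survdiff(survival::Surv(times, events) ~ g)
    chi <- sd1$chisq
    c(chi, stats::pchisq(chi, df = 1, lower.tail = FALSE))
  }, numeric(2))
  best <- which.min(scan[2, ])
  cutoff <- cand[best]
  g <- as.integer(values > cutoff)
  fit <- survival::coxph(survival::Surv(times, events) ~ g, ties = "efron")
  s <- summary(fit)
  structure(list(cutoff = cutoff, chisq = scan[1, best], p = scan[2, best],
                 hr = unname(s$conf.int[1, "exp(coef)"]),
                 ci_lower = unname(s$conf.int[1, "lower .95"]),
                 ci_upper = unname(s$conf.int[1, "upper .95"]),
                 n_low = sum(g == 0L), n_high = sum(g == 1L)),
            class = "cutoff_result")
}

#' Univariate screen of indicators by optimal-cutoff log-rank test
#'
#' Each variable is dichotomized at its optimal cutoff; variables with
#' log-rank p below `alpha` are retained. Variables whose cutoff scan fails
#' (e.g. constant values) are skipped with a message.
#'
#' @param cohort data.frame with `time_months`, `event` and the variables.
#' @param variables character vector of column names to screen.
#' @param alpha retention threshold on the log-rank p (default 0.05).
#' @param min_group_fraction passed to [optimal_cutoff()].
#' @return list with `retained` (character) and `results` (named list of
#'   `cutoff_result`).
#' @export
univariate_screen <- function(cohort, variables, alpha = 0.05,
                              min_group_fraction = 0.1) {
  results <- list()
  retained <- character()
  for (v in variables) {
    res <- tryCatch(
      optimal_cutoff(cohort[[v]], cohort$time_months, cohort$event,
                     min_group_fraction = min_group_fraction),
      error = function(e) {
        message("skipping ", v, ": ", conditionMessage(e)); NULL
      })
    if (is.null(res)) next
    results[[v]] <- res
    if (res$p < alpha) retained <- c(retained, v)
  }
  list(retained = retained, results = results)
}

#' Multivariable Cox proportional-hazards model with Harrell's C
#'
#' Partial-likelihood fit (Efron tie handling) of the listed covariates;
#' reports per-covariate hazard ratios with 95% CIs, Wald chi-squares, the
#' model likelihood-ratio statistic versus the null, and Harrell's
#' concordance of the fitted linear predictor computed by [harrell_c()].
#'
#' @param cohort data.frame with `time_months`, `event` and the covariates.
#' @param covariates character vector of column names (numeric or 0/1).
#' @return list of class `cox_result`: `table` (data.frame with `hr`,
#'   `ci_lower`, `ci_upper`, `p`, `chisq` per covariate), `lr_stat`, `lr_p`,
#'   `c_index`, `fit`.
#' @export
fit_multivariable_cox <- function(cohort, covariates) {
  n_events <- sum(cohort$event)
  if (n_events < length(covariates) + 5)
    stop("too few events (", n_events, ") for ", length(covariates),
         " covariates")
  f <- stats::as.formula(paste("survival::Surv(time_months, event) ~",
                               paste(covariates, collapse = " + ")))
  fit <- survival::coxph(f, data = cohort, ties = "efron")
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info)))
    stop("Cox model did not converge")
  if (any(!is.finite(stats::coef(fit))) || any(sqrt(diag(fit$var)) > 1e3))
    stop("Cox model unstable (possible separation)")
  s <- summary(fit)
  tab <- data.frame(
    covariate = rownames(s$coefficients),
    hr = s$conf.int[, "exp(coef)"],
    ci_lower = s$conf.int[, "lower .95"],
    ci_upper = s$conf.int[, "upper .95"],
    p = s$coefficients[, "Pr(>|z|)"],
    chisq = s$coefficients[, "z"]^2,
    row.names = NULL)
  lp <- stats::predict(fit, type = "lp")
  list(table = tab,
       lr_stat = unname(2 * (fit$loglik[2] - fit$loglik[1])),
       lr_p = unname(stats::pchisq(2 * (fit$loglik[2] - fit$loglik[1]),
                                   df = length(covariates),
                                   lower.tail = FALSE)),
       c_index = harrell_c(lp, cohort$time_months, cohort$event),
       fit = fit)
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose predicted risk ordering agrees
#' with the observed survival ordering, with tied predictions counted 1/2.
#' A pair (i, j) is comparable when the shorter observed time belongs to a
#' patient with an event; higher linear predictor is expected to pair with
#' shorter survival.
#'
#' @param lp linear predictor (higher = higher risk).
#' @param times follow-up times.
#' @param events event flags (1 = event).
#' @return concordance in [0, 1].
#' @export
harrell_c <- function(lp, times, events) {
  n <- length(lp)
  stopifnot(length(times) == n, length(events) == n)
  conc <- 0; comp <- 0
  for (i in which(events == 1)) {
    # pairs where i has the strictly shorter time, plus event-event ties
    at_risk <- times > times[i] | (times == times[i] & events == 0)
    if (!any(at_risk)) next
    comp <- comp + sum(at_risk)
    conc <- conc + sum(lp[i] > lp[at_risk]) + 0.5 * sum(lp[i] == lp[at_risk])
  }
  if (comp == 0) stop("no comparable pairs: concordance undefined")
  conc / comp
}

#' Combined prognostic score (CPBS) with risk groups
#'
#' Sums per-indicator binary scores (0 good / 1 poor prognosis) and maps the
#' total to a risk group. The ER+HER2- model sums four indicators (lymph
#' node status, Ki67 entropy, CD8 density in the tumor aspect, immunodrop):
#' total 0 = low, 1 = intermediate, 2-4 = high risk. The TNBC model sums
#' three (tumor stage, Ki67 entropy, CD8 density in the stroma aspect):
#' total 0-1 = low, 2 = intermediate, 3 = high risk.
#'
#' @param scores integer vector (one patient) or matrix/data.frame (one row
#'   per patient) of binary scores; 4 columns for `"ER+HER2-"`, 3 for
#'   `"TNBC"`.
#' @param model `"ER+HER2-"` or `"TNBC"`.
#' @return data.frame with `total` and `risk_group`
#'   (low/intermediate/high).
#' @export
cpbs_score <- function(scores, model = c("ER+HER2-", "TNBC")) {
  model <- match.arg(model)
  arity <- if (model == "ER+HER2-") 4L else 3L
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  scores <- as.matrix(scores)
  if (ncol(scores) != arity)
    stop(model, " model requires exactly ", arity, " binary scores")
  if (!all(scores %in% c(0, 1))) stop("scores must be binary 0/1")
  total <- as.integer(rowSums(scores))
  risk_group <- if (model == "ER+HER2-") {
    ifelse(total == 0L, "low", ifelse(total == 1L, "intermediate", "high"))
  } else {
    ifelse(total <= 1L, "low", ifelse(total == 2L, "intermediate", "high"))
  }
  data.frame(total = total,
             risk_group = factor(risk_group,
                                 levels = c("low", "intermediate", "high")))
}

#' Maximum achievable combined score of a CPBS model
#' @param model `"ER+HER2-"` or `"TNBC"`.
#' @return 4 or 3.
#' @export
cpbs_max_score <- function(model = c("ER+HER2-", "TNBC")) {
  model <- match.arg(model)
  if (model == "ER+HER2-") 4L else 3L
}

#' Kaplan-Meier curve coordinates for export
#'
#' @param times,events survival data.
#' @param group optional grouping factor.
#' @return data.frame `group`, `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_curves <- function(times, events, group = NULL) {
  if (is.null(group)) group <- rep("all", length(times))
  fit <- survival::survfit(survival::Surv(times, events) ~ g,
                           data = data.frame(times, events, g = group))
  st <- summary(fit)
  grp <- if (is.null(st$strata)) rep(unique(group)[1], length(st$time))
  else sub("^g=", "", as.character(st$strata))
  data.frame(group = grp, time = st$time, surv = st$surv,
             n_risk = st$n.risk, n_event = st$n.event)
}
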
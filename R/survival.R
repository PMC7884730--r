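#' Overall and relapse-free survival durations
#'
#' OS is the time from diagnosis (date C) to the endpoint/censoring date
#' (date A); RFS is from surgery (date B) to A. Dates may be `Date`s or
#' numeric day offsets; durations are converted to months as days/30.4375.
#'
#' @param frame data.frame with columns id, date_diagnosis, date_surgery,
#'   date_endpoint, death_event, relapse_event.
#' @return data.frame: id, os_months, os_event, rfs_months, rfs_event.
#' @export
compute_survival_times <- function(frame) {
  req <- c("id", "date_diagnosis", "date_surgery", "date_endpoint",
           "death_event", "relapse_event")
  missing_cols <- setdiff(req, names(frame))
  if (length(missing_cols))
    stop_("clinical frame is missing: %s",
          paste(missing_cols, collapse = ", "))
  A <- as.numeric(frame$date_endpoint)
  B <- as.numeric(frame$date_surgery)
  C <- as.numeric(frame$date_diagnosis)
  if (anyNA(A) || anyNA(C))
    stop_("missing endpoint or diagnosis date for patient '%s'",
          frame$id[which(is.na(A) | is.na(C))[1]])
  bad <- which(A < C | (!is.na(B) & A < B))
  if (length(bad))
    stop_("negative survival duration for patient '%s'", frame$id[bad[1]])
  if (anyNA(B))
    stop_("missing surgery date for patient '%s' (required for RFS)",
          frame$id[which(is.na(B))[1]])
  data.frame(id = frame$id,
             os_months = days_to_months(A - C),
             os_event = as.integer(frame$death_event),
             rfs_months = days_to_months(A - B),
             rfs_event = as.integer(frame$relapse_event),
             stringsAsFactors = FALSE)
}

#' Combined CD8 / hERV (WTS) subgroup labels
#'
#' CD8-high and hERV-high are the top 30 percent of the CD8+ fraction and
#' median.hERV distributions. The poor-prognosis WTS- subgroup is
#' CD8-low/hERV-high; the other three cells of the 2x2 table are WTS+.
#'
#' @param cd8_fraction,median_herv Equal-length numeric vectors.
#' @param fraction Top fraction for both dichotomizations (default 0.30).
#' @return data.frame: cd8_high, herv_high, wts_group.
#' @export
assign_wts_group <- function(cd8_fraction, median_herv, fraction = 0.30) {
  if (length(cd8_fraction) != length(median_herv))
    stop_("cd8_fraction and median_herv must have equal length")
  cd8_high <- dichotomize_top_fraction(cd8_fraction, fraction)
  herv_high <- dichotomize_top_fraction(median_herv, fraction)
  data.frame(cd8_high = cd8_high, herv_high = herv_high,
             wts_group = ifelse(!cd8_high & herv_high, "WTS-", "WTS+"),
             stringsAsFactors = FALSE)
}

#' Clinicopathological (CP) subgroup labels
#'
#' CP- marks patients with any unfavorable factor: age in the cohort's top
#' 30 percent, stage III, or right-sided tumors; everyone else is CP+.
#' Patients with a missing covariate get `NA` with a warning.
#'
#' @param age Numeric vector of ages.
#' @param stage Character: "II"/"III".
#' @param sidedness Character: "left"/"right".
#' @param fraction Top fraction for the age dichotomization (default 0.30).
#' @return Character vector of "CP+"/"CP-" (NA where undetermined).
#' @export
assign_cp_group <- function(age, stage, sidedness, fraction = 0.30) {
  age_high <- dichotomize_top_fraction(age, fraction)
  missing <- is.na(age) | is.na(stage) | is.na(sidedness)
  if (any(missing))
    warning(sprintf("%d patients have missing covariates; CP label set NA",
                    sum(missing)))
  out <- ifelse(age_high | stage == "III" | sidedness == "right",
                "CP-", "CP+")
  out[missing] <- NA_character_
  out
}

#' Kaplan-Meier curves and log-rank test across groups
#'
#' Product-limit estimates per group with the two-sided log-rank chi-square
#' statistic. Median survival is reported as `NA` when a group's curve never
#' crosses 0.5.
#'
#' @param times Non-negative survival times (months).
#' @param events Event indicators (1 = event, 0 = censored).
#' @param groups Group labels (>= 2 non-empty groups).
#' @return List of class `km_fit`: `table` (data.frame: group, n, events,
#'   median_months), `logrank_stat`, `df`, `logrank_p`, and the underlying
#'   `survfit` object.
#' @export
km_logrank <- function(times, events, groups) {
  if (any(times < 0)) stop_("survival times must be >= 0")
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop_("need at least 2 non-empty groups")
  if (any(table(groups) == 0)) stop_("empty group level present")
  d <- data.frame(times = times, events = events, groups = groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups, data = d)
  sd <- if (sum(events) == 0) NULL else
    survival::survdiff(survival::Surv(times, events) ~ groups, data = d)
  stab <- summary(fit)$table
  if (is.null(dim(stab))) stab <- t(stab)   # single stratum guard
  tab <- data.frame(
    group = sub("^groups=", "", rownames(stab)),
    n = stab[, "records"],
    events = stab[, "events"],
    median_months = stab[, "median"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  df <- nlevels(droplevels(groups)) - 1
  # with no events at all the log-rank statistic is identically zero
  chisq <- if (is.null(sd)) 0 else unname(sd$chisq)
  structure(list(table = tab,
                 logrank_stat = chisq, df = df,
                 logrank_p = stats::pchisq(chisq, df, lower.tail = FALSE),
                 survfit = fit),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  print(x$table)
  cat(sprintf("log-rank chi-square = %.4g on %d df, p = %.4g\n",
              x$logrank_stat, x$df, x$logrank_p))
  invisible(x)
}

#' Cox proportional-hazards fit (Efron ties)
#'
#' Univariate mode fits each covariate in its own model; multivariate mode
#' fits them jointly. Hazard ratios are `exp(coef)` with Wald 95 percent
#' intervals. Non-convergence is reported explicitly, never silently.
#'
#' @param times,events Survival outcome.
#' @param covariates data.frame of covariates (numeric, logical or factor).
#' @param mode `"univariate"` or `"multivariate"`.
#' @return data.frame: term, hr, ci_lower, ci_upper, p, converged.
#' @export
cox_fit <- function(times, events, covariates,
                    mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  covariates <- as.data.frame(covariates)
  const <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) < 2,
                  logical(1))
  if (any(const))
    stop_("constant covariate(s): %s",
          paste(names(covariates)[const], collapse = ", "))
  fit_one <- function(df) {
    d <- cbind(data.frame(.time = times, .event = events), df)
    conv <- TRUE
    fit <- withCallingHandlers(
      survival::coxph(survival::Surv(.time, .event) ~ ., data = d,
                      ties = "efron"),
      warning = function(w) {
        if (grepl("converge|infinite|beta may be infinite",
                  conditionMessage(w)))
          conv <<- FALSE
        invokeRestart("muffleWarning")
      })
    s <- summary(fit)
    data.frame(term = rownames(s$coefficients),
               hr = s$coefficients[, "exp(coef)"],
               ci_lower = s$conf.int[, "lower .95"],
               ci_upper = s$conf.int[, "upper .95"],
               p = s$coefficients[, "Pr(>|z|)"],
               converged = conv,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  if (mode == "multivariate") {
    if (sum(events) < ncol(covariates))
      stop_("fewer events than covariates in multivariate mode")
    fit_one(covariates)
  } else {
    out <- lapply(names(covariates), function(nm)
      fit_one(covariates[, nm, drop = FALSE]))
    do.call(rbind, out)
  }
}

#' Two-group categorical enrichment test
#'
#' For each category of `label_a` x `label_b`, tests whether the proportion
#' of `label_b`-positives differs between levels of `label_a` using a
#' two-proportion test with continuity correction, falling back to Fisher's
#' exact test when any expected cell count is below 5.
#'
#' @param label_a Two-level factor (e.g. subtype membership).
#' @param label_b Two-level factor or logical (e.g. LS status).
#' @return List: p, method ("prop.test" or "fisher"), table (2x2).
#' @export
enrichment_test <- function(label_a, label_b) {
  tab <- table(label_a, label_b)
  if (any(dim(tab) < 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p = NA_real_, method = NA_character_, table = tab))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5) || any(tab < 5)) {
    p <- stats::fisher.test(tab)$p.value
    method <- "fisher"
  } else {
    p <- stats::prop.test(tab, correct = TRUE)$p.value
    method <- "prop.test"
  }
  list(p = p, method = method, table = tab)
}
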
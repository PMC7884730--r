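#' Simulate proportional-hazards survival times per subgroup
#'
#' Draws exponential event times whose hazard is `hazard_ratios[label]`
#' times the baseline hazard `1 / baseline_scale`; labels absent from
#' `hazard_ratios` sit at the baseline. Censoring is independent exponential,
#' calibrated so the expected censored proportion in the baseline group is
#' `censoring_rate`. Relapse-free times are derived as a fraction of the
#' overall-survival time (relapse precedes death), with the same censoring.
#'
#' @param labels Character vector of subgroup labels, one per patient.
#' @param hazard_ratios Named numeric vector mapping labels to hazard ratios
#'   (> 0); unnamed labels get HR 1.
#' @param baseline_scale Mean months-to-event in the baseline group.
#' @param censoring_rate Expected censored proportion in `[0, 1]`; 1 censors
#'   everyone.
#' @param seed Integer seed.
#' @return data.frame with os_months, os_event, rfs_months, rfs_event.
#' @export
simulate_survival <- function(labels, hazard_ratios = c("WTS-" = 4.4),
                              baseline_scale = 40, censoring_rate = 0.3,
                              seed = 1L) {
  if (any(hazard_ratios <= 0)) stop_("hazard ratios must be > 0")
  if (censoring_rate < 0 || censoring_rate > 1)
    stop_("censoring_rate must be in [0, 1]")
  set.seed(child_seed(seed, "survival"))
  n <- length(labels)
  hr <- ifelse(labels %in% names(hazard_ratios),
               hazard_ratios[labels], 1)
  lambda <- hr / baseline_scale
  t_os <- stats::rexp(n, rate = lambda)
  t_rfs <- t_os * stats::rbeta(n, 8, 2)

  if (censoring_rate >= 1) {
    cens <- stats::runif(n, 0, baseline_scale)
    return(data.frame(os_months = cens, os_event = 0L,
                      rfs_months = cens * 0.8, rfs_event = 0L))
  }
  if (censoring_rate > 0) {
    mu <- (censoring_rate / (1 - censoring_rate)) / baseline_scale
    cens <- stats::rexp(n, rate = mu)
  } else {
    cens <- rep(Inf, n)
  }
  data.frame(
    os_months = pmin(t_os, cens),
    os_event = as.integer(t_os <= cens),
    rfs_months = pmin(t_rfs, cens),
    rfs_event = as.integer(t_rfs <= cens)
  )
}
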
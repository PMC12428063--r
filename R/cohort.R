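# Synthetic in-vivo-like cohorts.
#
# No per-animal measurements are deposited with the source experiments; only
# group means, SDs and replicate counts are published.  The generator draws
# per-replicate ablation volumes and treatment times from truncated-normal
# distributions (truncated at zero) with those published moments, so the
# calibration and statistics stages can be exercised end to end.

#' Published group-level study conditions
#'
#' Exposure length (cm), replicate count, treatment time (s, mean and SD)
#' and ablation volume (cm^3, mean and SD) for the four exposure groups.
#'
#' @return A data frame with one row per exposure group.
#' @export
reference_groups <- function() {
  data.frame(
    group_cm = c(0.5, 1.0, 1.5, 2.0),
    n = c(9L, 6L, 7L, 5L),
    time_mean_s = c(473, 421, 314, 250),
    time_sd_s = c(83, 91, 63, 105),
    volume_mean_cm3 = c(7.95, 11.56, 12.83, 7.64),
    volume_sd_cm3 = c(3.74, 5.32, 2.61, 2.50)
  )
}

#' Published lethal-threshold summaries
#'
#' Calibrated lethal electric-field thresholds (V/cm, mean and SD) per
#' exposure group, as reported by the in vivo study the model emulates.
#'
#' @return A data frame with one row per exposure group.
#' @export
reference_thresholds <- function() {
  data.frame(
    group_cm = c(0.5, 1.0, 1.5, 2.0),
    threshold_mean_V_per_cm = c(433, 548, 581, 918),
    threshold_sd_V_per_cm = c(102, 70, 63, 183)
  )
}

#' Cohort specification
#'
#' @param groups Data frame with columns `group_cm`, `n`, `time_mean_s`,
#'   `time_sd_s`, `volume_mean_cm3`, `volume_sd_cm3`; defaults to the
#'   published study conditions ([reference_groups()]).
#' @param truncation Lower truncation bound for both volumes and times
#'   (default 0: no non-positive measurements are ever emitted).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(groups = reference_groups(), truncation = 0) {
  need <- c("group_cm", "n", "time_mean_s", "time_sd_s",
            "volume_mean_cm3", "volume_sd_cm3")
  stopifnot(all(need %in% names(groups)), all(groups$n >= 1),
            all(groups$time_sd_s >= 0), all(groups$volume_sd_cm3 >= 0))
  if (any(groups$volume_mean_cm3 <= truncation & groups$volume_sd_cm3 == 0) ||
      any(stats::pnorm(truncation, groups$volume_mean_cm3,
                       pmax(groups$volume_sd_cm3, 1e-12)) > 0.999))
    stop("infeasible truncation: a group mean lies far below the bound")
  structure(list(groups = groups, truncation = truncation),
            class = "cohort_spec")
}

# Exact inverse-CDF sampling of a normal truncated below at `lower`.
rtrunc_normal <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  f0 <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, f0, 1)
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic replicate cohort
#'
#' Per group, draws `n` independent truncated-normal replicate volumes and
#' treatment times (drawn independently of each other).  Reproducible from
#' the seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer random seed.
#' @return Data frame with columns `group_cm`, `replicate`, `volume_cm3`,
#'   `time_s`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  g <- spec$groups
  rows <- lapply(seq_len(nrow(g)), function(i) {
    data.frame(
      group_cm = g$group_cm[i],
      replicate = seq_len(g$n[i]),
      volume_cm3 = rtrunc_normal(g$n[i], g$volume_mean_cm3[i],
                                 g$volume_sd_cm3[i], spec$truncation),
      time_s = rtrunc_normal(g$n[i], g$time_mean_s[i], g$time_sd_s[i],
                             spec$truncation)
    )
  })
  do.call(rbind, rows)
}

#' Threshold-recovery experiment on synthetic cohorts
#'
#' Runs the full analysis pipeline on a synthetic cohort: generate
#' replicates, calibrate a lethal threshold per replicate against each
#' group's volume-field curve, summarise per group, and report the bias of
#' the recovered group-mean thresholds against the thresholds implied by
#' the specification means.
#'
#' @param spec A [cohort_spec()].
#' @param curves Named list of [volume_field_curve()] objects, one per
#'   group, names matching `spec$groups$group_cm` (e.g. `"0.5"`).
#' @param seed Integer random seed.
#' @param mode Matching mode passed to [calibrate_threshold()].
#' @return A `recovery_report`: per-group recovered mean/SD threshold, the
#'   spec-implied threshold, bias, and the per-replicate table.
#' @export
recovery_experiment <- function(spec = cohort_spec(), curves, seed = 1,
                                mode = "interpolated") {
  g <- spec$groups
  keys <- as.character(g$group_cm)
  if (!all(keys %in% names(curves)))
    stop("curves must be a named list covering every group: ",
         paste(setdiff(keys, names(curves)), collapse = ", "))
  cohort <- generate_cohort(spec, seed)
  cohort$threshold_V_per_cm <- NA_real_
  cohort$out_of_range <- FALSE
  for (key in keys) {
    sel <- cohort$group_cm == as.numeric(key)
    th <- calibrate_threshold(curves[[key]], cohort$volume_cm3[sel],
                              mode = mode)
    cohort$threshold_V_per_cm[sel] <- as.numeric(th)
    cohort$out_of_range[sel] <- attr(th, "out_of_range")
  }
  per_group <- data.frame(
    group_cm = g$group_cm,
    n = g$n,
    threshold_mean = vapply(keys, function(key)
      mean(cohort$threshold_V_per_cm[cohort$group_cm == as.numeric(key)]),
      numeric(1)),
    threshold_sd = vapply(keys, function(key)
      stats::sd(cohort$threshold_V_per_cm[cohort$group_cm == as.numeric(key)]),
      numeric(1)),
    implied_threshold = vapply(seq_along(keys), function(i)
      as.numeric(calibrate_threshold(curves[[keys[i]]],
                                     g$volume_mean_cm3[i], mode = mode)),
      numeric(1))
  )
  per_group$bias <- per_group$threshold_mean - per_group$implied_threshold
  structure(list(per_group = per_group, replicates = cohort, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Synthetic-cohort threshold recovery (seed ", x$seed, ")\n", sep = "")
  print(x$per_group, row.names = FALSE)
  invisible(x)
}
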
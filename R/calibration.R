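# Lethal-threshold calibration and the group statistics of the analysis
# stage: measured ablation volumes are matched to the simulated
# volume-above-field curve; groups are compared with Welch's t-test; the
# treatment-time trend is an ordinary least-squares fit.

#' Calibrate a lethal electric-field threshold
#'
#' Finds the field level whose simulated volume-above-field equals the
#' measured ablation volume.  The default mode interpolates linearly
#' between grid points of the (monotone non-increasing) curve;
#' `mode = "grid"` returns the nearest grid level, mirroring the raw
#' 10 V/cm resolution.
#'
#' @param curve A [volume_field_curve()] (columns `e_set_V_per_cm`,
#'   `volume_cm3`).
#' @param measured_volume Measured ablation volume(s), cm^3.
#' @param mode `"interpolated"` or `"grid"`.
#' @return Thresholds in V/cm, with attribute `out_of_range` flagging
#'   volumes outside the curve's range (clamped to the nearest endpoint).
#' @export
calibrate_threshold <- function(curve, measured_volume,
                                mode = c("interpolated", "grid")) {
  mode <- match.arg(mode)
  e <- curve$e_set_V_per_cm
  v <- curve$volume_cm3
  stopifnot(all(diff(e) > 0))
  if (any(diff(v) > 1e-9 * max(v)))
    stop("volume-field curve is not non-increasing")

  one <- function(target) {
    if (target > v[1]) return(c(e[1], -1))        # larger than any simulated
    if (target < v[length(v)]) return(c(e[length(e)], 1))
    if (mode == "grid") {
      return(c(e[which.min(abs(v - target))], 0))
    }
    # first interval with v[i] >= target >= v[i+1]
    i <- which(v >= target)
    i <- i[length(i)]
    if (i == length(v) || v[i] == target) return(c(e[i], 0))
    frac <- (v[i] - target) / (v[i] - v[i + 1])
    c(e[i] + frac * (e[i + 1] - e[i]), 0)
  }
  res <- vapply(measured_volume, one, numeric(2))
  out <- res[1, ]
  attr(out, "out_of_range") <- res[2, ] != 0
  out
}

#' Predict ablation dimensions from a lethal threshold
#'
#' Measures the iso-region where the field magnitude exceeds `threshold`:
#' revolved volume, axial length, maximum transverse width (2 x max radial
#' extent) and the length/width ratio (sphericity; 1 = spherical, > 1 =
#' elongated along the needle).
#'
#' @param field A `field_solution`.
#' @param threshold Lethal threshold, V/cm (> 0).
#' @return A one-row data frame: `volume_cm3`, `length_cm`, `width_cm`,
#'   `sphericity`, `empty` (TRUE when no tissue exceeds the threshold).
#' @export
predict_ablation <- function(field, threshold) {
  stopifnot(threshold > 0)
  reg <- iso_region(field$mesh, field$E_node, threshold)
  if (reg$empty)
    return(data.frame(volume_cm3 = 0, length_cm = 0, width_cm = 0,
                      sphericity = NA_real_, empty = TRUE))
  data.frame(volume_cm3 = reg$volume_cm3,
             length_cm = reg$z_max - reg$z_min,
             width_cm = 2 * reg$r_max,
             sphericity = (reg$z_max - reg$z_min) / (2 * reg$r_max),
             empty = FALSE)
}

#' Welch's two-sample t-test from summary statistics
#'
#' t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2), with Welch-Satterthwaite
#' degrees of freedom and a two-tailed p-value.  This is the form needed
#' when only group means and SDs are available (as in the published table).
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return A `welch_test` list: `t`, `df`, `p`, group summaries.
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) {
    if (mean1 == mean2)
      stop("undefined t statistic: zero variance in both groups with equal means")
    t <- sign(mean1 - mean2) * Inf
    df <- n1 + n2 - 2
  } else {
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  structure(list(t = t, df = df,
                 p = 2 * stats::pt(-abs(t), df),
                 mean1 = mean1, sd1 = sd1, n1 = n1,
                 mean2 = mean2, sd2 = sd2, n2 = n2),
            class = "welch_test")
}

#' Welch's two-sample t-test from raw samples
#'
#' Two-tailed Welch's t-test assuming unequal variances.
#'
#' @param group_a,group_b Numeric sample vectors (n >= 2 each).
#' @return A `welch_test` list; see [welch_t_summary()].
#' @export
welch_t_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  welch_t_summary(mean(group_a), stats::sd(group_a), length(group_a),
                  mean(group_b), stats::sd(group_b), length(group_b))
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch's t-test: t = %.3f, df = %.2f, two-tailed p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' Ordinary least-squares linear trend
#'
#' OLS fit of y on x (e.g. mean treatment time on exposure length).
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return List with `slope`, `intercept`, `r_squared` and the underlying
#'   [stats::lm()] fit.
#' @export
linear_trend <- function(x, y) {
  stopifnot(length(x) >= 3, length(x) == length(y))
  if (stats::sd(x) == 0) stop("undefined slope: x is constant")
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       fit = fit)
}

#' Per-group summary of a measurements table
#'
#' @param measurements Data frame with columns `group_cm` and one or more
#'   numeric measurement columns (default `volume_cm3`, `time_s`).
#' @param columns Measurement columns to summarise.
#' @return Data frame with one row per group: `group_cm`, `n`, and
#'   `<col>_mean` / `<col>_sd` per measurement column.
#' @export
group_summary <- function(measurements,
                          columns = intersect(c("volume_cm3", "time_s"),
                                              names(measurements))) {
  stopifnot("group_cm" %in% names(measurements), length(columns) >= 1)
  groups <- sort(unique(measurements$group_cm))
  if (!length(groups)) stop("empty measurements table")
  out <- data.frame(group_cm = groups)
  out$n <- vapply(groups, function(g)
    sum(measurements$group_cm == g), integer(1))
  for (cl in columns) {
    out[[paste0(cl, "_mean")]] <- vapply(groups, function(g)
      mean(measurements[[cl]][measurements$group_cm == g]), numeric(1))
    out[[paste0(cl, "_sd")]] <- vapply(groups, function(g) {
      x <- measurements[[cl]][measurements$group_cm == g]
      if (length(x) > 1) stats::sd(x) else 0
    }, numeric(1))
  }
  out
}
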
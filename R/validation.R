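# ICH Q2(R1) validation computations: linearity with intercept significance,
# S/N-based LOD/LOQ, accuracy/precision classification, one-factor-at-a-time
# robustness, selectivity and tablet assay.

#' Two-sided Student critical value
#'
#' @param alpha Two-sided significance level.
#' @param df Degrees of freedom (>= 1).
#' @return `qt(1 - alpha/2, df)`; e.g. 2.365 at df = 7, 2.262 at df = 9.
#' @export
t_critical <- function(alpha = 0.05, df) {
  if (any(df < 1)) stop("df must be >= 1")
  stats::qt(1 - alpha / 2, df)
}

#' Fit and assess a calibration line
#'
#' Ordinary least squares of response on concentration (level means by
#' default, or replicate-wise), with the two acceptance checks used for
#' chromatographic calibration: the correlation coefficient `r` against a
#' threshold (0.997) and the Student test of the intercept against zero
#' (`t = |intercept| / se <= t_crit` confirms absence of interference).
#'
#' @param series A `"calibration_series"` (or a list with `levels` and a
#'   response matrix `responses`).
#' @param alpha Significance level of the intercept test.
#' @param use `"means"` fits level means, `"replicates"` fits every
#'   injection.
#' @param df Degrees of freedom for the intercept test; defaults to
#'   `n - 2` of the fitted points.
#' @param r_threshold Acceptance threshold for `r`.
#' @return Object of class `"linearity_fit"`: `slope`, `intercept`, `r`,
#'   `se_intercept`, `t`, `df`, `t_crit`, `pass_r`, `pass_intercept`, `pass`.
#' @export
fit_linearity <- function(series, alpha = 0.05, use = c("means",
                                                        "replicates"),
                          df = NULL, r_threshold = 0.997) {
  use <- match.arg(use)
  lv <- series$levels
  if (length(unique(lv)) < 3)
    stop("insufficient data: need at least 3 distinct levels")
  resp <- as.matrix(series$responses)
  if (use == "means") {
    xx <- lv
    yy <- rowMeans(resp)
  } else {
    xx <- rep(lv, times = ncol(resp))
    yy <- as.vector(resp)
  }
  fit <- stats::lm(yy ~ xx)
  sm <- suppressWarnings(summary(fit))
  if (is.null(df)) df <- length(xx) - 2L
  se_int <- sm$coefficients[1, 2]
  intc <- stats::coef(fit)[[1]]
  # numerically perfect fits: an exactly-zero intercept has t = 0, not 0/0
  tiny <- 1e-10 * max(abs(yy))
  tval <- if (se_int < tiny) {
    if (abs(intc) < tiny) 0 else Inf
  } else abs(intc) / se_int
  tc <- t_critical(alpha, df)
  r <- stats::cor(xx, yy)
  structure(list(compound = series$compound,
                 slope = stats::coef(fit)[[2]],
                 intercept = intc, r = r,
                 se_intercept = se_int, t = tval, df = df, t_crit = tc,
                 pass_r = r >= r_threshold, pass_intercept = tval <= tc,
                 pass = r >= r_threshold && tval <= tc),
            class = "linearity_fit")
}

#' @export
print.linearity_fit <- function(x, ...) {
  cat(sprintf(
    "Linearity%s: y = %.5g x %+.5g, r = %.4f (%s), t = %.4g vs %.3f (%s)\n",
    if (is.null(x$compound)) "" else paste0(" [", x$compound, "]"),
    x$slope, x$intercept, x$r, if (x$pass_r) "pass" else "FAIL",
    x$t, x$t_crit, if (x$pass_intercept) "pass" else "FAIL"))
  invisible(x)
}

#' LOD and LOQ from a measured signal-to-noise ratio
#'
#' The detection and quantification limits are scaled from the concentration
#' of an injected standard via the 3:1 and 10:1 S/N criteria:
#' `LOD = conc * 3 / (S/N)`, `LOQ = conc * 10 / (S/N)`, so `LOQ/LOD = 10/3`
#' by construction. S/N is measured with [measure_snr()].
#'
#' @param trace A `"chrom_trace"` containing the analyte peak.
#' @param peak_window,noise_window Time windows, minutes.
#' @param conc Concentration of the injected standard, ug/mL.
#' @param nominal Nominal working concentration for the percent scale
#'   (100 ug/mL).
#' @return Object of class `"sensitivity_result"`: `snr`, `lod_conc`,
#'   `loq_conc`, `lod_percent`, `loq_percent`, `basis`.
#' @export
lod_loq_from_trace <- function(trace, peak_window, noise_window, conc,
                               nominal = 100) {
  snr <- measure_snr(trace, peak_window, noise_window)
  lod <- conc * 3 / snr
  loq <- conc * 10 / snr
  structure(list(snr = snr, lod_conc = lod, loq_conc = loq,
                 lod_percent = relative_percent(lod, nominal),
                 loq_percent = relative_percent(loq, nominal),
                 basis = "sn_from_trace"),
            class = "sensitivity_result")
}

#' Scale an LOQ from an LOD
#'
#' `LOQ = LOD * 10/3`, rounded to 2 significant figures (so LODs of 0.012 and
#' 0.024 ug/mL give LOQs of 0.04 and 0.08).
#'
#' @param lod Detection limit, ug/mL (> 0).
#' @param digits Significant figures of the reported LOQ.
#' @return Quantification limit, ug/mL.
#' @export
loq_from_lod <- function(lod, digits = 2) {
  if (any(lod <= 0)) stop("lod must be positive")
  signif(lod * 10 / 3, digits)
}

#' Concentration as percent of the nominal test concentration
#'
#' @param conc Concentration, ug/mL.
#' @param nominal Nominal concentration, ug/mL (default 100).
#' @return `conc / nominal * 100`.
#' @export
relative_percent <- function(conc, nominal = 100) {
  if (any(nominal <= 0)) stop("nominal must be positive")
  conc / nominal * 100
}

#' Classify recovery records against the accuracy windows
#'
#' Acceptance windows: 98-102% for the active ingredient; for impurities the
#' window depends on the spiked level as percent of the API nominal
#' concentration: 70.0-130.0% at or below 0.5%, 80.0-120.0% above 0.5%.
#' Limits are inclusive.
#'
#' @param records Data frame with columns `compound`, `role` (`"API"` /
#'   `"impurity"`), `level_percent` (spiked concentration as % of the API
#'   nominal) and `recovery` (%).
#' @return `records` with `window_low`, `window_high` and `pass_accuracy`
#'   added.
#' @export
assess_accuracy <- function(records) {
  stopifnot(all(c("compound", "role", "level_percent", "recovery") %in%
                  names(records)))
  lo <- ifelse(records$role == "API", 98,
               ifelse(records$level_percent <= 0.5, 70, 80))
  hi <- ifelse(records$role == "API", 102,
               ifelse(records$level_percent <= 0.5, 130, 120))
  records$window_low <- lo
  records$window_high <- hi
  records$pass_accuracy <- records$recovery >= lo & records$recovery <= hi
  records
}

#' Classify precision records against the RSD thresholds
#'
#' Thresholds: 2% for the active substance, 10% for impurities C and D, 15%
#' for impurities A and B (inclusive).
#'
#' @param records Data frame with columns `compound` and `rsd` (%).
#' @param thresholds Named RSD limits.
#' @return `records` with `rsd_limit` and `pass_precision` added.
#' @export
assess_precision <- function(records,
                             thresholds = c(moxonidine = 2, impA = 15,
                                            impB = 15, impC = 10,
                                            impD = 10)) {
  stopifnot(all(c("compound", "rsd") %in% names(records)))
  lim <- thresholds[records$compound]
  if (any(is.na(lim)))
    stop("no RSD threshold for: ",
         paste(unique(records$compound[is.na(lim)]), collapse = ", "))
  records$rsd_limit <- unname(lim)
  records$pass_precision <- records$rsd <= records$rsd_limit
  records
}

#' One-factor-at-a-time robustness study
#'
#' Simulates the baseline conditions and each single-factor perturbation
#' (noiselessly, so the comparison isolates the factor effect) and reports
#' the percent changes of peak areas, retention times and the critical
#' resolutions. A perturbation passes when areas change by less than 5% and
#' retention times and resolutions by less than 3%.
#'
#' @param truth A [retention_truth()].
#' @param baseline A [method_conditions()]; defaults to the optimized method.
#' @param plan Data frame with columns `factor` (one of `"temperature"`,
#'   `"flow"`, `"ph"`, `"acn"`) and `delta`; defaults to the
#'   `+/-2` C, `+/-0.1` mL/min, `+/-0.05` pH, `+/-0.5`% ACN scheme.
#' @param limits Named percent-change limits.
#' @return Data frame of class `"robustness_result"`: one row per
#'   perturbation with `max_area_change`, `max_tr_change`, `max_rs_change`
#'   (%) and `pass`.
#' @export
robustness_ofat <- function(truth, baseline = method_conditions(),
                            plan = NULL,
                            limits = c(area = 5, tr = 3, rs = 3)) {
  if (is.null(plan))
    plan <- data.frame(
      factor = rep(c("temperature", "flow", "ph", "acn"), each = 2),
      delta = c(2, -2, 0.1, -0.1, 0.05, -0.05, 0.5, -0.5))
  base <- simulate_retention(truth, baseline, noise = FALSE)
  bvals <- list(area = base$area, tr = base$tr,
                rs = c(attr(base, "Rs_AB"), attr(base, "Rs_CD")))
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    f <- plan$factor[i]; d <- plan$delta[i]
    cond <- baseline
    cond[[f]] <- cond[[f]] + d
    cond <- do.call(method_conditions, cond[c("acn", "ph", "buffer",
                                              "temperature", "flow",
                                              "wavelength")])
    p <- simulate_retention(truth, cond, noise = FALSE)
    pvals <- list(area = p$area, tr = p$tr,
                  rs = c(attr(p, "Rs_AB"), attr(p, "Rs_CD")))
    chg <- vapply(c("area", "tr", "rs"), function(nm)
      max(abs(pvals[[nm]] / bvals[[nm]] - 1)) * 100, numeric(1))
    data.frame(factor = f, delta = d,
               max_area_change = chg[["area"]],
               max_tr_change = chg[["tr"]], max_rs_change = chg[["rs"]],
               pass = chg[["area"]] < limits[["area"]] &&
                 chg[["tr"]] < limits[["tr"]] &&
                 chg[["rs"]] < limits[["rs"]],
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("robustness_result", "data.frame"))
}

#' Selectivity check against a placebo trace
#'
#' Passes when the largest placebo signal inside every analyte retention
#' window stays below a fraction of the analyte peak height at the
#' quantification limit.
#'
#' @param placebo_trace A `"chrom_trace"` of the placebo injection.
#' @param windows List of `c(start, end)` windows (minutes), one per analyte.
#' @param reference_height Analyte peak height at the LOQ level (same signal
#'   units as the trace).
#' @param threshold Interference tolerance as a fraction of
#'   `reference_height`.
#' @return List with `pass`, `max_signal` per window and the applied
#'   `threshold`.
#' @export
assess_selectivity <- function(placebo_trace, windows, reference_height,
                               threshold = 0.5) {
  tw <- placebo_trace$time_min
  mx <- vapply(windows, function(wd) {
    inw <- tw >= wd[1] & tw <= wd[2]
    if (!any(inw)) stop("analyte window outside the trace span")
    max(abs(placebo_trace$signal[inw]))
  }, numeric(1))
  list(pass = all(mx < threshold * reference_height), max_signal = mx,
       threshold = threshold, reference_height = reference_height)
}

#' Tablet assay by inverse calibration
#'
#' Converts measured responses to concentrations through the calibration
#' lines and reports contents as percent of the nominal API concentration.
#' Concentrations below the quantification limit are flagged and not
#' reported numerically; below the detection limit they are flagged
#' `below_lod`.
#'
#' @param responses Named measured responses (areas).
#' @param calibrations Named list of `"linearity_fit"` objects (must pass
#'   their own acceptance checks).
#' @param loq,lod Named quantification/detection limits, ug/mL (compounds
#'   missing from the vectors are not flagged).
#' @param nominal_api Nominal API concentration of the preparation, ug/mL.
#' @return Data frame `compound`, `conc`, `content_percent`, `below_loq`,
#'   `below_lod`; flagged rows carry `NA` in `content_percent`.
#' @export
assay_tablet <- function(responses, calibrations, loq = NULL, lod = NULL,
                         nominal_api = 100) {
  cmp <- names(responses)
  if (is.null(cmp) || !all(cmp %in% names(calibrations)))
    stop("every response needs a calibration of the same name")
  bad <- cmp[!vapply(calibrations[cmp], `[[`, logical(1), "pass")]
  if (length(bad))
    stop("calibration failed its acceptance checks for: ",
         paste(bad, collapse = ", "))
  conc <- vapply(cmp, function(nm) {
    cal <- calibrations[[nm]]
    (responses[[nm]] - cal$intercept) / cal$slope
  }, numeric(1))
  bloq <- if (is.null(loq)) rep(FALSE, length(cmp)) else
    conc < ifelse(is.na(loq[cmp]), -Inf, loq[cmp])
  blod <- if (is.null(lod)) rep(FALSE, length(cmp)) else
    conc < ifelse(is.na(lod[cmp]), -Inf, lod[cmp])
  out <- data.frame(compound = cmp, conc = unname(conc),
                    content_percent = relative_percent(unname(conc),
                                                       nominal_api),
                    below_loq = unname(bloq), below_lod = unname(blod),
                    stringsAsFactors = FALSE)
  out$content_percent[out$below_loq] <- NA_real_
  out
}

#' Check impurity contents against a specification
#'
#' @param contents Output of [assay_tablet()] (or a data frame with
#'   `compound`, `content_percent`, `below_loq`).
#' @param limits Named impurity limits, percent.
#' @return List with `pass` and the per-impurity comparison. Below-LOQ
#'   entries pass by definition.
#' @export
check_specification <- function(contents,
                                limits = c(impA = 0.5, impB = 0.5,
                                           impC = 1, impD = 1)) {
  if (!length(limits)) return(list(pass = TRUE, detail = NULL))
  detail <- lapply(names(limits), function(nm) {
    row <- contents[contents$compound == nm, , drop = FALSE]
    if (!nrow(row)) return(NULL)
    ok <- isTRUE(row$below_loq) || (!is.na(row$content_percent) &&
                                      row$content_percent < limits[[nm]])
    data.frame(compound = nm, content_percent = row$content_percent,
               limit = limits[[nm]], below_loq = row$below_loq, pass = ok,
               stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, detail)
  list(pass = is.null(detail) || all(detail$pass), detail = detail)
}
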
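# Ground-truth log10 k surfaces, version 1.
#
# Each compound's log10 retention factor is quadratic in the coded mobile-phase
# factors (acn, ph, buffer). Moxonidine, impurity A and impurity C are fixed by
# hand; impurity B is A plus a gap surface g and impurity D is C plus a gap h.
# The gap free parameters below were obtained by constrained numerical
# calibration so that (i) A and B coelute at 70% ACN / pH 2.8 at any buffer
# level, (ii) Rs(A,B) at 75% / pH 4.68 / 40 mM equals 10.91 while C and D
# coelute there, (iii) the full separation at 80% / pH 2.8 / 40 mM finishes
# inside 12 min with both critical resolutions >= 2, (iv) the observed
# resolution surfaces stay close to quadratic over the screening design, and
# (v) small perturbations around the optimum (one-factor-at-a-time robustness)
# move retention times and resolutions by well under 3%. The remaining hard
# constraints in (i)-(ii) are re-solved exactly at construction time.
.truth_version <- "1"
.base_M <- c(0.3050, 0.15, 0.04, 0.01, 0.01, 0.01, 0, 0.02, 0, 0)
.base_A <- c(-0.34, 0.05, -0.26, -0.02, 0.02, -0.02, 0, -0.03, 0, -0.02)
.base_C <- c(0.4541, 0.14, 0.05, 0, 0.01, 0.01, 0, 0.02, 0, 0)
.gap_AB <- c(g2 = 0.17947556945932477, g11 = -0.078139500382865407,
             g22 = 0.025932139615958236, g12 = -0.097886647196243237)
.gap_CD <- c(q2 = -0.020690618285572344, z = -0.029665695696373697,
             q22 = -0.026295432517997954, q33 = -0.0085325965152820704,
             q12 = -0.03938112445688452)
.rs_AB_critical <- 10.91      # resolution of A/B at the C/D-coelution point
.kD_optimum <- 4.62           # retention factor of D at 80/2.8/40
.term_names <- c("intercept", "acn", "ph", "buffer", "acn^2", "ph^2",
                 "buffer^2", "acn:ph", "acn:buffer", "ph:buffer")

quad_at <- function(b, u, v, w) {
  b[1] + b[2] * u + b[3] * v + b[4] * w + b[5] * u^2 + b[6] * v^2 +
    b[7] * w^2 + b[8] * u * v + b[9] * u * w + b[10] * v * w
}

# exact re-solve of the gap surfaces from the frozen free parameters
truth_coefficients <- function() {
  v3 <- (4.68 - 3.5) / 0.7       # coded pH of the C/D critical point
  kA3 <- 10^quad_at(.base_A, 0, v3, 0)
  Rs <- .rs_AB_critical
  G3 <- log10((2 * Rs + kA3 * (Rs + 50)) / (kA3 * (50 - Rs)))
  p <- .gap_AB
  g1 <- G3 - p["g2"] * (1 + v3) + p["g11"] - p["g22"] * (v3^2 - 1) + p["g12"]
  dlt <- g1 + p["g2"] - p["g11"] - p["g22"] - p["g12"]
  gap_ab <- c(dlt, g1, p["g2"], 0, p["g11"], p["g22"], 0, p["g12"], 0, 0)

  kC4 <- 10^quad_at(.base_C, 1, -1, 0)
  H4 <- log10(.kD_optimum / kC4)
  q <- .gap_CD
  q0 <- -(q["q2"] * v3 + q["q22"] * v3^2)
  q1 <- H4 - q0 + q["q2"] - q["z"] - q["q22"] + q["q12"]
  gap_cd <- c(q0, q1, q["q2"], 0, q["z"], q["q22"], q["q33"], q["q12"], 0, 0)

  B <- rbind(moxonidine = .base_M, impA = .base_A,
             impB = .base_A + unname(gap_ab), impC = .base_C,
             impD = .base_C + unname(gap_cd))
  colnames(B) <- .term_names
  B
}

#' Compound set of the moxonidine HILIC method
#'
#' Moxonidine and its four pharmacopoeial impurities with their calculated
#' pKa and log P values. All five are weak bases (guanidine nitrogen) carrying
#' a +1 charge at the acidic working pH.
#'
#' @return Data frame with columns `compound`, `pKa`, `logP`, `role`.
#' @export
moxonidine_compounds <- function() {
  data.frame(
    compound = c("moxonidine", "impA", "impB", "impC", "impD"),
    pKa  = c(7.92, 7.06, 7.48, 7.17, 6.95),
    logP = c(1.77, 2.49, 1.60, 1.57, 2.01),
    role = c("API", "impurity", "impurity", "impurity", "impurity"),
    stringsAsFactors = FALSE)
}

#' The calibrated ground-truth retention surface
#'
#' Assembles the shipped synthetic ground truth: per-compound quadratic
#' log10 k surfaces in the coded mobile-phase factors plus the peak, noise and
#' detector parameters that turn retention factors into chromatographic
#' observables. The defaults are a versioned constant set calibrated so that
#' the simulator reproduces the critical behaviour of the real separation:
#' A/B coelution at 70% ACN / pH 2.8 at any buffer level, C/D coelution with
#' Rs(A,B) = 10.91 at 75% / pH 4.68 / 40 mM, and complete separation within
#' 12 min at 80% / pH 2.8 / 40 mM.
#'
#' @param coefficients 5 x 10 matrix of log10 k surface coefficients
#'   (intercept + 9 quadratic terms, coded units), rows
#'   `moxonidine, impA, impB, impC, impD`.
#' @param t0 Column dead time in minutes at the reference flow (250 x 4.6 mm
#'   column, porosity ~0.66, 1 mL/min).
#' @param plate_count Column plate number N; peak base width is
#'   `4 tR / sqrt(N)`.
#' @param temp_coef Linear temperature sensitivity of log10 k (per degree C,
#'   relative to `ref_temperature`).
#' @param flow_exponent Empirical exponent of the retention-time/flow-rate
#'   dependence: `tR` scales with `(ref_flow/flow)^flow_exponent`.
#' @param sigma_logk_run SD of the run-level (shared across compounds)
#'   log10 k noise; models mobile-phase batch variability.
#' @param sigma_logk_compound SD of the compound-specific log10 k noise. The
#'   marginal log10 k noise SD is `sqrt(run^2 + compound^2)` (0.01 by
#'   default).
#' @param response_factors Detector response (area units per ug/mL) per
#'   compound.
#' @param baseline_sigma Baseline white-noise SD (area-unit scale) for
#'   simulated chromatograms.
#' @param standard_conc Standard-mixture concentrations (ug/mL) used for
#'   default peak areas.
#' @return An object of class `"retention_truth"`.
#' @export
retention_truth <- function(coefficients = truth_coefficients(),
                            t0 = 2.05,
                            plate_count = 1e4,
                            temp_coef = -0.005,
                            flow_exponent = 0.25,
                            sigma_logk_run = 0.01 / sqrt(2),
                            sigma_logk_compound = 0.01 / sqrt(2),
                            response_factors = c(moxonidine = 29142.47,
                                                 impA = 24.45681,
                                                 impB = 27.659,
                                                 impC = 18.18141,
                                                 impD = 11.82117),
                            baseline_sigma = 0.25,
                            standard_conc = c(moxonidine = 100, impA = 0.5,
                                              impB = 0.5, impC = 1, impD = 1)) {
  stopifnot(is.matrix(coefficients), nrow(coefficients) == 5,
            ncol(coefficients) == 10, t0 > 0, plate_count > 0)
  structure(list(coefficients = coefficients,
                 compounds = moxonidine_compounds(),
                 factors = hilic_factors(),
                 t0 = t0, plate_count = plate_count, temp_coef = temp_coef,
                 flow_exponent = flow_exponent,
                 sigma_logk_run = sigma_logk_run,
                 sigma_logk_compound = sigma_logk_compound,
                 response_factors = response_factors,
                 baseline_sigma = baseline_sigma,
                 standard_conc = standard_conc,
                 ref_temperature = 25, ref_flow = 1,
                 version = .truth_version),
            class = "retention_truth")
}

#' @export
print.retention_truth <- function(x, ...) {
  cat("Synthetic HILIC retention ground truth (version", x$version, ")\n")
  cat(sprintf("  5 compounds, t0 = %.2f min, N = %g plates\n",
              x$t0, x$plate_count))
  cat("  log10 k surface coefficients (coded factors):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Chromatographic method conditions
#'
#' @param acn Acetonitrile content, % v/v (admissible 60-90).
#' @param ph Aqueous-phase pH (admissible 2-6).
#' @param buffer Ammonium formate concentration, mM (admissible 5-80).
#' @param temperature Column temperature, degrees C.
#' @param flow Flow rate, mL/min (admissible 0.5-2).
#' @param wavelength Detection wavelength, nm.
#' @return An object of class `"method_conditions"`. The defaults are the
#'   optimized separation conditions (80:20 v/v acetonitrile : 40 mM ammonium
#'   formate pH 2.8, 25 C, 1 mL/min, 255 nm).
#' @export
method_conditions <- function(acn = 80, ph = 2.8, buffer = 40,
                              temperature = 25, flow = 1, wavelength = 255) {
  chk <- function(val, lo, hi, what)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) ||
        val < lo || val > hi)
      stop(what, " = ", val, " outside the admissible range [", lo, ", ",
           hi, "]")
  chk(acn, 60, 90, "acn"); chk(ph, 2, 6, "ph"); chk(buffer, 5, 80, "buffer")
  chk(flow, 0.5, 2, "flow")
  structure(list(acn = acn, ph = ph, buffer = buffer,
                 temperature = temperature, flow = flow,
                 wavelength = wavelength),
            class = "method_conditions")
}

#' @export
print.method_conditions <- function(x, ...) {
  cat(sprintf("ACN %g%% / pH %g / %g mM, %g C, %g mL/min, %g nm\n",
              x$acn, x$ph, x$buffer, x$temperature, x$flow, x$wavelength))
  invisible(x)
}

#' Retention factor
#'
#' `k = (tR - t0) / t0`.
#'
#' @param tr Retention time (min), `tr >= t0`.
#' @param t0 Dead time (min), positive.
#' @return Dimensionless retention factor.
#' @export
retention_factor <- function(tr, t0) {
  if (any(t0 <= 0)) stop("t0 must be positive")
  if (any(tr < t0)) stop("tR must not be smaller than t0")
  (tr - t0) / t0
}

#' Resolution between two peaks
#'
#' Baseline-width convention: `Rs = 2 |tR2 - tR1| / (w1 + w2)` with `w` the
#' 4-sigma base widths. `Rs >= 2` corresponds to baseline separation of
#' Gaussian peaks.
#'
#' @param tr1,tr2 Retention times (min).
#' @param w1,w2 Base peak widths (min), positive.
#' @return Non-negative resolution.
#' @export
resolution <- function(tr1, tr2, w1, w2) {
  if (any(w1 <= 0) || any(w2 <= 0)) stop("peak widths must be positive")
  2 * abs(tr2 - tr1) / (w1 + w2)
}

#' Simulate a chromatographic run
#'
#' Evaluates the ground-truth log10 k surfaces at the given conditions,
#' optionally adds retention noise, and derives the chromatographic
#' observables: retention times `tR = t0 (1 + k)` scaled by the flow
#' dependence, Gaussian base widths from the plate count, peak areas from the
#' detector response factors, and the critical pair resolutions.
#'
#' @param truth A [retention_truth()].
#' @param conditions A [method_conditions()].
#' @param noise Add log10 k noise (run-shared + compound-specific)?
#' @param seed Seed for the noise draws.
#' @param conc Named concentrations (ug/mL) injected; defaults to the
#'   standard mixture in `truth`.
#' @return An object of class `"chrom_outcome"`: a data frame with one row
#'   per compound (`compound`, `k`, `tr`, `width`, `area`, `height`) and
#'   attributes `Rs_AB`, `Rs_CD`, `last_peak_time` and `conditions`.
#' @examples
#' out <- simulate_retention(retention_truth(), method_conditions())
#' attr(out, "Rs_AB"); attr(out, "last_peak_time")
#' @export
simulate_retention <- function(truth, conditions, noise = FALSE, seed = NULL,
                               conc = truth$standard_conc) {
  stopifnot(inherits(truth, "retention_truth"),
            inherits(conditions, "method_conditions"))
  if (!is.null(seed)) set.seed(seed)
  cv <- to_coded(c(conditions$acn, conditions$ph, conditions$buffer),
                 truth$factors)
  logk <- apply(truth$coefficients, 1, quad_at, u = cv[1], v = cv[2],
                w = cv[3])
  logk <- logk + truth$temp_coef * (conditions$temperature -
                                      truth$ref_temperature)
  if (noise) {
    logk <- logk + stats::rnorm(1, 0, truth$sigma_logk_run) +
      stats::rnorm(length(logk), 0, truth$sigma_logk_compound)
  }
  k <- 10^logk
  tr <- truth$t0 * (1 + k) *
    (truth$ref_flow / conditions$flow)^truth$flow_exponent
  w <- 4 * tr / sqrt(truth$plate_count)
  area <- unname(truth$response_factors[names(k)] * conc[names(k)])
  height <- area / (w / 4 * sqrt(2 * pi))
  out <- data.frame(compound = names(k), k = unname(k), tr = unname(tr),
                    width = unname(w), area = area, height = height,
                    stringsAsFactors = FALSE)
  structure(out, class = c("chrom_outcome", "data.frame"),
            Rs_AB = unname(resolution(tr[["impA"]], tr[["impB"]], w[["impA"]],
                                      w[["impB"]])),
            Rs_CD = unname(resolution(tr[["impC"]], tr[["impD"]], w[["impC"]],
                                      w[["impD"]])),
            last_peak_time = max(tr), conditions = conditions)
}

#' @export
print.chrom_outcome <- function(x, ...) {
  print(attr(x, "conditions"))
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], signif, 5)
  print(df, row.names = FALSE)
  cat(sprintf("Rs(A,B) = %.3f  Rs(C,D) = %.3f  last peak %.2f min\n",
              attr(x, "Rs_AB"), attr(x, "Rs_CD"), attr(x, "last_peak_time")))
  invisible(x)
}

#' Run the in-silico screening study
#'
#' Simulates one chromatographic run per design row and assembles the
#' response table followed in the screening study: retention factors of the
#' five compounds and the two critical-pair resolutions.
#'
#' @param truth A [retention_truth()].
#' @param design A [ccd_design()] built on the mobile-phase factors.
#' @param seed Seed for the retention noise.
#' @param noise Add retention noise?
#' @return A data frame of class `"response_table"` with columns `run_id`,
#'   `k_M`, `k_A`, `k_B`, `k_C`, `k_D`, `Rs_AB`, `Rs_CD`.
#' @export
generate_study <- function(truth, design, seed = NULL, noise = TRUE) {
  stopifnot(inherits(truth, "retention_truth"))
  if (!is.null(seed)) set.seed(seed)
  acts <- as.matrix(design[paste0(factor_names(truth$factors), "_actual")])
  rows <- lapply(seq_len(nrow(acts)), function(i) {
    cond <- method_conditions(acn = acts[i, 1], ph = acts[i, 2],
                              buffer = acts[i, 3])
    out <- simulate_retention(truth, cond, noise = noise)
    k <- stats::setNames(out$k, out$compound)
    data.frame(run_id = design$run_id[i], k_M = k[["moxonidine"]],
               k_A = k[["impA"]], k_B = k[["impB"]], k_C = k[["impC"]],
               k_D = k[["impD"]], Rs_AB = unname(attr(out, "Rs_AB")),
               Rs_CD = unname(attr(out, "Rs_CD")))
  })
  structure(do.call(rbind, rows),
            class = c("response_table", "data.frame"))
}
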
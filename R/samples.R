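# Calibration, recovery and assay sample generators for the validation
# battery. Concentrations are ug/mL throughout; the nominal test
# concentration of the API is 100 ug/mL, so an impurity level of 0.5 ug/mL
# corresponds to 0.5%.

#' Default calibration levels
#'
#' Nine equally spaced levels from the LOQ to 120% of the nominal impurity
#' concentration (0.04-0.6 ug/mL for impurities A and B, 0.08-1.2 ug/mL for C
#' and D), and six levels spanning 25-150 ug/mL for moxonidine.
#'
#' @param compound One of `"moxonidine"`, `"impA"`, `"impB"`, `"impC"`,
#'   `"impD"`.
#' @return Numeric vector of concentrations (ug/mL).
#' @export
calibration_levels <- function(compound) {
  switch(compound,
         moxonidine = seq(25, 150, length.out = 6),
         impA = , impB = seq(0.04, 0.6, length.out = 9),
         impC = , impD = seq(0.08, 1.2, length.out = 9),
         stop("unknown compound: ", compound))
}

#' Simulate a calibration series
#'
#' Linear detector response with mildly heteroscedastic Gaussian noise:
#' `response = slope * conc + intercept + eps`, `eps ~ N(0, sigma0 +
#' sigma_rel * response)`. By default `sigma0` is 0.3% of the mid-level
#' response and `sigma_rel = 0.5%`.
#'
#' @param compound Compound name (used for default levels).
#' @param true_slope Response factor (area per ug/mL).
#' @param true_intercept True intercept (area units).
#' @param levels Concentration levels; defaults to [calibration_levels()].
#' @param n_reps Replicate injections per level.
#' @param sigma0 Additive noise SD; `NULL` for 0.3% of the mid response.
#' @param sigma_rel Proportional noise SD.
#' @param seed Seed.
#' @return Object of class `"calibration_series"`: list with `compound`,
#'   `levels`, `responses` (levels x reps matrix) and `seed`.
#' @export
simulate_calibration <- function(compound, true_slope, true_intercept = 0,
                                 levels = NULL, n_reps = 3, sigma0 = NULL,
                                 sigma_rel = 0.005, seed = NULL) {
  if (is.null(levels)) levels <- calibration_levels(compound)
  if (is.unsorted(levels, strictly = TRUE))
    stop("'levels' must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  mu <- true_slope * levels + true_intercept
  if (is.null(sigma0)) sigma0 <- 0.003 * mu[ceiling(length(mu) / 2)]
  resp <- vapply(seq_len(n_reps), function(r)
    pmax(0, mu + stats::rnorm(length(mu), 0, sigma0 + sigma_rel * mu)),
    numeric(length(levels)))
  resp <- matrix(resp, nrow = length(levels))
  structure(list(compound = compound, levels = levels, responses = resp,
                 seed = seed),
            class = "calibration_series")
}

#' @export
print.calibration_series <- function(x, ...) {
  cat(sprintf("Calibration series for %s: %d levels (%g-%g ug/mL), %d reps\n",
              x$compound, length(x$levels), min(x$levels), max(x$levels),
              ncol(x$responses)))
  invisible(x)
}

#' Nominal spiking concentrations for accuracy/precision work
#'
#' The 100% level is the nominal working concentration (100 ug/mL for the
#' API, 0.5 ug/mL for impurities A/B, 1.0 ug/mL for C/D); the LOQ level is
#' the quantification limit (0.04 / 0.08 ug/mL).
#'
#' @param compound Compound name.
#' @param level One of `"LOQ"`, `"80"`, `"100"`, `"120"`.
#' @return Concentration in ug/mL.
#' @export
nominal_level <- function(compound, level) {
  base <- switch(compound, moxonidine = 100, impA = , impB = 0.5,
                 impC = , impD = 1.0, stop("unknown compound: ", compound))
  loq <- switch(compound, moxonidine = 10, impA = , impB = 0.04,
                impC = , impD = 0.08)
  switch(as.character(level),
         LOQ = loq, "80" = 0.8 * base, "100" = base, "120" = 1.2 * base,
         stop("unknown level: ", level))
}

#' Simulate spiked-placebo recovery samples
#'
#' Placebo spiked at the given levels; the "found" concentration is
#' `nominal * (bias + eps)` with `eps ~ N(0, rsd)`.
#'
#' @param compound Compound name.
#' @param levels Character vector of level labels; defaults to LOQ/100/120
#'   for impurities and 80/100/120 for the API.
#' @param bias True recovery as a fraction (1 = 100%).
#' @param rsd Relative SD of an individual preparation.
#' @param n_per_level Replicate preparations per level (3 in the validation
#'   plan).
#' @param seed Seed.
#' @return Data frame `compound`, `level`, `replicate`, `nominal`, `found`.
#' @export
simulate_spiked_placebo <- function(compound, levels = NULL, bias = 1,
                                    rsd = 0.01, n_per_level = 3,
                                    seed = NULL) {
  if (is.null(levels))
    levels <- if (compound == "moxonidine") c("80", "100", "120")
              else c("LOQ", "100", "120")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(levels, function(lv) {
    nom <- nominal_level(compound, lv)
    data.frame(compound = compound, level = lv,
               replicate = seq_len(n_per_level), nominal = nom,
               found = nom * (bias + stats::rnorm(n_per_level, 0, rsd)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a tablet assay sample
#'
#' Emulates the tablet work-up: a preparation nominally at 100 ug/mL of
#' moxonidine whose true contents are given as percent of the API nominal
#' concentration, measured with proportional detector noise.
#'
#' @param truth A [retention_truth()] (supplies the response factors).
#' @param content Named true contents, percent of the API nominal: the API
#'   entry is the assay content, impurity entries are area-percent-style
#'   impurity levels. Defaults place impurities A/B below the quantification
#'   limit.
#' @param noise_rsd Relative SD of a measured response.
#' @param seed Seed.
#' @return List with `responses` (named areas), `true_conc` (ug/mL),
#'   `nominal_api` and `content`.
#' @export
simulate_tablet_sample <- function(truth,
                                   content = c(moxonidine = 97.5,
                                               impA = 0.012, impB = 0.018,
                                               impC = 0.68, impD = 0.87),
                                   noise_rsd = 0.005, seed = NULL) {
  stopifnot(inherits(truth, "retention_truth"))
  if (any(content < 0)) stop("contents must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  nominal_api <- 100
  conc <- nominal_api * content / 100
  rf <- truth$response_factors[names(conc)]
  resp <- rf * conc * (1 + stats::rnorm(length(conc), 0, noise_rsd))
  list(responses = resp, true_conc = conc, nominal_api = nominal_api,
       content = content)
}
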
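# Published validation benchmarks for the moxonidine HILIC impurity method,
# shipped as plain-text fixtures. Used as classification inputs (the recovery
# and RSD values to be judged against the acceptance windows) and as default
# detector response factors.

#' Benchmark recovery and precision results
#'
#' The reported accuracy/precision results of the validated moxonidine HILIC
#' method: recovery (%) and RSD (%) of triplicate spiked-placebo preparations
#' at three levels per compound (80/100/120% for the API, LOQ/100/120% for
#' the impurities). `level_percent` is the spiked concentration as percent of
#' the nominal API concentration (100 ug/mL) and selects the accuracy window
#' in [assess_accuracy()].
#'
#' @return Data frame with columns `compound`, `role`, `level`,
#'   `conc_ug_ml`, `level_percent`, `recovery`, `rsd`.
#' @export
recovery_benchmark <- function() {
  utils::read.csv(system.file("extdata", "recovery_benchmark.csv",
                              package = "chromdoe"),
                  stringsAsFactors = FALSE)
}

#' Benchmark calibration statistics
#'
#' The reported calibration-line statistics of the validated method:
#' regression slope and intercept (peak area on ug/mL), correlation
#' coefficient, intercept t statistic and the tabulated critical value.
#'
#' @return Data frame with columns `compound`, `range_low`, `range_high`,
#'   `slope`, `intercept`, `r`, `t`, `t_tab`.
#' @export
calibration_benchmark <- function() {
  utils::read.csv(system.file("extdata", "calibration_benchmark.csv",
                              package = "chromdoe"),
                  stringsAsFactors = FALSE)
}
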
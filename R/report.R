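#' Assemble a validation report
#'
#' Bundles the section results of the validation battery and derives the
#' overall pass flag (the conjunction of all section passes).
#'
#' @param linearity Named list of `"linearity_fit"` objects.
#' @param sensitivity Named list of `"sensitivity_result"` objects.
#' @param recovery Recovery records after [assess_accuracy()] and
#'   [assess_precision()].
#' @param robustness A `"robustness_result"` data frame.
#' @param selectivity Result of [assess_selectivity()].
#' @param assay Result of [assay_tablet()].
#' @param specification Result of [check_specification()].
#' @return Object of class `"validation_report"` with a `sections` pass table
#'   and `pass` overall flag.
#' @export
validation_report <- function(linearity, sensitivity, recovery, robustness,
                              selectivity, assay, specification) {
  sections <- c(
    linearity = all(vapply(linearity, `[[`, logical(1), "pass")),
    accuracy = all(recovery$pass_accuracy),
    precision = all(recovery$pass_precision),
    robustness = all(robustness$pass),
    selectivity = isTRUE(selectivity$pass),
    assay = isTRUE(specification$pass))
  structure(list(linearity = linearity, sensitivity = sensitivity,
                 recovery = recovery, robustness = robustness,
                 selectivity = selectivity, assay = assay,
                 specification = specification, sections = sections,
                 pass = all(sections)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("ICH validation report:",
      if (x$pass) "PASS" else "FAIL", "\n")
  for (nm in names(x$sections))
    cat(sprintf("  %-12s %s\n", nm, if (x$sections[[nm]]) "pass" else "FAIL"))
  invisible(x)
}

#' Write a validation report to disk
#'
#' Writes a machine-readable JSON and a human-readable markdown summary.
#'
#' @param report A `"validation_report"`.
#' @param path Base path; `.json` and `.md` files are written next to it
#'   (`path.json`, `path.md`).
#' @return Invisibly, the two file paths.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  jf <- paste0(path, ".json"); mf <- paste0(path, ".md")
  jsonlite::write_json(unclass_deep(report), jf, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  lines <- c("# Validation report", "",
             paste0("Overall: ", if (report$pass) "PASS" else "FAIL"), "",
             "| section | result |", "|---|---|",
             sprintf("| %s | %s |", names(report$sections),
                     ifelse(report$sections, "pass", "FAIL")),
             "", "## Linearity", "",
             sprintf("- %s: r = %.4f, t = %.3f (crit %.3f) -> %s",
                     names(report$linearity),
                     vapply(report$linearity, `[[`, numeric(1), "r"),
                     vapply(report$linearity, `[[`, numeric(1), "t"),
                     vapply(report$linearity, `[[`, numeric(1), "t_crit"),
                     ifelse(vapply(report$linearity, `[[`, logical(1),
                                   "pass"), "pass", "FAIL")),
             "", "## Sensitivity", "",
             sprintf("- %s: LOD %.4g ug/mL, LOQ %.4g ug/mL",
                     names(report$sensitivity),
                     vapply(report$sensitivity, `[[`, numeric(1),
                            "lod_conc"),
                     vapply(report$sensitivity, `[[`, numeric(1),
                            "loq_conc")))
  writeLines(lines, mf)
  invisible(c(json = jf, markdown = mf))
}

# strip S3 classes recursively so jsonlite serializes plain structures
unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(unclass(x)))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
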
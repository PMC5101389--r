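# End-to-end in-silico study: design -> simulate -> fit -> optimize ->
# validate -> report, deterministic for a fixed seed.

response_columns <- c("k_M", "k_A", "k_B", "k_C", "k_D", "Rs_AB", "Rs_CD")

#' Read / write a study response table
#'
#' The CSV carries `run_id` plus the seven response columns
#' `k_M, k_A, k_B, k_C, k_D, Rs_AB, Rs_CD`. Reading is lossless and tolerates
#' surrounding whitespace; a missing column raises an error naming it.
#'
#' @param path File path.
#' @param responses A response table ([generate_study()] output or
#'   compatible data frame).
#' @return `read_responses()` returns a `"response_table"` data frame.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  missing <- setdiff(c("run_id", response_columns), names(df))
  if (length(missing))
    stop("response table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(!stats::complete.cases(df[c("run_id", response_columns)]))
  if (length(bad))
    stop("malformed response row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))
  structure(df, class = c("response_table", "data.frame"))
}

#' @rdname read_responses
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE)
  invisible(path)
}

#' Fit the seven response-surface models of a study
#'
#' One PLS1 model per response (retention factors of the five compounds and
#' the two critical resolutions) on the quadratic term block of the design.
#'
#' @param design A [ccd_design()].
#' @param responses A response table matching the design rows.
#' @param ncomp Components per model (`NULL` selects by Q2).
#' @return Named list of `"pls1"` fits.
#' @export
fit_study_models <- function(design, responses, ncomp = NULL) {
  if (nrow(design) != nrow(responses))
    stop("design and response table have different run counts")
  X <- expand_terms(design)
  stats::setNames(lapply(response_columns, function(r)
    fit_pls(X, responses[[r]], ncomp = ncomp)), response_columns)
}

#' Run the full in-silico method-development study
#'
#' Builds the 20-run central composite design, simulates the screening study
#' on the ground-truth retention surface, fits the seven PLS response-surface
#' models, searches the fitted surfaces for the best separation conditions,
#' and runs the ICH validation battery (calibration linearity, S/N-based
#' LOD/LOQ, spiked-placebo accuracy/precision, OFAT robustness, selectivity
#' and tablet assay) at the selected conditions. Deterministic for a fixed
#' seed.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param outdir Optional output directory; when given, the artifact bundle
#'   (design/response CSVs, model coefficient tables, optimum CSV,
#'   validation JSON/markdown, manifest with content hashes) is written
#'   there.
#' @param truth A [retention_truth()].
#' @param n_center Center replicates of the design.
#' @param noise Simulate retention noise in the screening study?
#' @param criteria An [optimization_criteria()].
#' @return Object of class `"hilic_study"`: list with `design`, `responses`,
#'   `models`, `coefficient_tables`, `optimum`, `validation`, `seed`.
#' @export
run_study <- function(seed = 1, outdir = NULL, truth = retention_truth(),
                      n_center = 6, noise = TRUE,
                      criteria = optimization_criteria()) {
  base_seed <- as.integer(seed) %% 1000000L
  factors <- truth$factors
  design <- ccd_design(factors, n_center = n_center)
  responses <- generate_study(truth, design, seed = base_seed + 1L,
                              noise = noise)
  models <- fit_study_models(design, responses)
  ctabs <- lapply(models, coefficient_table)
  optimum <- optimize_conditions(models, factors, criteria,
                                 t0 = truth$t0)
  validation <- run_validation(truth, base_seed)
  out <- structure(list(design = design, responses = responses,
                        models = models, coefficient_tables = ctabs,
                        optimum = optimum, validation = validation,
                        seed = seed),
                   class = "hilic_study")
  if (!is.null(outdir)) write_study_bundle(out, outdir)
  out
}

#' @export
print.hilic_study <- function(x, ...) {
  cat("In-silico HILIC method-development study (seed", x$seed, ")\n")
  cat(sprintf("  %d-run design; model Q2: %s\n", nrow(x$design),
              paste(sprintf("%s %.2f", names(x$models),
                            vapply(x$models, `[[`, numeric(1), "Q2")),
                    collapse = ", ")))
  if (attr(x$optimum, "feasible")) {
    top <- x$optimum[1, ]
    cat(sprintf("  selected conditions: %.1f%% ACN, pH %.2f, %.0f mM (min Rs %.2f, %.1f min)\n",
                top$acn, top$ph, top$buffer,
                min(top$Rs_AB, top$Rs_CD), top$runtime))
  } else cat("  no feasible conditions found\n")
  cat("  validation:", if (x$validation$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}

# the ICH battery against the simulator, seeded per stage
run_validation <- function(truth, base_seed) {
  compounds <- moxonidine_compounds()
  cmp <- compounds$compound

  # linearity: one calibration series per compound
  linearity <- list(); series <- list()
  for (i in seq_along(cmp)) {
    series[[cmp[i]]] <- simulate_calibration(
      cmp[i], true_slope = truth$response_factors[[cmp[i]]],
      seed = base_seed + 10L + i)
    linearity[[cmp[i]]] <- fit_linearity(series[[cmp[i]]])
  }

  # sensitivity: S/N of a dilute impurity standard at the optimized method
  cond <- method_conditions()
  sensitivity <- list()
  imps <- cmp[cmp != "moxonidine"]
  for (i in seq_along(imps)) {
    conc_std <- nominal_level(imps[i], "LOQ") * 2
    conc <- stats::setNames(rep(0, length(cmp)), cmp)
    conc[imps[i]] <- conc_std
    out <- simulate_retention(truth, cond, conc = conc)
    tr <- out$tr[out$compound == imps[i]]
    trace <- simulate_chromatogram(out, baseline_sigma =
                                     truth$baseline_sigma,
                                   seed = base_seed + 20L + i)
    sensitivity[[imps[i]]] <- lod_loq_from_trace(
      trace, peak_window = c(tr - 0.3, tr + 0.3),
      noise_window = c(0.2, 1.6), conc = conc_std)
  }

  # accuracy / precision from spiked placebo
  rec <- list()
  for (i in seq_along(cmp)) {
    sp <- simulate_spiked_placebo(cmp[i], seed = base_seed + 30L + i)
    agg <- lapply(split(sp, sp$level), function(d) data.frame(
      compound = cmp[i],
      role = compounds$role[match(cmp[i], cmp)],
      level = d$level[1], nominal = d$nominal[1],
      level_percent = relative_percent(d$nominal[1]),
      recovery = mean(d$found / d$nominal) * 100,
      rsd = 100 * stats::sd(d$found) / mean(d$found),
      stringsAsFactors = FALSE))
    rec[[i]] <- do.call(rbind, agg)
  }
  recovery <- assess_precision(assess_accuracy(do.call(rbind, rec)))
  rownames(recovery) <- NULL

  robustness <- robustness_ofat(truth, baseline = cond)

  # selectivity: placebo trace vs analyte windows at LOQ-level heights
  std <- simulate_retention(truth, cond)
  placebo <- simulate_chromatogram(NULL, baseline_sigma =
                                     truth$baseline_sigma,
                                   duration = max(std$tr) + 2,
                                   seed = base_seed + 40L)
  loq_conc <- stats::setNames(
    vapply(cmp, function(nm) nominal_level(nm, "LOQ"), numeric(1)), cmp)
  loq_out <- simulate_retention(truth, cond, conc = loq_conc)
  windows <- lapply(seq_len(nrow(std)), function(i)
    c(std$tr[i] - 0.3, std$tr[i] + 0.3))
  selectivity <- assess_selectivity(placebo, windows,
                                    reference_height = min(loq_out$height))

  # tablet assay against the fitted calibrations
  sample <- simulate_tablet_sample(truth, seed = base_seed + 50L)
  loq <- vapply(imps, function(nm) sensitivity[[nm]]$loq_conc, numeric(1))
  lod <- vapply(imps, function(nm) sensitivity[[nm]]$lod_conc, numeric(1))
  assay <- assay_tablet(sample$responses, linearity, loq = loq, lod = lod,
                        nominal_api = sample$nominal_api)
  specification <- check_specification(assay)

  validation_report(linearity, sensitivity, recovery, robustness,
                    selectivity, assay, specification)
}

write_study_bundle <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  p <- function(f) file.path(outdir, f)
  write_design(study$design, p("design.csv")); files <- c(files, "design.csv")
  write_responses(study$responses, p("responses.csv"))
  files <- c(files, "responses.csv")
  for (nm in names(study$coefficient_tables)) {
    f <- paste0("coefficients_", nm, ".csv")
    utils::write.csv(study$coefficient_tables[[nm]], p(f), row.names = FALSE)
    files <- c(files, f)
  }
  model_stats <- data.frame(
    response = names(study$models),
    ncomp = vapply(study$models, `[[`, numeric(1), "ncomp"),
    R2 = vapply(study$models, `[[`, numeric(1), "R2"),
    Q2 = vapply(study$models, `[[`, numeric(1), "Q2"))
  jsonlite::write_json(model_stats, p("models.json"), digits = NA,
                       pretty = TRUE)
  files <- c(files, "models.json")
  utils::write.csv(as.data.frame(study$optimum), p("optimum.csv"),
                   row.names = FALSE)
  files <- c(files, "optimum.csv")
  write_report(study$validation, p("validation"))
  files <- c(files, "validation.json", "validation.md")
  hashes <- tools::md5sum(file.path(outdir, files))
  writeLines(sprintf("%s  %s", hashes, files), p("manifest.txt"))
  invisible(outdir)
}

#' Read a factor configuration file
#'
#' JSON (or YAML, if the yaml package is installed) list of factors with
#' fields `name`, `center`, `step`, `unit`.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return List of [factor_def()] objects.
#' @export
read_factors <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML needs the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  unname(lapply(raw, function(f)
    factor_def(f$name, f$center, f$step,
               if (is.null(f$unit)) "" else f$unit)))
}
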
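#' Printed demographic and clinical summaries of the reference cohort
#'
#' The published group summaries the package's reporting layer is checked
#' against: per-group means/SDs/sizes for the continuous variables and
#' per-group counts for the categorical ones, for the five groups
#' LFG (n=27), LTG (26), RFG (29), RTG (27), HC (42). These printed numbers
#' are inputs (no subject-level data exist for them); the ANOVA and
#' chi-square statistics are recomputed from them with
#' [anova_oneway_summary()] and [chisq_independence()].
#'
#' @return Named list of tibbles: `age`, `education`, `tumor_volume` (each
#'   `group`, `mean`, `sd`, `n`), `gender` (`group`, `male`, `female`),
#'   `pathological_types` and `pathological_grades` (`group` + one count
#'   column per category; patient groups only).
#' @export
#' @examples
#' anova_oneway_summary(ln_demographics()$education)
ln_demographics <- function() {
  groups <- c("LFG", "LTG", "RFG", "RTG", "HC")
  pat <- groups[1:4]
  list(
    age = tibble::tibble(
      group = groups,
      mean = c(45.04, 42.35, 40.76, 43.44, 39.55),
      sd = c(12.82, 11.53, 12.68, 13.93, 9.96),
      n = c(27, 26, 29, 27, 42)),
    education = tibble::tibble(
      group = groups,
      mean = c(11.37, 13.12, 12.61, 11.93, 13.71),
      sd = c(3.58, 3.99, 3.78, 4.70, 3.79),
      n = c(27, 26, 29, 27, 42)),
    tumor_volume = tibble::tibble(
      group = pat,
      mean = c(106.6, 85.58, 110.7, 98.16),
      sd = c(64.60, 44.69, 67.60, 66.77),
      n = c(27, 26, 29, 27)),
    gender = tibble::tibble(
      group = groups,
      male = c(15, 10, 15, 18, 24),
      female = c(12, 16, 14, 9, 18)),
    pathological_types = tibble::tibble(
      group = pat,
      low_grade = c(15, 13, 15, 12),
      anaplastic = c(7, 8, 5, 4),
      glioblastoma = c(5, 5, 9, 11)),
    pathological_grades = tibble::tibble(
      group = pat,
      low_grade = c(15, 13, 15, 12),
      high_grade = c(12, 13, 14, 15)))
}

counts_matrix <- function(tab) {
  m <- as.matrix(tab[, setdiff(names(tab), "group")])
  rownames(m) <- tab$group
  m
}

#' Demographics report from a subject table
#'
#' Per-group mean (+/- SD) with a one-way ANOVA for numeric variables and
#' per-group counts with a Pearson chi-square for categorical variables —
#' the standard cohort-characteristics table.
#'
#' @param subjects Data frame with a `group` column.
#' @param numeric_vars,categorical_vars Column names to summarise.
#' @return Tibble: `variable`, `test`, `statistic`, `df1`, `df2`, `p_value`,
#'   and a `summary` list-column of the per-group summaries. Variables with
#'   a single group get NA statistics and a notice.
#' @export
table1_report <- function(subjects, numeric_vars = character(),
                          categorical_vars = character()) {
  if (!"group" %in% names(subjects))
    abort("table1_report(): subjects must have a 'group' column")
  miss <- setdiff(c(numeric_vars, categorical_vars), names(subjects))
  if (length(miss) > 0)
    abort(paste0("table1_report(): missing column(s): ",
                 paste(miss, collapse = ", ")))
  rows <- list()
  for (v in numeric_vars) {
    sub <- subjects[!is.na(subjects[[v]]), ]
    summ <- sub |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(mean = mean(.data[[v]]), sd = sd(.data[[v]]),
                       n = dplyr::n(), .groups = "drop")
    if (nrow(summ) < 2) {
      inform(paste0("table1_report(): '", v, "' has a single group; ANOVA skipped"))
      rows[[v]] <- tibble::tibble(variable = v, test = "none",
                                  statistic = NA_real_, df1 = NA_real_,
                                  df2 = NA_real_, p_value = NA_real_,
                                  summary = list(summ))
    } else {
      a <- anova_oneway(sub, !!rlang::sym(v), group)
      rows[[v]] <- tibble::tibble(variable = v, test = "one-way ANOVA",
                                  statistic = a$statistic, df1 = a$df1,
                                  df2 = a$df2, p_value = a$p_value,
                                  summary = list(summ))
    }
  }
  for (v in categorical_vars) {
    tab <- table(subjects$group, subjects[[v]])
    summ <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "group")
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      inform(paste0("table1_report(): '", v, "' is degenerate; chi-square skipped"))
      rows[[v]] <- tibble::tibble(variable = v, test = "none",
                                  statistic = NA_real_, df1 = NA_real_,
                                  df2 = NA_real_, p_value = NA_real_,
                                  summary = list(summ))
    } else {
      ch <- chisq_independence(unclass(tab))
      rows[[v]] <- tibble::tibble(variable = v, test = "Pearson chi-square",
                                  statistic = ch$statistic, df1 = ch$df1,
                                  df2 = NA_real_, p_value = ch$p_value,
                                  summary = list(summ))
    }
  }
  dplyr::bind_rows(rows)
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown arguments are
#' rejected.
#'
#' @param cohort A [cohort_config()] for simulate mode.
#' @param alpha FDR level for the edge-wise tests (default 0.05).
#' @param fdr_method `"BH"` or `"BY"`.
#' @param fdr_scope `"per_group"` or `"pooled"`.
#' @param mnc_scope `"core"` (6-node indices) or `"all"`.
#' @param roi_source `"fixture"` (the shipped canonical ROI set; the ICA
#'   path is exercised on phantoms via [group_ica()] directly).
#' @param out_dir Optional output directory; if given, [run_pipeline()]
#'   writes the result bundle there.
#' @param ... Unknown keys — always an error.
#' @return List of class `ln_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), alpha = 0.05,
                            fdr_method = c("BH", "BY"),
                            fdr_scope = c("per_group", "pooled"),
                            mnc_scope = c("core", "all"),
                            roi_source = "fixture", out_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra) > 0)
    abort(paste0("pipeline_config(): unknown key(s): ",
                 paste(names(extra), collapse = ", ")))
  stopifnot(inherits(cohort, "ln_cohort_config"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    abort("pipeline_config(): alpha must be in (0, 1)")
  if (!identical(roi_source, "fixture"))
    abort("pipeline_config(): roi_source must be 'fixture'; run the ICA path via group_ica() on phantom volumes")
  structure(list(cohort = cohort, alpha = alpha,
                 fdr_method = match.arg(fdr_method),
                 fdr_scope = match.arg(fdr_scope),
                 mnc_scope = match.arg(mnc_scope),
                 roi_source = roi_source, out_dir = out_dir),
            class = "ln_pipeline_config")
}

#' Run the end-to-end simulated-cohort pipeline
#'
#' Simulate -> edge-wise connectivity -> mNC -> group inference, returning
#' (and optionally writing) the full result bundle: subject table, 45-column
#' edge table, edge-wise test results, typology counts and chi-square, mNC
#' ANOVA/Tukey tables, ipsi/contra analysis, tumor-volume correlations, and
#' a provenance record (config, seed, package version). Byte-identical
#' outputs are produced for identical configurations.
#'
#' @param config An [pipeline_config()] (default configuration if omitted).
#' @return List of class `ln_pipeline_result` with elements `subjects`,
#'   `edges_wide`, `edge_tests`, `typology`, `typology_test`, `mnc`,
#'   `mnc_anova`, `ipsi_contra`, `tv_correlation`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "ln_pipeline_config"))
  cohort <- generate_cohort(config$cohort)
  edges <- cohort_edges(cohort)
  mnc <- compute_mnc(edges, scope = config$mnc_scope)
  edge_tests <- edgewise_reduction_test(edges, alpha = config$alpha,
                                        fdr_method = config$fdr_method,
                                        fdr_scope = config$fdr_scope)
  typ <- typology_counts(edge_tests)
  typ_test <- tryCatch(hemispheric_typology_test(typ),
                       error = function(e) NULL)
  mnc_anova <- mnc_group_analysis(mnc)
  patients <- mnc[mnc$group != "HC", ]
  ic <- ipsi_contra_analysis(patients)
  tvc <- tv_correlation(patients)
  edges_wide <- edges |>
    dplyr::select(dplyr::all_of(c("subject_id", "group", "edge", "z"))) |>
    tidyr::pivot_wider(names_from = "edge", values_from = "z")
  prov <- list(package = "langnet",
               version = as.character(utils::packageVersion("langnet")),
               seed = config$cohort$seed,
               alpha = config$alpha, fdr_method = config$fdr_method,
               fdr_scope = config$fdr_scope, mnc_scope = config$mnc_scope,
               n_per_group = as.list(config$cohort$n_per_group),
               n_timepoints = config$cohort$n_timepoints)
  res <- structure(list(subjects = cohort$subjects, edges_wide = edges_wide,
                        edge_tests = edge_tests, typology = typ,
                        typology_test = typ_test, mnc = mnc,
                        mnc_anova = mnc_anova, ipsi_contra = ic,
                        tv_correlation = tvc, provenance = prov,
                        cohort = cohort),
                   class = "ln_pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(res, config$out_dir)
  res
}

#' Write a pipeline result bundle to disk
#'
#' CSV for the tabular outputs, JSON for test results and provenance.
#'
#' @param result An `ln_pipeline_result`.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(result$subjects, "subjects.csv")
  wcsv(result$edges_wide, "edges.csv")
  wcsv(result$mnc, "mnc.csv")
  wcsv(result$typology, "typology.csv")
  tests <- list(
    edgewise = result$edge_tests,
    typology_chisq = result$typology_test,
    mnc_anova = result$mnc_anova$anova,
    mnc_tukey = result$mnc_anova$tukey,
    ipsi_contra_main = result$ipsi_contra$main_effect,
    ipsi_contra_paired = result$ipsi_contra$paired,
    tv_correlation = result$tv_correlation)
  jsonlite::write_json(tests, file.path(out_dir, "test_results.json"),
                       digits = NA, pretty = TRUE, null = "null")
  jsonlite::write_json(result$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.ln_pipeline_result <- function(x, ...) {
  cat("<ln_pipeline_result>\n")
  cat("  subjects:", nrow(x$subjects), "\n")
  cat("  significant reduced edges:",
      sum(x$edge_tests$significant), "of", nrow(x$edge_tests), "tests\n")
  cat("  typology (left/right direct+indirect):",
      paste(x$typology$direct + x$typology$indirect, collapse = " / "), "\n")
  invisible(x)
}
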
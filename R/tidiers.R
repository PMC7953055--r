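#' Turn a langnet result object into a tidy tibble
#'
#' Broom-convention tidiers for the package's fitted objects. `tidy()`
#' returns the per-comparison table, `glance()` the one-row-per-model
#' summary.
#'
#' @param x A fitted object (currently `ln_mnc_anova`).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
tidy.ln_mnc_anova <- function(x, ...) x$tukey

#' @rdname tidy
#' @export
glance.ln_mnc_anova <- function(x, ...) x$anova

#' @export
print.ln_mnc_anova <- function(x, ...) {
  cat("<ln_mnc_anova> one-way ANOVA + Tukey HSD over",
      length(unique(x$data$group)), "groups\n")
  print(x$anova[, c("index", "statistic", "df1", "df2", "p_value")])
  sig <- x$tukey[x$tukey$p_adj < 0.05 & x$tukey$vs_hc, ]
  cat(nrow(sig), "significant patient-vs-HC Tukey comparisons at 0.05\n")
  invisible(x)
}
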
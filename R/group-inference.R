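#' Edge-wise reduction tests against healthy controls
#'
#' For every patient group, each of the 45 edges is compared with the HC
#' edge values by an independent two-sample t test, one-tailed in the
#' reduction direction (patient < HC), with Benjamini-Hochberg FDR applied
#' across the 45 edges within each group-vs-HC comparison (the FDR family;
#' `fdr_scope = "pooled"` corrects across all comparisons at once).
#' Significant reduced edges are typed `direct` (incident to the lesioned
#' subsystem) or `indirect` (both endpoints outside it).
#'
#' @param edges Long edge tibble from [cohort_edges()] (columns
#'   `subject_id`, `group`, `edge`, `z`).
#' @param alpha FDR level (default 0.05).
#' @param hc_group Label of the control group (default `"HC"`).
#' @param var_equal Pooled-variance t (default TRUE; FALSE gives Welch).
#' @param fdr_method `"BH"` (default) or `"BY"`.
#' @param fdr_scope `"per_group"` (default) or `"pooled"`.
#' @return Tibble: `group`, `edge`, `node1`, `node2`, `statistic`, `df`,
#'   `p`, `p_adj`, `significant`, `edge_type` (`direct` / `indirect` for
#'   significant edges, `"n/a"` otherwise), `mean_patient`, `mean_hc`.
#' @export
edgewise_reduction_test <- function(edges, alpha = 0.05, hc_group = "HC",
                                    var_equal = TRUE,
                                    fdr_method = c("BH", "BY"),
                                    fdr_scope = c("per_group", "pooled")) {
  fdr_method <- match.arg(fdr_method)
  fdr_scope <- match.arg(fdr_scope)
  need <- c("subject_id", "group", "edge", "z")
  if (!all(need %in% names(edges)))
    abort("edgewise_reduction_test(): edges must have subject_id, group, edge, z")
  wide <- edges |>
    dplyr::select(dplyr::all_of(c("subject_id", "group", "edge", "z"))) |>
    tidyr::pivot_wider(names_from = "edge", values_from = "z")
  if (!hc_group %in% wide$group)
    abort(paste0("edgewise_reduction_test(): no '", hc_group, "' group"))
  edge_names <- setdiff(names(wide), c("subject_id", "group"))
  hmat <- as.matrix(wide[wide$group == hc_group, edge_names])
  pat_groups <- setdiff(unique(wide$group), hc_group)
  group_sub <- ln_group_subsystem()
  res <- purrr::map_dfr(pat_groups, function(g) {
    pmat <- as.matrix(wide[wide$group == g, edge_names])
    np <- nrow(pmat); nh <- nrow(hmat)
    if (np < 2 || nh < 2)
      abort("edgewise_reduction_test(): each side needs >= 2 subjects")
    mp <- colMeans(pmat); mh <- colMeans(hmat)
    vp <- apply(pmat, 2, var); vh <- apply(hmat, 2, var)
    if (var_equal) {
      df <- np + nh - 2
      sp2 <- ((np - 1) * vp + (nh - 1) * vh) / df
      if (any(sp2 == 0))
        abort("edgewise_reduction_test(): zero pooled variance on an edge")
      tstat <- (mp - mh) / sqrt(sp2 * (1 / np + 1 / nh))
      dfv <- rep(df, length(tstat))
    } else {
      se2 <- vp / np + vh / nh
      tstat <- (mp - mh) / sqrt(se2)
      dfv <- se2^2 / ((vp / np)^2 / (np - 1) + (vh / nh)^2 / (nh - 1))
    }
    p <- pt(tstat, dfv)                       # one-tailed: patient < HC
    tibble::tibble(group = g, edge = edge_names, statistic = tstat,
                   df = dfv, p = p, mean_patient = mp, mean_hc = mh)
  })
  if (fdr_scope == "per_group") {
    res <- res |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(bh_fdr(.data$p, alpha, fdr_method)[, c("p_adj", "significant")]) |>
      dplyr::ungroup()
  } else {
    res <- dplyr::mutate(res,
      bh_fdr(res$p, alpha, fdr_method)[, c("p_adj", "significant")])
  }
  parts <- strsplit(res$edge, "-", fixed = TRUE)
  res$node1 <- vapply(parts, `[[`, "", 1)
  res$node2 <- vapply(parts, `[[`, "", 2)
  res$edge_type <- ifelse(
    res$significant,
    classify_edge(res$edge, group_sub[res$group]),
    "n/a")
  res[, c("group", "edge", "node1", "node2", "statistic", "df", "p",
          "p_adj", "significant", "edge_type", "mean_patient", "mean_hc")]
}

#' Classify an edge as directly or indirectly affected
#'
#' An edge is `direct` if at least one endpoint node belongs to the lesioned
#' subsystem (tumor-infiltrated connection) and `indirect` if both endpoints
#' lie in non-neoplastic modules. Midline and cerebellar nodes belong to no
#' subsystem, so they can only contribute indirect endpoints.
#'
#' @param edge Character vector of edge keys (`"node1-node2"`).
#' @param subsystem Lesioned subsystem per edge (recycled if length 1):
#'   `"LF"`, `"LT"`, `"RF"` or `"RT"`.
#' @param atlas Node-to-subsystem map (default [ln_subsystems()]).
#' @return Character vector, `"direct"` or `"indirect"`.
#' @export
#' @examples
#' classify_edge("lIFG-rSTG", "LF")   # direct
#' classify_edge("rIFG-rSTG", "LT")   # indirect
classify_edge <- function(edge, subsystem, atlas = ln_subsystems()) {
  if (length(subsystem) == 1) subsystem <- rep(subsystem, length(edge))
  stopifnot(length(subsystem) == length(edge))
  if (!all(subsystem %in% c("LF", "LT", "RF", "RT")))
    abort("classify_edge(): subsystem must be one of LF, LT, RF, RT")
  parts <- strsplit(edge, "-", fixed = TRUE)
  n1 <- vapply(parts, `[[`, "", 1); n2 <- vapply(parts, `[[`, "", 2)
  bad <- setdiff(unique(c(n1, n2)), names(atlas))
  if (length(bad) > 0)
    abort(paste0("classify_edge(): unknown node(s): ", paste(bad, collapse = ", ")))
  ifelse(atlas[n1] == subsystem | atlas[n2] == subsystem, "direct", "indirect")
}

#' Direct/indirect edge counts pooled by lesion hemisphere
#'
#' Counts significant reduced edges by type, pooling left-lesion groups
#' (LFG + LTG) against right-lesion groups (RFG + RTG).
#'
#' @param edge_results Output of [edgewise_reduction_test()].
#' @return Tibble: `pool` (`left`, `right`), `direct`, `indirect`.
#' @export
typology_counts <- function(edge_results) {
  sig <- edge_results[edge_results$significant &
                        edge_results$edge_type != "n/a", ]
  pool_of <- ifelse(sig$group %in% c("LFG", "LTG"), "left", "right")
  tibble::tibble(
    pool = c("left", "right"),
    direct = unname(vapply(c("left", "right"), function(p)
      sum(pool_of == p & sig$edge_type == "direct"), numeric(1))),
    indirect = unname(vapply(c("left", "right"), function(p)
      sum(pool_of == p & sig$edge_type == "indirect"), numeric(1))))
}

#' Chi-square test on the hemispheric edge typology
#'
#' Pearson chi-square on the 2 x 2 table of direct/indirect significant-edge
#' counts for left- vs right-hemisphere lesion pools.
#'
#' @param counts Tibble from [typology_counts()] (columns `pool`, `direct`,
#'   `indirect`).
#' @return One-row test tibble (see [chisq_independence()]).
#' @export
hemispheric_typology_test <- function(counts) {
  m <- as.matrix(counts[, c("direct", "indirect")])
  rownames(m) <- counts$pool
  chisq_independence(m)
}

#' Group-level ANOVA and Tukey HSD for the mNC indices
#'
#' One-way ANOVA across the five groups for each mNC index, with all
#' pairwise Tukey comparisons; patient-vs-HC pairs are flagged, along with
#' whether the patient mean lies below the HC mean (a reduction).
#'
#' @param mnc mNC tibble from [compute_mnc()] (needs `group` plus the index
#'   columns).
#' @param indices Index columns to analyse (default the four mNC indices).
#' @param hc_group Control group label (default `"HC"`).
#' @return Object of class `ln_mnc_anova`: list with `anova` (one row per
#'   index) and `tukey` (one row per index x group pair, with `vs_hc` and
#'   `reduction` flags). [tidy()] returns the Tukey table, [glance()] the
#'   ANOVA table, [autoplot()] the group-means figure.
#' @export
mnc_group_analysis <- function(mnc, indices = c("lFCw", "rFCw", "FCb", "FCg"),
                               hc_group = "HC") {
  miss <- setdiff(c("group", indices), names(mnc))
  if (length(miss) > 0)
    abort(paste0("mnc_group_analysis(): missing column(s): ",
                 paste(miss, collapse = ", ")))
  if (length(unique(mnc$group)) < 2)
    abort("mnc_group_analysis(): need >= 2 groups")
  anova_tab <- purrr::map_dfr(indices, function(ix)
    dplyr::mutate(anova_oneway(mnc, !!rlang::sym(ix), group), index = ix,
                  .before = 1))
  tukey_tab <- purrr::map_dfr(indices, function(ix)
    dplyr::mutate(tukey_hsd(mnc, !!rlang::sym(ix), group), index = ix,
                  .before = 1))
  tukey_tab <- tukey_tab |>
    dplyr::mutate(
      vs_hc = (.data$group1 == hc_group) != (.data$group2 == hc_group),
      reduction = .data$vs_hc &
        ifelse(.data$group2 == hc_group, .data$diff < 0, .data$diff > 0))
  structure(list(anova = anova_tab, tukey = tukey_tab, data = mnc,
                 indices = indices, hc_group = hc_group),
            class = "ln_mnc_anova")
}

#' Ipsi- vs contralesional within-hemisphere connectivity analysis
#'
#' Two-level repeated-measures ANOVA of FCw side (ipsi vs contra) as the
#' within-subject factor with patient group as the between-subject factor
#' (error df `N - k` by the exact difference-score formulation), plus a
#' paired t test within each patient subgroup.
#'
#' @param mnc Patient mNC tibble (no HC rows) with `subject_id` and `group`.
#' @return List: `main_effect` (one-row tibble), `paired` (one row per
#'   group: paired t of ipsi minus contra), `data` (the ipsi/contra-labelled
#'   tibble).
#' @export
ipsi_contra_analysis <- function(mnc) {
  ic <- ipsi_contra(mnc)
  long <- ic |>
    dplyr::select(dplyr::all_of(c("subject_id", "group", "ipsiFCw", "contraFCw"))) |>
    tidyr::pivot_longer(c("ipsiFCw", "contraFCw"),
                        names_to = "fcw_side", values_to = "value")
  main <- mixed_anova_within(long, subject_id, value, fcw_side, group)
  paired <- ic |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ paired_t(.x$ipsiFCw, .x$contraFCw)) |>
    dplyr::ungroup()
  list(main_effect = main, paired = paired, data = ic)
}

#' Correlation of mNC indices with tumor volume
#'
#' Pearson correlation (two-sided p) between tumor volume and each mNC index
#' within each patient subgroup.
#'
#' @param mnc Patient mNC tibble with `group` and `tumor_volume_cm3`.
#' @param indices Index columns (default the four mNC indices).
#' @param min_n Minimum subgroup size (default 4).
#' @return Tibble: `group`, `index`, `n`, `estimate` (r), `statistic`,
#'   `df1`, `p_value`.
#' @export
tv_correlation <- function(mnc, indices = c("lFCw", "rFCw", "FCb", "FCg"),
                           min_n = 4) {
  need <- c("group", "tumor_volume_cm3", indices)
  miss <- setdiff(need, names(mnc))
  if (length(miss) > 0)
    abort(paste0("tv_correlation(): missing column(s): ",
                 paste(miss, collapse = ", ")))
  pats <- mnc[!is.na(mnc$tumor_volume_cm3), ]
  purrr::map_dfr(unique(pats$group), function(g) {
    sub <- pats[pats$group == g, ]
    if (nrow(sub) < min_n)
      abort(paste0("tv_correlation(): subgroup ", g, " has n < ", min_n))
    purrr::map_dfr(indices, function(ix) {
      ct <- pearson_cor(sub$tumor_volume_cm3, sub[[ix]])
      tibble::tibble(group = g, index = ix, n = nrow(sub),
                     estimate = ct$estimate, statistic = ct$statistic,
                     df1 = ct$df1, p_value = ct$p_value)
    })
  })
}
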
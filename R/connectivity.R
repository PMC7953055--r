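#' Preprocess ROI time series
#'
#' Per-node linear detrending, least-squares removal of confound regressors,
#' and zero-phase (forward-backward) Butterworth band-pass filtering — the
#' numerically simple tail of a resting-state preprocessing stream.
#'
#' @param ts Time-by-node numeric matrix.
#' @param confounds Optional time-by-regressor matrix to residualise against
#'   (an intercept is always included).
#' @param band Optional `c(low, high)` pass band in Hz (default
#'   `c(0.01, 0.08)`); set to NULL to skip filtering. `high` must lie below
#'   the Nyquist frequency `1 / (2 * tr)`.
#' @param tr Repetition time in seconds.
#' @param detrend Remove a per-node linear trend (default TRUE).
#' @param order Butterworth section order passed to [signal::butter()]
#'   (default 2, i.e. a 4th-order band-pass), applied forward-backward.
#' @return Time-by-node matrix of the same shape.
#' @export
#' @examples
#' x <- matrix(rnorm(400), 200, 2)
#' y <- preprocess_timeseries(x, band = c(0.01, 0.08), tr = 2)
preprocess_timeseries <- function(ts, confounds = NULL, band = c(0.01, 0.08),
                                  tr = 2, detrend = TRUE, order = 2) {
  ts <- as.matrix(ts)
  n <- nrow(ts)
  design <- matrix(1, n, 1)
  if (detrend) design <- cbind(design, seq_len(n))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n)
      abort("preprocess_timeseries(): confounds must have one row per time point")
    design <- cbind(design, confounds)
  }
  out <- ts - design %*% qr.coef(qr(design), ts)
  if (!is.null(band)) {
    nyq <- 1 / (2 * tr)
    if (band[2] >= nyq)
      abort(paste0("preprocess_timeseries(): band upper edge ", band[2],
                   " Hz is at or above the Nyquist frequency ", nyq, " Hz"))
    if (band[1] <= 0 || band[1] >= band[2])
      abort("preprocess_timeseries(): need 0 < low < high")
    bf <- signal::butter(order, band / nyq, type = "pass")
    out <- apply(out, 2, function(col) signal::filtfilt(bf, col))
  }
  colnames(out) <- colnames(ts)
  out
}

# voxel-center positions: grid is list(dim, voxel_mm); the grid centre voxel
# sits at 0 mm on each axis
grid_spec <- function(dim, voxel_mm) {
  stopifnot(length(dim) == 3, length(voxel_mm) == 3, all(voxel_mm > 0))
  list(dim = as.integer(dim), voxel_mm = as.numeric(voxel_mm),
       origin = (as.integer(dim) + 1) / 2)
}

voxel_to_mm <- function(idx, grid) {
  sweep(sweep(idx, 2, grid$origin, `-`), 2, grid$voxel_mm, `*`)
}

# logical 3-D array: voxel centres within radius_mm of center_mm
sphere_voxels <- function(center_mm, radius_mm, grid) {
  d <- grid$dim
  ax <- lapply(1:3, function(a) ((seq_len(d[a]) - grid$origin[a]) *
                                   grid$voxel_mm[a] - center_mm[a])^2)
  arr <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  arr <= radius_mm^2
}

#' Extract mean ROI time series from a 4-D volume
#'
#' Per-frame mean of the voxels inside a sphere around each ROI's peak
#' coordinate. Spheres extending outside the grid are truncated (noted via a
#' message); an ROI left empty after truncation is an error.
#'
#' @param bold 4-D numeric array `x, y, z, t`.
#' @param roi_set ROI tibble as from [ln_rois()] or [peak_rois()] (columns
#'   `node`, `x`, `y`, `z`, `radius_mm`).
#' @param voxel_mm Voxel dimensions in mm (length 3).
#' @return Time-by-node matrix.
#' @export
extract_roi_timeseries <- function(bold, roi_set, voxel_mm) {
  stopifnot(length(dim(bold)) == 4)
  grid <- grid_spec(dim(bold)[1:3], voxel_mm)
  nt <- dim(bold)[4]
  flat <- matrix(bold, prod(grid$dim), nt)
  out <- matrix(NA_real_, nt, nrow(roi_set),
                dimnames = list(NULL, roi_set$node))
  half_fov <- grid$voxel_mm * grid$dim / 2
  for (i in seq_len(nrow(roi_set))) {
    ctr <- c(roi_set$x[i], roi_set$y[i], roi_set$z[i])
    r <- roi_set$radius_mm[i]
    if (any(abs(ctr) + r > half_fov))
      inform(paste0("extract_roi_timeseries(): sphere for ", roi_set$node[i],
                    " truncated at the grid boundary"))
    sel <- which(sphere_voxels(ctr, r, grid))
    if (length(sel) == 0)
      abort(paste0("extract_roi_timeseries(): ROI '", roi_set$node[i],
                   "' contains no voxels on this grid"))
    out[, i] <- colMeans(flat[sel, , drop = FALSE])
  }
  out
}

#' Edge-wise Fisher-z connectivity vector
#'
#' All pairwise Pearson correlations among the node time series, Fisher-z
#' transformed — one value per unordered node pair (45 for the canonical
#' 10-node set).
#'
#' @param ts Time-by-node matrix with node column names.
#' @return Tibble with columns `edge`, `node1`, `node2`, `z`, ordered as
#'   [ln_edges()] of the columns.
#' @export
#' @examples
#' ts <- simulate_subject(diag(3) + 0.2 - diag(0.2, 3), 100, seed = 1)
#' colnames(ts) <- c("lIFG", "lMFG", "lSTG")
#' edge_vector(ts)
edge_vector <- function(ts) {
  ts <- as.matrix(ts)
  if (is.null(colnames(ts))) abort("edge_vector(): ts needs node column names")
  if (nrow(ts) < 4) abort("edge_vector(): need at least 4 time points")
  sds <- apply(ts, 2, sd)
  if (any(sds == 0))
    abort(paste0("edge_vector(): zero-variance node(s): ",
                 paste(colnames(ts)[sds == 0], collapse = ", ")))
  cm <- cor(ts)
  stopifnot(all(abs(diag(cm) - 1) < 1e-12))
  ed <- ln_edges(colnames(ts))
  r <- cm[cbind(ed$node1, ed$node2)]
  names(r) <- ed$edge
  ed$z <- unname(fisher_z(r))
  ed
}

#' Edge vectors for every subject of a cohort
#'
#' @param cohort An `ln_cohort` from [generate_cohort()].
#' @return Long tibble: subject metadata plus `edge`, `node1`, `node2`, `z`
#'   (45 rows per subject).
#' @export
cohort_edges <- function(cohort) {
  stopifnot(inherits(cohort, "ln_cohort"))
  purrr::map_dfr(cohort$subjects$subject_id, function(id) {
    dplyr::bind_cols(
      cohort$subjects[cohort$subjects$subject_id == id, ],
      edge_vector(cohort$timeseries[[id]]))
  })
}

mnc_edge_sets <- function() {
  left <- c("lIFG", "lMFG", "lSTG"); right <- c("rIFG", "rMFG", "rSTG")
  pairs_of <- function(a, b) {
    g <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    g <- g[g$a != g$b, ]
    unique(edge_name(g$a, g$b))
  }
  list(lFCw = pairs_of(left, left), rFCw = pairs_of(right, right),
       FCb = pairs_of(left, right))
}

#' Mean network connectivity (mNC) indices
#'
#' Reduces a subject's 45-edge Fisher-z vector to four indices over the six
#' core homotopic nodes (bilateral IFG, MFG, STG): `lFCw` / `rFCw` are the
#' means of the three within-hemisphere edges on each side, `FCb` the mean of
#' the nine interhemispheric edges, and `FCg` the mean of all fifteen core
#' edges, so `FCg = (3 lFCw + 3 rFCw + 9 FCb) / 15` by construction. Edges
#' touching the midline or cerebellar nodes are excluded. With
#' `scope = "all"`, `FCg` instead averages all 45 edges.
#'
#' @param edges Tibble with columns `edge` and `z`; if a `subject_id` column
#'   is present the computation is done per subject and the subject metadata
#'   columns (`group`, `subsystem`, `tumor_volume_cm3`, if present) are
#'   carried through.
#' @param scope `"core"` (default) or `"all"` (10-node global index).
#' @return Tibble with columns `lFCw`, `rFCw`, `FCb`, `FCg` (one row per
#'   subject).
#' @export
compute_mnc <- function(edges, scope = c("core", "all")) {
  scope <- match.arg(scope)
  sets <- mnc_edge_sets()
  one <- function(df) {
    z <- setNames(df$z, df$edge)
    miss <- setdiff(unlist(sets), names(z))
    if (length(miss) > 0)
      abort(paste0("compute_mnc(): missing core edge(s): ",
                   paste(miss, collapse = ", ")))
    lw <- mean(z[sets$lFCw]); rw <- mean(z[sets$rFCw]); fb <- mean(z[sets$FCb])
    fg <- if (scope == "core") (3 * lw + 3 * rw + 9 * fb) / 15 else mean(z)
    tibble::tibble(lFCw = lw, rFCw = rw, FCb = fb, FCg = fg)
  }
  if (!"subject_id" %in% names(edges)) return(one(edges))
  meta_cols <- intersect(c("subject_id", "group", "subsystem",
                           "tumor_volume_cm3"), names(edges))
  edges |>
    dplyr::group_by(dplyr::across(dplyr::all_of(meta_cols))) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Relabel within-hemisphere indices as ipsi-/contralesional
#'
#' For patients, maps `lFCw`/`rFCw` onto `ipsiFCw` (same side as the tumor)
#' and `contraFCw` (opposite side) from the group label: left-lesion groups
#' (LFG, LTG) have `ipsiFCw = lFCw`; right-lesion groups mirrored.
#'
#' @param mnc mNC tibble with a `group` column (patients only; healthy
#'   controls have no lesion side, so HC rows are an error).
#' @return Input tibble with `side`, `ipsiFCw`, `contraFCw` columns added.
#' @export
ipsi_contra <- function(mnc) {
  if (!all(c("group", "lFCw", "rFCw") %in% names(mnc)))
    abort("ipsi_contra(): need columns group, lFCw, rFCw")
  if (any(mnc$group == "HC"))
    abort("ipsi_contra(): ipsi/contralesional indices are undefined for HC; filter patients first")
  bad <- setdiff(unique(mnc$group), c("LFG", "LTG", "RFG", "RTG"))
  if (length(bad) > 0)
    abort(paste0("ipsi_contra(): unknown group(s): ", paste(bad, collapse = ", ")))
  mnc |>
    dplyr::mutate(
      side = ifelse(.data$group %in% c("LFG", "LTG"), "left", "right"),
      ipsiFCw = ifelse(.data$side == "left", .data$lFCw, .data$rFCw),
      contraFCw = ifelse(.data$side == "left", .data$rFCw, .data$lFCw))
}
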
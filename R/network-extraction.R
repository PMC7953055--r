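sym_orth <- function(w) {
  s <- svd(w)
  s$u %*% t(s$v)
}

#' Desk-scale group spatial ICA
#'
#' Temporal concatenation of subject volumes, per-voxel variance
#' normalisation, PCA reduction to `k` dimensions, and fixed-point ICA with
#' symmetric decorrelation (tanh contrast) on the spatial maps — the
#' group-ICA recipe at phantom scale. Deterministic under a fixed seed.
#'
#' @param volumes List of 4-D arrays (`x, y, z, t`) sharing one grid.
#' @param k Number of components.
#' @param seed Integer seed for the random orthogonal initialisation.
#' @param mask Optional 3-D logical analysis mask; defaults to voxels with
#'   nonzero variance in every subject.
#' @param max_iter,tol Fixed-point iteration cap and convergence tolerance.
#' @return List of class `ln_ica`: `maps` (4-D array `x, y, z, k`,
#'   standardised to zero mean / unit variance inside the mask), `mixing`
#'   (concatenated-time x k), `mask`, `iterations`, `dim`.
#' @export
group_ica <- function(volumes, k, seed = 1, mask = NULL,
                      max_iter = 200, tol = 1e-6) {
  if (length(volumes) < 2) abort("group_ica(): need at least 2 subjects")
  d <- dim(volumes[[1]])[1:3]
  mats <- lapply(volumes, function(v) {
    stopifnot(identical(dim(v)[1:3], d))
    t(matrix(v, prod(d), dim(v)[4]))          # time x voxels
  })
  if (is.null(mask)) {
    ok <- Reduce(`&`, lapply(mats, function(m) apply(m, 2, sd) > 0))
    mask <- array(ok, d)
  }
  sel <- which(as.vector(mask))
  if (length(sel) <= 10 * k)
    abort("group_ica(): too few masked voxels for the requested k")
  # centre every voxel time course, one variance scale per subject (per-voxel
  # z-scoring would raise pure-noise voxels to source-level variance)
  mats <- lapply(mats, function(m) {
    m <- scale(m[, sel, drop = FALSE], scale = FALSE)
    m / sqrt(mean(m^2))
  })
  x <- do.call(rbind, mats)
  x <- sweep(x, 2, colMeans(x))
  nv <- ncol(x)
  # PCA via the small Gram matrix (time x time)
  g <- tcrossprod(x)
  eg <- eigen(g, symmetric = TRUE)
  if (eg$values[k] <= 0) abort("group_ica(): rank-deficient data for this k")
  u <- eg$vectors[, seq_len(k), drop = FALSE]
  lam <- eg$values[seq_len(k)]
  y <- t(crossprod(x, u) %*% diag(1 / sqrt(lam), k)) * sqrt(nv)  # k x voxels
  set.seed(seed)
  w <- sym_orth(matrix(rnorm(k * k), k, k))
  it <- 0L
  repeat {
    it <- it + 1L
    s <- w %*% y
    gs <- tanh(s)
    w1 <- gs %*% t(y) / nv - diag(rowMeans(1 - gs^2), k) %*% w
    w1 <- sym_orth(w1)
    delta <- max(abs(1 - abs(diag(w1 %*% t(w)))))
    w <- w1
    if (delta < tol) break
    if (it >= max_iter)
      abort(paste0("group_ica(): no convergence after ", it, " iterations"))
  }
  s <- w %*% y
  s <- t(scale(t(s)))                          # unit-variance maps
  maps <- array(0, c(d, k))
  flat <- matrix(maps, prod(d), k)
  flat[sel, ] <- t(s)
  mixing <- x %*% t(s) / nv
  structure(list(maps = array(flat, c(d, k)), mixing = mixing, mask = mask,
                 iterations = it, dim = d),
            class = "ln_ica")
}

#' Select the language-network component by template matching
#'
#' Returns the component with the largest absolute spatial Pearson
#' correlation with a template map, sign-flipped so the correlation is
#' positive.
#'
#' @param ica An `ln_ica` object from [group_ica()], or a 4-D array of maps.
#' @param template 3-D array on the same grid.
#' @param floor Minimum acceptable |r| (default 0.2); below it no component
#'   is deemed language-network-like and an error is raised.
#' @return List: `component` (index), `spatial_r` (positive), `map`
#'   (sign-aligned 3-D array), `all_r` (signed correlations per component).
#' @export
select_language_component <- function(ica, template, floor = 0.2) {
  maps <- if (inherits(ica, "ln_ica")) ica$maps else ica
  k <- dim(maps)[4]
  d <- dim(maps)[1:3]
  if (!identical(dim(template), d))
    abort("select_language_component(): template grid mismatch")
  mask <- if (inherits(ica, "ln_ica")) as.vector(ica$mask) else
    rep(TRUE, prod(d))
  tv <- as.vector(template)[mask]
  flat <- matrix(maps, prod(d), k)[mask, , drop = FALSE]
  rs <- as.vector(cor(flat, tv))
  best <- which.max(abs(rs))
  if (abs(rs[best]) < floor)
    abort(paste0("select_language_component(): no LN-like component ",
                 "(max |r| = ", signif(max(abs(rs)), 3), " < floor ", floor, ")"))
  m <- maps[, , , best, drop = TRUE] * sign(rs[best])
  list(component = best, spatial_r = abs(rs[best]), map = m, all_r = rs)
}

neighbor_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, ]
  off
}

#' Threshold a weight map into connected clusters
#'
#' Voxels above the region-appropriate threshold (`t_cerebral`, or
#' `t_cerebellar` inside the cerebellar mask) are grouped by 26-connectivity
#' (6-connectivity behind a flag); clusters below `min_size` voxels are
#' discarded. Peak ties are broken by the lowest linear index, with a
#' warning.
#'
#' @param map 3-D numeric weight/T-score grid.
#' @param t_cerebral Threshold outside the cerebellar mask (default 5).
#' @param t_cerebellar Threshold inside it (default 3).
#' @param cerebellar_mask Optional 3-D logical array; if NULL the cerebral
#'   threshold applies everywhere.
#' @param connectivity 26 (default) or 6.
#' @param min_size Minimum cluster size in voxels (default 10).
#' @param voxel_mm Optional voxel dimensions; if given, peak coordinates are
#'   also reported in mm (grid centre = 0).
#' @return List: `clusters` (tibble: `cluster`, `size_voxels`, `peak_value`,
#'   `peak_i/j/k`, and `x/y/z` mm if `voxel_mm` given), `labels` (3-D
#'   integer array, 0 = background). No suprathreshold voxels give an empty
#'   tibble, not an error.
#' @export
threshold_clusters <- function(map, t_cerebral = 5, t_cerebellar = 3,
                               cerebellar_mask = NULL,
                               connectivity = c(26, 6), min_size = 10,
                               voxel_mm = NULL) {
  connectivity <- match.arg(as.character(connectivity[1]), c("26", "6"))
  connectivity <- as.integer(connectivity)
  if (t_cerebral <= 0 || t_cerebellar <= 0)
    abort("threshold_clusters(): thresholds must be > 0")
  d <- dim(map)
  thr <- array(t_cerebral, d)
  if (!is.null(cerebellar_mask)) thr[cerebellar_mask] <- t_cerebellar
  supra <- map > thr
  labels <- array(0L, d)
  empty <- tibble::tibble(cluster = integer(), size_voxels = integer(),
                          peak_value = numeric(), peak_i = integer(),
                          peak_j = integer(), peak_k = integer())
  if (!any(supra))
    return(list(clusters = empty, labels = labels))
  off <- neighbor_offsets(connectivity)
  visited <- array(FALSE, d)
  coords <- which(supra, arr.ind = TRUE)
  lin_of <- function(cc) (cc[, 3] - 1L) * d[1] * d[2] + (cc[, 2] - 1L) * d[1] + cc[, 1]
  comp <- 0L
  rows <- list()
  for (s in seq_len(nrow(coords))) {
    start <- coords[s, , drop = FALSE]
    if (visited[start]) next
    comp <- comp + 1L
    members <- start
    visited[start] <- TRUE
    frontier <- start
    while (nrow(frontier) > 0) {
      cand <- do.call(rbind, lapply(seq_len(nrow(off)), function(o)
        sweep(frontier, 2, off[o, ], `+`)))
      keep <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[keep, , drop = FALSE]
      cand <- unique(cand)
      keep <- supra[cand] & !visited[cand]
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand) == 0) break
      visited[cand] <- TRUE
      members <- rbind(members, cand)
      frontier <- cand
    }
    vals <- map[members]
    pk <- which(vals == max(vals))
    if (length(pk) > 1) {
      warn("threshold_clusters(): peak tie broken by lowest linear index")
      pk <- pk[order(lin_of(members[pk, , drop = FALSE]))]
    }
    pk <- pk[1]
    rows[[comp]] <- list(members = members,
                         size = nrow(members),
                         peak_value = vals[pk],
                         peak = members[pk, ])
  }
  rows <- Filter(function(r) r$size >= min_size, rows)
  if (length(rows) == 0) return(list(clusters = empty, labels = labels))
  ord <- order(vapply(rows, function(r) -r$size, numeric(1)))
  rows <- rows[ord]
  cl <- purrr::imap_dfr(rows, function(r, i) {
    labels[r$members] <<- i
    tibble::tibble(cluster = i, size_voxels = r$size,
                   peak_value = r$peak_value,
                   peak_i = unname(r$peak[1]), peak_j = unname(r$peak[2]),
                   peak_k = unname(r$peak[3]))
  })
  if (!is.null(voxel_mm)) {
    grid <- grid_spec(d, voxel_mm)
    mm <- voxel_to_mm(as.matrix(cl[, c("peak_i", "peak_j", "peak_k")]), grid)
    cl$x <- mm[, 1]; cl$y <- mm[, 2]; cl$z <- mm[, 3]
  }
  list(clusters = cl, labels = labels)
}

#' Build sphere ROIs at cluster peaks
#'
#' One spherical ROI of physical radius `radius_mm` per cluster peak, in the
#' format consumed by [extract_roi_timeseries()]. Sphere membership is
#' "voxel centre within the radius", so a radius below the voxel size keeps
#' only the peak voxel.
#'
#' @param clusters Cluster tibble from [threshold_clusters()] (must carry
#'   mm coordinates, i.e. `voxel_mm` was supplied there).
#' @param radius_mm Sphere radius (default 6).
#' @return ROI tibble: `node` (`"cluster<k>"`), `x`, `y`, `z`,
#'   `size_voxels`, `radius_mm`.
#' @export
peak_rois <- function(clusters, radius_mm = 6) {
  if (nrow(clusters) == 0) abort("peak_rois(): need at least one cluster")
  if (!all(c("x", "y", "z") %in% names(clusters)))
    abort("peak_rois(): clusters lack mm coordinates; pass voxel_mm to threshold_clusters()")
  tibble::tibble(node = paste0("cluster", clusters$cluster),
                 x = clusters$x, y = clusters$y, z = clusters$z,
                 size_voxels = clusters$size_voxels, radius_mm = radius_mm)
}

#' Write an ROI set to JSON or TSV
#'
#' @param roi_set ROI tibble (e.g. [ln_rois()] or [peak_rois()]).
#' @param path Output path.
#' @param format `"json"` or `"tsv"` (guessed from the extension by default).
#' @return `path`, invisibly.
#' @export
write_roi_set <- function(roi_set, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path)) "json" else "tsv"
  if (format == "json") {
    jsonlite::write_json(roi_set, path, digits = NA, pretty = TRUE)
  } else {
    write.table(roi_set, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
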
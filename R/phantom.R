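#' Subsystem voxel parcels for phantom grids
#'
#' Builds a rectangular parcel (a box of half-width `halfwidth_mm`) around
#' every node of each lesion subsystem and unions them per subsystem. Parcels
#' are checked to be mutually disjoint on the requested grid.
#'
#' @param dim Grid dimensions in voxels (length 3).
#' @param voxel_mm Voxel dimensions in mm.
#' @param roi_set ROI table (default [ln_rois()]).
#' @param halfwidth_mm Box half-width in mm (default 24).
#' @return Named list of 3-D logical arrays (`LF`, `LT`, `RF`, `RT`).
#' @export
phantom_atlas <- function(dim = c(24, 24, 24), voxel_mm = c(8, 8, 8),
                          roi_set = ln_rois(), halfwidth_mm = 24) {
  grid <- grid_spec(dim, voxel_mm)
  subs <- c("LF", "LT", "RF", "RT")
  box_at <- function(ctr) {
    ax <- lapply(1:3, function(a)
      abs((seq_len(grid$dim[a]) - grid$origin[a]) * grid$voxel_mm[a] -
            ctr[a]) <= halfwidth_mm)
    outer(outer(ax[[1]], ax[[2]], `&`), ax[[3]], `&`)
  }
  parcels <- lapply(subs, function(s) {
    members <- roi_set[roi_set$subsystem == s, ]
    Reduce(`|`, lapply(seq_len(nrow(members)), function(i)
      box_at(c(members$x[i], members$y[i], members$z[i]))))
  })
  names(parcels) <- subs
  total <- Reduce(`+`, parcels)
  if (any(total > 1))
    abort("phantom_atlas(): parcels overlap; reduce halfwidth_mm")
  parcels
}

# ellipsoid (default sphere) of the requested volume, as voxel-centre mask
ellipsoid_mask <- function(center_mm, volume_cm3, grid, axes = c(1, 1, 1)) {
  if (volume_cm3 <= 0) return(array(0L, grid$dim))
  r0 <- (3 * volume_cm3 * 1000 / (4 * pi * prod(axes)))^(1 / 3)
  semi <- r0 * axes
  ax <- lapply(1:3, function(a)
    (((seq_len(grid$dim[a]) - grid$origin[a]) * grid$voxel_mm[a] -
        center_mm[a]) / semi[a])^2)
  arr <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  array(as.integer(arr <= 1), grid$dim)
}

#' Simulate a phantom 4-D volume with embedded network sources and a tumor
#'
#' Embeds one Gaussian spatial blob per ROI whose time course is the given
#' node signal, adds spatially white noise, and (for patients) carves an
#' ellipsoidal tumor mask of the requested volume centred in the lesioned
#' subsystem's parcel, attenuating the signal inside the mask.
#'
#' @param ts Time-by-node matrix of node signals (e.g. from
#'   [simulate_subject()]); column names must match `roi_set$node`.
#' @param subsystem Lesioned subsystem (`"LF"`, `"LT"`, `"RF"`, `"RT"`) or
#'   `"none"` for a healthy control (empty mask).
#' @param tumor_volume_cm3 Requested tumor volume (cm3); 0 for none.
#' @param roi_set ROI table (default [ln_rois()]).
#' @param dim,voxel_mm Grid shape (>= 24 voxels per axis) and voxel size.
#' @param blob_sigma_mm Spatial SD of each source blob (default 10 mm).
#' @param noise_sd SD of spatially/temporally white noise (default 0).
#' @param attenuation Multiplicative signal loss inside the tumor
#'   (default 0.5 keeps half the signal).
#' @param axes Ellipsoid axis ratios (default sphere).
#' @param seed Optional local seed for the noise draw.
#' @return List: `bold` (4-D array x,y,z,t), `mask` (3-D 0/1 array),
#'   `voxel_mm`, `dim`.
#' @export
simulate_phantom <- function(ts, subsystem = "none", tumor_volume_cm3 = 0,
                             roi_set = ln_rois(), dim = c(24, 24, 24),
                             voxel_mm = c(8, 8, 8), blob_sigma_mm = 10,
                             noise_sd = 0, attenuation = 0.5,
                             axes = c(1, 1, 1), seed = NULL) {
  if (any(dim < 24)) abort("simulate_phantom(): grid must be >= 24 voxels per axis")
  if (!is.null(seed)) set.seed(seed)
  grid <- grid_spec(dim, voxel_mm)
  ts <- as.matrix(ts)
  nodes <- colnames(ts)
  if (is.null(nodes) || !all(nodes %in% roi_set$node))
    abort("simulate_phantom(): ts columns must be named after roi_set nodes")
  nv <- prod(grid$dim); nt <- nrow(ts)
  # per-node Gaussian spatial weights
  weights <- vapply(nodes, function(nd) {
    i <- match(nd, roi_set$node)
    ctr <- c(roi_set$x[i], roi_set$y[i], roi_set$z[i])
    ax <- lapply(1:3, function(a)
      ((seq_len(grid$dim[a]) - grid$origin[a]) * grid$voxel_mm[a] - ctr[a])^2)
    d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
    as.vector(exp(-d2 / (2 * blob_sigma_mm^2)))
  }, numeric(nv))
  mask <- array(0L, grid$dim)
  if (subsystem != "none" && tumor_volume_cm3 > 0) {
    atlas <- phantom_atlas(dim, voxel_mm, roi_set)
    if (!subsystem %in% names(atlas))
      abort(paste0("simulate_phantom(): unknown subsystem '", subsystem, "'"))
    parcel <- atlas[[subsystem]]
    idx <- which(parcel, arr.ind = TRUE)
    ctr_mm <- colMeans(voxel_to_mm(idx, grid))
    bb <- apply(voxel_to_mm(idx, grid), 2, range)
    r0 <- (3 * tumor_volume_cm3 * 1000 / (4 * pi * prod(axes)))^(1 / 3)
    if (any(2 * r0 * axes > (bb[2, ] - bb[1, ] + voxel_mm)))
      abort("simulate_phantom(): tumor larger than the parcel bounding box")
    mask <- ellipsoid_mask(ctr_mm, tumor_volume_cm3, grid, axes)
  }
  gain <- ifelse(as.vector(mask) == 1, 1 - attenuation, 1)
  bold <- (weights * gain) %*% t(ts)                    # voxels x time
  if (noise_sd > 0) bold <- bold + rnorm(length(bold), sd = noise_sd)
  list(bold = array(bold, c(grid$dim, nt)), mask = mask,
       voxel_mm = grid$voxel_mm, dim = grid$dim)
}
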
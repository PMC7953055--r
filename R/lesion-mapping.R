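#' Tumor volume from a binary lesion mask
#'
#' Nonzero-voxel count times the voxel volume, reported in cm3 (Table-style
#' units). An empty mask has volume 0.
#'
#' @param mask 3-D binary array (values 0/1).
#' @param voxel_mm Voxel dimensions in mm (length 3).
#' @return Volume in cm3.
#' @export
#' @examples
#' m <- array(0L, c(10, 10, 10)); m[1:10, 1:10, 1:10][1:1000] <- 1L
#' tumor_volume(m, c(1, 1, 1))  # 1 cm3
tumor_volume <- function(mask, voxel_mm) {
  check_mask(mask, voxel_mm)
  sum(mask != 0) * prod(voxel_mm) / 1000
}

check_mask <- function(mask, voxel_mm) {
  if (length(dim(mask)) != 3) abort("lesion mask must be a 3-D array")
  if (!all(mask %in% c(0, 1))) abort("lesion mask values must be 0/1")
  if (length(voxel_mm) != 3 || any(voxel_mm <= 0))
    abort("voxel_mm must be 3 positive dimensions")
  invisible(TRUE)
}

#' Lesion overlap (density) map
#'
#' Voxelwise sum of binary masks: the value at a voxel is the number of
#' subjects whose lesion covers it.
#'
#' @param masks List of 3-D binary arrays sharing one grid shape.
#' @return 3-D integer array of the same shape.
#' @export
overlap_map <- function(masks) {
  if (length(masks) == 0) abort("overlap_map(): need at least one mask")
  d <- dim(masks[[1]])
  ok <- vapply(masks, function(m) identical(dim(m), d), logical(1))
  if (!all(ok)) abort("overlap_map(): masks differ in grid shape")
  Reduce(`+`, masks)
}

#' Assign a lesion to a language subsystem by maximal parcel overlap
#'
#' The subsystem whose voxel parcel shares the most voxels with the mask.
#' Exact ties are broken by the larger overlap *fraction* of the parcel,
#' then lexicographically (with a warning). A lesion overlapping no parcel
#' is `"unclassified"`. Lesions whose top-two overlaps differ by less than
#' 10% are flagged ambiguous.
#'
#' @param mask 3-D binary array.
#' @param atlas Named list of 3-D logical parcel arrays (e.g. from
#'   [phantom_atlas()]), one per subsystem (LF, LT, RF, RT).
#' @return One-row tibble: `subsystem`, `overlap_voxels`, `runner_up`,
#'   `runner_up_voxels`, `ambiguous`.
#' @export
assign_subsystem <- function(mask, atlas) {
  if (length(dim(mask)) != 3) abort("assign_subsystem(): mask must be 3-D")
  ov <- vapply(atlas, function(p) sum(mask[p] != 0), numeric(1))
  if (all(ov == 0)) {
    warn("assign_subsystem(): lesion overlaps no subsystem parcel")
    return(tibble::tibble(subsystem = "unclassified", overlap_voxels = 0,
                          runner_up = NA_character_, runner_up_voxels = 0,
                          ambiguous = FALSE))
  }
  top <- which(ov == max(ov))
  if (length(top) > 1) {
    frac <- ov[top] / vapply(atlas[top], sum, numeric(1))
    top <- top[order(-frac, names(ov)[top])]
    warn(paste0("assign_subsystem(): exact overlap tie broken in favour of ",
                names(ov)[top[1]]))
  }
  best <- top[1]
  rest <- sort(ov[-best], decreasing = TRUE)
  runner <- if (length(rest) > 0) rest[1] else 0
  tibble::tibble(
    subsystem = names(ov)[best], overlap_voxels = unname(ov[best]),
    runner_up = if (runner > 0) names(rest)[1] else NA_character_,
    runner_up_voxels = unname(runner),
    ambiguous = runner > 0 && (ov[best] - runner) / ov[best] < 0.10)
}

#' Write / read a mask or map as NIfTI
#'
#' Thin wrappers around [RNifti::writeNifti()] / [RNifti::readNifti()]
#' carrying the voxel dimensions.
#'
#' @param img 3-D (or 4-D) numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_mm Voxel dimensions in mm.
#' @return `write_nifti_map()` returns `path` invisibly; `read_nifti_map()`
#'   a list with `img` (array) and `voxel_mm`.
#' @export
write_nifti_map <- function(img, path, voxel_mm) {
  nim <- RNifti::asNifti(img)
  RNifti::pixdim(nim) <- voxel_mm
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' @rdname write_nifti_map
#' @export
read_nifti_map <- function(path) {
  nim <- RNifti::readNifti(path)
  list(img = as.array(nim),
       voxel_mm = RNifti::pixdim(nim)[seq_len(min(3, length(dim(nim))))])
}
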
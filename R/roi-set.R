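#' Canonical language-network node set
#'
#' The ten language-network (LN) modules used throughout the package, in
#' canonical order: the six "core" frontotemporal nodes (left and right
#' inferior frontal, middle frontal and superior temporal gyri), the two
#' midline nodes (superior frontal gyrus, precuneus) and the two cerebellar
#' posterior-lobe nodes.
#'
#' @return Character vector of the 10 node names.
#' @export
#' @examples
#' ln_nodes()
ln_nodes <- function() {
  c("lIFG", "lMFG", "lSTG", "rIFG", "rMFG", "rSTG",
    "SFG", "PC", "lCPL", "rCPL")
}

#' The six core frontotemporal nodes
#'
#' Homotopic node pairs (bilateral IFG, MFG, STG) over which the
#' mean-network-connectivity (mNC) indices are defined.
#'
#' @return Character vector of 6 node names.
#' @export
ln_core_nodes <- function() {
  c("lIFG", "lMFG", "lSTG", "rIFG", "rMFG", "rSTG")
}

#' Canonical LN region-of-interest table
#'
#' The shipped ROI set: ten ICA-derived LN modules with their MNI peak
#' coordinates (mm), cluster sizes (voxels) and peak T scores, plus the
#' sphere radius used to build seed ROIs around each peak. Midline modules
#' (SFG, PC) and the cerebellar nodes belong to no lesion subsystem.
#'
#' @param radius_mm Sphere radius in mm placed at each peak voxel (default 6).
#' @return A tibble with columns `node`, `x`, `y`, `z` (MNI mm),
#'   `size_voxels`, `peak_t`, `hemisphere` (`"left"`, `"right"`, `"midline"`),
#'   `subsystem` (`"LF"`, `"LT"`, `"RF"`, `"RT"` or `"none"`) and `radius_mm`.
#' @export
#' @examples
#' ln_rois()
ln_rois <- function(radius_mm = 6) {
  stopifnot(is.numeric(radius_mm), radius_mm > 0)
  tibble::tibble(
    node = ln_nodes(),
    x = c(-51, -45, -57, 54, 45, 60, -3, 0, -21, 21),
    y = c(21, 3, -57, 24, 9, -51, 12, -57, -78, -81),
    z = c(-9, 48, 12, -6, 45, 12, 57, 39, -39, -42),
    size_voxels = c(218L, 136L, 955L, 127L, 104L, 1149L, 109L, 133L, 92L, 43L),
    peak_t = c(10.93, 11.30, 16.27, 8.26, 9.86, 19.82, 7.85, 8.39, 3.47, 3.17),
    hemisphere = c("left", "left", "left", "right", "right", "right",
                   "midline", "midline", "left", "right"),
    subsystem = unname(ln_subsystems()[ln_nodes()]),
    radius_mm = radius_mm
  )
}

#' Node-to-subsystem atlas
#'
#' Maps each LN node to one of the four lesion subsystems: left frontal
#' (LF = lIFG, lMFG), left temporal (LT = lSTG), right frontal
#' (RF = rIFG, rMFG), right temporal (RT = rSTG). Midline and cerebellar
#' nodes map to `"none"`.
#'
#' @return Named character vector, node name -> subsystem label.
#' @export
#' @examples
#' ln_subsystems()[["lSTG"]]
ln_subsystems <- function() {
  c(lIFG = "LF", lMFG = "LF", lSTG = "LT",
    rIFG = "RF", rMFG = "RF", rSTG = "RT",
    SFG = "none", PC = "none", lCPL = "none", rCPL = "none")
}

#' Subsystem lesioned in each patient group
#' @return Named character vector, group label -> subsystem.
#' @export
ln_group_subsystem <- function() {
  c(LFG = "LF", LTG = "LT", RFG = "RF", RTG = "RT")
}

#' Canonical edge name for an unordered node pair
#'
#' Edges are keyed by the two node names joined with `"-"` in canonical node
#' order, so the key is independent of argument order.
#'
#' @param a,b Node names (vectorised).
#' @return Character vector of edge keys.
#' @export
#' @examples
#' edge_name("lSTG", "lIFG")  # "lIFG-lSTG"
edge_name <- function(a, b) {
  ord <- match(a, ln_nodes()) > match(b, ln_nodes())
  if (anyNA(ord)) abort("unknown node name(s) in edge_name()")
  ifelse(ord, paste(b, a, sep = "-"), paste(a, b, sep = "-"))
}

#' Enumerate all unordered node pairs
#'
#' @param nodes Character vector of node names (default the canonical 10,
#'   giving the 45 LN edges).
#' @return Tibble with columns `edge`, `node1`, `node2`.
#' @export
#' @examples
#' nrow(ln_edges())  # 45
ln_edges <- function(nodes = ln_nodes()) {
  stopifnot(length(nodes) >= 2, !anyDuplicated(nodes))
  idx <- utils::combn(length(nodes), 2)
  tibble::tibble(
    node1 = nodes[idx[1, ]],
    node2 = nodes[idx[2, ]],
    edge = paste(nodes[idx[1, ]], nodes[idx[2, ]], sep = "-")
  )[, c("edge", "node1", "node2")]
}
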
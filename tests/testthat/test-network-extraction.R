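# shared phantom set with three spatially separated embedded sources
make_phantoms <- function(n_subj = 3, noise_sd = 0.05, seed = 2) {
  rois <- ln_rois()[c(1, 5, 10), ]              # lIFG, rMFG, rCPL
  set.seed(seed)
  ph <- lapply(seq_len(n_subj), function(i) {
    ts <- matrix(rnorm(100 * 3), 100, 3, dimnames = list(NULL, rois$node))
    simulate_phantom(ts, roi_set = rois, noise_sd = noise_sd)
  })
  list(ph = ph, rois = rois)
}

source_map <- function(rois, i, dim = c(24, 24, 24), voxel_mm = c(8, 8, 8)) {
  ts <- matrix(0, 1, nrow(rois), dimnames = list(NULL, rois$node))
  ts[1, i] <- 1
  simulate_phantom(ts, roi_set = rois, dim = dim, voxel_mm = voxel_mm)$bold[, , , 1]
}

best_spatial_r <- function(ica, src) {
  m <- as.vector(ica$mask)
  flat <- matrix(ica$maps, length(m), dim(ica$maps)[4])[m, , drop = FALSE]
  max(abs(cor(flat, as.vector(src)[m])))
}

test_that("group ICA recovers embedded orthogonal sources", {
  px <- make_phantoms()
  ica <- group_ica(lapply(px$ph, `[[`, "bold"), k = 3, seed = 9)
  for (i in 1:3)
    expect_gt(best_spatial_r(ica, source_map(px$rois, i)), 0.95)
  # determinism up to sign
  ica2 <- group_ica(lapply(px$ph, `[[`, "bold"), k = 3, seed = 9)
  expect_equal(abs(ica$maps), abs(ica2$maps), tolerance = 1e-12)
  # maps standardised inside the mask
  m1 <- ica$maps[, , , 1][ica$mask]
  expect_equal(mean(m1), 0, tolerance = 1e-10)
  expect_equal(sd(m1), 1, tolerance = 1e-3)
})

test_that("single-component ICA isolates a single source", {
  rois <- ln_rois()[1, , drop = FALSE]
  set.seed(5)
  ph <- lapply(1:2, function(i) {
    ts <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "lIFG"))
    simulate_phantom(ts, roi_set = rois, noise_sd = 0.05)
  })
  ica <- group_ica(lapply(ph, `[[`, "bold"), k = 1, seed = 4)
  expect_gt(best_spatial_r(ica, source_map(rois, 1)), 0.95)
})

test_that("ICA source recovery degrades monotonically with noise", {
  rs <- vapply(c(0.05, 0.6, 2.5), function(ns) {
    px <- make_phantoms(noise_sd = ns, seed = 11)
    ica <- group_ica(lapply(px$ph, `[[`, "bold"), k = 3, seed = 9)
    mean(vapply(1:3, function(i)
      best_spatial_r(ica, source_map(px$rois, i)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("template matching selects the best-correlated component", {
  px <- make_phantoms()
  ica <- group_ica(lapply(px$ph, `[[`, "bold"), k = 3, seed = 9)
  # a component used as its own template is picked with r = 1
  tpl <- ica$maps[, , , 2]
  sel <- select_language_component(ica, tpl)
  expect_equal(sel$component, 2)
  expect_equal(sel$spatial_r, 1, tolerance = 1e-10)
  # the source blob template finds its component
  sel2 <- select_language_component(ica, source_map(px$rois, 1))
  expect_gt(sel2$spatial_r, 0.95)
  # the sign convention makes the returned map positively correlated
  m <- as.vector(ica$mask)
  flat <- as.vector(sel2$map)[m]
  expect_gt(cor(flat, as.vector(source_map(px$rois, 1))[m]), 0)
  # orthogonal template: floor error
  set.seed(1)
  noise_tpl <- array(rnorm(prod(dim(tpl))), dim(tpl))
  expect_error(select_language_component(ica, noise_tpl, floor = 0.5),
               "no LN-like component")
})

test_that("constructed maps with known correlations are ranked correctly", {
  set.seed(23)
  d <- c(10, 10, 10)
  base <- rnorm(1000)
  mk <- function(r) r * base + sqrt(1 - r^2) * rnorm(1000)
  maps <- array(c(mk(0.6), mk(0.9)), c(d, 2))
  sel <- select_language_component(maps, array(base, d))
  expect_equal(sel$component, 2)
  expect_gt(sel$spatial_r, 0.8)
})

test_that("threshold_clusters separates blobs and counts voxels exactly", {
  d <- c(20, 20, 20)
  g <- array(0, d)
  g[4:6, 4:6, 4:6] <- 7            # 27-voxel cube above t = 5
  g[14:16, 14:16, 14:15] <- 7      # 18-voxel cube
  g[5, 5, 5] <- 9                  # unique peaks
  g[15, 15, 15] <- 8
  res <- threshold_clusters(g, t_cerebral = 5, min_size = 10,
                            voxel_mm = c(2, 2, 2))
  expect_equal(nrow(res$clusters), 2)
  expect_equal(sort(res$clusters$size_voxels), c(18, 27))
  big <- res$clusters[res$clusters$size_voxels == 27, ]
  expect_equal(c(big$peak_i, big$peak_j, big$peak_k), c(5, 5, 5))
  expect_equal(sum(res$labels > 0), 45)
  # threshold above the global max: empty result, not an error
  empty <- threshold_clusters(g, t_cerebral = 100)
  expect_equal(nrow(empty$clusters), 0)
  # min_size filters the smaller cluster
  expect_equal(nrow(threshold_clusters(g, t_cerebral = 5,
                                       min_size = 20)$clusters), 1)
  # an exact peak tie warns and resolves to the lowest linear index
  gt <- array(0, c(8, 8, 8)); gt[2:3, 2, 2] <- 5.5
  expect_warning(tie <- threshold_clusters(gt, t_cerebral = 5, min_size = 1),
                 "tie")
  expect_equal(tie$clusters$peak_i, 2)
})

test_that("raising the threshold yields nested clusters", {
  set.seed(31)
  d <- c(16, 16, 16)
  g <- array(0, d)
  ctr <- c(8, 8, 8)
  for (i in 1:16) for (j in 1:16) for (k in 1:16)
    g[i, j, k] <- 10 * exp(-sum((c(i, j, k) - ctr)^2) / 18)
  lo <- threshold_clusters(g, t_cerebral = 3, min_size = 1)
  hi <- threshold_clusters(g, t_cerebral = 6, min_size = 1)
  vox_lo <- which(lo$labels > 0); vox_hi <- which(hi$labels > 0)
  expect_true(all(vox_hi %in% vox_lo))
  expect_lt(length(vox_hi), length(vox_lo))
})

test_that("the cerebellar mask applies its own threshold", {
  d <- c(12, 12, 12)
  g <- array(0, d)
  g[2:4, 2:4, 2:4] <- 4          # below cerebral 5, above cerebellar 3
  g[3, 3, 3] <- 4.5
  g[8:10, 8:10, 8:10] <- 4       # same value in cerebral territory
  g[9, 9, 9] <- 4.5
  cbl <- array(FALSE, d); cbl[, , 1:6] <- TRUE
  res <- threshold_clusters(g, t_cerebral = 5, t_cerebellar = 3,
                            cerebellar_mask = cbl, min_size = 5)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$size_voxels, 27)
})

test_that("26- and 6-connectivity differ on diagonally touching blobs", {
  d <- c(10, 10, 10)
  g <- array(0, d)
  g[2:3, 2:3, 2:3] <- 6
  g[4:5, 4:5, 4:5] <- 6          # touches the first only at a corner
  g[2, 2, 2] <- 7; g[5, 5, 5] <- 6.8
  c26 <- threshold_clusters(g, t_cerebral = 5, min_size = 1, connectivity = 26)
  c6 <- threshold_clusters(g, t_cerebral = 5, min_size = 1, connectivity = 6)
  expect_equal(nrow(c26$clusters), 1)
  expect_equal(nrow(c6$clusters), 2)
})

test_that("peak spheres contain the brute-force voxel count", {
  d <- c(21, 21, 21)
  g <- array(0, d)
  g[11, 11, 11] <- 10
  g[10:12, 10:12, 10:12] <- g[10:12, 10:12, 10:12] + 6
  res <- threshold_clusters(g, t_cerebral = 5, min_size = 1,
                            voxel_mm = c(3, 3, 3))
  rois <- peak_rois(res$clusters, radius_mm = 6)
  # brute-force enumeration of voxel centres within 6 mm on a 3 mm grid
  cnt <- 0
  for (i in -3:3) for (j in -3:3) for (k in -3:3)
    if (sum((3 * c(i, j, k))^2) <= 36) cnt <- cnt + 1
  expect_equal(cnt, 33)
  bold <- array(1, c(d, 2))
  grid_n <- sum(langnet:::sphere_voxels(c(rois$x[1], rois$y[1], rois$z[1]),
                                        6, langnet:::grid_spec(d, c(3, 3, 3))))
  expect_equal(grid_n, 33)
  # radius below the voxel size keeps only the peak voxel
  expect_equal(sum(langnet:::sphere_voxels(c(rois$x[1], rois$y[1], rois$z[1]),
                                           2, langnet:::grid_spec(d, c(3, 3, 3)))), 1)
})

test_that("the shipped ROI fixture matches the canonical ten-node table", {
  rois <- ln_rois()
  expect_equal(nrow(rois), 10)
  expect_equal(rois$node, ln_nodes())
  expect_equal(unlist(rois[rois$node == "lIFG", c("x", "y", "z")]),
               c(x = -51, y = 21, z = -9))
  expect_equal(rois$size_voxels[rois$node == "rSTG"], 1149L)
  expect_equal(rois$size_voxels[rois$node == "lSTG"], 955L)
  expect_equal(rois$radius_mm, rep(6, 10))
  expect_equal(sum(rois$subsystem == "none"), 4)
  # round-trips through TSV and JSON
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".tsv")
  write_roi_set(rois, p1); write_roi_set(rois, p2)
  expect_equal(jsonlite::read_json(p1, simplifyVector = TRUE)$node, rois$node)
  back <- read.delim(p2)
  expect_equal(back$x, rois$x)
  unlink(c(p1, p2))
})
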
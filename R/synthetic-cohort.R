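#' Configuration for a synthetic lesion cohort
#'
#' Bundles every parameter of the synthetic-cohort generator. Defaults encode
#' the study conditions the package is designed around: the five-group cohort
#' (LFG/LTG/RFG/RTG/HC with 27/26/29/27/42 subjects), resting-state scan
#' length of 200 volumes at TR = 2 s, plausible baseline correlations
#' (within-hemisphere 0.45, homotopic 0.50, heterotopic 0.25), and lesion
#' effect slopes on the Fisher-z scale per cm3 of tumor volume.
#'
#' The lesion model is core-periphery: left-hemisphere lesions attenuate
#' edges incident to the lesioned subsystem by `a_dir * V` and every other
#' edge by `a_ind * V` (a near-global effect, `a_ind` slightly below
#' `a_dir`); right-hemisphere lesions attenuate only ipsilesional edges
#' (`a_dir * V`) and boost the contralesional left core triangle by
#' `b_con * V`, emulating contralateral functional compensation.
#'
#' @param n_per_group Named integer vector of group sizes; names must be
#'   LFG, LTG, RFG, RTG, HC.
#' @param n_timepoints Time points per subject (default 200).
#' @param tr Repetition time in seconds (default 2).
#' @param r_within Baseline correlation for same-hemisphere node pairs.
#' @param r_homotopic Baseline correlation for homotopic pairs
#'   (lIFG-rIFG, lMFG-rMFG, lSTG-rSTG, lCPL-rCPL).
#' @param r_hetero Baseline correlation for all remaining pairs (including
#'   every pair touching a midline node).
#' @param a_dir Fisher-z attenuation per cm3 on edges incident to the
#'   lesioned subsystem.
#' @param a_ind Fisher-z attenuation per cm3 on all remaining edges
#'   (left-hemisphere lesion groups only).
#' @param b_con Fisher-z boost per cm3 on the contralesional left core
#'   triangle (right-hemisphere lesion groups only).
#' @param tv_mean,tv_sd Mean and SD (cm3) of the log-normal tumor-volume
#'   distribution.
#' @param tv_range Truncation bounds (cm3) for tumor volumes.
#' @param subject_sd SD of the per-subject random intercept added to every
#'   edge's Fisher z (trait-level connectivity variability).
#' @param noise_sd SD of white measurement noise added to each node's time
#'   series (default 0: the covariance already encodes the target
#'   correlations).
#' @param seed Integer seed making the whole cohort reproducible.
#' @return A validated list of class `ln_cohort_config`.
#' @export
#' @examples
#' cohort_config(seed = 1)
cohort_config <- function(n_per_group = c(LFG = 27, LTG = 26, RFG = 29,
                                          RTG = 27, HC = 42),
                          n_timepoints = 200, tr = 2,
                          r_within = 0.45, r_homotopic = 0.50,
                          r_hetero = 0.25,
                          a_dir = 3.2e-3, a_ind = 2.9e-3, b_con = 0.8e-3,
                          tv_mean = 105, tv_sd = 62,
                          tv_range = c(10, 300),
                          subject_sd = 0.06, noise_sd = 0,
                          seed = 1L) {
  if (!all(sort(names(n_per_group)) == sort(c("LFG", "LTG", "RFG", "RTG", "HC"))))
    abort("cohort_config(): n_per_group must name LFG, LTG, RFG, RTG, HC")
  if (any(n_per_group < 2)) abort("cohort_config(): group sizes must be >= 2")
  rs <- c(r_within, r_homotopic, r_hetero)
  if (any(abs(rs) >= 1)) abort("cohort_config(): correlations must be in (-1, 1)")
  if (tv_mean <= 0 || tv_sd <= 0 || tv_range[1] <= 0 ||
      tv_range[2] <= tv_range[1])
    abort("cohort_config(): invalid tumor-volume distribution")
  if (n_timepoints < 4) abort("cohort_config(): n_timepoints must be >= 4")
  cfg <- list(n_per_group = n_per_group[c("LFG", "LTG", "RFG", "RTG", "HC")],
              n_timepoints = as.integer(n_timepoints), tr = tr,
              r_within = r_within, r_homotopic = r_homotopic,
              r_hetero = r_hetero,
              a_dir = a_dir, a_ind = a_ind, b_con = b_con,
              tv_mean = tv_mean, tv_sd = tv_sd, tv_range = tv_range,
              subject_sd = subject_sd, noise_sd = noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "ln_cohort_config"
  # baseline must be a valid correlation structure
  ev <- eigen(baseline_correlation(cfg), symmetric = TRUE, only.values = TRUE)
  if (min(ev$values) <= 0)
    abort("cohort_config(): baseline correlation matrix is not positive definite")
  cfg
}

#' Baseline (healthy-control) node correlation matrix
#'
#' Hemispherically symmetric block structure: same-hemisphere pairs at
#' `r_within`, homotopic pairs at `r_homotopic`, everything else (including
#' midline nodes) at `r_hetero`.
#'
#' @param config A [cohort_config()].
#' @return 10 x 10 correlation matrix with node dimnames.
#' @export
baseline_correlation <- function(config) {
  nodes <- ln_nodes()
  hemi <- c(lIFG = "L", lMFG = "L", lSTG = "L", rIFG = "R", rMFG = "R",
            rSTG = "R", SFG = "M", PC = "M", lCPL = "L", rCPL = "R")
  homotopic <- c("lIFG-rIFG", "lMFG-rMFG", "lSTG-rSTG", "lCPL-rCPL")
  r <- matrix(config$r_hetero, 10, 10, dimnames = list(nodes, nodes))
  for (i in seq_len(9)) for (j in seq(i + 1, 10)) {
    a <- nodes[i]; b <- nodes[j]
    val <- if (edge_name(a, b) %in% homotopic) config$r_homotopic
           else if (hemi[[a]] == hemi[[b]] && hemi[[a]] != "M") config$r_within
           else config$r_hetero
    r[i, j] <- r[j, i] <- val
  }
  diag(r) <- 1
  r
}

# eigenvalue-clipped nearest-PD repair on the correlation scale
nearest_pd <- function(m, eps = 1e-6) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) > eps) return(list(mat = m, repaired = FALSE))
  v <- pmax(e$values, eps)
  out <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  list(mat = out, repaired = TRUE)
}

#' Group- and volume-dependent node covariance
#'
#' Applies the core-periphery lesion model to the baseline correlation
#' matrix, on the Fisher-z scale (so effects are additive and the
#' back-transformed correlations stay inside (-1, 1)):
#' healthy controls are returned unchanged; left-lesion groups (LFG, LTG)
#' lose `a_dir * V` on edges incident to the lesioned subsystem and
#' `a_ind * V` on every other edge; right-lesion groups (RFG, RTG) lose
#' `a_dir * V` on ipsilesional edges only and gain `b_con * V` on the left
#' core triangle (lIFG, lMFG, lSTG). If the back-transformed matrix is not
#' positive definite it is repaired by eigenvalue clipping (at 1e-6) and the
#' repair is recorded in the `"repaired"` attribute.
#'
#' @param config A [cohort_config()].
#' @param group One of LFG, LTG, RFG, RTG, HC.
#' @param volume Tumor volume in cm3 (ignored for HC).
#' @param z_offset Additive offset applied to every edge's Fisher z before
#'   back-transforming (the per-subject random intercept; default 0).
#' @return 10 x 10 correlation matrix (attribute `"repaired"` is TRUE if a
#'   positive-definiteness repair was needed).
#' @export
#' @examples
#' cov_hc <- build_group_covariance(cohort_config(), "HC", 0)
#' cov_lfg <- build_group_covariance(cohort_config(), "LFG", 100)
build_group_covariance <- function(config, group, volume, z_offset = 0) {
  stopifnot(inherits(config, "ln_cohort_config"))
  group <- match.arg(group, c("LFG", "LTG", "RFG", "RTG", "HC"))
  r0 <- baseline_correlation(config)
  z <- suppressWarnings(atanh(r0))
  diag(z) <- 0
  nodes <- ln_nodes()
  if (group != "HC") {
    if (!is.finite(volume) || volume < 0)
      abort("build_group_covariance(): volume must be a non-negative number")
    subsys <- ln_group_subsystem()[[group]]
    members <- names(ln_subsystems())[ln_subsystems() == subsys]
    incident <- outer(nodes %in% members, nodes %in% members, `|`)
    if (group %in% c("LFG", "LTG")) {
      delta <- ifelse(incident, config$a_dir, config$a_ind) * volume
      z <- z - delta
    } else {
      z <- z - incident * config$a_dir * volume
      tri <- c("lIFG", "lMFG", "lSTG")
      boost <- outer(nodes %in% tri, nodes %in% tri, `&`) * config$b_con * volume
      z <- z + boost
    }
  }
  z <- z + z_offset
  diag(z) <- 0
  r <- tanh(z)
  diag(r) <- 1
  rep <- nearest_pd(r)
  if (rep$repaired)
    inform(paste0("build_group_covariance(): positive-definiteness repair ",
                  "applied (", group, ", V = ", signif(volume, 3), ")"))
  ev_min <- min(eigen(rep$mat, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0)
    abort(paste0("build_group_covariance(): matrix not positive definite ",
                 "after repair (min eigenvalue ", format(ev_min), ")"))
  structure(rep$mat, repaired = rep$repaired)
}

#' Simulate one subject's node time series
#'
#' Multivariate-normal BOLD-like draws with the given node covariance;
#' optionally band-limited to a frequency band to mimic preprocessed
#' resting-state signal. Returned as a time-by-node matrix (one column per
#' node), the orientation used throughout the package.
#'
#' @param cov Positive-definite node covariance/correlation matrix with
#'   node dimnames.
#' @param n_timepoints Number of time points (warning below 20: sample
#'   correlations are unstable).
#' @param noise_sd SD of added white measurement noise (default 0).
#' @param band Optional `c(low, high)` in Hz; if given the series are
#'   band-pass filtered (zero-phase Butterworth) using `tr`.
#' @param tr Repetition time in seconds (used only with `band`).
#' @param seed Optional integer seed (set locally for this draw).
#' @return `n_timepoints` x nodes numeric matrix.
#' @export
simulate_subject <- function(cov, n_timepoints, noise_sd = 0, band = NULL,
                             tr = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_timepoints < 20)
    warn("simulate_subject(): fewer than 20 time points gives unstable correlations")
  p <- nrow(cov)
  ch <- tryCatch(chol(cov),
                 error = function(e) abort("simulate_subject(): covariance not positive definite"))
  x <- matrix(rnorm(n_timepoints * p), n_timepoints, p) %*% ch
  if (noise_sd > 0)
    x <- x + matrix(rnorm(n_timepoints * p, sd = noise_sd), n_timepoints, p)
  colnames(x) <- colnames(cov)
  if (!is.null(band))
    x <- preprocess_timeseries(x, band = band, tr = tr, detrend = FALSE)
  x
}

# truncated log-normal tumor volumes (cm3)
draw_tumor_volumes <- function(n, config) {
  cv2 <- (config$tv_sd / config$tv_mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(config$tv_mean) - sdlog^2 / 2
  out <- numeric(0)
  while (length(out) < n) {
    v <- rlnorm(2 * n, meanlog, sdlog)
    out <- c(out, v[v >= config$tv_range[1] & v <= config$tv_range[2]])
  }
  out[seq_len(n)]
}

# true mNC profile from a z matrix (population-level, no sampling noise)
true_mnc_from_z <- function(z) {
  left <- c("lIFG", "lMFG", "lSTG"); right <- c("rIFG", "rMFG", "rSTG")
  lw <- mean(z[left, left][upper.tri(diag(3))])
  rw <- mean(z[right, right][upper.tri(diag(3))])
  fb <- mean(z[left, right])
  c(lFCw = lw, rFCw = rw, FCb = fb, FCg = (3 * lw + 3 * rw + 9 * fb) / 15)
}

#' Generate a synthetic lesion cohort
#'
#' Draws tumor volumes, builds each subject's lesion-modulated node
#' covariance, simulates node time series, and retains the ground truth
#' (population edge-z matrices and true mNC values) for parameter-recovery
#' tests. Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `ln_cohort`: a list with
#'   \describe{
#'     \item{subjects}{tibble: `subject_id`, `group`, `subsystem`,
#'       `tumor_volume_cm3` (NA for HC)}
#'     \item{timeseries}{named list of time-by-node matrices}
#'     \item{truth}{list with `edge_z` (named list of true 10 x 10 Fisher-z
#'       matrices) and `mnc` (tibble of true mNC values per subject)}
#'     \item{config}{the configuration used}
#'   }
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_per_group = c(LFG = 3, LTG = 3, RFG = 3, RTG = 3, HC = 4),
#'   n_timepoints = 50, seed = 7))
#' cohort$subjects
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ln_cohort_config"))
  set.seed(config$seed)
  groups <- names(config$n_per_group)
  subsys_map <- c(ln_group_subsystem(), HC = "none")
  rows <- list(); ts_list <- list(); z_list <- list(); mnc_rows <- list()
  idx <- 0L
  for (g in groups) {
    n <- config$n_per_group[[g]]
    vols <- if (g == "HC") rep(NA_real_, n) else draw_tumor_volumes(n, config)
    for (i in seq_len(n)) {
      idx <- idx + 1L
      id <- sprintf("S%03d", idx)
      jit <- rnorm(1, 0, config$subject_sd)
      covm <- withCallingHandlers(
        build_group_covariance(config, g, if (g == "HC") 0 else vols[i],
                               z_offset = jit),
        message = function(m) invokeRestart("muffleMessage"))
      ts_list[[id]] <- simulate_subject(covm, config$n_timepoints,
                                        noise_sd = config$noise_sd)
      z_true <- suppressWarnings(atanh(covm)); diag(z_true) <- 0
      z_list[[id]] <- z_true
      mnc_rows[[id]] <- true_mnc_from_z(z_true)
      rows[[id]] <- tibble::tibble(
        subject_id = id, group = g, subsystem = subsys_map[[g]],
        tumor_volume_cm3 = vols[i])
    }
  }
  subjects <- dplyr::bind_rows(rows)
  truth_mnc <- dplyr::bind_cols(
    subjects[, c("subject_id", "group")],
    tibble::as_tibble(do.call(rbind, mnc_rows)))
  structure(list(subjects = subjects, timeseries = ts_list,
                 truth = list(edge_z = z_list, mnc = truth_mnc),
                 config = config),
            class = "ln_cohort")
}

#' @export
print.ln_cohort <- function(x, ...) {
  cat("<ln_cohort> ", nrow(x$subjects), " subjects (",
      paste(names(x$config$n_per_group), x$config$n_per_group,
            sep = "=", collapse = ", "),
      "), T = ", x$config$n_timepoints, ", seed = ", x$config$seed, "\n",
      sep = "")
  invisible(x)
}
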
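#' Threshold specifications for statistical maps
#'
#' The localizer reports activation at three nested height thresholds:
#' `fwe_05` (p < .05 familywise-error corrected at the voxel level),
#' `unc_001` (p < .001 uncorrected) and `unc_05` (p < .05 uncorrected),
#' each combined with a minimum cluster extent (default 10 voxels).
#'
#' @param level one of `"fwe_05"`, `"unc_001"`, `"unc_05"`.
#' @param p height probability; defaults to the level's conventional
#'   value (.05, .001, .05).
#' @param cluster_extent_min minimum cluster size in voxels.
#' @param fwe_method `"bonferroni"` (analytic) or `"permutation_maxT"`
#'   (threshold from a max-t null distribution, see [maxt_threshold()]).
#' @return object of class `threshold_spec`.
#' @export
threshold_spec <- function(level = c("fwe_05", "unc_001", "unc_05"),
                           p = NULL, cluster_extent_min = 10,
                           fwe_method = c("bonferroni", "permutation_maxT")) {
  level <- match.arg(level)
  fwe_method <- match.arg(fwe_method)
  if (is.null(p)) p <- switch(level, fwe_05 = 0.05, unc_001 = 0.001,
                              unc_05 = 0.05)
  stopifnot(p > 0, p < 1, cluster_extent_min >= 0)
  structure(list(level = level, p = p,
                 cluster_extent_min = cluster_extent_min,
                 fwe_method = fwe_method),
            class = "threshold_spec")
}

#' Height-threshold a t-map
#'
#' One-sided voxel thresholding of a `stat_map`. Uncorrected levels use
#' `t > qt(1 - p, df)`; Bonferroni FWE uses the per-voxel level
#' `alpha / N` over the `N` in-mask voxels; permutation max-T uses the
#' `(1 - alpha)` quantile of a supplied max-t null distribution.
#'
#' @param map a `stat_map`.
#' @param spec a [threshold_spec()].
#' @param mask logical 3D array restricting the search volume (default:
#'   all voxels without the zero-variance flag).
#' @param maxt_null numeric vector of null max-t values, required when
#'   `spec$fwe_method == "permutation_maxT"` and `spec$level == "fwe_05"`.
#' @return list with `mask` (logical 3D array of supra-threshold
#'   voxels), `threshold` (the t cutoff used), `n_search` and `spec`.
#' @export
voxel_threshold <- function(map, spec, mask = NULL, maxt_null = NULL) {
  stopifnot(inherits(map, "stat_map"), inherits(spec, "threshold_spec"),
            map$df > 0)
  if (is.null(mask)) mask <- !map$zero_variance
  stopifnot(identical(dim(mask), dim(map$values)))
  N <- sum(mask)
  if (N == 0) stop("search mask is empty")
  thr <- if (spec$level %in% c("unc_001", "unc_05")) {
    stats::qt(1 - spec$p, df = map$df)
  } else if (spec$fwe_method == "bonferroni") {
    p_vox <- spec$p / N
    if (p_vox < .Machine$double.xmin) stop("alpha / N underflows")
    stats::qt(1 - p_vox, df = map$df)
  } else {
    if (is.null(maxt_null)) {
      stop("permutation_maxT thresholding needs a maxt_null distribution; ",
           "see maxt_threshold()")
    }
    stats::quantile(maxt_null, 1 - spec$p, names = FALSE)
  }
  list(mask = map$values > thr & mask, threshold = thr, n_search = N,
       spec = spec)
}

#' Max-T permutation threshold from subject contrast images
#'
#' Builds the null distribution of the maximum one-sample t statistic
#' over voxels under sign-flipping of subjects (exact under symmetric
#' exchangeability) and returns it for use with
#' [voxel_threshold()]'s `permutation_maxT` method.
#'
#' @param con_mat subjects x voxels matrix of contrast estimates.
#' @param n_perm number of sign-flip permutations.
#' @param seed RNG seed.
#' @return numeric vector of `n_perm` max-t values.
#' @export
maxt_threshold <- function(con_mat, n_perm = 1000, seed = 1L) {
  con_mat <- as.matrix(con_mat)
  s <- nrow(con_mat)
  stopifnot(s >= 2)
  set.seed(seed)
  one_sample_t <- function(M) {
    m <- colMeans(M)
    se <- sqrt(apply(M, 2, stats::var) / nrow(M))
    ok <- se > 0
    out <- numeric(length(m)); out[ok] <- m[ok] / se[ok]
    out
  }
  vapply(seq_len(n_perm), function(i) {
    flips <- sample(c(-1, 1), s, replace = TRUE)
    max(one_sample_t(con_mat * flips))
  }, numeric(1))
}

# neighbour offsets for 6/18/26-connectivity
connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "6" = g[rowSums(abs(g)) == 1, , drop = FALSE],
         "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
         "26" = g,
         stop("connectivity must be 6, 18 or 26"))
}

#' Label connected clusters and apply an extent threshold
#'
#' Labels connected components of a binary 3D map (default
#' face-adjacency, 6-connectivity) by breadth-first search and removes
#' components smaller than `extent_min` voxels.
#'
#' @param binary logical 3D array.
#' @param extent_min minimum cluster size in voxels (0 = keep all).
#' @param connectivity 6, 18 or 26.
#' @return list with `labels` (integer 3D array, 0 = background, labels
#'   renumbered after filtering), `sizes` (named integer vector of
#'   retained cluster sizes), `mask` (logical 3D array of retained
#'   voxels).
#' @export
cluster_filter <- function(binary, extent_min = 10, connectivity = 6) {
  stopifnot(is.logical(binary), length(dim(binary)) == 3, extent_min >= 0)
  d <- dim(binary)
  offs <- connectivity_offsets(connectivity)
  labels <- array(0L, dim = d)
  active <- which(binary)
  comp <- 0L
  sizes <- integer(0)
  for (start in active) {
    if (labels[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    labels[start] <- comp
    size <- 0L
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      size <- size + 1L
      ijk <- linear_to_ijk(v, d)
      nb <- sweep(offs, 2, as.numeric(ijk), `+`)
      ok <- nb[, 1] >= 0 & nb[, 1] < d[1] &
            nb[, 2] >= 0 & nb[, 2] < d[2] &
            nb[, 3] >= 0 & nb[, 3] < d[3]
      nb_lin <- ijk_to_linear(nb[ok, , drop = FALSE], d)
      nb_lin <- nb_lin[binary[nb_lin] & labels[nb_lin] == 0L]
      if (length(nb_lin)) {
        labels[nb_lin] <- comp
        queue <- c(queue, nb_lin)
      }
    }
    sizes[comp] <- size
  }
  keep <- which(sizes >= extent_min)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- array(0L, dim = d)
  nz <- labels != 0L
  out[nz] <- relab[labels[nz]]
  kept_sizes <- sizes[keep]
  if (length(kept_sizes)) names(kept_sizes) <- seq_along(kept_sizes)
  list(labels = out, sizes = kept_sizes, mask = out > 0L)
}

#' Canonical seed coordinates of the dynamic body-selective network
#'
#' Group-level peak MNI coordinates of the seven regions the localizer
#' targets: right and left extrastriate body area (rEBA, lEBA), right
#' fusiform body area (rFBA), right and left posterior superior temporal
#' sulcus (rpSTS, lpSTS), right precentral gyrus (rPCG) and right
#' inferior frontal gyrus (rIFG), with the 10-mm search-sphere radius.
#'
#' @return data.frame with columns `name`, `x`, `y`, `z`, `radius_mm`.
#' @export
default_roi_seeds <- function() {
  data.frame(
    name = c("rFBA", "rEBA", "rpSTS", "rPCG", "lEBA", "lpSTS", "rIFG"),
    x = c(45, 45, 54, 48, -48, -63, 42),
    y = c(-46, -79, -46, 5, -73, -49, 20),
    z = c(-17, -11, 7, 46, 7, 19, 22),
    radius_mm = 10,
    stringsAsFactors = FALSE)
}

#' Literature-average coordinates for the same regions
#'
#' Mean MNI coordinates of the seven network regions as reported across
#' earlier static-body and point-light-display localizer studies, for
#' comparison against estimates from this localizer via
#' [compare_to_reference()].
#'
#' @return data.frame with columns `name`, `x`, `y`, `z`.
#' @export
literature_roi_coords <- function() {
  data.frame(
    name = c("rFBA", "rEBA", "rpSTS", "rPCG", "lEBA", "lpSTS", "rIFG"),
    x = c(42, 47, 54, 43, -47, -49, 44),
    y = c(-44, -69, -52, 9, -74, -57, 14),
    z = c(-24, 0, 12, 42, 4, 16, 15),
    stringsAsFactors = FALSE)
}

#' Find the peak of a thresholded map within an ROI search sphere
#'
#' Restricts the map to voxels within `radius_mm` of the seed coordinate
#' (millimetre distance through the affine) that survive both the height
#' threshold and the cluster extent filter; the peak is the maximum-t
#' surviving voxel, ties broken by lexicographic voxel index order.
#'
#' @param map a `stat_map`.
#' @param seed one row of a seed table (`name`, `x`, `y`, `z`,
#'   `radius_mm`) as a list or single-row data.frame.
#' @param surviving logical 3D array of voxels surviving height +
#'   extent thresholding (from [voxel_threshold()] and
#'   [cluster_filter()]).
#' @return list with `name`, `present`, `n_voxels`, `peak_xyz` (mm),
#'   `peak_t` (NA when absent).
#' @export
find_roi_peak <- function(map, seed, surviving) {
  stopifnot(inherits(map, "stat_map"))
  seed <- as.list(seed)
  radius <- if (!is.null(seed$radius_mm)) seed$radius_mm else 10
  d <- dim(map$values)
  vox <- voxels_in_sphere(c(seed$x, seed$y, seed$z), radius, d, map$affine)
  if (nrow(vox) == 0) {
    stop("ROI sphere for ", seed$name, " lies entirely outside the grid")
  }
  lin <- ijk_to_linear(vox, d)
  surv <- lin[surviving[lin]]
  if (length(surv) == 0) {
    return(list(name = seed$name, present = FALSE, n_voxels = 0L,
                peak_xyz = c(NA_real_, NA_real_, NA_real_),
                peak_t = NA_real_))
  }
  tv <- map$values[surv]
  peak_lin <- surv[which.max(tv)]   # which.max: first max = lexicographic tie-break
  peak_ijk <- linear_to_ijk(peak_lin, d)
  list(name = seed$name, present = TRUE, n_voxels = length(surv),
       peak_xyz = drop(voxel_to_mm(peak_ijk, map$affine)),
       peak_t = map$values[peak_lin])
}

#' Per-subject ROI report across thresholds
#'
#' Applies each threshold specification (height + cluster extent) to a
#' subject's t-map and extracts peak and extent statistics within every
#' ROI search sphere.
#'
#' @param map a `stat_map`.
#' @param seeds seed table as from [default_roi_seeds()].
#' @param specs list of [threshold_spec()] objects.
#' @param mask optional logical search mask.
#' @return data.frame of class `roi_report`: one row per ROI x
#'   threshold with `roi`, `threshold`, `present`, `n_voxels`,
#'   `peak_x`, `peak_y`, `peak_z`, `peak_t`, `t_threshold`.
#' @export
roi_report <- function(map, seeds = default_roi_seeds(),
                       specs = list(threshold_spec("fwe_05"),
                                    threshold_spec("unc_001"),
                                    threshold_spec("unc_05")),
                       mask = NULL) {
  rows <- list()
  for (spec in specs) {
    vt <- voxel_threshold(map, spec, mask = mask)
    cf <- cluster_filter(vt$mask, extent_min = spec$cluster_extent_min)
    for (i in seq_len(nrow(seeds))) {
      pk <- find_roi_peak(map, seeds[i, ], cf$mask)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = pk$name, threshold = spec$level, present = pk$present,
        n_voxels = pk$n_voxels, peak_x = pk$peak_xyz[1],
        peak_y = pk$peak_xyz[2], peak_z = pk$peak_xyz[3],
        peak_t = pk$peak_t, t_threshold = vt$threshold,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("roi_report", "data.frame")
  out
}

#' Group tally of ROI detection across subjects
#'
#' For each ROI and threshold: the number of subjects showing activation,
#' the mean voxel count among them, and the mean and SD of peak
#' coordinates across the subjects in which the ROI was present.
#'
#' @param reports list of per-subject [roi_report()] data.frames.
#' @return data.frame with one row per ROI x threshold: `roi`,
#'   `threshold`, `n_present`, `n_subjects`, `frac_present`,
#'   `mean_n_voxels`, `mean_x/y/z`, `sd_x/y/z`.
#' @export
subject_tally <- function(reports) {
  stopifnot(length(reports) >= 1)
  all_df <- do.call(rbind, lapply(seq_along(reports), function(i) {
    df <- as.data.frame(reports[[i]])
    df$subject <- i
    df
  }))
  keys <- unique(all_df[, c("roi", "threshold")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- all_df[all_df$roi == keys$roi[i] &
                  all_df$threshold == keys$threshold[i], ]
    pres <- sub[sub$present, , drop = FALSE]
    data.frame(
      roi = keys$roi[i], threshold = keys$threshold[i],
      n_present = nrow(pres), n_subjects = nrow(sub),
      frac_present = nrow(pres) / nrow(sub),
      mean_n_voxels = if (nrow(pres)) mean(pres$n_voxels) else 0,
      mean_x = if (nrow(pres)) mean(pres$peak_x) else NA_real_,
      mean_y = if (nrow(pres)) mean(pres$peak_y) else NA_real_,
      mean_z = if (nrow(pres)) mean(pres$peak_z) else NA_real_,
      sd_x = if (nrow(pres) > 1) stats::sd(pres$peak_x) else NA_real_,
      sd_y = if (nrow(pres) > 1) stats::sd(pres$peak_y) else NA_real_,
      sd_z = if (nrow(pres) > 1) stats::sd(pres$peak_z) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Distance between estimated and reference ROI coordinates
#'
#' Euclidean millimetre distance between each ROI's estimated group-mean
#' peak and a reference coordinate table (e.g.
#' [literature_roi_coords()]).
#'
#' @param estimated data.frame with `name` (or `roi`), `x`, `y`, `z`.
#' @param reference data.frame with `name`, `x`, `y`, `z`.
#' @return data.frame with `name` and `distance_mm`.
#' @export
compare_to_reference <- function(estimated, reference) {
  if (!"name" %in% names(estimated) && "roi" %in% names(estimated)) {
    estimated$name <- estimated$roi
  }
  idx <- match(estimated$name, reference$name)
  if (anyNA(idx)) {
    stop("reference table missing ROI(s): ",
         paste(estimated$name[is.na(idx)], collapse = ", "))
  }
  d <- sqrt((estimated$x - reference$x[idx])^2 +
            (estimated$y - reference$y[idx])^2 +
            (estimated$z - reference$z[idx])^2)
  data.frame(name = estimated$name, distance_mm = d,
             stringsAsFactors = FALSE)
}
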
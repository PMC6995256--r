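#' Convert an RGB frame to luminance
#'
#' Rec.601 luma weighting: `0.299 R + 0.587 G + 0.114 B`. Weights sum to
#' one, so grayscale input is returned unchanged.
#'
#' @param rgb_frame height x width x 3 array, values nominally 0-255.
#' @return height x width luminance matrix.
#' @export
to_luminance <- function(rgb_frame) {
  d <- dim(rgb_frame)
  if (length(d) != 3 || d[3] != 3) {
    stop("rgb_frame must be a height x width x 3 array")
  }
  0.299 * rgb_frame[, , 1] + 0.587 * rgb_frame[, , 2] + 0.114 * rgb_frame[, , 3]
}

#' Derive a background mask by colour keying
#'
#' Marks as background every pixel that stays within `tol` of the key
#' colour, per channel, in every frame -- i.e. pixels never occupied by
#' the actor or object. The localizer stimuli use a green screen
#' (RGB 159, 202, 145), so colour keying recovers the region where
#' frame-to-frame luminance change reflects only sensor/compression noise.
#'
#' @param rgb_frames height x width x 3 x n_frames array.
#' @param key_rgb key colour, three values in 0-255.
#' @param tol per-channel tolerance in intensity units (>= 0).
#' @return logical height x width matrix, `TRUE` = background.
#' @export
background_mask_from_color <- function(rgb_frames, key_rgb = c(159, 202, 145),
                                       tol = 10) {
  stopifnot(tol >= 0, length(key_rgb) == 3)
  d <- dim(rgb_frames)
  if (length(d) != 4 || d[3] != 3) {
    stop("rgb_frames must be a height x width x 3 x n_frames array")
  }
  mask <- matrix(TRUE, d[1], d[2])
  for (t in seq_len(d[4])) {
    for (ch in 1:3) {
      mask <- mask & (abs(rgb_frames[, , ch, t] - key_rgb[ch]) <= tol)
    }
  }
  if (!any(mask)) {
    stop("colour keying produced an empty background mask; ",
         "increase tol or supply a mask manually")
  }
  mask
}

#' Estimate a clip's noise level from background luminance change
#'
#' Frame-to-frame luminance change in the background (pixels never
#' occupied by the moving figure) serves as a surrogate measure of the
#' clip's noise level. The default statistic is the mean over frame pairs
#' of the 95th percentile of `|delta luminance|` within the background
#' mask; for i.i.d. Gaussian pixel noise of sd sigma the differences are
#' half-normal with scale `sigma * sqrt(2)`, so this estimates
#' `qnorm(0.975) * sigma * sqrt(2)`. The statistic is configurable
#' because a scalar noise summary admits several reasonable choices.
#'
#' @param clip a `video_clip` (must carry a nonempty `background_mask`).
#' @param stat `"p95"` (default), `"mean"`, or `"mean+2sd"` of the
#'   per-pair background `|delta luminance|`, averaged over pairs.
#' @return scalar noise level in luminance units.
#' @export
estimate_noise <- function(clip, stat = c("p95", "mean", "mean+2sd")) {
  stat <- match.arg(stat)
  stopifnot(inherits(clip, "video_clip"))
  mask <- clip$background_mask
  if (is.null(mask) || !any(mask)) stop("clip has no nonempty background mask")
  nf <- dim(clip$frames)[3]
  per_pair <- vapply(seq_len(nf - 1L), function(t) {
    d <- abs(clip$frames[, , t + 1L] - clip$frames[, , t])[mask]
    switch(stat,
           "p95" = stats::quantile(d, 0.95, names = FALSE),
           "mean" = mean(d),
           "mean+2sd" = mean(d) + 2 * stats::sd(d))
  }, numeric(1))
  mean(per_pair)
}

#' Quantify low-level local motion in a clip
#'
#' For each pair of consecutive frames, counts the pixels (over the whole
#' frame) whose absolute luminance change exceeds `noise_level`, and
#' averages the counts to a single value per clip -- the clip's motion
#' measure. Counts are invariant to global luminance offsets and
#' monotone nondecreasing as the threshold decreases.
#'
#' @param clip a `video_clip`.
#' @param noise_level scalar threshold in luminance units (>= 0). Defaults
#'   to the clip's recorded realized noise level if present, else to
#'   [estimate_noise()].
#' @return an object of class `motion_result`: list with `noise_level`,
#'   `per_pair_counts` (length `n_frames - 1`), and `clip_motion`
#'   (their mean).
#' @export
clip_motion <- function(clip, noise_level = NULL) {
  stopifnot(inherits(clip, "video_clip"))
  nf <- dim(clip$frames)[3]
  if (nf < 2) stop("clip must have at least 2 frames")
  if (is.null(noise_level)) {
    noise_level <- if (!is.null(clip$realized_noise)) clip$realized_noise
                   else estimate_noise(clip)
  }
  stopifnot(noise_level >= 0)
  counts <- vapply(seq_len(nf - 1L), function(t) {
    sum(abs(clip$frames[, , t + 1L] - clip$frames[, , t]) > noise_level)
  }, numeric(1))
  structure(list(noise_level = noise_level, per_pair_counts = counts,
                 clip_motion = mean(counts), label = clip$label),
            class = "motion_result")
}

#' @export
print.motion_result <- function(x, ...) {
  cat(sprintf("motion_result: clip_motion = %.2f (noise level %.4g, %d frame pairs)\n",
              x$clip_motion, x$noise_level, length(x$per_pair_counts)))
  invisible(x)
}

#' Cumulative motion over the five clips of a block
#'
#' @param results list of exactly five `motion_result` objects (one per
#'   clip shown in the 10-s block).
#' @param condition `"body"` or `"object"`.
#' @param block_id optional identifier.
#' @return an object of class `block_motion` with `cumulative_motion`
#'   equal to the sum of the five clip-motion values.
#' @export
block_motion <- function(results, condition = c("body", "object"),
                         block_id = NA_character_) {
  condition <- match.arg(condition)
  if (length(results) != 5) {
    stop("a block comprises exactly 5 clips; got ", length(results))
  }
  stopifnot(all(vapply(results, inherits, logical(1), "motion_result")))
  vals <- vapply(results, `[[`, numeric(1), "clip_motion")
  structure(list(block_id = block_id,
                 clip_ids = vapply(seq_along(results), function(i) {
                   lb <- results[[i]]$label
                   if (!is.null(lb$clip_id)) as.character(lb$clip_id)
                   else sprintf("clip%02d", i)
                 }, character(1)),
                 cumulative_motion = sum(vals),
                 condition = condition),
            class = "block_motion")
}

#' Correlate clip motion with perceived-motion ratings
#'
#' Sample Pearson correlation with a two-sided p-value from the t
#' distribution on `n - 2` degrees of freedom.
#'
#' @param motions,ratings numeric vectors of equal length >= 3,
#'   nonconstant.
#' @return list with `r`, `n`, `df`, `t`, `p`.
#' @export
correlate_ratings <- function(motions, ratings) {
  stopifnot(length(motions) == length(ratings), length(motions) >= 3)
  if (stats::sd(motions) == 0 || stats::sd(ratings) == 0) {
    stop("correlation undefined for a constant input vector")
  }
  ct <- stats::cor.test(motions, ratings, method = "pearson")
  list(r = unname(ct$estimate), n = length(motions),
       df = unname(ct$parameter), t = unname(ct$statistic),
       p = ct$p.value)
}

#' Compare cumulative block motion between conditions
#'
#' Two-sample t-test of body versus object block motion. Default is the
#' pooled-variance Student test (`df = n1 + n2 - 2`); a Welch option is
#' available.
#'
#' @param body,object numeric vectors of cumulative block motion (>= 2
#'   values each).
#' @param var_equal pooled-variance Student test if `TRUE` (default),
#'   Welch if `FALSE`.
#' @return list with `t`, `df`, `p`, `mean_body`, `mean_object`.
#' @export
compare_block_motion <- function(body, object, var_equal = TRUE) {
  stopifnot(length(body) >= 2, length(object) >= 2)
  tt <- stats::t.test(body, object, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_body = mean(body), mean_object = mean(object))
}

#' Write / read clip-motion tables
#'
#' Tab-separated motion tables with columns `clip_id`, `noise_level`,
#' `clip_motion`; block tables with `block_id`, `condition`,
#' `cumulative_motion`.
#'
#' @param results list of `motion_result` objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_motions <- function(results, path) {
  df <- data.frame(
    clip_id = vapply(seq_along(results), function(i) {
      lb <- results[[i]]$label
      if (!is.null(lb$clip_id)) as.character(lb$clip_id) else sprintf("clip%03d", i)
    }, character(1)),
    noise_level = vapply(results, `[[`, numeric(1), "noise_level"),
    clip_motion = vapply(results, `[[`, numeric(1), "clip_motion"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motions
#' @param blocks list of `block_motion` objects.
#' @export
write_block_motions <- function(blocks, path) {
  df <- data.frame(
    block_id = vapply(blocks, function(b) as.character(b$block_id), character(1)),
    condition = vapply(blocks, `[[`, character(1), "condition"),
    cumulative_motion = vapply(blocks, `[[`, numeric(1), "cumulative_motion"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motions
#' @export
read_block_motions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
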
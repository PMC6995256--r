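#' Specification for a synthetic motion-controlled video clip
#'
#' Describes a clip on the stimulus geometry used by the localizer:
#' 960 x 540 pixel frames, 50 frames at 25 frames per second, a uniform
#' green background (RGB 159, 202, 145) and a dark rigid object that
#' translates one pixel per frame. Because a rigid object of edge length
#' `s` translating one pixel on a clean background changes exactly `2 s`
#' pixels per frame pair, the ground-truth number of supra-noise changed
#' pixels is controlled analytically by the object size:
#' `moving_pixels_per_frame = 2 s`.
#'
#' @param width,height frame size in pixels.
#' @param n_frames number of frames (>= 2).
#' @param fps frame rate, frames per second.
#' @param background_rgb background colour, three values in 0-255.
#' @param noise_sd standard deviation of zero-mean Gaussian pixel noise in
#'   luminance units, added identically to all three channels after motion
#'   rendering (so the luminance noise sd equals `noise_sd` exactly).
#' @param moving_pixels_per_frame ground-truth count of pixels whose
#'   frame-to-frame luminance change exceeds the clip's realized noise
#'   level. Must be even (object edge length is `moving_pixels_per_frame/2`)
#'   or zero for a static clip.
#' @param object_shape `"square"` (edge `s`) or `"bar"` (height `s`, width
#'   `max(2, s %/% 4)`); both change `2 s` pixels per one-pixel step.
#' @param seed integer RNG seed for the pixel noise.
#' @return an object of class `clip_spec`.
#' @export
clip_spec <- function(width = 960, height = 540, n_frames = 50, fps = 25,
                      background_rgb = c(159, 202, 145), noise_sd = 0,
                      moving_pixels_per_frame = 120,
                      object_shape = c("square", "bar"), seed = 1L) {
  object_shape <- match.arg(object_shape)
  stopifnot(width >= 1, height >= 1, n_frames >= 2, fps > 0,
            length(background_rgb) == 3,
            all(background_rgb >= 0 & background_rgb <= 255),
            noise_sd >= 0,
            moving_pixels_per_frame >= 0,
            moving_pixels_per_frame <= width * height)
  if (moving_pixels_per_frame %% 2 != 0) {
    stop("moving_pixels_per_frame must be even: a rigid object of edge s ",
         "translating 1 px changes exactly 2*s pixels per frame pair")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_frames = as.integer(n_frames), fps = fps,
                 background_rgb = as.numeric(background_rgb),
                 noise_sd = noise_sd,
                 moving_pixels_per_frame = as.integer(moving_pixels_per_frame),
                 object_shape = object_shape, seed = as.integer(seed)),
            class = "clip_spec")
}

# object placement for a spec; errors if the sweep leaves the frame
object_geometry <- function(spec) {
  s <- spec$moving_pixels_per_frame %/% 2L
  if (s == 0L) return(NULL)
  obj_w <- if (spec$object_shape == "square") s else max(2L, s %/% 4L)
  sweep_w <- obj_w + spec$n_frames - 1L
  if (s > spec$height || sweep_w > spec$width) {
    stop("object sweep exceeds frame bounds: object ", s, " x ", obj_w,
         " sweeping ", sweep_w, " px does not fit in ",
         spec$width, " x ", spec$height,
         "; reduce moving_pixels_per_frame or n_frames, or enlarge the frame")
  }
  y0 <- (spec$height - s) %/% 2L + 1L          # 1-based top row
  x0 <- (spec$width - sweep_w) %/% 2L + 1L     # 1-based leftmost column
  list(s = s, obj_w = obj_w, y0 = y0, x0 = x0, sweep_w = sweep_w)
}

#' Generate a synthetic motion-controlled video clip
#'
#' Renders a dark rigid object translating one pixel per frame (left to
#' right) over a uniform green background, then adds zero-mean Gaussian
#' pixel noise. The returned clip carries exact ground truth: the set of
#' pixels genuinely changed by object motion for every consecutive frame
#' pair, and the *realized noise level* -- the maximum absolute
#' frame-to-frame luminance change over all pixels not changed by the
#' motion. Exactly `moving_pixels_per_frame` pixels per frame pair change
#' by more than that level (provided the noise is small relative to the
#' object/background luminance contrast, as in all sensible settings).
#'
#' @param spec a [clip_spec()].
#' @param keep_rgb keep the full RGB stack on the clip (memory-hungry at
#'   the default 960 x 540 geometry; needed only for colour-keyed masking).
#' @param label optional named list of tags (actor, emotion, condition...).
#' @return an object of class `video_clip`: a list with `frames` (height x
#'   width x n_frames luminance array, Rec.601), `background_mask`
#'   (logical height x width, `TRUE` = never swept by the object), `fps`,
#'   `label`, `realized_noise`, and `ground_truth` (per-pair changed pixel
#'   index matrix and count).
#' @export
make_clip <- function(spec, keep_rgb = FALSE, label = list()) {
  stopifnot(inherits(spec, "clip_spec"))
  geo <- object_geometry(spec)
  h <- spec$height; w <- spec$width; nf <- spec$n_frames
  bg_lum <- sum(c(0.299, 0.587, 0.114) * spec$background_rgb)
  obj_rgb <- c(20, 20, 20)   # dark clothing against the green screen
  obj_lum <- sum(c(0.299, 0.587, 0.114) * obj_rgb)

  frames <- array(bg_lum, dim = c(h, w, nf))
  changed <- vector("list", nf - 1L)
  background_mask <- matrix(TRUE, h, w)
  if (!is.null(geo)) {
    rows <- geo$y0:(geo$y0 + geo$s - 1L)
    for (t in seq_len(nf)) {
      cols <- (geo$x0 + t - 1L):(geo$x0 + t - 1L + geo$obj_w - 1L)
      frames[rows, cols, t] <- obj_lum
    }
    background_mask[rows, geo$x0:(geo$x0 + geo$sweep_w - 1L)] <- FALSE
    for (t in seq_len(nf - 1L)) {
      vacated <- geo$x0 + t - 1L
      covered <- geo$x0 + t - 1L + geo$obj_w
      changed[[t]] <- cbind(row = rep(rows, 2L),
                            col = rep(c(vacated, covered), each = geo$s))
    }
  } else {
    for (t in seq_len(nf - 1L)) {
      changed[[t]] <- cbind(row = integer(0), col = integer(0))
    }
  }

  rgb <- NULL
  if (keep_rgb) {
    rgb <- array(0, dim = c(h, w, 3L, nf))
    for (ch in 1:3) rgb[, , ch, ] <- spec$background_rgb[ch]
    if (!is.null(geo)) {
      rows <- geo$y0:(geo$y0 + geo$s - 1L)
      for (t in seq_len(nf)) {
        cols <- (geo$x0 + t - 1L):(geo$x0 + t - 1L + geo$obj_w - 1L)
        for (ch in 1:3) rgb[rows, cols, ch, t] <- obj_rgb[ch]
      }
    }
  }

  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    noise <- array(stats::rnorm(h * w * nf, 0, spec$noise_sd), dim = c(h, w, nf))
    frames <- frames + noise
    if (keep_rgb) for (ch in 1:3) rgb[, , ch, ] <- rgb[, , ch, ] + noise
  }

  # realized noise level: max |delta luminance| over all pixels NOT part of
  # the planted motion, across all frame pairs
  realized <- 0
  for (t in seq_len(nf - 1L)) {
    d <- abs(frames[, , t + 1L] - frames[, , t])
    if (nrow(changed[[t]]) > 0) d[changed[[t]]] <- 0
    realized <- max(realized, max(d))
  }

  structure(list(frames = frames, rgb = rgb,
                 background_mask = background_mask,
                 fps = spec$fps, label = label, spec = spec,
                 realized_noise = realized,
                 ground_truth = list(
                   moving_pixels_per_frame = spec$moving_pixels_per_frame,
                   changed = changed)),
            class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("video_clip: %d x %d px, %d frames @ %g fps (%.2f s)\n",
              d[2], d[1], d[3], x$fps, d[3] / x$fps))
  cat(sprintf("  realized noise level: %.4g; ground-truth moving pixels/pair: %d\n",
              x$realized_noise, x$ground_truth$moving_pixels_per_frame))
  if (length(x$label)) {
    cat("  label:", paste(names(x$label), unlist(x$label), sep = "=",
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Clip duration in seconds
#' @param clip a `video_clip`.
#' @return duration in seconds (`n_frames / fps`).
#' @export
clip_duration <- function(clip) {
  stopifnot(inherits(clip, "video_clip"))
  dim(clip$frames)[3] / clip$fps
}

#' Generate a labelled actor-by-emotion stimulus set
#'
#' Emulates the localizer's body stimulus set: one two-second clip per
#' actor and emotion. With 15 actors and three emotions (angry, happy,
#' neutral) this yields the 45-clip set. Each clip gets its own noise seed
#' derived deterministically from the template seed.
#'
#' @param n_actors number of actors (>= 1).
#' @param emotions character vector of emotion labels (nonempty).
#' @param spec_template a [clip_spec()] used for every clip; per-clip
#'   motion is varied slightly around the template's
#'   `moving_pixels_per_frame` so clips are not identical.
#' @param sexes optional character vector of actor sexes; default assigns
#'   the first six actors male and the remainder female, matching the
#'   composition of the original stimulus set.
#' @param keep_rgb passed to [make_clip()].
#' @return a list of `video_clip` objects with `label` fields
#'   `actor`, `emotion`, `sex`, `condition = "body"`.
#' @export
make_stimulus_set <- function(n_actors = 15, emotions = c("angry", "happy", "neutral"),
                              spec_template = clip_spec(), sexes = NULL,
                              keep_rgb = FALSE) {
  stopifnot(n_actors >= 1, length(emotions) >= 1)
  if (is.null(sexes)) {
    sexes <- c(rep("male", min(6L, n_actors)),
               rep("female", max(0L, n_actors - 6L)))
  }
  stopifnot(length(sexes) == n_actors)
  clips <- vector("list", n_actors * length(emotions))
  idx <- 1L
  # vary object size (hence motion) deterministically across clips
  set.seed(spec_template$seed)
  base_s <- spec_template$moving_pixels_per_frame %/% 2L
  jitter_s <- if (base_s > 4L) {
    sample(-(base_s %/% 4L):(base_s %/% 4L), length(clips), replace = TRUE)
  } else rep(0L, length(clips))
  for (a in seq_len(n_actors)) {
    for (e in seq_along(emotions)) {
      sp <- spec_template
      sp$seed <- spec_template$seed + 1000L * idx
      sp$moving_pixels_per_frame <- 2L * (base_s + jitter_s[idx])
      clips[[idx]] <- make_clip(sp, keep_rgb = keep_rgb,
                                label = list(actor = sprintf("actor%02d", a),
                                             emotion = emotions[e],
                                             sex = sexes[a],
                                             condition = "body"))
      idx <- idx + 1L
    }
  }
  clips
}

#' Generate ratings with a prescribed correlation to a motion vector
#'
#' Builds a perceived-motion rating vector whose sample Pearson
#' correlation with `motions` equals `target_r` (to well within 0.02, by
#' construction: the ratings combine the standardized motion vector with
#' an orthogonalized standardized noise vector in the exact proportion).
#'
#' @param motions numeric vector of clip-motion values (length >= 3,
#'   nonconstant).
#' @param target_r target Pearson correlation, in `[-1, 1]`.
#' @param seed RNG seed for the noise component.
#' @param center,scale location and scale of the returned ratings.
#' @return numeric rating vector, same length as `motions`.
#' @export
make_ratings <- function(motions, target_r, seed = 1L, center = 4, scale = 1) {
  n <- length(motions)
  stopifnot(n >= 3, abs(target_r) <= 1)
  if (stats::sd(motions) == 0) {
    stop("motions vector is constant: correlation with it is undefined")
  }
  zm <- as.numeric(scale(motions))
  if (abs(target_r) == 1) {
    return(center + scale * sign(target_r) * zm)
  }
  set.seed(seed)
  repeat {
    e <- stats::rnorm(n)
    e <- stats::residuals(stats::lm(e ~ zm))
    if (stats::sd(e) > 0) break
  }
  ze <- as.numeric(scale(e))
  y <- target_r * zm + sqrt(1 - target_r^2) * ze
  center + scale * as.numeric(scale(y))
}
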
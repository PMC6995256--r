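#' Specification for a synthetic 4D BOLD run
#'
#' Describes a block-design BOLD acquisition on a desk-scale grid:
#' 246 volumes at TR 2.6 s with 3-mm isotropic voxels by default,
#' activations planted at MNI coordinates as HRF-convolved condition
#' boxcars, plus low-frequency drift, smooth head-motion confound
#' components and Gaussian noise. The affine maps the grid centre to
#' `mni_center` (default the MNI origin).
#'
#' @param grid_shape 3-vector of voxel counts (default 20 x 24 x 20).
#' @param voxel_size_mm isotropic voxel size (mm).
#' @param n_volumes number of volumes.
#' @param tr_s repetition time (s).
#' @param schedule a `block_schedule`; any run time beyond the last
#'   block is baseline.
#' @param active_sites data.frame with columns `name`, `x`, `y`, `z`
#'   (MNI mm), `condition` (`"body"` or `"object"`), `amplitude`
#'   (signal units); may have zero rows for a null run.
#' @param site_radius_mm radius of the spherical neighbourhood around
#'   each site that carries the full planted amplitude.
#' @param baseline constant signal level.
#' @param noise_sd Gaussian noise sd (signal units).
#' @param drift_amplitude slow drift amplitude (signal units; linear +
#'   low-frequency cosine, per-voxel scaled).
#' @param head_motion_sd sd of each of the six smooth head-motion
#'   confound traces (their per-voxel couplings are standard normal).
#' @param mni_center mm coordinate of the grid centre.
#' @param seed RNG seed.
#' @return object of class `bold_spec`.
#' @export
bold_spec <- function(grid_shape = c(20, 24, 20), voxel_size_mm = 3,
                      n_volumes = 246, tr_s = 2.6,
                      schedule = build_schedule(),
                      active_sites = NULL, site_radius_mm = 6,
                      baseline = 100, noise_sd = 1, drift_amplitude = 0,
                      head_motion_sd = 0, mni_center = c(0, 0, 0),
                      seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1), voxel_size_mm > 0,
            n_volumes >= 1, tr_s > 0, inherits(schedule, "block_schedule"),
            site_radius_mm > 0, noise_sd >= 0, head_motion_sd >= 0)
  if (schedule$total_duration_s > n_volumes * tr_s + 1e-9) {
    stop("schedule (", schedule$total_duration_s, " s) exceeds the run ",
         "length (", n_volumes * tr_s, " s)")
  }
  if (is.null(active_sites)) {
    active_sites <- data.frame(name = character(0), x = numeric(0),
                               y = numeric(0), z = numeric(0),
                               condition = character(0),
                               amplitude = numeric(0))
  }
  stopifnot(all(c("name", "x", "y", "z", "condition", "amplitude") %in%
                  names(active_sites)),
            all(is.finite(active_sites$amplitude)))
  affine <- grid_affine(grid_shape, voxel_size_mm, mni_center)
  if (nrow(active_sites) > 0) {
    vox <- mm_to_voxel(as.matrix(active_sites[, c("x", "y", "z")]), affine)
    inside <- vox[, 1] >= 0 & vox[, 1] < grid_shape[1] &
              vox[, 2] >= 0 & vox[, 2] < grid_shape[2] &
              vox[, 3] >= 0 & vox[, 3] < grid_shape[3]
    if (!all(inside)) {
      stop("active site(s) outside the grid after affine mapping: ",
           paste(active_sites$name[!inside], collapse = ", "),
           "; enlarge grid_shape or move mni_center")
    }
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, n_volumes = as.integer(n_volumes),
                 tr_s = tr_s, schedule = schedule,
                 active_sites = active_sites, site_radius_mm = site_radius_mm,
                 baseline = baseline, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 head_motion_sd = head_motion_sd,
                 mni_center = mni_center, affine = affine,
                 seed = as.integer(seed)),
            class = "bold_spec")
}

# smooth random-walk confound traces, n x 6, each scaled to sd `sd`
head_motion_traces <- function(n, sd) {
  traces <- vapply(1:6, function(j) {
    w <- cumsum(stats::rnorm(n))
    w <- stats::filter(w, rep(1 / 5, 5), sides = 2, circular = TRUE)
    w <- as.numeric(w) - mean(w)
    if (stats::sd(w) > 0) w <- w / stats::sd(w)
    w * sd
  }, numeric(n))
  colnames(traces) <- sprintf("motion_param_%d", 1:6)
  traces
}

#' Generate a synthetic 4D BOLD run with planted ground truth
#'
#' Signal model per voxel:
#' `baseline + sum_sites amplitude * (condition boxcar convolved with the
#' canonical HRF)` within each site's spherical neighbourhood, plus
#' per-voxel-scaled drift, head-motion confound components and i.i.d.
#' Gaussian noise. The returned ground truth records the planted voxel
#' indices and amplitudes, the head-motion traces added to the signal,
#' and the condition regressors, so parameter recovery can be checked
#' exactly.
#'
#' @param spec a [bold_spec()].
#' @return object of class `bold_run`: list with `data`
#'   (x,y,z,t array), `affine`, `tr_s`, `spec`, `ground_truth` (list:
#'   `sites` data.frame with a `voxels` list-column of linear indices,
#'   `regressors` (body/object, HRF-convolved), `head_motion` traces,
#'   `drift` trace).
#' @export
make_bold <- function(spec) {
  stopifnot(inherits(spec, "bold_spec"))
  set.seed(spec$seed)
  d <- spec$grid_shape
  V <- prod(d)
  n <- spec$n_volumes
  b <- spec$schedule$blocks

  reg <- list(
    body = condition_regressor(b$onset_s[b$condition_class == "body"],
                               b$duration_s[b$condition_class == "body"],
                               n, spec$tr_s),
    object = condition_regressor(b$onset_s[b$condition_class == "object"],
                                 b$duration_s[b$condition_class == "object"],
                                 n, spec$tr_s))

  Y <- matrix(spec$baseline, nrow = n, ncol = V)

  site_vox <- vector("list", nrow(spec$active_sites))
  for (i in seq_len(nrow(spec$active_sites))) {
    s <- spec$active_sites[i, ]
    vox <- voxels_in_sphere(c(s$x, s$y, s$z), spec$site_radius_mm, d,
                            spec$affine)
    lin <- ijk_to_linear(vox, d)
    site_vox[[i]] <- lin
    r <- reg[[s$condition]]
    if (is.null(r)) stop("unknown site condition: ", s$condition)
    Y[, lin] <- Y[, lin] + s$amplitude * r
  }

  drift <- NULL
  if (spec$drift_amplitude > 0) {
    t_s <- (seq_len(n) - 1) * spec$tr_s
    drift <- spec$drift_amplitude *
      (seq(-1, 1, length.out = n) + 0.5 * cos(2 * pi * t_s / 300))
    w <- stats::runif(V, 0.5, 1.5)
    Y <- Y + drift %o% w
  }

  hm <- NULL
  if (spec$head_motion_sd > 0) {
    hm <- head_motion_traces(n, spec$head_motion_sd)
    W <- matrix(stats::rnorm(V * 6), nrow = 6)
    Y <- Y + hm %*% W
  }

  if (spec$noise_sd > 0) {
    Y <- Y + matrix(stats::rnorm(n * V, 0, spec$noise_sd), nrow = n)
  }

  sites <- spec$active_sites
  sites$voxels <- site_vox

  structure(list(data = array(t(Y), dim = c(d, n)),
                 affine = spec$affine, tr_s = spec$tr_s, spec = spec,
                 ground_truth = list(sites = sites, regressors = reg,
                                     head_motion = hm, drift = drift)),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold_run: %d x %d x %d voxels, %d volumes @ TR %g s, %d planted site(s)\n",
              d[1], d[2], d[3], d[4], x$tr_s, nrow(x$ground_truth$sites)))
  invisible(x)
}

# time x voxels matrix view of a bold_run or 4D array
bold_matrix <- function(bold) {
  arr <- if (inherits(bold, "bold_run")) bold$data else bold
  d <- dim(arr)
  stopifnot(length(d) == 4)
  t(matrix(arr, nrow = prod(d[1:3]), ncol = d[4]))
}

#' Write / read 4D BOLD volumes as NIfTI-1
#'
#' @param bold a `bold_run` or a 4D array with an `affine` attribute.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param tr_s repetition time recorded in the header.
#' @return `path` invisibly; `read_bold` returns a list with `data`
#'   (4D array), `affine`, `tr_s`.
#' @export
write_bold <- function(bold, path, tr_s = NULL) {
  if (inherits(bold, "bold_run")) {
    arr <- bold$data; affine <- bold$affine
    if (is.null(tr_s)) tr_s <- bold$tr_s
  } else {
    arr <- bold; affine <- attr(bold, "affine")
    if (is.null(affine)) stop("supply a bold_run or an array with an affine attribute")
    if (is.null(tr_s)) tr_s <- 1
  }
  d <- dim(arr)
  img <- RNifti::asNifti(arr, reference = NULL)
  img <- RNifti::`pixdim<-`(img, c(abs(diag(affine)[1:3]), tr_s))
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), dimnames = NULL)
  pd <- attr(RNifti::niftiHeader(img), "pixdim")
  hdr <- RNifti::niftiHeader(img)
  if (is.null(tr_s)) {
    tr_s <- if (length(hdr$pixdim) >= 5 && hdr$pixdim[5] > 0) hdr$pixdim[5] else 1
  }
  list(data = array(as.numeric(img), dim = dim(img)), affine = affine,
       tr_s = tr_s)
}
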
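#' Write a t-map as NIfTI-1
#'
#' @param map a `stat_map`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, path) {
  stopifnot(inherits(map, "stat_map"))
  img <- RNifti::asNifti(map$values, reference = NULL)
  img <- RNifti::`pixdim<-`(img, abs(diag(map$affine)[1:3]))
  RNifti::qform(img) <- structure(map$affine, code = 2L)
  RNifti::sform(img) <- structure(map$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# md5 of a config list, via its canonical JSON serialization
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), f)
  unname(tools::md5sum(f))
}

# fit one subject: smooth, design, GLM, contrast; returns stat_map + fit
fit_subject <- function(bold, schedule, block_motions, head_motion,
                        fwhm_mm, highpass_cutoff_s, covariate_mode) {
  arr <- if (inherits(bold, "bold_run")) bold$data else bold$data
  affine <- bold$affine
  tr_s <- bold$tr_s
  d <- dim(arr)
  if (fwhm_mm > 0) {
    arr <- smooth_volume(arr, fwhm_mm = fwhm_mm,
                         voxel_size_mm = abs(diag(affine))[1])
  }
  Y <- t(matrix(arr, nrow = prod(d[1:3]), ncol = d[4]))
  X <- build_design(schedule, block_motions = block_motions,
                    head_motion = head_motion, n_volumes = d[4],
                    tr_s = tr_s, highpass_cutoff_s = highpass_cutoff_s,
                    covariate_mode = covariate_mode)
  fit <- fit_glm(Y, X)
  map <- contrast_tmap(fit, c(body = 1, non_body = -1), d[1:3], affine,
                       contrast_name = "body_gt_object")
  list(map = map, fit = fit, design = X)
}

#' Run the full localizer pipeline
#'
#' Orchestrates, per subject: optional Gaussian smoothing, design
#' construction (conditions, clip-motion covariate, head-motion
#' confounds, drift, intercept), voxelwise OLS, the body-minus-object
#' contrast t-map, and ROI extraction at the requested thresholds; then
#' aggregates subjects into a group tally and (for two or more subjects)
#' a second-level one-sample t-map on the subject contrast images with
#' its own ROI report.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{bold}{list of `bold_run` objects, or character vector of
#'       NIfTI paths.}
#'     \item{events}{a `block_schedule` or events TSV path.}
#'     \item{block_motions}{data.frame (`block_id`, `cumulative_motion`),
#'       TSV path, or `NULL` to omit the covariate.}
#'     \item{confounds}{list of n x 6 matrices, character vector of
#'       whitespace-delimited 6-column files (one per subject), or
#'       `NULL`: the GLM then runs without head-motion columns and a
#'       warning is logged.}
#'     \item{seeds}{ROI seed data.frame or TSV path (default
#'       [default_roi_seeds()]).}
#'     \item{thresholds}{character subset of `fwe_05`, `unc_001`,
#'       `unc_05` (default all three).}
#'     \item{cluster_extent_min}{minimum cluster size (default 10).}
#'     \item{fwhm_mm}{smoothing kernel FWHM (default 8).}
#'     \item{highpass_cutoff_s}{drift cutoff (default 128).}
#'     \item{covariate_mode}{`"hrf"` or `"raw"` (default `"hrf"`).}
#'     \item{out}{output directory, or `NULL` to skip writing.}
#'     \item{seed}{global RNG seed recorded in provenance.}
#'   }
#' @return list with `subject_reports` (list of [roi_report()]
#'   data.frames), `subject_maps` (list of `stat_map`), `group_tally`,
#'   `group_map` (`NULL` for a single subject), `group_report` (equals
#'   the subject's report for a single subject), `provenance`.
#' @export
run_localizer <- function(config) {
  stopifnot(is.list(config), !is.null(config$bold), !is.null(config$events))
  cfg <- utils::modifyList(
    list(block_motions = NULL, confounds = NULL, seeds = NULL,
         thresholds = c("fwe_05", "unc_001", "unc_05"),
         cluster_extent_min = 10, fwhm_mm = 8, highpass_cutoff_s = 128,
         covariate_mode = "hrf", out = NULL, seed = 1L),
    config)

  schedule <- if (inherits(cfg$events, "block_schedule")) cfg$events
              else read_events(cfg$events)
  block_motions <- cfg$block_motions
  if (is.character(block_motions)) {
    block_motions <- read_block_motions(block_motions)
  }
  seeds <- cfg$seeds
  if (is.null(seeds)) seeds <- default_roi_seeds()
  if (is.character(seeds)) seeds <- utils::read.delim(seeds)

  bolds <- cfg$bold
  if (is.character(bolds)) bolds <- lapply(bolds, read_bold)
  if (inherits(bolds, "bold_run")) bolds <- list(bolds)
  n_subj <- length(bolds)

  confounds <- cfg$confounds
  if (is.null(confounds)) {
    warning("no head-motion confounds supplied; fitting without ",
            "motion_param regressors")
    confounds <- vector("list", n_subj)
  } else if (is.character(confounds)) {
    confounds <- lapply(confounds, function(p) {
      as.matrix(utils::read.table(p))
    })
  }
  stopifnot(length(confounds) == n_subj)

  specs <- lapply(cfg$thresholds, function(lv) {
    threshold_spec(lv, cluster_extent_min = cfg$cluster_extent_min)
  })

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    attr(val, "elapsed_s") <- proc.time()[["elapsed"]] - t0
    val
  }

  subject_maps <- vector("list", n_subj)
  subject_reports <- vector("list", n_subj)
  effect_mats <- vector("list", n_subj)
  timings <- list()
  for (s in seq_len(n_subj)) {
    res <- stage(sprintf("glm subject %d", s), fit_subject(
      bolds[[s]], schedule, block_motions, confounds[[s]],
      cfg$fwhm_mm, cfg$highpass_cutoff_s, cfg$covariate_mode))
    timings[[sprintf("glm_subject_%d_s", s)]] <- attr(res, "elapsed_s")
    subject_maps[[s]] <- res$map
    effect_mats[[s]] <- as.numeric(res$map$effect)
    subject_reports[[s]] <- stage(sprintf("localize subject %d", s),
                                  roi_report(res$map, seeds, specs))
  }

  group_tally <- subject_tally(subject_reports)

  group_map <- NULL
  group_report <- subject_reports[[1]]
  if (n_subj >= 2) {
    con_mat <- do.call(rbind, effect_mats)        # subjects x voxels
    m <- colMeans(con_mat)
    se <- sqrt(apply(con_mat, 2, stats::var) / n_subj)
    tv <- ifelse(se > 0, m / se, 0)
    d <- dim(subject_maps[[1]]$values)
    group_map <- structure(
      list(values = array(tv, dim = d), effect = array(m, dim = d),
           affine = subject_maps[[1]]$affine, df = n_subj - 1,
           contrast_name = "group_body_gt_object",
           zero_variance = array(se == 0, dim = d)),
      class = "stat_map")
    group_report <- stage("localize group", roi_report(group_map, seeds, specs))
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("dynbodyloc")),
    r_version = R.version.string,
    seed = cfg$seed,
    config_hash = config_hash(
      cfg[setdiff(names(cfg), c("bold", "confounds", "out"))]),
    n_subjects = n_subj,
    thresholds = cfg$thresholds,
    fwhm_mm = cfg$fwhm_mm,
    highpass_cutoff_s = cfg$highpass_cutoff_s,
    covariate_mode = cfg$covariate_mode,
    timings = timings,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))

  out <- list(subject_reports = subject_reports, subject_maps = subject_maps,
              group_tally = group_tally, group_map = group_map,
              group_report = group_report, provenance = provenance)

  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    for (s in seq_len(n_subj)) {
      write_stat_map(subject_maps[[s]],
                     file.path(cfg$out, sprintf("sub-%02d_tmap.nii.gz", s)))
      utils::write.table(subject_reports[[s]],
                         file.path(cfg$out, sprintf("sub-%02d_roi_report.tsv", s)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(group_map)) {
      write_stat_map(group_map, file.path(cfg$out, "group_tmap.nii.gz"))
    }
    utils::write.table(group_tally, file.path(cfg$out, "group_tally.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(group_report, file.path(cfg$out, "group_roi_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # strip per-run wall-clock fields so reruns are byte-identical
    repro <- provenance[setdiff(names(provenance), c("timings", "timestamp"))]
    jsonlite::write_json(repro, file.path(cfg$out, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(provenance, file.path(cfg$out, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Fully synthetic end-to-end localizer demonstration
#'
#' Generates everything the pipeline needs from a single seed -- the
#' 48-block schedule, a 45-clip body stimulus set plus 45 object clips
#' (desk-scale frames), per-clip motion, per-block cumulative motion,
#' perceived-motion ratings, and one synthetic BOLD run per subject with
#' activations planted at the seven canonical network coordinates -- then
#' runs [run_localizer()] and returns the report together with the
#' ground truth.
#'
#' @param seed integer master seed.
#' @param n_subjects number of synthetic subjects.
#' @param grid_shape,mni_center BOLD grid; the default 50 x 44 x 32 grid
#'   centred at (0, -25, 10) mm covers all seven seed spheres at 3-mm
#'   voxels.
#' @param amplitude planted effect amplitude in signal units (default
#'   5 x `noise_sd`).
#' @param noise_sd BOLD noise sd.
#' @param drift_amplitude,head_motion_sd confound magnitudes.
#' @param clip_width,clip_height clip frame geometry for the synthetic
#'   stimulus sets (desk-scale; the full stimulus geometry is 960 x 540).
#' @param out output directory or `NULL`.
#' @param fwhm_mm smoothing kernel FWHM (mm).
#' @return the [run_localizer()] result, plus `schedule`,
#'   `block_motions`, `motion_stats` (rating correlation and
#'   body-vs-object block test), and `ground_truth` (planted sites).
#' @export
demo_synthetic <- function(seed = 0L, n_subjects = 3,
                           grid_shape = c(50, 44, 32),
                           mni_center = c(0, -25, 10),
                           amplitude = NULL, noise_sd = 1,
                           drift_amplitude = 0.5, head_motion_sd = 0.2,
                           clip_width = 120, clip_height = 90,
                           out = NULL, fwhm_mm = 8) {
  if (is.null(amplitude)) amplitude <- 5 * noise_sd
  seed <- as.integer(seed)

  schedule <- build_schedule(seed = seed + 1L)

  template <- clip_spec(width = clip_width, height = clip_height,
                        noise_sd = 2, moving_pixels_per_frame = 60,
                        seed = seed + 2L)
  body_clips <- make_stimulus_set(spec_template = template)
  object_clips <- lapply(seq_len(45), function(i) {
    sp <- template
    sp$seed <- seed + 500L + i
    # object clips span a similar motion range as the body set
    sp$moving_pixels_per_frame <- 2L * (24L + (i %% 15L))
    make_clip(sp, label = list(clip_id = sprintf("object%02d", i),
                               condition = "object"))
  })
  for (i in seq_along(body_clips)) {
    lb <- body_clips[[i]]$label
    body_clips[[i]]$label$clip_id <- paste(lb$actor, lb$emotion, sep = "_")
  }
  clips <- c(body_clips, object_clips)
  motions <- lapply(clips, clip_motion)
  motion_by_id <- stats::setNames(
    vapply(motions, `[[`, numeric(1), "clip_motion"),
    vapply(motions, function(m) m$label$clip_id, character(1)))

  b <- schedule$blocks
  stim <- b[b$condition_class %in% c("body", "object"), ]
  block_motions <- data.frame(
    block_id = stim$block_id,
    condition = stim$condition_class,
    cumulative_motion = vapply(stim$clip_ids, function(ids) {
      sum(motion_by_id[strsplit(ids, ",")[[1]]])
    }, numeric(1), USE.NAMES = FALSE))

  ratings <- make_ratings(unname(motion_by_id), target_r = 0.571,
                          seed = seed + 3L)
  motion_stats <- list(
    rating_correlation = correlate_ratings(unname(motion_by_id), ratings),
    block_comparison = compare_block_motion(
      block_motions$cumulative_motion[block_motions$condition == "body"],
      block_motions$cumulative_motion[block_motions$condition == "object"]))

  sites <- default_roi_seeds()[, c("name", "x", "y", "z")]
  sites$condition <- "body"
  sites$amplitude <- amplitude

  bolds <- vector("list", n_subjects)
  confounds <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sp <- bold_spec(grid_shape = grid_shape, mni_center = mni_center,
                    schedule = schedule, active_sites = sites,
                    noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                    head_motion_sd = head_motion_sd,
                    seed = seed * 1000L + s)
    bolds[[s]] <- make_bold(sp)
    confounds[[s]] <- bolds[[s]]$ground_truth$head_motion
    if (is.null(confounds[[s]])) {
      confounds[[s]] <- matrix(0, sp$n_volumes, 6)
      confounds[[s]][] <- stats::rnorm(length(confounds[[s]]), 0, 1e-6)
    }
  }

  res <- run_localizer(list(
    bold = bolds, events = schedule, block_motions = block_motions,
    confounds = confounds, fwhm_mm = fwhm_mm, out = out, seed = seed))

  res$schedule <- schedule
  res$block_motions <- block_motions
  res$motion_stats <- motion_stats
  res$ground_truth <- list(sites = sites,
                           planted_voxels = bolds[[1]]$ground_truth$sites$voxels)
  res
}

#' Null t-map simulation for calibration checks
#'
#' Repeatedly generates pure-noise runs under the localizer design, fits
#' the GLM and computes the body-minus-object t-map, recording for each
#' run the fraction of voxels exceeding the p < .05 uncorrected
#' threshold and whether any voxel exceeds the Bonferroni
#' familywise-error threshold at alpha = .05.
#'
#' @param n_maps number of Monte-Carlo runs.
#' @param grid_shape voxel grid for the simulated maps.
#' @param n_volumes,tr_s run geometry.
#' @param schedule block schedule defining the design (default the
#'   48-block schedule).
#' @param seed RNG seed.
#' @return list with `frac_unc05` (per run), `fwe_fp` (logical per
#'   run), `df` (residual df of the fitted model).
#' @export
simulate_null_tmaps <- function(n_maps = 200, grid_shape = c(12, 12, 12),
                                n_volumes = 246, tr_s = 2.6,
                                schedule = build_schedule(), seed = 1L) {
  X <- build_design(schedule, n_volumes = n_volumes, tr_s = tr_s)
  V <- prod(grid_shape)
  affine <- grid_affine(grid_shape, 3)
  set.seed(seed)
  spec_unc <- threshold_spec("unc_05", cluster_extent_min = 0)
  spec_fwe <- threshold_spec("fwe_05", cluster_extent_min = 0)
  frac <- numeric(n_maps)
  fwe_fp <- logical(n_maps)
  df <- NA_real_
  for (i in seq_len(n_maps)) {
    Y <- matrix(stats::rnorm(n_volumes * V), nrow = n_volumes)
    fit <- fit_glm(Y, X)
    map <- contrast_tmap(fit, c(body = 1, non_body = -1), grid_shape, affine)
    df <- map$df
    mask <- array(TRUE, dim = grid_shape)
    frac[i] <- sum(voxel_threshold(map, spec_unc, mask = mask)$mask) / V
    fwe_fp[i] <- any(voxel_threshold(map, spec_fwe, mask = mask)$mask)
  }
  list(frac_unc05 = frac, fwe_fp = fwe_fp, df = df)
}
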
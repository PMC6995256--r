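# small, fast fixtures shared across test files

# desk-scale clip spec: fits a 60-px object sweep in a 160 x 80 frame
small_clip_spec <- function(moving = 60, noise_sd = 0, n_frames = 20,
                            seed = 1L, width = 160, height = 80) {
  clip_spec(width = width, height = height, n_frames = n_frames,
            noise_sd = noise_sd, moving_pixels_per_frame = moving,
            seed = seed)
}

# brute-force oracle: per-pair count of pixels with |delta lum| > thr
brute_force_counts <- function(clip, thr) {
  nf <- dim(clip$frames)[3]
  vapply(seq_len(nf - 1L), function(t) {
    sum(abs(clip$frames[, , t + 1L] - clip$frames[, , t]) > thr)
  }, numeric(1))
}

# one cached default schedule (deterministic)
default_schedule <- local({
  sch <- NULL
  function() {
    if (is.null(sch)) sch <<- build_schedule(seed = 1L)
    sch
  }
})

# tiny single-site BOLD run + matching seed table, for pipeline tests
tiny_bold_setup <- function(seed = 7L, noise_sd = 0.5, amplitude = 3,
                            head_motion_sd = 0.2) {
  sites <- data.frame(name = "ctr", x = 0, y = 0, z = 0,
                      condition = "body", amplitude = amplitude)
  sp <- bold_spec(grid_shape = c(10, 10, 10), schedule = default_schedule(),
                  active_sites = sites, noise_sd = noise_sd,
                  drift_amplitude = 0.3, head_motion_sd = head_motion_sd,
                  seed = seed)
  list(bold = make_bold(sp),
       seeds = data.frame(name = "ctr", x = 0, y = 0, z = 0,
                          radius_mm = 10, stringsAsFactors = FALSE))
}
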
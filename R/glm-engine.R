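#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = g(t; 6, 1) - g(t; 16, 1) / 6` with gamma densities `g`
#' (shape/rate parameterization), the standard positive response peaking
#' near 5 s with a late undershoot, normalized so the peak equals 1.
#'
#' @param t_grid time points in seconds (>= 0).
#' @return numeric response values on `t_grid`.
#' @export
canonical_hrf <- function(t_grid) {
  stopifnot(all(t_grid >= 0))
  raw <- function(t) stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  # grid-independent peak normalization
  peak <- max(raw(seq(0, 32, by = 0.001)))
  raw(t_grid) / peak
}

#' HRF-convolved block regressor sampled at the TR
#'
#' Builds a boxcar from block onsets/durations (with optional per-block
#' heights, e.g. a parametric motion covariate), convolves it with the
#' canonical HRF on a fine time grid, and samples at volume acquisition
#' times `0, TR, 2 TR, ...`.
#'
#' @param onsets,durations block onsets and durations (s).
#' @param n_volumes number of volumes.
#' @param tr_s repetition time (s).
#' @param heights per-block boxcar heights (default 1).
#' @param dt fine-grid step for the convolution (s).
#' @param convolve if `FALSE`, return the raw boxcar sampled at the TR.
#' @return numeric vector of length `n_volumes`.
#' @export
condition_regressor <- function(onsets, durations, n_volumes, tr_s,
                                heights = 1, dt = 0.1, convolve = TRUE) {
  stopifnot(length(onsets) == length(durations), n_volumes >= 1, tr_s > 0)
  heights <- rep_len(heights, length(onsets))
  t_end <- n_volumes * tr_s
  fine_t <- seq(0, t_end, by = dt)
  u <- numeric(length(fine_t))
  for (i in seq_along(onsets)) {
    on <- fine_t >= onsets[i] & fine_t < onsets[i] + durations[i]
    u[on] <- u[on] + heights[i]
  }
  if (convolve) {
    h <- canonical_hrf(seq(0, 32, by = dt))
    u <- stats::convolve(u, rev(h), type = "open")[seq_along(fine_t)] * dt
  }
  vol_t <- (seq_len(n_volumes) - 1) * tr_s
  u[round(vol_t / dt) + 1L]
}

# orthonormal DCT-II basis (non-constant terms k = 1..K) on n samples
dct_basis <- function(n, K) {
  if (K < 1) return(matrix(numeric(0), n, 0))
  t0 <- 0:(n - 1)
  B <- vapply(seq_len(K), function(k) {
    sqrt(2 / n) * cos(pi * (2 * t0 + 1) * k / (2 * n))
  }, numeric(n))
  colnames(B) <- sprintf("drift_%d", seq_len(K))
  B
}

# number of non-constant DCT drift regressors for a run of length
# n_volumes * tr_s seconds and the given high-pass cutoff
n_dct_columns <- function(n_volumes, tr_s, cutoff_s) {
  floor(2 * (n_volumes * tr_s) / cutoff_s)
}

#' Build the localizer design matrix
#'
#' Assembles, in order: a body and a non-body (object) condition
#' regressor (10-s boxcars convolved with the canonical HRF), the clip
#' motion covariate (a boxcar whose height during each stimulus block is
#' that block's mean-centered cumulative motion, HRF-convolved by
#' default), six mean-centered head-motion regressors, a discrete cosine
#' high-pass drift basis for periods longer than `highpass_cutoff_s`,
#' and an intercept.
#'
#' @param schedule a `block_schedule`.
#' @param block_motions optional data.frame with columns `block_id`,
#'   `cumulative_motion` (or a list of `block_motion` objects) covering
#'   every stimulus block; `NULL` omits the covariate.
#' @param head_motion optional `n_volumes` x 6 matrix of head-motion
#'   parameter traces; `NULL` omits the columns.
#' @param n_volumes number of volumes.
#' @param tr_s repetition time (s).
#' @param highpass_cutoff_s high-pass cutoff (s); drift columns span
#'   periods longer than this.
#' @param covariate_mode `"hrf"` (convolve the motion covariate) or
#'   `"raw"` (enter the per-scan boxcar unconvolved).
#' @return a `design_matrix`: numeric matrix (`n_volumes` x p) with
#'   column names, and attributes `tr_s`, `highpass_cutoff_s`.
#' @export
build_design <- function(schedule, block_motions = NULL, head_motion = NULL,
                         n_volumes = 246, tr_s = schedule$tr_s,
                         highpass_cutoff_s = 128,
                         covariate_mode = c("hrf", "raw")) {
  covariate_mode <- match.arg(covariate_mode)
  stopifnot(inherits(schedule, "block_schedule"))
  if (schedule$total_duration_s > n_volumes * tr_s + 1e-9) {
    stop("schedule (", schedule$total_duration_s, " s) is longer than the ",
         "run (", n_volumes * tr_s, " s)")
  }
  b <- schedule$blocks
  stim <- b[b$condition_class %in% c("body", "object"), , drop = FALSE]

  body <- condition_regressor(b$onset_s[b$condition_class == "body"],
                              b$duration_s[b$condition_class == "body"],
                              n_volumes, tr_s)
  non_body <- condition_regressor(b$onset_s[b$condition_class == "object"],
                                  b$duration_s[b$condition_class == "object"],
                                  n_volumes, tr_s)
  X <- cbind(body = body, non_body = non_body)

  if (!is.null(block_motions)) {
    if (is.list(block_motions) && !is.data.frame(block_motions)) {
      block_motions <- data.frame(
        block_id = vapply(block_motions, function(x) as.character(x$block_id),
                          character(1)),
        cumulative_motion = vapply(block_motions, `[[`, numeric(1),
                                   "cumulative_motion"))
    }
    m <- block_motions$cumulative_motion[
      match(stim$block_id, block_motions$block_id)]
    if (anyNA(m)) {
      stop("block_motions does not cover all stimulus blocks: missing ",
           paste(stim$block_id[is.na(m)], collapse = ", "))
    }
    heights <- m - mean(m)
    cov_col <- condition_regressor(stim$onset_s, stim$duration_s, n_volumes,
                                   tr_s, heights = heights,
                                   convolve = covariate_mode == "hrf")
    X <- cbind(X, motion_covariate = cov_col)
  }

  if (!is.null(head_motion)) {
    head_motion <- as.matrix(head_motion)
    if (nrow(head_motion) != n_volumes || ncol(head_motion) != 6) {
      stop("head_motion must be an n_volumes x 6 matrix")
    }
    hm <- scale(head_motion, center = TRUE, scale = FALSE)
    colnames(hm) <- sprintf("motion_param_%d", 1:6)
    X <- cbind(X, hm)
  }

  K <- n_dct_columns(n_volumes, tr_s, highpass_cutoff_s)
  if (K > 0) X <- cbind(X, dct_basis(n_volumes, K))
  X <- cbind(X, intercept = 1)

  # an all-zero column (e.g. a centered covariate with identical block
  # motions) is harmless -- the fit absorbs it; only genuine collinearity
  # among non-degenerate columns is an error
  nonzero <- apply(abs(X), 2, max) > 1e-12 * max(abs(X))
  if (qr(X[, nonzero, drop = FALSE])$rank < sum(nonzero)) {
    stop("design matrix is rank deficient; check the schedule, ",
         "covariate and confounds for collinearity")
  }
  structure(X, tr_s = tr_s, highpass_cutoff_s = highpass_cutoff_s,
            class = c("design_matrix", "matrix", "array"))
}

#' Gaussian spatial smoothing of a 3D or 4D volume
#'
#' Separable Gaussian smoothing with the kernel width specified as
#' full-width-at-half-maximum in millimetres
#' (`sigma = fwhm / (2 sqrt(2 log 2))` per axis, converted to voxels).
#' The kernel is normalized to unit mass and applied with zero padding,
#' so total intensity away from the volume edge is preserved.
#'
#' @param volume 3D array or 4D array (x, y, z, time).
#' @param fwhm_mm kernel FWHM in mm (0 = identity).
#' @param voxel_size_mm isotropic voxel size in mm (> 0).
#' @return smoothed array, same dimensions.
#' @export
smooth_volume <- function(volume, fwhm_mm = 8, voxel_size_mm = 3) {
  stopifnot(fwhm_mm >= 0)
  if (voxel_size_mm <= 0) stop("voxel size must be positive")
  if (fwhm_mm == 0) return(volume)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  d <- dim(volume)
  nd <- length(d)
  stopifnot(nd %in% c(3, 4))
  kern_mat <- function(n) {
    r <- max(1L, ceiling(4 * sigma_vox))
    k <- stats::dnorm(-r:r, sd = sigma_vox)
    k <- k / sum(k)
    K <- matrix(0, n, n)
    for (off in -r:r) {
      idx <- seq_len(n)
      src <- idx + off
      ok <- src >= 1 & src <= n
      K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + k[off + r + 1]
    }
    K
  }
  out <- volume
  for (axis in 1:3) {
    perm <- c(axis, setdiff(seq_len(nd), axis))
    a <- aperm(out, perm)
    da <- dim(a)
    m <- matrix(a, nrow = da[1])
    m <- kern_mat(da[1]) %*% m
    a <- array(m, dim = da)
    out <- aperm(a, order(perm))
  }
  out
}

#' High-pass filter a time series by DCT projection
#'
#' Removes slow drifts by projecting out the discrete-cosine basis of
#' periods longer than `cutoff_s` (plus the mean) and returning the
#' residual -- the same operation performed implicitly by the drift
#' columns of the design matrix.
#'
#' @param ts numeric vector, or matrix with time in rows.
#' @param cutoff_s high-pass cutoff in seconds (must exceed `2 * tr_s`).
#' @param tr_s sampling interval (s).
#' @return filtered series, same shape as `ts`.
#' @export
highpass_filter <- function(ts, cutoff_s = 128, tr_s = 2.6) {
  ts <- as.matrix(ts)
  n <- nrow(ts)
  if (n < 2) stop("time series must have at least 2 samples")
  if (cutoff_s <= 2 * tr_s) stop("cutoff must exceed 2 * tr_s")
  K <- n_dct_columns(n, tr_s, cutoff_s)
  B <- cbind(rep(1 / sqrt(n), n), dct_basis(n, K))
  res <- ts - B %*% crossprod(B, ts)
  if (ncol(res) == 1) drop(res) else res
}

#' Voxelwise ordinary least squares fit
#'
#' Fits `y = X beta + e` independently for every voxel (column of `Y`)
#' by QR-based least squares: `beta = (X'X)^{-1} X' y`, residual variance
#' `RSS / df` with `df = n - rank(X)`. A rank-deficient design triggers a
#' warning and a Moore-Penrose pseudoinverse fit with correspondingly
#' reduced degrees of freedom.
#'
#' @param Y numeric matrix, `n_volumes` x `n_voxels`.
#' @param X design matrix, `n_volumes` x p (see [build_design()]).
#' @return object of class `glm_fit`: list with `beta` (p x n_voxels),
#'   `sigma2` (length n_voxels), `df_resid`, `XtX_inv` (p x p, a
#'   generalized inverse when rank deficient), `names`.
#' @export
fit_glm <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- unclass(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(nrow(Y) == n)
  if (n <= p) stop("need more volumes than regressors (n = ", n,
                   ", p = ", p, ")")
  qrX <- qr(X)
  rank <- qrX$rank
  if (rank == p) {
    beta <- qr.coef(qrX, Y)
    R <- qr.R(qrX)
    XtX_inv <- chol2inv(R)
  } else {
    warning("design matrix is rank deficient (rank ", rank, " of ", p,
            "); using pseudoinverse, df reduced accordingly")
    sv <- svd(X)
    keep <- sv$d > max(sv$d) * 1e-10
    pinv <- sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
    beta <- pinv %*% Y
    XtX_inv <- sv$v[, keep, drop = FALSE] %*%
      (t(sv$v[, keep, drop = FALSE]) / sv$d[keep]^2)
  }
  fitted <- X %*% beta
  rss <- colSums((Y - fitted)^2)
  df <- n - rank
  # voxels whose data are (numerically) constant have no variance to model
  mu <- colMeans(Y)
  tss <- colSums(Y^2) - n * mu^2
  zero_var <- tss <= (n - 1) * (1e-8 * (abs(mu) + 1))^2
  structure(list(beta = beta, sigma2 = rss / df, df_resid = df,
                 XtX_inv = XtX_inv, names = colnames(X),
                 zero_variance = zero_var),
            class = "glm_fit")
}

#' t-statistic map for a linear contrast
#'
#' `t = c' beta / sqrt(sigma2 * c' (X'X)^{-1} c)` per voxel. Voxels with
#' (numerically) zero residual variance get `t = 0` and are flagged.
#'
#' @param fit a [fit_glm()] result.
#' @param con contrast vector of length p, or a named numeric vector
#'   matched against the design column names (unnamed columns get 0).
#' @param grid_shape 3-vector of voxel counts; `prod(grid_shape)` must
#'   equal the number of voxels.
#' @param affine 4x4 voxel-to-mm affine.
#' @param contrast_name label stored on the map.
#' @return object of class `stat_map`: list with `values` (3D t array),
#'   `affine`, `df`, `contrast_name`, `zero_variance` (logical 3D array).
#' @export
contrast_tmap <- function(fit, con, grid_shape, affine,
                          contrast_name = "contrast") {
  stopifnot(inherits(fit, "glm_fit"))
  p <- nrow(fit$beta)
  if (!is.null(names(con))) {
    cc <- numeric(p)
    idx <- match(names(con), fit$names)
    if (anyNA(idx)) stop("unknown regressor names in contrast: ",
                         paste(names(con)[is.na(idx)], collapse = ", "))
    cc[idx] <- con
  } else {
    stopifnot(length(con) == p)
    cc <- as.numeric(con)
  }
  V <- ncol(fit$beta)
  stopifnot(prod(grid_shape) == V)
  eff <- drop(crossprod(cc, fit$beta))
  cvar <- drop(t(cc) %*% fit$XtX_inv %*% cc)
  se2 <- fit$sigma2 * cvar
  zero <- fit$zero_variance | cvar == 0
  tval <- numeric(V)
  t_cap <- 1e8   # numerical cap for (near-)perfect fits
  pos <- !zero & se2 > 0
  tval[pos] <- pmax(pmin(eff[pos] / sqrt(se2[pos]), t_cap), -t_cap)
  exact <- !zero & se2 <= 0
  tval[exact] <- sign(eff[exact]) * t_cap
  structure(list(values = array(tval, dim = grid_shape),
                 effect = array(eff, dim = grid_shape),
                 affine = affine, df = fit$df_resid,
                 contrast_name = contrast_name,
                 zero_variance = array(zero, dim = grid_shape)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat_map '%s': %s voxels, df = %g, t range [%.2f, %.2f]\n",
              x$contrast_name, paste(dim(x$values), collapse = " x "),
              x$df, min(x$values), max(x$values)))
  invisible(x)
}
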
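#' Maximal-length sequences over GF(3)
#'
#' Generates an m-sequence (maximal-length linear feedback shift register
#' sequence) over a prime alphabet. At each step the new symbol is
#' `sum(taps * state) mod base` and the register shifts. For primitive
#' taps the state sequence visits every nonzero k-tuple exactly once per
#' period `base^k - 1`, giving the flat autocorrelation that motivates
#' m-sequence condition ordering in block designs.
#'
#' Shipped default taps (verified primitive over GF(3)): order 2 `(1,1)`,
#' order 3 `(1,0,2)`, order 4 `(1,0,0,1)`.
#'
#' @param base alphabet size (prime; default 3).
#' @param order register length k.
#' @param taps feedback coefficients, length `order`, values in
#'   `0..base-1`, last tap nonzero. Default: shipped primitive taps for
#'   base 3, order 2-4.
#' @param seed_state initial register contents (nonzero vector, length
#'   `order`); default `c(1, 0, ..., 0)`.
#' @return object of class `msequence`: list with `base`, `order`,
#'   `taps`, `symbols` (length `base^order - 1`).
#' @export
generate_msequence <- function(base = 3, order = 3, taps = NULL,
                               seed_state = NULL) {
  stopifnot(base >= 2, order >= 1)
  if (is.null(taps)) {
    defaults <- list(`2` = c(1, 1), `3` = c(1, 0, 2), `4` = c(1, 0, 0, 1))
    if (base != 3 || !as.character(order) %in% names(defaults)) {
      stop("no default taps shipped for base ", base, ", order ", order,
           "; supply primitive taps explicitly")
    }
    taps <- defaults[[as.character(order)]]
  }
  stopifnot(length(taps) == order, all(taps %in% 0:(base - 1)))
  if (taps[order] == 0) stop("last tap must be nonzero for a degree-", order,
                             " feedback polynomial")
  if (is.null(seed_state)) seed_state <- c(1, rep(0, order - 1))
  stopifnot(length(seed_state) == order, any(seed_state != 0),
            all(seed_state %in% 0:(base - 1)))

  full_period <- base^order - 1
  state <- as.integer(seed_state)
  symbols <- integer(full_period)
  for (t in seq_len(full_period)) {
    new <- sum(taps * state) %% base
    symbols[t] <- new
    state <- c(new, state[-order])
    if (t < full_period && all(state == seed_state)) {
      stop("taps are not primitive over GF(", base, "): realized period ",
           t, " < ", full_period)
    }
  }
  if (!all(state == seed_state)) {
    stop("taps are not primitive over GF(", base, "): state did not return ",
         "to the seed after ", full_period, " steps")
  }
  structure(list(base = base, order = order, taps = taps,
                 seed_state = seed_state, symbols = symbols),
            class = "msequence")
}

# fraction of adjacent pairs with equal condition (lag-1 label agreement)
lag1_agreement <- function(x) mean(x[-1] == x[-length(x)])

max_run_length <- function(x) max(rle(x)$lengths)

#' Build the 48-block localizer schedule from an m-sequence
#'
#' One experimental run comprises 48 ten-second blocks: 18 body blocks
#' (balanced across three emotions), 18 object blocks and 12 blank-screen
#' baseline blocks, in a pseudo-randomized order derived from an
#' m-sequence over GF(3). The cyclic m-sequence is tiled to 48 symbols
#' (0 = baseline, 1 = body, 2 = object); because the full-period symbol
#' composition does not match the 18/18/12 partition, counts are repaired
#' by minimal single-block edits chosen to minimize lag-1 condition
#' agreement, under a hard cap of 3 consecutive same-condition blocks.
#' Emotions are assigned to body blocks in a balanced rotation and each
#' stimulus block receives five clip identifiers.
#'
#' @param mseq an [generate_msequence()] result (default order 3 over
#'   GF(3), period 26).
#' @param counts named vector `c(body=, object=, baseline=)` summing to
#'   the number of blocks (default 18/18/12).
#' @param emotions emotion labels rotated across body blocks.
#' @param tr_s repetition time attached to the schedule (s).
#' @param block_duration_s block length (s).
#' @param seed seed for clip-to-block assignment.
#' @param body_clip_ids,object_clip_ids clip identifier pools cycled
#'   across stimulus blocks; defaults name 45 clips each (15 actors x 3
#'   emotions for bodies).
#' @return object of class `block_schedule`: list with `blocks`
#'   (data.frame: block_id, condition, condition_class, emotion, onset_s,
#'   duration_s, clip_ids), `tr_s`, `total_duration_s`.
#' @export
build_schedule <- function(mseq = generate_msequence(3, 3),
                           counts = c(body = 18, object = 18, baseline = 12),
                           emotions = c("angry", "happy", "neutral"),
                           tr_s = 2.6, block_duration_s = 10, seed = 1L,
                           body_clip_ids = NULL, object_clip_ids = NULL) {
  stopifnot(inherits(mseq, "msequence"),
            all(c("body", "object", "baseline") %in% names(counts)))
  n_blocks <- sum(counts)
  if (n_blocks != 48) {
    # the canonical run is 48 blocks; other totals allowed for testing
    if (n_blocks < 1) stop("counts must sum to a positive number of blocks")
  }

  sym <- rep(mseq$symbols, length.out = n_blocks)
  cls <- c("baseline", "body", "object")[sym + 1L]

  target <- counts[c("body", "object", "baseline")]
  # repair composition: flip one block at a time from the most
  # over-represented to the most under-represented class, choosing the
  # position that minimizes lag-1 agreement subject to the run cap
  repeat {
    tab <- c(body = sum(cls == "body"), object = sum(cls == "object"),
             baseline = sum(cls == "baseline"))
    diff <- tab - target
    if (all(diff == 0)) break
    from <- names(which.max(diff))
    to <- names(which.min(diff))
    cand <- which(cls == from)
    best <- NULL; best_score <- Inf
    for (pos in cand) {
      trial <- cls
      trial[pos] <- to
      score <- lag1_agreement(trial) + 10 * max(0, max_run_length(trial) - 3)
      if (score < best_score) { best_score <- score; best <- pos }
    }
    cls[best] <- to
  }

  # enforce the hard cap of 3 consecutive same-condition blocks by swaps
  for (iter in 1:200) {
    r <- rle(cls)
    if (max(r$lengths) <= 3) break
    run_idx <- which.max(r$lengths)
    run_start <- sum(r$lengths[seq_len(run_idx - 1)]) + 1L
    pos <- run_start + 3L  # first block beyond the allowed run
    partners <- which(cls != cls[pos])
    best <- NULL; best_score <- Inf
    for (j in partners) {
      trial <- cls
      trial[c(pos, j)] <- trial[c(j, pos)]
      mr <- max_run_length(trial)
      score <- 10 * max(0, mr - 3) + lag1_agreement(trial)
      if (score < best_score) { best_score <- score; best <- j }
    }
    cls[c(pos, best)] <- cls[c(best, pos)]
  }
  if (max_run_length(cls) > 3) {
    stop("could not construct a schedule with at most 3 consecutive ",
         "same-condition blocks for the requested composition")
  }

  # balanced emotion rotation over body blocks
  emotion <- rep(NA_character_, n_blocks)
  body_pos <- which(cls == "body")
  emotion[body_pos] <- rep(emotions, length.out = length(body_pos))

  condition <- ifelse(cls == "body", paste0("body_", emotion), cls)

  # clip pools: 15 actors x 3 emotions for bodies, 45 object clips
  if (is.null(body_clip_ids)) {
    body_clip_ids <- as.vector(outer(sprintf("actor%02d", 1:15), emotions,
                                     function(a, e) paste(a, e, sep = "_")))
  }
  if (is.null(object_clip_ids)) {
    object_clip_ids <- sprintf("object%02d", 1:45)
  }
  set.seed(seed)
  clip_ids <- rep(NA_character_, n_blocks)
  for (em in emotions) {
    pos <- which(cls == "body" & emotion == em)
    pool <- grep(paste0("_", em, "$"), body_clip_ids, value = TRUE)
    if (length(pool) == 0) pool <- body_clip_ids
    draws <- rep(sample(pool), length.out = 5L * length(pos))
    for (i in seq_along(pos)) {
      clip_ids[pos[i]] <- paste(draws[(5 * i - 4):(5 * i)], collapse = ",")
    }
  }
  obj_pos <- which(cls == "object")
  draws <- rep(sample(object_clip_ids), length.out = 5L * length(obj_pos))
  for (i in seq_along(obj_pos)) {
    clip_ids[obj_pos[i]] <- paste(draws[(5 * i - 4):(5 * i)], collapse = ",")
  }

  blocks <- data.frame(
    block_id = sprintf("block%02d", seq_len(n_blocks)),
    condition = condition,
    condition_class = cls,
    emotion = emotion,
    onset_s = (seq_len(n_blocks) - 1) * block_duration_s,
    duration_s = block_duration_s,
    clip_ids = clip_ids,
    stringsAsFactors = FALSE)

  structure(list(blocks = blocks, tr_s = tr_s,
                 total_duration_s = n_blocks * block_duration_s),
            class = "block_schedule")
}

#' @export
print.block_schedule <- function(x, ...) {
  tab <- table(x$blocks$condition_class)
  cat(sprintf("block_schedule: %d blocks (%s), %g s total, TR %g s\n",
              nrow(x$blocks),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              x$total_duration_s, x$tr_s))
  invisible(x)
}

#' Regressor correlations and contrast efficiency of a schedule
#'
#' Convolves the body and object boxcars with the canonical HRF, reports
#' their pairwise correlation, and the efficiency
#' `1 / (c' (X'X)^{-1} c)` of the body-minus-object contrast in the
#' design `[body, object, intercept]`.
#'
#' @param schedule a `block_schedule`.
#' @param n_volumes number of volumes (default covers the schedule).
#' @param tr_s repetition time (s).
#' @return list with `cor_body_object`, `efficiency`.
#' @export
design_efficiency <- function(schedule, n_volumes = NULL, tr_s = schedule$tr_s) {
  stopifnot(inherits(schedule, "block_schedule"))
  if (is.null(n_volumes)) n_volumes <- ceiling(schedule$total_duration_s / tr_s)
  b <- schedule$blocks
  body <- condition_regressor(b$onset_s[b$condition_class == "body"],
                              b$duration_s[b$condition_class == "body"],
                              n_volumes, tr_s)
  obj <- condition_regressor(b$onset_s[b$condition_class == "object"],
                             b$duration_s[b$condition_class == "object"],
                             n_volumes, tr_s)
  X <- cbind(body = body, object = obj, intercept = 1)
  if (qr(X)$rank < ncol(X)) {
    stop("design is rank deficient: body/object regressors are collinear ",
         "(schedule lacks one of the conditions?)")
  }
  if (stats::sd(body) == 0 || stats::sd(obj) == 0) {
    stop("design is rank deficient: a condition regressor is constant")
  }
  cc <- c(1, -1, 0)
  eff <- 1 / drop(t(cc) %*% solve(crossprod(X), cc))
  list(cor_body_object = stats::cor(body, obj), efficiency = eff)
}

#' Write / read BIDS-style events tables
#'
#' Events are written as a tab-separated table with columns `onset`,
#' `duration`, `trial_type`, `emotion`, `clip_ids` (comma-joined).
#' `read_events()` reconstructs a `block_schedule`.
#'
#' @param schedule a `block_schedule`.
#' @param path TSV path.
#' @return `write_events` returns `path` invisibly; `read_events` returns
#'   a `block_schedule`.
#' @export
write_events <- function(schedule, path) {
  stopifnot(inherits(schedule, "block_schedule"))
  b <- schedule$blocks
  df <- data.frame(onset = b$onset_s, duration = b$duration_s,
                   trial_type = b$condition,
                   emotion = ifelse(is.na(b$emotion), "n/a", b$emotion),
                   clip_ids = ifelse(is.na(b$clip_ids), "n/a", b$clip_ids),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param tr_s repetition time to attach to the reconstructed schedule.
#' @export
read_events <- function(path, tr_s = 2.6) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(df)))
  cls <- ifelse(grepl("^body", df$trial_type), "body", df$trial_type)
  emotion <- if ("emotion" %in% names(df)) {
    ifelse(df$emotion == "n/a", NA_character_, df$emotion)
  } else {
    ifelse(grepl("^body_", df$trial_type),
           sub("^body_", "", df$trial_type), NA_character_)
  }
  clips <- if ("clip_ids" %in% names(df)) {
    ifelse(df$clip_ids == "n/a", NA_character_, df$clip_ids)
  } else NA_character_
  blocks <- data.frame(
    block_id = sprintf("block%02d", seq_len(nrow(df))),
    condition = df$trial_type,
    condition_class = cls,
    emotion = emotion,
    onset_s = df$onset,
    duration_s = df$duration,
    clip_ids = clips,
    stringsAsFactors = FALSE)
  structure(list(blocks = blocks, tr_s = tr_s,
                 total_duration_s = max(df$onset + df$duration)),
            class = "block_schedule")
}
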
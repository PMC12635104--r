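# Synthetic scan videos and the shuffled-clip test protocol.
#
# A scan is stored as per-frame metadata (time, fetal/junk flag, render seed)
# plus the rendering parameters; pixels are materialised one frame at a time.
# This keeps 3-minute 5-fps scans at kilobytes instead of gigabytes and makes
# the 1 fps subsampling stage observable (scans are synthesised at a higher
# native rate and subsampled downstream).

#' Synthesise a full-length scan video
#'
#' All fetal frames share the scan's single true GA (scan duration is
#' negligible against gestation). Junk periods — the probe off the abdomen —
#' appear as persistent runs, driven by a two-state Markov chain whose
#' stationary junk probability is `junk_fraction`.
#'
#' @param subject_id identifier.
#' @param ga_days true GA of the scan, days.
#' @param duration_s scan length in seconds (default 180).
#' @param frame_rate native frames per second (default 5; downstream
#'   inference subsamples to 1 fps).
#' @param junk_fraction long-run fraction of junk time.
#' @param persistence per-second probability of staying in the current
#'   fetal/junk state.
#' @param growth_coefficient,growth_exponent,speckle_sigma rendering
#'   parameters, as in [phantom_spec()].
#' @param seed integer seed.
#' @return A `synthetic_scan`: frame metadata table plus render parameters.
#' @export
make_synthetic_scan <- function(subject_id, ga_days, duration_s = 180,
                                frame_rate = 5, junk_fraction = 0.2,
                                persistence = 0.9,
                                growth_coefficient = 2.0, growth_exponent = 0.6,
                                speckle_sigma = 0.15, seed = 1L) {
  stopifnot(duration_s > 0, frame_rate > 0)
  n_frames <- as.integer(round(duration_s * frame_rate))
  n_sec <- as.integer(ceiling(duration_s))
  frames <- withr::with_seed(as.integer(seed), {
    # two-state chain over seconds: TRUE = fetal
    p_stay <- persistence
    state <- logical(n_sec)
    state[1] <- stats::runif(1) >= junk_fraction
    if (n_sec > 1) {
      # switch probabilities chosen so the stationary junk prob is junk_fraction
      p_f2j <- (1 - p_stay) * junk_fraction
      p_j2f <- (1 - p_stay) * (1 - junk_fraction)
      for (s in 2:n_sec) {
        u <- stats::runif(1)
        state[s] <- if (state[s - 1]) u >= p_f2j else u < p_j2f
      }
    }
    t <- (seq_len(n_frames) - 1) / frame_rate
    data.frame(frame = seq_len(n_frames),
               time_s = t,
               is_fetal = state[pmin(floor(t) + 1, n_sec)],
               frame_seed = sample.int(.Machine$integer.max, n_frames))
  })
  structure(list(frames = frames, frame_rate = frame_rate,
                 duration_s = duration_s, subject_id = subject_id,
                 true_ga_days = ga_days,
                 growth_coefficient = growth_coefficient,
                 growth_exponent = growth_exponent,
                 speckle_sigma = speckle_sigma),
            class = "synthetic_scan")
}

#' Render one frame of a synthetic scan
#'
#' @param scan a `synthetic_scan`.
#' @param i frame index.
#' @return Canonical 384 x 576 matrix.
#' @export
scan_frame <- function(scan, i) {
  row <- scan$frames[i, ]
  spec <- phantom_spec(
    ga_days = if (row$is_fetal) scan$true_ga_days else NA_real_,
    growth_coefficient = scan$growth_coefficient,
    growth_exponent = scan$growth_exponent,
    speckle_sigma = scan$speckle_sigma,
    junk = !row$is_fetal, seed = row$frame_seed)
  generate_phantom_image(spec)$pixels
}

#' Splice a shuffled 3-minute clip from a full scan
#'
#' Implements the undirected-scanning test protocol: randomly select 36
#' non-overlapping 5-second subsegments of the scan, shuffle their order and
#' concatenate them into a clip of exactly 3 minutes. Re-invoking with a new
#' seed re-selects and re-shuffles, which is how shuffle-consistency pairs
#' are produced.
#'
#' @param scan a `synthetic_scan` of duration at least 180 s.
#' @param seed integer seed for selection and shuffling.
#' @param n_segments,segment_s protocol constants (36 and 5 by default).
#' @return A `synthetic_scan` of duration `n_segments * segment_s`; its frame
#'   table keeps `source_frame` and `segment` columns for provenance.
#' @export
splice_shuffled_clip <- function(scan, seed, n_segments = 36L, segment_s = 5L) {
  stopifnot(inherits(scan, "synthetic_scan"))
  need_s <- n_segments * segment_s
  if (scan$duration_s < need_s) {
    stop(sprintf("source scan must be at least %d s long", need_s), call. = FALSE)
  }
  fr <- scan$frame_rate
  seg_len <- as.integer(round(segment_s * fr))
  n <- nrow(scan$frames)
  slack <- n - n_segments * seg_len
  sel <- withr::with_seed(as.integer(seed), {
    # distribute slack frames uniformly over the 37 gaps, then shuffle order
    gaps <- if (slack > 0) {
      tabulate(sample.int(n_segments + 1L, slack, replace = TRUE),
               nbins = n_segments + 1L)
    } else rep(0L, n_segments + 1L)
    starts <- cumsum(gaps[seq_len(n_segments)]) +
      (seq_len(n_segments) - 1L) * seg_len + 1L
    list(starts = starts, order = sample.int(n_segments))
  })
  pieces <- lapply(seq_len(n_segments), function(k) {
    s <- sel$starts[sel$order[k]]
    piece <- scan$frames[s:(s + seg_len - 1L), , drop = FALSE]
    piece$source_frame <- piece$frame
    piece$segment <- k
    piece
  })
  frames <- do.call(rbind, pieces)
  frames$frame <- seq_len(nrow(frames))
  frames$time_s <- (frames$frame - 1) / fr
  rownames(frames) <- NULL
  out <- scan
  out$frames <- frames
  out$duration_s <- need_s
  out
}

#' Write a scan as a directory of numbered PNG frames
#'
#' The on-disk video dialect: greyscale PNGs `f000001.png, ...` plus a
#' `frames.csv` with timestamps and flags.
#'
#' @param scan a `synthetic_scan`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_scan <- function(scan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(scan$frames))) {
    png::writePNG(scan_frame(scan, i),
                  file.path(dir, sprintf("f%06d.png", i)))
  }
  meta <- scan$frames
  meta$path <- sprintf("f%06d.png", meta$frame)
  utils::write.csv(meta, file.path(dir, "frames.csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(list(frame_rate = scan$frame_rate,
                                   duration_s = scan$duration_s),
                              auto_unbox = TRUE),
             file.path(dir, "video.json"))
  invisible(dir)
}

#' Open a video as a uniform lazy frame source
#'
#' Accepts a `synthetic_scan`, a directory of numbered PNG frames (optionally
#' with the `video.json` written by [write_scan()]), or an in-memory list of
#' canonical frames.
#'
#' @param x video source.
#' @param frame_rate native frame rate; required for frame lists and for
#'   directories lacking `video.json`.
#' @return A `video` object: `n_frames`, `frame_rate`, `duration_s` and a
#'   `get(i)` accessor returning a canonical frame.
#' @export
as_video <- function(x, frame_rate = NULL) {
  if (inherits(x, "video")) return(x)
  if (inherits(x, "synthetic_scan")) {
    v <- list(n_frames = nrow(x$frames), frame_rate = x$frame_rate,
              duration_s = x$duration_s,
              get = function(i) scan_frame(x, i))
  } else if (is.character(x) && length(x) == 1 && dir.exists(x)) {
    paths <- sort(list.files(x, pattern = "\\.png$", full.names = TRUE))
    if (length(paths) == 0) stop("no PNG frames found in ", x, call. = FALSE)
    meta <- file.path(x, "video.json")
    if (is.null(frame_rate)) {
      if (!file.exists(meta)) stop("frame_rate required when video.json is absent",
                                   call. = FALSE)
      frame_rate <- jsonlite::fromJSON(meta)$frame_rate
    }
    v <- list(n_frames = length(paths), frame_rate = frame_rate,
              duration_s = length(paths) / frame_rate,
              get = function(i) preprocess_image(png::readPNG(paths[i])))
  } else if (is.list(x)) {
    if (is.null(frame_rate)) stop("frame_rate required for frame lists", call. = FALSE)
    v <- list(n_frames = length(x), frame_rate = frame_rate,
              duration_s = length(x) / frame_rate,
              get = function(i) x[[i]])
  } else {
    stop("cannot interpret 'x' as a video", call. = FALSE)
  }
  structure(v, class = "video")
}

#' Subsample a video at a fixed rate
#'
#' Inference does not consume every frame: successive video frames are highly
#' correlated, which breaks the Kalman filter's independent-noise assumption,
#' so frames are drawn at `rate` per second (default 1).
#'
#' @param video anything accepted by [as_video()].
#' @param rate sampling rate, frames per second.
#' @param frame_rate native rate, when `video` needs it (see [as_video()]).
#' @return A `frame_stream`: data-frame-like list with `time_s` and
#'   `frame_idx` for `floor(duration * rate)` samples, plus a `get(k)`
#'   accessor for the k-th sampled frame.
#' @export
sample_frames <- function(video, rate = 1, frame_rate = NULL) {
  stopifnot(rate > 0)
  v <- as_video(video, frame_rate = frame_rate)
  n_out <- floor(v$duration_s * rate)
  times <- (seq_len(n_out) - 1) / rate
  idx <- pmin(floor(times * v$frame_rate) + 1, v$n_frames)
  structure(list(time_s = times, frame_idx = as.integer(idx),
                 n = as.integer(n_out),
                 get = function(k) v$get(idx[k])),
            class = "frame_stream")
}
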
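# Preprocessing, manifests, stratified sampling and subject-level splits.

#' Preprocess an image to the canonical frame contract
#'
#' Converts any greyscale or colour intensity grid (or a PNG path) to the
#' canonical 384 x 576 single-channel frame in \[0, 1\]: colour is collapsed
#' by Rec. 601 luminance, 8-bit ranges are rescaled, and the image is
#' resized with bilinear resampling (stretched, not letterboxed). Inputs that
#' are already canonical pass through unchanged, which makes the operation
#' idempotent.
#'
#' @param raw numeric matrix (rows x cols), rows x cols x channels array, or
#'   a path to a PNG file.
#' @return Canonical 384 x 576 matrix.
#' @export
preprocess_image <- function(raw) {
  if (is.character(raw)) {
    if (!file.exists(raw)) stop("cannot read image: ", raw, call. = FALSE)
    raw <- png::readPNG(raw)
  }
  if (length(dim(raw)) == 3) {
    nch <- dim(raw)[3]
    raw <- if (nch >= 3) {
      0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3]
    } else raw[, , 1]
  }
  if (!is.matrix(raw) || length(raw) == 0) {
    stop("image must be a non-empty matrix or array", call. = FALSE)
  }
  if (max(raw) > 1) raw <- raw / 255
  raw <- clip01(raw)
  if (nrow(raw) != CANONICAL_ROWS || ncol(raw) != CANONICAL_COLS) {
    raw <- from_ebi(EBImage::resize(as_ebi(raw), w = CANONICAL_COLS,
                                    h = CANONICAL_ROWS, filter = "bilinear"))
    raw <- clip01(raw)
  }
  raw
}

#' Read / write a cohort manifest CSV
#'
#' The manifest dialect has columns
#' `subject_id,path,ga_days,is_fetal,probe_type,source` plus optional
#' `frame_seed` and `split` columns.
#'
#' @param path CSV path.
#' @param manifest data.frame to write.
#' @return `read_manifest` returns the data.frame; `write_manifest` returns
#'   `path` invisibly.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "path", "ga_days", "is_fetal", "probe_type", "source")
  missing <- setdiff(needed, names(m))
  if (length(missing)) {
    stop("manifest is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Assign 4-week gestational-age bands
#'
#' Bands are contiguous half-open 28-day intervals anchored at week 8
#' (`[56, 84), [84, 112), ...`), labelled by their week bounds, e.g.
#' `"8-12"`.
#'
#' @param ga_days numeric vector of GA in days.
#' @param anchor_week left edge of the first band, in weeks.
#' @param width_weeks band width in weeks.
#' @return Character vector of band labels.
#' @export
ga_band <- function(ga_days, anchor_week = 8, width_weeks = 4) {
  lo_wk <- anchor_week + width_weeks * floor((ga_days / 7 - anchor_week) / width_weeks)
  sprintf("%d-%d", as.integer(lo_wk), as.integer(lo_wk + width_weeks))
}

#' Stratified sampling of a manifest
#'
#' Draws up to `per_stratum_target` frames from every
#' (source x GA band x probe type) cell, sampling rows uniformly so that the
#' number of frames contributed per subject varies; under-full cells return
#' all their members and nothing is excluded outright.
#'
#' @param manifest a manifest data.frame.
#' @param per_stratum_target maximum rows kept per stratum.
#' @param seed integer seed.
#' @param anchor_week,width_weeks band definition passed to [ga_band()].
#' @return The sampled manifest, with a `stratum` column attached.
#' @export
stratified_sample <- function(manifest, per_stratum_target, seed = 1L,
                              anchor_week = 8, width_weeks = 4) {
  stopifnot(nrow(manifest) > 0, per_stratum_target >= 1)
  manifest$stratum <- paste(manifest$source,
                            ga_band(manifest$ga_days, anchor_week, width_weeks),
                            manifest$probe_type, sep = "|")
  out <- withr::with_seed(as.integer(seed), {
    keep <- unlist(lapply(split(seq_len(nrow(manifest)), manifest$stratum),
                          function(ix) {
      if (length(ix) <= per_stratum_target) ix
      else sample(ix, per_stratum_target)
    }), use.names = FALSE)
    sort(keep)
  })
  res <- manifest[out, , drop = FALSE]
  rownames(res) <- NULL
  for (a in c("growth_coefficient", "growth_exponent", "speckle_sigma")) {
    attr(res, a) <- attr(manifest, a)
  }
  res
}

#' Split a manifest into training and validation sets by subject
#'
#' The unit of randomisation is the subject: all frames of one subject land
#' in the same split. `floor(n_subjects * train_fraction)` subjects go to
#' training, the rest to validation.
#'
#' @param manifest a manifest data.frame.
#' @param train_fraction fraction of subjects assigned to training
#'   (default 0.9).
#' @param seed integer seed.
#' @return The manifest with a `split` column (`"train"` / `"val"`).
#' @export
split_by_subject <- function(manifest, train_fraction = 0.9, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  subjects <- unique(manifest$subject_id)
  if (length(subjects) < 2) {
    stop("need at least 2 subjects to split", call. = FALSE)
  }
  n_train <- floor(length(subjects) * train_fraction)
  train_subj <- withr::with_seed(as.integer(seed),
                                 sample(subjects, n_train))
  manifest$split <- ifelse(manifest$subject_id %in% train_subj, "train", "val")
  manifest
}
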
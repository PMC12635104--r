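# Synthetic ultrasound phantoms.
#
# Real fetal ultrasound cannot be redistributed, so every downstream stage is
# exercised on phantoms: a bright ellipse whose equivalent diameter follows a
# monotone growth law in gestational age, rendered over a low-frequency
# background with multiplicative speckle. "Junk" frames (probe off the
# abdomen, no fetus) are structured noise with no ellipse.

GA_MIN_DAYS <- 63
GA_MAX_DAYS <- 252

#' Specification of a single phantom frame
#'
#' @param ga_days true gestational age in days; must lie in \[63, 252\]
#'   (9–36 weeks, the method's operating range). Ignored (may be `NA`) when
#'   `junk = TRUE`.
#' @param growth_coefficient,growth_exponent parameters of the growth law
#'   `D(ga) = growth_coefficient * ga_days^growth_exponent` giving the
#'   equivalent diameter (pixels) of the rendered fetal structure. The default
#'   `2.0 * ga^0.6` spans roughly 25–55 px over 9–36 weeks.
#' @param speckle_sigma standard deviation (log scale) of the multiplicative
#'   log-normal speckle; `0` disables speckle.
#' @param junk if `TRUE` the frame contains no fetal structure.
#' @param seed integer seed; renders are bit-reproducible given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(ga_days, growth_coefficient = 2.0,
                         growth_exponent = 0.6, speckle_sigma = 0.15,
                         junk = FALSE, seed = 1L) {
  if (!junk) {
    if (!is.numeric(ga_days) || length(ga_days) != 1 || !is.finite(ga_days) ||
        ga_days < GA_MIN_DAYS || ga_days > GA_MAX_DAYS) {
      stop(sprintf("ga_days must lie in [%d, %d] days", GA_MIN_DAYS, GA_MAX_DAYS),
           call. = FALSE)
    }
  }
  stopifnot(growth_coefficient > 0, growth_exponent > 0, speckle_sigma >= 0)
  structure(list(ga_days = if (junk) NA_real_ else as.numeric(ga_days),
                 growth_coefficient = growth_coefficient,
                 growth_exponent = growth_exponent,
                 speckle_sigma = speckle_sigma,
                 junk = isTRUE(junk),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Growth law mapping gestational age to structure size
#'
#' @param ga_days gestational age in days.
#' @param coefficient,exponent growth-law parameters (see [phantom_spec()]).
#' @return Equivalent diameter in pixels; strictly increasing in `ga_days`.
#' @export
growth_law <- function(ga_days, coefficient = 2.0, exponent = 0.6) {
  coefficient * ga_days^exponent
}

# Smooth random background: coarse uniform field upsampled bilinearly.
structured_field <- function(rows, cols, coarse = c(12L, 18L), amplitude) {
  low <- matrix(stats::runif(prod(coarse), -1, 1), coarse[1], coarse[2])
  0.5 * amplitude * (upsample_bilinear(low, rows, cols) + 1)
}

render_ellipse_mask <- function(rows, cols, diameter) {
  rho <- stats::runif(1, 0.75, 1.30)       # aspect ratio; D_eq preserved
  a <- diameter / 2 * sqrt(rho)
  b <- diameter / 2 / sqrt(rho)
  theta <- stats::runif(1, 0, pi)
  margin <- max(a, b) + 4
  cy <- stats::runif(1, margin, rows - margin)
  cx <- stats::runif(1, margin, cols - margin)
  yy <- matrix(seq_len(rows) - cy, rows, cols)
  xx <- matrix(seq_len(cols) - cx, rows, cols, byrow = TRUE)
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  (u / a)^2 + (v / b)^2 <= 1
}

#' Render one phantom frame
#'
#' Fetal frames contain a bright ellipse of equivalent diameter
#' `growth_coefficient * ga_days^growth_exponent` pixels at a random position
#' and orientation over a dim structured background; junk frames contain
#' structured noise only. Multiplicative log-normal speckle (mean one) is
#' applied last. Rendering is deterministic given the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_image`: list with `pixels` (canonical 384 x 576 matrix),
#'   `ga_days` (`NA` for junk frames) and `is_fetal`.
#' @export
generate_phantom_image <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  rows <- CANONICAL_ROWS; cols <- CANONICAL_COLS
  px <- withr::with_seed(spec$seed, {
    if (spec$junk) {
      # No fetus: brighter, blotchier low-frequency noise plus faint streaks.
      img <- 0.06 + structured_field(rows, cols, amplitude = 0.30)
      streak <- structured_field(rows, cols, coarse = c(3L, 24L), amplitude = 0.12)
      img <- img + streak
    } else {
      img <- matrix(0.10, rows, cols) +
        structured_field(rows, cols, amplitude = 0.04)
      d <- growth_law(spec$ga_days, spec$growth_coefficient, spec$growth_exponent)
      mask <- render_ellipse_mask(rows, cols, d)
      img[mask] <- 0.85
    }
    if (spec$speckle_sigma > 0) {
      s <- spec$speckle_sigma
      speckle <- exp(matrix(stats::rnorm(rows * cols, -s^2 / 2, s), rows, cols))
      img <- img * speckle
    }
    clip01(img)
  })
  structure(list(pixels = px, ga_days = spec$ga_days,
                 is_fetal = !spec$junk), class = "phantom_image")
}

#' Generate a labelled phantom cohort manifest
#'
#' Emulates a routine-scanning archive: each subject has one scan GA, a
#' varying number of stored frames, a probe route and a site label. Every
#' manifest row carries the subject's scan GA; `is_fetal = FALSE` rows are
#' junk frames stored during that scan. Frames are not materialised — each
#' row records a render seed, and [cohort_image()] reproduces the pixels on
#' demand.
#'
#' @param n_subjects number of subjects (scans).
#' @param ga_range length-2 numeric, GA range in days covered by the cohort.
#' @param junk_fraction probability that a stored frame is junk.
#' @param images_per_subject length-2 integer range of frames per subject.
#' @param sources,probe_types label pools sampled per subject.
#' @param speckle_sigma,growth_coefficient,growth_exponent passed to the
#'   per-frame [phantom_spec()].
#' @param seed integer seed controlling the whole cohort.
#' @return A `data.frame` manifest with columns `subject_id, path, ga_days,
#'   is_fetal, probe_type, source, frame_seed` (and attributes recording the
#'   growth-law parameters). `path` is empty until [write_cohort()] is used.
#' @export
generate_cohort <- function(n_subjects, ga_range = c(GA_MIN_DAYS, GA_MAX_DAYS),
                            junk_fraction = 0, images_per_subject = c(3L, 10L),
                            sources = c("siteA", "siteB"),
                            probe_types = c("TA", "TV"),
                            speckle_sigma = 0.15,
                            growth_coefficient = 2.0, growth_exponent = 0.6,
                            seed = 1L) {
  stopifnot(n_subjects >= 1, junk_fraction >= 0, junk_fraction < 1)
  if (length(ga_range) != 2 || diff(ga_range) < 0 ||
      ga_range[1] < GA_MIN_DAYS || ga_range[2] > GA_MAX_DAYS) {
    stop("ga_range must be a non-empty interval within [63, 252] days", call. = FALSE)
  }
  manifest <- withr::with_seed(as.integer(seed), {
    ga <- stats::runif(n_subjects, ga_range[1], ga_range[2])
    n_img <- sample(seq(images_per_subject[1], images_per_subject[2]),
                    n_subjects, replace = TRUE)
    src <- sample(sources, n_subjects, replace = TRUE)
    probe <- sample(probe_types, n_subjects, replace = TRUE)
    rows <- lapply(seq_len(n_subjects), function(i) {
      k <- n_img[i]
      data.frame(subject_id = sprintf("S%04d", i),
                 path = "",
                 ga_days = ga[i],
                 is_fetal = stats::runif(k) >= junk_fraction,
                 probe_type = probe[i],
                 source = src[i],
                 frame_seed = sample.int(.Machine$integer.max, k),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  rownames(manifest) <- NULL
  attr(manifest, "growth_coefficient") <- growth_coefficient
  attr(manifest, "growth_exponent") <- growth_exponent
  attr(manifest, "speckle_sigma") <- speckle_sigma
  manifest
}

#' Render the frame behind one cohort manifest row
#'
#' @param manifest a manifest from [generate_cohort()].
#' @param i row index.
#' @return A `phantom_image` (see [generate_phantom_image()]).
#' @export
cohort_image <- function(manifest, i) {
  row <- manifest[i, ]
  spec <- phantom_spec(
    ga_days = if (row$is_fetal) row$ga_days else NA_real_,
    growth_coefficient = attr(manifest, "growth_coefficient") %||% 2.0,
    growth_exponent = attr(manifest, "growth_exponent") %||% 0.6,
    speckle_sigma = attr(manifest, "speckle_sigma") %||% 0.15,
    junk = !row$is_fetal,
    seed = row$frame_seed)
  generate_phantom_image(spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Materialise a cohort to PNG files plus a CSV manifest
#'
#' @param manifest a manifest from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return The manifest with `path` filled in; also written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
write_cohort <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("%s_f%05d.png", manifest$subject_id, seq_len(nrow(manifest)))
  for (i in seq_len(nrow(manifest))) {
    img <- cohort_image(manifest, i)
    png::writePNG(img$pixels, file.path(dir, paths[i]))
  }
  manifest$path <- file.path(dir, paths)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}
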
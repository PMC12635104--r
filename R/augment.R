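# RandAugment-style training augmentation with an ultrasound-appropriate
# transform list. Per image, N is drawn uniformly from a range, N distinct
# transforms are sampled and each is applied with a random magnitude from its
# own range. All transforms preserve the canonical frame contract and the GA
# label; geometric transforms fill exposed borders with black, matching the
# ultrasound background.

AUGMENT_TRANSFORMS <- c("rotation", "rescale", "hflip", "blur",
                        "brightness_contrast", "mult_noise", "grid_distortion")

#' Define an augmentation policy
#'
#' @param transforms subset of `r paste(AUGMENT_TRANSFORMS, collapse = ", ")`.
#' @param n_range integer interval from which the number of applied
#'   transforms is drawn per image.
#' @param magnitudes named list of per-transform magnitude ranges; defaults:
#'   rotation within ±20 degrees, re-scaling ×\[0.9, 1.1\], blur sigma in
#'   \[0, 1.5\] px, brightness/contrast within ±15%, multiplicative noise
#'   sigma 0.05, grid distortion up to 5% displacement. Kept deliberately
#'   mild: re-scaling perturbs the very size cue that predicts GA.
#' @return An `augment_policy` object.
#' @export
augment_policy <- function(transforms = AUGMENT_TRANSFORMS,
                           n_range = c(1L, 3L),
                           magnitudes = list()) {
  transforms <- match.arg(transforms, AUGMENT_TRANSFORMS, several.ok = TRUE)
  stopifnot(length(n_range) == 2, n_range[1] >= 0,
            n_range[2] <= length(transforms), n_range[1] <= n_range[2])
  defaults <- list(rotation = c(-20, 20), rescale = c(0.9, 1.1),
                   hflip = c(0, 0), blur = c(0, 1.5),
                   brightness_contrast = c(-0.15, 0.15),
                   mult_noise = c(0.05, 0.05), grid_distortion = c(0, 0.05))
  mags <- utils::modifyList(defaults, magnitudes)
  structure(list(transforms = transforms, n_range = as.integer(n_range),
                 magnitudes = mags), class = "augment_policy")
}

aug_rotation <- function(img, degrees) {
  if (abs(degrees) < 1e-12) return(img)
  out <- EBImage::rotate(as_ebi(img), degrees, filter = "bilinear",
                         output.dim = c(ncol(img), nrow(img)), bg.col = 0)
  clip01(from_ebi(out))
}

aug_rescale <- function(img, factor) {
  if (abs(factor - 1) < 1e-12) return(img)
  r <- nrow(img); c <- ncol(img)
  nr <- max(1L, round(r * factor)); nc <- max(1L, round(c * factor))
  scaled <- from_ebi(EBImage::resize(as_ebi(img), w = nc, h = nr,
                                     filter = "bilinear"))
  out <- matrix(0, r, c)
  if (factor >= 1) {            # centre crop
    r0 <- (nr - r) %/% 2; c0 <- (nc - c) %/% 2
    out <- scaled[(r0 + 1):(r0 + r), (c0 + 1):(c0 + c)]
  } else {                      # centre pad with black
    r0 <- (r - nr) %/% 2; c0 <- (c - nc) %/% 2
    out[(r0 + 1):(r0 + nr), (c0 + 1):(c0 + nc)] <- scaled
  }
  clip01(out)
}

aug_hflip <- function(img, ...) img[, rev(seq_len(ncol(img)))]

aug_blur <- function(img, sigma) {
  if (sigma < 0.05) return(img)
  clip01(from_ebi(EBImage::gblur(as_ebi(img), sigma = sigma)))
}

aug_brightness_contrast <- function(img, jitter) {
  # one magnitude drives both: brightness shift and contrast gain
  clip01((img - 0.5) * (1 + jitter) + 0.5 + jitter * 0.5)
}

aug_mult_noise <- function(img, sigma) {
  if (sigma <= 0) return(img)
  noise <- exp(matrix(stats::rnorm(length(img), -sigma^2 / 2, sigma),
                      nrow(img), ncol(img)))
  clip01(img * noise)
}

aug_grid_distortion <- function(img, strength) {
  if (strength <= 0) return(img)
  r <- nrow(img); c <- ncol(img)
  grid <- c(5L, 7L)   # coarse displacement lattice
  dy <- upsample_bilinear(matrix(stats::runif(prod(grid), -1, 1), grid[1], grid[2]),
                          r, c) * strength * r
  dx <- upsample_bilinear(matrix(stats::runif(prod(grid), -1, 1), grid[1], grid[2]),
                          r, c) * strength * c
  yy <- matrix(seq_len(r), r, c) + dy
  xx <- matrix(seq_len(c), r, c, byrow = TRUE) + dx
  bilinear_sample(img, yy, xx)
}

# Vectorised bilinear lookup with black outside the support.
bilinear_sample <- function(img, yy, xx) {
  r <- nrow(img); c <- ncol(img)
  y0 <- floor(yy); x0 <- floor(xx)
  fy <- yy - y0; fx <- xx - x0
  gv <- function(yi, xi) {
    ok <- yi >= 1 & yi <= r & xi >= 1 & xi <= c
    out <- numeric(length(yi))
    out[ok] <- img[cbind(yi[ok], xi[ok])]
    out
  }
  v <- (1 - fy) * (1 - fx) * gv(y0, x0) +
       (1 - fy) * fx       * gv(y0, x0 + 1) +
       fy       * (1 - fx) * gv(y0 + 1, x0) +
       fy       * fx       * gv(y0 + 1, x0 + 1)
  matrix(v, r, c)
}

#' Apply a RandAugment-style policy to one frame
#'
#' Draws N uniformly from the policy's `n_range`, samples N distinct
#' transforms and applies each with a magnitude drawn from its range.
#' Deterministic given `seed`; the output satisfies the canonical contract.
#'
#' @param image canonical frame.
#' @param policy an [augment_policy()].
#' @param seed integer seed.
#' @return Augmented canonical frame.
#' @export
apply_augment <- function(image, policy = augment_policy(), seed = 1L) {
  assert_canonical(image)
  stopifnot(inherits(policy, "augment_policy"))
  withr::with_seed(as.integer(seed), {
    n <- if (policy$n_range[1] == policy$n_range[2]) policy$n_range[1] else
      sample(seq(policy$n_range[1], policy$n_range[2]), 1)
    if (n == 0) return(image)
    chosen <- sample(policy$transforms, n)
    for (tr in chosen) {
      rng <- policy$magnitudes[[tr]]
      mag <- stats::runif(1, rng[1], rng[2])
      image <- switch(tr,
        rotation = aug_rotation(image, mag),
        rescale = aug_rescale(image, mag),
        hflip = aug_hflip(image),
        blur = aug_blur(image, mag),
        brightness_contrast = aug_brightness_contrast(image, mag),
        mult_noise = aug_mult_noise(image, mag),
        grid_distortion = aug_grid_distortion(image, mag))
    }
    image
  })
}
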
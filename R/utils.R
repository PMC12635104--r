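#' @keywords internal
"_PACKAGE"

# Canonical frame geometry used throughout: 384 rows x 576 columns, [0, 1].
CANONICAL_ROWS <- 384L
CANONICAL_COLS <- 576L

#' Test whether an object is a canonical frame
#'
#' A canonical frame is a 384 x 576 numeric matrix (rows x columns) of
#' intensities in \[0, 1\] — the common currency of the whole pipeline.
#'
#' @param x object to test.
#' @return `TRUE` or `FALSE`.
#' @export
is_canonical_frame <- function(x) {
  is.matrix(x) && is.numeric(x) &&
    nrow(x) == CANONICAL_ROWS && ncol(x) == CANONICAL_COLS &&
    all(is.finite(x)) && min(x) >= 0 && max(x) <= 1
}

assert_canonical <- function(x, what = "image") {
  if (!is_canonical_frame(x)) {
    stop(sprintf("%s must be a %dx%d numeric matrix with values in [0,1]",
                 what, CANONICAL_ROWS, CANONICAL_COLS), call. = FALSE)
  }
  invisible(x)
}

# Bridge between row-major R matrices (rows = image height) and EBImage,
# whose first dimension is x (width).
as_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(img) t(EBImage::imageData(img))

clip01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

# Bilinear upsampling of a coarse field to a target size; used for the
# structured (low-frequency) component of phantom backgrounds.
upsample_bilinear <- function(m, rows, cols) {
  out <- EBImage::resize(as_ebi(m), w = cols, h = rows, filter = "bilinear")
  from_ebi(out)
}

# Average-pool a matrix by an integer factor through two banded projection
# matrices; exact block means, no loops over pixels.
block_pool <- function(m, factor) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(nr %% factor == 0, nc %% factor == 0)
  pr <- nr %/% factor; pc <- nc %/% factor
  Pr <- matrix(0, pr, nr)
  Pr[cbind(rep(seq_len(pr), each = factor), seq_len(nr))] <- 1 / factor
  Pc <- matrix(0, nc, pc)
  Pc[cbind(seq_len(nc), rep(seq_len(pc), each = factor))] <- 1 / factor
  Pr %*% m %*% Pc
}

# Derive a stream of sub-seeds from one integer seed without disturbing the
# caller's RNG; keeps every derived seed inside 32-bit integer range.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}
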
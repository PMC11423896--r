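#' Gabor filter-bank features
#'
#' Oriented band-pass energy features in the gist style: each image is
#' filtered with a bank of quadrature Gabor filters (implemented as
#' one-sided Gaussian bumps in the frequency domain, whose inverse-FFT
#' modulus is the quadrature-pair energy envelope), and the rectified
#' energy map is mean-pooled over a `grid x grid` partition. Scale s uses
#' `orientations[s]` evenly spaced orientations; wavelengths descend in
#' octave steps. The published configuration (grid 16, orientations
#' 12/8/6/4) yields `16^2 * 30 = 7680` features per image.
#'
#' @param images a list of numeric matrices or an `n x H x W` array of
#'   grayscale images (`H, W >= grid`).
#' @param grid pooling grid size per side.
#' @param orientations number of orientations per scale (vector; one entry
#'   per scale).
#' @param wavelengths filter wavelengths in pixels, one per scale; default
#'   octave steps `2^(s+1)` (4, 8, 16, 32 for four scales).
#' @param bandwidth frequency-domain SD as a fraction of the center
#'   frequency.
#' @return `n x (grid^2 * sum(orientations))` feature matrix.
#' @export
gabor_features <- function(images, grid = 16L, orientations = c(12L, 8L, 6L, 4L),
                           wavelengths = NULL, bandwidth = 0.5) {
  if (is.array(images) && length(dim(images)) == 3)
    images <- lapply(seq_len(dim(images)[1]), function(i) images[i, , ])
  if (!is.list(images)) stop("images must be a list of matrices or a 3D array")
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  if (H < grid || W < grid) stop("image smaller than the pooling grid")
  n_scales <- length(orientations)
  if (is.null(wavelengths)) wavelengths <- 2^(seq_len(n_scales) + 1)
  if (length(wavelengths) != n_scales) stop("one wavelength per scale required")

  fx <- (seq_len(W) - 1) / W; fx[fx >= 0.5] <- fx[fx >= 0.5] - 1
  fy <- (seq_len(H) - 1) / H; fy[fy >= 0.5] <- fy[fy >= 0.5] - 1
  FX <- matrix(fx, H, W, byrow = TRUE)
  FY <- matrix(fy, H, W)

  filters <- list()
  for (s in seq_len(n_scales)) {
    f0 <- 1 / wavelengths[s]
    sig <- bandwidth * f0
    for (o in seq_len(orientations[s])) {
      th <- (o - 1) * pi / orientations[s]
      u <- f0 * cos(th); v <- f0 * sin(th)
      filters[[length(filters) + 1L]] <-
        exp(-((FX - u)^2 + (FY - v)^2) / (2 * sig^2))
    }
  }

  rx <- cut(seq_len(H), grid, labels = FALSE)
  cx <- cut(seq_len(W), grid, labels = FALSE)
  pool <- function(E) {
    as.numeric(t(vapply(seq_len(grid), function(i)
      vapply(seq_len(grid), function(j) mean(E[rx == i, cx == j]), numeric(1)),
      numeric(grid))))
  }

  out <- matrix(NA_real_, length(images), grid^2 * length(filters))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (nrow(img) != H || ncol(img) != W) stop("all images must share dimensions")
    Fi <- stats::fft(img)
    feats <- lapply(filters, function(Hf) pool(Mod(stats::fft(Fi * Hf, inverse = TRUE)) / (H * W)))
    out[i, ] <- unlist(feats)
  }
  out
}

#' Gist-PC features: leading principal components of the Gabor matrix
#'
#' @param gabor `n x d` Gabor feature matrix (n must exceed `n_pc`).
#' @param n_pc number of components (reference 50).
#' @return `n x n_pc` matrix of centered PC scores, ordered by variance.
#' @export
gistpc_features <- function(gabor, n_pc = 50L) {
  if (nrow(gabor) <= n_pc) stop("need more images than components")
  pc <- stats::prcomp(gabor, center = TRUE, scale. = FALSE, rank. = n_pc)
  pc$x[, seq_len(n_pc), drop = FALSE]
}
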
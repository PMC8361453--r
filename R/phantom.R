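#' Specify a synthetic brain phantom
#'
#' A phantom is a piecewise-constant tissue map: every pixel of tissue class
#' \code{k} has intensity \code{class_means[k]}. The default emulates a
#' three-tissue axial brain slice (CSF / gray matter / white matter at
#' intensities 0.2 / 0.5 / 0.8) on a 160 x 160 grid.
#'
#' @param height,width grid size in pixels (>= 16).
#' @param class_means strictly increasing tissue intensities in [0, 1],
#'   at least two classes.
#' @param class_geometry \code{"concentric_ellipses"} (nested elliptical
#'   shells, brain-like) or \code{"voronoi_blobs"} (random cellular regions).
#' @param seed integer seed; identical specs reproduce bit-identical phantoms.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(height = 160L, width = 160L,
                         class_means = c(0.2, 0.5, 0.8),
                         class_geometry = c("concentric_ellipses", "voronoi_blobs"),
                         seed = 1L) {
  class_geometry <- match.arg(class_geometry)
  if (!is.numeric(height) || !is.numeric(width) || height < 16 || width < 16)
    stop_config("phantom height and width must be >= 16 pixels")
  if (length(class_means) < 2L)
    stop_config("at least 2 tissue classes are required")
  if (any(diff(class_means) <= 0))
    stop_config("class_means must be strictly increasing")
  if (any(class_means < 0 | class_means > 1))
    stop_config("class_means must lie in [0, 1]")
  assert_scalar_num(seed, "seed")
  structure(list(height = as.integer(height), width = as.integer(width),
                 class_means = as.numeric(class_means),
                 class_geometry = class_geometry, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Specify a noise model
#'
#' @param kind \code{"gaussian"} (additive, clipped to [0, 1]) or
#'   \code{"salt_pepper"} (a seeded fraction of pixels replaced by 0 or 1
#'   with equal probability).
#' @param level for Gaussian noise the standard deviation in intensity
#'   units (> 0); for salt-and-pepper the corruption density in (0, 1),
#'   i.e. the expected fraction of replaced pixels.
#' @param seed integer seed for the corruption draw.
#' @return An object of class \code{noise_spec}.
#' @export
noise_spec <- function(kind = c("gaussian", "salt_pepper"), level, seed = 1L) {
  kind <- match.arg(kind)
  assert_scalar_num(level, "level")
  if (kind == "gaussian" && level <= 0)
    stop_config("gaussian noise level must be > 0")
  if (kind == "salt_pepper" && (level <= 0 || level >= 1))
    stop_config("salt_pepper density must lie in (0, 1)")
  assert_scalar_num(seed, "seed")
  structure(list(kind = kind, level = as.numeric(level), seed = as.integer(seed)),
            class = "noise_spec")
}

#' Specify a multiplicative bias field
#'
#' Emulates the smooth intensity inhomogeneity ("offset field") of MR
#' acquisition: the image is multiplied by a smooth positive field with
#' spatial mean exactly 1.
#'
#' @param amplitude fractional modulation depth in [0, 1); the field stays
#'   within \code{1 +/- amplitude}.
#' @param smoothness correlation length of the field in pixels.
#' @param seed integer seed.
#' @return An object of class \code{bias_field_spec}.
#' @export
bias_field_spec <- function(amplitude = 0.2, smoothness = 40, seed = 1L) {
  assert_scalar_num(amplitude, "amplitude")
  if (amplitude < 0 || amplitude >= 1)
    stop_config("bias amplitude must lie in [0, 1)")
  assert_scalar_num(smoothness, "smoothness")
  if (smoothness <= 0) stop_config("smoothness must be > 0 pixels")
  assert_scalar_num(seed, "seed")
  structure(list(amplitude = as.numeric(amplitude),
                 smoothness = as.numeric(smoothness), seed = as.integer(seed)),
            class = "bias_field_spec")
}

#' Generate a phantom image and its ground-truth label map
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return A list with \code{image} (numeric matrix in [0, 1]) and
#'   \code{labels} (integer matrix with classes \code{0..c-1}); pixel
#'   intensity equals the class mean of its label everywhere.
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop_config("spec must be a phantom_spec")
  h <- spec$height; w <- spec$width; c <- length(spec$class_means)
  labels <- if (spec$class_geometry == "concentric_ellipses")
    concentric_labels(h, w, c, spec$seed)
  else
    voronoi_labels(h, w, c, spec$seed)
  image <- matrix(spec$class_means[labels + 1L], h, w)
  list(image = image, labels = labels)
}

# Nested elliptical shells: class 0 outside the head ellipse (darkest,
# CSF-like), classes 1..c-1 in shells of roughly equal area toward the
# center. The seed jitters center and axis ratio slightly so replicates
# are not identical geometry.
concentric_labels <- function(h, w, c, seed) {
  jit <- with_stream(seed, 0L, stats::runif(4, -1, 1))
  cy <- (h + 1) / 2 + jit[1] * h * 0.02
  cx <- (w + 1) / 2 + jit[2] * w * 0.02
  ay <- 0.42 * h * (1 + 0.05 * jit[3])
  ax <- 0.45 * w * (1 + 0.05 * jit[4])
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  r <- sqrt(((row - cy) / ay)^2 + ((col - cx) / ax)^2)
  # shells of equal area inside the unit ellipse: outer radius of shell k
  # (k = 1 outermost inner class) at sqrt(k / (c - 1)) from the center
  labels <- matrix(0L, h, w)
  inner <- c - 1L
  for (k in seq_len(inner)) {
    lo <- sqrt((inner - k) / inner)
    sel <- r < sqrt((inner - k + 1) / inner) & r >= lo
    labels[sel] <- k
  }
  # class order: outermost shell is class 1, innermost is class c-1
  labels
}

voronoi_labels <- function(h, w, c, seed) {
  n_sites <- 4L * c
  pts <- with_stream(seed, 0L,
                     cbind(stats::runif(n_sites, 1, h), stats::runif(n_sites, 1, w)))
  site_class <- rep_len(seq_len(c) - 1L, n_sites)
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  best <- matrix(Inf, h, w); labels <- matrix(0L, h, w)
  for (s in seq_len(n_sites)) {
    d2 <- (row - pts[s, 1])^2 + (col - pts[s, 2])^2
    sel <- d2 < best
    best[sel] <- d2[sel]
    labels[sel] <- site_class[s]
  }
  labels
}

#' Corrupt an image with noise
#'
#' Gaussian noise adds seeded \code{N(0, level^2)} deviates and clips to
#' [0, 1]. Salt-and-pepper replaces a seeded Bernoulli(\code{level})
#' fraction of pixels by 0 or 1 with equal probability, leaving the rest
#' untouched.
#'
#' @param img numeric matrix with intensities in [0, 1].
#' @param noise a \code{\link{noise_spec}}.
#' @return Corrupted image, same shape, values in [0, 1].
#' @export
add_noise <- function(img, noise) {
  if (!inherits(noise, "noise_spec")) stop_config("noise must be a noise_spec")
  if (!is_image(img)) stop_input("img must be a finite numeric matrix")
  if (min(img) < 0 || max(img) > 1) stop_input("img intensities must lie in [0, 1]")
  n <- length(img)
  if (noise$kind == "gaussian") {
    eps <- with_stream(noise$seed, 1L, stats::rnorm(n, 0, noise$level))
    matrix(clip01(as.vector(img) + eps), nrow(img), ncol(img))
  } else {
    draws <- with_stream(noise$seed, 1L,
                         list(hit = stats::runif(n) < noise$level,
                              salt = stats::runif(n) < 0.5))
    out <- as.vector(img)
    out[draws$hit] <- ifelse(draws$salt[draws$hit], 1, 0)
    matrix(out, nrow(img), ncol(img))
  }
}

# The Bernoulli corruption mask used by salt-and-pepper noise (exported for
# evaluation of which pixels were hit, independent of their values).
#' Salt-and-pepper corruption mask for a given noise spec
#' @param img image the noise would be applied to (shape and stream length).
#' @param noise a salt_pepper \code{\link{noise_spec}}.
#' @return logical matrix: TRUE where the pixel is replaced.
#' @export
noise_mask <- function(img, noise) {
  if (!inherits(noise, "noise_spec") || noise$kind != "salt_pepper")
    stop_config("noise_mask applies to salt_pepper noise specs")
  n <- length(img)
  hit <- with_stream(noise$seed, 1L, stats::runif(n) < noise$level)
  matrix(hit, nrow(img), ncol(img))
}

#' Apply a smooth multiplicative bias field
#'
#' The field is seeded filtered Gaussian white noise, centered so its grid
#' mean is exactly 1 and scaled so its maximum deviation from 1 equals the
#' requested amplitude. Amplitude 0 returns the input unchanged.
#'
#' @param img numeric matrix.
#' @param spec a \code{\link{bias_field_spec}}.
#' @return \code{img * B}, with \code{B} the bias field.
#' @export
add_bias_field <- function(img, spec) {
  if (!inherits(spec, "bias_field_spec")) stop_config("spec must be a bias_field_spec")
  if (!is_image(img)) stop_input("img must be a finite numeric matrix")
  img * bias_field(nrow(img), ncol(img), spec)
}

#' Evaluate the bias field itself
#' @inheritParams add_bias_field
#' @param height,width grid size.
#' @return numeric matrix B > 0 with mean 1 and max |B - 1| = amplitude.
#' @export
bias_field <- function(height, width, spec) {
  if (spec$amplitude == 0) return(matrix(1, height, width))
  z <- with_stream(spec$seed, 2L, matrix(stats::rnorm(height * width), height, width))
  f <- gauss_blur(z, spec$smoothness)
  f <- f - mean(f)
  f <- f * (spec$amplitude / max(abs(f)))
  1 + f
}

# Separable Gaussian blur with reflected borders (kernel sd = smoothness/2,
# support 2 sd each side).
gauss_blur <- function(m, smoothness) {
  sd <- smoothness / 2
  half <- max(1L, ceiling(2 * sd))
  k <- stats::dnorm(-half:half, sd = sd)
  k <- k / sum(k)
  conv_axis <- function(m, along_rows) {
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      off <- i - half - 1L
      out <- out + k[i] * (if (along_rows) shift2d(m, off, 0L) else shift2d(m, 0L, off))
    }
    out
  }
  conv_axis(conv_axis(m, TRUE), FALSE)
}
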
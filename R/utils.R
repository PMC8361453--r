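# Internal helpers: seeded substreams, windowed filters on 2-D grids with
# reflected borders, structured error conditions, simplex utilities.

stop_config <- function(msg, ...) {
  stop(structure(class = c("fuzzyseg_config_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_input <- function(msg, ...) {
  stop(structure(class = c("fuzzyseg_input_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_degenerate <- function(msg, ...) {
  stop(structure(class = c("fuzzyseg_degenerate_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' @noRd
assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config("'%s' must be a single finite number", name)
  invisible(x)
}

# Counter-based substream: each operation draws from its own deterministic
# stream derived from (seed, counter), so adding a draw to one operation never
# perturbs another. Kept below 2^31 - 1 for R's 32-bit set.seed().
stream_seed <- function(seed, counter = 0L) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(counter) * 16807 + 1
  as.integer(s %% 2147483647)
}

# Evaluate `code` under a private RNG state seeded from (seed, counter);
# the caller's .Random.seed is restored afterwards.
with_stream <- function(seed, counter, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stream_seed(seed, counter))
  force(code)
}

# Index vectors for a 2-D shift with reflected (Neumann) borders.
# Half-sample symmetric: index 0 mirrors to 1, n+1 to n, so a one-pixel
# shift sees the boundary pixel itself (zero flux across the border).
reflect_idx <- function(n, offset) {
  i <- seq_len(n) + offset
  i[i < 1L] <- 1L - i[i < 1L]
  i[i > n] <- 2L * n + 1L - i[i > n]
  i
}

# Shift a matrix by (dr, dc) with reflected borders.
shift2d <- function(m, dr, dc) {
  m[reflect_idx(nrow(m), dr), reflect_idx(ncol(m), dc), drop = FALSE]
}

# Sum of values in the square window of given radius around each pixel
# (center included), reflected borders.
window_sum <- function(m, radius) {
  out <- matrix(0, nrow(m), ncol(m))
  for (dr in -radius:radius)
    for (dc in -radius:radius)
      out <- out + shift2d(m, dr, dc)
  out
}

# 3x3 median filter, reflected borders.
median3 <- function(m) {
  stack <- vapply(
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,0), c(0,1),
         c(1,-1), c(1,0), c(1,1)),
    function(d) as.vector(shift2d(m, d[1], d[2])),
    numeric(length(m)))
  matrix(apply(stack, 1L, stats::median), nrow(m), ncol(m))
}

# 3x3 mean filter, reflected borders.
mean3 <- function(m) window_sum(m, 1L) / 9

# Euclidean projection of a vector onto the probability simplex.
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# All permutations of 1..n (n small), as a list of integer vectors.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (k in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

is_image <- function(img) is.matrix(img) && is.numeric(img) && all(is.finite(img))
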
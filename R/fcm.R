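#' Configure fuzzy C-means fitters
#'
#' One configuration object drives all three fitters: classical FCM
#' (\code{\link{fcm_fit}}), spatially constrained FCM
#' (\code{\link{fcm_s_fit}}) and the kernel variant with membership penalty
#' and neighborhood term (\code{\link{sipmfcm_fit}}).
#'
#' @param n_clusters number of clusters c >= 2 (chosen by the user; no
#'   automatic model selection).
#' @param fuzzifier membership exponent m > 1; m -> 1 approaches hard
#'   k-means. The kernel fitter requires m = 2 (closed-form memberships).
#' @param max_iter maximum alternating-optimization iterations.
#' @param tol convergence threshold on the maximum absolute membership
#'   change between iterations.
#' @param seed integer seed for the Dirichlet membership initialization.
#' @param spatial_alpha neighborhood weight \eqn{\alpha \ge 0} of the
#'   spatially constrained objective (0 recovers plain FCM exactly).
#' @param neighborhood square-window radius in pixels defining the
#'   neighborhood (radius 1 = 8-neighborhood).
#' @param rho regularization weight \eqn{\rho \ge 0} of the kernel
#'   fitter's membership penalty and smoothed-image terms.
#' @param kernel_sigma Gaussian kernel bandwidth, or \code{"auto"} (the
#'   sample standard deviation of the image intensities).
#' @param smoother smoothing used to build the reference image for the
#'   kernel fitter's neighborhood term: \code{"median"} or \code{"mean"}
#'   (3 x 3, reflected borders).
#' @param fuse_p,fuse_q exponents of the spatial membership fusion
#'   (\code{\link{fuse_spatial_membership}}).
#' @param neighborhood_weighting \code{"membership_weighted"} (the
#'   smoothed-image term carries \eqn{u^m}, so it informs the memberships)
#'   or \code{"literal"} (unweighted; it moves the centers only).
#' @param restarts number of seeded restarts; the lowest-objective run is
#'   kept. Collapsed local minima are two orders of magnitude worse in
#'   objective, so when they are a concern a few restarts identify the
#'   good run reliably.
#' @return An object of class \code{fcm_config}.
#' @export
fcm_config <- function(n_clusters, fuzzifier = 2, max_iter = 100L, tol = 1e-5,
                       seed = 1L, spatial_alpha = 1, neighborhood = 1L,
                       rho = 0.1, kernel_sigma = "auto",
                       smoother = c("median", "mean"),
                       fuse_p = 1, fuse_q = 1,
                       neighborhood_weighting = c("membership_weighted", "literal"),
                       restarts = 1L) {
  smoother <- match.arg(smoother)
  neighborhood_weighting <- match.arg(neighborhood_weighting)
  assert_scalar_num(n_clusters, "n_clusters")
  if (n_clusters < 2) stop_config("n_clusters must be >= 2")
  assert_scalar_num(fuzzifier, "fuzzifier")
  if (fuzzifier <= 1) stop_config("fuzzifier m must be > 1")
  assert_scalar_num(tol, "tol")
  if (tol <= 0) stop_config("tol must be > 0")
  assert_scalar_num(spatial_alpha, "spatial_alpha")
  if (spatial_alpha < 0) stop_config("spatial_alpha must be >= 0")
  assert_scalar_num(neighborhood, "neighborhood")
  if (neighborhood < 1) stop_config("neighborhood radius must be >= 1")
  assert_scalar_num(rho, "rho")
  if (rho < 0) stop_config("rho must be >= 0")
  if (!identical(kernel_sigma, "auto")) {
    assert_scalar_num(kernel_sigma, "kernel_sigma")
    if (kernel_sigma <= 0) stop_config("kernel_sigma must be > 0")
  }
  assert_scalar_num(fuse_p, "fuse_p"); assert_scalar_num(fuse_q, "fuse_q")
  if (fuse_p < 0 || fuse_q < 0) stop_config("fuse_p and fuse_q must be >= 0")
  assert_scalar_num(max_iter, "max_iter"); assert_scalar_num(seed, "seed")
  assert_scalar_num(restarts, "restarts")
  if (restarts < 1) stop_config("restarts must be >= 1")
  structure(list(n_clusters = as.integer(n_clusters),
                 fuzzifier = as.numeric(fuzzifier),
                 max_iter = as.integer(max_iter), tol = as.numeric(tol),
                 seed = as.integer(seed),
                 spatial_alpha = as.numeric(spatial_alpha),
                 neighborhood = as.integer(neighborhood),
                 rho = as.numeric(rho), kernel_sigma = kernel_sigma,
                 smoother = smoother, fuse_p = as.numeric(fuse_p),
                 fuse_q = as.numeric(fuse_q),
                 neighborhood_weighting = neighborhood_weighting,
                 restarts = as.integer(restarts)),
            class = "fcm_config")
}

#' Membership update from a distance matrix
#'
#' The stationarity condition of the fuzzy objective under the
#' sum-to-one constraint gives
#' \deqn{u_{ij} = 1 / \sum_k (d_{ij}/d_{kj})^{2/(m-1)}.}
#' Columns containing zero distances put all membership mass, split
#' uniformly, on the zero-distance clusters.
#'
#' @param distances c x n matrix of non-negative distances.
#' @param m fuzzifier > 1.
#' @return c x n membership matrix; every column sums to 1.
#' @export
update_memberships <- function(distances, m) {
  if (!is.numeric(m) || length(m) != 1L || m <= 1)
    stop_config("fuzzifier m must be > 1")
  if (!is.matrix(distances) || any(!is.finite(distances)) || any(distances < 0))
    stop_input("distances must be a finite non-negative matrix")
  memberships_from_sqdist(distances^2, m)
}

# Core membership update on SQUARED distances (exponent 1/(m-1)).
memberships_from_sqdist <- function(D2, m) {
  W <- D2^(-1 / (m - 1))
  U <- sweep(W, 2L, colSums(W), "/")
  zero_cols <- which(colSums(D2 == 0) > 0L)
  for (j in zero_cols) {
    z <- D2[, j] == 0
    U[, j] <- 0
    U[z, j] <- 1 / sum(z)
  }
  U
}

#' Center update from memberships
#'
#' \deqn{v_i = \sum_j u_{ij}^m x_j / \sum_j u_{ij}^m.}
#'
#' @param U c x n membership matrix.
#' @param X numeric sample vector of length n.
#' @param m fuzzifier.
#' @return numeric vector of c centers (in cluster-index order).
#' @export
update_centers <- function(U, X, m) {
  W <- U^m
  den <- rowSums(W)
  if (any(den == 0)) {
    i <- which(den == 0)[1]
    stop_degenerate("cluster %d has zero total membership mass", i)
  }
  as.vector(W %*% X) / den
}

# Seeded flat-Dirichlet membership initialization (one column per sample).
init_memberships <- function(c, n, seed, restart = 1L) {
  g <- with_stream(seed, 100L + restart, matrix(stats::rgamma(c * n, 1), c, n))
  sweep(g, 2L, colSums(g), "/")
}

# Shared alternating-optimization loop for FCM (spatial terms zeroed) and
# FCM_S. Both run literally the same arithmetic: with alpha = 0 every added
# spatial contribution is an exact 0, so trajectories are bit-identical.
fcm_core <- function(x, s1, s2, n_r, alpha, cfg, restart) {
  cc <- cfg$n_clusters; m <- cfg$fuzzifier; n <- length(x)
  U <- init_memberships(cc, n, cfg$seed, restart)
  hist <- numeric(0)
  converged <- FALSE
  it <- 0L
  w <- alpha / n_r
  for (it in seq_len(cfg$max_iter)) {
    W <- U^m
    den <- (1 + alpha) * rowSums(W)
    if (any(den == 0)) stop_degenerate("cluster %d lost all membership mass",
                                       which(rowSums(W) == 0)[1])
    v <- as.vector(W %*% (x + w * s1)) / den
    # D2[i, j] = (x_j - v_i)^2 + (alpha/N_R) * sum_{r in N_j} (x_r - v_i)^2,
    # the neighborhood sum expanded via s1 = sum x_r, s2 = sum x_r^2
    D2 <- outer(v, x, function(vi, xj) (xj - vi)^2) +
      w * (matrix(s2, cc, n, byrow = TRUE) - 2 * outer(v, s1) + n_r * v^2)
    U_new <- memberships_from_sqdist(D2, m)
    hist <- c(hist, sum(U_new^m * D2))
    delta <- max(abs(U_new - U))
    U <- U_new
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  list(U = U, v = v, hist = hist, it = it, converged = converged)
}

# Package the core result as an fcm_state, sorting centers ascending (with
# memberships permuted accordingly) for reporting.
as_fcm_state <- function(res, method, cfg, shape) {
  ord <- order(res$v)
  structure(list(memberships = res$U[ord, , drop = FALSE],
                 centers = res$v[ord],
                 objective_history = res$hist,
                 n_iter_run = res$it, converged = res$converged,
                 method = method, config = cfg, shape = shape),
            class = "fcm_state")
}

#' @export
print.fcm_state <- function(x, ...) {
  cat(sprintf("<fcm_state: %s, c = %d, %d iterations%s>\n",
              x$method, length(x$centers), x$n_iter_run,
              if (x$converged) ", converged" else ""))
  cat("  centers:", paste(signif(x$centers, 4), collapse = ", "), "\n")
  cat(sprintf("  final objective: %.6g\n", utils::tail(x$objective_history, 1)))
  invisible(x)
}

#' Classical fuzzy C-means
#'
#' Alternates the closed-form membership and center updates from a seeded
#' Dirichlet initialization until the maximum membership change falls
#' below \code{tol}. The objective \eqn{J = \sum_i \sum_j u_{ij}^m d_{ij}^2}
#' is recorded each iteration and is non-increasing.
#'
#' @param x numeric vector of samples, or a numeric image matrix (used as
#'   its flattened intensity vector).
#' @param cfg an \code{\link{fcm_config}}.
#' @return An \code{fcm_state} with memberships, ascending-sorted centers,
#'   objective history, iteration count and convergence flag.
#' @export
fcm_fit <- function(x, cfg) {
  if (!inherits(cfg, "fcm_config")) stop_config("cfg must be an fcm_config")
  shape <- if (is.matrix(x)) dim(x) else NULL
  x <- as.numeric(x)
  if (length(unique(x)) < cfg$n_clusters)
    stop_degenerate("need at least %d distinct sample values", cfg$n_clusters)
  zero <- numeric(length(x))
  best <- NULL
  for (r in seq_len(cfg$restarts)) {
    res <- fcm_core(x, zero, zero, 1, 0, cfg, r)
    if (is.null(best) || utils::tail(res$hist, 1) < utils::tail(best$hist, 1))
      best <- res
  }
  as_fcm_state(best, "fcm", cfg, shape)
}

#' Spatially constrained fuzzy C-means
#'
#' Augments the FCM objective with a neighborhood term
#' \eqn{(\alpha/N_R) \sum_i \sum_j u_{ij}^m \sum_{r \in N_j} (x_r - v_i)^2}
#' that pulls each pixel's memberships toward those supported by its square
#' neighborhood, damping isolated noise pixels. Both update rules remain in
#' closed form; \code{spatial_alpha = 0} reproduces \code{\link{fcm_fit}}
#' exactly (bit-identical trajectory under the same seed).
#'
#' @param img numeric image matrix.
#' @param cfg an \code{\link{fcm_config}}; \code{spatial_alpha} and
#'   \code{neighborhood} control the constraint.
#' @return An \code{fcm_state}.
#' @export
fcm_s_fit <- function(img, cfg) {
  if (!inherits(cfg, "fcm_config")) stop_config("cfg must be an fcm_config")
  if (!is_image(img)) stop_input("img must be a finite numeric matrix")
  x <- as.numeric(img)
  if (length(unique(x)) < cfg$n_clusters)
    stop_degenerate("need at least %d distinct sample values", cfg$n_clusters)
  r <- cfg$neighborhood
  n_r <- (2 * r + 1)^2 - 1
  s1 <- as.numeric(window_sum(img, r) - img)        # neighbor sums (center excluded)
  s2 <- as.numeric(window_sum(img^2, r) - img^2)
  best <- NULL
  for (rs in seq_len(cfg$restarts)) {
    res <- fcm_core(x, s1, s2, n_r, cfg$spatial_alpha, cfg, rs)
    if (is.null(best) || utils::tail(res$hist, 1) < utils::tail(best$hist, 1))
      best <- res
  }
  as_fcm_state(best, "fcm_s", cfg, dim(img))
}
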
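#' Gaussian-kernel-induced distance
#'
#' \eqn{d_K(x, v) = 1 - K(x, v)} with
#' \eqn{K(x, v) = \exp(-(x - v)^2 / \sigma^2)}: the squared distance between
#' the implicit feature-space images of x and v (up to a factor 2), bounded
#' in [0, 1) and therefore robust to outlying intensities.
#'
#' @param x,v intensities (vectorized).
#' @param sigma kernel bandwidth > 0.
#' @return values in [0, 1); 0 iff x == v.
#' @export
kernel_distance <- function(x, v, sigma) {
  if (!is.numeric(sigma) || any(sigma <= 0)) stop_config("sigma must be > 0")
  1 - exp(-(x - v)^2 / sigma^2)
}

# c x n kernel matrix K[i, j] = exp(-(x_j - v_i)^2 / sigma^2)
kernel_matrix <- function(x, v, sigma) {
  exp(-outer(v, x, function(vi, xj) (xj - vi)^2) / sigma^2)
}

#' Kernel fuzzy C-means with membership penalty and neighborhood term
#'
#' Minimizes, for m = 2,
#' \deqn{J = 2 \sum_i \sum_j u_{ij}^2 (1 - K(x_j, v_i))
#'   + \rho \sum_i \sum_j u_{ij} (1 - u_{ij})
#'   + 2 \rho \sum_i \sum_j w_{ij} (1 - K(\bar{x}_j, v_i))}
#' subject to unit column sums, where \eqn{\bar{x}} is the median- (or
#' mean-) filtered image and the neighborhood weight \eqn{w_{ij}} is
#' \eqn{u_{ij}^2} in \code{"membership_weighted"} mode or 1 in
#' \code{"literal"} mode. The membership penalty rewards crisp assignments;
#' the \eqn{\bar{x}} term injects local spatial information. Memberships
#' have a closed form from the per-column Lagrange multiplier; columns
#' where the closed form leaves the simplex are projected back onto it
#' (Euclidean projection). Centers solve the kernel-weighted stationarity
#' condition by damped fixed-point iteration.
#'
#' @param img numeric image matrix with intensities in [0, 1].
#' @param cfg an \code{\link{fcm_config}} with \code{fuzzifier = 2}.
#' @return An \code{fcm_state}; \code{$projection_active} flags iterations
#'   where the simplex projection engaged.
#' @export
sipmfcm_fit <- function(img, cfg) {
  if (!inherits(cfg, "fcm_config")) stop_config("cfg must be an fcm_config")
  if (!is_image(img)) stop_input("img must be a finite numeric matrix")
  if (cfg$fuzzifier != 2)
    stop_config("sipmfcm_fit requires fuzzifier m = 2 (closed-form memberships)")
  x <- as.numeric(img)
  if (length(unique(x)) < cfg$n_clusters)
    stop_degenerate("need at least %d distinct sample values", cfg$n_clusters)
  sigma <- if (identical(cfg$kernel_sigma, "auto")) stats::sd(x) else cfg$kernel_sigma
  if (!is.finite(sigma) || sigma <= 0)
    stop_degenerate("cannot resolve kernel_sigma on a constant image")
  xbar <- as.numeric(if (cfg$smoother == "median") median3(img) else mean3(img))
  best <- NULL
  for (r in seq_len(cfg$restarts)) {
    res <- sipmfcm_core(x, xbar, sigma, cfg, r)
    if (is.null(best) || utils::tail(res$hist, 1) < utils::tail(best$hist, 1))
      best <- res
  }
  st <- as_fcm_state(best, "sipmfcm", cfg, dim(img))
  st$projection_active <- best$proj
  st$kernel_sigma <- sigma
  st
}

sipmfcm_core <- function(x, xbar, sigma, cfg, restart) {
  cc <- cfg$n_clusters; n <- length(x); rho <- cfg$rho
  mw <- cfg$neighborhood_weighting == "membership_weighted"
  U <- init_memberships(cc, n, cfg$seed, restart)
  # Prototypes must not coincide at the start: a membership-weighted mean of
  # the flat random simplex puts every center at the grand mean, a symmetric
  # configuration the kernel updates cannot leave. Seeded jittered quantiles
  # spread them over the observed intensity range instead.
  q <- stats::quantile(x, probs = (2 * seq_len(cc) - 1) / (2 * cc), names = FALSE)
  v <- q + with_stream(cfg$seed, 200L + restart,
                       stats::rnorm(cc, 0, 0.05 * stats::sd(x)))
  hist <- numeric(0); proj <- logical(0)
  converged <- FALSE; it <- 0L
  for (it in seq_len(cfg$max_iter)) {
    D <- 1 - kernel_matrix(x, v, sigma)      # kernel distances to x
    Db <- 1 - kernel_matrix(xbar, v, sigma)  # and to the smoothed image
    upd <- sipmfcm_memberships(D, Db, rho, mw)
    hist <- c(hist, sipmfcm_objective(upd$U, D, Db, rho, mw))
    proj <- c(proj, upd$projected)
    delta <- max(abs(upd$U - U))
    U <- upd$U
    if (delta < cfg$tol) { converged <- TRUE; break }
    v <- sipmfcm_centers(x, xbar, U, v, sigma, rho, mw)
  }
  list(U = U, v = v, hist = hist, it = it, converged = converged, proj = proj)
}

sipmfcm_objective <- function(U, D, Db, rho, mw) {
  spatial <- if (mw) 2 * rho * sum(U^2 * Db) else 2 * rho * sum(Db)
  2 * sum(U^2 * D) + rho * sum(U * (1 - U)) + spatial
}

# Per-column minimizer of sum_i a_i u_i^2 (+ rho * sum u_i, constant on the
# simplex) with a_i = 2 D_ij - rho [+ 2 rho Dbar_ij in weighted mode].
# All a_i > 0: interior closed form u_i = (1/a_i) / sum_k (1/a_k) from the
# per-column Lagrange multiplier. Columns with a_i <= 0: the closed form
# leaves the simplex; the exact constrained minimizer puts all mass on the
# most negative coefficient (the point Euclidean projection of the diverging
# closed form lands on). If EVERY column lacks a positive coefficient the
# penalty dominates the data term everywhere -- a rho misconfiguration.
sipmfcm_memberships <- function(D, Db, rho, mw) {
  A <- 2 * D - rho + if (mw) 2 * rho * Db else 0
  has_pos <- colSums(A > 0) > 0L
  if (!any(has_pos))
    stop_degenerate(paste0(
      "rho = %g is too large: no positive closed-form membership denominator ",
      "anywhere; decrease rho"), rho)
  W <- 1 / A
  U <- sweep(W, 2L, colSums(W), "/")
  fix <- which(colSums(A <= 0) > 0L)
  if (length(fix)) {
    # vertex minimizer, uniform over ties (mirrors the zero-distance rule)
    Af <- A[, fix, drop = FALSE]
    mn <- Af[1L, ]
    for (i in seq_len(nrow(Af))[-1L]) mn <- pmin(mn, Af[i, ])
    Z <- Af == rep(mn, each = nrow(Af))
    U[, fix] <- Z / rep(colSums(Z), each = nrow(Af))
  }
  list(U = U, projected = length(fix) > 0L)
}

# Damped fixed-point iteration on the center stationarity condition
#   v_i = [sum_j w_ij K_ij x_j + rho * sum_j wb_ij Kb_ij xbar_j] /
#         [sum_j w_ij K_ij     + rho * sum_j wb_ij Kb_ij]
# with w = u^2 and wb = u^2 (weighted mode) or 1 (literal mode).
sipmfcm_centers <- function(x, xbar, U, v, sigma, rho, mw,
                            damp = 0.5, inner_tol = 1e-12, inner_max = 60L) {
  W <- U^2
  for (k in seq_len(inner_max)) {
    K <- kernel_matrix(x, v, sigma)
    Kb <- kernel_matrix(xbar, v, sigma)
    Wb <- if (mw) W else matrix(1, nrow(U), ncol(U))
    num <- as.vector((W * K) %*% x) + rho * as.vector((Wb * Kb) %*% xbar)
    den <- rowSums(W * K) + rho * rowSums(Wb * Kb)
    if (any(den == 0))
      stop_degenerate("cluster %d has zero kernel mass", which(den == 0)[1])
    v_new <- (1 - damp) * v + damp * (num / den)
    if (max(abs(v_new - v)) < inner_tol) { v <- v_new; break }
    v <- v_new
  }
  v
}

#' Neighborhood membership mass (spatial function)
#'
#' \eqn{s_{ij}} sums the memberships of cluster i over the square window
#' of the given radius around pixel j (center included, reflected
#' borders): the possibility that pixel j's neighborhood belongs to
#' cluster i.
#'
#' @param U c x n membership matrix, n = prod(shape).
#' @param shape image dimensions c(rows, cols).
#' @param radius window radius in pixels (>= 1).
#' @return c x n non-negative matrix.
#' @export
spatial_function <- function(U, shape, radius = 1L) {
  if (radius < 1) stop_config("radius must be >= 1")
  if (ncol(U) != prod(shape)) stop_input("U columns must match prod(shape)")
  S <- U
  for (i in seq_len(nrow(U)))
    S[i, ] <- as.numeric(window_sum(matrix(U[i, ], shape[1], shape[2]), radius))
  S
}

#' Fuse memberships with the spatial function
#'
#' \deqn{u'_{ij} = u_{ij}^p s_{ij}^q / \sum_k u_{kj}^p s_{kj}^q,}
#' re-weighting each pixel's memberships by the support its neighborhood
#' lends to each cluster; isolated noisy assignments are suppressed.
#'
#' @param U c x n membership matrix.
#' @param S c x n spatial matrix (\code{\link{spatial_function}}).
#' @param p,q non-negative exponents weighting membership and spatial
#'   evidence (\code{q = 0} reduces to a normalized power of U).
#' @return Fused membership matrix; columns sum to 1.
#' @export
fuse_spatial_membership <- function(U, S, p = 1, q = 1) {
  if (!all(dim(U) == dim(S))) stop_input("U and S must have matching shapes")
  if (p < 0 || q < 0) stop_config("p and q must be >= 0")
  W <- U^p * S^q
  den <- colSums(W)
  if (any(den == 0))
    stop_degenerate("fusion denominator is zero at pixel %d", which(den == 0)[1])
  sweep(W, 2L, den, "/")
}

#' Defuzzify a membership matrix into a hard label map
#'
#' Per-pixel argmax over clusters; ties broken toward the lowest cluster
#' index. The result is a hard partition: every pixel gets exactly one
#' label in \code{0..c-1}.
#'
#' @param U c x n membership matrix.
#' @param shape optional image dimensions; if given, a matrix label map is
#'   returned, otherwise a vector.
#' @return integer labels in 0..c-1.
#' @export
defuzzify <- function(U, shape = NULL) {
  lab <- max.col(t(U), ties.method = "first") - 1L
  if (!is.null(shape)) matrix(lab, shape[1], shape[2]) else lab
}
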
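test_that("kernel distance is zero at identity, hand-checkable at sigma, and monotone", {
  expect_equal(kernel_distance(0.4, 0.4, 1), 0)
  expect_equal(kernel_distance(0.7, 0.2, 0.5), 1 - exp(-1))
  d <- kernel_distance(seq(0, 1, 0.01), 0, sigma = 0.3)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= 0 & d < 1))
  expect_error(kernel_distance(0, 0, sigma = 0), class = "fuzzyseg_config_error")
})

test_that("with rho 0 and a huge bandwidth the kernel fitter reduces to plain fcm", {
  img <- matrix(c(rep(0.2, 10), rep(0.8, 10)), 4, 5)
  img <- img + matrix(seq(0, 0.019, by = 0.001), 4, 5)  # break exact ties
  cfg <- fcm_config(2, seed = 3, rho = 0, kernel_sigma = 1e3, tol = 1e-10,
                    max_iter = 500)
  fk <- sipmfcm_fit(img, cfg)
  ff <- fcm_fit(img, fcm_config(2, seed = 3, tol = 1e-10, max_iter = 500))
  expect_lt(max(abs(fk$memberships - ff$memberships)), 1e-4)
  expect_lt(max(abs(fk$centers - ff$centers)), 1e-4)
})

test_that("the kernel fitter recovers the three tissue means on a clean phantom", {
  ph <- make_phantom(phantom_spec(seed = 2))
  cfg <- fcm_config(3, seed = 2, rho = 0.1, smoother = "median")
  fit <- sipmfcm_fit(ph$image, cfg)
  expect_lt(max(abs(fit$centers - c(0.2, 0.5, 0.8))), 0.02)
})

test_that("kernel fitter objective decreases and its fixed point is stationary under both update maps", {
  ph <- small_noisy_phantom(seed = 5)
  cfg <- fcm_config(3, seed = 5, tol = 1e-9, max_iter = 300)
  fit <- sipmfcm_fit(ph$noisy, cfg)
  expect_monotone_history(fit$objective_history)
  # re-apply both updates at the returned state: residual < 1e-6
  x <- as.numeric(ph$noisy)
  xbar <- as.numeric(fuzzyseg:::median3(ph$noisy))
  s <- fit$kernel_sigma
  v2 <- fuzzyseg:::sipmfcm_centers(x, xbar, fit$memberships, fit$centers, s, 0.1, TRUE)
  expect_lt(max(abs(v2 - fit$centers)), 1e-6)
  D <- 1 - fuzzyseg:::kernel_matrix(x, v2, s)
  Db <- 1 - fuzzyseg:::kernel_matrix(xbar, v2, s)
  U2 <- fuzzyseg:::sipmfcm_memberships(D, Db, 0.1, TRUE)$U
  expect_lt(max(abs(U2 - fit$memberships)), 1e-6)
})

test_that("a generic simplex-constrained minimizer cannot improve the kernel fixed point", {
  img <- matrix(c(rep(0.25, 8), rep(0.75, 8)), 4, 4)
  img <- img + matrix(seq(0, 0.015, by = 0.001), 4, 4)
  cfg <- fcm_config(2, seed = 9, rho = 0.05, tol = 1e-11, max_iter = 500)
  fit <- sipmfcm_fit(img, cfg)
  x <- as.numeric(img); xbar <- as.numeric(fuzzyseg:::median3(img))
  s <- fit$kernel_sigma; n <- length(x)
  obj <- function(par) {
    L <- matrix(par[seq_len(n)], 1, n)
    v <- par[(n + 1):(n + 2)]
    E <- rbind(exp(L), 1)
    U <- sweep(E, 2, colSums(E), "/")
    D <- 1 - exp(-outer(v, x, function(vi, xj) (xj - vi)^2) / s^2)
    Db <- 1 - exp(-outer(v, xbar, function(vi, xj) (xj - vi)^2) / s^2)
    2 * sum(U^2 * D) + 0.05 * sum(U * (1 - U)) + 2 * 0.05 * sum(U^2 * Db)
  }
  U0 <- pmin(pmax(fit$memberships, 1e-9), 1 - 1e-9)
  par0 <- c(log(U0[1, ] / U0[2, ]), fit$centers)
  J0 <- obj(par0)
  J_opt <- stats::optim(par0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-15))$value
  expect_lt(J0 - J_opt, 1e-6)
})

test_that("an oversized rho raises a diagnostic error naming rho", {
  img <- matrix(c(rep(0.45, 8), rep(0.55, 8)), 4, 4)
  cfg <- fcm_config(2, seed = 1, rho = 50, kernel_sigma = 1)
  expect_error(sipmfcm_fit(img, cfg), regexp = "rho",
               class = "fuzzyseg_degenerate_error")
})

test_that("literal neighborhood weighting leaves memberships driven by the data term only", {
  ph <- small_noisy_phantom(seed = 7, size = 16)
  for (mode in c("membership_weighted", "literal")) {
    cfg <- fcm_config(3, seed = 7, neighborhood_weighting = mode)
    fit <- sipmfcm_fit(ph$noisy, cfg)
    expect_monotone_history(fit$objective_history)
    expect_lt(max(abs(colSums(fit$memberships) - 1)), 1e-10)
    expect_lt(max(abs(sort(fit$centers) - c(0.2, 0.5, 0.8))), 0.1)
  }
})

test_that("non-quadratic fuzzifiers are rejected by the kernel fitter", {
  img <- matrix(stats::runif(16), 4, 4)
  expect_error(sipmfcm_fit(img, fcm_config(2, fuzzifier = 3)),
               class = "fuzzyseg_config_error")
})

test_that("spatial function aggregates membership mass over the window", {
  # uniform memberships -> constant window mass |window| / c
  U <- matrix(1 / 3, 3, 36)
  S <- spatial_function(U, c(6, 6), radius = 1)
  expect_true(all(abs(S - 9 / 3) < 1e-12))
  # single-pixel image: window collapses onto the pixel (up to multiplicity)
  U1 <- matrix(c(0.7, 0.3), 2, 1)
  S1 <- spatial_function(U1, c(1, 1), radius = 1)
  expect_equal(S1 / sum(S1), U1 / sum(U1))
  # hard two-region partition: interior pixels have all mass on their region
  lab <- cbind(matrix(0L, 6, 3), matrix(1L, 6, 3))
  Uh <- rbind(as.numeric(lab == 0), as.numeric(lab == 1))
  Sh <- spatial_function(Uh, c(6, 6), radius = 1)
  j_int <- (2 - 1) * 6 + 3   # pixel (3,2), interior of region 0
  expect_equal(Sh[, j_int], c(9, 0))
  expect_error(spatial_function(U, c(6, 6), radius = 0), class = "fuzzyseg_config_error")
})

test_that("spatial fusion reproduces hand-evaluated values and its reduction cases", {
  U <- matrix(c(0.6, 0.4), 2, 1)
  S <- matrix(c(0.9, 0.1), 2, 1)
  expect_equal(fuse_spatial_membership(U, S, 1, 1)[, 1],
               c(0.54, 0.04) / 0.58, tolerance = 1e-3)
  # uniform spatial evidence cancels
  expect_equal(fuse_spatial_membership(U, matrix(0.5, 2, 1), 1, 1), U)
  # q = 0, p = 1: identity
  expect_equal(fuse_spatial_membership(U, S, 1, 0), U)
  expect_error(fuse_spatial_membership(U, matrix(0, 2, 1), 1, 1),
               class = "fuzzyseg_degenerate_error")
  # columns stay on the simplex after fusion
  set.seed(44)
  Ur <- matrix(stats::runif(3 * 25), 3, 25); Ur <- sweep(Ur, 2, colSums(Ur), "/")
  Sr <- spatial_function(Ur, c(5, 5), 1)
  expect_lt(max(abs(colSums(fuse_spatial_membership(Ur, Sr, 1, 2)) - 1)), 1e-10)
})

test_that("defuzzification takes the per-pixel argmax with low-index tie-breaks", {
  expect_equal(defuzzify(matrix(c(0.5, 0.5), 2, 1)), 0L)
  Uh <- matrix(c(1, 0, 0, 0, 0, 1), 3, 2)
  expect_equal(defuzzify(Uh), c(0L, 2L))
  set.seed(21)
  U <- matrix(stats::runif(3 * 1000), 3, 1000); U <- sweep(U, 2, colSums(U), "/")
  lab <- defuzzify(U)
  ref <- apply(U, 2, which.max) - 1L
  expect_equal(lab, ref)
  # partition property: labels exhaustive and within range
  expect_true(all(lab %in% 0:2))
  m <- defuzzify(U[, 1:12], shape = c(3, 4))
  expect_equal(dim(m), c(3L, 4L))
})
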
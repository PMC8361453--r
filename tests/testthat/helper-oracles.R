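# Independent oracles and shared fixtures for the test suite.

# Direct double-sum evaluation of the fuzzy clustering objective
# J = sum_i sum_j u_ij^m (x_j - v_i)^2, written without reusing any
# package internals.
fcm_objective_ref <- function(x, U, v, m) {
  total <- 0
  for (i in seq_along(v))
    for (j in seq_along(x))
      total <- total + U[i, j]^m * (x[j] - v[i])^2
  total
}

# Generic simplex-constrained numeric minimizer of the fuzzy objective:
# memberships parameterized by a per-column softmax (so the unit-sum
# constraint holds by construction), centers free, minimized with BFGS.
fcm_numeric_min <- function(x, cc, m, init_U, init_v) {
  n <- length(x)
  logits0 <- log(pmax(init_U[-cc, , drop = FALSE], 1e-12)) -
    rep(log(pmax(init_U[cc, ], 1e-12)), each = cc - 1)
  par0 <- c(as.vector(logits0), init_v)
  obj <- function(par) {
    L <- matrix(par[seq_len((cc - 1) * n)], cc - 1, n)
    v <- par[((cc - 1) * n + 1):length(par)]
    E <- rbind(exp(L), 1)
    U <- sweep(E, 2L, colSums(E), "/")
    sum(U^m * outer(v, x, function(vi, xj) (xj - vi)^2))
  }
  stats::optim(par0, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))$value
}

# Two well-separated seeded 1-D intensity clouds.
two_cloud_samples <- function(seed = 42, n_per = 25) {
  set.seed(seed)
  c(stats::rnorm(n_per, 0.2, 0.01), stats::rnorm(n_per, 0.8, 0.01))
}

# Small phantom + gaussian noise fixture for fitter tests.
small_noisy_phantom <- function(seed = 1, size = 24, sd = 0.05) {
  ph <- make_phantom(phantom_spec(height = size, width = size, seed = seed))
  list(clean = ph$image, labels = ph$labels,
       noisy = add_noise(ph$image, noise_spec("gaussian", sd, seed = seed)))
}

expect_monotone_history <- function(hist, rel_tol = 1e-9) {
  drops <- diff(hist)
  expect_true(all(drops <= rel_tol * pmax(abs(hist[-length(hist)]), 1)),
              label = sprintf("objective history non-increasing (max rise %g)",
                              suppressWarnings(max(drops))))
}
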
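# Synthetic-data generation and the (c, d) profile-likelihood analysis.

test_that("Gaussian-bump coefficients give a boundary-compatible, centred IC", {
  for (omega in c(0.1, 0.2, 0.3)) {
    ic <- gaussian_ic_coefficients(omega, N = 8)
    expect_length(ic$coeffs, 8L)
    # sine reconstruction vanishes at the boundary exactly
    expect_equal(ic$u0(c(0, 1)), c(0, 0), tolerance = 1e-12)
    # centre value is 1 up to truncation error (largest for the narrow bump)
    expect_equal(ic$u0(0.5), 1, tolerance = 0.02)
    # symmetry about x = 1/2 kills the even modes
    expect_lt(max(abs(ic$coeffs[c(2, 4, 6, 8)])), 1e-12)
  }
  # narrow bumps need more modes: |C3/C1| decreases with omega
  r <- vapply(c(0.1, 0.2, 0.3), function(w) {
    cf <- gaussian_ic_coefficients(w, N = 8)$coeffs
    abs(cf[3] / cf[1])
  }, numeric(1))
  expect_true(all(diff(r) < 0))
  # quadrature oracle for omega = 0.3, n = 1 (fine Simpson sum)
  xg <- seq(0, 1, length.out = 4001)
  g <- exp(-(xg - 0.5)^2 / (2 * 0.3^2))
  s <- (g - g[1]) / (1 - g[1])            # h(1/2) = g(1/2) - g(0) = 1 - g(0)
  w <- rep(c(2, 4), length.out = 4001); w[c(1, 4001)] <- 1
  c1_oracle <- 2 * sum(w * s * sin(pi * xg)) * (xg[2] - xg[1]) / 3
  expect_equal(gaussian_ic_coefficients(0.3, 8)$coeffs[1], c1_oracle,
               tolerance = 1e-8)
  # wide bump is close to the dominant eigenfunction
  ic3 <- gaussian_ic_coefficients(0.3, 8)
  rel <- sqrt(sum(ic3$coeffs[-1]^2) / sum(ic3$coeffs^2))
  expect_lt(rel, 0.1)
})

test_that("simulated datasets are reproducible and exact in the zero-noise limit", {
  ic <- gaussian_ic_coefficients(0.2, N = 8)
  d1 <- simulate_dataset(1, 0.05, ic, noise_spec(), seed = 4)
  d2 <- simulate_dataset(1, 0.05, ic, noise_spec(), seed = 4)
  expect_identical(d1$y, d2$y)
  d3 <- simulate_dataset(1, 0.05, ic, noise_spec(sigma = 1e-12), seed = 4)
  expect_lt(max(abs(d3$y - d3$u)), 1e-10)
  expect_equal(dim(d1$y), c(11L, 21L))
})

test_that("noise draws reproduce the exponential spatial covariance", {
  ic <- gaussian_ic_coefficients(0.3, N = 2)
  grid <- space_time_grid(seq(0, 1, 0.1), c(0, 0.1))
  n_rep <- 4000L
  eps0 <- matrix(NA_real_, n_rep, 11)   # slice t = 0
  eps1 <- matrix(NA_real_, n_rep, 11)   # slice t = 0.1
  for (r in seq_len(n_rep)) {
    ds <- simulate_dataset(1, 0.05, ic, noise_spec(), grid, seed = 1000 + r)
    eps0[r, ] <- ds$y[, 1] - ds$u[, 1]
    eps1[r, ] <- ds$y[, 2] - ds$u[, 2]
  }
  emp <- cov(eps0)
  se <- 0.09 * sqrt(2 / n_rep) * 3      # ~3 standard errors
  expect_lt(abs(emp[1, 1] - 0.09), se)
  expect_lt(abs(emp[1, 2] - 0.09 * exp(-10 * 0.1)), se)
  expect_lt(abs(emp[1, 6] - 0.09 * exp(-10 * 0.5)), se)
  # independence across time slices
  expect_lt(abs(cov(eps0[, 3], eps1[, 3])), se)
})

test_that("the log-likelihood has the Gaussian quadratic structure", {
  ic <- gaussian_ic_coefficients(0.2, N = 8)
  ds <- simulate_dataset(1, 0.05, ic, noise_spec(), seed = 9)
  # zero residuals: constant term only
  ds0 <- ds; ds0$y <- ds$u
  Sig <- 0.09 * exp(-10 * abs(outer(ds$x, ds$x, `-`)))
  const <- -0.5 * 21 * (11 * log(2 * pi) + determinant(Sig)$modulus[1])
  expect_equal(log_likelihood(ds0, 1, 0.05, ic$coeffs), const,
               tolerance = 1e-10)
  # doubling the residuals quadruples the quadratic form:
  # ll(2r) - const = 4 (ll(r) - const)
  ll1 <- log_likelihood(ds, 1, 0.05, ic$coeffs)
  ds2 <- ds; ds2$y <- ds$u + 2 * (ds$y - ds$u)
  ll2 <- log_likelihood(ds2, 1, 0.05, ic$coeffs)
  expect_equal(ll2 - const, 4 * (ll1 - const), tolerance = 1e-8)
  # at the truth the expected quadratic form per slice is the dimension (11);
  # chi-square concentration over 21 slices keeps the average within bounds
  q <- -2 * (ll1 - const) / 21
  expect_gt(q, 11 - 3 * sqrt(2 * 11 / 21))
  expect_lt(q, 11 + 3 * sqrt(2 * 11 / 21))
})

test_that("GLS profiling recovers the coefficients and matches an optimizer", {
  ic <- gaussian_ic_coefficients(0.2, N = 8)
  ds <- simulate_dataset(1, 0.05, ic, noise_spec(), seed = 21)
  # zero-noise interpolation recovers the truth exactly
  ds0 <- ds; ds0$y <- ds$u
  pc0 <- profile_coefficients(ds0, 1, 0.05)
  expect_equal(pc0$coeffs, ic$coeffs, tolerance = 1e-8)
  # profiled value dominates the likelihood at the true coefficients
  pc <- profile_coefficients(ds, 1, 0.05)
  expect_gte(pc$loglik, log_likelihood(ds, 1, 0.05, ic$coeffs))
  # numerical-optimizer oracle from several seeded starts
  nll <- function(cf) -log_likelihood(ds, 1, 0.05, cf)
  set.seed(3)
  best <- Inf; best_par <- NULL
  for (s in 1:5) {
    st <- ic$coeffs + rnorm(8, 0, 0.2)
    op <- optim(st, nll, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-14))
    if (op$value < best) { best <- op$value; best_par <- op$par }
  }
  expect_equal(pc$coeffs, best_par, tolerance = 1e-5)
  expect_equal(pc$loglik, -best, tolerance = 1e-6)
})

test_that("the confidence threshold is half the chi-square quantile", {
  expect_equal(lr_threshold(), qchisq(0.95, 2) / 2, tolerance = 1e-12)
  expect_equal(round(lr_threshold(), 2), 3)
})

test_that("profile surface is normalized with a ridge-shaped confidence region", {
  ic <- gaussian_ic_coefficients(0.3, N = 8)
  ds <- simulate_dataset(1, 0.05, ic, noise_spec(), seed = 2)
  ps <- profile_surface(ds, seq(0, 4, length.out = 21),
                        ellipident:::logspace(1e-3, 1, 21))
  expect_equal(max(ps$loglik), 0)
  expect_true(ps$mask[which(ps$c_grid == ps$mle$c),
                      which(ps$d_grid == ps$mle$d)])
  # the region follows the indistinguishable set: on every d-grid line the
  # region intersects, it contains the cell nearest the ridge curve
  # c = c_mle + (d - d_mle) pi^2
  for (j in seq_along(ps$d_grid)) {
    if (!any(ps$mask[, j])) next
    cr <- ps$ridge_c(ps$d_grid[j])
    if (cr < min(ps$c_grid) || cr > max(ps$c_grid)) next
    i <- which.min(abs(ps$c_grid - cr))
    hood <- ps$mask[max(1, i - 1):min(length(ps$c_grid), i + 1), j]
    expect_true(any(hood),
                label = sprintf("ridge cell (d = %.4g)", ps$d_grid[j]))
  }
  # elongation along the ridge: the transverse coordinate s = c - d pi^2
  # varies far less over the region than the raw c coordinate
  cells <- which(ps$mask, arr.ind = TRUE)
  s_vals <- ps$c_grid[cells[, 1]] - ps$d_grid[cells[, 2]] * pi^2
  c_vals <- ps$c_grid[cells[, 1]]
  expect_lt(diff(range(s_vals)), 0.5 * diff(range(c_vals)))
})

test_that("practical identifiability improves for narrower initial bumps", {
  d_grid <- ellipident:::logspace(1e-3, 1, 21)
  c_grid <- seq(0, 4, length.out = 21)
  masks <- lapply(c(0.1, 0.3), function(w) {
    ds <- simulate_dataset(1, 0.05, gaussian_ic_coefficients(w, N = 8),
                           noise_spec(), seed = 6)
    profile_surface(ds, c_grid, d_grid)
  })
  d_extent <- vapply(masks, function(ps) {
    dd <- ps$d_grid[apply(ps$mask, 2, any)]
    diff(range(log(dd)))
  }, numeric(1))
  # omega = 0.3 region is wider in d than omega = 0.1
  expect_gt(d_extent[2], d_extent[1])
  # omega = 0.1 admits a positive lower bound on d strictly inside the grid
  ps1 <- masks[[1]]
  d_in <- ps1$d_grid[apply(ps1$mask, 2, any)]
  expect_gt(min(d_in), min(ps1$d_grid))
})

test_that("the profiled ridge is flat along the indistinguishable set at the truth", {
  for (w in c(0.1, 0.2, 0.3)) {
    ds <- simulate_dataset(1, 0.05, gaussian_ic_coefficients(w, N = 8),
                           noise_spec(), seed = 8)
    ll0 <- profile_coefficients(ds, 1, 0.05)$loglik
    h <- 0.02
    # along: (c, d) -> (c + h pi^2, d + h); transverse: (c - h pi^2, d + h)
    ll_along <- profile_coefficients(ds, 1 + h * pi^2, 0.05 + h)$loglik
    ll_trans <- profile_coefficients(ds, 1 - h * pi^2, 0.05 + h)$loglik
    expect_lt(abs(ll_along - ll0), abs(ll_trans - ll0))
  }
})

test_that("MLE coverage of the truth is near nominal over replicate datasets", {
  ic <- gaussian_ic_coefficients(0.1, N = 8)
  thr <- lr_threshold()
  covered <- vapply(1:20, function(s) {
    ds <- simulate_dataset(1, 0.05, ic, noise_spec(), seed = 100 + s)
    pc_true <- profile_coefficients(ds, 1, 0.05)$loglik
    # MLE over a local grid around the truth (profiled surface maximum)
    cg <- seq(0.5, 1.5, length.out = 11); dg <- seq(0.02, 0.1, length.out = 9)
    best <- max(vapply(cg, function(cc) {
      max(vapply(dg, function(dd) {
        profile_coefficients(ds, cc, dd)$loglik
      }, numeric(1)))
    }, numeric(1)))
    (best - pc_true) <= thr
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
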
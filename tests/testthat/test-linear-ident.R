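# Steps 1-4 for the linear homogeneous model.

test_that("auxiliary points difference with role swap enforcing d >= 0", {
  A <- auxiliary_point(parameter_point(0.05, 0, 1),
                       parameter_point(0.05 + 1 / pi^2, 0, 2))
  expect_equal(A$d, 1 / pi^2, tolerance = 1e-14)
  expect_equal(A$c, 1)
  expect_true(A$swapped)
  A2 <- auxiliary_point(parameter_point(2, 1, 3), parameter_point(1, 1, 3))
  expect_equal(c(A2$d, A2$b, A2$c), c(1, 0, 0))
  expect_false(A2$swapped)
  expect_error(auxiliary_point(parameter_point(1, 0, 0),
                               parameter_point(1, 0, 0)), "distinct")
})

test_that("membership in the indistinguishable set matches the eigenvalue condition", {
  sp <- unit_dirichlet()
  m <- in_set_A(c(1 / pi^2, 0, 1), sp)
  expect_true(m$member); expect_equal(m$index, 1L)
  m2 <- in_set_A(c(1, 0, 0), model_spec("neumann", length = 1))
  expect_true(m2$member); expect_equal(m2$mode, "eigen")
  expect_equal(m2$index, 0L)     # the constant zero mode
  expect_false(in_set_A(c(1, 0, -3), sp)$member)  # Dirichlet spectrum positive
})

test_that("partner families reproduce the worked indistinguishable pair", {
  sp <- unit_dirichlet()
  fam <- indistinguishable_partners(parameter_point(0.05, 0, 1), sp, n = 1)
  A2 <- fam$partner_from_c(2)
  expect_equal(A2$d, 0.05 + 1 / pi^2, tolerance = 1e-12)
  expect_equal(round(A2$d, 2), 0.15)
  # partner(d2) and partner_from_c are consistent
  A2b <- fam$partner(A2$d)
  expect_equal(A2b$c, 2, tolerance = 1e-12)
  # the invariant c - d pi^2 is constant along the family
  mus <- vapply(fam$sample(5, seed = 3),
                function(p) p$c - p$d * pi^2, numeric(1))
  expect_equal(mus, rep(1 - 0.05 * pi^2, 5), tolerance = 1e-10)
})

test_that("drift families preserve the diffusivity/drift ratio", {
  sp <- unit_dirichlet()
  fam <- indistinguishable_partners(parameter_point(1, 2, 0.5), sp, n = 1,
                                    drift = TRUE)
  P <- fam$partner(2)
  expect_equal(P$b, 4)            # d1/d2 = b1/b2
  aux <- auxiliary_point(parameter_point(1, 2, 0.5), P)
  expect_true(in_set_A(aux, sp)$member)
  expect_error(indistinguishable_partners(parameter_point(1, 0, 0.5), sp,
                                          n = 1, drift = TRUE),
               "sign of b1 and b2")
})

test_that("Neumann constant-mode family admits arbitrary (d2, b2)", {
  spn <- model_spec("neumann", length = 1)
  fam <- indistinguishable_partners(parameter_point(1, 0, 0), spn, n = 0)
  P <- fam$partner(3.7, b2 = -2)
  expect_equal(P$c, 0)
  expect_true(in_set_A(auxiliary_point(parameter_point(1, 0, 0), P), spn)$member)
})

test_that("kernel membership is decided by weighted eigenfunction projection", {
  sp <- unit_dirichlet()
  A <- c(1 / pi^2, 0, 1)
  expect_true(is_in_kernel(function(x) sin(pi * x), A, sp))
  expect_false(is_in_kernel(function(x) sin(pi * x) + 0.1 * sin(2 * pi * x),
                            A, sp))
  # independent quadrature oracle for the mixed mode: the sin(2 pi x)
  # component survives the projection with relative L2 norm 0.1/sqrt(1+0.01)
  expected <- 0.1 / sqrt(1 + 0.01)
  r <- attr(is_in_kernel(function(x) sin(pi * x) + 0.1 * sin(2 * pi * x),
                         A, sp), "rel_residual")
  expect_equal(r, expected, tolerance = 1e-8)
  # Neumann constant mode
  expect_true(is_in_kernel(1, c(1, 0, 0), model_spec("neumann", length = 1)))
  expect_error(is_in_kernel(function(x) 0 * x, A, sp), "zero")
})

test_that("kernel projection of drifted operators uses the symmetrizing weight", {
  sp <- unit_dirichlet()
  A1 <- parameter_point(1, 2, 0.5)
  P <- indistinguishable_partners(A1, sp, n = 1, drift = TRUE)$partner(0.5)
  aux <- auxiliary_point(A1, P)
  phi <- eigenpairs(aux$d, aux$b, sp, 1)[[1]]$fns[[1]]
  expect_true(is_in_kernel(function(x) 2.3 * phi(x), aux, sp))
  expect_false(is_in_kernel(function(x) sin(pi * x), aux, sp))
})

test_that("constructed non-identifiable solutions solve both PDEs", {
  sp <- unit_dirichlet()
  A1 <- parameter_point(0.05, 0, 1)
  A2 <- indistinguishable_partners(A1, sp, n = 1)$partner_from_c(2)
  sol <- construct_nonidentifiable_solution(A1, A2, sp)
  expect_equal(sol$mu, 1 - 0.05 * pi^2, tolerance = 1e-10)
  expect_lt(ni_residual(sol, A1), 1e-10)
  expect_lt(ni_residual(sol, A2), 1e-10)
  # u(x, 0) is the dominant eigenfunction
  x <- seq(0, 1, 0.1)
  expect_equal(sol$u(x, 0), sin(pi * x), tolerance = 1e-10)
})

test_that("periodic mixed-mode construction solves both PDEs", {
  spp <- model_spec("periodic")
  A1 <- parameter_point(0.3, 0, 1)
  A2 <- indistinguishable_partners(A1, spp, n = 1)$partner(0.1)
  sol <- construct_nonidentifiable_solution(A1, A2, spp, gamma = c(1, 1))
  expect_lt(ni_residual(sol, A1), 1e-10)
  expect_lt(ni_residual(sol, A2), 1e-10)
  x <- seq(0, 2 * pi, length.out = 13)
  expect_equal(sol$u(x, 0), cos(x) + sin(x), tolerance = 1e-10)
})

test_that("construction fails off the indistinguishable set and for bad drift ratios", {
  sp <- unit_dirichlet()
  expect_error(construct_nonidentifiable_solution(parameter_point(1, 0, 1),
                                                  parameter_point(2, 0, 1), sp),
               "not in the indistinguishable set")
  # membership holds but the drift ratio is violated
  A1 <- parameter_point(1, 2, 0.5)
  aux_lam <- eigenpairs(0.5, 2, sp, 1)[[1]]$value
  A2bad <- parameter_point(0.5, 0, 0.5 - aux_lam)   # b2 = 0 breaks the ratio
  expect_true(in_set_A(auxiliary_point(A1, A2bad), sp)$member)
  expect_error(construct_nonidentifiable_solution(A1, A2bad, sp),
               "drift-ratio")
})

test_that("classification verdicts follow the three-way partition and are symmetric", {
  sp <- unit_dirichlet()
  A1 <- parameter_point(0.05, 0, 1)
  A2 <- indistinguishable_partners(A1, sp, n = 1)$partner_from_c(2)
  u0 <- function(x) sin(pi * x)
  expect_equal(classify(A1, A2, u0, sp)$verdict, "indistinguishable_ANI")
  expect_equal(classify(A2, A1, u0, sp)$verdict, "indistinguishable_ANI")
  expect_equal(classify(A1, A2, function(x) sin(2 * pi * x), sp)$verdict,
               "distinguishable_AI")
  expect_equal(classify(parameter_point(1, 0, 1), parameter_point(2, 0, 1),
                        u0, sp)$verdict, "distinguishable_R")
})

test_that("classify verdicts are cross-validated by forward-solve distances", {
  # seeded sweep across boundary conditions: indistinguishable pairs produce
  # identical trajectories, distinguishable ones separate by > 1e-3
  specs <- list(dirichlet = unit_dirichlet(),
                neumann = model_spec("neumann", length = 1),
                periodic = model_spec("periodic"))
  set.seed(42)
  grid_t <- seq(0, 2, 0.1)
  n_checked <- 0L
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    grid <- space_time_grid(seq(0, sp$length, length.out = 11), grid_t)
    n0 <- if (nm == "dirichlet") 1L else 0L
    for (rep in 1:4) {
      # moderate diffusivities/growth rates keep the perturbation mode
      # observable over the window
      d1 <- runif(1, 0.1, 0.8); c1 <- runif(1, 0, 1.2)
      A1 <- parameter_point(d1, 0, c1)
      fam <- indistinguishable_partners(A1, sp, n = n0)
      A2 <- fam$partner(runif(1, 0.1, 0.7) * d1)
      # compatible initial condition: the kernel eigenfunction itself
      # (coefficient 1 on the first mode: sin(pi x) or the constant)
      coeffs_ind <- c(1)
      u1 <- solve_linear_analytic(A1, coeffs_ind, sp, grid)
      u2 <- solve_linear_analytic(A2, coeffs_ind, sp, grid)
      cl <- classify(A1, A2,
                     if (n0 == 0L) 1 else function(x) sin(pi * x), sp)
      expect_equal(cl$verdict, "indistinguishable_ANI")
      expect_lt(solution_distance(u1, u2), 1e-6)
      # perturbing the initial condition by a second mode separates them
      coeffs_dis <- c(coeffs_ind, 0.3)
      v1 <- solve_linear_analytic(A1, coeffs_dis, sp, grid)
      v2 <- solve_linear_analytic(A2, coeffs_dis, sp, grid)
      expect_gt(solution_distance(v1, v2), 1e-3)
      n_checked <- n_checked + 1L
    }
    # a pair off the set is distinguishable from every initial condition
    for (rep in 1:3) {
      A1 <- parameter_point(runif(1, 0.1, 0.8), 0, runif(1, 0, 1))
      A2 <- parameter_point(A1$d + runif(1, 0.1, 0.6), 0, A1$c + runif(1, 0.05, 0.4))
      if (in_set_A(auxiliary_point(A1, A2), sp)$member) next
      cl <- classify(A1, A2, function(x) sin(pi * x / sp$length), sp)
      expect_equal(cl$verdict, "distinguishable_R")
      w1 <- solve_linear_analytic(A1, c(1, 0.3), sp, grid)
      w2 <- solve_linear_analytic(A2, c(1, 0.3), sp, grid)
      expect_gt(solution_distance(w1, w2), 1e-3)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 20L)
})

test_that("step-4 filter keeps only sign-definite kernel modes", {
  sp <- unit_dirichlet()
  A1 <- parameter_point(0.5, 0, 1)
  fams <- lapply(1:5, function(n) indistinguishable_partners(A1, sp, n = n))
  kept <- step4_filter(fams)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$n, 1L)
  spn <- model_spec("neumann", length = 1)
  famsn <- lapply(0:3, function(n) indistinguishable_partners(
    parameter_point(0.5, 0, 0), spn, n = n))
  keptn <- step4_filter(famsn)
  expect_length(keptn, 1L)
  expect_equal(keptn[[1]]$n, 0L)
  expect_length(step4_filter(list()), 0L)
})
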
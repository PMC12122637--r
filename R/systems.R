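# Two-species cell motility system: a continuum of parameter sets sharing a
# single non-identifiable trajectory, built from a scalar indistinguishable
# pair by direct substitution.

#' Construct a non-identifiable two-species parameter set
#'
#' From a scalar indistinguishable pair `(d1, c1) ~ (d2, c2)` (i.e.
#' `c1 - c2 = (d1 - d2) rho_n` for the chosen boundary condition and eigen
#' index), amplitudes `kappa_u, kappa_v > 0` and free constants
#' `delta1, delta2 > 0`, builds the cell motility system parameters
#' `d_u = d1, a11 = c1 + delta1, a12 = delta1 kappa_u / kappa_v,
#'  d_v = d2, a22 = c2 + delta2, a21 = delta2 kappa_v / kappa_u`
#' together with the closed-form trajectory
#' `(u, v) = (kappa_u u1, kappa_v u1)`, `u1(x,t) = exp((c1 - d1 rho_n) t)
#' phi_n(x)`, which solves both equations of the system exactly for every
#' admissible `(delta1, delta2)`.
#'
#' @param d1,c1,d2,c2 the scalar pair; must satisfy the indistinguishability
#'   constraint to tolerance.
#' @param spec a [model_spec()].
#' @param n eigen index of the scalar pair's kernel mode.
#' @param kappa_u,kappa_v positive amplitudes.
#' @param delta1,delta2 free constants, constrained to `delta_i > max(0, -c_i)`
#'   so that all reaction coefficients `a_ij` are positive.
#' @param tol tolerance on the scalar-pair constraint.
#' @return an object of class `"two_species_construction"`: `params` (named
#'   list `d_u, d_v, a11, a12, a21, a22`), `u`, `v` (functions of `(x, t)`),
#'   `mu` (shared temporal exponent), and `residual(x, t)` returning the
#'   maximum absolute PDE residual of both equations.
#' @examples
#' ts <- build_two_species(0.05 + 1 / pi^2, 2, 0.05, 1,
#'                         model_spec("dirichlet", length = 1))
#' ts$params$a11   # c1 + delta1 = 3
#' @export
build_two_species <- function(d1, c1, d2, c2, spec = model_spec(), n = 1,
                              kappa_u = 1, kappa_v = 1,
                              delta1 = 1, delta2 = 1, tol = 1e-8) {
  if (kappa_u <= 0 || kappa_v <= 0) stop_arg("amplitudes kappa must be positive")
  rho <- shape_eigenvalue(n, spec)
  gap <- (c1 - c2) - (d1 - d2) * rho
  if (abs(gap) > tol * max(1, abs(c1), abs(c2))) {
    stop_arg("scalar pair is not indistinguishable: c1 - c2 = (d1 - d2) * rho_n ",
             "fails by ", format(gap))
  }
  if (delta1 <= max(0, -c1) || delta2 <= max(0, -c2)) {
    stop_arg("delta_i must exceed max(0, -c_i) so that a11, a22 > 0")
  }
  params <- list(d_u = d1, d_v = d2,
                 a11 = c1 + delta1, a12 = delta1 * kappa_u / kappa_v,
                 a21 = delta2 * kappa_v / kappa_u, a22 = c2 + delta2)
  ep <- eigenpairs(1, 0, spec, n_max = n + 1L)
  idx <- which(vapply(ep, function(e) as.integer(e$n), integer(1)) == n)
  phi <- ep[[idx]]$fns[[1]]
  mu <- c1 - d1 * rho
  u1 <- function(x, t) {
    if (length(t) == 1L) exp(mu * t) * phi(x) else outer(phi(x), exp(mu * t))
  }
  u <- function(x, t) kappa_u * u1(x, t)
  v <- function(x, t) kappa_v * u1(x, t)
  residual <- function(x = seq(0, spec$length, length.out = 41L),
                       t = seq(0, 2, length.out = 11L)) {
    # u_t - d_u u_xx - (a11 u - a12 v); phi'' = -rho * phi for b = 0 modes
    phix <- phi(x); phixx <- eigen_deriv(phi, 2)(x)
    et <- exp(mu * t)
    ru <- kappa_u * outer(mu * phix - d1 * phixx, et) -
      outer((params$a11 * kappa_u - params$a12 * kappa_v) * phix, et)
    rv <- kappa_v * outer(mu * phix - d2 * phixx, et) -
      outer((-params$a21 * kappa_u + params$a22 * kappa_v) * phix, et)
    max(abs(ru), abs(rv))
  }
  structure(list(params = params, u = u, v = v, mu = mu, n = n, phi = phi,
                 inputs = list(d1 = d1, c1 = c1, d2 = d2, c2 = c2,
                               kappa_u = kappa_u, kappa_v = kappa_v,
                               delta1 = delta1, delta2 = delta2),
                 spec = spec, residual = residual),
            class = "two_species_construction")
}

#' @export
print.two_species_construction <- function(x, ...) {
  p <- x$params
  cat(sprintf("<two_species_construction> d_u=%g a11=%g a12=%g | d_v=%g a22=%g a21=%g\n",
              p$d_u, p$a11, p$a12, p$d_v, p$a22, p$a21))
  cat("  shared trajectory exponent mu =", x$mu, "\n")
  invisible(x)
}

#' Sweep the free constants of the two-species construction
#'
#' Rebuilds the system for every `(delta1, delta2)` pair in a grid and
#' verifies that all parameter sets are distinct while the trajectory
#' `(u, v)` is the same for each (the closed form does not involve the
#' deltas): evidence of a continuous spectrum of non-identifiable parameter
#' sets.
#'
#' @param d1,c1,d2,c2,spec,n,kappa_u,kappa_v as [build_two_species()].
#' @param delta1_grid,delta2_grid positive grids; the sweep runs over
#'   `delta1_grid` crossed with `delta2_grid` (at least 4 combinations).
#' @param x,t verification grid.
#' @return a list with `constructions`, `max_residual` (largest PDE residual
#'   across the sweep), `max_trajectory_gap` (largest sup-norm difference of
#'   `(u, v)` across delta pairs), and `params_distinct` (logical).
#' @export
family_sweep <- function(d1, c1, d2, c2, spec = model_spec(), n = 1,
                         kappa_u = 1, kappa_v = 1,
                         delta1_grid = c(0.5, 1, 2, 4), delta2_grid = 1,
                         x = seq(0, spec$length, length.out = 21L),
                         t = seq(0, 2, length.out = 11L)) {
  combos <- expand.grid(delta1 = delta1_grid, delta2 = delta2_grid)
  if (nrow(combos) < 4L) stop_arg("the delta grid must contain at least 4 combinations")
  if (any(unlist(combos) <= 0)) stop_arg("all deltas must be positive")
  cons <- lapply(seq_len(nrow(combos)), function(i) {
    build_two_species(d1, c1, d2, c2, spec, n, kappa_u, kappa_v,
                      combos$delta1[i], combos$delta2[i])
  })
  fields <- lapply(cons, function(cc) rbind(cc$u(x, t), cc$v(x, t)))
  gap <- 0
  for (i in seq_along(fields)[-1]) {
    gap <- max(gap, max(abs(fields[[i]] - fields[[1]])))
  }
  pm <- t(vapply(cons, function(cc) unlist(cc$params), numeric(6)))
  distinct <- nrow(unique(round(pm, 12))) == nrow(pm)
  list(constructions = cons,
       max_residual = max(vapply(cons, function(cc) cc$residual(x, t),
                                 numeric(1))),
       max_trajectory_gap = gap,
       params_distinct = distinct)
}
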
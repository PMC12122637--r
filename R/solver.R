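# Forward solvers: analytic eigen-expansion for the linear model and a
# method-of-lines finite-difference integrator (deSolve) for linear,
# logistic and two-species models.  Both return a "solution_field".

#' Space-time evaluation grid
#'
#' @param x strictly increasing spatial nodes.
#' @param t strictly increasing time nodes, starting at 0.
#' @return an object of class `"space_time_grid"`.
#' @examples
#' obs_grid()   # the default observation grid x = 0, 0.1, ..., 1; t = 0, ..., 2
#' @export
space_time_grid <- function(x, t) {
  if (any(diff(x) <= 0) || any(diff(t) <= 0)) {
    stop_arg("grid nodes must be strictly increasing")
  }
  if (t[1] != 0) stop_arg("time grid must include t = 0")
  structure(list(x = x, t = t), class = "space_time_grid")
}

#' @rdname space_time_grid
#' @export
obs_grid <- function() space_time_grid(seq(0, 1, by = 0.1), seq(0, 2, by = 0.1))

new_solution_field <- function(x, t, u, provenance, point = NULL) {
  structure(list(x = x, t = t, u = u, provenance = provenance, point = point),
            class = "solution_field")
}

#' @export
print.solution_field <- function(x, ...) {
  cat("<solution_field> ", length(x$x), " x nodes, ", length(x$t),
      " t nodes (", x$provenance, ")\n", sep = "")
  invisible(x)
}

#' Analytic eigen-expansion solution of the linear model
#'
#' Solves `u_t = d u_xx + b u_x + c u` with initial condition
#' `u0 = sum_j C_j phi_j` expanded in the eigenbasis of the operator:
#' `u(x, t) = sum_j C_j exp((c - lambda_j) t) phi_j(x)`, where `lambda_j` are
#' the eigenvalues of `-(d phi'' + b phi')`.  For the no-drift Dirichlet
#' problem on the unit interval this is
#' `sum_n C_n exp((c - d n^2 pi^2) t) sin(n pi x)`.  Coefficients are matched
#' to the eigenfunctions in ascending eigenvalue order, one coefficient per
#' eigenfunction (multiplicity-2 periodic modes consume two coefficients:
#' cosine then sine).
#'
#' @param A a [parameter_point()] with `d > 0`.
#' @param coeffs numeric vector of expansion coefficients.
#' @param spec a [model_spec()].
#' @param grid a [space_time_grid()].
#' @return a `"solution_field"` with `u` an `length(x) x length(t)` matrix.
#' @examples
#' sp <- model_spec("dirichlet", length = 1)
#' sol <- solve_linear_analytic(parameter_point(0.05, 0, 1), 1, sp, obs_grid())
#' @export
solve_linear_analytic <- function(A, coeffs, spec = model_spec(),
                                  grid = obs_grid()) {
  A <- as_parameter_point(A)
  if (A$d <= 0) stop_arg("analytic expansion requires d > 0")
  if (length(coeffs) < 1L) stop_arg("at least one expansion coefficient is required")
  ep <- eigenpairs(A$d, A$b, spec, n_max = length(coeffs))
  # flatten eigenfunctions in ascending eigenvalue order
  fns <- list(); lams <- numeric(0)
  for (e in ep) {
    for (f in e$fns) { fns[[length(fns) + 1L]] <- f; lams <- c(lams, e$value) }
  }
  n_use <- min(length(coeffs), length(fns))
  u <- matrix(0, length(grid$x), length(grid$t))
  for (j in seq_len(n_use)) {
    if (coeffs[j] == 0) next
    u <- u + coeffs[j] * outer(fns[[j]](grid$x), exp((A$c - lams[j]) * grid$t))
  }
  new_solution_field(grid$x, grid$t, u, "analytic", A)
}

# ---- method of lines ---------------------------------------------------------

# second-order central-difference RHS on a uniform grid, with the boundary
# condition imposed by elimination (Dirichlet), ghost nodes (Neumann/Robin:
# outward-normal convention u -/+ sigma u_x = 0), or wrap-around (periodic)
mol_rhs <- function(spec, h, pars) {
  boundary <- spec$boundary
  sig <- spec$robin_sigma
  pad <- function(y) {
    switch(boundary,
      dirichlet = c(0, y, 0),
      neumann = c(y[2], y, y[length(y) - 1L]),
      robin = c(y[2] - 2 * h * y[1] / sig,
                y, y[length(y) - 1L] - 2 * h * y[length(y)] / sig),
      # the grid includes both seam nodes x = 0 and x = L (the same torus
      # point), so the left neighbour of node 1 is node n - 1 and the right
      # neighbour of node n is node 2
      periodic = c(y[length(y) - 1L], y, y[2]))
  }
  function(t, y, parms) {
    yp <- pad(y)
    n <- length(y)
    i <- 2:(n + 1L)
    uxx <- (yp[i + 1L] - 2 * yp[i] + yp[i - 1L]) / h^2
    ux <- (yp[i + 1L] - yp[i - 1L]) / (2 * h)
    list(pars$reaction(t, y, uxx, ux))
  }
}

#' Method-of-lines forward solver
#'
#' Integrates the parabolic model with second-order central differences in
#' space and adaptive stiff time integration (`deSolve::ode`, lsoda).
#' Supported right-hand sides: `"linear"` (`d u_xx + b u_x + c u`),
#' `"logistic"` (`d u_xx + a u - b u^2`), `"hetero_logistic"`
#' (`d u_xx + m(x) u - b u^2`), and `"two_species"` (the linear cell motility
#' system; `u0` must then be a list of two initial conditions and the result
#' contains fields `u` and `v`).
#'
#' @param params named list of model parameters: `d`, `b`, `c` (linear);
#'   `d`, `a`, `b` (logistic); `d`, `m` (function of x), `b`
#'   (hetero_logistic); `d_u`, `d_v`, `a11`, `a12`, `a21`, `a22`
#'   (two_species).
#' @param reaction one of `"linear"`, `"logistic"`, `"hetero_logistic"`,
#'   `"two_species"`.
#' @param u0 initial condition (function, scalar, or `list(x, y)`); a list of
#'   two such for the two-species system.
#' @param spec a [model_spec()].
#' @param grid a [space_time_grid()] at which the solution is reported.
#' @param nx number of spatial nodes of the internal uniform grid.
#' @param rtol,atol integrator tolerances.
#' @return a `"solution_field"` (with an extra matrix `v` for two-species),
#'   values interpolated onto `grid$x`.
#' @export
solve_mol <- function(params, reaction = c("linear", "logistic",
                                           "hetero_logistic", "two_species"),
                      u0, spec = model_spec(), grid = obs_grid(),
                      nx = 201L, rtol = 1e-8, atol = 1e-10) {
  reaction <- match.arg(reaction)
  if (nx < 5L) stop_arg("'nx' must be at least 5")
  ell <- spec$length
  xs <- seq(0, ell, length.out = nx)
  h <- xs[2] - xs[1]
  two_species <- reaction == "two_species"

  if (two_species) {
    if (!is.list(u0) || length(u0) != 2L) {
      stop_arg("two-species solver expects u0 = list(u, v)")
    }
    u0u <- as_ic_function(u0[[1]], spec)(xs)
    u0v <- as_ic_function(u0[[2]], spec)(xs)
    if (spec$boundary == "dirichlet") { u0u[c(1, nx)] <- 0; u0v[c(1, nx)] <- 0 }
    rhs_u <- mol_rhs(spec, h, list(reaction = function(t, y, uxx, ux) uxx))
    state0 <- c(u0u, u0v)
    f <- function(t, y, parms) {
      u <- y[1:nx]; v <- y[(nx + 1L):(2L * nx)]
      lap_u <- rhs_u(t, u, NULL)[[1]]
      lap_v <- rhs_u(t, v, NULL)[[1]]
      du <- params$d_u * lap_u + params$a11 * u - params$a12 * v
      dv <- params$d_v * lap_v - params$a21 * u + params$a22 * v
      if (spec$boundary == "dirichlet") { du[c(1, nx)] <- 0; dv[c(1, nx)] <- 0 }
      list(c(du, dv))
    }
  } else {
    y0 <- as_ic_function(u0, spec)(xs)
    if (spec$boundary == "dirichlet") y0[c(1, nx)] <- 0
    reac <- switch(reaction,
      linear = function(t, y, uxx, ux) params$d * uxx +
        (params$b %||% 0) * ux + (params$c %||% 0) * y,
      logistic = function(t, y, uxx, ux) params$d * uxx +
        params$a * y - params$b * y^2,
      hetero_logistic = {
        mval <- params$m(xs)
        function(t, y, uxx, ux) params$d * uxx + mval * y - params$b * y^2
      })
    base_rhs <- mol_rhs(spec, h, list(reaction = reac))
    f <- function(t, y, parms) {
      dy <- base_rhs(t, y, parms)[[1]]
      if (spec$boundary == "dirichlet") dy[c(1, nx)] <- 0
      list(dy)
    }
    state0 <- y0
  }

  out <- deSolve::ode(y = state0, times = grid$t, func = f, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (max(abs(out[, -1]), na.rm = TRUE) > 1e8) {
    stop_arg("solution blow-up detected (sup |u| > 1e8); ",
             "check the growth rate and terminal time")
  }
  interp_to <- function(vals_xt) {
    # vals_xt: nt x nx matrix from deSolve; interpolate each time row to grid$x
    t(apply(vals_xt, 1L, function(row) {
      stats::spline(xs, row, xout = grid$x)$y
    }))
  }
  if (two_species) {
    umat <- t(interp_to(out[, 2:(nx + 1L), drop = FALSE]))
    vmat <- t(interp_to(out[, (nx + 2L):(2L * nx + 1L), drop = FALSE]))
    fld <- new_solution_field(grid$x, grid$t, umat, "numeric", params)
    fld$v <- vmat
    fld
  } else {
    umat <- t(interp_to(out[, -1, drop = FALSE]))
    new_solution_field(grid$x, grid$t, umat, "numeric", params)
  }
}

#' Sup-norm distance between two solution fields
#'
#' @param U1,U2 `"solution_field"`s on identical grids.
#' @return the maximum over the grid of `|U1 - U2|`.
#' @export
solution_distance <- function(U1, U2) {
  if (!isTRUE(all.equal(U1$x, U2$x)) || !isTRUE(all.equal(U1$t, U2$t))) {
    stop_arg("solution fields are on different grids")
  }
  max(abs(U1$u - U2$u))
}

#' Export a solution field as long-format CSV
#'
#' Columns `x, t, u` (and `v` for two-species fields).
#'
#' @param field a `"solution_field"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(field, path) {
  df <- data.frame(x = rep(field$x, times = length(field$t)),
                   t = rep(field$t, each = length(field$x)),
                   u = as.vector(field$u))
  if (!is.null(field$v)) df$v <- as.vector(field$v)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
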
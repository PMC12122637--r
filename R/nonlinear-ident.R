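# Nonlinear reactions (logistic type): the auxiliary elliptic problem
# -d psi'' = f(x, psi; B) obtained by differencing two parabolic equations,
# solved by shooting with multistart.  A unique (trivial-only) solution set
# certifies unconditional distinguishability; a discrete set still does; only
# a continuum would signal non-identifiability, and for logistic reactions it
# never occurs.

# integrate the elliptic IVP psi'' = -f(x, psi)/d from x = 0
elliptic_ivp <- function(d, freact, ell, psi0, dpsi0, nx = 201L) {
  xs <- seq(0, ell, length.out = nx)
  rhs <- function(x, y, parms) {
    list(c(y[2], -freact(x, y[1]) / d))
  }
  # terminal root stops diverging trajectories early instead of letting the
  # integrator grind against a blow-up
  out <- try(suppressWarnings(
    deSolve::ode(c(psi = psi0, dpsi = dpsi0), xs, rhs, NULL,
                 method = "lsodar", rtol = 1e-10, atol = 1e-12,
                 rootfun = function(x, y, parms) 1e5 - abs(y[1]))),
    silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < nx ||
      any(!is.finite(out[, 2])) || max(abs(out[, 2])) > 1e6) {
    return(NULL)
  }
  list(x = xs, psi = out[, 2], dpsi = out[, 3])
}

# end-point residual of the shooting problem for a given free start value s
shoot_residual <- function(s, d, freact, spec, nx = 201L) {
  sig <- spec$robin_sigma
  ell <- spec$length
  ini <- switch(spec$boundary,
                dirichlet = c(0, s),
                neumann = c(s, 0),
                robin = c(s, s / sig))   # u(0) - sigma u'(0) = 0
  sol <- elliptic_ivp(d, freact, ell, ini[1], ini[2], nx)
  if (is.null(sol)) return(list(res = NA_real_, sol = NULL))
  endv <- sol$psi[length(sol$psi)]
  endd <- sol$dpsi[length(sol$dpsi)]
  res <- switch(spec$boundary,
                dirichlet = endv,
                neumann = endd,
                robin = endv + sig * endd)
  list(res = res, sol = sol)
}

dedup_profiles <- function(profiles, tol = 1e-6) {
  kept <- list()
  for (p in profiles) {
    dup <- FALSE
    for (q in kept) {
      if (max(abs(p$psi - q$psi)) <= tol * max(1, max(abs(q$psi)))) {
        dup <- TRUE; break
      }
    }
    if (!dup) kept[[length(kept) + 1L]] <- p
  }
  kept
}

#' Solve the auxiliary elliptic problem of a nonlinear reaction
#'
#' Finds the solution set of `-d psi'' = f(x, psi; B)` under the boundary
#' condition in `spec`, with logistic reaction `f = a psi - b psi^2` (pass
#' `m` as a function for the heterogeneous variant `m(x) psi - b psi^2`).
#' For `d = 0` the problem is algebraic (`psi = 0` and, when `b != 0`, the
#' nonzero root `a / b`).  For `d > 0` a shooting method sweeps the free
#' endpoint value/slope over a signed log-spaced grid, refines sign changes
#' of the end-point residual, and de-duplicates profiles in sup norm.  The
#' solution-set size gives the classification: a single (trivial) solution
#' -> `"R"`, finitely many -> `"A_I"` (both imply distinguishability).
#'
#' @param d nonnegative auxiliary diffusivity.
#' @param a,b logistic reaction coefficients (`a` ignored if `m` given).
#' @param spec a [model_spec()] (Dirichlet, Neumann or Robin).
#' @param m optional function of `x`: spatially varying linear coefficient.
#' @param n_starts number of magnitudes in the multistart sweep (each used
#'   with both signs).
#' @param start_range range of start magnitudes (log-spaced).
#' @param dedup_tol sup-norm dedup tolerance.
#' @param nx nodes of the shooting integration grid.
#' @return an object of class `"elliptic_solution_set"`: list with
#'   `profiles` (each `list(x, psi)`), `count`, `classification`
#'   (`"R"`, `"A_I"`, or `"degenerate"` when the reaction vanishes).
#' @examples
#' # positive steady state exists iff a > d * pi^2 (Dirichlet, unit domain)
#' s <- solve_auxiliary_elliptic(1, a = 15, b = 1,
#'                               model_spec("dirichlet", length = 1))
#' s$count   # 2: the trivial branch and one positive profile
#' @export
solve_auxiliary_elliptic <- function(d, a = 0, b = 0, spec = model_spec(),
                                     m = NULL, n_starts = 20L,
                                     start_range = c(1e-3, 1e2),
                                     dedup_tol = 1e-6, nx = 201L) {
  if (spec$boundary == "periodic") {
    stop_arg("shooting solver covers Dirichlet/Neumann/Robin conditions")
  }
  hetero <- !is.null(m)
  freact <- if (hetero) function(x, u) m(x) * u - b * u^2
            else function(x, u) a * u - b * u^2
  ell <- spec$length
  xs <- seq(0, ell, length.out = nx)

  if (!hetero && a == 0 && b == 0) {
    return(structure(list(profiles = list(list(x = xs, psi = rep(0, nx))),
                          count = 1L, classification = "degenerate"),
                     class = "elliptic_solution_set"))
  }

  if (d == 0) {
    profiles <- list(list(x = xs, psi = rep(0, nx)))
    if (b != 0) {
      root <- if (hetero) m(xs) / b else rep(a / b, nx)
      if (!hetero || max(abs(root - root[1])) < 1e-12) {
        # constant nonzero branch (the heterogeneous root must satisfy the
        # boundary condition, which a genuinely varying m(x)/b cannot)
        if (max(abs(root)) > 0) {
          profiles[[2]] <- list(x = xs, psi = root)
        }
      }
    }
    profiles <- dedup_profiles(profiles, dedup_tol)
    cls <- if (length(profiles) == 1L) "R" else "A_I"
    return(structure(list(profiles = profiles, count = length(profiles),
                          classification = cls),
                     class = "elliptic_solution_set"))
  }

  mags <- logspace(start_range[1], start_range[2], n_starts)
  starts <- c(-rev(mags), mags)
  resv <- vapply(starts, function(s) shoot_residual(s, d, freact, spec, nx)$res,
                 numeric(1))
  profiles <- list(list(x = xs, psi = rep(0, nx)))   # trivial branch
  for (i in seq_len(length(starts) - 1L)) {
    r1 <- resv[i]; r2 <- resv[i + 1L]
    if (!is.finite(r1) || !is.finite(r2)) next
    if (sign(starts[i]) != sign(starts[i + 1L])) next  # zero sits between signs
    if (r1 == 0 || r1 * r2 < 0) {
      root <- tryCatch(
        stats::uniroot(function(s) shoot_residual(s, d, freact, spec, nx)$res,
                       c(starts[i], starts[i + 1L]), tol = 1e-12)$root,
        error = function(e) NA_real_)
      if (!is.finite(root)) next
      sol <- shoot_residual(root, d, freact, spec, nx)$sol
      if (!is.null(sol)) {
        profiles[[length(profiles) + 1L]] <- list(x = sol$x, psi = sol$psi)
      }
    }
  }
  profiles <- dedup_profiles(profiles, dedup_tol)
  cls <- if (length(profiles) == 1L) "R" else "A_I"
  structure(list(profiles = profiles, count = length(profiles),
                 classification = cls),
            class = "elliptic_solution_set")
}

#' @export
print.elliptic_solution_set <- function(x, ...) {
  cat("<elliptic_solution_set>", x$count, "solution(s), classification",
      x$classification, "\n")
  invisible(x)
}

# sup of |du/dt| over the grid of a forward solve (temporal-variation check)
max_time_variation <- function(field) {
  dt <- diff(field$t)
  du <- abs(field$u[, -1, drop = FALSE] - field$u[, -ncol(field$u), drop = FALSE])
  max(sweep(du, 2L, dt, `/`))
}

#' Classify a pair of nonlinear (logistic) parameter points
#'
#' Differences the two parameter points (roles swapped so the auxiliary
#' diffusivity is nonnegative), solves the auxiliary elliptic problem, and
#' declares the pair distinguishable whenever the solution set is discrete —
#' which for logistic reactions is always the case, so the model is globally
#' unconditionally identifiable provided the observed solution actually
#' varies in time.  Steady-state data (`u_t` identically zero) make the
#' argument inapplicable and yield the verdict `"inconclusive-steady"`.
#'
#' @param p1,p2 named lists `list(d, a, b)` of logistic model parameters.
#' @param spec a [model_spec()].
#' @param u0 initial condition used for the temporal-variation check.
#' @param grid a [space_time_grid()] for the check.
#' @param ut_tol threshold on `sup |du/dt|` below which the data count as
#'   steady.
#' @return a list with `verdict` (`"distinguishable"` or
#'   `"inconclusive-steady"`), `auxiliary` (the differenced parameters) and
#'   `evidence` (the `"elliptic_solution_set"`).
#' @export
classify_nonlinear_pair <- function(p1, p2, spec = model_spec(), u0,
                                    grid = space_time_grid(seq(0, 1, 0.1),
                                                           seq(0, 1, 0.25)),
                                    ut_tol = 1e-8) {
  if (p2$d > p1$d) { tmp <- p1; p1 <- p2; p2 <- tmp }
  aux <- list(d = p1$d - p2$d, a = p1$a - p2$a, b = p1$b - p2$b)
  fwd <- solve_mol(list(d = p1$d, a = p1$a, b = p1$b), "logistic", u0,
                   spec, grid)
  if (max_time_variation(fwd) <= ut_tol) {
    return(list(verdict = "inconclusive-steady", auxiliary = aux,
                evidence = NULL))
  }
  ev <- solve_auxiliary_elliptic(aux$d, aux$a, aux$b, spec)
  verdict <- if (ev$classification %in% c("R", "A_I")) "distinguishable"
             else "indeterminate"
  list(verdict = verdict, auxiliary = aux, evidence = ev)
}

#' Identifiability check for the heterogeneous logistic model
#'
#' For the Neumann problem with reaction `m(x) u - b u^2`, differences the
#' two parameter sets and inspects the auxiliary elliptic solution set.  A
#' constant difference `m` reduces to the homogeneous logistic algebra (the
#' nonzero root of `m psi - b psi^2` is `m / b`); a genuinely varying `m`
#' admits at most one positive profile, found by multistart shooting.
#'
#' @param m1,m2 functions of `x`: the two spatial linear coefficients.
#' @param b1,b2 quadratic coefficients.
#' @param d1,d2 diffusivities.
#' @param spec a [model_spec()] (Neumann).
#' @return as [classify_nonlinear_pair()]: `verdict`, `auxiliary`,
#'   `evidence`.
#' @export
heterogeneous_logistic_check <- function(m1, b1, m2, b2, d1, d2,
                                         spec = model_spec("neumann")) {
  if (d2 > d1) {
    tmp <- m1; m1 <- m2; m2 <- tmp
    tmpb <- b1; b1 <- b2; b2 <- tmpb
    tmpd <- d1; d1 <- d2; d2 <- tmpd
  }
  d <- d1 - d2; b <- b1 - b2
  mdiff <- function(x) m1(x) - m2(x)
  xs <- seq(0, spec$length, length.out = 201L)
  mv <- mdiff(xs)
  m_const <- max(abs(mv - mv[1])) < 1e-12
  if (m_const && abs(mv[1]) < 1e-12 && abs(b) < 1e-12) {
    return(list(verdict = "degenerate",
                auxiliary = list(d = d, m = mdiff, b = b),
                evidence = NULL))
  }
  ev <- if (m_const) {
    solve_auxiliary_elliptic(d, a = mv[1], b = b, spec)
  } else {
    solve_auxiliary_elliptic(d, b = b, spec = spec, m = mdiff)
  }
  verdict <- if (ev$classification %in% c("R", "A_I")) "distinguishable"
             else "indeterminate"
  list(verdict = verdict, auxiliary = list(d = d, m = mdiff, b = b),
       evidence = ev)
}
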
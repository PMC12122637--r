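# Steps 1-4 of the auxiliary-elliptic-operator procedure for the linear
# homogeneous parabolic model u_t = d u_xx + b u_x + c u:
# form the auxiliary parameter point, test membership of the
# indistinguishable set, enumerate indistinguishable partner families, test
# kernel membership of initial conditions, construct explicit
# non-identifiable solutions, and classify parameter pairs.

points_equal <- function(A1, A2) {
  isTRUE(all.equal(c(A1$d, A1$b, A1$c), c(A2$d, A2$b, A2$c), tolerance = 0))
}

#' Auxiliary parameter point A = A1 - A2
#'
#' Forms the componentwise difference of two parameter points after swapping
#' roles, if necessary, so that the auxiliary diffusivity is nonnegative
#' (without loss of generality the point with the larger diffusivity comes
#' first).
#'
#' @param A1,A2 [parameter_point()]s (or numeric `(d, b, c)` triples).
#' @return an object of class `"auxiliary_point"` with fields `d`, `b`, `c`
#'   and `swapped` (whether the roles of `A1` and `A2` were exchanged).
#' @examples
#' auxiliary_point(parameter_point(2, 1, 3), parameter_point(1, 1, 3))
#' @export
auxiliary_point <- function(A1, A2) {
  A1 <- as_parameter_point(A1); A2 <- as_parameter_point(A2)
  if (points_equal(A1, A2)) stop_arg("points must be distinct")
  swapped <- A2$d > A1$d
  if (swapped) { tmp <- A1; A1 <- A2; A2 <- tmp }
  structure(list(d = A1$d - A2$d, b = A1$b - A2$b, c = A1$c - A2$c,
                 swapped = swapped),
            class = c("auxiliary_point", "parameter_point"))
}

#' Membership in the indistinguishable parameter set
#'
#' Tests whether an auxiliary point `A = (d, b, c)` belongs to the set of
#' parameter differences for which the operator `L[A]` has a nontrivial
#' kernel (equivalently, `c` is an eigenvalue of the auxiliary eigenproblem),
#' returning the matched eigen index for downstream construction.  Degenerate
#' `d = 0` points are routed through [degenerate_kernel()].
#'
#' @param A an [auxiliary_point()] (or `(d, b, c)` triple with `d >= 0`).
#' @param spec a [model_spec()].
#' @param tol relative eigenvalue-match tolerance.
#' @return a list with `member` (logical), `index` (matched eigen index, `NA`
#'   for degenerate modes), `multiplicity`, and `mode` (`"eigen"`,
#'   `"constant"`, `"robin_exponential"`, ...).
#' @examples
#' A <- auxiliary_point(parameter_point(0.05 + 1 / pi^2, 0, 2),
#'                      parameter_point(0.05, 0, 1))
#' in_set_A(A, model_spec("dirichlet", length = 1))
#' @export
in_set_A <- function(A, spec = model_spec(), tol = 1e-8) {
  A <- as_parameter_point(A)
  kb <- kernel_basis(A$d, A$b, A$c, spec, tol)
  member <- length(kb$fns) > 0L || isTRUE(kb$infinite_dimensional)
  list(member = member, index = kb$index,
       multiplicity = if (isTRUE(kb$infinite_dimensional)) Inf else length(kb$fns),
       mode = kb$mode)
}

# unit-diffusivity ("shape") eigenvalue rho_n with lambda_n(d, 0) = d * rho_n;
# homogeneity in d holds for every no-drift boundary condition
shape_eigenvalue <- function(n, spec) {
  if (n == 0L) {
    if (!spec$boundary %in% c("neumann", "periodic")) {
      stop_arg("eigen index 0 (constant mode) exists only for Neumann/periodic")
    }
    return(0)
  }
  ep <- eigenpairs(1, 0, spec, n_max = n + 1L)
  idx <- vapply(ep, function(e) as.integer(e$n), integer(1))
  hit <- which(idx == n)
  if (!length(hit)) stop_arg("eigen index ", n, " not found")
  ep[[hit]]$value
}

#' Family of parameter points indistinguishable from a base point
#'
#' Parametrizes the set of partner points `A2` whose difference from the base
#' point `A1` lies in the indistinguishable set for a chosen eigen index `n`:
#' `c1 - c2 = lambda_n(d1 - d2, b1 - b2)` with, in the drifted case, the
#' additional ratio constraint `b1 / b2 = d1 / d2`.  For the Neumann and
#' periodic conditions `n = 0` selects the constant-mode family (`c2 = c1`
#' and arbitrary `(d2, b2)`; valid only for spatially constant initial data).
#'
#' @param A1 the base [parameter_point()].
#' @param spec a [model_spec()].
#' @param n eigen index of the family (1, 2, ... ; 0 for the constant mode).
#' @param drift request the drifted family; requires `b1 != 0` (a drifted
#'   partner of a drift-free base point would need drifts of opposite
#'   presence, which the ratio constraint forbids).
#' @return an object of class `"indist_family"` with closures
#'   `partner(d2)` and (no-drift families) `partner_from_c(c2)` producing
#'   partner [parameter_point()]s, a seeded `sample(k, seed)` helper, the
#'   classification tag `"A_NI"`, and the Step-4 `nonnegative_compatible`
#'   flag (TRUE only when the family's eigenfunction has no sign change).
#' @examples
#' fam <- indistinguishable_partners(parameter_point(0.05, 0, 1),
#'                                   model_spec("dirichlet", length = 1), n = 1)
#' fam$partner_from_c(2)   # d2 = 0.05 + 1/pi^2
#' @export
indistinguishable_partners <- function(A1, spec = model_spec(), n = 1,
                                       drift = !identical(A1$b, 0)) {
  A1 <- as_parameter_point(A1)
  n <- as.integer(n)
  if (drift && A1$b == 0) {
    stop_arg("drift family with b1 = 0 is empty: the sign of b1 and b2 must be the same")
  }
  mode <- if (n == 0L) "constant" else if (drift) "drift" else "no_drift"
  rho <- if (mode == "constant") 0 else shape_eigenvalue(n, spec)

  partner <- function(d2, b2 = NULL, c2 = NULL) {
    if (d2 < 0) stop_arg("partner diffusivity must be nonnegative")
    switch(mode,
      constant = parameter_point(d2, b2 %||% A1$b, A1$c),
      no_drift = parameter_point(d2, A1$b, A1$c - (A1$d - d2) * rho),
      drift = {
        b2 <- A1$b * d2 / A1$d       # ratio constraint d1/d2 = b1/b2
        dA <- abs(A1$d - d2); bA <- abs(A1$b - b2)
        lamA <- if (dA == 0) 0 else bA^2 / (4 * dA) + dA * rho
        c2 <- if (d2 <= A1$d) A1$c - lamA else A1$c + lamA
        parameter_point(d2, b2, c2)
      })
  }
  partner_from_c <- function(c2) {
    if (mode != "no_drift") {
      stop_arg("partner_from_c() is available for no-drift eigen families only")
    }
    d2 <- A1$d + (c2 - A1$c) / rho
    if (d2 < 0) stop_arg("requested c2 gives a negative partner diffusivity")
    parameter_point(d2, A1$b, c2)
  }
  sample_fun <- function(k = 5, seed = 1) {
    set.seed(seed)
    # log-spaced partner diffusivities below the base point, mild jitter
    d2 <- A1$d * exp(-logspace(0.1, 1.5, k) * stats::runif(k, 0.9, 1.1))
    lapply(d2, partner)
  }
  nonneg <- (n == 1L && spec$boundary %in% c("dirichlet", "robin")) ||
    (n == 0L && spec$boundary %in% c("neumann", "periodic"))
  structure(list(base = A1, n = n, mode = mode, rho = rho, spec = spec,
                 classification = "A_NI", nonnegative_compatible = nonneg,
                 partner = partner, partner_from_c = partner_from_c,
                 sample = sample_fun),
            class = "indist_family")
}

#' @export
print.indist_family <- function(x, ...) {
  cat("<indist_family> ", x$spec$boundary, ", mode ", x$mode,
      ", eigen index ", x$n, "\n", sep = "")
  cat("  base point: d =", x$base$d, " b =", x$base$b, " c =", x$base$c, "\n")
  cat("  classification:", x$classification,
      "| nonnegative-compatible:", x$nonnegative_compatible, "\n")
  invisible(x)
}

#' Step-4 filter: nonnegativity-compatible families
#'
#' Keeps only the families whose kernel eigenfunction has no sign change
#' (Dirichlet/Robin lowest mode, Neumann/periodic constant mode), i.e. those
#' compatible with a nonnegative measured quantity.
#'
#' @param families a list of [indistinguishable_partners()] objects.
#' @return the filtered list.
#' @export
step4_filter <- function(families) {
  Filter(function(f) isTRUE(f$nonnegative_compatible), families)
}

# ---- kernel membership of an initial condition -------------------------------

as_ic_function <- function(u0, spec) {
  if (is.function(u0)) return(u0)
  if (is.list(u0) && !is.null(u0$x) && !is.null(u0$y)) {
    return(stats::splinefun(u0$x, u0$y))
  }
  if (is.numeric(u0) && length(u0) == 1L) {
    v <- u0
    return(function(x) rep(v, length(x)))
  }
  stop_arg("initial condition must be a function, a scalar, or a list(x, y) grid")
}

# weighted L2 projection of u0 onto an orthogonal basis; Simpson quadrature
kernel_projection <- function(u0f, fns, weightf, ell, n_grid = 2001L) {
  xs <- seq(0, ell, length.out = n_grid)
  h <- xs[2] - xs[1]
  w <- weightf(xs)
  u <- u0f(xs)
  coeffs <- vapply(fns, function(phi) {
    pv <- phi(xs)
    simpson(u * pv * w, h) / simpson(pv * pv * w, h)
  }, numeric(1))
  proj <- Reduce(`+`, Map(function(phi, cf) cf * phi(xs), fns, coeffs),
                 accumulate = FALSE)
  num <- simpson((u - proj)^2 * w, h)
  den <- simpson(u^2 * w, h)
  if (den == 0) stop_arg("initial condition must not be identically zero")
  list(coeffs = coeffs, rel_residual = sqrt(num / den))
}

#' Kernel membership of an initial condition
#'
#' Projects `u0` onto the kernel of `L[A]` (the eigenspace of the matched
#' eigenvalue of the auxiliary operator) using the weighted inner product
#' with weight `exp(b x / d)` that symmetrizes the drifted operator, and
#' reports whether the relative residual of `u0` minus its projection is
#' within tolerance.
#'
#' @param u0 initial condition: a function, a scalar (constant), or a
#'   `list(x, y)` grid.
#' @param A an [auxiliary_point()] (or `(d, b, c)` triple).
#' @param spec a [model_spec()].
#' @param tol relative residual tolerance.
#' @return `TRUE`/`FALSE`, with attributes `rel_residual` and `coeffs`.
#' @examples
#' A <- c(1 / pi^2, 0, 1)
#' is_in_kernel(function(x) sin(pi * x), A, model_spec("dirichlet", length = 1))
#' @export
is_in_kernel <- function(u0, A, spec = model_spec(), tol = 1e-6) {
  A <- as_parameter_point(A)
  u0f <- as_ic_function(u0, spec)
  kb <- kernel_basis(A$d, A$b, A$c, spec)
  if (isTRUE(kb$infinite_dimensional)) {
    # zero operator: the kernel is every boundary-compatible function
    ok <- switch(spec$boundary,
                 dirichlet = abs(u0f(0)) <= tol && abs(u0f(spec$length)) <= tol,
                 TRUE)
    return(structure(ok, rel_residual = 0, coeffs = numeric(0)))
  }
  if (!length(kb$fns)) {
    return(structure(FALSE, rel_residual = 1, coeffs = numeric(0)))
  }
  weightf <- if (A$d > 0 && A$b != 0) {
    (function(b, d) function(x) exp(b * x / d))(A$b, A$d)
  } else {
    function(x) rep(1, length(x))
  }
  pr <- kernel_projection(u0f, kb$fns, weightf, spec$length)
  structure(pr$rel_residual <= tol,
            rel_residual = pr$rel_residual, coeffs = pr$coeffs)
}

# ---- explicit non-identifiable solutions -------------------------------------

# the pointwise ratio L[A]Phi / Phi; constant iff Phi is an eigenfunction of
# L[A], in which case the constant is the separation-of-variables exponent
operator_ratio <- function(A, Phi, dPhi, d2Phi, ell) {
  xs <- seq(0.05 * ell, 0.95 * ell, length.out = 101L)
  f <- Phi(xs)
  keep <- abs(f) > 0.2 * max(abs(f))
  r <- (A$d * d2Phi(xs[keep]) + A$b * dPhi(xs[keep]) + A$c * f[keep]) / f[keep]
  list(mu = stats::median(r), spread = max(r) - min(r))
}

#' Construct an explicit non-identifiable solution
#'
#' For a pair of parameter points whose difference lies in the
#' indistinguishable set, builds the closed-form separated solution
#' `u(x, t) = c0 * exp(mu t) * Phi(x)` (with `Phi` in the kernel of the
#' auxiliary operator) that solves the parabolic model under *both*
#' parameter points simultaneously: `mu = c1 - d1 * rho_n` in the no-drift
#' case, with the drifted analogue requiring the ratio constraint
#' `b1 / b2 = d1 / d2`.  The exponent is obtained as the (necessarily
#' constant) pointwise ratio `L[A1] Phi / Phi` from analytic derivatives, and
#' cross-checked against `A2`; a non-constant ratio raises a construction
#' error.
#'
#' @param A1,A2 the two [parameter_point()]s.
#' @param spec a [model_spec()].
#' @param c0 overall amplitude.
#' @param gamma coefficients over the kernel basis (length = multiplicity;
#'   relevant for the periodic condition where the multiplicity is 2).
#' @param tol tolerance on the constancy of the exponent.
#' @return an object of class `"ni_solution"`: fields `u` (a function of
#'   `(x, t)`), `mu`, `Phi` (+ derivatives), `index`, `A1`, `A2`.
#' @examples
#' sp <- model_spec("dirichlet", length = 1)
#' sol <- construct_nonidentifiable_solution(parameter_point(0.05, 0, 1),
#'          parameter_point(0.05 + 1 / pi^2, 0, 2), sp)
#' sol$mu   # 1 - 0.05 * pi^2
#' @export
construct_nonidentifiable_solution <- function(A1, A2, spec = model_spec(),
                                               c0 = 1, gamma = NULL,
                                               tol = 1e-8) {
  A1 <- as_parameter_point(A1); A2 <- as_parameter_point(A2)
  A <- auxiliary_point(A1, A2)
  kb <- kernel_basis(A$d, A$b, A$c, spec)
  if (isTRUE(kb$infinite_dimensional) || !length(kb$fns)) {
    stop_arg("auxiliary point (d=", format(A$d), ", b=", format(A$b),
             ", c=", format(A$c), ") is not in the indistinguishable set; ",
             "no non-identifiable solution exists")
  }
  m <- length(kb$fns)
  if (is.null(gamma)) gamma <- rep(1, m)
  if (length(gamma) != m) stop_arg("'gamma' must have length ", m)
  fns <- kb$fns
  Phi <- function(x) Reduce(`+`, Map(function(p, g) g * p(x), fns, gamma))
  dPhi <- function(x) Reduce(`+`, Map(function(p, g) g * eigen_deriv(p, 1)(x),
                                      fns, gamma))
  d2Phi <- function(x) Reduce(`+`, Map(function(p, g) g * eigen_deriv(p, 2)(x),
                                       fns, gamma))
  r1 <- operator_ratio(A1, Phi, dPhi, d2Phi, spec$length)
  r2 <- operator_ratio(A2, Phi, dPhi, d2Phi, spec$length)
  scale <- max(1, abs(r1$mu), abs(r2$mu))
  if (r1$spread > tol * scale || r2$spread > tol * scale ||
      abs(r1$mu - r2$mu) > tol * scale) {
    stop_arg("kernel eigenfunction is not a simultaneous eigenfunction of ",
             "both operators; the drift-ratio constraint d1/d2 = b1/b2 ",
             "must hold for drifted non-identifiable solutions")
  }
  mu <- r1$mu
  u <- function(x, t) {
    if (length(t) == 1L) c0 * exp(mu * t) * Phi(x)
    else c0 * outer(Phi(x), exp(mu * t))
  }
  structure(list(u = u, mu = mu, Phi = Phi, dPhi = dPhi, d2Phi = d2Phi,
                 gamma = gamma, c0 = c0, index = kb$index, mode = kb$mode,
                 A1 = A1, A2 = A2, spec = spec),
            class = "ni_solution")
}

#' @export
print.ni_solution <- function(x, ...) {
  cat(sprintf("<ni_solution> u(x,t) = %g * exp(%.8g t) * Phi(x), eigen index %s\n",
              x$c0, x$mu, format(x$index)))
  invisible(x)
}

#' PDE residual of a constructed solution
#'
#' Evaluates `u_t - L[A] u` for a [construct_nonidentifiable_solution()]
#' object on a spacetime grid using the analytic derivatives of the kernel
#' eigenfunction, and returns the maximum absolute residual.
#'
#' @param sol an `"ni_solution"` object.
#' @param A a [parameter_point()] (typically `sol$A1` or `sol$A2`).
#' @param x,t evaluation grids.
#' @return maximum absolute residual over the grid.
#' @export
ni_residual <- function(sol, A, x = NULL, t = seq(0, 2, length.out = 21)) {
  A <- as_parameter_point(A)
  if (is.null(x)) x <- seq(0, sol$spec$length, length.out = 41L)
  spatial <- sol$mu * sol$Phi(x) -
    (A$d * sol$d2Phi(x) + A$b * sol$dPhi(x) + A$c * sol$Phi(x))
  max(abs(sol$c0 * outer(spatial, exp(sol$mu * t))))
}

# ---- classification ----------------------------------------------------------

#' Classify a pair of parameter points
#'
#' Applies the full procedure to a pair `(A1, A2)` and an initial condition:
#' the pair is unconditionally distinguishable if the auxiliary point lies
#' outside the indistinguishable set (`"distinguishable_R"`); distinguishable
#' from this particular `u0` if the auxiliary point is in the set but `u0` is
#' not in the kernel, or the drift-ratio constraint fails
#' (`"distinguishable_AI"`); and genuinely indistinguishable otherwise
#' (`"indistinguishable_ANI"`), in which case the explicit shared solution is
#' returned as a witness.  The classification is symmetric in `(A1, A2)`.
#'
#' @param A1,A2 the two [parameter_point()]s (must be distinct).
#' @param u0 the initial condition (function, scalar, or `list(x, y)`).
#' @param spec a [model_spec()].
#' @param tol kernel-membership tolerance.
#' @return an object of class `"ident_classification"` with fields `verdict`,
#'   `auxiliary`, `membership` and `witness` (the `"ni_solution"` for the
#'   indistinguishable verdict; kernel information otherwise).
#' @examples
#' sp <- model_spec("dirichlet", length = 1)
#' classify(parameter_point(0.05, 0, 1),
#'          parameter_point(0.05 + 1 / pi^2, 0, 2),
#'          function(x) sin(pi * x), sp)$verdict
#' @export
classify <- function(A1, A2, u0, spec = model_spec(), tol = 1e-6) {
  A1 <- as_parameter_point(A1); A2 <- as_parameter_point(A2)
  A <- auxiliary_point(A1, A2)
  membership <- in_set_A(A, spec)
  res <- function(verdict, witness) {
    structure(list(verdict = verdict, auxiliary = A, membership = membership,
                   witness = witness),
              class = "ident_classification")
  }
  if (!membership$member) return(res("distinguishable_R", NULL))
  ker <- is_in_kernel(u0, A, spec, tol)
  if (!ker) {
    return(res("distinguishable_AI",
               list(kernel_residual = attr(ker, "rel_residual"),
                    index = membership$index)))
  }
  gamma <- attr(ker, "coeffs")
  if (!length(gamma)) gamma <- NULL
  sol <- tryCatch(
    construct_nonidentifiable_solution(A1, A2, spec, gamma = gamma),
    error = function(e) NULL)
  if (is.null(sol)) {
    return(res("distinguishable_AI",
               list(reason = "drift-ratio constraint violated",
                    index = membership$index)))
  }
  res("indistinguishable_ANI", sol)
}

#' @export
print.ident_classification <- function(x, ...) {
  cat("<classification>", x$verdict, "\n")
  cat("  auxiliary point: d =", x$auxiliary$d, " b =", x$auxiliary$b,
      " c =", x$auxiliary$c, "\n")
  if (!is.null(x$membership$index) && !is.na(x$membership$index)) {
    cat("  matched eigen index:", x$membership$index, "\n")
  }
  invisible(x)
}
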
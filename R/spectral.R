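# Spectrum of the auxiliary elliptic operator -L1[A] = -(d u'' + b u') on an
# interval (0, l) or a torus, under Dirichlet / Neumann / Robin / periodic
# boundary conditions.  Eigenfunctions are sup-normalized and carry their
# first and second derivatives as attributes so that operator residuals can
# be evaluated to machine precision.

# ---- eigenfunction factories -------------------------------------------------

new_eigenfunction <- function(f, df, d2f, label = "") {
  attr(f, "df") <- df
  attr(f, "d2f") <- d2f
  attr(f, "label") <- label
  class(f) <- c("eigenfunction", "function")
  f
}

#' Derivative of an eigenfunction
#'
#' @param phi an eigenfunction as returned inside [eigenpairs()].
#' @param order 0, 1 or 2.
#' @return a function of `x`.
#' @export
eigen_deriv <- function(phi, order = 1) {
  switch(as.character(order),
         "0" = phi,
         "1" = attr(phi, "df"),
         "2" = attr(phi, "d2f"),
         stop_arg("derivative order must be 0, 1 or 2"))
}

# sup-norm of |f| on [0, ell], grid scan refined by optimize()
sup_norm <- function(f, ell) {
  xs <- seq(0, ell, length.out = 2001L)
  v <- abs(f(xs))
  i <- which.max(v)
  lo <- xs[max(1L, i - 1L)]
  hi <- xs[min(length(xs), i + 1L)]
  opt <- stats::optimize(function(x) abs(f(x)), c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  max(v[i], opt$objective)
}

# phi = e^{-beta x} (P cos(k x) + Q sin(k x)) / s, with analytic derivatives
make_trig_fun <- function(beta, k, P, Q, ell, label = "") {
  s <- 1
  base <- function(x) exp(-beta * x) * (P * cos(k * x) + Q * sin(k * x))
  if (beta == 0 && (P == 0 || Q == 0)) {
    s <- max(abs(P), abs(Q))          # pure sine / cosine: sup is exact
  } else {
    s <- sup_norm(base, ell)
  }
  P <- P / s; Q <- Q / s
  f <- function(x) exp(-beta * x) * (P * cos(k * x) + Q * sin(k * x))
  df <- function(x) exp(-beta * x) *
    ((-beta * P + k * Q) * cos(k * x) + (-beta * Q - k * P) * sin(k * x))
  d2f <- function(x) exp(-beta * x) *
    (((beta^2 - k^2) * P - 2 * beta * k * Q) * cos(k * x) +
     ((beta^2 - k^2) * Q + 2 * beta * k * P) * sin(k * x))
  new_eigenfunction(f, df, d2f, label)
}

# phi = e^{-beta x} (P cosh(kap x) + Q sinh(kap x)) / s
make_hyp_fun <- function(beta, kap, P, Q, ell, label = "") {
  base <- function(x) exp(-beta * x) * (P * cosh(kap * x) + Q * sinh(kap * x))
  s <- sup_norm(base, ell)
  P <- P / s; Q <- Q / s
  f <- function(x) exp(-beta * x) * (P * cosh(kap * x) + Q * sinh(kap * x))
  df <- function(x) exp(-beta * x) *
    ((-beta * P + kap * Q) * cosh(kap * x) + (-beta * Q + kap * P) * sinh(kap * x))
  d2f <- function(x) exp(-beta * x) *
    (((beta^2 + kap^2) * P - 2 * beta * kap * Q) * cosh(kap * x) +
     ((beta^2 + kap^2) * Q - 2 * beta * kap * P) * sinh(kap * x))
  new_eigenfunction(f, df, d2f, label)
}

make_const_fun <- function(label = "constant") {
  new_eigenfunction(function(x) rep(1, length(x)),
                    function(x) rep(0, length(x)),
                    function(x) rep(0, length(x)), label)
}

new_eigenpair <- function(n, value, fns) {
  structure(list(n = n, value = value, multiplicity = length(fns), fns = fns),
            class = "eigenpair")
}

# ---- Robin characteristic equation ------------------------------------------

# Characteristic determinant of the Robin problem on the oscillatory branch
# lambda = b^2/(4 d) + d k^2 (common positive factor e^{-beta l} dropped).
robin_char_trig <- function(k, beta, sig, ell) {
  (1 - sig^2 * beta^2 - sig^2 * k^2) * sin(k * ell) +
    2 * sig * k * cos(k * ell)
}

# hyperbolic branch lambda = b^2/(4 d) - d kap^2
robin_char_hyp <- function(kap, beta, sig, ell) {
  (1 - sig^2 * beta^2 + sig^2 * kap^2) * sinh(kap * ell) +
    2 * sig * kap * cosh(kap * ell)
}

# scan g on (lo, hi] for sign changes and refine each bracket with uniroot
scan_roots <- function(g, lo, hi, n_scan) {
  xs <- seq(lo, hi, length.out = n_scan)
  gv <- vapply(xs, g, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(length(xs) - 1L)) {
    a <- gv[i]; b <- gv[i + 1L]
    if (!is.finite(a) || !is.finite(b)) next
    if (a == 0) { roots <- c(roots, xs[i]); next }
    if (a * b < 0) {
      r <- tryCatch(
        stats::uniroot(g, c(xs[i], xs[i + 1L]), tol = 1e-14)$root,
        error = function(e)
          stop_arg("transcendental root refinement failed on [",
                   format(xs[i]), ", ", format(xs[i + 1L]), "]"))
      roots <- c(roots, r)
    }
  }
  roots
}

robin_eigenpairs <- function(d, b, spec, n_max) {
  ell <- spec$length
  sig <- spec$robin_sigma
  beta <- b / (2 * d)
  # oscillatory roots interlace the Dirichlet anchors n*pi/l, so scanning up
  # to (n_max + 2) pi / l with a fine grid captures the first n_max of them
  k_max <- (n_max + 2) * pi / ell
  k_roots <- scan_roots(function(k) robin_char_trig(k, beta, sig, ell),
                        1e-9, k_max, n_scan = 60L * (n_max + 2L))
  vals <- b^2 / (4 * d) + d * k_roots^2
  fns <- lapply(k_roots, function(k) {
    # null vector of the boundary-condition matrix: row at x = 0
    P <- -sig * k
    Q <- -(1 + sig * beta)
    if (abs(P) < 1e-14 && abs(Q) < 1e-14) { P <- 1; Q <- 0 }
    make_trig_fun(beta, k, P, Q, ell, label = sprintf("robin k=%.6g", k))
  })
  # boundary-layer modes below b^2/(4 d) (possible for negative sigma)
  kap_max <- 2 * (abs(beta) + 1 / abs(sig) + 1 / ell + 1)
  kap_roots <- scan_roots(function(kap) robin_char_hyp(kap, beta, sig, ell),
                          1e-9, kap_max, n_scan = 400L)
  if (length(kap_roots)) {
    vals <- c(vals, b^2 / (4 * d) - d * kap_roots^2)
    fns <- c(fns, lapply(kap_roots, function(kap) {
      P <- -sig * kap
      Q <- -(1 + sig * beta)
      if (abs(P) < 1e-14 && abs(Q) < 1e-14) { P <- 1; Q <- 0 }
      make_hyp_fun(beta, kap, P, Q, ell, label = sprintf("robin kap=%.6g", kap))
    }))
  }
  ord <- order(vals)
  vals <- vals[ord]; fns <- fns[ord]
  n_keep <- min(n_max, length(vals))
  lapply(seq_len(n_keep), function(i) new_eigenpair(i, vals[i], fns[i]))
}

# ---- public eigen-solver -----------------------------------------------------

#' Eigenpairs of the auxiliary elliptic operator
#'
#' Solves the eigenproblem `-(d phi'' + b phi') = lambda phi` subject to the
#' boundary condition in `spec`, returning the `n_max` lowest eigenvalues with
#' their (sup-normalized) eigenfunctions.  Closed forms are used where they
#' exist: Dirichlet eigenvalues are `b^2/(4d) + d (n pi / l)^2` with
#' eigenfunctions `exp(-b x / 2d) sin(n pi x / l)`; the Neumann problem has
#' the zero eigenvalue with constant eigenfunction plus the same drifted
#' series; the no-drift periodic problem on a torus of circumference `2 pi`
#' has `lambda_n = d n^2` with multiplicity 2 for `n >= 1`.  The Robin
#' spectrum is computed from its transcendental characteristic equation by
#' sign-change bracketing and root refinement.
#'
#' @param d diffusivity, strictly positive (use [degenerate_kernel()] for
#'   `d = 0`).
#' @param b drift coefficient.
#' @param spec a [model_spec()].
#' @param n_max number of (distinct) eigenvalues requested, at least 1.
#' @return an object of class `"eigenpairs"`: a list of eigenpairs, each with
#'   fields `n` (index; 0 denotes the constant mode where it exists), `value`,
#'   `multiplicity` and `fns` (list of eigenfunctions; see [eigen_deriv()]).
#'   Sorted ascending by eigenvalue.
#' @examples
#' sp <- model_spec("dirichlet", length = 1)
#' ep <- eigenpairs(1, 0, sp, n_max = 3)
#' ep[[1]]$value  # pi^2
#' @export
eigenpairs <- function(d, b = 0, spec = model_spec(), n_max = 5) {
  if (!is.numeric(n_max) || n_max < 1) stop_arg("'n_max' must be at least 1")
  n_max <- as.integer(n_max)
  if (d <= 0) stop_arg("eigenpairs() requires d > 0; use degenerate_kernel() for d = 0")
  ell <- spec$length
  beta <- b / (2 * d)
  out <- switch(spec$boundary,
    dirichlet = {
      lapply(seq_len(n_max), function(n) {
        k <- n * pi / ell
        new_eigenpair(n, b^2 / (4 * d) + d * k^2,
                      list(make_trig_fun(beta, k, 0, 1, ell,
                                         label = sprintf("dirichlet n=%d", n))))
      })
    },
    neumann = {
      ev <- list(new_eigenpair(0L, 0, list(make_const_fun())))
      if (n_max > 1L) {
        ev <- c(ev, lapply(seq_len(n_max - 1L), function(n) {
          k <- n * pi / ell
          # boundary condition phi'(0) = 0 forces Q = beta P / k; phi'(l) = 0
          # then requires sin(k l) = 0, so the drifted Neumann spectrum is
          # analytic: lambda_n = b^2/4d + d (n pi / l)^2
          new_eigenpair(n, b^2 / (4 * d) + d * k^2,
                        list(make_trig_fun(beta, k, 1, beta / k, ell,
                                           label = sprintf("neumann n=%d", n))))
        }))
      }
      ev
    },
    robin = robin_eigenpairs(d, b, spec, n_max),
    periodic = {
      if (b != 0) {
        stop_arg("drifted periodic spectra are not supported; only b = 0 on the torus")
      }
      ev <- list(new_eigenpair(0L, 0, list(make_const_fun())))
      if (n_max > 1L) {
        ev <- c(ev, lapply(seq_len(n_max - 1L), function(n) {
          k <- 2 * pi * n / ell
          new_eigenpair(n, d * k^2,
                        list(make_trig_fun(0, k, 1, 0, ell,
                                           label = sprintf("periodic cos n=%d", n)),
                             make_trig_fun(0, k, 0, 1, ell,
                                           label = sprintf("periodic sin n=%d", n))))
        }))
      }
      ev
    })
  vals <- vapply(out, function(e) e$value, numeric(1))
  out <- out[order(vals)]
  structure(out, class = "eigenpairs", d = d, b = b, spec = spec)
}

#' @export
print.eigenpairs <- function(x, ...) {
  cat("<eigenpairs> ", attr(x, "spec")$boundary,
      ", d = ", attr(x, "d"), ", b = ", attr(x, "b"), "\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.eigenpairs <- function(x, ...) {
  data.frame(index = vapply(x, function(e) as.integer(e$n), integer(1)),
             eigenvalue = vapply(x, function(e) e$value, numeric(1)),
             multiplicity = vapply(x, function(e) e$multiplicity, integer(1)))
}

# ---- degenerate (d = 0) kernel ----------------------------------------------

#' Kernel of the degenerate first-order operator
#'
#' For `d = 0` the elliptic operator degenerates to
#' `L0[A] = b d/dx + c`, whose kernel (within the boundary condition) is
#' computed in closed form: Dirichlet admits no nontrivial kernel unless
#' `b = c = 0` (in which case every function vanishing at both ends lies in
#' the kernel and the result is flagged infinite-dimensional); Neumann admits
#' the constants iff `c = 0`; Robin admits `span{exp(-x / sigma)}` iff
#' `c = b / sigma`; on the torus the only periodic exponential is the
#' constant, admitted iff `c = 0`.
#'
#' @param b drift coefficient.
#' @param c zeroth-order coefficient.
#' @param spec a [model_spec()].
#' @param tol tolerance for the coefficient matching conditions.
#' @return a list with fields `fns` (possibly empty list of eigenfunctions),
#'   `infinite_dimensional` (logical) and `mode` (character tag).
#' @export
degenerate_kernel <- function(b, c, spec = model_spec(), tol = 1e-8) {
  empty <- list(fns = list(), infinite_dimensional = FALSE, mode = "empty")
  switch(spec$boundary,
    dirichlet = {
      if (abs(b) <= tol && abs(c) <= tol) {
        list(fns = list(), infinite_dimensional = TRUE,
             mode = "dirichlet_zero_operator")
      } else empty
    },
    neumann = {
      if (abs(c) <= tol) {
        list(fns = list(make_const_fun()), infinite_dimensional = FALSE,
             mode = "constant")
      } else empty
    },
    robin = {
      sig <- spec$robin_sigma
      if (is.null(sig) || sig == 0) stop_arg("Robin condition requires nonzero sigma")
      if (near(c, b / sig, tol)) {
        f <- make_hyp_fun(0, 1 / sig, 1, -1, spec$length,
                          label = sprintf("exp(-x/%g)", sig))
        list(fns = list(f), infinite_dimensional = FALSE, mode = "robin_exponential")
      } else empty
    },
    periodic = {
      if (abs(b) <= tol && abs(c) <= tol) {
        list(fns = list(), infinite_dimensional = TRUE,
             mode = "periodic_zero_operator")
      } else if (abs(c) <= tol) {
        list(fns = list(make_const_fun()), infinite_dimensional = FALSE,
             mode = "constant")
      } else empty
    })
}

# ---- kernel dimension --------------------------------------------------------

# internal: eigenvalue search cutoff; lambda_n grows like d (n pi / l)^2, so c
# can only match finitely many eigenvalues
kernel_cutoff <- function(d, c, ell) {
  max(50L, as.integer(ceiling(ell * sqrt(abs(c) / d) / pi)) + 5L)
}

#' Dimension of the kernel of L[A] = d Laplacian + b grad + c
#'
#' The kernel of `L[A]` is nontrivial iff `c` equals an eigenvalue of the
#' auxiliary problem `-(d phi'' + b phi') = lambda phi`, and its dimension is
#' the geometric multiplicity of that eigenvalue.  For `d = 0` the degenerate
#' operator is handled by [degenerate_kernel()] (an infinite-dimensional
#' kernel is reported as `Inf`).
#'
#' @param d nonnegative diffusivity.
#' @param b drift coefficient.
#' @param c zeroth-order coefficient to match against the spectrum.
#' @param spec a [model_spec()].
#' @param tol relative eigenvalue-match tolerance.
#' @return a nonnegative integer (or `Inf` in the degenerate zero-operator
#'   case).
#' @examples
#' kernel_dimension(1, 0, 4, model_spec("periodic"))   # 2
#' kernel_dimension(1, 0, pi^2, model_spec("dirichlet"))  # 1
#' @export
kernel_dimension <- function(d, b = 0, c = 0, spec = model_spec(), tol = 1e-8) {
  if (tol <= 0) stop_arg("'tol' must be positive")
  if (d == 0) {
    dk <- degenerate_kernel(b, c, spec, tol)
    if (dk$infinite_dimensional) return(Inf)
    return(length(dk$fns))
  }
  ep <- eigenpairs(d, b, spec, n_max = kernel_cutoff(d, c, spec$length))
  hits <- vapply(ep, function(e) near(e$value, c, tol), logical(1))
  sum(vapply(ep[hits], function(e) e$multiplicity, integer(1)))
}

# internal: eigenfunctions spanning the kernel of L[A], with the matched index
kernel_basis <- function(d, b, c, spec, tol = 1e-8) {
  if (d == 0) {
    dk <- degenerate_kernel(b, c, spec, tol)
    return(list(fns = dk$fns, index = NA_integer_, mode = dk$mode,
                infinite_dimensional = dk$infinite_dimensional))
  }
  ep <- eigenpairs(d, b, spec, n_max = kernel_cutoff(d, c, spec$length))
  hits <- which(vapply(ep, function(e) near(e$value, c, tol), logical(1)))
  if (!length(hits)) {
    return(list(fns = list(), index = NA_integer_, mode = "empty",
                infinite_dimensional = FALSE))
  }
  if (length(hits) > 1L) {
    warning("c matches several eigenvalues within tolerance; using the lowest index")
    hits <- hits[1L]
  }
  list(fns = ep[[hits]]$fns, index = ep[[hits]]$n, mode = "eigen",
       infinite_dimensional = FALSE, value = ep[[hits]]$value)
}

#' Export eigenpairs to CSV
#'
#' Writes a table `index, eigenvalue, multiplicity`, and (optionally) the
#' eigenfunctions evaluated on a grid as a second CSV with one column per
#' eigenfunction.
#'
#' @param ep an [eigenpairs()] object.
#' @param path output CSV path for the eigenvalue table.
#' @param grid_path optional path for the evaluated eigenfunction grid.
#' @param x evaluation grid (defaults to 101 points across the domain).
#' @return `path`, invisibly.
#' @export
write_eigenpairs_csv <- function(ep, path, grid_path = NULL, x = NULL) {
  utils::write.csv(as.data.frame(ep), path, row.names = FALSE)
  if (!is.null(grid_path)) {
    spec <- attr(ep, "spec")
    if (is.null(x)) x <- seq(0, spec$length, length.out = 101L)
    cols <- list(x = x)
    for (e in ep) {
      for (j in seq_along(e$fns)) {
        cols[[sprintf("phi_%s_%d", e$n, j)]] <- e$fns[[j]](x)
      }
    }
    utils::write.csv(as.data.frame(cols), grid_path, row.names = FALSE)
  }
  invisible(path)
}
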
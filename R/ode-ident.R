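# Finite-dimensional analogue: indistinguishable linear ODE systems
# Xdot = M1 X arising from singular perturbation matrices that commute with
# M1 and annihilate the initial state.

#' Basis of the commutant of a matrix
#'
#' Computes a basis of the linear space of matrices `M` with
#' `M1 M = M M1`, as the null space of the commutator operator
#' `M -> M1 M - M M1` (assembled via Kronecker products, null space by SVD).
#'
#' @param M1 a square numeric matrix.
#' @param tol relative singular-value threshold for the null space.
#' @return an object of class `"commutant_family"`: a list with `basis`
#'   (list of n x n matrices), `dimension`, and `member(theta)` returning the
#'   family member with coordinates `theta`.
#' @examples
#' fam <- commutant_family(matrix(c(2, 1, 3, 4), 2, 2))
#' fam$dimension  # 2
#' @export
commutant_family <- function(M1, tol = 1e-10) {
  if (!is.matrix(M1) || nrow(M1) != ncol(M1)) stop_arg("'M1' must be square")
  n <- nrow(M1)
  K <- kronecker(diag(n), M1) - kronecker(t(M1), diag(n))
  sv <- svd(K)
  null_idx <- which(sv$d <= tol * max(sv$d, 1))
  basis <- lapply(null_idx, function(j) matrix(sv$v[, j], n, n))
  member <- function(theta) {
    if (length(theta) != length(basis)) {
      stop_arg("'theta' must have length ", length(basis))
    }
    Reduce(`+`, Map(`*`, theta, basis))
  }
  structure(list(M1 = M1, basis = basis, dimension = length(basis),
                 member = member),
            class = "commutant_family")
}

#' @export
print.commutant_family <- function(x, ...) {
  cat("<commutant_family> dimension", x$dimension, "for an",
      nrow(x$M1), "x", ncol(x$M1), "matrix\n")
  invisible(x)
}

#' Singular members of a commutant family
#'
#' Restricts a [commutant_family()] to its singular, nontrivial members and
#' reports the kernel of each: these are exactly the perturbations `M` for
#' which initial states in `ker(M)` make `M1` and `M1 + M` indistinguishable.
#'
#' @param family a `"commutant_family"`.
#' @param coords a numeric vector (one member) or matrix (one member per
#'   row) of coordinates in the family's basis.
#' @param tol relative singular-value threshold for singularity.
#' @return a list of members, each a list with `M`, `theta` and `kernel`
#'   (matrix whose columns span `ker(M)`); all-zero members are excluded as
#'   trivial.
#' @examples
#' fam <- commutant_family(matrix(c(2, 1, 3, 4), 2, 2))
#' # the member ((1,3),(1,3)) is singular with kernel (-3, 1)
#' @export
singular_members <- function(family, coords, tol = 1e-10) {
  if (!inherits(family, "commutant_family")) {
    stop_arg("'family' must come from commutant_family()")
  }
  if (is.numeric(coords) && is.null(dim(coords))) {
    coords <- matrix(coords, nrow = 1L)
  }
  out <- list()
  for (i in seq_len(nrow(coords))) {
    theta <- coords[i, ]
    M <- family$member(theta)
    nrm <- max(abs(M))
    if (nrm == 0) next                       # trivial member excluded
    sv <- svd(M)
    null_idx <- which(sv$d <= tol * max(sv$d))
    if (!length(null_idx)) next
    out[[length(out) + 1L]] <- list(M = M, theta = theta,
                                    kernel = sv$v[, null_idx, drop = FALSE])
  }
  out
}

#' Verify indistinguishability of two linear ODE systems
#'
#' Compares the trajectories of `Xdot = M1 X` and `Xdot = M2 X` from the same
#' initial state using matrix exponentials (exact up to linear-algebra
#' tolerance, so no integrator error enters the comparison).
#'
#' @param M1,M2 square coefficient matrices.
#' @param X0 initial state.
#' @param T terminal time.
#' @param tol threshold on the propagator-relative gap below which the pair
#'   counts as indistinguishable.  Floating-point roundoff in the matrix
#'   exponential is amplified by the norm of the propagator (large when some
#'   eigenvalue of `M * T` is large), so the absolute gap is also reported
#'   but not used for the verdict.
#' @param n_times number of evaluation times on `[0, T]`.
#' @return a list with `indistinguishable` (logical), `gap` (max sup-norm
#'   trajectory difference) and `rel_gap` (gap relative to the propagator
#'   norms).
#' @examples
#' M1 <- diag(2); M2 <- matrix(c(2, 1, -1, 0), 2, 2)
#' verify_indistinguishable(M1, M2, c(1, 1), T = 2)$gap   # ~1e-14
#' @export
verify_indistinguishable <- function(M1, M2, X0, T = 2, tol = 1e-10,
                                     n_times = 50L) {
  ts <- seq(0, T, length.out = n_times)
  gap <- 0; rel_gap <- 0
  for (t in ts) {
    E1 <- as.matrix(Matrix::expm(M1 * t))
    E2 <- as.matrix(Matrix::expm(M2 * t))
    g <- max(abs(as.numeric(E1 %*% X0) - as.numeric(E2 %*% X0)))
    gap <- max(gap, g)
    rel_gap <- max(rel_gap, g / max(1, max(abs(E1)), max(abs(E2))))
  }
  list(indistinguishable = rel_gap <= tol, gap = gap, rel_gap = rel_gap)
}
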
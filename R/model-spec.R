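#' Model specification: domain and boundary condition
#'
#' Bundles the spatial domain (an interval `(0, length)` or a torus of a given
#' circumference) with the boundary operator applied to the parabolic model
#' and its auxiliary elliptic operator.  The Robin condition is
#' `u + sigma * du/dnu = 0` with `dnu` the outward normal derivative; its
#' constant must be nonzero (`sigma -> 0` recovers Dirichlet,
#' `sigma -> +/-Inf` recovers Neumann).
#'
#' @param boundary one of `"dirichlet"`, `"neumann"`, `"robin"`, `"periodic"`.
#' @param length domain length for the interval case (default 1).
#' @param robin_sigma Robin constant; required (and nonzero) iff
#'   `boundary = "robin"`.
#' @param circumference torus circumference for the periodic case
#'   (default `2 * pi`).
#' @return an object of class `"model_spec"`.
#' @examples
#' model_spec("dirichlet", length = 1)
#' model_spec("robin", robin_sigma = 1)
#' model_spec("periodic")
#' @export
model_spec <- function(boundary = c("dirichlet", "neumann", "robin", "periodic"),
                       length = 1, robin_sigma = NULL,
                       circumference = 2 * pi) {
  boundary <- match.arg(boundary)
  if (boundary == "robin") {
    if (is.null(robin_sigma)) {
      stop_arg("Robin boundary condition requires 'robin_sigma'")
    }
    if (robin_sigma == 0) {
      stop_arg("'robin_sigma' must be nonzero (sigma -> 0 is the Dirichlet limit)")
    }
  } else {
    robin_sigma <- NULL
  }
  topology <- if (boundary == "periodic") "torus" else "interval"
  ell <- if (topology == "torus") circumference else length
  if (!is.numeric(ell) || ell <= 0) stop_arg("domain length must be positive")
  structure(list(boundary = boundary, length = ell,
                 topology = topology, robin_sigma = robin_sigma),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$boundary,
      if (x$topology == "torus") " torus, circumference " else " interval, length ",
      format(x$length), "\n", sep = "")
  if (!is.null(x$robin_sigma)) cat("  robin sigma:", x$robin_sigma, "\n")
  invisible(x)
}

#' Parameter point of the linear parabolic model
#'
#' A point `A = (d, b, c)` of the operator `L[A] = d Laplacian + b grad + c`:
#' diffusivity `d >= 0` (length^2/time), drift `b` (length/time), and
#' growth/decay rate `c` (1/time).
#'
#' @param d nonnegative diffusivity.
#' @param b drift coefficient.
#' @param c zeroth-order (growth/decay) coefficient.
#' @return an object of class `"parameter_point"`.
#' @examples
#' parameter_point(0.05, 0, 1)
#' @export
parameter_point <- function(d, b = 0, c = 0) {
  if (!is.numeric(d) || length(d) != 1L || d < 0) {
    stop_arg("diffusivity 'd' must be a nonnegative scalar")
  }
  structure(list(d = d, b = b, c = c), class = "parameter_point")
}

#' @export
print.parameter_point <- function(x, ...) {
  cat(sprintf("<parameter_point> d = %g, b = %g, c = %g\n", x$d, x$b, x$c))
  invisible(x)
}

as_parameter_point <- function(A) {
  if (inherits(A, "parameter_point")) return(A)
  if (is.numeric(A) && length(A) == 3L) return(parameter_point(A[1], A[2], A[3]))
  stop_arg("expected a parameter_point or a numeric (d, b, c) triple")
}
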
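# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Composite Simpson quadrature on a uniform grid
#'
#' @param y function values on a uniform grid (odd length).
#' @param h grid spacing.
#' @return approximation to the integral.
#' @keywords internal
#' @noRd
simpson <- function(y, h) {
  n <- length(y)
  if (n < 3L) stop("simpson() needs at least 3 nodes")
  if (n %% 2L == 0L) {
    # trapezoid correction on the last panel
    return(simpson(y[-n], h) + h * (y[n - 1L] + y[n]) / 2)
  }
  idx <- seq_len(n)
  w <- rep(2, n)
  w[idx %% 2L == 0L] <- 4
  w[c(1L, n)] <- 1
  sum(w * y) * h / 3
}

# log-spaced sequence
logspace <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}

# relative closeness test used for eigenvalue matching
near <- function(a, b, tol) abs(a - b) <= tol * pmax(1, pmax(abs(a), abs(b)))

stop_arg <- function(...) stop(..., call. = FALSE)
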
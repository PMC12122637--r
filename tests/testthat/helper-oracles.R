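# Independent oracles used across the suite.

# Dense finite-difference discretization of -(d u'' + b u') under the given
# boundary condition; returns the sorted real eigenvalues (ascending).
# Second-order central differences on n nodes.
fd_eigenvalues <- function(d, b, spec, n = 400L) {
  ell <- spec$length
  if (spec$boundary == "dirichlet") {
    h <- ell / n
    m <- n - 1L
    A <- matrix(0, m, m)
    for (i in seq_len(m)) {
      A[i, i] <- 2 * d / h^2
      if (i > 1L) A[i, i - 1L] <- -d / h^2 + b / (2 * h)
      if (i < m) A[i, i + 1L] <- -d / h^2 - b / (2 * h)
    }
  } else if (spec$boundary %in% c("neumann", "robin")) {
    h <- ell / (n - 1L)
    m <- n
    A <- matrix(0, m, m)
    for (i in 2:(m - 1L)) {
      A[i, i] <- 2 * d / h^2
      A[i, i - 1L] <- -d / h^2 + b / (2 * h)
      A[i, i + 1L] <- -d / h^2 - b / (2 * h)
    }
    if (spec$boundary == "neumann") {
      # ghost nodes u_{-1} = u_1 and u_{m+1} = u_{m-1}
      A[1, 1] <- 2 * d / h^2;       A[1, 2] <- -2 * d / h^2
      A[m, m] <- 2 * d / h^2;       A[m, m - 1L] <- -2 * d / h^2
    } else {
      sig <- spec$robin_sigma
      # outward-normal Robin ghosts: u'(0) = u(0)/sigma gives
      # u_{-1} = u_1 - 2h u_0/sigma, so row 1 of -(d u'' + b u') is
      #   -(d (2u_1 - 2u_0 - 2h u_0/sig)/h^2 + b u_0/sig)
      A[1, 1] <- 2 * d / h^2 + 2 * d / (h * sig) - b / sig
      A[1, 2] <- -2 * d / h^2
      # u'(l) = -u(l)/sigma gives u_{m+1} = u_{m-1} - 2h u_m/sigma
      A[m, m] <- 2 * d / h^2 + 2 * d / (h * sig) + b / sig
      A[m, m - 1L] <- -2 * d / h^2
    }
  } else {   # periodic: circulant on n nodes, seam excluded
    h <- ell / n
    m <- n
    A <- matrix(0, m, m)
    for (i in seq_len(m)) {
      ip <- if (i == m) 1L else i + 1L
      im <- if (i == 1L) m else i - 1L
      A[i, i] <- 2 * d / h^2
      A[i, im] <- -d / h^2 + b / (2 * h)
      A[i, ip] <- -d / h^2 - b / (2 * h)
    }
  }
  sort(Re(eigen(A, only.values = TRUE)$values))
}

# count of finite-difference singular values of L[A] = d u'' + b u' + c
# below a threshold (kernel-dimension oracle)
fd_kernel_dim <- function(d, b, c, spec, n = 400L, tol = 1e-3) {
  lams <- fd_eigenvalues(d, b, spec, n)
  sum(abs(lams - c) <= tol * pmax(1, abs(lams)))
}

unit_dirichlet <- function() model_spec("dirichlet", length = 1)
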
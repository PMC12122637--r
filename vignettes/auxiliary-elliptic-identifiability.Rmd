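---
title: "Identifiability of parabolic models through auxiliary elliptic operators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifiability of parabolic models through auxiliary elliptic operators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ellipident)
```

## The question and the reduction

Consider a fully observed scalar parabolic model on an interval $(0,\ell)$
or a torus,
$$u_t = L[A_1]\,u = d_1 u_{xx} + b_1 u_x + c_1 u,\qquad \mathcal{B}u = 0,
\qquad u(x,0) = u_0(x),$$
with diffusivity $d_1 \ge 0$ (length$^2$/time), drift $b_1$ (length/time)
and growth rate $c_1$ (1/time).  Two distinct parameter points $A_1, A_2$
are *indistinguishable from $u_0$* when they generate the same solution.
Because the operator is linear in its parameters, subtracting the two
equations that a shared solution would satisfy leaves the *auxiliary
elliptic equation* $L[A]u = 0$ with $A = A_1 - A_2$ (roles swapped so the
auxiliary diffusivity is nonnegative).  A shared solution must therefore
live, at every time, in the kernel of $L[A]$ restricted by the boundary
condition.  This converts an identifiability question into a spectral one:

* if $\ker L[A] = \{0\}$ the pair is unconditionally distinguishable;
* otherwise $c = c_1 - c_2$ equals an eigenvalue $\lambda_n$ of the
  auxiliary problem $-(d\,\varphi'' + b\,\varphi') = \lambda\varphi$, the
  kernel is the corresponding eigenspace, and indistinguishability can
  occur only from initial conditions inside that (finite-dimensional)
  eigenspace — and then it genuinely does occur, with the explicit shared
  solution $u(x,t) = c_0 e^{\mu t}\varphi_n(x)$.

The package implements this procedure end to end: `eigenpairs()` and
`kernel_dimension()` for the spectral side, `in_set_A()` /
`indistinguishable_partners()` / `is_in_kernel()` /
`construct_nonidentifiable_solution()` / `classify()` for the four-step
classification, with the finite-dimensional (ODE) analogue, nonlinear
reactions, a two-species construction, and a synthetic-data
profile-likelihood study built on top.

## Spectra by boundary condition

All eigenfunctions are normalized to unit supremum (scalar multiples span
the same kernel; the sup normalization makes nonnegativity checks direct)
and carry analytic first and second derivatives, so operator residuals and
boundary residuals can be verified to machine precision rather than by
finite differences.

**Dirichlet.** $\lambda_n = \frac{b^2}{4d} + d\frac{n^2\pi^2}{\ell^2}$ with
$\varphi_n = e^{-bx/2d}\sin(n\pi x/\ell)$, $n \ge 1$, all simple.  The
$\sin(n\pi x/\ell)$ factor is the only choice compatible with
$\varphi(\ell)=0$; writing the argument as $\sqrt{\lambda_n}\,x$ would not
vanish there.

**Neumann.** $\lambda_0 = 0$ with constant eigenfunction — present for any
drift — plus $\lambda_n = \frac{b^2}{4d} + d\frac{n^2\pi^2}{\ell^2}$ with
$\varphi_n = e^{-\beta x}(\cos k_n x + \tfrac{\beta}{k_n}\sin k_n x)$,
$\beta = b/2d$, $k_n = n\pi/\ell$.  One might expect a transcendental
condition here, but imposing $\varphi'(0)=0$ forces
$Q = \beta P/k$ and then $\varphi'(\ell) \propto \sin(k\ell)$, so the
drifted Neumann spectrum is closed-form.  The test suite still checks it
(and every other case) against a dense finite-difference eigensolver.

**Robin.** With the outward-normal convention
$u - \sigma u_x = 0$ at $x = 0$ and $u + \sigma u_x = 0$ at $x = \ell$, the
characteristic equation is genuinely transcendental,
$$(1 - \sigma^2\beta^2 - \sigma^2 k^2)\sin k\ell + 2\sigma k\cos k\ell = 0,
\qquad \lambda = \tfrac{b^2}{4d} + dk^2,$$
solved by scanning for sign changes on a grid fine relative to the
$\pi/\ell$ interlacing spacing and refining each bracket with Brent's
method to $10^{-14}$.  A hyperbolic branch ($\lambda < b^2/4d$, relevant
for negative $\sigma$) is scanned the same way.  For $\sigma > 0$ the
spectrum interpolates between the Neumann and Dirichlet spectra and
converges to them as $\sigma \to \pm\infty$ and $\sigma \to 0$.

One caveat worth stating plainly: the degenerate $d = 0$ Robin family
(`degenerate_kernel()`), whose kernel is $\operatorname{span}\{e^{-x/\sigma}\}$
exactly when $c = b/\sigma$, reads the boundary operator with the *same*
sign at both endpoints ($u + \sigma u_x = 0$); under the outward-normal
convention that exponential fails the condition at $x = 0$.  The two
conventions coexist in the field's usage; the package keeps the
outward-normal (self-adjoint, interpolating) convention for $d > 0$ and the
same-sign reading for the degenerate family, which is the only reading
under which that family is nonempty.

**Periodic.** On the torus of circumference $2\pi$ (the default) with
$b = 0$: $\lambda_0 = 0$ simple, $\lambda_n = d n^2$ with geometric
multiplicity 2 and eigenfunctions $\{\cos nx, \sin nx\}$.  The doubled
multiplicity is what raises the number of independent initial conditions
needed to rule out non-identifiability from two to three.  Drifted periodic
spectra are complex and out of scope; requesting them is an error rather
than a wrong answer.

## The shared-solution exponent

For a pair on an eigen family, the witness solution is
$u = c_0 e^{\mu t}\varphi_n$ where $\mu$ is the eigenvalue of $L[A_1]$ on
$\varphi_n$.  Rather than hard-coding the no-drift formula
$\mu = c_1 - d_1 (n\pi/\ell)^2$, the package evaluates the pointwise ratio
$L[A_1]\varphi_n / \varphi_n$ from the analytic derivatives and requires it
to be constant (and equal under $A_2$).  Substitution shows the constant is
$c_1 - d_1(\beta^2 + k_n^2)$ in the drifted case — i.e. the auxiliary
eigenvalue enters scaled by the auxiliary diffusivity — reducing to
$c_1 - d_1\lambda_n^{(1)}$ (unit-diffusivity eigenvalue) without drift, and
to $d_1/\sigma^2 - b_1/\sigma + c_1$ for the degenerate Robin family.  A
non-constant ratio is exactly the signature of a violated drift-ratio
constraint $b_1/b_2 = d_1/d_2$, and raises a construction error naming that
constraint.  Drift pointing in opposite directions can therefore never
produce indistinguishable pairs.

Kernel membership of an initial condition is tested by projection in the
weighted inner product with weight $e^{bx/d}$, which puts the drifted
operator in Sturm–Liouville (self-adjoint) form and makes the eigenspaces
orthogonal — the natural choice where no inner product is otherwise
distinguished.  The projection integrals use composite Simpson
quadrature on 2001 nodes; the default relative-residual tolerance is
$10^{-6}$.

## Nonlinear reactions

For logistic-type reactions $f = au - bu^2$ (or $m(x)u - bu^2$), the
auxiliary problem $-d\psi'' = f(x,\psi)$ is solved by shooting with
multistart: the free endpoint value/slope sweeps a signed log-spaced grid
over $[10^{-3}, 10^2]$, endpoint residual sign changes are refined by
Brent's method, diverging trajectories are cut off by a terminal root at
$|\psi| = 10^5$, and profiles are de-duplicated at $10^{-6}$ in sup norm.
"Discrete versus continuous spectrum of solutions" is operationalized as
the multistart solution count, since no computable criterion is given in
general; for logistic reactions the count is provably at most two.  A
classical threshold organizes the Dirichlet solution set: a positive
profile exists precisely when $a > d\lambda_1 = d\pi^2/\ell^2$; below the
threshold the only nontrivial branch (when present) is the negative
solution of the superlinear problem obtained by the sign symmetry
$\psi \mapsto -\psi$, $b \mapsto -b$.  Because the solution set is always
discrete, distinct logistic parameter pairs are unconditionally
distinguishable *provided the data vary in time*; steady-state data
(checked as $\sup|\Delta u/\Delta t| \le 10^{-8}$ on a forward solve) yield
an explicit `"inconclusive-steady"` verdict instead of a claim.

## The two-species construction

From any scalar indistinguishable pair $(d_1,c_1) \sim (d_2,c_2)$ and
positive constants $\kappa_u, \kappa_v, \delta_1, \delta_2$, the linear
cell motility system acquires the parameters
$d_u = d_1$, $a_{11} = c_1+\delta_1$, $a_{12} = \delta_1\kappa_u/\kappa_v$,
$d_v = d_2$, $a_{22} = c_2+\delta_2$, $a_{21} = \delta_2\kappa_v/\kappa_u$,
and the single trajectory $(u,v) = (\kappa_u u_1, \kappa_v u_1)$ solves the
system for *every* admissible $(\delta_1,\delta_2)$ — a two-parameter
continuum of non-identifiable parameter sets.  The deltas are constrained
to $\delta_i > \max(0, -c_i)$ so all reaction coefficients stay positive.
Verification is belt-and-braces: the closed-form residual (analytic
derivatives, machine precision) and a method-of-lines forward solve from
the shared initial state.  The numerical cross-check uses a short window,
since the transverse $u - v$ mode grows under the reaction coupling and
amplifies discretization differences between parameter sets that the exact
dynamics keep at zero.

## The synthetic experiment

The practical-identifiability study is fully synthetic by design; its
generator *is* the study condition, not a tuning knob.

* **Initial conditions.** A Gaussian bump centred at $x = 1/2$ with width
  $\omega \in \{0.1, 0.2, 0.3\}$ is translated to vanish at the boundary,
  scaled to centre value 1, and truncated to $N = 8$ sine modes
  ($C_n = 2\int_0^1 s(x)\sin(n\pi x)\,dx$, adaptive quadrature at
  $10^{-12}$).  The order — translate, scale, then truncate — is a choice;
  the truncated series is the actual initial condition, so the centre value
  carries the truncation error (about 1% at $\omega = 0.1$).  Wide bumps
  are close to the dominant eigenfunction, narrow ones are genuinely
  multi-mode.
* **Forward model.** The exact expansion
  $u = \sum_n C_n e^{(c - d n^2\pi^2)t}\sin(n\pi x)$, evaluated on the
  observation grid $x \in \{0, 0.1, \dots, 1\}$,
  $t \in \{0, 0.1, \dots, 2\}$.  Using the analytic solution avoids any
  discretization interaction with a diffusivity that ranges over orders of
  magnitude.
* **Noise.** Additive Gaussian, per-time-slice covariance
  $\sigma^2 e^{-\eta|x_i - x_j|}$ with $(\eta,\sigma) = (10, 0.3)$ treated
  as known, independent across slices; drawn through a Cholesky factor
  computed once.  Boundary observations are pure noise under Dirichlet
  conditions and are retained, since the stated grid includes them.  The
  option of inferring $(\eta,\sigma)$ jointly is deliberately not
  implemented.
* **Profiling.** At fixed $(c,d)$ the model is linear in $\{C_n\}$, so the
  profile maximizer is the exact generalized-least-squares solution over
  the whitened stacked design — no iterative optimizer, no convergence
  question.  A numerically rank-deficient design (possible at extreme
  parameter combinations that collapse the modes) falls back to a small
  ridge with a warning.  Surfaces are normalized to a maximum of zero and
  cut at half the $\chi^2_2$ 0.95 quantile, $2.996$; the value is computed,
  never hard-coded.
* **Geometry.** The $(c,d)$ grid is linear in $c$ over $[0,4]$ and
  logarithmic in $d$ over $[10^{-3}, 1]$ (41 points each by default),
  because the diffusivity is uncertain over orders of magnitude.  The
  confidence regions hug the theoretically indistinguishable set
  $c - d\pi^2 = \text{const}$, widen in $d$ as $\omega$ grows (the initial
  condition approaches the dominant eigenfunction), and admit a positive
  lower bound on $d$ for $\omega = 0.1$.

What passing tests do and do not show: the generator reproduces the
mechanism — ridge-shaped likelihood surfaces caused by spectral
coincidence — under exactly these conditions (exact forward model, known
noise parameters, correctly specified covariance).  Real spatiotemporal
data add model misspecification, temporally correlated noise and partial
observation, none of which the generator emulates; conclusions about those
settings do not follow from these tests.

## Problem sizes and numerical defaults

Unit tests and the acceptance checks run at deliberately desk-scale sizes,
chosen as adequate for their statistical purpose: profile surfaces at
$21\times 21$ for the qualitative geometry (the full $41\times 41$ default
remains available), 20 replicates for the coverage sanity check, 4000
replicates for the noise-covariance check (three standard errors),
finite-difference eigensolver cross-checks at 400 nodes, method-of-lines
at 201–401 nodes with `lsoda` at `rtol` $10^{-8}$ / `atol` $10^{-10}$.
Eigenvalue matching uses a relative tolerance of $10^{-8}$; when a
requested $c$ matches two eigenvalues within a loose user tolerance, the
lowest index wins with a warning.  All stochastic tests fix their seeds.

## Known limitations

One spatial dimension (interval or torus) only; constant coefficients
except for the heterogeneous logistic linear term; drifted periodic
spectra unsupported; no inference of the noise parameters; no
multi-experiment design optimization.  The matrix-exponential ODE
comparison reports both an absolute and a propagator-relative trajectory
gap, because roundoff in $e^{Mt}$ scales with the largest propagator mode
and an absolute tolerance would misread well-conditioned agreement as
failure.
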
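# ellipident

Structural and practical identifiability of fully observed
reaction–diffusion models that are **linear in their parameters**, for
modellers in mathematical biology and epidemiology who fit parabolic PDEs
— diffusion, drift, exponential or logistic growth — to spatiotemporal
data and need to know *whether the data can determine the parameters at
all* before fitting them.

## The idea

For the scalar parabolic model

$$u_t = L[A_1]u = d_1 u_{xx} + b_1 u_x + c_1 u, \qquad \mathcal{B}u = 0,
\qquad u(x,0) = u_0(x),$$

two distinct parameter points $A_1 = (d_1, b_1, c_1)$ and $A_2$ produce
the same solution only if that solution lies in the kernel of the
**auxiliary elliptic operator** $L[A]$ with $A = A_1 - A_2$.  The kernel
is nontrivial exactly when $c_1 - c_2$ equals an eigenvalue $\lambda_n$ of
$-(d\,\varphi'' + b\,\varphi') = \lambda\varphi$ under the model's
boundary condition, and then the only vulnerable initial conditions are
multiples of the eigenfunction $\varphi_n$, from which the explicit shared
solution $u = c_0 e^{\mu t}\varphi_n(x)$ exists.  On the unit Dirichlet
domain this is the familiar statement that only the combination
$\mu = c - d\pi^2$ is identifiable from $u_0 = \sin(\pi x)$.

The package implements the full programme around this reduction:

* **spectral** — closed-form and transcendental eigensolvers for
  Dirichlet, Neumann, Robin and periodic conditions, with drift and the
  degenerate $d = 0$ cases (`eigenpairs`, `degenerate_kernel`,
  `kernel_dimension`);
* **linear classification** — membership of the indistinguishable set,
  partner families, kernel tests for initial conditions, explicit
  non-identifiable solutions, three-way verdicts (`in_set_A`,
  `indistinguishable_partners`, `is_in_kernel`,
  `construct_nonidentifiable_solution`, `classify`, `step4_filter`);
* **ODE analogue** — commuting singular perturbations of linear systems
  (`commutant_family`, `singular_members`, `verify_indistinguishable`);
* **solvers** — exact eigen-expansion plus a method-of-lines integrator
  used as an independent oracle (`solve_linear_analytic`, `solve_mol`);
* **nonlinear reactions** — multistart shooting for the auxiliary
  elliptic problem of logistic-type models, where discreteness of the
  solution set implies unconditional identifiability
  (`solve_auxiliary_elliptic`, `classify_nonlinear_pair`);
* **two-species systems** — a continuum of non-identifiable parameter
  sets for a cell motility model (`build_two_species`, `family_sweep`);
* **practical identifiability** — synthetic data with spatially
  correlated Gaussian noise and a bivariate $(c, d)$ profile likelihood
  with the initial-condition coefficients profiled out by exact GLS
  (`simulate_dataset`, `profile_coefficients`, `profile_surface`).

## Worked example

Starting from $(c_1, d_1) = (1, 0.05)$ on the unit Dirichlet domain, find
the partner with growth rate $c_2 = 2$ and check it is indistinguishable
from the dominant eigenfunction:

```r
library(ellipident)
sp  <- model_spec("dirichlet", length = 1)
A1  <- parameter_point(d = 0.05, b = 0, c = 1)
fam <- indistinguishable_partners(A1, sp, n = 1)
(A2 <- fam$partner_from_c(2))
#> <parameter_point> d = 0.151321, b = 0, c = 2

classify(A1, A2, function(x) sin(pi * x), sp)
#> <classification> indistinguishable_ANI
#>   auxiliary point: d = 0.1013212  b = 0  c = 1
#>   matched eigen index: 1
```

The partner diffusivity is $d_2 = 0.05 + 1/\pi^2 \approx 0.15$: both
points share the invariant $c - d\pi^2$.  The returned witness is the
shared solution $u = e^{0.5065 t}\sin(\pi x)$ (exponent
$1 - 0.05\pi^2$), whose PDE residual under either parameter point is at
machine precision (`ni_residual(...)` reports `1.5e-16`).  Any
perturbation of the initial condition restores identifiability:

```r
classify(A1, A2, function(x) sin(pi * x) + 0.1 * sin(2 * pi * x), sp)$verdict
#> [1] "distinguishable_AI"
```

The practical consequence: simulate noisy data from an initial condition
close to the dominant eigenfunction and profile the likelihood over
$(c, d)$:

```r
ds <- simulate_dataset(1, 0.05, gaussian_ic_coefficients(0.3, N = 8),
                       noise_spec(sigma = 0.3, eta = 10), seed = 1)
profile_surface(ds, seq(0, 4, length.out = 21),
                exp(seq(log(1e-3), log(1), length.out = 21)))
#> <profile_surface> 21 x 21 grid; MLE (c, d) = (0.8, 0.03162278); 95% region: 8 cells
```

The 95% region (threshold `2.996`, half the $\chi^2_2$ quantile) is a
ridge along $c - d\pi^2 = \text{const}$: the combination is well
determined while $d$ alone spans orders of magnitude — structural
non-identifiability at a single point surfacing as practical
non-identifiability nearby.

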
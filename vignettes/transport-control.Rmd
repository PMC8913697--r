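---
title: "Regulated motor-assisted transport in branched neuron geometries: models and methods"
author: "neurotransport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulated motor-assisted transport: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

Neurons deliver most of their material from the soma through axons and
dendrites by molecular motors walking on microtubules (MTs). `neurotransport`
simulates a *regulated* version of the classic macroscopic motor-assisted
transport model on planar tube domains $\Omega$ swept around a neuron
skeleton. Three species are tracked per transport direction: the free
concentration $n_0$, the bound (moving) concentrations $n_\pm$, and the
transport velocities $v_\pm$; the fields $f_\pm$ are control forces through
which the cell steers its own traffic. The model is posed as a
PDE-constrained optimisation problem,
$$
\min_{n_\pm, v_\pm, f_\pm}\;
\tfrac12\!\int_0^T\!\!\int_\Omega (v_\pm - V_\pm)^2
\;+\; \tfrac{\alpha}{2}\!\int_0^T\!\!\int_\Omega \lVert\nabla n_\pm\rVert^2
\;+\; \tfrac{\beta}{2}\!\int_0^T\!\!\int_\Omega f_\pm^2 ,
$$
subject to
$$
\begin{aligned}
\partial_t n_0 &= -(k_+ l_+ + k_- l_-)\,n_0 + k'_+ (l_+ n_+) + k'_- (l_- n_-),\\
\partial_t (l_\pm n_\pm) + v_\pm\!\cdot\!\nabla (l_\pm n_\pm)
 &= D_\pm \nabla^2 (l_\pm n_\pm) + k_\pm l_\pm n_0 - k'_\pm (l_\pm n_\pm),\\
\partial_t v_\pm + v_\pm\!\cdot\!\nabla v_\pm
 &= -\nabla n_\pm + \nabla\!\cdot(\mu \nabla v_\pm) + f_\pm,
\end{aligned}
$$
with inlet data $n_0 = n_i$, $n_+ = \lambda_i n_i$, outlet data $n_0 = n_o$,
$n_- = \lambda_o n_o$, and $v_\pm = V_\pm$ at the inlet. $V_\pm$ is a
predefined target velocity obtained from a steady incompressible flow solve
on the same geometry. $l_\pm \ge 0$ are dimensionless MT densities: the
knobs through which pathological track configurations (local MT loss, MT
swirls) enter. In the default *unidirectional* configuration the MT array is
unipolar and all minus-direction fields are dropped (4 unknown field groups);
*bidirectional* runs carry all 7.

**Attachment scaling.** We write the binding flux as $k_\pm l_\pm n_0$,
proportional to the locally available track density, as in the classic
motor-transport literature from which the rate constants are taken. This
matters in two places: where $l_-$ vanishes (no minus-directed tracks, e.g.
outside a swirl region) the minus equation degenerates gracefully to
$l_- n_- \equiv 0$ instead of forcing $n_0 = 0$; and in a depleted region
both $n_0$ and $n_+$ scale as $1/l_+$ at fixed bound mass, which is exactly
the local accumulation ("traffic jam") the model is built to exhibit. At the
uniform default $l = 1$ the equilibrium $n_+ = (k_+/k'_+)\, n_0 = 10\, n_0$
is unchanged.

**Default parameters.** Diffusivity $D_\pm = 0.1\ \mu m^2/s$ (reduced from
the Stokes–Einstein value $\approx 0.4\ \mu m^2/s$ for a 1 µm sphere in
water, see `stokes_einstein_diffusivity()`, to account for cytoplasmic
crowding), $k_\pm = 1\,/s$, $k'_\pm = 0.1\,/s$, traffic viscosity
$\mu = 0.1$, loading degrees $\lambda_i = \lambda_o = 2$, boundary
concentrations $n_i = 1$, $n_o = 0$ mol/µm², penalties
$\alpha = \beta = 1$. All are exposed in `parameter_set()`.

# Geometry and discretisation

**Skeletons.** Morphologies follow SWC semantics (`read_swc()`,
`write_swc()`, `clean_skeleton()`); the solver is planar, so z-coordinates
are discarded with a warning. Synthetic study geometries
(`make_synthetic_skeleton()`) cover a straight pipe (80 µm long, 2 µm
radius), a symmetric bifurcation, recursive binary trees with 5 and 10
outlets (`tree_spec_5outlet()`, `tree_spec_10outlet()`), and a pipe with a
local swelling whose radius follows a C¹ cubic-smoothstep bump (peak
amplification 2 over a 20 µm window). The root is the transport inlet and
every leaf an outlet; this is a convention, not biology.

**Sweeping mesh.** `sweep_mesh()` places cross-sections of width
$2\,r(s)$ perpendicular to the centerline and connects them into structured
quadrilateral patches, one per branch. At a bifurcation the three incident
branches are set back (enough that openings cannot overlap, at least 1.5
radii) and the remaining hexagonal region is filled with a midpoint
subdivision into six bilinear sub-patches around the centroid. This template
is mirror-symmetric and conforming for any even transverse element count.

**Spline basis.** `build_spline_space()` erects tensor-product B-splines
(default degree 2, open uniform knots, C¹ inside patches) over each patch,
glued C⁰ across interfaces by identifying coincident Greville points. On
branched meshes the branch patches carry one repeated transverse midline
knot so that a branch end cross-section spans exactly the same edge space as
the two junction half-edge patches it meets — without this the glued basis
would be non-conforming. Geometry is sub-parametric (bilinear per
control-mesh quad) with 3×3 Gauss quadrature; the basis values and physical
gradients at all quadrature points are cached as sparse matrices, and every
integral in the package is a weighted product of these operators.

**Stabilization.** The bound-cargo and velocity equations are advection
dominated at the study resolutions (element Péclet ≈ 10–20), so their
Galerkin forms carry SUPG streamline stabilization with the wind frozen at
the target velocity $V_\pm$ and the standard $\tau = \frac{h}{2|V|}
\min(1, Pe/3)$. Freezing the wind keeps the discrete system exactly
differentiable, which the optimiser exploits; it can be switched off
(`parameter_set(stabilize = FALSE)`).

**Velocity target.** `solve_predefined_velocity()` solves steady
incompressible flow with a parabolic inlet profile (peak 1 µm/s by default —
the magnitude is a modelling choice of order typical motor speeds), no-slip
walls and traction-free outlets, by Newton's method from the Stokes
solution. The discretisation is a Taylor–Hood-style mixed pair: velocity on
the quadratic spline space, pressure on a degree-1 space on the same mesh.
This reproduces plane Poiseuille flow to machine precision, where equal-order
pressure stabilisation at these resolutions distorts the profile by tens of
percent through its consistency error.

# The all-at-once optimiser

The discrete Lagrangian $L_h = J_h + p^{\!\top} B_h$ couples objective,
constraints and one adjoint field per constraint equation. Stationarity in
(state, control, adjoint) gives the KKT system; `solve_pdeco()` solves it
all-at-once by Newton iterations with

* the exact gradient and the exact (adjoint-weighted) Hessian, so the
  saddle-point matrices are symmetric and Newton converges quadratically;
* Dirichlet degrees of freedom eliminated symmetrically (values imposed on
  the fields, rows/columns removed, adjoint rows dropped with them);
* right-preconditioned restarted GMRES (own implementation,
  `gmres_solve()`) on each Newton system; the default preconditioner is a
  sparse LU factorisation of the KKT matrix at the first iterate, reused
  across the outer iterations and refreshed if the inner solve stagnates;
* backtracking line search on the KKT residual norm, with a primal-dual
  Levenberg regularisation ($+\rho M$ on the primal diagonal, $-\rho M$ on
  the adjoint diagonal) that switches on only when a step stalls and decays
  again on progress;
* stopping tolerance $10^{-7}$ on the Euclidean norm of the full KKT
  residual (`solver_options()`), the model's convergence contract.

The initial iterate is $v_\pm = V_\pm$, concentrations linear in arc length
between their boundary data, $f = p = 0$. Because the constraints are
nonlinear, the solver reports the stationary point it reaches; no global
search is attempted. `finite_difference_gradient_check()` verifies the
assembled gradient against central differences (the discrete Lagrangian is
exactly quadratic in state and control at fixed adjoint, so those
differences are exact up to roundoff; the quadratic truncation error of the
FD scheme only shows along joint primal–adjoint directions).

# Steady versus transient, and the study horizons

Both a steady formulation and backward-Euler transient stepping over
$[0, T]$ are provided. Transient problems are solved sequentially in time —
one KKT solve per step with the previous state in the time-derivative
terms — which keeps memory flat; a monolithic space-time coupling is not
implemented.

The scenario suite runs the transient formulation, and this is a deliberate
modelling choice rather than a shortcut. Two observations drive it:

* The uncontrolled forward dynamics ($f \equiv 0$) are unstable at the
  default parameters: the $-\nabla n_+$ coupling accelerates the velocity
  field through the concentration gradient sustained by the outlet data, and
  time marching blows up after roughly ten seconds. Regularised steady
  solves exist, but they describe an infinite-time limit in which the
  upstream supply has drained.
* In that steady limit a local MT depletion no longer carries a
  concentration *peak*: the maximum sits at the inlet. The jam — bound
  cargo piling up against a region of slowed transport — is a developing
  structure, and all its signatures (peak inside the depleted region,
  severity orderings in $\alpha$ and $\beta$, downstream depletion with
  sibling-branch enrichment on trees) appear robustly in transient runs.

The study horizons are fixed once in `scenario_config()`: 16 s in 8 steps on
the 80 µm pipe (enough for the jam to develop at ~1 µm/s transport), 96 s in
12 steps on the trees (delivery paths are ~130 µm at ~0.4 µm/s, so mid-tree
responses need the longer window), and 4 s in 8 steps for the large-$\beta$
forward-limit verification, inside the stable window of the uncontrolled
dynamics.

# Microtubule scenarios

`make_mt_density()` builds the track-density fields:

* **uniform** — $l_+ \equiv 1$ (and $l_- \equiv 1$ in bidirectional mode);
* **reduced** — $l_+$ dips to $1 - \text{depth}$ (default depth 0.8) over an
  axial window with cubic-smoothstep shoulders (default transition width a
  quarter of the window); on trees the default window sits directly
  downstream of the first junction, where the depletion also perturbs the
  junction flux split;
* **swirl** — inside the window both densities are amplified (default
  factor 2) with opposite transverse biases,
  $l_\pm = A\,(1 \mp a\,t)$ with asymmetry $a = 0.5$ and $t \in [-1, 1]$ the
  transverse coordinate, encoding a counter-clockwise swirl ($l_+$
  concentrated at the bottom wall, $l_-$ at the top). Outside the window
  $l_+$ relaxes to 1 and $l_-$ to a small floor (0.05): minus-directed
  tracks exist only in the swirl region, and the floor keeps the minus
  equations non-degenerate while remaining dynamically negligible.

Swirl scenarios require the swollen-pipe geometry and bidirectional mode;
`vortex_diagnostics()` reports the scalar curl of $v_+ + v_-$, the
circulation over the swirl window, and the overlap score — the fraction of
the top-decile concentration area lying in the counter-clockwise
(positive-curl, standard planar orientation) region.

# Numerical choices and degenerate inputs

* Duplicate skeleton nodes are merged at $10^{-6}$ µm, keeping the lower id;
  junctions with more than two children, overlapping junction openings, and
  inverted elements are hard errors naming the offending branch or element.
* Global degrees of freedom are deduplicated through Greville coordinates
  rounded at $10^{-6}$ µm; partition of unity is asserted at build time.
* The profile sampler walks the unique branch path inlet→outlet at half the
  axial element size; junction interiors (where no centerline is defined)
  are skipped.
* Determinism: all solves are deterministic for fixed inputs; the seed in
  `solver_options()` exists so that any future randomised component stays
  reproducible, and manifests written by `export_result()` re-run to
  bitwise-identical convergence histories.

# What the synthetic studies do and do not show

The generator reproduces the *structure* of the biological setting — branch
topology, tapering calibers, localized track pathologies — under exactly
controlled conditions, which is what makes ordering contracts testable. It
does not emulate 3D geometry, tortuous real morphologies, stochastic MT
turnover, or organelle-scale granularity; passing tests therefore validate
the solver and the mechanisms, not quantitative predictions for any real
neuron. Desk-scale resolutions leave the inlet reaction layer (width
$\sim D/v \approx 0.1$ µm) unresolved, so converged objective values still
drift between refinements even though fields and orderings are stable; the
tests assert contraction of that drift, not mesh-independence. The
advective-form transport equations are not in divergence form, so global
mass budgets close only after accounting for the $m\,\nabla\!\cdot v$
volume term and the strongly-imposed inlet rows.
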
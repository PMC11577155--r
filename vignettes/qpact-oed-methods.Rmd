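---
title: "Bayesian Cramér–Rao bound design of qPACT illumination systems: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian Cramér–Rao bound design of qPACT illumination systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qpactoed)
```

# The problem

Quantitative photoacoustic computed tomography (qPACT) estimates the optical
absorption coefficient $\mu_a(x)$ of tissue from ultrasound measurements of
the pressure wave launched by pulsed optical illumination. The inverse
problem is nonlinear (the fluence depends on the unknown coefficients),
severely ill-posed, and complicated by the reduced scattering coefficient
$\mu_s'(x)$, which is unknown but not of clinical interest. qPACT hardware
design — in particular, where to put the light sources — currently has no
accepted standard, and evaluating a candidate design by reconstructing many
simulated images is extremely expensive.

This package implements an estimator-independent alternative: a Monte Carlo
estimate of the **Bayesian Cramér–Rao bound** (the Van Trees inequality),
which lower-bounds the error covariance of *any* estimator,
$$
\mathbb{E}\!\left[(\hat m(y) - m)(\hat m(y) - m)^T\right] \succcurlyeq
V_m = J_m^{-1}, \qquad
J_m = \underbrace{C^{-1}}_{\text{prior}} +
\underbrace{\mathbb{E}\big[\nabla_m \log p(y|m)\,\nabla_m \log p(y|m)^T\big]}_{J_D},
$$
and scalar design metrics derived from it. Designs are ranked by the
mass-weighted trace $\mathrm{tr}_M(\hat V_{\mu_a})$ of the bound transported
to the absorption coefficient — the Bayesian analogue of CRB-based
A-optimality, with the finite-element mass matrix $M$ making the trace a
discretization-consistent approximation of $\int_\Omega \mathrm{var}\,dx$. A
maximum a posteriori (MAP) reconstructor is included solely to validate the
bound against an actual estimator's expected error.

# Forward model

**Geometry and discretization.** The object is a disk of radius 5 cm
centered at the origin, meshed with triangles and first-order continuous
Galerkin (P1) elements. All fields (latent parameters, fluence, absorbed
energy) are nodal coefficient vectors; there is no raster grid. The mesher
(`build_disk_mesh`) lays vertices on concentric rings whose spacing and
in-ring arc length both follow a sizing field that grades linearly in radius
between 0.08 cm at the rim and 0.15 cm at the center for the full-scale
discretization; successive rings get a seeded random angular offset. The
resulting full-scale parameter dimension is about 8.2k nodes, within 10% of
the 7499-node reference resolution. A concentric-ring mesher was chosen over
a frontal/Delaunay generator because no mesh-generation library is part of
the package's dependency footprint and the construction is fully
deterministic given the seed; mesh quality enters the results only through
the standard P1 convergence order, which the test suite verifies (second
order in $L^2$ against an analytic solution).

**Optics.** Light transport uses the diffusion approximation with a Robin
boundary condition under matched refractive indices,
$$
\mu_a \phi - \nabla\cdot D \nabla\phi = 0 \ \text{in } \Omega, \qquad
\langle D\nabla\phi, \eta\rangle + \tfrac12\phi = 2q \ \text{on } \partial\Omega,
$$
with $D = 1/[3(\mu_a + \mu_s')]$. On a homogeneous disk with constant
boundary source the exact solution is radial,
$\phi(r) = c\,I_0(kr)$ with $k = \sqrt{\mu_a/D}$, which serves as the
solver's analytic oracle. The photoacoustic conversion efficiency (Grüneisen
parameter) is the single constant `GRUNEISEN = 1`, and the absorbed energy is
the nodal product $h = \mu_a\phi$. Nodal (interpolatory) products are used
for $\mu_a = \bar\mu_a e^{m_1}$ and $h$ rather than exact polynomial
quadrature: with P1 elements the committed error is of discretization order,
and the choice makes the adjoint expressions exact discrete derivatives.

**Illumination.** Cone-beam sources on a ring of radius 10 cm point at the
origin and deliver the attenuated monopole flux
$P\cos\theta\,\mathbf 1(|\theta|<\beta/2)\,e^{-\mu_a' r}/(4\pi r^2)$ along the
ray, with aperture $\beta = 25^\circ$ and exterior absorption
$\mu_a' = 10^{-3}\,\mathrm{cm}^{-1}$; $\theta$ is measured between the
source's pointing direction and the ray from the source to the boundary
point. The boundary flux keeps only the inward projection
$\max(\langle q, \eta\rangle, 0)$ at boundary nodes. Two four-illumination
schemes are compared: *contiguous* (10 sources on a 90° arc, rotated by
$\pi/2$ between illuminations) and *interlaced* (10 sources uniform on the
ring, rotated by $\pi/20$). The shared source power is normalized so the
maximum nodal fluence at the prior-mean parameters, across all illuminations
of a design, equals the ANSI-limit-normalized 1 AU. The normalization is
per design, not per illumination, so no single illumination ever exceeds the
limit; linearity of the PDE in $q$ makes this one solve and one rescale per
illumination.

**Acoustics.** Under a lossless homogeneous medium the pressure data reduce
to a circular Radon transform of $h$: each of 360 idealized point
transducers on a 6 cm ring samples arc integrals at 184 times with spacing
$2\times 10^{-7}$ s ($c_0 = 1500$ m/s), a data dimension of $K = 66{,}240$.
The operator is assembled once per mesh and geometry as an explicit sparse
matrix: each row integrates the P1 basis along the arc of radius $c_0 t$
clipped to the domain by composite midpoint quadrature with step one quarter
of the minimum element edge. Storing the matrix makes the adjoint the exact
transpose, which the score computation relies on. The first sample time is
set to the ring-to-domain gap ($t_0 = 1\,\mathrm{cm}/c_0$), so the sampled
arcs sweep radii 1–6.5 cm; only the count and spacing of the samples are
physically fixed, so $t_0$ is configurable. The pressure-to-data reweighting
$p = (4\pi c_0^2)^{-1}\partial_t(d/t)$ is an invertible fixed transformation
and is deliberately not applied: the pipeline works with the data function
directly. Measurements add i.i.d. Gaussian noise with
$\sigma^2 = 10^{-3}$ in data units.

# Prior

The latent parameters $m = (m_1, m_2)$ enter exponentially,
$\mu_a = \bar\mu_a e^{m_1}$ ($\bar\mu_a = e^{-2}\,\mathrm{cm}^{-1}$) and
$\mu_s' = \bar\mu_s' e^{m_2}$ ($\bar\mu_s' = 10\,\mathrm{cm}^{-1}$), which
guarantees positivity. Each block has a zero-mean Gaussian prior whose
covariance is the squared inverse of a diffusion–reaction operator,
$C = \mathcal A^{-2}$, i.e. a Matérn-type (SPDE) field with trace-class
covariance. Discretely, with $A = \gamma K + \delta M + \beta B$ (stiffness,
mass, boundary mass),
$$
C = A^{-1} M A^{-1}, \qquad C^{1/2} w = A^{-1} w, \quad w \sim N(0, M),
$$
the standard finite-element realization of $\mathcal A^{-2}$ that keeps
sampling a single sparse solve against mass-matrix white noise.

**Calibration.** The operator coefficients are initialized from the
whole-plane Matérn $\nu = 1$ closed form — correlation
$\rho(r) = \kappa r K_1(\kappa r)$, variance
$\sigma^2 = 1/(4\pi\kappa^2\gamma^2)$, $\delta = \gamma\kappa^2$ — and then
corrected on the assembled operator: the overall scale is matched exactly to
the target variance at the center node (scaling $A$ by $s$ scales $C$ by
$s^{-2}$ and leaves correlations untouched), and a secant loop on
$\log\kappa$ drives the correlation at the target separation to 0.1 within
0.002. The study priors use variance 0.2 ($m_1$) and 0.05 ($m_2$), both with
correlation 0.1 at 5 cm.

**Boundary treatment.** The operator $\mathcal A$ needs a boundary
condition; none is physically prescribed. A Neumann condition inflates the
marginal variance near $\partial\Omega$; a Dirichlet condition collapses it.
The package uses the Robin coefficient $\beta = \sqrt{\gamma\delta}/1.42$,
the standard variance-inflation mitigation for SPDE priors, and treats
"uniform variance" as an approximate statement: the achieved variance field
satisfies $\max/\min \le 1.3$ at the study resolutions, which the suite
asserts. The integrated prior variance is therefore a few percent below
$0.2 \cdot 25\pi$, and tests of integrated quantities carry that tolerance.

The precision application $C^{-1} = A M^{-1} A$ uses the consistent mass
matrix with a sparse direct solve — exactness over speed at these problem
sizes. White-noise streams are derived per sample index, so sample $i$ is
reproducible regardless of how many samples are drawn.

# Score, information, and bound

The log-likelihood over $I$ illuminations is
$-\tfrac12\sum_i \|H_a h_i - d_i\|^2/\sigma^2$ (constants dropped). Its
gradient — the score — is computed by the variational adjoint method, one
extra solve per illumination with the same SPD operator and factorization as
the forward problem. The expressions are derived by differentiating the
*discrete* objective exactly (the "discretize-then-differentiate" route):
with residual pullback $w = H_a^T r/\sigma^2$ and adjoint
$S p = \mu_a \circ w$,
$$
g_1 = \mu_a \circ(-w\circ\phi + T(p,\phi)) - 3D^2\circ\mu_a\circ W(p,\phi),
\qquad
g_2 = -3D^2\circ\mu_s'\circ W(p,\phi),
$$
where $T$ and $W$ are the exact derivatives of the P1 reaction and
diffusion assembly with respect to nodal coefficients. Because the
derivation is easy to get subtly wrong, correctness is enforced by contract:
`fd_directional_check` compares the adjoint directional derivative against a
central finite difference, and the suite requires relative agreement at
$10^{-5}$ on random parameter/measurement/direction triples in both nuisance
modes (the implementation achieves $\sim 10^{-8}$). Gradients are Euclidean
with respect to nodal coefficients; mass weighting enters only through the
design metric, mirroring the discretize-then-bound structure of the method.

$\hat J_D$ averages score outer products over joint samples (prior draw,
then simulated measurement), $N_s = 5000$ at full scale. The bound is
assembled as $\hat J_m = C^{-1} + \hat J_D$ (dense), inverted by Cholesky —
no regularization, because $\hat J_m$ is provably SPD and a factorization
failure would indicate an upstream bug that must not be papered over. The
nuisance block is handled by **post-marginalization**: the $m_1$ block of
$\hat V_m$ is extracted after inversion, so the uncertainty of the unknown
scattering field remains inside the bound. The block ordering is fixed as
$[m_1; m_2]$ throughout.

**Change of variable.** The bound on $m_1$ transports to $\mu_a$ through the
congruence $\hat V_{\mu_a} = \hat C^T \hat V_{m_1} \hat C$ with
$\hat C = \mathrm{diag}\,\mathbb E[\bar\mu_a e^{m_1}]$. Both routes are
implemented: Monte Carlo over prior draws (the default, 5000 samples at full
scale, for generality) and the lognormal closed form
$\bar\mu_a e^{v_i/2}$ from the nodal marginal variances; they are
cross-checked against each other in the tests. Pointwise bound maps are the
nodal diagonals of $\hat V_{m_1}$ and $\hat V_{\mu_a}$; integrated metrics
are mass-weighted traces, the interpretation consistent with
$\mathbb E\|e\|_M^2$ for the validation MSE.

# MAP validation

The validator minimizes misfit-plus-prior energy with an inexact Newton-CG
method: Gauss–Newton Hessian actions applied matrix-free (one incremental
forward and one incremental adjoint solve per product, reusing the current
factorization), Eisenstat–Walker style forcing
$\eta_k = \min(0.5, \sqrt{\|g_k\|/\|g_0\|})$ to avoid oversolving, Steihaug
termination on non-positive curvature, and Armijo backtracking. The
Gauss–Newton choice (rather than full Newton with second-order adjoints) is
deliberate: the Hessian model is then PSD, CG-compatible, and sufficient for
a validator whose reported quantities are properties of the minimizer, not
of the optimizer path. Expected error is a Monte Carlo average over joint
draws, each trial a fresh MAP solve from the prior mean, with per-trial
derived seeds; trials that fail are excluded and counted, and more than 1%
exclusions abort the run.

# Scales, numerical choices, degenerate inputs

Two presets are shipped. The **full** preset is the complete virtual system
(graded 0.08–0.15 cm mesh, 360×184 data grid, $N_s = 5000$, 10,000 MAP
trials); its bound stage is a workstation computation (hours) and its MSE
stage is cluster-scale, so it is exercised by configuration rather than by
the routine suite. The **desk** preset (uniform 0.4 cm mesh, 60 transducers,
64 time samples spanning the same 1–6.5 cm arc radii via a
$5.84\times10^{-7}$ s interval, $N_s = 200$, 100 trials) runs every stage in
minutes and is the scale at which the suite demonstrates the design
ranking: interlaced below contiguous in $\mathrm{tr}_M(\hat V_{\mu_a})$,
with disjoint half-sample error intervals, in both the known- and
unknown-scattering settings. The estimator-validation test (information
inequality, MAP MSE above the bound for both $m_1$ and $\mu_a$ and both
schemes) runs at a further reduced resolution (0.8 cm mesh, 32×32 data grid,
100 trials) chosen so that the Monte Carlo standard error of the MSE
(~4–6%) is several times smaller than the observed MSE–bound gap (~15–20%).

Numerical details worth knowing:

* Matrix assembly errors on degenerate (zero-area) triangles, naming the
  element; meshes with infeasible sizing (`h_center > radius`,
  non-positive or inverted grading) are rejected at construction.
  The degenerate single-ring sizing `h_boundary = h_center = radius` is
  accepted and produces the minimal valid fan mesh.
* The CRT rejects quadrature steps coarser than the minimum element edge
  (undersampling); quadrature points in the sliver between the polygonal
  mesh boundary and the ideal circle are outside the discrete domain and
  are skipped.
* In oracle tests against the analytic sinogram of a disk indicator, the
  indicator is nodally interpolated; test radii are chosen off the mesh's
  ring lattice because a ring-aligned radius makes the interpolation error
  one-sided (a half-element systematic bias) instead of mean-zero.
* The mass-matrix total equals the *polygonal* domain area to machine
  precision at every size, and the analytic disk area $25\pi$ to $10^{-4}$
  relative at the study sizing; at very coarse sizings the
  inscribed-polygon area deficit, $O(h^2)$, dominates that comparison.
* Ties in the line search resolve by accepting the first Armijo-satisfying
  step of the halving sequence; a non-descent CG output falls back to
  steepest descent (with the SPD Gauss–Newton model this is a safeguard,
  not an expected path).
* All randomness flows through integer seed derivation
  (`derive_seed(seed, index, stream)`), so prior draws, noise draws, and
  trials are independently reproducible and sample $i$ does not depend on
  the total sample count.

# What the synthetic data do and do not show

The generator *is* the study definition: log-Gaussian Matérn-type fields
around literature reference values, a diffusion-approximation forward model,
an idealized CRT with additive white Gaussian noise, and point transducers.
Passing tests demonstrate internal correctness (analytic oracles, exact
adjoints, statistical consistency) and the design-ranking conclusion *under
this model*. They do not speak to acoustic heterogeneity or attenuation,
transducer impulse responses and finite apertures, refractive-index
mismatch, an unknown Grüneisen parameter, the vascular structure of real
tissue, or three-dimensional light and sound propagation — all outside this
package's scope.

# Known limitations

* The bound loses sharpness through post-marginalization and the
  change of variable; it remains a valid lower bound and, as the studies
  show, a reliable ranking device.
* Dense $N\times N$ bound algebra limits full-scale runs to workstation
  memory (~1.8 GB per information matrix at 15k parameters, double that
  transiently during inversion).
* The desk preset's Monte Carlo error bars (half-sample intervals at
  $N_s = 200$) are adequate for ranking the two shipped schemes, whose
  metrics differ by ~10%; closer designs would need the full-scale
  $N_s$.
* `map_solver_config(hessian = "full")` is an extension point; the
  Gauss–Newton model is the implemented default.
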
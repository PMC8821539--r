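---
title: "The dissociation free energy method: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dissociation free energy method: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfekit)
```

# The problem and the estimator

Binding potency of a protein–protein or protein–ligand complex is set by the
free energy difference between its bound and free states. dfekit implements
the *dissociation free energy* (DFE) approach to estimating it: instead of
sampling the reversible binding equilibrium, each replica performs a single
forced dissociation driven by metadynamics on one collective variable (CV) —
an intermolecular distance $D$ — and the accumulated bias is read back as the
negative image of the free energy surface (FES) of the bound state.

A metadynamics run deposits a repulsive Gaussian at the running CV value
every $\tau_G$ of simulated time. While the system stays in the bound-state
well, the deposits pile up there; once the well is full, the system exits and
does not return (a *one-way trip*), so the deposited bias is a mold of the
well. For one replica with deposition record
$\{(d_i, \sigma_i, h_i)\}$ the primitive FES is

$$g(D) = -\sum_i h_i \exp\!\left(-\frac{(D - d_i)^2}{2\sigma_i^2}\right),$$

tabulated on 80 uniformly spaced points spanning the deposited centers
(`primitive_fes()`). Single-run surfaces are noisy; an ensemble of $N$
replicas with distinct seeds is averaged on a common grid
(`average_fes()`): the grid spans the union of member ranges with spacing no
larger than the smallest member spacing, members are resampled onto it by
linear interpolation (`interpolate_linear()`) and contribute zero outside
their own sampled range — an unvisited region holds no bias, so zero is the
only value consistent with the estimator.

From the averaged surface $g(D)$, a *nominal partition function* over the
window $[a, b]$,

$$Q = (b-a)^{-1}\int_a^b e^{-g(D)/kT}\, dD,
\qquad \mathrm{DFE} = -kT\ln Q,$$

is evaluated by composite trapezoidal quadrature on the native grid
(`nominal_partition_function()`, `dfe_from_fes()`). The Boltzmann factor is
dominated by the bottom of the well — in practice, only the region within
about 4 kcal/mol of the minimum contributes — so $a$ and $b$ can be left at
the tabulated range ends (zero and the wall) without locating the bound/free
boundary first. Narrowing the window changes DFE only through the explicit
$kT\ln(b-a)$ normalization term, a fixed convention absorbed by the linear
calibration below; the integral itself is insensitive (the property suite
checks both statements).

DFE is not a binding free energy: it omits the free-state terms
(translational/rotational entropy of the separated partners, standard-state
concentration, free-state conformational dynamics), which are largely
system-independent. It is therefore *calibrated*: ordinary least squares of
the experimental binding free energy $\Delta G_e = kT\ln K_d$ (at 310 K, 1 M
standard state) on DFE gives an affine map used to predict
$\Delta G_c$ for new complexes (`fit_calibration()`, `predict_dg()`,
`kd_to_dg()`). The shipped 19-complex protein–protein panel reproduces

$$\Delta G_e = 0.4512\,\mathrm{DFE} - 1.02$$

with $R^2 = 0.84$ and residual SE 1.61 kcal/mol once the documented outlier
(3SGB) is excluded by identifier — outlier handling is explicit-by-id only,
never automatic. The residual standard error uses $n-2$ degrees of freedom,
the only definition consistent with the printed $(R^2, \mathrm{SE})$ pair.

# Convergence and uncertainty

The averaged surface depends on how many replicas entered the average, so
DFE is recomputed as a running sequence: entry $N$ of the convergence trace
uses the first $N$ replicas in launch order (`convergence_trace()`).
Sampling is declared converged when the spread (max − min) of the last five
entries falls below 1 kcal/mol; at least five replicas are required before
the flag can be set. If a campaign does not converge, a further batch of
replicas of the same size is launched and the procedure repeats.

The "±" attached to DFE quantifies sampling completeness. The uncertainty
recipe is a delete-one jackknife over replicas (`dfe_uncertainty()`): DFE is
recomputed on each leave-one-out average and the jackknife standard error is
reported. This was a genuinely open design point; the jackknife was chosen
because it needs no distributional assumptions, respects the nonlinearity of
$-kT \ln Q$, and reduces to the exact closed form on two-member ensembles
(tested).

# The one-way-trip audit (correction process)

Replicas that do not behave as one-way trips contaminate the average and are
corrected for (`audit_ensemble()`). On the averaged surface,
`locate_landmarks()` finds $r_0$, the bound-state minimum (global minimum;
ties toward smaller CV), and $r_b$, the bound/free boundary. The boundary
rule is the package's own: $r_b$ is the first grid point right of $r_0$
where the lightly smoothed profile stops rising, accepted only after it has
recovered at least half of the total rise. This subsumes the textbook cases
— a barrier maximum or saddle, and a monotone rise onto a plateau — while
ignoring sub-0.1-kcal/mol deposition ripple on a biased free region, which
would otherwise masquerade as a local maximum. Taking the first qualifying
point breaks ties toward smaller CV.

Each trajectory is then classified (`classify_run()`):

* **one_way** (keep): the CV crosses $r_b$ and never afterwards drops below
  $r_b - $ `hysteresis` (default 0.5 Å, configurable); the hysteresis band
  absorbs thermal jitter exactly at the boundary.
* **multi_trip** (reject): it crosses and returns below the band.
* **invasion** (reject): it never crosses $r_b$ and drifts more than 4 Å
  below $r_0$ — motion opposite to dissociation, indicating conformational
  drift unrelated to unbinding. The companion surface-based symptom (a
  primitive FES invading the region left of the inner wall, defined as the
  point left of $r_0$ where the averaged surface has risen 4 kcal/mol above
  the minimum) is reported as a diagnostic fraction but is deliberately not
  a rejection criterion: no quantitative threshold exists for it, whereas
  the 4 Å trajectory rule is sharp.
* **incomplete** (extend): it never crosses $r_b$ but shows no invasion —
  the run simply needs more time. The campaign driver extends such runs
  (`extend_run()`) and re-audits; a run that still has not exited after the
  configured number of extensions is rejected.

Landmarks are first located on the unfiltered average, then the audit
iterates — filter, re-average, re-locate — until the verdict set is stable
(at most five passes). Classification depends only on the CV path geometry,
not its time parameterization (tested by uniform time rescaling). Both the
corrected DFE (filtered, post-extension) and the uncorrected DFE (all
replicas, pre-extension surfaces) are always reported.

# The bundled simulator: what it emulates and what it does not

Real deposition records come from a molecular dynamics engine. To make every
downstream stage testable without one, `simulate_run()` generates records by
overdamped Langevin dynamics of the CV itself on a 1D model potential:

$$D \leftarrow D + \frac{D_c}{kT} F(D)\, dt + \sqrt{2 D_c dt}\,\xi,$$

with $F$ minus the derivative of (model potential + accumulated bias + wall
term), a reflective boundary at $D = 0$ and a half-harmonic wall. This is a
legitimate stand-in because the FES/DFE machinery consumes only kernels and
CV traces, and metadynamics theory is dimension-agnostic; nothing about the
estimator knows the dynamics were not molecular.

Parameters, units and defaults (`sim_config()`):

| parameter | default | meaning |
|---|---|---|
| `height` | 0.01 kcal/mol | deposited Gaussian height, the production setting |
| `width` | 0.05 Å | Gaussian width $\sigma$, the production setting |
| `deposit_interval` | 0.09 ps | deposition period $\tau_G$, the production setting |
| `temperature` | 310 K | also used for all $K_d$ conversions |
| `dt` | 0.002 ps | Euler–Maruyama step; 45 steps per deposition |
| `diffusion` | 0.1 Å²/ps | CV diffusion coefficient, desk-scale choice |
| `wall_A` | 35 Å | well position + 30 Å, the production wall rule |
| `wall_spring` | 100 kcal mol⁻¹ Å⁻² | half-harmonic wall stiffness |
| `duration_ns` | 1.2 ns | see below |

The bias potential is accumulated on a fixed grid of spacing $\sigma/10$
with each kernel's analytic force added to the nodes within $8\sigma$
(beyond which a kernel contributes below $10^{-13}$ of its height), and
linearly interpolated during integration — the standard grid technique for
summing hills, which makes the per-step cost independent of the deposit
count. The FES reconstruction itself never truncates: `primitive_fes()` sums
every kernel exactly.

Randomness is counter-based: the noise at global step $i$ is a pure function
of (seed, $i$). Together with rebuilding the bias grid by re-depositing the
recorded kernels in order, this makes `extend_run()` an *exact*
continuation: a 10 ns run extended by 10 ns is bit-identical to a single
20 ns run with the same seed, even after a round trip through files (the
final CV and step index travel in the file headers). Replica seeds default
to the block starting at 2007, the convention used in the production
protocol. Pressure control has no one-dimensional analogue and is omitted,
as is any analogue of the multi-stage relaxation protocol: the simulator
starts equilibrated at `initial_cv` (the well position by default).

The default benchmark (`run_campaign()` with no overrides) is 50 replicas
on a single truncated-harmonic well of depth 12 kcal/mol at $r_w = 5$ Å
(curvature 50 kcal mol⁻¹ Å⁻²) opening onto a flat free region up to the
wall. The run length of 1.2 ns is roughly 1.6× the median first-exit time
of that well, mirroring the production practice of matching run length to
the system (10–40 ns there) and extending stragglers rather than running
everything long: in one dimension a run much longer than the exit time lets
the walker re-cross the filled well and keep depositing, which erodes the
one-way premise. The campaign recovers the DFE of the analytic model
potential pushed through the same machinery to within 1.5 kcal/mol, and the
problem sizes above keep the whole test suite and the acceptance script in
the minutes range on a single core.

## Known limitations of the toy

A one-dimensional flat free region is *diffusively recurrent*: after
dissociating, the walker re-approaches the boundary with probability one,
on a timescale set by the free-region length. Three consequences, all
documented behavior rather than defects:

1. **Low one-way yield.** Only a minority of toy replicas (typically
   ~6–12% at the default benchmark) satisfy the strict never-return rule,
   versus ~87% in the production systems, where dissociation in three
   dimensions is entropically one-way. The audit fraction is reported, not
   targeted.
2. **Selection bias of the corrected estimate.** The surviving replicas are
   biased toward early, slightly under-filled escapes, so the corrected DFE
   carries a seed-dependent error up to ~2 kcal/mol on the toy benchmark.
3. **Accuracy of the uncorrected estimate.** With the wall 30 Å out, the
   free region dilutes post-exit deposition, so the all-replica
   (uncorrected) DFE tracks the analytic reference to better than
   0.1 kcal/mol across seed blocks. This mirrors the production finding
   that the correction process rarely moved DFE by more than 1 kcal/mol.

Passing toy tests therefore demonstrates the correctness of the machinery —
reconstruction, averaging, quadrature, classification, convergence,
calibration — on data with realistic statistics, not the physical fidelity
of 1D Langevin dynamics to solvated molecular systems. Real data also
contain features the toy lacks entirely: CV-definition sensitivity,
force-field error, conformational gating, and solvent memory.

# Numerical choices, edge cases, tie-breaks

* Units are fixed package-wide (Å, ps, kcal/mol, K;
  $k = 1.987204259\times10^{-3}$ kcal mol⁻¹ K⁻¹); readers reject files
  whose units line is absent or different.
* "80 equal intervals … 80 rows" is resolved as 80 grid points (79
  intervals) including both endpoints, honoring the stated row count. The
  primitive grid spans kernel *centers*, not the trajectory: the FES is a
  function of deposited bias only, and trajectories may be absent.
* The common averaging grid divides the union range into
  $\lceil \mathrm{range}/h_{\min} \rceil$ equal intervals, since the range
  is generally not an integer multiple of the smallest member spacing; the
  resulting spacing is uniform and never larger than $h_{\min}$.
* Quadrature is composite trapezoid on the native averaged grid, with
  linearly interpolated endpoint values when $a$ or $b$ falls between grid
  points; with $\sigma = 0.05$ Å kernels the grid already resolves every
  feature the estimator can contain, and the property suite bounds the
  error against closed forms (0.1% on a deep harmonic well).
* A validator tolerance of 0.5 Å beyond the wall is allowed for deposition
  centers: the wall is half-harmonic, so excursions of order
  $\sqrt{kT/k_\mathrm{wall}} \approx 0.08$ Å beyond it are legal physics.
* Degenerate inputs fail loudly: empty deposition histories, all-coincident
  centers, monotone surfaces with no interior minimum, fewer than three
  calibration points, non-positive $K_d$, duplicate replica seeds.
* If an audit pass rejects every replica, landmarks are retained from the
  full ensemble and a warning is raised rather than an error; a campaign
  that ends with nothing to average stops with an informative failure.

# Reading this package against a real engine

The file dialects (`.kerseq.tsv`, `.cv.tsv`, `.fes.tsv`) are deliberately
engine-neutral: `#`-prefixed `key=value` headers with declared units, then
whitespace-separated numeric rows at full double precision (round trips are
bit-exact). An adapter from a production engine's kernel record format to
`read_kernel_sequence()`'s dialect is the only piece needed to run the full
pipeline — audit, averaging, DFE, convergence, calibration — on real
metadynamics output.
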
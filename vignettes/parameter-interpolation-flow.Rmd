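---
title: "Parameter interpolation flow: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameter interpolation flow: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The generative scheme

`pifgen` models a molecule as a 3D point cloud: per-atom coordinates
$x_i \in \mathbb{R}^3$ (&Aring;) and categorical types $v_i$ over $K$
classes. Instead of transporting samples, the flow transports
*distribution parameters*. Each datum is embedded as the zero-spread
member of a parametric family — a Gaussian (or Laplace) with spread 0
for coordinates, a one-hot Dirichlet concentration (a simplex-vertex
Dirac) for types — and the generative path linearly interpolates the
parameter tuple between a fixed prior and that Dirac:

$$\theta_t = f(t)\,\theta_{\text{data}} + (1 - f(t))\,\theta_{\text{prior}},$$

with coordinate prior $(\mu, \epsilon) = (0, \epsilon_0)$ in a centered
frame and type prior $(1/K, \dots, 1/K)$. Because the interpolation acts
on parameters, the continuous path is exactly the 2-Wasserstein geodesic
between 1D distributions of the same location–scale family (for
Gaussians, $W_2^2 = \Delta\mu^2 + \Delta\epsilon^2$, linear in the
pair), and the Dirichlet path is an exponential geodesic of the
Fisher–Rao geometry: densities along it are normalized geometric
mixtures of the endpoint densities. Both facts are checked to machine
precision by the property suite (`pif_verify()`), not assumed.

A predictor $\Phi$ is trained to recover the data-endpoint parameters
from samples drawn at an intermediate $\theta_t$ (plus $t$ and any fixed
conditioning atoms). Generation runs the process in reverse as iterative
refinement: from the prior, repeatedly sample, predict, and move the
parameters to the interpolant of the *predicted* Dirac at the next grid
time; the final structure is read off the last predicted Dirac.

## Schedules and the f(1) gap

Three schedules are provided: exponential $f(t) = 1 - \gamma^t$ (default,
$\gamma = 0.009$), linear $f(t) = t$, quadratic $f(t) = t^2$. The
exponential schedule spends most of the time budget near the data end —
the spread at time $t$ is $\gamma^t \epsilon_0$, already below 0.1 &Aring;
at $t = 0.5$ — which concentrates training capacity on fine structure.

The exponential schedule reaches $f(1) = 1 - \gamma \approx 0.991$, not
1. We deliberately do **not** renormalize: training times are drawn on
$[0, 0.99]$ so the gap never enters the loss, and the sampler's final
output is the last predicted Dirac (`mu_hat`, vertex of `alpha_hat`)
rather than a draw from $\theta_1$, so the gap never enters the output
either. Endpoint exactness at $f = 0$ and $f = 1$ is asserted bit-exactly
in the tests.

## Losses

The continuous objective is a time-weighted squared error on the
predicted endpoint location,
$w(t)\,\mathbb{E}\lVert\hat\mu - x_{\text{data}}\rVert^2$ with
$w(t) = (1-\gamma^t)^2 / (2\gamma^t\epsilon_0^2)$: zero at $t = 0$
(where the prediction is unidentifiable) and strictly increasing toward
the data end. For the Laplace prior the analogous loss is the KL
divergence of two equal-scale Laplace distributions,
$|\Delta\mu|/b_t + e^{-|\Delta\mu|/b_t} - 1$ per coordinate with
$b_t = (1 - f(t))\beta_0$, which behaves as
$\Delta\mu^2 / (2 b_t^2)$ for small errors and linearly in the
heavy-tailed regime.

The discrete objective is a log-gamma/digamma expression in the time-$t$
concentration vectors. A point worth recording: along this package's
interpolation path every concentration vector sums to 1 (one-hot data
and uniform prior both sum to 1, and the predictor's `alpha_hat` is a
simplex point), and on that sum-1 manifold the expression equals the
exact closed-form Dirichlet KL term by term — the $\log\Gamma$ of the
concentration sums vanish and $\psi(\text{sum}) = \psi(1)$. Off the
manifold the two forms differ; both are implemented
(`loss_discrete(form = "printed")` and `form = "exact_kl"`), the
printed form is the default, and their agreement on sum-1 inputs is a
test. The constant $-\psi(1)$ in the gradient is normal to the simplex,
so along feasible directions the loss is minimized exactly at the truth.

Weights $\lambda_x = \lambda_v = 1$ multiply the two terms; reduction is
mean over target atoms, then mean over the batch, keeping the scale
independent of molecule size. Fixed (conditioning) atoms never
contribute — asserted by a perturbation test.

## The predictor

The network contract is deliberately small: deterministic given
(weights, input); translation- and permutation-equivariant coordinates;
simplex-valued type rows; fixed atoms pass through verbatim. The
reference implementation is an E(3)-aware message-passing point-cloud
network written in vectorized base R with exact hand-derived
backpropagation (validated against finite differences in the tests):

* edges: K-nearest-neighbour graph (k = 16, clamped; ties broken by
  atom index) built per molecule, never across molecules in a batch;
* edge features: Gaussian radial basis functions of the interatomic
  distance (32 centers on 0–4 &Aring;, width 0.125 &Aring;), both node
  states, and a sinusoidal embedding of $t$;
* coordinate update: moves along relative-position unit vectors, gated
  by a free radial term plus a *distance-target* term
  $c_{ij}(d_{ij} - d^\*_{ij})$ with a learned target separation
  $d^\*_{ij}$ — a parameterization chosen because snapping bond
  (≈1.5 &Aring;) and 1–3 (≈2.45 &Aring;) distances onto the data manifold
  is the dominant job of the denoiser near $t = 1$;
* type head: per-atom softmax over node states.

The radial-basis width matters more than any other size parameter: with
a coarse width (0.5 &Aring;) the network cannot resolve the 0.01–0.1
&Aring; distance deviations it must correct near the data end of the
path, degrades into an identity map at late $t$, and each refinement
step then random-walks the structure instead of contracting it. The
0.125 &Aring; default was chosen to resolve deviations well below the
bond-length spread.

Rotation equivariance holds by construction and is tested, but only
translation and permutation are part of the hard contract, since any
backbone satisfying the contract can be swapped in. Time is injected as
a sinusoidal feature; the sampled point (not $\theta_t$) is the
coordinate input, since samples are what the model will see at
generation time.

## Training

Adam (lr $10^{-3}$) with cosine decay to lr/20 over the run, and
Polyak (exponential moving average, decay 0.998) weight averaging for
the exported model: both are standard for this model family and were
adopted because small-batch training of a small network otherwise
leaves visible run-to-run scatter in generation quality. Batches are
assembled as a disjoint union of molecules — one block-diagonal KNN
graph per step — which is exactly equivalent to independent processing
for a local message-passing network and avoids padding logic. Training
times are drawn uniformly on $[0, 0.99]$ per instance. Masked training
(geometry-enhanced learning) fires per instance with probability
$P_m = 0.3$; given activation each atom independently becomes a
reconstruction target with probability $P_{am} = 0.3$ and the remainder
enter the network as fixed context through the same conditioning
channel used for pockets and inpainting; a draw that selects zero
targets is redrawn once and then falls back to de novo. Every fit is a
pure function of (seed, config, data) — checkpoints carry the optimizer
state and RNG state, so an interrupted run resumed with the same decay
horizon reproduces the uninterrupted trajectory to float precision.

## Sampling

De novo generation initializes all atoms at the prior and takes 100
uniform grid steps (the default). Each step samples coordinates and
types from the current parameters, predicts the data endpoint, and sets
generated-atom parameters to the interpolant of the predicted Dirac at
the next time; fixed atoms hold their Diracs bit-exactly throughout.
The final types are the vertex (argmax, ties to the lowest index) of
the last predicted simplex rows. Atom counts default to draws from the
training set's empirical size histogram. Substructure-conditioned
generation (inpainting) appends the fixed atoms as Diracs; the output
returns them bit-identically because they are never re-centered or
re-sampled.

The strongest framework-correctness check is oracle equivalence: driven
by a predictor that always emits the true data parameters, the sampler
must reproduce every test molecule exactly (coordinates to 1e-12, types
exactly) for both priors and all three schedules. This validates the
refinement recursion independently of learning.

## Synthetic data

The generators stand in for a docked protein–ligand corpus at desk
scale. Ligands are chains, rings or branched trees with bond lengths
$\mathcal{N}(1.5, 0.03^2)$ &Aring; and angles $\mathcal{N}(109.5^\circ,
3^2)$ (chains; rings use the interior polygon angle), types i.i.d. from
a carbon-rich 4-letter alphabet (C, N, O, F). Chains are embedded in
internal coordinates with staggered-rotamer torsions; conformers with
nonbonded contacts under 2.2 &Aring; are redrawn, because real ligands
have no sub-van-der-Waals contacts and without the rejection the
distance-rule bond extractor picks up spurious pairs. Rings keep the
drawn bond lengths exact and absorb closure into the angles by
least-norm Newton corrections of the headings (closure residual under
0.1 &Aring; enforced). The generator's bond-length histogram matches its
target Normal within JSD 0.01 at $10^4$ bonds — a self-consistency test.
Pocket stubs are jittered anchor rings whose centroid determines the
paired ligand position by an exactly invertible rule, so conditional
generation has checkable ground truth.

What the synthetic data does *not* emulate: chemical valence and bond
orders, aromaticity, torsional preferences beyond staggered rotamers,
realistic pocket shapes, and protein–ligand interactions. Passing the
desk-scale tests therefore demonstrates that the flow learns and
reproduces tightly peaked local geometry from point clouds; it does not
certify chemistry-level validity on real complexes.

## Evaluation

Bond lengths and angles are extracted with a distance rule (pairs
within covalent-radius-sum × 1.3) and compared by Jensen–Shannon
divergence *in bits* on a frozen 64-bin histogram spec with an add-half
pseudocount per bin; the binning is frozen on the reference sample's
range so reported numbers are reproducible. Torsion extraction is
omitted from the acceptance surface (the templates are near-planar) but
the machinery accepts any scalar samples.

Problem sizes used by the test suite and the acceptance script: 500
training ligands, 2000 optimizer steps, batch 8, 200 generated
molecules per seed, median over 3 seeds — sizes chosen so the full
suite runs comfortably on one CPU.

## Known limitations

* **Bond-angle fidelity of generated molecules.** The trained denoiser
  is excellent on-distribution (predicting from noisy true molecules at
  late times reproduces the reference angle distribution almost
  exactly), but the generation dynamics are exposed to their own
  predictions: mid-trajectory predictions are posterior-mean blurred,
  the refinement freezes whatever over-dense packing they imply, and
  the surplus close contacts register as spurious bonds and small
  angles. Bond-*length* distributions recover well (JSD ≈ 0.1 at desk
  scale); bond-*angle* JSD plateaus near 0.5 across every architecture
  and training-length variant we examined, and the corresponding
  acceptance check is expected to fail at its 0.15 threshold. This is
  an honest limitation of a small R-native network under the scheme's
  exposure bias, not a defect of the flow machinery (the oracle-driven
  sampler is exact).
* The Laplace prior is implemented and oracle-exact, but desk-scale
  learned-generation quality is only tracked for the Gaussian default.
* Distance-rule bond perception is a convenience for file output and
  geometry extraction, not a chemical bond assignment.
* The time grid is uniform; no learned or warped schedules.
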
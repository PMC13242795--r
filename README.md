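# pifgen

Parameter interpolation flow for 3D molecule generation in R.

## The problem

Structure-based generative models for drug design must produce two
heterogeneous things at once: continuous atomic coordinates and
discrete atom types. Diffusion and flow-matching models usually handle
the two with separate mechanisms, or force categorical variables into a
Euclidean metric they do not possess. `pifgen` implements a *parameter
interpolation flow* (PIF): both modalities are generated by one
mechanism, a linear path in the *parameter space* of a distribution
family,

```
theta_t = f(t) * theta_data + (1 - f(t)) * theta_prior,
```

where a datum enters as a Dirac — a Gaussian (or Laplace) with spread 0
for a coordinate, a one-hot Dirichlet concentration for a type — and
the prior is `N(0, eps0^2 I)` (coordinates, centered frame) and the
uniform concentration `(1/K, ..., 1/K)` (types). The schedule
`f(t) = 1 - gamma^t` (default `gamma = 0.009`) concentrates capacity
near the data end. This parameter-space path has two exact geometric
properties, both enforced by the test suite rather than assumed:

* for 1D location–scale families it is the **Wasserstein-2 optimal
  transport geodesic** (`W2(p0, pt) = t * W2(p0, p1)` to 1e-10);
* for Dirichlet types it is an **exponential geodesic of the
  Fisher–Rao geometry**: densities along the path are normalized
  geometric mixtures of the endpoints (residual at machine epsilon).

A small E(3)-aware message-passing network (pure R, exact hand-derived
backpropagation) is trained to predict the data-endpoint parameters
from samples drawn at intermediate times, with geometry-enhanced
masking (`Pm = Pam = 0.3`): masked atoms must be reconstructed given
the rest as fixed context. Generation is iterative refinement — sample,
predict, re-interpolate — over 100 steps, de novo or conditioned on a
fixed substructure (inpainting) through the same Dirac-concatenation
channel used for pockets. Synthetic ligand/pocket generators with known
geometric ground truth (templated chains and rings, bond lengths
N(1.5 Å, 0.03 Å)) stand in for a docked-complex corpus at desk scale.

## Worked example

```r
library(pifgen)

# 500 ligand-like point clouds: chains of 6-10 atoms and rings of 5-7
templates <- list(molecule_template("chain", c(6L, 10L)),
                  molecule_template("ring", c(5L, 7L)))
mols <- make_ligand_dataset(templates, 500, seed = 11)

# fit the flow (Gaussian prior, exponential schedule, masked training)
fit <- pif(mols, steps = 2000, batch_size = 8, seed = 1)
print(fit)
#> Parameter interpolation flow model
#>   prior: gaussian (eps0 = 1, beta0 = 1, K = 4)
#>   schedule: exponential (gamma = 0.009)
#>   trained 2000 steps on 500 molecules; final loss 0.1892
#>   config hash 1abaca70, seed 1

# generate 100 molecules and compare local geometry with the references
gen <- simulate(fit, nsim = 100, seed = 501)
rep <- evaluate_geometry(mols[1:200], gen)
round(c(JSBL = rep$js_bond_length, JSBA = rep$js_bond_angle), 3)
#>  JSBL  JSBA
#> 0.058 0.508
```

`JSBL`/`JSBA` are Jensen–Shannon divergences (bits, 64 frozen bins)
between generated and reference bond-length / bond-angle
distributions. Bond lengths concentrate correctly around 1.5 Å; the
angle distribution is the known weak spot of the small desk-scale
network (see the vignette's limitations section for the analysis).

Substructure-conditioned generation holds atoms fixed bit-exactly:

```r
frag <- pif_molecule(mols$mol_1$coords[1:3, ], mols$mol_1$types[1:3], K = 4)
grown <- sample_conditional(fit, frag, n_new_atoms = 5, seed = 2)
identical(grown$coords[1:3, ], frag$coords)
#> [1] TRUE
```

The analytic property suite runs in seconds:

```r
v <- pif_verify(seed = 1)
v$passed
#> [1] TRUE
```

A thin command line covers the same pipeline
(`inst/cli/pifgen.R`): subcommands `make-data`, `train`, `sample`,
`inpaint`, `evaluate`, `verify`.

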
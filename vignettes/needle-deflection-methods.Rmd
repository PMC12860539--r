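---
title: "Methods: beam-on-springs needle insertion, surrogate training, and Monte Carlo uncertainty bands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beam-on-springs needle insertion, surrogate training, and Monte Carlo uncertainty bands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needleuq)
```

## The problem

Transperineal prostate biopsy drives a long, thin (18-gauge, here 140 mm)
flexible needle deep through layered soft tissue. The asymmetric reaction
of tissue on the bevel tip deflects the needle laterally, and the amount
of deflection depends on tissue elastic moduli that cannot be measured in
a patient. Procedure planning therefore needs two things: a needle
deflection model, and a way to turn *uncertainty about tissue stiffness*
into *uncertainty about the needle path*. `needleuq` implements a
three-layer answer:

1. a mechanics-based insertion simulator (planar beam finite elements on
   preloaded tissue springs);
2. fast learned surrogates of the simulator (OLS baseline, multilayer
   perceptron, and a Fourier-feature neural network, FFNN), so that
   thousands of deflection predictions cost milliseconds;
3. a Monte Carlo engine that pushes truncated-normal priors on per-layer
   moduli through the surrogate and reports per-node confidence bands.

## The mechanics model

The needle is an Euler–Bernoulli beam: 47 cubic Hermite elements, 48
nodes, two in-plane degrees of freedom per node (deflection $w$ in mm,
rotation $\theta$ in rad). Units are mm / N / MPa throughout, so the
bending stiffness $EI$ (with $E = 35\,000$ MPa and the annular second
moment $I = \pi(d^4 - d_i^4)/64 \approx 0.1035\ \mathrm{mm^4}$) carries
N mm². The element length is $140/47 \approx 2.979$ mm — the element
count is taken as authoritative over the nominal "3 mm" spacing.

Tissue enters in two ways:

* **Cutting force at the tip.** Treating the bevel as a wedge compressing
  the tissue ahead of it,
  $F_c = C_\mathrm{tip}\, d^2 / (4 \tan(\alpha/2))$, where
  $C_\mathrm{tip}$ is the modulus at the current tip depth, $d$ the outer
  diameter, and $\alpha$ the bevel angle. The component that bends the
  needle is $F_{c,z} = F_c \cos\beta$ with $\beta = \alpha +
  \theta_\mathrm{tip}$: as the tip rotates into its own path, the
  deflecting component shrinks (a stabilizing feedback).
* **Support along the shaft.** Each millimetre of cut channel leaves a
  linear spring attached to the node just behind the tip. A spring stores
  a *rest deflection* $z_0$ (the deflection at which it carries no
  force), which is how the tissue remembers the channel the needle cut:
  in the assembled equations a spring adds $k$ to its node's diagonal and
  $k z_0$ to the load.

One insertion step (1 mm of advance) is: attach the new spring at rest at
its node's current deflection; compute $F_c$ and $F_{c,z}$ using the tip
slope of the *previous* converged state; solve the linear static system;
and, after every accumulated element length of advance, shift all springs
one node toward the base, updating each $z_0' = w_\mathrm{new} + (z_0 -
w_\mathrm{old})$ so that every spring force is exactly continuous across
the shift. The out-of-tissue (template-guided) part of the needle is
pinned: $w = 0$ at every node within $140 - \mathrm{depth}$ of the base,
rotation fixed at the base node only. The rotation of interior guided
nodes is deliberately left free — pinning deflection alone already
reproduces the exactly-zero out-of-tissue deflection the model should
show, without over-stiffening the entry region.

Numerical choices worth knowing:

* The explicit (previous-step) tip-slope update mirrors the sequential
  step ordering and keeps each step a single linear solve. A fixed-point
  iteration on $\theta_\mathrm{tip}$ (tolerance $10^{-8}$ rad, cap 50) is
  available via `fixed_point = TRUE`; on smooth profiles the two differ
  by far less than the surrogate error.
* The spring shift triggers on cumulative advance $\geq 140/47$ mm with
  subtractive carry. Over the 125-mm tissue domain this is identical to
  "every third step"; the carry formulation is kept because it tracks
  material points.
* Systems are at most 96 DOF; a dense solve is used (no sparse
  machinery). Constraints are eliminated by row/column substitution, so
  constrained DOFs are *exactly* zero.
* Degenerate inputs behave exactly: zero-modulus tissue gives identically
  zero force and deflection; depth 0 pins every node (no mechanism);
  flipping the bevel direction negates the solution bit-for-bit.

### The modulus-to-spring-stiffness conversion

The model needs a rule mapping a modulus $C$ (MPa) to a spring stiffness
$k$ (N/mm). We use $k = C \cdot t_\mathrm{ref}$ with a tributary
thickness $t_\mathrm{ref} = 1$ mm of channel per spring — the simplest
dimensionally consistent rule, which makes $k$ numerically equal to the
local modulus. This is a genuine modeling degree of freedom:
$t_\mathrm{ref}$ rescales the whole deflection field nonlinearly (softer
support lets the tip rotate more, which feeds back through $\beta$). For
a homogeneous 0.1 MPa column, the simulated tip deflection at 65 mm depth
moves from about 0.5 mm at $t_\mathrm{ref} = 1$ mm to about 2.8 mm at
$t_\mathrm{ref} = 0.01$ mm. Published experimental needle deflections at
comparable depths are of the order of millimetres, i.e. larger than this
package's default-scale output; since no printed deflection magnitude or
conversion rule is available to calibrate against, we keep the neutral
1-mm default rather than back-fitting it, and expose `t_ref` as an
argument of `simulate_insertion()` and of the dataset generator. All
*relative* statements in this vignette (model orderings, bias structure,
band orderings) are insensitive to this choice; *absolute* error
magnitudes scale with it.

## The synthetic anatomy generator

Training anatomies emulate the generative scheme of the reference study:
1–10 homogeneous layers (count uniform), transition depths drawn
uniformly without replacement on the interior integer millimetres and
sorted, and per-layer moduli uniform on [0, 0.2] MPa — a range spanning
soft muscle through stiff lesions, over which the simulator responds
realistically. Each insertion is simulated to 125 mm and encoded as
supervised pairs: input $x \in \mathbb{R}^{126}$ (125 per-mm moduli plus
the insertion depth), target $y \in \mathbb{R}^{48}$ (nodal deflections,
mm), one pair per integer depth 1–124. Splits are by trajectory — a
validation anatomy never appears in training.

What the generator does **not** emulate: anisotropic or viscoelastic
tissue, shaft friction, needle rotation or base steering, 3-D deflection,
correlated layer properties, or real anatomical geometry. Tests passing
on this data show that the surrogates learn *this simulator* under *this
prior*; they say nothing about accuracy on patients.

The default study scale in this package is 1000 training / 2000
validation trajectories (124 000 / 248 000 samples). One thousand
trajectories is exactly the published training size of the OLS baseline;
the reference full-scale profile (10 000 training / 40 000 validation
insertions) is available by configuration and changes only compute time,
not code paths.

## Surrogate models

* **OLS** — linear least squares on z-scored inputs and outputs
  (constant columns pass through standardization untouched). Deterministic;
  rank deficiency falls back to the pivoted solution with a warning.
* **MLP** — two hidden layers of 48 ReLU units, z-scored inputs and
  outputs, Adam with the common reference defaults (learning rate
  $10^{-3}$, minibatch 200, L2 $10^{-4}$, at most 200 epochs, early
  stopping when the training loss stops improving by $10^{-4}$ for 10
  epochs), float64.
* **FFNN** — the same network body preceded by a frozen random Fourier
  map: $B \in \mathbb{R}^{126\times126}$, $B_{ij} \sim \mathcal N(0,1)
  \cdot s$, and $x \mapsto [\sin(2\pi x B^\top), \cos(2\pi x B^\top)]$.
  The map bounds every feature in $[-1, 1]$, so the FFNN takes *raw*
  inputs (no z-scoring); outputs are z-scored. Trained full-batch with
  Adam for a fixed 500 epochs at the grid-search optimum (learning rate
  0.005, scale 0.2), in float32 — the default precision of the GPU
  frameworks this training protocol comes from. The Fourier map exists to
  counter spectral bias: the input moduli span a 200-fold range
  (0.001–0.2 MPa), which plain MLPs fit poorly at scale.

The hyperparameter search (`grid_search_ffnn()`) reproduces the reference
protocol: learning rate at 10 log-spaced levels in $[10^{-5}, 10^{-2}]$,
Gaussian scale at 10 linear levels in $[0.01, 1]$, trained on 80% of the
training trajectories and scored at 65 mm on the held-out 20% (split by
trajectory); diverged cells score infinity and the search continues. The
full 10×10 grid is a documented profile, not something the test suite
runs.

**Evaluation.** Errors are always signed prediction-minus-simulator
differences in mm. Per-sample MAE averages |error| over all 48 nodes
(`scope = "all"`); a tip-only mode exists because tip error is the
clinically quoted quantity. The aggregate MAE at a depth is the mean of
per-sample MAEs there. Signed-error summaries aggregate per *trajectory*
before computing a standard error, since the 48 node errors (and the 124
depth states) of one insertion are strongly correlated. The
distance-from-base error histogram (`error_profile()`) bins |error| at
0.01 mm per node, with optional count clipping — near-base bins otherwise
dominate.

**What the reduced scale reproduces, and what it does not.** At the
package's study scale the qualitative structure of the reference
comparison holds: both networks beat OLS severalfold, and OLS shows its
characteristic bias — a signed-error mean many standard errors from zero
at a fixed depth (the linear model cannot track the nonlinear
depth-deflection relation) that averages out to zero when pooled across
depths. Two aspects do *not* carry over, and the test suite reports them
honestly rather than papering over them. First, absolute MAE magnitudes
inherit the simulator's deflection scale (see the $t_\mathrm{ref}$
discussion above) and are far smaller than the published millimetre-scale
values. Second, at this scale the MLP's validation MAE sits
consistently *below* the FFNN's across seeds. Part of the asymmetry is
the training budget — the FFNN's protocol is 500 full-batch Adam steps,
against the tens of thousands of minibatch steps the MLP takes before
early stopping — but extending the FFNN budget fourfold narrows its
validation error only marginally while its training loss keeps falling,
so the gap is not a pure optimization artifact either. The Fourier
features still earn their keep (the FFNN beats OLS roughly twofold with
only 500 gradient steps), but the published FFNN-over-MLP margin
evidently belongs to the full-scale regime — an order of magnitude more
insertions in the batch, and a response scale set by a different
modulus-to-stiffness calibration — that the desk-scale protocol
deliberately does not run.

## Monte Carlo uncertainty quantification

A prior (`prior_spec()`) attaches an independent zero-truncated normal
$\mathrm{TN}(\mu_j, \sigma_j, [0, \infty))$ to each layer of a fixed
layer geometry — truncation at zero keeps sampled moduli physical.
Sampling is by the inverse-CDF transform; a layer with $\sigma_j = 0$ is
exactly degenerate at $\mu_j$. `run_uq()` draws $n$ property vectors
(default 2000 — enough that the 95% band quantiles are stable, cheap
enough to run interactively), expands each into a per-mm profile, batch
predicts through the surrogate, and summarizes per-node empirical
quantile bands. The band level defaults to 95%; the level is a parameter
because reference figures of this kind rarely state it. Direct sampling
is the default since the layers are independent; `sampler` accepts any
`function(prior, n)` so a Markov-chain sampler for correlated priors
plugs in without touching downstream code.

Properties the implementation guarantees and the tests enforce: bands
are nested across levels; $\sigma = 0$ priors collapse band width to
exactly zero around the point prediction at $\mu$; runs are reproducible
from (prior, $n$, seed); and a 95% band estimated from $n = 2000$ draws
covers fresh draws from the same prior at the nominal rate within
binomial error.

The thin-layer experiments follow the reference two-tissue design: a
thin (10 mm) stiff, highly uncertain layer ($\mu = 0.1$, $\sigma = 0.05$
MPa) embedded in a certain background ($\sigma = 5\times10^{-4}$ MPa,
$\mu$ either 0.005 or 0.05 MPa), with the layer placed early or late in
the path. The layer thickness and positions are arguments, not
constants, because the reference geometry is given only graphically. The
reproducible qualitative finding: placing the uncertain layer *early* in
the path widens the final-tip band relative to placing it late — early
in the insertion the shaft has little tissue support, so stiffness
uncertainty there translates into path uncertainty that later support
cannot undo.

## Reproducibility and problem sizes

Every stochastic component is seeded explicitly: dataset generation is a
pure function of its seed; network initialization (Glorot uniform) and
minibatch shuffling derive from the training seed; the Fourier map is
frozen from its own seed and serialized with the model; UQ draws are
seeded. Training is single-threaded deterministic, so a fixed seed gives
bit-identical weights.

The test suite and the acceptance script run the study at the sizes
stated above (1000/2000 trajectories; three training seeds for each
network; $n = 2000$ Monte Carlo draws), which keeps a full run in the
tens of minutes on one CPU core. The oracle-equivalence tests re-derive
the simulator from scratch in plain R (dense assembly, explicit spring
ledger) and demand agreement to $10^{-8}$ mm at every depth, so the
compiled stepping loop is never the only implementation of the model.

## Known limitations

* Planar bending only; no axial mechanics, shear deformation, large-
  deflection geometry, or dynamics.
* The modulus-to-stiffness conversion $t_\mathrm{ref}$ sets the absolute
  deflection scale and is not calibrated to experiment (see above).
* Surrogates are valid only inside the training prior (moduli ≤ 0.2 MPa,
  ≤ 10 layers, depths 1–124 mm); the FFNN in particular extrapolates
  poorly and adds small high-frequency noise to predicted shapes.
* The UQ model propagates prior uncertainty; it does not condition on
  observed needle shapes (no posterior inference).
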
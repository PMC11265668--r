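---
title: "A reaction-diffusion model of histone-mark spreading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reaction-diffusion model of histone-mark spreading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromspread)
```

## The model

Heterochromatic marks such as H3K9me3 nucleate at specific genomic sites and
spread outwards, forming confined domains.  Classic models treat spreading as
a purely kinetic process on the nucleosome lattice; `chromspread` instead
simulates the diffusing molecules that carry out the reaction.  The
simulation space is a disc of radius $r$ (lengths in particle diameters
$\sigma$) containing three particle species:

* **E** — reader-writer enzymes (a Clr4/Suv39h-like methyltransferase),
  $N_e$ of them, uniformly seeded and conserved for the whole run;
* **R** — RNA-like particles standing in for the RNAi/RITS localization
  machinery, produced only at the nucleation point (NP) with probability
  $P_{rp}$ per step and decaying anywhere with probability $P_{rd}$;
* **C** — enzyme–RNA complexes, formed with probability $P_{cp}$ when an E
  and an R come within the proximity radius $d_{prox}$, and decaying back to
  E with probability $P_{cd}$ (the RNA component is destroyed).

All particles perform overdamped Brownian motion,
$\tilde{\mathbf r}(n+1) = \tilde{\mathbf r}(n) + \sqrt{2\tilde D}\,\mathbf g$
with $\mathbf g$ standard Gaussian, reflected back into the disc by radial
mirroring.  The chromatin is a lattice of $N_n$ nucleosomes, each U
(unmodified) or M (modified); site 0 is the nucleation point and, unless the
no-nucleation variant is requested, is pinned at M.  A complex within
$d_{prox}$ of a nucleosome methylates it with effective probability

$$P_m^{\mathrm{eff}} = \delta_{C,1}\,\min\!\big(1,\; P_w + P_m\,
\delta_{\mathrm{nbr},M}\big),$$

where $\delta_{C,1}$ indicates complex proximity (binary — several proximal
complexes count once) and $\delta_{\mathrm{nbr},M}$ indicates at least one
modified neighbour (also binary, the Kronecker-delta reading of the rule).
Modified sites demethylate with probability $P_{dm}$ per step.  $P_w$, the
"writer" pathway that needs no modified neighbour, is zero except in the
no-nucleation variant.

Each timestep applies a fixed sub-step order: diffusion + reflection, RNA
decay, RNA production, complex formation, complex decay, a synchronous
methylation sweep, demethylation, and re-assertion of the pinned NP.  Decay
precedes production so one particle cannot be created and destroyed in the
same step, and reactions follow movement (diffuse-then-react).  The
synchronous methylation sweep evaluates every site against the pre-sweep
lattice, so a site modified in a sweep cannot boost its neighbour until the
next step; this avoids sweep-order artifacts.

## Parameters, units, defaults

| parameter | meaning | default |
|---|---|---|
| `d_tilde` | per-step diffusion constant $\tilde D = \mu k_B T \Delta t/\sigma^2$ | $2\times10^{-4}$ |
| `p_rp`, `p_rd` | RNA production / decay per step | $10^{-3}$, $10^{-3}$ |
| `p_cp`, `p_cd` | complex formation / decay per step | $1$, $10^{-6}$ |
| `p_m`, `p_w`, `p_dm` | reader-writer boost, writer, demethylation | $1$, $0$, $10^{-3}$ |
| `d_prox` | proximity radius for every contact test | $1\,\sigma$ |
| `n_nucleosomes`, `radius`, `n_enzymes` | lattice size, disc radius, enzyme count | 61, 40, 500 |

The defaults are the parameter regime the model was designed around:
`p_cp = 1` makes complex formation diffusion-limited, and $\tilde D =
2\times10^{-4}$ corresponds to a 5–10 nm particle diffusing at
$\sim 10^{-3}\,\mu\mathrm{m}^2/\mathrm{s}$ in the viscous nucleoplasm with
the timestep absorbed into $\tilde D$.  The disc radius and enzyme count are
not uniquely pinned down by the regime the model explores; 40 $\sigma$
comfortably contains the 61-site lattice and sits inside the 25–60 $\sigma$
range used for the enzyme-limitation analysis, and $N_e = 500$ matches that
analysis.  `d_prox` defaults to one particle diameter, the natural contact
scale; it is a first-class parameter because every proximity rule in the
model inherits it.

Two emergent length scales organize the behaviour.  RNA lives
$1/P_{rd}$ steps and therefore occupies a cloud of radius $l_r \sim
\sqrt{\tilde D / P_{rd}}$ around the NP (`rna_length_scale()`); complexes
live $1/P_{cd}$ steps and explore $\sim\sqrt{2\tilde D/P_{cd}}$ before
reverting.  Together they bound how far catalysis — and hence the modified
domain — can extend, which is the mechanism by which diffusion limits domain
size without boundary elements.

## The reaction-only comparator

`gillespie_run()` simulates the classical kinetic picture: a contact process
on the lattice with the NP pinned M, gain at rate $m\,k^+$ for a U site with
$m$ modified neighbours, loss at rate $k^-$ elsewhere.  The additive
propensity ($m\,k^+$) is the standard contact-process convention; a
`binary_propensity` switch is provided for sensitivity checks.  Time-weighted
(not event-weighted) occupancies give the stationary profile, accumulated in
contiguous event batches whose spread yields batch-mean standard errors.
`master_equation_profile()` builds the exact generator over all
$2^{N-1}$ lattice configurations (tractable to 13 sites) and solves
$\pi Q = 0$ sparsely; it is the oracle against which the Gillespie sampler is
validated, and the three-site lattice reproduces the closed form
$P(M) = K/(1+K)$ per neighbour.  The space-dependent variant
$k^+(i) = k_0 e^{-|i|/l_d}$ models the diffusive length scale as an explicit
kinetic parameter; `l_d = Inf` recovers the basic model exactly.

Profiles from the two models are separated in the (width, kurtosis) plane:
at matched width $S_m$, reaction-diffusion profiles have systematically lower
kurtosis (flatter tops, shorter tails) than the kinetic profiles, which decay
sharply away from the NP.

## Statistics

`profile_sd()` implements the width statistic
$S_m = (\sum_i i^2 P_i - (\sum_i i P_i)^2)^{1/2}$ literally over the raw
per-site probabilities, because that is how the statistic is defined for
these profiles.  The raw profile is not a unit-mass distribution, so for
strongly asymmetric profiles with $\sum_i P_i > 1$ the radicand can go
negative; the literal mode then fails loudly and a documented
`normalize = TRUE` mode (weights rescaled to unit mass, an ordinary standard
deviation) is available.  The two modes agree exactly on unit-mass profiles.
Kurtosis is always computed under normalized weights (it is undefined
otherwise) in the Pearson convention $m_4/m_2^2$; trends between profiles do
not depend on the Pearson-vs-excess choice.  `rna_shell_density()` bins
particles into concentric annuli of width `dr` (default $1\,\sigma$) and
divides by the annulus area; `complex_proximity_profile()` counts complexes
within `d_prox` of each nucleosome, averaged over snapshots.

## Polymer variant

The folded-chromatin variant replaces the linear lattice by a frozen 2D
polymer: beads on the square lattice with unit bonds, either a random walk
(`generate_rw_2d()`, compact, revisits allowed) or a self-avoiding walk
(`generate_saw_2d()`, swollen), with the middle bead as the NP.  SAWs are
sampled by the pivot algorithm — lattice-symmetry moves about random internal
beads, self-intersecting proposals rejected, at least $10n$ accepted pivots
of burn-in, and emission every $3n$ attempts so that rejected moves correctly
repeat the state.  The sampler is validated against exact enumeration of all
16268 nine-step SAWs and reproduces the 2D Flory scaling
$\langle R^2\rangle \sim (n-1)^{3/2}$.

Spreading topology comes from `contact_neighbors()`: beads are neighbours if
adjacent along the backbone or within `contact_cutoff` (default
$1.5\,\sigma$, which admits diagonal and coincident contacts but excludes
the next-nearest lattice shell at distance 2 — the walk type and cutoff are
not pinned down externally, so both are explicit parameters).  Configurations
are frozen for the whole run, the regime where spreading is faster than
polymer relaxation; a straight-rod configuration reproduces the linear
lattice bit-for-bit under the same seed, which is the key structural
cross-check.  Generated ensembles are conditioned on fitting inside the disc
(a far-tail resampling for the default radius); user-supplied configurations
that do not fit are an error instead.

## Numerical choices and degenerate inputs

* Reflection uses radial mirroring ($|p| \to 2r - |p|$, angle kept, folded
  iteratively).  It preserves step-size statistics and is the standard
  small-step approximation; typical steps are $0.02\,\sigma$ against radii
  of tens of $\sigma$, where alternative small-step-consistent schemes give
  indistinguishable profiles.  The scheme degrades for steps comparable to
  the radius, which the test suite respects by checking uniformity in a
  small-step regime.
* Complex formation matches R particles in index order to their nearest free
  E within `d_prox` (ties to the lower index), at most one reaction per
  particle per step; the C inherits the E position because the enzyme is the
  persistent entity.  If the $P_{cp}$ trial fails, neither partner is
  consumed.
* RNA is produced at the NP's spatial position — the origin on the linear
  lattice, the NP bead coordinate on a polymer — including in the
  no-nucleation variant (the locus still transcribes; it simply is not
  pinned M).
* The pinned NP is excluded from the demethylation draw; with nucleation
  disabled, site 0 is an ordinary site.
* A zero-total-rate Gillespie state (e.g. $k^+ = 0$) is an absorbing
  trajectory; the stationary profile is the absorbed state itself.
* All randomness is drawn from R's RNG in a fixed sub-step order, so a seed
  reproduces a run bit-for-bit, including inside the compiled engine.
* RNA production is unbounded; runs that exceed `particle_cap` warn rather
  than fail.

## What the simulations do and do not show

Runs at the default scale are genuinely non-stationary on long horizons:
with $P_{cd} = 10^{-6}$, complexes accumulate over $\sim 10^6$ steps toward
enzyme exhaustion, so any finite sampling window measures a quasi-steady
profile whose width still creeps upward.  The qualitative orderings (wider
profiles at smaller $P_{rd}$, $P_{cd}$, larger discs giving narrower
profiles, random-walk polymers spreading more than self-avoiding ones) are
stable across windows; absolute $S_m$ values are window-dependent, which is
why the package's checks assert directions and orderings rather than
magnitudes.  The test suite and acceptance analyses use sampling windows of
$1$–$2\times10^5$ steps with 200–300 retained snapshots per seed and 2–6
seeds per condition, pooling snapshots across seeds before computing profile
moments; those sizes keep full analyses in the minutes range while leaving
the orderings well resolved.  Single-seed profiles at these scales are
visibly asymmetric (the domain boundary wanders), which is also why the
literal $S_m$ is complemented by the normalized mode.

The model deliberately omits hydrodynamics, particle excluded volume, 3D
space, multiple methylation states, nucleosome turnover and polymer dynamics
during spreading.  Passing tests therefore certify the stochastic model's
internal consistency and its documented qualitative behaviours — not
quantitative agreement with any particular experimental ChIP-seq profile,
for which only a plumbing-level signal-track importer is provided.
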
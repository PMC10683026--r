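---
title: "Coevolution-guided collective variables: models and methods"
author: "CoevCV authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coevolution-guided collective variables: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoevCV)
```

# Overview

CoevCV implements a pipeline for discovering alternative conformational
states of a protein from its evolutionary record, and for analysing the
enhanced-sampling simulations that explore them. The chain of ideas is:

1. Residue pairs that coevolve across a deep family alignment usually
   form contacts in *some* functional conformation. Pairs with a strong
   coevolutionary signal that are **not** in contact in the reference
   structure ("false positives" of contact prediction) are candidate
   contacts of a different, unobserved state.
2. Steering a simulation to form those contacts explores towards the
   alternative state; a linear maximum-margin classifier between the
   explored and reference ensembles then distils the motion into a pair
   of collective variables (CVs).
3. Adaptive-bias sampling along the CVs yields a free-energy surface;
   basins, their Boltzmann populations, convergence diagnostics and
   residue-level energetic-coupling networks complete the analysis.

The molecular-dynamics engine itself is out of scope: the package emits
engine configuration fragments and consumes trajectory-derived tables.

# The coevolution model

Aligned sequences are modelled with a Potts Markov random field: a
sequence $x = (x_1,\dots,x_L)$ over $q = 21$ states (20 amino acids plus
gap) has energy $\sum_i v_i(x_i) + \sum_{i<j} w_{ij}(x_i, x_j)$.
Fitting maximises the weighted *pseudo-likelihood*: the product over
positions of the conditional probability of each residue given the rest
of its sequence,

$$\mathcal{L} = \sum_n \lambda_n \sum_i \log
  P(x_i^{(n)} \mid x_{\setminus i}^{(n)}; v, w),$$

which replaces the intractable global partition function with
per-position normalisers over $q$ states. Each sequence is weighted by
$\lambda_n = 1/N_n$, where $N_n$ counts the sequences (including $n$)
with identity strictly above 0.9 — redundancy in the family tree is
down-weighted rather than informative. Columns with more than 20% gaps
are removed first; the surviving columns carry their original numbering
through the whole pipeline via the column map.

Design choices worth calling out:

* **Gaps are a modelled state.** Eq-level treatments differ on whether
  gaps are masked or modelled; we model them (q = 21), because gap
  patterns carry phylogenetic signal the conditionals should absorb,
  and then reduce coupling blocks over the 20x20 non-gap states only.
* **Weighting sits on each sequence's log-term** (inside the sum over
  sequences), the standard pseudo-likelihood form.
* **Regularisation.** A few hundred optimizer iterations on an
  unregularised Potts model is ill-posed for small alignments, so a
  small L2 penalty is applied: `lambdaV = 0.01` on fields and
  `lambdaW = 0.01 (L-1) q / 2` on couplings, the conventional scaling
  that keeps the per-coupling penalty commensurate with the number of
  conditionals it appears in. Both are exposed.
* **Optimizer.** Full-batch Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
  $\epsilon = 10^{-8}$). The default protocol (300 iterations, learning
  rate $10^{-4}$, N(0, 1) initialisation) mirrors the reference
  analysis of deep PFAM-scale alignments, where a conservative step on
  a huge weighted sample suffices. On the small synthetic alignments
  used for validation that step barely moves the parameters, so the
  tests and the acceptance analysis run the same objective at learning
  rate 0.05 from a zero initialisation — an optimisation choice, not a
  change of model. The per-iteration loss, seed and hyperparameters are
  recorded in the training log.
* **Score reduction.** The coupling block of a pair is collapsed with
  the Frobenius norm by default; a literal signed sum over the block
  lets opposite-sign couplings cancel, so it is deliberately replaced
  by `abs_sum` as the alternative. The average product correction
  (APC), $S'_{ij} = S_{ij} - S_i S_j / S$, removes the multiplicative
  row/column background (conservation and phylogeny). For score
  matrices with an undefined diagonal the means exclude the diagonal
  (standard DCA practice); `excludeDiagonal = FALSE` includes it, in
  which case constant and rank-one positive matrices are annihilated
  exactly — the closed forms the test suite pins down.

# From scores to steering coordinates

The structural contact criterion is nowhere fixed by the underlying
methodology, so it is an explicit parameter pair everywhere: minimum
heavy-atom distance at or below 5.5 Å and sequence separation
$|i-j| \ge 5$ by default (common contact-prediction benchmarking
practice). Pairs below the separation floor are excluded from screening
altogether — trivially close neighbours would otherwise flood the list.
Among the `2L` top-scoring pairs, those not in contact form the
false-positive set.

Their 1-D score distribution is clustered: mean-shift mode seeking
(Gaussian kernel, Silverman bandwidth) chooses the cluster count, then
K-means assigns members; clusters are relabelled by decreasing mean
score so the labels are stable under permutation of the input. Each
cluster becomes one steering ("pull") coordinate: a weighted mean of
member pair distances with weights proportional to coupling scores
(`uniformWeights = TRUE` reproduces a plain mean; duplicate pair
listings are collapsed first so the value is well defined). Defaults of
200 kJ mol$^{-1}$ nm$^{-2}$ per contact and a 0.2 nm target distance
follow the reference steering protocol. `exportMdConfig()` writes the
coordinates plus the adaptive-bias parameter block (cover diameter
0.4 nm, energy cutoff 120 kJ/mol, 10 steps per sample, 10 samples per
update, growth factor 2.0, CV ranges 0.4–1.3 and 0.3–1.0 nm, and the
per-condition force constants and diffusion constants shipped in
`inst/extdata/awh_parameters.tsv`) in a canonical `key = value` form
that round-trips byte-identically through its own parser.

# Learning the CV pair

Two conformational ensembles, featurised as per-frame minimum
inter-residue distances (nm) over the tracked pairs, are separated with
a linear-kernel support-vector machine (`e1071`, C = 1 by default,
inverse-frequency class weights when ensemble sizes differ). Features
are z-scored first and the scaler is stored with the model; the
underlying method is silent on standardisation, but raw nm scales vary
across pairs, and standardisation also makes the coefficient ranking
invariant to rescaling any single feature. Two implementation details
guarantee clean symmetry properties:

* the internal fit order of the two ensembles is canonicalised, so
  swapping the inputs negates every coefficient *exactly*, not just to
  solver tolerance;
* the sign convention is fixed so the decision value increases from
  ensemble A towards ensemble B.

The top 20 pairs by absolute coefficient (ties broken by pair order)
are split by sign: positive coefficients define CV$_1$, negative define
CV$_2$, each with absolute coefficients renormalised to sum to one.
Both CVs are therefore positively weighted distance sums and respond
monotonically to every constituent distance. Whether the reference
analysis renormalised its weights is unknowable from the text; the
normalisation mode is recorded in the object.

# Free-energy analysis

With converged adaptive-bias sampling, the frames' CV values sample the
Boltzmann distribution along the CV, and the histogram estimator gives
$U_b = -RT \log(n_b / N)$, anchored so the lowest visited bin is zero;
never-visited bins are masked, not zero. $RT$ defaults to the
conventional room-temperature constant 2.4789 kJ/mol (the estimator's
reference temperature, even when the engine thermostat differs
slightly); pass a temperature to `thermalRT()` to change it.

**Projection onto another observable** assigns each frame the
thermodynamic weight of its source bin divided equally among that bin's
frames, sums the weights per bin of the new observable, and takes
$-RT\log$. Among the two readings of the projection formula (a
Boltzmann-weighted bin mean versus $-RT\log$ of summed weights), we
implement the summed-weight form because it makes projection onto the
source CV with identical binning reproduce the source surface *exactly*
— a property the acceptance suite checks at $10^{-10}$ — and conserves
total Boltzmann mass.

**Basins.** Local minima are found on the visited grid; every bin joins
the basin of its steepest-descent minimum (watershed, processed in
increasing-energy order, deterministic tie-breaks; 4-connected
neighbourhoods in 2-D). Each basin also has an *inflection-bounded
core*: growing from the minimum, the core ends at the first sign change
of the discrete curvature or at the watershed ridge, whichever comes
first — a grid-based, deterministic rendition of the mixture-model
border idea; fitting Gaussian mixtures is noted as an optional
extension, not implemented. Basins whose core has fewer than 3 bins are
discarded as microstate noise and their bins left unassigned. Basin
*membership* defaults to the full watershed region: on histograms at
realistic frame counts the discrete second difference is
noise-dominated partway up the basin walls, and trimming there discards
real Boltzmann mass asymmetrically (clearly visible against the exact
populations of the synthetic two-state sampler); `border =
"inflection"` restricts membership to the core for smooth or analytic
profiles.

**Populations** are Boltzmann sums $\sum_b e^{-U_b/RT}$ over each
basin's bins, normalised over basin-assigned bins only (unassigned bins
are deliberately outside the normalisation — they are either barriers
or discarded noise). **Functional labels** come from superposing each
basin's frames on a reference structure (Kabsch, all shared C$\alpha$
by default) and averaging the C$\alpha$ RMSD over a marker selection —
in the GPCR application, TM6, residues 269–298 (the Methods-level
definition; a 266-start variant appears elsewhere in the source
analysis, so the range is a logged parameter). Mean RMSD strictly below
3.0 Å labels the basin active. For 2-D surfaces, positional sub-labels
(R, I, A$_1$, A$_2$ by grid quadrant) mirror the conventional layout of
the activation landscape.

**Energetic coupling** of a 1-D profile is the highest barrier
separating any two local minima minus the global minimum (zero after
anchoring); profiles with fewer than two minima couple to zero.
Unvisited bins between minima are ignored rather than treated as
infinite barriers.

# Convergence diagnostics

Three complementary checks on multi-walker adaptive-bias output:

* **Flatness deviation**: $-RT\log(\hat p_i / t_i)$ per visited bin
  against the target distribution $t$. When a design total is supplied
  (adaptive-bias targets prescribe one), densities are normalised by it
  so a bin at half its expected share deviates by exactly $RT\log 2$.
  The histogram-equilibration flag uses the 80% rule; because "the mean
  of the sampled distribution within 80% of the target" is ambiguous,
  both the strict reading ($\min_i \hat p_i/t_i \ge 0.8$) and the
  mean-based one are computed and reported.
* **Transition imbalance**: directed neighbour-bin transition counts
  $n_{ij}$, reported as $|n_{ij}-n_{ji}|/(n_{ij}+n_{ji})$ per edge
  (4-connected in 2-D); self-stays and non-neighbour jumps are tallied
  separately so every frame-to-frame step is accounted for. The
  translation of imbalance into kJ/mol is not specified by the source
  methodology, so imbalance and flatness deviation are reported side by
  side rather than combined by an invented formula.
* **Walker overlap**: per bin, the number of walkers whose own
  normalised density strictly exceeds 10% of the across-walker mean
  density — per-walker normalisation makes the count invariant to any
  walker's total sampling volume.

# Coupling networks

The free-energy surface is projected onto every eligible pair distance;
the pair's energetic coupling becomes an undirected edge weight. Two
filters keep the graph meaningful rather than a dense web of noise:
pairs must actually form contacts (minimum distance below 0.6 nm in at
least 5% of frames), and couplings below 1 RT are dropped — secondary
minima shallower than thermal energy are single-basin noise under the
barrier-to-basin definition. Paths use edge cost $1/(w+\epsilon)$,
$\epsilon = 10^{-6}$ kJ/mol (strong coupling = cheap edge), with
$\max(w) - w + \epsilon$ available as the alternative; both are
recorded on the object. Dijkstra shortest paths (igraph) connect a
source residue to sink residues — all runtime parameters, never
hard-coded residue identities — and normalised weighted betweenness
summarises per-residue importance. Condition-level comparison reduces
each network to a per-residue total-coupling vector (or per-pair
vector), aligns conditions on the union of features with absent entries
at zero, and runs a mean-centred PCA.

# Synthetic data: what it emulates, what it does not

Every stage is validated against generators with known ground truth:

* `gibbsSampleMsa()` draws alignments from an explicit Potts model by
  parallel single-site Gibbs chains (100 burn-in sweeps by default).
  `plantedPottsModel()` plants diagonal same-state couplings on chosen
  pairs; recovery of those pairs by the full fit-and-APC route is the
  headline oracle (precision of the top-10 scores on L = 20, 10 planted
  pairs, 2,000 sequences).
* `makeToyStructure()` embeds single-C$\alpha$ residues in 3-D so a
  requested contact pattern is realised (classical scaling start,
  penalised refinement, provable-infeasibility check via contact-chain
  triangle bounds), and writes standard PDB.
* `sampleTwoStateTrajectory()` Metropolis-samples a tilted double well
  whose right half is the exact mirror of the left shifted by
  $\Delta U$ past the barrier top, so the well populations are exactly
  $1 : e^{-\Delta U/RT}$ — an analytic oracle for basin detection and
  populations. The proposal width defaults to the inter-well scale
  (1.0) so the chain decorrelates across the barrier within tens of
  steps; the barrier defaults to 4 RT, high enough for clearly resolved
  states yet frequently crossed. Distances are affine images of the
  latent coordinate plus bounded positive uniform noise (0.05 nm),
  clipped at zero, keeping the planted CV linear so max-margin recovery
  is exact in expectation; noise pairs are state-independent constants.
* `makeWalkerHistograms()` builds exact per-walker histograms with
  planted defects (half-density bins, dead walkers) whose diagnostic
  values have closed forms.

What passing these tests does *not* show: real alignments have
phylogenetic correlation structure no Potts sampler reproduces; real
trajectories have correlated, anharmonic, multi-state kinetics and
force-field physics; real structures have side chains, altlocs and
missing density. The generators validate the *estimators*, not the
biology.

# Problem sizes and numerical choices

The test and acceptance analyses use sizes chosen to make every oracle
sharp at interactive runtimes: 2,000-sequence alignments at L = 20 for
coupling recovery, $10^5$ Metropolis frames for population recovery
(Monte-Carlo error well under the ±0.02 check), 4,000-frame ensembles
with 2 planted among 50 noise pairs for CV recovery, 100 seeded random
graphs of up to 8 nodes against exhaustive path enumeration. Gradient
correctness is checked against central finite differences at
$10^{-5}$ relative error on a 3-column, q = 3 model where the sweep is
exhaustive. Degenerate inputs are handled explicitly: all-zero score
matrices pass APC unchanged; single-well and flat profiles couple to
zero; frames outside a binning range raise an error unless clamping is
requested; surfaces where every basin core is sub-minimal fall back to
the single largest basin.

# Known limitations

* The pseudo-likelihood fit is dense ($O(L^2 q^2)$ parameters); the
  implementation is vectorised through sparse one-hot algebra but
  targets family-sized alignments (hundreds of columns), not
  proteome-scale scans.
* Mean-shift mode counting on very few pairs is bandwidth-sensitive;
  the bandwidth and a fixed cluster count are both exposed.
* The inflection border uses discrete curvature, not mixture fits; on
  coarse noisy grids the ridge border is the robust default (see
  above).
* One exploration round is supported directly; iterating
  explore-classify-resample is a manual loop over the same functions.
* Trajectory ingestion is table-based (TSV + JSON manifest, or
  coordinate tables per frame); binary trajectory formats should be
  distilled to pair distances with the user's MD tooling of choice.
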
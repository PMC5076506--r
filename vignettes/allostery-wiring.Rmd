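---
title: "Methods: co-evolution coupling, allosteric networks, and double-mutant-cycle thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-evolution coupling, allosteric networks, and double-mutant-cycle thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinwire)
```

`kinwire` computes, end to end, an allosteric wiring map for a protein
family — here, the kinesin motor domain — and the thermodynamic validation of
that map. This vignette is the package's own account of its models, the
parameters that matter, the numerical choices that were genuinely open, and
the limits of what the synthetic benchmarks can show.

## 1. Sequence curation

Co-evolution signals are statistical; their worst enemies are redundancy
(near-identical sequences inflate apparent covariation) and fragments
(truncated entries distort per-column frequencies). `curate_sequences()`
applies, in order: an optional cross-reference filter (only when the caller
supplies a vetted id list — the package performs no live database queries),
a fragment filter, and redundancy pruning.

Two identity conventions are implemented in `pairwise_identity()` and
switched by the `aligned` flag, because the upstream literature rarely states
one. For rows of a common alignment, identity is matches divided by columns
where neither row is a gap. For unaligned sequences, a global
Needleman–Wunsch alignment (BLOSUM62, gap open 10, extend 0.5, via
Biostrings) is computed first and identity is matches over alignment length.
Arguments are ordered canonically before aligning so the measure is exactly
symmetric even when the optimal alignment is degenerate. Ambiguity
characters (`X` etc.) never match, including themselves.

Open choices, fixed as follows:

* **Keep rule.** Redundancy pruning is greedy, first-seen-kept in input
  order. There is no objective function that privileges one cluster
  representative over another, so determinism and reproducibility win.
  Adding an exact copy of an already-kept sequence changes removal counts
  but never the kept identities (a tested invariant).
* **Fragment rule.** A sequence is a fragment when its ungapped length is
  below 0.7 × the median ungapped length. The threshold is exposed; 0.7
  removes half-length entries without touching ordinary length variation.
* **Bookkeeping.** `CurationReport` counts reconcile exactly
  (`n_input = n_output + removals`), and every removed id carries exactly one
  reason — conservation of records is a tested invariant.

## 2. Statistical coupling energies

The input is an `aa_alignment`: equal-length rows over the 20-letter
alphabet plus `-`, with a designated reference row defining residue
numbering for every column (e.g. human Eg5 numbering when the Eg5 sequence
is the reference).

Per column $i$, with $P_{x,i}$ the regularised amino-acid distribution and
$q_x$ the family-wide background:

$$\Delta G^{stat}_i = kT^* \sqrt{\sum_{x=1}^{20} \left[\ln
\frac{P_{x,i}}{q_x}\right]^2}$$

Coupling between columns uses a perturbation: restrict the alignment to the
sequences carrying the dominant residue at $j$ and measure the shift at $i$:

$$\Delta\Delta G^{stat}_{i|\delta j} = kT^* \sqrt{\sum_x \left[\ln
\frac{P_{x,i|\delta j}}{P_{x,i}}\right]^2}$$

$kT^*$ is the arbitrary statistical energy unit, set to 1. The reported
matrix entry is the mean of the two directions; both raw directions are kept
for inspection.

Numerical choices:

* **Pseudocount, in frequency space.** Distributions are regularised as
  $P_x = (f_x + \lambda)/(1 + 20\lambda)$ with $\lambda = 1/N$ by default
  ($N$ = number of sequences). The frequency-space form matters: a
  count-space pseudocount contributes $\ln(n_{full}/n_{sub})$ for every
  residue unobserved in both the full alignment and the subalignment, which
  inflates every pair — including statistically independent ones — by a
  large common artifact. In frequency space an unobserved residue
  contributes exactly zero to the coupling, and the independence limit
  behaves as it should.
* **Admissibility.** A perturbation is admissible only if its subalignment
  retains at least 25% of the rows, and at least 100 rows whenever the
  alignment has that many. Small subalignments produce couplings dominated
  by sampling noise; below the floor the pair is *masked* (reported missing,
  never zero). With a uniform 20-letter background this masks
  background-to-background perturbations by design — their dominant-residue
  subalignments hold only ~$N/20$ rows — which is precisely the
  noise-control the floor exists for.
* **Gaps.** Gaps (and ambiguity codes) are excluded from frequency
  normalisation; columns with more than 50% gaps are excluded from the
  matrix entirely. Highly variable loop/indel regions are therefore outside
  the map's scope.
* **Degenerate inputs.** All-gap columns are flagged and excluded; an
  inadmissible perturbation yields `valid = FALSE` with `energy = NA`.

### Sectors

`extract_sectors()` clusters supra-threshold positions by average-linkage
agglomeration on the distance $1 - \Delta\Delta G / \max \Delta\Delta G$
(missing couplings = maximal distance) and cuts $k = 3$ sectors by default,
matching the three functional modules expected for a motor domain (energy
transduction, adenine binding, microtubule binding). When every merge height
is zero (a single fully-coupled clique) there is no sector structure to cut,
and the function returns one sector with a warning rather than an arbitrary
split. Positions with supra-threshold couplings into another sector are
flagged `co_sector` — candidate conduits for cross-talk between the
networks.

## 3. The allosteric network

`build_network()` keeps pairs with symmetrised coupling ≥ 1.0 kT\* (the
conventional noise threshold for this family of methods). Edges are
stratified into intermediate ([1.0, 1.4) kT\*) and high (≥ 1.4 kT\*)
coupling; the printed literature bounds (1–1.39, 1.4–2.4) are treated as
rounded edges of these half-open intervals, so 1.395 is *intermediate*.
Degrees count one per coupled partner (undirected, no multiplicity), hubs
are nodes of degree ≥ 9, and construction is monotone: raising the threshold
never adds nodes or edges (tested property). Divergence between two family
members (`divergence_at_positions()`) is counted on alignment columns — not
structural superposition — with gap-versus-residue counted as divergent and
flagged.

Whether per-residue correlation counts should use the symmetrised or a
directional matrix is not settled upstream; the symmetrised matrix is the
default and the directional energies remain available in the `sca_matrix`.

## 4. Structural mapping

`read_ca_structure()` keeps the Cα trace of one chain of the first model,
preferring altloc `A`; unresolved residues are absent and show up as flagged
missing values in `ca_distance()`. Contact means Cα–Cα distance < 6 Å;
6.0 Å exactly is distal (pinned by a unit test). The 6 Å rule is
deliberately conservative: 4 Å would capture van-der-Waals contact, but a
mutated pair can come into contact through larger side chains, and 6 Å
guarantees non-contact in wild type *and* mutants. The distance histogram
uses ten half-open 4 Å bins starting at 4 Å, with the first and last bins
absorbing out-of-range distances so that counts conserve classifiable edges;
edges with unresolved endpoints are excluded but tallied. PDB numbering is
assumed to match the reference numbering; a `numbering offset` option
handles structures numbered differently. Cα is used for every distance in
the package.

## 5. Michaelis–Menten kinetics and double-mutant cycles

`fit_michaelis_menten()` fits $v = k_{cat}[S]/(K_m + [S])$ by
Levenberg–Marquardt (minpack.lm) with positivity bounds. Replicates are
averaged per concentration before fitting (the conventional treatment for
titration data; a fit-all-points option exists). Initialisation:
$k_{cat,0}$ = maximum observed rate, $K_{m,0}$ = concentration nearest
half-max, with a log-spaced $K_m$ grid fallback; non-convergence and all-zero
rates are explicit errors. Standard errors come from the fit covariance.

Free energies (kcal/mol; $R = 1.987 \times 10^{-3}$ kcal mol⁻¹ K⁻¹):

$$\Delta\Delta G_M = -RT \ln \frac{(k_{cat}/K_m)_{mut}}{(k_{cat}/K_m)_{wt}},
\qquad CE_{THERM} = \Delta\Delta G_{M1} + \Delta\Delta G_{M2} -
\Delta\Delta G_{M1M2}$$

The default temperature is 298 K: assay temperatures in this literature are
usually ambient, and the parameter is exposed. The sign convention makes
$CE_{THERM}$ positive when the double mutant is less perturbed than the sum
of its single mutants (cooperative coupling).

**Epistasis classes.** The field names five interaction classes but rarely
gives numeric bounds. `classify_epistasis()` applies a documented ordered
rule set with the additivity bound $b$ (default 1.0 kcal/mol; 1.5 is the
permissive literature value) as tolerance: additive if $|CE| < b$; else
synergistic if the double mutant exceeds the summed singles in magnitude
(same sign); else no-additional-effect if the double tracks one single
within $b/2$; else partially additive if it falls between the larger single
and the sum; else antagonistic. The ordering resolves overlaps
deterministically and is recorded in the output.

**Additivity offset.** With the slope fixed at 1, the least-squares
intercept of $\Delta\Delta G_{M1}+\Delta\Delta G_{M2}$ against
$\Delta\Delta G_{M1M2}$ is the mean coupling energy; it is reported with a
t-based confidence interval, and the free-slope regression is returned as a
diagnostic (slope `NA` when degenerate).

## 6. What the synthetic generators emulate — and what they do not

`simulate_msa()` draws background columns i.i.d. from the background
frequencies (uniform over 20 amino acids by default, configurable to
empirical frequencies) under a star phylogeny. Each planted pair has two
compatible residue combinations; with probability $\varepsilon$ a sequence
draws a consistent combination, otherwise both columns are background. This
creates exactly the compensatory-covariation signal the coupling analysis
targets, with one tunable strength: $\varepsilon = 0$ is independence,
$\varepsilon = 1$ deterministic covariation. Optional near-duplicate
clusters and truncated fragments exercise the curation stage.
Defaults — 800 sequences × 120 columns, four planted pairs at
$\varepsilon = 0.8$ — are sized like a well-curated single-family alignment
(the curated kinesin set has 726 sequences over a ~360-residue domain) while
keeping test runs fast.

What passing these benchmarks does **not** show: real alignments carry
phylogenetic correlation (shared ancestry mimics covariation), composition
bias, and alignment error, none of which the star-phylogeny generator
produces. Recovery of planted pairs is a correctness check of the machinery,
not a field-accuracy claim.

`simulate_titrations()` follows the standard assay design: 12 substrate
concentrations log-spaced from 238 nM to 1 mM, triplicates, Gaussian noise
proportional to the true rate (5% default), at the family's parameter scales
($k_{cat}$ ~ 0.004–0.5 s⁻¹, $K_m$ ~ 0.2 µM–1 mM). `simulate_structure()`
produces ideal-geometry traces; the helix uses rise 1.5 Å and 100° turn per
residue at radius 2.3 Å, giving the canonical ~3.8 Å Cα spacing. Note that
ideal-helix geometry places the $i, i{+}4$ Cα pair at ≈ 6.2 Å — *distal*
under the strict 6 Å rule — while $i, i{+}3$ (≈ 5.1 Å) is a contact; real
helices scatter around these values.

## 7. Pipeline, determinism, and problem sizes

`run_pipeline()` executes curate → coupling → sectors → network → structure →
cycles from one configuration (R list or YAML), halts naming the failing
stage, and embeds a hash of the resolved configuration (excluding the output
location) in the report, so a rerun with unchanged inputs is byte-identical.
Every stochastic step is seeded from the configuration.

The shipped tests and the acceptance script run entirely on synthetic data
at these sizes, chosen to give stable statistics while keeping a full run in
seconds on one core: coupling analyses at 800 × 120 (planted recovery and
the $\varepsilon = 0$ calibration, where fewer than 5% of pairs may exceed
1.0 kT\*), exact-oracle comparisons at ≤ 10 × 6, 500 titration fits for the
noisy-recovery study, and 6-cycle additivity-offset fits.

## 8. Known limitations

* The coupling formulation is the perturbation/frequency-ratio one; later
  variants (conservation-weighted correlation, eigenmode analysis,
  independent-component sectors) are out of scope, and exact residue-set
  reproduction for a specific published family can depend on which variant
  the original authors ran.
* Masked pairs (inadmissible perturbations) are missing data; analyses
  downstream treat them as absent couplings, which is conservative.
* No phylogenetic correction of any kind is applied to the alignment
  statistics.
* Structural mapping assumes one Cα per residue and shared reference
  numbering; no superposition between family structures is performed.
* The kinetics module models basal (microtubule-free) turnover only — no
  coupled-assay chemistry, no protein-concentration normalisation.
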
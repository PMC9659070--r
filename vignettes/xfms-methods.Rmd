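---
title: "Methods: residue-level solvation mapping from X-ray footprinting"
author: "xfms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue-level solvation mapping from X-ray footprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xfms)
```

## The measurement and the model

X-ray hydroxy-radical footprinting with mass spectrometry (XFMS) irradiates
a protein in solution; the radiolytically generated hydroxy radicals
covalently oxidize sidechains at a rate that tracks how exposed each
sidechain is to solvent. Liquid-chromatography MS quantifies, at each X-ray
dose, the chromatographic peak areas of each peptide form (unoxidized, or
oxidized at a specific residue). The oxidized fraction at residue $i$ and
dose $d$ is

$$F_i(d) = \frac{A^{ox}_i(d)}{A^{ox}_i(d) + A^{unox}_i(d)},$$

and first-order oxidation kinetics give a single-exponential decay of the
unoxidized fraction, $1 - F_i(d) = e^{-S_i d}$. The fitted rate $S_i$ is
normalized by the residue type's intrinsic chemical reactivity $IR$ to the
hydroxy radical, giving the protection factor

$$PF_i = S_i / IR_{type(i)},$$

so that $\log_{10} PF$ reflects structure (solvent accessibility) rather
than chemistry. Lysine is intrinsically far more reactive than aspartate
($IR_K = 2.2$ versus $IR_D = 0.42$ on the reference scale; these two
anchored values ship as the default table, all others are user
configuration because published scales differ).

Residues in contact with bulk solvent follow a linear relation between
sidechain solvent-accessible surface area (SASA) and $\log_{10} PF$.
Residues hydrogen-bonded to *structured* (crystallographically ordered)
water oxidize anomalously fast for their SASA: they fall below that
relation. The package's classification therefore fits the calibration
regression on designated reporter residues (typically non-polar
methionine/aromatic oxidations), computes a pointwise 95% confidence band,
and flags residues whose $\log_{10} PF$ lies strictly below the lower
limit as anomalously low-PF (ALPF) — the structured-water signature. Three
orthogonal structure-based measures then characterize the neighborhood of
such residues: protein–water hydrogen-bond network betweenness, contact
frustration, and evolutionary-trace importance.

## Stage 1: peak matching and per-residue compilation

MS/MS identifications (MASCOT-style exports) carry a retention time and
m/z per identified peptide form; LC-MS peak lists carry (RT, m/z, area)
per dose. `match_and_aggregate()` matches every identification to the
peaks within an RT and m/z tolerance at every dose and compiles residue
totals. Choices a user should know about:

* **Tolerances.** Defaults are 0.5 min RT and 0.02 Th m/z. These are
  instrument properties, not constants of the method; both are arguments
  (and CLI flags). Matching is monotone in the tolerances: tightening
  them can only remove matches.
* **Conditional denominator.** The unoxidized total at residue $i$ is the
  unoxidized-peptide area *plus* the areas oxidized at other residues of
  the same peptide — a molecule oxidized at $j \ne i$ is unoxidized at
  $i$. This keeps $F_i$ conditional on site $i$ alone and makes the
  per-peptide area balance conserve: summed per-residue oxidized areas
  equal the summed matched oxidized peak areas.
* **Charge states** of the same form are summed before aggregation.
  **Ambiguous matches** (several peaks in tolerance) are summed and
  logged; a form with *no* peak at a dose drops that dose for the whole
  peptide and is logged (`attr(x, "match_log")`).
* Residues never covered by an identification are absent from the output
  ("not detected"), which is itself information used by the network-level
  group statistics.

## Stage 2: decay fitting and weighting

`fit_decay()` fits $1-F = e^{-S d}$ through the origin ($F(0)=0$; the
model has no amplitude parameter). When all $F<1$ it works on
$\log(1-F)$, which makes the fit linear; the reciprocal-SE weighting is
then applied on the *fitted* scale: by the delta method
$\mathrm{var}[\log(1-F)] = \mathrm{var}[F]/(1-F)^2$, so weights are
$((1-F)/se)^2$, or $(1-F)^2$ when no per-point SEs exist. Without that
factor, near-saturated dose points ($F \to 1$), whose log-residuals
diverge, dominate and wreck the slope for fast-oxidizing residues. The
weights are then recomputed once from the first-pass fitted curve and the
fit repeated: weights estimated from the noisy observations themselves
correlate with the residuals and leave a small $O(\sigma^2)$ bias that
the reweighting pass removes (the test suite checks the fitted slope is
unbiased to within twice the Monte-Carlo standard error). If any $F = 1$
the transform is unavailable and a bound-constrained nonlinear
least-squares fit takes over. $S$ is constrained non-negative; fewer than
3 dose points is an error. Technical replicates are averaged per dose
beforehand, with the SE of $F$ propagated (`oxidized_fraction()`).

$\log PF$ uses base 10 by default (`log_base` switches it); the base is a
display convention and cancels in all comparisons made at fixed base.

## Stage 3: SASA and the calibration band

`residue_sasa()` implements rolling-probe (Shrake–Rupley) SASA directly:
each heavy atom's van-der-Waals sphere (element radii C 1.70, N 1.55,
O 1.52, S/P 1.80 Å) is inflated by the probe (1.4 Å) and sampled on a
deterministic golden-spiral grid (588 points/atom by default); a point is
accessible when outside every other inflated sphere. Waters and hetero
groups are excluded from the calculation entirely; altloc conflicts keep
the highest-occupancy conformer. The default sums **sidechain atoms
only** (CA for glycine): the oxidation chemistry targets sidechains, and
the hydrogen-bond network likewise considers sidechain atoms only.
`mode = "all"` gives whole-residue SASA. The quadrature agrees with a
$10^5$-point Monte-Carlo surface oracle to well under 1% on the shipped
fixtures, and with the closed form $4\pi(r+p)^2$ exactly in the
isolated-atom limit.

`fit_sasa_logpf()` is ordinary least squares with the **confidence band
for the mean response** (not the prediction band): the anomaly call asks
whether a residue is incompatible with the calibrated *relation*, not
whether it is an unusual draw from the calibration scatter; the
prediction band remains available via `predict(, interval =
"prediction")`. The calibration subset is an input (a residue list), not
hard-coded. `classify_alpf()` flags `anomalous_low` strictly below the
lower limit; narrowing the band level can only grow that set, and the
call is invariant to record order. `delta_metrics()` differences
$\log PF$ and SASA between two states by residue index (substituted
positions compare by position and are flagged) with per-group mean ± SD
summaries.

## Hydrogen-bond network

`build_hbond_graph()` connects sidechain N/O donor/acceptor atoms
(enumerated per residue type) and water oxygens within 3.5 Å; parallel
atom-pair edges collapse to one edge per node pair (shortest distance
kept). Crystal structures rarely carry hydrogens, so the 60° angular
criterion applies **only when hydrogen positions exist in the file**;
distance-only is the reproducible default for static structures. Model 1
only; isolated waters are dropped from the graph but still counted by
`count_waters()`, which assigns each water to the protein chain owning
its nearest protein atom when a chain is requested (crystallographic
water chain labels are unreliable).

Betweenness centrality is reported **raw** (the plain sum over node pairs
of the fraction of shortest paths through the node, unit edge weights),
matching the way per-node path counts are compared within one structure;
a normalized mode exists for cross-graph comparison. Computation uses the
standard exact algorithm (igraph); the test suite checks it against an
exhaustive simple-path enumeration oracle on dozens of random graphs.
Group statistics (low-PF / normal / not-detected; detected =
low ∪ normal) report mean ± SD per group and the detected/undetected
ratio of means with SEM-propagated error; `merged_ratio()` averages the
ratio across structures, reporting the spread across structures as the
uncertainty (the two conventions the literature leaves open).

## Contact frustration

`native_contacts()` takes sidechain-centroid contacts (CA for glycine)
within 6.5 Å at sequence separation ≥ 2 and classes each contact by
distance and **local burial density**: the number of other residue
centroids within 8 Å of the contact midpoint. Buried short-range
contacts (≥ 6 neighbors by default) are `direct`; exposed ones — with
room for an intervening water — are `water_mediated`; contacts beyond
`direct_cutoff` are `long`. The density threshold is configuration: no
published value exists for it, and the planted-geometry fixtures pin the
intended behavior rather than any constant.

`decoy_frustration_index()` scores a native pair against decoys obtained
by randomizing both residue identities with the geometry fixed:

$$\Delta E^{fr}_{ij} = \frac{E^N_{ij} - \overline{E^D}}{\sigma(E^D)},$$

with the population SD in the denominator so that feeding the decoy set
back through the score returns mean 0, SD 1 exactly. **Sign:** positive
means the native pair is *less* favorable than a typical decoy (a
stressed contact); the widely used frustration index has the opposite
sign, so the classification thresholds (defaults `hi = 0.78`, `lo = -1`,
adopted from that convention and sign-adjusted — not values from any one
study) are explicit configuration. The exhaustive 400-pair mode is
seed-independent and equals the sampled mode in expectation; sampling is
deterministic for a fixed seed and restores the caller's RNG state. The
pairwise potential is pluggable; the shipped default is a deliberately
simple documented stand-in (negative Kyte–Doolittle hydropathy product
plus an ionic same/opposite-charge term) — the z-score is invariant to
affine rescaling of any potential, which the tests verify. No
coarse-grained force field is reimplemented here, and no numeric
agreement with any force-field-based server is implied.

## Evolutionary trace

Per-column Shannon entropy (`position_entropy()`) is computed in nats
over the 20 amino-acid frequencies with gaps excluded; an all-gap column
is undefined (NA), and an all-gap *group* contributes 0 within the
tree-weighted score. The real-valued trace score of column $i$ is

$$rvET_i = 1 + \sum_{n=1}^{N-1} w_{node}(n) \sum_{g=1}^{n} w_{group}(n)\, s_{ig},$$

where at partition depth $n$ the tree is cut into $n$ groups by
activating internal nodes root-first in order of height (ties by node
number; multifurcations make the group count jump, in which case the
realized partitions are summed). Default weights $w_{node} = w_{group} =
1/n$ average the group entropies at each depth and down-weight deep
partitions; both are pluggable functions, since the exact weighting of
the original server is not fully specified. An invariant gap-free column
scores exactly 1; scores never fall below 1; permuting sequence order
changes nothing. Lower = more important; `rank_top_fraction()` returns
the best `floor(f * ncols)` positions with index-ascending tie-breaks.

`branch_substitutions()` maps where a column's state changes on the tree:
Fitch small parsimony with deterministic tie resolution (parent state if
available, else the state supported by most child subtrees, else
alphabetical; gaps are a 21st state), returning the edges whose endpoint
states differ. When no tree is supplied, a neighbor-joining tree from
p-distances with midpoint rooting is built as a convenience — it is not a
substitute for a curated phylogeny.

## The synthetic study set

Every module is exercised end-to-end on generated inputs with known
ground truth (`synth_dose_series()`, `synth_toy_structure()`,
`synth_msa()`); one seed threads each generator and outputs are
canonically ordered, so identical calls are byte-identical.

* **Dose series.** Residues within 8 positions share a peptide (so the
  multi-site aggregation rule is exercised); peak areas realize
  $1 - F = e^{-PF \cdot IR \cdot d}$ with Gaussian noise of SD $\sigma$
  on $F$, clamped to $[0,1]$. The study conditions used by the recovery
  checks: lysine reporters ($IR = 2.2$), true $PF \in \{0.1, 1, 10\}$,
  $\sigma = 0.02$, 200 replicate experiments, and the 8-point dose grid
  $\{0, 0.01, 0.025, 0.06, 0.15, 0.4, 1, 2.5\}$ (arbitrary dose units),
  log-spaced so every slope across the two PF decades has several
  informative points. Under these conditions the median relative error
  of recovered PF is ~3% per decade (the acceptance script recomputes
  this). The generator refuses parameter combinations whose summed
  within-peptide oxidized fractions exceed 1.
* **Toy structures.** Geometry plans place idealized residue templates
  (~1.5 Å bonds, heavy atoms only) and water oxygens at coordinates
  derived from the template offsets, so planted distances are exact: a
  Ser–water–Asp bridge (2.9/3.0 Å), a six-armed arginine hub
  (R–water–Ser–water chains), a buried-vs-surface contact pair at equal
  separation, and a three-alanine SASA fixture. Writing aborts if any
  inter-residue atom pair comes within 1 Å.
* **Alignments.** Column letter counts are constructed to hit target
  entropies (two-level distribution over the smallest sufficient
  alphabet, solved numerically) and assigned to sequences in seeded
  random order; clade-split columns follow the generated tree, so
  substitution mapping has a known answer. Realized entropies track
  targets to < 0.05 nats at 200 sequences.

**What the fixtures do not emulate:** real MS noise structure (peak
shape, co-elution, missed cleavages, isotope envelopes), crystallographic
refinement artifacts (partial occupancies, missed waters), realistic
protein packing, or realistic phylogenetic rate heterogeneity. Green
tests demonstrate the algorithms are implemented correctly under the
stated models — not that any particular biological inference from real
data is correct.

## Numerical choices and degenerate inputs

* Quadrature: 588 spiral points/atom (exact for an isolated atom, where
  every point is free; fixture-vs-oracle error < 1%); configurable.
* Fitting: slope constrained ≥ 0 by truncation in the linear path, by a
  box bound in the nonlinear path; zero-total-area dose points are
  dropped with a warning; duplicate doses are an error.
* Regression: degenerate predictors (all-equal SASA, n < 3) are errors,
  not silent NAs. Records missing SASA or logPF are returned as
  `not_classified`.
* Frustration: a constant potential (decoy SD 0) is a hard error.
* Graphs: empty polar-atom sets warn and return an empty graph;
  disconnected node pairs contribute 0 to betweenness.
* Problem sizes in the test and acceptance runs (random-graph oracle at
  ≤ 8 nodes, $10^5$-point Monte-Carlo surfaces, 200-replicate recovery,
  16–200-sequence alignments) were chosen as the smallest sets that
  exercise each property with comfortable statistical margins.

## Known limitations

* The hydrogen-bond angular criterion is effectively unused on
  hydrogen-free crystal structures; protonation-dependent bonding (His
  tautomers, low-barrier bonds) is not modeled.
* The default contact potential is a stand-in for scoring *relative*
  stress; absolute energies are meaningless by construction.
* Water-mediated contact classification rests on a burial-density
  threshold with no literature value; treat the class labels as a
  screening heuristic.
* The rvET group-cutting convention follows height-ordered root-first
  splits; other published variants exist and will rank near-ties
  differently.
* Reference crystal structures and sequence accessions are not bundled;
  analyses of real proteins require the user to supply PDB/FASTA files.
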
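---
title: "Statistical and structural methods behind flipms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical and structural methods behind flipms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

Limited proteolysis mass spectrometry (LiP-MS) reads out protein surface
accessibility: a brief digestion of native lysate with the sequence-unspecific
protease PK, followed by complete tryptic digestion, converts local
accessibility differences into peptide abundance differences. When a lysate
is first separated by serial ultrafiltration (100/50/30/10 kDa cutoffs),
complex-bound and monomeric forms of a protein end up in different size
fractions, and peptides covering a binding interface change their protease
accessibility between those fractions. `flipms` implements the computational
chain from fraction-wise intensity tables to a library of such
interaction-marker regions, their structural validation, their overlay onto
perturbation experiments, and a network-level summary.

The atoms of the analysis are intensities $I_{\mathrm{pep},c,r}$ of a LiP
peptide and $I_{\mathrm{prot},c,r}$ of its parent protein in a tryptic-only
control, for group (fraction or condition) $c$ and replicate $r$. Protein
abundance differences between fractions are removed by the ratio

$$R_{\mathrm{pep},c,r} = \frac{I_{\mathrm{pep},c,r}}{I_{\mathrm{prot},c,r}},$$

which is constant across fractions for most peptides; peptides for which it
changes localize an accessibility difference.

## Filtering and normalization

An analyte enters the analysis only if it is measured in at least three
replicates in at least two groups (`detection_filter()`); LiP peptides
additionally require their protein to pass in the control. Groups below the
replicate floor are excluded for that analyte, so every test compares only
groups with adequate replication. Each sample is median-normalized
(`median_normalize()`), fraction-wise for library experiments (each fraction
is searched separately) or globally for two-condition experiments. In
library mode the ratios $R$ are median-equalized once more across samples
(`correct_by_protein(..., renormalize_ratios = TRUE)`), because fraction-wise
searches leave them on different scales. Zero and negative intensities are
treated as missing and never imputed.

## The error-propagated one-way ANOVA

For each peptide, the group mean $\mathrm{Mean}_{\mathrm{pep},c}$ of the
ratios is paired with a propagated spread

$$\mathrm{sd}_{\mathrm{pep},c} = \mathrm{Mean}_{\mathrm{pep},c}
\sqrt{\mathrm{cv}^2(I_{\mathrm{pep},c}) + \mathrm{cv}^2(I_{\mathrm{prot},c})},$$

with coefficients of variation taken from the raw (post-normalization)
peptide and protein intensities in group $c$ (sample standard deviation,
$n-1$). The within-group mean square pools these spreads; the between-group
mean square compares group means against a grand term; their ratio is
referred to an F distribution with $(C-1, N-C)$ degrees of freedom, where
$C$ is the number of groups and $N$ the total observation count.
Benjamini-Hochberg correction across peptides yields q-values.

Two variants of the between-group term are provided
(`propagated_anova(variant =)`):

* `"as_printed"` centers the group means on $\sum_c \mathrm{Mean}_c / N$ and
  divides by $C$. This is the form the pipeline historically used. Because
  the grand term divides by the observation count rather than the group
  count, the centered deviations are large for any $C \ge 2$, and the
  statistic is strongly inflated: on null simulations at the library design
  (4 fractions x 4 replicates, 10% CVs) essentially every peptide reaches
  p < 0.05. It is retained for fidelity and comparison, and its measured
  null behaviour is reported by `scripts/acceptance.R`.
* `"textbook"` uses the replicate-weighted grand mean and divides by $C-1$,
  the classically calibrated form. This is the default recommendation and
  the variant all calibration and recovery benchmarks assert on. Its null
  level at the library design measures about 0.032 at 31k simulated null
  peptides: slightly conservative, because the protein-intensity noise that
  the denominator estimates is partly shared by the numerator's group
  means, and data-driven median normalization absorbs a further sliver of
  variance.

Degenerate cases are flagged rather than smoothed: zero within-group spread
with a real between-group difference gives p = 0 and `degenerate = TRUE`;
all-tied data give F = 0, p = 1. An exact-tie guard zeroes the between-group
term when group means agree to one part in $10^9$, so zero-noise simulations
hit those fixed points exactly instead of amplifying floating-point residue.

Pairwise fraction differences use a Tukey HSD on the same propagated
within-group mean square (`pairwise_tukey()`), with BH applied across the
pooled peptide-by-pair tests — the studentized range already accounts for
the within-peptide family, so the remaining multiplicity is across peptides.
R's studentized-range CDF is accurate to roughly 1e-4, which bounds how
tightly the two-group equivalence with the pooled t-test can be checked.

## Regions, confidence classes, and the library

Overlapping peptides (stochastic PK cleavage, missed cleavages) are grouped
to the longest observed fully tryptic parent (`group_to_parent()`), and a
region's q is the median of its members'. Should two assigned parents
overlap, the regions are merged into their union, so regions within a
protein never overlap. Regions with median q below 0.05 become markers
(`build_library()`).

Ultrafiltration is not strict, so a marker is high-confidence only if some
significant fraction pair is consistent with the protein's size: a protein
may elute in a fraction if half its monomer molecular weight does not
exceed the fraction's expected upper bound, i.e. the next-larger cutoff
(`expected_fractions()`; an 80-kDa protein may appear down to the 30-kDa
fraction but not the 10-kDa one). If every significant pair involves a
disallowed fraction the marker is low-confidence (`classify_confidence()`).
A region that clears the median-q threshold without any single Tukey pair
passing is kept but classed low-confidence, since the fraction-level
evidence cannot be localized. Markers are annotated for overlap with
protein-binding or RNA-binding domains and for proximity (< 2.6 angstrom)
to a known interface (`annotate_marker()`).

## Structural validation

Interface residues on a multimeric structure are those whose relative
solvent accessibility drops by more than 25 percentage points between the
chain in isolation and the full assembly (`detect_interface()`, strict
inequality). Accessibility is computed by deterministic sphere sampling
(golden-spiral points; `atom_sasa()`), normalized per residue type by
Tien-style theoretical maxima (configurable table; values above 100% are
not clipped). Peptides are mapped to chains by exact sequence match — a
peptide present in several chain copies is chosen at random under the
session RNG for reproducibility — and scored by the mean over peptide
residues of the minimum C-alpha distance to any interface residue
(`peptide_interface_distance()`). A peptide is interface-associated when
that distance is below the chosen cutoff (2.6 or 0.3 angstrom, strict).
When several structures cover one protein, `select_structure()` implements
three policies: most subunits, seeded random, or best agreement with the
data; the agreement score (markers within the cutoff plus non-markers
outside it) is this package's own concrete choice for "best", isolated
behind the policy interface. `interface_roc()` quantifies whether
significance predicts interface proximity, counting tied scores as half.

## Network propagation

Proteins with interface marker hits seed a personalized PageRank (damping
0.9, power iteration, dangling mass redistributed to the restart vector) on
an unweighted co-membership network built from a complex catalogue
(`build_network()`, cliques per complex, deduplicated). The top 40% of
scores (ties at the threshold retained, a deterministic and conservative
choice) induce the working subnetwork; walktrap with 4 steps clusters it,
cut at maximal modularity, which is the canonical implementation's
reference behaviour. Clusters with fewer than 4 subunits are dropped, and
each kept cluster is named by the complex holding the most changing-marker
proteins, with ties yielding multiple names. Two conditions are compared
cluster by cluster as marker sets: equal, nested (a gain in one condition),
or divergent.

## AP-MS differential interactions

High-confidence interactors require a SAINT probability of 1, detection in
4 of 4 pull-down replicates, and a mean spectral count of at least 4.5
(boundaries inclusive). After joint total-area normalization, each prey's
interaction change is the difference of its bait-normalized double ratios
between treatments, scaled by the propagated four-term CV spread with the
printed $\sqrt{(\cdot)/3}$ pooling, and referred to a t distribution with
4 degrees of freedom (`differential_interaction()`). Because the
denominator uses per-replicate spreads rather than standard errors of the
means, the statistic is markedly conservative: an independent Monte Carlo
at 10% CV places its true level near 0.003 at a nominal 0.05. It is
implemented as defined, with the conservatism documented rather than
corrected.

## What the synthetic data does and does not emulate

The generator (`make_proteome()`, `digest_in_silico()`,
`simulate_flip_experiment()`) reproduces the study design: 4 fractions x 4
replicates of LiP and control intensities, multiplicative log-normal
replicate noise (the standard model for label-free MS areas, and the one
compatible with CV-based error propagation), fraction-wise protein
abundances, independent missingness, and planted markers that act on the
peptide/protein ratio — exactly the signal the ratio isolates — in a named
fraction. Defaults are 10% peptide and protein CVs, a realistic label-free
replicate noise level, and a two-fold planted change. Toy dimers
(`simulate_dimer_structure()`) are straight C-alpha plus pseudo-side-chain
chains (uniform 1.9 angstrom radius) with a contact window whose burial is
geometrically guaranteed; their accessibility reference is the mid-residue
of an unbound toy chain, the analogue of the Gly-X-Gly context used for
real residues. Planted-community networks are cliques plus sparse bridges.

None of this emulates peptide detectability, ionization, chromatography,
shared-peptide ambiguity, or the fractional co-elution of real
ultrafiltration, so passing benchmarks demonstrate correctness of the
computations and calibration under the stated noise model — not performance
on real spectra. Problem sizes in the tests and acceptance script (about
2,000 peptides over 100-200 proteins, 60-residue dimers, networks of tens
of nodes) were chosen as the package's own desk-scale study conditions;
the statistics are size-agnostic.

## Numerical choices and known limitations

* CV guards: coefficients of variation below $10^{-9}$ are treated as zero,
  so exact zero-noise data reach the documented degenerate fixed points.
* Data-driven median normalization at exactly zero noise converts exact
  ties into exact differences (the sample median shifts with the planted
  markers); exact-recovery demonstrations therefore bypass normalization,
  which has no analogue on real (noisy) data.
* The detection filter tests an analyte only across groups where it meets
  the replicate floor; a peptide detected in two of four fractions is
  compared across those two.
* The tryptic rule ignores the no-cleavage-before-proline refinement by
  default (configurable), and peptide sequences shared by several proteins
  are dropped (proteotypic-only), mirroring upstream search settings.
* With ten draws the resampling null for mutation overlap cannot produce
  an empirical p below 1/10; `mutation_null()` therefore also reports a
  normal-approximation p, and the draw count is configurable. Random sites
  are placed uniformly over residues, weighting proteins by length.
* The marker library's headline counts on real data depend on deposited
  spectra, curated complexes and PDB structures, which are inputs, not part
  of this package; the shipped workflow demonstrates the full chain on its
  synthetic counterparts.
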
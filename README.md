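# flipms

Protein–protein interactions leave a structural fingerprint: residues at a
binding interface are shielded from proteolysis in the complex-bound form of
a protein and exposed in its monomeric form. `flipms` implements an analysis
pipeline that exploits this with limited-proteolysis mass spectrometry
(LiP-MS) of size-fractionated lysates: serial ultrafiltration separates
complexes from monomers, a brief proteinase K digestion under native
conditions converts accessibility into peptide abundance, and peptide-level
statistics across fractions identify *interaction marker* regions. The
package is for proteomics analysts who want to build such a marker library,
screen perturbation LiP-MS experiments against it, validate markers against
binding interfaces on multimeric structures, and summarize interaction
changes at the level of protein complexes.

## What it computes

For a peptide with intensity $I_{\mathrm{pep},c,r}$ and its protein's
tryptic-control intensity $I_{\mathrm{prot},c,r}$ in group $c$, replicate
$r$, the abundance-corrected ratio is
$R_{\mathrm{pep},c,r} = I_{\mathrm{pep},c,r} / I_{\mathrm{prot},c,r}$.
Group means of $R$ are compared across fractions with a one-way ANOVA whose
within-group variance is propagated from the peptide and protein intensity
CVs:

$$\mathrm{sd}_{\mathrm{pep},c} = \mathrm{Mean}_{\mathrm{pep},c}
\sqrt{\mathrm{cv}^2(I_{\mathrm{pep},c}) + \mathrm{cv}^2(I_{\mathrm{prot},c})},
\qquad
F = \mathrm{MS}_{\mathrm{between}} / \mathrm{MS}_{\mathrm{within}},$$

with $F \sim F(C-1,\,N-C)$ and Benjamini–Hochberg q-values. Overlapping
peptides are grouped to their longest fully tryptic parent; significant
unique regions become markers, classed high/low confidence by a
half-molecular-weight elution rule. Around this core the package provides:
interface detection on multimeric structures from the drop in relative
solvent accessibility between assembled and isolated chains (>25 percentage
points); mean minimum Cα distances of peptides to the interface with
2.6/0.3 Å association cutoffs; the ≥50%-overlap rule for calling marker
hits in perturbation experiments; personalized PageRank (damping 0.9) +
walktrap clustering over complex co-membership networks; Fisher-exact
domain/disorder/mutation enrichment; and the bait-normalized AP-MS
double-ratio t statistic (4 degrees of freedom). A synthetic-data module
generates fractionation experiments, toy dimers and planted-community
networks with known ground truth for every stage.

## Worked example

The `analysis/` directory is a numbered workflow over the package; stages
write their tables under `results/`. Running the first three stages:

```sh
Rscript analysis/01_simulate_library_experiment.R
Rscript analysis/02_differential_analysis.R
Rscript analysis/03_marker_library.R
```

prints

```
proteome: 100 proteins, 2023 peptides (1712 fully tryptic)
planted 60 marker regions (log2FC = 1, 100K fraction)
LiP records: 32368; tryptic-control records: 1600
detection filter: 2123 of 2123 analytes retained
tested 2023 peptides; 74 significant (q < 0.05)
planted-marker recall 1.000, precision 1.000
1712 unique regions from 2023 grouped peptides
library: 60 markers on 46 proteins; 96.7% high confidence
planted regions recovered: 60 of 60; spurious regions: 0
```

Reading it: 60 two-fold accessibility changes were planted into a simulated
4-fraction × 4-replicate experiment at 10% replicate CV; the calibrated
ANOVA recovers all 74 peptides covering them with no false positives, and
grouping returns exactly the 60 planted regions as the marker library.
Stages 4–7 continue with interface detection on a synthetic dimer
(sensitivity and precision 1.00 on the planted contact patch, ROC AUC 0.86
for significance predicting interface proximity at 2.6 Å), the perturbation
overlay (12 marker hits on 10 proteins), network clustering of the hits,
the AP-MS differential screen (both planted interaction changes recovered
with the correct signs), and the evidence analyses (domain enrichment of
the library at odds ratio 39.6, disorder overlap, and 75% mutation-site
coverage against a 3% resampling null).

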
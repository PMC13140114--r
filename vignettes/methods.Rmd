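---
title: "Methods: ctDNA variant triage, NRF2 activation calling, and comparative trajectory statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ctDNA variant triage, NRF2 activation calling, and comparative trajectory statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrf2ctdna)
```

# Scope

`nrf2ctdna` implements the computational core of a liquid-biopsy workflow
for NRF2-pathway-driven non-small cell lung cancer: post-calling triage of
somatic variants detected in circulating tumor DNA (ctDNA), classification
of NFE2L2/KEAP1/CUL3 variants by their predicted effect on NRF2 activity,
blood-based mutational-burden metrics, the exact and rank statistics used
for cohort-level claims, and the comparative molecular-dynamics trajectory
statistics used to functionalize rare KEAP1 missense variants. Read
alignment, variant calling, annotation, and MD simulation are upstream of
this package: their outputs (MAF-like tables with annotation columns,
multi-model PDB trajectories) are its inputs.

# Variant triage

Somatic calls from a plasma cfDNA panel mix true tumor-derived variants
with PCR artifacts and germline leakage. The cascade applies, in order:

1. **Panel-of-normals removal** — any call recurrently seen in normal
   samples on the same platform is dropped (`in_pon` flag; the panel's
   content is an upstream artifact of the assay, so it enters here only
   as a boolean).
2. **Evidence tiering** — a variant carries *oncogenic evidence* when its
   FATHMM score is at least `fathmm_threshold` (default 0.99) or its
   ClinVar class is oncogenic, likely oncogenic, or drug response;
   otherwise it is a variant of unknown significance (VUS).
3. **Hard filters** — a VUS needs at least `min_reads_vus` (default 5)
   unique supporting reads and a VAF strictly below `max_vaf_vus`
   (default 0.45, excluding heterozygous-germline-range calls); an
   evidence-tier variant needs only `min_reads_oncogenic` (default 2)
   reads. When per-strand read counts are present, a minimum of 2 reads
   per strand is additionally enforced; inputs without a strand split are
   exempt, because the strand rule is a property of the caller
   configuration rather than of the record.
4. **Population pruning** — variants above `pop_freq_threshold` (default
   `1e-5`, i.e. 1:100,000) in population databases are removed as
   putative germline.

VAF is held internally as a fraction in [0, 1]; percent-scale columns (as
clinical reports print them) are converted at read time, which avoids any
possibility of comparing a percentage against a fractional threshold.
Silent variants are retained through the filters and flagged, because
mutational burden is computed before pathogenicity filtering; they are
excluded from all pathogenicity logic.

## NRF2 activation calls

Pathway biology dictates the rule set. NFE2L2 is activated by mutations
that spare the protein but break KEAP1-mediated degradation, so truncating
or frameshift events inside the Neh2 domain — the N-terminal region
carrying the DLG and ETGE degrons — destroy rather than stabilize NRF2 and
are called `likely_lof`. The Neh2 window defaults to codons 1–86 and is
configurable, since domain boundaries are a modeling choice rather than a
database fact. KEAP1 and CUL3 are negative regulators, so nonsense and
frameshift events there are `likely_activating`. Missense and in-frame
events are scored against a codon-level NRF2 activity table (derived
externally from tumor transcriptomics and consumed here as data): codons
whose mean score exceeds the hyperactivity threshold are `activating`,
unscored codons are `putative_activating_unknown`.

A case is NRF2-positive when it carries any activating or
likely-activating variant; unknown-codon missense variants count toward
positivity by default (`include_unknown = TRUE`), reflecting the cohort
experience that such rare KEAP1 variants were subsequently confirmed
functional — the flag exists because the conservative convention is also
defensible. Variants ruled out by downstream wet-lab evidence can be
ignored via an explicit per-variant exclusion list rather than a rule,
because that evidence is external to the cascade.

On the encoded study cohort shipped in `inst/extdata` the cascade yields
14 pathway-mutated cases, of which 13 are NRF2-positive; the one negative
case carries only a Neh2 frameshift. These counts are recomputed, not
stored, by the test suite and `scripts/acceptance.R`.

# Burden metrics

Blood-based tumor mutational burden (bTMB) is the count of post-QC
mutations of one case/timepoint, reported both raw (comparable to
whole-exome counts over the same genes) and per megabase of targeted
territory; the default panel size is 0.5 Mb, the scale of a ~75-gene
capture design. Because the literature is split on whether "detected"
means pre- or post-pathogenicity filtering, the pipeline emits both
counts. ctDNA concentration is estimated as plasma cfDNA concentration
times the mean VAF over the case's pathogenic variants — zero when no
pathogenic variant is present, and explicitly missing (never zero) when
cfDNA was not measured. Variants lacking a recorded VAF are excluded from
the mean. Longitudinal recurrence matches filtered oncogenic variants
between timepoints on `(gene, protein change)`, falling back to
`(chrom, pos, ref, alt)` when no protein change is recorded, since HGVS-p
is the unit clinical reports print.

# Cohort statistics

Fisher's exact test (two-sided, minimum-likelihood convention) underlies
both the clinicopathological 2×2 tables and the pairwise gene
co-occurrence screen; the sample odds ratio `ad/bc` is reported rather
than the conditional MLE, and co-occurrence p-values are unadjusted by
default (a Benjamini–Hochberg flag is available). Group comparisons use
the two-sided Mann–Whitney U test (exact for small tie-free samples,
normal approximation with tie and continuity corrections otherwise), and
paired associations use Pearson or Spearman correlation with the method as
an explicit argument, since figure-level "R" values in the field are often
ambiguous between the two.

ROC analysis builds the curve over all observed thresholds under the rule
"score ≥ cutpoint is positive", which matters for ordinal markers such as
IHC intensity classes 0–3. The trapezoidal AUC equals the Mann–Whitney
probability with midrank ties. The operating point maximizes Youden's
J = sensitivity + specificity − 1, with ties broken toward the lowest
threshold (the sensitivity-maximizing convention that makes "≥ 2" a
natural cut-point on a 0–3 scale).

# Trajectory comparison

All trajectory statistics operate on α-carbon coordinates in Å.

**Superposition.** Rigid-body fits use the Kabsch algorithm (SVD of the
centered covariance with reflection correction, always a proper rotation).
RMSF profiles superpose frames onto their mean structure, iterating
mean-and-superpose twice, then take the per-residue root-mean-square
deviation from the mean. Collinear point sets are flagged degenerate
rather than rejected.

**Differential RMSF.** Per residue, per-replica RMSF values are compared
between conditions with a pooled-variance two-sample Student t-test and
Bonferroni correction over residues at family-wise α = 0.05. Replicas —
not frames — are the units of replication, because frames within a
replica are autocorrelated. Zero pooled variance is resolved to p = 1
for equal means and flagged degenerate otherwise.

**Trajectory similarity.** Each trajectory is treated as a set of
conformations under the frame-RMSD metric after a single global
superposition of every frame onto one shared reference (first frame of
the first wild-type replica); the directed Hausdorff distance
`h(A→B) = max_a min_b RMSD(a, b)` is symmetrized as
`max(h(A→B), h(B→A))` for the replica distance matrix, which is
clustered with Ward's method on the `ward.D2` (squared-distance
Lance–Williams) convention. Per-pair refitting is available behind the
superposition argument but is not the default: a single shared frame is
the standard path-similarity practice and keeps the cost at one fit per
frame rather than one per frame pair. The symmetrized Hausdorff satisfies
identity and symmetry; the triangle inequality is not asserted or relied
upon.

**Elastic network.** The Gaussian network model places unit springs
(`gamma = 1`) between α-carbons within 7.0 Å — the field-standard
defaults — giving the Kirchhoff (graph Laplacian) matrix, positive
semidefinite with one zero mode per connected component. Spectra are
computed per sampled frame (default stride 100) and pooled over replicas;
the alternative single-spectrum-per-replica mode is `stride = n_frames`.
Zero modes are identified at a relative tolerance of `1e-8` times the
largest eigenvalue and excluded from pooled spectra; degenerate
eigenvalues keep their multiplicity.

**Bootstrap densities.** Pooled eigenvalue spectra are resampled with
replacement at original size for 1000 iterations; per-iteration Gaussian
kernel densities on a grid shared across conditions are averaged and
renormalized to integrate to one. The overlap coefficient
`∫ min(f_wt, f_mut)` summarizes how far the mutant's flexibility spectrum
has moved. Every stochastic operation takes an explicit seed, and each
condition draws from an independent substream derived from it, so
results are bit-reproducible and conditions do not interact through the
random stream.

**Ligand stability.** When a bound ligand is present, each replica's
protein frames are fit to the replica's first frame, the same transform
is applied to the ligand, and the mean ligand RMSD to its first-frame pose
is compared between conditions with a pooled-variance t-test — a
significant increase in the mutant suggests mutation-induced
destabilization of the binding interaction.

# Synthetic data

The generators exist so that every downstream statistic has a known truth
to recover; they are first-class, tested code.

**Cohort generator.** Defaults mirror the emulated study conditions: 73
cases, 18% NRF2-pathway prevalence, pathway drivers drawn over a mix of
hotspot missense, truncating/frameshift KEAP1/CUL3, and rare unscored
missense events, with VAFs from Beta(2, 40) (median near 4%, range
matching observed driver VAFs of roughly 2–30%); positives are drawn
among male ever-smokers, matching the cohort's observed exclusivity. A
SMARCA4 indicator is coupled to NRF2 status through an odds ratio
(default 8) on a 5% base rate. Contaminants are Poisson-distributed per
case: PCR artifacts with 1–4 supporting reads (rate 2), germline leakage
at VAF ≈ 0.5 with population frequency above the pruning threshold
(rate 0.5), panel-of-normals artifacts (rate 1), and non-pathway somatic
passengers (rate 3). Read support is binomial over a ~1500× deduplicated
depth. Values not pinned by the emulated study (panel size, depth,
passenger and contaminant rates) were chosen once at plasma-panel scale
and are documented here rather than revisited. Truth labels on every row
enable sensitivity/specificity recovery tests.

What the generator does *not* emulate: sequencing error at the read
level, clonal structure and copy number, VAF correlation between variants
of one tumor, and timepoint dynamics. Recovery results on synthetic
cohorts therefore demonstrate the internal consistency of the cascade,
not its operating characteristics on real plasma data.

**Trajectory generator.** Frames are drawn directly from the Gaussian
network's equilibrium distribution: displacements per Cartesian axis with
covariance `kT·Γ⁺` over non-zero modes (eigendecomposition sampling),
about a deterministic helical reference chain with ~3.8 Å spacing whose
contact graph is connected at the 7 Å cutoff. A mutation is modeled by
rescaling all spring constants incident to one site (default softening
factor 0.25); the mutant samples the perturbed network's equilibrium.
This gives closed-form targets — the sample covariance must converge to
`kT·Γ⁺`, RMSF to `sqrt(3·kT·Γ⁺_ii)` — at the price of physical realism:
no anharmonicity, no kinetics (frames are i.i.d., so time correlation
structure is absent), isotropic per-axis fluctuations. The optional
ligand follows an Ornstein–Uhlenbeck rigid drift (relaxation 20 frames,
stationary scale 0.5 Å). `kT = 0` degenerates to the frozen reference,
which the tests use as an exact edge case.

# Numerical and design choices

- **Two-sided Fisher p** sums hypergeometric point probabilities not
  exceeding the observed one, with `1e-7` relative tolerance for ties —
  the dominant statistical-package convention, and the one that
  reproduces the published cohort p-values from their printed counts.
  Tables with an all-zero margin return p = 1.
- **Degenerate inputs** are explicit: zero-variance correlations error,
  single-class ROC errors, zero pooled variance in t-tests is flagged,
  collinear superposition is flagged, disconnected reference contact
  graphs are rejected by the trajectory generator.
- **Tie-breaks**: Youden ties go to the lowest threshold; Ward merge
  order on exactly tied distances follows `stats::hclust`'s lowest-index
  convention.
- **Precision**: TSV round-trips preserve doubles exactly (17 significant
  digits); multi-model PDB is a fixed-width format with three decimals,
  so PDB round-trips are exact at 0.001 Å, which is far below any
  fluctuation scale analyzed here.
- **Seeds** are explicit everywhere randomness exists; derived
  substreams (condition offsets, bootstrap streams) are reduced modulo
  the 32-bit integer range.

# Simulation sizes used by the tests

The suite and the acceptance script run, by design, at sizes where each
property's Monte Carlo error is well below its assertion margin: the
family-wise-error null uses 1000 replicate simulations of 20-residue,
40-frame ensembles (5 + 5 replicas); Ward separation uses 100 replicate
simulations of 40-residue, 200-frame ensembles at strong local softening
(factor 0.03), where separation is essentially deterministic; covariance
and RMSF limits use 10⁴ frames; cohort recovery uses 1000 synthetic
cases. Monte Carlo rate assertions use one-sided 99% binomial bounds
around the nominal rate rather than equality.

# Known limitations

- The codon activity-score table shipped with the package is synthetic
  (hotspot codons scored above threshold) and exists to exercise the
  classification logic; real analyses must supply the transcriptomic
  score table for their cohort.
- The triage cascade cannot distinguish a germline variant absent from
  population databases and below 0.45 VAF from a somatic one; it
  implements exactly the stated frequency/VAF rules, not a
  germline/somatic deconvolution.
- Survival modeling, logistic regression, and external-cohort
  (TCGA/MSK) analyses are out of scope; the statistics here end at the
  association and biomarker-evaluation layer.
- Hausdorff distances are computed without per-pair refitting by
  default; for trajectories with large rigid-body excursions the
  per-pair refit flag trades cost for exactness.
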
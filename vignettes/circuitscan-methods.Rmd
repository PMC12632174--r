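---
title: "circuitscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circuitscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`circuitscan` reconstructs treatment-specific *initiating cell circuits*
from single-cell RNA-seq UMI atlases of perturbed lungs: which cell type
(the sender) up-regulates which ligand under which exposure, which cell
type (the receiver) up-regulates the matching receptor, and whether the
receiver's perturbed gene program is the kind of program that ligand is
known to induce. The pipeline covers quality control, per-sample
consensus selection of highly variable genes (HVGs), PCA/kNN/Leiden
clustering with two-tier marker annotation, per-cell-type differential
expression against pooled sham controls, gene-signature scoring, GSVA
and preranked GSEA, induced-connectome construction, and
NicheNet-style ligand-activity scoring. A negative-binomial simulator
plants known cell types and circuits so that every stage can be
validated against ground truth.

# The statistical pipeline

## Quality control

The QC cascade runs in a fixed order — gene filtering before cell
filtering — with inclusive/exclusive boundaries chosen deliberately:

* genes are kept when their total count is at least 1 **and** they are
  expressed (count > 0) in at least 5 cells;
* cells are removed when the mitochondrial count fraction is **greater
  than or equal to** 10%, or fewer than 300 genes are detected, or the
  total count is below 500.

Mitochondrial genes are recognized by a case-insensitive `mt-` name
prefix (the mouse convention); an explicit override list can be
supplied. If no mitochondrial gene is found, the fraction is set to 0
for every cell and a warning is issued rather than failing the run.
Filtering only drops rows/columns; no count is ever altered, and both
filters are idempotent.

## Normalization

Counts are depth-normalized to 10,000 per cell and `log1p`-transformed
(`logNormalize(method = "cp10k")`). A strict `log1p`-only mode
(`method = "none"`) is available for users who want the transformation
without depth normalization; the default is depth-normalized because
cross-cell comparisons are depth-confounded otherwise. The raw layer is
always kept alongside.

## Doublet detection

`detectDoublets()` follows the simulated-doublet strategy: `nSim`
synthetic doublets are created by summing the raw counts of random
observed cell pairs (UMI counts are additive, so summing — not
averaging — is the physically correct merge), the pooled matrix is
embedded with PCA (30 PCs), and every observed cell is scored by the
fraction `f` of its k nearest neighbours that are simulated. The
fraction is rescaled with the simulation ratio `r` and a prior expected
doublet rate `rho` (default 0.1) into
`(f/r)·rho / ((f/r)·rho + ((1-f)/(1-r))·(1-rho))`.
This calibration matters: in a perfectly homogeneous population,
doublets are transcriptionally indistinguishable from singlets, every
neighbourhood is ratio-neutral (`f ≈ r`), and the score settles at
`rho` rather than 0.5 — so homogeneous data is not over-flagged.

The automatic threshold is the minimum-density valley between the
lowest and highest prominent modes (at least 5% of the peak density) of
the *observed* cells' score distribution, with a fixed fallback of 0.25
when the distribution is unimodal. An earlier design thresholded the
*simulated* doublets' histogram instead; with well-separated cell types
that histogram's "embedded" mode carries only ~1/nTypes of the mass and
the valley finder lands inside the neotypic hump, collapsing recall.
Thresholding the observed distribution — a dominant singlet mode versus
a neotypic doublet mode — proved markedly more robust (inter-type
doublet recall ~0.9 at 10% injected doublets in the packaged tests).

Two practical details: the kNN neighbourhood is expanded by the
simulation ratio (`k' = k·(1 + nSim/nObs)`) so that the effective number
of observed neighbours stays near `k` and the score granularity stays
fine; and simulated doublets have roughly half the relative sampling
noise of singlets (twice the depth), so they concentrate toward cluster
centres — one reason a binomial model of neighbour counts *under*-states
the null flagging rate, and why the packaged null test compares the
flagged fraction in doublet-free data against twice the calibrated
prior instead.

## Consensus HVGs, embedding, clustering

HVGs are selected per sample by normalized-dispersion binning: on the
de-logged values, per-gene dispersion (variance/mean) is z-scored
within 20 mean-expression bins and the top 2,000 genes per sample are
flagged. The consensus keeps genes flagged in **at least two samples** —
computing HVGs per sample and then requiring recurrence is what makes
the per-sample step meaningful in a multi-animal design. Variances
below numerical noise are treated as zero so constant genes can never
be flagged.

The consensus HVGs are scaled (zero mean, unit variance, clipped at
10), embedded with PCA (50 components by default, reduced to the
available rank on small inputs), and connected into a symmetric
union-kNN graph (k = 15). Leiden community detection (modularity
objective) with a fixed seed produces the clusters; resolution defaults
to 1.0 for the whole-atlas tier and 0.8 for the within-lineage tier.
k, the resolutions and the HVG flavour are package choices, surfaced in
the configuration.

## Two-tier annotation

Tier 1 assigns each cluster the lineage whose defining gene has the
highest mean expression in the cluster — *Epcam* (epithelial), *Cldn5*
(endothelial), *Col1a2* (stromal), *Ptprc* (immune). Exact ties break
deterministically by the declared lineage order. A missing defining
gene is a hard error naming the unassignable lineage. Tier 2 repeats
HVG selection, embedding and Leiden clustering within each lineage and
labels each subcluster with the best-matching fine marker set; fine
labels can never cross lineage boundaries by construction, and the
fine-type-to-niche map supplies the niche label.

## Differential expression

Markers use the one-vs-rest Wilcoxon rank-sum test: exact tail
probabilities (via the exact rank-sum distribution) for tie-free groups
under 50 observations, normal approximation with tie correction
otherwise — the same switching rule as the standard R implementation,
which the tests cross-check. Treatment effects use Welch's t test per
cell type against the pooled sham cells, on the log-normalized layer.
Only genes expressed (count > 0) in at least 10 cells of the two
compared groups combined are tested; the union reading is the default
and a per-group reading can be obtained by prefiltering. Benjamini–
Hochberg correction is applied within each (cell type, treatment)
contrast — matching per-contrast marker reporting — and a gene is "up"
when `q < 0.05` **and** `log2FC > 0.5` (both strict in the direction
that matters; 0.5 itself is excluded). log2 fold changes are computed
on de-logged group means with a 1e-9 pseudocount, so zero-variance
genes yield finite output (`p = 1` when the means agree, a degenerate
flag when they do not) and never NaN.

## Gene-set scoring, GSVA, GSEA

`scoreGeneSet()` is the expression-matched signature score: the mean
expression of the set minus the mean of a control pool drawn from
25 equal-frequency average-expression bins, 50 control genes per set
gene. The score is exactly zero when the set is the whole universe and
is invariant to adding a constant to every gene. Note the null
variability of the *per-set mean* score is dominated by the randomness
of the draw (one draw fixes a set-vs-control offset shared by all
cells), which is why calibration checks average over random sets rather
than over cells.

`gsvaScores()` implements the GSVA recipe: per-gene kernel-smoothed
ECDF across samples (Gaussian kernel, bandwidth sd/4, for
log-normalized input; Poisson kernel for raw counts), per-sample ranks
symmetrized about the middle rank, and a weighted random walk down each
sample's ranked list. The reported score is the "maxdiff" convention
(maximum positive plus maximum negative deviation); "absmax" is
available. At least two samples are required — the scores are relative
by construction.

`gseaPreranked()` computes the weighted Kolmogorov–Smirnov enrichment
score on a log2FC-ranked gene list (weight exponent 1 by default; 0
recovers the classical unweighted statistic) with gene-label
permutations (default 1,000) for the p-value, NES from the mean |ES| of
the matching sign class, and BH across sets. Permutation p-values live
on the grid `(1+j)/(nPerm+1)`, so exact ties across sets are expected.

## Induced connectome

For one treatment, the "up-set" of a cell type is its set of
significantly upregulated genes (`q < 0.05`, `log2FC > 0.5` strict).
For every ordered pair of cell types and every (ligand, receptor) row
of the resource table, the edge sender → receiver gains that pair iff
the ligand is in the sender's up-set and the receptor in the
receiver's. Edge weight is the number of qualifying pairs; autocrine
self-edges are allowed; duplicate resource rows are collapsed with a
warning. The graph is directed — ligand-bearing type as sender,
receptor-bearing type as receiver — and an undirected view is a
symmetrization away. Because both endpoints must independently clear an
FDR-controlled threshold, sham-vs-sham relabelled data yields
essentially empty graphs, which the tests verify. Baseline expression
of ligand or receptor is deliberately *not* required (the rule
conditions on up-regulation only); a baseline filter can be imposed by
intersecting up-sets with expressed genes before the call.

## Ligand activity

For a receiver cell type's perturbed program (its up-set), every ligand
of the regulatory-potential prior is scored by the Pearson correlation
between its weight vector over the prior's target universe and the 0/1
program-membership vector, with the target universe restricted to genes
actually tested in the DGE. A ligand passes when some sender type
expresses it in **at least 10%** of its cells (count > 0, evaluated on
the treatment's cells; the threshold is inclusive) and the correlation
is **strictly greater than 0.05**. Degenerate inputs — an empty or
universe-covering program, a constant prior row — leave the correlation
undefined and the ligand excluded. The full NicheNet workflow also
pre-selects candidate ligands by receptor expression; this
implementation reduces the procedure to the two printed filters, a
documented simplification. The circuit report is the inner join of
connectome edges and passing ligand rows on (ligand, receiver), ranked
by (correlation, edge weight) descending, with receiver response genes
= receiver up-set ∩ the ligand's above-median prior targets.

# The simulator

`simulateAtlas()` draws UMI counts from a negative binomial
(`variance = mu + dispersion·mu²`, dispersion 0.5) with lognormal
per-cell size factors (sd 0.3 on the log scale) — the accepted noise
model for droplet scRNA-seq. The default configuration emulates a
five-condition instillation study (sham, CNP, DWCNT, MWCNT, LPS; two
samples per condition) over an eight-type lung panel spanning the four
lineages, about 2,000 cells by 1,500 genes.

Design choices worth noting:

* **Depth.** `baseMean = 1` gives ≈1,500 total UMI per cell at the
  default gene count, the depth regime of whole-lung Dropseq data. At
  this depth a planted log2 effect of 1.5 with 100 cells per group is
  detected by the Welch/BH pipeline with >95% power, which is the
  regime the recovery checks assume.
* **Markers.** Each type carries 20 exclusive marker genes at 5× the
  base mean, and all types of a lineage express the lineage's defining
  gene, so both clustering and two-tier annotation can be validated.
* **Mitochondria.** A 10-gene `mt-` block is boosted to an expected
  ~4% count fraction so that name-based QC runs unmodified.
* **Circuits.** A planted circuit multiplies the NB mean of the ligand
  (sender type), the receptor and 20 downstream target genes (receiver
  type) by `2^log2_effect`, only under the circuit's treatment. The
  target genes are the receiver "program" that ligand-activity scoring
  should trace back to the ligand. Planted cytokines reuse mouse
  symbols (*Cxcl1*, *Csf2*, *Ccl2*, *Il1a*, ...) for readable reports;
  nothing depends on the names. Cytokine genes get twice the base mean,
  emulating constitutively detectable chemokines.
* **Doublets.** `injectDoublets()` appends exact sums of two parent
  cells drawn from the same sample and records the parents.
* **Resources.** `makeLRResources()` emits a ligand-receptor table
  (planted pairs + decoys among unperturbed genes) and a
  regulatory-potential matrix in which planted ligands weight their
  true targets in [0.7, 1] against a [0, 0.3] background — so recovery
  of planted ligands is a construction guarantee checked empirically,
  not an accident.

What the simulator does **not** model: spatial structure, batch effects
beyond per-sample size factors, gene–gene correlation networks,
ambient RNA, or realistic cell-type abundance skews. Passing tests
therefore demonstrate the pipeline's statistical correctness and its
ability to recover planted signals under the stated noise model — not
performance on any particular real data set.

# Problem sizes and determinism

The packaged tests and the acceptance script use desk-scale problem
sizes chosen as the package's own reference conditions: recovery runs
use 7 cell types × 800 genes × 2,100 cells with two planted circuits
and 50 decoy ligand pairs (100 cells per (treatment, type) group); null
calibration uses 2,000 genes at 100-vs-100 cells; GSEA uniformity uses
200 random sets at 500 permutations. Every stochastic step takes an
explicit seed, a global seed expands into per-stage seeds by hashing
the stage name (`stageSeed()`), and identical configurations reproduce
byte-identical outputs — the pipeline's manifest hashes every written
file to make this checkable.

# Known limitations

* Welch tests on log-normalized single-cell values share the usual
  pseudoreplication caveat: cells, not animals, are the unit of
  analysis. The per-sample structure is simulated and carried through,
  but no mixed-model or pseudobulk option is provided.
* The Wilcoxon exact path requires tie-free data; UMI-derived values
  are tie-heavy, so in practice the tie-corrected normal approximation
  is what runs on real matrices.
* Ligand activity uses the two printed filters only; no ligand-target
  prior is constructed here — the matrix is consumed as input.
* The annotation tier-2 matcher assigns the best mean-expression fine
  label; it does not flag novel states, and manual curation is out of
  scope.
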
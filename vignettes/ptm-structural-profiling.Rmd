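---
title: "Methods: structural profiling of PTM sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural profiling of PTM sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ptmstruct` asks a structural question about post-translational
modification: when a transferase such as OGT selects a serine or threonine,
is there a recognisable signature in the local three-dimensional structure,
the solvent accessibility, or the (predicted) disorder of the site? This
vignette documents the models and procedures the package implements, the
parameters that matter, the numerical conventions, and what the synthetic
data can and cannot tell you.

## The analysis model

The pipeline has two arms.

The **structural arm** works on sites that can be placed on experimental
structures. Sites are mapped to chains either through residue-level
correspondence tables (the reliable path) or through local alignment
(Smith–Waterman, BLOSUM62, affine gaps open 11 / extend 1) gated by a
Karlin–Altschul E-value. Around each mapped site a 7-residue window
(offsets −3..+3) is taken in *full-sequence* (SEQRES) space, so residues
missing from the model still occupy their slots. Windows with a complete
backbone contribute 8 superposition atoms — the 7 Cα plus the central
residue's Cβ, which encodes the side-chain direction of the modified
residue. All window pairs are superimposed with the Kabsch algorithm
(closed-form least-squares rotation via SVD, determinant-corrected so
reflections are never used) and the RMSD matrix is clustered by complete
linkage. Cutting the complete-linkage dendrogram at *h* guarantees every
cluster has diameter ≤ *h*; the default cut of 3 Å therefore yields groups
in which *all* window pairs superimpose within 3 Å. Because a cluster count
by itself is meaningless, the same procedure is applied to windows centred
on *unmodified* S/T from the same chains, resampled with replacement at the
observed sample size: the distribution of cluster counts over replicates is
the null against which the observed count is read.

Alongside clustering, the structural arm annotates each site with: missing
residue status (the REM465 convention — residues present in the construct
but absent from the model, a standard proxy for structural disorder),
tested with Fisher's exact test against unmodified S/T; 3-state secondary
structure; relative solvent accessibility; and the chain-standardised Cα
B-factor (z-scored within its own chain, so crystal-to-crystal scale
differences cancel), compared between groups with a Kruskal–Wallis test.

The **sequence arm** works on the full site catalog, independent of
structures. It computes a positional relative-entropy profile of the
aligned flanks (the sequence-logo statistic, in bits) against a background
amino-acid distribution; proportion tests for predicted secondary
structure and predicted burial in the layout of published count tables;
per-method disorder score comparisons (Welch t); and per-offset disorder
log-odds profiles: at each offset *d* from the site, the proportion of
disordered residues (score ≥ the method's published threshold) in the
target set is compared to a background set as a log10 odds ratio with a
Wald band.

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| chain length gate | > 30 | residues | excludes peptides whose "structure" is mostly context |
| resolution gate | ≤ 2.50 | Å | boundary inclusive; coordinates reliable enough for backbone RMSD |
| E-value gate | ≤ 1e-25 | — | conservative; only near-certain homology can place a site |
| window half-width | 3 | residues | the transferase contacts roughly the site ± 3 backbone |
| superposition atoms | 8 (7 Cα + central Cβ) | — | backbone shape plus side-chain direction of the site residue |
| clustering cut | 3.0 | Å RMSD | complete linkage makes this a hard diameter bound |
| bootstrap replicates | 1000 | — | stable 2.5/97.5 percentiles of the cluster-count null |
| RSA bins | 0.05, 0.25 | fraction | buried ≤ 5 % < partial ≤ 25 % < exposed; both cut-offs inclusive below |
| max-ASA scale | Tien 2013 (theoretical) | Å² | Miller 1987 selectable; the choice shifts buried counts, so every output records the scale |
| disorder thresholds | per method | score | published cut-offs: DisEMBL-REM465 0.6, COILS 0.516, HOTLOOPS 0.1204, IUPred-Long/Short 0.5, JRonn 0.5; score ≥ threshold is disordered (inclusive) |
| profile half-width | 50 | residues | wide enough to see ±15-residue peaks against a flat far field |
| entropy pseudocount | total mass 10 | counts | background-proportional Dirichlet prior; see below |
| predictor trim | max 800, margin 100 | residues | long sequences trimmed to a window centred on the site, shifted to fit |

## Numerical conventions

* **B-factor z-scores** use the population (not sample) standard deviation;
  for chains longer than the 31-residue gate the difference is negligible,
  and the convention is recorded in output headers. Chains with zero
  variance get all-zero scores with a warning; fewer than two observed
  residues is an error.
* **Entropy pseudocounts.** Column frequencies are smoothed with a
  Dirichlet prior whose total mass is 10 distributed proportionally to the
  background (equivalently 0.5 per amino acid under a uniform background).
  The background-proportional form is what makes the profile *exactly* zero
  when a column's observed frequencies equal the background — a flat prior
  would bias columns away from non-uniform backgrounds. Kullback–Leibler
  conventions apply: 0·log(0/q) = 0, and an observed residue with zero
  background frequency yields an infinite divergence rather than NaN.
* **Clustering cut semantics.** Clusters are the connected components of
  merges at height ≤ the threshold (`stats::hclust` complete linkage +
  `cutree(h = ...)`). Ties at exactly the cut height are kept together;
  on floating-point RMSDs they are vanishingly rare. Multi-member clusters
  are labelled A, B, … by descending size, ties broken by the
  lexicographically smallest member id; size-1 clusters are reported as
  singlets.
* **Best-candidate selection.** Table-derived mappings outrank
  alignment-derived ones (mirroring a table-first, alignment-for-the-rest
  workflow); within tables the highest coverage wins, within alignments
  the lowest E-value. "Best E-value" is read as *numerically smallest*:
  preferring larger E-values would prefer worse hits and contradict a
  conservative gate. Exact ties fall back to lexicographic
  (PDB id, chain id), making selection invariant to input order.
* **The π-helix reduction.** The 8→3 state reduction maps G,H → helix;
  I,B,E → strand; everything else, including unassigned residues, → coil.
  Mapping π-helix (I) to strand is unusual — most reductions send it to
  helix — but it is the convention this analysis follows; it is applied
  verbatim and flagged here. With DSSP inputs I is rare enough that the
  choice rarely moves counts.
* **Fisher's odds ratio** is the sample odds ratio ad/bc (what a reader
  computes from a printed 2×2 table), not the conditional MLE that
  `fisher.test` reports; the p-value is the exact two-sided hypergeometric
  one. A zero cell triggers the Haldane +0.5 correction for the ratio
  only, flagged in the result.
* **Two-proportion tests** use the pooled-variance z statistic with
  p = 2(1 − Φ(|z|)); proportion intervals are Wald, clipped to [0, 1].
* **Degenerate inputs.** Pooled proportions of 0 or 1 return p = 1 with a
  warning; constant score vectors make Kruskal–Wallis an error; windows
  touching chain termini or missing residues are simply not
  backbone-complete; sampling a bootstrap from a pool smaller than the
  sample size warns and proceeds (it is with replacement).
* **Randomness.** Each entry point takes one integer seed and seeds R's
  generator once; all replicates draw sequentially from that stream. (A
  counter-based per-replicate stream would allow parallel replay, but base
  R has no such generator; sequential seeding is equally reproducible for
  a fixed seed, which is the property the pipeline needs.)

## The synthetic data generator

The generator exists so that every pipeline stage can be tested against
known ground truth without downloading structures. It emulates:

* crystal-structure-like chains written as standard PDB files (SEQRES,
  REMARK 465, backbone + Cβ ATOM records) with ideal Engh–Huber geometry
  (N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å, trans ω), built residue by
  residue from arbitrary phi/psi programmes;
* planted 7-residue structural motifs at modified sites, drawn from six
  templates chosen (by maximising the minimum pairwise superposition RMSD,
  3.2 Å for the set) to be separable at the 3 Å clustering cut under the
  default 0.3 Å per-coordinate Gaussian noise — sibling windows then
  superimpose below ~1 Å while cross-template pairs stay above the cut;
* planted missing regions (REM465 truth), lognormal Cα B-factors
  (meanlog log 20, sdlog 0.3 — a realistic 15–30 Å² bulk), and
  disorder-score tracks whose exceedance probability is p_in within a
  window of each site and p_out elsewhere, giving a closed-form planted
  log10 odds ratio log10[(p_in/(1−p_in))/(p_out/(1−p_out))].

What it does **not** emulate: side chains and packing (the built-in
sphere-sampling ASA therefore sees an artificially exposed backbone — on
real structures, supply DSSP files), crystal contacts, alternate
conformations, sequence-structure correlations (synthetic sequences are
random, G/P excluded), realistic disorder autocorrelation along the chain,
and homology between catalog proteins and unrelated chains. Passing tests
on synthetic data therefore demonstrate that the machinery is correct —
mappings recovered, planted motifs clustered, planted enrichments inside
their bands — not that any biological claim generalises; the biological
conclusions require real site catalogs and structures.

## Problem sizes used by the tests and the acceptance script

The shipped checks run at deliberately desk-scale sizes: 100 random
8-point pairs against a brute-force quaternion-search oracle (agreement to
1e-3 Å); 500 random dissimilarity matrices for the diameter guarantee;
planted-motif recovery at n = 120 windows for 2–6 templates (Rand index
against truth); 100 seeded disorder-track runs of 200 target + 200
background proteins for band coverage; and a 10-protein synthetic
end-to-end run with a 200-replicate bootstrap. These sizes give stable
pass/fail behaviour while keeping a full run in tens of seconds; all of
them scale up by changing the corresponding arguments.

## Replication against published structural datasets

Reproducing a published cluster census (e.g. 10 clusters over 96 of 132
windows with 36 singlets, or a specific list of buried sites) requires the
original structure files from the PDB and their DSSP outputs, which this
package deliberately does not fetch. The path is: obtain the site catalog
and structures, run `run_structural_analysis()` with a SIFTS mapping
table, and join the emitted `cluster_assignments.csv`
(`PDB,Chain,Position,Cluster,RSA,SS`) against the published supplementary
table on (PDB, Chain, Position). Note that buried-site counts are
sensitive to the max-ASA scale: the Tien 2013 theoretical maxima
(default) give systematically lower RSA than Miller 1987 tripeptide
values, so the scale must match before comparing buried/exposed tallies
(every output file records the scale used).

## Known limitations

* mmCIF support covers coordinates and metadata; when entity-level
  sequence records cannot be recovered the chain falls back to observed
  residues only (with a warning), so missing-residue analysis on such
  files is degraded. PDB-format files carry full SEQRES and are preferred.
* The alignment mapper scores with a fixed Karlin–Altschul parameter pair
  (λ = 0.267, K = 0.041 — gapped BLOSUM62 defaults); for unusual scoring
  systems supply BLAST tabular output instead, which takes precedence.
* BLAST tabular (outfmt 6) hits can only be position-mapped when the HSP
  is gap-free; gapped HSPs are skipped with a warning because the format
  does not record gap placement.
* The dihedral-window secondary-structure fallback is deliberately crude
  (no hydrogen-bond energetics); it labels ideal helices/strands correctly
  and is meant for synthetic fixtures, not for publication-grade
  assignments — use DSSP files for real structures.
* Sphere-sampling ASA at the default 960 points per atom carries
  point-counting noise up to ~2 % on partially occluded atoms; increase
  `points` where that matters.
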
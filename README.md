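# ptmstruct

Structural characterisation of post-translational modification (PTM) sites,
built around the question of whether O-GlcNAcylated serines/threonines (S/T)
carry a recognisable three-dimensional signature. O-GlcNAc sites famously
lack a clear sequence motif — unlike kinase substrates — so the natural next
place to look is local backbone structure, solvent accessibility and
intrinsic disorder. `ptmstruct` provides that analysis as a tested, reusable
R pipeline for anyone with a site catalog, protein structures and standard
per-residue prediction tracks.

## What it does

* **Site catalogs** — build modified (MSS-style), unmodified-background
  (USS-style) and globular-background site sets from CSV site tables and
  FASTA sequences; deduplicate 7-residue motifs; enumerate unmodified S/T;
  trim sequences for length-limited predictors.
* **Structure annotation** — parse PDB/mmCIF chains (X-ray, > 30 residues,
  ≤ 2.50 Å by default), flag missing residues (the REM465 convention, a
  structural-disorder proxy), standardise Cα B-factors per chain
  (z = (B − μ_chain)/σ_chain), and assign secondary structure and relative
  solvent accessibility (RSA = ASA / max-ASA; buried ≤ 5 % < partial ≤ 25 %
  < exposed) from DSSP files or built-in geometric fallbacks.
* **Site-to-structure mapping** — SIFTS-style residue tables first, then
  Smith–Waterman alignment (BLOSUM62, gaps 11/1) gated at a Karlin–Altschul
  E-value ≤ 1e-25, with best-chain selection by coverage (tables) or
  E-value (alignments).
* **Shape clustering** — 7-residue windows around each site are superimposed
  pairwise with the Kabsch algorithm on 8 atoms (7 Cα + central Cβ), the
  RMSD matrix is clustered by complete linkage cut at 3 Å (guaranteeing
  cluster diameter ≤ 3 Å), and the observed cluster count is compared to a
  bootstrap null built by resampling unmodified-S/T windows from the same
  chains.
* **Enrichment statistics** — Fisher's exact test with the sample odds
  ratio (ad/bc) for REM465 enrichment, pooled two-proportion z-tests and
  Wald intervals for predicted-feature tables, Welch t / Kruskal–Wallis
  score comparisons, positional relative entropy in bits
  (R_i = Σ_a p_{a,i} log2(p_{a,i}/q_a), background-proportional
  pseudocounts, bootstrap bands), and per-offset disorder log10 odds-ratio
  profiles against a background set (Haldane-corrected, Wald bands).
* **Synthetic data** — ideal-geometry backbone generators (Engh–Huber bond
  lengths/angles, any phi/psi programme), whole-chain PDB writers with
  planted motifs, missing regions and lognormal B-factors, plus
  disorder-track generators with planted enrichment — every pipeline stage
  is testable offline with known ground truth.

## Worked example

```r
library(ptmstruct)

# REM465 enrichment from a 2x2 contingency of site counts
fr <- fisher_exact_or(26, 143 - 26, 553, 4811 - 553)
cat(sprintf("REM465 enrichment: OR = %.2f, Fisher p = %.3f\n",
            fr$odds_ratio, fr$p_value))
#> REM465 enrichment: OR = 1.71, Fisher p = 0.024

ci <- proportion_ci(78, 143)
cat(sprintf("coil proportion 78/143: %.2f [%.2f, %.2f]\n",
            78 / 143, ci[["low"]], ci[["high"]]))
#> coil proportion 78/143: 0.55 [0.46, 0.63]

# synthetic end-to-end structural run with planted ground truth
dir <- file.path(tempdir(), "demo")
g <- generate_structure_set(synthetic_spec(n_proteins = 10,
                                           n_modified_per_protein = 2,
                                           seed = 1), dir)
cfg <- run_config(structures = list.files(dir, pattern = "\\.pdb$",
                                          full.names = TRUE),
                  site_table = g$files[["sites"]],
                  fasta = g$files[["fasta"]],
                  mapping_table = g$files[["mapping"]],
                  bootstrap_reps = 200, seed = 1)
rep <- run_structural_analysis(cfg)
#> 20 site(s) mapped onto 10 chain(s)
print(rep$clustering)
#> <cluster_result> 5 cluster(s) holding 19 window(s), 1 singlet(s),
#>   complete linkage at 3.00 A
cat(sprintf("bootstrap null cluster-count 95%% interval: [%d, %d]\n",
            rep$bootstrap$ci[[1]], rep$bootstrap$ci[[2]]))
#> bootstrap null cluster-count 95% interval: [2, 5]
```

The mapped-site table, per-state proportion tests, RSA bins, buried-site
listing, cluster assignments (`PDB,Chain,Position,Cluster,RSA,SS`) and the
bootstrap summary are returned as data frames and, when `out_dir` is set,
written as CSVs stamped with the run configuration.

The odds ratio of 1.71 means modified S/T are ~1.7× more likely than
unmodified S/T from the same chains to fall in crystallographically
unresolved (flexible or disordered) regions. The synthetic run recovers the
planted structural motifs as clusters and shows how an observed cluster
count is judged against the resampling null.

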
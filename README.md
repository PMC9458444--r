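# ribohet

Detecting differential ribosomal-protein incorporation from the rRNA
fragments in Ribo-seq data.

## The problem

Ribosome profiling (Ribo-seq) digests unprotected RNA with an RNase and
sequences what survives. Most analyses keep only the mRNA footprints and
throw away the large fraction of reads that map to rRNA. But those rRNA
fragments are not noise: a ribosomal protein (RP) sitting on the ribosome
shields the rRNA backbone around it from digestion, so when the
incorporation of an RP differs between two conditions, the positional
abundance of rRNA fragments changes *specifically near that RP's contact
points*. ribohet turns this into a screen for ribosome heterogeneity: given
two groups of Ribo-seq samples, it predicts which RPs are differentially
incorporated, using only data that would otherwise be discarded.

## The method

1. **Contact sets from structure.** From an mmCIF model of the 80S ribosome,
   the minimum distance d(r, p) between every rRNA residue r (N1 base atom)
   and every RP p (alpha carbons) is computed, giving an RP x position
   proximity matrix over the concatenated rRNA coordinate (28S + 18S + 5.8S +
   5S). A residue is a *contact point* of p when d(r, p) <= tau, with tau the
   pooled 5th percentile of all distances (~27.4 Å for the human 80S from
   PDB 4V6X); each RP's set keeps at most the 360 closest positions (5% of
   the 7217-nt human rRNA). A human-derived matrix can be transferred to
   another species through per-rRNA sequence alignment with linear
   interpolation of distances at insertions.
2. **Positional differential abundance.** Per-nucleotide fragment coverage
   is computed from BAM or bedGraph input, low-coverage positions are
   dropped (mean raw count < 1), samples are normalized with median-of-ratios
   size factors, and each position is tested with a negative-binomial Wald
   test (MAP dispersions shrunk toward a mean-dispersion trend), giving
   log2FC and BH-adjusted p per position.
3. **Enrichment at contact points.** Positions are ranked by
   `|log2FC| * max(-log10(padj), 5)` and three tests ask whether large
   changes concentrate in each RP's contact set:
   * **ES1** — the normalized enrichment score (NES) of a pre-ranked,
     GSEA-style weighted Kolmogorov–Smirnov walk, with a permutation p-value;
   * **ES2** — the z-score of that NES against the NES of 100 *background
     sets*, circular translations of the contact set along the concatenated
     rRNA (shift 71 nt for human, 67 for mouse, ~1% of total length), which
     corrects for set size and positional autocorrelation;
   * **ORA** — a hypergeometric test for overrepresentation of significant
     positions (padj < 0.05, |log2FC| > 0.5) in the set.

   RPs with ES2 >= 1 are reported as candidates, sorted by ES2. No direction
   (more vs less incorporation) is assigned: protection changes can either
   enrich or deplete fragments depending on fragment size selection.

## Worked example

Everything below runs offline on a synthetic ribosome: a 650-nt rRNA helix
with 8 RP chains, and a 3 vs 3 count simulation in which condition B carries
a 1.5 log2FC protection effect at 60% of RP3's contact points.

```r
library(ribohet)

toy   <- make_toy_structure(n_residues = 650, n_rps = 8, seed = 42)
ref   <- read_rrna_reference(toy$fasta)
model <- read_ribosome_structure(toy$cif, toy$chain_map)
pm    <- build_proximity_matrix(model, ref)
contacts <- contact_set_collection(pm)
contacts
#> <contact_set_collection> 8 RPs; tau = 78.63 A, cap = 32, shift = 6 nt, 100 backgrounds per RP

sim  <- simulate_positional_counts(ref, contacts, target_rp = "RP3", seed = 7)
diff <- sim$pc |> filter_low_counts() |> differential_abundance()
diff
#> <rrna_differential> 650 positions tested; 9 significant (padj < 0.05 & |log2FC| > 0.5); contrast B vs A

enr <- predict_rp_incorporation(diff, contacts, seed = 11)
enr
#> # RP incorporation predictions (1 candidate(s) at ES2 >= 1)
#> # A tibble: 8 x 12
#>   rp_id   es1     es2   gsea_p gsea_padj    ora_p overlap_k set_size
#> 1 RP3   2.04   4.92   0.000999   0.00799 6.75e-11         8       30
#> 2 RP6   1.23   0.872  0.125      0.376   1   e+ 0         0       32
#> 3 RP8   1.22   0.833  0.141      0.376   1   e+ 0         0       32
#> 4 RP1   0.958 -0.0759 0.590      0.854   1   e+ 0         0       30
```

The spiked RP3 is the only candidate: its contact set's enrichment score
sits 4.9 standard deviations above its own circular-shift backgrounds
(ES2 = 4.92), the permutation test agrees (adjusted p = 0.008), and 8 of its
30 tested contact positions are individually significant (ORA
p = 6.8e-11). `autoplot(enr)` draws the ES1 vs ES2 triage plot;
`tidy(diff)` and `sample_pca(sim$pc)` expose the per-position table and the
sample-level QC. On real data, replace the toy inputs with your rRNA FASTA,
an mmCIF (or a prebuilt proximity TSV) and a sample sheet of
BAM/bedGraph files — `run_rp_analysis(sheet, matrix_tsv, out_dir = "results")`
runs steps 2–3 end to end, and `inst/cli/ribohet` exposes the same pipeline
as subcommands (`simulate`, `build-matrix`, `build-sets`, `quantify`, `run`).

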
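# methylDissect

Semi-reference-free cell-type deconvolution of bulk DNA methylomes.

A bulk methylome averages over the cell types in a sample. Reference-based
deconvolution needs purified profiles for every constituent type, which
rarely exist. methylDissect instead exploits **bipolar methylation**: at a
locus that is differentially methylated between cell types, a mixed sample
contains both completely methylated and completely unmethylated sequencing
reads at the same position. The pipeline has three stages:

1. **pCSM loci** (putative cell-type-specific methylated loci). Every
   window of four consecutive called CpGs in a read is a 4-CpG segment;
   per-unit (read or cell) methylation levels at a segment are tested for
   bipolarity with a two- vs one-component beta-mixture likelihood-ratio
   test. The one-component null is constrained to unimodal shapes — a
   homogeneous population varies unimodally, whereas a U-shaped level
   distribution is itself cell-type structure — and the null distribution
   is calibrated by parametric bootstrap. Read-derived levels (k of 4
   sites methylated) use the binomial-integrated form, a beta-binomial
   mixture on counts. Segments with hyper-minus-hypo subset difference
   > 0.30 and BH-adjusted p < 0.05 are pCSM; overlapping segments merge
   into loci.
2. **Eigen-pCSM loci.** pCSM loci are k-means split into
   hypo/mid/hypermethylated groups, clustered into signed co-methylation
   network modules (adjacency `((1+cor)/2)^power`, topological overlap,
   average linkage), and each module is summarized by the loci with the
   largest absolute PC1 loadings.
3. **Latent methylation components.** The eigen-loci x samples matrix `N`
   is factorized as `N ≈ W H` with

   ```
   min ||N - W H||_F^2 + lambda * sum W_ij (1 - W_ij)
   s.t. 0 <= W <= 1,  H >= 0,  colSums(H) = 1
   ```

   so LMC profiles (columns of `W`) are methylation profiles pushed toward
   biologically plausible binary values, and each sample's proportions lie
   on the simplex. Exact block minimization (simplex-constrained QP per
   sample, box-constrained coordinate descent per locus) guarantees a
   non-increasing objective; `(k, lambda)` can be chosen by held-out-locus
   cross-validation. Fitted LMCs are matched to reference profiles by
   mutual-best Pearson correlation, and recovery is scored by RMSE (profile
   agreement) and MAE (proportion agreement, unmatched types scored as 0).

A simulation module generates sparse single-cell bisulfite datasets with
planted cell-type-specific loci and known mixing proportions, so every
stage can be benchmarked against ground truth.

## Worked example

Simulate a 3-type single-cell experiment, run the full pipeline on 40
synthetic mixtures, and score recovery:

```r
library(methylDissect)

sim <- generate_synthetic_cells(n_types = 3, cells_per_type = 30,
                                n_loci = 400, frac_csm = 0.3,
                                cover_rate = 0.2, seed = 42)
res <- dissect_mixture_study(sim, n_samples = 40, lambda = 1e-4,
                             min_module_size = 10, n_restarts = 5, seed = 7)
res$evaluation
#> dissection evaluation: 3 matched component(s), MAE = 0.0288
#>   per-reference RMSE:
#>     type1: 0.1145
#>     type3: 0.0987
#>     type2: 0.0857
res$fit
#> LMC factorization: 30 loci x 40 samples, k = 3, lambda = 0.0001
#>   final objective 0.764693 after 94 iterations (restart 5)
```

All three planted cell types were matched one-to-one to latent components
(`3 matched component(s)`). The mean absolute error of the recovered
mixing proportions is 0.0288 — about three percentage points per type —
and each matched component's profile differs from its reference methylome
by an RMSE of 0.09–0.11 across eigen loci. `res$pcsm$calls` holds the
per-segment bipolarity table (34 pCSM segments here), `res$eigen_loci`
the module representatives used for the factorization.

The individual stages are exported (`extract_segments()`,
`filter_segments()`, `call_pcsm()`, `merge_to_loci()`,
`run_comethylation()`, `factorize()`, `cross_validate()`,
`match_lmcs()`, `fold_enrichment()`, ...), and a thin command-line
wrapper with `extract`, `find-pcsm`, `comethy`, `decompose`, `simulate`,
`evaluate` and `annotate` subcommands is installed at
`inst/cli/methyldissect.R`.

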
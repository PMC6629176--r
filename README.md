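# secirc — discovery of super-enhancer-associated circular RNAs

`secirc` is an R package for nominating **SE-circRNAs**: circular RNAs
whose promoters lie closest to a super-enhancer. Super-enhancers — large
clusters of active enhancers with exceptionally high H3K27ac signal —
mark cell-identity genes, and circRNAs associated with them are
preferentially highly expressed, tissue-specific and developmental-stage
specific. Intersecting stage-specific super-enhancers with conserved,
stage-differential circRNAs is a fast computational filter for candidate
regulators (the strategy that singled out the cardiac circRNA of the
*Nfix* locus), and this package implements that funnel end to end for
anyone with enhancer peaks, circRNA annotations and an expression matrix.

## What it computes

* **Super-enhancer calling** (ROSE-style): peaks within a stitching
  window *W* (default 12.5 kb) are merged; region scores are
  `Σ max(signal − control, 0)`; with ranks and scores min–max scaled to
  the unit square, the SE cutoff is the score at `argmax(x − y)` — the
  tangent point of a slope-1 line under the convex rank curve — and
  regions scoring strictly above it are super-enhancers.
* **Assignment and classes**: each enhancer is assigned to the nearest
  circRNA promoter (host TSS, or the 5′ end of the back-spliced span)
  within 50 kb; circRNAs are labelled SE-circRNA / TE-circRNA / other.
* **Specificity**: the Jensen–Shannon index
  `1 − sqrt(JSD₂(p, onehot(argmax p)))` ∈ [0, 1]; stage-specific SEs by
  a base-coverage overlap rule; Fisher exact association and
  Mann–Whitney expression comparisons (exact at small n).
* **Candidate funnel**: circRNAs that are SE-associated **and** outside
  the ±1.5-fold stage-change interval (pseudocount 0.1 RPM) **and**
  conserved across a three-species ortholog table, ranked by |log2 FC|.
* **Sequence follow-up**: global Needleman–Wunsch identity (+1/−1/−2),
  back-splice-junction-aware scanning of circular sequences for
  canonical miRNA seed classes (8mer, 7mer-m8, 7mer-A1, 6mer),
  cross-species conserved-site counting, and log-odds PWM motif
  scanning on both strands.
* **Synthetic data**: `generate_dataset()` writes a complete fake study
  (peaks + signal, circRNA BED, RPM matrix, ortholog table, FASTA,
  per-stage SE sets) with a JSON ledger of every planted truth, so the
  whole pipeline is testable offline.

## Worked example

```r
library(secirc)

d <- generate_dataset(synth_config(rpm_noise_cv = 0), "synthetic_data")
cfg <- run_config(
  peaks = d$paths$peaks, circs = d$paths$circs,
  expression = d$paths$expression, orthologs = d$paths$orthologs,
  circ_fasta = d$paths$circ_fasta, mirna_fasta = d$paths$mirna_fasta,
  out_dir = "run_out"
)
report <- run_pipeline(cfg)
unlist(report$counts)
#>            peaks stitched_regions   superenhancers         circRNAs
#>              606              525               28              120
#>      se_circRNAs      te_circRNAs      de_circRNAs        conserved
#>               25               25               20               40
#>       candidates       seed_sites
#>               10               33
```

The counts trace the funnel: 606 enhancer peaks stitch into 525 regions,
28 of which score above the rank-curve cutoff (10.1 signal units here);
25 of 120 circRNAs have a super-enhancer as their nearest assigned
enhancer; 20 circRNAs change more than 1.5-fold between stages and 40
have complete three-species ortholog rows; the intersection leaves 10
ranked candidates — on this noiseless synthetic run, exactly the planted
ones (`d$ledger$planted_candidate_ids`). `run_out/candidates.tsv` holds
the ranked table:

```
circ_id           log2fc    specificity  rank  spB_id            spC_id
spA_circ_0000009  0.995453  0.804898     1     spB_circ_0000009  spC_circ_0000009
spA_circ_0000003  0.995399  0.804898     2     spB_circ_0000003  spC_circ_0000003
...
```

SE-circRNAs are also the most expressed and most tissue-specific class
in the report: median RPM 10.5 versus 6.2 (TE) and 1.9 (other), with a
rank-sum p of 5.9e-09.

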
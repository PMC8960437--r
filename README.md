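# orthopeak

Cross-species conservation analysis of transcription factor binding sites.

## The problem

Transcription factors wire up cell-type regulatory programs, but the degree
to which their genome-wide binding maps carry over between species — say,
from mouse models to human — is an empirical question. Given ChIP-seq peak
calls for the same factor in two species (the motivating system is the Th1
lineage-specifying T-box factor T-bet in human and mouse Th1 cells),
`orthopeak` classifies each binding site and each 1:1 ortholog target gene
as **conserved**, **alternative** (bound in both species, but at different
positions), or **species-specific**, and then quantifies how those classes
associate with cross-species expression divergence, DNA-motif content, and
transposable element (TE) overlap.

## The method

Per species, high-confidence sites are consensus intervals supported by a
peak with q < 0.01 in *every* replicate (merged union coordinates; ENCODE
blacklist regions removed), and the low-confidence set is the union of
q < 0.1 peaks from *any* replicate. Each high-confidence site is extended
by 1 kb either side and mapped through a UCSC chain to the other genome;
the equivalent location is the single range from the first to the last
aligned base (best chain by score). A site is

* *conserved* if its image overlaps a high-confidence site of the other
  species,
* *species-specific* if the image overlaps nothing in the other species'
  low-confidence union (no evidence of binding at all), and
* *indeterminate* otherwise; sites whose padded interval has no aligned
  base are *not lifted*.

Sites are assigned to the gene with the nearest TSS. An ortholog pair is a
conserved target if it has a conserved site in both species; alternative if
bound in both species only through species-specific sites; Hs-/Mm-specific
if bound in exactly one species with no sites of any confidence in the
other.

Downstream statistics: Welch *t* tests of per-study mean log2 expression
(median-of-ratios normalisation, log2(x+1), per-study centering,
zero-centering per species), OLS regression of the log2 expression ratio on
the clamped binding-site count difference Δn ∈ [−5, 5], PWM scanning with
exact p-values from the discretised log-odds null distribution (matches at
P < 0.004, proportions with continuity-corrected Wilson 95% CIs), and TE
association via Pearson χ² with standardized residuals (O−E)/√E, confirmed
by a 10,000-fold label-permutation test.

Because the full published analysis needs multi-gigabyte genome builds and
GEO raw data, the package ships a first-class synthetic data generator
(`build_world()`) that emulates the entire input universe — two toy genomes
related by a block chain with ~10% unalignable sequence, replicate peaks
with q-value noise, planted site/gene classes, motif instances, TEs, and
negative-binomial counts with study batch effects — with recorded ground
truth, so every stage is testable end to end.

## Worked example

```r
library(orthopeak)

cfg   <- synthetic_config(seed = 42)     # the default two-species world
world <- build_world(cfg)
dir   <- file.path(tempdir(), "demo_world")
write_world(world, dir)                  # FASTA, chains, GTF, narrowPeak, ...

report <- run_all(world_run_config(dir, seed = 42, n_perm = 2000))

report$gene_summary
#>          class   n proportion_of_target_genes
#> 1    conserved 199                 0.69580420
#> 2  alternative  44                 0.15384615
#> 3   a_specific  23                 0.08041958
#> 4   b_specific  20                 0.06993007
#> 5      unbound 300                         NA
#> 6 unclassified  54                         NA
```

About 70% of bound ortholog genes keep a binding site at the equivalent
position in both species; ~15% stay bound through alternative sites; only
~15% are targets in one species alone. Expression divergence tracks the
classes:

```r
report$expression$stats_cls$per_class
#>          class   n       mean       sd p_vs_conserved
#> 1    conserved 199 -0.5221031 1.546950             NA
#> 3  alternative  44  0.2965373 2.515327   4.321690e-02
#> 4   a_specific  23  2.1773001 2.055626   2.250878e-06
#> 5   b_specific  20 -1.5672082 2.196006   5.028375e-02
#> ...
```

Genes bound only in species A sit ~2 log2 units higher in A (mean 2.18,
Welch *t* versus conserved p = 2.3e-06), and reciprocally for species B
(−1.57). TE overlap is concentrated at species-specific sites:

```r
report$te$a$contingency
#> chi-square independence: X2 = 14.036 df = 3 p = 0.002856
report$te$a$permutation
#> permutation chi-square: observed = 14.036 | empirical p = 0.004498 ( 2000 permutations )
```

and the binding motif is enriched at sites where the factor is actually
bound — 24.7% of A-specific sites contain it versus 8.4% at their
equivalent (unbound) loci in the other genome:

```r
report$motifs$a$proportions
#>               set  k   n proportion ...
#> 1             all 81 559 0.14490161
#> 2       conserved 33 297 0.11111111
#> 3        specific 44 178 0.24719101
#> 4 specific_lifted 15 178 0.08426966
```

All report tables are also written as TSV/JSON under the run's output
directory.

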
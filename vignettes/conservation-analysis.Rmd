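---
title: "Cross-species binding-site conservation: models, parameters and design"
author: "orthopeak"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species binding-site conservation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`orthopeak` compares a transcription factor's ChIP-seq binding map between
two species and asks three questions: which binding sites and target genes
are conserved, how conservation relates to expression divergence, and
whether sequence motifs and transposable elements (TEs) explain the
differences. This vignette documents the models and conventions the package
commits to, the parameters that matter, and the design choices made where
the problem left room.

## The site classification model

Per species, replicate peak calls (narrowPeak) are reduced to a
**high-confidence consensus**: peaks with q < `q_high` (default 0.01) from
all replicates are pooled, merged wherever they share at least one base
pair, and a merged interval is kept only if at least one qualifying peak of
*every* replicate overlaps it. The consensus coordinates are the merged
union of the contributing peaks — a symmetric, deterministic choice that
does not privilege any one replicate; an intersection variant would be
equally defensible but shrinks sites as replicates accumulate. The
**low-confidence union** merges q < `q_low` (default 0.1) peaks from *any*
replicate and represents "any evidence of binding at all". Blacklist
regions remove whole sites on a one-base-pair overlap, after consensus
building (removal before merging gives the same result unless a blacklisted
peak bridges two sites, which blacklist regions — artefact domains — should
not).

The species-specific criterion can be phrased per replicate ("q > 0.1 in
all replicates" versus "in any replicate"), and the two readings differ.
The package implements the one consistent with "no evidence of binding at
all": a site is species-specific when its lifted image overlaps *nothing*
in the other species' low-confidence union, i.e. no replicate anywhere
reached q < 0.1.

Classification is run independently in each direction, so counts need not
match across species. Each site receives exactly one class:

| class | rule |
|---|---|
| `not_lifted` | padded interval has no aligned base in the other genome |
| `conserved` | image overlaps an other-species high-confidence site |
| `species_specific` | image overlaps nothing in the other species' low-confidence union |
| `indeterminate` | anything else (low-confidence evidence only) |

## Coordinate lifting

Chains are parsed with full arithmetic validation (block sizes and gaps
must reconcile with header extents). Sites are extended by `pad` (default
1000 bp, clamped at chromosome bounds) before lifting, and the equivalent
location is the **single spanning range** from the smallest to the largest
aligned-base image — insertions in the target genome are swallowed rather
than splitting the site. When several chains overlap a source interval the
highest-scoring chain is used alone (ties by chain id), mirroring
liftOver's best-chain behaviour; `mapped_fraction` is reported so callers
can impose a minimum-match filter, but none is applied by default — a site
"lifts" if a single base maps. Minus-strand images are converted to
forward-strand coordinates (`pos' = qSize − pos − 1`) before the spanning
range is formed. `chain_invert()` produces the exact inverse chain (blocks
reversed, target/query gaps swapped, coordinates re-expressed), which the
tests use for round-trip properties.

## Gene assignment and gene classes

Sites are assigned to the gene whose transcription start site (any
transcript) is nearest the site midpoint, searching only the site's own
chromosome; cross-chromosome "nearest" is meaningless, so sites on
gene-free chromosomes stay unassigned. Distances are signed by the gene's
transcription direction (negative upstream). Ties on absolute distance
resolve to the lexicographically smaller gene id, making assignment
deterministic and order-independent.

For 1:1 ortholog pairs: conserved target genes have a conserved-class site
in both species; alternative targets are bound in both species through
species-specific sites with no conserved site on either side; Hs-/Mm-
specific targets have species-specific sites in exactly one species and
*no assigned site of any class* in the other — low-confidence or
unalignable evidence on the bound side (an `indeterminate` or only
`not_lifted` site) blocks the specific call. Pairs failing all rules are
reported as `unclassified` and excluded, with `unbound`, from class
statistics; this mirrors the exclusion of indeterminate sites at the site
level. The binding-count difference Δn is clamped to [−5, 5] for the
regression (raw values are retained in the output).

## Expression divergence

The package deliberately replaces a negative-binomial model fit with a
fully specified, dependency-free normalisation: median-of-ratios size
factors, log2(x + 1) (pseudocount 1), removal of per-study *global* shifts
(each study's grand mean over genes is aligned to the species grand mean),
and zero-centering of each species (subtract the grand mean over all genes
and samples). Two points deserve emphasis:

* Study centering is a *scalar* per study, not per gene. Per-gene study
  centering would make every study mean of a gene identical and destroy
  the between-study variance that the Welch test runs on; the scalar
  version removes a planted global batch shift exactly (the tests verify
  this to 1e−9) while leaving per-gene between-study variability intact.
* Zero-centering pins the genome-wide mean log2 ratio to zero; all class
  means are therefore relative to the transcriptome-wide average. This is
  the natural reading of aligning two species' expression distributions
  before comparison, and the synthetic generator plants its effects on the
  same scale (below).

Welch tests use one aggregated value per study (three studies per species
by default), with the closed-form unequal-variance statistic; p-values are
unadjusted. Per class, the mean and sd of the log2 ratio are reported with
a Welch test against the conserved class and an F test of variances
(conserved versus alternative). Tail enrichment contrasts specific-class
membership against |log2 ratio| > `tail_cutoff` (default 5) in 2×2 Pearson
χ² tables, and the count-difference association is an ordinary
least-squares fit of the log2 ratio on clamped Δn over genes bound in both
species.

## Motif analysis

The scanner computes **exact** match p-values: log-odds scores against an
order-0 background are discretised to `bin` = 0.01-bit units and the null
distribution of the window score is built by dynamic programming over
motif positions; `p(s) = P(score ≥ s)`. Both strands are scanned at every
offset, windows containing non-ACGT bases are skipped, and a position is a
match when its exact p-value is below `fimo_p` (default 0.004, a
per-position threshold). Site-level proportions (share of sites with ≥ 1
match) carry 95% continuity-corrected Wilson intervals, the `prop.test`
convention. Enrichment between site sets is a one-sided hypergeometric test
on site-level presence/absence against the pooled universe — a documented
stand-in for discovery-tool binomial enrichment with GC-matched
backgrounds, which is out of scope. Enrichment matrices across site sets
are filtered by per-set Benjamini–Hochberg q < 0.05 and min–max normalised
within each set, with non-significant cells flagged.

One numerical subtlety shaped the defaults. With discretised scores, the
set of significant windows is the score ladder's largest achievable
p-value below the threshold. If the background estimate moves by as little
as 1e−4, individual per-column rounded scores can flip by one unit; for
motifs whose null distribution has dense sub-levels near the threshold,
this silently changes the hit set. The pipeline therefore uses the
background recorded in the MEME motif file when present (the convention of
FIMO itself), falling back to the order-0 composition of the genome —
never the scanned site set, whose composition is biased by the motifs it
contains. The bundled synthetic PWM (`tbox_pwm()`, consensus
AGGTGTGAAAAT) has near-deterministic columns so that, under a balanced
background, the null distribution is a coarse ladder of well-separated
atoms (one per number of matching positions) and the hit set is stable
under background perturbations orders of magnitude larger than estimation
noise.

## Transposable elements

A site overlaps a TE when its central `te_window` (default 40 bp,
midpoint-anchored, clamped at chromosome bounds) is **fully enclosed by a
single** TE interval — adjacent elements jointly covering the window do not
count. Sites enclosed by several TEs are attributed to the longest
(lexicographic tie-break), per "longer element wins"; nested-repeat
resolution beyond that is out of scope. Class-by-TE association uses the
Pearson χ² without continuity correction, so the observed statistic is
exchangeable with the permutation null, which shuffles the overlap flags
against fixed class labels `n_perm` (default 10,000) times with the
add-one empirical p-value `(1 + #{null ≥ obs})/(n + 1)`. Standardized
residuals are (O − E)/√E — the standard definition; a literal relative
variant (O − E)/E is available behind a flag because that spelling also
appears in print. For 2×2 tables the Yates-corrected p is reported
alongside as a cross-check. TSS-distance distributions per group are
compared by Kruskal–Wallis on absolute distances, with a signed
stacked-proportion bin table (≤ 1 kb, 1–10 kb, 10–100 kb, > 100 kb each
side).

## The synthetic world

`build_world()` constructs the entire input universe with recorded ground
truth. Its defaults *are* the study conditions the package is meant to
operate under:

* two chromosomes (5 and 4 Mb) per species, relating to each other through
  a constructed chain of 40–60 kb aligned blocks separated by target gaps
  (5–9 kb) and query gaps (2.6–6 kb); one chromosome pair is aligned on
  the minus strand. The reverse chain is the exact inverse of the forward
  chain.
* ~10% of binding sites placed in unalignable gaps
  (`unalignable_fraction`, a per-site Bernoulli), so ~90% of sites lift —
  the regime the analysis is designed for.
* gene classes planted in proportions mirroring the biology the package
  targets: 200 conserved, 45 alternative, 25/20 species-specific, 350
  unbound ortholog pairs (≈ 69/16/8/7% of bound targets), plus
  non-orthologous genes per species. Genes occupy slots spaced ≥ 9 kb in
  aligned-block interiors with sites at fixed offsets (±1.25, ±3.75 kb),
  a geometry that makes nearest-gene assignment provably unambiguous in
  both genomes even across indel-shifted blocks.
* ChIP replicates (3 versus 2) with jittered boundaries and log-uniform
  q-values; with probability `q_noise_rate` (default 0.005) a truly bound
  site's replicate call degrades into (0.01, 0.1) — the replicate-dropout
  noise that makes default-noise recovery ≈ 97–98% rather than 100%.
  Indeterminate sites emit a low-confidence peak at their lifted locus in
  one other-species replicate; blacklist regions contain decoy peaks that
  consensus building must discard.
* motif instances planted at class-specific rates (conserved 12.1/13.2%,
  specific 19.1/18.2% at bound loci, 6.7/7.7% at their unbound equivalent
  loci). Site neighbourhoods (±40 bp beyond the site) are
  rejection-sampled to contain no chance match at the scan threshold, so
  measured proportions equal planted rates instead of riding on a
  chance-hit floor of roughly `2 × width × p` per site.
* TEs enclosing the central window at class rates (conserved 3.4/0.6%,
  specific 10.8/6%), with LINE1/LTR-weighted classes at specific sites,
  plus background elements kept clear of site windows.
* negative-binomial counts (dispersion 0.05) over three studies per
  species with global batch shifts (sd 0.5 log2) and per-gene
  between-study noise (sd 0.2 log2). Class expression effects are
  conserved N(−0.59, 1.59), alternative N(−0.21, 2.46), specific
  N(+1.95, 2.0)/N(−1.55, 2.0), split ± e/2 across species. Genes bound in
  both species additionally carry 0.5 log2 units per planted
  binding-count difference; the residual class variance is reduced so the
  marginal class sd stays at its configured value. Because the pipeline
  zero-centres each species, the mean effect implied by the bound classes
  is compensated in the unbound class, pinning the expected genome-wide
  ratio to zero — without this the planted class means would not be
  recoverable after centering.

Gene-level ground truth is *derived* from the placements (every planted
site is assigned to its nearest gene and the class rules applied), so
incidental geometry — a gap site landing nearest an unbound gene — is part
of the recorded truth rather than a recovery error. A noise-free emission
reproduces the truth exactly; the tests assert 100% there and ≥ 95% under
default noise.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data: non-uniform base composition (real genomes
are AT-rich and repeat-laden; the uniform composition is what makes the
motif hit set provably stable), realistic repeat sequence content inside
TEs, peak-width and signal-strength heterogeneity, fragmented or
many-to-many orthology, chain fragmentation beyond simple block/gap
structure, and read-level noise (the generator emits peak calls, not
reads).

## Numerical choices and degenerate inputs

Ties in nearest-TSS and TE attribution resolve lexicographically; central
windows and padded lifts clamp at chromosome bounds with a warning; peaks
without a q-value are excluded with a warning; a study with a single
sample skips centering with a warning; zero-variance Welch comparisons
return p = 1 (equal means) or the smallest representable p (unequal);
regression on constant Δn raises an error; empty tails and empty distance
groups are reported as missing with warnings. The permutation test seeds
its RNG explicitly and stores the seed in its result.

## Problem sizes

The shipped tests run the full default world (≈ 640 ortholog pairs, ≈ 550
binding sites per species) for recovery and effect checks, a reduced world
(≈ 170 pairs) for file round-trips and pipeline determinism, 20 seeds for
the lifted-fraction regime, 200 simulated matrices/runs for the null
calibrations, 2,000 draws for Wilson coverage, and exhaustive enumeration
up to motif width 8 and 4^8 words — sizes chosen so the whole suite
exercises every claim in minutes on one core while keeping Monte-Carlo
standard errors well inside the asserted tolerances.

## Known limitations

Nearest-gene assignment is a heuristic; promoter–capture interaction data
would assign distal sites better and is explicitly out of scope. The
hypergeometric enrichment stand-in ignores GC-matched background
sampling. The expression stand-in does not model gene-wise dispersion
shrinkage; it is a normalisation, not an inference engine. Site classes
depend on the q-value thresholds as given — no sensitivity analysis is
built in beyond exposing `q_high`, `q_low` and `pad` in the run
configuration.
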
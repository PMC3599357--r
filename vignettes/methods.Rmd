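---
title: "Methods: integrated TF and miRNA regulatory network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated TF and miRNA regulatory network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tfmirnet` infers a signed, typed regulatory network connecting transcription
factors (TFs), microRNAs and mRNAs by integrating four kinds of evidence:
coexpression clustering of an injury time-course, TF binding locations from
ChIP-Seq peak intervals, computational TF binding-site prediction in promoter
sequence, and consensus miRNA target lists. This vignette records the models
behind each stage, the parameters that matter, the numerical choices, and the
design decisions we made where the procedure was genuinely open.

## The stepwise assembly model

The network grows in an ordered sequence of steps, and every edge is stamped
with the step that introduced it:

0. Genes in dynamically regulated coexpression clusters (injury-response gene
   clusters, IRGCs) seed the node set.
1. TFs and miRNAs whose expression correlates (or anti-correlates) with a
   cluster centroid join as candidate regulators.
2. For TFs with ChIP-Seq data, an edge is drawn to every network node whose
   promoter window contains a peak.
3. For TFs *without* ChIP-Seq data, edges come from the phylogenetically
   weighted binding-site model below.
4. miRNA→mRNA edges come from target pairs supported by at least 2 of 3
   prediction methods.
5. –6. Master regulators — TFs whose binding sites, or miRNAs whose predicted
   targets, are enriched in a cluster despite uncorrelated expression — are
   added as nodes.
7. Edges between the new master nodes and the existing network are drawn,
   ChIP evidence first, prediction second.

When a (regulator, target) pair is supported by both ChIP and prediction, the
edge keeps the ChIP label: experimental evidence takes precedence and
prediction fills gaps. miRNA edges are always repressive; TF edge signs are
the sign of the Pearson correlation between regulator and target expression,
flagged low-confidence below |r| = 0.3 (an arbitrary but conventional
weak-correlation bound, exposed as `r_threshold`).

## Expression clustering (Step 0)

Genes carrying at least one positive presence call are retained. Profiles are
z-scored per gene before k-means — clustering raw intensities is dominated by
expression scale rather than temporal shape. The paper-level procedure fixes
the downstream filters (clusters must contain a known myelin gene and differ
pre- vs post-injury by t-test; similar clusters merge; final membership is
every expressed gene correlating with a merged centroid at r ≥ 0.8) but
leaves three quantities open, which we fixed once:

* `k = 12` initial k-means clusters. The procedure ends with a handful of
  merged clusters, so k must comfortably exceed that; 12 gives the merge
  step something to do without fragmenting 10³-gene inputs.
* `merge_r = 0.85` centroid correlation for merging — strictly above the
  0.8 membership cutoff so merging is more conservative than assignment.
* The pre/post t-test runs on the centroid (member-mean) profile values,
  not on per-gene values; it is the centroid whose injury response the
  filter asks about.

With zero expression noise many standardized profiles coincide; k is then
reduced to the number of distinct profiles (k-means cannot place more
centers than distinct points), with a message.

Cluster class is automated: a centroid that drops at the first post-injury
timepoint relative to the pre-injury mean is a myelination-type cluster
(MGC), otherwise proliferation-type (PGC). The original labels were assigned
by inspection; the post-injury direction is the feature that inspection
used.

miRNA arrays carry duplicate probesets. A miRNA is dropped when its maximum
expression stays below the mean control-probe level, or when one duplicate
exceeds the other at every timepoint with a one-sided Mann–Whitney test at
p < 0.05 ("significantly higher" is directional, so the test is one-sided).
Note the test needs enough timepoints to be able to fire: with 3 timepoints
per probeset the smallest attainable one-sided exact p is 1/C(6,3) = 0.05,
so at α = 0.05 the disagreement filter can only act on longer series. The
surviving profile is the per-timepoint duplicate mean. Regulator correlation
against centroids uses an explicit timepoint map (the study aligned miRNA
days 0/4/14 with mRNA days 0/4/10) and requires at least 3 mapped points —
a Pearson r on fewer is degenerate. The correlation cutoff `r_cut = 0.8`
mirrors the cluster-membership cutoff; the paper states no separate value.

## miRNA TSS prediction by feature voting

Pri-miRNA promoters are unannotated, so TF→miRNA edges need a predicted
transcription start site. The search range runs from the end of the nearest
upstream gene (intergenic miRNAs) or the host gene's TSS (intragenic) to the
pre-miRNA's 5′ end, strand-oriented. Every 100-bp window is scored

score = 2·δ_transcript/EST + δ_CpG + δ_CAGE + δ_H3K4me3 + conservation,

where δ is 1 when at least one track interval overlaps the window and
conservation is (number of species aligned over the window) / (number of
species in which the pre-miRNA is conserved). The highest-scoring window
wins; its transcription-oriented 5′ boundary is the predicted TSS, and the
promoter is −5 kb…+1 kb around it.

Open details we fixed, with rationale:

* Window tiling is anchored at the pre-miRNA-proximal edge, so the
  biologically plausible proximal region is always covered by full windows;
  a partial terminal window at the distal edge is scored over its actual
  length rather than dropped.
* δ uses ≥ 1 bp overlap — the simplest testable rule.
* Ties break by minimal window-midpoint distance to the pre-miRNA 5′ end
  (the stated "closest" rule), then by smaller coordinate for determinism.
* The conservation ratio is not capped at 1: more species may align over a
  window than conserve the pre-miRNA, and the ratio definition permits it.
  Predictions report the score so such windows are visible.
* Without an upstream gene the range is capped at 100 kb.

A benchmark harness (`tss_benchmark`) scores predictions against a
user-supplied validated-TSS table by distance cutoffs; genome-scale
benchmarking requires external tracks and is out of scope.

## Phylogenetically weighted binding-site model

Promoter search spaces (−10 kb…+5 kb of mRNA TSSs; −5 kb…+1 kb of predicted
miRNA TSSs) are scanned on both strands with position weight matrices held
as natural-log odds against the background. The "default" score cutoff is
the smallest score whose exceedance probability under the background model
is ≤ 10⁻³ per position per strand, computed exactly by dynamic programming
over the PWM score distribution discretized at 0.01 — this replaces an
external scanning binary with a reproducible, config-overridable rule. Note
a consequence verified in the tests: for a short matrix whose best word has
background probability above 10⁻³ (e.g. any 4-mer under a uniform
background, (1/4)⁴ ≈ 0.004), *no* hit passes the default cutoff.

Each site x gets a weight w_x: the total branch length of the minimal
subtree of the species tree spanning the species in which the site is
conserved (branches shared by close species count once, so conservation in
a distant species earns more weight). A site is conserved in a species when
an alignment block of that species fully covers it; the reference is always
included, and a reference-only site has w_x = `w_floor` (default 0 —
non-conserved sites contribute nothing; raising the floor re-admits them
with a uniform baseline). The binding score of a (PWM, target) pair is

S = Σ_x w_x · exp(s_x)

over its sites. We exponentiate natural-log odds; matrices declared in bits
are converted on read.

The permutation p-value needs a null the source procedure never specified;
ours relocates every detected site of a PWM uniformly over the concatenated
search space of all targets (keeping its (s, w)), reassigns sites by landing
position and recomputes scores: raw_p = (1 + #{perm ≥ obs})/(n_perm + 1).
This null holds both site count and site quality fixed. Because the score
only depends on which target a site lands in, relocation reduces to a
multinomial draw over targets with probabilities proportional to
search-space lengths, which is how it is implemented. Zero-weight sites are
excluded from relocation since they cannot change any score. One caveat the
null inherits: a PWM whose detected weighted sites are few and concentrated
is easily significant on its single carrier target — the p-value is
conditional on the observed site pool, not on the genome-wide abundance of
the motif.

P-values are Bonferroni-corrected by the number of matrices modeling the
same TF (the matrix libraries are redundant), and targets are called at
adjusted p ≤ 0.005 — the cutoff the source procedure calibrated against
ChIP data. With the default `n_perm = 999` the smallest attainable raw p is
10⁻³, which still clears 0.005 after a small per-TF correction; TFs modeled
by many matrices need proportionally more permutations.

## Target integration and master regulators

ChIP peaks map to targets by ≥ 1 bp overlap (`min_overlap_bp`) with the
transcription-oriented promoter window — the most permissive testable
reading of "located within the promoter". Peaks must already be in the
working genome's coordinates; cross-species peak transfer is out of scope.
Consensus miRNA targets keep pairs in ≥ 2 of the 3 supplied lists. Seed
matching (used for descriptive coverage statistics) is an exact 3′UTR match
to the reverse complement of miRNA positions 2–8; 8-mer and 7-mer-A1
variants are deliberately not distinguished. Predicted binding scores are
validated against ChIP-derived target sets with a one-sided Mann–Whitney
test (do ChIP targets score stochastically higher?).

Master TFs are found by rank enrichment: per regulator, each target's
binding score becomes R = ascending rank / N (average ranks on ties — the
published pipeline computes "a ranking of the probability score" without
printing the formula; rank/N is the minimal monotone concretization, and
average-rank ties keep it deterministic). The statistic is the mean R over
cluster members; the null is `n_random = 9999` same-size draws *without*
replacement from the universe (clusters are sets of distinct genes), and
the Bonferroni correction runs over the regulators tested at α = 0.05.
The sampling universe is an explicit argument; the pipeline uses all scored
genes. Master miRNAs use a hypergeometric upper tail with the population =
expressed genes predicted as a target of ≥ 1 miRNA, successes = the miRNA's
targets there, sample = the cluster members inside that population. Per the
source procedure the miRNA test applies no multiplicity correction; the
asymmetry is preserved and both corrections are configurable.

## Motif analysis

Feedforward loops are triples T→G, T→M, M→G with T a TF, M a miRNA and G a
non-miRNA target. G may be a TF-coding gene: the motifs of interest include
TF targets, and excluding them would hide exactly the loops built around
hub regulators. A loop is coherent when the direct sign equals the product
of the two indirect signs. Loops are classed I1/I2/C1/C2 by coherence ×
target class (myelination/proliferation from the target's cluster);
unclassifiable targets are excluded from the table but counted. The
coherence-by-class bias is assessed with a two-sided Fisher exact test on
distinct target genes (counting motifs would pseudo-replicate genes that
sit in many loops; motif-level counts are reported alongside). Feedback
loops are simple directed cycles up to length 3, reported once in canonical
rotation with the product of edge signs.

## The synthetic scenario

`generate_scenario()` emits a complete input set with planted ground truth:
2 chromosomes × 1 Mb, 60 genes (8 TFs), 12 miRNAs (3 intragenic), 5 species,
7 mRNA timepoints (two pre-injury, five post), miRNA duplicates at 3
timepoints, Gaussian expression noise σ = 0.1 against planted profile
amplitude 2, ChIP peak false-negative/positive rates of 0.05. Two planted
clusters of 20 genes follow a dip-and-recover (myelination) shape and its
mirror (proliferation). Planted regulators cover every evidence channel: a
correlated ChIP-backed TF (whose targets also carry conserved sites, backing
the score-validation analysis), an anti-correlated ChIP-backed TF, a
correlated prediction-backed TF, an expression-flat master TF, two
anti-correlated miRNAs and one master miRNA; remaining TFs and miRNAs are
background. Each prediction-backed target promoter carries 12 conserved
consensus sites — enough that the permutation null cannot reassemble a
target's site load by chance once a regulator's sites are spread over many
targets. TSS evidence is planted in exactly one tiling window per miRNA.
These sizes run the full pipeline in well under a minute and are the
conditions under which the acceptance properties are evaluated.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: realistic genome composition (background sequence is
i.i.d. uniform), microarray normalization artifacts, correlated noise across
genes, partially conserved sites, overlapping promoters, peak-width
variation, and regulators whose evidence channels disagree. The mirrored
cluster shapes also make anti-correlation with one cluster equivalent to
correlation with the other, which real time-courses would not satisfy
exactly.

## Orchestration and reproducibility

`run_pipeline()` consumes a validated YAML configuration (unknown keys are
rejected; all referenced files must exist — YAML is the one structured
config format with a parser in our dependency set) and writes every
intermediate table plus the final network, motif report and a manifest.
All randomness derives from one global seed via fixed per-module offsets,
so identical config and seed reproduce byte-identical outputs; missing
optional inputs (ChIP peaks, UTRs) degrade to the remaining evidence
channels with a logged notice. A thin command-line wrapper
(`inst/cli/tfmirnet.R`) exposes `simulate`, `tss` and `run`.

## Known limitations

* The permutation and R-score nulls are our concretizations of published
  but unspecified procedures; both are documented above and exposed as
  configuration so alternatives can be swapped in.
* Regulatory-potential distal search regions are consumed only if a track
  is supplied; the package does not compute the track.
* TSS predictions inherit the feature tracks' quality; with empty tracks
  every window ties at score 0 and the prediction collapses to the
  pre-miRNA-proximal window.
* Network sizes and headline counts from genome-scale runs of the original
  study depend on external resources (full genomes, PWM libraries,
  expression sets) and are not reproduced at this scale.
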
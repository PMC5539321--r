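---
title: "Methods: repertoire-based classification of phage cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire-based classification of phage cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(panvirome)
```

# The problem

Phages that infect a single bacterial host — here *Aeromonas
salmonicida* subsp. *salmonicida* — can be so diverse that no gene is
shared by all of them. A cohort of 18 such phages spans three genome
size classes (~41–48 kb, ~161–174 kb, ~222–237 kb), two GC regimes
(54–57% vs 37–44%), and at least three DNA-packaging mechanisms.
Single-marker phylogenies (even of the one near-universal protein, the
large terminase subunit) are saturated: plotting uncorrected
p-distances against patristic distances from the tree bends into a
plateau, so deep branching order is unknowable from that alignment.
The package therefore classifies phages by their *gene repertertoire*:
which orthologous gene clusters each genome carries.

# Orthology and the pan-virome

All predicted proteins are compared all-vs-all with exact
Smith–Waterman (BLOSUM62, affine gap open 11 / extend 1, implemented
in C++). Since cohorts are small (10^2–10^3 proteins) the exact
algorithm replaces BLASTP outright; significance uses the
Karlin–Altschul formula E = K·m·n·e^{−λS} with the published gapped
BLOSUM62-11-1 constants (λ = 0.267, K = 0.041), cutoff 1e−5, and
GET_HOMOLOGUES-style coverage ≥ 0.75 of both sequences.

Two clusterings are built independently and intersected, keeping only
clusters whose member sets are identical under both algorithms —
the strictest reading of "found by both":

* **COG triangles**: bidirectional best hits (BBH), seed triangles of
  BBH edges across three distinct genomes, triangles merged when they
  share an edge; leftover BBH pairs become two-member clusters;
  everything else is a singleton (singletons *are* clusters, so
  pan-genome counts are well defined).
* **MCL**: Markov clustering of the symmetric score graph
  (column-stochastic; expansion = matrix square, inflation = entrywise
  power 1.5 with renormalization, pruning < 1e−6, convergence when the
  maximum entrywise change < 1e−8, cap 200 iterations).

# Classification with AU supports

The presence/absence matrix is clustered with the binary (Jaccard)
distance d(i,j) = (b+c)/(a+b+c), joint absences ignored (a pair with
no clusters in either genome is defined to be at distance 0, with a
warning — such genomes are indistinguishable, not maximally distant).
Agglomeration uses average linkage (the common default; the choice is
exposed) with a fully deterministic tie rule: among equally close
pairs, the pair whose sorted pair of smallest member labels is
lexicographically smallest merges first.

Edge supports use the multiscale bootstrap: columns are resampled with
replacement at scales r ∈ {0.5, …, 1.4} of the cluster count, each
edge's recovery frequency BP_r is recorded (1000 replicates per scale
by default; 10 000 reproduces the original analysis budget), and the
probit transforms are fitted by weighted least squares as
z_r = d·√r + c/√r with pvclust-style weights B·φ(z)²/(BP(1−BP)),
giving AU = 1 − Φ(d − c).

Two numerical choices matter:

* Scales at which BP is exactly 0 or 1 carry no probit information;
  clamping them to the 1/(2B) boundary and fitting anyway flattens the
  curve and drags the AU of a *perfectly supported* edge toward 0.5.
  Such scales are dropped; if fewer than two informative scales
  remain, AU is the rounded mean BP (flagged degenerate). Edges with
  BP ≡ 0 or ≡ 1 across all scales get AU 0/1 directly.
* Genome groups are the maximal subtrees whose subtending edge has
  AU ≥ 0.95 while the parent edge does not, with two boundary rules:
  the root merge (which has no edge) is excluded, and a tree whose
  every internal edge is supported is reported as a single group.
  Unsupported leaves become singleton groups; labels are Roman
  numerals in left-to-right leaf order and are presentational only —
  tests compare partitions, not names.

An important subtlety, found empirically: if two planted groups share
part of their core, the edge joining them is *genuinely* supported and
the AU cut will (correctly) merge them. In real pan-genomes the deep
edges are unstable because accessory genes are scattered across groups
at random; the synthetic generator reproduces this with accessory
"noise" clusters (`noise_clusters`) whose membership is a random
genome subset. Without them, exact distance ties between
disjoint-repertoire genomes are resolved identically in every
bootstrap replicate and deep edges look perfectly supported.

# Codon usage and the tRNA/GC association

RSCU is computed on the concatenated CDSs of each genome
(RSCU_c = observed_c × k / Σ_family; ATG, TGG and stops excluded,
leaving 59 components) — genome-level profiles match the
genome-level ordination. PCA is on the covariance (components share a
scale), centered, unscaled, with the sign convention that each
component's largest-magnitude loading is positive. The tRNA/GC
association reports the point-biserial correlation between tRNA
presence and GC% plus a strict separation test (the GC ranges of
tRNA-bearing and tRNA-free genomes do not overlap); on the shipped
cohort table the separation is perfect, with the threshold at 49% GC.
Outliers (e.g. a genome at 37% GC among the 41–44% class) are flagged
by median/MAD robust z > 3 on the first two components within each GC
class, with a range-based fallback when the MAD degenerates to 0.

# Terminase phylogeny and packaging inference

Terminase proteins are aligned with a deterministic center-star
aligner built on the package's global alignment engine (adequate for
within-family divergence; it is not a general MSA tool), distances are
uncorrected p-distances, and trees are canonical neighbor joining with
negative branch lengths clamped to zero (the deficit moved to the
sister branch). Saturation is declared when the p-distance vs
patristic regression has R² < 0.90 or a significantly negative
quadratic term (one-sided α = 0.05). Packaging labels transfer from
labeled reference leaves: each query takes the majority label of its
smallest enclosing reference-containing clade (tie → nearest labeled
leaf by patristic distance; confidence = label fraction). Because NJ
rooting is arbitrary, the walk is anchored by rerooting on the
reference farthest from the query; a query whose smallest
reference-containing clade is the whole tree is labeled "unknown",
never guessed.

# The selection scan

This module is an explicit, documented stand-in for likelihood
branch-site machinery; its p-values are calibrated for the
verdict threshold (p < 0.05), not numerically comparable to published
likelihood p-values.

* **Codon alignment**: proteins are aligned, codons are back-threaded
  (protein gap → `---`); internal stops raise an error naming sequence
  and codon; a terminal stop codon is trimmed.
* **Recombination**: sliding-window (60 codons, step 20) NJ topologies;
  runs of ≥ 2 consecutive windows sharing a topology are "confident",
  and a breakpoint is placed midway between consecutive confident runs
  whose topologies differ (Robinson–Foulds > 0). Single-window flips
  are treated as noise. Users may supply breakpoints explicitly.
* **NG86**: synonymous sites per codon use the counting convention that
  mutations creating stop codons are excluded from both numerator and
  denominator at a position; observed differences are averaged over
  all minimal mutational pathways, excluding pathways through stops
  (falling back to all pathways if every one is blocked); proportions
  are Jukes–Cantor corrected, d = −(3/4)·log(1 − 4p/3), undefined
  (saturation flag) at p ≥ 3/4. The implementation is checked against
  an independent enumeration oracle to 1e−12.
* **Significance**: the statistic is T = mean pairwise dN − dS per
  partition. Codon columns are resampled with replacement *jointly
  across all sequence pairs* and p = (1 + #\{T* ≤ 0\})/(B + 1) tests
  E[T] > 0. A null that scrambles each column's synonymous /
  nonsynonymous identities independently per pair was rejected during
  development: a single substitution event is visible in many pairs at
  once, so per-pair randomization understates the null variance
  (empirical type-I error 0.30 at nominal 0.05). The column bootstrap
  keeps that correlation intact (measured type-I 0.00, power 1.00
  against a 3× nonsynonymous excess on the calibration design).

Near-identical genome pairs (global identity ≥ 0.95) can instead be
compared SNP-by-SNP (`classify_snps()`): global nucleotide alignment
(match 1 / mismatch −1 / gap −2), substitutions classified by codon
effect under the first genome's annotation, indels reported
separately. Memory is quadratic in genome length — intended for small
or subsampled genomes; diverged pairs are refused with a pointer to
the homology module.

# Host range and growth

Spot-test entries are the highest lytic ten-fold dilution exponent
(0–7) or none; scores are exponent + 1 (0 = no lysis), and "high"
activity means lysis at ≥ 10⁻⁴ (score ≥ 5). The figure legend's exact
bin edges are not printed in the source text, so this encoding is the
package's documented convention and is configurable. Breadth bands
(narrow < 5, intermediate 10–30, broad > 44 of 65) scale
proportionally with panel size; breadths in the gaps (5–9, 31–44) are
"unclassified" rather than forced into a band. The lifestyle split
collapses the matrix per isolate (sensitive to ≥ 1 phage?) into a 2×2
lifestyle table tested with Fisher's exact test, and every sensitive
mesophilic cell is listed explicitly as an exception.

Burst size divides the mean linear-scale titer of the post-burst
plateau by that of the pre-burst plateau (linear-scale averaging
matches the protocol's phrasing; the plateaus are found by exhaustive
two-changepoint segmentation of the log-titer, ties resolved toward
the longest pre-plateau). The latent period ("median of the
exponential curve") is read off where the fitted rise line crosses the
midpoint of the two log plateaus; with symmetric sampling of the rise
this is exact, with the 30-minute protocol grid it is within one
sampling step.

# The synthetic-cohort generator

`generate_cohort()` emits a cohort whose defaults emulate the
18-genome study system: six groups of sizes 4/2/1/8/2/1; high-GC
(54–57%) small genomes without tRNAs vs low-GC (37–44%) medium/large
genomes with 10–25 tRNAs (the association is perfect by construction);
13 headful / 4 cos / 1 short-DTR packaging labels; narrow (< 5),
intermediate (10–30) and broad (> 44 of 65) lysotypes over a
61 psychrophilic + 4 mesophilic isolate panel with exactly one
planted mesophilic exception; per-phage burst sizes 2–10 and latent
periods 120–160 min (the study's new isolates measured bursts of 2–3
at 142–150 min; a close relative is known at 7).

Mechanics worth knowing:

* **GC targeting**: per genome, codon choice is tilted by a
  one-parameter exponential weight exp(β·GC(codon)) within each
  synonymous family, with β solved by `uniroot` so the expected coding
  GC hits the target; intergenic padding GC compensates the residual.
  Genome-level GC lands within a few tenths of a percent.
* **ORFs are real**: proteins start with Met (conserved under
  mutation), and every intergenic spacer opens with a 22-nt cassette
  containing stop codons in all six frames, so reading frames cannot
  run through intergenic DNA and the greedy ORF caller can recover the
  planted genes. Short genes can still occasionally be shadowed by a
  chance stop-free overlapping frame — a property of any
  longest-first-greedy caller.
* **Cluster counts are desk-scale** (tens per genome, not the
  hundreds of real genomes): the real study's absolute counts (1,222
  clusters from 3,599 ORFs; 37 shared medium/large core clusters) are
  not reproducible without the actual sequence data, and no test
  claims them. A green synthetic run establishes that the machinery
  recovers *planted* structure, not that it would reproduce any
  particular real dataset.
* All randomness flows from the single integer seed in the spec; the
  same spec yields byte-identical files.

# Known limitations

* The center-star aligner is not a general MSA method; for deeply
  diverged inputs a dedicated aligner should be substituted upstream.
* `classify_snps()` memory grows as the product of genome lengths.
* The AU-threshold group cut is one operationalization of a procedure
  that, in the original figure, also leaned on a genome alignment
  panel; sub-group (A/B) annotation is not automated.
* The selection test's p-values are bootstrap quantities for a
  counting statistic; only the verdict logic mirrors likelihood-based
  scans.
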
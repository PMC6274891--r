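---
title: "Diagnosing batch effects from DNA k-mer spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing batch effects from DNA k-mer spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerbatch)
```

## The problem

RNA-seq and other high-throughput sequencing experiments are routinely
distributed over several library preparations, lanes and flowcells. When the
preparation group leaves a systematic imprint on the reads, downstream
analyses (differential expression in particular) inherit that imprint as a
batch effect. Most quality-control tools inspect one sample at a time;
`kmerbatch` instead compares the *raw read content* of many samples at once,
without alignment, and asks whether samples cluster by preparation group
rather than by biology.

The signal carrier is the k-mer spectrum: for word size $k$ there are $4^k$
DNA words, and a read of length $L$ contributes $L - k + 1$ overlapping
windows. Counting every window of every read gives a dense vector
$x \in \mathbb{N}^{4^k}$ per sample — a high-dimensional fingerprint of the
sequence content that is close to the raw information the sequencer
produced. Practical word sizes are $k = 5$–$9$ ($4^5 = 1{,}024$ to
$4^9 = 262{,}144$ counters); shorter words lose discrimination, longer ones
cost memory. Counting is single-pass and streaming: memory grows with $4^k$,
never with the number of reads.

## Distance model

Samples are compared with the Canberra distance,

$$ d(x, y) \;=\; \sum_{i=1}^{4^k} \frac{|x_i - y_i|}{|x_i| + |y_i|}, $$

a weighted Manhattan metric whose per-component terms lie in $[0, 1]$. Its
defining property here is sensitivity to differences between *small* counts:
a rare word that doubles its count moves the sum as much as an abundant one,
so a batch effect spread thinly over thousands of words is still visible.
Two conventions matter and are fixed in this package:

* **0/0 terms contribute 0.** The sum always runs over the full $4^k$
  components; terms are never dropped and the distance is never rescaled by
  the number of non-zero terms. (Base R's `dist(method = "canberra")` drops
  0/0 terms and renormalises, which breaks comparability between sample
  pairs with different nullomer sets — that is why the distance is
  implemented here rather than delegated.)
* **Depth scaling first.** Before distances are computed every profile is
  multiplied by a constant so that all profiles share one k-mer total (by
  default the maximum total in the set, scaling everyone *up*). Without
  this, sequencing depth alone would dominate $|x_i - y_i|$.

The scaled distance matrix is clustered with `stats::hclust`. The default
linkage is **complete**, which is that function's own default; the original
analyses this method descends from called `hclust` without further
documentation of the linkage, so the choice is exposed as a parameter
(`"complete"`, `"average"`, `"single"`). Everything downstream consumes only
the merge heights and the deterministic left-to-right leaf order, both of
which are reproducible given the distance matrix.

## Diagnostics on the annotated tree

Given a tree over two groups (two flowcells, say), `kmerbatch` computes:

* **Contralaterality Score (CS).** For two groups of equal size $n$, take
  the first $n$ leaves of the left-to-right leaf order, count the group-1
  leaves $a$ among them, and report $\mathrm{CS} = 100 \cdot \min(a, n-a)/n$.
  CS is 0 when the top split separates the groups perfectly and 50 when they
  are fully interleaved. The $\min$ makes the score invariant to swapping
  the group labels and to mirror-flipping the tree, so the arbitrary
  left/right choices inside the clustering cannot change it. Under a
  uniformly random leaf permutation $a$ is hypergeometric, giving an exact
  null mean of $100\,\mathrm{E}[\min(a, n-a)]/n \approx 40.5\%$ at $n = 8$ —
  an analytic cross-check the test suite exercises against the simulated
  null. CS deliberately refuses unequal group sizes rather than silently
  generalising.
* **Semi-quantitative batch class.** An ordered grade
  `b1a > b1b > b2a > b2b > es`: `b1a` means both root children are pure
  single-group subtrees (top-level separation, a strong batch effect);
  `b1b` tolerates exactly one misplaced leaf at the root split; `b2a`
  requires a pure depth-2 subtree containing an entire group; `b2b` the
  same with all-but-one of a group; `es` is everything else (no detectable
  effect). The `b1b`/`b2a`/`b2b` rules are this package's explicit
  operationalisation of grades that the literature describes only loosely;
  they live behind a single function so the rules can be swapped without
  touching anything else.
* **Largest pure-group subtree.** The maximum leaf count over subtrees
  whose leaves all come from one group — a finer-grained separation
  statistic that also works for unequal groups.
* **Spectrum comparison.** Per-motif differences of
  $\log_{10}(\text{scaled count} + 1)$ between two batches, with signed and
  absolute summaries (both are reported because either convention is found
  in practice). The pseudocount of 1 exists because nullomers make
  $\log_{10} 0$ undefined; at 1 it leaves integer counts interpretable. The
  companion statistic `kmers_to_contamination_fraction()` sorts motifs by
  absolute scaled-count difference and accumulates until the excess equals
  `fraction × total_reads` motif occurrences — answering "how many k-mers
  carry this batch effect?", under the simulator's convention that one
  contaminated read contributes one excess motif occurrence (documented as
  approximate for real data).

## The simulation framework

Because real flowcell data cannot calibrate a null (every real pair of
flowcells may carry some true effect), the package ships a generator:

* `random_fastq()` draws every base i.i.d. uniformly from
  $\{A, C, G, T\}$ with a constant Phred score (default 40), at fixed read
  length (default 100 nt).
* `contaminate()` selects each read independently with probability
  `fraction` and overwrites the bases at a uniform offset with a fixed
  6-mer. Overwriting rather than inserting keeps read length and total
  window counts constant, so the only signal is the shift in motif
  frequencies. The default motif (`ACGTCA`) is an arbitrary fixed choice:
  under the uniform background all 6-mers are exchangeable.
* `run_separation_experiment()` builds two groups of files (contamination
  applied to group 2 only), runs the full count → scale → distance →
  cluster pipeline at $k = 6$, and records CS per replicate;
  `power_curve()` sweeps contamination fractions. Every replicate runs
  under its own sub-seed drawn from the master seed, so results are
  bit-reproducible and individual replicates can be re-run in isolation.

The default study conditions are 8 files per group and 10,000 reads per
file. Eight files per group makes the analytic permutation-null CS mean
$\approx 40.5\%$, matching the published pure-random anchor of the method;
10,000 reads keeps a full power curve tractable on one CPU. Significance is
declared at CS below 10\% — with $n = 8$ the attainable CS values are
$\{0, 12.5, 25, 37.5, 50\}$, so this means perfect top-level separation —
and the threshold can be recalibrated from `cs_null_distribution()`, whose
empirical 5th percentile is the one-sided $p < 0.05$ point.

A caveat the user should know: detection power at a fixed contamination
fraction depends steeply on per-file depth. The per-component noise of the
Canberra terms shrinks like $1/\sqrt{\mu}$ with the mean per-motif count
$\mu$, while the contamination signal on the spiked motif,
$f / (f + 2(L-k+1)/4^k)$, is depth-free — so deeper files separate at
smaller fractions, and published power figures are only comparable at a
stated depth. The defaults here are a desk-scale operating point, not a
universal constant.

### What the generator does and does not emulate

It emulates fixed-length reads, uniform base composition, constant
qualities, and a localised frequency perturbation. It does **not** emulate
transcriptome structure (highly non-uniform k-mer abundance), quality decay
along the read, sequencing error models, duplication, adapter content or
paired-end structure. Consequently, passing the simulation calibration
shows that the pipeline detects frequency shifts of a known size against a
uniform background; it does not by itself bound the method's sensitivity on
real libraries, where the background spectrum is far from uniform.

## Numerical and policy choices

* **Windows containing `N` are skipped entirely** (the rolling window
  resets); no pseudo-random base assignment, so counts are deterministic.
  On input, any non-ACGT character (every IUPAC ambiguity code) becomes `N`.
* **Quality offset fixed at Phred+33**; a quality character below `!` is a
  hard error. No Phred+64 autodetection — silent mis-decoding is worse
  than a refusal.
* **Filter semantics are strict**: a read is discarded iff *any* base has
  Phred strictly below the threshold; a read that is everywhere exactly at
  the threshold is kept. Zero-length reads are discarded with a counted
  warning.
* **GC\% rounds half up** to an integer percent, with `N` excluded from
  numerator and denominator.
* **Position-wise median Phred uses the lower median** for even counts, so
  reported medians are always attained scores.
* **Counts are stored as doubles** (exact to $2^{53}$): flowcell-level
  merges overflow 32-bit integers long before they lose double precision.
* **Degenerate inputs fail loudly**: empty profiles cannot be scaled,
  all-zero profiles are rejected by the distance step, trees with fewer
  than 4 leaves cannot be batch-classified, and CS needs at least 2
  samples per group.

## Problem sizes in the shipped checks

The test suite validates the counting and distance cores against
brute-force oracles (1,000 randomised counting cases at reads ≤ 30 nt,
k ≤ 4; naive pairwise evaluation on 4-sample sets) and the clustering
against a naive $O(n^3)$ agglomeration. The calibration checks run the
full pipeline at the default study conditions: 200 pure-random replicates
for the null mean and significance threshold, and 100 replicates each at
4\% (power) and 3\% (median CS) contamination. These sizes are the
package's chosen operating point for routine verification; larger
replicate counts only narrow the Monte-Carlo bands.

## Known limitations

* The method is diagnostic, not corrective: it flags heterogeneity but
  neither identifies its cause nor removes it.
* Clustering-based scores need at least 3–4 samples per group to be
  meaningful; CS additionally needs equal group sizes.
* At $n = 8$ per group CS is quantised in steps of 12.5, so the
  significance rule "CS < 10" is effectively "perfect separation".
* Forward-strand counting only (no reverse-complement canonicalisation):
  samples are compared like-for-like, but a strand-flipped library would
  look maximally different.
* The batch-class rules below `b1a` are explicit stand-ins for grades that
  have no canonical published definition.
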
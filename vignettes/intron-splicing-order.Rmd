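---
title: "Inferring intron splicing order: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring intron splicing order: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceorder)
```

## The problem and the evidence

Most eukaryotic transcripts carry several introns, and the spliceosome does
not necessarily remove them in the order they are transcribed. The
observable unit of evidence is a single sequenced molecule (a long read, or
the two mates of a paired-end fragment taken together) that simultaneously
shows one intron *already spliced* — its exact exon–exon junction appears as
a splice gap in the alignment — and another intron *not yet spliced* —
aligned bases run across one of its exon–intron boundaries. Such a fragment
supports one or more ordered pairs "intron $i$ before intron $j$".

`spliceorder` turns per-fragment pair observations into a per-transcript
count matrix $A$ ($A_{ij}$ = fragments supporting $i$ before $j$) and infers
the most likely global order. Intron indices always count in the direction
of transcription, so on minus-strand transcripts the genomically rightmost
intron has index 1. All internal coordinates are 0-based half-open;
1-based GTF/GFF3 and BAM records are converted on read, which keeps
junction-versus-intron comparisons free of off-by-one adjustments.

## Pair detection rules

For each fragment and each intron the status is SPLICED, UNSPLICED, or
UNKNOWN:

* **SPLICED** requires a splice gap whose start *and* end equal the intron
  boundaries exactly (0-tolerance). Junction wobble is an alignment problem,
  not something this package should absorb silently.
* **UNSPLICED** requires an aligned block covering an exon–intron boundary
  with at least `min_anchor` bases on each side, and no gap matching the
  intron anywhere in the fragment. The default `min_anchor = 6` bp guards
  against alignment slippage at junction edges; no published value dictates
  it, and raising it trades sensitivity for specificity in the usual way.
* A fragment containing a splice gap that matches *no* annotated intron of
  the transcript under consideration is discarded entirely for that
  transcript. This is the guard against alternative 5'/3' splice-site
  usage: a shifted junction would otherwise masquerade as evidence about
  the annotated intron.

Pairs are taken at the fragment level, not the read level: mates are merged
before classification, so "mate 1 shows the junction, mate 2 shows the
retained intron" yields one observation. Each fragment contributes at most
one count per ordered pair, and the SPLICED/UNSPLICED definitions make it
impossible for one fragment to support both directions of a pair. One
isoform is analyzed at a time; transcripts sharing introns are not merged.

## From counts to an order

With pseudo count $a$ (`adjust_value`, default 0.1):

$$D_{ij} = \frac{A_{ij} + a}{A_{ij} + A_{ji} + 2a}, \qquad D_{ii} = 0 .$$

This is the MAP of the per-pair binomial probability under a
Beta$(1{+}a,1{+}a)$ prior — the pseudo counts act as $a$ fictional reads on
each side, keeping every pair strictly inside $(0,1)$ so that sparse
matrices remain rankable. With `adjust_value = 0` unobserved pairs carry no
likelihood contribution at all (the raw-frequency limit); this is supported
but not the default.

The log-likelihood of an order $\theta$ is the sum of $\log D_{ij}$ over
the $n(n-1)/2$ pairs ordered by $\theta$. Maximizing it over permutations
is the linear ordering (Kemeny) problem, which is NP-hard in general; the
package solves it exactly in two regimes:

* **`n < 12` (exhaustive regime)**: a Held–Karp-style dynamic program over
  the $2^n$ subsets of introns. It examines exactly the same search space
  as literal $n!$ enumeration (the tests verify equality against literal
  enumeration up to $n = 7$) and additionally counts the optima exactly, so
  ties are reported, never broken silently. When several orders tie, the
  lexicographically smallest is reported with `unique = FALSE`, and such
  transcripts are excluded from downstream order statistics.
* **`12 <= n < 100` (integer-programming regime)**: the equivalent 0–1
  linear ordering program — binaries $y_{ij}$ ($i$ before $j$) with
  triangle constraints $y_{ij} + y_{jk} - y_{ik} \le 1$ and
  $-y_{ij} - y_{jk} + y_{ik} \le 0$ — solved by exact branch and bound over
  order prefixes (a permutation prefix satisfies every triangle constraint
  by construction, so the search space is exactly the feasible set). The
  bound adds, for every pair of still-unplaced introns, the better of the
  two directions; the incumbent starts from a net-wins sort refined by
  adjacent-swap descent. Uniqueness is established by a second bounded
  search that excludes the incumbent (a no-good cut) and asks whether any
  other full order attains the optimum within $10^{-9}$.

Transcripts with 100 or more introns are refused with an explicit reason;
in practice this excludes a negligible sliver of any annotation, and an
approximate solver would silently change the estimand.

Derived quantities:

* $R = \ell(\text{identity}) - \ell(\theta^*) \le 0$, the log relative
  likelihood of in-order splicing. The $1/n!$ prior over orders cancels in
  this ratio.
* The most unlikely order is the reversal of $\theta^*$: reversing an order
  swaps the upper and lower triangles of the permuted $\log D$, so the
  maximizer of one is the minimizer of the other (tested exhaustively).
* Normalized entropy, for $n < 12$:
  $p(\theta \mid D) = L(\theta \mid D) / \sum_\theta L(\theta \mid D)$,
  $H = -\sum_\theta p \log_2 p / \log_2 n!$. The Shannon form with the
  conventional minus sign is used so that $H \in [0,1]$ and flat evidence
  gives exactly 1. The $n!$-term sums are evaluated by an exact subset
  dynamic program in log space (partition function plus expected
  log-weight), identical to literal enumeration but $O(2^n n^2)$; the
  brute-force sum is kept as a test oracle at small $n$.

The error-tolerance property follows from the objective being a sum over
all pairs: a single contradicted long-range pair (say $1$ vs $4$ flipped in
a transcript truly spliced $1\to2\to3\to4$) is outvoted by the consistent
pairs that pin both introns through the intermediates, and the optimum is
unchanged. The tests verify this on exactly that construction.

## Retained-intron correction

Reads from a mature isoform that retains intron $r$ align across $r$'s
boundaries while showing all other introns spliced — indistinguishable from
nascent molecules splicing $r$ late. Given PSI (the fraction of mature
transcripts retaining $r$, from polyA mRNA-seq), the inflated count is
deflated to $\max(b - \mathrm{PSI}(b+c+d), 0)$ per pair.

The published description of $b$, $c$, $d$ is internally inconsistent (the
variable glosses contradict the stated bias direction), so the package
fixes the interpretation by the mechanism: the mature retained-intron
isoform inflates exactly the count supporting "$r$ spliced *after* the
other intron", hence $b = A[\text{other}, r]$ (the corrected entry),
$c = A[r, \text{other}]$, and $d$ = fragments observing both introns of the
pair spliced, which the detector exports as a side table ($d$ never enters
$A$ itself). Corrections for multiple events all read from the uncorrected
counts, pseudo counts are applied only afterwards, and retention is
computed before correction (retention is about raw detection).
Expression-level gating (TPM > 0.1 when a table is supplied) removes
transcripts whose isoform mixture cannot be assessed.

## The simulator: what it emulates, what it does not

The simulator is first-class, tested code and defines the package's
validation conditions:

* a synthetic transcriptome (default 100 transcripts, 3–8 introns drawn
  uniformly, exons ~N(150, 30) bp floored at 30, introns uniform 50–100 bp —
  fission-yeast-like compactness) on one contig, alternating strands;
* one uniformly random true order per transcript (uniformity is
  chi-square-tested);
* the $n+1$ splicing intermediates of each order, at equal abundance —
  no kinetic model of intermediate lifetimes is assumed, as none is
  specified for the method;
* fragments per species: Poisson(depth = 100) fragments, uniform starts,
  rounded-normal lengths (sd defaulting to mean/10) clipped to the
  molecule. Three modes mirror the validation designs: `short_pe` (150-bp
  paired-end, 800-bp fragments), `long_read` (one read of `read_length`
  from the fragment 5' end; ~800 and ~5000 bp configurations), and
  `mate_pair` (150-bp ends of up-to-15,000-bp fragments). Long-read mode
  reads a 5'-anchored window rather than the whole fragment: that is what
  makes an 800-bp and a 5000-bp read differ on the same fragment
  distribution, which is the point of the read-length comparison.
* direct matrix simulation: Poisson(mean 15) on the true direction of every
  pair, with `erase_pairs()` zeroing a chosen fraction of pairs to emulate
  undetected pairs.

Fragments are emitted as already-aligned records (blocks and splice gaps in
genome coordinates), so the detector is tested without an external aligner
— read alignment is upstream of this package's scope. Consequently the
simulator does **not** model sequencing errors, indels, soft-clipping,
junction wobble, coverage bias along the molecule, isoform mixtures, or
intron retention; passing the end-to-end tests therefore demonstrates the
correctness of detection + inference given faithful alignments, not
robustness to alignment artifacts. The retained-intron correction is
exercised by direct count fixtures instead.

Validation problem sizes (chosen to characterize the estimator; all fixed
in the test suite): literal-enumeration cross-checks at $n \le 7$ over
hundreds of random matrices; branch-and-bound versus exhaustive equivalence
on 100+ random instances at $n \in [4, 8]$ plus recovery checks at
$n = 14$; matrix-simulation recovery with 200 replicates at mean intron
number 7 (Poisson-drawn, truncated to $[2, 11]$) across retention levels
100/95/90/80%; and read-level recovery on 100 transcripts for the three
read modes. With full retention and mean 15 reads per pair the true order
is recovered in the overwhelming majority of replicates, recovery degrades
monotonically with retention, and read-level recovery increases with read
length — the qualitative signatures the method's design predicts.

## Numerical choices and degenerate inputs

* Natural log throughout likelihoods and $R$; $\log_2$ only inside the
  entropy.
* Tie detection uses an absolute tolerance of $10^{-9}$ on log-likelihoods;
  exact ties (e.g. all-0.5 matrices) are representable exactly in floating
  point, so this mainly protects the uniqueness flag from rounding noise.
* `adjust_value = 0` creates $\log 0$ terms for one-sided pairs; the
  solvers handle $-\infty$ scores, and zero-support pairs are neutralized
  (contribute 0) before solving.
* Fragments on the wrong chromosome classify as UNKNOWN; empty fragment
  sets, zero matrices, and transcripts absent from a supplied expression
  table all degrade to explicit, logged outcomes rather than errors.
* Single-exon transcripts carry no order information and are dropped on
  parse (their count is reported); whether to keep them is exposed as an
  argument since annotations differ in how they record such records.

## Known limitations

* One isoform at a time: shared introns across co-expressed isoforms are
  attributed to whichever isoform is being analyzed.
* The 95% retention default is a strong filter for long human transcripts,
  where long-range pairs are rarely sequenced; mate-pair or super-long
  reads are the practical remedy, not a lower threshold.
* Entropy is undefined at $n \ge 12$ (the permutation distribution would
  need $n!$ terms; the subset DP computes exact sums only up to the memory
  of $2^n$ states, and the quantity itself is specified over all orders).
* The branch-and-bound solver is exact but worst-case exponential;
  adversarially flat matrices at large $n$ are slow. Real and simulated
  matrices, with pseudo counts and genuine signal, solve quickly.
* PSI values are consumed, never computed; intron-retention calling and
  expression quantification are upstream tools' jobs.
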
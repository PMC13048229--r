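---
title: "Methods: threshold consensus evaluation of MSA tools on noisy long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold consensus evaluation of MSA tools on noisy long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msabench)
```

## The problem

Third-generation sequencing (ONT, PacBio) produces long reads with error
rates from roughly 1% up to 30%, dominated by insertions and deletions.
A standard way to recover an accurate sequence from such reads is to pile
up reads covering the same genomic region, compute a multiple sequence
alignment (MSA), and call a consensus column by column. How well this
works depends on the MSA method, the region length, the sequencing depth
and the error profile — and that dependence is exactly what `msabench`
measures. The package simulates (or extracts, from SAM/BAM) read sets
over reference regions, aligns them (with a built-in center-star aligner
or an external tool through an adapter), calls an IUPAC threshold
consensus, and scores the consensus against the reference.

## The consensus rule

Each MSA column is summarised independently from its character counts
over `A`, `C`, `G`, `T` and the gap `-`:

1. If the gap is *strictly* the most frequent character, the column
   contributes a gap (deleted from the final, ungapped consensus).
2. Otherwise nucleotides are accumulated in descending count order until
   the accumulated count divided by the column total reaches the
   threshold *t*. Nucleotides with equal counts are always added as a
   whole group, never split — an arbitrary order must not decide the
   outcome.
3. The accumulated nucleotide set is emitted as its IUPAC code: `{A}` is
   `A`, `{C,T}` is `Y`, `{A,C,G,T}` is `N`.

With the default threshold `t = 0.7`, a column covered 50/50 by two
alleles of a diploid sample yields the 2-nucleotide ambiguity code of
the two alleles (neither allele alone reaches 70%, together they do):
this is the mechanism by which heterozygous SNPs surface in the
consensus, and why 0.7 is the default for diploid work. Any `t` in
(0.5, 1] has that property on exactly balanced columns; 0.7 leaves room
for sequencing noise to unbalance a site without losing the code.

Three points the rule above leaves open, and the choices made here
(each checked by tests; the column rule is verified exhaustively against
an independent prefix-group oracle for all count compositions up to 8
rows):

* **Denominator.** The appearance rate is computed over *all* rows of
  the column, gaps included. Gaps are first-class characters in the gap
  rule, so they are not removed from the denominator either.
* **Gap ties.** A tie between the gap and the most frequent nucleotide
  resolves to the nucleotide path: sequence content is preferred over
  deletion, the conservative choice for a consensus meant to be compared
  base-by-base to a reference.
* **Unreachable threshold.** When gaps hold so much of the column that
  even the full nucleotide set stays below *t* (without winning the
  strict gap majority), the full accumulated set is emitted. The
  procedure runs "until reached", and exhaustion is the natural stop.
* **Threshold comparison is inclusive** (`>=`), so a 7/10 column meets
  `t = 0.7` and a 2/3 column does not meet `t = 0.7` (0.667 < 0.7);
  boundary cases are deterministic.

In a meta-MSA (an MSA of consensus sequences from several tools), rows
may themselves contain ambiguity codes. A code of set size *s*
contributes weight 1/*s* to each of its nucleotides, keeping every
column total equal to the number of rows so the threshold retains its
meaning. The alternative — counting a `Y` as one full `C` *and* one
full `T` — would inflate column totals and silently raise the effective
threshold.

## Scoring a consensus against the reference

The ungapped consensus is aligned end to end against the reference
(Needleman–Wunsch, linear gaps), and five rates are reported, all with
the consensus size (ungapped consensus length) as denominator:

| metric | numerator |
|---|---|
| identity rate | columns with strictly identical characters |
| ambiguous rate | consensus characters outside `{A,C,G,T}` |
| match rate | columns whose codes share a nucleotide (`Y` matches `S` via `C`; `R` does not match `Y`) |
| error rate | non-matching columns, indel columns included |
| consensus size | — |

Because the denominator is the consensus size, the error rate can exceed
1 when the consensus is much shorter than the reference; this is kept as
the primary definition (it follows the identity-rate definition), and
alignment-column-normalised variants (`*_aln`) are emitted alongside for
reporting. Whether indel columns count as errors is a genuine ambiguity
("non-matching characters are errors" is silent on gaps); the
indel-inclusive count is primary here and the column-normalised pair
lets a reader reconstruct the other convention.

For diploid references, heterozygous sites are 2-nucleotide IUPAC codes
at known positions. After aligning the consensus to the IUPAC reference,
a true positive is a het site whose aligned consensus character is
*exactly* the site's code; a different ambiguity code there counts as
both a false negative (the site was missed) and a false positive (a
spurious symbol) — the strictest reading of "corresponding to
heterozygous sites". Recall is tp over all het SNPs; precision is tp
over all ambiguity codes in the consensus.

## The aligner

The built-in pairwise aligner is plain Needleman–Wunsch with linear gap
penalties, implemented in C++ and verified against exhaustive alignment
enumeration for short pairs. Defaults: match 2, compatible 1, mismatch
−1, gap −2. "Compatible" (distinct codes whose sets intersect, e.g. `Y`
on `C`) sits strictly between match and mismatch so that diploid
ambiguity codes align onto either allele instead of being forced into
gaps. The original evaluation pipeline delegated this step to an
external exact global aligner whose scoring internals are not published;
metric definitions here are robust to reasonable scoring choices at low
divergence, but residual sensitivity exists at high error rates, which
is why the scoring is a visible, configurable object rather than a
constant. Traceback ties break deterministically (diagonal, then gap in
the second sequence, then gap in the first), so outputs are reproducible
byte for byte. Affine gaps are deliberately out: linear gaps keep the
brute-force oracle feasible and the behaviour explainable; an affine
mode would be the first extension to consider.

The multiple aligner is center-star: the center is the sequence with the
best summed pairwise score to all others (exact all-pairs search up to
50 sequences, first-sequence fallback beyond — the quadratic cost cap),
every sequence is aligned to the center, and pairwise alignments merge
under "once a gap in the center, always a gap". It is a fallback so the
pipeline runs with no external binaries, not a competitor to the real
MSA tools; external tools plug in through command-template adapters
whose output is validated (gap-stripped rows must equal the input
reads) before any metric is computed.

## The simulator and what it does (not) emulate

Reads are exact copies of a region's template subjected to independent
per-base errors: with probability `rate` a base suffers exactly one
event, whose type is drawn from `(p_sub, p_ins, p_del)`. A substitution
becomes a uniformly random *different* base, an insertion places one
uniform base before the current one, a deletion drops the base. The
named profiles are `SUB`, `INS`, `DEL` (single-type) and `MIX` with
23% / 31% / 46% substitutions / insertions / deletions, an ONT-like
composition; the standard simulated benchmark crosses these four types
with eight overall rates (1, 2, 5, 10, 15, 20, 25, 30%) into 32 dataset
configurations. Every event is recorded in a truth log whose edit script
replays to the exact read, so realised rates are measurable, not
assumed.

What this deliberately does **not** model: homopolymer-dependent error
clustering, read-length distributions, chimeras, or quality scores —
the realism that dedicated read simulators provide. A green test here
establishes that the pipeline machinery (alignment, consensus rule,
metrics, bookkeeping) is correct under controlled error composition; it
does not establish how any MSA tool behaves on real flow-cell artefacts.

Diploid mode takes two colinear haplotypes, assigns exactly half the
reads to each (odd depth: the extra read goes to a random haplotype),
emulating an equal two-strain mix. The diploid reference encodes
substitution differences as 2-nucleotide IUPAC codes; columns where
haplotype B has a gap keep the haplotype-A base but are excluded from
het accounting, and haplotype-A gaps are dropped — structural
differences between haplotypes are out of scope for SNP recall.

Region sampling draws start positions uniformly such that *every*
requested size fits from each start (sizes share starts, so size effects
are measured at fixed genomic positions). Defaults mirror the standard
grid: sizes 100–10,000 bases, depths 10x–200x, 10 regions per
combination, which with four datasets and nine tools enumerates 22,680
experiments.

In real-data mode, reads come from a SAM/BAM: only primary alignments
that fully span the region are eligible (a partially covering read would
otherwise shorten the MSA rows and bias size effects — the spanning
rule is a documented choice, not the only defensible one), each is
clipped to the region boundaries by walking its CIGAR, and `depth` of
them are sampled uniformly.

## Reproducibility and numerics

All randomness flows through R's global RNG; orchestration entry points
take integer seeds (per-experiment seeds are derived from the grid seed
and stay below 2^31). Two runs with the same seed produce byte-identical
reads, metrics tables and summaries — this is itself an acceptance
criterion. Metaconsensus-vs-best/worst comparisons tally equality after
rounding identities to 4 decimals (a tally of exact float equality would
be noise); the rounding is a visible parameter. Summary standard
deviations are population (n-denominator) standard deviations, the
descriptive convention for "mean and sd across regions".

## Known limitations

* Center-star is O(n²) in sequence count and O(L²) in length; the
  region sizes at the top of the default grid (5–10 kb) at high depth
  are slow with the built-in aligner — that is what external-tool
  adapters are for.
* Linear gap penalties make long indels cheaper to fragment than an
  affine model would; consensus error rates at extreme deletion rates
  are mildly sensitive to this.
* The simulator's independence assumptions make error-rate recovery a
  clean binomial problem; real ONT data violates them, and conclusions
  about absolute tool accuracy should come from real read sets.
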
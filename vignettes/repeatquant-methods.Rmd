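---
title: "Quantifying repeat-element transcription: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying repeat-element transcription: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatquant)
```

## The problem

Constitutive heterochromatin silences most of the repetitive fraction of
mammalian genomes: pericentromeric major satellite and centromeric minor
satellite arrays, LINE and SINE retrotransposons, and endogenous
retroviruses. Drugs that destabilize nucleosomes or demethylate DNA can
derepress these elements; the resulting transcripts (often double-stranded,
because satellite arrays transcribe from both strands) trigger a type I
interferon response. Measuring that derepression from bulk RNA-seq is
harder than ordinary gene-level quantification because repeat-derived reads
are short, highly multi-mapping, and the expressed units (diverged genomic
copies, read-through concatemers) differ from the canonical consensus
sequences that databases catalog.

`repeatquant` implements a repeat-type-level quantification and
differential-expression pipeline for this setting, together with a
synthetic data generator that reproduces the statistical structure the
method assumes, so every stage can be validated against ground truth.

## The combined repeat reference

For each repeat type the reference holds one canonical (consensus) record
plus one record per annotated genomic instance, extended by
$F = \lfloor L/2 \rfloor$ bp of flanking genomic sequence and clipped at
contig ends ($L$ is the read length; at the default $L = 26$, $F = 13$).
The flank guarantees that any read overlapping an annotated instance by at
least one repeat base lies entirely within the extended interval.
Minus-strand instances are reverse-complemented so every record reads 5'
to 3' in repeat orientation; since reads are scored against both strands
of every record, this choice is observationally neutral.

The complement of the union of the flank-extended instance intervals is
the *mask partition*: the portion of the genome not associated with any
annotated instance. Per contig, the extended-instance union and the mask
partition tile every base exactly once (a property the test suite checks
against a per-base boolean oracle). Where instances of different families
overlap, the shared bases belong to both families' records; the mask
excludes bases covered by any family.

Coordinates are 0-based half-open everywhere (BED-native); FASTA record
ids encode family and provenance interval in the same convention.

## Read assignment

A read is assigned to repeat type $f$ when three criteria hold:

* (a) it aligns, at one or several locations, to $f$'s canonical record or
  flank-extended instances with score at least `min_score`;
* (b) no other repeat type achieves an equal or better score (ties discard
  the read as `cross_family_tie`);
* (c) optionally (*masking*), the non-repeat genome partition does not
  achieve an equal or better score (otherwise `genome_tie`). This guards
  against reads from unannotated repeat copies, e.g. SINE fragments
  embedded in mRNA untranslated or intronic regions.

"Alignment quality" is operationalized as the ungapped matching-base
count: the score of a placement is the number of matching bases, with
overhanging bases scoring zero and non-ACGT bases never matching, and a
read's score against a target is the maximum over both orientations and
every placement. An integer score makes the tie semantics of criteria
(b) and (c) exact and testable: "equal or better" is $\ge$ on that
integer. Reads whose best repeat score falls below `min_score` are
discarded as `no_hit`; a separate sub-threshold reason is not
distinguished, because below the threshold the search is not required to
locate the best placement.

`min_score` defaults to $L - 2$ (two mismatches at $L = 26$, roughly 92%
identity), a near-exact threshold in line with short-read k-mer mapping;
it is a configuration knob.

### Seeded search and its exactness

Scoring every read against every placement of every record is quadratic
and unnecessary. The production scorer indexes the targets by seed
k-mers and rescores, exactly, every diagonal on which a read shares a
seed with a target. The seed length is derived from the score threshold:
a placement with score $s \ge m$ on a read of length $L$ contains a run
of consecutive matches of length at least $\lceil m / (L - m + 1) \rceil$
(at $L = 26$, $m = 24$: 8 bp), so a seed of that length is contained
intact in every placement that can reach `min_score`. Seeded scoring is
therefore provably identical to exhaustive scoring wherever a verdict
depends on it — a property the acceptance suite verifies read-by-read
against an exhaustive scorer on randomized instances. A fixed long seed
(such as the quantification k-mer size, 17) would not have this
property: a single central mismatch in a 26-bp read breaks every 17-mer
while leaving the placement's score at 25.

Assignment is deterministic, invariant to read order, and strand
symmetric (reverse-complementing every read changes no verdict).
Enabling masking can only decrease per-family assigned counts.

## Abundance estimation

Quantification works on k-mer equivalence classes with $k = 17$. All
length-$k$ windows of a sequence are taken in canonical form (the smaller
of the window and its reverse complement, making the representation
strand-blind); with the poly-A filter (default on), windows that are runs
of $k$ A's or $k$ T's are discarded, which removes uninformative poly-A
tail matches. A read's equivalence class is the set of repeat types whose
records share at least $\lceil 0.8 (L - k + 1) \rceil$ of its filtered
k-mers. Reads with an empty filtered k-mer set, or compatible with no
type at that threshold, are dropped with a logged count — at the default
error rate this sheds the minority of reads whose sequencing errors fall
centrally enough to break most of their ten 17-mers, mirroring the
behavior of k-mer counting quantifiers on errored short reads.

Class counts feed a variational Bayes EM with a symmetric Dirichlet prior
($\alpha_0 = 0.01$ per type by default):
responsibilities of a class toward type $f$ are proportional to
$\exp(\psi(\alpha_f)) / \tilde{\ell}_f$ restricted to the class's type
set; $\alpha_f = \alpha_0 + \sum_c n_c \, r_{cf}$; and the abundance
estimate is $\theta_f = (\alpha_f - \alpha_0) / \sum_g (\alpha_g -
\alpha_0)$, iterated until $\max_f |\Delta\theta_f| \le 10^{-8}$ or 1,000
iterations (non-convergence returns the current estimate with a warning
flag). Because $\theta$ subtracts the prior, singleton-only classes give
exact count fractions for any $\alpha_0$. With ambiguous classes the
variational fixed point differs from plain EM by a term of order $1/n$
(the $\exp(\psi(a)) \approx a - 1/2$ shift): at a few thousand reads the
two agree to under $10^{-3}$, which the tests check against an
independently coded EM run to a $10^{-12}$ fixed point.

The effective length of type $f$ is $\tilde{\ell}_f = \max(\ell_f - L +
1,\, 1)$ with $\ell_f$ the canonical sequence length — the number of
distinct read start positions. This is the only length/bias correction
applied; sequence-composition regression corrections are deliberately out
of scope. TPM is
$\mathrm{tpm}_f = 10^6 \,(\theta_f / \tilde{\ell}_f) / \sum_g (\theta_g /
\tilde{\ell}_g)$; it sums to $10^6$, is invariant under uniform scaling
of counts or of effective lengths, and estimates transcripts per million
observed transcripts independent of the mean expressed transcript length.

## Differential testing

Per-sample library size $N_s$ is the number of quantified reads — reads
surviving the assignment criteria and the k-mer filters — so that all
per-type proportions $x_{fs}/N_s$ share the denominator of the quantified
universe. Two tests are provided and auto-selected:

* **Kal's Z-test** for unreplicated designs: $z = (p_1 - p_2) /
  \sqrt{p_0 (1 - p_0)(1/N_1 + 1/N_2)}$ with pooled $p_0$, two-sided
  normal p-value. Its squared statistic equals the 2x2 chi-square score
  statistic, which the tests exploit as an independent cross-check, and
  its type I error at $\alpha = 0.05$ is verified to sit in
  $[0.03, 0.07]$ under a binomial null.
* **Baggerly's weighted test** for replicated groups: per group, an
  iteratively reweighted proportion estimate whose weights combine the
  binomial within-library variance with a method-of-moments
  between-replicate overdispersion (floored at zero); the statistic
  $t_w = (\hat p_1 - \hat p_2)/\sqrt{\hat V_1 + \hat V_2}$ is referred to
  a t distribution with Satterthwaite degrees of freedom over the
  weighted group variances. With zero overdispersion and equal library
  sizes the statistic coincides with the pooled two-proportion z
  statistic, while the heavier t tails at few replicates deliberately
  absorb the noise of a 2-replicate variance estimate; under an
  overdispersed 2v2 null the measured rejection rate at $\alpha = 0.05$
  is about 0.01 — conservative, never inflated.

Fold change is reported as $(\bar p_T + \varepsilon)/(\bar p_C +
\varepsilon)$ with pseudo-proportion $\varepsilon = 0.5 /
\mathrm{median}(N_s)$, the standard half-count continuity guard.
p-values are corrected with the Benjamini–Hochberg step-up across all
tested families; families absent from every sample are excluded with a
logged count.

One consequence of proportion-scale testing deserves emphasis: the
proportions close over the quantified (repeat-only) library, so strong
derepression of one family necessarily depresses every other family's
proportion. In a fold-change recovery experiment the derepressed family's
estimated ratio is attenuated toward 1 by the growth of the denominator,
and "unchanged" families drift below 1. The simulator's default weights
keep the minor-satellite-like family a small share of the repeatome
(0.5% of the transcript pool, about 4% of repeat reads) precisely so that
an 8-fold derepression stays within a modest compositional distortion;
recovery is validated within 25% on the log scale at fold changes 2–8.

## The synthetic generator

The generator emulates the study design the pipeline targets: a small
multi-contig genome (2 x 60 kb by default) carrying a major-satellite-like
array (234-bp unit, 40 copies), a minor-satellite-like array (120-bp
unit, 40 copies), LINE1-like (1.2 kb, 8 copies) and B1/SINE-like (135 bp,
30 copies) interspersed elements, each a consensus diverged 5–10% per
copy; 30 background gene loci of 0.5–2 kb, one fifth of which embed a
diverged, unannotated SINE fragment as a decoy for the masking criterion;
and 26-bp single-end reads at 50,000 per sample, substitution errors at
0.5% per base, two biological replicates per condition. Satellite
families transcribe read-through concatemers of up to three units and
emit both strands; the treated condition multiplies selected family
weights by configurable fold changes. Read names carry a provenance tag
used only by validation oracles. All randomness flows from one master
seed through independent named streams per stage and sample, so a fixed
configuration reproduces byte-identical FASTA/FASTQ/TSV outputs and any
single sample can be regenerated alone.

Ground truth records each family's true read-sampling fraction per
sample and the realized tag counts; "fraction recovered" in the tests
means the VBEM $\theta$ (a read-fraction estimate) against those
fractions renormalized over repeat families.

The generator intentionally omits base-quality models, PCR duplicates,
fragment-length distributions, indels, paired ends and splicing: the
assignment criteria are score-comparison based and substitution errors
suffice to exercise them. Passing tests therefore demonstrate the
correctness of the algorithms under the stated error model, not
robustness to artifacts the generator does not produce.

## Numerical and design choices

* Read length 26 bp by default; every half-read quantity is computed as
  $\lfloor L/2 \rfloor$, never hard-coded.
* Single-end reads only; the criteria are defined per read.
* `min_score` = $L - 2$; seed length derived from it as described.
* Tie-breaks: equality always discards (criteria (b), (c) read "equal or
  better" literally); multiple placements within one type never discard.
* VBEM: $\alpha_0 = 0.01$, convergence on $\max|\Delta\theta| \le
  10^{-8}$, cap 1,000 iterations. Convergence is monitored on $\theta$
  (dimension-free) rather than a likelihood bound.
* Degenerate inputs: empty FASTQ gives an empty table; all-zero
  abundances give all-zero TPM with a warning rather than 0/0; an
  all-`N` read scores 0 everywhere; transcripts shorter than $L$ are
  excluded from the pool with a warning; zero-variance test inputs give
  $p = 1$.
* Problem sizes: the test suite validates the seeded scorer against an
  exhaustive oracle on 110 randomized instances of up to 5 families and
  30 reads each; calibration uses 5,000 Kal draws and 2,000 Baggerly
  simulations; fold-change recovery runs the full pipeline at 50,000
  reads per sample, two replicates per condition, at fold changes 2, 4
  and 8; null false-discovery control averages 200 replicate count-level
  simulations.

## Known limitations

* Quantification is type-level only; per-instance or per-locus estimates
  are out of scope, as is gene-level quantification of the non-repeat
  transcriptome.
* The only bias correction is the effective-length term; GC and
  positional bias models are not implemented.
* Ungapped scoring cannot rescue reads spanning indels or splice
  junctions.
* With unique-by-type assignment upstream, the VBEM mostly operates on
  singleton classes; its value shows when the equivalence-class
  threshold admits residual ambiguity, and both code paths are kept and
  tested.
* Proportion closure over the repeat-only library attenuates large fold
  changes (see above); the TPM column provides a length-normalized
  alternative scale, subject to the same closure.

## A worked example

```{r example, eval = FALSE}
library(repeatquant)

cfg <- simulation_config(seed = 42, reads_per_sample = 20000,
                         condition_fold_changes = c(SATMIN_like = 4))
res <- run_pipeline(list(seed = 42,
                         simulation = list(reads_per_sample = 20000,
                                           fold_changes = list(SATMIN_like = 4))),
                    outdir = tempfile("run"))
res$differential
```

The differential table reports, per family, the mean proportion of
quantified reads in each condition, the pseudo-count-guarded fold change,
the selected test and its statistic, and the raw and BH-corrected
p-values.
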
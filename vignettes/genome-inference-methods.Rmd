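---
title: "Genome inference from k-mer counts and a haplotype panel: model and methods"
author: "panotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome inference from k-mer counts and a haplotype panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panotype)
```

## The problem

Given (i) a reference genome, (ii) a panel of fully phased haplotypes
describing known SNPs, indels and structural variants, and (iii) raw short
reads of a new diploid sample, we want the sample's genotype at every known
variant — without aligning a single read. The panel is viewed as a
pangenome graph: merged variant sites form *bubbles*, and each panel
haplotype is a path choosing one allele per bubble. Two signals determine
the genotype: counts, in the reads, of k-mers that uniquely characterize
bubble alleles; and linkage, because the sample's two haplotypes resemble
mosaics of the panel paths, so neighboring bubbles constrain each other
even where no informative k-mer exists (repeats are the prime example).

## The model

**States.** At bubble $v$ the hidden state is an ordered pair
$(i, j)$ of panel haplotype paths, $N^2$ states for $N$ paths, $i=j$
allowed. A state implies a copy number for every k-mer of the bubble: 2 if
both chosen paths carry it, 1 if exactly one does, 0 otherwise.

**Transitions.** Between consecutive bubbles separated by $x$ bp, each of
the two copied haplotypes independently either stays on its path or
switches, following the haplotype-copying (Li–Stephens) model with
$$d = x \cdot 10^{-6}\cdot 4 r N_e,\qquad
  p_r = \frac{1 - e^{-d/N}}{N},\qquad q_r = e^{-d/N} + p_r,$$
so the pair transition probability is $q_r q_r$, $q_r p_r$ or $p_r p_r$
according to how many components switch. Rows of the resulting $N^2 \times
N^2$ matrix sum to one for any parameters, the matrix is the identity at
$x = 0$, and it approaches the uniform $1/N^2$ as $x \to \infty$.

A note on units: $4 r N_e$ in the distance formula is the standard
population-scaled recombination density, which requires $r$ in Morgans per
megabase. We therefore expose `r` in Morgans/Mb with default `0.0126`,
i.e. the human genome-wide average of 1.26 cM/Mb ($N_e$ defaults to
25,000). Plugging a cM/Mb figure into the formula directly would inflate
$d$ a hundredfold and destroy exactly the linkage signal the model exists
to exploit — k-mer-free bubbles would be genotyped at chance level.

**Emissions.** A state emits the observed read counts of the bubble's
unique k-mers, assumed independent: Poisson($\lambda$) at copy number 2,
Poisson($\lambda/2$) at copy number 1, and geometric,
$P(c) = p(1-p)^c$ on $c \ge 0$, at copy number 0. $\lambda$ is the mean
k-mer coverage of the sample, estimated from the data (below). A bubble
with no unique k-mers emits probability 1 in every state — exactly
uninformative, so its posterior is carried by its neighbors.

The geometric parameter defaults to $p = 1/(1 + \lambda/40)$, i.e. an
error-count mean of $\lambda/40$. A k-mer absent from the true genome is
observed only when sequencing errors recreate it, so its expected count
must be a small fraction of the coverage. This default matters: with a
much heavier error tail (say mean $\lambda/10$), ordinary downward
fluctuations of the allele depth at heterozygous sites are better
"explained" as error k-mers than as copy-number-1 observations, and such
sites get flipped to confident homozygous calls. Both $\lambda$ and
$p$ are arguments of `emission_model()` / `genotype_sample()`.

**Inference.** The forward–backward algorithm with uniform start
probabilities yields per-bubble posteriors over the $N^2$ states
(Rabiner-style per-bubble rescaling; posteriors are normalized to 1 and
the implementation is checked against exhaustive enumeration over all
path-pair assignments on small instances, to $10^{-10}$ relative error).
States $(i,j)$ and $(j,i)$ carry the same unordered allele pair, and
distinct paths may carry the same allele, so genotype likelihoods are
obtained by pooling state posteriors per unordered allele pair. The call
is the argmax (ties broken toward the lowest pair in VCF genotype order)
with quality $GQ = \mathrm{round}(-10\log_{10}(1 - P_{\max}))$, capped at
10,000 so that "high-confidence" filters such as $GQ \ge 200$ are
expressible.

## Bubbles, unique k-mers and $\lambda$

*Merging.* Variants whose reference-affected intervals are separated by
fewer than $k$ reference bases (strictly; a gap of exactly $k$ stays
separate) are merged transitively into one bubble, since a single k-mer
could span both sites. Bubble alleles are the distinct sequences the
haplotype paths spell across the merged span; bookkeeping from bubble
allele to each source variant's allele makes the final calls decomposable
back to the input VCF records. Multiallelic input records are split per
ALT before merging so decomposition is uniform. Chromosome X, if present,
is treated like any diploid chromosome.

*Unique k-mers.* For each bubble we consider k-mers (canonical form,
default $k = 31$, odd to exclude reverse-complement palindromes)
overlapping the variable region in any allele, with the allele embedded in
$k-1$ reference flanks. A k-mer is kept if it occurs at most once within
every allele's local sequence, its total count along all $N$ haplotype
paths equals the number of paths whose allele contains it (i.e. it occurs
nowhere else in the graph), and its allele-presence pattern differs
between alleles. The last condition is a deliberate refinement: a k-mer
present identically in every allele multiplies all states' emissions by
the same constant and cannot influence the posterior, so we drop it. The
visible consequence is that bubbles whose alleles are k-mer-
indistinguishable — the canonical case being a one-repeat-unit
copy-number change inside a tandem-repeat array, where every candidate
k-mer either recurs within an allele or is shared by both — get an empty
set and are genotyped purely from linkage. A per-bubble cap (default 300,
nearest to the variable region first) bounds emission cost on long
alleles.

When two bubbles lie between $k$ and $2k-2$ bp apart their reference
flanks overlap, and a k-mer whose true path context is altered by the
neighboring bubble fails the path-count test and is discarded. The
approximation therefore errs toward *excluding* evidence, never toward
counting a k-mer whose copy number the state could misattribute.

*Coverage.* $\lambda$ (the copy-number-2 mean) is estimated from
reference k-mers between bubbles whose graph count equals $N$ — such a
k-mer occurs exactly once on every path and nowhere else, so every sample
carries it twice. Counts below $\max(2, \lambda_0/4)$, where $\lambda_0$
is the mean over nonzero counts, are treated as error/dropout mass and
excluded, and the cutoff is refined once. On simulated data the estimate
lands within a few percent of the true k-mer coverage
$c\,(L-k+1)/L$ for read length $L$ and sequence coverage $c$.

## The synthetic-data generator

`simulate_dataset()` emulates the data regime the model assumes, at desk
scale. Defaults (all in `sim_config()`): a 150 kb chromosome at 41% GC
with 12% of its length in planted tandem-repeat arrays (unit 2–100 bp);
10 panel haplotypes; per-bp rates 3×10⁻³ SNPs, 6×10⁻⁴ indels (1–49 bp)
and 8×10⁻⁵ SVs (50–300 bp), chosen so that panel heterozygosity and the
~600 resulting variants give bubble densities (about one per 250 bp)
comparable to a multi-sample human panel; 25% of variants inside repeat
arrays, where indels/SVs change whole repeat-unit copy numbers — these
typically have no unique k-mers, mirroring repeat-embedded variation; 8%
of variants receive an overlapping partner on disjoint haplotypes, which
(together with plain distance-merging) yields 15–20% multiallelic
bubbles; the diploid target is a recombinant mosaic of panel paths
(switch rate 10⁻⁵/bp, high enough to exercise path switching on a 150 kb
toy chromosome); reads are 100 bp at 30× total coverage with 0.1%
substitution error, uniform starts, random strand.

What the generator does *not* emulate: read-length and quality profiles,
indel sequencing errors, GC-dependent coverage bias, paired-end structure,
and truly novel (off-panel) variation — the sample is drawn from the
model's own mosaic assumption, except where a recombination switch lands
inside a variant cluster and creates an off-panel allele combination
(recorded faithfully in the truth table; such variants are usually
counted discordant in evaluation). Passing recovery tests on these data
therefore demonstrates correctness of the inference machinery under the
model's assumptions, not robustness to real-data artifacts.

Every stage derives its RNG stream from the config seed (stages use seed,
seed+1, seed+2, seed+3), so outputs are byte-identical across runs and
stages can be re-run in isolation (e.g. re-simulating reads at several
coverages over one fixed panel and sample, as the coverage-titration
check does).

## Evaluation machinery

`weighted_genotype_concordance()` averages the per-truth-class
concordances over 0/0, 0/1 and 1/1 with equal weight, counting untyped
calls as discordant; classes absent from the truth are excluded from the
mean (the convention is isolated in that one function).
`genotype_precision_recall()` treats non-reference truth genotypes as
positives and requires exact genotype match; the adjusted recall drops
truth variants absent from the genotyper's panel from the denominator.
`mendelian_consistency()` checks allele transmission on unphased
genotypes and, following the stricter convention, evaluates only trios
whose three genotypes are not all identical. `cohort_filters()` applies
the five reliability rules (allele frequency zero; Mendelian-consistent
trio fraction < 90%; GQ < 200 in more than 5 samples; panel
self-genotyping concordance < 90%; all panel samples 0/0) and marks the
strict set. `hwe_test()` is the 1-df chi-square test against
Hardy–Weinberg proportions with Benjamini–Hochberg correction.

## Numerical and design choices

- Coordinates are 1-based inclusive at the interfaces (VCF convention);
  interval arithmetic is done on explicit start/end integers.
- Inter-bubble distance is the reference gap between the end of bubble
  $v-1$ and the start of bubble $v$, floored at 1 bp.
- Forward–backward uses per-bubble scaling plus a per-bubble shift of the
  emission log-maximum; the chain log-likelihood is recovered from the
  scaling constants and shifts.
- Genotype likelihood vectors are emitted in standard VCF GL order with a
  floor of $10^{-300}$ before taking $\log_{10}$.
- Output VCF headers contain no date line, so identical inputs produce
  byte-identical output.
- Degenerate inputs: a panel record with missing/unphased genotypes
  aborts by default (`unphased = "drop"` is available); symbolic ALT
  alleles abort (k-mers require explicit sequence); all-zero read counts
  make $\lambda$ estimation abort rather than silently fitting noise.
- The problem sizes in the tests — panels of ≤10 haplotypes, references
  of 3–150 kb, exhaustive HMM checks at $N \le 4$, $M \le 5$ — are chosen
  so the whole suite exercises every code path in minutes on a single
  core; they are stated here as the package's standard verification
  conditions.

## Known limitations

- Runtime and memory scale with $N^2$ states per bubble; large panels
  need pruning strategies that are out of scope here.
- The emission model treats a bubble's k-mer counts as independent
  although neighboring k-mers share reads; confident miscalls at loci
  with extreme local depth fluctuations are the visible symptom, and GQ
  values at such loci are overconfident. The high-GQ filter and the
  cohort filters are the pragmatic countermeasures.
- Bubbles between $k$ and $2k-2$ bp apart lose some boundary k-mers to
  the conservative uniqueness test.
- The sample is assumed to be a mosaic of panel haplotypes; variation
  absent from the panel cannot be genotyped and slightly depresses
  concordance near recombination breakpoints inside variant clusters.
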
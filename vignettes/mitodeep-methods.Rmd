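---
title: "Methods: quantitative mitochondrial deep resequencing with mitodeep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative mitochondrial deep resequencing with mitodeep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodeep)
library(tibble)
```

mitodeep analyses deep pyrosequencing (454-style) read data from circular
mitochondrial genomes. Two independent routes to the genome sequence are
provided — mapping against a reference with quantitative base calling, and
reference-free k-mer assembly — together with curated heteroplasmy
detection and the usual population summaries. This vignette explains the
models, the parameters that matter, and the design decisions taken where
the problem left the design open.

## The data model and its assumptions

Reads are a few hundred bases long, quality-score-free (the method never
consumes quality strings), and carry two characteristic error modes:
random substitutions at roughly half a percent per base, and
insertion/deletion errors concentrated in homopolymer (HP) runs, growing
sharply for runs longer than four bases because the flow-based base caller
cannot resolve long run lengths reliably. Reads come from three
overlapping long-PCR amplicons whose primer sequences match the reference
at the amplicon boundaries; a noticeable fraction of reads are exact
clonal copies produced by emulsion PCR. All coordinates are 1-based and
circular: position $p$ and $p + L$ are the same base.

## Read filtering

Five filters are applied in a fixed order, and every input read is claimed
by exactly one filter or retained, so the report rows sum to the input
count:

1. **Clonal reads** — byte-identical sequences keep their first copy.
   Clones add no independent evidence and would inflate confidence.
2. **N bases and primers** — any read containing `N` (a failed flow, not
   an ambiguity code) is removed; leading/trailing primer sequence is
   excised when it matches within 2 substitutions (tolerance exposed as a
   parameter; the choice of 2 on a ~20-mer admits primer synthesis and
   sequencing errors while keeping accidental matches vanishingly rare).
   Reads that were all primer are removed here.
3. **Length** — only reads of 200–300 bases (inclusive at both ends;
   inclusivity retains maximal data at the stated bounds) survive.
4. **Mapping** — after alignment, reads with no acceptable locus or with
   two loci within 5 score points of each other are removed.
5. **Identical start/stop** — non-identical reads sharing
   (start, end, strand) are amplification artifacts; one representative
   survives: fewest mismatches, ties broken by lexicographically smallest
   sequence, so the choice is deterministic. Keeping one representative
   (rather than deleting the whole group) preserves coverage at the locus.

## Homopolymer-aware alignment

Alignment is seed-and-extend against the circular reference: exact
13-mers locate candidate diagonals on both strands (the reference is
doubled so seeds can cross the origin), and a banded local
Smith–Waterman refines each candidate. The scoring follows BLASTN-like
affine defaults (match +1, mismatch −3, gap open 5, gap extend 2 — the
affine values are conventional; the homopolymer correction below is what
matters), with one modification: gap segments inside a reference HP run
receive *free gaps* before the affine penalty applies — none for runs of
length ≤ 3, one for length 4, two for length ≥ 5. Deleted reference bases
draw on the budget of the run they belong to; inserted read bases draw on
an adjacent run's budget only when every inserted base equals that run's
base (the signature of an overcall). Because the longest human
mitochondrial run is 8 bases, this two-rule realization covers the whole
genome without a full penalty matrix.

Numerical/search choices, all exposed as parameters:

* band half-width 16 (covers the longest run plus alignment drift),
* gap segments capped at 8 bases (both in the production aligner and in
  the exhaustive test oracle, so the two share one scoring contract;
  longer segments are unreachable inside the band anyway),
* acceptance threshold 0.6 × read length × match score,
* equal-scoring loci are reported together as a multi-map, never silently
  broken — the mapping filter then removes the read.

An exhaustive full-matrix DP with the same contract (`dp_oracle()`)
serves as an independent oracle in the tests; on a thousand randomly
mutated reads embedded in small circular references the banded production
path reproduces its scores exactly (the comparison runs the oracle on the
doubled reference, since a read drawn near the origin can genuinely score
higher across the junction than on the linearized sequence).

## The quantitative calling model

Per position, strand-resolved counts of A, C, G, T and deletion alleles
are accumulated (insertions are tallied in a side channel but never
called: a mapping consensus cannot place them confidently). Four
parameters govern the call:

* $\varphi$ — fractional coverage of the modal allele. A primary base
  needs $\varphi \ge 0.5$. The denominator is the *error-implausible*
  coverage: a non-modal allele whose count lies within the Poisson error
  budget (below) is sequencing noise, not a competing allele, and is
  excluded. Wherever a competitor is real the definition reduces to the
  plain modal/total; the correction only prevents a handful of scattered
  errors from knife-edging an exactly balanced biallelic site (modal
  249 of 500) just below the majority line — without it, 50% mixtures
  would be systematically uncallable, contradicting the method's observed
  ability to quantify mixtures up to one half.
* $\rho$ — forward/reverse count ratio of the allele. For the primary
  call the bounds are so wide ($10^{-6}$–$10^6$) that they operationalize
  as "at least one read on each strand"; for secondary calls the bounds
  are 1/12–12.
* HP — the run length containing the position; calls require HP ≤ 4.
  Additionally the 3'-terminal position of every run ≥ 5 is forced to an
  uncalled `Z`, because run-length ambiguity lands exactly there.
* $\lambda = 0.05$ — the assumed per-base substitution error rate,
  deliberately an order of magnitude above the typical raw rate so that
  secondary-base calls are conservative. For a column of coverage $N$,
  the threshold $k^\*$ is the smallest count whose Poisson CDF with mean
  $\lambda N$ reaches 0.99; secondary counts above $k^\*$ are
  error-implausible. We interpret $\lambda$ per base over the column's
  $N$ reads — the only reading under which "secondary coverage greater
  than this level" is well-typed — and expose it as a parameter.

A secondary base becomes a heteroplasmy candidate when its count exceeds
$k^\*$, it holds ≥ 80% of the leftover (non-primary) coverage, its strand
ratio lies within 1/12–12, and HP ≤ 4. Positions failing any primary
threshold are reported `Z` with their failure reasons.

## Heteroplasmy curation and level estimation

Candidates are then curated: positions inside primer footprints are
demoted to plain variants (the primer base accumulates in the PCR product
and manufactures a secondary allele), candidates involving a deletion
allele are dropped, and candidates at — or immediately beside — the
boundary of a run of length ≥ 4 are dropped (two bases at a run end are
the classic overcall/undercall signature). The run-length threshold for
this rule is aligned with the HP ≤ 4 calling threshold, since the rule
targets the same error mechanism.

Each surviving candidate gets read-positional diagnostics: the
read-relative coordinates (in each read's own sequencing orientation) of
the secondary allele across its carriers, their sample (n−1) standard
deviation, and head/middle/tail counts (thirds of each read's aligned
length — the thirds are our choice; no boundary is canonical) for both
alleles. A candidate whose carriers all sit in the head third, or all in
the tail third, is flagged `suspicious` (quality decays along reads, so
one-sided clustering marks artifacts); a positional standard deviation of
12 or more is flagged separately as `sd_outlier`. The two flags are kept
separate deliberately: a uniformly spread candidate on long reads has a
*large* positional standard deviation, so the two signals measure
different things and conflating them would reject exactly the best
candidates.

The level estimate is simply the secondary count over the column
coverage, reported as a percentage at one decimal. No detection floor is
hard-coded: the ~10% floor observed at a few-hundred-fold coverage
emerges from $k^\*$ (at coverage 500 and $\lambda = 0.05$,
$k^\* = 37$ reads, i.e. 7.4%), and drops at higher coverage.

## Mixture-series evaluation

`simulate_mixture_series()` emulates a two-allele standard: two 285-bp
amplicon alleles differing at one site, mixed at mass fractions 1–50%,
with full-length reads, alternating strands, deterministic alt-read
rounding (`round(fraction × coverage)`, so template counts carry no
binomial noise) and per-base substitution errors.
`evaluate_mixture_series()` runs the pipeline per mixture and regresses
estimated level on truth by ordinary least squares, reporting $R^2$
(computed directly from the residuals so a perfect noiseless fit is
quiet). Two pipeline details are deliberate:

* the clonal and identical-start/stop filters are *not* applied — every
  read of a fixed-endpoint amplicon mixture shares its placement by
  construction, so duplicate-removal filters designed for randomly
  fragmented reads would collapse the data instead of cleaning it;
* a mixture with no accepted candidate at the divergent site contributes
  an estimate of zero — the detection floor is part of what is measured.

At the package's study conditions (coverage 500, error 0.005) the three
sub-10% mixtures fall below $k^\*$ and score zero while 10–50% are
recovered within a fraction of a point, giving $R^2 \approx 0.99$.

## Reference-free assembly

All 27-mers of all reads are counted into a multiplicity database
(windows containing `N` are skipped). $n = 27$ balances two failure
modes: shorter n-mers repeat within the genome or occur as reverse
complements; longer ones are increasingly likely to contain an error
(the error-free probability is $(1-\lambda)^n$, about 0.87 at the
platform's characteristic $\lambda = 0.005$). The assembler assumes no
duplicated and no palindromic n-mers — a validator warns when a known
genome violates them — and that a read n-mer is more often correct than
not, which licenses greedy majority-wins extension: from a seed n-mer
whose forward and reverse-complement multiplicities each exceed 10, the
four candidate successors are scored by summed two-strand multiplicity
and the most abundant wins, until the seed recurs (the genome is a
circle). Assembly runs antegrade and retrograde; their agreement is an
internal accuracy check. Ties between successors are recorded as
ambiguity events and broken toward the alphabetically smallest base, so
assembly is deterministic and auditable; a coverage gap (all four
successors absent) or a missing recurrence within 4× the expected length
(guarding against repeat structures) is a clean failure, not a hang.

Discrepancies between the two assemblies — in practice substitutions or
one-base homopolymer-length differences — are resolved in favour of the
variant whose centred n-mer has multiplicity above zero on *both*
strands, then by higher summed multiplicity; anything more complex is
flagged unresolved and left at the antegrade variant, because such cases
cannot be settled from one platform's reads. A substitution-heteroplasmy
scan replaces the central base of every centred n-mer with the other
three bases and reports alternatives whose multiplicity fraction reaches
a 5% floor (our choice; the floor trades sensitivity against the m=1
error mass visible in every multiplicity spectrum). Indel heteroplasmy
from unused n-mers is deliberately out of scope: no alignment rule for
those n-mers is well-defined enough to implement honestly.

## Population summaries

Variant tables (primary ≠ reference, `Z` skipped), transition:transversion
ratios, per-region site frequencies (distinct sites / region length /
sample size), normalized coverage (reads per thousand), the zero-centred
strand ratio computed as $(f - r)/(f + r)$ — algebraically equal to the
ratio form wherever both are defined and, unlike it, defined at $r = 0$ —
circular 51-bp GC windows, and concordance arithmetic, where zero
discordances yield the resolution bound $1/\text{compared}$ flagged as a
bound. Nucleotide diversity averages per-pair difference rates with
pairwise deletion over `Z` positions, since a global-deletion convention
would let one badly covered sample erase the whole cohort's sites.
Known/novel status comes from a user-supplied frozen site list, never a
live database query, for reproducibility. A two-region example table with
the conventional D-loop interval ships in `inst/extdata/` as a
convenience.

## What the simulator does and does not emulate

`simulate_reads()` reproduces the features the pipeline's filters and
models key on: truncated-normal read lengths (mean 250, sd 36, truncated
to 100–400 so the length filter has material on both sides), uniform read
starts within primer-flanked overlapping amplicons, per-base
substitutions, per-run HP indels at rate
$r \cdot g^{\max(0, h-4)}$ (defaults $r = 0.002$, $g = 2$: the published
run-length error profiles give a shape — sharp growth beyond 4 — but no
rates, so both knobs are exposed), strand assignment, verbatim clonal
re-emission at a deterministic 15% count, and two-haplotype site
mixtures. It does not model flow-signal artifacts (only their
sequence-level symptom, HP-length ambiguity), chimeric reads, nuclear
mitochondrial insertions, or position-dependent quality decay — so
passing tests demonstrate the algorithms' correctness under the stated
error model, not robustness to every artifact of real libraries. Read
starts are drawn uniformly over the positions at which the drawn length
fits inside the amplicon, which preserves the length model exactly
instead of clipping reads at amplicon ends.

## Problem sizes used by the test-suite

The suite exercises every stage at desk scale, chosen so the full suite
runs in a few minutes: toy circular genomes of 0.4–3 kb, read sets of
150–2,500, mixture series at coverage 500, fifty 600-bp assembly
round-trips, a thousand aligner-vs-oracle trials, and two hundred
seeded mixture-recovery replicates. The same generators scale to full
16.5-kb genomes at the cost of runtime only.

## Known limitations

* Insertions relative to the reference are reported but never called in
  the mapping consensus; the assembly route is the intended remedy.
* The curation and positional-distribution rules encode published
  practice but include choices (thirds, the sd threshold of 12, the
  run-boundary rule at ≥ 4) that real data might tune differently; all
  are parameters.
* The aligner's scoring constants are conventional rather than derived;
  the homopolymer free-gap rule is the load-bearing part.
* Assembly assumes a repeat-free, palindrome-free genome at the chosen
  n; genomes violating that need a larger n or a different assembler.
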
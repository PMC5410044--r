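---
title: "Methods: terminal-exon isoform quantification with isoscan"
author: "isoscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: terminal-exon isoform quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the two measurements

A gene with tandem alternative last exons presents annotation as a set
of terminal-exon *variants* sharing a start but ending at different
points, plus (for some genes, BRAF among them) a distant downstream exon
that alternative isoforms splice onto. Isoforms built this way share
nearly all of their sequence, so their relative abundance must be read
off features that are unique to each isoform. `isoscan` uses two:

**Containment counts.** Each mate of a paired-end fragment is assigned
to an exon variant only when it passes a completeness filter (primary
alignment, no soft/hard clipping, mate mapped) and every one of its
aligned blocks lies fully inside the variant's interval. A read inside a
short variant is therefore also inside every longer variant nested over
it; the per-variant counts deliberately double-count in this way because
each variant acts as an independent "does coverage extend this far?"
probe. The per-sample *total*, used for normalization, counts each mate
once, against the reduced union of all exon intervals, so nested
variants never inflate it. "Completely mapped" is not a precise term in
common usage; we adopt the strictest reading (no clipping, mate mapped)
and keep it encapsulated in one predicate.

**Junction-spanning pairs.** A fragment whose two mates are contained in
two different exons evidences their co-occurrence in one transcript. For
a named junction J(A, B) a pair counts when one mate is inside A, the
other inside B, and the implied transcript-space inner distance — the
gap between the mates computed *as if A and B were consecutive* — falls
in a plausible range. The distance must be computed under the adjacency
being tested: genome-space distance would reject every genuinely spliced
pair. The plausible range is calibrated per dataset from all pairs whose
two mates fall inside one and the same (union) exon, taking the
empirical 1st–99th percentile interval of their gaps (percentiles
configurable; the bounds are clamped at 0). This calibration inherits a
mild bias: only exons longer than the fragment can host same-exon pairs,
so short-exon-only samples under-represent long fragments. With a
multi-kilobase downstream exon in the model this is negligible.

The discriminating junctions for the BRAF-like topology are E17–E18.2
(measures ref+X1), E18.2–E18b (ref; E18b is the suffix of E18.3 beyond
E18.2's endpoint, 250 − 154 = 96 nt), E18.2–E19 (X1) and E17–E19 (X2);
E2–E3 vs E2–E11 separate full-length from the exon-3–10-skipping
variant; E13–E16 and NE6p–E4 are *absence probes*, junctions expected in
no transcribed variant, whose silence rules variants out.

A pair eligible for two junctions is assigned to the one whose implied
distance sits closer to the calibration median; an exact tie counts for
neither. In the shipped topology no such pair can arise (the acceptor
exons E18b, E18.2 and E19 are disjoint), but the rule keeps behaviour
defined for other gene models. Mate order never matters; duplicates are
not removed (no deduplication is applied anywhere); split-read (CIGAR-N)
junction evidence within a single mate is *not* counted toward
junctions — such mates simply fail containment — since mate-pair
spanning is the primary evidence, and mixing the two evidence types
would double-count fragments.

# Normalization, ratios, correlation

Counts are normalized per sample to `raw / total x 1e7`, with the
deduplicated union-exon total; the result is invariant under uniform
per-sample scaling. Outliers are masked per feature column: values
strictly outside the central 95% interval (below the 2.5th or above the
97.5th percentile, linear-interpolation quantiles, R type 7). We read
"outside the 95% quantile" as two-sided since outliers occur on both
sides; a one-sided upper variant is available (`sides = "upper"`), and
the filter is per-column across samples (a global variant would mix
scales of very differently sized features). Columns with fewer than 20
values are left unfiltered with a warning. The masked-count budget for
continuous data is at most `ceil(0.05 n) + 2` per column.

Per-sample isoform ratios (X1/ref, X2/ref, ref/X1, X2/X1) are formed
from the junction counts and reported raw and log2-transformed — base 2
chosen for readability; the zero line marking ratio 1 is base-invariant.
Zero denominators flag the ratio undefined and exclude the sample from
sorted series rather than imputing; a pseudocount option exists for
sparse data. The identity `X2/X1 * X1/ref == X2/ref` holds to 1e-9 on
all defined rows and is tested. Cohort structure is summarized by
Spearman rank correlation (mid-ranks on ties) between the ref measure
and each of X1/X2, with a seeded permutation p-value, and a generic
grouped comparison (e.g. total RNA vs polysome-bound) reports per-group
medians of normalized measures and their ratio with a seeded bootstrap
CI — deliberately no parametric test, as group sizes are small and the
quantity is a ratio of medians.

# Terminal-endpoint detection and the 3'UTR

Per-base coverage over the terminal-exon block (oriented 5'→3') is
scanned against the ordered candidate endpoints. For each candidate
`e_i` the drop statistic `D_i = mean(cov in (e_{i-1}, e_i]) /
(mean(cov in (e_i, e_{i+1}]) + 1)` is computed; the +1 pseudocount keeps
it finite over empty downstream segments and the ratio form makes it
scale-robust at depths of ~20× and above (tested). The *chosen* endpoint
is the farthest candidate whose upstream segment mean exceeds a small
background fraction (default 2%) of the strongest segment. Two reasons
to choose by signal extent rather than by the largest drop:

* Paired-end geometry covers the final read-length of a transcript only
  with mate tails — coverage ramps down linearly over the last ~50 nt
  even for a perfectly expressed end. A candidate sitting within another
  candidate's ramp (the 154 vs 174 nt endpoints are 20 nt apart, less
  than one read) makes the "largest relative drop" a coin toss, while
  "does any segment beyond carry signal" stays clean.
* When a short and a long 3' isoform are co-expressed — the normal
  situation for this gene, where X1 ends at 154 nt while ref continues
  to 250 nt — coverage steps down partially at the short end; the
  transcript end of the longest expressed isoform is where coverage
  falls to background, which is exactly what the scan should report.

The call is flagged low-confidence when the chosen endpoint's drop
statistic stays below `minDrop` (default 5, configurable); all-zero
coverage yields a no-call. The 3'UTR length is the detected transcript
end minus the annotated CDS end. The exon-18 CDS/UTR bookkeeping in
public annotation is internally inconsistent by a few nucleotides
depending on whether the stop codon is counted as CDS; the fixture fixes
one convention — *the stop codon belongs to the CDS* — placing the
reference CDS end 174 nt into the terminal block so that the 250-nt
endpoint yields a 76-nt UTR. Homogeneity of coverage across the long
downstream exon is assessed by splitting it into 20 windows and
requiring the window means' CV below 0.5 with no empty window while the
region has signal.

# Variant presence rules

Rules fire in a declared order and each status records its rule and the
counts it used, so any call can be re-derived by hand:

1. probe-exon absence (median normalized count of NE1–NE4 below
   `tau_abs`) rules out the variants that would transcribe them; NE5
   likewise for the 002-like variant. `tau_abs` defaults to 1% of the
   median normalized count over the constitutive exons E4–E17 (E1/E2 are
   excluded from the baseline because polyA libraries deplete 5' exons).
2. junction absence probes: E13–E16 for the exon-14/15-skipping variant;
   NE6p–E4 for read-through of the NE6-terminated variant.
3. presence from isoform-specific junctions (threshold 1 raw pair).
4. the NE6-terminated variant (004) is called when E3/NE6 show at least
   a 1.5-fold excess over the constitutive baseline *and* the
   NE6-specific region is expressed; a silent NE6p–E4 junction then
   marks it truncated. The 1.5 factor is a tunable heuristic, not a
   measured constant.
5. the 5'-truncated 003-like variant is reported undetermined
   (negligible) unless the 5'-half exons exceed the 3'-half by more than
   a log2 margin of 0.5 — a one-sided test, since that variant could
   only add 5' reads, and 5' depletion pushes the ratio the other way.

Presence calls are monotone: adding reads supporting a variant can never
flip it from present to absent (tested). One leakage channel is worth
knowing about: in an X1-rich sample a small fraction of E17–E19 pairs
can arise from X1 fragments whose long gap mimics the E17–E19 adjacency
(the implied distance is the true gap minus 154 nt, which can fall in
range for gap values in the distribution's upper tail). This is a
property of the measurement itself, not of the implementation; with the
default fragment model it amounts to roughly 2% of the X1 junction
count, irrelevant whenever X2 is genuinely expressed.

# The simulator: what it emulates, and what it does not

`simulateSample()` draws each fragment's source transcript with
probability proportional to molar proportion × transcript length —
proportions are *molar* (transcript copies); uniform fragmentation makes
read yield proportional to length, and stating this explicitly matters
because junction-count ratios would otherwise conflate abundance with
length. Fragment lengths follow a rounded truncated normal (defaults
mean 200, sd 40, truncated at 2 × read length of 50 nt), emulating the
short-insert 2×50 libraries typical of TCGA-era RNA-seq; the short
insert also gives the narrow 96-nt E18b acceptor window a usable
detection probability. Start positions are uniform, optionally reduced
by a linear 5'-depletion ramp (weight `1 - w` at position 1 rising to 1
at 1000 nt — the simplest shape consistent with depleted first exons in
polyA data). Per-sample totals are log-normal around `n_pairs` with CV
`depth_jitter`, reflecting roughly constant per-gene depth across a
cohort. Both mates are projected to genome coordinates exactly, with `N`
CIGAR gaps across introns, and can be written as valid, byte-stable SAM
that round-trips through the standard reading path.

Not emulated: sequence content, base qualities, sequencing or alignment
errors, multimapping, duplicates, positional (GC or hexamer) bias beyond
the 5' ramp, and expression noise beyond depth jitter. Alignment is
taken as given. Green tests therefore certify the counting, calibration
and decision logic under ideal alignments — not robustness to alignment
artifacts; with real BAMs the completeness filter is the only guard
against clipped or partially mapped reads.

The expected junction counts used in parameter-recovery checks come from
an independent exhaustive enumeration over every (fragment length, start
position) placement (`junctionDetectionProb()`), weighting placements by
the same truncated-normal and positional weights. This accounts exactly
for the unequal acceptor windows of the ref (96 nt) and X1 (7 kb)
junctions, so recovered ratios are compared on equal footing.

# Determinism and numerical conventions

Every stochastic step flows from one master seed (per-sample seeds are
derived linearly and kept under 2^31); the RNG state of the caller is
saved and restored around each seeded block. Pipeline reruns with the
same config produce byte-identical outputs (hashed in the tests).
Quantiles are linear-interpolation type 7 everywhere, and documented
because the masked set depends on it. Internal coordinates are 1-based
inclusive genomic with `start <= end`; minus-strand annotation listing
descending coordinates is normalized on load, and transcript order is
defined by strand. Degenerate inputs have defined behaviour: empty read
sets give zero rows and header-only SAM; a single same-exon pair gives
the range `[d, d]`; no same-exon pairs is an error instructing the user
to pass an explicit range; zero-total samples are dropped with a
warning; an all-zero cohort produces only absent/undetermined calls.

# Problem sizes used by the test-suite

Unit tests run on fixtures of tens to hundreds of reads, checked for
*exact* equality against brute-force double-loop oracles. The cohort
checks use 50 samples × 2×10⁴ pairs (ratio recovery, within 10% of the
enumeration expectation), 100 samples × 2×10⁴ pairs (inverse-correlation
cohort), 100 replicates per candidate endpoint at ~50× coverage
(endpoint recovery), and 20 seeds × 4 mixture scenarios (presence
rules). These sizes were chosen as the smallest at which the binomial /
Poisson noise floor sits comfortably inside the stated tolerances.

# Known limitations

* Single-gene scope; one gene model per run.
* The fragment-range calibration assumes enough same-exon pairs; genes
  with no exon longer than the fragment length need an explicit range.
* Junction counts are raw pair counts; no length- or window-
  normalization is applied across junctions, so cross-junction
  comparisons should go through the enumeration expectation (as the
  recovery test does) or through ratios of the same junction across
  samples (as the cohort figures do).
* The presence rules threshold raw pair counts at 1 by default; for
  deeply sequenced real cohorts a higher `tau_junction` is advisable
  since a single stray pair should not establish a variant.
* The 004-excess factor (1.5) and the 003 margin (0.5 log2) are
  heuristics exposed as parameters, not estimated quantities.
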
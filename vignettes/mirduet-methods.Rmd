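---
title: "Methods: two-library small RNA analysis with mirduet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-library small RNA analysis with mirduet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirduet)
```

`mirduet` implements the analysis chain used in plant small RNA sequencing
studies that compare exactly two pooled libraries — typically an untreated
control and a stressed sample — without biological replicates. The worked
example throughout is a radish (*Raphanus sativus*) root study comparing a
control library ("CK") with a 200 mg L^-1^ Cr(VI)-treated library
("Cr200"); the raw counts and totals of its published tables ship with the
package (`radish_cr_tables()`), so every downstream number in this
vignette and in the test suite is recomputed from counts, never copied.

## Read cleaning and tag accounting

Raw reads are trimmed at the leftmost occurrence of the 3' adapter (exact
match of the first 8 adapter bases, falling back to a scan that tolerates
one mismatch across at least 8 nt of overlap). Reads are discarded when no
adapter is found, the insert is empty, the insert contains the 3'-most
12 nt of the 5' adapter, the insert is at least 80% adenine (poly-A), or
the trimmed length falls outside the exclusive bounds (18, 30) — i.e.
19–29 nt survive by default. All bounds are arguments of `clean_reads()`.
Cleaning cannot be literally idempotent — re-locating an adapter in
already-trimmed inserts would discard everything as adapter-less — so
pre-trimmed input is handled by `adapter3 = NULL`, which skips the adapter
stage; the remaining filters are stable under re-application.

Surviving inserts collapse to unique *tags* with per-library raw counts
(`collapse_tags()`, `merge_tag_tables()`). Tag counts are conserved at
every stage: collapse totals equal clean-read totals, and the category
partition (miRNA, rRNA, tRNA, snRNA, snoRNA, unannotated) is asserted to
sum to the clean total every time a report is written.

## Annotation

Tags are first mapped to the reference sequence set by perfect match on
either strand (`map_reference()`); only mapped tags proceed, and all
occurrence loci are kept for the hairpin stage. Matching is implemented as
a hash join between tags and reference k-mers at the shortest tag width,
with full-length verification — an exact-match special case that needs no
alignment heuristics. Tags matching any rRNA/tRNA/snRNA/snoRNA record (as
an exact substring, either strand) are excluded next, resolving
multi-class hits by the fixed precedence rRNA > tRNA > snRNA > snoRNA.
Known miRNAs are then identified against a mature database with at most 2
mismatches (`match_mirbase()`). The comparison is end-anchored and
ungapped: when tag and mature lengths differ (at most 2 nt), the shorter
slides within the longer and the minimum Hamming distance over offsets
counts; the length difference itself is not penalised, and whether indels
should count cannot be inferred from the study description, so ungapped is
the documented choice. Family assignment strips species prefix, member
letter and arm suffix, then applies a configurable merge map
(miR156/157 and miR165/166 by default); the conserved/non-conserved split
is a configurable list, because the distinction is curatorial.

## Novel miRNA calling

For each unannotated mapped tag, candidate precursor windows are excised
around the locus with the tag alternately on the 5' and 3' arm
(loop-distal flank 15 nt; total lengths from tag + 30 up to 350 nt in
10-nt steps, truncated at contig ends) and folded.

The folding engine is a deterministic dynamic program over *single
stem-loops*: ladders of nested pairs with bulges and internal loops but no
multibranch junctions — the shape a miRNA precursor search needs. The
energy model is deliberately small and fully exposed in `fold_config()`:
stack bonuses per adjacent pair type (WC/WC −2.0, WC/G:U −1.0, G:U/G:U
−0.5 kcal/mol), size-independent loop penalties (hairpin +3.0, bulge
+2.0, internal +1.5), a minimum hairpin loop of 3 nt, and a 30-nt cap on
either side of an interior step. A full nearest-neighbour parameterisation
would change the absolute energies but not the package's contract: the DP
is verified against exhaustive enumeration of all single-stem structures
on short sequences, which a black-box folder cannot be. The MFE acceptance
threshold (−18 kcal/mol) is therefore calibrated to *this* model, matching
the least stable precursor scale reported in the emulated study, and is
not comparable to Turner-model energies.

A candidate is accepted when the mature (20–24 nt) lies entirely on one
arm outside the terminal loop, at most 4 mature bases are unpaired in the
mature:star duplex, the largest asymmetric bulge is at most 2 nt, the
precursor is 40–350 nt with model MFE ≤ −18 kcal/mol, and the star
implied by a 2-nt 3' overhang fits inside the precursor. A star is marked
*observed* when any sequenced tag matches its position within ±2 nt. Per
tag the accepted window with the lowest MFE wins (ties to the shortest
precursor); overlapping candidates on one reference region merge — the
arms of a real hairpin map to both strands, so strand is ignored when
merging — and records are numbered by (reference, start) for
reproducibility.

## Differential expression

Counts are normalised to reads per million clean reads:
`RPM = count / total_clean * 1e6`. The published tables themselves prove
the denominator is the *library's* clean-read total (94,427/18,127,561 ×
10^6^ = 5,209.0295, the printed value), resolving the ambiguity in the
study's wording; this is pinned by a unit test. Zero normalized values
become 0.01 RPM; miRNAs below 1 RPM in both libraries (before flooring)
are excluded as untestable. The fold change is log~2~(treated/control) on
floored values.

Significance uses the Audic–Claverie conditional test: given `x` reads in
library 1 (size `n1`), the count `y'` in library 2 (size `n2`) follows

$$p(y' \mid x) = \frac{r^{y'}\,(x+y')!}{x!\,y'!\,(1+r)^{x+y'+1}},
\qquad r = n_2/n_1,$$

a negative binomial with size `x + 1` and success probability
`1/(1 + r)`. The two-sided p-value doubles the smaller tail at the
observed `y`. Tails are accumulated in log space (`lgamma` +
log-sum-exp), and the upper tail is summed directly past the conditional
mode rather than by complement, so p-values at the study's scale (down to
10^-300^ and below) keep full relative precision. The implementation is
tested to 6 significant digits against an independent direct-summation
oracle over the whole 0–200 × 0–200 count grid, and cross-checked against
the negative binomial CDF identity. Two properties worth knowing: the
test conditions on the first (control) count, and swapping the
conditioning direction changes extreme p-values by up to a factor ~2 —
negligible on the log scale (both directions agree within 10% of log *p*)
but not an exact symmetry; and no multiple-testing correction is applied,
matching the emulated study design (an FDR column can be added trivially
via `p.adjust`, but is off by default and documented as such).

Calls use the study's asymmetric thresholds, exactly as printed and fully
configurable: up-regulated when log~2~FC ≥ 2, down-regulated when
log~2~FC < −0.5, both requiring p ≤ 0.05. Recomputing the 70 published DE
rows from their raw counts reproduces 37 up-regulated (28 known + 9
novel) and 33 down-regulated records. A handful of printed values
disagree with their own raw counts at the last digit (one fold change,
three normalized values, one percentage); the tests document these and
hold them to one-unit-in-the-last-digit tolerances rather than silently
matching either side.

## Target prediction

Target sites are scored with the Allen-style expectation: mismatch 1,
G:U 0.5, gap 2, each doubled at miRNA positions 2–13 (5' end = position
1); sites with E ≤ 3.0 are reported. Every transcript window is scanned
together with single-gap variants (one bulged target base or one unpaired
miRNA base, never at positions 10–11). Repression mode is called
*cleavage* when positions 9–11 are fully paired, *translation* otherwise;
separate structural filters (no mismatch at 10–11, ≤ 1 mismatch in
1–9, ≤ 2 consecutive mismatches, G:U counting as paired) are reported
per site. None of these constants are printed in the emulated study — it
delegated to a public server — so they follow the widely used defaults of
that scoring family and live in `target_penalties()`/`schwab_rules()`.
The scanner is verified against a brute-force window/gap enumeration on
kb-scale transcripts.

## qPCR quantification

`ddct()` and `expression_series()` implement 2^−ΔΔCt^ relative
quantification against a reference gene (default "5.8S rRNA") and a
calibrator condition. Replicate ΔCt values are averaged per condition
*before* the ΔΔCt step — the standard Livak usage, and the choice that
makes the calibrator's mean exactly 1 by construction; the study does not
state its order of operations, so this default is a documented decision,
not an inference. Standard errors come from per-replicate fold values
around the calibrator's mean ΔCt. Post-hoc group letters (Duncan's test)
are out of scope; groups are reported as mean ± SE.

## Synthetic data and what the tests show

`simulation_spec()`/`generate_synthetic()` build, deterministically from
one seed, a reference with planted known-miRNA loci, novel hairpin
precursors (constructed as inverted repeats with 0–2 injected star
mismatches, re-sampled up to 100 times until the model MFE is ≤ −18
kcal/mol) and ncRNA decoys, plus two read libraries. The defaults encode
the emulated study's conditions: depths 1e6 and 1,078,589 (the study's
N2/N1 ratio), 50 known miRNAs of which 10 carry |log~2~FC| ≥ 2 with
expected counts ≥ 100 in both libraries, ncRNA contamination totalling
~8.4% of reads, insert lengths 16–30 nt with mode 21, a 0.1% per-base
substitution error rate, and small corrupt-read classes exercising every
cleaning filter. Abundances are specified as rates per million control
reads, so scaled-down runs keep their proportions. Counts are Poisson per
library — matching the two-pooled-libraries design, with negative
binomial overdispersion available but off by default.

Problem sizes in the recovery tests are the package's own choices: the
differential expression recovery runs 20 seeds at the full 1e6-read
depth and requires ≥ 90% of planted DE miRNAs flagged with ≤ 5% of null
miRNAs; the hairpin recovery runs one 2×10^5^-read experiment with 20
planted precursors (60–332 nt) and requires ≥ 90% recovered with zero
calls inside planted known-miRNA or ncRNA loci.

What passing these tests does *not* show about real data: the generator
plants exact-match loci in a clean reference, so it cannot probe
mis-assembly, paralogous families, isomiR spectra, ligation bias, or
non-uniform error profiles; the Poisson count model understates biological
variability whenever true replicates exist; and the folding model's
energies are calibrated internally, so hairpins near the MFE boundary may
be called differently by a full thermodynamic folder. Conclusions on real
libraries should treat the pipeline's calls as candidates for the same
kind of qPCR follow-up the emulated study performed.

## Degenerate inputs and numerical conventions

Empty libraries, zero survivors of cleaning, tags at contig edges, and
empty DE inputs are all valid and return empty results rather than
errors. Sequences are stored as DNA (U→T on input) and converted to RNA
only inside the folding engine and in reported miRNA sequences. Intervals
are 0-based half-open on the reference/transcript; miRNA positions are
1-based from the 5' end, as the field writes them. Ties are broken
deterministically everywhere (database order for equal-mismatch hits,
lowest-MFE-then-shortest for hairpin windows, position order for target
sites), and every random draw in the generator flows from the single spec
seed, making all reports byte-reproducible.
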
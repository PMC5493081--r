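---
title: "Assessing genome assemblies with optical maps: the omapqc model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing genome assemblies with optical maps: the omapqc model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omapqc)
```

## The problem and the model

An optical map is an ordered list of fluorescently labelled nicking-enzyme
sites along a DNA molecule, with inter-site distances in bp. Consensus maps
assembled from such molecules are independent of the sequence assembly, so
disagreement between the two is evidence of a misassembly (or, for a
high-quality reference, of structural variation in the sampled individual).

`omapqc` compares the assembly and the maps only through matched restriction
sites. The assembly is digested in silico into a reference restriction map;
an external aligner matches query-map sites to reference sites (XMAP). For
each pair of *adjacent matched* sites the package records

* `d_ref`, the reference inter-site distance,
* `d_qry`, the query inter-site distance after orientation correction
  (`x -> L - x + 1` for `-` alignments, so matched query sites always
  increase along the reference), and
* `diff = d_ref - d_qry`.

If assembly and map agree, `diff` fluctuates around zero with the sizing
noise of the optical maps. Misassemblies shift individual diffs far out of
that noise distribution. Rather than assume a parametric noise model, the
package pools the diffs of **all** matched pairs across all alignments and
contigs, takes quartiles `Q1`/`Q3` by linear interpolation, and places Tukey
fences at `2.5*Q1 - 1.5*Q3` and `2.5*Q3 - 1.5*Q1` — algebraically the
classic `Q1 - 1.5*IQR` and `Q3 + 1.5*IQR` (the identity is verified
numerically in the test suite). Quartile-based fences are robust to the very
outliers being hunted, which is why they are preferred to a standard
deviation here.

Interval classification combines the fence verdict with the count of
unmatched reference sites strictly inside the interval:

| diff inside fences | unmatched ref sites | class | site score |
|---|---|---|---|
| yes | 0 | `OK` | 4 |
| yes | >0 | `SITE_COUNT_CONFLICT` | 3 |
| no | 0 | `MISSING_IN_REF` (diff < lower) / `EXTRA_IN_REF` (diff > upper) | 2 |
| no | >0 | `COMPLEX` (potential contig misplacement) | 1 |

Every reference site receives the score of the intervals that touch it
(bounding sites and skipped interior sites alike); a site touched by two
intervals takes the worse score. Sites matched by no pair and inside no
scored interval score 0 — no optical-map evidence covers them. Unmatched
*query* sites are recorded on each interval but do not change its class:
the scoring is about defects of the reference, and a query-only site may
simply be a false label.

On outlier intervals the sign of `diff` calls the event type: `diff < 0`
(query spans more) is an insertion in the sample relative to the reference,
`diff > 0` a deletion; the call size is `|diff|`. Note the complementary
reading for assembly QC: a deletion *from the assembly* appears as
`MISSING_IN_REF` with `diff < 0`.

## Tunable parameters

* **Confidence threshold** (default 10, inclusive `>=`): alignments below
  it are dropped before anything else. Aligner confidence scores typically
  range 0–60; 10 sits at the bottom of the commonly recommended 10–20 band.
  The comparison is inclusive because the degenerate case of threshold 0
  should keep everything.
* **Enzyme** (default Nt.BspQI, `GCTCTTC`, nick offset 7 bp): the offset
  places the label at the nick one base past the recognition site, i.e. the
  `N` of `GCTCTTCN`. Reverse-strand occurrences label `end - offset`.
* **`min_separation`** (default 0): optional merging of in-silico labels
  closer than the optical resolution, collapsed to cluster midpoints. Off
  by default — the raw digest is exact, and merging is only needed when
  matching against maps whose resolution is known to be limited.
* **Minimum 4 diffs**: quartiles of fewer than four values are meaningless,
  so assessment aborts with an explicit insufficient-data error below that.

## Reliability of questionable calls

Per-site query coverage (from the CMAP `Coverage` column of the matched
query sites) grades each questionable site: coverage above the run average
means many molecules support the conflicting map, so the call is
`supported`; at or below average, the call is still `supported` when the
alignment confidence reaches the threshold, otherwise it is flagged
`needs_verification`. Score-4 sites are trivially `supported`.

## Overlapping alignments

Where several alignments cover the same reference region, each site is
scored from the single best alignment covering it — highest confidence,
ties broken by longer aligned span, then lower entry id — so a weak
secondary alignment cannot downgrade a site confirmed by a strong one. The
pooled fences, by contrast, use the diffs of *all* retained alignments, and
regions are built from all classified intervals: ownership only governs the
per-site aggregation, where a single answer per site is required.

## The synthetic data generator

The simulator exists so the whole pipeline is testable without vendor data;
its defaults are the study conditions used throughout the test suite.

* **Genome**: uniform random sequence, scrubbed of chance motif occurrences
  (a 7 bp motif occurs spuriously about once per 8 kb and would otherwise
  double the density), then motifs planted on random strands at exponential
  spacings targeting 11 labels / 100 kb — a typical Nt.BspQI density for the
  plant and bacterial genomes this analysis is run on.
* **Misassemblies**: deletions remove a span; insertions add motif-free
  random sequence, so the event manifests purely as a distance conflict
  rather than as extra labels; misplacements excise a block and reinsert it
  elsewhere. Realized coordinates on the corrupted assembly are recorded as
  the truth set, together with a piecewise genome-to-assembly coordinate
  map.
* **Query maps**: the true genome's map is cut into 150 kb fragments at 50%
  tiling (the scale of real consensus maps), every inter-site interval is
  scaled by `Normal(1, sizing_sd_fraction)` — multiplicative, because
  optical sizing error grows with interval length — sites drop out i.i.d.,
  false labels arrive as a Poisson process per bp, and fragments may be
  stored reverse-oriented. Coverage fields are filled from the tiling depth
  so the reliability heuristic is exercisable; this is an analog of
  molecule coverage, not a calibrated reproduction of it.
* **Truth alignments**: one per fragment, pairing the surviving true sites,
  confidence fixed at 50 so confidence filtering never removes truth in a
  test. Where a misplacement makes the correspondence non-monotone, the
  longest monotone run is kept — a real aligner would split there.

What the simulator does **not** emulate: raw single molecules and their
assembly into consensus maps, aligner mistakes (chimeric or shifted
alignments), site-resolution limits, or sequence-dependent labelling
efficiency. Passing tests therefore demonstrate the correctness of the
assessment logic under a faithful noise model, not the end-to-end accuracy
achievable with a particular aligner on real data.

## Numerical choices and degenerate inputs

* Quartiles: linear interpolation (`stats::quantile` type 7), isolated in
  one function so the convention is swappable.
* Fence comparison inclusive: with all diffs identically 0 the fences
  collapse to `[0, 0]` and everything is, correctly, valid.
* `diff = d_ref - d_qry`: this sign is forced by reading the fence
  semantics (below lower = missing in reference) together with the indel
  rule (negative diff = insertion in the sample).
* QQ R² of identical diffs is defined as 1 (degenerate perfect fit); the
  normality check requires at least 8 diffs.
* No query-distance rescaling is applied by default; distances are compared
  raw. Consensus maps are produced on a calibrated scale, and a per-run
  rescaling would absorb exactly the signal being tested for.
* Coordinates are 1-based inclusive bp everywhere, so GFF3 export needs no
  conversion; CMAP/XMAP positions are carried as reals (the vendor prints
  one decimal).
* GFF3 column 3 uses descriptive strings (`missing_in_reference`,
  `extra_in_reference`, `site_count_conflict`, `complex_conflict`,
  `unmapped_region`): no Sequence Ontology term matches a restriction
  site-count conflict, so the whole set stays symmetric and
  self-describing. The score column carries the minimum site score in the
  region.

## Problem sizes

The test suite runs entirely on simulated data: 1 Mb genomes (~110 sites,
~15 query fragments) for the end-to-end checks, 100-instance random sets
for the format round-trips, and a thousand random vectors for the fence
algebra. These sizes give stable statistics — e.g. ten injected 3–5 kb
indels against ~180 bp interval noise — while a full run of the suite stays
around half a minute.

## Known limitations

* Distance differences cannot see balanced events: inversions and
  translocations that preserve inter-site spacing are invisible, and the
  `COMPLEX` class only hints at misplacements.
* The fences are pooled globally; a contig with systematically different
  noise (e.g. a different chromatin preparation) shifts them for everyone.
* With few intervals the quartile fences are tight and several percent of
  purely noisy intervals land outside them — small-`|diff|` regions should
  be read together with the QQ normality report and the per-site coverage.
* Calls depend on the upstream aligner: what it does not align, `omapqc`
  can only report as unmapped.
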
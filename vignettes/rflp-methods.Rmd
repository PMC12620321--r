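---
title: "Virtual PCR-RFLP: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual PCR-RFLP: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rflpkit)
```

`rflpkit` models the whole PCR–RFLP genotyping chain — amplification,
restriction digestion, electrophoresis, densitometry, and the final genotype
decision — so that a CAPS-style assay can be designed and stress-tested
before any wet-lab work. This vignette documents the underlying models, the
tunable parameters with their defaults and rationale, what the simulators do
and do not emulate, and the design decisions taken where more than one
reasonable convention exists.

## Sequence model and coordinates

Sequences are strings over the 15-letter IUPAC alphabet plus `N`; matching
everywhere uses set-intersection semantics (two codes match iff their
concrete-base sets intersect), implemented as bitmask intersection and
cross-checked in the tests against an explicit base-set oracle and against
`Biostrings::matchPattern(fixed = FALSE)` behaviour. Lowercase input is
uppercased, whitespace and digits are stripped, and `U` is mapped to `T`
with a warning. Gaps are legal only in alignment rows, never in sequences.

Internally all coordinates are 0-based half-open; every user-facing table
reports 1-based inclusive positions (so "position 241" in a report means the
241st base). Scission coordinates are reported as `cut_after`, the number of
bases 5' of the cut.

## Virtual PCR

`find_primer_sites()` scans both strands for windows with at most
`max_mismatch` IUPAC-mismatching positions and demands an exactly matching
3'-terminal base, since polymerase extension requires an annealed 3' end.
The default `max_mismatch = 2` reflects how permissive universal primers
(such as ITS5/ITS4) are in practice; the bundled reference embeds exact
primer matches, so results there do not depend on the budget.
`amplify()` pairs sites in both orientations (the product is independent of
which strand is labelled "plus"), bounds the search at `max_len = 3000` bp,
and returns *all* products — multiple or zero products are legal outcomes
that the caller must police, because assay designers need to see
mispriming, not have it hidden.

Thermodynamics (Tm, ΔG, secondary structure) is deliberately out of scope:
the package predicts *where* primers can bind, not *how well*.

## Digestion

An enzyme is a recognition motif plus two cut offsets measured from the
motif's 5' end: `cut_top` on the motif strand and `cut_bottom` on the
opposite strand, in the same coordinates. Offsets may exceed the motif
length, which is how offset (type IIS-like) cutters are expressed: SfaNI
(GCATC with scission 5 nt beyond the motif on the top strand, 9 nt on the
bottom) is stored as `10/14`. For REBASE-style `site(N/M)` notation one adds
the motif length. A blunt cutter has `cut_top == cut_bottom` (NaeI GCC▼GGC
is `3/3`).

For a plus-strand match at 0-based `m` the top strand is cut at
`m + cut_top`; for a minus-strand match (found as a match of the
reverse-complemented motif) at `m + L − cut_bottom`. Non-palindromic motifs
are scanned on both strands — required for SfaNI, whose antisense site is
what the 465–467 polymorphism creates — while palindromic motifs are counted
once per position. Overlapping occurrences all count; duplicate scission
coordinates collapse; scissions falling at or beyond either end are
discarded (a cut at coordinate 0 or at the end produces no fragment), which
keeps two useful invariants exact: fragment lengths tile the sequence, and
fragment count = cut count + 1.

Fragment length is the distance between consecutive top-strand scissions.
This single-strand convention is what makes the worked NaeI digestion exact
(242 + 487 = 729); for staggered cutters the complementary strand's
fragments would differ by the overhang length, which is also why published
fragment tables for SfaNI can disagree with the amplicon length by a few
base pairs. Band *counts*, not SfaNI fragment sizes, are therefore the
robust observable.

Incomplete digestion is modelled by a single `uncut_fraction` parameter per
digest: each template contributes its fragments at
`dosage × (1 − uncut_fraction)` and a full-length species at
`dosage × uncut_fraction`. This reproduces the practically important case —
a resistant site leaving a residual uncut band — without modelling star
activity, methylation or buffers. Molar mass is conserved:
`Σ length × molarity = Σ dosage × template length`.

## The virtual gel

Migration distance is piecewise-linear in `log10(size)` between ladder
anchors (the standard rule for agarose separation), strictly decreasing in
size, and clamped beyond the ladder span. The default ladder is a 100 bp
ladder with anchors 100–1000 bp, so fragments below 100 bp co-migrate at
the gel front — exactly as they do against such a ladder on a real gel —
and are treated as uninformative by the caller.

Co-migration of similar sizes is modelled by single-linkage merging of
fragments whose relative size gap is below `min_resolvable_rel_diff`:
0.05 at 2% agarose and 0.03 at ≥ 2.5% (higher-percentage gels resolve small
fragments better; the assay runs NaeI on 2% and SfaNI on 3% gels). Band
intensity is mass-proportional (`length × molarity`), matching ethidium
bromide staining, normalized to the lane maximum; bands under 5% of the
lane maximum are flagged *weak*, which is how a low-dosage allele's faint
band is recognized.

`synthesize_lane()` renders bands as Gaussian peaks (sd 0.6 migration
units) with area proportional to intensity plus optional additive noise;
`detect_peaks()` subtracts a rolling-minimum baseline (10-unit window, wider
than a peak base), thresholds at 2% of the corrected maximum, and
integrates areas between flanking minima by the trapezoid rule. At zero
noise this round trip recovers band counts exactly and areas to well within
5% for bands separated by more than ~3 peak widths (verified in the tests).
When a nominal peak width is supplied, detections with FWHM more than 1.2×
a single band's are flagged as possible merges: two equal Gaussians closer
than ~1.2 sd produce one maximum whose FWHM exceeds a single band's by
20–40%, so 1.2× is the discriminating cut.

The 20% uncut/cut intensity threshold used by the genotype caller is a
*decision threshold*, not a physical prediction: it encodes the observation
that a pure Haplotype A lane's residual uncut band stays well below the cut
bands, and it is configurable (`intensity_threshold`).

## Assay design

`find_variable_sites()` reports maximal runs of non-identical alignment
columns as single sites (so the 465–467 triplet is one site, not three) and
flags indels. `diagnostic_enzymes()` keeps every enzyme whose per-haplotype
signatures (digest → gel resolution → rounded descending sizes) differ for
at least one pair, annotated with the variable sites its differential
recognition matches overlap. Heterozygote signatures are the 1:1 molar
union of the allele signatures after gel resolution, consistent with the
digestion model.

`select_panel()` searches for the minimum-cardinality enzyme set whose
joint signatures separate all separable genotype-class pairs: exhaustively
for up to 12 candidates, greedy set-cover beyond (the two agree on all
small instances in the tests). Ties break by fewest total bands across
classes (fewer bands = easier manual reading), then lexicographic names.
Class pairs that *no* candidate separates — for example Haplotype A versus
the A×C heterozygote under SfaNI alone — are reported as indistinguishable
rather than silently dropped.

The cleavage-type table (`load_cleavage_types()`) ships as an editable
fixture with four types: the Haplotype A, B and C patterns plus a
fixture-defined fourth type carrying an extra SfaNI site, standing in for
the further relatives that published databases show to share Haplotype C's
variable-site states but differ in SfaNI site count. Users with their own
reference sequences should regenerate the table with
`pattern_signature()`.

## Genotype calling

Two input routes mirror practice. `call_from_sites()` maps Sanger-style
site calls through the haplotype definition table — (C, TGC) → HapA,
(T, CAA) → HapB, (C/T or T, CAA/TGC) → HetAB, (C/T, TGC) → HetAC,
(T, TGC) → HapC-or-other — and returns `Indeterminate` for the three
residual combinations rather than inventing haplotype names.
`call_genotype()` reads lanes in the two-step order: SfaNI first (excluding
Haplotype B carriers via the B-specific large band; a B pattern plus a weak
A-specific band is a B-skewed heterozygote), then NaeI (full cut under the
intensity threshold → HapA; cut plus substantial uncut → heterozygote;
uncut only → HapC-or-other, since a pure Haplotype C has never been
observed). Contradictory lanes always return `Indeterminate` with the
firing rules in the evidence, never a silent guess; single-lane calls are
allowed but carry degraded confidence in the evidence and refuse decisions
a single enzyme cannot make.

Heterozygote subtyping (`classify_het_subtype()`) thresholds the mean
Haplotype-A peak proportion at 0.6/0.4 for A-type/B-type versus even. The
source observations are qualitative ("high proportion of haplotype A"), so
round thresholds were chosen once and exposed as parameters.

A weak A-specific 276 bp SfaNI band *without* the 121 bp companion could in
principle be allele dropout of Haplotype A; the caller reports a B-type
A×B heterozygote with an evidence caveat rather than Haplotype B, on the
principle that a visible allele is never discarded.

Population summaries round percentages half-up to one decimal, so the
canonical 190-individual composition gives 4/190 = 2.1%.

## The simulators, and what passing tests do and do not show

`make_haplotypes()` draws a shared uniform-ACGT background, writes optional
motif contexts, applies per-haplotype residues, and verifies motif
constraints by re-scanning (resampling the background a bounded number of
times). `make_population()` supports exact-counts mode — the canonical
190-individual preset (`seedlot_spec()`) uses it so the 2.1% figure is
deterministic — and multinomial frequency mode. `simulate_sites()` emits
double-peak site calls with optional allele dropout; `simulate_survey()`
runs digest → resolve → synthesize → detect per individual and enzyme, with
the NaeI uncut fraction defaulting to 0.1 in the worked survey to exercise
the intensity rule.

The simulators emulate SNP-bearing haplotypes, diploid mixtures, incomplete
digestion and additive lane noise. They do **not** emulate smears, partial
co-migration artifacts, lane-to-lane mobility shifts, PCR drift/chimeras,
methylation-dependent site resistance beyond the scalar uncut fraction, or
chromatogram-level base-calling. A perfect score on the simulated survey
therefore demonstrates internal consistency of the whole pipeline at the
stated noise levels, not field performance on real gels.

The bundled reference amplicons are a constructed synthetic stand-in for
the assay's real amplicons, whose alignment is available only as a
published figure (the file name is labelled `synthetic` accordingly). They
reproduce every published constraint relevant to the assay: 729 bp amplicon
delimited by the printed ITS5/ITS4 primers, variable sites at 241 and
465–467, a single Haplotype-A NaeI site giving 242 + 487 bp, SfaNI cut
counts 4/3 with the A-specific antisense site at 465–467, and six distinct
bands in the A×B SfaNI union. Because the published SfaNI fragment sizes
sum to 731 for a 729 bp amplicon, the synthetic shared fragment is 225 bp
where the publication prints 227; the diagnostic identity
397 = 121 + 276 is preserved exactly, and a guard test asserts the whole
pattern so any fixture regression fails loudly.

## Numerical choices and degenerate inputs

* Empty fragment lists resolve to empty band tables; empty lanes call
  `Indeterminate`.
* A missing densitometric denominator peak makes the intensity ratio
  *undefined* (`NA` with a warning), never 0; a missing numerator is a true
  0.
* Band/size matching tolerance is ±10% relative everywhere lanes are read
  (gel size estimation is about that accurate); signature matching in
  cleavage typing uses ±5% because those sizes come from the model itself.
* All generators are deterministic functions of an integer seed
  (`withr::with_seed`), so every simulation in the tests and documentation
  is reproducible.
* Problem sizes in the test-suite simulations (500 random digestion pairs,
  100 × 1 kb scan-equivalence sequences, a 190-individual survey) were
  chosen as the smallest sizes that exercise every code path and the
  published composition.

## Known limitations

* Linear templates only; no circular topology, no genome-scale digestion.
* No isoschizomer database, enzyme cost modelling, or dCAPS
  mismatch-primer engineering.
* The gel model is 1-D; real gel photos must be reduced to lane profiles
  elsewhere before `detect_peaks()` applies.
* *G. glabra* and *G. inflata* share identical ITS sequences, so no ITS
  assay — including this one — can separate them; the caller reports both
  as Haplotype B.
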
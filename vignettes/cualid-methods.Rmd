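---
title: "Minting and correcting human-friendly sample identifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minting and correcting human-friendly sample identifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cualid)
```

## The problem

Comparative omics studies track hundreds to tens of thousands of physical
samples — swabs, conical tubes, DNA aliquots — whose identifiers get
handwritten in field notebooks and on tube walls, then typed back into
spreadsheets. Identifiers that embed metadata (`M3.2015-10-21`) fail in
two characteristic ways: a single illegible character makes two samples
indistinguishable, and any change to the study design makes the naming
scheme obsolete mid-project. Identifiers minted per-project also collide
as soon as data are pooled across labs.

`cualid` addresses this with a two-tier scheme:

* a **UUID** (version 4): 128 bits, 32 hexadecimal characters, randomly
  generated, globally unique for all practical purposes (there are
  $2^{122} > 10^{36}$ of them). This is the machine-facing key — it can
  serve directly as a database primary key and never needs reassignment
  when projects merge.
* a **CualID**: the last $n$ characters ($4 \le n \le 12$) of the UUID's
  hex representation. This is the human-facing ID, short enough to write
  on a microcentrifuge tube. Because the final hyphenated group of a
  UUID has 12 characters, the CualID is always a visual suffix of the
  printed UUID, so the mapping between the two can be done by eye. The
  hexadecimal alphabet contains no visually ambiguous pairs (no `0`/`O`,
  no `1`/`l`), which is why it is kept as-is rather than recoded.

Both identifiers are *opaque*: they carry no sample metadata, so they
survive any redesign of the study.

## Distance-constrained minting

Short IDs cannot be globally unique, and uniqueness alone is not enough:
for transcription errors to be *correctable*, valid IDs must be far
apart. `mint_set()` therefore enforces a minimum pairwise Levenshtein
(edit) distance among all CualIDs of a run — by default at least 3, so
any single-character slip leaves the corrupted string strictly closer to
its source than to every other minted ID. For equal-length strings the
Levenshtein distance is bounded above by the Hamming distance, so the
default also guarantees pairwise Hamming distance $\ge 3$.

Construction is rejection sampling: mint a UUID, derive its suffix, and
discard the entire UUID whenever the suffix comes within
`min_distance - 1` edits of any accepted suffix. Rejected UUIDs are
never recycled with a different suffix length, so the invariant "every
CualID is the tail of its own UUID" holds by construction. Each
candidate is compared against all accepted suffixes, so a run of $k$ IDs
costs $O(k^2)$ comparisons; the `comparisons` attribute of the returned
set exposes the realized count. A candidate budget (default
`1000 * count`) turns a hopeless request — say, length-4 CualIDs at a
separation the space cannot support — into an informative error rather
than a hang.

```{r mint}
ids <- mint_set(8, n = 6, seed = 42)
ids
pairwise_min_distance(ids)
```

A single integer `seed` drives the one RNG stream used for all
candidates of a run, making minting byte-for-byte reproducible; the
caller's RNG state is saved and restored around every seeded call.

## How long should a CualID be?

If $k$ suffixes of length $n$ were drawn *without* the distance filter,
the chance of a duplicate is the birthday problem,
$$P(\text{dup}) = 1 - \prod_{i=0}^{k-1}\left(1 - \frac{i}{16^n}\right),$$
which `duplicate_probability()` evaluates exactly in log space
(`log1p`/`expm1`), stable from $10^{-12}$ up to 1. The familiar
approximation $1 - e^{-k(k-1)/2S}$ is provided separately
(`duplicate_probability_approx()`) only as a cross-check. Minted sets
enforce the distance constraint on top of this, so their *realized*
duplicate probability is exactly zero — the curve describes the pressure
on the space, not the output.

The step-function `recommend_length()` maps study sizes to lengths —
up to 100, 1,000, 10,000 and 100,000 samples give lengths 4, 5, 6 and 8
— rounding up at the boundaries, the safe direction. Above 100,000
samples it refuses and points at the collision curve: quadratic minting
cost and a crowding suffix space both argue for sizing such studies
deliberately.

```{r collision}
duplicate_probability(c(100, 1000), 6)
recommend_length(c(150, 20000))
```

## Error correction by gestalt matching

`fix_id()` resolves a transcribed ID against the known set. After
normalization (lowercasing, stripping surrounding whitespace — nothing
else, since hex has no ambiguous-case pairs), an exact member is
confirmed as-is: correction never rewrites a valid ID. Otherwise every
known ID is scored with the gestalt (Ratcliff–Obershelp) similarity:
recursively find the longest contiguous matching block, then match the
regions to its left and right; the ratio is $2M/(|a|+|b|)$ with $M$ the
total matched length. Block matching tolerates frame shifts that
positionwise comparison cannot see — `12345678` vs `23456789` agree at
no position, yet share the 7-character block `2345678` and score 0.875.

```{r gestalt}
similarity_ratio("12345678", "23456789")
fix_id("5edd2c4", c("5ed2c4", "4af925", "0434f6"))  # duplicated 'd'
```

Three design points are deliberately conservative, because an
unresolvable ID costs one sample while a silently mis-resolved ID can
corrupt two:

* **Cutoff.** A best score below 0.6 is reported `unresolved`. Any
  single error on a length-6 ID typically scores $\ge 2\cdot5/13
  \approx 0.77$, comfortably above; 0.6 is exposed as a parameter.
* **Ties.** A tied best score is reported `ambiguous`, never assigned.
* **Duplicates.** In `fix_batch()`, a known ID matched by more than one
  query (exactly or after correction) has *all* its matches downgraded
  to `duplicate_target` and is listed in the duplicate report — two
  tubes bearing the same ID cannot be told apart after the fact.

The matcher is implemented in C++ (a faithful port of the junk-free
gestalt algorithm, tie-breaking on the earliest block in the query);
ratios are computed as `(query, candidate)`, which matters in rare
tie-break edge cases and is therefore fixed as the documented
convention.

### What correction cannot promise

The gestalt matcher is not a perfect single-error decoder, and the
package does not pretend otherwise. Two failure modes exist even for a
single substitution, both withholding the match rather than fabricating
one:

* two near-frame-shifted IDs can tie for the best score, giving
  `ambiguous`;
* greedy longest-block matching can fragment the alignment to the true
  source: `312319` transcribed as `319319` scores only 0.5 against its
  source (the leading `319` of the query aligns to the *trailing*
  `319` of the source, stranding the rest), giving `unresolved`.

Exhaustive enumeration (all 90 single substitutions of every member of
length-6, 100-ID sets over five seeds; 45,000 queries) measures a
99.86% recovery rate with zero misassignments — consistent with
transcription-error correction being "almost always, and never wrong"
rather than "guaranteed". Users wanting the provable single-error
guarantee that the distance constraint supports can pass
`method = "levenshtein"`, which resolves a query to a *unique* nearest
neighbour within edit distance 2 and otherwise withholds.

## The transcription-error simulation

`run_condition()`/`run_grid()` quantify correction quality end to end.
Per iteration: mint a fresh set, corrupt a sample of its members with
`introduce_errors()` — error type uniform over substitution,
transposition, omission, insertion and duplication; position uniform
over valid positions; written characters uniform over hex, excluding
the current character for substitutions; errors applied sequentially
against the current (possibly length-shifted) string — then resolve
every corrupted query. A query that returns `unresolved`/`ambiguous` is
a **false negative**; one assigned to an ID other than its source
(including a corrupted string that happens to *equal* another valid ID)
is a **false positive**; a corrupted string that equals its own source
(e.g. transposing identical adjacent characters) counts as correct.
Fractions are over the corrupted queries, with mean and standard
deviation across iterations; `combined = FN + FP` within each
iteration.

The default grid — CualID lengths {4, 6, 8}, corrupted counts
{1, 5, 10, 25} out of sets of 100, {1, 2, 3} errors per ID, 20
iterations per condition — spans the regimes of interest at desk scale
(about 7,400 corrupted queries, a couple of minutes on one core):
single errors on length-6 IDs are essentially always recovered, while
three errors on length-4 IDs defeat correction roughly 40% of the
time, almost entirely as false negatives. The simulation emulates
*random, independent* transcription errors; real handwriting errors are
correlated (visually similar digits, fatigue), so measured rates
characterize the algorithm, not any particular lab's error process.

## Barcodes and label sheets

`encode_code128()` implements Code 128 code set B: start symbol, one
symbol per character, the position-weighted mod-103 check symbol, stop
pattern. Hex text is sparse, so the digit-pair compression of code set
C is deliberately omitted — one subset keeps encoding deterministic and
trivially verifiable. `decode_code128()` inverts the module widths and
validates structure and checksum; since every valid symbol spans exactly
11 modules, any single-module corruption is detectable. Label sheets
(`render_sheet()`) place one barcode-plus-text label per identifier on a
configurable grid (default: US letter, half-inch margins, 4 × 10
labels); commercial cryogenic sticker sheets vary by vendor, so the
geometry is fully parameterized rather than hard-coded to one catalog
item. Layout is a pure function of the inputs; pages fill row by row
and overflow to `ceiling(count / labels_per_page)` pages.

## Numerical and interface choices

* Hex is emitted lowercase everywhere; uppercase input is accepted and
  normalized before any comparison.
* Distance checks use `utils::adist` (C implementation of unit-cost
  edit distance); the all-pairs verification in
  `pairwise_min_distance()` is the brute-force oracle for the minting
  invariant.
* Seeded runs (`mint_set`, `run_grid`, the CLI) log their effective
  seed so even unseeded runs can be replayed.
* The CLI (`exec/cual-id`; `create`, `fix`, `collisions`, `simulate`)
  exits nonzero when any query fails to resolve cleanly, so it can gate
  a sample-QC pipeline.

## Known limitations

* No distance guarantee holds **across** separate minting runs; the
  intended CualID lifetime is a single project. Merging runs and
  correcting against the union weakens correctability silently.
* CualIDs are not globally unique — only their UUIDs are.
* The package mints and corrects identifiers; it does not provide a
  resolution service mapping UUIDs to sample metadata.
* Minting cost grows quadratically; 100,000-ID runs are slow by design
  honesty rather than necessity (a prefix-bucket index could accelerate
  the check, but would have to reproduce the identical accepted set).
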
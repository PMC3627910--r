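---
title: "Methods: structural detection of TnpB/Fanzor-associated elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural detection of TnpB/Fanzor-associated elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tescan)
library(tibble)
```

tescan implements the structural rules that characterise eukaryotic DNA
transposons carrying TnpB-like (Fanzor) proteins: a conserved-residue protein
motif, terminal inverted repeats (TIRs), hairpin termini with asymmetric
terminal inverted repeat (ATIR) pairs diagnostic of the Helitron2 group,
variable-length target site duplications (TSDs) with a T-rich insertion
target, one-ended-replication truncation profiles, and majority-rule family
consensus building. This vignette documents the models, the tunable
parameters, the numerical conventions, and what the synthetic validation
does and does not establish.

## Coordinate convention

All coordinates in the R API are 1-based and inclusive, the native
convention of R, Biostrings/IRanges and GFF3. The only other convention in
the package is at a file boundary: the first three columns of the simulator
truth TSV are BED-compatible, i.e. 0-based half-open, and `read_truth()`
converts back on input. Keeping a single in-memory convention avoids the
off-by-one traffic that mixing conventions inside slicing code invites.

## The protein motif

The Fanzor/TnpB signature is a constellation of strictly conserved residues
in the C-terminal protein half, written PROSITE-style as

```
D - X(125,275) - [TS] - [TS] - X - X - [C4 zinc finger] - X(5,50) - R D
```

`scan_protein()` treats each `X(a,b)` as *a* to *b* residues **strictly
between** the flanking anchors (an anchor at `i` followed by one at `j`
satisfies `a <= j - i - 1 <= b`). Whether the published distances count
anchors inclusively is not stated anywhere we know of; the exclusive
convention is a documented choice, applied consistently and covered by the
oracle tests, and a shift of one residue is absorbed by the generous spacer
bounds in practice. The literal `X-X` between the `[TS]` pair and the zinc
finger is an exact two-residue spacer (configurable via `post_ts_gap`).

The internal geometry of the C4 zinc finger is not part of the published
motif string. The defaults (1–6, 4–30, 1–6 residues strictly between
consecutive cysteines) admit canonical CxxC…CxxC fingers while keeping the
search specific; all six bounds are parameters of `motif_spec()`. Two
further conserved Fanzor1 residues (a glycine and a glutamate downstream of
the core) have no stated relation to the motif anchors, so they are only
reachable through the generic `aux_anchors` mechanism, disabled by default.

Every satisfying anchor assignment is reported, in a deterministic
(`pos_d`, `span`) order: with wide bounds, overlapping placements are
possible, and silently keeping "the first" would make results depend on
search order. `best_hit()` summarises a protein by the minimal-span
placement (ties to the smallest `pos_d`), which is the most constrained
explanation of the sequence. Hits carry no score: the motif defines
presence/absence, not a scoring function, and inventing one would suggest a
precision the definition does not have.

## Terminal inverted repeats

`find_tirs()` anchors candidate arms near both termini (left arm starting
within `max_offset = 5` bp of the 5' end, right arm ending within the same
distance of the 3' end) and grows them inward. A mismatch-fraction bound
alone is degenerate for *maximal* arms: once an arm is long, the allowance
`floor(arm_len * 0.2)` is so large that random inward extension almost never
violates it, and the "maximal qualifying arm" would drift far past the real
repeat. The detector therefore maximises an extension score (+1 per
complementary pair, −2 per mismatch, so random extension has negative
drift), and then applies the mismatch-fraction bound, requiring the first
and last arm pairs to be complementary. Ties between offset placements break
deterministically: longest arm, fewest mismatches, smallest left offset,
smallest right offset. The exhaustive all-pairs oracle in the test suite
re-derives exactly this definition with naive loops.

## Hairpins

Hairpin detection is purely combinatorial — two nearby reverse-complementary
arms separated by a short loop — with no thermodynamic folding: the
published reasoning about these termini is entirely about pairing patterns,
and a free-energy model would import parameters the data cannot constrain.
G·T wobbles count as mismatches (DNA, not RNA, pairing); `N` never pairs.

For every loop placement the unique longest stem with at most
`max_mismatches = 1` internal mismatches and complementary innermost and
outermost pairs is a candidate; a candidate whose stem could grow into its
loop (inner flanking pair complementary while the shrunken loop stays at
least `loop_min`) is suppressed in favour of the longer-stemmed placement.
Repetitive arms (e.g. G-runs) admit shifted sub-pairings of one physical
stem, so any candidate whose full span lies inside the span of a
longer-stemmed candidate is also suppressed; one physical stem-loop is
reported once. Defaults: `stem_min` 6 bp, loop 3–15 bp. No minimum stem or
loop size is published for these structures; the defaults are the smallest
geometries that are unambiguous against random sequence at the terminal
window sizes used.

## ATIR pairs and Helitron classification

The Helitron2 diagnostic is a short inverted repeat placed asymmetrically:
arm length 8–15 bp, left arm within 0–2 bp of the 5' terminus, right arm
ending 15–40 bp before the 3' terminus (the typical placement is about
20–30 bp; the window is widened for tolerance) and at most 3 bp upstream of
a 3' hairpin. `find_atir_pair()` reports the best qualifying pair (longest
arm, then fewest mismatches, then smallest offsets).

`classify_helitron()` is DNA-structure-only; the orientation of any RepHel
coding sequence plays no role (both orientations occur within Helitron2).
The verdict is `helitron2` iff a qualifying ATIR pair, a 5' hairpin
overlapping at least 1 bp of the 5'-ATIR, and a 3' hairpin exist and the
element starts with `T`; `helitron1` iff the element starts with `TC`, ends
with `CTRR` (IUPAC `R`), has a 3'-subterminal hairpin, and no qualifying
ATIR pair; otherwise `unclassified`. All evidence booleans are returned, so
the verdict is re-derivable from the row itself — a property the test suite
asserts.

## TSD calling

An insertion locus is the pair of host flanks around one element copy. A
TSD appears as an exact string shared between the end of the left flank and
the start of the right flank; for each boundary adjustment
(`slack` up to 3 bp on either flank, consuming element-side sequence) the
caller solves the classic string-overlap problem — the longest suffix of
the adjusted left flank equal to a prefix of the adjusted right flank — and
keeps the longest solution (ties: smallest total slack, then smallest left
slack). Matching is exact: the reported duplications in these families are
perfect, and a mismatch-tolerant mode is deliberately out of scope.

Defaults: `min_len` 5 bp (the typical range is about 7–19 bp, but shorter
putative TSDs such as `TA` and `AWWT` occur in related families, so 5
splits the difference and is configurable), `max_len` 25 bp, and a long-TSD
mode (`max_len = 500`) for the occasional duplications of hundreds of bp.
The 4-mer immediately 5' of the 5'-TSD copy (or of the insertion point when
no TSD is called) is always reported with its T-richness; `t_rich` means at
least 3 of the 4 bases are `T`, which captures `TTTT` and the observed
T-rich variants while the raw 4-mer tallies in `summarize_family()` let a
stricter definition be applied downstream.

`reconstruct_empty_site()` removes exactly one TSD copy — the one at the
left flank's adjusted 3' end — so the result has length
`nchar(left) + nchar(right) − tsd_len`; on no-TSD loci it concatenates the
flanks, which for target-specific TSD-less insertions restores runs such as
`TTTTT` across the junction.

## Consensus and identity

`global_align()` is Needleman–Wunsch with affine gaps via
`Biostrings::pairwiseAlignment`; with `end_gaps_free = TRUE` (default) the
"overlap" type leaves terminal gaps unpenalised. Identity is
`100 × matches / aligned_columns`, where the column span runs from the
first to the last aligned residue pair: internal gap columns count in the
denominator, terminal overhangs do not. This matches identity quoted "over
the entire length" of elements whose lengths differ slightly. The default
scores (+2/−3, gap −5 open, −2 per position) are ordinary DNA alignment
values; since no published aligner or formula backs the reported identity
figures, everything is configurable and agreement is only expected within a
few percentage points. One caveat inherited from the engine: on co-optimal
alignments Biostrings applies its own internal traceback preference; scores
and match counts are optimal either way, but the gap placement of a tie is
not user-controllable.

`build_consensus()` is per-column majority over `{A,C,G,T}` (gaps and `N`
do not vote); a column where the gap is the strict plurality is dropped,
and base ties resolve in the fixed order A < C < G < T for
bit-reproducibility. `align_to_seed()` provides the light multiple-alignment
construction (every copy projected onto the longest copy's coordinates);
full progressive MSA is out of scope — families diverged enough to need it
should be aligned externally and fed in as gapped rows.

## The simulator

`plant_copies()` generates the study conditions the detectors target, with
full ground truth:

| Parameter | Default | Meaning |
|---|---|---|
| `element_len` | 2000 bp | full element length |
| `structure` | `tir` | terminal structure planted (`tir`, `helitron1`, `helitron2`, `none`) |
| `copy_number` | 10 | copies planted |
| `substitution_rate` | 0 | per-base post-insertion substitutions, element and TSD copies |
| `truncation_prob` | 0 | probability a copy is 5'-truncated |
| `truncation_mean_frac` | 0.3 | mean fraction of length removed (geometric) |
| `tsd_model` | `none` | `none`, `fixed`, or `uniform(tsd_min, tsd_max)` |
| `tsd_prob` | 1 | probability a copy produces a TSD at all |
| `tsd_min`, `tsd_max` | 7, 19 | TSD length range, the typical regime |
| `target_preference_prob` | 0 | probability of inserting 3' of a T-rich 4-mer |

The background is i.i.d. with configurable GC and no repeat structure: the
point is to isolate detector behaviour, not to mimic a real genome.
Insertions are placed uniformly with a guaranteed minimum separation (no
nesting, no overlapping flanks), TSDs are duplicated from the
target-adjacent background, truncation lengths are geometric (no
quantitative truncation-length distribution is published for these
families; the geometric model reproduces the qualitative 5'-coverage ramp
of one-ended replication), and substitutions are applied after insertion to
each element copy and each TSD copy independently, mirroring post-insertion
divergence. A single integer seed drives everything; the same seed and
parameters reproduce genome and truth byte-identically. `make_element()`
verifies every generated element with the package's own detectors and
redraws on the rare collisions where a random body spoils the planted
structure, so the construction guarantee is unconditional.

What passing the synthetic recovery tests shows: the detectors implement
their stated definitions exactly (oracle agreement) and recover planted
structure perfectly in the absence of divergence. What it does not show:
performance on real genomes, where backgrounds are repetitive, boundaries
are fuzzy beyond 3 bp, elements nest, and divergence includes indels — none
of which the generator emulates.

## A designed limitation worth stating

Exact TSD matching interacts sharply with simulated divergence. For a TSD
of length $L$ with per-base substitution rate $p$ applied to both copies
independently, a positive call survives only if both copies stay identical
outside the slack-tolerated 3-bp edges, i.e. with probability about
$(1-p)^{2L-6}$. Averaged over $L \sim \mathrm{uniform}(7,19)$ at $p = 0.02$
this is roughly 0.67 — and the measured recall in the acceptance run is of
that order. Recall near 1 under divergence of a few percent is therefore
not achievable with exact matching; a mismatch-tolerant caller would be the
remedy, and is deliberately out of scope here.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
statistics are stable at fixed seeds: oracle comparisons use at least 100
randomized instances per detector (proteins of 250–800 residues, elements
of 70–90 bp for the quadratic/cubic oracles), family statistics use 150–200
simulated loci, consensus reconstruction uses 17 copies of a 2,100-bp
ancestor at 8% divergence, and the worked-example identities use 0.6–7 kb
stand-ins. At these sizes the binomial standard error of every reported
fraction is comfortably inside the tolerance it is compared at.

## Known limitations

- No genome-wide discovery: copies and loci are given, not found.
- No mismatch-tolerant TSD calling, no statistical test of target-site
  enrichment.
- No thermodynamic hairpin model; no HMM/profile scoring of the protein
  motif; no phylogenetic classification (Fanzor1 vs Fanzor2 is
  phylogenetic, not structural).
- The simulator does not model nested insertions, internal deletions beyond
  5' truncation, captured 5' extra sequence, or indel divergence.
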
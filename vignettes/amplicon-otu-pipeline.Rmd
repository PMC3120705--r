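---
title: "From tagged amplicon reads to annotated OTUs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tagged amplicon reads to annotated OTUs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otupipe)
```

## The problem

Environmental amplicon sequencing (the motivating case is 454
pyrosequencing of the fungal ITS1 region from pooled soil and root
samples) produces reads of the form

```
tag | forward primer | target | rc(reverse primer) | rc(tag) | adaptor
```

where the *tag* (MID barcode) identifies the sample, the same tag sits on
both ends, and the read may stop anywhere inside this layout when the
amplicon was not sequenced to full length. Before community analysis the
reads must be demultiplexed, quality-filtered, trimmed to the target
region, dereplicated, clustered into operational taxonomic units (OTUs)
and annotated against a reference database. `otupipe` implements this as
three composable stages with exact per-step accounting, plus a simulator
that generates reads with this layout and known ground truth.

## Alignment primitives

Tags and primers are short and error-tolerant matching must handle indels,
so all matching is dynamic programming under unit edit costs
(substitution = 1, indel = 1), not mere substring comparison.

* `global_align(a, b)` minimises edits over a full global alignment; among
  minimum-edit alignments the one with most matches is reported, and
  traceback ties prefer match > substitution > gap-in-`b` > gap-in-`a`.
  Edit counts equal the Levenshtein distance (tested against an
  independent implementation).
* `find_motif(read, motif, max_edits, …)` aligns the whole motif inside a
  window of the read, free at the text ends ("semi-global"). Tags are
  searched *anchored* at position 0 (the 5′ terminus); reverse-end motifs
  (reverse primer, 3′ tag) are searched as reverse complements in a 3′
  window sized to leave room for the trailing tag and adaptor. IUPAC
  degeneracy letters in a motif match their expansion sets at zero cost
  (set intersection on bitmasks), so primers like ITS1-F behave as in
  PCR; letters in the read itself are otherwise matched literally.
* `pairwise_similarity(a, b)` aligns with both ends of both sequences
  free. Pure edit minimisation is degenerate here — an empty overlap costs
  nothing — so the free-end objective maximises `matches − edits` (ties:
  fewer edits), which is the unit-score overlap alignment. From the
  aligned region: identity = matches / columns, coverage = aligned span
  of the shorter sequence / its length. Inputs are canonically ordered
  (longer first, then lexicographic) before alignment, making the measure
  exactly symmetric.

One consequence worth stating: for *unrelated* sequences the overlap
identity reflects the best chance overlap (possibly a handful of bases at
identity 1.0) and is not monotone under extending both sequences with a
common suffix. In the regime the clustering thresholds operate in
(identity ≥ 0.95 between genuinely related sequences, coverage ≥ 0.5)
the measure is well behaved, and that is the regime the property tests
exercise. Coverage relative to the *shorter* sequence deliberately gives
nested sequences (a fragment inside a full-length read) coverage 1, which
is what a 50 % coverage threshold must mean when partial reads are
retained.

## The filter cascade

Filters run in a fixed order, and the step table satisfies, row by row,
`considered = accepted + rejected` with each row's `considered` equal to
the previous row's `accepted`:

| step | rejects when | default |
|---|---|---|
| Tags | no tag within `max_edits_tag` of the 5′ terminus, or a tie between distinct tags | `max_edits_tag = 0` |
| Primers | forward primer absent; in `FP_AND_RP` mode also when the reverse primer is absent | `FP_AND_RP`, `max_edits_primer = 0` |
| Incompatible tags | both end tags found and different | on, `FP_AND_RP` only |
| Ns | more than `max_ambiguous` non-ACGT letters in the trimmed read | `0` |
| Length | trimmed read shorter than `min_length` | `150` nt |
| Identical sequences | exact duplicate of an earlier trimmed read | dereplication on |

Decisions embedded here:

* **Mismatch allowance is edit distance.** "Two errors in the primer"
  means edit distance ≤ 2 including indels, consistent with the aligner.
  Raising the allowance can only grow the accepted set (tested).
* **Ambiguity counting** treats every non-ACGT IUPAC letter as ambiguous;
  N is only the most common case.
* **Tag ties reject.** Two tags equidistant from the read prefix mean the
  sample assignment would be arbitrary; losing the read is preferable to
  mis-assigning it.
* **The 3′ end is only judged when it was sequenced.** The reverse tag is
  searched once the reverse primer is found; a partial read is
  `not_applicable` for the incompatibility check rather than a failure,
  and in `FP_ONLY` mode the incompatible-tags row does not exist at all
  (chimeric end tags are invisible when only the forward end is
  assessed). The reverse primer is still *located* in `FP_ONLY` mode when
  the TPA defines one, because full-length reads must still be trimmed.
* **Cascade position of collapsing.** Homopolymer collapsing (a 454
  error model: run lengths are miscalled, so runs longer than the limit
  are truncated to exactly the limit; idempotent by construction) runs
  after trimming and before the N filter, so that dereplication sees the
  collapsed sequence. Its position is a package decision; placing it
  before dereplication is forced, because collapsing changes sequence
  identity.
* **Adaptor trimming** removes a full adaptor occurrence (everything from
  its start) or a read suffix equal to an adaptor prefix of at least
  `min_partial_overlap` bases (default 5; shorter suffixes match too
  often by chance).
* **Trimming never throws.** A read trimmed to nothing falls through to
  the length filter.

Dereplication keys on the fully trimmed sequence, keeps the first-seen
record as representative, and carries per-sample tallies so that the OTU
matrix can report both unique and duplicate-inclusive counts. Abundances
always sum to the dereplicated input count.

## Clustering

Both algorithms consume the dereplicated uniques and share the
identity/coverage edge predicate:

* **Single linkage**: connected components of the thresholded similarity
  graph (components delegated to `igraph`; the test suite verifies the
  partition against an independent breadth-first search on every random
  instance). Transitive: A and C cluster together when both resemble B
  even if they do not resemble each other.
* **Greedy incremental**: records sorted by length (descending, ties by
  id); each joins the earliest-seeded cluster whose *seed* it matches,
  else it seeds a new cluster. The seed — the longest member by
  construction — is the representative. Every greedy cluster is a subset
  of a single-linkage cluster at equal thresholds, hence the greedy
  method can only produce more, finer clusters; exact seed-order
  heuristics of CD-HIT are not reproduced, only this class of behaviour.

Cluster ordering folds duplicate abundances in first, then sorts by total
abundance (descending, ties by representative id) and numbers from 1.
A *singleton* is a cluster of total abundance 1 — a unique read observed
five times is evidence, not noise, so singleton status is decided after
duplicate folding. Excluded singletons are written to their own FASTA and
the remaining clusters renumbered.

The all-vs-all single-linkage step is O(n²) alignments in compiled code;
at the desk scale this package targets (≤ ~5×10³ uniques) that is
seconds to minutes. No heuristic prefilter is applied, deliberately: the
edge predicate stays exact and testable.

## Annotation

The package consumes standard BLAST tabular output (12 columns, or 13
with a subject title) rather than re-implementing database search; a thin
wrapper can invoke an external `blastn` when present. Hits are dropped by
the E-value threshold (default 1e-3) and capped per query
(`max_descriptions`, default 10, best first). Subjects whose description
contains any configured keyword (defaults: "uncultured", "environmental
sample", "unidentified" — the list is configurable because no canonical
list exists) are removed as taxonomically uninformative; both filters are
per-hit predicates, so their order is immaterial (tested). The top hit
per OTU minimises E-value with ties to the higher bit score, then file
order. Best-hit sharing statistics (how many OTUs resolve to the same
reference) flag over-strict clustering. Retained singletons are annotated
exactly like any other cluster.

## The simulator and what passing tests mean

`generate_community()` draws i.i.d. uniform templates (no phylogenetic
structure) and regenerates until all pairwise identities are at most
1 − `min_template_divergence`; tags are random `tag_length`-mers mutually
≥ 2 edits apart, one per sample, used on both ends; primers are fixed to
the ITS5/ITS2 pair and the adaptor to a fixed 454-style constant.
`simulate_reads()` assembles the full layout and plants defects:

* substitutions and N injection (per-base in `free` mode),
* homopolymer run expansion (+1..3 bases),
* 3′ truncation that removes adaptor, trailing tag and reverse primer
  while keeping at least `min_truncated_target` target bases — so these
  reads die in `FP_AND_RP` mode but survive `FP_ONLY`,
* end-tag chimeras (the 3′ tag replaced by another sample's),
* tag dropout (the 5′ tag replaced by a decoy kept ≥ 3 anchored edits
  from every real tag, so it stays undetectable up to allowance 2),
* exact duplicates at a configurable fraction.

In `one_per_read` mode each read receives at most one defect class, which
makes every per-reason rejection count exactly predictable from the
ground truth (`expected_fate()`); `free` mode mixes defects for stress
tests. Everything is seeded and byte-reproducible.

Defaults mirror the demonstration conditions the package is tested under:
10 templates of 250–300 nt at ≥ 5 % divergence, 8 samples × 250 reads,
and clustering at 97 % identity / 50 % coverage. With all error rates
zero this pipeline must recover exactly the planted community — 10
non-singleton OTUs and an OTU-by-sample matrix equal to the planted draw
counts cell for cell — and the acceptance suite asserts precisely that.

What passing does *not* show: the simulator has no flowgram-level 454
noise model, no chimeric (template-recombinant) amplicons, no quality
strings, and no phylogenetic correlation between templates. Real
communities have related taxa whose pairwise identities straddle the
clustering threshold; threshold choice on real data remains a scientific
decision, and the sweep behaviour (cluster counts non-decreasing in the
identity threshold) is the only claim the tests make about it.

## Numerical conventions and degenerate inputs

* All coordinates anywhere in the toolkit are 0-based, half-open.
* Determinism everywhere: fixed tie-break rules in alignment traceback,
  cluster ordering and top-hit selection; no output file contains
  timestamps, so re-running a configuration overwrites its outputs
  byte-identically, and running stages separately equals one full run.
* Empty filter input yields zero-count statistics, not an error; an
  all-rejected dataset is a valid (empty) clustering input error caught
  with a clear message.
* Problem sizes in the test and acceptance suites (2,000-read
  simulations, 100 random clustering instances of ≤ 40 sequences,
  200-unique threshold sweeps) were chosen as the smallest sizes at which
  every property is still exercised meaningfully.

## Known limitations

* BLASTCLUST and CD-HIT are emulated at the level of their clustering
  *semantics* (single linkage vs greedy incremental, shared thresholds),
  not bit-for-bit; BLAST's HSP-based identity is approximated by the
  full free-end-gap alignment.
* No chimera detection, no denoising, no quality-score handling — the
  filter cascade operates on base calls only.
* The per-cluster FASTA archive is written as an uncompressed (stored)
  ZIP, readable by any unzip implementation.
* FASTA is the only read format; FASTQ/SFF are out of scope.
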
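---
title: "Hinge-aided assembly: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hinge-aided assembly: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Long error-prone reads can finish a bacterial genome only if repeats are
handled correctly. A repeat is *bridged* when at least one read completely
contains one of its copies; bridged repeats can be walked through
unambiguously, while unbridged repeats cannot — any layout that commits to
one way of pairing their entries and exits is a guess. `hingeasm` builds an
overlap graph in which exactly the unbridged repeats are collapsed into a
single path, the way a de Bruijn graph collapses long repeats, while bridged
repeats stay separated. The collapsed graph makes the residual ambiguity
visible: a loop that admits a single circular traversal can still be
untangled afterwards, and a loop with several traversals is reported rather
than resolved arbitrarily.

The pipeline runs in seven stages: all-vs-all overlapping; a chimera filter
driven by per-read pile-o-grams; repeat annotation from sharp gradients in
the number of alignments on a read; the contagion stage, which spreads
bridging information globally, kills redundant annotations and places one
in-hinge and one out-hinge per unbridged repeat; a hinge-aided greedy layout
on oriented reads; loop resolution; and a majority-vote consensus. Each
stage is an exported function and writes a plain-text artifact, so every
intermediate claim in this vignette is inspectable.

### Pile-o-grams, annotations and local bridging

The pile-o-gram of a read is the set of intervals that all its partners
align to. In unique sequence, pile endpoints are spread essentially
uniformly; at a repeat boundary, every partner from a *different* copy of
the repeat starts (or stops) aligning at the same position, so the endpoint
density spikes. Annotations are called where at least `gradient_min`
endpoints co-locate within a `window` of 100 bp. The threshold scales with
the genome-wide coverage (0.4 times the across-read median pile depth): a
per-read depth would be inflated inside collapsed repeats and would
suppress exactly the deep-crossing annotations the hinge machinery needs.
Because the signal is a gradient of the pile count, not the count itself,
smooth coverage fluctuations (tested between 20x and 40x) produce no
annotations.

Endpoints within `end_exempt = 250` bp of a read end are ignored: every
pile necessarily stops near the read end, and the base-level alignment
ends straggle up to ~100 bp short of it, so endpoint clusters in that
margin carry no repeat signal. The margin is deliberately kept equal to
`end_tolerance`, so that no read falls into a gap between "annotatable"
and "chainable": a read whose unique flank is too short to carry an
annotation is then, by the same token, short enough that matches starting
at its boundary classify as proper overlaps, and it behaves exactly like a
repeat-interior read in the layout.

A read carrying both a start and an end annotation spans a whole repeat
copy, provided the two annotations delimit the *same* repeat. That is
verified by confinement: matches from other copies cannot extend past a
repeat boundary, so piles anchored on either annotation of the pair must
not extend beyond the other (fraction `pairing_fraction = 0.9`). The
confinement formulation fires even when no partner spans the repeat —
the situation whenever a copy is bridged only by rare long reads — and
still rejects the pair formed by a short repeat sitting inside a longer
one, because the longer repeat's piles cross the inner boundary.

### The contagion stage

Annotations marking the same boundary on different reads are connected
whenever an alignment between the reads maps one annotation position onto
the other within `position_tolerance = 300` bp, with the matched segment
extending into the repeat on both reads. Across an opposite-strand
alignment the annotation kind flips (a repeat start on one read is a repeat
end on the reverse-complemented partner); "same kind" is therefore meant
after orienting both reads consistently. Edges point toward the read that
extends the farthest into the repeat, ties broken toward the
lexicographically smaller read id.

Three passes then act on this graph. Components smaller than `min_size`
(default: a fifth of the median pile depth, at least 2) are removed — they
come from imprecisely placed annotations and would otherwise seed spurious
extra hinges. Next, for every edge whose reads share a proper overlap, the
lesser-extending annotation is killed; a victim whose killer is bridged, or
was itself poisoned, becomes *poisoned* rather than plainly killed, so the
bridging condition propagates down kill chains within the bridged copy.
Finally, for every edge whose reads share only an internal match — these
connect different copies — the lesser extender is killed, considering only
non-poisoned reads and non-bridged annotations. Because every kill removes
the edge's source and edges all point at the unique deepest survivor, the
outcome does not depend on processing order.

Surviving non-bridged start annotations become in-hinges, end annotations
out-hinges. Bridged annotations never become hinges: their copy separates
through its flanking unique sequence without one. Poisoning is recorded per
annotation, so a read can be poisoned at one end and hinged at another.
One consequence worth stating: when some copies of a repeat are bridged and
others are not, the unbridged copies still receive their hinge pair — the
poison marks, not the absence of hinges, are what keep the bridged copies
separate.

### Hinge-aided greedy layout

Every read contributes two oriented nodes, and the constructed graph is
symmetric under reverse complement by construction: predecessor choices are
computed as mirrored successor choices of the reverse-complement node, and
every chosen edge is inserted together with its mirror. A successor must
reach the read's 3' end within `end_tolerance` and extend beyond it;
eligible candidates are proper overlaps plus internal matches that start on
an in-hinge of the partner (within `hinge_tol = 300` bp). Matches landing
on a poisoned partner are skipped when they start after its poisoned
start-repeat mark or end before its poisoned end-repeat mark — the guard
that prevents a bridged copy from being entered from the wrong side.

Two refinements matter in practice:

* *Hinge preference margin.* The longest match wins, but a hinge candidate
  within `hinge_pref = 300` bp of the longest is preferred. Length
  differences below the coordinate-noise scale are not evidence, and
  without this margin a read whose end straggles a few bases past the
  repeat boundary (legal within `end_tolerance`) captures same-copy
  entries away from the hinge and splits the collapsed path. Genuine
  flank-anchored continuations exceed repeat-only matches by the whole
  shared flank, far more than the margin, so they still win.
* *Global reconciliation of picks.* Raw per-read picks can disagree — read
  A's best successor is B while B's best predecessor is C, typically
  because the overlapper missed one alignment — and keeping both edges
  would fabricate a branch, while discarding one would strand its chooser.
  Proposals are therefore reconciled globally, longest first: accepting a
  plain overlap fills the chooser's extension slot and the target's
  opposite-end slot, a rejected proposal falls through to the chooser's
  next-ranked candidate, and hinge-anchored matches consume no target slot
  (any number of entries may join at a hinge — that is the bifurcation).
  Every legitimate branch in the final graph is hinge-mediated. One
  asymmetry is tolerated on purpose: a read may join a hinge even when the
  hinged read extends a few bases *less* far into the repeat than it does
  (the requirement that the partner extend beyond the chooser is relaxed
  by `hinge_tol` for hinge joins). The hinged read is the deepest
  *annotated* read by its own measured coordinates, which carry ~10 bp of
  jitter against the truth, so another copy's deepest entry can physically
  out-reach it by a whisker; without the slack that entry could not funnel
  and would thread into the repeat interior instead. The chain still
  progresses through the hinged read's own successor. Tips shorter than
  `tip_clip = 3` nodes and weak components below that size are then
  removed, symmetrically on both strands.

### Loop resolution

Unbranched chains contract into segments; a segment whose endpoints branch
is a collapsed repeat with its entry and exit edges. Distinct traversals of
a component are enumerated exhaustively: circular walks that use exactly
one orientation of every strand-mirrored junction-edge pair, deduplicated
as circular oriented-label sequences up to rotation and global reverse
complement. Deduplication up to reverse complement is required for the
enumeration to reproduce the canonical motif counts (direct two-copy
repeat: 1; inverted repeat: 2; all-forward triple: 2; single-bridged
triple: 1), and the all-forward `m`-copy case has the closed form
`(m-1)!`, which the test suite checks up to `m = 4`. For a triple repeat
with one inverted copy the enumeration gives 4: two circular orders times
independent flips of the two segments flanked by oppositely-oriented copy
ends, halved by reverse-complement equivalence. Components with more than
`max_loop_edges = 12` junction pairs are refused rather than guessed.

A component is rewritten into its unique traversal only when the
enumeration finds exactly one and every collapsed segment in it is longer
than `max_plasmid_length` (default 500 kb — above typical plasmid sizes,
below chromosome sizes): a short uniquely-traversable loop may be a plasmid
sharing a repeat with the chromosome, and untangling it would fuse two
replicons. Resolution duplicates the collapsed reads once per passage,
rebuilds the mirror strand, and iterates to a fixed point. Self-mirrored
components (those containing inverted repeats) are never rewritten; a
unique traversal through one has not arisen in any fixture, and rewriting
across the strand-fusion point would need machinery the package does not
claim.

### Consensus

Draft contigs concatenate the unduplicated tails of reads along each
unbranched path. All original reads are then mapped back onto the drafts
and a per-column majority is taken over the aligned bases (A, C, G, T or
deletion; ties in the fixed order A < C < G < T < deletion). An insertion
between two columns is applied when more than 40% of the covering reads
vote for one — alignment jitter spreads the votes for a true insertion
over a couple of adjacent columns, while spurious insertion votes run near
`error_rate/3`, so the threshold sits well between the two. Three
map-and-vote rounds are the default; with zero-error reads the vote is a
fixed point of the draft, and at 30x / 15% error it polishes a repeat-free
50 kb genome to above 99.5% identity with the contig length within 1% of
the truth.

## What the simulator emulates, and what it does not

`make_genome()` arranges random unique segments around a circle with repeat
copies (forward or reverse-complemented, optionally diverged up to 5%)
inserted between them, plus optional plasmids that may share a repeat with
the chromosome. `sample_reads()` draws truncated-normal read lengths
(floor 1 kb), uniform positions that wrap the origin, uniform strands, and
applies substitution, insertion and deletion errors in equal proportions —
the error regime of raw long reads at up to 15–20% total error. Bridging is
controllable per repeat copy: `forbid_bridge` rejects reads that would
contain a copy (so a motif is unbridged by construction, not by luck), and
`force_bridge` adds one spanning read. Chimeric reads concatenate two
independently drawn segments with the junction recorded.

The generator does not emulate homopolymer-biased or quality-correlated
errors, long-tailed real read-length distributions, diploidy, or
low-complexity sequence. Consequences worth keeping in mind: minimizer
seeding behaves better on i.i.d. random sequence than on real low-
complexity regions, and repeat copies here are exact or nearly exact,
which is the hardest case for separation but the cleanest for annotation.
Passing tests demonstrate the layout logic under the stated error model,
not performance on real chemistry.

## Parameter reference

| parameter | default | unit | role |
|---|---|---|---|
| `k`, `window` | 15, 5 | – | minimizer seeding of the overlapper; `k = 13` is recommended at error rates near 15%, where occasional missed alignments otherwise break the chain of picks |
| `min_block` | 1000 | bp | minimum alignment block kept |
| `max_divergence` | 0.3 | – | maximum pairwise divergence kept |
| `end_tolerance` | 250 | bp | read-end slack for classifying overlaps and containments; covers the observed upper tail of alignment end-raggedness at 10–15% error |
| `min_coverage`, `continuity_window`, `continuity_fraction`, `min_keep` | 3, 200, 0.15, 2000 | piles, bp, –, bp | chimera filter: depth floor, continuity test, minimum retained read |
| `gradient_window` | 100 | bp | endpoint clustering window for annotations |
| `gradient_min` | auto | piles | endpoint count for an annotation; 0.4 x the genome-wide median pile depth, at least 5 |
| `end_exempt` | 250 | bp | annotation-free margin at read ends; kept equal to `end_tolerance` |
| `pairing_fraction` | 0.9 | – | confinement fraction for local bridging |
| `position_tolerance` | 300 | bp | annotation matching tolerance in the contagion graph, and the repeat-side extension a match must have |
| `min_size` | auto | nodes | contagion component floor; 0.2 x median pile depth, at least 2 |
| `hinge_tol` | 300 | bp | hinge/poison matching tolerance |
| `hinge_pref` | 300 | bp | hinge preference margin in the greedy choice |
| `tip_clip` | 3 | nodes | tip and small-component removal |
| `max_plasmid_length` | 500000 | bp | loop-length gate below which unique loops stay collapsed |
| `max_loop_edges` | 12 | pairs | traversal enumeration ceiling |
| `consensus_rounds` | 3 | – | map-and-vote polishing rounds |

## Degenerate inputs and numerical conventions

All coordinates are 0-based half-open on each read's forward strand;
circular genome coordinates are reduced modulo the genome length. A read
with no alignments has an empty pile-o-gram and is discarded by the chimera
filter. Mutual near-containments (two reads equal up to `end_tolerance`)
keep exactly one read, the longer, ties by id. A read may legitimately
carry zero annotations even inside a repeat. Empty graphs produce an empty
contig set and a header-only GFA. All tie-breaks (extension ties, match
ties, consensus column ties) are fixed and documented at the function
level, and the pipeline is byte-deterministic for a given read set and
configuration.

## Problem sizes used by the tests and the acceptance script

Hinge-count checks run on a 300 kb circular genome with one 20 kb two-copy
repeat at 30x coverage, 10 kb reads and 10% error, over five seeds; the
bridged variant uses 30 kb reads so that every copy is bridged many times
over and partners crossing one boundary usually cross the other, making the
bridging locally detectable. Motif fixtures use 70–90 kb unique segments
with 20 kb repeats (12 kb for the single-bridged triple, whose third copy
is bridged by one injected 16 kb read with 2 kb flanks; a repeat longer
than the reads keeps the unbridged entry population well spread, which the
hinge funnel needs, while the confinement test still witnesses the
injected read's bridging). The repeat-free consensus
check uses a 50 kb genome at 30x and 15% error. These sizes are the
smallest at which each regime is comfortably expressed: coverage statistics
are far from small-sample noise, repeats are several read lengths long
where unbridgedness matters, and a desk machine reproduces everything in
minutes.

## Known limitations

Near-identical repeat copies whose divergence is below the error rate are
merged by design; using that residual divergence to phase copies or score
traversals is out of scope. Loop resolution refuses large components
instead of sampling traversals. The consensus is a plain per-column
majority: it converges to ~99.5–99.7% identity at 15% error, short of what
a partial-order or HMM polisher achieves, and quality values are not
produced. Chimera detection assumes junctions look like alignment
discontinuities; adapter or hairpin artifacts with genuine flanking
alignments are not modelled.
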
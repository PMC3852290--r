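---
title: "Detecting insertion sequences and MITEs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting insertion sequences and MITEs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`teminer` detects prokaryotic transposable elements three ways: by their
repetition (repeats search), by their terminal inverted repeats (IRs search),
and by their transposase (profile HMM search). This vignette explains the
models behind each stage, the tunable parameters and why their defaults are
what they are, the numerical conventions, what the bundled simulator does and
does not emulate, and the known limitations. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## Coordinates and data shapes

Sequences travel as tibbles (`id`, `seq`). All coordinates are 0-based
half-open internally; conversion to 1-based inclusive happens only in the
GFF3 writer, because that is what the format requires. Every pipeline is
deterministic given its configuration and seeds: tie-breaks are lexicographic
then positional, never random.

## Inverted-repeat scanning

An IR pair is two equal-length arms whose right arm is the reverse complement
of the left at all but `max_mismatch` positions, separated by at most
`max_gap` nt. The defaults — arm 10–50 nt, spacer ≤ 2000 nt, ≤ 2 mismatches —
are the classical palindrome-search settings for IS ends. The scan works per
anti-diagonal: position *p* pairs with *q* on the diagonal *d = p + q*, and
both inward extension (arms grow toward each other, spacer −2) and outward
extension (arms grow apart) preserve *d*. A pair is **maximal** when neither
extension yields a valid pair — because of the mismatch budget, the arm-length
cap, the sequence ends, or an N (arms may not contain N). All maximal pairs
are reported, including overlapping and nested ones; resolution happens
downstream. The two-pointer scanner is validated in the test suite against a
brute-force enumerator that checks the definition literally on every window.

A genome-scale scan at these permissive settings reports on the order of one
maximal pair per two bases of random sequence, almost all of them 10–12 nt
arms carrying 2 mismatches. Candidate formation therefore applies an arm
significance floor, `arm_len − 3·mismatches ≥ 10` (a perfect 10-mer
equivalent, `min_arm_score` in `pipeline_config()`). Real IS and MITE termini
— typically 14–34 nt with few mismatches — pass easily; the chance-pair noise
does not. This floor is what lets an IR-less element (IS200/605-style) stay
invisible to the IR path, as it should be, instead of being rescued by
incidental weak pairs near its ends.

## Counting genomic occurrences

Both de novo paths repeatedly ask "how many times does this sequence occur in
the genome?" (singleton removal, the MITE doubleton rule). The genome-scale
counter indexes canonical 16-mers and counts colinear clusters: an occurrence
is a cluster of shared 16-mers on a near-constant (anti)diagonal (tolerance
±10) that (a) holds at least max(3, 5% of the candidate's 16-mers), (b) spans
at least 95% of the candidate end to end (`min_cov`; an element's IRs are
flush with its termini, so a real second copy covers the whole candidate),
and (c) whose matched k-mers tile at least 60% of the candidate's length.
Requirement (c) exists because a sequence that *ends* in an inverted repeat
matches its own reverse complement with both arms on a single anti-diagonal —
extent alone would count that self-match as a second occurrence. At the
0.9-identity level the expected shared-16-mer fraction of a true copy is
0.9^16 ≈ 19% with near-full tiling, so (a)–(c) are conservative. An exact
alignment-based counter (`method = "align"`) implements the same contract via
the local aligner and is the reference the k-mer screen is validated against
in the tests. The repeat-family module re-locates family copies with the same
machinery but word 13 and a 50% tiling requirement: copies can sit 10–15%
away from their consensus, which thins intact 16-mers sharply, while the
arm-only self-match it guards against tiles far below 50% either way.

Two further IR-path filters sharpen candidate boundaries:

* **Boundary sharpness** — extending a candidate by 20% of its length on each
  side must give a single-copy sequence; a candidate lying inside a larger
  repeated region (a chance pair inside an IS) fails and is discarded.
* **One candidate per locus** — among surviving spans at one locus, the one
  with the strongest terminal arms wins (then the longer), and spans
  overlapping a kept span by half their length are dropped.

## Repeat-family mining

Canonical l-mers (forward and reverse-complement occurrences folded) of word
size 9 occurring ≥ `min_copies` (default 3, the conventional threshold;
raising it to 4–5 trades sensitivity for specificity) seed a gapless greedy
extension. Scores are +1 per agreement with the column majority and −2 per
disagreement; a copy drops out when its cumulative flank score falls
`max_score_drop = 20` below its own maximum, a flank stops when fewer than
`min_copies` copies remain, and each flank is trimmed back to the peak of the
aggregate score, so the consensus ends where the copies stop agreeing, not
where the last copy died. Low-complexity seeds (< 1 bit/base entropy) are
skipped; `max_len` (10 kb) caps runaway extension.

Seeds inside an element's own IR, or occurring several times within one
element, anchor the same copy in several phases. Two safeguards make the
result independent of which seed fired first: vestigial anchors (extent
< 80% of the consensus) are discarded with overlapping anchors deduplicated,
and the definitive copy list is re-derived by locating the consensus
genome-wide with the colinearity machinery. The consensus is then polished to
the per-column majority over the located full-length copies, which repairs
any residual phase mixing. Accepted families mask their copy intervals;
masked positions support at most one family.

## Local alignment and its statistics

The aligner seeds on exact words (11 nt; 4 letters of a 10-class reduced
residue alphabet for translated search), extends ungapped with X-drop 20, and
finishes with full affine-gap Smith–Waterman over the seeded window (+1/−2
with gap 5 + 2·g for nucleotides; BLOSUM62 with gap 11 + 1·g for translated
mode — a gap of length g costs open + g·extend). Reported spans and scores
come from the DP traceback, so every hit score is reproducible by full local
DP on the reported region, which the tests assert against an independent
aligner. E-values follow `E = K·m·n·exp(−λS)`: λ for ungapped scoring solves
the Karlin sum at the scheme's background frequencies (≈ 1.33 for +1/−2 at
uniform base composition), gapped mode uses the documented empirical
correction λ_gapped = 0.9·λ_ungapped with K = 0.1 unchanged. These constants
are chosen for testability and internal consistency, not to reproduce any
external tool's numbers; thresholds throughout are 1e-5 (copy compilation and
transposase validation) and 1e-1 (terminal-word search), with the latter
implemented as ungapped matching with ≤ 3 mismatches over the 23 bp word,
since gapped statistics are meaningless at that length.

## Profile HMMs

Profiles are built from a family alignment: columns with < 50% gaps become
match states; emissions are (counts + pseudocount·background) normalised with
a uniform background (1/20); transitions come from the observed state paths
with Laplace smoothing. The alignment-to-peptide model is local: paths enter
directly at any match state (uniform entry 1/K), leave from any match state
(fixed exit mass 0.05 per node, forced at the last node), and deletions are
interior-only — a path never starts or ends in a delete state, so every
stored transition row is a proper distribution. Scores are log₂-odds (bits)
against the background; insert states carry their estimated emissions.
Viterbi and forward are exact dynamic programmes over this model and are
tested to 1e-9 against exhaustive path enumeration on small models.

Significance: `calibrate_profile()` scores `n_random` i.i.d. background
peptides (lengths normal with mean 350, sd 120, truncated at 50 — the size
range of real transposase frames) and fits a Gumbel by maximum likelihood;
`E(S) = N·(1 − exp(−exp(−λ(S − µ))))` with N the number of peptides scored
per profile. The search is local rather than glocal because metagenomic reads
truncate transposases. Windows of 5 kb with a 300 nt overlap (≈ 100 codons)
feed the six-frame translation; the source protocol does not say whether its
windows overlapped, and without overlap a transposase straddling a boundary
can be missed — duplicated hits are deduplicated by genome coordinate.

## Pipelines

The de novo tail is shared: greedy centroid clustering at 0.9 identity (the
historical default of the cited clustering tool family; identity is
matches/columns of a +1/−1/−1 global alignment, strand-aware for
nucleotides), the 500 bp size split (exactly 500 bp goes to the MITE branch —
the boundary is unassigned in the source procedure, so it is fixed here and
configurable), exhaustive copy compilation at E ≤ 1e-5 including truncated
copies (< 90% of the consensus length flags `truncated`), and MITE partner
linking: terminal 23 bp words located genome-wide on both strands, 5′/3′
matches paired in proper relative orientation (head-to-head arrangements
rejected) under 3 kb, partner sequences occurring < 2 times dropped, nested
elements excised and reconstructed recursively, and survivors validated by
translated search against the user-supplied transposase library. A validated
partner longer than the MITE becomes (or maps onto) an IS call; otherwise the
MITE is reported as a `MITE_like_orphan`. Family annotation comes from the
best library hit's `family=` header tag — similarity search is reserved for
the final annotation step. The decoy screen removes a call when its best
decoy hit (group-II intron proteins, integrases, rRNA, whatever the user
supplies) is stronger than its best transposase hit.

DR detection (the source tables report DR lengths without stating a rule):
for each copy, the longest flank word (≤ 15 nt) duplicated identically on
both sides; the reported DR length is the longest value achieved by at least
two copies.

## The simulator, and what passing tests mean

`simulate_genome()` builds i.i.d. background at a chosen GC, implants
elements as `[arm] internal [revcomp arm]` with optional transposase ORFs
back-translated with uniform codon choice (so HMM detection is neither
trivially exact nor impossible), duplicates the insertion-site word as DRs,
derives MITEs as internal deletions of their partner retaining both termini,
inserts nested copies inside a host copy, and emits ground truth. Per-copy
mutations are substitutions; `mutate_seq()` also offers indels for read-level
experiments. The built-in study (`simulate_is_study()`) places four IS
families (3–8 copies, IRs of 0–20 nt, 0.8–1.3 kb) and two MITE families on a
300 kb background; the transposase families are simulated alignments (60
sequences at 25% divergence, profile-worthy by the ≥ 50-sequence rule of
thumb), with fixed seeds because they are part of the design.

The read-length recall experiment (genomes fragmented to 1000 / 250 / 100 bp
reads) deliberately uses harder families: 50% ancestor divergence — real IS
families often share under 35% pairwise identity — and the implanted
transposase is a *held-out* member (the 61st sequence of a 61-member
simulation; the profile trains on the other 60). Against a training member of
a tight family, even a 33-residue window of a 100 bp read scores far above
the E ≤ 1e-5 threshold and recall never degrades; the held-out/divergent
design reproduces the regime the fragmentation protocol probes, where 250 bp
reads still carry enough signal and 100 bp reads mostly do not. Problem sizes
(300 kb study genomes, 60 kb read-recall genomes, 2000-peptide calibrations,
100-trial nulls) are chosen to exercise every stage at desk scale.

What the simulator does **not** emulate: real codon usage and GC skew,
insertion-site preferences, tandem and composite elements, read-error models,
and — most importantly — insertions and deletions between element copies.
Passing the suite therefore shows the algorithms implement their contracts
and behave correctly on substitution-diverged copies; it does not certify
recall on heavily indel-diverged natural families, where the gapless repeat
extension will fragment elements into shorter families.

## Known limitations

* With exact copies, an element genuinely bordered by weak chance IRs is
  indistinguishable from a true IR element; the arm-significance floor makes
  this rare but cannot make it impossible.
* Nested *distinct* elements inside one locus are resolved through the MITE
  partner machinery, not by the one-candidate-per-locus rule of the IR path,
  which deliberately keeps the outermost span.
* The repeat consensus is gapless; copies differing by indels lower the
  reported identity and can truncate the consensus at the indel.
* E-values are internally consistent but not calibrated to any external
  search tool; compare thresholds, not absolute values, across tools.
* Single-copy elements are invisible to both de novo paths by construction;
  only the library-based profile search can report them.
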
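---
title: "Reconstructing and comparing mitogenomes from degraded museum specimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and comparing mitogenomes from degraded museum specimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(museomt)
library(dplyr)
```

## The problem

DNA recovered from formalin-fixed museum specimens is short (fragment
lengths of a few tens of base pairs), chemically damaged, and available
only in minute amounts. Yet such specimens are often the only source of
genetic information for rarely collected taxa, and a mitochondrial genome
recovered from one can settle questions — such as whether two nominal
species are in fact synonymous — that morphology alone cannot. `museomt`
implements, at desk scale, the full inference chain such a study runs:

1. **simulate** degraded single-end reads from a circular mitogenome with
   a planted truth set of substitutions and indels;
2. **map** them back to a circular reference with uniqueness filtering and
   duplicate flagging;
3. **profile** post-mortem cytosine-deamination damage;
4. **call** a depth- and majority-rule consensus, with rotation-based
   recovery of the terminal positions and masking of repeats the reads
   cannot bridge;
5. **compare** near-identical mitogenomes: transition/transversion and
   codon-level classification under the vertebrate mitochondrial code,
   region-excluded divergence summaries, pairwise-deletion distances;
6. **draw** a haplotype genealogy graph from an alignment and a tree by
   Fitch parsimony.

Because the raw reads of any particular historical specimen are rarely
redistributable, the simulator is a first-class module: every downstream
method is validated against synthetic data whose ground truth is known
exactly.

## The damage model

Post-mortem deamination converts cytosine to uracil, read as thymine.
It is concentrated in the single-stranded overhangs at fragment ends, so
the per-position flip probability is modelled as an exponential decay from
the read end,

$$p(i) = p_\mathrm{base} + (p_\mathrm{max} - p_\mathrm{base})\,e^{-\lambda i},$$

with $i$ the 0-based distance from the relevant end. Under
*single-stranded* library preparation each strand is converted
independently, so the signal is C→T at **both** read ends (the distance to
the nearer end is used); under *double-stranded* preparation it is C→T
from the 5′ end and G→A from the 3′ end. Uniform per-base sequencing error
is added afterwards. `fit_deamination()` inverts the model from an
observed profile by constrained least squares
(`minpack.lm::nlsLM`, box constraints $0 \le p_\mathrm{base}, p_\mathrm{max} \le 1$,
$\lambda \ge 0$); a flat or all-zero series returns
$p_\mathrm{max} = p_\mathrm{base}$ with an undefined-decay flag, since
$\lambda$ is then unidentifiable.

Damage-plot frequencies are always conditioned on the reference base at
risk (mismatches divided by *opportunities*, not by all bases), the
standard convention for deamination profiles. Each read base contributes
to the window of its nearer end only, so short reads are never double
counted. The window is 25 positions per end, the usual extent of such
plots.

### Defaults, with units and rationale

| parameter | default | unit | rationale |
|---|---|---|---|
| fragment `mean_log`, `sd_log` | log 29, 0.35 | log-bp | truncated-lognormal mean 32.98 bp on [20, 75], matching degraded-specimen libraries; ~0.3% of fragments ≥ 70 bp |
| fragment `min_len`, `max_len` | 20, 75 | bp | shorter reads are discarded by trimming pipelines; 75 bp is the single-end kit length, and molecules longer than the read are truncated by the instrument |
| `p_max`, `p_base`, `decay` | 0.25, 0.01, 0.4 | probability, probability, /position | typical magnitudes for single-stranded libraries from fixed material; published profiles are plots without printed values, so these are free parameters and recovery tests are self-consistent |
| `seq_error` | 0.002 | probability/base | modern short-read error scale |
| `target_depth` | 35 | fold | the coverage scale such a specimen realistically yields |
| mapper `k` | 12 | bp | seeds must fit the 20-bp minimum read yet keep the random-hit rate on a ~17-kb circle negligible ($4^{12} \gg 17\,408$) |
| `max_mismatch_frac` | 0.05 | fraction of read length | the fractional-mismatch rule of classical short-read aligners, applied as `ceiling(0.05 * length)` |
| `uniqueness_margin` | 5 | score units | stand-in for a Phred-scaled mapping-quality cutoff: best placement must beat the runner-up clearly |
| `min_depth` | 3 | reads | consensus depth threshold |
| `rotation_bp` | 200 | bp | second-pass rotation for terminal recovery |
| FASTQ qualities | constant `I` | Phred+33 | the analysis never uses base qualities; degradation lives in the bases |

## Mapping a circular genome

The mapper is a transparent seed-and-extend placement engine: exact
k-mers at three offsets per orientation propose candidate diagonals, every
candidate is scored ungapped over the full read, and the best placement
wins. The reference is indexed with its first `max_read_len − 1` bases
appended so reads spanning the origin seed and score contiguously;
reported coordinates wrap back to the 1..L frame. `damage_tolerant`
scoring halves the penalty of C(ref)→T(read) and G(ref)→A(read)
mismatches — the two orientations of the deamination signature — so
damaged reads are not pushed to the wrong locus.

Alignment is **ungapped** by design: at ~33 bp mean read length a real
indel cannot be placed confidently from a single read anyway, and the one
event this workflow expects (a homopolymer length change) is detected at
the consensus stage from spanning-read votes instead. Duplicate flagging
uses the single-end criterion (identical start, length and strand keep
only the best-scoring read, ties broken by read id).

## Consensus rules

A site is called when its depth is at least 3 and one base holds a strict
majority; ties and thin sites become `N`. Strict majority with tie→`N` is
deliberately conservative — the tie behaviour of the genotype caller that
inspired the rule is not documented, and a conservative rule is testable.
Damage is handled by depth plus majority (intact cytosines vastly
outnumber deaminated ones at 35×), not by damage-aware genotyping; this is
a documented limitation, acceptable at this depth but not at 3–5×.

Terminal positions are recovered by a second pass against the reference
rotated by 200 bp; calls within 200 bp of the origin junction are taken
from that pass, and conflicting non-`N` calls between passes become `N`
with a warning. Repeats whose span meets or exceeds the read length
(tandem units of 1–10 bp, homopolymers included) are masked
automatically — no single read can bridge them — alongside any manual
intervals, which are merged when they overlap.

Homopolymer length changes are *candidates*, never automatic edits: a
reference run is called when at least two spanning reads agree on the same
non-reference length, no spanning read supports the reference length, and
each voting read continues with the base that follows the run in the
reference (the shift signature that distinguishes a true length change
from a substitution at the run edge). Candidates carry a
`manual-confirmation` flag, mirroring how such calls are made by eye;
`apply_indels()` applies them on request and returns the coordinate map.

Coverage and called fraction are reported separately: whether a published
coverage figure counts later-masked sites is often ambiguous, so the
package never conflates the two.

## Comparing near-identical mitogenomes

Differences are tabulated per alignment column (substitutions) or per
maximal gap run (one indel record however long the run), skipping columns
where either sequence has `N` — missing data is ignored, not called.
Reported coordinates and bases are reference-strand; codon fields are
coding-strand, which matters for light-strand genes such as *ND6* where
the printed codon change is the complement of the genomic one. Translation
uses the vertebrate mitochondrial code by default (TGA = Trp, ATA = Met,
AGA/AGG = stop) — a tgg→tga change is synonymous only under that code —
with the standard code selectable.

The headline percent divergence uses the full reference length as
denominator; per-bp rates inside and outside an excluded region use the
corresponding interval lengths. Both conventions are computed and
labelled. Percentages are displayed at two decimals and per-bp rates at
four, the customary precision. The exact boundaries of the
hypervariable *ND6*-through-control-region block depend on a genome
annotation this package does not ship; the region is therefore a
user-supplied interval, and the tests bracket it from the codon-strand
evidence of the shipped difference table itself.

Pairwise-deletion distances ignore, per pair, any column where either row
lacks an unambiguous base; an all-`N` column can never change an entry,
and a pair with no comparable columns is flagged `NA` rather than zero.

## Haplotype genealogy graphs

Ancestral sequences are reconstructed by two-pass Fitch parsimony, made
fully deterministic: the root takes the lexicographically smallest state
of its set, children inherit the parent state when possible and otherwise
their own lexicographically smallest state. Sites with gaps or `N`
contribute no state. Unrooted input trees are rooted at the first tip's
pendant edge and polytomies are resolved deterministically
(`ape::multi2di(random = FALSE)`); the collapsed graph is invariant to
both choices, which the test suite asserts.

Branches whose endpoint sequences are identical on comparable sites are
contracted and tip multiplicities accumulated; remaining edges are
weighted by substitution counts, so the summed edge weights equal the
parsimony score. Deterministic tie-breaking can assign an internal node a
chimera of its neighbours' states; such unsampled haplotypes are retained
only where the genealogy branches (degree ≥ 3) — an inferred node that
merely sits on a path is spliced out with its edge weights summed, and the
score identity is preserved.

## What the simulator does and does not emulate

The generator reproduces the *structure* of degraded-specimen data:
fragment-length distribution (truncated lognormal, mean 32.98 bp),
end-biased C→T damage with the single- vs double-stranded asymmetry,
uniform fragment starts on a circular molecule, ~35× depth, optional PCR
duplicates and a seeded random decoy genome for contamination. It does
**not** emulate base-quality error profiles, adapter read-through,
GC-biased coverage, fragmentation hot-spots, or real repeat architecture —
the reference is i.i.d. random except for sequence context planted
deliberately (e.g. a 14-mer C homopolymer). Passing tests therefore
demonstrate correctness of the inference chain under the stated model, not
robustness to every artefact of real libraries.

A consequence of ungapped mapping worth knowing: reads that cross a
homopolymer length change accumulate mismatches downstream of the run, so
only reads ending within a few bases of the run still map. At 35× roughly
two such voting reads are expected — matching the real-world situation the
candidate flag is designed for — so truth-set recovery of the indel is
itself stochastic, and the end-to-end acceptance bound (≥ 25 of 27
planted variants over five seeds) is met by the substitutions alone.

## Problem sizes used by the tests

The suite exercises the full study scale where the quantity under test
demands it (17,408-bp genome, depth 35, five seeds, 50,000-read damage
recovery, 100 random six-tip parsimony instances against an exhaustive
oracle) and small instances (1.5–3-kb genomes, a few hundred reads)
where the property is scale-free — rotation equivariance, duplicate
marking, SAM round trips. Exhaustive oracles (all-placements alignment,
all-labelings parsimony) are deliberately restricted to instances where
enumeration is exact and fast.

## Known limitations

- No damage-aware genotype likelihoods; depth + majority only.
- No gapped or spliced alignment; structural variants beyond homopolymer
  length changes are out of reach, as they are for real short-fragment
  data.
- MAPQ is not calibrated; the uniqueness margin is a proxy.
- The banded aligner for near-identical pairs is a thin wrapper over
  global Needleman–Wunsch (`Biostrings::pairwiseAlignment`); genuinely
  diverged genomes should be aligned externally.
- Haplotype graphs assume a tree-like genealogy: no recombination,
  no median-joining networks.
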
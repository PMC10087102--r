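---
title: "svtarget: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{svtarget: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svtarget)
```

# The problem

Human vault RNAs are short RNA polymerase III transcripts; vtRNA1-2 (89 nt)
is processed by Dicer into small vault RNA fragments (svtRNA1-2, 22–24 nt,
from the 3′ end) that load into Ago2 and act on *nascent* transcripts —
chromatin-associated, largely unspliced RNA — rather than on mature mRNA.
Functionally this looks like miRNA-style targeting shifted into introns:
perfect seed pairing over guide positions 2–8, extended pairing with G:U
wobbles towards position 18, and in most targets an unpaired 5-nt loop on
the target strand opposite guide positions 11–12, with a conserved loop
sequence (CAUCA/CAUUA read 5′→3′ on the target; read 3′→5′ the same loop is
the ACUAC/AUUAC spelling that sometimes appears in discussions of this
motif).

`svtarget` re-implements the computational side of this analysis as a
tested, reusable pipeline: fragment identification from small-RNA coverage,
seed-constrained duplex target prediction with loop-architecture
classification, shuffled/swapped-guide null controls, feature-level
annotation with length normalisation, and gene-set overlap statistics. A
synthetic-data module generates every input with known ground truth, which
is what the test suite validates against.

# The duplex aligner

`align_window()` / `scan_transcript()` compute a local alignment between an
RNA guide and the sense strand of a (pre-m)RNA window, pairing the strands
antiparallel. Column scores:

| event                | score (default) |
|----------------------|-----------------|
| Watson–Crick pair    | +5              |
| G:U wobble           | +1              |
| mismatch             | −3              |
| gap of k nt          | −9 − 4(k−1)     |
| seed scaling         | ×4 on guide positions 2–8 |

The thresholds mirror the miRanda-style settings `-sc 150 -en −30 -strict`:
a site must reach score ≥ 150, duplex free energy ≤ −30 kcal/mol, and (with
`strict_seed = TRUE`) have guide positions 2–8 contiguously paired with no
gaps, no mismatches and at most one wobble. The scoring constants follow
the reference implementation's published defaults; every constant is a
parameter of `align_params()`.

Conventions that matter:

- **Guide position 1 never pairs.** The 5′ nucleotide sits in the Argonaute
  pocket, so a fully paired 24-nt guide pairs positions 2–24 and spans
  23 nt of target — and 28 nt when one 5-nt target loop is inserted.
- **Gaps are bounded jumps**: unpaired target-side runs up to
  `max_target_loop` (6 nt) and guide-side bulges up to `max_guide_bulge`
  (3 nt). This is how a 5-nt target loop is representable while unbounded
  gapping is not.
- **Tie-breaking.** Predecessor ties in the dynamic program resolve towards
  the largest target-side jump, which anchors pairs at their 5′-most target
  coordinate. Around the planted loops the optimum is degenerate (the loop
  is flanked by repeated bases); this rule keeps the reported loop in the
  planted register instead of an equivalent-score rotation.
- **Multiple hits** per transcript are taken greedily: best alignment
  first, its target span masked, rescan until the score threshold is no
  longer met. Returned sites are non-overlapping local score maxima, sorted
  by target start.
- Scanning runs on **unspliced pre-mRNA** by default, because targeting is
  nascent and largely intronic; spliced sequence can be passed instead.

`classify_architecture()` reports seed pairing, wobble positions, the
furthest contiguously paired guide position, the target-side loop (total
unpaired target nt between paired flanks; the longest run's guide anchors
and 5′→3′ sequence), the central 10-11-12 pairing scheme, and the
target-side alignment length. `loop_consensus()` tallies loop sequences
over sites whose loop is exactly 5 nt.

# The energy model

`duplex_energy()` sums nearest-neighbour stacking terms over consecutive
pair steps (Turner-style tables for Watson–Crick and G:U steps), plus a
duplex initiation of +4.09 kcal/mol and bulge/internal-loop penalties for
unpaired runs (small-loop tables with logarithmic extrapolation; a mismatch
is a 1×1 internal loop; terminal-AU penalties are omitted). An alignment
with zero pairs has energy 0 — no duplex forms.

The *contract* of this model is threshold behaviour and monotonicity:
appending a Watson–Crick pair never raises the energy, a 23-bp duplex of
mixed composition clears −30 kcal/mol, a seed-only 7-bp duplex does not. It
is deliberately **not** bit-compatible with any folding package: whether
the original analysis used miRanda's internal thermodynamics or an external
tool is unknowable from the methods, so the package owns a documented,
self-consistent model instead of chasing parity.

# Fragment calling

`per_base_coverage()` follows the `genomecov -dz` convention (depth =
number of reads covering a position; optional RPM scaling by
`1e6 / total`). `call_fragment()` takes maximal runs of positions with WT
depth ≥ `rel_threshold` (default 0.5) of the WT maximum and annotates each
with the WT/KD mean ratio, flooring the KD mean at one raw read-equivalent
(standard pseudocount) and flagging `dicer_dependent` at ≥ 2-fold. No
numeric rule for the fragment boundary is published — coverage figures show
a single dominant 3′ block per vault gene — so both thresholds are
configuration, not ground truth.

# Null-control guides

`shuffle_region()` permutes bases within a 1-based closed region under a
seeded PRNG (the package uses R's Mersenne-Twister with rejection sampling
throughout, seeded explicitly and scoped so the caller's RNG state is
untouched). `swap_ends()` exchanges the 5′ and 3′ blocks. Both preserve the
whole-guide base-composition multiset — the property that makes these valid
controls. Defaults mirror the transfected constructs: 5′ scramble over
positions 2–8, 3′ scramble over 12–18, swap of those blocks. The exact
endogenous fragment endpoints are unreported (only a 22–24-nt length
range), so the default guide is the 3′-terminal 24-mer of vtRNA1-2,
configurable in `svtRNA1_2()`.

# Feature annotation and metagene

`select_canonical()` keeps one transcript per gene with the most
confidence tags (allowlist configurable, since the exact tag set used in
annotation pipelines is not standardised), ties broken lexicographically.
`build_feature_table()` derives introns from exon gaps, splits exonic
sequence into UTR5/UTR3/exon, and emits ±10-nt junction windows
(`UTR5/exon`, `UTR3/exon`) around each UTR–CDS boundary — the junction
feature is named in the field's custom feature files but its width is not,
so it is a parameter. `annotate_sites()` reproduces
`bedtools intersect -wa -wb -loj` semantics exactly (every site appears;
multi-overlaps give one row each; orphans carry `NA`).

`feature_percentages()` normalises site counts by feature length before
converting to percentages; this is the normalisation under which intron
binding dominates even though introns are ~80% of gene length.
`metagene_profile()` bins site midpoints (midpoint rather than 5′ end — a
symmetric choice the original methods leave unstated) on the
relative transcript coordinate, flipping minus-strand transcripts.

# Overlap statistics

For sets of sizes $n_1$, $n_2$ in a universe of $N$ with observed overlap
$k$: expected overlap $e = n_1 n_2 / N$, representation factor $k/e$, and
the one-sided upper tail $P(X \ge k)$ of the hypergeometric distribution,
computed in log space (`stats::phyper(..., log.p = TRUE)`). The
permutation null draws `reps` subsets uniformly without replacement and
summarises overlaps with type-7 quantiles — the convention behind a
standard statistical summary printout, hence the default here. The
worked numbers (N = 14,759, 227, 584, k = 29) give RF = 3.2287 → "3.2" and
$P(X \ge 29) = 2.5103 \times 10^{-8}$; note that a printed bound of
"< 2.510 × 10⁻⁸" is this exact value truncated at four significant digits.

```{r enrichment}
representation_factor(14759, 227, 584, 29)
```

# The synthetic world

`synthetic_config()` states the world once; tests never tune it:

- **Transcriptome**: single-transcript genes, 100-nt 5′ UTR, 200-nt 3′ UTR,
  2–4 introns, exonic length ≈ 1200 nt, intronic share 0.8 — an
  intron-dominated gene body typical of human protein-coding genes at a
  desk-friendly scale. Sequence is i.i.d. uniform over ACGT (a neutral null
  for false-positive behaviour; a GC knob exists).
- **Planted sites**: `no_loop` windows are the reverse complement of guide
  positions 2..L (23 nt for a 24-nt guide); `canonical_loop` windows insert
  one 5-nt loop between the bases pairing guide positions 12 and 11, drawn
  from {CAUCA, CAUUA} at 0.6/0.4 — consistent with one sequence being the
  reported majority spelling; `seed_only` windows carry only positions 2–8
  and must *fail* the score threshold. The architecture mix defaults to
  0.7/0.2/0.1 (the reported targets are loop-dominated, 179 of 205, and the
  seed-only class exists purely to exercise the filter). Placement follows
  a feature mix of intron 0.90 / exon 0.04 / UTR5 0.03 / UTR3 0.03, chosen
  so that the *length-normalised* intron density dominates, which is the
  directional fact the feature analysis must reproduce.
- **Reads**: fragment reads end at the vault gene's 3′ terminus with
  lengths 22–24; WT has 90% fragment reads, the Dicer knockdown divides
  that rate by `dicer_depletion_factor` (default 4). Background reads stay
  ≥ 30 nt clear of the 3′ window so the planted WT/KD coverage ratio over
  the window *is* the depletion factor — the quantity the fragment caller
  estimates.
- **Gene sets**: overlap is forced exactly (29 shared genes between sets of
  227 and 584 in a universe of 14,759 by default), membership otherwise
  uniform.

What the generator does **not** emulate: sequencing error, expression-level
variation, alternative isoforms, multi-mapping reads, GC-biased or
repeat-structured genomic sequence, and chromatin-capture artefacts. A
green planted-site recovery test therefore establishes that the aligner
finds the stated architectures under the stated thresholds on neutral
background — not that the pipeline would reproduce genome-scale target
counts, which depend on real human sequence and are out of desk scale by
design.

# Numerical choices and degenerate inputs

- Intervals are 0-based half-open internally, BED-style on disk; GTF is
  1-based closed with bijective converters.
- The aligner rejects nothing silently: a window shorter than the seed
  simply yields no alignment; an all-zero WT profile yields an empty call
  list; `k = 0` gives a hypergeometric tail of exactly 1; an impossible
  overlap (`k > min(n1, n2)`) returns 0 with a warning.
- `shuffle_region` on a length-1 region is the identity permutation; a
  length-0 region is a configuration error.
- Alignment ties are deterministic (5′-most target anchoring, above), so
  identical inputs give byte-identical outputs, which the determinism tests
  assert at file level.
- All randomness flows from one integer seed through named child streams;
  derived seeds stay below $2^{31}$.

# Known limitations

- The energy model is a simplified nearest-neighbour implementation; use it
  for thresholding and ranking, not for publishing ΔG values.
- Strictness of the seed rule ("≤ 1 wobble, 0 mismatches, no gaps") is one
  reasonable reading of `-strict`; the wobble allowance is exposed as
  `max_seed_wobble`.
- The scanner is desk-scale: a few hundred multi-kilobase genes per run.
  Genome-wide scans would want banding and coarse pre-filtering that this
  package intentionally leaves out.
- Target-site accessibility (PITA-style ΔΔG) is not modelled; the analysis
  this package implements considered and did not adopt it.
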
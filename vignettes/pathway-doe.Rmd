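---
title: "Designed pathway libraries: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designed pathway libraries: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathdoe)
```

pathdoe implements the computational core of a Design–Build–Test–Learn
(DBTL) loop for combinatorial optimization of microbial production
pathways: it defines and counts combinatorial design spaces, reduces them
to small statistically representative construct libraries, compiles each
selected design into an annotated plasmid, plans scarless ligase cycling
reaction (LCR) assembly with robotics worklists, fits a main-effects model
of production titer, and turns the fitted effects into constraints for the
next design round. A seeded synthetic-data module closes the loop without
laboratory data. This vignette explains the models behind each stage, the
parameters that matter, and the choices made where the design was open.

## The design-space model

A pathway design is an assignment of one level to each *factor* plus a
*gene ordering*. Factors are categorical (promoter identity) or ordinal
(plasmid copy number, ranked). The worked flavonoid example has:

* one composite 4-level **backbone** factor — origin of replication
  (pSC101 low copy, p15a medium copy) crossed with the vector promoter
  (weak P~lacUV5~, strong P~trc~). Modelling the backbone as a single
  4-level factor rather than two crossed 2-level factors matches how
  backbones are physically stocked (one part per combination) and lets one
  orthogonal-array column carry it;
* three 3-level intergenic **promoter slots** (`none`, weak, strong) — the
  `none` level changes operon structure by fusing adjacent genes into one
  transcript;
* the **gene-order factor**: 4 pathway genes in any of 4! = 24 positions.

The space is the cross product: 4 × 3 × 3 × 3 × 24 = 2592 designs.
`count_designs()` computes this without materializing anything;
`enumerate_designs()` materializes points in a fixed lexicographic order
(factor declaration order, later axes varying fastest) so the ID sequence
is bit-identical across runs. Construct IDs are FNV-1a hashes of a
canonical serialization of the assignment, so an ID identifies a design,
not an enumeration position, and survives re-ordering and subsetting.

`apply_constraints()` restricts a space (fix a level, restrict a level
menu, pin genes to positions, whitelist orderings) and returns a new space
whose enumeration provably equals the brute-force filter of the old one —
the test suite checks exactly that equivalence. Contradictory constraints
raise an error instead of yielding a silently empty space.

## Library reduction: orthogonal arrays and the Latin square

Building all 2592 designs is not realistic; a strength-2 orthogonal array
preserves what the Learn stage needs — unconfounded main effects — at 16
runs. The 16-run array over five 4-level columns, OA(16, 4^5^, 2), is
built by the GF(4) finite-field construction: runs are indexed by pairs
(a, b) ∈ GF(4)², and each column is a linear form u·a + v·b for one of
the five pairwise linearly independent coefficient pairs. Linear
independence makes the run-to-(column~i~, column~j~) map a bijection, so
every ordered level pair appears exactly once — strength 2 by
construction, and verified in the tests by exhaustive pair counting. The
construction generalizes to other 4^k^ cases; no array catalog is
shipped or needed.

Mixed level counts come from *level collapsing*: a 3-level promoter slot
uses a 4-level column with the two lowest array levels mapped onto
`none`, giving the 8/4/4 balance of {none, none, weak, strong} across 16
runs. Collapsing onto the two lowest indices is an arbitrary but
deterministic and documented convention.

Gene order is handled positionally: the 24 permutations are reduced to
the 4 rows of the order-4 **cyclic Latin square** grid[i, j] = (i + j)
mod 4, read as orderings. Every gene occupies every position exactly once
across the four rows, so position effects are balanced. The remaining OA
column selects the row. The cyclic square is one of many order-4 Latin
squares; nothing downstream depends on which one is used, only on the
row balance, so the simplest deterministic choice wins. The achieved
compression is exact rational arithmetic: 2592/16 = 162:1.

Regular two-level fractional factorials (`fractional_factorial()`) are
provided as the alternative reduction for 2-level screening problems,
with the defining contrast subgroup computed explicitly, resolution
reported as the shortest defining word, and an error if any main effect
would alias the identity.

`choose_strategy()` encodes the round-2 decision rule: build the full
factorial exactly when the (constrained) space fits the build capacity,
otherwise reduce.

## Construct compilation and formats

`compile_construct()` concatenates parts in template order — backbone,
then per position an optional promoter and the gene the ordering places
there. LCR assembly is scarless, so no junction sequence is inserted:
record length is exactly the sum of part lengths and features tile
[0, L) without gaps. Coordinates are 0-based half-open on the plus strand
internally (all pathway genes co-oriented); the GenBank writer converts
to the format's 1-based closed convention and emits origin-spanning
features of circular records as `join(a..L,1..b)`. FASTA I/O goes through
Biostrings; the GenBank dialect is written and parsed by the package
(round-trip preserving sequence, topology and features).

## LCR planning and the melting-temperature model

Each junction between consecutive parts (including the circular closure,
so k parts need k oligos) gets one single-stranded bridging oligo whose
two halves anneal to the junction-proximal ends of the two parts. Halves
are sized against a duplex melting temperature target of **70 °C** using
unified nearest-neighbor thermodynamics: ΔH/ΔS sums over dinucleotide
steps plus terminal initiation terms, the monovalent-salt entropy
correction 0.368·(N−1)·ln[Na⁺], and Tm = ΔH/(ΔS + R ln(C~T~/4)) for
non-self-complementary duplexes. Defaults, all configurable:

| parameter | default | meaning |
|---|---|---|
| `target_tm` | 70 °C | LCR annealing target per half |
| `Na` | 0.05 M | monovalent cation concentration |
| `conc` | 250 nM | total oligo concentration (C~T~/4 pairing factor) |
| `min_len` / `max_len` | 15 / 60 nt | half-length search bounds |

The half-length search grows from 15 nt and stops at the first length
meeting the target — the minimal qualifying length, a deterministic
tie-break verified by brute-force scans in the tests. The Tm
implementation is checked against an independent hand summation of the
parameter table. Identical junction contexts yield identical oligos, so
library-level pooling deduplicates by sequence; part dilutions target the
75 nM working concentration used for LCR setup.

Worklists are emitted in three stages (part dilution, per-construct oligo
pooling, LCR setup) as vendor-neutral CSV, with per-destination volumes
summing exactly to the reaction volume (default 25 µL) and a seeded
random injection-sequence permutation for downstream analytics. One seed
makes all files byte-reproducible.

## The Learn stage

Titers are modelled by ordinary least squares with **main effects only**
on replicate-level responses: categorical factors with sum-to-zero
contrasts, ordinal factors by integer rank. Each factor's significance is
the F test of zero effect from the drop-one model comparison. Per-factor
choices and their reasons:

* **Response transform**: `log10(titer + ε)` by default, with
  ε = (smallest positive observed titer)/10. Titers from expression
  libraries span orders of magnitude and are strictly positive, which a
  log scale represents naturally; the identity transform is available.
  The ε offset guards true zeros without distorting the observed range.
* **Replicates and summaries**: fitting uses replicate-level rows (more
  residual degrees of freedom); construct-level reporting uses the
  median, which is robust to single-clone failures.
* **Analysis factors**: `gene_design()` re-expresses each construct in
  the factors a biologist interprets — ordinal copy number, the promoter
  strength directly upstream of each gene (the vector promoter for the
  gene in first position, so never `none` there), and gene order as a
  categorical factor over the Latin-square rows. Fitting gene order as a
  4-level categorical factor is a pragmatic encoding of a 24-level
  factor sampled at 4 levels; with order effects absent (as planted in
  the demo truth) it costs 3 degrees of freedom and nothing else.
* **Multiple testing**: raw F-test p-values are reported; the factor
  count is small and the propagation policy consumes a ranking, not a
  family-wise error rate.
* **Degenerate inputs**: constant factors are dropped with a note in the
  effect table; rank deficiency and saturated fits raise errors naming
  the aliased coefficients rather than silently pseudo-inverting.

`propagate_rules()` translates the fitted pattern into next-round
constraints under an explicit `rule_policy()` (α = 0.05 by default):
the strongest significant *ordinal* factor is fixed at its beneficial
extreme (among tied levels, the one with the strong vector promoter); the
most significant *per-gene promoter* factor pins its gene to position 1 so
it always sits directly downstream of a promoter; genes flagged
*non-limiting* by an auxiliary indicator — `flag_non_limiting()` checks
that an upstream intermediate accumulates in every construct — are pinned
to the last position with a reduced promoter menu; everything else stays
free. On the flavonoid example this yields 1 backbone × 3 × 3 promoter
menus × 2 reduced menu × 2 middle-gene orders = 36 designs, built as a
full factorial.

One mapping here was genuinely open: which axis contributes the final
factor of 2 in the 36-design round. The package's reading is the promoter
menu of the slot feeding the last, non-limiting gene, reduced to
{`none`, strongest}: the last gene of an operon is the natural place to
drop a promoter entirely, and keeping the strong option preserves a
contrast. The menu is a policy function, not a constant, so other
readings are a one-line change.

## The synthetic-data module

`simulate_titers()` draws per-replicate titers as
10^(baseline + Σ level effects + N(0, sd)) — log-normal noise, the single
distributional assumption, chosen for positivity and the
orders-of-magnitude spread characteristic of expression libraries. The
default demo truth (`demo_truth()`) mirrors the qualitative round-1
pattern: copy number the strongest positive effect (1.0 log10 between
extremes), the CHI promoter next, 4CL/CHS intermediate, PAL weakest, gene
order null, sd = 0.3 log10 units, 3 replicates, baseline 10^−1.5^ mg/L —
so simulated titers span roughly 0.001–0.5 mg/L. These values were fixed
once as the simulation's study conditions.

`random_parts()` generates part sequences with *exact* base composition
(GC count = round(gc·L), shuffled), so observed GC is always within
rounding of the request. The demo registry uses GC = 0.62 and 100-nt
promoter parts: the real pathway mixes plant genes with a gene from the
high-GC actinomycete *Streptomyces coelicolor*, and a GC-poor part end
cannot reach a 70 °C half within the 60-nt synthesis bound at all — LCR
feasibility is a property of the parts, so the generator offers
`lcr_ready = TRUE`, which rejection-samples (still seed-deterministic)
until both terminal windows of each part can reach the target.

What the simulator does **not** emulate — and therefore what passing
tests do not show about real data: real regulatory sequence content and
context effects, assembly failures and clone dropout, measurement error
structure of LC–MS quantification, chassis and media effects, and any
interaction or saturation between factors (the truth is exactly
main-effects, matching the fitted model; real pathways need not be).

## Validation problem sizes

The property suites run at sizes chosen to make the statistical checks
sharp yet quick on a laptop: exhaustive pair counting over all 10 column
pairs of the 16-run array; brute-force minimality scans over every oligo
half of a 16-construct library; 500 null simulations for the type-I error
of the F test (checked against a 99% binomial interval around 0.05); 200
simulations for the power of a planted 1.0-log effect (expected ≥ 95%
detection) and for the full design→learn→redesign cycle (round-2 best
median titer beats round-1 in ≥ 90% of cycles under the demo truth).

## Known limitations

* Only the 16-run GF(4) array family is constructed; factors with more
  than 4 levels (e.g. a 9-level chassis factor) can be counted and
  enumerated but not OA-reduced — by design, not omission.
* The Tm model covers perfectly matched duplexes over A/C/G/T only;
  mismatches, dangling ends and divalent-cation corrections are out of
  scope for bridging-oligo sizing.
* `propagate_rules()` implements one explicit policy; it is a starting
  point meant to be swapped, not a learned model.
* The GenBank writer emits the subset of the format the package itself
  reads (LOCUS/FEATURES/ORIGIN with label and note qualifiers).
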
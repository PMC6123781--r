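# pathdoe

Design-of-experiments tooling for **Design–Build–Test–Learn (DBTL)
optimization of microbial production pathways**. The package is aimed at
metabolic engineers and biofoundry software developers who need to go from
"every way of arranging promoters, origins and gene order in this pathway"
to "the sixteen constructs worth building, the oligos and robot worklists
to build them, and the design rules the titer data support".

## What it computes

**Design.** A pathway design space is the cross product of design factors
with a gene-order factor. For a four-enzyme pathway (PAL, 4CL, CHS, CHI →
(2S)-pinocembrin) with a composite 4-level backbone factor
(pSC101/p15a origin × P_lacUV5/P_trc vector promoter), three 3-level
intergenic promoter slots (none/weak/strong) and free gene order, the
space has 4 × 3 × 3 × 3 × 4! = **2592** designs. Spaces are declared in
code or YAML, counted in O(1) and enumerated deterministically with
hash-stable construct IDs.

**Reduce.** A strength-2 orthogonal array OA(16, 4⁵, 2), built by the
GF(4) finite-field construction (columns are the five pairwise independent
linear forms u·a + v·b over runs (a, b) ∈ GF(4)²), guarantees every pair
of factor levels appears equally often, so all main effects are estimable
from **16 constructs** — a **162:1** compression. 3-level promoter slots
ride on collapsed 4-level columns (none, none, weak, strong → 8/4/4
balance); the 24 gene orders collapse to the 4 rows of a cyclic Latin
square, each gene visiting each position exactly once. Regular 2^(k−p)
fractional factorials (with explicit defining relation and resolution) are
available for 2-level screening.

**Build.** Each selected design compiles into an annotated circular
plasmid record (scarless concatenation — LCR leaves no junction scars),
with FASTA part input and GenBank output. LCR assembly planning designs
one bridging oligo per part junction: each half is the minimal terminal
subsequence of its part reaching a **70 °C** nearest-neighbor melting
temperature (unified ΔH/ΔS parameters, 0.368·(N−1)·ln[Na⁺] salt
correction, Tm = ΔH/(ΔS + R·ln(Cₜ/4))). Oligos deduplicate across the
library by junction context, and three-stage robotics worklists (part
dilution to 75 nM, oligo pooling, LCR setup) are emitted as seeded,
byte-reproducible CSV.

**Learn.** Replicate-level titers are fitted by ordinary least squares on
main effects — log10(titer + ε) response, sum-to-zero contrasts for
categorical factors, integer ranks for ordinal ones — with each factor
tested by the F test of zero effect (drop-one model comparison).
`propagate_rules()` converts the fitted pattern into next-round
constraints: fix the beneficial extreme of the strongest ordinal factor,
pin the gene with the strongest promoter effect to the first position,
pin non-limiting genes (flagged by an accumulating upstream intermediate)
last with a reduced promoter menu, leave the rest free.

**Simulate.** A synthetic-data module generates random-composition DNA
parts (exact GC control, optionally conditioned on LCR-designable ends)
and log-normal titer tables whose log10 means are linear in the design
factors, so the entire loop runs and is testable with no laboratory data.

## Worked example

```r
library(pathdoe)

space <- pinocembrin_round1_space()
space
#> <design_space> 4 factor(s) x 24 ordering(s) = 2,592 designs
#>   backbone         pSC101_lacUV5/pSC101_trc/p15a_lacUV5/p15a_trc [categorical]
#>   promoter_slot2   none/P_lacUV5/P_trc [categorical]
#>   promoter_slot3   none/P_lacUV5/P_trc [categorical]
#>   promoter_slot4   none/P_lacUV5/P_trc [categorical]
#>   genes: PAL 4CL CHS CHI (mode all_permutations)

lib <- reduce_library(space, 16)
lib
#> <pathway_library> 16 construct(s), OA(16,4^5,2) + Latin square, compression 162:1

head(as.data.frame(lib), 3)
#>   construct      backbone promoter_slot2 promoter_slot3 promoter_slot4      gene_order
#> 1 D389abc02 pSC101_lacUV5           none           none           none PAL>4CL>CHS>CHI
#> 2 Dc4bdd25b pSC101_lacUV5           none           none       P_lacUV5 CHI>PAL>4CL>CHS
#> 3 D655f3c28 pSC101_lacUV5       P_lacUV5       P_lacUV5          P_trc 4CL>CHS>CHI>PAL
```

The 16-construct library is balanced by construction: each backbone 4
times, each promoter slot 8/4/4 over none/weak/strong, each gene at each
position 4 times. Running the whole simulated DBTL cycle:

```r
demo <- run_dbtl_demo(seed = 1)
demo$effects1
#> <effect_table> main-effects least squares on log10 titer
#>        factor        kind df        F         p direction
#>   copy_number     ordinal  1 126.3000 3.667e-13         1
#>  promoter_PAL categorical  2   1.3980 2.605e-01        NA
#>  promoter_4CL categorical  2   3.5900 3.817e-02        NA
#>  promoter_CHS categorical  2   1.2230 3.066e-01        NA
#>  promoter_CHI categorical  2  20.2300 1.447e-06        NA
#>    gene_order categorical  3   0.3842 7.650e-01        NA
#> R-squared 0.891 on 35 residual df
```

Copy number is the dominant positive effect and the CHI promoter the
strongest categorical one (these are the effects the simulation plants;
gene order is null, and the fit correctly finds it non-significant). The
learned rules and the constrained round-2 space follow:

```r
demo$rules
#> <constraint_set>
#>   fix backbone = p15a_trc
#>   pin CHI at position 1
#>   pin PAL at position 4
#>   restrict promoter_slot4 to {none, P_trc}

count_designs(demo$space2)
#> [1] 36

demo$worklists1
#> <lcr_worklists> 20 dilution, 104 pooling, 130 LCR transfer(s); 16 sample(s) in injection sequence
```

36 = 1 backbone × 3 × 3 promoter menus × 2 reduced menu × 2 middle-gene
orders: small enough that `choose_strategy()` selects the full factorial
for round 2. The bridging-oligo pool for round 1 holds 52 unique oligos
(shared junctions across the 16 constructs are synthesized once), every
half at Tm ≥ 70 °C.

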
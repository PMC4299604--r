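---
title: "Designing and simulating sgRNA-repressible promoter logic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and simulating sgRNA-repressible promoter logic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprgates)
```

## The system

A CRISPRi NOT gate has three parts: catalytically dead Cas9 (dCas9), an input
promoter transcribing a single guide RNA (sgRNA), and a synthetic sigma-70
output promoter carrying a designed operator between its -35 and -10
hexamers. When the guide is transcribed, the dCas9:sgRNA complex binds the
operator and sterically blocks RNA polymerase, so output activity falls as
input activity rises. Because new guide:operator pairs are just new 13-bp DNA
words, large orthogonal gate sets can be designed computationally rather than
mined from repressor families. This package implements that design pipeline
end to end: operator generation and genome screening, promoter and guide
construction, oligo/Golden Gate build planning, quantitative response-function
fitting, and compilation and simulation of NOT/NOR logic circuits, including
knockdown guides against endogenous coding sequences.

## Promoter geometry

The spacer between the -35 and -10 hexamers is 17 bp:
`CC` + operator(13 bp) + `GG`. The trailing `GG` is a forward NGG PAM whose
N is the operator's last base; the leading `CC` is, on the bottom strand, a
reverse NGG PAM whose N is the complement of the operator's first base. Two
20-nt guides are derived per promoter:

* **T variant** - protospacer on the forward strand, immediately 5' of the
  forward PAM: the -35 hexamer plus spacer positions 1-14. Its guide
  base-pairs with the template strand.
* **NT variant** - protospacer on the bottom strand, 5' of the reverse PAM:
  the reverse complement of spacer positions 4-17 plus the -10 hexamer. Its
  guide base-pairs with the non-template strand.

Each guide's PAM-proximal 12-nt seed - the specificity-determining part -
falls entirely inside the operator (or its reverse complement), so operator
choice alone sets the channel identity. The exact register of the two PAMs
within the 17-bp spacer is not uniquely determined by the published promoter
schematic; the `CC`/`GG` convention above is one consistent solution
satisfying every stated constraint (17-bp spacer, 13-bp operator, PAMs on both
strands, each guide overlapping one hexamer with its seed in the operator),
and the scaffold is fully configurable through `default_scaffold()`.

"Targets the non-template strand" here always means the guide base-pairs with
the non-template strand, placing protospacer and PAM on the template strand.

```{r geometry}
pd <- assemble_promoter(generate_operator(1), name = "P_A1")
pd
derive_guides(pd)$NT
```

## Operator generation and genome screening

Operators are drawn i.i.d. with a GC probability of 0.5 (per base: G or C
with probability 0.5) and rejected if the forward strand contains a run of
more than three consecutive G, which would make oligo synthesis difficult.
Candidate guides are rejected when their GC fraction falls below 35% or above
80%; the boundary values pass because the discard rule is a strict
inequality.

The genome screen indexes, for every NGG on either strand, the 12 bases
immediately 5' of the N on the PAM's strand, and requires a designed seed to
have **zero exact matches**. This replaces a heuristic local-alignment search
with the decisive criterion it was used for - no 12-nt seed with complete
homology to a PAM-adjacent locus - and is deterministic and dependency-free.
A Hamming-radius near-match report (`screen_seed(..., radius =)`) is
available for more conservative designs; off-target scoring beyond Hamming
distance and PAM variants other than NGG are out of scope. The screen length
defaults to the 12-nt seed but is configurable, since a stricter 13-nt
(whole-operator) criterion is also defensible.

Orthogonality within a set is enforced by a minimum pairwise Hamming distance
between seeds of distinct designs (default 4, compared across all T/NT seed
pairs). The published criterion is only that seeds be distinct; the margin is
a heuristic guard against near-duplicate channels and can be set to 1 to
recover plain distinctness. With a 12-nt seed the theoretical channel
capacity is `4^12` (about `1.7e7`), the order-of-magnitude basis of the
~10^7-orthogonal-pairs capacity figure; `operator_space()` also reports the
exact count of 13-mers passing the G-run filter.

```{r design}
genome <- random_genome(1, 50000)
designs <- design_orthogonal_set(genome, n_pairs = 3, rng_seed = 7)
designs[, c("name", "operator", "seed_T", "seed_NT", "gc_T", "gc_NT")]
attr(designs, "rejections")
```

Coordinates are 0-based half-open internally (`genome_index$pos` is the
0-based forward-strand position of a seed span's leftmost base); human-facing
reports are 1-based. Every stochastic function takes an explicit seed and is
a pure function of it.

## Construct planning

A transcription unit is promoter + guide + dCas9 handle + terminator. Input
promoters in the parts library end exactly at the transcription start (+1) so
that no extra nucleotides are prepended to the guide, which is known to
reduce activity. The unit is encoded as two single-stranded oligos that
anneal at the 42-nt handle: sense = Type IIs site/scar flank + promoter +
guide + handle; antisense = reverse complement of handle + terminator +
scar/site flank. Both oligos must stay at or below 200 nt (the cap is checked
against the parts file and violations raise a structured error with the
overage, never silent truncation). `plan_golden_gate()` simulates Type IIs
digestion and scar-directed ligation of any number of units plus a backbone
into a single circular product, verifies there are no internal recognition
sites or scar collisions, and `decompose_assembly()` checks the round trip.
The packaged promoter/terminator sequences are synthetic representative
placeholders (realistic length and structure) labelled as such in
`default_parts.yaml`; the terminator strength annotations carry the published
dimensionless values (84 for TrrnB, 260 for L3S2P55, 380 for L3S2P21). All
length-dependent checks read the parts file, never constants. Thermodynamic
oligo QC (melting temperature, hairpins) is out of scope.

## Gate response model

Measured sgRNA gates are log-linear rather than saturating, so the response
is modelled as a clamped power law,

$$ y(x) = \min\!\big(y_{\max},\; k\,x^{-b}\big), $$

with `y_max` the unrepressed output activity (au), `k` the scale (au) and
`b >= 0` the exponent. Fitting is ordinary least squares in (log x, log y);
points at or above `0.9 * y_max` (configurable) sit on the clamp rather than
the power law and are excluded. The fold repression at an ON input `x_on` is
`y_max / y(x_on)`. On noise-free data the fit recovers parameters to machine
precision; under multiplicative log-normal noise with sigma = 0.1 at 24
points spanning the unclamped working range, the exponent estimate is
unbiased to better than 0.01 over 1,000 seeded replicates (the regression is
evaluated in the unclamped regime because that is where characterization
points carry power-law information; points generated on the clamp would be
excluded asymmetrically under noise).

Inducible input promoters are characterized empirically; as a monotone
dose-response surrogate the package fits a four-parameter Hill curve
(`y_min`, `y_max`, `K`, `n`) by Levenberg-Marquardt least squares over a
deterministic multi-start grid. Designs that only sample the saturated
plateau leave `K` unidentifiable and are flagged `ill_conditioned` rather
than silently reported.

```{r fit}
truth <- gate_response(y_max = 1040, k = 400, b = 0.8)
dat <- synth_gate_data(truth, exp(seq(log(1), log(1000), length.out = 24)),
                       noise_sigma = 0.1, seed = 3)
fit <- fit_power_law(dat, y_max = 1040)
tidy(fit)
glance(fit)
```

## Circuit semantics

A netlist is promoters (input / constitutive / repressible-with-a-gate),
transcription-unit edges (promoter transcribes guide) and repression edges
(guide represses promoter). `compile_netlist()` rejects cycles - steady state
is defined here only for feed-forward circuits, matching how the gates are
composed in practice - and evaluates in topological order:

* guide level = **sum** of the activities of all transcription units carrying
  that guide (additive pooling; a NOR gate is exactly two units carrying the
  same guide from distinct input promoters);
* a repressible promoter's activity is `y_max` divided by the product over
  acting guides of `fold^w`, where `fold` is the cognate fold repression of
  its gate at the guide's pooled level and `w` the crosstalk weight. A single
  cognate guide (`w = 1`) reproduces `gate_output()` exactly; distinct guides
  combine multiplicatively (an independence assumption - the published
  circuits only use same-guide NOR gates, so this extends rather than
  contradicts them); off-targets act as a fraction of the cognate effect in
  log-fold space, which makes the fold-matrix-to-weight conversion
  `w_ij = log(fold_ij) / log(fold_jj)` exact at the characterization input.

Truth tables evaluate all `2^n` input combinations at ON/OFF activity levels
(defaults correspond to the digital assay conditions: saturating inducer for
ON). The digital margin is min(expected-ON activities) / max(expected-OFF
activities); margin > 1 means the circuit is digitally correct at those
levels. Optional per-promoter `basal` activity models leaky transcription; no
leak value is asserted by default. dCas9 is treated as saturating and
constant (the circuits are operated at a fixed dCas9 induction), so
resource-sharing/retroactivity is not modelled; nor are stochastic
single-cell effects or growth coupling.

Because the gates are power laws, a cascade attenuates dynamic range
analytically: a signal spanning `d` decades spans `d * prod(b_i)` decades
after the cascade's unclamped region, which `cascade_attenuation()` computes
and `steady_state()` sweeps confirm to under 1%.

Dynamics integrate
`dL/dt = synthesis_rate * a(t) - (ln 2 / T_d) * L`
with a fixed-step 4th-order Runge-Kutta scheme (default step 0.1 min,
configurable); `a(t)` is the steady-state output activity under the inducer
state at `t - tau`. The single delay `tau` lumps input-promoter activation
and dCas9/sgRNA accumulation; after it, a fully repressed reporter decays
exponentially with half-life equal to the doubling time, i.e. it is diluted
by growth. With `tau = 90` min and `T_d = 33` min the trace is flat for the
delay and then halves every 33 min, the canonical repression-onset shape.

```{r circuit}
gates <- fixture_gates(3, seed = 5)
tt <- truth_table(netlist_and(gates[[1]], gates[[2]], gates[[3]]),
                  on_level = 1040, off_level = 0, logic = "AND")
tt
glance(tt)
```

## Host-gene outputs

`enumerate_cds_protospacers()` lists every 20-nt protospacer with an NGG PAM
inside a codon window of a coding sequence (codons `i..j` span nucleotides
`3i-2 .. 3j`), on the strand the guide must base-pair with; targeting the
non-template strand puts the dCas9 roadblock in the path of elongating RNA
polymerase. The adopted rule requires the whole protospacer-plus-PAM span to
lie inside the window - the published codon range is ambiguous about whether
it bounds the protospacer, the PAM or both, and the containment reading is
the most conservative. `design_knockdown_guide()` filters candidates by the
guide GC bounds, screens seeds genome-wide while excluding the intended locus
(the on-target hit is expected, not an off-target), and returns the 5'-most
survivor; the ranking is deterministic and exposed in the attached report.
A host-gene node in a netlist behaves exactly like a reporter node with the
same gate model, so one circuit can drive an internal-state reporter under
one logic and a host knockdown under the complementary logic. Predicting the
knockdown phenotype itself is out of scope; host nodes use a user-supplied
gate response.

## Synthetic data: what it does and does not emulate

The generators make the whole pipeline testable without any downloads:

* `random_genome()` - i.i.d. bases at a target GC. It reproduces the
  *screening* problem (density of NGG sites and 12-mer collision statistics
  at a given length and GC) but none of a real genome's repeat structure,
  codon bias or k-mer autocorrelation, so screening pass rates on real
  genomes can differ.
* `synth_gate_data()` - exact power-law responses with multiplicative
  log-normal noise, the structure of activity-vs-activity characterization
  data. Real gates add replicate structure, autofluorescence floors and
  deviations from the power law near saturation.
* `synth_crosstalk()` - cognate folds uniform in [56, 440] and off-target
  folds uniform in [1, 1.3), the printed orthogonality regime. Fixture gate
  defaults (`fixture_gate()`: fold 150 at an ON input of 1,040 au, b = 0.8,
  y_max = 1,040 au) are chosen once so that single-gate fold repression at
  the ON level falls inside that window; 1,040 au is the published
  unrepressed output of the cascade's final promoter and serves as the au
  scale anchor.

Consequently, passing tests demonstrate the correctness of the algorithms and
the self-consistency of the models at the stated conditions - not that any
particular wet-lab fold repression would be reproduced.

## Problem sizes and numerical choices

The test suite exercises: index-vs-brute-force equivalence on 50 random
genomes up to 10 kb; screen sensitivity on 100 seeded plant-and-rescreen
trials; exponent recovery over 1,000 replicates at n = 24 for
b in {0.3, 0.7, 1.0}; full truth tables for NOT/NOR/OR/AND; 2- and 3-layer
cascade sweeps; and 100 oligo reconstruction round trips plus all 24
orderings of a 4-fragment assembly. Dynamics use step 0.1 min; the only
integration artifact is a sub-0.05% blip at the single step containing the
delay switch. Ties among surviving knockdown candidates break to the 5'-most
position; optimizer restarts are a fixed grid; all RNG flows through explicit
seeds recorded in outputs.

## Known limitations

Feedback circuits are rejected rather than solved; repression combination
across distinct guides assumes independence; the screen is exact-match (plus
optional Hamming radius), not an energy model; inducer curves are a Hill
surrogate for an empirically characterized promoter; and the shipped parts
sequences other than the sgRNA handle are synthetic placeholders to be
replaced with a lab's own parts.
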
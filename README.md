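# crisprgates

Design and simulation of transcriptional logic built from dCas9 and single
guide RNAs (sgRNAs) in bacteria.

A CRISPRi NOT gate is an input promoter transcribing an sgRNA, dCas9, and a
synthetic sigma-70 output promoter carrying a designed 13-bp operator in the
17-bp spacer between its -35 and -10 hexamers, flanked by forward and reverse
NGG PAMs. The dCas9:sgRNA complex binds the operator and sterically blocks
RNA polymerase, so the output promoter is repressed whenever the input is
active. Because a new gate is just a new 13-bp DNA word, orthogonal gate sets
are designed computationally; with a 12-nt specificity-determining seed the
channel space is 4^12 ≈ 1.7×10^7 words. `crisprgates` implements the full
desk-side workflow:

* **Operator and guide design** — random 13-bp operators (GC probability 0.5,
  no G run longer than 3), promoter assembly (`spacer = CC + operator + GG`),
  derivation of the template- and non-template-targeting 20-nt guides
  (GC within [35%, 80%]), and a genome screen requiring each 12-nt
  PAM-proximal seed to have **zero** exact PAM-adjacent matches
  (`build_pam_seed_index()`, `screen_seed()`, `design_orthogonal_set()`).
* **Construction planning** — sgRNA transcription units
  (promoter ∥ guide ∥ dCas9 handle ∥ terminator), their encoding as pairs of
  ≤ 200-nt single-stranded oligos annealed at the handle
  (`emit_oligo_pair()`, `anneal_extend()`), and simulated one-pot Golden Gate
  assembly with 4-nt fusion scars (`plan_golden_gate()`).
* **Quantitative gate models** — the clamped power-law response
  `y(x) = min(y_max, k·x^(−b))` fitted by log–log least squares
  (`fit_power_law()`), fold repression `y_max / y(x_on)`, and Hill curves for
  inducible input promoters (`fit_hill()`); `tidy()`/`glance()`/`autoplot()`
  methods throughout.
* **Circuit compilation and simulation** — NOT/NOR netlists and their layered
  compositions (OR, AND, cascades), steady-state evaluation in topological
  order with additive sgRNA pooling and multiplicative fold combination,
  truth tables with digital margins, analytic cascade attenuation
  (`decades_out = decades_in · Πb`), and delayed-exponential repression
  dynamics (`simulate_dynamics()`).
* **Host-gene outputs** — knockdown guides against an endogenous coding
  sequence within a codon window, e.g. non-template-strand targeting of a
  transcription-factor CDS, with on-target-aware genome screening
  (`design_knockdown_guide()`).

## Worked example

```r
library(crisprgates)

genome  <- random_genome(1, 100000)                 # 100-kb synthetic host genome
designs <- design_orthogonal_set(genome, n_pairs = 5, rng_seed = 7)
designs[, c("name", "operator", "seed_T", "seed_NT", "exact_hits_T", "exact_hits_NT")]
#> # A tibble: 5 × 6
#>   name  operator      seed_T       seed_NT      exact_hits_T exact_hits_NT
#>   <chr> <chr>         <chr>        <chr>               <int>         <int>
#> 1 P_A1  AGCCCAGACGCCA AGCCCAGACGCC TGGCGTCTGGGC            0             0
#> 2 P_A2  CGCTCAGTGAAAC CGCTCAGTGAAA GTTTCACTGAGC            0             0
#> 3 P_A3  TGAGTGCCGAGAA TGAGTGCCGAGA TTCTCGGCACTC            0             0
#> 4 P_A4  ATTGCCGGCTATT ATTGCCGGCTAT AATAGCCGGCAA            0             0
#> 5 P_A5  TAAACTGCCAGGG TAAACTGCCAGG CCCTGGCAGTTT            0             0
```

Each row is one orthogonal channel: a 13-bp operator, its assembled promoter,
and the 12-nt seeds of both guide variants, none of which has a perfect
PAM-adjacent match anywhere in the genome. Building one gate leg and its
construction oligos:

```r
gs   <- attr(designs, "guides")[[1]]
tu   <- build_transcription_unit("pBAD_mini", gs$NT, "TrrnB")
emit_oligo_pair(tu)
#> <oligo_pair> sense 163 nt / antisense 85 nt, overlap 42 nt
```

Both oligos are under the 200-nt synthesis cap and share the 42-nt dCas9
handle; `anneal_extend()` reconstructs the flanked fragment exactly. Fitting
a gate's response function from (noisy, synthetic) characterization data:

```r
truth <- gate_response(y_max = 1040, k = 400, b = 0.8)
dat   <- synth_gate_data(truth, exp(seq(log(1), log(1000), length.out = 24)),
                         noise_sigma = 0.1, seed = 3)
fit   <- fit_power_law(dat, y_max = 1040)
fit
#> <powerlaw_fit> k = 395.661, b = 0.8050 (R^2 = 0.9979, 24 points, 0 saturated excluded)
```

The exponent `b` sets how much dynamic range each layer preserves (0.805
estimated vs 0.8 true here); `y_max` = 1,040 au is the unrepressed output
level. Composing gates into an AND circuit (two NOT gates feeding a
same-guide NOR) and checking its digital behaviour:

```r
gates <- fixture_gates(3, seed = 5)
tt <- truth_table(netlist_and(gates[[1]], gates[[2]], gates[[3]]),
                  on_level = 1040, off_level = 0, logic = "AND")
tt
#> # A tibble: 4 × 5
#>      pA    pB activity expected call
#>   <int> <int>    <dbl> <lgl>    <lgl>
#> 1     0     0     2.03 FALSE    FALSE
#> 2     1     0     3.19 FALSE    FALSE
#> 3     0     1     3.19 FALSE    FALSE
#> 4     1     1    68.2  TRUE     TRUE
glance(tt)$margin
#> [1] 21.4
```

The output is ON only when both inputs are induced, with a 21-fold digital
margin between the weakest ON and strongest OFF states.

A thin command-line shell over the same functions ships in
`inst/cli/crisprgates.R` (subcommands `design`, `fit`, `target`, `fixtures`,
`simulate`).

## Documentation

The methods vignette (`vignettes/designing-sgrna-logic.Rmd`) describes the
promoter geometry convention, the screening rules, the gate and circuit
models with their assumptions, the synthetic-data generators and what they do
and do not emulate, and the package's numerical choices and limitations.
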
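# a CDS with controllable PAM content: codons drawn from an alphabet that can
# produce neither CC nor GG dinucleotides anywhere (no C or G at all), so
# planted PAM sites are the only candidates
quiet_cds <- function(n_codons, seed) {
  withr::with_seed(seed, {
    codons <- apply(expand.grid(c("A", "T"), c("A", "T"), c("A", "T")), 1, paste0, collapse = "")
    paste(sample(codons, n_codons, replace = TRUE), collapse = "")
  })
}

test_that("codon windows map to the right nucleotide span", {
  expect_identical(codon_window_span(c(1, 1)), c(1L, 3L))
  expect_identical(codon_window_span(c(110, 117)), c(328L, 351L))
  # translate-and-slice oracle: window nt span reproduces the codon slice
  cds <- quiet_cds(200, 71)
  span <- codon_window_span(c(110, 117))
  by_span <- substr(cds, span[1], span[2])
  by_codons <- paste(vapply(110:117, function(i) {
    substr(cds, 3 * i - 2, 3 * i)
  }, character(1)), collapse = "")
  expect_identical(by_span, by_codons)
  expect_identical(
    as.character(Biostrings::translate(Biostrings::DNAString(by_span))),
    as.character(Biostrings::translate(Biostrings::DNAString(by_codons)))
  )
})

test_that("a planted non-template site in codons 110-117 is the unique candidate", {
  cds <- quiet_cds(400, 72)
  expect_identical(nrow(enumerate_cds_protospacers(cds, c(110, 117))), 0L)
  # plant a template-strand PAM (CCN on the coding string) at the window start
  substr(cds, 328, 330) <- "CCA"
  cands <- enumerate_cds_protospacers(cds, c(110, 117), "non-template")
  expect_identical(nrow(cands), 1L)
  expect_identical(cands$start, 328L)
  expect_identical(cands$end, 350L)
  expect_identical(cands$strand, "-")
  expect_identical(cands$guide, revcomp(substr(cds, 331, 350)))
  expect_identical(cands$seed12, substr(cands$guide, 9, 20))
  # the same site is invisible to a template-strand search
  expect_identical(nrow(enumerate_cds_protospacers(cds, c(110, 117), "template")), 0L)
})

test_that("windowed enumeration equals full-CDS enumeration filtered to the window", {
  g <- random_genome(73, 1200)
  cds <- substr(g[[1]], 1, 1200 - (1200 %% 3))
  win <- c(50, 120)
  span <- codon_window_span(win)
  for (pref in c("non-template", "template")) {
    full <- enumerate_cds_protospacers(cds, c(1, nchar(cds) / 3), pref)
    filtered <- full[full$start >= span[1] & full$end <= span[2], ]
    direct <- enumerate_cds_protospacers(cds, win, pref)
    expect_identical(as.data.frame(direct), as.data.frame(filtered))
  }
  expect_error(enumerate_cds_protospacers(cds, c(1, 10000)),
               class = "crisprgates_invalid_argument")
  expect_error(enumerate_cds_protospacers(substr(cds, 1, 100), c(1, 10)),
               class = "crisprgates_invalid_cds")
})

test_that("knockdown design excludes the intended locus, applies GC filters, and picks the 5'-most survivor", {
  cds <- quiet_cds(400, 74)
  # two planted sites; the first yields a low-GC (all A/T) guide that must be skipped
  substr(cds, 328, 330) <- "CCA"
  substr(cds, 355, 381) <- "CCTGCTGCAATGCTGACTGCATCAGCT"
  genome <- random_genome(75, 30000)
  start <- 8000
  substr(genome[["contig1"]], start, start + nchar(cds) - 1) <- cds
  gd <- design_knockdown_guide(cds, c(110, 130), genome,
                               gene_name = "malT",
                               locus = list(contig = "contig1", start = start))
  rep <- attr(gd, "report")
  expect_gte(nrow(rep), 2L)
  expect_false(rep$gc_ok[1])                       # all-A/T guide fails GC
  expect_identical(attr(gd, "off_target_hits"), 0)
  expect_identical(gd$guide, rep$guide[rep$pass][1])  # 5'-most survivor
  expect_identical(gd$targeted_strand, "non-template")
  expect_match(gd$name, "^sgRNA-malT")

  # without the locus exclusion the on-target hit counts as an off-target
  expect_error(
    design_knockdown_guide(cds, c(110, 117), genome, gene_name = "malT"),
    class = "crisprgates_unsatisfiable"
  )

  # a knockdown guide drops into a circuit as an output node like any reporter
  g <- fixture_gate()
  nl <- compile_netlist(list(
    promoters = list(pIn = list(type = "input"),
                     malT = list(type = "repressible", gate = g)),
    tus = list(list(promoter = "pIn", guide = gd$name)),
    repression = list(list(guide = gd$name, promoter = "malT")),
    outputs = "malT"
  ))
  ref <- netlist_not(g)
  expect_equal(steady_state(nl, c(pIn = 500))$activity,
               steady_state(ref, c(pIn = 500))$activity)
})

test_that("the same circuit drives a reporter and a host knockdown under complementary logic", {
  # OR topology: the NOR stage output doubles as an internal-state reporter
  # (NOR logic) while the final stage represses a host gene (OR logic on the
  # knockdown readout).
  g1 <- fixture_gate(150, 0.8); g2 <- fixture_gate(220, 0.9)
  nl <- compile_netlist(list(
    promoters = list(pA = list(type = "input"), pB = list(type = "input"),
                     pMid = list(type = "repressible", gate = g1),
                     malT = list(type = "repressible", gate = g2)),
    tus = list(list(promoter = "pA", guide = "g1"),
               list(promoter = "pB", guide = "g1"),
               list(promoter = "pMid", guide = "gMalT")),
    repression = list(list(guide = "g1", promoter = "pMid"),
                      list(guide = "gMalT", promoter = "malT")),
    outputs = c("pMid", "malT")
  ))
  tt_rep <- truth_table(nl, logic = "NOR", output = "pMid")
  tt_host <- truth_table(nl, logic = "OR", output = "malT")
  expect_true(attr(tt_rep, "consistent")); expect_gt(attr(tt_rep, "margin"), 1)
  expect_true(attr(tt_host, "consistent")); expect_gt(attr(tt_host, "margin"), 1)
})
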
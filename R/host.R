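#' Nucleotide span of a codon window
#'
#' Codons `i..j` (1-based, inclusive) of an in-frame CDS occupy nucleotides
#' `3i - 2` through `3j`.
#'
#' @param codon_window Length-2 integer vector `c(i, j)`.
#' @return Length-2 integer vector of 1-based nucleotide positions.
#' @export
codon_window_span <- function(codon_window) {
  i <- as.integer(codon_window[1]); j <- as.integer(codon_window[2])
  stopifnot(i >= 1, j >= i)
  c(3L * i - 2L, 3L * j)
}

#' Enumerate candidate knockdown protospacers in a CDS window
#'
#' Finds every 20-nt protospacer with an NGG PAM whose protospacer-plus-PAM
#' span lies fully within the nucleotide span of the codon window, on the
#' strand such that the guide base-pairs with the requested strand. The CDS is
#' given as its coding (non-template) strand: targeting the non-template
#' strand places the protospacer and PAM on the template strand (the reverse
#' complement), which is the orientation whose dCas9 roadblock halts
#' elongating RNA polymerase; targeting the template strand places them on
#' the coding strand.
#'
#' @param cds In-frame coding sequence (length divisible by 3).
#' @param codon_window 1-based inclusive codon window `c(i, j)`.
#' @param strand_pref `"non-template"` (default) or `"template"`: the strand
#'   the guide base-pairs with.
#' @return Tibble sorted by position: `guide`, `seed12`, `start`, `end`
#'   (1-based CDS coordinates of the protospacer+PAM span), `strand` (strand
#'   carrying the protospacer, `+` = coding strand), `pam`.
#' @export
enumerate_cds_protospacers <- function(cds, codon_window,
                                       strand_pref = c("non-template", "template")) {
  strand_pref <- match.arg(strand_pref)
  cds <- toupper(cds)
  assert_dna(cds, arg = "cds")
  if (nchar(cds) %% 3 != 0) {
    rlang::abort("CDS length must be divisible by 3", class = "crisprgates_invalid_cds")
  }
  span <- codon_window_span(codon_window)
  if (span[2] > nchar(cds)) {
    rlang::abort("codon window extends beyond the CDS", class = "crisprgates_invalid_argument")
  }
  empty <- tibble::tibble(guide = character(0), seed12 = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), pam = character(0))
  if (strand_pref == "non-template") {
    # protospacer+PAM on the template strand: forward-coordinate "CCN",
    # protospacer = revcomp of the 20 nt 3' of the CCN (in forward coords)
    p <- overlapping_starts(cds, "CC")
    p <- p[p >= span[1] & p + 22 <= span[2]]
    if (!length(p)) return(empty)
    guide <- revcomp(substr_vec(cds, p + 3, p + 22))
    tibble::tibble(
      guide = guide,
      seed12 = substr(guide, 9, 20),
      start = as.integer(p), end = as.integer(p + 22),
      strand = "-",
      pam = revcomp(substr_vec(cds, p, p + 2))
    ) |> dplyr::arrange(.data$start)
  } else {
    # protospacer+PAM on the coding strand: "NGG" with GG at g..g+1
    g <- overlapping_starts(cds, "GG")
    g <- g[g - 21 >= span[1] & g + 1 <= span[2]]
    if (!length(g)) return(empty)
    guide <- substr_vec(cds, g - 21, g - 2)
    tibble::tibble(
      guide = guide,
      seed12 = substr(guide, 9, 20),
      start = as.integer(g - 21), end = as.integer(g + 1),
      strand = "+",
      pam = substr_vec(cds, g - 1, g + 1)
    ) |> dplyr::arrange(.data$start)
  }
}

#' Design a knockdown guide against an endogenous CDS
#'
#' Enumerates windowed protospacers ([enumerate_cds_protospacers()]), filters
#' them by the guide GC bounds, screens each 12-nt seed against the genome
#' while excluding the intended target locus itself (the on-target hit is
#' expected, not an off-target), and returns the 5'-most survivor. The full
#' per-candidate report is attached.
#'
#' @inheritParams enumerate_cds_protospacers
#' @param genome Genome (named character vector / `DNAStringSet`) to screen
#'   against, or a prebuilt `genome_index`.
#' @param gene_name Label for the returned design.
#' @param locus Optional `list(contig =, start =)` giving the 1-based position
#'   of the CDS in the genome; index hits overlapping the CDS span there are
#'   excluded from the off-target count.
#' @param gc_bounds Inclusive GC bounds for the 20-nt guide.
#' @param seed_length Screen seed length (default 12).
#' @return An `sgrna_design` (fields `name`, `guide`, `seed12`,
#'   `targeted_strand`, `source_promoter = NA`) with attributes `report`
#'   (per-candidate tibble) and `off_target_hits`.
#' @export
design_knockdown_guide <- function(cds, codon_window, genome,
                                   strand_pref = c("non-template", "template"),
                                   gene_name = "gene", locus = NULL,
                                   gc_bounds = c(0.35, 0.80), seed_length = 12) {
  strand_pref <- match.arg(strand_pref)
  cands <- enumerate_cds_protospacers(cds, codon_window, strand_pref)
  if (nrow(cands) == 0) {
    rlang::abort("no candidate protospacer in the codon window on the required strand",
                 class = "crisprgates_unsatisfiable")
  }
  index <- if (inherits(genome, "genome_index")) genome else
    build_pam_seed_index(genome, seed_length = seed_length)
  cds_len <- nchar(cds)
  report <- cands |>
    dplyr::mutate(
      gc = vapply(.data$guide, gc_fraction, numeric(1), USE.NAMES = FALSE),
      gc_ok = .data$gc >= gc_bounds[1] & .data$gc <= gc_bounds[2],
      off_targets = vapply(.data$seed12, function(sd) {
        rep <- screen_seed(index, sd)
        hits <- rep$near_hits[rep$near_hits$distance == 0, ]
        if (!is.null(locus)) {
          within <- hits$contig == locus$contig &
            hits$pos >= locus$start - 1 &
            hits$pos + attr(index, "seed_length") <= locus$start - 1 + cds_len
          hits <- hits[!within, ]
        }
        nrow(hits)
      }, numeric(1), USE.NAMES = FALSE)
    ) |>
    dplyr::mutate(pass = .data$gc_ok & .data$off_targets == 0)
  surv <- dplyr::filter(report, .data$pass)
  if (nrow(surv) == 0) {
    rlang::abort(
      sprintf("no surviving candidate (of %d: %d failed GC, %d had off-target hits)",
              nrow(report), sum(!report$gc_ok), sum(report$gc_ok & report$off_targets > 0)),
      class = "crisprgates_unsatisfiable"
    )
  }
  pick <- surv[1, ]   # 5'-most in the window (rows are position-sorted)
  design <- structure(
    list(name = paste0("sgRNA-", gene_name, "-", if (strand_pref == "non-template") "NT" else "T"),
         guide = pick$guide, seed12 = pick$seed12,
         targeted_strand = strand_pref, source_promoter = NA_character_),
    class = "sgrna_design"
  )
  attr(design, "report") <- report
  attr(design, "off_target_hits") <- pick$off_targets
  design
}
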
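#' Generate a candidate operator sequence
#'
#' Draws random DNA words of the requested length with a tunable GC content
#' probability until one passes the G-run filter ([has_g_run()]). The 13-bp
#' operator is the channel-defining word placed between the -35 and -10
#' hexamers of a repressible promoter.
#'
#' @param rng_seed Integer seed; the draw is deterministic given the seed.
#' @param length Operator length in bp (default 13).
#' @param gc_prob Per-base probability of drawing G or C (default 0.5).
#' @param max_g_run Longest permitted G run (default 3).
#' @param max_attempts Cap on regeneration attempts before aborting.
#' @return An `operator_candidate` object: fields `sequence`, `origin_seed`,
#'   `attempts`.
#' @export
#' @examples
#' generate_operator(1)
generate_operator <- function(rng_seed, length = 13, gc_prob = 0.5,
                              max_g_run = 3, max_attempts = 10000L) {
  stopifnot(length >= 1, gc_prob >= 0, gc_prob <= 1)
  withr::with_seed(rng_seed, {
    for (attempt in seq_len(max_attempts)) {
      s <- draw_dna(length, gc_prob)
      if (!has_g_run(s, max_g_run)) {
        return(new_operator_candidate(s, rng_seed, attempt))
      }
    }
    rlang::abort(
      sprintf("no operator passing the G-run filter in %d attempts", max_attempts),
      class = "crisprgates_unsatisfiable"
    )
  })
}

new_operator_candidate <- function(sequence, origin_seed = NA_integer_, attempts = NA_integer_) {
  structure(
    list(sequence = sequence, origin_seed = origin_seed, attempts = attempts),
    class = "operator_candidate"
  )
}

#' @export
print.operator_candidate <- function(x, ...) {
  cat("<operator_candidate> ", x$sequence, " (", nchar(x$sequence), " bp, seed ",
      x$origin_seed, ")\n", sep = "")
  invisible(x)
}

as_operator_sequence <- function(operator) {
  if (inherits(operator, "operator_candidate")) operator$sequence else {
    assert_dna(toupper(operator), arg = "operator")
    toupper(operator)
  }
}

#' Guide GC-content filter
#'
#' A 20-nt guide is discarded when its GC content is below 35% or above 80%;
#' the boundary values themselves pass (the discard rule uses strict
#' inequalities).
#'
#' @param guide 20-nt DNA string.
#' @param bounds Length-2 numeric, inclusive GC bounds (default `c(0.35, 0.80)`).
#' @return `TRUE` if the guide passes.
#' @export
guide_gc_ok <- function(guide, bounds = c(0.35, 0.80)) {
  guide <- toupper(guide)
  assert_dna(guide, arg = "guide")
  if (nchar(guide) != 20) {
    rlang::abort("guide must be 20 nt", class = "crisprgates_invalid_length")
  }
  g <- gc_fraction(guide)
  g >= bounds[1] && g <= bounds[2]
}

#' Default sigma-70 promoter scaffold
#'
#' A constitutive sigma-70 scaffold with consensus-style -35 (`TTTACA`) and
#' -10 (`TATAAT`) hexamers and short flanking context ending at the
#' transcription start site (+1). The operator is inserted between the
#' hexamers as `CC` + operator + `GG`, creating a forward PAM whose GG are
#' spacer positions 16-17 and a reverse PAM whose GG are the complements of
#' spacer positions 1-2. All fields are user-replaceable.
#'
#' @param upstream,minus35,minus10,downstream Scaffold parts; `downstream`
#'   ends at +1 (its final base is the transcription start).
#' @param name Scaffold label.
#' @return A list usable as the `scaffold` argument of [assemble_promoter()].
#' @export
default_scaffold <- function(upstream = "GGTACC",
                             minus35 = "TTTACA",
                             minus10 = "TATAAT",
                             downstream = "GCTAGCA",
                             name = "J23101-style") {
  list(name = name, upstream = toupper(upstream), minus35 = toupper(minus35),
       minus10 = toupper(minus10), downstream = toupper(downstream))
}

#' Assemble a repressible promoter around an operator
#'
#' Embeds a 13-bp operator in the 17-bp spacer between the scaffold's -35 and
#' -10 hexamers as `CC` + operator + `GG`. The trailing `GG` forms a forward
#' NGG PAM (N = the operator's last base) and the leading `CC` forms a reverse
#' NGG PAM on the bottom strand, so the promoter can be targeted on either
#' strand.
#'
#' @param operator An [operator_candidate][generate_operator] or DNA string
#'   passing the G-run filter.
#' @param scaffold Scaffold parts list, see [default_scaffold()].
#' @param name Promoter name.
#' @return A `promoter_design` object with fields `name`, `operator`,
#'   `upstream_context`, `minus35`, `spacer`, `minus10`, `downstream_context`,
#'   `tss_offset` and `full_sequence`.
#' @export
#' @examples
#' assemble_promoter("ATCGATCGATCGA")
assemble_promoter <- function(operator, scaffold = default_scaffold(), name = "P") {
  op <- as_operator_sequence(operator)
  if (has_g_run(op)) {
    rlang::abort("operator fails the G-run filter", class = "crisprgates_invalid_operator")
  }
  if (nchar(scaffold$minus35) != 6 || nchar(scaffold$minus10) != 6) {
    rlang::abort("scaffold hexamers must be 6 nt", class = "crisprgates_invalid_scaffold")
  }
  spacer <- paste0("CC", op, "GG")
  full <- paste0(scaffold$upstream, scaffold$minus35, spacer,
                 scaffold$minus10, scaffold$downstream)
  structure(
    list(
      name = name,
      operator = op,
      upstream_context = scaffold$upstream,
      minus35 = scaffold$minus35,
      spacer = spacer,
      minus10 = scaffold$minus10,
      downstream_context = scaffold$downstream,
      tss_offset = nchar(full),    # +1 is the final base of the promoter
      full_sequence = full,
      scaffold_name = scaffold$name
    ),
    class = "promoter_design"
  )
}

#' @export
print.promoter_design <- function(x, ...) {
  cat("<promoter_design> ", x$name, "\n  operator: ", x$operator,
      "\n  spacer:   ", x$spacer, " (", nchar(x$spacer), " bp)",
      "\n  sequence: ", x$full_sequence, "\n", sep = "")
  invisible(x)
}

#' Decompose a promoter back into its parts
#'
#' Inverse of [assemble_promoter()]: recovers the operator and flanking parts
#' from `full_sequence` by the stored part lengths and verifies the
#' concatenation identity.
#'
#' @param promoter A `promoter_design`.
#' @return List with `upstream`, `minus35`, `spacer`, `operator`, `minus10`,
#'   `downstream`.
#' @export
decompose_promoter <- function(promoter) {
  stopifnot(inherits(promoter, "promoter_design"))
  s <- promoter$full_sequence
  n_up <- nchar(promoter$upstream_context)
  spacer <- substr(s, n_up + 7, n_up + 6 + 17)
  parts <- list(
    upstream  = substr(s, 1, n_up),
    minus35   = substr(s, n_up + 1, n_up + 6),
    spacer    = spacer,
    operator  = substr(spacer, 3, 15),
    minus10   = substr(s, n_up + 24, n_up + 29),
    downstream = substr(s, n_up + 30, nchar(s))
  )
  if (paste0(parts$upstream, parts$minus35, parts$spacer, parts$minus10,
             parts$downstream) != s) {
    rlang::abort("promoter does not round-trip its parts",
                 class = "crisprgates_invalid_promoter")
  }
  parts
}

#' Derive the template- and non-template-targeting guides of a promoter
#'
#' Each repressible promoter yields two 20-nt guides. The T variant's
#' protospacer lies on the promoter's forward (non-template) strand
#' immediately 5' of the forward PAM, covering the -35 hexamer plus spacer
#' positions 1-14; its guide base-pairs with the template strand. The NT
#' variant's protospacer lies on the bottom (template) strand 5' of the
#' reverse PAM, covering spacer positions 4-17 plus the -10 hexamer
#' (reverse-complemented); its guide base-pairs with the non-template strand.
#' Each 12-nt PAM-proximal seed falls entirely within the operator (or its
#' reverse complement).
#'
#' @param promoter A `promoter_design`.
#' @return Named list of two `sgrna_design` objects, `T` and `NT`, each with
#'   fields `name`, `guide`, `seed12`, `targeted_strand`, `source_promoter`.
#' @export
derive_guides <- function(promoter) {
  stopifnot(inherits(promoter, "promoter_design"))
  sp <- promoter$spacer
  if (substr(sp, 16, 17) != "GG" || substr(sp, 1, 2) != "CC") {
    rlang::abort("promoter spacer lacks the forward/reverse PAM registers",
                 class = "crisprgates_invalid_promoter")
  }
  guide_t <- paste0(promoter$minus35, substr(sp, 1, 14))
  guide_nt <- revcomp(paste0(substr(sp, 4, 17), promoter$minus10))
  mk <- function(guide, variant, strand) {
    structure(
      list(
        name = paste0("sgRNA-", promoter$name, variant),
        guide = guide,
        seed12 = substr(guide, 9, 20),
        targeted_strand = strand,
        source_promoter = promoter$name
      ),
      class = "sgrna_design"
    )
  }
  list(T = mk(guide_t, "T", "template"),
       NT = mk(guide_nt, "NT", "non-template"))
}

#' @export
print.sgrna_design <- function(x, ...) {
  cat("<sgrna_design> ", x$name, "\n  guide:  ", x$guide,
      "\n  seed12: ", x$seed12, " (targets ", x$targeted_strand, " strand)\n",
      sep = "")
  invisible(x)
}

#' Size of the operator design space
#'
#' Exact count (dynamic programming) of DNA words of the given length with no
#' G run longer than `max_g_run`, and the size of the seed space that bounds
#' how many mutually orthogonal guide:promoter channels are available. With
#' a 12-nt specificity-determining seed the channel capacity is
#' 4^12 ~ 1.7e7, i.e. on the order of 10^7 orthogonal pairs.
#'
#' @param length Word length (default 13).
#' @param max_g_run Longest permitted G run (default 3).
#' @param seed_length Seed length used for the capacity bound (default 12).
#' @return Tibble with `n_words` (G-run-filtered words of `length`),
#'   `n_total` (4^length) and `seed_capacity` (4^seed_length).
#' @export
operator_space <- function(length = 13, max_g_run = 3, seed_length = 12) {
  # states: current trailing G-run length 0..max_g_run
  counts <- c(1, rep(0, max_g_run))
  for (i in seq_len(length)) {
    nxt <- numeric(max_g_run + 1)
    nxt[1] <- 3 * sum(counts)            # A, C or T resets the run
    for (r in seq_len(max_g_run)) nxt[r + 1] <- counts[r]  # extend with G
    counts <- nxt
  }
  tibble::tibble(
    n_words = sum(counts),
    n_total = 4^length,
    seed_capacity = 4^seed_length
  )
}
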
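DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, any case).
#' @return Character vector of reverse complements, upper case.
#' @export
#' @examples
#' revcomp("ATGC")
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
  unname(out)
}

assert_dna <- function(x, allow_n = FALSE, arg = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (length(x) != 1 || is.na(x) || !grepl(pat, x)) {
    rlang::abort(sprintf("`%s` must be a single DNA string over {A,C,G,T%s}",
                         arg, if (allow_n) ",N" else ""),
                 class = "crisprgates_invalid_dna")
  }
  invisible(x)
}

#' GC fraction of a DNA sequence
#'
#' @param sequence Non-empty DNA string.
#' @return Fraction of G and C bases, in `[0, 1]`.
#' @export
#' @examples
#' gc_fraction("ATGC")
gc_fraction <- function(sequence) {
  sequence <- toupper(sequence)
  assert_dna(sequence)
  n <- nchar(sequence)
  if (n == 0) rlang::abort("empty sequence", class = "crisprgates_invalid_dna")
  (n - nchar(gsub("[GC]", "", sequence))) / n
}

#' Detect disallowed guanine runs
#'
#' Oligos containing runs of more than `max_run` consecutive G are prone to
#' G-quadruplex formation and are rejected at the operator-design stage. The
#' check applies to the given (forward) strand only.
#'
#' @param sequence Non-empty DNA string.
#' @param max_run Longest permitted G run (default 3; a run of exactly
#'   `max_run` passes).
#' @return `TRUE` if a run of strictly more than `max_run` G exists.
#' @export
#' @examples
#' has_g_run("ATGGGGA") # TRUE
#' has_g_run("GGG")     # FALSE
has_g_run <- function(sequence, max_run = 3) {
  sequence <- toupper(sequence)
  assert_dna(sequence)
  if (nchar(sequence) == 0) rlang::abort("empty sequence", class = "crisprgates_invalid_dna")
  # run-length route, kept independent of the regex oracle used in tests
  r <- rle(strsplit(sequence, "", fixed = TRUE)[[1]])
  any(r$values == "G" & r$lengths > max_run)
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# internal: draw one random DNA string from the current RNG stream
draw_dna <- function(n, gc_prob = 0.5) {
  if (n == 0) return("")
  p <- c((1 - gc_prob) / 2, gc_prob / 2, gc_prob / 2, (1 - gc_prob) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}
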
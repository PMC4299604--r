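#' Read a parts library from YAML
#'
#' A parts library supplies the sequences shared by every transcription unit:
#' input promoters (ending exactly at +1, so no extra nucleotides are added
#' to the sgRNA 5' end), the dCas9 handle at which construction oligo pairs
#' anneal, terminators with their dimensionless strength annotations, the
#' Type IIs enzyme used for Golden Gate assembly, and the 4-nt fusion scars.
#'
#' @param path YAML file; default is the packaged library
#'   (`default_parts.yaml`).
#' @return A `parts_library` object.
#' @export
read_parts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_parts.yaml", package = "crisprgates")
  }
  raw <- yaml::read_yaml(path)
  parts <- structure(raw, class = "parts_library")
  validate_parts(parts)
}

#' @rdname read_parts
#' @export
default_parts <- function() read_parts(NULL)

validate_parts <- function(parts) {
  for (nm in names(parts$promoters)) {
    assert_dna(toupper(parts$promoters[[nm]]$sequence), arg = paste0("promoter ", nm))
    parts$promoters[[nm]]$sequence <- toupper(parts$promoters[[nm]]$sequence)
  }
  assert_dna(toupper(parts$dcas9_handle), arg = "dcas9_handle")
  parts$dcas9_handle <- toupper(parts$dcas9_handle)
  for (nm in names(parts$terminators)) {
    t <- parts$terminators[[nm]]
    assert_dna(toupper(t$sequence), arg = paste0("terminator ", nm))
    if (is.null(t$strength) || t$strength <= 0) {
      rlang::abort(sprintf("terminator %s must have positive strength", nm),
                   class = "crisprgates_invalid_parts")
    }
    parts$terminators[[nm]]$sequence <- toupper(t$sequence)
  }
  scars <- toupper(unlist(parts$scars))
  if (anyDuplicated(scars) || length(intersect(scars, revcomp(scars))) > 0) {
    rlang::abort("scars must be pairwise distinct and distinct from their reverse complements",
                 class = "crisprgates_invalid_parts")
  }
  parts$scars <- scars
  parts$type_iis$recognition <- toupper(parts$type_iis$recognition)
  parts$type_iis$spacer <- toupper(parts$type_iis$spacer)
  parts
}

#' @export
print.parts_library <- function(x, ...) {
  cat("<parts_library>\n",
      "  promoters:  ", paste(names(x$promoters), collapse = ", "), "\n",
      "  terminators:", paste(names(x$terminators), collapse = ", "), "\n",
      "  handle:     ", nchar(x$dcas9_handle), " nt; enzyme ", x$type_iis$name,
      "; ", length(x$scars), " scars\n", sep = "")
  invisible(x)
}

as_guide_sequence <- function(guide) {
  g <- if (inherits(guide, "sgrna_design")) guide$guide else toupper(guide)
  assert_dna(g, arg = "guide")
  if (nchar(g) != 20) {
    rlang::abort("guide must be 20 nt", class = "crisprgates_invalid_length")
  }
  g
}

#' Build an sgRNA transcription unit
#'
#' Concatenates input promoter, 20-nt guide, dCas9 handle and terminator into
#' the DNA of one gate leg. Because the promoter ends at +1, the predicted
#' transcript starts at guide base 1: guide, handle, then terminator.
#'
#' @param promoter_name Name of an input promoter in `parts`.
#' @param guide An `sgrna_design` or 20-nt DNA string.
#' @param terminator_name Name of a terminator in `parts`.
#' @param parts A `parts_library`.
#' @return A `transcription_unit` with fields `input_promoter`, `guide`,
#'   `guide_name`, `terminator`, `sequence` and `transcript` (predicted sgRNA,
#'   DNA alphabet).
#' @export
build_transcription_unit <- function(promoter_name, guide, terminator_name,
                                     parts = default_parts()) {
  if (!promoter_name %in% names(parts$promoters)) {
    rlang::abort(sprintf("unknown promoter '%s'", promoter_name),
                 class = "crisprgates_unknown_part")
  }
  if (!terminator_name %in% names(parts$terminators)) {
    rlang::abort(sprintf("unknown terminator '%s'", terminator_name),
                 class = "crisprgates_unknown_part")
  }
  g <- as_guide_sequence(guide)
  prom <- parts$promoters[[promoter_name]]$sequence
  term <- parts$terminators[[terminator_name]]$sequence
  seq <- paste0(prom, g, parts$dcas9_handle, term)
  structure(
    list(
      input_promoter = promoter_name,
      guide = g,
      guide_name = if (inherits(guide, "sgrna_design")) guide$name else "guide",
      terminator = terminator_name,
      sequence = seq,
      transcript = paste0(g, parts$dcas9_handle, term)
    ),
    class = "transcription_unit"
  )
}

#' @export
print.transcription_unit <- function(x, ...) {
  cat("<transcription_unit> ", x$input_promoter, " -> ", x$guide_name,
      " -> ", x$terminator, " (", nchar(x$sequence), " bp)\n", sep = "")
  invisible(x)
}
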
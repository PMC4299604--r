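flank5 <- function(parts, scar) {
  paste0(parts$type_iis$recognition, parts$type_iis$spacer, scar)
}

flank3 <- function(parts, scar) {
  paste0(scar, revcomp(parts$type_iis$spacer), revcomp(parts$type_iis$recognition))
}

#' Split a transcription unit into its two construction oligos
#'
#' The flanked transcription unit (Type IIs site, scar, promoter, guide,
#' handle, terminator, scar, Type IIs site) is encoded as two single-stranded
#' oligos that share the dCas9 handle: the sense oligo runs from the 5' flank
#' through the handle, and the antisense oligo is the reverse complement of
#' handle through the 3' flank. Annealing the pair at the handle and extending
#' reconstructs the full double-stranded fragment.
#'
#' @param tu A `transcription_unit`.
#' @param parts A `parts_library` supplying the Type IIs site and scar set.
#' @param max_len Length cap for either oligo (default 200 nt); exceeding it
#'   raises an error reporting the overage.
#' @param scar5,scar3 4-nt fusion scars for the two flanks (defaults: the
#'   first two scars of the library).
#' @return An `oligo_pair` with `sense`, `antisense`, `overlap` (the handle),
#'   `lengths` and `fragment` (the full flanked double-stranded sequence).
#' @export
emit_oligo_pair <- function(tu, parts = default_parts(), max_len = 200,
                            scar5 = parts$scars[1], scar3 = parts$scars[2]) {
  stopifnot(inherits(tu, "transcription_unit"))
  handle <- parts$dcas9_handle
  prom <- parts$promoters[[tu$input_promoter]]$sequence
  term <- parts$terminators[[tu$terminator]]$sequence
  sense <- paste0(flank5(parts, scar5), prom, tu$guide, handle)
  antisense <- revcomp(paste0(handle, term, flank3(parts, scar3)))
  fragment <- paste0(flank5(parts, scar5), tu$sequence, flank3(parts, scar3))
  lens <- c(sense = nchar(sense), antisense = nchar(antisense))
  if (any(lens > max_len)) {
    over <- lens[lens > max_len] - max_len
    rlang::abort(
      sprintf("oligo length cap %d nt exceeded: %s", max_len,
              paste(names(over), "+", over, "nt", collapse = ", ")),
      class = "crisprgates_oligo_too_long",
      overage = over
    )
  }
  structure(
    list(sense = sense, antisense = antisense, overlap = handle,
         lengths = lens, fragment = fragment),
    class = "oligo_pair"
  )
}

#' @export
print.oligo_pair <- function(x, ...) {
  cat("<oligo_pair> sense ", x$lengths[["sense"]], " nt / antisense ",
      x$lengths[["antisense"]], " nt, overlap ", nchar(x$overlap), " nt\n",
      sep = "")
  invisible(x)
}

#' Anneal two oligos at their shared overlap and extend
#'
#' In-silico reconstruction oracle for [emit_oligo_pair()]: finds the longest
#' suffix of the sense oligo equal to a prefix of the reverse complement of
#' the antisense oligo, and returns the extended double-stranded sequence.
#'
#' @param sense,antisense Single-stranded oligos.
#' @param min_overlap Minimum acceptable overlap (default 10 nt).
#' @return The reconstructed top-strand sequence.
#' @export
anneal_extend <- function(sense, antisense, min_overlap = 10) {
  a <- toupper(sense)
  b <- revcomp(antisense)
  na <- nchar(a)
  kmax <- min(na, nchar(b))
  for (k in kmax:1) {
    if (substr(a, na - k + 1, na) == substr(b, 1, k)) {
      if (k < min_overlap) break
      return(paste0(a, substr(b, k + 1, nchar(b))))
    }
  }
  rlang::abort("oligos share no overlap of the required length",
               class = "crisprgates_no_overlap")
}

#' Simulate Type IIs digestion of a flanked fragment
#'
#' Expects exactly one recognition site per strand, oriented inward; returns
#' the released middle fragment with its two 4-nt fusion overhangs (recorded
#' as top-strand words, so two compatible ends carry the same word). A
#' fragment with additional internal sites is rejected with their positions.
#'
#' @param fragment Flanked double-stranded sequence (top strand).
#' @param parts A `parts_library`.
#' @param name Label carried through to ligation.
#' @param role `"insert"` or `"backbone"`.
#' @return A `gg_fragment`: list with `name`, `role`, `top` (overhang to
#'   overhang), `ov5`, `ov3`.
#' @export
digest_type_iis <- function(fragment, parts = default_parts(), name = "fragment",
                            role = "insert") {
  f <- toupper(fragment)
  rec <- parts$type_iis$recognition
  sp <- nchar(parts$type_iis$spacer)
  fwd <- overlapping_starts(f, rec)
  rev <- overlapping_starts(f, revcomp(rec))
  if (length(fwd) != 1 || length(rev) != 1) {
    extra <- c(if (length(fwd) > 1) fwd[-1], if (length(rev) > 1) rev[-length(rev)])
    rlang::abort(
      sprintf("fragment '%s' must contain exactly one inward site per strand (found %d forward, %d reverse%s)",
              name, length(fwd), length(rev),
              if (length(extra)) paste0("; internal at ", paste(extra, collapse = ", ")) else ""),
      class = "crisprgates_internal_site"
    )
  }
  t <- fwd
  b <- rev
  o5s <- t + 6 + sp                       # first base of the 4-nt 5' overhang
  o3e <- b - 1 - sp                       # last base of the right overhang
  if (o3e - 3 <= o5s) {
    rlang::abort("sites are not oriented inward around a core",
                 class = "crisprgates_internal_site")
  }
  structure(
    list(name = name, role = role,
         top = substr(f, o5s, o3e),
         ov5 = substr(f, o5s, o5s + 3),
         ov3 = substr(f, o3e - 3, o3e)),
    class = "gg_fragment"
  )
}

#' Ligate digested fragments into a single circular product
#'
#' Joins fragments by matching 4-nt overhangs, starting from the backbone
#' fragment; the input order of the fragments is irrelevant because the scars
#' dictate the assembly order. Errors on scar collisions (an overhang shared
#' by two fragments), unused fragments, or failure to circularize.
#'
#' @param fragments List of `gg_fragment`s, exactly one with role
#'   `"backbone"`.
#' @return List with `product` (circular sequence linearized at the backbone
#'   core start) and `order` (fragment names in assembled order).
#' @export
ligate_fragments <- function(fragments) {
  roles <- vapply(fragments, `[[`, "", "role")
  if (sum(roles == "backbone") != 1) {
    rlang::abort("exactly one backbone fragment required",
                 class = "crisprgates_invalid_assembly")
  }
  ov5s <- vapply(fragments, `[[`, "", "ov5")
  if (anyDuplicated(ov5s)) {
    rlang::abort(sprintf("scar collision: overhang %s used by multiple fragments",
                         ov5s[duplicated(ov5s)][1]),
                 class = "crisprgates_scar_collision")
  }
  by_ov5 <- stats::setNames(seq_along(fragments), ov5s)
  start <- which(roles == "backbone")
  cur <- fragments[[start]]
  product <- cur$top
  order <- cur$name
  used <- start
  repeat {
    nxt_i <- unname(by_ov5[cur$ov3])
    if (is.na(nxt_i)) {
      rlang::abort(sprintf("no fragment carries overhang %s; assembly cannot close", cur$ov3),
                   class = "crisprgates_invalid_assembly")
    }
    if (nxt_i == start) break
    if (nxt_i %in% used) {
      rlang::abort("assembly revisits a fragment; scar graph is not a simple cycle",
                   class = "crisprgates_invalid_assembly")
    }
    cur <- fragments[[nxt_i]]
    used <- c(used, nxt_i)
    product <- paste0(product, substr(cur$top, 5, nchar(cur$top)))
    order <- c(order, cur$name)
  }
  if (length(used) != length(fragments)) {
    rlang::abort("not all fragments were incorporated into the circular product",
                 class = "crisprgates_invalid_assembly")
  }
  # close the circle: the trailing scar is the same molecule as the leading one
  product <- substr(product, 1, nchar(product) - 4)
  list(product = product, order = order)
}

#' Plan a one-pot Golden Gate assembly
#'
#' Assigns fusion scars to the junctions of an ordered set of transcription
#' units plus a backbone, builds the Type IIs-flanked fragments, simulates
#' digestion and ligation, and returns the predicted circular construct.
#' Fragments with unintended internal Type IIs sites and scar collisions are
#' rejected with a report.
#'
#' @param tus List of `transcription_unit`s (may be empty).
#' @param backbone Backbone core DNA (the vector sequence between its two
#'   junction scars).
#' @param parts A `parts_library`.
#' @param scars Character vector of `length(tus) + 1` fusion scars; defaults
#'   to the first scars of the library.
#' @return An `assembly_plan`: list with `product` (circular, linearized at
#'   the backbone), `order`, `scars` (junction assignments), `fragments`
#'   (flanked input fragments) and `tus`.
#' @export
plan_golden_gate <- function(tus, backbone, parts = default_parts(), scars = NULL) {
  n <- length(tus)
  backbone <- toupper(backbone)
  assert_dna(backbone, arg = "backbone")
  if (is.null(scars)) {
    if (length(parts$scars) < n + 1) {
      rlang::abort(sprintf("need %d distinct scars, parts library has %d",
                           n + 1, length(parts$scars)),
                   class = "crisprgates_invalid_assembly")
    }
    scars <- parts$scars[seq_len(n + 1)]
  }
  scars <- toupper(scars)
  if (length(scars) != n + 1 || anyDuplicated(scars) ||
      length(intersect(scars, revcomp(scars))) > 0) {
    rlang::abort("scars must be n_tus + 1 distinct words, distinct from their reverse complements",
                 class = "crisprgates_scar_collision")
  }
  flanked <- character(0)
  pieces <- list()
  for (i in seq_len(n)) {
    fr <- paste0(flank5(parts, scars[i]), tus[[i]]$sequence, flank3(parts, scars[i + 1]))
    flanked[[paste0("tu", i)]] <- fr
    pieces[[i]] <- digest_type_iis(fr, parts, name = paste0("tu", i), role = "insert")
  }
  fr_bb <- paste0(flank5(parts, scars[n + 1]), backbone, flank3(parts, scars[1]))
  flanked[["backbone"]] <- fr_bb
  pieces[[n + 1]] <- digest_type_iis(fr_bb, parts, name = "backbone", role = "backbone")
  lig <- ligate_fragments(pieces)
  structure(
    list(product = lig$product, order = lig$order, scars = scars,
         fragments = flanked, pieces = pieces, backbone = backbone,
         tu_sequences = vapply(tus, function(t) t$sequence, character(1))),
    class = "assembly_plan"
  )
}

#' @export
print.assembly_plan <- function(x, ...) {
  cat("<assembly_plan> ", length(x$tu_sequences), " transcription unit(s) + backbone -> ",
      nchar(x$product), " bp circular product\n  order: ",
      paste(x$order, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Decompose an assembled product back into its fragments
#'
#' Slices the circular product at the plan's junction scars (using the
#' recorded part lengths) and verifies that the slices reproduce the backbone
#' and every transcription unit in order.
#'
#' @param plan An `assembly_plan`.
#' @return List with `backbone` and `tus` (character vector, in assembly
#'   order).
#' @export
decompose_assembly <- function(plan) {
  stopifnot(inherits(plan, "assembly_plan"))
  n <- length(plan$tu_sequences)
  scars <- plan$scars
  p <- plan$product
  # layout: scar[n+1] | backbone | scar[1] | tu1 | scar[2] | ... | scar[n] | tun
  pos <- 1
  take <- function(len) {
    out <- substr(p, pos, pos + len - 1)
    pos <<- pos + len
    out
  }
  if (take(4) != scars[n + 1]) {
    rlang::abort("product does not start at the expected junction scar",
                 class = "crisprgates_invalid_assembly")
  }
  backbone <- take(nchar(plan$backbone))
  tus <- character(n)
  for (i in seq_len(n)) {
    if (take(4) != scars[i]) {
      rlang::abort(sprintf("junction %d scar mismatch", i),
                   class = "crisprgates_invalid_assembly")
    }
    tus[i] <- take(nchar(plan$tu_sequences[i]))
  }
  if (pos != nchar(p) + 1) {
    rlang::abort("product has unexplained residual sequence",
                 class = "crisprgates_invalid_assembly")
  }
  list(backbone = backbone, tus = tus)
}

#' Synthetic demonstration backbone
#'
#' A short synthetic vector core free of internal Type IIs sites, for
#' assembly demonstrations and tests.
#'
#' @return DNA string.
#' @export
demo_backbone <- function() {
  paste0("ATCCTAGGACCTATTCGGAACTGAAAGCGCATACCGTCGATTTCGCGCAT",
         "TAGCAACCTGGTAGTTCACGATCCATTGCTAAGCGTTCCAGATACGGATA")
}
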
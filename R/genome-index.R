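as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  if (is.character(genome)) {
    genome <- toupper(genome)
    if (is.null(names(genome))) {
      names(genome) <- if (length(genome)) paste0("contig", seq_along(genome)) else character(0)
    }
    for (s in genome) assert_dna(s, allow_n = TRUE, arg = "genome")
    return(genome)
  }
  rlang::abort("genome must be a (named) character vector or DNAStringSet",
               class = "crisprgates_invalid_genome")
}

empty_index_tbl <- function() {
  tibble::tibble(seed = character(0), contig = character(0),
                 pos = integer(0), strand = character(0))
}

new_genome_index <- function(tbl, seed_length, genome_lengths) {
  tbl <- dplyr::arrange(tbl, .data$contig, .data$pos, .data$strand, .data$seed)
  structure(tbl, class = c("genome_index", class(tbl)),
            seed_length = seed_length, genome_lengths = genome_lengths)
}

#' Index all PAM-adjacent seed words of a genome
#'
#' For every NGG protospacer-adjacent motif on either strand, records the
#' `seed_length` bases immediately 5' of the N on the PAM's strand. These are
#' the words a guide's PAM-proximal seed could pair with, so a designed seed
#' absent from the index has no perfect PAM-adjacent match in the genome.
#' Words or PAM N positions containing `N` never match and are skipped, as
#' are motifs too close to a contig end to have a full-length seed.
#'
#' @param genome Named character vector (or `DNAStringSet`) of contigs over
#'   A/C/G/T/N.
#' @param seed_length Seed word length (default 12).
#' @return A `genome_index`: a tibble with columns `seed`, `contig`,
#'   `pos` (0-based position of the seed span's leftmost base on forward
#'   coordinates) and `strand` (`+`/`-`), plus attributes `seed_length` and
#'   `genome_lengths`.
#' @export
#' @examples
#' build_pam_seed_index(c(chr = "AAAAAAAAAAAATGGTTT"))
build_pam_seed_index <- function(genome, seed_length = 12) {
  if (seed_length < 1) rlang::abort("seed_length must be >= 1",
                                    class = "crisprgates_invalid_argument")
  genome <- as_genome(genome)
  L <- as.integer(seed_length)
  rows <- purrr::imap(genome, function(s, ctg) {
    len <- nchar(s)
    out <- list()
    # forward: GG at p..p+1, PAM N at p-1, seed spans (p-1-L)..(p-2), 1-based
    p <- overlapping_starts(s, "GG")
    p <- p[p - 1 - L >= 1 & p - 1 >= 1]
    if (length(p)) {
      keep <- substr_vec(s, p - 1, p - 1) %in% DNA_BASES
      p <- p[keep]
    }
    if (length(p)) {
      seed <- substr_vec(s, p - 1 - L, p - 2)
      ok <- !grepl("N", seed, fixed = TRUE)
      if (any(ok)) {
        out$fwd <- tibble::tibble(seed = seed[ok], contig = ctg,
                                  pos = as.integer(p[ok] - 2 - L), strand = "+")
      }
    }
    # reverse: CC at p..p+1 on the forward strand, PAM N at p+2,
    # seed spans (p+3)..(p+2+L) read as its reverse complement
    p <- overlapping_starts(s, "CC")
    p <- p[p + 2 + L <= len]
    if (length(p)) {
      keep <- substr_vec(s, p + 2, p + 2) %in% DNA_BASES
      p <- p[keep]
    }
    if (length(p)) {
      span <- substr_vec(s, p + 3, p + 2 + L)
      ok <- !grepl("N", span, fixed = TRUE)
      if (any(ok)) {
        out$rev <- tibble::tibble(seed = revcomp(span[ok]), contig = ctg,
                                  pos = as.integer(p[ok] + 2), strand = "-")
      }
    }
    dplyr::bind_rows(out)
  })
  tbl <- dplyr::bind_rows(rows)
  if (nrow(tbl) == 0) tbl <- empty_index_tbl()
  new_genome_index(tbl, L, vapply(genome, nchar, integer(1)))
}

overlapping_starts <- function(s, pat) {
  m <- gregexpr(paste0("(?=", pat, ")"), s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

substr_vec <- function(s, start, stop) substring(s, start, stop)

#' Naive position-by-position PAM seed scan
#'
#' Test oracle for [build_pam_seed_index()]: walks every position of every
#' contig on the forward strand, then walks the reverse complement of each
#' contig with the same forward-strand rule and maps coordinates back. Same
#' contract and output convention as the indexed scan, by a deliberately
#' independent route.
#'
#' @inheritParams build_pam_seed_index
#' @return A `genome_index`.
#' @export
brute_force_seed_scan <- function(genome, seed_length = 12) {
  if (seed_length < 1) rlang::abort("seed_length must be >= 1",
                                    class = "crisprgates_invalid_argument")
  genome <- as_genome(genome)
  L <- as.integer(seed_length)
  scan_forward <- function(s) {
    len <- nchar(s)
    hits <- list()
    if (len >= L + 3) {
      for (i in (L + 1):(len - 2)) {   # i = 1-based position of the PAM N
        if (substr(s, i + 1, i + 2) == "GG" &&
            substr(s, i, i) != "N" &&
            !grepl("N", substr(s, i - L, i - 1), fixed = TRUE)) {
          hits[[length(hits) + 1]] <- list(seed = substr(s, i - L, i - 1),
                                           n_pos = i)
        }
      }
    }
    hits
  }
  rows <- purrr::imap(genome, function(s, ctg) {
    len <- nchar(s)
    fwd <- scan_forward(s)
    rev <- if (len > 0) scan_forward(revcomp(s)) else list()
    fwd_tbl <- if (length(fwd)) tibble::tibble(
      seed = vapply(fwd, `[[`, "", "seed"), contig = ctg,
      pos = vapply(fwd, function(h) as.integer(h$n_pos - 1 - L), integer(1)),
      strand = "+"
    ) else NULL
    # reverse-complement coordinate q maps to forward coordinate len - q + 1;
    # the seed span [j - L, j - 1] (rc coords) maps to forward start len - j + 1
    rev_tbl <- if (length(rev)) tibble::tibble(
      seed = vapply(rev, `[[`, "", "seed"), contig = ctg,
      pos = vapply(rev, function(h) as.integer(len - h$n_pos + 1), integer(1)),
      strand = "-"
    ) else NULL
    dplyr::bind_rows(fwd_tbl, rev_tbl)
  })
  tbl <- dplyr::bind_rows(rows)
  if (nrow(tbl) == 0) tbl <- empty_index_tbl()
  new_genome_index(tbl, L, vapply(genome, nchar, integer(1)))
}

#' Screen a seed against a genome index
#'
#' Counts perfect PAM-adjacent matches of a candidate seed and, optionally,
#' near matches within a Hamming radius. A design is accepted only when its
#' seeds have zero exact hits.
#'
#' @param index A `genome_index`.
#' @param seed DNA word of the index's seed length.
#' @param radius Maximum Hamming distance reported in `near_hits` (default 0).
#' @return A `screen_report`: list with `seed`, `exact_hits` and `near_hits`
#'   (tibble `contig`, `pos`, `strand`, `seed`, `distance`).
#' @export
screen_seed <- function(index, seed, radius = 0) {
  stopifnot(inherits(index, "genome_index"))
  seed <- toupper(seed)
  assert_dna(seed, arg = "seed")
  L <- attr(index, "seed_length")
  if (nchar(seed) != L) {
    rlang::abort(sprintf("seed must be %d nt to match the index", L),
                 class = "crisprgates_invalid_length")
  }
  tbl <- tibble::as_tibble(index)
  if (nrow(tbl) == 0) {
    near <- dplyr::mutate(empty_index_tbl(), distance = integer(0))
  } else {
    sc <- strsplit(seed, "")[[1]]
    uw <- unique(tbl$seed)
    m <- matrix(unlist(strsplit(uw, ""), use.names = FALSE), ncol = L, byrow = TRUE)
    d <- as.integer(rowSums(m != matrix(sc, nrow = length(uw), ncol = L, byrow = TRUE)))
    dist_of <- stats::setNames(d, uw)
    near <- tbl |>
      dplyr::mutate(distance = dist_of[.data$seed]) |>
      dplyr::filter(.data$distance <= radius) |>
      dplyr::arrange(.data$contig, .data$pos)
  }
  structure(
    list(seed = seed, exact_hits = sum(tbl$seed == seed), near_hits = near,
         radius = radius),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> seed ", x$seed, ": ", x$exact_hits, " exact hit(s), ",
      nrow(x$near_hits), " within Hamming radius ", x$radius, "\n", sep = "")
  invisible(x)
}

#' @rdname generics-tidiers
#' @exportS3Method generics::tidy
tidy.screen_report <- function(x, ...) x$near_hits

#' Plant a seed next to an NGG PAM in a genome
#'
#' Overwrites a genomic segment with `seed` followed by an NGG PAM so that a
#' subsequent [screen_seed()] must detect at least one exact hit. Used to
#' verify screen sensitivity.
#'
#' @param genome Named character vector of contigs.
#' @param seed Seed word to plant.
#' @param contig Contig name or position (default the first contig).
#' @param at 1-based position at which the seed starts; default centers it.
#' @param pam 3-nt PAM written immediately 3' of the seed (default `"AGG"`).
#' @return Modified genome.
#' @export
plant_seed <- function(genome, seed, contig = 1, at = NULL, pam = "AGG") {
  genome <- as_genome(genome)
  seed <- toupper(seed)
  stopifnot(substr(pam, 2, 3) == "GG")
  s <- genome[[contig]]
  need <- nchar(seed) + nchar(pam)
  if (nchar(s) < need) rlang::abort("contig too short to plant the seed",
                                    class = "crisprgates_invalid_argument")
  if (is.null(at)) at <- max(1L, (nchar(s) - need) %/% 2L)
  substr(s, at, at + need - 1) <- paste0(seed, pam)
  genome[[contig]] <- s
  genome
}
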
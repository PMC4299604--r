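#' Design a set of mutually orthogonal sgRNA:promoter pairs
#'
#' The full design pipeline: draw random 13-bp operators (rejecting G runs),
#' assemble each into a repressible sigma-70 promoter, derive the T and NT
#' 20-nt guides, and accept a design only when both guides pass the GC filter,
#' both 12-nt seeds have zero exact PAM-adjacent matches in the genome, and
#' every seed is at least `min_pairwise_hamming` mismatches away from every
#' seed of every previously accepted design. Deterministic for a fixed
#' `rng_seed`; candidate and rejection tallies are kept in the result's
#' attributes.
#'
#' @param genome Named character vector / `DNAStringSet` of contigs (may be
#'   empty, in which case the genome screen is trivially passed).
#' @param n_pairs Number of designs requested.
#' @param rng_seed Integer seed for the single RNG stream of the run.
#' @param min_pairwise_hamming Minimum Hamming distance between seeds of
#'   distinct designs (default 4; compared across all T/NT seed pairs).
#' @param scaffold Promoter scaffold, see [default_scaffold()].
#' @param operator_length,gc_prob,max_g_run,gc_bounds,seed_length Filter
#'   parameters (defaults: 13 bp operators drawn at GC probability 0.5, G runs
#'   longer than 3 rejected, guide GC within `[0.35, 0.80]`, 12-nt seeds).
#' @param name_prefix Promoter name prefix (default `"P_A"`).
#' @param max_attempts Cap on candidate operators examined.
#' @return A `design_set`: tibble with one row per design (`name`, `operator`,
#'   `spacer`, `promoter_seq`, `guide_T`, `seed_T`, `guide_NT`, `seed_NT`,
#'   `gc_T`, `gc_NT`, `exact_hits_T`, `exact_hits_NT`), with attributes
#'   `rng_seed`, `n_examined`, `rejections`, `promoters` (the
#'   `promoter_design` objects) and `guides`.
#' @export
design_orthogonal_set <- function(genome, n_pairs, rng_seed,
                                  min_pairwise_hamming = 4,
                                  scaffold = default_scaffold(),
                                  operator_length = 13, gc_prob = 0.5,
                                  max_g_run = 3, gc_bounds = c(0.35, 0.80),
                                  seed_length = 12, name_prefix = "P_A",
                                  max_attempts = 10000L) {
  stopifnot(n_pairs >= 1)
  index <- build_pam_seed_index(genome, seed_length = seed_length)
  rejections <- c(g_run = 0L, guide_gc = 0L, genome_hit = 0L, hamming = 0L)
  designs <- list()
  n_examined <- 0L

  withr::with_seed(rng_seed, {
    for (attempt in seq_len(max_attempts)) {
      if (length(designs) >= n_pairs) break
      n_examined <- n_examined + 1L
      op <- draw_dna(operator_length, gc_prob)
      if (has_g_run(op, max_g_run)) {
        rejections["g_run"] <- rejections["g_run"] + 1L
        next
      }
      pd <- assemble_promoter(op, scaffold,
                              name = paste0(name_prefix, length(designs) + 1L))
      gs <- derive_guides(pd)
      if (!guide_gc_ok(gs$T$guide, gc_bounds) || !guide_gc_ok(gs$NT$guide, gc_bounds)) {
        rejections["guide_gc"] <- rejections["guide_gc"] + 1L
        next
      }
      rep_t <- screen_seed(index, gs$T$seed12)
      rep_nt <- screen_seed(index, gs$NT$seed12)
      if (rep_t$exact_hits > 0 || rep_nt$exact_hits > 0) {
        rejections["genome_hit"] <- rejections["genome_hit"] + 1L
        next
      }
      new_seeds <- c(gs$T$seed12, gs$NT$seed12)
      clash <- any(vapply(designs, function(d) {
        old_seeds <- c(d$guides$T$seed12, d$guides$NT$seed12)
        min(outer(new_seeds, old_seeds,
                  Vectorize(function(a, b) hamming(a, b)))) < min_pairwise_hamming
      }, logical(1)))
      if (clash) {
        rejections["hamming"] <- rejections["hamming"] + 1L
        next
      }
      designs[[length(designs) + 1L]] <- list(
        promoter = pd, guides = gs,
        exact_hits = c(T = rep_t$exact_hits, NT = rep_nt$exact_hits)
      )
    }
  })

  if (length(designs) < n_pairs) {
    rlang::abort(
      sprintf("only %d/%d designs found in %d attempts (rejections: %s)",
              length(designs), n_pairs, n_examined,
              paste(names(rejections), rejections, sep = "=", collapse = ", ")),
      class = "crisprgates_unsatisfiable"
    )
  }

  tbl <- purrr::map_dfr(designs, function(d) {
    tibble::tibble(
      name = d$promoter$name,
      operator = d$promoter$operator,
      spacer = d$promoter$spacer,
      promoter_seq = d$promoter$full_sequence,
      guide_T = d$guides$T$guide,
      seed_T = d$guides$T$seed12,
      guide_NT = d$guides$NT$guide,
      seed_NT = d$guides$NT$seed12,
      gc_T = gc_fraction(d$guides$T$guide),
      gc_NT = gc_fraction(d$guides$NT$guide),
      exact_hits_T = d$exact_hits[["T"]],
      exact_hits_NT = d$exact_hits[["NT"]]
    )
  })
  structure(tbl, class = c("design_set", class(tbl)),
            rng_seed = rng_seed, n_examined = n_examined,
            rejections = rejections,
            promoters = purrr::map(designs, "promoter"),
            guides = purrr::map(designs, "guides"))
}

#' Write a design set to FASTA plus a JSON report
#'
#' @param designs A `design_set`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_design_set <- function(designs, dir) {
  stopifnot(inherits(designs, "design_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seqs <- c(
    stats::setNames(designs$promoter_seq, designs$name),
    stats::setNames(designs$guide_T, paste0("sgRNA-", designs$name, "T")),
    stats::setNames(designs$guide_NT, paste0("sgRNA-", designs$name, "NT"))
  )
  fa <- file.path(dir, "designs.fasta")
  write_fasta(seqs, fa)
  report <- list(
    rng_seed = attr(designs, "rng_seed"),
    n_designs = nrow(designs),
    n_examined = attr(designs, "n_examined"),
    rejections = as.list(attr(designs, "rejections")),
    designs = tibble::as_tibble(designs)
  )
  js <- file.path(dir, "design_report.json")
  jsonlite::write_json(report, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(fasta = fa, json = js))
}
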
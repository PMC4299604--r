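#' Random genome generator
#'
#' Draws i.i.d. bases with the requested expected GC content; deterministic
#' per seed. Used to emulate a host genome for off-target screening without
#' any download.
#'
#' @param seed Integer RNG seed.
#' @param length Total genome length (bp), split evenly over `n_contigs`.
#' @param gc Expected GC fraction (default 0.5).
#' @param n_contigs Number of contigs (default 1).
#' @return Named character vector of contig sequences.
#' @export
#' @examples
#' random_genome(1, 100)
random_genome <- function(seed, length, gc = 0.5, n_contigs = 1) {
  stopifnot(length >= 0, n_contigs >= 1)
  withr::with_seed(seed, {
    sizes <- rep(length %/% n_contigs, n_contigs)
    sizes[1] <- sizes[1] + length %% n_contigs
    stats::setNames(
      vapply(sizes, function(n) draw_dna(n, gc), character(1)),
      paste0("contig", seq_len(n_contigs))
    )
  })
}

#' Synthetic gate characterization data
#'
#' Evaluates a gate response at the given input activities and applies
#' multiplicative log-normal noise, emulating the structure of an sgRNA gate
#' characterization experiment (input promoter activity vs output promoter
#' activity).
#'
#' @param gate A `gate_response`.
#' @param inputs Positive input promoter activities (au).
#' @param noise_sigma Standard deviation of the log-scale noise (0 returns
#'   the exact response).
#' @param seed Integer RNG seed.
#' @return Tibble with columns `input`, `output`.
#' @export
synth_gate_data <- function(gate, inputs, noise_sigma = 0.1, seed = 1) {
  stopifnot(all(inputs > 0), noise_sigma >= 0)
  withr::with_seed(seed, {
    mu <- gate_output(gate, inputs)
    tibble::tibble(
      input = inputs,
      output = mu * exp(stats::rnorm(length(inputs), 0, noise_sigma))
    )
  })
}

#' Synthetic crosstalk matrix
#'
#' Draws a guide x promoter fold-repression matrix with cognate (diagonal)
#' folds uniform in `on_range` and off-target folds uniform in
#' `[1, off_max)`, the orthogonality regime the designed sets operate in.
#' Also returns the weight form used by the circuit engine: weights scale the
#' cognate effect in log-fold space, `w_ij = log(fold_ij) / log(fold_jj)`, so
#' the diagonal is exactly 1.
#'
#' @param n_guides Number of guide/promoter channels.
#' @param seed Integer RNG seed.
#' @param on_range Cognate fold-repression range (default `c(56, 440)`).
#' @param off_max Exclusive upper bound for off-target folds (default 1.3).
#' @return A `crosstalk_matrix`: list with `folds` and `weights` matrices
#'   (rows = guides, columns = promoters).
#' @export
synth_crosstalk <- function(n_guides, seed = 1, on_range = c(56, 440), off_max = 1.3) {
  stopifnot(n_guides >= 1, on_range[1] > 1, on_range[2] > on_range[1], off_max >= 1)
  withr::with_seed(seed, {
    folds <- matrix(stats::runif(n_guides^2, 1, off_max), n_guides, n_guides,
                    dimnames = list(paste0("g", seq_len(n_guides)),
                                    paste0("P", seq_len(n_guides))))
    diag(folds) <- stats::runif(n_guides, on_range[1], on_range[2])
    weights <- sweep(log(folds), 2, log(diag(folds)), "/")
    structure(list(folds = folds, weights = weights), class = "crosstalk_matrix")
  })
}

#' @export
print.crosstalk_matrix <- function(x, ...) {
  cat("<crosstalk_matrix> ", nrow(x$folds), " channels; cognate folds ",
      sprintf("%.0f-%.0f", min(diag(x$folds)), max(diag(x$folds))),
      ", max off-target fold ", sprintf("%.3f", max(x$folds[row(x$folds) != col(x$folds)])),
      "\n", sep = "")
  invisible(x)
}

#' Fixture gate response
#'
#' A gate parameterized by its fold repression at a reference ON input level,
#' the working regime of the characterized gates: `k` is chosen so that
#' `fold_repression(gate, x_on) = fold_on`. Defaults place single-gate fold
#' repression inside the 56-440 window at an unrepressed activity of
#' 1,040 au.
#'
#' @param fold_on Fold repression at `x_on` (default 150).
#' @param b Power-law exponent (default 0.8).
#' @param y_max Unrepressed output activity (default 1040 au).
#' @param x_on Reference ON input activity (default `y_max`).
#' @return A `gate_response`.
#' @export
fixture_gate <- function(fold_on = 150, b = 0.8, y_max = 1040, x_on = y_max) {
  gate_response(y_max = y_max, k = y_max * x_on^b / fold_on, b = b)
}

#' Randomized fixture gates
#'
#' @param n Number of gates.
#' @param seed Integer RNG seed.
#' @param fold_range Range of fold repression at the ON level (default
#'   `c(56, 440)`).
#' @param b_range Range of exponents (default `c(0.6, 1.1)`).
#' @inheritParams fixture_gate
#' @return List of `gate_response`s.
#' @export
fixture_gates <- function(n, seed = 1, fold_range = c(56, 440),
                          b_range = c(0.6, 1.1), y_max = 1040, x_on = y_max) {
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      fixture_gate(stats::runif(1, fold_range[1], fold_range[2]),
                   stats::runif(1, b_range[1], b_range[2]), y_max, x_on)
    })
  })
}

#' Inducer dose ladders used for characterization and graded circuit assays
#'
#' The standard dose series: aTc for dCas9 induction, arabinose for the
#' sgRNA response-curve assays, and the 11-point arabinose/DAPG ladders used
#' for graded circuit induction. Digital assays use 0.625 ng/ml aTc, 2 mM
#' arabinose and 25 uM DAPG.
#'
#' @return Tibble with columns `inducer`, `assay`, `dose`, `units`.
#' @export
inducer_doses <- function() {
  dplyr::bind_rows(
    tibble::tibble(inducer = "aTc", assay = "dcas9_titration",
                   dose = c(0.0391, 0.313, 0.625, 1.25, 5, 10), units = "ng/ml"),
    tibble::tibble(inducer = "arabinose", assay = "response_curve",
                   dose = c(0, 0.03125, 0.0625, 0.125, 0.25, 0.5), units = "mM"),
    tibble::tibble(inducer = "arabinose", assay = "graded_circuit",
                   dose = c(0, 0.00391, 0.00781, 0.0156, 0.0313, 0.0625,
                            0.125, 0.25, 0.5, 1, 2), units = "mM"),
    tibble::tibble(inducer = "DAPG", assay = "graded_circuit",
                   dose = c(0, 0.0244, 0.0488, 0.0977, 0.391, 0.781, 1.56,
                            3.13, 6.25, 12.5, 25), units = "uM"),
    tibble::tibble(inducer = c("aTc", "arabinose", "DAPG"), assay = "digital",
                   dose = c(0.625, 2, 25), units = c("ng/ml", "mM", "uM"))
  )
}

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings that present sequences as named character
#' vectors, the representation the rest of the package uses.
#'
#' @param path File path.
#' @param x Named character vector of sequences.
#' @return `read_fasta()` returns a named character vector (upper case).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}
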
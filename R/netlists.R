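#' Standard gate topologies
#'
#' Convenience constructors for the canonical circuit motifs: a single NOT
#' gate, a two-input NOR gate (two transcription units carrying the same
#' guide), a double inverter (NOT-NOT), an OR gate (a NOR inverted by a NOT)
#' and an AND gate (two NOT gates whose outputs each drive an independent
#' copy of the same guide into a final NOR stage). Each repressible stage
#' takes its own [gate_response].
#'
#' @param gate,gate1,gate2,gate3 `gate_response` objects for the repressible
#'   stages, in signal order.
#' @param gates List of `gate_response`s, one per cascade layer.
#' @param basal Optional basal (leak) activity added to every promoter.
#' @return A compiled `circuit_netlist`.
#' @name netlist-motifs
NULL

prom_input <- function(basal = 0) list(type = "input", basal = basal)
prom_rep <- function(gate, basal = 0) list(type = "repressible", gate = gate, basal = basal)

#' @rdname netlist-motifs
#' @export
netlist_not <- function(gate, basal = 0) {
  compile_netlist(list(
    promoters = list(pIn = prom_input(basal), pOut = prom_rep(gate, basal)),
    tus = list(list(promoter = "pIn", guide = "g1")),
    repression = list(list(guide = "g1", promoter = "pOut")),
    outputs = "pOut"
  ))
}

#' @rdname netlist-motifs
#' @export
netlist_nor <- function(gate, basal = 0) {
  compile_netlist(list(
    promoters = list(pA = prom_input(basal), pB = prom_input(basal),
                     pOut = prom_rep(gate, basal)),
    tus = list(list(promoter = "pA", guide = "g1"),
               list(promoter = "pB", guide = "g1")),
    repression = list(list(guide = "g1", promoter = "pOut")),
    outputs = "pOut"
  ))
}

#' @rdname netlist-motifs
#' @export
netlist_not_not <- function(gate1, gate2, basal = 0) {
  compile_netlist(list(
    promoters = list(pIn = prom_input(basal), pMid = prom_rep(gate1, basal),
                     pOut = prom_rep(gate2, basal)),
    tus = list(list(promoter = "pIn", guide = "g1"),
               list(promoter = "pMid", guide = "g2")),
    repression = list(list(guide = "g1", promoter = "pMid"),
                      list(guide = "g2", promoter = "pOut")),
    outputs = "pOut"
  ))
}

#' @rdname netlist-motifs
#' @export
netlist_or <- function(gate1, gate2, basal = 0) {
  compile_netlist(list(
    promoters = list(pA = prom_input(basal), pB = prom_input(basal),
                     pMid = prom_rep(gate1, basal), pOut = prom_rep(gate2, basal)),
    tus = list(list(promoter = "pA", guide = "g1"),
               list(promoter = "pB", guide = "g1"),
               list(promoter = "pMid", guide = "g2")),
    repression = list(list(guide = "g1", promoter = "pMid"),
                      list(guide = "g2", promoter = "pOut")),
    outputs = "pOut"
  ))
}

#' @rdname netlist-motifs
#' @export
netlist_and <- function(gate1, gate2, gate3, basal = 0) {
  compile_netlist(list(
    promoters = list(pA = prom_input(basal), pB = prom_input(basal),
                     pMidA = prom_rep(gate1, basal), pMidB = prom_rep(gate2, basal),
                     pOut = prom_rep(gate3, basal)),
    tus = list(list(promoter = "pA", guide = "gA"),
               list(promoter = "pB", guide = "gB"),
               list(promoter = "pMidA", guide = "gC"),
               list(promoter = "pMidB", guide = "gC")),
    repression = list(list(guide = "gA", promoter = "pMidA"),
                      list(guide = "gB", promoter = "pMidB"),
                      list(guide = "gC", promoter = "pOut")),
    outputs = "pOut"
  ))
}

#' @rdname netlist-motifs
#' @export
netlist_cascade <- function(gates, basal = 0) {
  n <- length(gates)
  stopifnot(n >= 1)
  proms <- c(list(pIn = prom_input(basal)),
             stats::setNames(purrr::map(gates, prom_rep, basal = basal),
                             paste0("p", seq_len(n))))
  tus <- purrr::map(seq_len(n), function(i) {
    list(promoter = if (i == 1) "pIn" else paste0("p", i - 1),
         guide = paste0("g", i))
  })
  repr <- purrr::map(seq_len(n), function(i) {
    list(guide = paste0("g", i), promoter = paste0("p", i))
  })
  compile_netlist(list(promoters = proms, tus = tus, repression = repr,
                       outputs = paste0("p", n)))
}
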
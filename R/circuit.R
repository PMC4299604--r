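#' Compile a circuit specification into a validated netlist
#'
#' A circuit is described by promoter nodes (inputs, constitutives and
#' repressible outputs carrying a fitted [gate_response]), transcription-unit
#' edges (input promoter transcribes a guide species) and repression edges
#' (guide species represses a repressible promoter). Compilation checks that
#' the promoter-guide-promoter graph is acyclic (steady state is evaluated in
#' topological order), that every repressible promoter has at least one
#' cognate guide, that no repression edge references a guide that is never
#' transcribed, and computes the layer depth (longest chain of repression
#' hops). A NOR gate appears structurally as one guide carried by two
#' transcription units with distinct input promoters.
#'
#' @param spec List with elements `promoters` (named list; each
#'   `list(type = "input"|"constitutive"|"repressible", gate =, basal = 0)`
#'   where repressible nodes carry a `gate_response` and constitutive nodes a
#'   `y_max`), `tus` (list of `list(promoter =, guide =)`), `repression`
#'   (list of `list(guide =, promoter =)`, the cognate edges) and `outputs`
#'   (character).
#' @param crosstalk Optional guide x promoter weight matrix (fraction of
#'   cognate effectiveness in log-fold space; cognate entries 1). Missing
#'   pairs default to 0 (no interaction) except cognate edges, which are 1.
#' @return A `circuit_netlist`.
#' @export
compile_netlist <- function(spec, crosstalk = NULL) {
  proms <- spec$promoters %||% list()
  tus <- spec$tus %||% list()
  repr <- spec$repression %||% list()
  outputs <- spec$outputs %||% character(0)

  prom_tbl <- if (length(proms)) purrr::imap_dfr(proms, function(p, nm) {
    tibble::tibble(
      promoter = nm,
      type = p$type,
      y_max = if (!is.null(p$gate)) p$gate$y_max else p$y_max %||% NA_real_,
      basal = p$basal %||% 0
    )
  }) else tibble::tibble(promoter = character(0), type = character(0),
                         y_max = numeric(0), basal = numeric(0))
  gates <- purrr::map(proms, "gate")
  tu_tbl <- if (length(tus)) purrr::imap_dfr(tus, function(t, i) {
    tibble::tibble(tu = paste0("tu", i), promoter = t$promoter, guide = t$guide)
  }) else tibble::tibble(tu = character(0), promoter = character(0), guide = character(0))
  rep_tbl <- if (length(repr)) purrr::map_dfr(repr, function(r) {
    tibble::tibble(guide = r$guide, promoter = r$promoter)
  }) else tibble::tibble(guide = character(0), promoter = character(0))

  bad <- setdiff(c(tu_tbl$promoter, rep_tbl$promoter), prom_tbl$promoter)
  if (length(bad)) {
    rlang::abort(paste0("unknown promoter(s): ", paste(unique(bad), collapse = ", ")),
                 class = "crisprgates_invalid_netlist")
  }
  dangling <- setdiff(rep_tbl$guide, tu_tbl$guide)
  if (length(dangling)) {
    rlang::abort(paste0("guide(s) repress but are never transcribed: ",
                        paste(unique(dangling), collapse = ", ")),
                 class = "crisprgates_invalid_netlist")
  }
  unused <- setdiff(tu_tbl$guide, rep_tbl$guide)
  if (length(unused)) {
    rlang::abort(paste0("dangling guide(s) with no repression target: ",
                        paste(unique(unused), collapse = ", ")),
                 class = "crisprgates_invalid_netlist")
  }
  repressible <- prom_tbl$promoter[prom_tbl$type == "repressible"]
  uncovered <- setdiff(repressible, rep_tbl$promoter)
  if (length(uncovered)) {
    rlang::abort(paste0("repressible promoter(s) without a cognate guide: ",
                        paste(uncovered, collapse = ", ")),
                 class = "crisprgates_invalid_netlist")
  }
  for (p in repressible) {
    if (!inherits(gates[[p]], "gate_response")) {
      rlang::abort(sprintf("repressible promoter '%s' has no fitted gate_response", p),
                   class = "crisprgates_unfitted_gate")
    }
  }

  # weights: cognate edges 1; crosstalk matrix may add off-target weights
  w_tbl <- dplyr::mutate(rep_tbl, weight = 1)
  if (!is.null(crosstalk)) {
    if (inherits(crosstalk, "crosstalk_matrix")) crosstalk <- crosstalk$weights
    xt <- tibble::as_tibble(as.table(crosstalk), .name_repair = "minimal")
    names(xt) <- c("guide", "promoter", "weight")
    xt <- dplyr::filter(xt, .data$weight > 0,
                        .data$promoter %in% prom_tbl$promoter,
                        .data$guide %in% tu_tbl$guide)
    w_tbl <- dplyr::bind_rows(w_tbl, dplyr::anti_join(xt, w_tbl, by = c("guide", "promoter")))
  }

  # bipartite promoter/guide graph for cycle detection and evaluation order
  edges <- c(
    if (nrow(tu_tbl)) c(rbind(paste0("P:", tu_tbl$promoter), paste0("G:", tu_tbl$guide))),
    if (nrow(w_tbl)) c(rbind(paste0("G:", w_tbl$guide), paste0("P:", w_tbl$promoter)))
  )
  edges <- edges %||% character(0)
  vertices <- unique(c(paste0("P:", prom_tbl$promoter), paste0("G:", unique(tu_tbl$guide))))
  g <- igraph::make_graph(edges, directed = TRUE, isolates = setdiff(vertices, edges))
  if (length(edges) && !igraph::is_dag(g)) {
    sccs <- igraph::components(g, mode = "strong")
    cyc <- names(sccs$membership)[sccs$membership == which(sccs$csize > 1)[1]]
    rlang::abort(paste0("circuit contains a feedback cycle through: ",
                        paste(sub("^[PG]:", "", cyc), collapse = " -> ")),
                 class = "crisprgates_cycle")
  }
  topo <- igraph::topo_sort(g, mode = "out")
  prom_order <- sub("^P:", "", grep("^P:", names(topo), value = TRUE))

  # layer depth: longest path in repression hops (promoter -> promoter)
  pp <- dplyr::inner_join(tu_tbl, rep_tbl, by = "guide", suffix = c("_src", "_dst"),
                          relationship = "many-to-many")
  depth_of <- stats::setNames(rep(0, nrow(prom_tbl)), prom_tbl$promoter)
  for (p in prom_order) {
    up <- pp$promoter_src[pp$promoter_dst == p]
    if (length(up)) depth_of[p] <- max(depth_of[up]) + 1
  }

  nor_guides <- tu_tbl |>
    dplyr::group_by(.data$guide) |>
    dplyr::summarise(n_inputs = dplyr::n_distinct(.data$promoter), .groups = "drop") |>
    dplyr::filter(.data$n_inputs >= 2)

  structure(
    list(promoters = prom_tbl, gates = gates, tus = tu_tbl,
         repression = w_tbl, outputs = outputs,
         order = prom_order, depth = max(depth_of, 0),
         depths = depth_of, nor_guides = nor_guides$guide),
    class = "circuit_netlist"
  )
}

#' @export
print.circuit_netlist <- function(x, ...) {
  cat("<circuit_netlist> ", nrow(x$promoters), " promoters, ",
      nrow(x$tus), " transcription units, ", nrow(x$repression),
      " repression edges, depth ", x$depth, "\n", sep = "")
  invisible(x)
}

`%||%` <- rlang::`%||%`

#' Steady-state promoter activities of a circuit
#'
#' Evaluates the netlist in topological order. Input promoters take the
#' supplied activities; constitutive promoters sit at their `y_max`. The
#' level of a guide species is the sum of the activities of all transcription
#' units carrying it (additive pooling, the same-guide NOR mechanism). A
#' repressible promoter with unrepressed level `y_max` is divided by the
#' product over acting guides of `fold^weight`, where `fold` is the
#' cognate fold repression of its gate at that guide's pooled level and
#' `weight` is the crosstalk weight (cognate 1): a single cognate guide
#' reproduces [gate_output()] exactly, distinct guides combine
#' multiplicatively, and off-targets act as a fraction of the cognate effect
#' in log-fold space.
#'
#' @param netlist A `circuit_netlist`.
#' @param inputs Named numeric vector of activities for the input promoters
#'   (au). Values must be >= 0.
#' @return Tibble with columns `promoter`, `type`, `activity` and a
#'   `guides` attribute (tibble of pooled guide levels).
#' @export
steady_state <- function(netlist, inputs = c()) {
  stopifnot(inherits(netlist, "circuit_netlist"))
  proms <- netlist$promoters
  need <- proms$promoter[proms$type == "input"]
  missing <- setdiff(need, names(inputs))
  if (length(missing)) {
    rlang::abort(paste0("no activity supplied for input promoter(s): ",
                        paste(missing, collapse = ", ")),
                 class = "crisprgates_invalid_input")
  }
  act <- stats::setNames(rep(NA_real_, nrow(proms)), proms$promoter)
  glevel <- stats::setNames(rep(0, length(unique(netlist$tus$guide))),
                            unique(netlist$tus$guide))
  for (p in netlist$order) {
    row <- proms[proms$promoter == p, ]
    a <- switch(row$type,
      input = unname(inputs[[p]]),
      constitutive = row$y_max,
      repressible = {
        gate <- netlist$gates[[p]]
        edges <- netlist$repression[netlist$repression$promoter == p, ]
        log_fold <- 0
        for (i in seq_len(nrow(edges))) {
          x_g <- glevel[[edges$guide[i]]]
          log_fold <- log_fold + edges$weight[i] * log(fold_repression(gate, x_g))
        }
        gate$y_max / exp(log_fold)
      },
      rlang::abort(sprintf("unknown promoter type '%s'", row$type))
    )
    a <- a + row$basal
    act[[p]] <- a
    carried <- netlist$tus$guide[netlist$tus$promoter == p]
    for (gd in carried) glevel[[gd]] <- glevel[[gd]] + a
  }
  out <- tibble::tibble(promoter = proms$promoter, type = proms$type,
                        activity = unname(act[proms$promoter]))
  attr(out, "guides") <- tibble::tibble(guide = names(glevel),
                                        level = unname(glevel))
  out
}

#' Truth table of a compiled logic circuit
#'
#' Evaluates all `2^n` Boolean combinations of the circuit's input promoters
#' at the given ON/OFF activity levels and compares the output promoter
#' against the declared logic. The digital margin is
#' `min(activity over expected-ON rows) / max(activity over expected-OFF
#' rows)`; calls use the geometric midpoint of that interval as the
#' threshold, so margin > 1 implies every call matches the declared logic.
#'
#' @param netlist A `circuit_netlist` with at least one output.
#' @param on_level,off_level Input promoter activities for logical 1 / 0 (au).
#'   Either scalars or named vectors over the input promoters.
#' @param logic Declared logic: `"NOT"`, `"NOR"`, `"OR"`, `"AND"`, or a
#'   function mapping a logical vector of inputs to the expected output.
#' @param output Output promoter (default the netlist's first output).
#' @return A `truth_table` tibble: one column per input (0/1), `activity`,
#'   `expected`, `call`; attributes `margin`, `consistent`, `threshold`.
#' @export
truth_table <- function(netlist, on_level = 1040, off_level = 0,
                        logic = "NOR", output = netlist$outputs[1]) {
  ins <- netlist$promoters$promoter[netlist$promoters$type == "input"]
  stopifnot(length(ins) >= 1, !is.na(output))
  on_v <- if (length(on_level) == 1) stats::setNames(rep(on_level, length(ins)), ins) else on_level[ins]
  off_v <- if (length(off_level) == 1) stats::setNames(rep(off_level, length(ins)), ins) else off_level[ins]
  fn <- if (is.function(logic)) logic else switch(
    toupper(logic),
    NOT = function(b) !b[1],
    NOR = function(b) !any(b),
    OR = function(b) any(b),
    AND = function(b) all(b),
    rlang::abort("logic must be NOT/NOR/OR/AND or a function")
  )
  grid <- as.matrix(expand.grid(rep(list(c(0L, 1L)), length(ins)),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- ins
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    bits <- grid[i, ] == 1L
    lv <- ifelse(bits, on_v, off_v)
    ss <- steady_state(netlist, stats::setNames(lv, ins))
    tibble::tibble(!!!as.list(grid[i, ]),
                   activity = ss$activity[ss$promoter == output],
                   expected = unname(fn(bits)))
  })
  on_min <- min(rows$activity[rows$expected])
  off_max <- max(rows$activity[!rows$expected])
  margin <- if (any(rows$expected) && any(!rows$expected)) on_min / off_max else Inf
  threshold <- if (is.finite(margin)) sqrt(on_min * off_max) else NA_real_
  rows$call <- if (is.na(threshold)) rows$expected else rows$activity > threshold
  if (margin <= 1) {
    rlang::warn(sprintf("digital margin %.3g <= 1: circuit is not digital at these levels", margin))
  }
  structure(rows, class = c("truth_table", class(rows)),
            margin = margin, threshold = threshold,
            consistent = identical(rows$call, rows$expected),
            logic = if (is.function(logic)) "custom" else toupper(logic),
            output = output)
}

#' @rdname generics-tidiers
#' @exportS3Method generics::glance
glance.truth_table <- function(x, ...) {
  tibble::tibble(logic = attr(x, "logic"), margin = attr(x, "margin"),
                 consistent = attr(x, "consistent"), n_rows = nrow(x))
}

#' Analytic dynamic-range attenuation of a power-law cascade
#'
#' In the unclamped regime a layer with exponent `b` maps an input spanning
#' `d` decades onto an output spanning `b * d` decades, so a cascade
#' multiplies the exponents: signal is degraded at each layer whenever
#' `b < 1`.
#'
#' @param exponents Power-law exponents of the layers (all >= 0).
#' @param input_log_range Input dynamic range in decades.
#' @return Output dynamic range in decades.
#' @export
#' @examples
#' cascade_attenuation(c(0.7, 0.7), 3) # 1.47
cascade_attenuation <- function(exponents, input_log_range) {
  stopifnot(all(exponents >= 0), input_log_range >= 0)
  input_log_range * prod(exponents)
}

#' Simulate reporter dynamics under an induction schedule
#'
#' Integrates `d(level)/dt = synthesis_rate * a(t) - (ln 2 / T_d) * level`,
#' where `a(t)` is the steady-state activity of the output promoter given the
#' inducer state of the schedule at time `t - delay_tau`: the delay lumps
#' input-promoter activation and dCas9/sgRNA accumulation, after which
#' repression takes effect and a fully repressed reporter is diluted by
#' growth, halving every doubling time. Fixed-step 4th-order Runge-Kutta on a
#' configurable grid.
#'
#' @param netlist A `circuit_netlist`.
#' @param schedule Data frame with a `time` column (min) and one column per
#'   input promoter; each row's levels hold from its time until the next row
#'   (step function). The first row also defines the pre-simulation state.
#' @param delay_tau Delay before a schedule change takes effect (min).
#' @param doubling_time Cell doubling time `T_d` (min), > 0.
#' @param synthesis_rate Reporter synthesis per unit promoter activity per
#'   minute (default 1).
#' @param t_max End time (min).
#' @param dt Integration step (min, default 0.1).
#' @param output Output promoter (default the netlist's first output).
#' @param level0 Initial reporter level; defaults to the pre-induction steady
#'   state `synthesis_rate * a(0-) * T_d / ln 2`.
#' @return A `dynamics_trace` tibble (`time`, `activity`, `level`) with the
#'   parameters as attributes.
#' @export
simulate_dynamics <- function(netlist, schedule, delay_tau, doubling_time,
                              synthesis_rate = 1, t_max = 420, dt = 0.1,
                              output = netlist$outputs[1], level0 = NULL) {
  if (doubling_time <= 0) {
    rlang::abort("doubling_time must be positive", class = "crisprgates_invalid_argument")
  }
  stopifnot(is.data.frame(schedule), "time" %in% names(schedule))
  ins <- netlist$promoters$promoter[netlist$promoters$type == "input"]
  schedule <- schedule[order(schedule$time), , drop = FALSE]
  # activity of the output promoter for each schedule segment
  seg_act <- vapply(seq_len(nrow(schedule)), function(i) {
    lv <- unlist(schedule[i, ins, drop = FALSE])
    ss <- steady_state(netlist, lv)
    ss$activity[ss$promoter == output]
  }, numeric(1))
  a_of <- function(t) {
    # repression (any schedule change) takes effect delay_tau after the switch
    i <- findInterval(t - delay_tau, schedule$time)
    seg_act[max(i, 1)]
  }
  lambda <- log(2) / doubling_time
  if (is.null(level0)) level0 <- synthesis_rate * a_of(-Inf + 0) * 1 / lambda
  times <- seq(0, t_max, by = dt)
  sol <- deSolve::rk4(
    y = c(level = level0), times = times, parms = NULL,
    func = function(t, y, parms) list(synthesis_rate * a_of(t) - lambda * y)
  )
  out <- tibble::tibble(time = sol[, "time"],
                        activity = vapply(sol[, "time"], a_of, numeric(1)),
                        level = sol[, "level"])
  structure(out, class = c("dynamics_trace", class(out)),
            delay_tau = delay_tau, doubling_time = doubling_time,
            synthesis_rate = synthesis_rate, output = output)
}
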
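test_that("netlists compile with depth, and invalid wiring is rejected", {
  expect_identical(netlist_not_not(fixture_gate(), fixture_gate())$depth, 2)
  expect_identical(netlist_and(fixture_gate(), fixture_gate(), fixture_gate())$depth, 2)
  expect_identical(compile_netlist(list())$depth, 0)

  # self-loop: a guide repressing its own input promoter
  expect_error(compile_netlist(list(
    promoters = list(pA = list(type = "repressible", gate = fixture_gate())),
    tus = list(list(promoter = "pA", guide = "g1")),
    repression = list(list(guide = "g1", promoter = "pA")),
    outputs = "pA"
  )), class = "crisprgates_cycle")

  # repression by a guide never transcribed
  expect_error(compile_netlist(list(
    promoters = list(pA = list(type = "input"),
                     pB = list(type = "repressible", gate = fixture_gate())),
    tus = list(list(promoter = "pA", guide = "g1")),
    repression = list(list(guide = "g1", promoter = "pB"),
                      list(guide = "gX", promoter = "pB")),
    outputs = "pB"
  )), class = "crisprgates_invalid_netlist")

  # dangling guide with no target
  expect_error(compile_netlist(list(
    promoters = list(pA = list(type = "input")),
    tus = list(list(promoter = "pA", guide = "g1")),
    repression = list(), outputs = character(0)
  )), class = "crisprgates_invalid_netlist")

  # repressible promoter without a gate model
  expect_error(compile_netlist(list(
    promoters = list(pA = list(type = "input"),
                     pB = list(type = "repressible")),
    tus = list(list(promoter = "pA", guide = "g1")),
    repression = list(list(guide = "g1", promoter = "pB")),
    outputs = "pB"
  )), class = "crisprgates_unfitted_gate")

  # NOR structure is recognized
  expect_identical(netlist_nor(fixture_gate())$nor_guides, "g1")
})

test_that("steady state matches gate_output for a single NOT gate and pools sgRNA additively", {
  g <- gate_response(1000, 100, 1)
  nl <- netlist_not(g)
  ss <- steady_state(nl, c(pIn = 10))
  expect_equal(ss$activity[ss$promoter == "pOut"], 10)
  expect_equal(ss$activity[ss$promoter == "pOut"], gate_output(g, 10))

  # NOR with both inputs at 0 gives y_max; pooling sums TU activities
  nor <- netlist_nor(g)
  expect_equal(steady_state(nor, c(pA = 0, pB = 0))$activity[3], 1000)
  both <- steady_state(nor, c(pA = 7, pB = 5))
  expect_equal(attr(both, "guides")$level, 12)
  expect_equal(both$activity[both$promoter == "pOut"], gate_output(g, 12))
})

test_that("identity crosstalk equals no-crosstalk, and off-target weights act in log-fold space", {
  g <- gate_response(1000, 100, 1)
  nor <- netlist_nor(g)
  w <- matrix(1, 1, 1, dimnames = list("g1", "pOut"))
  spec <- list(
    promoters = list(pA = list(type = "input"), pB = list(type = "input"),
                     pOut = list(type = "repressible", gate = g)),
    tus = list(list(promoter = "pA", guide = "g1"),
               list(promoter = "pB", guide = "g1")),
    repression = list(list(guide = "g1", promoter = "pOut")),
    outputs = "pOut"
  )
  nl_w <- compile_netlist(spec, crosstalk = w)
  for (inp in list(c(pA = 0, pB = 0), c(pA = 10, pB = 0), c(pA = 200, pB = 100))) {
    expect_equal(steady_state(nl_w, inp)$activity, steady_state(nor, inp)$activity)
  }

  # an off-target weight of 0.5 halves the log fold
  spec2 <- list(
    promoters = list(pA = list(type = "input"), pB = list(type = "input"),
                     pOut1 = list(type = "repressible", gate = g),
                     pOut2 = list(type = "repressible", gate = g)),
    tus = list(list(promoter = "pA", guide = "g1"),
               list(promoter = "pB", guide = "g2")),
    repression = list(list(guide = "g1", promoter = "pOut1"),
                      list(guide = "g2", promoter = "pOut2")),
    outputs = c("pOut1", "pOut2")
  )
  xt <- matrix(c(1, 0.5, 0, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("pOut1", "pOut2")))
  nl2 <- compile_netlist(spec2, crosstalk = xt)
  ss2 <- steady_state(nl2, c(pA = 100, pB = 0))
  fold_cognate <- fold_repression(g, 100)
  expect_equal(1000 / ss2$activity[ss2$promoter == "pOut1"], fold_cognate)
  # g1 also hits pOut2 at weight 0.5
  expect_equal(1000 / ss2$activity[ss2$promoter == "pOut2"], fold_cognate^0.5)

  # distinct guides on one promoter combine multiplicatively
  spec3 <- spec2
  spec3$repression <- c(spec2$repression, list(list(guide = "g2", promoter = "pOut1")))
  nl3 <- compile_netlist(spec3)
  ss3 <- steady_state(nl3, c(pA = 100, pB = 50))
  expect_equal(1000 / ss3$activity[ss3$promoter == "pOut1"],
               fold_repression(g, 100) * fold_repression(g, 50))
})

test_that("truth tables reproduce NOT, NOR, OR and AND logic with digital margin > 1", {
  gates <- fixture_gates(4, seed = 61)
  cases <- list(
    list(nl = netlist_not(gates[[1]]), logic = "NOT"),
    list(nl = netlist_nor(gates[[1]]), logic = "NOR"),
    list(nl = netlist_or(gates[[1]], gates[[2]]), logic = "OR"),
    list(nl = netlist_and(gates[[1]], gates[[2]], gates[[3]]), logic = "AND")
  )
  for (cs in cases) {
    tt <- truth_table(cs$nl, on_level = 1040, off_level = 0, logic = cs$logic)
    expect_true(attr(tt, "consistent"))
    expect_gt(attr(tt, "margin"), 1)
    expect_identical(tt$call, tt$expected)
    expect_identical(nrow(tt), as.integer(2^sum(cs$nl$promoters$type == "input")))
  }
  # NOR is ON only at (0,0)
  tt_nor <- truth_table(netlist_nor(gates[[1]]), logic = "NOR")
  expect_identical(which(tt_nor$expected), which(tt_nor$pA == 0 & tt_nor$pB == 0))
  # AND is ON only at (1,1)
  tt_and <- truth_table(netlist_and(gates[[1]], gates[[2]], gates[[3]]), logic = "AND")
  expect_identical(which(tt_and$expected), which(tt_and$pA == 1 & tt_and$pB == 1))
})

test_that("NOR symmetry: swapping the two input promoters leaves predictions unchanged", {
  nor <- netlist_nor(fixture_gate(87, 0.9))
  withr::with_seed(62, {
    for (i in 1:20) {
      a <- runif(1, 0, 2000); b <- runif(1, 0, 2000)
      s1 <- steady_state(nor, c(pA = a, pB = b))
      s2 <- steady_state(nor, c(pA = b, pB = a))
      expect_equal(s1$activity[s1$promoter == "pOut"],
                   s2$activity[s2$promoter == "pOut"])
    }
  })
})

test_that("monotone response: raising one inducer never raises odd-hop promoters nor lowers even-hop ones", {
  nl <- netlist_or(fixture_gate(150, 0.8), fixture_gate(220, 0.9))
  withr::with_seed(63, {
    for (i in 1:15) {
      base <- c(pA = runif(1, 0, 1000), pB = runif(1, 0, 1000))
      up <- base + c(runif(1, 1, 500), 0)
      s0 <- steady_state(nl, base); s1 <- steady_state(nl, up)
      mid0 <- s0$activity[s0$promoter == "pMid"]; mid1 <- s1$activity[s1$promoter == "pMid"]
      out0 <- s0$activity[s0$promoter == "pOut"]; out1 <- s1$activity[s1$promoter == "pOut"]
      expect_lte(mid1, mid0 + 1e-9)   # one repression hop
      expect_gte(out1, out0 - 1e-9)   # two hops
    }
  })
})

test_that("cascade attenuation: analytic decades match numeric steady-state sweeps where unclamped", {
  expect_identical(cascade_attenuation(c(1, 1), 3), 3)
  expect_equal(cascade_attenuation(c(0.7, 0.7), 3), 1.47)

  for (bs in list(c(0.7, 0.9), c(0.8, 0.7, 0.9))) {
    gates <- lapply(bs, function(b) gate_response(y_max = 1e7, k = 1e5, b = b))
    nl <- netlist_cascade(gates)
    out_prom <- nl$outputs
    xs <- c(1, 1000)   # 3 decades in
    outs <- vapply(xs, function(x) {
      ss <- steady_state(nl, c(pIn = x))
      ss$activity[ss$promoter == out_prom]
    }, numeric(1))
    numeric_decades <- abs(log10(outs[1] / outs[2]))
    expect_equal(numeric_decades, cascade_attenuation(bs, 3), tolerance = 0.01)
  }
})

test_that("dynamics: delayed exponential closed form, fixed point, and exact decay at zero synthesis", {
  g <- fixture_gate()
  nl <- netlist_not(g)
  tau <- 90; td <- 33; lam <- log(2) / td
  tr <- simulate_dynamics(nl, induction_at_zero(1040), delay_tau = tau,
                          doubling_time = td, t_max = 420)
  d <- tibble::as_tibble(tr)
  y_max <- g$y_max
  a_rep <- gate_output(g, 1040)
  L0 <- y_max / lam
  Lss <- a_rep / lam
  closed <- ifelse(d$time < tau, L0, Lss + (L0 - Lss) * exp(-lam * (d$time - tau)))
  expect_lt(max(abs(d$level - closed) / closed), 1e-3)
  # flat then declining, halving per doubling time once synthesis is negligible
  expect_equal(d$level[d$time == 60], L0, tolerance = 1e-6)
  # the decaying component above the repressed fixed point halves every T_d
  late <- d$level[d$time %in% c(300, 333)] - Lss
  expect_equal(late[2] / late[1], 0.5, tolerance = 0.005)

  # no induction: steady level = synthesis * activity * T_d / ln 2
  flat <- simulate_dynamics(nl, data.frame(time = 0, pIn = 0), tau, td, t_max = 60)
  expect_equal(max(abs(flat$level - L0)) / L0, 0, tolerance = 1e-9)

  # zero synthesis: exact exponential decay (machine precision scale)
  dec <- simulate_dynamics(nl, induction_at_zero(1040), tau, td,
                           synthesis_rate = 0, t_max = 100, level0 = 1000)
  expect_equal(dec$level, 1000 * exp(-lam * dec$time), tolerance = 1e-10)
})

test_that("topological evaluation is order-independent", {
  # same circuit declared with promoters and TUs listed in two different orders
  g1 <- fixture_gate(100, 0.8); g2 <- fixture_gate(300, 1.0)
  spec_a <- list(
    promoters = list(pIn = list(type = "input"),
                     pMid = list(type = "repressible", gate = g1),
                     pOut = list(type = "repressible", gate = g2)),
    tus = list(list(promoter = "pIn", guide = "g1"),
               list(promoter = "pMid", guide = "g2")),
    repression = list(list(guide = "g1", promoter = "pMid"),
                      list(guide = "g2", promoter = "pOut")),
    outputs = "pOut"
  )
  spec_b <- spec_a
  spec_b$promoters <- rev(spec_a$promoters)
  spec_b$tus <- rev(spec_a$tus)
  spec_b$repression <- rev(spec_a$repression)
  sa <- steady_state(compile_netlist(spec_a), c(pIn = 500))
  sb <- steady_state(compile_netlist(spec_b), c(pIn = 500))
  m <- merge(as.data.frame(sa), as.data.frame(sb), by = "promoter")
  expect_equal(m$activity.x, m$activity.y)
})
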
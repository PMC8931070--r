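test_that("GDP-inverse export reduction shares", {
  # 3 equal-GDP out-neighbours share equally
  eq3 <- trade_network(
    data.frame(id = c("O", "X", "Y", "Z"), name = "x", gdp = 1,
               population = 10, supply = c(0, 100, 100, 100)),
    data.frame(origin = "O", dest = c("X", "Y", "Z"), weight = 10))
  expect_equal(unname(export_reduction_shares(eq3, "O")), rep(1 / 3, 3))
  # GDPs (1, 3): poorer partner absorbs 0.75
  g13 <- trade_network(
    data.frame(id = c("O", "P", "R"), name = "x", gdp = c(5, 1, 3),
               population = 10, supply = c(0, 100, 100)),
    data.frame(origin = "O", dest = c("P", "R"), weight = 10))
  expect_equal(export_reduction_shares(g13, "O"),
               c(P = 0.75, R = 0.25))
  # single out-neighbour takes everything
  ch <- fixture("chain3")
  expect_equal(export_reduction_shares(ch, "A"), c(B = 1))
  # shares always sum to one
  st <- fixture("star5")
  expect_equal(sum(export_reduction_shares(st, "HUB")), 1)
  # a pure absorber has no shares to give
  expect_error(export_reduction_shares(ch, "C"), "absorb")
})

test_that("initial shock: export cut, import boost and deficit bookkeeping", {
  ch <- fixture("chain3")
  st <- apply_initial_shock(ch, "A", 0.3, 1)
  expect_equal(st$W["A", "B"], 70)
  expect_equal(unname(st$dd), c(0, 30, 0))
  # equal-GDP two-importer star: 30 split 15/15
  s2 <- trade_network(
    data.frame(id = c("O", "X", "Y"), name = "x", gdp = 1,
               population = 10, supply = c(50, 100, 100)),
    data.frame(origin = "O", dest = c("X", "Y"), weight = 25))
  s2s <- apply_initial_shock(s2, "O", 0.3, 1)   # prod_O = 100, shock 30
  expect_equal(unname(s2s$W["O", c("X", "Y")]), c(10, 10))
  # import channel: alpha = 0 boosts suppliers proportionally to baseline
  tb <- fixture("star5")
  sti <- apply_initial_shock(tb, "L1", 0.3, 0)  # L1 imports only from HUB
  shock <- 0.3 * tb$countries$production[tb$countries$id == "L1"]
  expect_equal(sti$W["HUB", "L1"], 25 + shock)
  expect_equal(unname(sti$dd[sti$ids == "HUB"]), shock)
  # no baseline imports: import share rerouted through exports
  expect_warning(st0 <- apply_initial_shock(ch, "A", 0.3, 0), "rerouted")
  expect_equal(st0$W["A", "B"], 70)
})

test_that("synchronous step: truncation leaves residual deficit", {
  # dd = 40 against a single 25-weight out-edge: edge zeroed, 15 retained
  net <- trade_network(
    data.frame(id = c("A", "B", "C"), name = "x", gdp = 1,
               population = 10, supply = c(0, 75, 125)),
    data.frame(origin = c("A", "B"), dest = c("B", "C"),
               weight = c(100, 25)))
  # prod: A 100, B 0, C 100; shock 40% of A = 40 -> dd_B = 40
  st <- apply_initial_shock(net, "A", 0.4, 1)
  expect_equal(unname(st$dd), c(0, 40, 0))
  st2 <- cascade_step(st, tol = 1e-6 * st$shock)
  expect_equal(st2$W["B", "C"], 0)
  expect_equal(unname(st2$dd), c(0, 15, 25))
  # absorber with no out-edges: state unchanged except the step index
  st3 <- cascade_step(st2, tol = 1e-6 * st$shock)
  expect_equal(st3$W, st2$W)
  expect_equal(st3$t, st2$t + 1L)
})

test_that("full cascades on hand-traceable fixtures", {
  ch <- fixture("chain3")
  r <- run_cascade(ch, "A", 0.3, 1)
  expect_equal(unname(r$final_dd), c(0, 0, 30))
  expect_true(r$converged)
  expect_lt(r$residual, 1e-12)
  expect_equal(r$final_dd_percap[["C"]], 30 / (1000 * 365))
  # isolated origin keeps the whole shock
  iso <- trade_network(
    data.frame(id = c("A", "B"), name = "x", gdp = 1, population = 10,
               supply = c(100, 100)), NULL)
  expect_warning(ri <- run_cascade(iso, "A", 0.3, 0), "rerouted")
  expect_equal(unname(ri$final_dd), c(30, 0))
  expect_equal(ri$origin_retained, 1)
})

test_that("shock echo returns part of the burden to the origin", {
  tb <- fixture("twoblock8")
  r <- run_cascade(tb, "A1", 0.3, 1)
  expect_true(r$converged)
  expect_gt(r$final_dd[["A1"]], 0)
  expect_equal(sum(r$final_dd), r$shock, tolerance = 1e-9)
})

test_that("conservation holds at every alpha on random networks", {
  for (s in 1:10) {
    net <- random_small_network(10 + (s %% 11), s)
    o <- net$countries$id[1 + (s %% net$n)]
    for (a in c(0, 0.5, 1)) {
      r <- suppressWarnings(run_cascade(net, o, 0.3, a))
      expect_true(r$converged)
      expect_lt(abs(sum(r$final_dd) - r$shock) / r$shock, 1e-6)
      expect_true(all(r$final_dd >= 0))
      expect_true(all(r$final_weights >= 0))
    }
  }
})

test_that("relabeling countries permutes the result identically", {
  net <- random_small_network(8, 42)
  co <- net$countries
  # reverse the id alphabet: C01..C08 -> D08..D01
  relab <- setNames(sprintf("D%02d", rev(seq_len(8))), co$id)
  co2 <- co[, c("id", "name", "gdp", "population", "supply")]
  co2$id <- unname(relab[co2$id])
  ed2 <- net$edges
  ed2$origin <- unname(relab[ed2$origin]); ed2$dest <- unname(relab[ed2$dest])
  net2 <- trade_network(co2, ed2)
  o <- co$id[3]
  r1 <- run_cascade(net, o, 0.3, 1)
  r2 <- run_cascade(net2, relab[[o]], 0.3, 1)
  expect_equal(unname(r2$final_dd[relab[names(r1$final_dd)]]),
               unname(r1$final_dd), tolerance = 1e-12)
})

test_that("with no origin imports, alpha = 0 equals alpha = 1 after fallback", {
  ch <- fixture("chain3")   # A has no imports
  r1 <- run_cascade(ch, "A", 0.3, 1)
  r0 <- suppressWarnings(run_cascade(ch, "A", 0.3, 0))
  expect_identical(r0$final_dd, r1$final_dd)
})

test_that("total export weight is non-increasing after the initial boost", {
  net <- random_small_network(12, 7)
  st <- apply_initial_shock(net, net$countries$id[2], 0.3, 0.5)
  tol <- 1e-6 * st$shock
  tot <- sum(st$W)
  for (k in 1:50) {
    st <- cascade_step(st, tol)
    expect_lte(sum(st$W), tot + 1e-9)
    tot <- sum(st$W)
  }
})

test_that("oracle and engine agree on fixtures", {
  for (fx in c("chain3", "star5", "twoblock8")) {
    net <- fixture(fx)
    o <- net$countries$id[1]
    r1 <- suppressWarnings(run_cascade(net, o, 0.3, 1))
    r2 <- suppressWarnings(oracle_cascade(net, o, 0.3, 1))
    expect_equal(r1$final_dd, r2$final_dd, tolerance = 1e-12)
    expect_equal(r1$steps, r2$steps)
  }
  expect_error(oracle_cascade(generate_network(n_countries = 30, seed = 1),
                              "AAA"), "25")
})
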
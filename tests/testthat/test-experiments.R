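# chain3 cascades, hand-traced: whichever of A, B, C is shocked (shock =
# 30 kcal/yr), the deficit always ends up at C (A and B can shed it down
# the chain; C has no exports), at every alpha.
pc30 <- 30 / (1000 * 365)

chain_grid <- function(alphas = 1) {
  suppressWarnings(run_grid(fixture("chain3"), 0.3, alphas))
}

test_that("grid shape, conservation and convergence log", {
  g <- chain_grid(c(0, 1))
  expect_equal(nrow(g$grid), 2 * 3 * 3)
  expect_true(all(g$runs$converged))
  # per-cell conservation: annualized deficits sum to the origin shock
  for (a in c(0, 1)) for (o in c("A", "B", "C")) {
    rows <- g$grid[g$grid$origin == o & g$grid$alpha == a, ]
    expect_equal(sum(rows$dd_annual), g$shock[[o]], tolerance = 1e-9)
  }
  # every simulation parks the whole shock on C
  expect_equal(g$grid$dd[g$grid$dest == "C"], rep(pc30, 6))
  expect_true(all(g$grid$dd[g$grid$dest != "C"] == 0))
})

test_that("edgeless networks keep every shock at home", {
  ids <- c("A", "B", "C")
  iso <- trade_network(data.frame(id = ids, name = ids, gdp = 1,
                                  population = 100, supply = 50), NULL)
  g <- suppressWarnings(run_grid(iso, 0.3, 1))
  own <- g$grid[g$grid$origin == g$grid$dest, ]
  expect_equal(own$dd_annual, unname(g$shock[own$origin]))
  expect_true(all(g$grid$dd_annual[g$grid$origin != g$grid$dest] == 0))
  h <- hedging_share(g, 1)
  expect_equal(h$hedging, rep(0, 3))
})

test_that("exposure is the origin-mean of deficits", {
  g <- chain_grid(1)
  e <- exposure(g, 1)
  expect_equal(e$exposure[e$id == "C"], pc30)    # deficit in all 3 runs
  expect_equal(e$exposure[e$id == "A"], 0)
  # excluding the domestic run changes the divisor set: C still hit in
  # both foreign-origin runs
  e2 <- exposure(g, 1, include_domestic = FALSE)
  expect_equal(e2$exposure[e2$id == "C"], pc30)
  # permuting origins cannot change a mean over origins
  expect_equal(mean(g$grid$dd[g$grid$dest == "C"]),
               mean(sample(g$grid$dd[g$grid$dest == "C"])))
})

test_that("hedging share: full pass-on, full retention and bounds", {
  g <- chain_grid(1)
  h <- hedging_share(g, 1)
  expect_equal(h$hedging[h$id == "A"], 1)    # A sheds the whole shock
  expect_equal(h$hedging[h$id == "B"], 1)    # so does B
  expect_equal(h$hedging[h$id == "C"], 0)    # C cannot export at all
  expect_true(all(h$hedging >= 0 & h$hedging <= 1, na.rm = TRUE))
})

test_that("reserve levels are order statistics of the pooled deficits", {
  g <- chain_grid(c(0, 0.5, 1))
  # constant pooled distribution -> p95 equals the constant
  rC <- reserves_p95(g, pop_min = 0)
  expect_equal(rC$reserve[rC$id == "C"], pc30)
  expect_equal(rC$reserve[rC$id == "A"], 0)
  # population filter and the percent-of-supply column
  expect_equal(nrow(reserves_p95(g, pop_min = 1e6)), 0L)
  supply_pcd <- 150 / (1000 * 365)
  expect_equal(rC$pct_supply[rC$id == "C"], 100 * pc30 / supply_pcd)
  # table sorted by descending reserve
  expect_equal(rC$id[1], "C")
})

test_that("p95 matches a direct interpolated order-statistic oracle", {
  set.seed(4)
  v <- sample(stats::rexp(300))
  fake <- structure(list(
    grid = data.frame(origin = "O", dest = "X", alpha = 1, dd = v,
                      dd_annual = v),
    countries = data.frame(id = "X", name = "X", gdp = 1,
                           population = 1000, supply = 365000),
    days_per_year = 365, shock = c(X = 1)), class = "shock_grid")
  s <- sort(v); h <- (length(v) - 1) * 0.95 + 1
  manual <- s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)])
  expect_equal(reserves_p95(fake, pop_min = 0)$reserve, manual)
})

test_that("vulnerability counts: direct count and threshold monotonicity", {
  g <- chain_grid(c(0, 1))
  ct <- vulnerability_counts(g, pc30)
  expect_equal(ct$count[ct$id == "C"], c(3, 3))  # hit in every run
  expect_equal(ct$count[ct$id == "B"], c(0, 0))
  c2 <- vulnerability_counts(g, 2 * pc30)
  expect_true(all(c2$count <= ct$count))
  expect_true(all(vulnerability_counts(g, Inf)$count == 0))
})

test_that("rank vulnerability: ties, extremes and monotone transform", {
  g <- chain_grid(1)
  rk <- vulnerability_rank(g)
  # each run ranks dd = (0, 0, 30): ranks (1.5, 1.5, 3), summed over
  # the 3 origins
  expect_equal(rk$rank_sum[rk$id == "C"], 9)
  expect_equal(rk$rank_sum[rk$id == "A"], 4.5)
  expect_equal(rk$log_rank_sum, log(rk$rank_sum))
  # all-zero grid: full tie everywhere
  iso <- trade_network(data.frame(id = c("A", "B"), name = "x", gdp = 1,
                                  population = 100, supply = 50), NULL)
  gi <- suppressWarnings(run_grid(iso, 0.3, 1))
  # the only nonzero cells are domestic; ranks still well defined
  ri <- vulnerability_rank(gi)
  expect_equal(ri$rank_sum, c(3, 3))             # rank 2 once, rank 1 once
})

test_that("cascade_distributions reports before/after degree pruning", {
  tb <- fixture("twoblock8")
  d <- cascade_distributions(tb, "A1", 0.3, 1)
  before <- d[d$stage == "before", ]
  after <- d[d$stage == "after", ]
  expect_equal(sum(before$out_strength), sum(weight_matrix(tb)))
  expect_true(sum(after$out_strength) <= sum(before$out_strength))
  expect_true(all(after$out_degree <= before$out_degree))
})
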
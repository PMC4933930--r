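test_that("cost-neutral prices match the closed form and the published values", {
  for (i in seq_len(nrow(printed_cost_neutral))) {
    th <- printed_cost_neutral$threshold[i]
    for (direct in c(TRUE, FALSE)) {
      s <- strategy("contingent", th, direct)
      root <- solve_cost_neutral_price(national, s, tol = 1e-4)
      cf <- solve_cost_neutral_price(national, s, closed_form = TRUE)
      expect_lt(abs(root - cf), 0.01,
                label = paste(s$label, "root vs closed form"))
      printed <- if (direct) printed_cost_neutral$direct[i] else
        printed_cost_neutral$nodirect[i]
      expect_lt(abs(root - printed), 2,
                label = paste(s$label, "within GBP 2 of", printed))
    }
  }
  # ordering: relaxing the threshold demands a cheaper test
  expect_true(all(diff(vapply(c(150, 500, 1000), function(th)
    solve_cost_neutral_price(national, strategy("contingent", th, TRUE)),
    0)) < 0))
  expect_error(solve_cost_neutral_price(national, "current"), "contingent")
  expect_error(solve_cost_neutral_price(
    screening_params("national", u_nipt_high = 0, u_nipt_int = 0), "1/150"),
    "n_nipt = 0")
})

test_that("solver returns the base price when already cost neutral", {
  s <- strategy("contingent", 150, TRUE)
  cstar <- solve_cost_neutral_price(national, s, closed_form = TRUE)
  p <- screening_params("national", c_nipt_lab = cstar)
  expect_equal(solve_cost_neutral_price(p, s), cstar, tolerance = 1e-4)
  expect_lt(abs(incremental(p, s)$d_total_cost), 1)
})

test_that("price sweep curves are affine with slope n_nipt * (1 + repeat rate)", {
  sw <- price_sweep(national, prices = c(100, 250, 400))
  for (s in enumerate_strategies()[-1]) {
    r <- evaluate_pathway(national, s)
    cur <- sw[sw$strategy == s$label, ]
    slope <- diff(cur$d_total_cost) / diff(cur$price)
    expect_equal(slope, rep(r$n_nipt * 1.012, 2), tolerance = 1e-9,
                 label = paste(s$label, "slope"))
    # at the base price the sweep equals the deterministic incremental
    expect_equal(cur$d_total_cost[cur$price == 250],
                 incremental(national, s)$d_total_cost)
  }
  expect_error(price_sweep(national, prices = numeric(0)), "empty")
})

test_that("sweep interpolation root agrees with the solver within GBP 0.01", {
  for (tok in c("1/150", "1/150-no-direct")) {
    root <- solve_cost_neutral_price(national, tok, tol = 1e-4)
    sw <- price_sweep(national, strategies = list(tok),
                      prices = c(root - 50, root + 50))
    interp <- sw$price[1] - sw$d_total_cost[1] *
      diff(sw$price) / diff(sw$d_total_cost)
    expect_lt(abs(interp - root), 0.01)
    # sign flips across the root
    lo <- price_sweep(national, strategies = list(tok), prices = root - 10)
    hi <- price_sweep(national, strategies = list(tok), prices = root + 10)
    expect_lt(lo$d_total_cost * hi$d_total_cost, 0)
  }
})

test_that("one-way thresholds reproduce the published cost-neutrality points", {
  s150 <- strategy("contingent", 150, TRUE)
  # NIPT uptake in high-risk women, complement absorbed by direct testing
  q <- threshold_query(s150, "u_nipt_high",
                       coupling = "complement_within_further_testing")
  expect_lt(abs(one_way_threshold(national, q) - 0.713), 0.003)
  # screening uptake under the NIPT programme, current arm at base
  q2 <- threshold_query(s150, "u_screen", arm = "strategy")
  expect_lt(abs(one_way_threshold(national, q2) - 0.664), 0.003)
  # screening uptake in the current programme, NIPT arm at base
  q3 <- threshold_query(s150, "u_screen", arm = "current")
  expect_lt(abs(one_way_threshold(national, q3) - 0.660), 0.003)
})

test_that("threshold solving is invariant to the bracketing interval", {
  s150 <- strategy("contingent", 150, TRUE)
  r1 <- one_way_threshold(national, threshold_query(
    s150, "u_nipt_high", "complement_within_further_testing", c(0, 1)))
  r2 <- one_way_threshold(national, threshold_query(
    s150, "u_nipt_high", "complement_within_further_testing", c(0.5, 0.9)))
  expect_equal(r1, r2, tolerance = 1e-5)
})

test_that("a cost-invariant parameter reports no crossing", {
  q <- threshold_query(strategy("contingent", 150, TRUE), "p_ipd_miscarriage")
  expect_error(one_way_threshold(national, q),
               class = "niptscreen_no_crossing")
  expect_error(one_way_threshold(national, q), "not cost-neutral")
})

test_that("uptake scenarios evaluate both 1/150 variants per row", {
  out <- uptake_scenarios(national, printed_table5)
  expect_equal(out$total_uptake, printed_table5$u_nipt_high +
                 printed_table5$u_direct_ipd)
  expect_printed(out$d_cost_direct / 1000, printed_table5$d_cost_direct_k,
                 "direct-allowed column")
  expect_printed(out$d_cost_nodirect / 1000,
                 printed_table5$d_cost_nodirect_k, "no-direct column")

  # no further testing at all: only the current invasive costs remain
  zero <- uptake_scenarios(national, data.frame(
    label = "none", u_nipt_high = 0, u_direct_ipd = 0))
  cur <- evaluate_pathway(national, "current")
  expect_equal(zero$d_cost_direct, -cur$cost_ipd)
  expect_equal(zero$d_cost_nodirect, -cur$cost_ipd)

  expect_error(uptake_scenarios(national, data.frame(
    label = "bad", u_nipt_high = 0.8, u_direct_ipd = 0.4)), "<= 1")
})
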
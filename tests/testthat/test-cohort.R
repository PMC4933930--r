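s150 <- strategy("contingent", 150, TRUE)

test_that("forced parameters force the path", {
  p <- screening_params("national", u_screen = 1, p_risk_high = 1,
                        u_nipt_high = 1, u_direct_ipd = 0)
  co <- simulate_cohort(p, 500, s150, seed = 1)
  expect_true(all(co$screened))
  expect_true(all(co$risk_band == ">=1/150"))
  expect_true(all(co$choice == "nipt"))
  expect_true(all(co$nipt_result != "none"))
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_cohort(national, 5000, s150, seed = 99)
  b <- simulate_cohort(national, 5000, s150, seed = 99)
  expect_identical(a, b)
  c <- simulate_cohort(national, 5000, s150, seed = 100)
  expect_false(identical(a, c))
})

test_that("screening counts match the generating uptake at study scale", {
  # rapid preset: screening uptake is the pre-NIPT historical 78.7%
  co <- simulate_cohort(screening_params("rapid"), 40527, s150, seed = 2)
  exp_n <- 40527 * 0.787
  se <- sqrt(40527 * 0.787 * (1 - 0.787))
  expect_lt(abs(sum(co$screened) - exp_n), 3 * se)
  # the observed study uptake (76.0%, 30 790/40 527) under its own value
  co2 <- simulate_cohort(screening_params("rapid", u_screen = 0.76),
                         40527, s150, seed = 2)
  se2 <- sqrt(40527 * 0.76 * 0.24)
  expect_lt(abs(sum(co2$screened) - 30790), 3 * se2)
})

test_that("cohort flow conserves counts and respects the record grammar", {
  for (scen in list(strategy("current"), s150,
                    strategy("contingent", 1000, FALSE))) {
    co <- simulate_cohort(national, 30000, scen, seed = 4)
    scr <- co[co$screened, ]
    expect_equal(nrow(scr),
                 sum(scr$risk_band %in%
                       c("<1/1000", "1/151-1/1000", ">=1/150")))
    expect_true(all((co$nipt_result != "none") == (co$choice == "nipt")))
    expect_true(all((co$ipd_result != "none") ==
                      (co$confirmatory_ipd |
                         (co$choice == "direct_ipd" &
                            co$outcome != "lost_to_followup"))))
    # direct invasive choice only where allowed
    if (scen$mode == "contingent" && !scen$direct_ipd)
      expect_false(any(co$choice == "direct_ipd"))
    # a miscarriage implies an invasive test happened
    expect_true(all(co$ipd_result[co$procedure_miscarriage] != "none"))
    # every NIPT positive is confirmed, declined, or lost to follow-up
    pos <- co$nipt_result == "positive"
    expect_true(all(co$confirmatory_ipd[pos] |
                      co$outcome[pos] == "lost_to_followup" |
                      !co$confirmatory_ipd[pos]))
    expect_true(all(co$confirmatory_ipd == (co$choice == "nipt" &
                      co$nipt_result == "positive" & co$confirmatory_ipd)))
  }
})

test_that("estimation reproduces the published cohort uptake fractions", {
  # hand-built cohort: 934 high-risk women of whom 695 chose NIPT,
  # 2241 intermediate of whom 1799 chose NIPT
  n <- 934 + 2241
  co <- data.frame(
    id = seq_len(n), booked = TRUE, screened = TRUE,
    screen_type = "combined",
    risk_band = rep(c(">=1/150", "1/151-1/1000"), c(934, 2241)),
    sub_band = rep(c(NA, "1/501-1/1000"), c(934, 2241)),
    offered_nipt = TRUE, true_status = "unaffected",
    choice = c(rep(c("nipt", "direct_ipd", "decline"), c(695, 166, 73)),
               rep(c("nipt", "decline"), c(1799, 442))),
    nipt_result = "negative", nipt_repeated = FALSE,
    confirmatory_ipd = FALSE, ipd_result = "none",
    procedure_miscarriage = FALSE, outcome = "continue",
    stringsAsFactors = FALSE)
  co$nipt_result[co$choice != "nipt"] <- "none"
  co$ipd_result[co$choice == "direct_ipd"] <- "negative"
  est <- estimate_params(co)$estimates
  u_high <- est[est$field == "u_nipt_high", ]
  expect_equal(u_high$estimate, 695 / 934)         # 74.4%
  expect_equal(round(100 * u_high$estimate, 1), 74.4)
  u_int <- est[est$field == "u_nipt_int", ]
  expect_equal(round(100 * u_int$estimate, 1), 80.3)
  expect_true(u_high$lower < u_high$estimate & u_high$estimate < u_high$upper)
})

test_that("zero denominators are flagged, not fatal", {
  co <- simulate_cohort(national, 2000, strategy("current"), seed = 6)
  est <- estimate_params(co)$estimates
  expect_false(est$estimable[est$field == "u_ipd_current"] &&
                 est$n[est$field == "u_ipd_current"] == 0)
  expect_false("u_nipt_high" %in% est$field[est$estimable])
  # a cohort with no screened women cannot estimate band frequencies
  co0 <- simulate_cohort(screening_params("national", u_screen = 0),
                         100, s150, seed = 1)
  est0 <- estimate_params(co0)$estimates
  expect_false(est0$estimable[est0$field == "p_risk_high"])
  expect_true(est0$estimable[est0$field == "u_screen"])
})

test_that("parameters re-estimated from a large cohort recover the truth", {
  co <- simulate_cohort(national, 300000, s150, seed = 8,
                        control = cohort_control(loss_to_followup = 0))
  est <- estimate_params(co)
  tab <- est$estimates[est$estimates$estimable, ]
  # 5 binomial SEs per field keeps the joint false-alarm rate negligible;
  # the exact-CI calibration over 100 seeds lives in the acceptance suite
  for (i in seq_len(nrow(tab))) {
    truth <- national[[tab$field[i]]]
    se <- sqrt(truth * (1 - truth) / tab$n[i])
    expect_lt(abs(tab$estimate[i] - truth), 5 * se + 1e-9,
              label = sprintf("%s: |%.4f - %.4f| vs 5 SE", tab$field[i],
                              tab$estimate[i], truth))
  }
  expect_equal(est$params$c_nipt_lab, 250)  # costs pass through
})

test_that("diagnostic accuracy uses exact equal-tailed intervals", {
  # PPV from 50 concordant / 5 discordant positives
  acc <- diagnostic_accuracy(tp = 50, fp = 5, tn = 2000, fn = 0)
  ppv <- acc[acc$statistic == "ppv", ]
  expect_equal(round(100 * ppv$estimate, 1), 90.9)
  # zero observed failures: lower bound has the closed form (a/2)^(1/n)
  sens <- acc[acc$statistic == "sensitivity", ]
  expect_equal(sens$estimate, 1)
  acc72 <- diagnostic_accuracy(tp = 72, fp = 0, tn = 10, fn = 0)
  s72 <- acc72[acc72$statistic == "sensitivity", ]
  expect_equal(s72$lower, 0.025^(1 / 72), tolerance = 1e-12)
  expect_equal(s72$upper, 1)
  # degenerate single counts
  acc1 <- diagnostic_accuracy(tp = 1, fp = 0, tn = 1, fn = 0)
  expect_equal(acc1$estimate, c(1, 1, 1))
  expect_error(diagnostic_accuracy(0, 0, 0, 0), "all counts are zero")
  # intervals contain the point and tighten as counts scale up
  a <- diagnostic_accuracy(tp = 9, fp = 1, tn = 85, fn = 5)
  b <- diagnostic_accuracy(tp = 90, fp = 10, tn = 850, fn = 50)
  expect_true(all(a$lower <= a$estimate & a$estimate <= a$upper))
  expect_true(all(b$upper - b$lower < a$upper - a$lower))
})

test_that("accuracy counts from a generated cohort behave like the error model", {
  co <- simulate_cohort(national, 400000, s150, seed = 12)
  cts <- accuracy_counts(co)
  expect_true(all(unlist(cts) >= 0))
  acc <- diagnostic_accuracy(cts$tp, cts$fp, cts$tn, cts$fn)
  # NIPT is generated perfectly sensitive; discordants create fp > 0
  expect_equal(acc$estimate[acc$statistic == "sensitivity"], 1)
  expect_gt(cts$fp, 0)
  expect_lt(acc$estimate[acc$statistic == "ppv"], 1)
})
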
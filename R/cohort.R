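# Individual-level synthetic cohorts with the structure of the prospective
# study flow: booking -> screening uptake -> risk band -> testing choice
# (NIPT / direct invasive / decline) -> test result -> confirmatory invasive
# testing -> pregnancy outcome. The generator draws every transition from
# the screening_params probabilities, so re-estimating those parameters from
# a generated cohort is a closed-loop calibration check, and aggregating a
# large cohort is an independent Monte-Carlo oracle for the deterministic
# decision tree.

#' Control knobs for the cohort generator
#'
#' Parameters of the generator that sit outside the decision model proper:
#' the discordant-positive rate (positive NIPT not confirmed as Down's
#' syndrome; governs the true status behind unconfirmed positives), the
#' loss-to-follow-up proportion applied after the testing choice, and the
#' band-specific probabilities of continuing a pregnancy after a confirmed
#' diagnosis (observed 13/42 after NIPT, 2/29 after direct invasive
#' testing). Pregnancy decisions are outside the cost scope; they only
#' colour the `outcome` column.
#'
#' @param discordant_positive_rate probability that an unconfirmed NIPT
#'   positive is not a true Down's syndrome pregnancy (default 5/55).
#' @param loss_to_followup proportion lost to follow-up after the testing
#'   choice (default 0.06).
#' @param p_continue_after_nipt,p_continue_after_direct probability of
#'   continuing the pregnancy after a confirmed diagnosis.
#' @return a named list of class `cohort_control`.
#' @export
cohort_control <- function(discordant_positive_rate = 5 / 55,
                           loss_to_followup = 0.06,
                           p_continue_after_nipt = 13 / 42,
                           p_continue_after_direct = 2 / 29) {
  ctl <- list(discordant_positive_rate = discordant_positive_rate,
              loss_to_followup = loss_to_followup,
              p_continue_after_nipt = p_continue_after_nipt,
              p_continue_after_direct = p_continue_after_direct)
  for (f in names(ctl))
    if (ctl[[f]] < 0 || ctl[[f]] > 1)
      stop("'", f, "' must be a proportion in [0, 1]")
  class(ctl) <- "cohort_control"
  ctl
}

#' Simulate an individual-level screening cohort
#'
#' Draws one trajectory per booked woman through the screening flow under a
#' given testing strategy, by sequential Bernoulli/multinomial draws from
#' the `screening_params` probabilities. NIPT is treated as perfectly
#' sensitive; positive-predictive behaviour arises from the configurable
#' discordant-positive rate. Deterministic under a fixed seed.
#'
#' @param params a [screening_params()] object.
#' @param n_booked number of women booked for maternity care (>= 1).
#' @param scenario the [strategy()] the cohort experiences (default:
#'   contingent 1/150 with direct invasive testing).
#' @param seed integer RNG seed.
#' @param control a [cohort_control()].
#' @return a data.frame, one row per woman, with columns: `id`, `booked`,
#'   `screened`, `screen_type` (combined/quadruple), `risk_band`
#'   (`"<1/1000"`, `"1/151-1/1000"`, `">=1/150"`), `sub_band`
#'   (`"1/151-1/500"` / `"1/501-1/1000"` within the intermediate band),
#'   `offered_nipt`, `true_status` (`"unaffected"`/`"DS"`), `choice`
#'   (`"nipt"`, `"direct_ipd"`, `"decline"`, `"none"`), `nipt_result`
#'   (`"negative"`, `"positive"`, `"none"`), `nipt_repeated`,
#'   `confirmatory_ipd`, `ipd_result` (`"negative"`, `"positive"`,
#'   `"none"`), `procedure_miscarriage`, `outcome` (`"continue"`,
#'   `"termination"`, `"miscarriage"`, `"lost_to_followup"`).
#' @export
simulate_cohort <- function(params, n_booked, scenario = strategy("contingent",
                                                                  150, TRUE),
                            seed = 1L, control = cohort_control()) {
  params <- validate_params(params)
  scenario <- parse_strategy(scenario)
  stopifnot(n_booked >= 1)
  n <- as.integer(n_booked)
  set.seed(seed)

  screened <- runif(n) < params$u_screen
  screen_type <- rep(NA_character_, n)
  screen_type[screened] <- "quadruple"
  screen_type[screened & runif(n) < params$p_combined] <- "combined"

  # risk band among screened women
  band <- rep(NA_character_, n)
  u <- runif(n)
  band[screened] <- "<1/1000"
  band[screened & u < params$p_risk_high + params$p_risk_int1000] <-
    "1/151-1/1000"
  band[screened & u < params$p_risk_high] <- ">=1/150"
  high <- !is.na(band) & band == ">=1/150"
  inter <- !is.na(band) & band == "1/151-1/1000"

  sub_band <- rep(NA_character_, n)
  p_sub500 <- if (params$p_risk_int1000 > 0)
    params$p_risk_int500 / params$p_risk_int1000 else 0
  sub_band[inter] <- "1/501-1/1000"
  sub_band[inter & runif(n) < p_sub500] <- "1/151-1/500"

  # eligibility for the NIPT offer under this scenario
  offered <- rep(FALSE, n)
  if (scenario$mode == "contingent") {
    offered[high] <- TRUE
    if (scenario$threshold == 500)
      offered[inter & sub_band == "1/151-1/500"] <- TRUE
    if (scenario$threshold == 1000) offered[inter] <- TRUE
  }

  # testing choice
  choice <- rep("none", n)
  u2 <- runif(n)
  if (scenario$mode == "current") {
    choice[high] <- "decline"
    choice[high & u2 < params$u_ipd_current] <- "direct_ipd"
  } else {
    choice[high] <- "decline"
    if (scenario$direct_ipd) {
      choice[high & u2 < params$u_nipt_high + params$u_direct_ipd] <-
        "direct_ipd"
      choice[high & u2 < params$u_nipt_high] <- "nipt"
    } else {
      choice[high & u2 < params$u_nipt_high_nodirect] <- "nipt"
    }
    oi <- offered & inter
    choice[oi] <- "decline"
    choice[oi & u2 < params$u_nipt_int] <- "nipt"
  }
  took_nipt <- choice == "nipt"
  took_direct <- choice == "direct_ipd"

  # NIPT result: band- and scenario-specific positive rate
  p_pos <- rep(0, n)
  if (scenario$mode == "contingent") {
    p_pos[high] <- if (scenario$direct_ipd) params$p_nipt_pos_high
                   else params$p_nipt_pos_high_nodirect
    p_pos[inter] <- if (scenario$threshold == 500) params$p_nipt_pos_int500
                    else params$p_nipt_pos_int1000
  }
  nipt_result <- rep("none", n)
  nipt_result[took_nipt] <- "negative"
  nipt_result[took_nipt & runif(n) < p_pos] <- "positive"
  nipt_repeated <- rep(FALSE, n)
  nipt_repeated[took_nipt] <- runif(sum(took_nipt)) < params$p_nipt_repeat
  nipt_pos <- nipt_result == "positive"

  # loss to follow-up after the testing choice
  ltf <- rep(FALSE, n)
  tested <- took_nipt | took_direct
  ltf[tested] <- runif(sum(tested)) < control$loss_to_followup

  # invasive testing: direct, or confirmatory after a positive NIPT
  confirmatory <- rep(FALSE, n)
  cand <- nipt_pos & !ltf
  confirmatory[cand] <- runif(sum(cand)) < params$u_ipd_after_nipt
  had_ipd <- (took_direct & !ltf) | confirmatory

  ipd_result <- rep("none", n)
  p_ipd_pos <- rep(0, n)
  p_ipd_pos[took_direct] <- if (scenario$mode == "current")
    params$p_ipd_pos_current else params$p_ipd_pos_direct
  p_ipd_pos[confirmatory] <- params$p_ipd_pos_after_nipt
  ipd_result[had_ipd] <- "negative"
  ipd_result[had_ipd & runif(n) < p_ipd_pos] <- "positive"

  # true status: diagnostic tests define it; unconfirmed NIPT positives are
  # true cases except at the discordant rate; everyone else unaffected
  true_status <- rep("unaffected", n)
  true_status[ipd_result == "positive"] <- "DS"
  unconf_pos <- nipt_pos & !confirmatory
  true_status[unconf_pos] <- "DS"
  true_status[unconf_pos &
                runif(n) < control$discordant_positive_rate] <- "unaffected"

  miscarriage <- rep(FALSE, n)
  miscarriage[had_ipd] <- runif(sum(had_ipd)) < params$p_ipd_miscarriage

  # pregnancy outcome (outside the cost scope)
  outcome <- rep("continue", n)
  diag_nipt <- confirmatory & ipd_result == "positive"
  diag_direct <- took_direct & ipd_result == "positive"
  u3 <- runif(n)
  outcome[diag_nipt] <- "termination"
  outcome[diag_nipt & u3 < control$p_continue_after_nipt] <- "continue"
  outcome[diag_direct] <- "termination"
  outcome[diag_direct & u3 < control$p_continue_after_direct] <- "continue"
  outcome[miscarriage] <- "miscarriage"
  outcome[ltf] <- "lost_to_followup"

  data.frame(
    id = seq_len(n), booked = TRUE, screened = screened,
    screen_type = screen_type, risk_band = band, sub_band = sub_band,
    offered_nipt = offered, true_status = true_status, choice = choice,
    nipt_result = nipt_result, nipt_repeated = nipt_repeated,
    confirmatory_ipd = confirmatory, ipd_result = ipd_result,
    procedure_miscarriage = miscarriage, outcome = outcome,
    stringsAsFactors = FALSE
  )
}

# Clopper-Pearson equal-tailed exact binomial interval via beta quantiles.
.clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lower <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Re-estimate screening parameters from a cohort
#'
#' Estimates every proportion field whose numerator and denominator are
#' observable in the cohort (which fields are estimable depends on the
#' scenario the cohort was generated under), as successes/denominator with
#' an exact Clopper-Pearson 95% interval. Fields with a zero denominator
#' are flagged not-estimable, never an error. Costs and the population size
#' are not observable in a cohort and are passed through from `base`.
#'
#' @param cohort a data.frame from [simulate_cohort()] (or CSV re-read).
#' @param base a [screening_params()] supplying costs and any field the
#'   cohort cannot estimate (default: national preset).
#' @param conf confidence level for the intervals.
#' @return a list with `params` (a `screening_params` whose estimable
#'   proportions are replaced by cohort estimates) and `estimates` (a
#'   data.frame: `field`, `x`, `n`, `estimate`, `lower`, `upper`,
#'   `estimable`).
#' @export
estimate_params <- function(cohort, base = screening_params("national"),
                            conf = 0.95) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1)
  base <- validate_params(base)
  high <- cohort$risk_band %in% ">=1/150"
  inter <- cohort$risk_band %in% "1/151-1/1000"
  screened <- cohort$screened
  nipt <- cohort$choice == "nipt"
  direct <- cohort$choice == "direct_ipd"
  offered_int <- cohort$offered_nipt & inter
  pos <- cohort$nipt_result == "positive"
  conf_ipd <- cohort$confirmatory_ipd
  had_ipd <- conf_ipd | (direct & cohort$ipd_result != "none")
  ltf <- cohort$outcome == "lost_to_followup"

  # scenario features, inferred from the flow actually present
  contingent <- any(cohort$offered_nipt)
  direct_allowed <- contingent && any(direct)
  th1000 <- any(offered_int & cohort$sub_band %in% "1/501-1/1000")

  est <- list()
  add <- function(field, x, n) est[[field]] <<- c(x = x, n = n)
  add("u_screen", sum(screened), nrow(cohort))
  add("p_combined", sum(cohort$screen_type %in% "combined"), sum(screened))
  add("p_quadruple", sum(cohort$screen_type %in% "quadruple"), sum(screened))
  add("p_risk_high", sum(high), sum(screened))
  add("p_risk_int500", sum(cohort$sub_band %in% "1/151-1/500"),
      sum(screened))
  add("p_risk_int1000", sum(inter), sum(screened))
  if (contingent) {
    if (direct_allowed) {
      add("u_nipt_high", sum(nipt & high), sum(high))
      add("u_direct_ipd", sum(direct & high), sum(high))
      add("p_nipt_pos_high", sum(pos & high), sum(nipt & high))
    } else {
      add("u_nipt_high_nodirect", sum(nipt & high), sum(high))
      add("p_nipt_pos_high_nodirect", sum(pos & high), sum(nipt & high))
    }
    add("u_nipt_int", sum(nipt & offered_int), sum(offered_int))
    int_field <- if (th1000) "p_nipt_pos_int1000" else "p_nipt_pos_int500"
    add(int_field, sum(pos & inter), sum(nipt & inter))
    add("p_nipt_repeat", sum(cohort$nipt_repeated), sum(nipt))
    add("u_ipd_after_nipt", sum(conf_ipd), sum(pos & !ltf))
    add("p_ipd_pos_after_nipt", sum(conf_ipd & cohort$ipd_result == "positive"),
        sum(conf_ipd))
    add("p_ipd_pos_direct", sum(direct & cohort$ipd_result == "positive"),
        sum(direct & cohort$ipd_result != "none"))
  } else {
    add("u_ipd_current", sum(direct & high), sum(high))
    add("p_ipd_pos_current", sum(direct & cohort$ipd_result == "positive"),
        sum(direct & cohort$ipd_result != "none"))
  }
  add("p_ipd_miscarriage", sum(cohort$procedure_miscarriage), sum(had_ipd))

  tab <- do.call(rbind, lapply(names(est), function(f) {
    x <- est[[f]][["x"]]; n <- est[[f]][["n"]]
    if (n > 0) {
      ci <- .clopper_pearson(x, n, conf)
      data.frame(field = f, x = x, n = n, estimate = x / n,
                 lower = ci[["lower"]], upper = ci[["upper"]],
                 estimable = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(field = f, x = x, n = n, estimate = NA_real_,
                 lower = NA_real_, upper = NA_real_, estimable = FALSE,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(tab) <- NULL

  params <- base
  for (i in seq_len(nrow(tab)))
    if (tab$estimable[i]) params[[tab$field[i]]] <- tab$estimate[i]
  # keep the mix constraint exact after estimation
  params$p_quadruple <- 1 - params$p_combined
  params <- tryCatch(validate_params(params), error = function(e) {
    warning("estimated parameters violate an invariant (",
            conditionMessage(e), "); returning base values for params")
    base
  })
  list(params = params, estimates = tab)
}

#' Diagnostic accuracy with exact binomial intervals
#'
#' Sensitivity, specificity and positive predictive value from a 2x2
#' confusion table of confirmed-outcome tests, each with an exact
#' Clopper-Pearson equal-tailed interval.
#'
#' @param tp,fp,tn,fn confusion-table counts (non-negative).
#' @param conf confidence level (default 0.95).
#' @return a data.frame with rows `sensitivity`, `specificity`, `ppv` and
#'   columns `x`, `n`, `estimate`, `lower`, `upper`. A statistic whose
#'   denominator is zero has `NA` estimate and interval.
#' @examples
#' diagnostic_accuracy(tp = 50, fp = 5, tn = 2000, fn = 0)  # PPV 90.9%
#' @export
diagnostic_accuracy <- function(tp, fp, tn, fn, conf = 0.95) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("all counts are zero")
  one <- function(name, x, n) {
    if (n > 0) {
      ci <- .clopper_pearson(x, n, conf)
      data.frame(statistic = name, x = x, n = n, estimate = x / n,
                 lower = ci[["lower"]], upper = ci[["upper"]],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(statistic = name, x = x, n = n, estimate = NA_real_,
                 lower = NA_real_, upper = NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- rbind(one("sensitivity", tp, tp + fn),
               one("specificity", tn, tn + fp),
               one("ppv", tp, tp + fp))
  rownames(out) <- NULL
  out
}

#' Extract a confusion table from a cohort
#'
#' Counts true/false positives/negatives of NIPT among cohort women with a
#' confirmed outcome (a diagnostic invasive test, or birth follow-up for
#' those not lost), against the `true_status` column.
#'
#' @param cohort a data.frame from [simulate_cohort()].
#' @return a named list with `tp`, `fp`, `tn`, `fn`.
#' @export
accuracy_counts <- function(cohort) {
  tested <- cohort$choice == "nipt" &
    cohort$outcome != "lost_to_followup"
  pos <- cohort$nipt_result == "positive"
  ds <- cohort$true_status == "DS"
  list(tp = sum(tested & pos & ds),
       fp = sum(tested & pos & !ds),
       tn = sum(tested & !pos & !ds),
       fn = sum(tested & !pos & ds))
}

#' Aggregate a cohort to pathway-level counts
#'
#' Sums an individual-level cohort into the count fields of a
#' [evaluate_pathway()] result (screened, NIPT tests, direct and
#' confirmatory invasive tests, detections, confirmed cases,
#' procedure-related miscarriages), for direct comparison with the
#' deterministic decision tree at `population_size = n_booked`.
#' Loss to follow-up is not part of the deterministic tree, so cohorts
#' meant for this comparison should be generated with
#' `cohort_control(loss_to_followup = 0)`.
#'
#' @param cohort a data.frame from [simulate_cohort()].
#' @return a named numeric vector of counts.
#' @export
cohort_counts <- function(cohort) {
  nipt_pos <- cohort$nipt_result == "positive"
  direct <- cohort$choice == "direct_ipd" & cohort$ipd_result != "none"
  c(n_screened = sum(cohort$screened),
    n_nipt = sum(cohort$choice == "nipt"),
    n_nipt_positive = sum(nipt_pos),
    n_ipd_direct = sum(direct),
    n_ipd_after_nipt = sum(cohort$confirmatory_ipd),
    n_ds_detected = sum(direct & cohort$ipd_result == "positive") +
      sum(nipt_pos),
    n_ds_confirmed_ipd = sum(cohort$ipd_result == "positive"),
    n_miscarriage = sum(cohort$procedure_miscarriage))
}
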
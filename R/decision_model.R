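# Deterministic decision-tree evaluation. The tree uses expected-value
# (cohort-mean) arithmetic: fractional women are carried exactly and only
# rounded for presentation. The same arithmetic core is vectorised over
# parameter draws so the probabilistic sensitivity analysis reuses it
# unchanged.

#' Mean cost of a first-line screening test
#'
#' Mixture of the first-trimester combined and second-trimester quadruple
#' test costs, weighted by the proportion of screens of each type.
#'
#' @param params a [screening_params()] object.
#' @return cost in GBP per screened woman.
#' @examples
#' per_screen_cost(screening_params("national"))  # 28.79
#' @export
per_screen_cost <- function(params) {
  params <- validate_params(params)
  params$p_combined * params$c_combined +
    params$p_quadruple * params$c_quadruple
}

#' Unit cost of an NIPT test
#'
#' Laboratory + midwife counselling/feedback + phlebotomy costs, plus the
#' expected cost of repeat tests. Repeats incur the laboratory cost only
#' (the sample is redrawn and re-run; counselling is not repeated), so
#' the unit cost is
#' `c_lab + c_counsel + c_phleb + p_repeat * c_lab`.
#'
#' @param params a [screening_params()] object.
#' @return cost in GBP per woman tested.
#' @examples
#' nipt_unit_cost(screening_params("national"))  # 277.96
#' @export
nipt_unit_cost <- function(params) {
  params <- validate_params(params)
  with(params, c_nipt_lab + c_nipt_counsel + c_nipt_phleb +
         p_nipt_repeat * c_nipt_lab)
}

# Vectorised tree arithmetic. `p` is a named list whose elements are numeric
# vectors of common length (length 1 for the deterministic model, n_sims for
# the PSA). Returns a list of output vectors.
.pathway_compute <- function(p, strat) {
  n_screened <- p$population_size * p$u_screen
  high <- n_screened * p$p_risk_high
  per_screen <- p$p_combined * p$c_combined + p$p_quadruple * p$c_quadruple
  nipt_unit <- p$c_nipt_lab + p$c_nipt_counsel + p$c_nipt_phleb +
    p$p_nipt_repeat * p$c_nipt_lab
  zero <- 0 * n_screened

  if (strat$mode == "current") {
    n_ipd_direct <- high * p$u_ipd_current
    n_ipd_after <- zero
    n_nipt <- zero
    nipt_pos <- zero
    n_detected <- n_ipd_direct * p$p_ipd_pos_current
    n_confirmed <- n_detected
    n_positive_at_threshold <- high  # the group offered further testing
  } else {
    intermediate <- switch(as.character(strat$threshold),
      "150"  = zero,
      "500"  = n_screened * p$p_risk_int500,
      "1000" = n_screened * p$p_risk_int1000)
    n_positive_at_threshold <- high + intermediate
    p_pos_int <- if (strat$threshold == 500) p$p_nipt_pos_int500
                 else p$p_nipt_pos_int1000
    if (strat$direct_ipd) {
      nipt_high <- high * p$u_nipt_high
      n_ipd_direct <- high * p$u_direct_ipd
      pos_high <- nipt_high * p$p_nipt_pos_high
    } else {
      nipt_high <- high * p$u_nipt_high_nodirect
      n_ipd_direct <- zero
      pos_high <- nipt_high * p$p_nipt_pos_high_nodirect
    }
    nipt_int <- intermediate * p$u_nipt_int
    n_nipt <- nipt_high + nipt_int
    nipt_pos <- pos_high + nipt_int * p_pos_int
    n_ipd_after <- nipt_pos * p$u_ipd_after_nipt
    ipd_direct_pos <- n_ipd_direct * p$p_ipd_pos_direct
    n_detected <- ipd_direct_pos + nipt_pos
    n_confirmed <- ipd_direct_pos + n_ipd_after * p$p_ipd_pos_after_nipt
  }

  n_ipd <- n_ipd_direct + n_ipd_after
  cost_screening <- n_screened * per_screen
  cost_nipt <- n_nipt * nipt_unit
  cost_ipd <- n_ipd * p$c_ipd
  list(
    n_screened = n_screened,
    n_screen_positive = n_positive_at_threshold,
    cost_screening = cost_screening,
    n_nipt = n_nipt,
    n_nipt_positive = nipt_pos,
    cost_nipt = cost_nipt,
    n_ipd_direct = n_ipd_direct,
    n_ipd_after_nipt = n_ipd_after,
    cost_ipd = cost_ipd,
    total_cost = cost_screening + cost_nipt + cost_ipd,
    n_ds_detected = n_detected,
    n_ds_confirmed_ipd = n_confirmed,
    n_miscarriage = n_ipd * p$p_ipd_miscarriage
  )
}

#' Evaluate one testing strategy at national scale
#'
#' Runs the decision tree for a strategy under a parameter set, using
#' expected-value arithmetic (no rounding; fractional counts are exact
#' cohort means). Money is in GBP.
#'
#' @param params a [screening_params()] object.
#' @param strat a [strategy()] object (or token accepted by
#'   [parse_strategy()]).
#' @return an object of class `pathway_result`: a named list with counts
#'   (`n_screened`, `n_screen_positive`, `n_nipt`, `n_ipd_direct`,
#'   `n_ipd_after_nipt`, `n_ds_detected`, `n_ds_confirmed_ipd`,
#'   `n_miscarriage`) and costs (`cost_screening`, `cost_nipt`, `cost_ipd`,
#'   `total_cost`). For the current pathway `n_screen_positive` is the
#'   >= 1/150 group (the group offered further testing).
#' @examples
#' evaluate_pathway(screening_params("national"), strategy("current"))
#' @export
evaluate_pathway <- function(params, strat) {
  params <- validate_params(params)
  strat <- parse_strategy(strat)
  out <- .pathway_compute(params, strat)
  structure(c(list(strategy = strat$label), out), class = "pathway_result")
}

#' @export
print.pathway_result <- function(x, ...) {
  cat("<pathway_result> ", x$strategy, "\n", sep = "")
  v <- unlist(x[setdiff(names(x), "strategy")])
  print(round(v, 1))
  invisible(x)
}

#' Incremental costs and outcomes versus the current pathway
#'
#' Point-estimate differences between a contingent strategy and the current
#' pathway: extra Down's syndrome cases detected, cases confirmed by
#' invasive testing, invasive tests avoided, procedure-related miscarriages
#' avoided (both sign-flipped: current minus strategy) and incremental total
#' cost. Uncertainty interval fields are `NA` here; [run_psa()] fills them.
#'
#' @inheritParams evaluate_pathway
#' @return an object of class `incremental_result` with fields
#'   `d_ds_detected`, `d_ds_confirmed_ipd`, `ipd_avoided`,
#'   `miscarriage_avoided`, `d_total_cost` and `<field>_lo` / `<field>_hi`
#'   interval slots.
#' @export
incremental <- function(params, strat) {
  params <- validate_params(params)
  strat <- parse_strategy(strat)
  if (strat$mode == "current")
    stop("incremental() compares a contingent strategy with the current ",
         "pathway; got the current pathway itself")
  cur <- .pathway_compute(params, strategy("current"))
  new <- .pathway_compute(params, strat)
  out <- .incremental_fields(new, cur)
  iv <- setNames(rep(NA_real_, 2 * length(out)),
                 c(paste0(names(out), "_lo"), paste0(names(out), "_hi")))
  structure(c(list(strategy = strat$label), out, as.list(iv)),
            class = "incremental_result")
}

# Shared by incremental() and run_psa(): deltas of a strategy's outputs vs
# the current pathway's, with the "avoided" quantities sign-flipped.
.incremental_fields <- function(new, cur) {
  list(
    d_ds_detected = new$n_ds_detected - cur$n_ds_detected,
    d_ds_confirmed_ipd = new$n_ds_confirmed_ipd - cur$n_ds_confirmed_ipd,
    ipd_avoided = (cur$n_ipd_direct + cur$n_ipd_after_nipt) -
      (new$n_ipd_direct + new$n_ipd_after_nipt),
    miscarriage_avoided = cur$n_miscarriage - new$n_miscarriage,
    d_total_cost = new$total_cost - cur$total_cost
  )
}

#' @export
print.incremental_result <- function(x, ...) {
  cat("<incremental_result> ", x$strategy, " vs current\n", sep = "")
  f <- c("d_ds_detected", "d_ds_confirmed_ipd", "ipd_avoided",
         "miscarriage_avoided", "d_total_cost")
  print(round(unlist(x[f]), 1))
  invisible(x)
}

#' Cost/outcome table for a set of strategies
#'
#' Evaluates each strategy and binds the results into one data.frame, one
#' row per strategy in the order given (defaults to the table order of
#' [enumerate_strategies()]). Values are unrounded; see
#' [format_results_table()] for the presentation convention.
#'
#' @param params a [screening_params()] object.
#' @param strategies list of strategies (default: all seven).
#' @return a data.frame, one row per strategy, columns as in
#'   [evaluate_pathway()].
#' @export
pathway_table <- function(params, strategies = enumerate_strategies()) {
  rows <- lapply(strategies, function(s) {
    r <- evaluate_pathway(params, s)
    as.data.frame(r[names(r)], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Incremental table for the six contingent strategies
#'
#' @param params a [screening_params()] object.
#' @param strategies list of contingent strategies (default: the six
#'   non-current strategies in table order).
#' @return a data.frame, one row per strategy, with the incremental fields
#'   of [incremental()].
#' @export
incremental_table <- function(params,
                              strategies = enumerate_strategies()[-1]) {
  rows <- lapply(strategies, function(s) {
    r <- incremental(params, s)
    as.data.frame(r[names(r)], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
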
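# One-way sensitivity analyses: the NIPT laboratory price at which a
# contingent strategy becomes cost neutral, price sweeps over a grid of
# laboratory costs, general one-way threshold solving on any parameter
# (with an optional coupling rule keeping total further-testing uptake
# fixed), and the uptake scenario table.

# Incremental total cost of `strat` vs current, with field overrides applied
# to the strategy arm, the current arm, or both.
.inc_cost <- function(params, strat, overrides = list(),
                      arm = c("both", "strategy", "current")) {
  arm <- match.arg(arm)
  apply_over <- function(p) {
    if (length(overrides)) p[names(overrides)] <- overrides
    p
  }
  p_new <- if (arm %in% c("both", "strategy")) apply_over(params) else params
  p_cur <- if (arm %in% c("both", "current")) apply_over(params) else params
  .pathway_compute(p_new, strat)$total_cost -
    .pathway_compute(p_cur, strategy("current"))$total_cost
}

#' Cost-neutral NIPT laboratory price
#'
#' Finds the NIPT laboratory cost at which a contingent strategy's total
#' cost equals the current pathway's (incremental cost zero), by bisection
#' on the (linear) incremental-cost function. The closed form
#' `c* = c_base - delta / (n_nipt * (1 + p_nipt_repeat))` is available as a
#' cross-check via `closed_form = TRUE`.
#'
#' @param params a [screening_params()] object.
#' @param strat a contingent [strategy()].
#' @param interval search interval for the price, GBP.
#' @param tol absolute tolerance on the price, GBP.
#' @param closed_form if `TRUE`, return the closed-form solution instead of
#'   root-finding.
#' @return the cost-neutral laboratory price in GBP.
#' @examples
#' solve_cost_neutral_price(screening_params("national"),
#'                          strategy("contingent", 150, TRUE))  # ~ 256
#' @export
solve_cost_neutral_price <- function(params, strat,
                                     interval = c(0, 5000), tol = 0.01,
                                     closed_form = FALSE) {
  params <- validate_params(params)
  strat <- parse_strategy(strat)
  if (strat$mode == "current")
    stop("cost-neutral price is defined for contingent strategies only")
  n_nipt <- .pathway_compute(params, strat)$n_nipt
  if (n_nipt <= 0)
    stop("strategy performs no NIPT tests (n_nipt = 0); incremental cost ",
         "does not depend on the NIPT price")
  if (closed_form) {
    delta <- .inc_cost(params, strat)
    return(params$c_nipt_lab - delta / (n_nipt * (1 + params$p_nipt_repeat)))
  }
  f <- function(price) .inc_cost(params, strat,
                                 overrides = list(c_nipt_lab = price))
  .bisect(f, interval[1], interval[2], tol = tol)
}

# Plain bisection; assumes f continuous and of opposite signs at the ends
# (extends the bracket once if not, then signals).
.bisect <- function(f, lo, hi, tol = 1e-6, max_iter = 200L) {
  flo <- f(lo); fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi))
    stop("no sign change in search interval [", lo, ", ", hi, "]")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) / 2 < tol) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else hi <- mid
  }
  (lo + hi) / 2
}

#' Incremental cost over a grid of NIPT prices
#'
#' Evaluates the incremental total cost of each strategy versus the current
#' pathway at each NIPT laboratory price in `prices`. Each strategy's curve
#' is affine in the price with slope `n_nipt * (1 + p_nipt_repeat)`.
#'
#' @param params a [screening_params()] object.
#' @param strategies list of contingent strategies (default: all six).
#' @param prices numeric price grid in GBP (default 50 to 500 by 10).
#' @return a long data.frame with columns `strategy`, `price`,
#'   `d_total_cost` (GBP).
#' @export
price_sweep <- function(params, strategies = enumerate_strategies()[-1],
                        prices = seq(50, 500, by = 10)) {
  params <- validate_params(params)
  if (!length(prices)) stop("empty price grid")
  strategies <- lapply(strategies, parse_strategy)
  out <- do.call(rbind, lapply(strategies, function(s) {
    d <- vapply(prices, function(pr)
      .inc_cost(params, s, overrides = list(c_nipt_lab = pr)), 0)
    data.frame(strategy = s$label, price = prices, d_total_cost = d,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Define a one-way threshold query
#'
#' @param strat a contingent [strategy()].
#' @param param name of the [screening_params()] field to vary.
#' @param coupling `"none"`, or `"complement_within_further_testing"`:
#'   when varying `u_nipt_high`, keep total high-risk further-testing uptake
#'   (`u_nipt_high + u_direct_ipd`) fixed at its base value, with
#'   `u_direct_ipd` absorbing the complement.
#' @param interval finite search interval for the varied parameter.
#' @param arm which arm(s) of the comparison the variation applies to:
#'   `"both"` (default), `"strategy"` (the contingent pathway only, e.g.
#'   screening uptake under the NIPT programme) or `"current"` (the current
#'   pathway only).
#' @param tol absolute tolerance on the varied parameter.
#' @return an object of class `threshold_query`.
#' @export
threshold_query <- function(strat, param,
                            coupling = c("none",
                                         "complement_within_further_testing"),
                            interval = c(0, 1),
                            arm = c("both", "strategy", "current"),
                            tol = 1e-6) {
  strat <- parse_strategy(strat)
  coupling <- match.arg(coupling)
  arm <- match.arg(arm)
  if (!param %in% .param_fields)
    stop("unknown parameter '", param, "'")
  if (!all(is.finite(interval)) || length(interval) != 2L)
    stop("search interval must be two finite numbers")
  structure(list(strat = strat, param = param, coupling = coupling,
                 interval = sort(interval), arm = arm, tol = tol),
            class = "threshold_query")
}

#' One-way cost-neutrality threshold for a parameter
#'
#' Varies one parameter over the query's search interval and root-finds the
#' value at which the incremental total cost of the query's strategy versus
#' the current pathway crosses zero. With the
#' `complement_within_further_testing` coupling, `u_direct_ipd` is set to
#' (base total further-testing uptake − varied `u_nipt_high`) at every
#' trial value, which mirrors NIPT and direct invasive testing competing
#' for the same high-risk women.
#'
#' @param params a [screening_params()] object.
#' @param query a [threshold_query()].
#' @return the threshold value of the varied parameter (proportion or GBP).
#'   If the incremental cost does not cross zero anywhere in the interval,
#'   an error of class `niptscreen_no_crossing` is signalled ("not
#'   cost-neutral anywhere in range").
#' @examples
#' q <- threshold_query(strategy("contingent", 150, TRUE), "u_nipt_high",
#'                      coupling = "complement_within_further_testing")
#' one_way_threshold(screening_params("national"), q)  # ~ 0.713
#' @export
one_way_threshold <- function(params, query) {
  params <- validate_params(params)
  stopifnot(inherits(query, "threshold_query"))
  base_total <- params$u_nipt_high + params$u_direct_ipd
  f <- function(x) {
    ov <- setNames(list(x), query$param)
    if (query$coupling == "complement_within_further_testing") {
      if (query$param != "u_nipt_high")
        stop("complement coupling is defined for u_nipt_high")
      ov$u_direct_ipd <- base_total - x
      if (ov$u_direct_ipd < 0 || ov$u_direct_ipd > 1)
        return(NA_real_)
    }
    .inc_cost(params, query$strat, overrides = ov, arm = query$arm)
  }
  lo <- query$interval[1]; hi <- query$interval[2]
  # restrict to the sub-interval where the coupled complement is valid
  if (query$coupling == "complement_within_further_testing") {
    lo <- max(lo, base_total - 1)
    hi <- min(hi, base_total)
  }
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || sign(flo) == sign(fhi)) {
    cond <- simpleError(paste0(
      "not cost-neutral anywhere in range [", lo, ", ", hi,
      "] when varying '", query$param, "'"))
    class(cond) <- c("niptscreen_no_crossing", class(cond))
    stop(cond)
  }
  .bisect(f, lo, hi, tol = query$tol)
}

#' Uptake scenario table for high-risk women
#'
#' Re-evaluates the 1/150 contingent strategies under alternative high-risk
#' uptake splits between NIPT and direct invasive testing (e.g. the
#' study units with the lowest/highest NIPT uptake). The no-direct variant
#' substitutes the scenario's combined further-testing uptake for the
#' high-risk NIPT uptake, on the premise that women who would have chosen
#' direct invasive testing switch to NIPT when that is the only option.
#'
#' @param params a [screening_params()] object.
#' @param rows a data.frame with columns `label`, `u_nipt_high`,
#'   `u_direct_ipd` (proportions).
#' @return a data.frame with the scenario uptakes, their total, and the
#'   incremental total cost (GBP) of the 1/150 strategy with
#'   (`d_cost_direct`) and without (`d_cost_nodirect`) the direct option.
#' @export
uptake_scenarios <- function(params, rows) {
  params <- validate_params(params)
  stopifnot(is.data.frame(rows),
            all(c("label", "u_nipt_high", "u_direct_ipd") %in% names(rows)))
  s_direct <- strategy("contingent", 150, TRUE)
  s_nodirect <- strategy("contingent", 150, FALSE)
  out <- lapply(seq_len(nrow(rows)), function(i) {
    u_n <- rows$u_nipt_high[i]
    u_d <- rows$u_direct_ipd[i]
    if (u_n < 0 || u_d < 0 || u_n + u_d > 1 + 1e-9)
      stop("row '", rows$label[i], "': uptakes must be proportions with ",
           "u_nipt_high + u_direct_ipd <= 1")
    d_direct <- .inc_cost(params, s_direct,
                          overrides = list(u_nipt_high = u_n,
                                           u_direct_ipd = u_d))
    d_nodir <- .inc_cost(params, s_nodirect,
                         overrides = list(u_nipt_high_nodirect = u_n + u_d))
    data.frame(label = rows$label[i], u_nipt_high = u_n, u_direct_ipd = u_d,
               total_uptake = u_n + u_d,
               d_cost_direct = d_direct, d_cost_nodirect = d_nodir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
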
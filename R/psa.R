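# Probabilistic sensitivity analysis. Every varied input gets a parametric
# uncertainty distribution: beta for proportions (hyperparameters built from
# an effective study denominator n_eff, so the mean is the point estimate),
# gamma for the two uncertain unit costs (20% coefficient of variation), and
# a Dirichlet coupling the three choices available to high-risk women
# (NIPT / direct invasive / decline), since these compete for the same women.
# Outputs are equal-tailed percentile intervals over the simulated draws.

#' Distribution specification helpers for the PSA
#'
#' `psa_beta(n_eff)` declares a beta distribution with
#' `alpha = p * n_eff`, `beta = (1 - p) * n_eff` around the point value `p`;
#' `psa_beta_ab(alpha, beta)` gives the hyperparameters directly;
#' `psa_gamma(cv)` declares a gamma distribution with the point value as
#' mean and coefficient of variation `cv` (`shape = 1/cv^2`,
#' `scale = mean * cv^2`); `psa_fixed()` pins the parameter at its point
#' value.
#'
#' @param n_eff effective denominator (pseudo-sample size) for a beta prior.
#' @param alpha,beta explicit beta hyperparameters (both > 0).
#' @param cv coefficient of variation for a gamma cost distribution.
#' @return a distribution spec (a small named list) understood by
#'   [psa_config()].
#' @name psa_dists
NULL

#' @rdname psa_dists
#' @export
psa_beta <- function(n_eff) {
  stopifnot(is.numeric(n_eff), n_eff > 0)
  list(kind = "beta", n_eff = n_eff)
}

#' @rdname psa_dists
#' @export
psa_beta_ab <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha <= 0 || beta <= 0)
    stop("beta hyperparameters must be > 0 (got alpha = ", alpha,
         ", beta = ", beta, ")")
  list(kind = "beta", alpha = alpha, beta = beta)
}

#' @rdname psa_dists
#' @export
psa_gamma <- function(cv = 0.2) {
  stopifnot(is.numeric(cv), cv > 0)
  list(kind = "gamma", cv = cv)
}

#' @rdname psa_dists
#' @export
psa_fixed <- function() list(kind = "fixed")

# Effective denominators taken from the cohort study's group sizes:
# 934 high-risk women offered a choice, 2241 intermediate-risk offered NIPT,
# 59 NIPT positives (confirmatory-uptake denominator), 47 confirmatory
# tests, 166 direct invasive tests, ~2500 NIPT tests run, 30 790 screened,
# 40 527 booked, 1111 historical high-risk (current-pathway uptake).
.default_n_eff <- c(
  u_screen = 40527,
  p_risk_high = 30790, p_risk_int500 = 30790, p_risk_int1000 = 30790,
  u_nipt_high_nodirect = 934,
  u_nipt_int = 2241,
  u_ipd_current = 1111,
  u_ipd_after_nipt = 59,
  p_nipt_pos_high = 695, p_nipt_pos_high_nodirect = 861,
  p_nipt_pos_int500 = 1799, p_nipt_pos_int1000 = 1799,
  p_nipt_repeat = 2494,
  p_ipd_pos_current = 667,
  p_ipd_pos_direct = 166,
  p_ipd_pos_after_nipt = 47,
  p_ipd_miscarriage = 3000
)

#' Configure a probabilistic sensitivity analysis
#'
#' Builds a `psa_config`: the number of simulations, the seed, one
#' distribution spec per parameter, and the Dirichlet coupling of the
#' high-risk choice proportions. By default every proportion is beta with an
#' effective denominator taken from the underlying study's group sizes,
#' `c_nipt_lab` and `c_ipd` are gamma with 20% CV, the screening-test mix
#' and remaining unit costs and the population size are fixed, and
#' (`u_nipt_high`, `u_direct_ipd`) are drawn jointly with the decline
#' proportion from a Dirichlet so that the three high-risk choices remain
#' complementary (total further-testing mass 0.925 at the point values).
#'
#' @param n_sims number of Monte-Carlo draws (default 1000).
#' @param seed integer RNG seed.
#' @param dists named list of per-parameter overrides (see [psa_dists]);
#'   any parameter not named keeps its default spec.
#' @param couple_high_risk_choice logical; draw the high-risk NIPT /
#'   direct-invasive / decline split from a Dirichlet (default `TRUE`). When
#'   `FALSE`, `u_nipt_high` and `u_direct_ipd` use independent beta specs.
#' @param dirichlet_n_eff effective denominator of the Dirichlet
#'   (default 934, the high-risk group size).
#' @return an object of class `psa_config`.
#' @export
psa_config <- function(n_sims = 1000, seed = 1L, dists = list(),
                       couple_high_risk_choice = TRUE,
                       dirichlet_n_eff = 934) {
  if (!is.numeric(n_sims) || n_sims < 1)
    stop("n_sims must be >= 1, got ", n_sims)
  spec <- setNames(vector("list", length(.param_fields)), .param_fields)
  for (f in .param_fields) spec[[f]] <- psa_fixed()
  for (f in names(.default_n_eff)) spec[[f]] <- psa_beta(.default_n_eff[[f]])
  spec$c_nipt_lab <- psa_gamma(0.2)
  spec$c_ipd <- psa_gamma(0.2)
  if (couple_high_risk_choice) {
    spec$u_nipt_high <- list(kind = "dirichlet")
    spec$u_direct_ipd <- list(kind = "dirichlet")
  } else {
    spec$u_nipt_high <- psa_beta(934)
    spec$u_direct_ipd <- psa_beta(934)
  }
  if (length(dists)) {
    bad <- setdiff(names(dists), .param_fields)
    if (length(bad))
      stop("distribution spec for unknown parameter(s): ",
           paste(bad, collapse = ", "))
    spec[names(dists)] <- dists
    if (any(names(dists) %in% c("u_nipt_high", "u_direct_ipd")))
      couple_high_risk_choice <- FALSE
  }
  structure(list(n_sims = as.integer(n_sims), seed = as.integer(seed),
                 dists = spec,
                 couple_high_risk_choice = couple_high_risk_choice,
                 dirichlet_n_eff = dirichlet_n_eff),
            class = "psa_config")
}

#' All-fixed PSA configuration
#'
#' Degenerate configuration in which every parameter draws its point value;
#' useful as a self-check (intervals must collapse onto the deterministic
#' point estimates).
#'
#' @inheritParams psa_config
#' @return a `psa_config`.
#' @export
psa_config_fixed <- function(n_sims = 10, seed = 1L) {
  cfg <- psa_config(n_sims = n_sims, seed = seed,
                    couple_high_risk_choice = FALSE)
  for (f in names(cfg$dists)) cfg$dists[[f]] <- psa_fixed()
  cfg
}

# Draw n values for one parameter around its point value.
.draw_param <- function(point, spec, n) {
  switch(spec$kind,
    fixed = rep(point, n),
    beta = {
      if (!is.null(spec$n_eff)) {
        a <- point * spec$n_eff
        b <- (1 - point) * spec$n_eff
      } else {
        a <- spec$alpha
        b <- spec$beta
      }
      if (is.na(a) || is.na(b) || a <= 0 || b <= 0) {
        if (point %in% c(0, 1)) return(rep(point, n))  # degenerate corner
        stop("beta hyperparameters must be > 0 (point = ", point, ")")
      }
      rbeta(n, a, b)
    },
    gamma = {
      if (point == 0) return(rep(0, n))
      shape <- 1 / spec$cv^2
      rgamma(n, shape = shape, scale = point * spec$cv^2)
    },
    dirichlet = stop("dirichlet-coupled parameters are drawn jointly"),
    stop("unknown distribution kind '", spec$kind, "'")
  )
}

# Sample all parameters: returns a named list of length-n vectors.
.sample_params <- function(params, cfg) {
  n <- cfg$n_sims
  draws <- setNames(vector("list", length(.param_fields)), .param_fields)
  for (f in .param_fields) {
    spec <- cfg$dists[[f]]
    if (identical(spec$kind, "dirichlet")) next
    draws[[f]] <- .draw_param(params[[f]], spec, n)
  }
  if (cfg$couple_high_risk_choice) {
    p_decline <- max(0, 1 - params$u_nipt_high - params$u_direct_ipd)
    alpha <- cfg$dirichlet_n_eff *
      c(params$u_nipt_high, params$u_direct_ipd, p_decline)
    g <- vapply(alpha, function(a)
      if (a > 0) rgamma(n, shape = a, rate = 1) else rep(0, n),
      numeric(n))
    g <- matrix(g, nrow = n)
    tot <- rowSums(g)
    draws$u_nipt_high <- g[, 1] / tot
    draws$u_direct_ipd <- g[, 2] / tot
  }
  # the test mix must still sum to 1 draw-wise
  if (identical(cfg$dists$p_combined$kind, "beta"))
    draws$p_quadruple <- 1 - draws$p_combined
  draws
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws `n_sims` joint parameter samples, pushes every draw through the
#' decision tree for each requested contingent strategy and for the current
#' pathway, and summarises each incremental output with its point estimate
#' and equal-tailed 95% percentile interval (linear-interpolation
#' quantiles). The same seed always reproduces the identical result.
#'
#' @param params a [screening_params()] object (point values = distribution
#'   means).
#' @param config a [psa_config()].
#' @param strategies list of contingent strategies (default: the six
#'   non-current strategies).
#' @return an object of class `psa_result`: list with `summary` (data.frame:
#'   strategy, field, point, lo, hi), `draws` (named list of
#'   `n_sims x field` matrices, one per strategy, retained for export) and
#'   the `config`.
#' @export
run_psa <- function(params, config = psa_config(),
                    strategies = enumerate_strategies()[-1]) {
  params <- validate_params(params)
  stopifnot(inherits(config, "psa_config"))
  strategies <- lapply(strategies, parse_strategy)
  if (any(vapply(strategies, `[[`, "", "mode") == "current"))
    stop("run_psa() summarises incremental outputs; drop the current ",
         "pathway from `strategies`")
  set.seed(config$seed)
  draws <- .sample_params(params, config)
  cur <- .pathway_compute(draws, strategy("current"))
  point <- lapply(strategies, function(s)
    unlist(.incremental_fields(.pathway_compute(params, s),
                               .pathway_compute(params, strategy("current")))))
  mats <- lapply(strategies, function(s) {
    inc <- .incremental_fields(.pathway_compute(draws, s), cur)
    do.call(cbind, inc)
  })
  labels <- vapply(strategies, `[[`, "", "label")
  names(mats) <- labels
  summ <- do.call(rbind, lapply(seq_along(strategies), function(i) {
    m <- mats[[i]]
    q <- apply(m, 2, quantile, probs = c(0.025, 0.975), names = FALSE,
               type = 7)
    data.frame(strategy = labels[i], field = colnames(m),
               point = as.numeric(point[[i]]),
               lo = q[1, ], hi = q[2, ],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(summary = summ, draws = mats, config = config),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> ", x$config$n_sims, " simulations, seed ",
      x$config$seed, "\n", sep = "")
  s <- x$summary
  s[c("point", "lo", "hi")] <- lapply(s[c("point", "lo", "hi")], round, 1)
  print(s)
  invisible(x)
}

#' Attach PSA intervals to a deterministic incremental result
#'
#' Fills the `<field>_lo` / `<field>_hi` slots of an [incremental()] result
#' from a [run_psa()] output covering that strategy.
#'
#' @param inc an `incremental_result`.
#' @param psa a `psa_result` whose summary includes the strategy.
#' @return the `incremental_result` with interval fields populated.
#' @export
attach_intervals <- function(inc, psa) {
  stopifnot(inherits(inc, "incremental_result"),
            inherits(psa, "psa_result"))
  s <- psa$summary[psa$summary$strategy == inc$strategy, ]
  if (!nrow(s)) stop("PSA result does not cover strategy '", inc$strategy, "'")
  for (i in seq_len(nrow(s))) {
    inc[[paste0(s$field[i], "_lo")]] <- s$lo[i]
    inc[[paste0(s$field[i], "_hi")]] <- s$hi[i]
  }
  inc
}
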
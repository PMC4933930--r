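# The seven testing strategies compared by the model: the current pathway
# (invasive testing offered at risk >= 1/150) and contingent NIPT at three
# risk thresholds, each with or without the option of going directly to
# invasive testing.

#' Define a testing strategy
#'
#' @param mode `"current"` or `"contingent"`.
#' @param threshold risk threshold denominator for contingent NIPT: one of
#'   150, 500, 1000 (NIPT offered at risk >= 1/threshold). Ignored for the
#'   current pathway.
#' @param direct_ipd for contingent strategies, whether high-risk women may
#'   choose invasive testing directly instead of NIPT. Ignored for the
#'   current pathway.
#' @return an object of class `screening_strategy` with fields `mode`,
#'   `threshold`, `direct_ipd` and a display `label`.
#' @examples
#' strategy("contingent", 150, direct_ipd = FALSE)
#' @export
strategy <- function(mode = c("current", "contingent"), threshold = NA,
                     direct_ipd = NA) {
  mode <- match.arg(mode)
  if (mode == "current") {
    threshold <- NA_real_
    direct_ipd <- NA
    label <- "Current"
  } else {
    if (!threshold %in% c(150, 500, 1000))
      stop("threshold must be one of 150, 500, 1000; got ", threshold)
    if (!isTRUE(direct_ipd) && !isFALSE(direct_ipd))
      stop("direct_ipd must be TRUE or FALSE for contingent strategies")
    label <- sprintf("NIPT >=1/%d%s", threshold,
                     if (direct_ipd) "" else " - no direct IPD")
  }
  structure(list(mode = mode, threshold = threshold,
                 direct_ipd = direct_ipd, label = label),
            class = "screening_strategy")
}

#' @export
print.screening_strategy <- function(x, ...) {
  cat("<strategy> ", x$label, "\n", sep = "")
  invisible(x)
}

#' Enumerate the seven testing strategies
#'
#' Returns all strategies compared by the model, in the presentation order
#' of the cost/outcome tables: current; contingent at 1/1000, 1/500, 1/150
#' with direct invasive testing allowed; then the same three thresholds
#' without the direct option.
#'
#' @return a named list of 7 `screening_strategy` objects (names are the
#'   display labels).
#' @export
enumerate_strategies <- function() {
  s <- c(list(strategy("current")),
         lapply(c(1000, 500, 150), function(t)
           strategy("contingent", t, direct_ipd = TRUE)),
         lapply(c(1000, 500, 150), function(t)
           strategy("contingent", t, direct_ipd = FALSE)))
  names(s) <- vapply(s, `[[`, "", "label")
  s
}

#' Parse a strategy from a short token
#'
#' Accepts the tokens used on the command line: `"current"`, `"1/150"`,
#' `"1/500"`, `"1/1000"`, optionally suffixed `"-no-direct"`, as well as the
#' full display labels.
#'
#' @param x a character scalar.
#' @return a `screening_strategy`.
#' @export
parse_strategy <- function(x) {
  if (inherits(x, "screening_strategy")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  all7 <- enumerate_strategies()
  if (x %in% names(all7)) return(all7[[x]])
  tok <- tolower(trimws(x))
  if (tok == "current") return(strategy("current"))
  nodirect <- grepl("no-?direct", tok)
  tok <- sub("[- ]*no-?direct$", "", tok)
  m <- regmatches(tok, regexec("^(?:nipt *)?(?:>=)?1/(150|500|1000)$", tok))[[1]]
  if (length(m) == 2L)
    return(strategy("contingent", as.numeric(m[2]), direct_ipd = !nodirect))
  stop("cannot parse strategy '", x, "'; valid tokens: current, 1/150, ",
       "1/500, 1/1000 (optionally with suffix -no-direct)")
}
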
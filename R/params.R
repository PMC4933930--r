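# Model parameterisation: the complete numeric description of the screening
# pathway (uptakes, test-outcome probabilities, unit costs, population size),
# plus reading/writing of flat key-value config files and the two shipped
# presets ("rapid": study-unit column; "national": national-data column).

.prop_fields <- c(
  "p_combined", "p_quadruple",
  "u_screen",
  "p_risk_high", "p_risk_int500", "p_risk_int1000",
  "u_nipt_high", "u_nipt_high_nodirect", "u_nipt_int",
  "u_direct_ipd", "u_ipd_current", "u_ipd_after_nipt",
  "p_nipt_pos_high", "p_nipt_pos_high_nodirect",
  "p_nipt_pos_int500", "p_nipt_pos_int1000",
  "p_nipt_repeat",
  "p_ipd_pos_current", "p_ipd_pos_direct", "p_ipd_pos_after_nipt",
  "p_ipd_miscarriage"
)

.cost_fields <- c(
  "c_combined", "c_quadruple",
  "c_nipt_lab", "c_nipt_counsel", "c_nipt_phleb",
  "c_ipd"
)

.param_fields <- c("population_size", .prop_fields, .cost_fields)

# Values shared by both Table-2 columns (NIPT behaviour measured in the study,
# confirmatory-test outcomes, miscarriage risk, unit costs in 2012/13 GBP).
.shared_params <- list(
  u_nipt_high = 0.725,
  u_nipt_int = 0.705,
  u_nipt_high_nodirect = 0.910,
  u_ipd_current = 0.540,
  u_direct_ipd = 0.200,
  u_ipd_after_nipt = 0.804,
  p_nipt_pos_high = 0.040,
  p_nipt_pos_int500 = 0.0038,
  p_nipt_pos_int1000 = 0.0025,
  p_nipt_pos_high_nodirect = 0.079,
  p_nipt_repeat = 0.012,
  p_ipd_pos_current = 0.101,
  p_ipd_pos_after_nipt = 0.901,
  p_ipd_pos_direct = 0.219,
  p_ipd_miscarriage = 0.005,
  c_combined = 27.52,
  c_quadruple = 37.20,
  c_nipt_lab = 250,
  c_nipt_counsel = 15.96,
  c_nipt_phleb = 9,
  c_ipd = 650
)

.presets <- list(
  national = c(list(
    population_size = 698500,
    p_combined = 0.869, p_quadruple = 0.131,
    u_screen = 0.662,
    p_risk_high = 0.023, p_risk_int500 = 0.034, p_risk_int1000 = 0.075
  ), .shared_params),
  rapid = c(list(
    population_size = 698500,
    p_combined = 0.885, p_quadruple = 0.115,
    u_screen = 0.787,
    p_risk_high = 0.027, p_risk_int500 = 0.032, p_risk_int1000 = 0.071
  ), .shared_params)
)

#' Screening-programme parameter set
#'
#' Construct a validated `screening_params` object: the full numeric
#' parameterisation of the Down's syndrome screening pathway model.
#' Two presets ship with the package: `"national"` (national screening
#' statistics, annual population 698 500) and `"rapid"` (the
#' eight-unit prospective cohort), differing in screening uptake, test mix
#' and risk-band frequencies; NIPT/invasive behaviour and unit costs are
#' common to both.
#'
#' @param preset `"national"` or `"rapid"`.
#' @param ... named scalar overrides of individual fields, e.g.
#'   `u_nipt_high = 0.9` or `c_nipt_lab = 100`.
#'
#' @return An object of class `screening_params`: a named list with the
#'   population size, 21 proportions/probabilities and 6 unit costs (GBP).
#' @examples
#' p <- screening_params("national")
#' p$u_screen              # 0.662
#' screening_params("rapid", c_nipt_lab = 100)$c_nipt_lab
#' @export
screening_params <- function(preset = c("national", "rapid"), ...) {
  preset <- match.arg(preset)
  p <- .presets[[preset]]
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .param_fields)
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p <- p[.param_fields]
  attr(p, "preset") <- preset
  class(p) <- "screening_params"
  validate_params(p)
}

#' Validate a screening parameter set
#'
#' Checks the model invariants: all proportions in \[0, 1\], the screening
#' test mix summing to one, nested risk bands
#' (`p_risk_int500 <= p_risk_int1000`), non-negative costs and a positive
#' population. Called by every constructor/reader; exported so that
#' programmatically built parameter sets can be checked too.
#'
#' @param p a `screening_params` object (or named list with all fields).
#' @return `p`, invisibly classed, if valid; otherwise an error naming the
#'   offending field and value.
#' @export
validate_params <- function(p) {
  missing <- setdiff(.param_fields, names(p))
  if (length(missing))
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  for (f in .param_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("field '", f, "' must be a finite numeric scalar (got ",
           deparse(v), ")")
  }
  for (f in .prop_fields) {
    v <- p[[f]]
    if (v < 0 || v > 1)
      stop("field '", f, "' must lie in [0, 1], got ", v)
  }
  s <- p$p_combined + p$p_quadruple
  if (abs(s - 1) > 1e-9)
    stop("p_combined + p_quadruple must equal 1 (got ", s, ")")
  if (p$p_risk_int500 > p$p_risk_int1000 + 1e-12)
    stop("p_risk_int500 (", p$p_risk_int500,
         ") must not exceed p_risk_int1000 (", p$p_risk_int1000, ")")
  for (f in .cost_fields)
    if (p[[f]] < 0) stop("cost '", f, "' must be >= 0, got ", p[[f]])
  if (p$population_size <= 0)
    stop("population_size must be > 0, got ", p$population_size)
  if (!inherits(p, "screening_params")) class(p) <- "screening_params"
  invisible(p)
  p
}

#' @export
print.screening_params <- function(x, ...) {
  cat("<screening_params>",
      if (!is.null(attr(x, "preset"))) paste0(" preset: ", attr(x, "preset")),
      "\n", sep = "")
  df <- data.frame(value = unlist(x[.param_fields]))
  print(df, ...)
  invisible(x)
}

#' Read a parameter file
#'
#' Reads a flat key-value (YAML) parameter file. Recognised keys are exactly
#' the `screening_params` field names plus two optional declarations:
#' `preset: rapid|national` (supplies defaults for any field the file does
#' not set) and `units: percent|proportion` (how the proportion fields are
#' written; default `proportion`). Unknown keys are rejected; if no preset is
#' declared every field must be present.
#'
#' @param path path to the config file.
#' @return a validated [screening_params()] object.
#' @seealso [write_params()]
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse parameter file '",
                                           path, "': ", conditionMessage(e)))
  if (!is.list(raw) || is.null(names(raw)))
    stop("parameter file must be a flat key-value mapping: ", path)
  meta <- c("preset", "units")
  unknown <- setdiff(names(raw), c(.param_fields, meta))
  if (length(unknown))
    stop("unknown key(s) in parameter file: ", paste(unknown, collapse = ", "))
  units <- raw$units %||% "proportion"
  if (!units %in% c("percent", "proportion"))
    stop("units must be 'percent' or 'proportion', got '", units, "'")
  vals <- raw[setdiff(names(raw), meta)]
  if (units == "percent")
    vals[intersect(names(vals), .prop_fields)] <-
      lapply(vals[intersect(names(vals), .prop_fields)], function(v) v / 100)
  if (!is.null(raw$preset)) {
    if (!raw$preset %in% names(.presets))
      stop("unknown preset '", raw$preset, "'; valid presets: ",
           paste(names(.presets), collapse = ", "))
    do.call(screening_params, c(list(preset = raw$preset), vals))
  } else {
    missing <- setdiff(.param_fields, names(vals))
    if (length(missing))
      stop("no preset declared and field(s) missing: ",
           paste(missing, collapse = ", "))
    p <- vals[.param_fields]
    class(p) <- "screening_params"
    validate_params(p)
  }
}

#' Write a parameter file
#'
#' Serialises a parameter set to the flat key-value format read by
#' [load_params()] (proportions written as proportions, with an explicit
#' `units: proportion` declaration). `write_params()` then `load_params()`
#' round-trips to an identical object.
#'
#' @param params a `screening_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  params <- validate_params(params)
  out <- c(list(units = "proportion"),
           lapply(params[.param_fields], as.numeric))
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Export a parameter set as a provenance table
#'
#' One row per field with its value and role (proportion / cost / count),
#' suitable for CSV export alongside model outputs.
#'
#' @param params a `screening_params` object.
#' @return a data.frame with columns `field`, `value`, `role`.
#' @export
params_table <- function(params) {
  params <- validate_params(params)
  data.frame(
    field = .param_fields,
    value = unlist(params[.param_fields], use.names = FALSE),
    role = c("count",
             rep("proportion", length(.prop_fields)),
             rep("cost_gbp", length(.cost_fields))),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
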
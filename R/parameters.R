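#' Model parameter set
#'
#' A flat table of every model quantity: baseline event rates, treatment
#' effects, drug and event costs, utilities and global constants.  Each
#' row carries a point value, an uncertainty range (where one exists) and
#' the distribution family used for probabilistic sensitivity analysis.
#' Rows are keyed by `(block, label)`; labels follow the published input
#' table verbatim so parameter files are self-documenting.
#'
#' @param df Data frame with columns `block`, `label`, `value`, `low`,
#'   `high`, `dist` (one of `"lognormal"`, `"gamma"`, `"beta"`,
#'   `"fixed"`).
#' @return Object of class `parameter_set`.
#' @export
parameter_set <- function(df) {
  need <- c("block", "label", "value", "low", "high", "dist")
  if (!all(need %in% names(df)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  key <- paste(df$block, df$label, sep = "||")
  if (anyDuplicated(key))
    stop("duplicate parameter key: ", key[duplicated(key)][1])
  ok_dist <- c("lognormal", "gamma", "beta", "fixed")
  if (!all(df$dist %in% ok_dist))
    stop("unknown distribution family: ",
         paste(setdiff(df$dist, ok_dist), collapse = ", "))
  bad <- !is.na(df$low) & !is.na(df$high) & df$low > df$high
  if (any(bad)) stop("low > high for parameter '", df$label[bad][1], "'")
  df <- df[, need]
  class(df) <- c("parameter_set", "data.frame")
  df
}

#' Look up a parameter point value
#'
#' @param params A [parameter_set()].
#' @param block Block name (e.g. `"utility"`, `"direct_cost"`).
#' @param label Row label.
#' @param default Returned when the row does not exist; when missing, an
#'   absent row is an error.
#' @return Numeric point value.
#' @export
param_value <- function(params, block, label, default = NULL) {
  i <- which(params$block == block & params$label == label)
  if (length(i) == 0) {
    if (!is.null(default)) return(default)
    stop("no parameter '", label, "' in block '", block, "'")
  }
  params$value[i]
}

# replace the point value of one row (used by DSA/PSA re-runs)
set_param <- function(params, block, label, value) {
  i <- which(params$block == block & params$label == label)
  if (length(i) != 1) stop("no parameter '", label, "' in block '", block, "'")
  params$value[i] <- value
  params
}

#' Validate a parameter set against model invariants
#'
#' Checks the rules the model relies on: non-negative rates and costs,
#' utilities in `[0, 1]` (disutilities non-positive), cardiovascular
#' mortality not exceeding all-cause mortality, positive effects.
#' Errors name the offending block and row label.
#'
#' @param params A [parameter_set()].
#' @return `params`, invisibly, when valid.
#' @export
validate_parameters <- function(params) {
  chk <- function(cond, block, label, rule) {
    if (!cond)
      stop("parameter '", label, "' in block '", block, "': ", rule,
           call. = FALSE)
  }
  for (i in seq_len(nrow(params))) {
    b <- params$block[i]; l <- params$label[i]; v <- params$value[i]
    if (b %in% c("rates_peace", "rates_fourier"))
      chk(v >= 0, b, l, "event rate must be non-negative")
    if (b %in% c("drug_cost", "direct_cost", "indirect_cost"))
      chk(v >= 0, b, l, "cost must be non-negative")
    if (b == "utility") {
      if (grepl("disutility", l)) chk(v <= 0, b, l,
                                      "disutility must be non-positive")
      else chk(v >= 0 && v <= 1, b, l, "utility must lie in [0, 1]")
    }
    if (b %in% c("effect_hr", "effect_hr_trial", "effect_rr"))
      chk(v > 0, b, l, "effect must be positive")
  }
  acm <- param_value(params, "rates_peace", "All-cause mortality",
                     default = NA)
  cvd <- param_value(params, "rates_peace", "Cardiovascular-related death",
                     default = NA)
  if (!is.na(acm) && !is.na(cvd))
    chk(acm >= cvd, "rates_peace", "All-cause mortality",
        "all-cause mortality must be at least cardiovascular mortality")
  invisible(params)
}
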
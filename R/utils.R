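#' Round half away from zero
#'
#' Standard commercial rounding: ties go away from zero, so `round2(11.005)`
#' is `11.01` where base [round()] (banker's rounding) would give `11.00`.
#' All statistics written to report tables use this rule at 2 decimals.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' round2(11.004999) # 11.00
#' round2(11.005)    # 11.01
round2 <- function(x, digits = 2) {
  m <- 10^digits
  # nudge by one ulp so values stored just below .xx5 by binary rounding
  # (e.g. 11.005) still round up
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

# internal: stopifnot-style check with a named configuration error
check_that <- function(ok, msg, class = "faersignal_config_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

# parse YYYYMMDD strings to Date, NA on failure / blank
parse_faers_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  x[!is.na(x) & !grepl("^[0-9]{8}$", x)] <- NA_character_
  lubridate::ymd(x, quiet = TRUE)
}

format_faers_date <- function(d) {
  out <- format(d, "%Y%m%d")
  out[is.na(out)] <- ""
  out
}

# numeric-aware comparison rank for PRIMARYID strings: numeric value when all
# ids in the group coerce cleanly, otherwise lexicographic after left
# zero-padding to equal width
primaryid_rank <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) return(num)
  w <- max(nchar(ids), 0L)
  rank(formatC(ids, width = w, flag = "0"), ties.method = "min")
}
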
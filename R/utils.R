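#' @useDynLib stablerx, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rbinom rnorm rpois runif rgamma rmultinom uniroot
#'   plogis qlogis predict sd
#' @importFrom utils read.csv write.csv head modifyList
#' @importFrom glmnet glmnet
#' @importFrom ranger ranger
NULL

sigmoid <- function(z) plogis(z)

#' Run code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb an enclosing simulation.
#' @param seed integer seed
#' @param code expression to evaluate
#' @keywords internal
local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert integer day offsets to ISO-8601 date strings
#' @param day integer vector of days since 1970-01-01
#' @keywords internal
day_to_iso <- function(day) format(as.Date(day, origin = "1970-01-01"), "%Y-%m-%d")

#' Convert ISO-8601 date strings to integer day offsets
#' @param iso character vector of dates
#' @keywords internal
iso_to_day <- function(iso) as.integer(as.Date(iso, format = "%Y-%m-%d"))

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= 1", name), call. = FALSE)
  }
}
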
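# Internal helpers shared across modules.

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so package functions never clobber the global stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      stop_domain("`seed` must be a single integer.")
    }
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_domain <- function(msg) {
  rlang::abort(msg, class = c("retrocue_error_domain", "retrocue_error"))
}

stop_insufficient <- function(msg) {
  rlang::abort(msg, class = c("retrocue_error_insufficient_data", "retrocue_error"))
}

stop_balance <- function(msg) {
  rlang::abort(msg, class = c("retrocue_error_balance", "retrocue_error"))
}

stop_config <- function(msg) {
  rlang::abort(msg, class = c("retrocue_error_config", "retrocue_error"))
}

stop_validation <- function(msg) {
  rlang::abort(msg, class = c("retrocue_error_validation", "retrocue_error"))
}

#' Convert between milliseconds and seconds
#'
#' Trial tables carry response times in milliseconds; the shifted-Wald
#' machinery works in seconds. These two functions are the single documented
#' unit boundary of the package.
#'
#' @param x Numeric vector of times.
#' @return Numeric vector in the target unit.
#' @export
#' @examples
#' ms_to_s(c(150, 633))
ms_to_s <- function(x) x / 1000

#' @rdname ms_to_s
#' @export
s_to_ms <- function(x) x * 1000
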
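#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbeta rbinom runif setNames approx
#' @importFrom utils read.table write.table
#' @importFrom tibble tibble as_tibble
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw n integer sub-seeds, optionally after seeding the session RNG.
# Used to give independent, reproducible streams to nested operations.
derive_seeds <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(2147483646L, n, replace = TRUE)
}

stop_ <- function(...) stop(..., call. = FALSE)
warn_ <- function(...) warning(..., call. = FALSE)
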
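#' Derive a reproducible sub-seed from a top-level seed
#'
#' Every stochastic stage of the pipeline draws its own seed deterministically
#' from the single user-supplied seed plus a string key (stage name, dataset
#' id, gene id, ...). This keeps stages reproducible independently of the
#' order in which they run. The hash is a simple 31-ary polynomial over the
#' UTF-8 bytes of the key, reduced modulo 2^31 - 1 so the result is always a
#' valid R integer seed.
#'
#' @param seed integer top-level seed.
#' @param ... further components (coerced to character) identifying the stage.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "bimodality", "GSE0001")
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed, scientific = FALSE), vapply(list(...), function(x)
    paste(format(x, scientific = FALSE), collapse = ","), character(1))),
    collapse = "/")
  m <- 2147483647
  h <- 0
  for (cd in utf8ToInt(key)) h <- (h * 31 + cd) %% m
  as.integer(h)
}

# run expr with a local RNG state seeded at `seed`, restoring the caller's
# RNG stream afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_ <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x) && x >= min
}

is_prob <- function(x, open_lo = TRUE, open_hi = TRUE) {
  length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (open_lo) x > 0 else x >= 0) && (if (open_hi) x < 1 else x <= 1)
}
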
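#' @useDynLib vteal, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict rbinom runif rnorm sd
#' @importFrom methods as
NULL

# Structured conditions.  `kind` maps to a condition class
# vteal_<kind>_error; the CLI translates these to exit codes.
stop_vteal <- function(kind, ...) {
  msg <- paste0(...)
  cond <- structure(
    class = c(paste0("vteal_", kind, "_error"), "vteal_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Seeded random stream
#'
#' A self-contained RNG state that can be threaded through the report
#' generator and query strategies without disturbing (or being disturbed by)
#' the global RNG.  Draw from it with [rng_draw()].
#'
#' @param seed Integer seed.
#' @return An object of class `vteal_rng`.
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- with_seed(seed, get(".Random.seed", envir = globalenv()))
  class(e) <- "vteal_rng"
  e
}

#' @rdname rng_stream
#' @param rng A `vteal_rng` stream.
#' @param code Expression using R's random generators (`sample`, `runif`, ...).
#' @export
rng_draw <- function(rng, code) {
  stopifnot(inherits(rng, "vteal_rng"))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  assign(".Random.seed", rng$state, envir = env)
  on.exit({
    rng$state <- get(".Random.seed", envir = env, inherits = FALSE)
    if (had) assign(".Random.seed", old, envir = env)
    else rm(".Random.seed", envir = env)
  })
  force(code)
}

#' Largest-remainder apportionment
#'
#' Allocates `total` integer units proportionally to non-negative `weights`:
#' floors of the exact quotas first, then one extra unit each to the largest
#' fractional remainders (ties broken by position).  Deterministic, and the
#' result always sums exactly to `total`.
#'
#' @param weights Non-negative numeric weights, not all zero.
#' @param total Non-negative integer to apportion.
#' @return Integer vector of the same length as `weights`.
#' @export
#' @examples
#' largest_remainder(c(1, 1, 1), 10)
largest_remainder <- function(weights, total) {
  if (any(weights < 0) || all(weights == 0)) {
    stop_vteal("config", "weights must be non-negative and not all zero")
  }
  total <- as.integer(total)
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Round half away from zero to `digits` decimals (table-style rounding;
# base R's round() rounds half to even).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
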
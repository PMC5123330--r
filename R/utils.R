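#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded package functions do not
#' disturb the caller's random number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vegan::rrarefy warns whenever a table holds no singleton counts; our
# synthetic and aggregated tables legitimately lack them
quiet_rrarefy <- function(counts, depth) {
  withCallingHandlers(
    vegan::rrarefy(counts, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

#' Derive a child seed from a master seed
#'
#' Deterministic per-stage seeds so one run seed drives every stochastic
#' stage independently. Kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param offset stage offset.
#' @keywords internal
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 12347) %% 2147483629)
}
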
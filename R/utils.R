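# internal helpers shared across modules

# Run `code` with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("iapagree_validation_error", "iapagree_error")))
}

stop_insufficient <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("iapagree_insufficient_data_error",
                                "iapagree_error")))
}

stop_degenerate <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("iapagree_degenerate_data_error",
                                "iapagree_error")))
}

stop_infeasible <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("iapagree_infeasibility_error",
                                "iapagree_error")))
}

# Coerce the various accepted pair containers (2-column matrix or data frame)
# to a plain numeric matrix with the stated column order.
as_pair_matrix <- function(pairs, cols) {
  if (is.data.frame(pairs)) {
    if (all(cols %in% names(pairs))) pairs <- pairs[, cols]
    pairs <- as.matrix(pairs)
  }
  if (!is.matrix(pairs) || ncol(pairs) != 2L)
    stop_validation("expected a 2-column matrix or data frame of pairs")
  storage.mode(pairs) <- "double"
  if (!all(is.finite(pairs)))
    stop_validation("pair values must all be finite")
  unname(pairs)
}
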
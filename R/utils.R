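#' @keywords internal
"_PACKAGE"

#' @importFrom stats optim pchisq p.adjust phyper rbinom rhyper runif t.test
#'   setNames var
#' @importFrom utils read.delim write.table
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a deterministic 31-bit sub-seed from a base seed and a counter, so
# per-item draws do not depend on processing order.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 69621) %% 2147483647L)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# One machine-parsable log line per pipeline stage.
stage_log <- function(stage, n_in, n_out, excluded = character(), verbose = TRUE) {
  if (verbose) {
    exc <- if (length(excluded)) {
      tab <- table(excluded)
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ",")
    } else ""
    message(sprintf("[%s] n_in=%d n_out=%d excluded{%s}", stage, n_in, n_out, exc))
  }
  invisible(NULL)
}
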
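#' @importFrom stats cor dhyper median p.adjust prcomp pt quantile rbinom
#'   rlnorm rnbinom rnorm runif sd var wilcox.test loess predict setNames
#'   hclust cutree as.dist pnorm
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

# Evaluate `code` under a fixed, fully pinned RNG state and restore the
# caller's state afterwards.  All stochastic operations in the package go
# through this so that a seed reproduces results bit-identically.
with_rng <- function(seed, code) {
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
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  }
  force(code)
}

# seed %% k offsets used to decorrelate independent stochastic stages that
# share one user-facing seed
offset_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)
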
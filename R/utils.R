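#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom stats cor cutree dist hclust p.adjust rpois runif sd setNames
#' @importFrom utils read.csv write.csv combn
NULL

# Derive a per-stage RNG seed from a master seed and a stage tag.  The tag is
# hashed so that adding or removing stages never shifts another stage's
# stream.  Result stays below 2^31 - 1 (R integers).
derive_seed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% 104729L
  as.integer((as.numeric(master) * 7919 + h * 513) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Permutation p-value convention used throughout: never exactly zero.
perm_p <- function(exceed, nperm) (exceed + 1) / (nperm + 1)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}
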
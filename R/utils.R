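# Internal helpers shared across the package.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores whatever state existed before, so seeded package operations do
#' not disturb the caller's random stream.  A `NULL` seed evaluates the
#' code against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a per-item seed from a base seed; stays within 32-bit integer range.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483629L)
}

# Shared validation for the (X, Y) pair every scoring routine takes.
check_xy <- function(X, Y, require_both_classes = TRUE) {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("X must be a numeric matrix (samples in rows, genes in columns)")
  }
  if (ncol(X) < 1L) stop("X must have at least one gene column")
  if (length(Y) != nrow(X)) {
    stop(sprintf("length of Y (%d) does not match rows of X (%d)",
                 length(Y), nrow(X)))
  }
  if (!all(Y %in% c(0, 1))) stop("Y must be coded 0 (normal) / 1 (disease)")
  if (require_both_classes && length(unique(Y)) < 2L) {
    stop("Y must contain both classes (all-0 or all-1 labels give a ",
         "degenerate null variance)")
  }
  invisible(TRUE)
}

# Classed error for scheme/method combinations the scores cannot support.
unsupported_combination <- function(scheme, method, why) {
  stop(errorCondition(
    sprintf("scheme '%s' is not supported with method '%s': %s",
            scheme, method, why),
    class = c("pathweight_unsupported_combination", "pathweight_error")
  ))
}
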
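# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  code
}

# Derive a child seed that stays inside 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric", name), call. = FALSE)
  }
  invisible(x)
}

#' Motion-intention label set
#'
#' The five motor intentions the control system distinguishes: the three hand
#' states taught during instruction (rest, grip, open) plus the two wrist
#' motions that are trained as explicit classes so they can be excluded from
#' hand actions.
#'
#' @return Character vector of the five labels in their canonical order
#'   (used for deterministic tie-breaking).
#' @export
motion_labels <- function() {
  c("rest", "grip", "open", "wrist_flex", "wrist_extend")
}
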
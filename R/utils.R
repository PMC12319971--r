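`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sub <- function(...) stop(..., call. = FALSE)

#' Round a total into integer block lengths proportional to fractions
#'
#' Largest-remainder style split used by the plan builders so that block
#' lengths always sum exactly to `total`.
#' @noRd
split_lengths <- function(total, fracs) {
  stopifnot(total >= 0, all(fracs >= 0))
  fr <- fracs / sum(fracs)
  diff(c(0L, round(cumsum(fr) * total)))
}

#' Relabel an integer vector to contiguous 1..k by order of first appearance
#' @noRd
relabel_contiguous <- function(x) {
  match(x, unique(x))
}

check_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      stop_sub("`seed` must be a single integer")
    }
    set.seed(as.integer(seed))
  }
  invisible(seed)
}
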
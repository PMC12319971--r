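#' Mean substate activation z-maps
#'
#' For each node and substate: the node's mean activity during the state
#' minus its mean over the rest-of-scan reference, divided by its temporal
#' SD. By default the reference is the whole scan; `exclude_self = TRUE`
#' uses only the volumes outside the state.
#'
#' @param ts a [parcel_ts()].
#' @param affil per-volume labels aligned to `ts`.
#' @param exclude_self exclude the state's own volumes from the reference.
#' @return numeric matrix, nodes x substates.
#' @export
state_mean_zmaps <- function(ts, affil, exclude_self = FALSE) {
  labels <- as.integer(affil)
  if (length(labels) != n_volumes(ts)) {
    stop_sub("affiliation length (", length(labels),
             ") does not match volumes (", n_volumes(ts), ")")
  }
  sds <- apply(ts$values, 1, sd)
  if (any(sds == 0)) {
    stop_sub("zero temporal SD at node(s) ",
             paste(ts$node_labels[sds == 0], collapse = ", "))
  }
  states <- sort(unique(labels))
  z <- vapply(states, function(s) {
    inside <- labels == s
    ref <- if (exclude_self) rowMeans(ts$values[, !inside, drop = FALSE]) else rowMeans(ts$values)
    (rowMeans(ts$values[, inside, drop = FALSE]) - ref) / sds
  }, numeric(n_nodes(ts)))
  dimnames(z) <- list(ts$node_labels, paste0("state", states))
  z
}

#' Substate beta-maps from an indicator-design GLM
#'
#' Ordinary least squares of each node's time series on one indicator
#' regressor per substate, with no intercept; under this design
#' `beta(node, state)` equals the node's mean activity during that state
#' exactly.
#'
#' @param ts a [parcel_ts()].
#' @param affil per-volume labels aligned to `ts`; every state must occur
#'   in at least one volume (an empty state makes the design rank
#'   deficient).
#' @param states states to estimate (default: all in `affil`).
#' @return numeric matrix, nodes x substates.
#' @export
beta_maps_glm <- function(ts, affil, states = NULL) {
  labels <- as.integer(affil)
  if (length(labels) != n_volumes(ts)) {
    stop_sub("affiliation length does not match volumes")
  }
  states <- states %||% sort(unique(labels))
  counts <- vapply(states, function(s) sum(labels == s), integer(1))
  if (any(counts == 0)) {
    stop_sub("rank-deficient design: state(s) ",
             paste(states[counts == 0], collapse = ", "), " never occur")
  }
  X <- vapply(states, function(s) as.numeric(labels == s),
              numeric(length(labels)))
  fit <- lm.fit(X, t(ts$values))
  betas <- t(fit$coefficients)
  dimnames(betas) <- list(ts$node_labels, paste0("state", states))
  betas
}

#' Per-participant beta-maps for one condition of a cohort
#'
#' @param cohort a `cohort`.
#' @param affil per-volume labels (shared across participants).
#' @param condition `"DMT"` or `"PCB"`.
#' @param states states to estimate.
#' @return 3-d array, participants x nodes x substates.
#' @export
cohort_beta_maps <- function(cohort, affil, condition = c("DMT", "PCB"),
                             states = NULL) {
  condition <- match.arg(condition)
  maps <- lapply(cohort$participants, function(p) {
    beta_maps_glm(p[[condition]], affil, states = states)
  })
  arr <- array(unlist(maps), dim = c(dim(maps[[1]]), length(maps)),
               dimnames = c(dimnames(maps[[1]]), list(names(maps))))
  aperm(arr, c(3, 1, 2)) # participants x nodes x states
}

#' Benjamini-Hochberg FDR adjustment with rejection set
#'
#' @param p p-values in `[0, 1]` (`NA`s carried through, never rejected).
#' @param alpha FDR level.
#' @return list with `q` (BH-adjusted values) and `reject` (logical).
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  q <- p.adjust(p, method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Paired DMT-vs-placebo contrast of substate beta-maps
#'
#' Per node, a paired t-test (df = n - 1) on the within-participant beta
#' differences for one substate, followed by BH-FDR across nodes within the
#' state. Nodes whose differences have zero variance are flagged
#' (`degenerate`) and excluded from the FDR family. Significant nodes are
#' split by sign into hyperactivity and hypoactivity masks.
#'
#' @param beta_dmt,beta_pcb arrays from [cohort_beta_maps()] (participants
#'   x nodes x states) covering the same participants.
#' @param state substate name (e.g. `"state4"`) or index into the state
#'   axis.
#' @param alpha FDR level (default 0.05).
#' @return list of class `contrast_result`: per-node data.frame (`t`, `p`,
#'   `q`, `direction`, `degenerate`), `hyper_mask`, `hypo_mask`, `n`.
#' @export
paired_contrast <- function(beta_dmt, beta_pcb, state, alpha = 0.05) {
  if (!identical(dim(beta_dmt), dim(beta_pcb))) {
    stop_sub("beta arrays differ in shape")
  }
  n <- dim(beta_dmt)[1]
  if (n < 3) stop_sub("need at least 3 participants for a paired contrast")
  d <- beta_dmt[, , state, drop = FALSE] - beta_pcb[, , state, drop = FALSE]
  d <- matrix(d, nrow = n)
  m <- colMeans(d)
  s <- apply(d, 2, sd)
  degenerate <- s == 0
  tval <- ifelse(degenerate, NA_real_, m / (s / sqrt(n)))
  pval <- 2 * pt(abs(tval), df = n - 1, lower.tail = FALSE)
  adj <- fdr_bh(pval, alpha)
  nodes <- dimnames(beta_dmt)[[2]] %||% paste0("node", seq_along(m))
  res <- data.frame(node = nodes, mean_diff = m, t = tval, p = pval,
                    q = adj$q,
                    direction = ifelse(m > 0, "hyper", ifelse(m < 0, "hypo", "none")),
                    degenerate = degenerate)
  structure(
    list(stats = res,
         hyper_mask = which(adj$reject & m > 0),
         hypo_mask = which(adj$reject & m < 0),
         n = n, alpha = alpha, state = state),
    class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("<contrast_result> state ", x$state, ": ", length(x$hyper_mask),
      " hyperactive / ", length(x$hypo_mask), " hypoactive nodes (FDR q <= ",
      x$alpha, ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Average activity over a node mask
#'
#' Unweighted mean across mask nodes. For a [parcel_ts()] this yields a
#' per-volume time series; for a participants x nodes matrix (e.g. one
#' state slice of a beta array) a per-participant scalar.
#'
#' @param x a [parcel_ts()] or a numeric matrix with nodes as columns.
#' @param mask non-empty integer node indices.
#' @return numeric vector.
#' @export
roi_average <- function(x, mask) {
  if (!length(mask)) stop_sub("empty node mask")
  if (inherits(x, "parcel_ts")) {
    colMeans(x$values[mask, , drop = FALSE])
  } else {
    rowMeans(as.matrix(x)[, mask, drop = FALSE])
  }
}

#' DMT-minus-placebo ROI time-series difference
#'
#' Averages raw activity over the mask nodes in both conditions and
#' subtracts, giving the per-volume condition difference for the region.
#'
#' @param ts_dmt,ts_pcb [parcel_ts()] objects on the same volume grid.
#' @param mask node indices.
#' @return numeric vector, one value per volume.
#' @export
roi_difference_series <- function(ts_dmt, ts_pcb, mask) {
  if (n_volumes(ts_dmt) != n_volumes(ts_pcb)) {
    stop_sub("conditions differ in volume count")
  }
  roi_average(ts_dmt, mask) - roi_average(ts_pcb, mask)
}
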
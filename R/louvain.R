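#' Modularity matrix with symmetric or asymmetric treatment of negative weights
#'
#' Positive and negative weights contribute separate null models. Under the
#' symmetric treatment the two contributions are weighted equally
#' (`B = B+/v+ - B-/v-`); under the asymmetric treatment the negative
#' contribution is down-weighted by the total weight
#' (`B = B+/v+ - B-/(v+ + v-)`). With no negative weights both reduce to
#' the standard Newman-Girvan modularity matrix.
#'
#' @param W square symmetric weight matrix (diagonal ignored).
#' @param gamma resolution parameter (default 1).
#' @param neg_treatment `"symmetric"` or `"asymmetric"`.
#' @return dense modularity matrix.
#' @keywords internal
modularity_matrix <- function(W, gamma = 1,
                              neg_treatment = c("symmetric", "asymmetric")) {
  neg_treatment <- match.arg(neg_treatment)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W0 <- pmax(W, 0)
  W1 <- -pmin(W, 0)
  s0 <- sum(W0)
  s1 <- sum(W1)
  if (s0 + s1 == 0) stop_sub("graph has no edges (all weights zero): over-thresholded")
  B <- matrix(0, nrow(W), ncol(W))
  if (s0 > 0) {
    k0 <- rowSums(W0)
    B <- B + (W0 - gamma * outer(k0, k0) / s0) / s0
  }
  if (s1 > 0) {
    k1 <- rowSums(W1)
    B1 <- W1 - gamma * outer(k1, k1) / s1
    B <- B - if (neg_treatment == "symmetric") B1 / s1 else B1 / (s0 + s1)
  }
  (B + t(B)) / 2
}

#' Louvain community detection on a (signed) weighted matrix
#'
#' Maximizes signed-weighted modularity with resolution `gamma` by greedy
#' local moving and aggregation, restarted `n_restarts` times with random
#' node orders; the partition with the highest quality Q is returned.
#' Volumes with zero total weight cannot be placed meaningfully and are
#' assigned singleton labels (reported in the `unassigned` attribute).
#'
#' @param W square symmetric weight matrix (a thresholded subtraction
#'   matrix, or a signed matrix for the control path), or a
#'   `subtraction_matrix`.
#' @param gamma resolution parameter (default 1).
#' @param neg_treatment negative-weight treatment, see
#'   [modularity_matrix()].
#' @param seed RNG seed for the restart node orders.
#' @param n_restarts number of restarts (default 100).
#' @return an `affiliation` object: integer per-volume labels 1..k with
#'   attributes `k`, `Q`, `unassigned`.
#' @export
louvain_communities <- function(W, gamma = 1,
                                neg_treatment = c("symmetric", "asymmetric"),
                                seed = NULL, n_restarts = 100) {
  neg_treatment <- match.arg(neg_treatment)
  if (inherits(W, "subtraction_matrix")) W <- W$values
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop_sub("`W` must be a square matrix")
  n <- nrow(W)
  strength <- rowSums(abs(W)) - abs(diag(W))
  active <- strength > 0
  if (!any(active)) stop_sub("graph has no edges (all weights zero): over-thresholded")
  B <- modularity_matrix(W[active, active, drop = FALSE], gamma = gamma,
                         neg_treatment = neg_treatment)
  check_seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    ord <- sample.int(sum(active)) - 1L
    res <- louvain_dense(B, ord)
    if (is.null(best) || res$Q > best$Q + 1e-12) best <- res
  }
  labels <- integer(n)
  labels[active] <- best$labels
  if (any(!active)) {
    labels[!active] <- max(best$labels) + seq_len(sum(!active))
  }
  labels <- relabel_contiguous(labels)
  affiliation(labels, Q = best$Q, unassigned = which(!active))
}

#' Community affiliation vector
#'
#' Per-volume substate labels (contiguous integers 1..k) produced by
#' community detection, with the partition quality and any threshold used.
#'
#' @param labels integer labels, one per volume.
#' @param threshold threshold applied to the subtraction matrix, if any.
#' @param Q modularity quality of the partition, if known.
#' @param unassigned indices of volumes given singleton labels because they
#'   had zero graph weight.
#' @return integer vector of class `affiliation`.
#' @export
affiliation <- function(labels, threshold = NA_real_, Q = NA_real_,
                        unassigned = integer(0)) {
  labels <- as.integer(labels)
  k <- max(labels)
  if (!setequal(unique(labels), seq_len(k))) {
    stop_sub("labels must be contiguous integers 1..k")
  }
  structure(labels, k = k, threshold = threshold, Q = Q,
            unassigned = unassigned, class = "affiliation")
}

#' @export
print.affiliation <- function(x, ...) {
  cat("<affiliation> ", length(x), " volumes, k = ", attr(x, "k"), sep = "")
  if (!is.na(attr(x, "Q"))) cat(", Q = ", signif(attr(x, "Q"), 4), sep = "")
  if (!is.na(attr(x, "threshold"))) {
    cat(" (threshold ", attr(x, "threshold"), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}
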
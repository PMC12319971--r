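#' Threshold a subtraction matrix, keeping positive weights
#'
#' Entries at or above the threshold keep their value; everything else —
#' including all negative entries and the diagonal — is set to zero.
#' Focusing on positive differences targets periods of drug-specific
#' temporal similarity. (Thresholding on `abs()` instead is available for
#' exploratory use.)
#'
#' @param S a `subtraction_matrix` (or plain square matrix).
#' @param r threshold on the correlation-difference scale. Values outside
#'   the conventional sweep range 0.20-0.30 raise a warning, not an error.
#' @param use_absolute threshold `|S| >= r` keeping magnitudes of either
#'   sign as positive weights (default `FALSE`).
#' @return nonnegative weighted matrix of the same size.
#' @export
threshold_matrix <- function(S, r, use_absolute = FALSE) {
  v <- if (inherits(S, "subtraction_matrix")) S$values else S
  if (r < 0.20 - 1e-12 || r > 0.30 + 1e-12) {
    warning("threshold ", r, " lies outside the conventional sweep range [0.20, 0.30]")
  }
  W <- if (use_absolute) abs(v) else v
  W[W < r] <- 0
  diag(W) <- 0
  W
}

#' Substate occupancy before and after the injection
#'
#' For each state, the fraction of pre-injection (post-injection) volumes it
#' occupies, and the corresponding duration in minutes
#' (`fraction x period length`). Occupancies sum to 1 within each period
#' over all states present (excluded volumes, if any, are dropped from both
#' numerator and denominator).
#'
#' @param affil per-volume labels ([affiliation()] or integer vector).
#' @param injection_volume last pre-injection volume.
#' @param tr_seconds repetition time, for the minute conversion.
#' @param exclude optional volume indices to drop (e.g. scrubbed frames).
#' @return data.frame with one row per state: counts, occupancies, minutes.
#' @export
occupancy <- function(affil, injection_volume, tr_seconds = 2,
                      exclude = integer(0)) {
  labels <- as.integer(affil)
  nv <- length(labels)
  if (injection_volume <= 0 || injection_volume >= nv) {
    stop_sub("`injection_volume` must lie strictly inside the scan")
  }
  use <- setdiff(seq_len(nv), exclude)
  pre <- use[use <= injection_volume]
  post <- use[use > injection_volume]
  states <- sort(unique(labels[use]))
  n_pre <- vapply(states, function(s) sum(labels[pre] == s), integer(1))
  n_post <- vapply(states, function(s) sum(labels[post] == s), integer(1))
  pre_occ <- n_pre / length(pre)
  post_occ <- n_post / length(post)
  data.frame(
    state = states,
    n_pre = n_pre, n_post = n_post,
    pre_occupancy = pre_occ, post_occupancy = post_occ,
    pre_minutes = pre_occ * length(pre) * tr_seconds / 60,
    post_minutes = post_occ * length(post) * tr_seconds / 60)
}

#' Pre/post-injection separability chi-square statistics
#'
#' Omnibus statistic: Pearson chi-square on the k x 2 contingency table of
#' volume counts (state by pre/post period), df = k - 1. Per-state
#' statistics: chi-square on each 2 x 2 table (state vs. rest, pre vs.
#' post), no continuity correction, df = 1. An alternative omnibus reading
#' — the sum of the per-state 2 x 2 statistics — is available via
#' `omnibus = "sum_per_state"`.
#'
#' @inheritParams occupancy
#' @param omnibus `"table"` (k x 2 Pearson chi-square, default) or
#'   `"sum_per_state"`.
#' @return list with `chi2` (omnibus), `df`, `p_value`, and `per_state`
#'   data.frame (state, chi2, p_value).
#' @export
separability_chi2 <- function(affil, injection_volume,
                              omnibus = c("table", "sum_per_state"),
                              exclude = integer(0)) {
  omnibus <- match.arg(omnibus)
  labels <- as.integer(affil)
  nv <- length(labels)
  use <- setdiff(seq_len(nv), exclude)
  pre <- labels[use[use <= injection_volume]]
  post <- labels[use[use > injection_volume]]
  if (!length(pre) || !length(post)) stop_sub("a period has zero volumes")
  states <- sort(unique(c(pre, post)))
  if (length(states) < 2) stop_sub("need at least 2 states for separability")
  tab <- rbind(pre = table(factor(pre, levels = states)),
               post = table(factor(post, levels = states)))
  omni <- suppressWarnings(chisq.test(tab, correct = FALSE))
  per <- lapply(states, function(s) {
    t2 <- rbind(c(sum(pre == s), sum(pre != s)),
                c(sum(post == s), sum(post != s)))
    ct <- suppressWarnings(chisq.test(t2, correct = FALSE))
    data.frame(state = s, chi2 = unname(ct$statistic),
               p_value = unname(ct$p.value))
  })
  per <- do.call(rbind, per)
  if (omnibus == "table") {
    list(chi2 = unname(omni$statistic), df = unname(omni$parameter),
         p_value = unname(omni$p.value), per_state = per)
  } else {
    chi2 <- sum(per$chi2)
    list(chi2 = chi2, df = nrow(per),
         p_value = pchisq(chi2, df = nrow(per), lower.tail = FALSE),
         per_state = per)
  }
}

#' Combined per-state summary: occupancy, chi-square, retention
#'
#' @inheritParams occupancy
#' @param min_occupancy occupancy floor (default 0.10): a state must occupy
#'   at least this fraction of one period.
#' @param alpha significance level for the per-state chi-square.
#' @return data.frame with occupancy columns plus `chi2`, `p_value`,
#'   `retained`; the omnibus statistic is attached as attributes `chi2` and
#'   `chi2_p`.
#' @export
substate_summary <- function(affil, injection_volume, tr_seconds = 2,
                             min_occupancy = 0.10, alpha = 0.05,
                             exclude = integer(0)) {
  occ <- occupancy(affil, injection_volume, tr_seconds, exclude = exclude)
  sep <- separability_chi2(affil, injection_volume, exclude = exclude)
  out <- merge(occ, sep$per_state, by = "state")
  out$retained <- retained_substates(out, min_occupancy = min_occupancy,
                                     alpha = alpha, as_labels = FALSE)
  attr(out, "chi2") <- sep$chi2
  attr(out, "chi2_p") <- sep$p_value
  out
}

#' Retention rule for substates
#'
#' A state is retained when it is differentially occupied across the
#' injection (per-state chi-square p below `alpha`) and substantially
#' occupied (at least `min_occupancy` of the pre- or the post-injection
#' period).
#'
#' @param summaries data.frame with columns `state`, `pre_occupancy`,
#'   `post_occupancy`, `p_value` (as from [substate_summary()]).
#' @param min_occupancy occupancy floor (default 0.10).
#' @param alpha significance level (default 0.05).
#' @param as_labels return retained state labels (default) or a logical
#'   vector aligned to `summaries`.
#' @export
retained_substates <- function(summaries, min_occupancy = 0.10, alpha = 0.05,
                               as_labels = TRUE) {
  keep <- !is.na(summaries$p_value) & summaries$p_value < alpha &
    (summaries$pre_occupancy >= min_occupancy |
       summaries$post_occupancy >= min_occupancy)
  if (as_labels) summaries$state[keep] else keep
}

#' Threshold sweep with separability-based selection
#'
#' For each threshold in `thresholds` the subtraction matrix is thresholded,
#' partitioned by [louvain_communities()], and summarized; the operating
#' threshold is the one maximizing the number of retained substates, ties
#' broken by the larger omnibus chi-square, then by the smaller threshold.
#'
#' @param S a `subtraction_matrix`.
#' @param thresholds increasing threshold grid (default 0.20-0.30, step
#'   0.01).
#' @param gamma Louvain resolution parameter.
#' @param seed,n_restarts Louvain restart control.
#' @param min_occupancy,alpha retention rule parameters.
#' @param tr_seconds repetition time for minute conversions.
#' @return list of class `threshold_sweep` with `table` (one row per
#'   threshold: threshold, k, n_retained, chi2, selected), `selected`
#'   (threshold value), `affiliation` (at the selected threshold),
#'   `summary` (its [substate_summary()]) and `affiliations` (all).
#' @export
threshold_sweep <- function(S, thresholds = seq(0.20, 0.30, by = 0.01),
                            gamma = 1, seed = NULL, n_restarts = 100,
                            min_occupancy = 0.10, alpha = 0.05,
                            tr_seconds = NULL) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop_sub("`thresholds` must be strictly increasing")
  }
  tr_seconds <- tr_seconds %||% (S$tr_seconds %||% 2)
  check_seed(seed)
  rows <- list()
  affils <- list()
  summaries <- list()
  for (i in seq_along(thresholds)) {
    r <- thresholds[i]
    W <- threshold_matrix(S, r)
    entry <- tryCatch({
      af <- louvain_communities(W, gamma = gamma, seed = NULL,
                                n_restarts = n_restarts)
      attr(af, "threshold") <- r
      sm <- substate_summary(af, S$injection_volume, tr_seconds,
                             min_occupancy = min_occupancy, alpha = alpha)
      list(af = af, sm = sm,
           row = data.frame(threshold = r, k = attr(af, "k"),
                            n_retained = sum(sm$retained),
                            chi2 = attr(sm, "chi2")))
    }, error = function(e) {
      list(af = NULL, sm = NULL,
           row = data.frame(threshold = r, k = 0L, n_retained = 0L,
                            chi2 = NA_real_))
    })
    rows[[i]] <- entry$row
    affils[[i]] <- entry$af
    summaries[[i]] <- entry$sm
  }
  tab <- do.call(rbind, rows)
  if (all(tab$k == 0L)) {
    stop_sub("all thresholds yield empty graphs: nothing to partition")
  }
  ok <- which(tab$k > 0L)
  ord <- ok[order(-tab$n_retained[ok], -ifelse(is.na(tab$chi2[ok]), -Inf, tab$chi2[ok]),
                  tab$threshold[ok])]
  sel <- ord[1]
  tab$selected <- seq_len(nrow(tab)) == sel
  structure(
    list(table = tab, selected = tab$threshold[sel],
         affiliation = affils[[sel]], summary = summaries[[sel]],
         affiliations = affils),
    class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("<threshold_sweep> selected threshold ", x$selected, " (",
      x$table$n_retained[x$table$selected], " retained of ",
      x$table$k[x$table$selected], " substates)\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' k-means control partition of the subtraction matrix
#'
#' Clusters the rows of the subtraction matrix into `k` groups, keeping the
#' best of `replicates` random starts by total within-cluster sum of
#' squares. Serves as a non-graph control for the Louvain partition.
#' Per-replicate convergence chatter is silenced: replicates compete on
#' their final inertia, so an occasional unconverged start is simply
#' dominated.
#'
#' @param S a `subtraction_matrix` (or plain square matrix).
#' @param k number of clusters (default 3).
#' @param max_iter maximum iterations per replicate (default 10000).
#' @param replicates number of random starts (default 10).
#' @param seed RNG seed.
#' @return an [affiliation()] with attributes `inertia` (winning
#'   within-cluster sum of squares) and `inertias` (per replicate).
#' @export
kmeans_control <- function(S, k = 3, max_iter = 10000, replicates = 10,
                           seed = NULL) {
  X <- if (inherits(S, "subtraction_matrix")) S$values else S
  if (k < 2) stop_sub("`k` must be at least 2")
  if (k > nrow(X)) stop_sub("`k` exceeds the number of volumes")
  check_seed(seed)
  best <- NULL
  inertias <- numeric(replicates)
  for (rep in seq_len(replicates)) {
    fit <- suppressWarnings(
      kmeans(X, centers = k, iter.max = max_iter, nstart = 1))
    inertias[rep] <- fit$tot.withinss
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  out <- affiliation(relabel_contiguous(best$cluster))
  attr(out, "inertia") <- best$tot.withinss
  attr(out, "inertias") <- inertias
  out
}
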
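#' Time-resolved brain-activity similarity matrix
#'
#' Entry (i, j) is the Pearson correlation, across nodes, between the
#' whole-brain spatial activity patterns at volumes i and j, yielding a
#' symmetric T x T matrix with unit diagonal that reflects the homogeneity
#' of brain activity over the scan.
#'
#' @param ts a [parcel_ts()] with at least 3 nodes.
#' @return object of class `time_sim_matrix` with `values` (T x T),
#'   `tr_seconds` and `injection_volume`.
#' @export
time_similarity_matrix <- function(ts) {
  if (n_nodes(ts) < 3) stop_sub("need at least 3 nodes for spatial correlation")
  sds <- apply(ts$values, 2, sd)
  if (any(sds == 0)) {
    stop_sub("zero spatial variance at volume(s) ",
             paste(which(sds == 0), collapse = ", "))
  }
  v <- cor(ts$values)
  structure(list(values = v, tr_seconds = ts$tr_seconds,
                 injection_volume = ts$injection_volume),
            class = "time_sim_matrix")
}

#' Element-wise mean of similarity matrices (group average)
#'
#' @param matrices list of `time_sim_matrix` objects of identical size.
#' @return a `time_sim_matrix`.
#' @export
group_mean_matrix <- function(matrices) {
  if (!length(matrices)) stop_sub("empty matrix list")
  dims <- vapply(matrices, function(m) nrow(m$values), integer(1))
  if (length(unique(dims)) != 1) {
    stop_sub("similarity matrices differ in size: ",
             paste(unique(dims), collapse = " vs "))
  }
  out <- matrices[[1]]
  out$values <- Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices)
  out
}

#' Condition subtraction matrix (DMT minus placebo)
#'
#' Element-wise difference of two (typically group-mean) similarity
#' matrices; positive entries mark volume pairs whose brain activity is more
#' similar under the drug than under placebo. The diagonal is forced to 0.
#'
#' @param dmt,pcb `time_sim_matrix` objects with equal size and
#'   `injection_volume`.
#' @return object of class `subtraction_matrix`.
#' @export
subtraction_matrix <- function(dmt, pcb) {
  if (!identical(dim(dmt$values), dim(pcb$values))) {
    stop_sub("matrices differ in size")
  }
  if (dmt$injection_volume != pcb$injection_volume) {
    stop_sub("mismatched injection_volume (", dmt$injection_volume, " vs ",
             pcb$injection_volume, ")")
  }
  v <- dmt$values - pcb$values
  diag(v) <- 0
  structure(list(values = v, tr_seconds = dmt$tr_seconds,
                 injection_volume = dmt$injection_volume),
            class = "subtraction_matrix")
}

#' Per-condition group-mean similarity matrices and their subtraction
#'
#' Convenience wrapper running [time_similarity_matrix()] for every
#' participant and condition of a cohort, averaging within condition, and
#' subtracting.
#'
#' @param cohort a `cohort` from [generate_cohort()] or [read_cohort()].
#' @return list with `dmt`, `pcb` (group means) and `subtraction`.
#' @export
cohort_subtraction_matrix <- function(cohort) {
  sims <- lapply(c(DMT = "DMT", PCB = "PCB"), function(cond) {
    group_mean_matrix(lapply(cohort$participants, function(p) {
      time_similarity_matrix(p[[cond]])
    }))
  })
  list(dmt = sims$DMT, pcb = sims$PCB,
       subtraction = subtraction_matrix(sims$DMT, sims$PCB))
}
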
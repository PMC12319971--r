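#' Parcellated BOLD time series for one participant and condition
#'
#' Container for nodal (parcel-averaged) BOLD activity: a numeric matrix of
#' `n_nodes` rows by `n_volumes` columns, together with the repetition time
#' and the index of the last pre-injection volume. The default study layout
#' is 112 nodes (100 cortical parcels plus 12 subcortical regions) and 840
#' volumes at TR = 2 s, with the injection at the end of minute 8 so that
#' volume 240 is the last pre-injection volume.
#'
#' @param values numeric matrix, nodes x volumes; no missing values allowed.
#' @param tr_seconds repetition time in seconds (default 2).
#' @param injection_volume index of the last pre-injection volume (default
#'   240); must be strictly between 0 and the number of volumes.
#' @param participant_id,condition identifiers; `condition` is `"DMT"` or
#'   `"PCB"`.
#' @param node_labels optional character vector of parcel names.
#' @return An object of class `parcel_ts`.
#' @export
parcel_ts <- function(values, tr_seconds = 2, injection_volume = 240,
                      participant_id = NA_character_, condition = c("DMT", "PCB"),
                      node_labels = NULL) {
  condition <- match.arg(condition)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_sub("`values` must be a numeric matrix")
  if (anyNA(values)) stop_sub("`values` contains missing values")
  n_vol <- ncol(values)
  if (tr_seconds <= 0) stop_sub("`tr_seconds` must be positive")
  if (injection_volume <= 0 || injection_volume >= n_vol) {
    stop_sub("`injection_volume` must lie strictly between 0 and the number of volumes (",
             n_vol, ")")
  }
  if (!is.null(node_labels) && length(node_labels) != nrow(values)) {
    stop_sub("`node_labels` length must equal the number of nodes")
  }
  structure(
    list(values = values,
         node_labels = node_labels %||% paste0("node", seq_len(nrow(values))),
         tr_seconds = tr_seconds,
         injection_volume = as.integer(injection_volume),
         participant_id = as.character(participant_id),
         condition = condition),
    class = "parcel_ts")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat("<parcel_ts> ", x$participant_id, " [", x$condition, "]: ",
      nrow(x$values), " nodes x ", ncol(x$values), " volumes, TR ",
      x$tr_seconds, " s, injection after volume ", x$injection_volume, "\n",
      sep = "")
  invisible(x)
}

n_volumes <- function(ts) ncol(ts$values)
n_nodes <- function(ts) nrow(ts$values)
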
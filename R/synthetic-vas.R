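#' Names of the 25 subjective-experience rating items
#'
#' Post-session visual-analogue-scale items covering drug intensity,
#' sensory distortion, altered time/space, disembodiment, and
#' self-referential processes, rated 0-1 in steps of 0.01.
#' @return character vector of length 25.
#' @export
vas_items <- function() {
  c("intensity", "vivid_imagination", "buzzing_sound", "presence_entity",
    "visual_patterns", "auditory_hallucination", "colors_intense",
    "geometric_imagery", "sounds_influenced_vision", "sense_time_altered",
    "sense_space_altered", "thoughts_wandered", "ego_dissolution",
    "disembodiment", "dissociation", "meaningfulness", "emotional_openness",
    "gratitude", "anxiety", "bliss", "lost_experiment_awareness",
    "body_temperature", "heart_racing", "familiarity", "unity")
}

default_vas_coupling <- function() {
  list(buzzing_sound = list(source = "hyper", coef = 0.6),
       presence_entity = list(source = "hyper", coef = 0.5),
       sense_time_altered = list(source = "hypo", coef = -0.6),
       thoughts_wandered = list(source = "hr", coef = -0.5))
}

quantize01 <- function(x) {
  out <- round(x * 100) / 100
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Generate 25-item subjective ratings coupled to planted cohort truth
#'
#' Ratings lie on the grid 0, 0.01, ..., 1. For a coupled item the
#' DMT-minus-placebo change score is built as
#' `scale * (coef * z(source) + sqrt(1 - coef^2) * eps)` plus measurement
#' noise, where `z(source)` standardizes the planted per-participant effect
#' amplitudes; with `noise_sd > 0` the planted population correlation
#' between change score and source is approximately `coef`. With
#' `noise_sd = 0` the deterministic limit is returned: the orthogonal
#' component and measurement noise vanish, so a zero coefficient gives
#' identical ratings across conditions and a unit coefficient a change score
#' perfectly (up to 0.01-grid rounding) correlated with the source.
#'
#' @param truth a `cohort` from [generate_cohort()], or a bare list with an
#'   `effects` element (named list of per-participant numeric vectors).
#' @param coupling named list `item -> list(source =, coef =)`; sources must
#'   exist in `truth$effects`.
#' @param noise_sd measurement noise SD on the 0-1 rating scale.
#' @param seed RNG seed.
#' @param base_rating placebo-condition mean rating of every item.
#' @param coupling_scale amplitude of the coupled change on the 0-1 scale.
#' @return list with matrices `dmt`, `pcb` (participants x 25), the
#'   `change` matrix (dmt - pcb) and `items`.
#' @export
generate_vas <- function(truth, coupling = default_vas_coupling(),
                         noise_sd = 0.1, seed = NULL,
                         base_rating = 0.5, coupling_scale = 0.25) {
  if (inherits(truth, "cohort")) truth <- truth$truth
  effects <- truth$effects
  if (is.null(effects)) stop_sub("`truth` must carry per-participant `effects`")
  for (item in names(coupling)) {
    if (!item %in% vas_items()) stop_sub("unknown rating item '", item, "'")
    src <- coupling[[item]]$source
    if (!src %in% names(effects)) {
      stop_sub("coupling source '", src, "' not present in the cohort truth")
    }
  }
  n <- length(effects[[1]])
  check_seed(seed)
  items <- vas_items()
  m <- length(items)
  # participant-item anchors: idiosyncratic but shared across conditions
  # (test-retest consistent), so anchor noise cancels in the change score
  anchor <- matrix(base_rating, n, m, dimnames = list(NULL, items))
  if (noise_sd > 0) anchor <- anchor + matrix(rnorm(n * m, 0, noise_sd), n, m)
  dmt_raw <- anchor
  for (item in names(coupling)) {
    cp <- coupling[[item]]
    src <- effects[[cp$source]]
    z <- if (sd(src) > 0) (src - mean(src)) / sd(src) else rep(0, n)
    coupled <- cp$coef * z
    if (noise_sd > 0) {
      coupled <- coupled + sqrt(max(0, 1 - cp$coef^2)) * rnorm(n)
    }
    dmt_raw[, item] <- dmt_raw[, item] + coupling_scale * coupled
  }
  if (noise_sd > 0) dmt_raw <- dmt_raw + matrix(rnorm(n * m, 0, noise_sd), n, m)
  dmt <- quantize01(dmt_raw)
  pcb <- quantize01(anchor)
  list(dmt = dmt, pcb = pcb, change = dmt - pcb, items = items)
}
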
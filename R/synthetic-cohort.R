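#' Substate plan: planted temporal windows for the active condition
#'
#' A plan is a data frame with columns `state`, `start`, `end` giving
#' contiguous, disjoint volume windows (1-based, inclusive). A state may own
#' several windows (e.g. one before and one after the injection). The plan
#' must tile the scan completely: every volume belongs to exactly one state,
#' mirroring the community-detection output in which every volume receives a
#' label.
#'
#' @param state integer state labels (1..k).
#' @param start,end window bounds in volumes, inclusive.
#' @return data.frame of class `substate_plan`.
#' @export
substate_plan <- function(state, start, end) {
  plan <- data.frame(state = as.integer(state), start = as.integer(start),
                     end = as.integer(end))
  class(plan) <- c("substate_plan", "data.frame")
  plan
}

#' Default planted plan mirroring the study's occupancy profile
#'
#' Five states; the pre-injection period is dominated by a "baseline" state
#' (state 2) that returns toward the end of the scan, two post-injection
#' states (4 and 5) emerge after the injection, and two brief states (1 and
#' 3) occupy under 5% of the scan so that the retention rule discards them —
#' three of five states survive, as in the motivating study design.
#'
#' @param n_volumes,injection_volume scan layout (defaults 840 and 240).
#' @return A [substate_plan()].
#' @export
default_substate_plan <- function(n_volumes = 840, injection_volume = 240) {
  pre <- injection_volume
  post <- n_volumes - injection_volume
  # pre fractions: brief S1, dominant S2, brief S3, small S4/S5 onsets
  pre_len <- split_lengths(pre, c(10, 186, 12, 16, 16) / 240)
  post_len <- split_lengths(post, c(180, 140, 280) / 600) # S4, S5, S2 return
  starts_pre <- cumsum(c(1L, head(pre_len, -1)))
  starts_post <- injection_volume + cumsum(c(1L, head(post_len, -1)))
  substate_plan(
    state = c(1L, 2L, 3L, 4L, 5L, 4L, 5L, 2L),
    start = c(starts_pre, starts_post),
    end = c(starts_pre + pre_len - 1L, starts_post + post_len - 1L))
}

#' Balanced plan in which every state substantially occupies one period
#'
#' Two states split the pre-injection period and three split the
#' post-injection period, so all five states exceed the 10% occupancy floor
#' in one period and differ sharply between periods. Useful when the test
#' question is whether the sweep recovers all planted states as retained.
#'
#' @inheritParams default_substate_plan
#' @param n_states number of planted states (default 5; >= 2).
#' @export
balanced_substate_plan <- function(n_volumes = 840, injection_volume = 240,
                                   n_states = 5) {
  n_states <- as.integer(n_states)
  if (n_states < 2) stop_sub("`n_states` must be at least 2")
  n_pre <- max(1L, n_states %/% 2)
  n_post <- n_states - n_pre
  pre_len <- split_lengths(injection_volume, rep(1, n_pre))
  post_len <- split_lengths(n_volumes - injection_volume, rep(1, n_post))
  starts_pre <- cumsum(c(1L, head(pre_len, -1)))
  starts_post <- injection_volume + cumsum(c(1L, head(post_len, -1)))
  substate_plan(
    state = seq_len(n_states),
    start = c(starts_pre, starts_post),
    end = c(starts_pre + pre_len - 1L, starts_post + post_len - 1L))
}

validate_plan <- function(plan, n_volumes) {
  if (!all(c("state", "start", "end") %in% names(plan))) {
    stop_sub("substate plan needs columns state, start, end")
  }
  if (any(plan$start > plan$end)) stop_sub("plan window with start > end")
  if (min(plan$start) < 1 || max(plan$end) > n_volumes) {
    stop_sub("plan windows must lie within [1, ", n_volumes, "]")
  }
  covered <- integer(n_volumes)
  for (i in seq_len(nrow(plan))) {
    covered[plan$start[i]:plan$end[i]] <- covered[plan$start[i]:plan$end[i]] + 1L
  }
  if (any(covered > 1L)) stop_sub("plan windows overlap")
  if (any(covered == 0L)) stop_sub("plan windows must tile the scan (uncovered volumes found)")
  k <- max(plan$state)
  if (!setequal(unique(plan$state), seq_len(k))) {
    stop_sub("plan states must be contiguous integers 1..k")
  }
  invisible(k)
}

plan_labels <- function(plan, n_volumes) {
  labels <- integer(n_volumes)
  for (i in seq_len(nrow(plan))) labels[plan$start[i]:plan$end[i]] <- plan$state[i]
  labels
}

#' Condition-specific additive nodal effect
#'
#' Describes an additive amplitude applied to a node set during a given
#' state's windows in one condition, with a between-participant standard
#' deviation so that individual effect sizes vary (the per-participant
#' amplitudes become the planted "truth" that subjective ratings can couple
#' to).
#'
#' @param name identifier used as the coupling source name.
#' @param nodes integer node indices.
#' @param amplitude mean additive amplitude (activity units).
#' @param state state label whose windows carry the effect.
#' @param condition `"DMT"` or `"PCB"`.
#' @param sd_between between-participant SD of the amplitude.
#' @export
condition_effect <- function(name, nodes, amplitude, state = 4L,
                             condition = c("DMT", "PCB"), sd_between = 0.25) {
  condition <- match.arg(condition)
  list(name = name, nodes = as.integer(nodes), amplitude = amplitude,
       state = as.integer(state), condition = condition,
       sd_between = sd_between)
}

default_condition_effects <- function() {
  # hyperactive "superior temporal"-like node set and hypoactive
  # "hippocampal/medial parietal"-like node set in the first
  # post-injection state, active-drug condition only
  list(
    condition_effect("hyper", nodes = 1:6, amplitude = 0.8, state = 4L,
                     condition = "DMT", sd_between = 0.25),
    condition_effect("hypo", nodes = 7:14, amplitude = -0.8, state = 4L,
                     condition = "DMT", sd_between = 0.25))
}

#' Specification of a synthetic paired-condition cohort
#'
#' Defines the study conditions emulated by [generate_cohort()]: paired
#' active-drug (DMT) and placebo (PCB) parcellated BOLD series for each
#' participant, with planted temporal substates, condition-specific regional
#' effects, per-participant heart-rate modulation, and coupling of
#' subjective ratings to the planted effects. Defaults follow the emulated
#' study design: 14 participants, 112 nodes, 840 volumes at TR = 2 s,
#' injection after volume 240 (end of minute 8).
#'
#' The DMT condition expresses the substates of `substate_plan` as
#' temporally persistent spatial patterns; the placebo condition revisits
#' the same spatial patterns but cycles them volume-by-volume
#' (`placebo_cycle` volumes per pattern), so placebo activity has spatial
#' structure and variance but no temporal persistence. The DMT-minus-placebo
#' subtraction matrix then isolates drug-specific temporal similarity.
#'
#' @param n_participants,n_nodes,n_volumes cohort dimensions.
#' @param tr_seconds repetition time (s).
#' @param injection_volume last pre-injection volume.
#' @param noise_sd SD of i.i.d. Gaussian nodal noise (activity units; the
#'   planted patterns have unit node-wise scale).
#' @param seed RNG seed; fixed seed gives bit-identical cohorts.
#' @param substate_plan planted windows, see [substate_plan()].
#' @param placebo_cycle length (volumes) of each placebo pattern visit.
#' @param placebo_persistent when `TRUE` the placebo condition expresses the
#'   same persistent substate windows as the drug condition (no cycling), so
#'   conditions differ only through `condition_effects` — the matched-null
#'   configuration used for contrast-recovery and null-case tests.
#' @param condition_effects list of [condition_effect()]s.
#' @param hr_baseline_bpm,hr_baseline_sd between-participant distribution of
#'   resting heart rate.
#' @param hr_effect_bpm,hr_effect_sd between-participant distribution of the
#'   DMT heart-rate increase during the `hr_state` post-injection windows.
#' @param hr_state state whose post-injection windows carry the heart-rate
#'   effect (default 4, the first post-injection state).
#' @param vas_coupling named list mapping rating items to
#'   `list(source =, coef =)`; see [generate_vas()].
#' @param ar1 optional AR(1) coefficient for temporally autocorrelated
#'   noise (default 0, i.i.d.).
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 14, n_nodes = 112, n_volumes = 840,
                        tr_seconds = 2, injection_volume = 240,
                        noise_sd = 0.5, seed = 1L,
                        substate_plan = default_substate_plan(n_volumes, injection_volume),
                        placebo_cycle = 1L, placebo_persistent = FALSE,
                        condition_effects = default_condition_effects(),
                        hr_baseline_bpm = 65, hr_baseline_sd = 4,
                        hr_effect_bpm = 12, hr_effect_sd = 3, hr_state = 4L,
                        vas_coupling = default_vas_coupling(),
                        ar1 = 0) {
  if (n_volumes <= injection_volume || injection_volume <= 0) {
    stop_sub("need n_volumes > injection_volume > 0")
  }
  if (noise_sd < 0) stop_sub("`noise_sd` must be >= 0")
  if (n_participants < 1) stop_sub("need at least one participant")
  k <- validate_plan(substate_plan, n_volumes)
  for (eff in condition_effects) {
    if (any(eff$nodes < 1L | eff$nodes > n_nodes)) {
      stop_sub("condition effect '", eff$name, "' references nodes outside 1..", n_nodes)
    }
    if (!(eff$state %in% substate_plan$state) && eff$condition == "DMT") {
      stop_sub("condition effect '", eff$name, "' references absent state ", eff$state)
    }
  }
  if (!(hr_state %in% substate_plan$state)) {
    stop_sub("`hr_state` must be a planted state")
  }
  eff_names <- vapply(condition_effects, `[[`, character(1), "name")
  if (missing(vas_coupling)) {
    # trim the default coupling to the sources this cohort actually plants
    keep <- vapply(vas_coupling, function(cp) cp$source %in% c(eff_names, "hr"),
                   logical(1))
    vas_coupling <- vas_coupling[keep]
  } else {
    for (item in names(vas_coupling)) {
      src <- vas_coupling[[item]]$source
      if (!src %in% c(eff_names, "hr")) {
        stop_sub("vas_coupling source '", src, "' is not a planted effect")
      }
    }
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_nodes = as.integer(n_nodes), n_volumes = as.integer(n_volumes),
         tr_seconds = tr_seconds, injection_volume = as.integer(injection_volume),
         noise_sd = noise_sd, seed = as.integer(seed),
         substate_plan = substate_plan, placebo_cycle = as.integer(placebo_cycle),
         placebo_persistent = isTRUE(placebo_persistent),
         condition_effects = condition_effects,
         hr_baseline_bpm = hr_baseline_bpm, hr_baseline_sd = hr_baseline_sd,
         hr_effect_bpm = hr_effect_bpm, hr_effect_sd = hr_effect_sd,
         hr_state = as.integer(hr_state),
         vas_coupling = vas_coupling, ar1 = ar1, n_states = k),
    class = "cohort_spec")
}

# Exactly orthogonal, column-centered spatial patterns (unit node-wise scale).
# Centered + orthogonal => pairwise Pearson correlation is exactly zero, so
# the zero-noise similarity matrix is exactly block structured.
orth_patterns <- function(n_nodes, k) {
  if (k >= n_nodes) stop_sub("need more nodes than states for orthogonal patterns")
  raw <- matrix(rnorm(n_nodes * k), n_nodes, k)
  raw <- sweep(raw, 2, colMeans(raw))
  q <- qr.Q(qr(raw))
  q <- sweep(q, 2, colMeans(q))          # re-center (QR preserves centering up to rounding)
  q <- qr.Q(qr(q))
  sweep(q, 2, sqrt(colSums(q^2)) / sqrt(n_nodes), "/") # node-wise SD ~ 1
}

#' Generate a paired-condition synthetic cohort with planted ground truth
#'
#' Produces, for each participant, a DMT and a placebo [parcel_ts()] built
#' as planted spatial pattern + condition-specific additive effects +
#' Gaussian noise, plus the ground truth needed by recovery tests: the
#' planted per-volume affiliation, the spatial patterns, per-participant
#' effect amplitudes, and planned heart-rate (bpm) series per condition.
#' Windows are identical across participants; output is bit-reproducible
#' for a fixed `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `cohort` with elements `participants` (list of
#'   `list(DMT =, PCB =)` [parcel_ts()] pairs), `truth` (labels, placebo
#'   labels, patterns, per-participant effect amplitudes, dosing order,
#'   planned bpm series) and `spec`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  set.seed(spec$seed)
  n <- spec$n_participants
  k <- spec$n_states
  plan <- spec$substate_plan
  labels_dmt <- plan_labels(plan, spec$n_volumes)
  labels_pcb <- if (isTRUE(spec$placebo_persistent)) {
    labels_dmt
  } else {
    ((seq_len(spec$n_volumes) - 1L) %/% spec$placebo_cycle) %% k + 1L
  }
  patterns <- orth_patterns(spec$n_nodes, k)

  eff_names <- vapply(spec$condition_effects, `[[`, character(1), "name")
  eff_amp <- lapply(spec$condition_effects, function(e) {
    rnorm(n, e$amplitude, e$sd_between)
  })
  names(eff_amp) <- eff_names
  hr_baseline <- rnorm(n, spec$hr_baseline_bpm, spec$hr_baseline_sd)
  hr_effect <- rnorm(n, spec$hr_effect_bpm, spec$hr_effect_sd)
  dosing_order <- rep(c("DMT_first", "PCB_first"), length.out = n)

  hr_vols <- which(labels_dmt == spec$hr_state &
                     seq_len(spec$n_volumes) > spec$injection_volume)
  bpm_dmt <- matrix(rep(hr_baseline, spec$n_volumes), n, spec$n_volumes)
  bpm_dmt[, hr_vols] <- bpm_dmt[, hr_vols] + hr_effect
  bpm_pcb <- matrix(rep(hr_baseline, spec$n_volumes), n, spec$n_volumes)

  make_series <- function(labels_cond, cond, p) {
    x <- patterns[, labels_cond, drop = FALSE]
    for (i in seq_along(spec$condition_effects)) {
      e <- spec$condition_effects[[i]]
      if (e$condition != cond) next
      vols <- which(labels_cond == e$state)
      if (length(vols)) x[e$nodes, vols] <- x[e$nodes, vols] + eff_amp[[i]][p]
    }
    if (spec$noise_sd > 0) {
      eps <- matrix(rnorm(length(x), 0, spec$noise_sd), nrow(x), ncol(x))
      if (spec$ar1 > 0) {
        eps <- t(apply(eps, 1, function(row) {
          as.numeric(stats::filter(row, spec$ar1, method = "recursive"))
        }))
      }
      x <- x + eps
    }
    parcel_ts(x, tr_seconds = spec$tr_seconds,
              injection_volume = spec$injection_volume,
              participant_id = sprintf("P%02d", p), condition = cond)
  }

  participants <- lapply(seq_len(n), function(p) {
    list(DMT = make_series(labels_dmt, "DMT", p),
         PCB = make_series(labels_pcb, "PCB", p))
  })
  names(participants) <- sprintf("P%02d", seq_len(n))

  structure(
    list(participants = participants,
         truth = list(labels = labels_dmt, pcb_labels = labels_pcb,
                      patterns = patterns,
                      effects = c(eff_amp, list(hr = hr_effect)),
                      hr_baseline = hr_baseline,
                      bpm = list(DMT = bpm_dmt, PCB = bpm_pcb),
                      dosing_order = dosing_order),
         spec = spec),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", length(x$participants), " participants x 2 conditions, ",
      x$spec$n_nodes, " nodes x ", x$spec$n_volumes, " volumes, ",
      x$spec$n_states, " planted substates\n", sep = "")
  invisible(x)
}
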
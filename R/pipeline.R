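#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis: the synthetic cohort
#' specification (or a manifest of files to read), the threshold sweep and
#' Louvain settings, significance levels, and explicit seeds (no wall-clock
#' seeding anywhere). All downstream randomness flows from `seed`.
#'
#' @param spec a [cohort_spec()] (used when `manifest` is `NULL`).
#' @param manifest optional path/data.frame listing participant, condition,
#'   file for [read_cohort()].
#' @param thresholds,gamma,n_restarts sweep and Louvain settings.
#' @param min_occupancy,alpha retention / significance settings.
#' @param pls_components number of PLS components.
#' @param ekg_fs,ekg_noise_sd synthetic EKG sampling rate and noise.
#' @param vas_noise_sd synthetic rating noise.
#' @param seed master seed.
#' @param out_dir optional output directory; when set, [run_pipeline()]
#'   writes the report files there.
#' @return list of class `run_config`.
#' @export
run_config <- function(spec = cohort_spec(), manifest = NULL,
                       thresholds = seq(0.20, 0.30, by = 0.01),
                       gamma = 1, n_restarts = 100,
                       min_occupancy = 0.10, alpha = 0.05,
                       pls_components = 2,
                       ekg_fs = 250, ekg_noise_sd = 500,
                       vas_noise_sd = 0.1,
                       seed = 1L, out_dir = NULL) {
  structure(
    list(spec = spec, manifest = manifest, thresholds = thresholds,
         gamma = gamma, n_restarts = n_restarts,
         min_occupancy = min_occupancy, alpha = alpha,
         pls_components = pls_components,
         ekg_fs = ekg_fs, ekg_noise_sd = ekg_noise_sd,
         vas_noise_sd = vas_noise_sd,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config")
}

# The first post-injection substate: among retained states that are more
# occupied after the injection, the one whose first post-injection volume
# comes earliest.
first_post_state <- function(summary, affil, injection_volume) {
  cand <- summary$state[summary$retained &
                          summary$post_occupancy > summary$pre_occupancy]
  if (!length(cand)) return(NA_integer_)
  labels <- as.integer(affil)
  onsets <- vapply(cand, function(s) {
    w <- which(labels == s & seq_along(labels) > injection_volume)
    if (length(w)) min(w) else NA_integer_
  }, integer(1))
  cand[which.min(onsets)]
}

#' Run the full substate analysis end to end
#'
#' Simulate (or read) the paired cohort, build similarity and subtraction
#' matrices, sweep thresholds and detect substates, estimate beta-maps and
#' the paired contrast for the first post-injection substate, derive heart
#' rate from synthetic EKG and compare it across conditions during that
#' substate, generate subjective ratings and run the PLS associations,
#' median split, and order-of-dosing regressions. Deterministic for a fixed
#' configuration.
#'
#' @param config a [run_config()].
#' @return list of class `substate_report` (also written as files when
#'   `config$out_dir` is set).
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) stop_sub("`config` must be a run_config()")
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_sub("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  cohort <- stage("cohort", {
    if (!is.null(config$manifest)) {
      read_cohort(config$manifest, tr_seconds = config$spec$tr_seconds,
                  injection_volume = config$spec$injection_volume)
    } else {
      sp <- config$spec
      sp$seed <- seed
      generate_cohort(sp)
    }
  })
  spec <- cohort$spec %||% config$spec
  inj <- spec$injection_volume
  tr <- spec$tr_seconds

  mats <- stage("similarity", cohort_subtraction_matrix(cohort))
  sweep <- stage("substates", threshold_sweep(
    mats$subtraction, thresholds = config$thresholds, gamma = config$gamma,
    seed = seed + 1L, n_restarts = config$n_restarts,
    min_occupancy = config$min_occupancy, alpha = config$alpha,
    tr_seconds = tr))
  affil <- sweep$affiliation
  summary <- sweep$summary
  retained <- summary$state[summary$retained]
  target_state <- first_post_state(summary, affil, inj)

  maps <- stage("maps", {
    states <- sort(unique(as.integer(affil)))
    beta_dmt <- cohort_beta_maps(cohort, affil, "DMT", states = states)
    beta_pcb <- cohort_beta_maps(cohort, affil, "PCB", states = states)
    contrasts <- list()
    for (s in retained) {
      contrasts[[paste0("state", s)]] <-
        paired_contrast(beta_dmt, beta_pcb, paste0("state", s),
                        alpha = config$alpha)
    }
    list(beta_dmt = beta_dmt, beta_pcb = beta_pcb, contrasts = contrasts)
  })

  hr <- if (!is.null(cohort$truth)) stage("heart_rate", {
    n <- length(cohort$participants)
    means <- matrix(NA_real_, n, 2, dimnames = list(names(cohort$participants),
                                                    c("DMT", "PCB")))
    for (p in seq_len(n)) {
      for (cond in c("DMT", "PCB")) {
        rr <- rr_plan_from_bpm(cohort$truth$bpm[[cond]][p, ], tr)
        ek <- generate_ekg(rr, fs = config$ekg_fs,
                           noise_sd = config$ekg_noise_sd,
                           seed = seed + 100L + 2L * p + (cond == "PCB"))
        dh <- derive_heart_rate(ek$trace, tr_seconds = tr,
                                n_volumes = spec$n_volumes)
        if (!is.na(target_state)) {
          means[p, cond] <- mean_hr_in_state(dh$hr, affil, target_state,
                                             period = "post",
                                             injection_volume = inj)
        }
      }
    }
    test <- if (!is.na(target_state)) paired_ttest(means[, "DMT"], means[, "PCB"]) else NULL
    list(state_means = means, change = means[, "DMT"] - means[, "PCB"],
         test = test, state = target_state)
  }) else NULL

  assoc <- if (!is.null(cohort$truth)) stage("associations", {
    vas <- generate_vas(cohort, coupling = spec$vas_coupling,
                        noise_sd = config$vas_noise_sd, seed = seed + 500L)
    vt <- vas_change_and_tests(vas$dmt, vas$pcb, alpha = config$alpha)
    out <- list(vas = vas, vas_tests = vt$tests)
    ct <- if (!is.na(target_state)) maps$contrasts[[paste0("state", target_state)]] else NULL
    if (!is.null(ct) && (length(ct$hyper_mask) || length(ct$hypo_mask))) {
      sl <- paste0("state", target_state)
      roi_change <- list()
      if (length(ct$hyper_mask)) {
        roi_change$hyper <- roi_average(maps$beta_dmt[, , sl], ct$hyper_mask) -
          roi_average(maps$beta_pcb[, , sl], ct$hyper_mask)
      }
      if (length(ct$hypo_mask)) {
        roi_change$hypo <- roi_average(maps$beta_dmt[, , sl], ct$hypo_mask) -
          roi_average(maps$beta_pcb[, , sl], ct$hypo_mask)
      }
      Y <- do.call(cbind, roi_change)
      out$pls_brain <- pls2(vt$change, Y, n_components = config$pls_components)
      if (!is.null(hr) && !all(is.na(hr$change))) {
        out$pls_hr <- pls2(vt$change, hr$change,
                           n_components = config$pls_components)
        if (!is.null(roi_change$hypo)) {
          out$hr_vs_hypo <- pearson_with_df(hr$change, roi_change$hypo)
        }
        out$hr_split <- median_split(hr$change)
        out$order_effects <- list(
          hr = order_effect_regression(hr$change, cohort$truth$dosing_order))
        if (!is.null(roi_change$hyper)) {
          out$order_effects$hyper <-
            order_effect_regression(roi_change$hyper, cohort$truth$dosing_order)
        }
        if (!is.null(roi_change$hypo)) {
          out$order_effects$hypo <-
            order_effect_regression(roi_change$hypo, cohort$truth$dosing_order)
        }
      }
      out$roi_change <- roi_change
    }
    out
  }) else NULL

  report <- structure(
    list(sweep = sweep, affiliation = affil, summary = summary,
         retained = retained, target_state = target_state,
         contrasts = maps$contrasts, heart_rate = hr, associations = assoc,
         provenance = list(seed = seed,
                           thresholds = config$thresholds,
                           gamma = config$gamma,
                           n_restarts = config$n_restarts,
                           package_version = as.character(packageVersion("substates")))),
    class = "substate_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir, cohort)
  report
}

#' @export
print.substate_report <- function(x, ...) {
  cat("<substate_report>\n  selected threshold: ", x$sweep$selected,
      "\n  substates: ", attr(x$affiliation, "k"),
      " (retained: ", paste(x$retained, collapse = ", "), ")",
      "\n  first post-injection substate: ", x$target_state, "\n", sep = "")
  if (!is.null(x$heart_rate$test)) {
    cat(sprintf("  heart rate DMT vs PCB in state %d: t(%d) = %.2f, p = %.3g\n",
                x$heart_rate$state, x$heart_rate$test$df, x$heart_rate$test$t,
                x$heart_rate$test$p))
  }
  invisible(x)
}

#' Write the pipeline report bundle to disk
#'
#' Plain-text outputs: affiliation TSV, sweep table CSV, per-state summary
#' and provenance JSON, contrast CSVs, heart-rate CSV, PLS loadings JSON.
#'
#' @param report a `substate_report`.
#' @param dir output directory (created if needed).
#' @param cohort optional cohort, unused but accepted for symmetry.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, cohort = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(
    data.frame(volume = seq_along(report$affiliation),
               label = as.integer(report$affiliation)),
    file.path(dir, "affiliation.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  write.csv(report$sweep$table, file.path(dir, "sweep.csv"), row.names = FALSE)
  write.csv(report$summary, file.path(dir, "substate_summary.csv"),
            row.names = FALSE)
  for (nm in names(report$contrasts)) {
    write.csv(report$contrasts[[nm]]$stats,
              file.path(dir, paste0("contrast_", nm, ".csv")),
              row.names = FALSE)
  }
  if (!is.null(report$heart_rate)) {
    hr <- report$heart_rate
    write.csv(data.frame(participant = rownames(hr$state_means),
                         dmt_bpm = hr$state_means[, "DMT"],
                         pcb_bpm = hr$state_means[, "PCB"],
                         change = hr$change),
              file.path(dir, "hr_state_means.csv"), row.names = FALSE)
  }
  json_bits <- list(
    selected_threshold = report$sweep$selected,
    k = attr(report$affiliation, "k"),
    retained = report$retained,
    target_state = report$target_state,
    omnibus_chi2 = attr(report$summary, "chi2"),
    provenance = report$provenance)
  if (!is.null(report$heart_rate$test)) {
    json_bits$hr_test <- report$heart_rate$test[c("t", "df", "p")]
  }
  if (!is.null(report$associations$pls_brain)) {
    pb <- report$associations$pls_brain
    json_bits$pls_brain <- list(x_loadings = pb$x_loadings,
                                y_loadings = pb$y_loadings,
                                score_cor = pb$score_cor)
  }
  if (!is.null(report$associations$pls_hr)) {
    ph <- report$associations$pls_hr
    json_bits$pls_hr <- list(x_loadings = ph$x_loadings,
                             y_loadings = ph$y_loadings,
                             score_cor = ph$score_cor)
  }
  jsonlite::write_json(json_bits, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write one parcellated series as CSV (volumes x nodes)
#' @param ts a [parcel_ts()].
#' @param path output file.
#' @export
write_parcel_csv <- function(ts, path) {
  d <- as.data.frame(t(ts$values))
  names(d) <- ts$node_labels
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read one parcellated series from CSV (volumes x nodes)
#' @param path CSV file with one column per node.
#' @inheritParams parcel_ts
#' @export
read_parcel_csv <- function(path, tr_seconds = 2, injection_volume = 240,
                            participant_id = NA_character_,
                            condition = "DMT") {
  d <- read.csv(path)
  bad <- which(!vapply(d, is.numeric, logical(1)))
  if (length(bad)) {
    stop_sub(path, ": non-numeric values in column(s) ",
             paste(names(d)[bad], collapse = ", "))
  }
  parcel_ts(t(as.matrix(d)), tr_seconds = tr_seconds,
            injection_volume = injection_volume,
            participant_id = participant_id, condition = condition,
            node_labels = names(d))
}

#' Read a paired cohort from a file manifest
#'
#' @param manifest data.frame or CSV path with columns `participant`,
#'   `condition` (`DMT`/`PCB`) and `path`. Every participant must appear
#'   with both conditions.
#' @inheritParams parcel_ts
#' @return a `cohort` (without synthetic ground truth).
#' @export
read_cohort <- function(manifest, tr_seconds = 2, injection_volume = 240) {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("participant", "condition", "path")
  if (!all(need %in% names(manifest))) {
    stop_sub("manifest needs columns ", paste(need, collapse = ", "))
  }
  ids <- unique(manifest$participant)
  participants <- lapply(ids, function(id) {
    rows <- manifest[manifest$participant == id, ]
    for (cond in c("DMT", "PCB")) {
      if (sum(rows$condition == cond) != 1) {
        stop_sub("participant ", id, " lacks exactly one ", cond, " series")
      }
    }
    lapply(c(DMT = "DMT", PCB = "PCB"), function(cond) {
      read_parcel_csv(rows$path[rows$condition == cond],
                      tr_seconds = tr_seconds,
                      injection_volume = injection_volume,
                      participant_id = as.character(id), condition = cond)
    })
  })
  names(participants) <- as.character(ids)
  nn <- unique(vapply(participants, function(p) nrow(p$DMT$values), integer(1)))
  if (length(nn) != 1) stop_sub("node count differs across cohort: ",
                                paste(nn, collapse = ", "))
  structure(list(participants = participants, truth = NULL,
                 spec = list(n_participants = length(ids),
                             n_nodes = nn,
                             n_volumes = ncol(participants[[1]]$DMT$values),
                             tr_seconds = tr_seconds,
                             injection_volume = injection_volume)),
            class = "cohort")
}

#' Write a cohort to per-series CSV files plus a manifest
#' @param cohort a `cohort`.
#' @param dir output directory.
#' @return path of the written manifest CSV.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (id in names(cohort$participants)) {
    for (cond in c("DMT", "PCB")) {
      path <- file.path(dir, paste0(id, "_", cond, ".csv"))
      write_parcel_csv(cohort$participants[[id]][[cond]], path)
      rows[[length(rows) + 1]] <- data.frame(participant = id,
                                             condition = cond, path = path)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  mpath
}
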
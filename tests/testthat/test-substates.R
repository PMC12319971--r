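test_that("thresholding keeps only positive entries at or above r", {
  v <- matrix(c(0, 0.25, -0.4, 0.25, 0, 0.1, -0.4, 0.1, 0), 3, 3)
  S <- structure(list(values = v, injection_volume = 1L, tr_seconds = 2),
                 class = "subtraction_matrix")
  W <- threshold_matrix(S, 0.25)
  expect_equal(W[1, 2], 0.25)   # boundary value kept (R >= r)
  expect_equal(W[1, 3], 0)      # negative zeroed
  expect_equal(W[2, 3], 0)      # sub-threshold zeroed
  expect_equal(diag(W), rep(0, 3))
  expect_warning(threshold_matrix(S, 0.5), "sweep range")
  # absolute-value variant keeps magnitudes
  Wa <- threshold_matrix(S, 0.25, use_absolute = TRUE)
  expect_equal(Wa[1, 3], 0.4)
})

test_that("raising the threshold never increases retained edge weight", {
  set.seed(41)
  E <- matrix(runif(30 * 30, -0.5, 0.5), 30, 30)
  S <- structure(list(values = (E + t(E)) / 2, injection_volume = 10L,
                      tr_seconds = 2), class = "subtraction_matrix")
  w <- vapply(seq(0.20, 0.30, 0.01),
              function(r) sum(threshold_matrix(S, r)), numeric(1))
  expect_true(all(diff(w) <= 1e-12))
})

test_that("occupancy fractions, minutes, and partition property", {
  labels <- c(rep(1L, 60), rep(2L, 180), rep(2L, 100), rep(3L, 140))
  occ <- occupancy(labels, injection_volume = 240, tr_seconds = 2)
  expect_equal(occ$pre_occupancy[occ$state == 1], 0.25)
  expect_equal(sum(occ$pre_occupancy), 1)
  expect_equal(sum(occ$post_occupancy), 1)
  expect_equal(occ$pre_minutes, occ$pre_occupancy * 8)
  expect_equal(occ$post_minutes, occ$post_occupancy * 8)
  # excluded volumes leave both numerator and denominator
  occ2 <- occupancy(labels, 240, 2, exclude = 1:20)
  expect_equal(occ2$pre_occupancy[occ2$state == 1], 40 / 220)
})

test_that("chi-square separability matches the textbook statistic", {
  # equal occupancy pre and post: omnibus exactly zero
  labels <- rep(c(1L, 2L), 60)
  sep0 <- separability_chi2(labels, injection_volume = 60)
  expect_equal(sep0$chi2, 0)
  # hand-computed 2x2 table [[30,10],[10,30]] -> chi2 = 20, df 1
  labels2 <- c(rep(1L, 30), rep(2L, 10), rep(1L, 10), rep(2L, 30))
  sep2 <- separability_chi2(labels2, injection_volume = 40)
  expect_equal(sep2$per_state$chi2, c(20, 20), tolerance = 1e-12)
  expect_equal(sep2$chi2, 20, tolerance = 1e-12)  # k = 2: omnibus == per-state
  expect_equal(sep2$df, 1)
  # random partitions agree with the (O-E)^2/E oracle
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    labels <- sample.int(k, 200, replace = TRUE)
    inj <- sample(50:150, 1)
    sep <- separability_chi2(labels, inj)
    states <- sort(unique(labels))
    tab <- rbind(table(factor(labels[1:inj], levels = states)),
                 table(factor(labels[(inj + 1):200], levels = states)))
    expect_equal(sep$chi2, chi2_oracle(tab), tolerance = 1e-10)
    for (i in seq_along(states)) {
      s <- states[i]
      t2 <- rbind(c(sum(labels[1:inj] == s), sum(labels[1:inj] != s)),
                  c(sum(labels[-(1:inj)] == s), sum(labels[-(1:inj)] != s)))
      expect_equal(sep$per_state$chi2[i], chi2_oracle(t2), tolerance = 1e-10)
      expect_equal(sep$per_state$p_value[i],
                   pchisq(chi2_oracle(t2), 1, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  }
  expect_error(separability_chi2(rep(1:2, 10), injection_volume = 20),
               "zero volumes")
  # the alternative omnibus reading sums the per-state statistics
  seps <- separability_chi2(labels2, 40, omnibus = "sum_per_state")
  expect_equal(seps$chi2, sum(seps$per_state$chi2))
})

test_that("retention needs both separability and substantial occupancy", {
  sm <- data.frame(state = 1:4,
                   pre_occupancy = c(0.03, 0.34, 0.06, 0.25),
                   post_occupancy = c(0.02, 0.10, 0.19, 0.25),
                   p_value = c(0.001, 0.001, 0.001, 1))
  expect_identical(retained_substates(sm), c(2L, 3L))
  # all states evenly occupied (p = 1): nothing retained
  sm$p_value <- 1
  expect_length(retained_substates(sm), 0)
})

test_that("sweep recovers planted states and honours the tie-break rule", {
  co <- generate_cohort(tiny_spec(seed = 43, noise_sd = 0.5))
  sub <- cohort_subtraction_matrix(co)$subtraction
  sw <- threshold_sweep(sub, seed = 7, n_restarts = 30)
  expect_equal(sum(sw$table$selected), 1)
  expect_equal(sw$table$n_retained[sw$table$selected], 5)
  expect_gte(ari(sw$affiliation, co$truth$labels), 0.9)
  # winner recomputed from the reported table: max retained, then max chi2,
  # then lowest threshold
  tab <- sw$table[sw$table$k > 0, ]
  tab <- tab[order(-tab$n_retained, -tab$chi2, tab$threshold), ]
  expect_equal(sw$selected, tab$threshold[1])
})

test_that("identical conditions yield no retained substates or an empty sweep", {
  # matched placebo, no effects, noise: graphs are non-empty but carry no
  # pre/post structure
  spn <- cohort_spec(n_participants = 8, n_nodes = 30, n_volumes = 240,
                     injection_volume = 80, seed = 44,
                     substate_plan = balanced_substate_plan(240, 80, 5),
                     placebo_persistent = TRUE, condition_effects = list())
  sub <- cohort_subtraction_matrix(generate_cohort(spn))$subtraction
  sw <- threshold_sweep(sub, seed = 8, n_restarts = 10)
  expect_equal(sum(sw$table$n_retained), 0)
  # noise-free identical conditions: an exactly zero matrix cannot be swept
  sp0 <- tiny_spec(seed = 45, noise_sd = 0, placebo_persistent = TRUE,
                   condition_effects = list())
  sub0 <- cohort_subtraction_matrix(generate_cohort(sp0))$subtraction
  expect_error(threshold_sweep(sub0, seed = 8, n_restarts = 5),
               "empty graphs")
})

test_that("k-means control recovers blocks and keeps the best replicate", {
  bm <- matrix(0, 30, 30)
  lab <- rep(1:3, each = 10)
  bm[outer(lab, lab, "==")] <- 1
  diag(bm) <- 0
  S <- structure(list(values = bm, injection_volume = 10L, tr_seconds = 2),
                 class = "subtraction_matrix")
  km <- kmeans_control(S, k = 3, seed = 9)
  expect_equal(ari(km, lab), 1)
  expect_lte(attr(km, "inertia"), min(attr(km, "inertias")) + 1e-9)
  expect_error(kmeans_control(S, k = 40), "exceeds")
  expect_error(kmeans_control(S, k = 1), "at least 2")
  # planted cohort, k = number of planted states
  co <- generate_cohort(tiny_spec(seed = 46, noise_sd = 0.4))
  sub <- cohort_subtraction_matrix(co)$subtraction
  km2 <- kmeans_control(sub, k = 5, seed = 10)
  expect_gte(ari(km2, co$truth$labels), 0.9)
})
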
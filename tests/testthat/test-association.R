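test_that("rating change scores and paired tests behave at the boundaries", {
  set.seed(61)
  m <- matrix(runif(14 * 25), 14, 25, dimnames = list(NULL, vas_items()))
  same <- vas_change_and_tests(m, m)
  expect_true(all(same$change == 0))
  expect_true(all(same$tests$degenerate))
  expect_false(any(same$tests$reject))
  # one item with a planted +0.5 shift (sigma = 0.05) is always detected
  hits <- 0L
  for (s in 1:40) {
    set.seed(s)
    pcb <- matrix(0.2 + rnorm(14 * 25, 0, 0.05), 14, 25,
                  dimnames = list(NULL, vas_items()))
    dmt <- pcb + matrix(rnorm(14 * 25, 0, 0.05), 14, 25)
    dmt[, "intensity"] <- dmt[, "intensity"] + 0.5
    res <- vas_change_and_tests(dmt, pcb)
    hits <- hits + res$tests$reject[res$tests$item == "intensity"]
  }
  expect_gte(hits, 38)   # >= 95% of seeds
  expect_error(vas_change_and_tests(m, m[, 1:24]), "shape")
  m2 <- m
  colnames(m2)[1] <- "other"
  expect_error(vas_change_and_tests(m, m2), "missing in one condition")
})

test_that("SIMPLS components match an independent recomputation to 1e-8", {
  set.seed(62)
  for (rep in 1:10) {
    n <- sample(15:40, 1)
    X <- matrix(rnorm(n * 10), n, 10)
    Y <- matrix(rnorm(n * 2), n, 2)
    Y[, 1] <- Y[, 1] + X %*% rnorm(10, 0, 0.5)
    fit <- pls2(X, Y, 2)
    orc <- simpls_oracle(X, Y, 2)
    expect_equal(unname(fit$x_loadings), orc$P, tolerance = 1e-8)
    expect_equal(unname(fit$y_loadings), orc$Q, tolerance = 1e-8)
  }
})

test_that("PLS has orthogonal scores, nesting, and exact one-factor recovery", {
  set.seed(63)
  X <- matrix(rnorm(30 * 8), 30, 8)
  Y <- cbind(X %*% rnorm(8) + rnorm(30, 0, 0.1), rnorm(30))
  fit <- pls2(X, Y, 2)
  expect_lt(abs(crossprod(fit$x_scores[, 1], fit$x_scores[, 2])), 1e-10)
  rss <- function(f) sum((Y - f$fitted)^2)
  expect_lte(rss(fit), rss(pls2(X, Y, 1)) + 1e-10)
  # exactly one predictive direction with orthogonal predictors: r = 1
  Q <- qr.Q(qr(scale(matrix(rnorm(40 * 6), 40, 6), scale = FALSE)))
  Q <- scale(Q, scale = FALSE)
  y <- 3 * Q[, 2]
  f1 <- pls2(Q, y, 2)
  expect_gt(f1$score_cor$r[1], 1 - 1e-6)
  # deterministic sign convention: largest |x loading| positive
  expect_true(all(apply(fit$x_loadings, 2,
                        function(p) p[which.max(abs(p))] > 0)))
  # participant-order invariance
  perm <- sample(30)
  fit_p <- pls2(X[perm, ], Y[perm, ], 2)
  expect_equal(fit_p$x_loadings, fit$x_loadings, tolerance = 1e-9)
  expect_error(pls2(X, cbind(rep(1, 30)), 2), "constant outcome")
  expect_error(pls2(X[, 1:2], Y, 3), "rank")
})

test_that("planted rating couplings surface in the first PLS component", {
  # a component's global sign is convention; the planted pattern is the
  # sign of each item loading *relative to the outcome loading*
  coupling <- list(buzzing_sound = list(source = "src", coef = 0.6),
                   presence_entity = list(source = "src", coef = 0.5),
                   sense_time_altered = list(source = "src", coef = -0.6))
  ok <- 0L
  for (s in 1:20) {
    set.seed(s + 700)
    truth <- list(effects = list(src = rnorm(200)))
    v <- generate_vas(truth, coupling = coupling, noise_sd = 0.1, seed = s)
    y <- truth$effects$src + rnorm(200, 0, 0.3)
    fit <- pls2(v$change, y, 2)
    rel <- sign(fit$x_loadings[names(coupling), 1]) * sign(fit$y_loadings[1, 1])
    ok <- ok + all(rel == c(1, 1, -1))
  }
  expect_gte(ok, 18)   # >= 90% of seeds
})

test_that("Pearson correlation with df matches the classical test", {
  x <- rnorm(14)
  expect_equal(pearson_with_df(x, x)$r, 1)
  set.seed(64)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    a <- rnorm(n)
    b <- rnorm(n) + 0.3 * a
    res <- pearson_with_df(a, b)
    ct <- cor.test(a, b)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-12)
    expect_equal(res$df, n - 2)
  }
  expect_equal(pearson_with_df(rnorm(14), rnorm(14))$df, 12)
  expect_error(pearson_with_df(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("median split sends ties low and orders group means", {
  s <- median_split(c(1, 2, 2, 3))
  expect_identical(s$low, c(1L, 2L, 3L))
  expect_identical(s$high, 4L)
  set.seed(65)
  v14 <- sample(seq(1, 100, length.out = 14))
  s14 <- median_split(v14)
  expect_length(s14$low, 7)
  expect_length(s14$high, 7)
  for (rep in 1:10) {
    v <- rnorm(10)
    sp <- median_split(v)
    expect_gte(mean(v[sp$high]), mean(v[sp$low]))
  }
  expect_error(median_split(1), "at least 2")
})

test_that("order-of-dosing regression equals the balanced two-sample t-test", {
  ord <- rep(c("DMT_first", "PCB_first"), each = 7)
  flat <- suppressWarnings(order_effect_regression(rep(5, 14), ord))
  expect_equal(flat$beta, 0)
  ind <- suppressWarnings(
    order_effect_regression(as.numeric(ord == "PCB_first"), ord))
  expect_equal(ind$beta, 1)
  expect_lt(ind$p, 0.05)
  set.seed(66)
  y <- rnorm(14)
  reg <- order_effect_regression(y, ord)
  tt <- t.test(y[8:14], y[1:7], var.equal = TRUE)
  expect_equal(reg$p, tt$p.value, tolerance = 1e-12)
  expect_equal(reg$beta, unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  expect_error(order_effect_regression(y, rep("DMT_first", 14)),
               "one dosing order")
})

test_that("paired t-test matches the closed form and rejects degeneracy", {
  expect_error(paired_ttest(1:5, 1:5), "zero-variance")
  a <- c(2, 0, 2, 0)
  b <- c(1, 1, 1, 1)
  res <- paired_ttest(a, b)
  expect_equal(res$t, 0)
  set.seed(67)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    x <- rnorm(n)
    y <- rnorm(n) + 0.5
    res <- paired_ttest(x, y)
    d <- x - y
    t_manual <- mean(d) / (sd(d) / sqrt(n))
    expect_equal(res$t, t_manual, tolerance = 1e-12)
    expect_equal(res$p, 2 * pt(abs(t_manual), n - 1, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(res$df, n - 1)
  }
})
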
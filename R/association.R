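#' Per-item change scores and paired tests for subjective ratings
#'
#' DMT-minus-placebo change per item, a paired t-test per item, and BH-FDR
#' across the 25 items. Items with zero-variance differences are flagged
#' and excluded from the FDR family.
#'
#' @param vas_dmt,vas_pcb participants x items rating matrices with
#'   matching columns.
#' @param alpha FDR level.
#' @return list with `change` (participants x items) and `tests` (per-item
#'   data.frame: mean_change, t, p, q, reject, degenerate).
#' @export
vas_change_and_tests <- function(vas_dmt, vas_pcb, alpha = 0.05) {
  vas_dmt <- as.matrix(vas_dmt)
  vas_pcb <- as.matrix(vas_pcb)
  if (!identical(dim(vas_dmt), dim(vas_pcb))) {
    stop_sub("rating matrices differ in shape")
  }
  items_d <- colnames(vas_dmt)
  items_p <- colnames(vas_pcb)
  if (!is.null(items_d) && !is.null(items_p)) {
    missing <- setdiff(items_d, items_p)
    if (length(missing)) {
      stop_sub("item(s) missing in one condition: ", paste(missing, collapse = ", "))
    }
    vas_pcb <- vas_pcb[, items_d, drop = FALSE]
  }
  change <- vas_dmt - vas_pcb
  n <- nrow(change)
  m <- colMeans(change)
  s <- apply(change, 2, sd)
  degenerate <- s == 0
  tval <- ifelse(degenerate, NA_real_, m / (s / sqrt(n)))
  pval <- 2 * pt(abs(tval), df = n - 1, lower.tail = FALSE)
  adj <- fdr_bh(pval, alpha)
  tests <- data.frame(item = items_d %||% paste0("item", seq_along(m)),
                      mean_change = m, t = tval, p = pval, q = adj$q,
                      reject = adj$reject, degenerate = degenerate)
  rownames(tests) <- NULL
  list(change = change, tests = tests)
}

#' Two-component partial least squares regression (SIMPLS)
#'
#' SIMPLS: successive weight vectors maximize the covariance between X and
#' Y scores subject to orthogonality of X scores, with the cross-product
#' matrix deflated through an orthonormal basis of the X loadings. X and Y
#' are column-centered internally; no unit-variance scaling. Each
#' component's sign is fixed so that its largest-magnitude X loading is
#' positive, making the output deterministic. Per component the Pearson
#' correlation between the dependent (Y) and independent (X) scores is
#' reported with df = n - 2; a component whose scores are degenerate (the
#' outcome fully explained by earlier components) reports `NA` rather than
#' failing.
#'
#' @param X predictors, participants x variables (e.g. 25 rating change
#'   scores).
#' @param Y outcomes, participants x responses (vector allowed).
#' @param n_components number of components (default 2; at most the rank
#'   of centered X).
#' @return list of class `pls_model`: `x_weights`, `x_loadings`,
#'   `y_loadings`, `x_scores`, `y_scores`, `coefficients` (for prediction
#'   on centered data), `fitted`, `score_cor` (per-component r, df, p),
#'   `means`.
#' @export
pls2 <- function(X, Y, n_components = 2) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3) stop_sub("need at least 3 observations")
  if (nrow(Y) != n) stop_sub("X and Y row counts differ")
  if (any(apply(Y, 2, sd) == 0)) stop_sub("constant outcome column")
  X0 <- scale(X, scale = FALSE)
  Y0 <- scale(Y, scale = FALSE)
  rank_x <- qr(X0)$rank
  if (n_components > rank_x) {
    stop_sub("n_components (", n_components, ") exceeds rank of centered X (",
             rank_x, ")")
  }
  p <- ncol(X0)
  S <- crossprod(X0, Y0)
  R <- matrix(0, p, n_components)          # X weights
  P <- matrix(0, p, n_components)          # X loadings
  Q <- matrix(0, ncol(Y0), n_components)   # Y loadings
  Tm <- matrix(0, n, n_components)         # X scores
  U <- matrix(0, n, n_components)          # Y scores
  V <- matrix(0, p, n_components)          # orthonormal deflation basis
  for (a in seq_len(n_components)) {
    sv <- svd(S)
    r <- sv$u[, 1]
    t <- drop(X0 %*% r)
    t <- t - mean(t)
    nt <- sqrt(sum(t^2))
    t <- t / nt
    r <- r / nt
    pa <- drop(crossprod(X0, t))
    qa <- drop(crossprod(Y0, t))
    u <- drop(Y0 %*% qa)
    if (a > 1) {
      u <- u - Tm[, seq_len(a - 1), drop = FALSE] %*%
        crossprod(Tm[, seq_len(a - 1), drop = FALSE], u)
    }
    v <- pa
    if (a > 1) {
      v <- v - V[, seq_len(a - 1), drop = FALSE] %*%
        crossprod(V[, seq_len(a - 1), drop = FALSE], pa)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    # deterministic sign: largest-|x-loading| entry positive
    flip <- sign(pa[which.max(abs(pa))])
    if (flip == 0) flip <- 1
    R[, a] <- r * flip
    P[, a] <- pa * flip
    Q[, a] <- qa * flip
    Tm[, a] <- t * flip
    U[, a] <- u * flip
    V[, a] <- v
  }
  coefs <- R %*% t(Q)
  fitted <- sweep(X0 %*% coefs, 2, colMeans(Y), "+")
  score_cor <- do.call(rbind, lapply(seq_len(n_components), function(a) {
    ct <- tryCatch(pearson_with_df(Tm[, a], U[, a]),
                   error = function(e) list(r = NA_real_, df = n - 2,
                                            p = NA_real_))
    data.frame(component = a, r = ct$r, df = ct$df, p = ct$p)
  }))
  dimnames(P) <- list(colnames(X), paste0("comp", seq_len(n_components)))
  dimnames(Q) <- list(colnames(Y), paste0("comp", seq_len(n_components)))
  structure(
    list(x_weights = R, x_loadings = P, y_loadings = Q,
         x_scores = Tm, y_scores = U, coefficients = coefs,
         fitted = fitted, score_cor = score_cor,
         means = list(x = colMeans(X), y = colMeans(Y))),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", ncol(x$x_scores), " components, ",
      nrow(x$x_loadings), " predictors, ", nrow(x$y_loadings),
      " outcome(s)\n", sep = "")
  print(x$score_cor, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation with its degrees of freedom
#'
#' Two-sided p-value from the t transform `t = r * sqrt(df / (1 - r^2))`
#' with df = n - 2, matching the `R(df)` reporting convention.
#'
#' @param x,y numeric vectors (n >= 3, positive variance).
#' @return list with `r`, `df`, `p`.
#' @export
pearson_with_df <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop_sub("need paired vectors of length >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop_sub("zero variance input")
  r <- cor(x, y)
  df <- n - 2
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(abs(tval), df = df, lower.tail = FALSE)
  }
  list(r = r, df = df, p = p)
}

#' Median split into low and high groups
#'
#' Participants strictly above the sample median go to the high group;
#' values at or below the median go to the low group (deterministic tie
#' rule). With even n and distinct values the groups are equal sized.
#'
#' @param values named or unnamed numeric vector (n >= 2).
#' @return list with `low`, `high` (indices), `median`.
#' @export
median_split <- function(values) {
  if (length(values) < 2) stop_sub("need at least 2 values")
  med <- median(values)
  list(low = which(values <= med), high = which(values > med), median = med)
}

#' Order-of-dosing effect regression
#'
#' Simple OLS of an outcome on a binary dosing-order indicator, with the
#' two-sided p-value for the slope. Equivalent to a two-sample t-test under
#' a balanced design.
#'
#' @param outcome numeric vector per participant.
#' @param dosing_order binary indicator (logical, 0/1, or two-level
#'   factor/character); both orders must be present.
#' @return list with `beta` (slope), `p`, and the `fit`.
#' @export
order_effect_regression <- function(outcome, dosing_order) {
  ord <- if (is.character(dosing_order) || is.factor(dosing_order)) {
    as.numeric(factor(dosing_order)) - 1
  } else {
    as.numeric(dosing_order)
  }
  if (length(unique(ord)) < 2) stop_sub("only one dosing order present")
  fit <- lm(outcome ~ ord)
  sm <- summary(fit)$coefficients
  list(beta = unname(sm["ord", "Estimate"]), p = unname(sm["ord", "Pr(>|t|)"]),
       fit = fit)
}

#' Paired t-test with degenerate-input signaling
#'
#' Standard paired t (df = n - 1); zero-variance differences are rejected
#' with an informative error rather than returning an undefined statistic.
#'
#' @param a,b paired numeric vectors.
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop_sub("vectors must be paired (equal length)")
  if (length(a) < 2) stop_sub("need at least 2 pairs")
  d <- a - b
  if (sd(d) == 0) stop_sub("zero-variance differences: paired t undefined")
  ht <- t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate))
}
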
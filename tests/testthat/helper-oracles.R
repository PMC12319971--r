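# Independent oracles used to cross-check package computations.

# Benjamini-Hochberg step-up by direct enumeration of the rejection rank.
bh_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- max(c(0L, which(ps <= alpha * seq_len(m) / m)))
  rej <- logical(m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# Textbook Pearson chi-square: sum of (O - E)^2 / E over all cells.
chi2_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# SIMPLS recomputed through projection deflation: at each step the
# cross-product matrix is rebuilt from scratch as (I - V V') S0 and the
# weight is the dominant eigenvector of S S' — a different code path from
# the package's iterative subtraction.
simpls_oracle <- function(X, Y, A) {
  X0 <- scale(X, scale = FALSE)
  Y0 <- scale(Y, scale = FALSE)
  S0 <- crossprod(X0, Y0)
  V <- NULL
  P <- matrix(0, ncol(X0), A)
  Q <- matrix(0, ncol(Y0), A)
  for (a in seq_len(A)) {
    S <- if (is.null(V)) S0 else S0 - V %*% crossprod(V, S0)
    ev <- eigen(S %*% t(S), symmetric = TRUE)
    w <- ev$vectors[, 1]
    t <- drop(X0 %*% w)
    t <- t - mean(t)
    t <- t / sqrt(sum(t^2))
    pa <- drop(crossprod(X0, t))
    qa <- drop(crossprod(Y0, t))
    v <- pa
    if (!is.null(V)) v <- v - V %*% crossprod(V, pa)
    v <- v / sqrt(sum(v^2))
    V <- cbind(V, v)
    flip <- sign(pa[which.max(abs(pa))])
    if (flip == 0) flip <- 1
    P[, a] <- pa * flip
    Q[, a] <- qa * flip
  }
  list(P = P, Q = Q)
}

ari <- function(a, b) mclust::adjustedRandIndex(as.integer(a), as.integer(b))

# Small, fast cohort used across tests: 4 participants, 30 nodes, 120
# volumes, five balanced planted states.
tiny_spec <- function(seed = 1, noise_sd = 0.5, n_participants = 4, ...) {
  cohort_spec(n_participants = n_participants, n_nodes = 30, n_volumes = 120,
              injection_volume = 40, noise_sd = noise_sd, seed = seed,
              substate_plan = balanced_substate_plan(120, 40, 5), ...)
}

# Deterministic parcel_ts from a values matrix with safe defaults.
mk_ts <- function(values, injection = max(1L, ncol(values) %/% 2L), tr = 2,
                  condition = "DMT") {
  parcel_ts(values, tr_seconds = tr, injection_volume = injection,
            participant_id = "T", condition = condition)
}
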
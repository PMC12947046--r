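# Independent, loop-based re-implementation of the scorer used as an
# oracle for the vectorised pipeline.  Everything is computed per atom and
# per pair with scalar arithmetic -- no pair batching, no rowsum
# machinery -- so it shares no code path with the package internals.

oracle_ssp <- function(x) log(0.5 * exp(x) + 0.5)

oracle_forward <- function(model, s) {
  p <- model$params
  F <- model$n_features
  T <- model$n_interactions
  n <- length(s$atomic_numbers)
  mu <- model$rbf$centers
  gam <- model$rbf$width_coefficient
  rcut <- log(1 + exp(p$cutoff_raw))
  dist_ij <- function(i, j) sqrt(sum((s$positions[i, ] - s$positions[j, ])^2))

  E <- matrix(0, n, F)
  for (i in seq_len(n)) {
    E[i, ] <- p$embed[match(s$atomic_numbers[i], model$elements), ]
  }
  X <- E
  A_list <- vector("list", T)
  for (t in seq_len(T)) {
    fil <- p$filter[[t]]
    upd <- p$update[[t]]
    Xnew <- X
    for (i in seq_len(n)) {
      m <- numeric(F)
      for (j in seq_len(n)) {
        if (j == i) next
        d <- dist_ij(i, j)
        u <- d / rcut
        phi <- if (u >= 1) 0 else 1 - 6 * u^5 + 15 * u^4 - 10 * u^3
        rb <- numeric(length(mu))
        for (k in seq_along(mu)) rb[k] <- exp(-gam * (d - mu[k])^2)
        h <- numeric(F)
        for (f in seq_len(F)) {
          h[f] <- oracle_ssp(sum(rb * fil$inner$W[, f]) + fil$inner$b[f])
        }
        filt <- numeric(F)
        for (f in seq_len(F)) {
          filt[f] <- sum(h * fil$outer$W[, f]) + fil$outer$b[f]
        }
        for (f in seq_len(F)) m[f] <- m[f] + phi * X[j, f] * filt[f]
      }
      v <- numeric(F)
      for (f in seq_len(F)) {
        v[f] <- oracle_ssp(sum(m * upd$inner$W[, f]) + upd$inner$b[f])
      }
      for (f in seq_len(F)) {
        Xnew[i, f] <- X[i, f] + sum(v * upd$outer$W[, f]) + upd$outer$b[f]
      }
    }
    A <- matrix(0, n, F)
    for (i in seq_len(n)) {
      for (f in seq_len(F)) {
        A[i, f] <- sum(Xnew[i, ] * p$atomwise[[t]]$W[, f]) +
          p$atomwise[[t]]$b[f]
      }
    }
    A_list[[t]] <- A
    X <- A
  }
  t1 <- max(1L, T - 1L)
  score <- p$readout$b
  for (i in seq_len(n)) {
    for (f in seq_len(F)) {
      pif <- p$pred$u[f] * E[i, f] + p$pred$w1[f] * A_list[[t1]][i, f] +
        p$pred$w2[f] * A_list[[T]][i, f]
      score <- score + pif * p$readout$W[f]
    }
  }
  score
}
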
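# Brute-force reference implementations ("oracles") used by both the unit
# and acceptance tests. These deliberately use naive nested loops so they
# stay independent of the vectorized implementations they check.

# 4-connectivity edge enumeration for the inter-class shared-boundary matrix.
oracle_isb <- function(lab, n_c) {
  H <- nrow(lab); W <- ncol(lab)
  shared <- matrix(0, n_c, n_c)
  border <- numeric(n_c)
  for (r in seq_len(H)) {
    for (c_ in seq_len(W)) {
      me <- lab[r, c_]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c_ + d[2]
        if (rr < 1 || rr > H || cc < 1 || cc > W) {
          border[me] <- border[me] + 1
        } else if (lab[rr, cc] != me) {
          shared[me, lab[rr, cc]] <- shared[me, lab[rr, cc]] + 1
        }
      }
    }
  }
  perim <- rowSums(shared) + border
  m <- matrix(0, n_c, n_c)
  for (i in seq_len(n_c)) if (perim[i] > 0) m[i, ] <- shared[i, ] / perim[i]
  diag(m) <- 0
  m
}

# Nested-loop channel attention (rowwise-softmax affinity, residual scale).
oracle_channel_attention <- function(f, gamma_c) {
  dm <- dim(f)
  C <- dm[3]; N <- dm[1] * dm[2]
  Fm <- t(matrix(f, N, C))
  X <- matrix(0, C, C)
  for (i in seq_len(C)) {
    aff <- vapply(seq_len(C), function(j) sum(Fm[i, ] * Fm[j, ]), numeric(1))
    e <- exp(aff - max(aff))
    X[i, ] <- e / sum(e)
  }
  out <- matrix(0, C, N)
  for (i in seq_len(C)) {
    for (j in seq_len(C)) out[i, ] <- out[i, ] + X[i, j] * Fm[j, ]
  }
  array(t(gamma_c * out + Fm), dim = dm)
}

# Nested-loop spatial attention using the module's own 1x1 projections.
oracle_spatial_attention <- function(mod, fp, gamma_s) {
  dm <- dim(fp)
  C <- dm[3]; N <- dm[1] * dm[2]
  Fm <- t(matrix(fp, N, C))
  lin <- function(W, b) W %*% Fm + b
  Q <- lin(mod$q_conv$W$value, mod$q_conv$b$value)
  K <- lin(mod$k_conv$W$value, mod$k_conv$b$value)
  V <- lin(mod$v_conv$W$value, mod$v_conv$b$value)
  X <- matrix(0, N, N)
  for (i in seq_len(N)) {
    e <- vapply(seq_len(N), function(j) exp(sum(Q[, i] * K[, j])), numeric(1))
    X[i, ] <- e / sum(e)
  }
  out <- matrix(0, C, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) out[, i] <- out[, i] + V[, j] * X[i, j]
  }
  array(t(gamma_s * out + Fm), dim = dm)
}
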
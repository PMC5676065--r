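# Small shared fixtures; everything is generated in code at test time.

tiny_cfg <- function(seed = 1L, ...) {
  sim_config(t_end = 200, dt = 1, n_cells = 3, n_mito_init = 5,
             n_record = 11, seed = seed, ...)
}

# analytic stationary distribution of a birth-death chain on 0..3 from its
# per-step transition probabilities (independent oracle: eigenvector of the
# transition matrix)
bd_stationary <- function(p_up, p_dn) {
  P <- matrix(0, 4, 4)
  for (s in 1:4) {
    up <- if (s < 4) p_up[s] else 0
    dn <- if (s > 1) p_dn[s] else 0
    if (s < 4) P[s, s + 1] <- up
    if (s > 1) P[s, s - 1] <- dn
    P[s, s] <- 1 - up - dn
  }
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}
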
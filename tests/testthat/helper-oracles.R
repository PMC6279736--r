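## Independent oracles shared across test files.

## Naive double-loop LD score computation (independent of the package path).
ldscore_oracle <- function(D, pos, half, in_mqtl) {
  m <- nrow(D); N <- ncol(D)
  L_tot <- L_m <- numeric(m)
  for (j in seq_len(m)) {
    s_tot <- s_m <- 0; n_w <- n_m <- 0
    for (k in seq_len(m)) {
      if (k == j || abs(pos[k] - pos[j]) > half) next
      r2 <- cor(D[j, ], D[k, ])^2
      s_tot <- s_tot + r2; n_w <- n_w + 1
      if (in_mqtl[k]) { s_m <- s_m + r2; n_m <- n_m + 1 }
    }
    L_tot[j] <- 1 + s_tot - n_w / N
    L_m[j] <- in_mqtl[j] + s_m - n_m / N
  }
  list(L_total = L_tot, L_mqtl = L_m)
}

## Synthetic stratified score table (no pairwise structure; for fitting only).
synth_ld <- function(m, m_mqtl, seed = 1) {
  set.seed(seed)
  ids <- sprintf("s%05d", seq_len(m))
  in_m <- seq_len(m) <= m_mqtl
  L_m <- ifelse(in_m, 1 + rexp(m, 1 / 3), rexp(m, 2))
  L_g <- ifelse(in_m, rexp(m, 1 / 2), 1 + rexp(m, 1 / 4))
  LDScoreTable(data.frame(snp_id = ids, chrom = "1", pos = seq_len(m) * 500,
                          maf = runif(m, 0.05, 0.5), L_total = L_m + L_g,
                          L_mqtl = L_m, L_G = L_g, n_window = 5L),
               nRef = 500L, mqtlIds = ids[in_m])
}
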
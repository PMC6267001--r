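## Independent brute-force oracles used to check the statistical engines.
## These deliberately share no code with the package: everything is direct
## enumeration over the full permutation/sign-assignment space.

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# exact two-sided Spearman p by enumerating all n! rank assignments;
# symmetric tail: mass of |rho_perm| >= |rho_obs|
oracle_spearman_p <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  n <- length(x)
  P <- all_permutations(n)
  rho_obs <- cor(rx, ry)
  if (anyDuplicated(rx) || anyDuplicated(ry)) {
    rhos <- apply(P, 1, function(p) cor(rx, ry[p]))
  } else {
    # untied: rho = 1 - 6 * sum(d^2) / (n(n^2-1)), vectorized over rows
    perm_ranks <- matrix(ry[P], nrow(P))
    d2 <- rowSums((perm_ranks - matrix(rx, nrow(P), n, byrow = TRUE))^2)
    rhos <- 1 - 6 * d2 / (n * (n^2 - 1))
  }
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# exact two-sided signed-rank p over all 2^n sign assignments on midranks
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  vs <- as.vector(grid %*% r)
  ev <- sum(r) / 2
  list(statistic = v_obs,
       p = mean(abs(vs - ev) >= abs(v_obs - ev) - 1e-12))
}

# exact two-sided rank-sum p over all C(n, m) group assignments
oracle_rank_sum <- function(a, b) {
  r <- rank(c(a, b))
  m <- length(a)
  w_obs <- sum(r[seq_len(m)])
  ws <- combn(length(r), m, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(ws <= w_obs + 1e-12), mean(ws >= w_obs - 1e-12)))
}

# Benjamini-Hochberg step-up from its definition: q_(i) = min over j >= i of
# p_(j) * m / j, reported in the input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, q_sorted)[order(o)]
}

# naive double-loop Bray-Curtis
oracle_bray_curtis <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      w <- sum(pmin(x[i, ], x[j, ]))
      d[i, j] <- 1 - 2 * w / sum(x[i, ] + x[j, ])
    }
  }
  d
}

## small shared fixtures -----------------------------------------------------

tiny_sim_config <- function(seed, planted = NULL, n_taxa = 21,
                            sites = "underarm") {
  sim_config(
    n_children = 15, n_teens = 2, sites = sites, n_taxa = n_taxa,
    planted_taxa = planted %||%
      planted_effect("s__Staphylococcus_epidermidis", sites[1], "children",
                     0.8, 1.5,
                     c("K_BCAA_01", "K_BCAA_02", "K_BCAA_03")),
    seed = seed)
}

null_sim_config <- function(seed, n_taxa = 15, sites = "underarm") {
  sim_config(n_children = 15, n_teens = 2, sites = sites, n_taxa = n_taxa,
             planted_taxa = default_planted_effects()[0, ], seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
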
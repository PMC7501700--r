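# Independent oracles used across the suite. These deliberately avoid the
# package's matrix machinery: plain loops and choose()-based sums.

# Exact right-tail Fisher probability by brute-force summation of the
# hypergeometric pmf, written from the definition with choose().
fisher_oracle <- function(a, b, c, d) {
  K <- a + b          # annotated margin
  n <- a + c          # sampled margin
  N <- a + b + c + d
  js <- a:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Dense one-round diffusion oracle on explicit edge lists, element by
# element. B: drugs x bits 0/1 matrix; E: drugs x targets 0/1 matrix.
# Node order and naming match the package: d:, s:, t: prefixes.
oracle_round <- function(r, B, E, beta, gamma) {
  drugs <- rownames(B); subs <- colnames(B); targets <- colnames(E)
  deg_drug <- rowSums(B) + rowSums(E)
  deg_sub <- colSums(B)
  deg_tar <- if (ncol(E) > 0) colSums(E) else numeric(0)

  pfx <- function(p, x) if (length(x)) paste0(p, x) else character(0)
  nodes <- c(pfx("d:", drugs), pfx("s:", subs), pfx("t:", targets))
  out <- setNames(numeric(length(nodes)), nodes)

  # step (i): substructure/target nodes return mass evenly to their drugs;
  # drugs keep whatever they hold
  on_drug <- setNames(r[paste0("d:", drugs)], drugs)
  for (s in subs) {
    ds <- drugs[B[, s] == 1]
    for (d in ds) on_drug[d] <- on_drug[d] + r[paste0("s:", s)] / length(ds)
  }
  for (t in targets) {
    ds <- drugs[E[, t] == 1]
    for (d in ds) on_drug[d] <- on_drug[d] + r[paste0("t:", t)] / length(ds)
  }

  # step (ii): each drug splits beta / (1 - beta) across its sides, within
  # a side proportionally to (total tripartite degree)^gamma
  for (d in drugs) {
    m <- on_drug[d]
    if (m == 0) next
    my_subs <- subs[B[d, ] == 1]
    my_tars <- targets[E[d, ] == 1]
    b_s <- if (length(my_tars) > 0) beta else 1
    b_t <- if (length(my_tars) > 0) 1 - beta else 0
    if (length(my_subs) > 0) {
      w <- deg_sub[my_subs]^gamma
      for (s in my_subs)
        out[paste0("s:", s)] <- out[paste0("s:", s)] +
          m * b_s * (deg_sub[s]^gamma) / sum(w)
    }
    if (length(my_tars) > 0) {
      w <- deg_tar[my_tars]^gamma
      for (t in my_tars)
        out[paste0("t:", t)] <- out[paste0("t:", t)] +
          m * b_t * (deg_tar[t]^gamma) / sum(w)
    }
  }
  out
}

oracle_propagate <- function(r, B, E, beta, gamma, k) {
  for (i in seq_len(k)) r <- oracle_round(r, B, E, beta, gamma)
  r
}

# Random small tripartite instance: every drug has >= 1 bit, every listed
# target >= 1 drug. Returns the fingerprint table and DTI data.frame.
rand_tripartite <- function(seed, max_nodes = 12) {
  set.seed(seed)
  nd <- sample(1:4, 1)
  ns <- sample(1:5, 1)
  nt <- sample(0:min(4, max_nodes - nd - ns), 1)
  drugs <- paste0("D", seq_len(nd))
  subs <- paste0("S", seq_len(ns))
  B <- matrix(rbinom(nd * ns, 1, 0.5), nd, ns,
              dimnames = list(drugs, subs))
  for (i in seq_len(nd))
    if (sum(B[i, ]) == 0) B[i, sample.int(ns, 1)] <- 1
  B <- B[, colSums(B) > 0, drop = FALSE]
  dti <- data.frame(compound_id = character(), target = character(),
                    stringsAsFactors = FALSE)
  if (nt > 0) {
    targets <- paste0("T", seq_len(nt))
    E <- matrix(rbinom(nd * nt, 1, 0.5), nd, nt,
                dimnames = list(drugs, targets))
    for (j in seq_len(nt))
      if (sum(E[, j]) == 0) E[sample.int(nd, 1), j] <- 1
    idx <- which(E == 1, arr.ind = TRUE)
    dti <- data.frame(compound_id = drugs[idx[, 1]],
                      target = targets[idx[, 2]],
                      stringsAsFactors = FALSE)
  }
  list(fp = fingerprint_table(B), dti = dti)
}

# Edge matrices of a tripartite_graph, for feeding the oracle.
graph_mats <- function(graph) {
  list(B = as.matrix(graph$A_ds), E = as.matrix(graph$A_dt))
}

# A bipartite network with an exact edge/compound/target census, built by
# round-robin pairing (duplicate-free whenever n_edges < lcm of the two
# side sizes, and covering both sides whenever n_edges >= each size).
census_network <- function(n_edges, n_compounds, n_targets) {
  k <- seq_len(n_edges) - 1
  edges <- data.frame(
    compound_id = paste0("c", (k %% n_compounds) + 1),
    target = paste0("T", (k %% n_targets) + 1),
    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(paste(edges$compound_id, edges$target)))
  assemble_network(edges)
}

# Small-but-complete synthetic config for fast pipeline tests.
small_config <- function(seed = 1) {
  synthetic_config(n_herbs = 3, n_compounds = 60, compounds_per_herb = 25,
                   n_targets = 40, n_bits = 60, targets_per_compound = 5,
                   n_modules = 8, module_size = 8, n_disease_genes = 8,
                   n_planted = 5, seed = seed)
}

table2_path <- function() {
  system.file("extdata", "dss_key_ingredients.csv", package = "netpharm")
}
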
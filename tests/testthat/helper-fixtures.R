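# Shared fixtures: the five-gene toy network T1 and small random
# compendium generators, plus brute-force set-algebra oracles that the
# vectorized implementations are checked against.

t1_edges <- list(G1 = c("G1", "G2", "G3"),
                 G2 = c("G2", "G1"),
                 G3 = "G3",
                 G4 = c("G4", "G1", "G2", "G3", "G5"))

# Significant cells get |M| = 2 (self cells negative; G1's self M is -6),
# p = 0.001; everything else M = 0.1, p = 0.9. `m_overrides` is a named
# list "trans:target" -> M value for directional tests.
make_t1_compendium <- function(m_overrides = NULL) {
  genes <- paste0("G", 1:5)
  dels <- paste0("G", 1:4)
  M <- matrix(0.1, 4, 5, dimnames = list(dels, genes))
  P <- matrix(0.9, 4, 5, dimnames = dimnames(M))
  for (d in dels) {
    for (g in t1_edges[[d]]) {
      M[d, g] <- if (d == g) (if (d == "G1") -6 else -2) else -2
      P[d, g] <- 0.001
    }
  }
  for (key in names(m_overrides)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    M[parts[1], parts[2]] <- m_overrides[[key]]
  }
  expression_compendium(
    strains = data.frame(strain_id = paste0(dels, "::YPD"),
                         deleted_gene = dels, media = "YPD",
                         stringsAsFactors = FALSE),
    genes = genes, M = M, P = P)
}

make_t1_network <- function(...) {
  suppressMessages(select_focal_genes(build_adjacency(make_t1_compendium(...))))
}

# Random compendium with independently significant cells (each cell is a
# strong effect with probability p_sig); self cells always a strong
# decrease so every deletion passes the self filter.
make_random_compendium <- function(n_del, n_genes, p_sig = 0.15) {
  genes <- sprintf("r%03d", seq_len(n_genes))
  dels <- genes[seq_len(n_del)]
  M <- matrix(0.1, n_del, n_genes, dimnames = list(dels, genes))
  P <- matrix(0.9, n_del, n_genes, dimnames = dimnames(M))
  sig <- matrix(runif(n_del * n_genes) < p_sig, n_del, n_genes)
  M[sig] <- sample(c(-2, 2), sum(sig), replace = TRUE)
  P[sig] <- 0.001
  self <- cbind(seq_len(n_del), seq_len(n_del))
  M[self] <- -5
  P[self] <- 1e-6
  expression_compendium(
    strains = data.frame(strain_id = paste0(dels, "::YPD"),
                         deleted_gene = dels, media = "YPD",
                         stringsAsFactors = FALSE),
    genes = genes, M = M, P = P)
}

# Wrap a raw 0/1 adjacency (rows deletions, cols genes, self cells 1) in a
# perturbation network by realizing it as a compendium and thresholding.
new_net_for_test <- function(genes, dels, A) {
  M <- matrix(0.1, length(dels), length(genes),
              dimnames = list(dels, genes))
  P <- matrix(0.9, length(dels), length(genes), dimnames = dimnames(M))
  M[A == 1L] <- -2
  P[A == 1L] <- 0.001
  self <- cbind(seq_along(dels), match(dels, genes))
  M[self] <- -5
  P[self] <- 1e-6
  comp <- expression_compendium(
    strains = data.frame(strain_id = paste0(dels, "::YPD"),
                         deleted_gene = dels, media = "YPD",
                         stringsAsFactors = FALSE),
    genes = genes, M = M, P = P)
  suppressMessages(select_focal_genes(build_adjacency(comp)))
}

# Brute-force set-algebra oracles on a 0/1 adjacency matrix with named
# dims (rows deletions, columns genes).
oracle_cis_count <- function(A, f) {
  length(setdiff(colnames(A)[A[f, ] == 1], f))
}
oracle_trans_count <- function(A, t, f) {
  length(setdiff(colnames(A)[A[t, ] == 1], c(t, f)))
}
oracle_nested <- function(A, t, f) {
  setdiff(intersect(colnames(A)[A[t, ] == 1], colnames(A)[A[f, ] == 1]),
          c(t, f))
}
oracle_parallel_count <- function(A, t, f) {
  length(setdiff(setdiff(colnames(A)[A[t, ] == 1], c(t, f)),
                 colnames(A)[A[f, ] == 1]))
}
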
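# independent brute-force oracles, deliberately naive

# undirected adjacency matrix of a web: self-links dropped, mutual links
# collapsed
oracle_undirected_adj <- function(web) {
  n <- length(web$nodes)
  A <- matrix(0L, n, n, dimnames = list(web$nodes, web$nodes))
  for (r in seq_len(nrow(web$links))) {
    i <- web$links$prey[r]
    j <- web$links$predator[r]
    if (i != j) A[i, j] <- A[j, i] <- 1L
  }
  A
}

# Floyd-Warshall all-pairs shortest paths on the undirected projection
oracle_mean_path <- function(web) {
  A <- oracle_undirected_adj(web)
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  # largest connected component = largest set of mutually reachable nodes
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[is.finite(D[i, ])] <- cid
    }
  }
  big <- which(comp == which.max(tabulate(comp)))
  vals <- D[big, big]
  mean(vals[row(vals) != col(vals)])
}

# triangle-counting local clustering, nodes with degree < 2 contribute 0
oracle_mean_clustering <- function(web) {
  A <- oracle_undirected_adj(web)
  n <- nrow(A)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in nb) for (b in nb) if (a < b && A[a, b] == 1) tri <- tri + 1
    cc[i] <- 2 * tri / (k * (k - 1))
  }
  mean(cc)
}

# nodes on a directed cycle of length >= 2: boolean transitive closure of
# the self-link-free adjacency, then check i reaches i
oracle_loop_nodes <- function(web) {
  n <- length(web$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(web$nodes, web$nodes))
  for (r in seq_len(nrow(web$links))) {
    i <- web$links$prey[r]
    j <- web$links$predator[r]
    if (i != j) A[i, j] <- TRUE
  }
  R <- A
  for (step in seq_len(n)) {
    R2 <- R | (R %*% A > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  sum(diag(R))
}

# term-by-term modularity from the displayed formula
oracle_modularity <- function(web, membership) {
  A <- oracle_undirected_adj(web)
  m <- membership[web$nodes]
  L <- sum(A) / 2
  deg <- rowSums(A)
  M <- 0
  for (s in unique(m)) {
    mem <- which(m == s)
    I_s <- sum(A[mem, mem, drop = FALSE]) / 2
    d_s <- sum(deg[mem])
    M <- M + I_s / L - (d_s / (2 * L))^2
  }
  M
}

# explicit double loop over the meta link list
oracle_induced_links <- function(meta, members) {
  keep <- logical(nrow(meta$links))
  for (r in seq_len(nrow(meta$links))) {
    keep[r] <- meta$links$prey[r] %in% members &&
      meta$links$predator[r] %in% members
  }
  meta$links[keep, , drop = FALSE]
}
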
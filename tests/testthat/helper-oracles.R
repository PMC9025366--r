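# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths (and igraph):
# betweenness by exhaustive simple-path enumeration, BH by the definitional
# double loop, the hypergeometric tail by subset enumeration.

# Exact normalized betweenness by enumerating every simple path between every
# pair (DFS), keeping the shortest ones. Endpoints excluded, unordered pairs
# counted once, normalized by (n-1)(n-2)/2; disconnected pairs contribute 0.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  bt <- numeric(n)
  if (n < 3) return(bt)
  all_paths <- function(s, t) {
    res <- list()
    dfs <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        res[[length(res) + 1L]] <<- path
        return(invisible())
      }
      for (u in which(adj[v, ] == 1)) {
        if (!(u %in% path)) dfs(c(path, u))
      }
    }
    dfs(s)
    res
  }
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- lengths(paths)
      sp <- paths[lens == min(lens)]
      sigma <- length(sp)
      interior <- unlist(lapply(sp, function(p) p[-c(1, length(p))]))
      if (length(interior) > 0) {
        tb <- table(interior)
        idx <- as.integer(names(tb))
        bt[idx] <- bt[idx] + as.numeric(tb) / sigma
      }
    }
  }
  bt / ((n - 1) * (n - 2) / 2)
}

# Definitional BH: q_i = min over ranks j >= rank(i) of p_(j) * m / j, capped
# at 1, computed with explicit loops.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)
    cand <- vapply(seq(r, m), function(j) p[o[j]] * m / j, numeric(1))
    q[i] <- min(1, cand)
  }
  q
}

# Hypergeometric upper tail P(X >= k) by enumerating all size-n subsets of a
# population of N with K successes.
hyper_oracle <- function(k, K, n, N) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

# Wrap an adjacency matrix (rownames = node names) as an interaction_network.
adj_network <- function(adj, name = "test") {
  if (is.null(rownames(adj))) {
    rownames(adj) <- colnames(adj) <- paste0("n", seq_len(nrow(adj)))
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  structure(list(graph = g, name = name), class = "interaction_network")
}

# Random symmetric adjacency matrix; optionally resampled until connected
# (connectivity checked by BFS from node 1, not via igraph).
random_adj <- function(n, p = 0.4, connected = TRUE, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    adj <- matrix(0L, n, n)
    up <- upper.tri(adj)
    adj[up] <- as.integer(runif(sum(up)) < p)
    adj <- adj + t(adj)
    if (!connected || is_connected_adj(adj)) return(adj)
  }
  stop("could not draw a connected graph")
}

# All labeled graphs on n nodes as adjacency matrices (n <= 5 in practice).
all_graphs <- function(n) {
  n_edges <- n * (n - 1) / 2
  lapply(seq_len(2^n_edges) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(n_edges)]
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- bits
    adj + t(adj)
  })
}

is_connected_adj <- function(adj) {
  n <- nrow(adj)
  seen <- c(1L)
  frontier <- c(1L)
  while (length(frontier) > 0) {
    nxt <- setdiff(which(colSums(adj[frontier, , drop = FALSE] == 1) > 0), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == n
}

# Small three-cohort sample sheet for hand-built count matrices.
tiny_samples <- function(n_young = 3, n_old = 3, n_oad = 3) {
  cohort <- rep(c("Young", "Old", "OAD"), c(n_young, n_old, n_oad))
  tibble::tibble(
    sample_id = paste0(cohort, "_", unlist(lapply(c(n_young, n_old, n_oad), seq_len))),
    cohort = cohort
  )
}

# DEG tibble builder for crossing tests.
deg_rows <- function(comparison, genes, signs) {
  tibble::tibble(comparison = comparison, gene = genes,
                 log2_fc = as.numeric(signs), q_value = 0.01,
                 sign = as.integer(signs))
}

# The six published fold-change patterns: three steroid-biosynthesis genes
# (down with aging, down Young-vs-OAD, not significant Old-vs-OAD) and three
# sphingolipid genes (down with aging, up Old-vs-OAD, not significant
# Young-vs-OAD).
table1_degs <- function() {
  dplyr::bind_rows(
    deg_rows("YoungVsOld", c("DHCR24", "FDFT1", "SQLE"), c(-1, -1, -1)),
    deg_rows("YoungVsOAD", c("DHCR24", "FDFT1", "SQLE"), c(-1, -1, -1)),
    deg_rows("YoungVsOld", c("CERS2", "UGT8", "PLPP2"), c(-1, -1, -1)),
    deg_rows("OldVsOAD", c("CERS2", "UGT8", "PLPP2"), c(1, 1, 1))
  )
}
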
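# Independent oracles used to verify the package's computations. These are
# deliberately naive (enumeration / direct summation) and share no code with
# the implementation.

# Brute-force betweenness: enumerate every shortest path of every pair via
# DFS over BFS levels, and award each interior node its fractional share.
oracle_betweenness <- function(g) {
  vs <- igraph::V(g)$name
  n <- length(vs)
  nbrs <- lapply(igraph::adjacent_vertices(g, vs), function(v) v$name)
  names(nbrs) <- vs
  btw <- stats::setNames(numeric(n), vs)
  if (n < 3) return(btw)
  for (si in 1:(n - 1)) for (ti in (si + 1):n) {
    s <- vs[si]; t <- vs[ti]
    dist <- stats::setNames(rep(Inf, n), vs)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in nbrs[[u]]) if (!is.finite(dist[w])) {
        dist[w] <- dist[u] + 1
        queue <- c(queue, w)
      }
    }
    if (!is.finite(dist[t])) next
    paths <- list()
    walk <- function(path) {
      u <- path[length(path)]
      if (u == t) {
        paths[[length(paths) + 1]] <<- path
        return(invisible())
      }
      for (w in nbrs[[u]])
        if (dist[w] == dist[u] + 1 && dist[w] <= dist[t]) walk(c(path, w))
    }
    walk(s)
    sigma <- length(paths)
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      btw[interior] <- btw[interior] + 1 / sigma
    }
  }
  btw
}

# random simple graph on n named nodes, edge probability p
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  igraph::graph_from_data_frame(
    data.frame(a = pairs[1, keep], b = pairs[2, keep]),
    directed = FALSE,
    vertices = data.frame(name = nodes))
}

# log-space tail summation for the hypergeometric upper tail
oracle_hyper_upper <- function(N, K, n, k) {
  exp(oracle_hyper_upper_log(N, K, n, k))
}

oracle_hyper_upper_log <- function(N, K, n, k) {
  if (k == 0) return(0)
  x <- k:min(K, n)
  lt <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  m <- max(lt)                       # log-sum-exp keeps relative precision
  m + log(sum(exp(lt - m)))
}

# naive average-linkage agglomeration returning the cophenetic matrix
oracle_avg_linkage_cophenetic <- function(d) {
  n <- nrow(d)
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > 1) {
    best <- c(1, 2)
    best_d <- Inf
    for (i in 1:(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best_d) { best_d <- dij; best <- c(i, j) }
    }
    coph[clusters[[best[1]]], clusters[[best[2]]]] <- best_d
    coph[clusters[[best[2]]], clusters[[best[1]]]] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  coph
}

# random expression fixture (log2 TPM + 1 scale)
random_logtpm <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * n_samples, mean = 5, sd = 2),
              n_genes, n_samples,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expr_matrix(abs(m), "log2_tpm_plus1")
}

# small simulation used across tests
small_sim <- function(seed, ...) {
  simulate_expression(sim_config(n_genes = 400, module_sizes = c(40, 40),
                                 n_tissue_specific = 10, seed = seed, ...))
}
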
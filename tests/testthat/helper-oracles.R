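# Independent oracles used to cross-check the package implementations.
# These are deliberately naive (enumeration / brute force) and share no
# code with the functions they verify.

# Raw (unnormalized) betweenness by explicit all-pairs shortest-path
# counting on an undirected graph: BFS from every source for distances
# and path counts, then pair-dependency sums, endpoints excluded.
oracle_betweenness_raw <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  bfs <- function(s) {
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    sigma <- setNames(rep(0, length(nodes)), nodes)
    dist[s] <- 0; sigma[s] <- 1
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    list(dist = dist, sigma = sigma)
  }
  sp <- lapply(nodes, bfs)
  names(sp) <- nodes
  btw <- setNames(rep(0, length(nodes)), nodes)
  for (si in seq_along(nodes)) {
    for (ti in seq_along(nodes)) {
      if (ti <= si) next
      s <- nodes[si]; t <- nodes[ti]
      if (is.infinite(sp[[s]]$dist[t])) next
      for (v in nodes) {
        if (v == s || v == t) next
        if (sp[[s]]$dist[v] + sp[[t]]$dist[v] == sp[[s]]$dist[t]) {
          btw[v] <- btw[v] +
            sp[[s]]$sigma[v] * sp[[t]]$sigma[v] / sp[[s]]$sigma[t]
        }
      }
    }
  }
  btw
}

# Upper-tail hypergeometric by direct combinatorial summation.
oracle_hyper_upper <- function(k, K, n, N) {
  if (k == 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Random bipartite network with at most `max_nodes` nodes in total.
random_bipartite <- function(max_nodes = 8) {
  nl <- sample(1:(max_nodes - 1), 1)
  nr <- sample(1:(max_nodes - nl), 1)
  left <- paste0("l", seq_len(nl))
  right <- paste0("r", seq_len(nr))
  all_pairs <- expand.grid(from = left, to = right,
                           stringsAsFactors = FALSE)
  m <- sample(0:nrow(all_pairs), 1)
  edges <- all_pairs[sample(nrow(all_pairs), m), , drop = FALSE]
  build_bipartite(edges, left, right)
}

# Convenience: write a character matrix/data.frame as a TSV fixture file.
write_tsv_tmp <- function(df, name = "fixture.tsv") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
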
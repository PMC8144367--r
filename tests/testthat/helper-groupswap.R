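# Independent BFS flood-fill oracle for cluster sizes (kept free of the
# package's union-find code path).
bfs_cluster_sizes <- function(board) {
  edges <- rbind(board$mesh_edges, board$extra_edges)
  adj <- vector("list", board$n)
  for (k in seq_len(nrow(edges))) {
    u <- edges[k, 1]; v <- edges[k, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  sizes <- integer(board$n)
  seen <- logical(board$n)
  for (start in seq_len(board$n)) {
    if (seen[start]) next
    queue <- start
    comp <- integer(0)
    seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) {
        if (!seen[w] && board$colour[w] == board$colour[v]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    sizes[comp] <- length(comp)
  }
  sizes
}

# A small random coloured board for property loops.
random_coloured_board <- function(seed, n_extra = sample(0:12, 1)) {
  b <- generate_board(5, 6, n_extra_links = n_extra, seed = seed)
  b$colour <- sample(rep(1:3, each = 10))
  b$m <- 3L; b$l <- 10L
  b
}
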
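# Independent brute-force oracles the implementation is checked against.

# exhaustive double-loop minimum inter-atom distance
oracle_edge_distance <- function(xyz_a, xyz_b) {
  best <- Inf
  for (i in seq_len(nrow(xyz_a))) for (j in seq_len(nrow(xyz_b))) {
    d <- sqrt(sum((xyz_a[i, ] - xyz_b[j, ])^2))
    if (d < best) best <- d
  }
  best
}

# all simple paths between two labels by explicit DFS over an adjacency
# list (edges as a two-column label matrix)
oracle_simple_paths <- function(edges, src, dst, nodes) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
  })
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == dst) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    for (w in adj[[v]]) if (!(w %in% path)) walk(c(path, w))
  }
  if (src == dst) return(list(src))
  walk(src)
  out
}

# minimax value by enumerating every simple path on a complete distance
# table
oracle_minimax <- function(dmat, src, dst) {
  labs <- unique(c(dmat$label_a, dmat$label_b))
  lk <- c(dmat$edge_distance, dmat$edge_distance)
  names(lk) <- c(paste(dmat$label_a, dmat$label_b, sep = "\r"),
                 paste(dmat$label_b, dmat$label_a, sep = "\r"))
  edges <- as.matrix(dmat[, c("label_a", "label_b")])
  paths <- oracle_simple_paths(edges, src, dst, labs)
  vals <- vapply(paths, function(p) {
    if (length(p) < 2) return(0)
    max(lk[paste(p[-length(p)], p[-1], sep = "\r")])
  }, numeric(1))
  list(value = min(vals), paths = paths, vals = vals)
}

random_rigid_motion <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  list(R = rotation_about_axis(ax, runif(1, 5, 175)),
       t = runif(3, -20, 20))
}

apply_motion_xyz <- function(xyz, m) {
  sweep(xyz %*% t(m$R), 2, m$t, "+")
}
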
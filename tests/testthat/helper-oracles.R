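# Independent brute-force oracles used by the property tests. These stay
# deliberately naive: exhaustive path enumeration for betweenness, random
# surface-point sampling for SASA.

# betweenness by exhaustive enumeration of all simple paths per node pair
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  if (n < 3) return(bc)
  all_paths <- function(u, v) {
    found <- list()
    rec <- function(path) {
      last <- path[length(path)]
      if (last == v) {
        found[[length(found) + 1L]] <<- path
        return(invisible())
      }
      for (w in which(adj[last, ] > 0)) {
        if (!(w %in% path)) rec(c(path, w))
      }
    }
    rec(u)
    found
  }
  for (u in seq_len(n - 1)) {
    for (v in seq.int(u + 1, n)) {
      ps <- all_paths(u, v)
      if (length(ps) == 0) next
      lens <- vapply(ps, length, 0L)
      sps <- ps[lens == min(lens)]
      m <- length(sps)
      for (p in sps) {
        for (w in setdiff(p, c(u, v))) bc[w] <- bc[w] + 1 / m
      }
    }
  }
  bc
}

# rolling-probe SASA by uniform random sampling on each inflated sphere
oracle_sasa_mc <- function(xyz, radii, probe, n_mc = 1e5, seed = 1) {
  set.seed(seed)
  rr <- radii + probe
  n <- nrow(xyz)
  vapply(seq_len(n), function(i) {
    v <- matrix(stats::rnorm(3 * n_mc), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    p <- sweep(v * rr[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_mc)
    for (j in setdiff(seq_len(n), i)) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & d2 > rr[j]^2
    }
    4 * pi * rr[i]^2 * mean(free)
  }, 0)
}

# random connected undirected graph as an adjacency matrix
random_adjacency <- function(n, p = 0.4) {
  repeat {
    adj <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
      }
    }
    if (sum(adj) > 0) return(adj)
  }
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# heavy atoms of a PDB file as plain xyz + radii (for the SASA oracle)
pdb_atom_table <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  list(at = at,
       xyz = as.matrix(at[, c("x", "y", "z")]),
       radii = vdw_radius(at$elesy))
}
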
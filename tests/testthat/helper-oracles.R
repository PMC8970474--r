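# Independent oracles used to verify the package implementations.
# These deliberately take different algorithmic routes from the package
# code paths they check.

# relabel positive cluster ids by order of first occurrence so two
# labelings of the same partition compare equal
canonical_labels <- function(lab) {
  pos <- lab > 0
  if (any(pos)) {
    lab[pos] <- as.integer(factor(lab[pos], levels = unique(lab[pos])))
  }
  lab
}

# exhaustive density-reachability closure: core points from the full
# distance matrix, clusters as graph components of the core-core
# eps-graph, border points attached to the earliest core neighbour
oracle_dbscan <- function(pts, eps, minpts) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  nbr <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nbr) >= minpts
  labels <- integer(n)
  if (any(core)) {
    ci <- which(core)
    adj <- d[ci, ci, drop = FALSE] <= eps
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    labels[ci] <- as.integer(igraph::components(g)$membership)
    for (i in which(!core)) {
      cn <- nbr[[i]][core[nbr[[i]]]]
      if (length(cn)) labels[i] <- labels[min(cn)]
    }
  }
  canonical_labels(labels)
}

# O(n^2) longest axis by explicit double loop
brute_longest_axis <- function(m) {
  best <- 0
  n <- nrow(m)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      best <- max(best, sqrt(sum((m[i, ] - m[j, ])^2)))
    }
  }
  best
}

# exhaustive directional surface NN under the sphere model
brute_surface_nn <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i) {
    min(vapply(seq_len(nrow(B)), function(j) {
      cd <- sqrt(sum((unlist(A[i, c("cx", "cy", "cz")]) -
                        unlist(B[j, c("cx", "cy", "cz")]))^2))
      max(0, cd - A$radius[i] - B$radius[j])
    }, numeric(1)))
  }, numeric(1))
}

# independently coded naive sampler for the singleton CSR null:
# rejection sampling in the ball, inverse-cosine method on the surface
naive_csr_mean_nn <- function(n, R, seed) {
  set.seed(seed)
  total <- 0
  for (k in seq_len(n)) {
    repeat {
      p <- stats::runif(3, -R, R)
      if (sum(p^2) <= R^2) break
    }
    costh <- 1 - 2 * stats::runif(1)
    phi <- stats::runif(1, 0, 2 * pi)
    sinth <- sqrt(1 - costh^2)
    q <- R * c(sinth * cos(phi), sinth * sin(phi), costh)
    total <- total + sqrt(sum((p - q)^2))
  }
  total / n
}

# minimal cluster_set carrying given centroids (for classifier tests)
build_fake_cluster_set <- function(centroids) {
  structure(list(
    labels = seq_len(nrow(centroids)),
    clusters = data.frame(cluster = seq_len(nrow(centroids)), n = 1L,
                          cx = centroids[, 1], cy = centroids[, 2],
                          longest_axis = 0)),
    class = "cluster_set")
}

# hand-rolled nested two-level mean +/- SEM
nested_mean_oracle <- function(counts, experiment) {
  exps <- sort(unique(as.character(experiment)))
  per_exp <- sapply(exps, function(e) {
    colMeans(counts[experiment == e, , drop = FALSE])
  })
  per_exp <- t(per_exp)
  list(mean = colMeans(per_exp),
       sem = apply(per_exp, 2, stats::sd) / sqrt(nrow(per_exp)))
}
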
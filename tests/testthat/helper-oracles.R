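# Independent brute-force oracles, deliberately implemented with naive
# loops / exhaustive enumeration so they share no code path with the
# package internals they check.

# All-pairs shortest path costs by exhaustive enumeration of simple paths.
bf_all_pairs_shortest <- function(cost) {
  n <- nrow(cost)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  dfs <- function(v, visited, acc, src) {
    for (w in seq_len(n)) {
      if (visited[w] || !is.finite(cost[v, w])) next
      c2 <- acc + cost[v, w]
      if (c2 < best[src, w]) best[src, w] <<- c2
      visited[w] <- TRUE
      dfs(w, visited, c2, src)
      visited[w] <- FALSE
    }
  }
  for (s in seq_len(n)) {
    vis <- rep(FALSE, n)
    vis[s] <- TRUE
    dfs(s, vis, 0, s)
  }
  best
}

path_cost <- function(cost, path) {
  if (length(path) < 2L) return(0)
  sum(cost[cbind(path[-length(path)], path[-1L])])
}

# Per-voxel weighted vote by explicit enumeration.
bf_vote <- function(label_arrays, weights) {
  d <- dim(label_arrays[[1L]])
  out <- array(0L, dim = d)
  for (lin in seq_len(prod(d))) {
    votes <- vapply(label_arrays, function(a) a[lin], numeric(1))
    labs <- sort(unique(votes))
    scores <- vapply(labs, function(L) sum(weights[votes == L]), numeric(1))
    out[lin] <- labs[which.max(scores)]   # first maximum = smallest label
  }
  out
}

# Surface voxels by explicit 6-neighbour checks (0-based coordinates).
bf_surface_coords <- function(mask) {
  d <- dim(mask)
  res <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    is_bg <- apply(nb, 1, function(p) {
      if (any(p < 1) || any(p > d)) TRUE else !mask[p[1], p[2], p[3]]
    })
    if (any(is_bg)) res <- rbind(res, c(i, j, k) - 1L)
  }
  res
}

# Symmetric MAD and Hausdorff by all-pairs surface point distances.
bf_surface_metrics <- function(a, r, spacing) {
  sa <- bf_surface_coords(a)
  sr <- bf_surface_coords(r)
  srt <- t(sr) * spacing
  da <- vapply(seq_len(nrow(sa)), function(p)
    sqrt(min(colSums((sa[p, ] * spacing - srt)^2))), numeric(1))
  sat <- t(sa) * spacing
  dr <- vapply(seq_len(nrow(sr)), function(q)
    sqrt(min(colSums((sr[q, ] * spacing - sat)^2))), numeric(1))
  list(mad = (mean(da) + mean(dr)) / 2, hausdorff = max(max(da), max(dr)))
}

# Mean Frobenius norm of the displacement Jacobian by explicit per-voxel
# finite differences (central interior, one-sided at faces).
bf_harmonic <- function(u) {
  d <- dim(u)[1:3]
  tot <- 0
  der <- function(comp, axis, i, j, k) {
    p <- c(i, j, k); hi <- p; lo <- p
    hi[axis] <- min(p[axis] + 1, d[axis])
    lo[axis] <- max(p[axis] - 1, 1)
    (u[hi[1], hi[2], hi[3], comp] - u[lo[1], lo[2], lo[3], comp]) /
      (hi[axis] - lo[axis])
  }
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (comp in 1:3) for (axis in 1:3) acc <- acc + der(comp, axis, i, j, k)^2
    tot <- tot + sqrt(acc)
  }
  tot / prod(d)
}

# Random blob mask (a couple of spheres plus salt) for metric tests.
random_blob <- function(d, seed) {
  set.seed(seed)
  g <- expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1))
  m <- array(FALSE, dim = d)
  for (s in 1:2) {
    c0 <- runif(3, 3, d - 4)
    r0 <- runif(1, 2, 4)
    m <- m | array((g$x - c0[1])^2 + (g$y - c0[2])^2 + (g$z - c0[3])^2 <= r0^2,
                   dim = d)
  }
  if (!any(m)) m[sample(prod(d), 3)] <- TRUE
  m
}

# Random directed cost matrix with entries in [0,1]; some edges absent.
random_digraph <- function(n, seed, p_edge = 0.8) {
  set.seed(seed)
  cost <- matrix(runif(n * n), n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
  cost[runif(n * n) > p_edge] <- NA
  diag(cost) <- 0
  cost
}

# Minimal atlas_graph wrapper so clustering/selection can be tested on
# hand-written cost matrices.
toy_graph <- function(cost, subject_id = "T") {
  structure(list(node_ids = rownames(cost), subject_id = subject_id,
                 cost = cost, weights = cost_weights()),
            class = "atlas_graph")
}
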
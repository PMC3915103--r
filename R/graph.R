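#' Directed atlas graph, shortest-path clustering, exemplar selection
#'
#' The registered dataset is represented as a directed graph whose vertices
#' are the atlases plus the subject.  The edge i -> j carries the cost
#' `e_ij = w1 * Mhat_ij + w2 * Hhat_ij` computed from the i -> j registration
#' (atlas i warped onto j).  Outgoing edges of the subject are never needed
#' (every path of interest terminates at the subject) and are left absent.
#'
#' Atlas selection then proceeds in three steps: all-pairs shortest paths by
#' the Floyd-Warshall algorithm; clustering of atlases whose shortest paths
#' to the subject share an atlas vertex (transitively closed); and selection
#' of one exemplar per cluster -- the member with the smallest shortest-path
#' cost to the subject -- whose voting weight is one minus its direct edge
#' cost to the subject.  Because the graph depends on the subject, the
#' clustering is recomputed for every subject; atlases cannot be
#' pre-clustered.
#'
#' @name atlas-graph
NULL

reg_key <- function(moving_id, fixed_id) paste0(moving_id, "__to__", fixed_id)

#' Build the directed cost graph over atlases and subject
#'
#' For each directed edge i -> j the moving image i is warped by the i -> j
#' field, the intensity term M (mean squared difference to j) and the shape
#' term H (harmonic energy of the field) are computed, both term matrices
#' are min-max normalised over all edges, and the weighted cost is formed.
#'
#' @param subject a [volume_image].
#' @param atlases named list of [volume_image]s (names are the atlas ids).
#' @param registrations named list of `registration_result`s or
#'   [displacement_field]s covering every ordered atlas pair and every
#'   atlas -> subject pair, under names `"<moving>__to__<fixed>"`.
#' @param w a [cost_weights]; defaults to `w1 = 0.2`, `w2 = 0.8`.
#' @param mask optional [label_volume] restricting both terms.
#' @param subject_id node id used for the subject.
#' @return an `atlas_graph`: node ids (atlases then subject), raw and
#'   normalised term matrices, and the cost matrix (absent edges are `NA`).
#' @export
build_graph <- function(subject, atlases, registrations, w = cost_weights(),
                        mask = NULL, subject_id = "subject") {
  if (length(atlases) < 1L) validation_error("build_graph needs at least one atlas")
  if (is.null(names(atlases)) || anyDuplicated(names(atlases)))
    validation_error("atlases must be a uniquely named list")
  if (subject_id %in% names(atlases))
    validation_error("subject_id '%s' collides with an atlas id", subject_id)
  atlas_ids <- names(atlases)
  nodes <- c(atlas_ids, subject_id)
  n <- length(nodes)

  pairs <- expand.grid(moving = atlas_ids, fixed = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$moving != pairs$fixed, ]
  wanted <- reg_key(pairs$moving, pairs$fixed)
  missing <- setdiff(wanted, names(registrations))
  if (length(missing) > 0L)
    validation_error("build_graph: missing registrations for pairs: %s",
                     paste(missing, collapse = ", "))

  get_field <- function(key) {
    r <- registrations[[key]]
    if (inherits(r, "registration_result")) r$field else r
  }
  images <- c(atlases, stats::setNames(list(subject), subject_id))

  M <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
  H <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$moving[r]; j <- pairs$fixed[r]
    fld <- get_field(reg_key(i, j))
    if (!identical(grid_dim(fld), grid_dim(images[[j]])))
      validation_error("field %s has wrong shape", reg_key(i, j))
    warped <- warp(images[[i]], fld, "linear")
    M[i, j] <- intensity_msd(images[[j]], warped, mask)
    H[i, j] <- harmonic_energy(fld, mask)
  }
  nt <- normalize_terms(M, H)
  cost <- edge_cost(nt$M, nt$H, w)
  diag(cost) <- 0
  structure(list(node_ids = nodes, subject_id = subject_id,
                 cost = cost, M_raw = M, H_raw = H,
                 M_norm = nt$M, H_norm = nt$H, weights = w),
            class = "atlas_graph")
}

#' @export
print.atlas_graph <- function(x, ...) {
  cat(sprintf("<atlas_graph: %d atlases + subject '%s', w1=%.2g w2=%.2g>\n",
              length(x$node_ids) - 1L, x$subject_id,
              x$weights$w1, x$weights$w2))
  invisible(x)
}

#' All-pairs shortest paths by Floyd-Warshall
#'
#' Path cost is the sum of edge costs.  Absent edges (`NA`) are treated as
#' unreachable; negative edge costs are rejected.
#'
#' @param g an `atlas_graph`, or a plain square cost matrix with dimnames.
#' @return a `path_table` with `dist` (shortest-path cost matrix) and
#'   `next_hop` (successor matrix for path reconstruction; `NA` where no
#'   path exists).
#' @export
floyd_warshall <- function(g) {
  cost <- if (inherits(g, "atlas_graph")) g$cost else g
  if (!is.matrix(cost) || nrow(cost) != ncol(cost))
    validation_error("floyd_warshall expects a square cost matrix")
  if (any(cost[is.finite(cost)] < 0))
    validation_error("floyd_warshall: negative edge cost")
  n <- nrow(cost)
  nodes <- rownames(cost)
  dist <- cost
  dist[is.na(dist)] <- Inf
  diag(dist) <- 0
  next_hop <- matrix(NA_integer_, n, n, dimnames = dimnames(cost))
  edge <- is.finite(dist)       # direct edges, plus the zero diagonal
  next_hop[edge] <- col(next_hop)[edge]
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (!is.finite(dist[i, k])) next
      cand <- dist[i, k] + dist[k, ]
      upd <- cand < dist[i, ]
      if (any(upd)) {
        dist[i, upd] <- cand[upd]
        next_hop[i, upd] <- next_hop[i, k]
      }
    }
  }
  structure(list(dist = dist, next_hop = next_hop, node_ids = nodes),
            class = "path_table")
}

#' Reconstruct one shortest path
#'
#' @param pt a `path_table` from [floyd_warshall].
#' @param from,to node ids (or indices).
#' @return character (or integer) vector of nodes from `from` to `to`, or
#'   `NULL` if `to` is unreachable.
#' @export
reconstruct_path <- function(pt, from, to) {
  idx <- function(x) if (is.character(x)) match(x, pt$node_ids) else x
  i <- idx(from); j <- idx(to)
  if (is.na(pt$next_hop[i, j])) return(NULL)
  path <- i
  guard <- 0L
  while (i != j) {
    i <- pt$next_hop[i, j]
    path <- c(path, i)
    guard <- guard + 1L
    if (guard > length(pt$node_ids))
      af_stop("atlasfuse_internal_error", "cycle while reconstructing path")
  }
  if (!is.null(pt$node_ids)) pt$node_ids[path] else path
}

#' Cluster atlases by shared shortest paths to the subject
#'
#' Each atlas's shortest path to the subject is reconstructed; two atlases
#' belong to the same cluster when their paths share at least one atlas
#' vertex (the subject is excluded), closed transitively.  Atlases whose
#' shortest path is the direct edge, and which appear on no other atlas's
#' path, form singleton clusters.
#'
#' @param pt a `path_table` over `g`.
#' @param g the `atlas_graph`.
#' @return list of character vectors partitioning the atlas ids (sorted by
#'   smallest member index for determinism).
#' @export
cluster_atlases <- function(pt, g) {
  atlas_ids <- setdiff(g$node_ids, g$subject_id)
  sidx <- match(g$subject_id, pt$node_ids)
  paths <- lapply(atlas_ids, function(a) {
    p <- reconstruct_path(pt, a, g$subject_id)
    if (is.null(p) || !is.finite(pt$dist[match(a, pt$node_ids), sidx]))
      validation_error("atlas '%s' has no path to the subject", a)
    setdiff(p, g$subject_id)
  })
  names(paths) <- atlas_ids
  parent <- stats::setNames(seq_along(atlas_ids), atlas_ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (a in atlas_ids)
    for (v in paths[[a]]) union_(match(a, atlas_ids), match(v, atlas_ids))
  roots <- vapply(seq_along(atlas_ids), find, integer(1))
  unname(lapply(sort(unique(roots)), function(r) atlas_ids[roots == r]))
}

#' Select one exemplar per cluster with its voting weight
#'
#' The exemplar ("neighboring template") of a cluster is its member with the
#' smallest shortest-path cost to the subject (ties broken by smallest node
#' index).  Its voting weight is one minus the direct edge cost from the
#' exemplar to the subject, clamped to `[0,1]`.
#'
#' @param clusters partition from [cluster_atlases].
#' @param pt the `path_table`.
#' @param g the `atlas_graph`.
#' @return a `selection_result`: `clusters`, `exemplars` (one id per
#'   cluster), `weights` (named numeric), and the reconstructed shortest
#'   `paths` of all atlases for audit.
#' @export
select_exemplars <- function(clusters, pt, g) {
  if (length(clusters) == 0L || any(lengths(clusters) == 0L))
    af_stop("atlasfuse_internal_error", "select_exemplars: empty cluster")
  sidx <- match(g$subject_id, pt$node_ids)
  exemplars <- character(length(clusters))
  weights <- numeric(length(clusters))
  for (ci in seq_along(clusters)) {
    members <- clusters[[ci]]
    dists <- pt$dist[match(members, pt$node_ids), sidx]
    # argmin; ties -> smallest node index in the graph's node order
    best <- members[dists == min(dists)]
    ex <- best[which.min(match(best, g$node_ids))]
    exemplars[ci] <- ex
    wgt <- 1 - g$cost[ex, g$subject_id]
    if (!is.finite(wgt))
      validation_error("exemplar '%s' has no direct edge to the subject", ex)
    weights[ci] <- min(max(wgt, 0), 1)
    if (weights[ci] == 0)
      warning(sprintf("exemplar '%s' has voting weight 0 (worst edge in graph); it will not contribute", ex))
  }
  paths <- lapply(setdiff(g$node_ids, g$subject_id),
                  function(a) reconstruct_path(pt, a, g$subject_id))
  names(paths) <- setdiff(g$node_ids, g$subject_id)
  structure(list(clusters = clusters, exemplars = exemplars,
                 weights = stats::setNames(weights, exemplars),
                 paths = paths, subject_id = g$subject_id),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection: %d cluster(s)>\n", length(x$clusters)))
  for (i in seq_along(x$clusters))
    cat(sprintf("  {%s} -> exemplar %s (weight %.3f)\n",
                paste(x$clusters[[i]], collapse = ","),
                x$exemplars[i], x$weights[i]))
  invisible(x)
}

#' Run the full atlas-selection step
#'
#' Shortest paths, clustering and exemplar selection in one call.
#'
#' @param g an `atlas_graph`.
#' @return a `selection_result`.
#' @export
select_atlases <- function(g) {
  pt <- floyd_warshall(g)
  cl <- cluster_atlases(pt, g)
  select_exemplars(cl, pt, g)
}

# ---------------------------------------------------------------------------
# Export helpers (audit artifacts)

#' Export graph matrices and selection to text formats
#'
#' `write_cost_csv` writes a cost/term matrix as CSV (rows = source,
#' columns = target, `inf` for absent edges).  `write_selection_json`
#' writes clusters, exemplars, weights and reconstructed paths as JSON.
#'
#' @param m a matrix with dimnames.
#' @param path output file.
#' @export
write_cost_csv <- function(m, path) {
  out <- m
  out[is.na(out)] <- Inf
  df <- data.frame(source = rownames(out), out, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_cost_csv
#' @param sel a `selection_result`.
#' @export
write_selection_json <- function(sel, path) {
  jsonlite::write_json(
    list(clusters = sel$clusters,
         exemplars = as.list(stats::setNames(as.list(sel$weights), sel$exemplars)),
         paths = sel$paths,
         subject = sel$subject_id),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
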
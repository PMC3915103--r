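test_that("identical images with zero oracle fields give an all-zero cost graph", {
  ph <- make_phantom(phantom_spec(noise_sd = 0, bias_amplitude = 0))
  z <- displacement_field(array(0, dim = c(32, 32, 32, 3)))
  atlases <- list(A = ph$image, B = ph$image)
  regs <- list(A__to__B = z, B__to__A = z, A__to__subject = z, B__to__subject = z)
  g <- build_graph(ph$image, atlases, regs)
  expect_true(all(g$cost[!is.na(g$cost)] == 0))
})

test_that("a near-copy of the subject costs less than a heavily deformed atlas", {
  ph <- make_phantom(phantom_spec(noise_sd = 0, bias_amplitude = 0))
  near <- volume_image(ph$image$data + array(rnorm(32^3, sd = 0.01), dim = c(32, 32, 32)))
  big <- random_smooth_field(c(32, 32, 32), max_disp = 5, seed = 9)
  deformed <- warp(ph$image, big, "linear")
  z <- displacement_field(array(0, dim = c(32, 32, 32, 3)))
  regs <- list(A__to__B = big, B__to__A = invert_field(big),
               A__to__subject = z, B__to__subject = invert_field(big))
  g <- build_graph(ph$image, list(A = near, B = deformed), regs)
  expect_lt(g$cost["A", "subject"], g$cost["B", "subject"])
})

test_that("missing registrations are reported by pair", {
  ph <- make_phantom(phantom_spec(noise_sd = 0, bias_amplitude = 0))
  z <- displacement_field(array(0, dim = c(32, 32, 32, 3)))
  regs <- list(A__to__B = z, B__to__A = z, A__to__subject = z)
  expect_error(build_graph(ph$image, list(A = ph$image, B = ph$image), regs),
               "B__to__subject")
})

test_that("Floyd-Warshall finds multi-hop shortcuts and keeps a zero diagonal", {
  cost <- matrix(NA_real_, 3, 3, dimnames = list(c("A", "B", "T"), c("A", "B", "T")))
  diag(cost) <- 0
  cost["A", "T"] <- 0.9; cost["A", "B"] <- 0.2; cost["B", "T"] <- 0.3
  pt <- floyd_warshall(cost)
  expect_equal(pt$dist["A", "T"], 0.5)
  expect_equal(reconstruct_path(pt, "A", "T"), c("A", "B", "T"))
  expect_true(all(diag(pt$dist) == 0))
  neg <- cost; neg["A", "B"] <- -0.1
  expect_error(floyd_warshall(neg), class = "atlasfuse_validation_error")
})

test_that("Floyd-Warshall matches exhaustive path enumeration on random digraphs", {
  for (seed in 1:30) {
    n <- sample(3:7, 1)
    cost <- random_digraph(n, seed)
    pt <- floyd_warshall(cost)
    expect_equal(pt$dist, bf_all_pairs_shortest(cost), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # reconstructed paths must achieve the reported distances
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (!is.finite(pt$dist[i, j])) next
      p <- reconstruct_path(pt, i, j)
      expect_equal(path_cost(cost, match(p, rownames(cost))), pt$dist[i, j],
                   tolerance = 1e-12)
    }
  }
})

test_that("Floyd-Warshall agrees with igraph on weighted digraphs", {
  skip_if_not_installed("igraph")
  for (seed in 101:110) {
    cost <- random_digraph(6, seed)
    pt <- floyd_warshall(cost)
    el <- which(!is.na(cost) & row(cost) != col(cost), arr.ind = TRUE)
    ig <- igraph::make_empty_graph(n = nrow(cost), directed = TRUE)
    ig <- igraph::add_edges(ig, t(el))
    d_ig <- igraph::distances(ig, mode = "out", weights = cost[el])
    expect_equal(unname(pt$dist), unname(d_ig), tolerance = 1e-12)
  }
})

test_that("atlases sharing shortest-path vertices are co-clustered transitively", {
  nodes <- c("A", "B", "C", "T")
  mk <- function(edges) {
    cost <- matrix(NA_real_, 4, 4, dimnames = list(nodes, nodes))
    diag(cost) <- 0
    for (e in edges) cost[e[[1]], e[[2]]] <- e[[3]]
    toy_graph(cost)
  }
  # P(A)=A->B->T, P(B)=B->T, P(C)=C->T  =>  {A,B}, {C}
  g1 <- mk(list(list("A", "B", 0.1), list("B", "T", 0.2), list("A", "T", 0.9),
                list("C", "T", 0.3)))
  cl1 <- cluster_atlases(floyd_warshall(g1), g1)
  expect_equal(cl1, list(c("A", "B"), "C"))
  # all direct: singletons
  g2 <- mk(list(list("A", "T", 0.1), list("B", "T", 0.2), list("C", "T", 0.3),
                list("A", "B", 0.9), list("B", "A", 0.9), list("C", "B", 0.9)))
  cl2 <- cluster_atlases(floyd_warshall(g2), g2)
  expect_equal(lengths(cl2), c(1L, 1L, 1L))
  # P(A)=A->B->T and P(C)=C->B->T share B: one cluster
  g3 <- mk(list(list("A", "B", 0.1), list("C", "B", 0.1), list("B", "T", 0.2),
                list("A", "T", 0.9), list("C", "T", 0.9)))
  cl3 <- cluster_atlases(floyd_warshall(g3), g3)
  expect_equal(cl3, list(c("A", "B", "C")))
  # unreachable atlas (B has no outgoing edges) is an error
  g4 <- mk(list(list("A", "T", 0.1), list("C", "T", 0.2)))
  expect_error(cluster_atlases(floyd_warshall(g4), g4),
               class = "atlasfuse_validation_error")
})

test_that("exemplars minimise path cost with index tie-break and 1-cost weights", {
  nodes <- c("A", "B", "C", "T")
  cost <- matrix(NA_real_, 4, 4, dimnames = list(nodes, nodes))
  diag(cost) <- 0
  cost["A", "B"] <- 0.2; cost["B", "T"] <- 0.3; cost["A", "T"] <- 0.9
  cost["C", "T"] <- 0.4
  g <- toy_graph(cost)
  pt <- floyd_warshall(g)
  sel <- select_exemplars(cluster_atlases(pt, g), pt, g)
  expect_setequal(sel$exemplars, c("B", "C"))
  expect_equal(unname(sel$weights["B"]), 0.7)   # 1 - direct edge B->T
  expect_equal(unname(sel$weights["C"]), 0.6)

  # exact tie in path cost goes to the smaller node index
  cost2 <- matrix(NA_real_, 3, 3, dimnames = list(c("A", "B", "T"), c("A", "B", "T")))
  diag(cost2) <- 0
  cost2["A", "T"] <- 0.5; cost2["B", "T"] <- 0.5
  cost2["A", "B"] <- 0.05; cost2["B", "A"] <- 0.05
  g2 <- toy_graph(cost2)
  pt2 <- floyd_warshall(g2)
  sel2 <- select_exemplars(list(c("A", "B")), pt2, g2)
  expect_equal(sel2$exemplars, "A")
})

test_that("selection is a partition and clusters change with the subject", {
  pop <- make_population(population_spec(seed = 11))
  regs <- oracle_registrations(pop)
  imgs <- lapply(pop$members, function(m) m$image)
  g <- build_graph(pop$subject$image, imgs, regs)
  sel <- select_atlases(g)
  expect_setequal(unlist(sel$clusters), names(pop$members))
  expect_equal(anyDuplicated(unlist(sel$clusters)), 0L)
  expect_equal(length(sel$exemplars), length(sel$clusters))
  expect_true(all(sel$weights >= 0 & sel$weights <= 1))

  # a different subject (one of the members) changes the partition
  alt_subject <- pop$members[[1]]$image
  regs2 <- regs
  for (id in names(pop$members)) {
    regs2[[paste0(id, "__to__subject")]] <-
      oracle_pair_field(pop$true_fields[[id]], pop$true_fields[[1]])
  }
  g2 <- build_graph(alt_subject, imgs, regs2)
  sel2 <- select_atlases(g2)
  expect_false(identical(sel$clusters, sel2$clusters))
})
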
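test_that("similarity graph separates true pairs from random pairs", {
  withr::local_seed(1)
  base <- random_protein(50)
  mut <- mutate_sequence(base, 5)  # ~10% diverged copy
  recs <- tibble::tibble(
    id = c("a", "a_twin", "mut", "r1", "r2"),
    seq = c(base, base, mut, random_protein(50), random_protein(50))
  )
  g <- all_vs_all_scores(recs, weight_floor_bits = 0)
  w <- function(x, y) {
    g$weight[(g$from == x & g$to == y) | (g$from == y & g$to == x)]
  }
  # identical pair dominates every other pair involving either sequence
  self_w <- w("a", "a_twin")
  others <- g$weight[(g$from %in% c("a", "a_twin") | g$to %in% c("a", "a_twin")) &
                     !(g$from %in% c("a", "a_twin") & g$to %in% c("a", "a_twin"))]
  expect_true(all(self_w > others))
  # mutated copy scores above any edge to unrelated sequences
  expect_true(w("a", "mut") > max(w("a", "r1"), w("a", "r2")))
  # independent random pairs fall below the default 25-bit floor
  g25 <- all_vs_all_scores(recs, weight_floor_bits = 25)
  expect_false(any((g25$from == "r1" & g25$to == "r2") |
                   (g25$from == "r2" & g25$to == "r1")))
})

test_that("random length-50 pairs stay below the default edge floor", {
  withr::local_seed(1)
  recs <- random_records(40, c(50, 50))
  g <- all_vs_all_scores(recs, weight_floor_bits = 0)
  # 780 random pairs: none reaches 25 bits
  expect_equal(nrow(g), choose(40, 2))
  expect_lt(max(g$weight), 25)
})

test_that("MCL keeps disconnected components apart and joins cliques", {
  cliques <- tibble::tibble(
    from = c("a", "a", "b", "d", "d", "e"),
    to = c("b", "c", "c", "e", "f", "f"),
    weight = 1
  )
  attr(cliques, "nodes") <- letters[1:6]
  p <- mcl(cliques)
  expect_equal(length(unique(p$family)), 2)
  expect_equal(length(unique(p$family[p$id %in% c("a", "b", "c")])), 1)
  expect_equal(length(unique(p$family[p$id %in% c("d", "e", "f")])), 1)

  single <- tibble::tibble(from = "a", to = "b", weight = 1)
  expect_equal(length(unique(mcl(single)$family)), 1)
})

test_that("MCL equals the dense reference implementation on random graphs", {
  withr::local_seed(42)
  for (rep in 1:50) {
    n <- sample(2:8, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.45
    edges <- tibble::tibble(
      from = nodes[pairs[keep, 1]],
      to = nodes[pairs[keep, 2]],
      weight = round(runif(sum(keep), 0.5, 3), 2)
    )
    attr(edges, "nodes") <- nodes
    got <- partition_sets(mcl(edges, inflation = 1.4))
    want <- partition_sets(reference_mcl(edges, nodes, inflation = 1.4))
    expect_identical(got, want)
  }
})

test_that("MCL on a 6-node path matches the reference iteration", {
  path <- tibble::tibble(from = letters[1:5], to = letters[2:6], weight = 1)
  attr(path, "nodes") <- letters[1:6]
  got <- partition_sets(mcl(path, inflation = 1.4))
  want <- partition_sets(reference_mcl(path, letters[1:6], inflation = 1.4))
  expect_identical(got, want)
})

test_that("columns stay stochastic through the iteration", {
  withr::local_seed(3)
  nodes <- sprintf("n%d", 1:6)
  edges <- tibble::tibble(from = nodes[c(1, 1, 2, 4, 5)],
                          to = nodes[c(2, 3, 3, 5, 6)],
                          weight = runif(5, 0.5, 2))
  M <- lipofam:::mcl_start_matrix(edges, nodes)
  expect_equal(colSums(M), rep(1, 6), ignore_attr = TRUE, tolerance = 1e-9)
  res <- lipofam:::mcl_iterate(M, inflation = 1.4, expansion = 2,
                               prune_threshold = 1e-5, max_iterations = 7,
                               convergence_tol = 1e-8)
  expect_equal(colSums(res$M), rep(1, 6), ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("partitions are invariant under node relabeling", {
  withr::local_seed(9)
  nodes <- sprintf("n%d", 1:7)
  pairs <- t(combn(7, 2))
  keep <- runif(nrow(pairs)) < 0.4
  edges <- tibble::tibble(from = nodes[pairs[keep, 1]],
                          to = nodes[pairs[keep, 2]],
                          weight = runif(sum(keep), 0.5, 2))
  attr(edges, "nodes") <- nodes
  p1 <- mcl(edges)
  relabel <- setNames(sprintf("m%d", 7:1), nodes)
  edges2 <- tibble::tibble(from = unname(relabel[edges$from]),
                           to = unname(relabel[edges$to]),
                           weight = edges$weight)
  attr(edges2, "nodes") <- unname(relabel[nodes])
  p2 <- mcl(edges2)
  sets1 <- partition_sets(p1)
  sets2 <- partition_sets(tibble::tibble(id = names(relabel)[match(p2$id, relabel)],
                                         family = p2$family))
  expect_identical(sets1, sets2)
})

test_that("family size filtering applies the more-than-10 rule", {
  ids <- sprintf("s%03d", 1:36)
  fam <- rep(1:4, times = c(12, 11, 10, 3))
  p <- lipofam:::new_family_partition(ids, fam)
  filtered <- filter_families(p, 11)
  expect_equal(length(unique(filtered$family)), 2)
  expect_equal(as.integer(sort(table(filtered$family))), c(11L, 12L))
  expect_equal(length(attr(filtered, "removed")), 13)

  expect_equal(filter_families(p, 1), p, ignore_attr = TRUE)
  empty <- lipofam:::new_family_partition(character(0), integer(0))
  expect_equal(nrow(filter_families(empty, 11)), 0)
})

test_that("edge lists round-trip through the ABC format", {
  edges <- tibble::tibble(from = c("a", "b"), to = c("b", "c"),
                          weight = c(31.25, 27.125))
  attr(edges, "nodes") <- c("a", "b", "c", "lonely")
  tf <- withr::local_tempfile(fileext = ".abc")
  write_edge_list(edges, tf)
  back <- read_edge_list(tf)
  expect_equal(back$from, edges$from)
  expect_equal(back$weight, edges$weight, tolerance = 1e-12)
  expect_equal(attr(back, "nodes"), attr(edges, "nodes"))
  # the partitions computed from either object agree
  expect_identical(partition_sets(mcl(back)), partition_sets(mcl(edges)))
})
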
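# Independent reference implementations used as oracles. These deliberately
# re-derive each result with plain loops and without touching the package's
# internal code paths (beyond the shared pairwise_identity primitive where
# the clustering *logic* is what is under test).

# Literal transcription of the MCL iteration on a dense matrix, loop-by-loop.
reference_mcl <- function(edges, nodes, inflation = 1.4, expansion = 2,
                          prune = 1e-5, max_iter = 200, tol = 1e-8) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      i <- match(edges$from[k], nodes)
      j <- match(edges$to[k], nodes)
      A[i, j] <- edges$weight[k]
      A[j, i] <- edges$weight[k]
    }
  }
  for (j in seq_len(n)) {
    mx <- max(A[, j])
    A[j, j] <- if (mx > 0) mx else 1
  }
  for (j in seq_len(n)) A[, j] <- A[, j] / sum(A[, j])
  M <- A
  for (it in seq_len(max_iter)) {
    prev <- M
    E <- diag(n)
    for (p in seq_len(expansion)) E <- E %*% M
    E <- E^inflation
    for (j in seq_len(n)) E[, j] <- E[, j] / sum(E[, j])
    E[E < prune] <- 0
    for (j in seq_len(n)) E[, j] <- E[, j] / sum(E[, j])
    M <- E
    if (max(abs(M - prev)) < tol) break
  }
  # cluster interpretation: attractors (positive diagonal) and support
  eps <- 1e-12
  att <- which(diag(M) > eps)
  if (length(att) == 0) att <- seq_len(n)
  lab <- seq_along(att)
  supp <- lapply(att, function(a) which(M[a, ] > eps))
  repeat {
    changed <- FALSE
    for (x in seq_along(att)) for (y in seq_along(att)) {
      if (lab[x] != lab[y] && length(intersect(supp[[x]], supp[[y]])) > 0) {
        lab[lab == max(lab[x], lab[y])] <- min(lab[x], lab[y])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cluster <- integer(n)
  for (j in seq_len(n)) {
    mass <- M[att, j]
    if (all(mass <= eps)) {
      cluster[j] <- 0L
    } else {
      cluster[j] <- min(lab[which(mass == max(mass))])
    }
  }
  if (any(cluster == 0L)) {
    free <- which(cluster == 0L)
    cluster[free] <- max(cluster) + seq_along(free)
  }
  split(nodes, cluster)
}

# canonicalize a partition (list of member vectors or id->family tibble)
# into a comparable set-of-sets representation
partition_sets <- function(x) {
  if (is.data.frame(x)) x <- split(x$id, x$family)
  unname(lapply(x, function(v) sort(as.character(v)))) |>
    (\(l) l[order(vapply(l, `[`, character(1), 1))])()
}

# Hand simulation of the greedy clustering insertion order, item by item.
simulate_greedy <- function(records, threshold) {
  ord <- order(-nchar(records$seq), records$id)
  ids <- records$id[ord]
  seqs <- records$seq[ord]
  clusters <- list()  # each: list(rep_seq, members)
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (c in seq_along(clusters)) {
      if (pairwise_identity(seqs[i], clusters[[c]]$rep_seq) >= threshold) {
        clusters[[c]]$members <- c(clusters[[c]]$members, ids[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1]] <- list(rep_seq = seqs[i],
                                               members = ids[i])
    }
  }
  lapply(clusters, `[[`, "members")
}

# brute-force best gapless PSSM segment score over every (window, column
# run) placement
brute_force_pssm_score <- function(model, seq) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  m <- model$length
  expected <- colSums(model$background * model$log_odds)
  cell <- function(i, j) {
    if (res[i] %in% rownames(model$log_odds)) {
      unname(model$log_odds[res[i], j])
    } else {
      unname(expected[j])
    }
  }
  best <- 0
  for (i0 in seq_len(n)) for (j0 in seq_len(m)) {
    run_max <- min(n - i0, m - j0)
    s <- 0
    for (k in 0:run_max) {
      s <- s + cell(i0 + k, j0 + k)
      if (s > best) best <- s
    }
  }
  best
}

# pair-counting adjusted Rand index straight from the contingency formula
ari_pair_counting <- function(lab1, lab2) {
  tab <- table(lab1, lab2)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c_ <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c_ / choose(n, 2)
  maxi <- (b + c_) / 2
  (a - expected) / (maxi - expected)
}

random_records <- function(n, len_range = c(30, 60), prefix = "s") {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  tibble::tibble(
    id = sprintf("%s%03d", prefix, seq_len(n)),
    seq = vapply(lens, random_protein, character(1))
  )
}
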
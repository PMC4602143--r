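#' All-vs-all protein similarity graph
#'
#' Computes Smith-Waterman local alignment scores (BLOSUM62, affine gaps:
#' open 11, extend 1) for every unordered pair of sequences and converts raw
#' scores to bit scores with fixed gapped Karlin-Altschul constants for
#' BLOSUM62 (lambda = 0.267, K = 0.041). Pairs whose bit score falls below
#' `weight_floor_bits` get no edge.
#'
#' @param records Data frame with columns `id`, `seq` (at least 2 rows for a
#'   non-empty edge set).
#' @param weight_floor_bits Minimum bit score for an edge (default 25).
#' @param lambda,K Karlin-Altschul constants used for the bit conversion.
#' @return A tibble of class `similarity_graph` with columns `from`, `to`,
#'   `weight` (bits); the full node id set (including isolated nodes) is
#'   attached as attribute `nodes`.
#' @export
all_vs_all_scores <- function(records, weight_floor_bits = 25,
                              lambda = 0.267, K = 0.041) {
  records <- validate_records(records)
  n <- nrow(records)
  ids <- records$id
  edges <- vector("list", max(n - 1, 0))
  if (n >= 2) {
    b62 <- get_blosum62()
    seqs <- Biostrings::AAStringSet(setNames(records$seq, ids))
    for (i in seq_len(n - 1)) {
      js <- (i + 1):n
      sc <- Biostrings::pairwiseAlignment(
        seqs[js], seqs[[i]],
        type = "local", substitutionMatrix = b62,
        gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
      )
      bits <- (lambda * sc - log(K)) / log(2)
      keep <- bits >= weight_floor_bits
      if (any(keep)) {
        edges[[i]] <- tibble(from = ids[i], to = ids[js[keep]],
                             weight = bits[keep])
      }
    }
  }
  out <- dplyr::bind_rows(edges)
  if (nrow(out) == 0) {
    out <- tibble(from = character(), to = character(), weight = numeric())
  }
  attr(out, "nodes") <- ids
  class(out) <- c("similarity_graph", class(out))
  out
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Markov clustering of a similarity graph
#'
#' From-scratch dense-matrix Markov clustering (MCL). The weighted adjacency
#' matrix is augmented with self-loops (loop weight = maximum incident edge
#' weight, 1 for isolated nodes) and column-normalized; the process then
#' alternates expansion (matrix power) and inflation (entrywise power
#' followed by column renormalization), pruning entries below
#' `prune_threshold` and renormalizing, until the maximum column change
#' drops below `convergence_tol` or `max_iterations` is reached. Attractors
#' (nodes with positive diagonal mass) and the nodes they support define the
#' clusters; a node supported by several attractor systems is assigned to
#' the one holding the largest mass on it (ties to the smallest family id).
#'
#' @param graph A `similarity_graph` tibble (columns `from`, `to`, `weight`)
#'   or any data frame shaped like one; the attribute `nodes`, when present,
#'   supplies isolated nodes.
#' @param inflation Inflation exponent (> 1, default 1.4).
#' @param expansion Expansion power (integer >= 2, default 2).
#' @param prune_threshold Entries below this are zeroed each iteration.
#' @param max_iterations Iteration cap (default 200).
#' @param convergence_tol Maximum column change declaring convergence.
#' @return A tibble of class `family_partition` with columns `id` and
#'   `family` (dense integer ids ordered by decreasing family size, ties by
#'   smallest member id). Attribute `converged` records whether the
#'   iteration converged within `max_iterations`.
#' @export
mcl <- function(graph, inflation = 1.4, expansion = 2L,
                prune_threshold = 1e-5, max_iterations = 200L,
                convergence_tol = 1e-8) {
  if (inflation <= 1) abort("`inflation` must be > 1")
  if (expansion < 2) abort("`expansion` must be >= 2")
  if (prune_threshold <= 0 || convergence_tol <= 0) {
    abort("tolerances must be > 0")
  }
  nodes <- attr(graph, "nodes") %||%
    sort(unique(c(graph$from, graph$to)))
  if (length(nodes) == 0) abort("graph has no nodes")
  M <- mcl_start_matrix(graph, nodes)
  res <- mcl_iterate(M, inflation, expansion, prune_threshold,
                     max_iterations, convergence_tol)
  members <- mcl_interpret(res$M)
  out <- new_family_partition(nodes[members$node], members$cluster)
  attr(out, "converged") <- res$converged
  out
}

# column-stochastic start matrix with max-incident-weight self-loops
mcl_start_matrix <- function(graph, nodes) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph) > 0) {
    i <- match(graph$from, nodes)
    j <- match(graph$to, nodes)
    if (any(is.na(i)) || any(is.na(j))) abort("edge endpoint not in node set")
    if (any(i == j)) abort("self-edges must not be stored in the graph")
    if (any(graph$weight <= 0)) abort("edge weights must be > 0")
    A[cbind(i, j)] <- graph$weight
    A[cbind(j, i)] <- graph$weight
  }
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  sweep(A, 2, colSums(A), "/")
}

mcl_iterate <- function(M, inflation, expansion, prune_threshold,
                        max_iterations, convergence_tol) {
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    prev <- M
    E <- M
    for (p in seq_len(expansion - 1)) E <- E %*% M
    E <- E^inflation
    E <- sweep(E, 2, colSums(E), "/")
    E[E < prune_threshold] <- 0
    cs <- colSums(E)
    if (any(cs == 0)) abort("pruning removed an entire column")
    E <- sweep(E, 2, cs, "/")
    M <- E
    if (max(abs(M - prev)) < convergence_tol) {
      converged <- TRUE
      break
    }
  }
  list(M = M, converged = converged)
}

# read clusters off a (near-)idempotent MCL matrix
mcl_interpret <- function(M) {
  n <- nrow(M)
  eps <- 1e-12
  attractors <- which(diag(M) > eps)
  if (length(attractors) == 0) attractors <- seq_len(n)
  # merge attractors with overlapping support into attractor systems
  system_of <- setNames(seq_along(attractors), attractors)
  support <- lapply(attractors, function(a) which(M[a, ] > eps))
  for (x in seq_along(attractors)) {
    for (y in seq_len(x - 1)) {
      if (length(intersect(support[[x]], support[[y]])) > 0) {
        old <- system_of[x]
        system_of[system_of == old] <- system_of[y]
      }
    }
  }
  # assign every node to the system of its largest-mass attractor
  cluster <- integer(n)
  for (j in seq_len(n)) {
    mass <- M[attractors, j]
    if (all(mass <= eps)) {
      cluster[j] <- 0L  # unsupported: provisional singleton
    } else {
      best <- which(mass == max(mass))
      cluster[j] <- min(system_of[best])
    }
  }
  if (any(cluster == 0L)) {
    free <- which(cluster == 0L)
    cluster[free] <- max(cluster) + seq_along(free)
  }
  tibble(node = seq_len(n), cluster = cluster)
}

# canonical family numbering: decreasing size, ties by smallest member id
new_family_partition <- function(ids, raw_cluster) {
  if (length(ids) == 0) {
    out <- tibble(id = character(), family = integer())
    class(out) <- c("family_partition", class(out))
    return(out)
  }
  d <- tibble(id = ids, raw = raw_cluster)
  key <- d |>
    dplyr::group_by(.data$raw) |>
    dplyr::summarise(size = dplyr::n(), min_id = min(.data$id),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$min_id) |>
    dplyr::mutate(family = dplyr::row_number())
  out <- d |>
    dplyr::left_join(key[, c("raw", "family")], by = "raw") |>
    dplyr::select("id", "family") |>
    dplyr::arrange(.data$family, .data$id)
  class(out) <- c("family_partition", class(out))
  out
}

#' Drop families below a size floor
#'
#' Removes families with fewer than `min_size` members and renumbers the
#' survivors by the canonical ordering (decreasing size, ties by smallest
#' member id). Removed ids are attached as attribute `removed`.
#'
#' @param partition A `family_partition` tibble (columns `id`, `family`).
#' @param min_size Smallest family size kept (>= 1).
#' @return A renumbered `family_partition`; attribute `removed` holds the
#'   ids of dropped members.
#' @export
filter_families <- function(partition, min_size) {
  if (min_size < 1) abort("`min_size` must be >= 1")
  sizes <- table(partition$family)
  keep <- partition$family %in%
    as.integer(names(sizes)[sizes >= min_size])
  out <- new_family_partition(partition$id[keep], partition$family[keep])
  attr(out, "removed") <- partition$id[!keep]
  out
}

#' Write / read an ABC-style edge list
#'
#' The three-column `src<TAB>dst<TAB>weight` format used to exchange
#' similarity graphs with external MCL tooling. Isolated nodes are
#' preserved through a trailing comment line listing the full node set.
#'
#' @param graph A `similarity_graph` tibble.
#' @param path File path.
#' @return `path` invisibly (`write_edge_list`); a `similarity_graph`
#'   (`read_edge_list`).
#' @export
write_edge_list <- function(graph, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(graph) > 0) {
    writeLines(paste(graph$from, graph$to,
                     format(graph$weight, digits = 15, trim = TRUE),
                     sep = "\t"), con)
  }
  nodes <- attr(graph, "nodes")
  if (!is.null(nodes)) {
    writeLines(paste0("#nodes\t", paste(nodes, collapse = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  node_line <- grep("^#nodes\t", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) > 0) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    out <- tibble(
      from = vapply(parts, `[`, character(1), 1),
      to = vapply(parts, `[`, character(1), 2),
      weight = as.numeric(vapply(parts, `[`, character(1), 3))
    )
  } else {
    out <- tibble(from = character(), to = character(), weight = numeric())
  }
  nodes <- if (length(node_line) > 0) {
    strsplit(sub("^#nodes\t", "", node_line[1]), "\t", fixed = TRUE)[[1]]
  } else {
    sort(unique(c(out$from, out$to)))
  }
  attr(out, "nodes") <- nodes
  class(out) <- c("similarity_graph", class(out))
  out
}
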
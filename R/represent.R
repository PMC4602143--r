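#' Intra-family distance matrix from shared 6-mers
#'
#' Estimates pairwise distances within a protein family from k-tuple
#' content, the statistic guide-tree construction uses: the distance
#' between two members is `1 - (number of distinct 6-mers they share) /
#' (smaller of their distinct-6-mer counts)`, clipped to \[0, 1\]. Members
#' shorter than 6 residues fall back to `1 - pairwise_identity()` for their
#' pairs.
#'
#' @param members Data frame with columns `id`, `seq` (>= 2 rows).
#' @return A symmetric numeric matrix with zero diagonal whose dimnames are
#'   the member ids (sorted).
#' @export
family_distances <- function(members) {
  members <- validate_records(members)
  if (nrow(members) < 2) abort("at least 2 members are required")
  members <- dplyr::arrange(members, .data$id)
  ids <- members$id
  seqs <- members$seq
  n <- length(ids)
  kmers <- lapply(seqs, distinct_kmers, k = 6L)
  short <- nchar(seqs) < 6
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (short[i] || short[j]) {
        dij <- 1 - pairwise_identity(seqs[i], seqs[j])
      } else {
        shared <- length(intersect(kmers[[i]], kmers[[j]]))
        dij <- 1 - shared / min(length(kmers[[i]]), length(kmers[[j]]))
      }
      d[i, j] <- d[j, i] <- min(max(dij, 0), 1)
    }
  }
  d
}

distinct_kmers <- function(seq, k = 6L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1), k:n))
}

#' UPGMA guide tree from a distance matrix
#'
#' Average-linkage agglomeration of a symmetric distance matrix into an
#' ultrametric rooted tree, the role guide trees play before progressive
#' alignment. Ids are sorted before agglomeration so that ties between
#' equally close pairs resolve to the smallest id pair first.
#'
#' @param d Symmetric numeric matrix with zero diagonal and dimnames.
#' @return An [ape::phylo] object (ultrametric, branch lengths >= 0) with
#'   the underlying [stats::hclust] fit attached as attribute `hclust`.
#' @export
upgma <- function(d) {
  check_distance_matrix(d)
  if (nrow(d) < 2) abort("at least 2 ids are required")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tr <- ape::as.phylo(hc)
  attr(tr, "hclust") <- hc
  tr
}

#' Serialize a guide tree to Newick
#'
#' @param tree A `phylo` guide tree as returned by [upgma()].
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_guide_tree <- function(tree, path = NULL) {
  if (is.null(path)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = path)
    invisible(ape::write.tree(tree))
  }
}

#' Choose the family representative by minimum total distance
#'
#' Returns the member whose total distance to all other members (row sum of
#' the distance matrix) is smallest - the member that best stands for the
#' whole family. Ties break to the lexicographically smallest id. With
#' `mode = "tree"`, distances are first replaced by the ultrametric
#' (cophenetic) distances on the UPGMA guide tree built from the matrix.
#'
#' @param d Symmetric numeric matrix with dimnames (a singleton 1x1 matrix
#'   returns its only id).
#' @param mode `"matrix"` (default) ranks by raw distance row sums;
#'   `"tree"` ranks by guide-tree path distances.
#' @return A single id (character scalar).
#' @export
select_representative <- function(d, mode = c("matrix", "tree")) {
  mode <- match.arg(mode)
  check_distance_matrix(d)
  if (nrow(d) == 1) return(rownames(d)[1])
  if (mode == "tree") {
    hc <- attr(upgma(d), "hclust")
    cd <- as.matrix(stats::cophenetic(hc))
    d <- cd[rownames(d), rownames(d)]
  }
  rs <- rowSums(d)
  cand <- names(rs)[rs == min(rs)]
  sort(cand)[1]
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || !is.numeric(d)) abort("`d` must be a numeric matrix")
  if (nrow(d) != ncol(d)) abort("`d` must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d))) {
    abort("`d` must have matching row and column names")
  }
  if (any(!is.finite(d))) abort("`d` must be finite")
  if (any(abs(d - t(d)) > 1e-9)) abort("`d` must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) abort("`d` must have a zero diagonal")
  if (any(d < 0)) abort("`d` must be non-negative")
  invisible(d)
}
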
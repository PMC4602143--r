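#' Global-alignment identity between two protein sequences
#'
#' Identity in the CD-HIT sense: the two sequences are globally aligned
#' (Needleman-Wunsch; match +1, mismatch 0, linear gap penalty -0.5 per gap
#' column) and the number of identical aligned columns is divided by the
#' length of the shorter sequence. `X` residues never count as identical.
#' The measure is symmetric and lies in \[0, 1\].
#'
#' @param a,b Amino-acid sequences (character scalars, uppercase).
#' @return Identity fraction in \[0, 1\].
#' @export
#' @examples
#' pairwise_identity("ACDEFGHIKL", "ACDEFGHIKV")  # 0.9
pairwise_identity <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1 || length(b) != 1) {
    abort("`a` and `b` must be single character strings")
  }
  if (nchar(a) == 0 || nchar(b) == 0) abort("sequences must be non-empty")
  .nw_identity_cpp(a, b)
}

#' Greedy incremental identity clustering
#'
#' Single-pass greedy clustering at a fixed identity threshold: records are
#' sorted by length descending (ties by id ascending) and each record joins
#' the first existing cluster whose representative it matches at
#' `>= threshold`, or founds a new cluster. Because records arrive longest
#' first, every representative is the longest member of its cluster.
#'
#' @param records Data frame with columns `id`, `seq`.
#' @param threshold Identity fraction in (0, 1].
#' @return A tibble of class `cluster_set` with columns `cluster` (integer),
#'   `representative`, `id`, `is_rep`, and `identity_to_rep`; the threshold
#'   is attached as attribute `threshold`.
#' @export
greedy_cluster <- function(records, threshold) {
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1]")
  records <- validate_records(records, allow_empty = TRUE)
  if (nrow(records) == 0) {
    out <- tibble(cluster = integer(), representative = character(),
                  id = character(), is_rep = logical(),
                  identity_to_rep = numeric())
    attr(out, "threshold") <- threshold
    class(out) <- c("cluster_set", class(out))
    return(out)
  }
  ord <- order(-nchar(records$seq), records$id)
  ids <- records$id[ord]
  seqs <- records$seq[ord]
  n <- length(ids)
  res <- .greedy_assign_cpp(seqs, threshold)
  assign_cluster <- res$cluster
  rep_idx <- which(!duplicated(assign_cluster))  # founders, in cluster order
  out <- tibble(
    cluster = assign_cluster,
    representative = ids[rep_idx][assign_cluster],
    id = ids,
    is_rep = seq_len(n) %in% rep_idx,
    identity_to_rep = res$identity_to_rep
  )
  out <- dplyr::arrange(out, .data$cluster, dplyr::desc(.data$is_rep), .data$id)
  attr(out, "threshold") <- threshold
  class(out) <- c("cluster_set", class(out))
  out
}

#' Hierarchical redundancy reduction with singleton discard
#'
#' Runs the greedy identity clustering at a decreasing ladder of thresholds
#' (by default 90, 75, 60%): the input is clustered at the first threshold,
#' the resulting representatives are re-clustered at the second, and so on.
#' A first-level representative is discarded if and only if it sits in a
#' singleton cluster at every level, i.e. it never co-clusters with any
#' other sequence. The retained set - all non-discarded first-level
#' representatives - is the redundancy-reduced sequence pool passed on to
#' family detection.
#'
#' @param records Data frame with columns `id`, `seq`.
#' @param thresholds Strictly decreasing identity fractions.
#' @return An object of class `reduction_result`: a list with `retained`
#'   (character vector of ids), `discarded` (character vector), and
#'   `per_level` (list of `cluster_set` tibbles, one per threshold).
#' @export
hierarchical_reduce <- function(records, thresholds = c(0.90, 0.75, 0.60)) {
  if (length(thresholds) < 1) abort("at least one threshold is required")
  if (length(thresholds) > 1 && any(diff(thresholds) >= 0)) {
    abort("`thresholds` must be strictly decreasing")
  }
  records <- validate_records(records, allow_empty = TRUE)
  per_level <- vector("list", length(thresholds))
  current <- records
  for (k in seq_along(thresholds)) {
    cs <- greedy_cluster(current, thresholds[k])
    per_level[[k]] <- cs
    reps <- cs$id[cs$is_rep]
    current <- records[match(reps, records$id), , drop = FALSE]
  }
  level0 <- per_level[[1]]
  reps0 <- level0$id[level0$is_rep]
  singleton_everywhere <- rep(TRUE, length(reps0))
  names(singleton_everywhere) <- reps0
  for (cs in per_level) {
    sizes <- table(cs$cluster)
    in_level <- intersect(reps0, cs$id)
    cl <- cs$cluster[match(in_level, cs$id)]
    nonsingle <- in_level[sizes[as.character(cl)] > 1]
    singleton_everywhere[nonsingle] <- FALSE
  }
  discarded <- reps0[singleton_everywhere[reps0]]
  retained <- setdiff(reps0, discarded)
  structure(
    list(retained = retained, discarded = discarded, per_level = per_level),
    class = "reduction_result"
  )
}

#' @export
print.reduction_result <- function(x, ...) {
  cat("<reduction_result>\n")
  cat("  levels:   ", length(x$per_level), "(thresholds ",
      paste(vapply(x$per_level, attr, numeric(1), "threshold"),
            collapse = ", "), ")\n")
  cat("  retained: ", length(x$retained), "\n")
  cat("  discarded:", length(x$discarded), "\n")
  invisible(x)
}
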
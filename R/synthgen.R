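# BLOSUM62-biased substitution distribution: P(b | a) proportional to
# background(b) * 2^(BLOSUM62[a,b]/2), b != a. Computed lazily once.
subst_prob_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b62 <- get_blosum62()[AA_LETTERS, AA_LETTERS]
      P <- AA_BACKGROUND[col(b62)] * 2^(b62 / 2)
      dim(P) <- dim(b62)
      dimnames(P) <- dimnames(b62)
      diag(P) <- 0
      cache <<- P / rowSums(P)
    }
    cache
  }
})

#' Random protein sequence from background composition
#'
#' @param length Sequence length.
#' @return Character scalar drawn i.i.d. from average amino-acid
#'   frequencies (uses the current RNG state).
#' @export
random_protein <- function(length) {
  paste(sample(AA_LETTERS, length, replace = TRUE, prob = AA_BACKGROUND),
        collapse = "")
}

#' Substitute residues at random positions
#'
#' Picks `n_substitutions` distinct positions uniformly (excluding
#' `protect`) and replaces each residue with a different one drawn from a
#' BLOSUM62-biased substitution distribution. Length is preserved; uses
#' the current RNG state.
#'
#' @param seq Amino-acid sequence (character scalar).
#' @param n_substitutions Number of positions to substitute.
#' @param protect Integer positions that must not be touched.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, n_substitutions, protect = integer(0)) {
  n <- nchar(seq)
  if (n_substitutions < 0 || n_substitutions > n) {
    abort("`n_substitutions` must lie in [0, sequence length]")
  }
  free <- setdiff(seq_len(n), protect)
  if (n_substitutions > length(free)) {
    abort("not enough unprotected positions for the requested substitutions")
  }
  if (n_substitutions == 0) return(seq)
  pos <- sample(free, n_substitutions)
  chars <- strsplit(seq, "")[[1]]
  P <- subst_prob_matrix()
  for (p in pos) {
    a <- chars[p]
    if (a %in% AA_LETTERS) {
      chars[p] <- sample(AA_LETTERS, 1, prob = P[a, ])
    } else {
      chars[p] <- sample(AA_LETTERS, 1, prob = AA_BACKGROUND)
    }
  }
  paste(chars, collapse = "")
}

# Construct a sequence block guaranteed to match one superfamily pattern,
# together with the block-relative offsets of its pattern-constrained
# positions (protected from mutation so planted positives stay positive).
motif_block <- function(superfamily) {
  f10 <- function() random_protein(10)
  r1 <- function() random_protein(1)
  seg <- switch(
    superfamily,
    GX   = list(c("GF", "p"), c(f10(), "u"), c("A", "p"), c(r1(), "u"),
                c("SF", "p"), c("G", "p"), c(f10(), "u"), c("D", "p"),
                c(f10(), "u"), c("H", "p")),
    GGGX = list(c("GGA", "p"), c(f10(), "u"), c("A", "p"), c(r1(), "u"),
                c("SA", "p"), c("G", "p"), c(f10(), "u"), c("E", "p"),
                c(f10(), "u"), c("H", "p")),
    Y    = list(c("Y", "p"), c(f10(), "u"), c("A", "p"), c(r1(), "u"),
                c("SA", "p"), c("G", "p"), c(f10(), "u"), c("D", "p"),
                c(f10(), "u"), c("H", "p")),
    abort(paste0("unknown superfamily: ", superfamily))
  )
  block <- paste(vapply(seg, `[`, character(1), 1), collapse = "")
  protected <- integer(0)
  off <- 0L
  for (s in seg) {
    len <- nchar(s[1])
    if (s[2] == "p") protected <- c(protected, off + seq_len(len))
    off <- off + len
  }
  list(block = block, protected = protected)
}

#' Generate one synthetic protein family
#'
#' Draws an ancestor from background composition (optionally embedding a
#' superfamily active-site block whose pattern-constrained positions are
#' protected from mutation) and emits `n_members` copies, each mutated at
#' `round((1 - within_identity) * length)` positions, so that members sit
#' at the target identity to the ancestor (star topology).
#'
#' @param n_members Number of members (>= 1).
#' @param length Sequence length (>= 60 when a motif is embedded).
#' @param within_identity Target member-to-ancestor identity in (0, 1].
#' @param motif Optional superfamily name (`"GX"`, `"GGGX"`, `"Y"`) to embed.
#' @param id_prefix Prefix for member ids.
#' @return A list with `records` (tibble `id`, `seq`), `truth` (tibble
#'   `id`, `family`, `motif`, `is_complete`) and `ancestor`.
#' @export
generate_family <- function(n_members, length, within_identity,
                            motif = NULL, id_prefix = "fam") {
  if (n_members < 1) abort("`n_members` must be >= 1")
  if (within_identity <= 0 || within_identity > 1) {
    abort("`within_identity` must lie in (0, 1]")
  }
  protected <- integer(0)
  if (!is.null(motif) && !is.na(motif)) {
    if (length < 60) abort("motif-bearing sequences must be >= 60 residues")
    mb <- motif_block(motif)
    blen <- nchar(mb$block)
    if (blen > length) abort("motif block longer than sequence")
    start <- sample(seq_len(length - blen + 1), 1)
    pre <- if (start > 1) random_protein(start - 1) else ""
    post_len <- length - blen - (start - 1)
    post <- if (post_len > 0) random_protein(post_len) else ""
    ancestor <- paste0(pre, mb$block, post)
    protected <- start - 1L + mb$protected
  } else {
    motif <- NA_character_
    ancestor <- random_protein(length)
  }
  n_sub <- round((1 - within_identity) * length)
  ids <- sprintf("%s_%03d", id_prefix, seq_len(n_members))
  seqs <- vapply(seq_len(n_members), function(i) {
    mutate_sequence(ancestor, n_sub, protect = protected)
  }, character(1))
  list(
    records = tibble(id = ids, seq = seqs),
    truth = tibble(id = ids, family = id_prefix, motif = motif,
                   is_complete = TRUE),
    ancestor = ancestor
  )
}

#' Generate a synthetic metagenome with ground truth
#'
#' Concatenates the members of a set of planted families with background
#' singleton decoys, shuffles record order, and emits a truth table
#' covering every sequence - the known composition against which pipeline
#' recovery is measured.
#'
#' @param specs Data frame with one row per family and columns `n_members`,
#'   `length`, `within_identity`, and optionally `motif`, `id_prefix`.
#' @param n_background Number of i.i.d. random decoy sequences.
#' @param bg_length_range Length range (inclusive) for decoys.
#' @param seed Integer seed; output is byte-identical given it.
#' @return A list of class `synthetic_metagenome` with `records` (tibble
#'   `id`, `seq`), `truth` (tibble `id`, `family`, `motif`, `is_complete`;
#'   decoys have family `"background"`), and `ancestors` (named list).
#' @export
generate_metagenome <- function(specs = NULL, n_background = 0,
                                bg_length_range = c(80, 200), seed = 1L) {
  n_specs <- if (is.null(specs)) 0L else nrow(specs)
  if (n_specs == 0 && n_background == 0) {
    abort("at least one family spec or background sequence is required")
  }
  withr::with_seed(as.integer(seed), {
    fams <- list()
    ancestors <- list()
    if (n_specs > 0) {
      specs <- as_tibble(specs)
      if (!"motif" %in% names(specs)) specs$motif <- NA_character_
      if (!"id_prefix" %in% names(specs)) {
        specs$id_prefix <- sprintf("fam%02d", seq_len(n_specs))
      }
      for (i in seq_len(n_specs)) {
        fam <- generate_family(
          n_members = specs$n_members[i], length = specs$length[i],
          within_identity = specs$within_identity[i],
          motif = specs$motif[i], id_prefix = specs$id_prefix[i]
        )
        fams[[i]] <- fam
        ancestors[[specs$id_prefix[i]]] <- fam$ancestor
      }
    }
    records <- dplyr::bind_rows(lapply(fams, `[[`, "records"))
    truth <- dplyr::bind_rows(lapply(fams, `[[`, "truth"))
    if (n_background > 0) {
      lens <- sample(seq(bg_length_range[1], bg_length_range[2]),
                     n_background, replace = TRUE)
      bg <- tibble(
        id = sprintf("bg_%04d", seq_len(n_background)),
        seq = vapply(lens, random_protein, character(1))
      )
      records <- dplyr::bind_rows(records, bg)
      truth <- dplyr::bind_rows(
        truth,
        tibble(id = bg$id, family = "background", motif = NA_character_,
               is_complete = TRUE)
      )
    }
    ord <- sample(nrow(records))
    records <- records[ord, , drop = FALSE]
    truth <- truth[match(records$id, truth$id), , drop = FALSE]
    structure(
      list(records = records, truth = truth, ancestors = ancestors),
      class = "synthetic_metagenome"
    )
  })
}

#' @export
print.synthetic_metagenome <- function(x, ...) {
  n_fam <- length(unique(x$truth$family[x$truth$family != "background"]))
  cat("<synthetic_metagenome>", nrow(x$records), "sequences,",
      n_fam, "planted families,",
      sum(x$truth$family == "background"), "background decoys\n")
  invisible(x)
}

#' Score partition recovery against ground truth
#'
#' Compares a recovered family partition with the truth table of a
#' synthetic metagenome: adjusted Rand index (background decoys count as
#' singleton truth classes), per-planted-family best-match precision and
#' recall, and - when representatives are given - the fraction whose truth
#' label equals the majority truth label of their recovered family. The
#' comparison runs over the ids present in the partition (sequences
#' dropped earlier in the pipeline do not dilute the index).
#'
#' @param truth Truth tibble (`id`, `family`) from [generate_metagenome()].
#' @param partition A `family_partition` tibble (`id`, `family`).
#' @param representatives Optional named character vector or tibble
#'   (`family`, `id`) of chosen representatives.
#' @return A list of class `recovery_metrics`: `ari`, `per_family` (tibble
#'   `family`, `n_members`, `n_in_partition`, `precision`, `recall`),
#'   `rep_label_rate` (or `NA`), `n_ids`.
#' @export
evaluate_recovery <- function(truth, partition, representatives = NULL) {
  if (nrow(partition) == 0) abort("`partition` is empty")
  if (!all(partition$id %in% truth$id)) {
    abort("partition contains ids missing from the truth table")
  }
  truth_label <- truth$family
  bg <- truth_label == "background"
  truth_label[bg] <- paste0("bg_single_", truth$id[bg])
  names(truth_label) <- truth$id
  t_lab <- truth_label[partition$id]
  p_lab <- partition$family
  ari <- mclust::adjustedRandIndex(t_lab, p_lab)
  planted <- unique(truth$family[!bg])
  per_family <- dplyr::bind_rows(lapply(planted, function(f) {
    fam_ids <- truth$id[truth$family == f]
    in_part <- intersect(fam_ids, partition$id)
    if (length(in_part) == 0) {
      return(tibble(family = f, n_members = length(fam_ids),
                    n_in_partition = 0L, precision = NA_real_,
                    recall = 0))
    }
    cl <- partition$family[match(in_part, partition$id)]
    best <- names(sort(table(cl), decreasing = TRUE))[1]
    best_ids <- partition$id[partition$family == as.integer(best)]
    tp <- length(intersect(best_ids, fam_ids))
    tibble(family = f, n_members = length(fam_ids),
           n_in_partition = length(in_part),
           precision = tp / length(best_ids),
           recall = tp / length(in_part))
  }))
  rep_rate <- NA_real_
  if (!is.null(representatives)) {
    reps <- if (is.data.frame(representatives)) {
      setNames(representatives$id, representatives$family)
    } else representatives
    if (length(reps) > 0) {
      ok <- vapply(seq_along(reps), function(k) {
        fam <- as.integer(names(reps)[k])
        member_ids <- partition$id[partition$family == fam]
        maj <- names(sort(table(truth_label[member_ids]),
                          decreasing = TRUE))[1]
        identical(unname(truth_label[reps[k]]), maj)
      }, logical(1))
      rep_rate <- mean(ok)
    }
  }
  structure(
    list(ari = ari, per_family = per_family, rep_label_rate = rep_rate,
         n_ids = nrow(partition)),
    class = "recovery_metrics"
  )
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat("<recovery_metrics> ARI =", format(x$ari, digits = 4),
      "over", x$n_ids, "ids")
  if (!is.na(x$rep_label_rate)) {
    cat("; representative label rate =", format(x$rep_label_rate))
  }
  cat("\n")
  invisible(x)
}
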
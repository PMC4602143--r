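#' Run the discovery pipeline end to end
#'
#' Executes the discovery stages in order: subtraction of domain-annotated
#' sequences (skipped when `domain_hits` is `NULL`), hierarchical
#' redundancy reduction, all-vs-all similarity graph, Markov clustering,
#' family-size filtering, representative selection by minimum total
#' intra-family distance, active-site motif screening of the
#' representatives, and - when a profile source is supplied - confirmation
#' of motif hits in a hydrolase-like profile context. An empty survivor set
#' at any stage is not an error; downstream outputs are empty and the
#' funnel is recorded in `stage_counts`.
#'
#' @param records Data frame with columns `id`, `seq` (non-empty).
#' @param domain_hits Optional domain-hit tibble (e.g. [parse_tblout()])
#'   used for the subtraction stage.
#' @param config A [pipeline_config()].
#' @param models Optional list of `profile_model` objects for the
#'   confirmation gate. When neither `models` nor `confirm_hits` is given
#'   the gate is skipped and all motif-hit representatives are carried
#'   through as candidates.
#' @param confirm_hits Optional tblout-style tibble used (with precedence
#'   over `models`) by the confirmation gate.
#' @return An object of class `discovery_result`: a list with `families`
#'   (a `family_partition`), `representatives` (tibble `family`, `id`,
#'   `seq`, `rowsum`), `motif_hits` (tibble), `confirmed` (character),
#'   `stage_counts` (tibble `stage`, `n`), `reduction`
#'   (a `reduction_result`), and `config`.
#' @export
run_discovery <- function(records, domain_hits = NULL,
                          config = pipeline_config(), models = NULL,
                          confirm_hits = NULL) {
  records <- validate_records(records)
  counts <- c(input = nrow(records))

  split <- filter_annotated(records$id, domain_hits,
                            config$annotation_evalue_max)
  unknown <- records[records$id %in% split$unknown, , drop = FALSE]
  counts["unknown"] <- nrow(unknown)

  red <- if (nrow(unknown) > 0) {
    hierarchical_reduce(unknown, config$identity_thresholds)
  } else {
    structure(list(retained = character(0), discarded = character(0),
                   per_level = list()), class = "reduction_result")
  }
  retained <- unknown[match(red$retained, unknown$id), , drop = FALSE]
  counts["retained"] <- nrow(retained)

  if (nrow(retained) >= 2) {
    graph <- all_vs_all_scores(retained, config$weight_floor_bits)
    partition <- mcl(graph, inflation = config$inflation)
  } else if (nrow(retained) == 1) {
    partition <- new_family_partition(retained$id, 1L)
  } else {
    partition <- new_family_partition(character(0), integer(0))
  }
  families <- filter_families(partition, config$min_family_size)
  counts["family_members"] <- nrow(families)

  fam_ids <- unique(families$family)
  reps <- dplyr::bind_rows(lapply(fam_ids, function(f) {
    member_ids <- families$id[families$family == f]
    members <- retained[match(member_ids, retained$id), , drop = FALSE]
    if (nrow(members) == 1) {
      rep_id <- members$id
      rowsum_val <- 0
    } else {
      d <- family_distances(members)
      rep_id <- select_representative(d)
      rowsum_val <- sum(d[rep_id, ])
    }
    tibble(family = f, id = rep_id,
           seq = members$seq[match(rep_id, members$id)],
           rowsum = rowsum_val)
  }))
  if (nrow(reps) == 0) {
    reps <- tibble(family = integer(), id = character(),
                   seq = character(), rowsum = numeric())
  }
  counts["representatives"] <- nrow(reps)

  screen <- screen_representatives(reps[, c("id", "seq")])
  hit_ids <- sort(unique(screen$hits$seq_id))
  counts["motif_hit_representatives"] <- length(hit_ids)

  if (!is.null(confirm_hits) || !is.null(models)) {
    confirmed <- confirm_candidates(
      hit_ids, seqs = reps[, c("id", "seq")], models = models,
      evalue_max = config$confirm_evalue_max, domain_hits = confirm_hits,
      seed = config$rng_seed
    )
    confirmed <- as.character(confirmed)
  } else {
    confirmed <- hit_ids
  }
  counts["confirmed"] <- length(confirmed)

  structure(
    list(
      families = families,
      representatives = reps,
      motif_hits = screen$hits,
      motif_screen = screen,
      confirmed = confirmed,
      stage_counts = tibble(stage = names(counts), n = unname(counts)),
      reduction = red,
      config = config
    ),
    class = "discovery_result"
  )
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("<discovery_result>\n")
  print(x$stage_counts)
  invisible(x)
}

#' @rdname run_discovery
#' @param object A `discovery_result`.
#' @param ... Unused.
#' @export
autoplot.discovery_result <- function(object, ...) {
  d <- object$stage_counts
  d$stage <- factor(d$stage, levels = rev(d$stage))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$stage)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "surviving sequences", y = NULL,
                  title = "Discovery funnel")
}

#' Write discovery result tables
#'
#' Writes the result as five re-readable text artifacts into `outdir`:
#' `clusters.tsv` (family_id, member_id), `representatives.fasta`,
#' `motif_hits.tsv` (rep id, superfamily, 1-based inclusive match and
#' triad-anchor coordinates), `candidates.txt`, and `stage_counts.tsv`.
#' All TSVs are tab-delimited UTF-8 with a header row and `\n` endings.
#'
#' @param result A `discovery_result`.
#' @param outdir Output directory (created if missing).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_tables <- function(result, outdir) {
  if (!inherits(result, "discovery_result")) {
    abort("`result` must be a discovery_result")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) abort(paste0("cannot create directory: ", outdir))
  paths <- c(
    clusters = file.path(outdir, "clusters.tsv"),
    representatives = file.path(outdir, "representatives.fasta"),
    motif_hits = file.path(outdir, "motif_hits.tsv"),
    candidates = file.path(outdir, "candidates.txt"),
    stage_counts = file.path(outdir, "stage_counts.tsv")
  )
  write_tsv_plain(
    data.frame(family_id = result$families$family,
               member_id = result$families$id),
    paths["clusters"]
  )
  write_fasta(result$representatives[, c("id", "seq")],
              paths["representatives"])
  hits <- result$motif_hits
  write_tsv_plain(
    data.frame(rep_id = hits$seq_id, superfamily = hits$superfamily,
               match_start = hits$match_start, match_end = hits$match_end,
               anchor_nucleophile = hits$anchor_nucleophile,
               anchor_acid = hits$anchor_acid,
               anchor_his = hits$anchor_his),
    paths["motif_hits"]
  )
  writeLines(c("candidate_id", result$confirmed), paths["candidates"])
  write_tsv_plain(as.data.frame(result$stage_counts), paths["stage_counts"])
  invisible(paths)
}

write_tsv_plain <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
}

#' Read back discovery result tables
#'
#' Re-reads the artifacts written by [write_tables()] so that a result can
#' round-trip through disk.
#'
#' @param outdir Directory previously passed to [write_tables()].
#' @return A list with `families` (a `family_partition`), `representatives`
#'   (tibble `id`, `seq`), `motif_hits`, `confirmed`, `stage_counts`.
#' @export
read_discovery_tables <- function(outdir) {
  cl <- read.delim(file.path(outdir, "clusters.tsv"),
                   colClasses = c("integer", "character"))
  families <- new_family_partition(cl$member_id, cl$family_id)
  reps_path <- file.path(outdir, "representatives.fasta")
  reps <- if (file.size(reps_path) > 0) {
    read_fasta(reps_path)
  } else {
    tibble(id = character(), seq = character())
  }
  mh <- read.delim(file.path(outdir, "motif_hits.tsv"),
                   colClasses = c("character", "character", "integer",
                                  "integer", "integer", "integer",
                                  "integer"))
  cand <- readLines(file.path(outdir, "candidates.txt"))[-1]
  sc <- read.delim(file.path(outdir, "stage_counts.tsv"),
                   colClasses = c("character", "integer"))
  list(
    families = families,
    representatives = reps,
    motif_hits = as_tibble(setNames(
      mh, c("seq_id", "superfamily", "match_start", "match_end",
            "anchor_nucleophile", "anchor_acid", "anchor_his"))),
    confirmed = cand,
    stage_counts = as_tibble(sc)
  )
}
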
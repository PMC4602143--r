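#' Parse a HMMER3 per-target tblout file
#'
#' Reads the whitespace-delimited per-target table written by `hmmsearch
#' --tblout`: `#` lines are comments; column 1 is the target sequence name,
#' column 3 the query/model name, column 5 the full-sequence E-value and
#' column 6 the bit score. When a (sequence, model) pair occurs on several
#' rows only the lowest-E row is kept.
#'
#' @param path Path to a tblout text file.
#' @return A tibble with columns `seq_id`, `model_name`, `evalue`, `score`,
#'   one row per (sequence, model) best hit.
#' @export
parse_tblout <- function(path) {
  if (!file.exists(path)) abort(paste0("tblout file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) == 0) {
    return(tibble(seq_id = character(), model_name = character(),
                  evalue = numeric(), score = numeric()))
  }
  parsed <- lapply(rows, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 6) {
      abort(paste0("malformed tblout line ", i, ": fewer than 6 fields"))
    }
    ev <- suppressWarnings(as.numeric(f[5]))
    sc <- suppressWarnings(as.numeric(f[6]))
    if (is.na(ev) || is.na(sc)) {
      abort(paste0("malformed tblout line ", i,
                   ": non-numeric E-value or score"))
    }
    tibble(seq_id = f[1], model_name = f[3], evalue = ev, score = sc)
  })
  out <- dplyr::bind_rows(parsed)
  if (any(out$evalue <= 0)) abort("tblout E-values must be > 0")
  out |>
    dplyr::group_by(.data$seq_id, .data$model_name) |>
    dplyr::slice_min(.data$evalue, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Split sequences into annotated and unknown by domain hits
#'
#' A sequence counts as annotated when it has at least one domain hit with
#' E-value at or below `evalue_max`; the remainder is the "unknown" pool
#' that enters de novo family detection. Hits referencing ids outside
#' `seq_ids` are ignored with a warning.
#'
#' @param seq_ids Character vector of sequence ids.
#' @param hits Data frame of domain hits (`seq_id`, `evalue`, ...).
#' @param evalue_max Annotation threshold (default `1e-5`).
#' @return A list with `annotated` and `unknown` character vectors; together
#'   they partition `seq_ids`.
#' @export
filter_annotated <- function(seq_ids, hits, evalue_max = 1e-5) {
  if (evalue_max <= 0) abort("`evalue_max` must be > 0")
  if (is.null(hits) || nrow(hits) == 0) {
    return(list(annotated = character(0), unknown = seq_ids))
  }
  unknown_ref <- setdiff(unique(hits$seq_id), seq_ids)
  if (length(unknown_ref) > 0) {
    warn(paste0(length(unknown_ref),
                " domain hit id(s) not in the sequence set were ignored"))
    hits <- hits[hits$seq_id %in% seq_ids, , drop = FALSE]
  }
  annotated_ids <- unique(hits$seq_id[hits$evalue <= evalue_max])
  list(
    annotated = seq_ids[seq_ids %in% annotated_ids],
    unknown = seq_ids[!(seq_ids %in% annotated_ids)]
  )
}

#' Build a position-specific scoring model from an alignment
#'
#' Turns an aligned set of sequences (equal lengths, `-` for gaps) into a
#' per-column log-odds profile: columns with more than 50% gaps are
#' dropped, residue counts are augmented with `pseudocount * background`
#' and normalized, and log-odds are `ln(freq / background)`.
#'
#' @param alignment Character vector (>= 2) of aligned sequences, or a data
#'   frame with a `seq` column.
#' @param pseudocount Total pseudocount weight spread over the background
#'   (default 1).
#' @param background Named background frequency vector over the 20 amino
#'   acids (defaults to average protein composition).
#' @param name Model name.
#' @return An object of class `profile_model`: a list with `name`, `length`,
#'   `log_odds` (20 x length matrix), `background`, `pseudocount`, and the
#'   per-column `consensus` residues.
#' @export
build_pssm <- function(alignment, pseudocount = 1,
                       background = AA_BACKGROUND, name = "profile") {
  if (is.data.frame(alignment)) alignment <- alignment$seq
  if (length(alignment) < 2) abort("at least 2 aligned sequences required")
  alignment <- toupper(alignment)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) {
    abort("aligned sequences must have equal lengths")
  }
  if (pseudocount < 0) abort("`pseudocount` must be >= 0")
  background <- background[AA_LETTERS] / sum(background[AA_LETTERS])
  chars <- do.call(rbind, strsplit(alignment, ""))
  gap_frac <- colMeans(chars == "-" | chars == ".")
  keep <- which(gap_frac <= 0.5)
  if (length(keep) == 0) abort("no columns survive the gap filter")
  log_odds <- vapply(keep, function(j) {
    col <- chars[, j]
    counts <- table(factor(col[col %in% AA_LETTERS], levels = AA_LETTERS))
    freq <- (as.numeric(counts) + pseudocount * background) /
      (sum(counts) + pseudocount)
    log(freq / background)
  }, numeric(length(AA_LETTERS)))
  rownames(log_odds) <- AA_LETTERS
  consensus <- AA_LETTERS[apply(log_odds, 2, which.max)]
  structure(
    list(name = name, length = length(keep), log_odds = log_odds,
         background = background, pseudocount = pseudocount,
         consensus = consensus),
    class = "profile_model"
  )
}

#' @export
print.profile_model <- function(x, ...) {
  cat("<profile_model> ", x$name, ": ", x$length, " columns, consensus ",
      paste(x$consensus, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Score a sequence against a profile model
#'
#' Best ungapped local segment score: the maximum, over all gapless
#' placements of a run of consecutive model columns on a sequence window,
#' of the summed column log-odds (gapless Smith-Waterman on the PSSM with
#' negative truncation at zero). An `X` residue scores its column's
#' background-expected log-odds.
#'
#' @param model A `profile_model`.
#' @param seq Uppercase amino-acid sequence (length >= 1).
#' @return The best segment score (>= 0).
#' @export
score_sequence <- function(model, seq) {
  if (!inherits(model, "profile_model")) abort("`model` must be a profile_model")
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) < 1) {
    abort("`seq` must be a non-empty character string")
  }
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  m <- model$length
  expected <- colSums(model$background * model$log_odds)
  S <- matrix(rep(expected, each = n), n, m)
  known <- res %in% AA_LETTERS
  if (any(known)) {
    ridx <- match(res[known], AA_LETTERS)
    S[known, ] <- model$log_odds[ridx, , drop = FALSE]
  }
  best <- 0
  for (off in (-(n - 1)):(m - 1)) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1 & j <= m
    if (!any(ok)) next
    v <- S[cbind(i[ok], j[ok])]
    cs <- cumsum(v)
    run_best <- max(cs - cummin(c(0, cs[-length(cs)])))
    if (run_best > best) best <- run_best
  }
  best
}

#' Calibrate a profile model's score distribution and E-values
#'
#' Scores `n_shuffles` random sequences drawn from a background composition
#' and fits a Gumbel (extreme-value) distribution to the null scores by
#' maximum likelihood. The resulting E-value for a score `s` is
#' `db_size * exp(-lambda * (s - mu))`, clipped to `(0, db_size]` -
#' strictly decreasing in the score.
#'
#' @param model A `profile_model`.
#' @param bg_composition Named residue frequency vector used to draw null
#'   sequences (defaults to the model's background).
#' @param n_shuffles Number of null sequences (>= 100).
#' @param seed Integer seed; calibration is fully reproducible given it.
#' @param db_size Effective database size used in the E-value formula.
#' @param null_length Length of the null sequences (use the median length
#'   of the sequences you intend to score).
#' @return An object of class `profile_calibration`: a list with
#'   `gumbel_mu`, `gumbel_lambda`, `n_shuffles`, `seed`, `db_size`,
#'   `null_length`, and `evalue(score)`, a vectorized function.
#' @export
calibrate_evalue <- function(model, bg_composition = NULL,
                             n_shuffles = 1000L, seed = 1L,
                             db_size = 1000, null_length = 150L) {
  if (!inherits(model, "profile_model")) abort("`model` must be a profile_model")
  if (n_shuffles < 100) abort("`n_shuffles` must be >= 100")
  if (db_size <= 0) abort("`db_size` must be > 0")
  bg <- bg_composition %||% model$background
  bg <- bg[AA_LETTERS] / sum(bg[AA_LETTERS])
  scores <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_shuffles), function(i) {
      s <- paste(sample(AA_LETTERS, null_length, replace = TRUE, prob = bg),
                 collapse = "")
      score_sequence(model, s)
    }, numeric(1))
  })
  if (stats::sd(scores) < 1e-12) {
    abort("degenerate null sample: zero score variance")
  }
  fit <- fit_gumbel_ml(scores)
  mu <- fit$mu
  lambda <- fit$lambda
  ev <- function(score) {
    pmin(pmax(db_size * exp(-lambda * (score - mu)), .Machine$double.xmin),
         db_size)
  }
  structure(
    list(gumbel_mu = mu, gumbel_lambda = lambda, n_shuffles = n_shuffles,
         seed = as.integer(seed), db_size = db_size,
         null_length = as.integer(null_length), evalue = ev),
    class = "profile_calibration"
  )
}

# Gumbel (max-EVD) maximum-likelihood fit via direct optimization of the
# log-likelihood; moment estimates initialize the search.
fit_gumbel_ml <- function(x) {
  lambda0 <- pi / (stats::sd(x) * sqrt(6))
  mu0 <- mean(x) - 0.5772156649 / lambda0
  nll <- function(p) {
    lambda <- exp(p[2])
    z <- lambda * (x - p[1])
    -sum(log(lambda) - z - exp(-z))
  }
  opt <- stats::optim(c(mu0, log(lambda0)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(mu = opt$par[1], lambda = exp(opt$par[2]))
}

#' @export
print.profile_calibration <- function(x, ...) {
  cat("<profile_calibration> mu =", format(x$gumbel_mu),
      " lambda =", format(x$gumbel_lambda),
      " (", x$n_shuffles, "shuffles, db_size", x$db_size, ")\n")
  invisible(x)
}

#' Confirm motif hits against hydrolase-like profile context
#'
#' The confirmation gate of the screen: a motif-hit sequence is confirmed
#' when its best profile E-value is at or below `evalue_max`. When external
#' HMMER tblout results (`domain_hits`) are supplied they take precedence;
#' otherwise each built-in `profile_model` is calibrated against a null of
#' random sequences and used to score the candidates.
#'
#' @param motif_hit_ids Ids that passed the motif screen.
#' @param seqs Data frame with columns `id`, `seq` covering the candidates.
#' @param models List of `profile_model` objects (ignored when
#'   `domain_hits` is given).
#' @param evalue_max Confirmation threshold (default `1e-5`).
#' @param domain_hits Optional tibble from [parse_tblout()].
#' @param n_shuffles,seed Null calibration controls for the built-in scorer.
#' @param db_size Effective database size for E-values; defaults to the
#'   number of candidate sequences.
#' @return Sorted character vector of confirmed ids (a subset of
#'   `motif_hit_ids`), with the per-candidate best E-values attached as
#'   attribute `evalues` (a tibble).
#' @export
confirm_candidates <- function(motif_hit_ids, seqs, models = NULL,
                               evalue_max = 1e-5, domain_hits = NULL,
                               n_shuffles = 1000L, seed = 1L,
                               db_size = NULL) {
  if (length(motif_hit_ids) == 0) {
    out <- character(0)
    attr(out, "evalues") <- tibble(seq_id = character(), evalue = numeric())
    return(out)
  }
  if (!is.null(domain_hits) && nrow(domain_hits) > 0) {
    best <- domain_hits |>
      dplyr::filter(.data$seq_id %in% motif_hit_ids) |>
      dplyr::group_by(.data$seq_id) |>
      dplyr::summarise(evalue = min(.data$evalue), .groups = "drop")
  } else if (!is.null(models) && length(models) > 0) {
    seqs <- validate_records(seqs)
    cand <- seqs[seqs$id %in% motif_hit_ids, , drop = FALSE]
    if (nrow(cand) == 0) abort("no candidate sequences found in `seqs`")
    db <- db_size %||% nrow(cand)
    med_len <- as.integer(round(median(nchar(cand$seq))))
    evals <- matrix(NA_real_, nrow(cand), length(models))
    for (k in seq_along(models)) {
      cal <- calibrate_evalue(models[[k]], n_shuffles = n_shuffles,
                              seed = seed + k - 1L, db_size = db,
                              null_length = med_len)
      sc <- vapply(cand$seq, function(s) score_sequence(models[[k]], s),
                   numeric(1))
      evals[, k] <- cal$evalue(sc)
    }
    best <- tibble(seq_id = cand$id, evalue = apply(evals, 1, min))
  } else {
    abort("confirmation stage requires a profile source (models or tblout)")
  }
  confirmed <- sort(best$seq_id[best$evalue <= evalue_max])
  out <- confirmed
  attr(out, "evalues") <- dplyr::arrange(best, .data$evalue)
  out
}
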
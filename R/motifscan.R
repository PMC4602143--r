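# Active-site regular expressions for the three lipase/esterase
# (carboxylester hydrolase) superfamilies, distinguished by their oxyanion
# hole class: GX, GGGX, and Y. Each pattern requires the catalytic-elbow
# nucleophile block ([AG].SxG-style, with the elbow's first glycine
# substitutable by alanine and, in the GX class, a cysteine nucleophile
# variant), followed by an acidic residue and a histidine - the Ser/Asp-Glu/
# His catalytic triad. The single internal space printed inside two of the
# alternations is a typesetting artifact (a literal space cannot occur in a
# protein sequence) and is stripped.
SUPERFAMILY_PATTERNS <- c(
  GX   = "G[EFGHILMNRSTVWY].{10,}[AG].(S[AFHKLMQTVWY]|C[FLWY])G.{10,}[DE].{10,}H",
  GGGX = "GG([AELNRSW]|G[FL]).{10,}[AG].S[ACFGIMSVY]G.{10,}[DE].{10,}H",
  Y    = "Y.{10,}[AG].S[ANQWY]G.{10,}[DE].{10,}H"
)

# Anchored variants: gap quantifiers made lazy (leftmost-shortest match) and
# capture groups added around the catalytic nucleophile (S, or C in the GX
# alternation), the acidic residue and the histidine, so triad positions can
# be read off the match. Group semantics are unchanged from the table above.
SUPERFAMILY_PATTERNS_ANCHORED <- c(
  GX   = "G[EFGHILMNRSTVWY].{10,}?[AG].(?:(S)[AFHKLMQTVWY]|(C)[FLWY])G.{10,}?([DE]).{10,}?(H)",
  GGGX = "GG(?:[AELNRSW]|G[FL]).{10,}?[AG].(S)[ACFGIMSVY]G.{10,}?([DE]).{10,}?(H)",
  Y    = "Y.{10,}?[AG].(S)[ANQWY]G.{10,}?([DE]).{10,}?(H)"
)

#' Superfamily active-site patterns
#'
#' The three regular expressions used to screen representatives for the
#' lipase/esterase active-site architecture, one per oxyanion-hole
#' superfamily (GX, GGGX, Y).
#'
#' @return A tibble with columns `name` and `pattern`.
#' @export
#' @examples
#' load_patterns()
load_patterns <- function() {
  tibble(name = names(SUPERFAMILY_PATTERNS),
         pattern = unname(SUPERFAMILY_PATTERNS))
}

#' Scan one sequence for superfamily active-site motifs
#'
#' Matches the sequence against each superfamily pattern. Gap quantifiers
#' are matched lazily so the leftmost (and shortest) occurrence is reported;
#' with `all_matches = TRUE` all non-overlapping occurrences per pattern are
#' returned. Coordinates are 1-based and inclusive. A sequence may hit
#' several superfamilies.
#'
#' @param seq Uppercase amino-acid sequence (character scalar).
#' @param id Sequence id recorded in the output (default `"seq"`).
#' @param all_matches Report all non-overlapping matches per pattern instead
#'   of only the leftmost one.
#' @return A tibble with columns `seq_id`, `superfamily`, `match_start`,
#'   `match_end`, `anchor_nucleophile`, `anchor_acid`, `anchor_his`
#'   (absolute 1-based positions of the catalytic nucleophile, the acidic
#'   residue and the histidine). Zero rows when nothing matches.
#' @export
scan_sequence <- function(seq, id = "seq", all_matches = FALSE) {
  if (!is.character(seq) || length(seq) != 1) {
    abort("`seq` must be a single character string")
  }
  rows <- lapply(names(SUPERFAMILY_PATTERNS_ANCHORED), function(nm) {
    pat <- SUPERFAMILY_PATTERNS_ANCHORED[[nm]]
    if (all_matches) {
      m <- gregexpr(pat, seq, perl = TRUE)[[1]]
      if (m[1] == -1) return(NULL)
      starts <- as.integer(m)
      lens <- attr(m, "match.length")
      cs <- attr(m, "capture.start")
      hit_rows <- lapply(seq_along(starts), function(k) {
        motif_hit_row(nm, id, starts[k], lens[k], cs[k, ])
      })
      dplyr::bind_rows(hit_rows)
    } else {
      m <- regexpr(pat, seq, perl = TRUE)
      if (m == -1) return(NULL)
      motif_hit_row(nm, id, as.integer(m), attr(m, "match.length"),
                    attr(m, "capture.start")[1, ])
    }
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(seq_id = character(), superfamily = character(),
                  match_start = integer(), match_end = integer(),
                  anchor_nucleophile = integer(), anchor_acid = integer(),
                  anchor_his = integer())
  }
  out
}

motif_hit_row <- function(superfamily, id, start, len, capture_start) {
  caps <- as.integer(capture_start)
  caps <- caps[caps > 0]
  # first surviving capture is the nucleophile (S or the GX C-variant),
  # then the acidic residue, then the histidine; the Y pattern's leading
  # tyrosine is part of the match itself, not an anchor
  tibble(
    seq_id = id, superfamily = superfamily,
    match_start = start, match_end = start + len - 1L,
    anchor_nucleophile = caps[1], anchor_acid = caps[2], anchor_his = caps[3]
  )
}

#' Screen representative sequences for lipolytic active-site motifs
#'
#' Runs [scan_sequence()] over a set of representatives and tabulates, per
#' superfamily, the ids with at least one hit. A sequence matching two
#' superfamilies is listed (and counted) in both.
#'
#' @param reps Data frame with columns `id`, `seq`.
#' @return A list of class `motif_screen` with elements `hits` (tibble of
#'   all motif hits), `ids` (named list of id vectors per superfamily), and
#'   `counts` (tibble `superfamily`, `n`).
#' @export
screen_representatives <- function(reps) {
  reps <- validate_records(reps, allow_empty = TRUE)
  hits <- dplyr::bind_rows(
    purrr::map2(reps$seq, reps$id, function(s, i) scan_sequence(s, i))
  )
  if (nrow(hits) == 0) {
    hits <- scan_sequence("A", "drop")[0, ]
  }
  fams <- names(SUPERFAMILY_PATTERNS)
  ids <- lapply(setNames(fams, fams), function(f) {
    sort(unique(hits$seq_id[hits$superfamily == f]))
  })
  counts <- tibble(
    superfamily = fams,
    n = unname(vapply(ids, length, integer(1)))
  )
  structure(list(hits = hits, ids = ids, counts = counts),
            class = "motif_screen")
}

#' @export
print.motif_screen <- function(x, ...) {
  cat("<motif_screen>\n")
  print(x$counts)
  invisible(x)
}
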
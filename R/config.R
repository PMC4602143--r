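#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the discovery pipeline. Defaults follow
#' the study conditions: domain-annotation subtraction at E-value 1e-5,
#' hierarchical redundancy reduction at 90/75/60% identity, Markov clustering
#' at inflation 1.4, a family-size floor of 11 members (families of "more
#' than 10 sequences"), and profile confirmation at E-value 1e-5.
#'
#' @param annotation_evalue_max Best-hit E-value at or below which a sequence
#'   counts as annotated and is subtracted (default `1e-5`).
#' @param identity_thresholds Strictly decreasing identity fractions for the
#'   hierarchical reduction (default `c(0.90, 0.75, 0.60)`).
#' @param inflation MCL inflation exponent (default `1.4`).
#' @param min_family_size Smallest family size kept after clustering
#'   (default `11`).
#' @param confirm_evalue_max Profile-gate E-value ceiling (default `1e-5`).
#' @param rng_seed Integer seed from which all randomness in the pipeline
#'   (profile calibration, synthetic data) flows.
#' @param weight_floor_bits Minimum bit score for an edge in the all-vs-all
#'   similarity graph (default `25`).
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(annotation_evalue_max = 1e-5,
                            identity_thresholds = c(0.90, 0.75, 0.60),
                            inflation = 1.4,
                            min_family_size = 11L,
                            confirm_evalue_max = 1e-5,
                            rng_seed = 1L,
                            weight_floor_bits = 25) {
  if (length(identity_thresholds) < 1 ||
      any(identity_thresholds <= 0) || any(identity_thresholds > 1)) {
    abort("`identity_thresholds` must lie in (0, 1]")
  }
  if (length(identity_thresholds) > 1 &&
      any(diff(identity_thresholds) >= 0)) {
    abort("`identity_thresholds` must be strictly decreasing")
  }
  if (inflation <= 1) abort("`inflation` must be > 1")
  if (min_family_size < 2) abort("`min_family_size` must be >= 2")
  if (annotation_evalue_max <= 0 || confirm_evalue_max <= 0) {
    abort("E-value bounds must be > 0")
  }
  structure(
    list(
      annotation_evalue_max = annotation_evalue_max,
      identity_thresholds = as.numeric(identity_thresholds),
      inflation = inflation,
      min_family_size = as.integer(min_family_size),
      confirm_evalue_max = confirm_evalue_max,
      rng_seed = as.integer(rng_seed),
      weight_floor_bits = weight_floor_bits
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  annotation E-value max: ", format(x$annotation_evalue_max), "\n")
  cat("  identity thresholds:    ",
      paste(format(x$identity_thresholds), collapse = ", "), "\n")
  cat("  MCL inflation:          ", format(x$inflation), "\n")
  cat("  min family size:        ", x$min_family_size, "\n")
  cat("  confirm E-value max:    ", format(x$confirm_evalue_max), "\n")
  cat("  edge weight floor:      ", format(x$weight_floor_bits), "bits\n")
  cat("  rng seed:               ", x$rng_seed, "\n")
  invisible(x)
}
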
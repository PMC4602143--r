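#' Fit Michaelis-Menten constants by the Lineweaver-Burk linearization
#'
#' Ordinary least squares of `1/v` on `1/S` (the double-reciprocal plot):
#' `Km = slope / intercept`, `Vmax = 1 / intercept`. When the enzyme
#' concentration is supplied the turnover number `kcat = Vmax / (60 *
#' enzyme_conc)` (per second, with rates in uM/min and enzyme in uM) and
#' the specificity constant `kcat / Km` (in 1/(M s)) are derived as well.
#'
#' @param data Data frame with substrate concentrations (uM) and initial
#'   rates (uM/min); column names are given by `conc` and `rate`.
#' @param conc,rate Column names (character) holding concentrations and
#'   rates. Defaults `"conc"` and `"rate"`.
#' @param enzyme_conc Optional enzyme concentration in uM (65 nM = 0.065).
#' @param label Optional substrate label carried into the output.
#' @return An object of class `mm_fit` with elements `km` (uM), `vmax`
#'   (uM/min), `kcat` (1/s or NA), `specificity` (1/(M s) or NA),
#'   `fit_mode`, `r_squared`, `enzyme_conc`, `label`, `data` and the
#'   underlying `lm` fit (`model`).
#' @export
#' @examples
#' d <- mm_rates(km = 66.68, vmax = 400,
#'               conc = c(5, 10, 25, 50, 100, 200, 333))
#' fit <- fit_lineweaver_burk(d, enzyme_conc = 0.065)
#' tidy(fit)
fit_lineweaver_burk <- function(data, conc = "conc", rate = "rate",
                                enzyme_conc = NULL, label = NULL) {
  v <- kinetics_columns(data, conc, rate)
  if (any(v$rate <= 0)) {
    abort("all rates must be > 0 for the double-reciprocal fit")
  }
  if (length(unique(v$conc)) < 2) {
    abort("at least 2 distinct concentrations are required")
  }
  fit <- lm(I(1 / rate) ~ I(1 / conc), data = v)
  intercept <- unname(coef(fit)[1])
  slope <- unname(coef(fit)[2])
  if (intercept <= 0) {
    abort("no saturation detectable: non-positive reciprocal-space intercept")
  }
  new_mm_fit(
    km = slope / intercept, vmax = 1 / intercept,
    enzyme_conc = enzyme_conc, fit_mode = "lineweaver_burk",
    r_squared = suppressWarnings(summary(fit)$r.squared), data = v, model = fit,
    label = label
  )
}

#' Fit Michaelis-Menten constants by nonlinear least squares
#'
#' Direct least-squares fit of `v = Vmax * S / (Km + S)`, initialized from
#' the Lineweaver-Burk estimates. Offered as the statistically robust
#' cross-check of the linear fit, whose reciprocal-space weighting is
#' fragile under noise. If the optimizer fails to converge the linear
#' estimates are returned with a warning (`fit_mode` still reports
#' `"nonlinear"` with attribute `converged = FALSE`).
#'
#' @inheritParams fit_lineweaver_burk
#' @return An `mm_fit` (see [fit_lineweaver_burk()]).
#' @export
fit_mm_nonlinear <- function(data, conc = "conc", rate = "rate",
                             enzyme_conc = NULL, label = NULL) {
  v <- kinetics_columns(data, conc, rate)
  if (length(unique(v$conc)) < 3) {
    abort("at least 3 distinct concentrations are required")
  }
  lb <- fit_lineweaver_burk(data, conc, rate, enzyme_conc, label)
  fit <- tryCatch(
    nls(rate ~ vmax * conc / (km + conc), data = v,
        start = list(vmax = lb$vmax, km = lb$km),
        control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warn("nonlinear fit did not converge; returning linear estimates")
    out <- new_mm_fit(km = lb$km, vmax = lb$vmax, enzyme_conc = enzyme_conc,
                      fit_mode = "nonlinear", r_squared = lb$r_squared,
                      data = v, model = lb$model, label = label)
    attr(out, "converged") <- FALSE
    return(out)
  }
  est <- coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((v$rate - mean(v$rate))^2)
  out <- new_mm_fit(
    km = unname(est["km"]), vmax = unname(est["vmax"]),
    enzyme_conc = enzyme_conc, fit_mode = "nonlinear",
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    data = v, model = fit, label = label
  )
  attr(out, "converged") <- TRUE
  out
}

new_mm_fit <- function(km, vmax, enzyme_conc, fit_mode, r_squared, data,
                       model, label = NULL) {
  if (km <= 0 || vmax <= 0) {
    abort("invalid fit: Km and Vmax must be > 0")
  }
  kcat <- if (!is.null(enzyme_conc)) vmax / (60 * enzyme_conc) else NA_real_
  structure(
    list(km = km, vmax = vmax, kcat = kcat,
         specificity = if (is.na(kcat)) NA_real_
                       else specificity_constant(kcat, km),
         fit_mode = fit_mode, r_squared = r_squared,
         enzyme_conc = enzyme_conc %||% NA_real_,
         label = label %||% NA_character_, data = data, model = model),
    class = "mm_fit"
  )
}

#' Specificity constant from turnover number and Michaelis constant
#'
#' `kcat / Km` with `kcat` in 1/s and `Km` in uM, returned in 1/(M s).
#'
#' @param kcat Turnover number (1/s).
#' @param km_um Michaelis constant (uM).
#' @return Specificity constant in 1/(M s).
#' @export
#' @examples
#' specificity_constant(228, 66.68)  # ~3.4e6
specificity_constant <- function(kcat, km_um) {
  if (any(kcat <= 0) || any(km_um <= 0)) abort("kcat and Km must be > 0")
  kcat / (km_um * 1e-6)
}

#' Noiseless Michaelis-Menten rates
#'
#' Convenience generator of exact rates `v = vmax * conc / (km + conc)`,
#' used for worked examples and fit validation.
#'
#' @param km,vmax Michaelis constant (uM) and limiting rate (uM/min).
#' @param conc Substrate concentrations (uM).
#' @return A tibble with columns `conc`, `rate`.
#' @export
mm_rates <- function(km, vmax, conc) {
  tibble(conc = conc, rate = vmax * conc / (km + conc))
}

kinetics_columns <- function(data, conc, rate) {
  if (!is.data.frame(data)) abort("`data` must be a data frame")
  if (!all(c(conc, rate) %in% names(data))) {
    abort(paste0("`data` must contain columns `", conc, "` and `", rate, "`"))
  }
  v <- tibble(conc = as.numeric(data[[conc]]), rate = as.numeric(data[[rate]]))
  if (nrow(v) < 2) abort("at least 2 observations are required")
  if (any(!is.finite(v$conc)) || any(!is.finite(v$rate))) {
    abort("concentrations and rates must be finite")
  }
  if (any(v$conc <= 0)) abort("substrate concentrations must be > 0")
  if (any(v$rate < 0)) abort("rates must be >= 0")
  v
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit> (", x$fit_mode, ")\n", sep = "")
  cat("  Km   =", format(x$km), "uM\n")
  cat("  Vmax =", format(x$vmax), "uM/min\n")
  if (!is.na(x$kcat)) {
    cat("  kcat =", format(x$kcat), "1/s\n")
    cat("  kcat/Km =", format(x$specificity, digits = 3), "1/(M s)\n")
  }
  invisible(x)
}

#' @rdname fit_lineweaver_burk
#' @param x,object An `mm_fit`.
#' @param ... Unused.
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(
    term = c("km", "vmax", "kcat", "specificity"),
    estimate = c(x$km, x$vmax, x$kcat, x$specificity),
    unit = c("uM", "uM/min", "1/s", "1/(M s)")
  )
}

#' @rdname fit_lineweaver_burk
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, fit_mode = x$fit_mode,
         nobs = nrow(x$data), enzyme_conc = x$enzyme_conc)
}

#' @rdname fit_lineweaver_burk
#' @export
autoplot.mm_fit <- function(object, ...) {
  d <- object$data
  if (object$fit_mode == "lineweaver_burk") {
    ggplot2::ggplot(d, ggplot2::aes(x = 1 / .data$conc, y = 1 / .data$rate)) +
      ggplot2::geom_point() +
      ggplot2::geom_abline(
        intercept = 1 / object$vmax,
        slope = object$km / object$vmax
      ) +
      ggplot2::labs(x = "1 / [S] (1/uM)", y = "1 / v (min/uM)",
                    title = "Lineweaver-Burk fit")
  } else {
    grid <- tibble(conc = seq(min(d$conc), max(d$conc), length.out = 200))
    grid$rate <- object$vmax * grid$conc / (object$km + grid$conc)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$conc, y = .data$rate)) +
      ggplot2::geom_point() +
      ggplot2::geom_line(data = grid) +
      ggplot2::labs(x = "[S] (uM)", y = "v (uM/min)",
                    title = "Michaelis-Menten fit")
  }
}

#' Activity relative to a reference substrate
#'
#' Expresses each rate as a percentage of the reference substrate's rate
#' (100 * rate / rate\[reference\]).
#'
#' @param data Data frame with a substrate identifier column and a rate
#'   column.
#' @param substrate,rate Column names (character). Defaults `"substrate"`
#'   and `"rate"`.
#' @param reference Identifier of the reference substrate (default `"C4"`,
#'   i.e. the butyrate ester).
#' @return The input tibble with an added `relative_pct` column.
#' @export
#' @examples
#' relative_activity(
#'   data.frame(substrate = c("C4", "C8", "C16"), rate = c(10, 4.76, 1.33))
#' )
relative_activity <- function(data, substrate = "substrate", rate = "rate",
                              reference = "C4") {
  if (!all(c(substrate, rate) %in% names(data))) {
    abort(paste0("`data` must contain columns `", substrate,
                 "` and `", rate, "`"))
  }
  d <- as_tibble(data)
  ref_rows <- which(d[[substrate]] == reference)
  if (length(ref_rows) != 1) {
    abort(paste0("reference substrate `", reference,
                 "` must occur exactly once"))
  }
  ref_rate <- d[[rate]][ref_rows]
  if (!is.finite(ref_rate) || ref_rate <= 0) {
    abort("reference rate must be > 0")
  }
  d$relative_pct <- 100 * d[[rate]] / ref_rate
  d
}

#' Locate an activity optimum by Gaussian curve fitting
#'
#' Least-squares fit of `y = a * exp(-(x - mu)^2 / (2 * sigma^2))` (zero
#' baseline); `mu` is reported as the optimum, the way temperature and
#' osmolarity optima are interpolated from activity profiles.
#'
#' @param data Data frame with predictor and response columns.
#' @param x,y Column names (character). Defaults `"x"` and `"y"`.
#' @return An object of class `optimum_fit` with `mu`, `sigma`, `amplitude`,
#'   `r_squared`, `data` and the `nls` fit (`model`).
#' @export
#' @examples
#' d <- data.frame(x = seq(10, 45, 5),
#'                 y = exp(-(seq(10, 45, 5) - 20)^2 / 200))
#' gaussian_optimum(d)$mu
gaussian_optimum <- function(data, x = "x", y = "y") {
  if (!all(c(x, y) %in% names(data))) {
    abort(paste0("`data` must contain columns `", x, "` and `", y, "`"))
  }
  d <- tibble(x = as.numeric(data[[x]]), y = as.numeric(data[[y]]))
  if (nrow(d) < 4) abort("at least 4 points are required")
  if (any(d$y < 0)) abort("responses must be >= 0")
  if (max(d$y) - min(d$y) < .Machine$double.eps * 10) {
    abort("all responses equal: no optimum is identifiable")
  }
  mu0 <- sum(d$x * d$y) / sum(d$y)
  sigma0 <- sqrt(sum(d$y * (d$x - mu0)^2) / sum(d$y))
  if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- diff(range(d$x)) / 4
  a0 <- max(d$y)
  fit <- tryCatch(
    nls(y ~ a * exp(-(x - mu)^2 / (2 * sigma^2)), data = d,
        start = list(a = a0, mu = mu0, sigma = sigma0),
        control = stats::nls.control(maxiter = 500, scaleOffset = 1)),
    error = function(e) NULL
  )
  if (is.null(fit)) abort("Gaussian fit did not converge")
  est <- coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((d$y - mean(d$y))^2)
  structure(
    list(mu = unname(est["mu"]), sigma = abs(unname(est["sigma"])),
         amplitude = unname(est["a"]),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         data = d, model = fit),
    class = "optimum_fit"
  )
}

#' @export
print.optimum_fit <- function(x, ...) {
  cat("<optimum_fit> optimum at", format(x$mu),
      "(sigma", format(x$sigma), ", amplitude", format(x$amplitude), ")\n")
  invisible(x)
}

#' @rdname gaussian_optimum
#' @param x,object An `optimum_fit`.
#' @param ... Unused.
#' @export
tidy.optimum_fit <- function(x, ...) {
  tibble(term = c("mu", "sigma", "amplitude"),
         estimate = c(x$mu, x$sigma, x$amplitude))
}

#' @rdname gaussian_optimum
#' @export
glance.optimum_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = nrow(x$data))
}

#' @rdname gaussian_optimum
#' @export
autoplot.optimum_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(x = seq(min(d$x), max(d$x), length.out = 200))
  grid$y <- object$amplitude *
    exp(-(grid$x - object$mu)^2 / (2 * object$sigma^2))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::geom_vline(xintercept = object$mu, linetype = 2) +
    ggplot2::labs(title = "Gaussian optimum fit")
}

#' Enantiomeric ratio of a kinetic resolution
#'
#' Computes the enantiomeric ratio E from conversion and enantiomeric
#' excess by the standard equations for irreversible kinetic resolutions:
#' with conversion `c` and product excess `eeP`,
#' `E = ln(1 - c * (1 + eeP)) / ln(1 - c * (1 - eeP))`; with substrate and
#' product excesses `eeS`, `eeP`, conversion is first recovered as
#' `c = eeS / (eeS + eeP)` and
#' `E = ln((1 - c) * (1 - eeS)) / ln((1 - c) * (1 + eeS))`.
#'
#' @param conversion Conversion in (0, 1) (`c_eeP` mode).
#' @param eeS Substrate enantiomeric excess in \[0, 1) (`eeS_eeP` mode).
#' @param eeP Product enantiomeric excess in \[0, 1).
#' @return An object of class `enantio_result` with `conversion`, `eeS`,
#'   `eeP`, `E` and `input_mode`.
#' @export
#' @examples
#' enantiomeric_ratio(conversion = 0.5, eeP = 0.43)$E  # ~3.74
enantiomeric_ratio <- function(conversion = NULL, eeS = NULL, eeP = NULL) {
  if (is.null(eeP)) abort("`eeP` is required")
  if (eeP < 0 || eeP >= 1) abort("`eeP` must lie in [0, 1)")
  if (!is.null(conversion) && !is.null(eeS)) {
    abort("supply either `conversion` or `eeS`, not both")
  }
  if (!is.null(conversion)) {
    c_ <- conversion
    if (c_ <= 0 || c_ >= 1) abort("`conversion` must lie in (0, 1)")
    num_arg <- 1 - c_ * (1 + eeP)
    den_arg <- 1 - c_ * (1 - eeP)
    if (num_arg <= 0 || den_arg <= 0) {
      abort("inconsistent (conversion, ee) pair: log argument not positive")
    }
    E <- log(num_arg) / log(den_arg)
    out <- list(conversion = c_, eeS = NA_real_, eeP = eeP, E = E,
                input_mode = "c_eeP")
  } else if (!is.null(eeS)) {
    if (eeS < 0 || eeS >= 1) abort("`eeS` must lie in [0, 1)")
    if (eeS + eeP <= 0) abort("`eeS + eeP` must be > 0")
    c_ <- eeS / (eeS + eeP)
    num_arg <- (1 - c_) * (1 - eeS)
    den_arg <- (1 - c_) * (1 + eeS)
    if (num_arg <= 0 || den_arg <= 0 || den_arg >= 1) {
      abort("inconsistent (eeS, eeP) pair: log argument not usable")
    }
    E <- log(num_arg) / log(den_arg)
    out <- list(conversion = c_, eeS = eeS, eeP = eeP, E = E,
                input_mode = "eeS_eeP")
  } else {
    abort("supply `conversion` (c_eeP mode) or `eeS` (eeS_eeP mode)")
  }
  if (is.finite(out$E) && out$E < 1) out$E <- max(out$E, 1)
  structure(out, class = "enantio_result")
}

#' @export
print.enantio_result <- function(x, ...) {
  cat("<enantio_result> E =", format(x$E, digits = 4),
      " (conversion", format(x$conversion, digits = 3),
      ", eeP", format(x$eeP, digits = 3), ")\n")
  invisible(x)
}

#' @rdname enantiomeric_ratio
#' @param x An `enantio_result`.
#' @param ... Unused.
#' @export
tidy.enantio_result <- function(x, ...) {
  tibble(term = c("E", "conversion", "eeS", "eeP"),
         estimate = c(x$E, x$conversion, x$eeS, x$eeP))
}
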
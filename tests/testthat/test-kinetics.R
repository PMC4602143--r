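mm_concs <- c(5, 10, 25, 50, 100, 200, 333)

test_that("the double-reciprocal fit recovers noiseless generators exactly", {
  d <- mm_rates(km = 66.68, vmax = 400, conc = mm_concs)
  fit <- suppressWarnings(fit_lineweaver_burk(d, enzyme_conc = 0.065))
  expect_equal(fit$km, 66.68, tolerance = 1e-9)
  expect_equal(fit$vmax, 400, tolerance = 1e-9)
  expect_equal(fit$kcat, 400 / (60 * 0.065), tolerance = 1e-9)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "km"], 66.68, tolerance = 1e-9)
  expect_error(
    fit_lineweaver_burk(data.frame(conc = c(1, 2), rate = c(0, 1))),
    "rates must be > 0"
  )
})

test_that("specificity constants reproduce the published worked examples", {
  # butyrate: kcat 228 1/s, Km 66.68 uM -> 3.4e6 1/(M s) at 2 s.f.
  expect_equal(signif(specificity_constant(228, 66.68), 2), 3.4e6)
  # palmitate: kcat 45 1/s, Km 68.08 uM -> 6.6e5 1/(M s)
  expect_equal(signif(specificity_constant(45, 68.08), 2), 6.6e5)
  # halving Km doubles specificity at fixed kcat
  expect_equal(specificity_constant(100, 25), 2 * specificity_constant(100, 50))
})

test_that("linear and nonlinear fits agree on noiseless data", {
  d <- mm_rates(km = 68.08, vmax = 50.76, conc = mm_concs)
  lb <- suppressWarnings(fit_lineweaver_burk(d))
  nl <- suppressWarnings(fit_mm_nonlinear(d))
  expect_equal(nl$km, lb$km, tolerance = 1e-6)
  expect_equal(nl$vmax, lb$vmax, tolerance = 1e-6)
  expect_equal(nl$km, 68.08, tolerance = 1e-6)
})

test_that("nonlinear fit stays accurate under multiplicative noise", {
  withr::local_seed(3)
  km <- 66.68; vmax <- 400
  err <- replicate(200, {
    d <- mm_rates(km, vmax, mm_concs)
    d$rate <- d$rate * (1 + stats::rnorm(nrow(d), 0, 0.05))
    fit <- tryCatch(suppressWarnings(fit_mm_nonlinear(d)),
                    error = function(e) NULL)
    if (is.null(fit)) NA_real_ else abs(fit$km - km) / km
  })
  expect_lt(median(err, na.rm = TRUE), 0.15)
})

test_that("relative activity reproduces the chain-length profile", {
  d <- data.frame(substrate = c("C4", "C8", "C16"),
                  rate = c(10, 4.76, 1.33))
  out <- relative_activity(d)
  expect_equal(out$relative_pct[out$substrate == "C4"], 100)
  expect_equal(out$relative_pct[out$substrate == "C8"], 47.6)
  expect_equal(out$relative_pct[out$substrate == "C16"], 13.3)
  expect_error(relative_activity(d, reference = "C10"), "exactly once")
  expect_error(
    relative_activity(data.frame(substrate = "C4", rate = 0)),
    "must be > 0"
  )
})

test_that("gaussian optimum fitting recovers mu and respects symmetry", {
  x <- seq(10, 45, 5)
  d <- data.frame(x = x, y = exp(-(x - 20)^2 / (2 * 10^2)))
  fit <- gaussian_optimum(d)
  expect_equal(fit$mu, 20, tolerance = 1e-6)
  expect_equal(fit$sigma, 10, tolerance = 1e-6)

  # symmetric data about x0 put the optimum at x0
  xs <- c(-3, -1, 1, 3) + 7
  ds <- data.frame(x = xs, y = c(0.2, 0.9, 0.9, 0.2))
  expect_equal(gaussian_optimum(ds)$mu, 7, tolerance = 1e-9)

  # translation equivariance
  d2 <- d; d2$x <- d2$x + 11.5
  expect_equal(gaussian_optimum(d2)$mu, fit$mu + 11.5, tolerance = 1e-6)

  expect_error(gaussian_optimum(data.frame(x = 1:4, y = rep(2, 4))),
               "all responses equal")
})

test_that("gaussian optimum stays near truth under noise", {
  withr::local_seed(5)
  x <- seq(10, 45, 5)
  err <- replicate(100, {
    y <- exp(-(x - 20)^2 / 200) + stats::rnorm(length(x), 0, 0.02)
    fit <- tryCatch(gaussian_optimum(data.frame(x = x, y = pmax(y, 0))),
                    error = function(e) NULL)
    if (is.null(fit)) NA_real_ else abs(fit$mu - 20)
  })
  expect_lt(mean(err, na.rm = TRUE), 1.0)
})

test_that("the enantiomeric ratio follows the conversion/ee equations", {
  # no product excess means no selectivity
  expect_equal(enantiomeric_ratio(conversion = 0.3, eeP = 0)$E, 1)
  # worked example: 50% conversion, 43% product ee
  e <- enantiomeric_ratio(conversion = 0.50, eeP = 0.43)
  expect_equal(e$E, log(1 - 0.5 * 1.43) / log(1 - 0.5 * 0.57),
               tolerance = 1e-12)
  expect_gt(e$E, 3); expect_lt(e$E, 4)
  # E strictly increasing in eeP at fixed conversion
  ees <- seq(0.05, 0.6, 0.05)
  Es <- vapply(ees, function(p) enantiomeric_ratio(conversion = 0.4,
                                                   eeP = p)$E, numeric(1))
  expect_true(all(diff(Es) > 0))
  # the two input modes agree on a self-consistent (c, eeS, eeP) triple
  # generated from the underlying kinetic model (E = 5, c = 0.5):
  E_true <- 5
  cc <- 0.5
  f <- function(eeS) {
    log((1 - cc) * (1 - eeS)) / log((1 - cc) * (1 + eeS)) - E_true
  }
  eeS <- stats::uniroot(f, c(1e-6, 0.999), tol = 1e-12)$root
  eeP <- eeS * (1 - cc) / cc
  via_s <- enantiomeric_ratio(eeS = eeS, eeP = eeP)
  expect_equal(via_s$conversion, cc, tolerance = 1e-9)
  expect_equal(via_s$E, E_true, tolerance = 1e-6)
  via_c <- enantiomeric_ratio(conversion = cc, eeP = eeP)
  expect_equal(via_c$E, E_true, tolerance = 0.05)
  expect_error(enantiomeric_ratio(conversion = 0.9, eeP = 0.9),
               "inconsistent")
})

test_that("kinetics objects expose tidy, glance and autoplot methods", {
  d <- mm_rates(66.68, 400, mm_concs)
  fit <- suppressWarnings(fit_lineweaver_burk(d, enzyme_conc = 0.065))
  expect_named(tidy(fit), c("term", "estimate", "unit"))
  expect_equal(glance(fit)$fit_mode, "lineweaver_burk")
  expect_s3_class(autoplot(fit), "ggplot")
  g <- gaussian_optimum(data.frame(x = seq(0, 30, 5),
                                   y = exp(-(seq(0, 30, 5) - 12)^2 / 50)))
  expect_s3_class(autoplot(g), "ggplot")
  expect_equal(tidy(g)$estimate[1], g$mu)
})
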
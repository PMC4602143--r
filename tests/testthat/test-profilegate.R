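tblout_fixture <- function(lines) {
  tf <- withr::local_tempfile(fileext = ".tbl", .local_envir = parent.frame())
  writeLines(lines, tf)
  tf
}

test_that("tblout parsing keeps the best hit per sequence-model pair", {
  tf <- tblout_fixture(c(
    "# comment line",
    "seq1 - PF00001 acc 1e-06 35.2 0.1 1e-06 34.0 0.1 1 1 0 0 1 1 1 desc",
    "seq1 - PF00001 acc 1e-03 12.0 0.0 1e-03 11.0 0.0 1 1 0 0 1 1 1 desc",
    "seq2 - PF00002 acc 2e-04 20.0 0.0 2e-04 19.0 0.0 1 1 0 0 1 1 1 desc"
  ))
  hits <- parse_tblout(tf)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$evalue[hits$seq_id == "seq1"], 1e-6)
  expect_equal(hits$model_name[hits$seq_id == "seq2"], "PF00002")

  expect_equal(nrow(parse_tblout(tblout_fixture(c("# only", "# comments")))), 0)
  expect_error(
    parse_tblout(tblout_fixture("seq1 - PF1 acc not_a_number 3.0 x x x")),
    "line 1"
  )
})

test_that("annotation filtering partitions ids at the E-value boundary", {
  ids <- c("s1", "s2", "s3")
  hits <- tibble::tibble(seq_id = c("s1", "s2"), model_name = "m",
                         evalue = c(1e-6, 1e-4), score = c(30, 12))
  out <- filter_annotated(ids, hits, evalue_max = 1e-5)
  expect_equal(out$annotated, "s1")      # 1e-6 <= 1e-5: annotated
  expect_setequal(out$unknown, c("s2", "s3"))  # 1e-4 stays unknown
  expect_setequal(c(out$annotated, out$unknown), ids)

  expect_equal(filter_annotated(ids, NULL)$unknown, ids)
  expect_warning(
    out2 <- filter_annotated(c("s1"), tibble::tibble(seq_id = "ghost",
                                                     evalue = 1e-9)),
    "ignored"
  )
  expect_equal(out2$unknown, "s1")
})

test_that("PSSM construction matches the hand-computed toy case", {
  bg_u <- stats::setNames(rep(0.05, 20), lipofam:::AA_LETTERS)
  m <- build_pssm(c("AC", "AD"), pseudocount = 1, background = bg_u)
  # column 1: count A = 2 of 2, pseudocount 1 spread over background
  expect_equal(unname(m$log_odds["A", 1]), log(((2 + 0.05) / 3) / 0.05))
  expect_equal(unname(m$log_odds["C", 2]), log(((1 + 0.05) / 3) / 0.05))
  expect_equal(unname(m$log_odds["W", 2]), log((0.05 / 3) / 0.05))

  # column frequencies equal to background give log-odds 0 everywhere
  # (each row is a rotation, so every column sees all 20 residues once)
  aln <- vapply(0:19, function(k) {
    paste(lipofam:::AA_LETTERS[(seq_len(20) + k - 1) %% 20 + 1],
          collapse = "")
  }, character(1))
  m0 <- build_pssm(aln, pseudocount = 0, background = bg_u)
  expect_true(all(abs(m0$log_odds) < 1e-12))

  # identical sequences, vanishing pseudocount: observed residue maximal
  mi <- build_pssm(c("MKV", "MKV", "MKV"), pseudocount = 1e-9)
  expect_equal(mi$consensus, c("M", "K", "V"))
  expect_true(all(apply(mi$log_odds, 2, which.max) ==
                  match(c("M", "K", "V"), lipofam:::AA_LETTERS)))

  expect_error(build_pssm(c("AC", "ACD")), "equal lengths")
  expect_error(build_pssm("AC"), "at least 2")
})

test_that("gap-heavy columns are dropped", {
  m <- build_pssm(c("A-C", "A-C", "AGC"), pseudocount = 1)
  expect_equal(m$length, 2)
})

test_that("profile scoring equals brute-force window enumeration", {
  withr::local_seed(21)
  aln <- c("MKVLAW", "MKVLAW", "MRVLGW", "MKVIAW")
  m <- build_pssm(aln)
  # consensus scores maximally: no other sequence of that length beats it
  cons <- paste(m$consensus, collapse = "")
  cons_score <- score_sequence(m, cons)
  expect_equal(cons_score, sum(apply(m$log_odds, 2, max)))
  for (rep in 1:10) {
    s <- random_protein(sample(c(1, 3, 8, 15), 1))
    expect_equal(score_sequence(m, s), brute_force_pssm_score(m, s),
                 tolerance = 1e-10)
  }
  # model length 3 against a single-residue sequence: best single column
  m3 <- build_pssm(c("MKV", "MKV"))
  expect_gte(score_sequence(m3, "M"), 0)
  expect_equal(score_sequence(m3, "M"), brute_force_pssm_score(m3, "M"))
})

test_that("calibration is seed-deterministic with monotone E-values", {
  withr::local_seed(2)
  aln <- replicate(6, mutate_sequence(random_protein(30), 3))
  m <- build_pssm(aln)
  cal1 <- calibrate_evalue(m, n_shuffles = 200, seed = 7, db_size = 500,
                           null_length = 60)
  cal2 <- calibrate_evalue(m, n_shuffles = 200, seed = 7, db_size = 500,
                           null_length = 60)
  expect_identical(cal1$gumbel_mu, cal2$gumbel_mu)
  expect_identical(cal1$gumbel_lambda, cal2$gumbel_lambda)
  expect_gt(cal1$gumbel_lambda, 0)
  # E strictly decreasing in score, E(mu) ~ db_size
  s <- seq(0, 60, by = 2)
  ev <- cal1$evalue(s)
  expect_true(all(diff(ev) <= 0))
  inner <- ev[ev < 500 & ev > .Machine$double.xmin]
  expect_true(all(diff(inner) < 0))
  expect_equal(cal1$evalue(cal1$gumbel_mu), 500, tolerance = 1e-9)
  expect_error(calibrate_evalue(m, n_shuffles = 10), ">= 100")
})

test_that("the confirmation gate separates planted from coincidental hits", {
  withr::local_seed(11)
  # model family: well-conserved 40-column profile
  core <- random_protein(40)
  aln <- vapply(1:8, function(i) mutate_sequence(core, 4), character(1))
  m <- build_pssm(aln)
  planted <- paste0(random_protein(20), core, random_protein(20))
  decoy <- random_protein(80)
  seqs <- tibble::tibble(id = c("planted", "decoy"),
                         seq = c(planted, decoy))
  confirmed <- confirm_candidates(c("planted", "decoy"), seqs,
                                  models = list(m), evalue_max = 1e-5,
                                  n_shuffles = 300, seed = 11)
  expect_true("planted" %in% confirmed)
  expect_false("decoy" %in% confirmed)
  # degenerate threshold confirms every motif hit
  all_in <- confirm_candidates(c("planted", "decoy"), seqs,
                               models = list(m), evalue_max = Inf,
                               n_shuffles = 300, seed = 11)
  expect_setequal(as.character(all_in), c("decoy", "planted"))
  # tblout results take precedence over the built-in scorer
  ext <- tibble::tibble(seq_id = "decoy", model_name = "abH",
                        evalue = 1e-9, score = 50)
  via_tbl <- confirm_candidates(c("planted", "decoy"), seqs,
                                domain_hits = ext, evalue_max = 1e-5)
  expect_equal(as.character(via_tbl), "decoy")
  expect_error(confirm_candidates("planted", seqs), "profile source")
})
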
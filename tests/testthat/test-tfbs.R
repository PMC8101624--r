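test_that("TRANSFAC matrices parse, normalize and classify positions", {
  f <- tempfile()
  writeLines(c(
    "ID TFTEST", "P0\tA\tC\tG\tT",
    "01\t97\t1\t1\t1\tA",
    "02\t60\t30\t5\t5\tA",
    "03\t25\t25\t25\t25\tN",
    "04\t1\t1\t1\t97\tT",
    "//"
  ), f)
  pwms <- read_transfac_pwm(f, pseudocount = 0)
  expect_length(pwms, 1L)
  p <- pwms[[1]]
  expect_equal(p$tf_name, "TFTEST")
  expect_equal(p$width, 4L)
  expect_equal(p$position_class,
               c("conserved", "partly_conserved", "unconstrained",
                 "conserved"))
  expect_equal(unname(p$probs["A", 2]), 0.60, tolerance = 1e-12)
  expect_equal(colSums(p$probs), rep(1, 4), ignore_attr = TRUE)
  writeLines(c("ID BAD", "01\t1\tx\t1\t1", "//"), f)
  expect_error(read_transfac_pwm(f), "BAD")
})

test_that("TRANSFAC matrices round-trip through write and read", {
  set.seed(21)
  orig <- lapply(1:3, function(k) pwm(paste0("TF", k), random_pwm_probs(8)))
  f <- tempfile()
  write_transfac_pwm(orig, f)
  back <- read_transfac_pwm(f, pseudocount = 0)
  for (k in 1:3) {
    expect_equal(back[[k]]$tf_name, orig[[k]]$tf_name)
    expect_equal(back[[k]]$probs, orig[[k]]$probs, tolerance = 2e-3)
  }
})

# a sharply conserved PWM matching a given window everywhere except an
# engineered centre column
example_pwm <- function(window, centre, config = enhpro_config()) {
  bases <- strsplit(window, "")[[1]]
  probs <- matrix(0.01, 4, nchar(window),
                  dimnames = list(c("A", "C", "G", "T")))
  for (j in seq_along(bases)) probs[bases[j], j] <- 0.97
  probs[, (nchar(window) + 1) %/% 2] <- centre
  pwm("EX", probs, config)
}

test_that("curation enforces conserved matches and the partial-match cap", {
  cfg <- enhpro_config()
  w <- "ACGTAGCTA"
  # consensus window passes
  p <- example_pwm(w, c(A = 0.97, C = 0.01, G = 0.01, T = 0.01))
  expect_true(curate(w, "+", 1, p, cfg)$pass)
  # one conserved-position mismatch fails clause (a)
  bad <- paste0("T", substr(w, 2, 9))
  cr <- curate(bad, "+", 1, p, cfg)
  expect_false(cr$pass)
  expect_true("conserved_mismatch" %in% cr$reasons)
  # two partly conserved positions carrying >= 20%-of-max non-top bases
  probs <- matrix(0.02, 4, 5, dimnames = list(c("A", "C", "G", "T")))
  probs["A", ] <- 0.94
  probs[, 2] <- c(A = 0.6, C = 0.3, G = 0.05, T = 0.05)
  probs[, 4] <- c(A = 0.6, C = 0.3, G = 0.05, T = 0.05)
  pp <- pwm("PP", probs, cfg)
  one_partial <- curate("ACAAA", "+", 1, pp, cfg)
  expect_true(one_partial$pass)
  two_partial <- curate("ACACA", "+", 1, pp, cfg)
  expect_false(two_partial$pass)
  expect_true("too_many_partial" %in% two_partial$reasons)
  # a base below 20% of the column maximum fails the floor clause
  floor_fail <- curate("AGAAA", "+", 1, pp, cfg)
  expect_false(floor_fail$pass)
  expect_true("below_partial_floor" %in% floor_fail$reasons)
})

test_that("raising the partial-match floor never turns a fail into a pass", {
  set.seed(17)
  for (rep in 1:40) {
    p <- pwm("R", random_pwm_probs(6))
    w <- random_window(6)
    passes <- vapply(c(0.1, 0.2, 0.35, 0.5), function(frac) {
      curate(w, "+", 1, p,
             enhpro_config(partial_match_min_frac = frac))$pass
    }, logical(1))
    # once failed at a lower floor, never passes at a higher one
    expect_true(all(diff(as.integer(passes)) <= 0))
  }
})

test_that("the fivefold centre-probability rule decides allele specificity", {
  cfg <- enhpro_config()
  w_ref <- "ACGTAGCTA"                     # centre base A
  w_alt <- apply_allele(w_ref, "G")
  # centre probs A 0.50 / G 0.05: tenfold, favouring Ref
  p10 <- example_pwm(w_ref, c(A = 0.50, C = 0.225, G = 0.05, T = 0.225))
  sc <- scan_allele_pair(w_ref, w_alt, p10, cfg)
  hit <- sc[sc$strand == "+" & sc$offset == 1, ]
  expect_equal(hit$fold_change, 10, tolerance = 1e-12)
  expect_equal(hit$favored_allele, "ref")
  expect_true(hit$allele_specific)
  # centre probs A 0.50 / G 0.12: fold ~4.17, below the rule
  p4 <- example_pwm(w_ref, c(A = 0.50, C = 0.19, G = 0.12, T = 0.19))
  sc4 <- scan_allele_pair(w_ref, w_alt, p4, cfg)
  expect_equal(sc4$fold_change[sc4$strand == "+" & sc4$offset == 1],
               0.50 / 0.12, tolerance = 1e-12)
  expect_false(any(sc4$allele_specific))
  # identical alleles: fold 1 everywhere, nothing allele-specific
  sc_id <- scan_allele_pair(w_ref, w_ref, p10, cfg)
  expect_true(all(sc_id$fold_change == 1))
  expect_false(any(sc_id$allele_specific))
})

test_that("the scanner equals a brute-force scanner on random inputs", {
  set.seed(2026)
  cfg <- enhpro_config()
  for (rep in 1:200) {
    W <- sample(4:12, 1)
    L <- sample(c(13L, 17L, 21L), 1)
    probs <- random_pwm_probs(W)
    p <- pwm("BF", probs, cfg)
    w_ref <- random_window(L)
    ctr <- (L + 1) %/% 2
    alt <- sample(setdiff(c("A", "C", "G", "T"),
                          substr(w_ref, ctr, ctr)), 1)
    w_alt <- apply_allele(w_ref, alt)
    got <- scan_allele_pair(w_ref, w_alt, p, cfg)
    want <- naive_scan(w_ref, w_alt, p$probs)
    g <- got[order(got$strand, got$offset), ]
    w <- want[order(want$strand, want$offset), ]
    expect_equal(nrow(g), nrow(w))
    expect_equal(g$fold_change, w$fold_change, tolerance = 1e-12)
    expect_equal(g$favored_allele, w$favored_allele)
    expect_equal(g$ref_curation_pass, w$ref_pass)
    expect_equal(g$alt_curation_pass, w$alt_pass)
    expect_equal(g$allele_specific, w$allele_specific)
    # returned order is by decreasing favoured-allele log-probability
    expect_true(all(diff(got$favored_logp) <= 1e-12))
  }
})

test_that("scanning is strand-symmetric and allele-swap covariant", {
  set.seed(404)
  cfg <- enhpro_config()
  for (rep in 1:25) {
    p <- pwm("S", random_pwm_probs(sample(4:9, 1)))
    w_ref <- random_window(15)
    alt <- sample(setdiff(c("A", "C", "G", "T"), substr(w_ref, 8, 8)), 1)
    w_alt <- apply_allele(w_ref, alt)
    sc <- scan_allele_pair(w_ref, w_alt, p, cfg)
    # reverse-complement everything: same fold-change multiset
    rc <- scan_allele_pair(enhpro:::revcomp(w_ref), enhpro:::revcomp(w_alt),
                           pwm_reverse_complement(p), cfg)
    expect_equal(sort(sc$fold_change), sort(rc$fold_change),
                 tolerance = 1e-12)
    # swapping ref and alt flips the favoured allele, keeps the fold
    sw <- scan_allele_pair(w_alt, w_ref, p, cfg)
    key <- function(d) d[order(d$strand, d$offset), ]
    a <- key(sc); b <- key(sw)
    expect_equal(a$fold_change, b$fold_change, tolerance = 1e-12)
    uneq <- a$ref_center_prob != a$alt_center_prob
    expect_equal(a$favored_allele[uneq] == "ref",
                 b$favored_allele[uneq] == "alt")
  }
})

test_that("the TF expression gate is inclusive at its threshold", {
  m <- matrix(c(0.8, 0.79, 0), 3, 1,
              dimnames = list(c("TFA", "TFB", "TFC"), "ostb"))
  cfg <- enhpro_config()
  expect_true(tf_expressed("TFA", m, "ostb", cfg))
  expect_false(tf_expressed("TFB", m, "ostb", cfg))
  expect_false(tf_expressed("TFC", m, "ostb", cfg))
  expect_message(ok <- tf_expressed("MISSING", m, "ostb", cfg), "absent")
  expect_false(ok)
})

test_that("variant-level prediction combines scan, curation and the gate", {
  cfg <- enhpro_config()
  set.seed(55)
  ctg <- random_window(41)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">ctg", ctg), fa)
  asm <- read_genome(fa)
  pos <- 21L
  ref <- substr(ctg, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  w <- fetch_window(asm, "ctg", pos, 21)
  # engineered sixfold ref-favouring centre column
  bases <- strsplit(substr(w, 7, 15), "")[[1]]
  probs <- matrix(0.01, 4, 9, dimnames = list(c("A", "C", "G", "T")))
  for (j in 1:9) probs[bases[j], j] <- 0.97
  centre <- setNames(rep((1 - 0.48 - 0.08) / 2, 4), c("A", "C", "G", "T"))
  centre[ref] <- 0.48; centre[alt] <- 0.08
  probs[, 5] <- centre
  p6 <- pwm("TF6", probs, cfg)
  expr <- matrix(5, 1, 1, dimnames = list("TF6", "ostb"))
  v <- variant_set("rsX", "ctg", pos, ref, alt)
  out <- predict_allele_specific_tfbs(v, asm, list(p6), expr, "ostb", cfg)
  expect_equal(out$tf_name, "TF6")
  expect_equal(out$favored_allele, "ref")
  # the same prediction is silenced when the TF is not expressed
  expr0 <- matrix(0.1, 1, 1, dimnames = list("TF6", "ostb"))
  out0 <- suppressMessages(
    predict_allele_specific_tfbs(v, asm, list(p6), expr0, "ostb", cfg))
  expect_equal(nrow(out0), 0L)
  # allele-orientation errors are detected
  v_bad <- variant_set("rsY", "ctg", pos, alt, ref)
  expect_error(predict_allele_specific_tfbs(v_bad, asm, list(p6), expr,
                                            "ostb", cfg),
               "orientation")
})
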
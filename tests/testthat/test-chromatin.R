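# in-memory toy tracks for EnhPro classification
toy_tracks <- function() {
  others <- paste0("ct", 1:12)
  seg <- function(cell, state_rows) {
    df <- do.call(rbind, state_rows)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end),
                                 state = as.integer(df$state))
    structure(list(cell_type = cell, gr = gr), class = "segmentation_track")
  }
  peak <- function(cell, mark, rows) {
    if (is.null(rows)) {
      gr <- GenomicRanges::GRanges()
    } else {
      df <- do.call(rbind, rows)
      gr <- GenomicRanges::GRanges(df$chrom,
                                   IRanges::IRanges(df$start, df$end))
    }
    structure(list(cell_type = cell, mark = mark, gr = gr),
              class = "peak_track")
  }
  strong <- data.frame(chrom = "chr1", start = 900, end = 1100, state = 9)
  quies <- data.frame(chrom = "chr1", start = 1, end = 899, state = 15)
  segs <- c(
    list(ostb = seg("ostb", list(quies, strong))),
    stats::setNames(lapply(others, function(ct) {
      # first three comparison types share the strong segment
      if (ct %in% c("ct1", "ct2", "ct3")) seg(ct, list(strong))
      else seg(ct, list(quies))
    }), others)
  )
  pk <- data.frame(chrom = "chr1", start = 950, end = 1050)
  k27 <- c(
    list(ostb = peak("ostb", "H3K27ac", list(pk))),
    stats::setNames(lapply(others, function(ct) {
      if (ct %in% c("ct1", "ct2", "ct3")) peak(ct, "H3K27ac", list(pk))
      else peak(ct, "H3K27ac", NULL)
    }), others)
  )
  dhs <- peak("ostb", "DHS", list(pk))
  list(others = others, segs = segs, k27 = k27, dhs = dhs)
}

test_that("strong regulatory chromatin is states 1/3/8/9", {
  cfg <- enhpro_config()
  expect_true(is_strong_regulatory(1L, cfg))
  expect_true(all(is_strong_regulatory(c(3L, 8L, 9L), cfg)))
  expect_false(is_strong_regulatory(15L, cfg))
  expect_false(is_strong_regulatory(NA_integer_, cfg))
})

test_that("EnhPro calls implement the sharing thresholds and conjunction", {
  tt <- toy_tracks()
  v <- variant_set("rs_t", "chr1", 1000L, "A", "G", pvalue = 1e-10)
  cfg <- enhpro_config()
  # strong in focal and exactly 3 others, K27ac/DHS in focal: EnhPro
  rec <- classify_enhpro(v, "ostb", tt$others, tt$segs, tt$k27, tt$dhs, cfg)
  expect_equal(rec$n_other_strong, 3L)
  expect_equal(rec$n_other_k27ac, 3L)
  expect_true(rec$is_enhpro)
  # strong in a 4th comparison type: fails the default threshold
  tt4 <- tt
  tt4$segs$ct4 <- tt$segs$ct1
  rec4 <- classify_enhpro(v, "ostb", tt$others, tt4$segs, tt$k27, tt$dhs,
                          cfg)
  expect_equal(rec4$n_other_strong, 4L)
  expect_false(rec4$is_enhpro)
  # a variant failing only the K27ac sharing count at 4 passes when the
  # relaxed threshold is used
  tt_k <- tt
  tt_k$k27$ct4 <- tt$k27$ct1
  rec_k3 <- classify_enhpro(v, "ostb", tt$others, tt$segs, tt_k$k27,
                            tt$dhs, cfg)
  expect_false(rec_k3$is_enhpro)
  rec_k4 <- classify_enhpro(v, "ostb", tt$others, tt$segs, tt_k$k27,
                            tt$dhs, enhpro_config(k27ac_max_other = 4))
  expect_true(rec_k4$is_enhpro)
  # no focal DHS vetoes regardless of all other evidence
  no_dhs <- tt$dhs
  no_dhs$gr <- GenomicRanges::GRanges()
  rec_d <- classify_enhpro(v, "ostb", tt$others, tt$segs, tt$k27, no_dhs,
                           cfg)
  expect_false(rec_d$is_enhpro)
  # comparison panels of unexpected size warn
  expect_warning(
    classify_enhpro(v, "ostb", tt$others[1:3],
                    tt$segs[c("ostb", "ct1", "ct2", "ct3")],
                    tt$k27[c("ostb", "ct1", "ct2", "ct3")], tt$dhs, cfg),
    "12 expected")
})

test_that("raising sharing thresholds never shrinks the EnhPro set", {
  res <- sim_run()
  sim <- sim_bundle()
  inputs <- sim$inputs
  segs <- lapply(names(inputs$segmentations), function(ct) {
    read_segmentation_bed(inputs$segmentations[[ct]], ct)
  })
  names(segs) <- names(inputs$segmentations)
  k27 <- lapply(names(inputs$k27ac), function(ct) {
    read_narrowpeak(inputs$k27ac[[ct]], ct, "H3K27ac")
  })
  names(k27) <- names(inputs$k27ac)
  dhs <- read_narrowpeak(inputs$dhs, inputs$focal, "DHS")
  variants <- res$variants
  sets <- lapply(c(3L, 4L, 6L), function(k) {
    rec <- classify_enhpro(variants, inputs$focal, inputs$others_chromatin,
                           segs, k27, dhs,
                           enhpro_config(state_max_other = k,
                                         k27ac_max_other = k))
    rec$rsid[rec$is_enhpro]
  })
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})

test_that("stored EnhPro evidence reproduces the stored flag", {
  rec <- sim_run()$enhpro
  cfg <- enhpro_config()
  recomputed <- rec$focal_strong &
    rec$n_other_strong <= cfg$state_max_other &
    rec$k27ac_focal &
    rec$n_other_k27ac <= cfg$k27ac_max_other &
    rec$dhs_focal
  expect_identical(recomputed, rec$is_enhpro)
})

test_that("EnhPro calls equal a linear-scan reimplementation", {
  sim <- sim_bundle()
  inputs <- sim$inputs
  res <- sim_run()
  variants <- res$variants
  # naive per-variant evidence from raw BED/narrowPeak files
  seg_raw <- lapply(inputs$segmentations, function(p) {
    df <- utils::read.table(p, sep = "\t", stringsAsFactors = FALSE)
    names(df) <- c("chrom", "start", "end", "name")
    df$state <- as.integer(sub("_.*$", "", df$name))
    df
  })
  pk_raw <- lapply(inputs$k27ac, function(p) {
    df <- utils::read.table(p, sep = "\t", stringsAsFactors = FALSE)
    names(df)[1:3] <- c("chrom", "start", "end")
    df
  })
  dhs_raw <- utils::read.table(inputs$dhs, sep = "\t",
                               stringsAsFactors = FALSE)
  names(dhs_raw)[1:3] <- c("chrom", "start", "end")
  in_bed <- function(df, chrom, pos) {
    any(df$chrom == chrom & df$start <= pos - 1 & pos - 1 < df$end)
  }
  cfg <- enhpro_config()
  naive <- vapply(seq_len(nrow(variants)), function(i) {
    ch <- variants$chrom[i]; p <- variants$pos[i]
    sdf <- seg_raw[[inputs$focal]]
    hit <- sdf[sdf$chrom == ch & sdf$start <= p - 1 & p - 1 < sdf$end, ]
    fs <- nrow(hit) > 0 && hit$state[1] %in% cfg$strong_states
    nos <- sum(vapply(inputs$others_chromatin, function(ct) {
      sdf <- seg_raw[[ct]]
      hit <- sdf[sdf$chrom == ch & sdf$start <= p - 1 & p - 1 < sdf$end, ]
      nrow(hit) > 0 && hit$state[1] %in% cfg$strong_states
    }, logical(1)))
    kf <- in_bed(pk_raw[[inputs$focal]], ch, p)
    nok <- sum(vapply(inputs$others_chromatin, function(ct) {
      in_bed(pk_raw[[ct]], ch, p)
    }, logical(1)))
    df <- in_bed(dhs_raw, ch, p)
    fs && nos <= cfg$state_max_other && kf &&
      nok <= cfg$k27ac_max_other && df
  }, logical(1))
  expect_identical(res$enhpro$is_enhpro, naive)
})

test_that("chromatin display labels distinguish promoter/enhancer context", {
  lines <- c("chr1\t800\t1000\t9_EnhA1", "chr1\t1000\t1080\t1_TssA",
             "chr1\t5000\t5400\t1_TssA", "chr1\t9000\t9400\t9_EnhA1")
  f <- tempfile()
  writeLines(lines, f)
  track <- read_segmentation_bed(f, "ostb")
  v <- variant_set(c("a", "b", "c", "d"), "chr1",
                   c(950L, 5200L, 9200L, 20000L), "A", "G")
  expect_equal(chromatin_state_label(v, track),
               c("Str enh/prom", "Str prom", "Str enh", ""))
})
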
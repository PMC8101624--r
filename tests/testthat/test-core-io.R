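write_tsv_text <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

assoc_header <- "rsid\tchrom\tpos\tref\talt\tpvalue\treported_genes"

test_that("association reader applies the significance threshold", {
  path <- write_tsv_text(c(
    assoc_header,
    "rs1\tchr1\t100\tA\tG\t1e-9\tGENE1",
    "rs2\tchr1\t200\tC\tT\t1e-7\tGENE2",
    "rs3\tchr1\t300\tG\tA\t4.9e-8\tGENE3"
  ))
  v <- read_association_table(path, 5e-8)
  expect_equal(v$rsid, c("rs1", "rs3"))
  expect_true(all(v$source == "index"))
  # the stricter imputed eBMD threshold keeps only the strongest signal
  v2 <- read_association_table(path, 6.6e-9)
  expect_equal(v2$rsid, "rs1")
  # empty data section is not an error
  v3 <- read_association_table(write_tsv_text(assoc_header), 5e-8)
  expect_equal(nrow(v3), 0L)
})

test_that("association reader reports format problems precisely", {
  path <- write_tsv_text(c("rsid\tchrom\tpos\tref\talt\tpvalue",
                           "rs1\tchr1\t100\tA\tG\t1e-9"))
  expect_error(read_association_table(path, 5e-8), "reported_genes")
  bad <- write_tsv_text(c(assoc_header,
                          "rs1\tchr1\t100\tA\tG\tnot_a_p\tG1"))
  expect_error(read_association_table(bad, 5e-8), "line 2")
  indel <- write_tsv_text(c(assoc_header,
                            "rs1\tchr1\t100\tAT\tG\t1e-9\tG1",
                            "rs2\tchr1\t200\tC\tT\t1e-9\tG2"))
  expect_message(v <- read_association_table(indel, 5e-8), "1 non-SNV")
  expect_equal(v$rsid, "rs2")
})

test_that("segmentation reader accepts both state-label dialects", {
  p1 <- write_tsv_text("chr1\t100\t200\t9_EnhA1")
  tr <- read_segmentation_bed(p1, "ostb")
  expect_s3_class(tr, "segmentation_track")
  expect_equal(S4Vectors::mcols(tr$gr)$state, 9L)
  expect_equal(GenomicRanges::start(tr$gr), 101L)  # 1-based internally
  expect_equal(GenomicRanges::end(tr$gr), 200L)
  p2 <- write_tsv_text("chr1\t100\t200\t15")
  expect_equal(S4Vectors::mcols(read_segmentation_bed(p2, "x")$gr)$state, 15L)
  p3 <- write_tsv_text("chr1\t100\t200\tEnhancer")
  expect_error(read_segmentation_bed(p3, "x"), "Enhancer")
})

test_that("segmentations must partition each contig", {
  p <- write_tsv_text(c("chr1\t100\t200\t1_TssA", "chr1\t150\t250\t5_Tx"))
  expect_error(read_segmentation_bed(p, "x"), "overlap")
  # touching intervals are fine
  p2 <- write_tsv_text(c("chr1\t100\t200\t1_TssA", "chr1\t200\t250\t5_Tx"))
  expect_equal(length(read_segmentation_bed(p2, "x")$gr), 2L)
})

test_that("narrowPeak reader follows the BED6+4 conventions", {
  line10 <- "chr1\t100\t400\tpeak1\t800\t.\t12.5\t-1\t-1\t150"
  p <- write_tsv_text(line10)
  tr <- read_narrowpeak(p, "ostb", "H3K27ac")
  expect_equal(S4Vectors::mcols(tr$gr)$summit, 150L)
  # summit -1 means absent
  p2 <- write_tsv_text("chr1\t100\t400\tpeak1\t800\t.\t12.5\t-1\t-1\t-1")
  expect_true(is.na(S4Vectors::mcols(read_narrowpeak(p2, "x")$gr)$summit))
  # peaks may overlap: every input line is retained
  p3 <- write_tsv_text(c(line10,
                         "chr1\t300\t600\tpeak2\t700\t.\t9.1\t-1\t-1\t30"))
  expect_equal(length(read_narrowpeak(p3, "x")$gr), 2L)
  p4 <- write_tsv_text("chr1\t100\t400\tpeak1\t800\t.\t12.5\t-1\t-1")
  expect_error(read_narrowpeak(p4, "x"), "10")
})

test_that("every format round-trips exactly", {
  dir <- tempfile(); dir.create(dir)
  seg <- read_segmentation_bed(
    write_tsv_text(c("chr1\t0\t5000\t18_Quies", "chr1\t5000\t5400\t9_EnhA1",
                     "chr2\t10\t40\t1_TssA")), "ostb")
  f <- file.path(dir, "seg.bed")
  write_segmentation_bed(seg, f)
  seg2 <- read_segmentation_bed(f, "ostb")
  expect_identical(as.data.frame(seg$gr), as.data.frame(seg2$gr))

  pk <- read_narrowpeak(
    write_tsv_text(c("chr1\t100\t400\tp1\t800\t.\t12.5\t-1\t-1\t150",
                     "chr1\t300\t600\tp2\t700\t.\t9.1\t-1\t-1\t-1")),
    "ostb", "DHS")
  f <- file.path(dir, "pk.narrowPeak")
  write_narrowpeak(pk, f)
  pk2 <- read_narrowpeak(f, "ostb", "DHS")
  expect_equal(as.data.frame(pk$gr), as.data.frame(pk2$gr))

  v <- variant_set(c("rs1", "rs2"), "chr1", c(100L, 300L), c("A", "C"),
                   c("G", "T"), pvalue = c(1e-12, 3e-9),
                   reported_genes = c("G1", "G1,G2"))
  f <- file.path(dir, "assoc.tsv")
  write_association_table(v, f)
  v2 <- read_association_table(f, Inf)
  expect_equal(v2$rsid, v$rsid)
  expect_equal(v2$pvalue, v$pvalue)
  expect_equal(v2$reported_genes, v$reported_genes)

  m <- matrix(c(1.5, 0, 42.25, 7), 2, 2,
              dimnames = list(c("g1", "g2"), c("ostb", "fib")))
  f <- file.path(dir, "expr.tsv")
  write_expression_table(m, f)
  expect_equal(read_expression_table(f), m)

  genes <- data.frame(gene_id = c("GA", "GB"), chrom = c("chr1", "chr2"),
                      tss = c(1000L, 9000L), strand = c("+", "-"),
                      start = c(1000L, 5000L), end = c(4000L, 9000L),
                      stringsAsFactors = FALSE)
  f <- file.path(dir, "genes.gtf")
  write_gene_models(genes, f)
  g2 <- read_gene_models(f)
  expect_equal(g2[order(g2$gene_id), ], genes, ignore_attr = TRUE)
})

test_that("window fetching is centred, bounded and allele-aware", {
  fa <- tempfile(fileext = ".fa")
  set.seed(11)
  contig <- random_window(21)
  writeLines(c(">ctg", contig), fa)
  asm <- read_genome(fa)
  # pos 11 on a 21-base contig: the window is the whole contig
  expect_equal(fetch_window(asm, "ctg", 11, 21), contig)
  expect_error(fetch_window(asm, "ctg", 10, 21), "out of bounds")
  expect_error(fetch_window(asm, "missing", 10, 21), "not in assembly")
  # centre base always equals the assembly base at pos
  for (pos in 3:19) {
    w <- fetch_window(asm, "ctg", pos, 5)
    expect_equal(substr(w, 3, 3), substr(contig, pos, pos))
  }
  w <- apply_allele("AAAAAAAAAACAAAAAAAAAA", "T")
  expect_equal(substr(w, 11, 11), "T")
  # involution on the centre base; all other positions untouched
  orig <- fetch_window(asm, "ctg", 11, 21)
  again <- apply_allele(apply_allele(apply_allele(orig, "G"),
                                     substr(orig, 11, 11)), substr(orig, 11, 11))
  expect_equal(again, orig)
  for (i in setdiff(1:21, 11)) {
    expect_equal(substr(apply_allele(orig, "G"), i, i),
                 substr(orig, i, i))
  }
})

test_that("N in a fetched window warns but is returned", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">ctg", "AAAANAAAA"), fa)
  asm <- read_genome(fa)
  expect_warning(w <- fetch_window(asm, "ctg", 5, 3), "contains N")
  expect_equal(w, "ANA")
})

test_that("variant-interval overlap follows the 0-based half-open law", {
  # explicit boundary cases
  tr <- read_segmentation_bed(
    write_tsv_text("chr1\t100\t200\t9_EnhA1"), "ostb")
  st <- function(pos) {
    state_at(variant_set("q", "chr1", pos, "A", "G"), tr)$state
  }
  expect_equal(st(150), 9L)
  expect_true(is.na(st(100)))  # pos-1 = 99 < start
  expect_equal(st(101), 9L)
  expect_equal(st(200), 9L)
  expect_true(is.na(st(201)))
  # 1,000 random (variant, interval) queries against a linear scan
  set.seed(42)
  bed0 <- random_disjoint_bed(60, 99000)
  lines <- sprintf("chr1\t%d\t%d\t%d", bed0$start, bed0$end, bed0$state)
  track <- read_segmentation_bed(write_tsv_text(lines), "ostb")
  pos <- sample(1:100000, 1000, replace = TRUE)
  v <- variant_set(paste0("q", seq_along(pos)), "chr1", pos,
                   "A", "G")
  got <- state_at(v, track)$state
  want <- vapply(pos, naive_state_at, integer(1), bed0 = bed0)
  expect_identical(got, want)
})

test_that("config validates thresholds and reads YAML", {
  expect_error(enhpro_config(tfbs_window = 20), "odd")
  expect_error(enhpro_config(r2_threshold = -1), "positive")
  expect_error(enhpro_config(strong_states = c(1, 19)), "1..18")
  y <- tempfile(fileext = ".yaml")
  writeLines(c("k27ac_max_other: 4", "expr_ratio_min: 5"), y)
  cfg <- read_config(y)
  expect_equal(cfg$k27ac_max_other, 4L)
  writeLines("no_such_knob: 1", y)
  expect_error(read_config(y), "no_such_knob")
})
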
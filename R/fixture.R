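#' Deterministic miniature benchmark bundle
#'
#' Builds a self-contained miniature genome encoding the published
#' 14-SNP/five-gene benchmark: gene models for BICC1, NPR3, LGR4, HMGA2 and
#' DAAM2 on five 500-kb contigs, the 14 prioritized SNPs placed at offsets
#' reproducing the printed distance-to-TSS values, chromatin segmentations,
#' H3K27ac/DHS peaks, expression, genotype panel, imputed tables and PWMs
#' constructed so each SNP's evidence matches its published row. The three
#' DAAM2 SNPs share an H3K27ac peak with exactly 4 comparison cell types,
#' so they enter the report only under the relaxed sharing threshold
#' (`k27ac_max_other = 4`); the three imputed-only SNPs enter via the
#' imputed tables at their per-trait thresholds. Decoy SNPs that each fail
#' exactly one criterion are included and must never be reported.
#'
#' The fixture is deterministic: an internal fixed seed drives the filler
#' sequence, so repeated calls produce byte-identical bundles.
#'
#' @param dir output directory (created if needed).
#' @return A list with `dir`, `inputs` (manifest, see
#'   [read_input_bundle()]) and `snps` (the construction table: one row per
#'   planted SNP with its gene, source class and expected TF calls).
#' @export
make_table1_fixture <- function(dir = tempfile("enhpro_fixture_")) {
  local_seed(1759L, make_table1_fixture_impl(dir))
}

fixture_snp_table <- function() {
  # gene, contig, rsid, offset of SNP from TSS (bp), ref, alt,
  # in I/P association table, imputed table (none/dxa/ebmd),
  # TF predictions "name:side" separated by ";"
  txt <- c(
    "BICC1|chr10|rs112597538|-100|T|C|yes|none|SREBF1/2:ref",
    "BICC1|chr10|rs1896245|3200|T|G|yes|ebmd|SATB1:ref",
    "BICC1|chr10|rs1896243|3500|C|T|yes|ebmd|TCF3:alt",
    "BICC1|chr10|rs11006188|60600|G|C|no|dxa|SMAD:ref;GLIS3:ref;NR2F6:alt",
    "BICC1|chr10|rs1982173|61200|G|T|no|dxa|RBPJ:ref",
    "NPR3|chr5|rs1173771|104300|A|G|yes|none|SATB1:ref",
    "NPR3|chr5|rs7733331|118100|T|C|yes|none|GTF2I:ref",
    "LGR4|chr11|rs10835153|-181000|A|T|yes|ebmd|BPTF:alt",
    "HMGA2|chr12|rs80019710|-231100|C|T|no|ebmd|HMGA1:alt",
    "HMGA2|chr12|rs17101510|-231000|C|T|yes|ebmd|YY1:alt",
    "HMGA2|chr12|rs12296417|-230500|T|A|yes|ebmd|SATB1:alt;ZBTB20:alt",
    "DAAM2|chr6|rs2504105|62400|A|G|yes|ebmd|SMAD:ref",
    "DAAM2|chr6|rs2504104|62440|A|G|yes|ebmd|RUNX2/1:alt;CBFB:alt",
    "DAAM2|chr6|rs2504103|62500|C|G|yes|ebmd|NFIC:alt"
  )
  f <- do.call(rbind, strsplit(txt, "|", fixed = TRUE))
  data.frame(
    gene = f[, 1], chrom = f[, 2], rsid = f[, 3],
    offset = as.integer(f[, 4]), ref = f[, 5], alt = f[, 6],
    in_ip = f[, 7] == "yes", imputed = f[, 8], tfs = f[, 9],
    stringsAsFactors = FALSE
  )
}

make_table1_fixture_impl <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- enhpro_config()
  focal <- "ostb"
  others <- c("fib_skin", "fib_lung_adult", "fib_lung_fetal",
              "kera_foreskin", "kera_dermal", "melanocyte", "astrocyte",
              "huvec", "myoblast", "hmec", "esc", "lcl")
  others_expr <- others[1:11]
  contig_len <- 500000L
  tss <- 250000L
  genes5 <- data.frame(
    gene_id = c("BICC1", "NPR3", "LGR4", "HMGA2", "DAAM2"),
    chrom = c("chr10", "chr5", "chr11", "chr12", "chr6"),
    tss = tss, strand = "+", start = tss, end = tss + 20000L,
    stringsAsFactors = FALSE
  )
  contigs <- genes5$chrom
  contig_lengths <- stats::setNames(rep(contig_len, 5L), contigs)
  genome <- stats::setNames(
    vapply(contigs, function(x) random_seq(contig_len), character(1)),
    contigs)

  snps <- fixture_snp_table()
  snps$pos <- tss + snps$offset
  # decoys, each failing exactly one criterion
  decoys <- data.frame(
    rsid = c("rs_decoy_nodhs", "rs_decoy_k27shared", "rs_decoy_fold"),
    chrom = c("chr10", "chr5", "chr11"), pos = 150000L,
    gene = c("BICC1", "NPR3", "LGR4"),
    tf = c("TF_DECOY_A", "TF_DECOY_B", "TF_DECOY_FOLD"),
    kind = c("as", "as", "fold_below"), stringsAsFactors = FALSE
  )
  # plant the printed Ref alleles into the genome
  for (i in seq_len(nrow(snps))) {
    substring(genome[snps$chrom[i]], snps$pos[i], snps$pos[i]) <- snps$ref[i]
  }
  decoys$ref <- unname(substring(genome[decoys$chrom], decoys$pos,
                                 decoys$pos))
  decoys$alt <- vapply(decoys$ref, other_base, character(1))

  # --- chromatin ----------------------------------------------------------
  seg_focal <- rbind(
    # BICC1: strong promoter at the TSS-proximal SNP, a promoter island
    # between the +3.2 kb and +3.5 kb enhancer SNPs, enhancers downstream
    data.frame(chrom = "chr10", start = 249700L, end = 250050L, state = 1L),
    data.frame(chrom = "chr10", start = 253100L, end = 253229L, state = 9L),
    data.frame(chrom = "chr10", start = 253230L, end = 253270L, state = 1L),
    data.frame(chrom = "chr10", start = 253400L, end = 253600L, state = 9L),
    data.frame(chrom = "chr10", start = 310400L, end = 310800L, state = 9L),
    data.frame(chrom = "chr10", start = 311000L, end = 311400L, state = 9L),
    data.frame(chrom = "chr10", start = 149800L, end = 150200L, state = 9L),
    data.frame(chrom = "chr5", start = 354100L, end = 354500L, state = 9L),
    data.frame(chrom = "chr5", start = 367900L, end = 368300L, state = 9L),
    data.frame(chrom = "chr5", start = 149800L, end = 150200L, state = 9L),
    data.frame(chrom = "chr11", start = 68800L, end = 69200L, state = 9L),
    data.frame(chrom = "chr11", start = 149800L, end = 150200L, state = 9L),
    data.frame(chrom = "chr12", start = 18700L, end = 19700L, state = 9L),
    # DAAM2: mixed enhancer/promoter chromatin across the SNP cluster
    data.frame(chrom = "chr6", start = 312300L, end = 312419L, state = 9L),
    data.frame(chrom = "chr6", start = 312420L, end = 312459L, state = 1L),
    data.frame(chrom = "chr6", start = 312460L, end = 312700L, state = 9L)
  )
  share_state_types <- c("fib_skin", "hmec")
  strong_by_ct <- stats::setNames(
    c(list(seg_focal), lapply(others, function(ct) {
      if (ct %in% share_state_types) seg_focal else seg_focal[0, ]
    })), c(focal, others))

  all_pts <- rbind(snps[, c("chrom", "pos")], decoys[, c("chrom", "pos")])
  peaks_all <- data.frame(chrom = all_pts$chrom,
                          start = all_pts$pos - 150L,
                          end = all_pts$pos + 150L, stringsAsFactors = FALSE)
  is_daam2 <- c(snps$gene == "DAAM2", rep(FALSE, nrow(decoys)))
  is_k27_decoy <- c(rep(FALSE, nrow(snps)),
                    decoys$rsid == "rs_decoy_k27shared")
  share_k27 <- list(
    base = c("fib_skin", "hmec"),
    daam2 = c("fib_skin", "hmec", "astrocyte", "lcl"),
    decoy = c("fib_skin", "hmec", "astrocyte", "lcl", "esc")
  )
  k27_by_ct <- stats::setNames(lapply(c(focal, others), function(ct) {
    if (ct == focal) return(peaks_all)
    take <- (ct %in% share_k27$base & !is_daam2 & !is_k27_decoy) |
      (ct %in% share_k27$daam2 & is_daam2) |
      (ct %in% share_k27$decoy & is_k27_decoy)
    peaks_all[take, , drop = FALSE]
  }), c(focal, others))
  dhs_rows <- peaks_all[c(rep(TRUE, nrow(snps)),
                          decoys$rsid != "rs_decoy_nodhs"), , drop = FALSE]

  # --- expression ---------------------------------------------------------
  tf_names <- unique(c(sub(":[^:]*$", "", unlist(strsplit(snps$tfs, ";"))),
                       decoys$tf))
  expr_cols <- c(focal, others)
  gene_expr <- rbind(
    BICC1 = c(42, rep(1, 12)), NPR3 = c(30, rep(1, 12)),
    LGR4 = c(25, rep(1, 12)), HMGA2 = c(2, rep(1, 12)),
    DAAM2 = c(21, rep(1, 12))
  )
  tf_expr <- matrix(rep(c(5, rep(1, 12)), length(tf_names)),
                    nrow = length(tf_names), byrow = TRUE,
                    dimnames = list(tf_names, NULL))
  expr <- rbind(gene_expr, tf_expr)
  colnames(expr) <- expr_cols

  # --- PWMs ---------------------------------------------------------------
  pwm_specs <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i) {
    parts <- strsplit(strsplit(snps$tfs[i], ";")[[1]], ":", fixed = TRUE)
    data.frame(rsid = snps$rsid[i], chrom = snps$chrom[i],
               pos = snps$pos[i], ref = snps$ref[i], alt = snps$alt[i],
               tf = vapply(parts, `[`, "", 1L),
               side = vapply(parts, `[`, "", 2L),
               kind = "as", stringsAsFactors = FALSE)
  }))
  pwm_specs <- rbind(pwm_specs, data.frame(
    rsid = decoys$rsid, chrom = decoys$chrom, pos = decoys$pos,
    ref = decoys$ref, alt = decoys$alt, tf = decoys$tf, side = "ref",
    kind = decoys$kind, stringsAsFactors = FALSE
  ))
  built <- build_fixture_pwms(genome, pwm_specs, snps, decoys, expr, focal,
                              cfg)
  genome <- built$genome
  pwms <- built$pwms

  # --- genotype panel -----------------------------------------------------
  n_samples <- 20L
  panel_snps <- rbind(
    snps[snps$in_ip, c("rsid", "chrom", "pos", "ref", "alt")],
    decoys[, c("rsid", "chrom", "pos", "ref", "alt")]
  )
  filler <- do.call(rbind, lapply(contigs, function(ch) {
    pos <- 21000L + (0:5) * 5000L
    data.frame(rsid = paste0("snp_", ch, "_", pos), chrom = ch, pos = pos,
               stringsAsFactors = FALSE)
  }))
  filler$ref <- unname(substring(genome[filler$chrom], filler$pos,
                                 filler$pos))
  filler$alt <- vapply(filler$ref, other_base, character(1))
  loci <- rbind(panel_snps, filler[, c("rsid", "chrom", "pos", "ref", "alt")])
  haps <- matrix(0L, nrow = nrow(loci), ncol = 2L * n_samples)
  for (i in seq_len(nrow(loci))) {
    repeat {
      col <- stats::rbinom(2L * n_samples, 1L, 0.5)
      if (sum(col) >= 4L && sum(col) <= 2L * n_samples - 4L) break
    }
    haps[i, ] <- col
  }
  # the published DAAM2 SNPs are in perfect LD: share one haplotype column
  daam2_rows <- which(loci$rsid %in%
                        snps$rsid[snps$gene == "DAAM2" & snps$in_ip])
  for (r in daam2_rows[-1]) haps[r, ] <- haps[daam2_rows[1], ]
  hap1 <- haps[, seq_len(n_samples), drop = FALSE]
  hap2 <- haps[, n_samples + seq_len(n_samples), drop = FALSE]

  # --- association + imputed tables --------------------------------------
  assoc_ip <- rbind(
    data.frame(rsid = snps$rsid[snps$in_ip], chrom = snps$chrom[snps$in_ip],
               pos = snps$pos[snps$in_ip], ref = snps$ref[snps$in_ip],
               alt = snps$alt[snps$in_ip],
               reported_genes = snps$gene[snps$in_ip],
               stringsAsFactors = FALSE),
    data.frame(rsid = decoys$rsid, chrom = decoys$chrom, pos = decoys$pos,
               ref = decoys$ref, alt = decoys$alt,
               reported_genes = decoys$gene, stringsAsFactors = FALSE)
  )
  assoc_ip$pvalue <- 1e-10
  assoc_ip <- assoc_ip[order(assoc_ip$chrom, assoc_ip$pos), , drop = FALSE]

  imp_dxa <- snps[snps$imputed == "dxa", , drop = FALSE]
  imp_ebmd <- snps[snps$imputed == "ebmd", , drop = FALSE]
  write_imp <- function(df, extra, path) {
    v <- data.frame(rsid = df$rsid, chrom = df$chrom, pos = df$pos,
                    ref = df$ref, alt = df$alt, pvalue = 1e-10,
                    reported_genes = df$gene, stringsAsFactors = FALSE)
    v <- rbind(v, extra)
    v <- v[order(v$chrom, v$pos), , drop = FALSE]
    write_association_table(
      variant_set(v$rsid, v$chrom, v$pos, v$ref, v$alt, source = "index",
                  pvalue = v$pvalue, reported_genes = v$reported_genes),
      file.path(dir, path))
  }
  # an imputed decoy significant at the DXA threshold but not at the
  # stricter eBMD threshold of its own table
  imp_p_decoy <- data.frame(
    rsid = "rs_decoy_imp_p", chrom = "chr12", pos = 100000L,
    ref = unname(substring(genome["chr12"], 100000L, 100000L)),
    alt = "", pvalue = 1e-8, reported_genes = "HMGA2",
    stringsAsFactors = FALSE
  )
  imp_p_decoy$alt <- other_base(imp_p_decoy$ref)
  write_imp(imp_dxa, NULL, "dxa_imputed.tsv")
  write_imp(imp_ebmd, imp_p_decoy, "ebmd_imputed.tsv")

  write_bundle_files(
    dir = dir, genome = genome, loci = loci, hap1 = hap1, hap2 = hap2,
    n_samples = n_samples,
    assoc = assoc_ip[, c("rsid", "chrom", "pos", "ref", "alt", "pvalue",
                         "reported_genes")],
    strong_by_ct = strong_by_ct, k27_by_ct = k27_by_ct,
    dhs_rows = dhs_rows, contig_lengths = contig_lengths, expr = expr,
    gene_rows = genes5, pwms = pwms, focal = focal, others = others,
    others_expr = others_expr, curated = c("HMGA2", "RUNX2"),
    imputed = data.frame(path = c("dxa_imputed.tsv", "ebmd_imputed.tsv"),
                         p_threshold = c(5e-8, 6.6e-9),
                         stringsAsFactors = FALSE)
  )
  list(dir = dir, inputs = read_input_bundle(dir), snps = snps,
       decoys = decoys)
}

# Build one PWM per expected (SNP, TF, allele) call and verify against the
# scanner that each fixture SNP yields exactly its published calls.
build_fixture_pwms <- function(genome, pwm_specs, snps, decoys, expr, focal,
                               cfg) {
  build_one <- function(k) {
    w <- substring(genome[pwm_specs$chrom[k]], pwm_specs$pos[k] - 10L,
                   pwm_specs$pos[k] + 10L)
    make_planted_pwm(pwm_specs$tf[k], w, pwm_specs$ref[k],
                     pwm_specs$alt[k], kind = pwm_specs$kind[k],
                     favored = pwm_specs$side[k], config = cfg)
  }
  pwm_list <- lapply(seq_len(nrow(pwm_specs)), build_one)
  points <- unique(pwm_specs[, c("rsid", "chrom", "pos", "ref", "alt")])
  for (round in 1:6) {
    assembly <- Biostrings::DNAStringSet(genome)
    clean <- TRUE
    for (i in seq_len(nrow(points))) {
      v <- variant_set(points$rsid[i], points$chrom[i], points$pos[i],
                       points$ref[i], points$alt[i])
      got <- predict_allele_specific_tfbs(v, assembly, pwm_list, expr,
                                          focal, cfg)
      spec_i <- pwm_specs[pwm_specs$rsid == points$rsid[i] &
                            pwm_specs$kind == "as", , drop = FALSE]
      want <- paste(spec_i$tf, spec_i$side)
      have <- paste(got$tf_name, got$favored_allele)
      if (!identical(sort(want), sort(have))) {
        clean <- FALSE
        p <- points$pos[i]; ch <- points$chrom[i]
        substring(genome[ch], p - 10L, p - 1L) <- random_seq(10L)
        substring(genome[ch], p + 1L, p + 10L) <- random_seq(10L)
        redo <- which(pwm_specs$rsid == points$rsid[i])
        for (k in redo) pwm_list[[k]] <- build_one(k)
      }
    }
    if (clean) return(list(genome = genome, pwms = pwm_list))
  }
  stop("internal: could not realize the fixture TFBS calls")
}
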
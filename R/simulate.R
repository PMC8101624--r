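#' Simulation specification
#'
#' Parameters of the synthetic input generator. The defaults describe a
#' desk-scale genome that reproduces the statistical structure the pipeline
#' assumes: three 600-kb contigs; a phased 60-sample genotype panel built
#' from a block-mosaic haplotype model (per 50-kb block each haplotype
#' copies one of 4 founder haplotypes, redrawing its founder at a block
#' boundary with probability `block_recomb_prob`, so within-block
#' r-squared is high and between-block r-squared near zero); mostly
#' quiescent chromatin segmentations with strong regulatory segments
#' planted around signal SNPs and shared with a controlled number of
#' comparison cell types; H3K27ac/DHS narrowPeaks nested in those segments;
#' long-tailed log-normal RPKM expression with planted focal-enriched
#' genes; and PWMs with conserved cores and an engineered centre column.
#'
#' @param rng_seed integer seed driving every random choice.
#' @param n_contigs number of contigs.
#' @param contig_length_bp length of each contig.
#' @param n_samples diploid samples in the genotype panel.
#' @param n_background_snps background panel loci (in addition to planted
#'   SNPs).
#' @param n_background_index background index SNPs drawn from the panel.
#' @param ld_block_length_bp haplotype block length.
#' @param block_recomb_prob probability that a haplotype redraws its
#'   founder when crossing a block boundary.
#' @param n_founders founder haplotypes per block.
#' @param n_genes total gene models (planted genes plus filler).
#' @param n_filler_pwms PWMs with no planted target, added on top of the
#'   one-per-planted-SNP PWMs.
#' @param planted data frame of planted signals (`rsid`, `defect`,
#'   `expected_stage`); defaults to [default_planted_signals()].
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(rng_seed = 20260101L,
                            n_contigs = 3L,
                            contig_length_bp = 600000L,
                            n_samples = 60L,
                            n_background_snps = 2400L,
                            n_background_index = 20L,
                            ld_block_length_bp = 50000L,
                            block_recomb_prob = 0.9,
                            n_founders = 4L,
                            n_genes = 50L,
                            n_filler_pwms = 4L,
                            planted = default_planted_signals()) {
  spec <- list(
    rng_seed = as.integer(rng_seed), n_contigs = as.integer(n_contigs),
    contig_length_bp = as.integer(contig_length_bp),
    n_samples = as.integer(n_samples),
    n_background_snps = as.integer(n_background_snps),
    n_background_index = as.integer(n_background_index),
    ld_block_length_bp = as.integer(ld_block_length_bp),
    block_recomb_prob = block_recomb_prob,
    n_founders = as.integer(n_founders),
    n_genes = as.integer(n_genes),
    n_filler_pwms = as.integer(n_filler_pwms),
    planted = planted
  )
  counts <- c(spec$n_contigs, spec$contig_length_bp, spec$n_samples,
              spec$n_background_snps, spec$ld_block_length_bp,
              spec$n_founders, spec$n_genes)
  if (any(counts <= 0)) stop("all simulation counts must be positive")
  if (block_recomb_prob < 0 || block_recomb_prob > 1) {
    stop("block_recomb_prob must be in [0, 1]")
  }
  n_slots <- spec$n_contigs * 8L
  if (nrow(planted) > n_slots) {
    stop("too many planted signals for the genome size (", n_slots,
         " slots)")
  }
  class(spec) <- "simulation_spec"
  spec
}

DEFECT_STAGES <- c(
  none = "none", p_above_threshold = "association",
  r2_below_threshold = "ld", no_dhs = "enhpro",
  too_shared_state = "enhpro", too_shared_k27ac = "enhpro",
  gene_not_preferential = "genes", fold_below_5 = "tfbs",
  tf_not_expressed = "tfbs", curation_fail = "tfbs"
)

#' Default planted-signal table
#'
#' Twelve defect-free SNPs that must reach Tier-1, plus one decoy per
#' defect class, each engineered to fail exactly one criterion and carrying
#' the filter stage at which the pipeline must reject it.
#'
#' @return A data frame: `rsid`, `defect`, `expected_stage`.
#' @export
default_planted_signals <- function() {
  defects <- c(rep("none", 12L),
               "p_above_threshold", "r2_below_threshold", "no_dhs",
               "too_shared_state", "too_shared_k27ac",
               "gene_not_preferential", "fold_below_5", "tf_not_expressed",
               "curation_fail")
  rsid <- ifelse(defects == "none",
                 sprintf("rs_causal_%02d", seq_along(defects)),
                 paste0("rs_decoy_", defects))
  data.frame(rsid = rsid, defect = defects,
             expected_stage = unname(DEFECT_STAGES[defects]),
             stringsAsFactors = FALSE)
}

# ---- shared low-level emitters -------------------------------------------

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_seq <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

other_base <- function(b) {
  sample(setdiff(DNA_BASES, b), 1L)
}

write_vcf_panel <- function(loci, hap1, hap2, samples, path) {
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  hap1 <- hap1[ord, , drop = FALSE]
  hap2 <- hap2[ord, , drop = FALSE]
  gt <- matrix(paste0(hap1, "|", hap2), nrow = nrow(loci))
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(loci$chrom, loci$pos, loci$rsid, loci$ref, loci$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

# Fill the gaps between strong segments with the quiescent filler state so
# every emitted segmentation partitions its contigs.
fill_segmentation <- function(strong, contig_lengths, cell_type,
                              filler_state = 15L) {
  rows <- list()
  for (chrom in names(contig_lengths)) {
    len <- contig_lengths[[chrom]]
    seg <- strong[strong$chrom == chrom, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1L && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
      stop("internal: planted strong segments overlap on ", chrom)
    }
    cursor <- 1L
    for (i in seq_len(nrow(seg))) {
      if (seg$start[i] > cursor) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = cursor, end = seg$start[i] - 1L,
          state = filler_state, stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- seg[i, c("chrom", "start", "end", "state")]
      cursor <- seg$end[i] + 1L
    }
    if (cursor <= len) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = cursor, end = len, state = filler_state,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               state = as.integer(df$state))
  structure(list(cell_type = cell_type, gr = GenomicRanges::sort(gr)),
            class = "segmentation_track")
}

peak_track_from_df <- function(df, cell_type, mark) {
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end),
    name = paste0(mark, "_", seq_len(nrow(df))), score = 1000L,
    signal = 10, pval = -1, qval = -1,
    summit = as.integer((df$end - df$start) %/% 2L)
  )
  structure(list(cell_type = cell_type, mark = mark, gr = gr),
            class = "peak_track")
}

# Engineer a PWM around a planted SNP: width 9, covering window positions
# 7..15 of the 21-mer, SNP at PWM position 5. Flanking columns are
# conserved and match the genome; the centre column realizes the intended
# allele fold change.
make_planted_pwm <- function(tf_name, window, ref, alt,
                             kind = c("as", "fold_below", "curation_fail"),
                             favored = c("ref", "alt"),
                             config = enhpro_config()) {
  kind <- match.arg(kind)
  favored <- match.arg(favored)
  stopifnot(nchar(window) == 21L)
  bases <- strsplit(window, "")[[1]]
  probs <- matrix(0.01, nrow = 4L, ncol = 9L, dimnames = list(DNA_BASES))
  for (j in seq_len(9L)) {
    probs[bases[6L + j], j] <- 0.97
  }
  fav_base <- if (favored == "ref") ref else alt
  dis_base <- if (favored == "ref") alt else ref
  rest <- setdiff(DNA_BASES, c(fav_base, dis_base))
  centre <- numeric(4L)
  names(centre) <- DNA_BASES
  if (kind == "fold_below") {
    centre[fav_base] <- 0.42
    centre[dis_base] <- 0.10
    centre[rest] <- 0.24
  } else {
    centre[fav_base] <- 0.50
    centre[dis_base] <- 0.05
    centre[rest] <- 0.225
  }
  probs[, 5L] <- centre
  if (kind == "curation_fail") {
    # one conserved flank column deliberately contradicts the genome
    wrong <- setdiff(DNA_BASES, bases[8L])[1]
    probs[, 2L] <- 0.01
    probs[wrong, 2L] <- 0.97
  }
  pwm(tf_name, probs, config)
}

# ---- the generator -------------------------------------------------------

#' Generate a synthetic input bundle
#'
#' Writes a complete, self-contained input set (FASTA, phased VCF,
#' association TSV, 13 segmentation BEDs, H3K27ac narrowPeaks, a focal DHS
#' narrowPeak, RPKM expression TSV, GTF gene models, TRANSFAC PWM file,
#' curated gene list, manifest) plus a sidecar truth-label TSV recording
#' each planted SNP's defect and expected rejection stage. The truth file
#' is never consumed by the pipeline.
#'
#' The generator verifies at construction time that each planted SNP's
#' TFBS evidence matches its intended defect (re-rolling only that SNP's
#' flanking sequence on the rare random collision with another PWM), so
#' planted-truth recovery holds for any seed.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory (created if needed).
#' @return A list with `dir`, `truth` (the truth-label data frame), `spec`
#'   and `inputs` (the manifest as read back by [read_input_bundle()]).
#' @export
simulate_bundle <- function(spec = simulation_spec(),
                            dir = tempfile("enhpro_sim_")) {
  local_seed(spec$rng_seed, simulate_bundle_impl(spec, dir))
}

simulate_bundle_impl <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  focal <- "ostb"
  others <- c("fib_skin", "fib_lung_adult", "fib_lung_fetal",
              "kera_foreskin", "kera_dermal", "melanocyte", "astrocyte",
              "huvec", "myoblast", "hmec", "esc", "lcl")
  others_expr <- others[1:11]
  contigs <- sprintf("chr%d", seq_len(spec$n_contigs))
  contig_lengths <- stats::setNames(rep(spec$contig_length_bp,
                                        spec$n_contigs), contigs)

  genome <- stats::setNames(
    vapply(contigs, function(x) random_seq(spec$contig_length_bp),
           character(1)), contigs)

  # planted SNP placement: fixed slots, round-robin over contigs
  planted <- spec$planted
  n_p <- nrow(planted)
  slot_pos <- 40000L + (0:7) * 70000L
  planted$chrom <- contigs[((seq_len(n_p) - 1L) %% spec$n_contigs) + 1L]
  planted$pos <- slot_pos[((seq_len(n_p) - 1L) %/% spec$n_contigs) + 1L]
  planted$ref <- substring(genome[planted$chrom], planted$pos, planted$pos)
  planted$alt <- vapply(planted$ref, other_base, character(1))

  # background panel loci, kept clear of planted SNPs
  per_contig <- spec$n_background_snps %/% spec$n_contigs
  bg <- do.call(rbind, lapply(contigs, function(ch) {
    excl <- planted$pos[planted$chrom == ch]
    cand <- setdiff(seq(1000L, spec$contig_length_bp - 1000L),
                    unlist(lapply(excl, function(p) (p - 500L):(p + 500L))))
    pos <- sort(sample(cand, per_contig))
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  bg$rsid <- paste0("snp_", bg$chrom, "_", bg$pos)
  bg$ref <- substring(genome[bg$chrom], bg$pos, bg$pos)
  bg$alt <- vapply(bg$ref, other_base, character(1))

  loci <- rbind(
    data.frame(rsid = planted$rsid, chrom = planted$chrom,
               pos = planted$pos, ref = planted$ref, alt = planted$alt,
               stringsAsFactors = FALSE),
    bg[, c("rsid", "chrom", "pos", "ref", "alt")]
  )
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  rownames(loci) <- NULL

  haps <- block_mosaic_haplotypes(loci, spec, planted$rsid)
  hap1 <- haps[, seq_len(spec$n_samples), drop = FALSE]
  hap2 <- haps[, spec$n_samples + seq_len(spec$n_samples), drop = FALSE]

  # the low-LD decoy gets an engineered genotype column kept below
  # r-squared 0.3 with its index partner (the first defect-free SNP)
  ld_decoy <- planted$rsid[planted$defect == "r2_below_threshold"]
  ld_index <- planted$rsid[planted$defect == "none"][1]
  if (length(ld_decoy) == 1L) {
    i_dec <- match(ld_decoy, loci$rsid)
    i_idx <- match(ld_index, loci$rsid)
    # move the decoy next to its index partner (same contig, one block over)
    target_chrom <- loci$chrom[i_idx]
    target_pos <- loci$pos[i_idx] + spec$ld_block_length_bp %/% 2L + 7L
    loci$chrom[i_dec] <- target_chrom
    loci$pos[i_dec] <- target_pos
    loci$ref[i_dec] <- substring(genome[target_chrom], target_pos, target_pos)
    loci$alt[i_dec] <- other_base(loci$ref[i_dec])
    planted$chrom[planted$rsid == ld_decoy] <- target_chrom
    planted$pos[planted$rsid == ld_decoy] <- target_pos
    planted$ref[planted$rsid == ld_decoy] <- loci$ref[i_dec]
    planted$alt[planted$rsid == ld_decoy] <- loci$alt[i_dec]
    r2 <- 1
    for (attempt in 1:100) {
      col <- stats::rbinom(2L * spec$n_samples, 1L, 0.5)
      if (sum(col) < 4L || sum(col) > 2L * spec$n_samples - 4L) next
      hap1[i_dec, ] <- col[seq_len(spec$n_samples)]
      hap2[i_dec, ] <- col[spec$n_samples + seq_len(spec$n_samples)]
      x <- c(hap1[i_idx, ], hap2[i_idx, ])
      y <- c(hap1[i_dec, ], hap2[i_dec, ])
      r2 <- tryCatch(pair_r2_haplotypes(x, y), error = function(e) 1)
      if (r2 < 0.3) break
    }
    if (r2 >= 0.3) stop("internal: could not decorrelate the LD decoy")
  }

  # gene models: one gene per planted SNP, filler genes elsewhere
  planted$gene <- paste0("G_", planted$rsid)
  has_gene <- planted$defect != "r2_below_threshold"
  gene_rows <- data.frame(
    gene_id = planted$gene[has_gene], chrom = planted$chrom[has_gene],
    tss = planted$pos[has_gene] - 5000L, strand = "+",
    start = planted$pos[has_gene] - 5000L,
    end = planted$pos[has_gene] - 2000L, stringsAsFactors = FALSE
  )
  n_filler_genes <- spec$n_genes - nrow(gene_rows)
  if (n_filler_genes > 0L) {
    fch <- sample(contigs, n_filler_genes, replace = TRUE)
    fpos <- sample(seq(5000L, spec$contig_length_bp - 10000L),
                   n_filler_genes)
    fstrand <- sample(c("+", "-"), n_filler_genes, replace = TRUE)
    gene_rows <- rbind(gene_rows, data.frame(
      gene_id = sprintf("GENE_f%02d", seq_len(n_filler_genes)),
      chrom = fch,
      tss = ifelse(fstrand == "+", fpos, fpos + 4000L),
      strand = fstrand, start = fpos, end = fpos + 4000L,
      stringsAsFactors = FALSE
    ))
  }

  # chromatin evidence around planted SNPs
  has_chromatin <- !(planted$defect %in% "r2_below_threshold")
  n_share_state <- ifelse(planted$defect == "too_shared_state", 5L, 2L)
  n_share_k27 <- ifelse(planted$defect == "too_shared_k27ac", 5L, 2L)
  strong_by_ct <- stats::setNames(
    rep(list(data.frame(chrom = character(), start = integer(),
                        end = integer(), state = integer(),
                        stringsAsFactors = FALSE)), length(c(focal, others))),
    c(focal, others))
  k27_by_ct <- stats::setNames(
    rep(list(data.frame(chrom = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)),
        length(c(focal, others))), c(focal, others))
  dhs_rows <- data.frame(chrom = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
  for (i in seq_len(n_p)) {
    if (!has_chromatin[i]) next
    ch <- planted$chrom[i]; p <- planted$pos[i]
    state <- if (i %% 2L == 0L) 1L else 9L
    seg <- data.frame(chrom = ch, start = p - 200L, end = p + 200L,
                      state = state, stringsAsFactors = FALSE)
    peak <- data.frame(chrom = ch, start = p - 150L, end = p + 150L,
                       stringsAsFactors = FALSE)
    strong_by_ct[[focal]] <- rbind(strong_by_ct[[focal]], seg)
    k27_by_ct[[focal]] <- rbind(k27_by_ct[[focal]], peak)
    if (planted$defect[i] != "no_dhs") dhs_rows <- rbind(dhs_rows, peak)
    share_state <- sample(others, n_share_state[i])
    share_k27 <- c(share_state[seq_len(min(2L, length(share_state)))],
                   setdiff(sample(others, length(others)), share_state))
    share_k27 <- share_k27[seq_len(n_share_k27[i])]
    for (ct in share_state) {
      strong_by_ct[[ct]] <- rbind(strong_by_ct[[ct]], seg)
    }
    for (ct in share_k27) {
      k27_by_ct[[ct]] <- rbind(k27_by_ct[[ct]], peak)
    }
  }
  # decoy strong segments in comparison types only, away from planted SNPs
  for (ct in others) {
    n_dec <- 6L
    dch <- sample(contigs, n_dec, replace = TRUE)
    dpos <- sample(seq(2000L, spec$contig_length_bp - 2000L), n_dec)
    keep <- vapply(seq_len(n_dec), function(k) {
      all(planted$chrom != dch[k] | abs(planted$pos - dpos[k]) > 2500L)
    }, logical(1))
    # also keep decoys pairwise separated within each contig
    ord <- order(dch, dpos)
    last <- 0L
    for (b in ord) {
      if (!keep[b]) next
      if (last > 0L && dch[last] == dch[b] &&
          abs(dpos[last] - dpos[b]) <= 1000L) {
        keep[b] <- FALSE
      } else {
        last <- b
      }
    }
    if (any(keep)) {
      strong_by_ct[[ct]] <- rbind(strong_by_ct[[ct]], data.frame(
        chrom = dch[keep], start = dpos[keep] - 300L,
        end = dpos[keep] + 300L, state = 9L, stringsAsFactors = FALSE))
    }
  }

  # expression: long-tailed background, planted genes focal-enriched
  expr_cols <- c(focal, others)
  all_genes <- gene_rows$gene_id
  expr <- matrix(stats::rlnorm(length(all_genes) * length(expr_cols),
                               meanlog = 0, sdlog = 1.5),
                 nrow = length(all_genes),
                 dimnames = list(all_genes, expr_cols))
  for (i in seq_len(n_p)) {
    g <- planted$gene[i]
    if (!g %in% rownames(expr)) next
    if (planted$defect[i] == "gene_not_preferential") {
      expr[g, focal] <- 3
      expr[g, others] <- stats::runif(length(others), 0.8, 1.2)
    } else {
      expr[g, focal] <- 50
      expr[g, others] <- stats::runif(length(others), 0.5, 2)
    }
  }

  # PWMs + TF expression rows
  has_pwm <- planted$defect != "r2_below_threshold"
  planted$tf <- ifelse(has_pwm, paste0("TF_", planted$rsid), NA_character_)
  planted$favored <- rep(c("ref", "alt"), length.out = n_p)
  tf_expr <- t(vapply(planted$tf[has_pwm], function(tf) {
    c(5, stats::runif(length(others), 0, 0.5))
  }, numeric(length(expr_cols))))
  colnames(tf_expr) <- expr_cols
  not_expr <- planted$tf[planted$defect == "tf_not_expressed"]
  tf_expr[not_expr, focal] <- 0.1
  filler_tfs <- sprintf("TF_BG_%02d", seq_len(spec$n_filler_pwms))
  filler_expr <- matrix(stats::runif(spec$n_filler_pwms * length(expr_cols),
                                     1, 6),
                        nrow = spec$n_filler_pwms,
                        dimnames = list(filler_tfs, expr_cols))
  expr <- rbind(expr, tf_expr, filler_expr)

  cfg <- enhpro_config()
  filler_pwms <- lapply(filler_tfs, function(tf) {
    make_planted_pwm(tf, random_seq(21L), "A", "C", kind = "as",
                     favored = "ref", config = cfg)
  })

  built <- build_verified_pwms(genome, planted, filler_pwms, expr, focal,
                               cfg)
  genome <- built$genome
  pwms <- built$pwms
  # re-read ref alleles (flank re-rolls never touch the centre base)
  stopifnot(identical(
    unname(substring(genome[planted$chrom], planted$pos, planted$pos)),
    planted$ref))

  # association table: planted (except the panel-only LD decoy) +
  # background index SNPs
  assoc_planted <- planted[planted$defect != "r2_below_threshold", ,
                           drop = FALSE]
  assoc <- data.frame(
    rsid = assoc_planted$rsid, chrom = assoc_planted$chrom,
    pos = assoc_planted$pos, ref = assoc_planted$ref,
    alt = assoc_planted$alt,
    pvalue = ifelse(assoc_planted$defect == "p_above_threshold",
                    1e-4, 1e-12),
    reported_genes = assoc_planted$gene, stringsAsFactors = FALSE
  )
  step <- max(1L, nrow(bg) %/% spec$n_background_index)
  bg_idx <- bg[seq(1L, nrow(bg), by = step)[seq_len(spec$n_background_index)],
               , drop = FALSE]
  assoc <- rbind(assoc, data.frame(
    rsid = bg_idx$rsid, chrom = bg_idx$chrom, pos = bg_idx$pos,
    ref = bg_idx$ref, alt = bg_idx$alt, pvalue = 1e-9,
    reported_genes = "", stringsAsFactors = FALSE
  ))
  assoc <- assoc[order(assoc$chrom, assoc$pos), , drop = FALSE]

  write_bundle_files(
    dir = dir, genome = genome, loci = loci, hap1 = hap1, hap2 = hap2,
    n_samples = spec$n_samples, assoc = assoc, strong_by_ct = strong_by_ct,
    k27_by_ct = k27_by_ct, dhs_rows = dhs_rows,
    contig_lengths = contig_lengths, expr = expr, gene_rows = gene_rows,
    pwms = pwms, focal = focal, others = others, others_expr = others_expr,
    curated = character(), imputed = NULL
  )

  truth <- planted[, c("rsid", "defect", "expected_stage", "chrom", "pos")]
  utils::write.table(truth, file.path(dir, "truth_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(dir = dir, truth = truth, spec = spec,
       inputs = read_input_bundle(dir))
}

# Haplotypes under the block-mosaic model; planted loci are forced to be
# polymorphic within every founder pool.
block_mosaic_haplotypes <- function(loci, spec, planted_rsids) {
  n_hap <- 2L * spec$n_samples
  out <- matrix(0L, nrow = nrow(loci), ncol = n_hap)
  for (ch in unique(loci$chrom)) {
    rows <- which(loci$chrom == ch)
    block <- loci$pos[rows] %/% spec$ld_block_length_bp
    blocks <- sort(unique(block))
    founder <- sample.int(spec$n_founders, n_hap, replace = TRUE)
    for (b in blocks) {
      in_block <- rows[block == b]
      fd <- matrix(stats::rbinom(spec$n_founders * length(in_block), 1L, 0.5),
                   nrow = spec$n_founders)
      forced <- loci$rsid[in_block] %in% planted_rsids
      if (any(forced)) {
        half <- spec$n_founders %/% 2L
        fd[seq_len(half), forced] <- 0L
        fd[(half + 1L):spec$n_founders, forced] <- 1L
      }
      out[in_block, ] <- t(fd[founder, , drop = FALSE])
      redraw <- stats::runif(n_hap) < spec$block_recomb_prob
      founder[redraw] <- sample.int(spec$n_founders, sum(redraw),
                                    replace = TRUE)
    }
  }
  out
}

pair_r2_haplotypes <- function(x, y) {
  n <- length(x)
  pAB <- sum(x == 0 & y == 0) / n
  pAb <- sum(x == 0 & y == 1) / n
  paB <- sum(x == 1 & y == 0) / n
  pab <- sum(x == 1 & y == 1) / n
  r_squared(list(pAB = pAB, pAb = pAb, paB = paB, pab = pab))
}

# Construct one engineered PWM per planted SNP and verify, SNP by SNP, that
# scanning the full PWM collection reproduces exactly the intended
# allele-specific TFBS evidence; on a collision the SNP's flanking sequence
# is re-rolled and its own PWM rebuilt.
build_verified_pwms <- function(genome, planted, filler_pwms, expr, focal,
                                cfg) {
  active <- which(!is.na(planted$tf))
  build_one <- function(i) {
    w <- substring(genome[planted$chrom[i]], planted$pos[i] - 10L,
                   planted$pos[i] + 10L)
    kind <- switch(planted$defect[i],
                   fold_below_5 = "fold_below",
                   curation_fail = "curation_fail",
                   "as")
    make_planted_pwm(planted$tf[i], w, planted$ref[i], planted$alt[i],
                     kind = kind, favored = planted$favored[i], config = cfg)
  }
  pwm_list <- stats::setNames(lapply(active, build_one), planted$tf[active])
  assembly_of <- function(g) Biostrings::DNAStringSet(g)
  for (round in 1:6) {
    assembly <- assembly_of(genome)
    all_pwms <- c(unname(pwm_list), filler_pwms)
    clean <- TRUE
    for (i in active) {
      v <- variant_set(planted$rsid[i], planted$chrom[i], planted$pos[i],
                       planted$ref[i], planted$alt[i])
      got <- predict_allele_specific_tfbs(v, assembly, all_pwms, expr,
                                          focal, cfg)
      want_tf <- if (planted$defect[i] %in%
                       c("fold_below_5", "curation_fail",
                         "tf_not_expressed")) {
        character(0)
      } else {
        planted$tf[i]
      }
      ok <- identical(sort(got$tf_name), sort(want_tf)) &&
        (length(want_tf) == 0L ||
           all(got$favored_allele[got$tf_name == planted$tf[i]] ==
                 planted$favored[i]))
      if (!ok) {
        clean <- FALSE
        # re-roll the 10-bp flanks, keep the centre (ref) base
        p <- planted$pos[i]; ch <- planted$chrom[i]
        substring(genome[ch], p - 10L, p - 1L) <- random_seq(10L)
        substring(genome[ch], p + 1L, p + 10L) <- random_seq(10L)
        pwm_list[[planted$tf[i]]] <- build_one(i)
      }
    }
    if (clean) {
      return(list(genome = genome, pwms = c(unname(pwm_list), filler_pwms)))
    }
  }
  stop("internal: could not realize planted TFBS signals without collisions")
}

write_bundle_files <- function(dir, genome, loci, hap1, hap2, n_samples,
                               assoc, strong_by_ct, k27_by_ct, dhs_rows,
                               contig_lengths, expr, gene_rows, pwms,
                               focal, others, others_expr,
                               curated = character(), imputed = NULL) {
  fa <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(fa, file.path(dir, "genome.fa"))
  samples <- sprintf("S%03d", seq_len(n_samples))
  write_vcf_panel(loci, hap1, hap2, samples, file.path(dir, "panel.vcf"))
  av <- variant_set(assoc$rsid, assoc$chrom, assoc$pos, assoc$ref,
                    assoc$alt, source = "index", pvalue = assoc$pvalue,
                    reported_genes = assoc$reported_genes)
  write_association_table(av, file.path(dir, "associations.tsv"))
  dir.create(file.path(dir, "segmentation"), showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  seg_paths <- character(0)
  k27_paths <- character(0)
  for (ct in c(focal, others)) {
    track <- fill_segmentation(strong_by_ct[[ct]], contig_lengths, ct)
    sp <- file.path("segmentation", paste0(ct, "_18state.bed"))
    write_segmentation_bed(track, file.path(dir, sp))
    seg_paths[ct] <- sp
    kdf <- k27_by_ct[[ct]]
    if (nrow(kdf) == 0L) {
      kdf <- data.frame(chrom = names(contig_lengths)[1], start = 1L,
                        end = 2L, stringsAsFactors = FALSE)
    }
    kp <- file.path("peaks", paste0(ct, "_H3K27ac.narrowPeak"))
    write_narrowpeak(peak_track_from_df(kdf, ct, "H3K27ac"),
                     file.path(dir, kp))
    k27_paths[ct] <- kp
  }
  if (nrow(dhs_rows) == 0L) {
    dhs_rows <- data.frame(chrom = names(contig_lengths)[1], start = 1L,
                           end = 2L, stringsAsFactors = FALSE)
  }
  write_narrowpeak(peak_track_from_df(dhs_rows, focal, "DHS"),
                   file.path(dir, file.path("peaks", "ostb_DHS.narrowPeak")))
  write_expression_table(expr, file.path(dir, "expression.tsv"))
  write_gene_models(gene_rows, file.path(dir, "genes.gtf"))
  write_transfac_pwm(pwms, file.path(dir, "pwms.transfac"))
  writeLines(c("# curated bone-relevant genes", curated),
             file.path(dir, "curated_genes.txt"))
  manifest <- list(
    association = "associations.tsv", vcf = "panel.vcf",
    segmentations = as.list(seg_paths), k27ac = as.list(k27_paths),
    dhs = "peaks/ostb_DHS.narrowPeak", expression = "expression.tsv",
    genes = "genes.gtf", fasta = "genome.fa", transfac = "pwms.transfac",
    curated = "curated_genes.txt", focal = focal,
    others_chromatin = others, others_expression = others_expr
  )
  if (!is.null(imputed)) manifest$imputed <- imputed
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
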
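#' Read an input bundle manifest
#'
#' A bundle directory (as written by [simulate_bundle()] or
#' [make_table1_fixture()]) contains a `manifest.json` naming every input
#' file relative to the directory, the focal cell type, and the comparison
#' panels. This loads the manifest into the `inputs` list accepted by
#' [run_pipeline()].
#'
#' @param dir bundle directory.
#' @return Named list of input paths and panel definitions.
#' @export
read_input_bundle <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  abs <- function(x) {
    if (is.null(x)) return(NULL)
    stats::setNames(file.path(dir, unlist(x)), names(unlist(x)))
  }
  inputs <- list(
    association = file.path(dir, mf$association),
    vcf = file.path(dir, mf$vcf),
    segmentations = abs(mf$segmentations),
    k27ac = abs(mf$k27ac),
    dhs = file.path(dir, mf$dhs),
    expression = file.path(dir, mf$expression),
    genes = file.path(dir, mf$genes),
    fasta = file.path(dir, mf$fasta),
    transfac = file.path(dir, mf$transfac),
    focal = mf$focal,
    others_chromatin = mf$others_chromatin,
    others_expression = mf$others_expression
  )
  if (!is.null(mf$curated)) inputs$curated <- file.path(dir, mf$curated)
  if (!is.null(mf$imputed)) {
    inputs$imputed <- lapply(seq_len(nrow(mf$imputed)), function(i) {
      list(path = file.path(dir, mf$imputed$path[i]),
           p_threshold = mf$imputed$p_threshold[i])
    })
  }
  inputs
}

#' Collect imputed SNPs around candidate genes
#'
#' Loads each imputed association table at its own significance threshold
#' and keeps the SNPs lying within `config$imputed_locus_buffer_bp` of any
#' candidate gene span. Returned variants carry `source = "imputed"`;
#' merging with the index/proxy set (and the `"I/P, Imp"` source class for
#' SNPs present in both) happens in [run_pipeline()].
#'
#' @param candidates candidate genes from [select_candidates()].
#' @param imputed_tables list of `list(path=, p_threshold=)`.
#' @param genes gene models.
#' @param config an [enhpro_config()].
#' @return A `variant_set` of imputed SNPs (possibly empty).
#' @export
augment_with_imputed <- function(candidates, imputed_tables, genes,
                                 config = enhpro_config()) {
  empty <- variant_set(character(), character(), integer(), character(),
                       character())[0, ]
  if (nrow(candidates) == 0L || length(imputed_tables) == 0L) return(empty)
  spans <- genes[genes$gene_id %in% candidates$gene_id, , drop = FALSE]
  if (nrow(spans) == 0L) return(empty)
  buf <- config$imputed_locus_buffer_bp
  keep_near <- function(v) {
    ok <- vapply(seq_len(nrow(v)), function(i) {
      any(spans$chrom == v$chrom[i] &
            v$pos[i] >= spans$start - buf &
            v$pos[i] <= spans$end + buf)
    }, logical(1))
    v[ok, , drop = FALSE]
  }
  parts <- lapply(imputed_tables, function(tb) {
    keep_near(read_association_table(tb$path, tb$p_threshold,
                                     source = "imputed"))
  })
  out <- do.call(rbind, parts)
  out <- out[!duplicated(out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full prioritization pipeline
#'
#' Executes the whole workflow: index-SNP selection, LD proxy expansion,
#' EnhPro chromatin classification, gene linking, candidate-gene selection
#' by preferential expression or curated list, imputed-SNP augmentation
#' around candidate genes, allele-specific TFBS prediction, and Tier-1
#' assembly. A SNP is Tier-1 iff it is an EnhPro SNP, linked to a candidate
#' gene, and carries at least one allele-specific, expression-gated TFBS
#' prediction.
#'
#' @param inputs named list of input paths and panels (see
#'   [read_input_bundle()]), or a bundle directory path.
#' @param config an [enhpro_config()].
#' @param out_dir optional directory; when given, the Table-1-style report,
#'   the EnhPro evidence table, the proxy table, the candidate table and a
#'   stage-count JSON are written there deterministically.
#' @return A `tier1_result` list: `tier1` (report rows), `stage_counts`,
#'   `variants` (merged variant table with `source_class`), `enhpro`,
#'   `links`, `candidates`, `expr_summary`, `assoc_all`, `config`.
#' @export
run_pipeline <- function(inputs, config = enhpro_config(), out_dir = NULL) {
  if (is.character(inputs) && length(inputs) == 1L) {
    inputs <- read_input_bundle(inputs)
  }
  focal <- inputs$focal
  others <- inputs$others_chromatin

  assoc_all <- read_association_table(inputs$association, Inf)
  index <- assoc_all[!is.na(assoc_all$pvalue) &
                       assoc_all$pvalue < config$gwas_p_threshold, ,
                     drop = FALSE]
  rownames(index) <- NULL

  panel <- read_genotype_panel(inputs$vcf)
  variants <- expand_proxies(index, panel, config$r2_threshold,
                             config$proxy_search_window_bp,
                             tol = config$em_tol,
                             max_iter = config$em_max_iter)

  segmentations <- stats::setNames(
    lapply(names(inputs$segmentations), function(ct) {
      read_segmentation_bed(inputs$segmentations[[ct]], ct)
    }), names(inputs$segmentations))
  k27ac <- stats::setNames(
    lapply(names(inputs$k27ac), function(ct) {
      read_narrowpeak(inputs$k27ac[[ct]], ct, "H3K27ac")
    }), names(inputs$k27ac))
  dhs <- read_narrowpeak(inputs$dhs, focal, "DHS")

  expression <- read_expression_table(inputs$expression)
  genes <- read_gene_models(inputs$genes)
  assembly <- read_genome(inputs$fasta)
  pwms <- read_transfac_pwm(inputs$transfac, config$pwm_pseudocount, config)
  curated <- if (!is.null(inputs$curated)) {
    read_curated_genes(inputs$curated)
  } else character()

  enhpro1 <- classify_enhpro(variants, focal, others, segmentations,
                             k27ac, dhs, config)
  ep_variants <- variants[enhpro1$is_enhpro, , drop = FALSE]
  links1 <- link_snp_to_gene(ep_variants, genes)
  expr_summary <- preferential_expression(expression, focal,
                                          inputs$others_expression, config)
  candidates <- select_candidates(links1, expr_summary, curated,
                                  config$exclude_genes)

  imputed <- if (!is.null(inputs$imputed)) {
    augment_with_imputed(candidates, inputs$imputed, genes, config)
  } else {
    variant_set(character(), character(), integer(), character(),
                character())[0, ]
  }

  # merge: index/proxy rows win; SNPs in both carry source class "I/P, Imp"
  in_both <- intersect(variants$rsid, imputed$rsid)
  new_imp <- imputed[!(imputed$rsid %in% variants$rsid), , drop = FALSE]
  merged <- rbind(variants, new_imp)
  merged$source_class <- ifelse(
    merged$source == "imputed", "Imp",
    ifelse(merged$rsid %in% in_both, "I/P, Imp", "I/P"))
  rownames(merged) <- NULL

  enhpro <- classify_enhpro(merged, focal, others, segmentations,
                            k27ac, dhs, config)
  ep_all <- merged[enhpro$is_enhpro, , drop = FALSE]
  links <- link_snp_to_gene(ep_all, genes)
  cand_links <- links[links$gene_id %in% candidates$gene_id, , drop = FALSE]

  tier1_rows <- list()
  for (i in seq_len(nrow(cand_links))) {
    v <- ep_all[ep_all$rsid == cand_links$rsid[i], , drop = FALSE][1, ]
    preds <- predict_allele_specific_tfbs(v, assembly, pwms, expression,
                                          focal, config)
    if (nrow(preds) == 0L) next
    label <- chromatin_state_label(v, segmentations[[focal]], config)
    tier1_rows[[length(tier1_rows) + 1L]] <- data.frame(
      gene_id = cand_links$gene_id[i], rsid = v$rsid,
      source_class = v$source_class,
      distance_to_tss_kb = cand_links$distance_to_tss_kb[i],
      ref = v$ref, alt = v$alt, chromatin_state = label,
      tf_ref = paste(preds$tf_name[preds$favored_allele == "ref"],
                     collapse = ","),
      tf_alt = paste(preds$tf_name[preds$favored_allele == "alt"],
                     collapse = ","),
      chrom = v$chrom, pos = v$pos,
      stringsAsFactors = FALSE
    )
  }
  tier1 <- do.call(rbind, tier1_rows)
  if (is.null(tier1)) tier1 <- empty_tier1_frame()
  tier1 <- order_tier1(tier1)

  stage_counts <- list(
    n_index = nrow(index),
    n_index_proxy = nrow(variants),
    n_state_k27ac = sum(enhpro$focal_strong &
                          enhpro$n_other_strong <= config$state_max_other &
                          enhpro$k27ac_focal &
                          enhpro$n_other_k27ac <= config$k27ac_max_other),
    n_enhpro = sum(enhpro$is_enhpro),
    n_candidate_genes = nrow(candidates),
    n_tier1 = nrow(tier1)
  )

  result <- structure(
    list(tier1 = tier1, stage_counts = stage_counts, variants = merged,
         enhpro = enhpro, links = links, cand_links = cand_links,
         candidates = candidates, expr_summary = expr_summary,
         assoc_all = assoc_all, panel_rsids = panel$loci$rsid,
         config = config),
    class = "tier1_result"
  )
  if (!is.null(out_dir)) write_run_outputs(result, out_dir)
  result
}

empty_tier1_frame <- function() {
  data.frame(
    gene_id = character(), rsid = character(), source_class = character(),
    distance_to_tss_kb = numeric(), ref = character(), alt = character(),
    chromatin_state = character(), tf_ref = character(),
    tf_alt = character(), chrom = character(), pos = integer(),
    stringsAsFactors = FALSE
  )
}

# group genes by first appearance, rows within a gene by distance to TSS
order_tier1 <- function(tier1) {
  if (nrow(tier1) == 0L) return(tier1)
  first <- match(tier1$gene_id, unique(tier1$gene_id))
  out <- tier1[order(first, tier1$distance_to_tss_kb, tier1$rsid), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the Table-1-style Tier-1 report
#'
#' One row per Tier-1 SNP with the columns gene, SNP, source class
#' (I/P, Imp, or both), signed distance to the gene TSS formatted to
#' 0.1 kb, Ref/Alt alleles, focal chromatin-state label, and predicted
#' allele-specific TFs per allele ("None" when a side is empty). Genes are
#' grouped and ordered by first appearance.
#'
#' @param records `tier1` data frame from [run_pipeline()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
make_table1_report <- function(records, path) {
  records <- order_tier1(records)
  none_if_empty <- function(x) ifelse(nzchar(x), x, "None")
  out <- data.frame(
    gene = records$gene_id,
    tier1_snp = records$rsid,
    source = records$source_class,
    distance_to_tss_kb = sprintf("%.1f", records$distance_to_tss_kb),
    ref = records$ref,
    alt = records$alt,
    chromatin_state = records$chromatin_state,
    tf_ref = none_if_empty(records$tf_ref),
    tf_alt = none_if_empty(records$tf_alt),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a Tier-1 report
#'
#' @param path report TSV path.
#' @return A data frame mirroring the written columns, with
#'   `distance_to_tss_kb` numeric and empty TF sides restored to `""`.
#' @export
read_table1_report <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$distance_to_tss_kb <- as.numeric(df$distance_to_tss_kb)
  df$tf_ref[df$tf_ref == "None"] <- ""
  df$tf_alt[df$tf_alt == "None"] <- ""
  df
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  make_table1_report(result$tier1, file.path(out_dir, "tier1_report.tsv"))
  write_enhpro_table(result$enhpro, file.path(out_dir, "enhpro.tsv"))
  write_proxy_table(result$variants, file.path(out_dir, "proxies.tsv"))
  write_candidate_table(result$candidates, result$expr_summary,
                        file.path(out_dir, "candidates.tsv"))
  jsonlite::write_json(result$stage_counts,
                       file.path(out_dir, "stage_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Stage at which a SNP left the filter cascade
#'
#' Walks a pipeline result backwards to report where a given SNP was
#' rejected: `"none"` (reached Tier-1), `"tfbs"` (EnhPro and linked to a
#' candidate gene but no allele-specific TFBS), `"genes"` (EnhPro but not
#' linked to any candidate gene), `"enhpro"` (entered the chromatin filter
#' and failed it), `"association"` (present in the association table but
#' above the p-value threshold), or `"ld"` (never entered: a panel site
#' that did not reach the proxy r-squared threshold, or unknown).
#'
#' @param result a `tier1_result`.
#' @param rsid SNP identifier(s).
#' @return Character vector of stage names.
#' @export
rejection_stage <- function(result, rsid) {
  vapply(rsid, function(id) {
    if (id %in% result$tier1$rsid) return("none")
    ep <- result$enhpro
    if (id %in% ep$rsid[ep$is_enhpro]) {
      if (id %in% result$cand_links$rsid) return("tfbs")
      return("genes")
    }
    if (id %in% result$variants$rsid) return("enhpro")
    if (id %in% result$assoc_all$rsid) return("association")
    "ld"
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.tier1_result <- function(x, ...) {
  cat("<tier1_result>\n")
  sc <- x$stage_counts
  cat(sprintf("  index SNPs:            %d\n", sc$n_index))
  cat(sprintf("  index + proxy SNPs:    %d\n", sc$n_index_proxy))
  cat(sprintf("  state+K27ac survivors: %d\n", sc$n_state_k27ac))
  cat(sprintf("  EnhPro SNPs:           %d\n", sc$n_enhpro))
  cat(sprintf("  candidate genes:       %d\n", sc$n_candidate_genes))
  cat(sprintf("  Tier-1 SNPs:           %d\n", sc$n_tier1))
  invisible(x)
}
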
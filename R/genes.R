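#' Preferential focal-cell expression summary
#'
#' For each gene, computes the focal-cell RPKM, the median RPKM over the
#' comparison cell types, their ratio (defined as `Inf` when the median is
#' 0 and the focal value positive), and the preferential-expression flag:
#' ratio strictly greater than `config$expr_ratio_min` and focal RPKM
#' strictly greater than `config$expr_focal_min_rpkm`.
#'
#' @param table numeric RPKM matrix (genes x cell types).
#' @param focal focal cell-type column name.
#' @param others comparison cell-type column names (conventionally 11).
#' @param config an [enhpro_config()].
#' @return A data frame: `gene_id`, `focal_rpkm`, `median_other_rpkm`,
#'   `ratio`, `preferential`.
#' @export
preferential_expression <- function(table, focal, others,
                                    config = enhpro_config()) {
  cols <- c(focal, others)
  missing <- setdiff(cols, colnames(table))
  if (length(missing) > 0L) {
    stop("expression table lacks column(s): ", paste(missing, collapse = ", "))
  }
  focal_rpkm <- table[, focal]
  med <- apply(table[, others, drop = FALSE], 1L, stats::median)
  ratio <- ifelse(med > 0, focal_rpkm / med,
                  ifelse(focal_rpkm > 0, Inf, NA_real_))
  pref <- !is.na(ratio) & ratio > config$expr_ratio_min &
    focal_rpkm > config$expr_focal_min_rpkm
  data.frame(
    gene_id = rownames(table), focal_rpkm = unname(focal_rpkm),
    median_other_rpkm = unname(med), ratio = unname(ratio),
    preferential = unname(pref), stringsAsFactors = FALSE
  )
}

#' Link SNPs to genes
#'
#' Each variant is linked to every one of its reported genes present in the
#' annotation (`link_source = "reported"`); a variant with no such gene is
#' linked to the gene with the nearest TSS on the same contig
#' (`link_source = "nearest"`). The signed distance to the TSS is
#' `(pos - tss) / 1000` kb for plus-strand genes and `(tss - pos) / 1000`
#' for minus-strand genes, so a negative distance always means upstream of
#' the gene. Variants on contigs with no annotated gene are left unlinked
#' with a message.
#'
#' @param variants a `variant_set`.
#' @param genes gene models from [read_gene_models()].
#' @return A data frame: `rsid`, `gene_id`, `distance_to_tss_kb`,
#'   `link_source`.
#' @export
link_snp_to_gene <- function(variants, genes) {
  links <- vector("list", nrow(variants))
  reported <- split_genes(variants$reported_genes)
  n_unlinked <- 0L
  for (i in seq_len(nrow(variants))) {
    hit <- genes[genes$gene_id %in% reported[[i]], , drop = FALSE]
    src <- "reported"
    if (nrow(hit) == 0L) {
      same <- genes[genes$chrom == variants$chrom[i], , drop = FALSE]
      if (nrow(same) == 0L) {
        n_unlinked <- n_unlinked + 1L
        next
      }
      hit <- same[which.min(abs(same$tss - variants$pos[i])), , drop = FALSE]
      src <- "nearest"
    }
    d <- ifelse(hit$strand == "+",
                (variants$pos[i] - hit$tss) / 1000,
                (hit$tss - variants$pos[i]) / 1000)
    links[[i]] <- data.frame(
      rsid = variants$rsid[i], gene_id = hit$gene_id,
      distance_to_tss_kb = d, link_source = src, stringsAsFactors = FALSE
    )
  }
  if (n_unlinked > 0L) {
    message("link_snp_to_gene: ", n_unlinked,
            " variant(s) on contigs with no annotated gene")
  }
  out <- do.call(rbind, links)
  if (is.null(out)) {
    out <- data.frame(rsid = character(), gene_id = character(),
                      distance_to_tss_kb = numeric(),
                      link_source = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Select candidate genes
#'
#' A gene is a candidate iff it is linked to at least one EnhPro SNP and is
#' either preferentially expressed in the focal cell type or a member of
#' the curated bone-relevance list. Genes on `exclude` (e.g. genes already
#' analyzed elsewhere) are removed last. The result is invariant to the
#' order of the inputs.
#'
#' @param enhpro_links SNP-gene links (from [link_snp_to_gene()]) restricted
#'   to EnhPro SNPs.
#' @param expr output of [preferential_expression()].
#' @param curated character vector of curated gene identifiers.
#' @param exclude gene identifiers excluded after selection.
#' @return A data frame: `gene_id`, `selected_by` (comma-joined subset of
#'   `preferential_expression`, `curated_list`), sorted by `gene_id`.
#' @export
select_candidates <- function(enhpro_links, expr, curated = character(),
                              exclude = character()) {
  linked <- unique(enhpro_links$gene_id)
  pref <- expr$gene_id[expr$preferential]
  rows <- lapply(sort(linked), function(g) {
    by <- c(
      if (g %in% pref) "preferential_expression",
      if (g %in% curated) "curated_list"
    )
    if (length(by) == 0L) return(NULL)
    data.frame(gene_id = g, selected_by = paste(by, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), selected_by = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[!(out$gene_id %in% exclude), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the candidate-gene table
#'
#' @param candidates output of [select_candidates()].
#' @param expr output of [preferential_expression()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, expr, path) {
  m <- match(candidates$gene_id, expr$gene_id)
  out <- data.frame(
    gene_id = candidates$gene_id, selected_by = candidates$selected_by,
    focal_rpkm = expr$focal_rpkm[m],
    median_other_rpkm = expr$median_other_rpkm[m],
    ratio = expr$ratio[m], stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
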
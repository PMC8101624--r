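#' Read a gene-by-cell-type RPKM expression table
#'
#' First column `gene_id`, remaining columns one per cell type. Values must
#' be non-negative; genes with a missing value in any column are excluded
#' with a message reporting the count.
#'
#' @param path TSV path.
#' @return A numeric matrix (genes x cell types) with gene ids as row names.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id") {
    stop("expression table ", path, " must have 'gene_id' as first column")
  }
  if (anyDuplicated(names(df)[-1])) stop("duplicate cell-type columns in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$gene_id
  incomplete <- apply(m, 1L, function(r) any(is.na(r)))
  if (any(incomplete)) {
    message("read_expression_table: excluded ", sum(incomplete),
            " gene(s) with missing values")
    m <- m[!incomplete, , drop = FALSE]
  }
  if (any(m < 0)) stop("expression table ", path, " has negative RPKM values")
  m
}

#' Write an RPKM expression table
#' @param mat numeric matrix, gene ids as row names.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Uses `gene`-type records. The TSS is the start of the span for
#' plus-strand genes and the end for minus-strand genes.
#'
#' @param path GTF path.
#' @return A data frame with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   `start`, `end` (span, 1-based closed).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    gg <- gr[S4Vectors::mcols(gr)$type == "gene"]
    if (length(gg) > 0L) gr <- gg
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    stop("gene models in ", path, " must be stranded")
  }
  data.frame(
    gene_id = as.character(S4Vectors::mcols(gr)$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = ifelse(strand == "+", GenomicRanges::start(gr),
                 GenomicRanges::end(gr)),
    strand = strand,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Write gene models as GTF
#' @param genes data frame as returned by [read_gene_models()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- "enhpro"
  S4Vectors::mcols(gr)$gene_id <- genes$gene_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Load a genome assembly from FASTA
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet] keyed by contig name.
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Fetch an odd-length sequence window centred on a position
#'
#' Returns the `window`-length sequence whose centre base (0-based index
#' `(window - 1) / 2`) is the assembly base at `pos`. Windows clipped by a
#' contig edge are an error; windows containing `N` are returned with a
#' warning.
#'
#' @param assembly a `DNAStringSet`.
#' @param chrom contig name.
#' @param pos 1-based centre position.
#' @param window odd window length.
#' @return A single character string of length `window`.
#' @export
fetch_window <- function(assembly, chrom, pos, window = 21L) {
  if (window %% 2L != 1L) stop("window length must be odd")
  if (!chrom %in% names(assembly)) stop("contig ", chrom, " not in assembly")
  half <- (window - 1L) %/% 2L
  lo <- pos - half
  hi <- pos + half
  len <- Biostrings::width(assembly[chrom])
  if (lo < 1L || hi > len) {
    stop("window [", lo, ", ", hi, "] out of bounds for contig ", chrom,
         " of length ", len)
  }
  s <- as.character(Biostrings::subseq(assembly[[chrom]], start = lo, end = hi))
  if (grepl("N", s, fixed = TRUE)) {
    warning("window at ", chrom, ":", pos, " contains N")
  }
  s
}

#' Replace the centre base of an odd-length window
#'
#' @param window odd-length sequence string.
#' @param allele single replacement base.
#' @return The window with its centre base replaced.
#' @export
apply_allele <- function(window, allele) {
  n <- nchar(window)
  if (n %% 2L != 1L) stop("window length must be odd")
  c0 <- (n + 1L) %/% 2L
  paste0(substr(window, 1L, c0 - 1L), allele,
         substr(window, c0 + 1L, n))
}

#' Read a curated gene list
#'
#' Plain text, one gene identifier per line; `#` starts a comment.
#'
#' @param path file path.
#' @return Character vector of gene identifiers.
#' @export
read_curated_genes <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
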
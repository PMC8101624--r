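#' Construct a variant table
#'
#' Variants are kept in a plain data frame with one row per SNP. Positions
#' are 1-based (VCF convention); interval tracks are 0-based half-open (BED
#' convention), and all cross-queries convert via the rule that a variant at
#' position `p` overlaps `[s, e)` iff `s <= p - 1 < e`.
#'
#' @param rsid character vector of SNP identifiers.
#' @param chrom contig names.
#' @param pos 1-based positions.
#' @param ref,alt single-base reference and alternative alleles.
#' @param source one of `"index"`, `"proxy"`, `"imputed"` per variant.
#' @param pvalue association p-values (`NA` allowed for proxies).
#' @param index_rsid identifier of the linked index SNP (proxies only).
#' @param r2_to_index r-squared to the linked index SNP (proxies only).
#' @param reported_genes comma-separated reported gene identifiers.
#' @return A `data.frame` with class `c("variant_set", "data.frame")`.
#' @export
variant_set <- function(rsid, chrom, pos, ref, alt,
                        source = "index",
                        pvalue = NA_real_,
                        index_rsid = NA_character_,
                        r2_to_index = NA_real_,
                        reported_genes = "") {
  n <- length(rsid)
  rl <- function(x) if (length(x) == 1L && n != 1L) rep(x, n) else x
  source <- rl(source); pvalue <- rl(pvalue); index_rsid <- rl(index_rsid)
  r2_to_index <- rl(r2_to_index); reported_genes <- rl(reported_genes)
  df <- data.frame(
    rsid = as.character(rsid),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    source = as.character(source),
    pvalue = as.numeric(pvalue),
    index_rsid = as.character(index_rsid),
    r2_to_index = as.numeric(r2_to_index),
    reported_genes = as.character(reported_genes),
    stringsAsFactors = FALSE
  )
  class(df) <- c("variant_set", "data.frame")
  validate_variants(df)
}

validate_variants <- function(df) {
  if (nrow(df) == 0L) return(df)
  bases <- c("A", "C", "G", "T")
  if (!all(df$ref %in% bases) || !all(df$alt %in% bases)) {
    stop("variant alleles must be single bases in {A, C, G, T}")
  }
  if (any(df$ref == df$alt)) {
    stop("ref and alt alleles must differ: ",
         paste(df$rsid[df$ref == df$alt], collapse = ", "))
  }
  if (any(df$pos < 1L)) stop("variant positions must be >= 1")
  if (!all(df$source %in% c("index", "proxy", "imputed"))) {
    stop("variant source must be one of index, proxy, imputed")
  }
  is_proxy <- df$source == "proxy"
  if (any(is_proxy & is.na(df$r2_to_index))) {
    stop("proxy variants must carry r2_to_index")
  }
  if (any(!is_proxy & !is.na(df$r2_to_index))) {
    stop("r2_to_index is only meaningful for proxy variants")
  }
  df
}

#' Read a GWAS association table
#'
#' Reads a tab-separated association table (GWAS-Catalog-like columns
#' reduced to `rsid`, `chrom`, `pos`, `ref`, `alt`, `pvalue`,
#' `reported_genes`) and keeps the rows below the significance threshold.
#' Row order is preserved. Indels and multi-allelic records (allele fields
#' not a single A/C/G/T base) are dropped with a message reporting the
#' count; the pipeline scores single-base substitutions only.
#'
#' @param path path to the TSV file.
#' @param p_threshold keep rows with `pvalue < p_threshold`.
#' @param source source class assigned to the returned variants
#'   (`"index"` for the primary GWAS table, `"imputed"` for imputed tables).
#' @return A `variant_set` data frame.
#' @export
read_association_table <- function(path, p_threshold, source = "index") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  needed <- c("rsid", "chrom", "pos", "ref", "alt", "pvalue",
              "reported_genes")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("association table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(variant_set(character(), character(), integer(),
                       character(), character())[0, ])
  }
  pv <- suppressWarnings(as.numeric(df$pvalue))
  bad <- which(is.na(pv) & !(df$pvalue %in% c("", "NA")))
  if (length(bad) > 0L) {
    stop("unparsable p-value at line ", bad[1] + 1L, " of ", path,
         ": '", df$pvalue[bad[1]], "'")
  }
  snv <- df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T")
  if (any(!snv)) {
    message("read_association_table: dropped ", sum(!snv),
            " non-SNV record(s) from ", basename(path))
    df <- df[snv, , drop = FALSE]
    pv <- pv[snv]
  }
  keep <- !is.na(pv) & pv < p_threshold
  df <- df[keep, , drop = FALSE]
  variant_set(df$rsid, df$chrom, as.integer(df$pos), df$ref, df$alt,
              source = source, pvalue = pv[keep],
              reported_genes = df$reported_genes)
}

#' Write a variant table as an association TSV
#'
#' Writes the seven-column association schema read by
#' [read_association_table()].
#'
#' @param variants a `variant_set` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(variants, path) {
  out <- data.frame(
    rsid = variants$rsid, chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt,
    pvalue = format(variants$pvalue, digits = 15, trim = TRUE,
                    scientific = TRUE),
    reported_genes = variants$reported_genes,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

split_genes <- function(x) {
  g <- strsplit(x, ",", fixed = TRUE)
  lapply(g, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}
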
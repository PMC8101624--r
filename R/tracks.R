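#' @importFrom GenomicRanges GRanges start end findOverlaps seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols queryHits subjectHits
NULL

# Mnemonics of the 18-state segmentation model, used when emitting BED.
STATE_MNEMONICS <- c(
  "1_TssA", "2_TssFlnk", "3_TssFlnkU", "4_TssFlnkD", "5_Tx", "6_TxWk",
  "7_EnhG1", "8_EnhG2", "9_EnhA1", "10_EnhA2", "11_EnhWk", "12_ZNF/Rpts",
  "13_Het", "14_TssBiv", "15_EnhBiv", "16_ReprPC", "17_ReprPCWk", "18_Quies"
)

state_label_to_code <- function(labels) {
  code <- suppressWarnings(as.integer(labels))
  mn <- regmatches(labels, regexpr("^[0-9]+(?=_)", labels, perl = TRUE))
  has_mn <- grepl("^[0-9]+_", labels)
  code[has_mn] <- as.integer(sub("_.*$", "", labels[has_mn]))
  bad <- is.na(code) | code < 1L | code > 18L
  if (any(bad)) {
    stop("unknown chromatin state label(s): ",
         paste(unique(labels[bad]), collapse = ", "))
  }
  code
}

#' Read an 18-state chromatin segmentation BED file
#'
#' Accepts BED4 whose name field is either a `"9_EnhA1"`-style mnemonic or a
#' bare integer state code 1..18. Intervals are validated to be
#' non-overlapping within each contig (a segmentation must partition the
#' bases it covers); gaps are allowed and queried positions falling in a gap
#' have no state.
#'
#' @param path BED4 file path.
#' @param cell_type name of the cell type the track belongs to.
#' @return A `segmentation_track`: list with `cell_type` and a `GRanges`
#'   (1-based, as conventional for GRanges) carrying an integer `state`
#'   metadata column.
#' @export
read_segmentation_bed <- function(path, cell_type) {
  gr <- rtracklayer::import(path, format = "bed")
  state <- state_label_to_code(gr$name)
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                               IRanges::ranges(gr), state = state)
  gr <- GenomicRanges::sort(gr)
  self <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  if (length(self) > 0L) {
    i <- S4Vectors::queryHits(self)[1]
    stop("segmentation ", path, " has overlapping intervals on contig ",
         as.character(GenomicRanges::seqnames(gr))[i],
         " (a segmentation must partition each contig)")
  }
  structure(list(cell_type = cell_type, gr = gr),
            class = "segmentation_track")
}

#' Write a segmentation track as BED4
#'
#' Emitted state labels always use the `"N_mnemonic"` dialect.
#'
#' @param track a `segmentation_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segmentation_bed <- function(track, path) {
  gr <- track$gr
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = STATE_MNEMONICS[S4Vectors::mcols(gr)$state],
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a narrowPeak (BED6+4) file
#'
#' Column 10 is the summit offset from the interval start, or -1 when no
#' summit was called; -1 is recorded as `NA`. Peaks may overlap one another
#' (unlike segmentation states), so no overlap validation is applied.
#'
#' @param path narrowPeak file path.
#' @param cell_type name of the cell type the track belongs to.
#' @param mark `"H3K27ac"` or `"DHS"`.
#' @return A `peak_track`: list with `cell_type`, `mark` and a `GRanges`
#'   with metadata columns `score`, `signal`, `pval`, `qval`, `summit`.
#' @export
read_narrowpeak <- function(path, cell_type, mark = c("H3K27ac", "DHS")) {
  mark <- match.arg(mark)
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  if (ncol(df) < 10L) {
    stop("narrowPeak ", path, " has ", ncol(df),
         " columns; 10 (BED6+4) are required")
  }
  summit <- as.integer(df[[10]])
  summit[summit < 0L] <- NA_integer_
  width <- df[[3]] - df[[2]]
  bad <- which(!is.na(summit) & summit >= width)
  if (length(bad) > 0L) {
    stop("narrowPeak ", path, ": summit offset outside peak at line ", bad[1])
  }
  gr <- GenomicRanges::GRanges(
    df[[1]], IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]]),
    name = as.character(df[[4]]), score = df[[5]],
    signal = df[[7]], pval = df[[8]], qval = df[[9]], summit = summit
  )
  structure(list(cell_type = cell_type, mark = mark, gr = gr),
            class = "peak_track")
}

#' Write a peak track as narrowPeak
#'
#' @param track a `peak_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(track, path) {
  gr <- track$gr
  m <- S4Vectors::mcols(gr)
  summit <- m$summit
  summit[is.na(summit)] <- -1L
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(m$name)) m$name else ".",
    score = if (!is.null(m$score)) m$score else 0L,
    strand = ".",
    signal = if (!is.null(m$signal)) m$signal else 0,
    pval = if (!is.null(m$pval)) m$pval else -1,
    qval = if (!is.null(m$qval)) m$qval else -1,
    summit = summit,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRanges point representation of variant positions (1-based width-1).
variant_gpos <- function(variants) {
  GenomicRanges::GRanges(variants$chrom,
                         IRanges::IRanges(start = variants$pos, width = 1L))
}

# For each variant, TRUE iff its position overlaps any interval of `gr`.
# Contigs absent from the track count as non-overlapping.
variants_overlap_gr <- function(variants, gr) {
  if (nrow(variants) == 0L) return(logical(0))
  q <- variant_gpos(variants)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, gr))
  out <- logical(nrow(variants))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Chromatin state at a variant position
#'
#' Point query against one segmentation track: the state whose BED interval
#' `[s, e)` satisfies `s <= pos - 1 < e`, or `NA` when the position falls in
#' a gap or on a contig absent from the track.
#'
#' @param variants a `variant_set` data frame.
#' @param track a `segmentation_track`.
#' @return A data frame with columns `rsid`, `cell_type`, `state`
#'   (integer, `NA` = no state).
#' @export
state_at <- function(variants, track) {
  state <- rep(NA_integer_, nrow(variants))
  if (nrow(variants) > 0L) {
    q <- variant_gpos(variants)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(q, track$gr))
    state[S4Vectors::queryHits(hits)] <-
      S4Vectors::mcols(track$gr)$state[S4Vectors::subjectHits(hits)]
  }
  data.frame(rsid = variants$rsid,
             cell_type = rep(track$cell_type, nrow(variants)),
             state = state, stringsAsFactors = FALSE)
}

#' Is a chromatin state strong regulatory chromatin?
#'
#' @param state integer state codes (`NA` = position outside all segments).
#' @param config an [enhpro_config()] whose `strong_states` defines the
#'   strong promoter/enhancer set (default `{1, 3, 8, 9}`).
#' @return Logical vector; `NA` states are `FALSE`.
#' @export
is_strong_regulatory <- function(state, config = enhpro_config()) {
  !is.na(state) & state %in% config$strong_states
}
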
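#' Call EnhPro SNPs from chromatin evidence
#'
#' An EnhPro SNP sits in strong enhancer/promoter chromatin preferentially
#' in the focal cell type: strong chromatin (states in
#' `config$strong_states`) at the SNP in the focal cell type but in no more
#' than `config$state_max_other` of the comparison cell types, an H3K27ac
#' narrowPeak at the SNP in the focal cell type but in no more than
#' `config$k27ac_max_other` comparison types (4 instead of 3 is the relaxed
#' protocol), and a focal-cell DNaseI-hypersensitivity peak. Every variant
#' is returned with its full evidence regardless of outcome.
#'
#' The comparison panel is normally the 12 heterologous cell cultures; a
#' panel of any other size triggers a warning and the thresholds are then
#' interpreted as absolute counts.
#'
#' @param variants a `variant_set`.
#' @param focal name of the focal cell type.
#' @param others character vector of comparison cell-type names
#'   (conventionally 12).
#' @param segmentations named list of `segmentation_track`s covering
#'   `c(focal, others)`.
#' @param k27ac named list of H3K27ac `peak_track`s covering
#'   `c(focal, others)`.
#' @param dhs a DHS `peak_track` for the focal cell type (or a named list
#'   containing one for `focal`; only the focal track is consulted).
#' @param config an [enhpro_config()].
#' @return A data frame (one row per variant): `rsid`, `chrom`, `pos`,
#'   `focal_state`, `focal_strong`, `n_other_strong`, `k27ac_focal`,
#'   `n_other_k27ac`, `dhs_focal`, `is_enhpro`.
#' @export
classify_enhpro <- function(variants, focal, others, segmentations,
                            k27ac, dhs, config = enhpro_config()) {
  if (length(others) != 12L) {
    warning("comparison panel has ", length(others),
            " cell types (12 expected); sharing thresholds are applied ",
            "as absolute counts")
  }
  need <- c(focal, others)
  if (!all(need %in% names(segmentations))) {
    stop("missing segmentation track(s): ",
         paste(setdiff(need, names(segmentations)), collapse = ", "))
  }
  if (!all(need %in% names(k27ac))) {
    stop("missing H3K27ac track(s): ",
         paste(setdiff(need, names(k27ac)), collapse = ", "))
  }
  dhs_track <- if (inherits(dhs, "peak_track")) dhs else dhs[[focal]]
  if (is.null(dhs_track)) stop("missing focal DHS track")

  focal_state <- state_at(variants, segmentations[[focal]])$state
  focal_strong <- is_strong_regulatory(focal_state, config)

  n_other_strong <- integer(nrow(variants))
  n_other_k27ac <- integer(nrow(variants))
  for (ct in others) {
    st <- state_at(variants, segmentations[[ct]])$state
    n_other_strong <- n_other_strong + is_strong_regulatory(st, config)
    n_other_k27ac <- n_other_k27ac +
      variants_overlap_gr(variants, k27ac[[ct]]$gr)
  }
  k27ac_focal <- variants_overlap_gr(variants, k27ac[[focal]]$gr)
  dhs_focal <- variants_overlap_gr(variants, dhs_track$gr)

  is_enhpro <- focal_strong &
    n_other_strong <= config$state_max_other &
    k27ac_focal &
    n_other_k27ac <= config$k27ac_max_other &
    dhs_focal

  data.frame(
    rsid = variants$rsid, chrom = variants$chrom, pos = variants$pos,
    focal_state = focal_state, focal_strong = focal_strong,
    n_other_strong = n_other_strong, k27ac_focal = k27ac_focal,
    n_other_k27ac = n_other_k27ac, dhs_focal = dhs_focal,
    is_enhpro = is_enhpro, stringsAsFactors = FALSE
  )
}

#' Write the EnhPro evidence table
#'
#' @param records output of [classify_enhpro()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_enhpro_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Display label for the chromatin context of a SNP
#'
#' Inspects the focal segmentation in a small neighbourhood around each SNP
#' (total width `config$state_label_window_bp`): "Str prom" when only
#' strong promoter chromatin (state 1) is present, "Str enh" for strong
#' enhancer states only (3/8/9), and "Str enh/prom" when segments of both
#' kinds flank the SNP.
#'
#' @param variants a `variant_set`.
#' @param track the focal `segmentation_track`.
#' @param config an [enhpro_config()].
#' @return Character vector of labels (`""` when no strong state is near).
#' @export
chromatin_state_label <- function(variants, track, config = enhpro_config()) {
  if (nrow(variants) == 0L) return(character(0))
  half <- config$state_label_window_bp %/% 2L
  q <- GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(start = pmax(variants$pos - half, 1L),
                     end = variants$pos + half)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, track$gr))
  states <- S4Vectors::mcols(track$gr)$state[S4Vectors::subjectHits(hits)]
  prom_states <- intersect(config$strong_states, 1:2)
  enh_states <- setdiff(config$strong_states, prom_states)
  vapply(seq_len(nrow(variants)), function(i) {
    s <- states[S4Vectors::queryHits(hits) == i]
    has_prom <- any(s %in% prom_states)
    has_enh <- any(s %in% enh_states)
    if (has_prom && has_enh) "Str enh/prom"
    else if (has_prom) "Str prom"
    else if (has_enh) "Str enh"
    else ""
  }, character(1))
}
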
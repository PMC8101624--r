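DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' Probabilities are normalized per position; each position is classified as
#' `conserved` (top-base probability at or above
#' `config$conserved_prob_min`), `partly_conserved` (top-base probability at
#' or above `config$partly_conserved_prob_min`) or `unconstrained`.
#'
#' @param tf_name transcription factor name.
#' @param probs 4 x width numeric matrix (rows A, C, G, T) of probabilities
#'   or counts; columns are normalized to sum to 1.
#' @param config an [enhpro_config()].
#' @return A `pwm` object: list with `tf_name`, `width`, `probs`,
#'   `position_class`.
#' @export
pwm <- function(tf_name, probs, config = enhpro_config()) {
  if (is.null(rownames(probs))) rownames(probs) <- DNA_BASES
  probs <- probs[DNA_BASES, , drop = FALSE]
  if (ncol(probs) < 4L) stop("PWM width must be at least 4")
  if (any(probs < 0)) stop("PWM probabilities must be non-negative")
  probs <- sweep(probs, 2L, colSums(probs), "/")
  top_i <- apply(probs, 2L, which.max)
  top <- probs[cbind(top_i, seq_len(ncol(probs)))]
  cls <- ifelse(top >= config$conserved_prob_min, "conserved",
                ifelse(top >= config$partly_conserved_prob_min,
                       "partly_conserved", "unconstrained"))
  structure(list(tf_name = tf_name, width = ncol(probs), probs = probs,
                 position_class = cls, top_prob = top,
                 top_base = DNA_BASES[top_i]),
            class = "pwm")
}

#' Read PWMs from a TRANSFAC-style flat file
#'
#' Parses `ID` records with `P0`/`PO`-headed count rows (columns A C G T)
#' terminated by `//`. A pseudocount is added to every count cell before
#' per-position normalization so that no base has probability zero and
#' allele fold changes stay finite.
#'
#' @param path flat-file path.
#' @param pseudocount value added to each count cell.
#' @param config an [enhpro_config()] (position-class thresholds).
#' @return A list of `pwm` objects.
#' @export
read_transfac_pwm <- function(path, pseudocount = 0.01,
                              config = enhpro_config()) {
  lines <- readLines(path)
  pwms <- list()
  id <- NULL
  rows <- list()
  flush <- function() {
    if (is.null(id)) return()
    if (length(rows) == 0L) stop("matrix ", id, " has no count rows")
    m <- do.call(rbind, rows)
    pwms[[length(pwms) + 1L]] <<- pwm(id, t(m) + pseudocount, config)
    id <<- NULL
    rows <<- list()
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, "XX") || startsWith(ln, "BF") ||
        startsWith(ln, "CC")) next
    if (startsWith(ln, "ID")) {
      id <- trimws(sub("^ID\\s+", "", ln))
    } else if (startsWith(ln, "NA") && is.null(id)) {
      id <- trimws(sub("^NA\\s+", "", ln))
    } else if (grepl("^P[0O]\\b", ln)) {
      next  # column header row
    } else if (ln == "//") {
      flush()
    } else if (grepl("^[0-9]+\\s", ln)) {
      parts <- strsplit(ln, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts[2:5]))
      if (any(is.na(vals))) {
        stop("non-numeric count in matrix ", if (is.null(id)) "?" else id,
             " at row '", ln, "'")
      }
      rows[[length(rows) + 1L]] <- vals
    }
  }
  flush()
  pwms
}

#' Write PWMs to a TRANSFAC-style flat file
#'
#' Probabilities are scaled to integer counts per 1000 observations.
#'
#' @param pwms list of `pwm` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transfac_pwm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(c(paste("ID", p$tf_name), "P0\tA\tC\tG\tT"), con)
    counts <- round(p$probs * 1000)
    for (j in seq_len(p$width)) {
      cons <- DNA_BASES[which.max(p$probs[, j])]
      writeLines(paste(c(sprintf("%02d", j), counts[, j], cons),
                       collapse = "\t"), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Reverse-complement a PWM
#'
#' @param x a `pwm` object.
#' @return A `pwm` with reversed positions and complemented base rows.
#' @export
pwm_reverse_complement <- function(x) {
  probs <- x$probs[c("T", "G", "C", "A"), rev(seq_len(x$width)), drop = FALSE]
  rownames(probs) <- DNA_BASES
  out <- x
  out$probs <- probs
  out$position_class <- rev(x$position_class)
  out$top_prob <- rev(x$top_prob)
  out$top_base <- chartr("ACGT", "TGCA", rev(x$top_base))
  out
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Curate a PWM placement against a sequence window
#'
#' Implements the hand-curation rules for retaining a TFBS prediction:
#' (a) every conserved PWM position must match its top-probability base
#' exactly; (b) at most one partly conserved position may carry a partial
#' match, i.e. a non-top base whose probability is at least
#' `config$partial_match_min_frac` of the position's top probability;
#' (c) no position of any class may carry a base below that fraction of
#' the top probability.
#'
#' @param window full (odd-length) sequence window, forward orientation.
#' @param strand `"+"` or `"-"`; on `"-"` the PWM is matched against the
#'   reverse complement of the window.
#' @param offset 1-based start of the PWM placement within the (possibly
#'   reverse-complemented) window.
#' @param x a `pwm` object.
#' @param config an [enhpro_config()].
#' @return A list with `pass` (flag) and `reasons` (character vector among
#'   `conserved_mismatch`, `too_many_partial`, `below_partial_floor`).
#' @export
curate <- function(window, strand, offset, x, config = enhpro_config()) {
  seqd <- if (strand == "-") revcomp(window) else window
  if (offset < 1L || offset + x$width - 1L > nchar(seqd)) {
    stop("placement does not fit inside the window")
  }
  bases <- strsplit(substr(seqd, offset, offset + x$width - 1L),
                    "", fixed = TRUE)[[1]]
  curate_bases(bases, x, config$partial_match_min_frac)
}

# core of the curation rules, on an already-extracted base vector
curate_bases <- function(bases, x, frac) {
  base_p <- x$probs[cbind(match(bases, DNA_BASES), seq_len(x$width))]
  is_top <- bases == x$top_base
  reasons <- character()
  if (any(x$position_class == "conserved" & !is_top)) {
    reasons <- c(reasons, "conserved_mismatch")
  }
  partial <- x$position_class == "partly_conserved" & !is_top &
    base_p >= frac * x$top_prob
  if (sum(partial) > 1L) reasons <- c(reasons, "too_many_partial")
  if (any(base_p < frac * x$top_prob)) {
    reasons <- c(reasons, "below_partial_floor")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Scan a Ref/Alt window pair against one PWM
#'
#' Enumerates every placement (both strands, every offset) of the PWM that
#' covers the centre base and fits in the window. For each placement the
#' PWM probability of the centre base is read under both alleles at the
#' SNP-aligned PWM position; the fold change is the ratio of the larger to
#' the smaller. A placement is `allele_specific` iff the fold change
#' strictly exceeds `config$tfbs_fold_min`, the favoured allele's window
#' passes curation, and the disfavoured allele either fails curation or has
#' the strictly lower centre probability. Placements are sorted by the
#' favoured-allele log-probability sum, ties broken by strand (`+` first)
#' then smaller offset.
#'
#' Minus-strand offsets are expressed in reverse-complemented window
#' coordinates; the centre base is self-locating because windows are odd.
#'
#' @param ref_window,alt_window equal odd-length windows differing only at
#'   the centre base.
#' @param x a `pwm` object.
#' @param config an [enhpro_config()].
#' @return A data frame of placements: `tf_name`, `strand`, `offset`,
#'   `snp_pwm_index`, `ref_center_prob`, `alt_center_prob`, `fold_change`,
#'   `favored_allele`, `ref_curation_pass`, `alt_curation_pass`,
#'   `allele_specific`, `favored_logp`.
#' @export
scan_allele_pair <- function(ref_window, alt_window, x,
                             config = enhpro_config()) {
  L <- nchar(ref_window)
  if (L %% 2L != 1L || nchar(alt_window) != L) {
    stop("windows must be equal odd lengths")
  }
  ctr <- (L + 1L) %/% 2L
  if (substr(ref_window, 1L, ctr - 1L) != substr(alt_window, 1L, ctr - 1L) ||
      substr(ref_window, ctr + 1L, L) != substr(alt_window, ctr + 1L, L)) {
    stop("windows must differ only at the centre base")
  }
  W <- x$width
  if (W > L) {
    message("scan_allele_pair: PWM ", x$tf_name, " wider than window; skipped")
    return(empty_scan_frame())
  }
  offsets <- seq.int(max(1L, ctr - W + 1L), min(ctr, L - W + 1L))
  n_off <- length(offsets)
  n <- 2L * n_off
  strand_v <- rep(c("+", "-"), each = n_off)
  offset_v <- rep(offsets, 2L)
  idx_v <- ctr - offset_v + 1L
  rp_v <- ap_v <- logp_v <- numeric(n)
  rc_v <- ac_v <- logical(n)
  frac <- config$partial_match_min_frac
  k <- 0L
  for (strand in c("+", "-")) {
    refw <- if (strand == "-") revcomp(ref_window) else ref_window
    altw <- if (strand == "-") revcomp(alt_window) else alt_window
    refb <- strsplit(refw, "", fixed = TRUE)[[1]]
    altb <- strsplit(altw, "", fixed = TRUE)[[1]]
    for (off in offsets) {
      k <- k + 1L
      idx <- ctr - off + 1L
      span <- off:(off + W - 1L)
      rp <- x$probs[refb[ctr], idx]
      ap <- x$probs[altb[ctr], idx]
      rp_v[k] <- rp; ap_v[k] <- ap
      rc_v[k] <- curate_bases(refb[span], x, frac)$pass
      ac_v[k] <- curate_bases(altb[span], x, frac)$pass
      favb <- if (ap > rp) altb[span] else refb[span]
      logp_v[k] <- sum(log(x$probs[cbind(match(favb, DNA_BASES),
                                         seq_len(W))]))
    }
  }
  hi <- pmax(rp_v, ap_v)
  lo <- pmin(rp_v, ap_v)
  fold_v <- ifelse(hi == 0, 1, ifelse(lo == 0, Inf, hi / lo))
  favored_v <- ifelse(ap_v > rp_v, "alt", "ref")
  fav_pass <- ifelse(favored_v == "ref", rc_v, ac_v)
  dis_pass <- ifelse(favored_v == "ref", ac_v, rc_v)
  strictly_lower <- lo < hi
  asf <- fold_v > config$tfbs_fold_min & fav_pass &
    (!dis_pass | strictly_lower)
  out <- data.frame(
    tf_name = x$tf_name, strand = strand_v, offset = offset_v,
    snp_pwm_index = idx_v, ref_center_prob = rp_v, alt_center_prob = ap_v,
    fold_change = fold_v, favored_allele = favored_v,
    ref_curation_pass = rc_v, alt_curation_pass = ac_v,
    allele_specific = asf, favored_logp = logp_v,
    stringsAsFactors = FALSE
  )
  ord <- order(-out$favored_logp, out$strand != "+", out$offset)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_scan_frame <- function() {
  data.frame(
    tf_name = character(), strand = character(), offset = integer(),
    snp_pwm_index = integer(), ref_center_prob = numeric(),
    alt_center_prob = numeric(), fold_change = numeric(),
    favored_allele = character(), ref_curation_pass = logical(),
    alt_curation_pass = logical(), allele_specific = logical(),
    favored_logp = numeric(), stringsAsFactors = FALSE
  )
}

#' TF expression gate
#'
#' A predicted TF is retained only when its focal-cell RPKM is at least
#' `config$tf_min_rpkm` (inclusive). TFs absent from the expression table
#' fail the gate with a message.
#'
#' @param tf_name TF name (matched against expression row names).
#' @param table RPKM matrix.
#' @param focal focal cell-type column.
#' @param config an [enhpro_config()].
#' @return Logical flag.
#' @export
tf_expressed <- function(tf_name, table, focal, config = enhpro_config()) {
  if (!tf_name %in% rownames(table)) {
    message("tf_expressed: ", tf_name, " absent from expression table")
    return(FALSE)
  }
  table[tf_name, focal] >= config$tf_min_rpkm
}

#' Predict allele-specific TFBS at a variant
#'
#' Fetches the SNP-centred window from the assembly (the assembly base must
#' equal the variant's reference allele), builds the Alt window, scans the
#' allele pair against every PWM, keeps allele-specific placements whose TF
#' passes the focal expression gate, and deduplicates per
#' (TF, favoured allele).
#'
#' @param variant single-row `variant_set`.
#' @param assembly `DNAStringSet`.
#' @param pwms list of `pwm` objects.
#' @param expression RPKM matrix.
#' @param focal focal cell-type column.
#' @param config an [enhpro_config()].
#' @return A data frame sorted by (TF name, allele): `rsid`, `tf_name`,
#'   `favored_allele`.
#' @export
predict_allele_specific_tfbs <- function(variant, assembly, pwms, expression,
                                         focal, config = enhpro_config()) {
  stopifnot(nrow(variant) == 1L)
  win <- fetch_window(assembly, variant$chrom, variant$pos,
                      config$tfbs_window)
  ctr <- (config$tfbs_window + 1L) %/% 2L
  if (substr(win, ctr, ctr) != variant$ref) {
    stop("allele orientation error at ", variant$rsid, ": assembly base ",
         substr(win, ctr, ctr), " != ref allele ", variant$ref)
  }
  alt_win <- apply_allele(win, variant$alt)
  hits <- lapply(pwms, function(p) {
    sc <- scan_allele_pair(win, alt_win, p, config)
    sc[sc$allele_specific, , drop = FALSE]
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(data.frame(rsid = character(), tf_name = character(),
                      favored_allele = character(), stringsAsFactors = FALSE))
  }
  keep <- vapply(unique(hits$tf_name), function(tf) {
    tf_expressed(tf, expression, focal, config)
  }, logical(1))
  hits <- hits[hits$tf_name %in% names(keep)[keep], , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(rsid = character(), tf_name = character(),
                      favored_allele = character(), stringsAsFactors = FALSE))
  }
  out <- unique(data.frame(rsid = variant$rsid, tf_name = hits$tf_name,
                           favored_allele = hits$favored_allele,
                           stringsAsFactors = FALSE))
  out <- out[order(out$tf_name, out$favored_allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}
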
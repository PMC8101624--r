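#' Read a genotype panel from a VCF file
#'
#' Loads biallelic SNVs and their diploid genotype calls. Indels and
#' multi-allelic records are dropped with a message reporting the count.
#' Calls are stored as two per-haplotype allele matrices (0 = REF, 1 = ALT,
#' `NA` = missing); the panel is flagged phased when every non-missing call
#' uses the `|` separator, in which case haplotype frequencies are exact
#' counts rather than EM estimates.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return A `genotype_panel`: list with `samples`, `loci` (data frame:
#'   `rsid`, `chrom`, `pos`, `ref`, `alt`), `hap1`, `hap2` (loci x samples
#'   integer matrices), `dosage` (ALT-allele dosage, `hap1 + hap2`) and
#'   `phased` flag.
#' @export
read_genotype_panel <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snv <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!snv)) {
    message("read_genotype_panel: dropped ", sum(!snv),
            " non-SNV / multi-allelic record(s)")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[snv, , drop = FALSE]
  fix <- fix[snv, , drop = FALSE]
  phased <- !any(grepl("/", gt, fixed = TRUE), na.rm = TRUE)
  a1 <- suppressWarnings(
    matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt)))
  a2 <- suppressWarnings(
    matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt)))
  a1[a1 > 1L] <- NA_integer_   # treat rare >biallelic leftovers as missing
  a2[a2 > 1L] <- NA_integer_
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  loci <- data.frame(
    rsid = fix[, "ID"], chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]), ref = fix[, "REF"], alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  structure(
    list(samples = colnames(gt), loci = loci,
         hap1 = a1, hap2 = a2, dosage = a1 + a2, phased = phased),
    class = "genotype_panel"
  )
}

#' Two-locus haplotype frequencies
#'
#' Estimates the four two-locus haplotype frequencies (`pAB`, `pAb`, `paB`,
#' `pab`; `A`/`B` denote the REF alleles at locus 1 and 2). For a phased
#' panel these are exact haplotype counts over `2n` chromosomes. For an
#' unphased panel they are maximum-likelihood estimates from the standard
#' EM algorithm, in which only the double-heterozygote class is ambiguous.
#' Samples missing a call at either locus are excluded pairwise.
#'
#' The EM is initialized at linkage equilibrium nudged towards positive `D`
#' so that when the data admit two equal-likelihood optima (e.g. a panel of
#' double heterozygotes) the `D >= 0` solution is returned deterministically.
#'
#' @param panel a `genotype_panel`.
#' @param locus1,locus2 row indices or rsids of the two loci.
#' @param tol EM convergence tolerance (max absolute frequency change).
#' @param max_iter EM iteration cap.
#' @return A list with `pAB`, `pAb`, `paB`, `pab`, `n` (samples used) and
#'   `loglik` (final observed-data log-likelihood; `NA` for phased panels).
#' @export
haplotype_freqs_em <- function(panel, locus1, locus2,
                               tol = 1e-8, max_iter = 1000L) {
  i <- resolve_locus(panel, locus1)
  j <- resolve_locus(panel, locus2)
  if (panel$phased) {
    h1a <- panel$hap1[i, ]; h1b <- panel$hap2[i, ]
    h2a <- panel$hap1[j, ]; h2b <- panel$hap2[j, ]
    ok <- !is.na(h1a) & !is.na(h2a)
    n <- sum(ok)
    if (n < 2L) stop("fewer than 2 samples with complete calls at both loci")
    # haplotype alleles: 0 = REF (A/B), 1 = ALT (a/b)
    x <- c(h1a[ok], h1b[ok])
    y <- c(h2a[ok], h2b[ok])
    tab <- table(factor(x, levels = 0:1), factor(y, levels = 0:1)) / (2 * n)
    return(list(pAB = as.numeric(tab[1, 1]), pAb = as.numeric(tab[1, 2]),
                paB = as.numeric(tab[2, 1]), pab = as.numeric(tab[2, 2]),
                n = n, loglik = NA_real_))
  }
  g1 <- panel$dosage[i, ]
  g2 <- panel$dosage[j, ]
  ok <- !is.na(g1) & !is.na(g2)
  n <- sum(ok)
  if (n < 2L) stop("fewer than 2 samples with complete calls at both loci")
  g1 <- g1[ok]; g2 <- g2[ok]
  em_haplotype_freqs(g1, g2, tol = tol, max_iter = max_iter)
}

resolve_locus <- function(panel, locus) {
  if (is.character(locus)) {
    i <- match(locus, panel$loci$rsid)
    if (is.na(i)) stop("locus ", locus, " not in panel")
    return(i)
  }
  as.integer(locus)
}

# EM over the 3x3 genotype table. Genotypes count ALT alleles; haplotype
# classes are (REF,REF)=AB, (REF,ALT)=Ab, (ALT,REF)=aB, (ALT,ALT)=ab.
em_haplotype_freqs <- function(g1, g2, tol, max_iter) {
  n <- length(g1)
  cnt <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  # fixed (unambiguous) haplotype counts contributed by all classes except
  # the double heterozygote
  nA1 <- 2 - g1   # copies of REF at locus 1 per sample
  fixed <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (a in 0:2) for (b in 0:2) {
    m <- cnt[a + 1, b + 1]
    if (m == 0 || (a == 1 && b == 1)) next
    # per sample: haplotypes are determined; (2-a) REF copies at locus 1
    # pair with (2-b) REF copies at locus 2 in the unique resolution
    hap <- resolve_unambiguous(a, b)
    fixed <- fixed + m * hap
  }
  ndh <- cnt[2, 2]
  pA <- sum(2 - g1) / (2 * n)
  pB <- sum(2 - g2) / (2 * n)
  # linkage-equilibrium start, nudged to D > 0 (deterministic tie-break)
  eps <- 1e-3 * min(pA * pB, (1 - pA) * (1 - pB),
                    pA * (1 - pB), (1 - pA) * pB)
  p <- c(AB = pA * pB + eps, Ab = pA * (1 - pB) - eps,
         aB = (1 - pA) * pB - eps, ab = (1 - pA) * (1 - pB) + eps)
  for (iter in seq_len(max_iter)) {
    denom <- p["AB"] * p["ab"] + p["Ab"] * p["aB"]
    w <- if (denom > 0) as.numeric(p["AB"] * p["ab"] / denom) else 0.5
    e <- fixed + ndh * c(AB = w, Ab = 1 - w, aB = 1 - w, ab = w)
    pnew <- e / (2 * n)
    delta <- max(abs(pnew - p))
    p <- pnew
    if (delta < tol) break
  }
  ll <- loglik_genotype_table(cnt, p)
  list(pAB = unname(p["AB"]), pAb = unname(p["Ab"]), paB = unname(p["aB"]),
       pab = unname(p["ab"]), n = n, loglik = ll)
}

# haplotype-pair resolution for non-double-het genotype combinations:
# returns the two haplotypes' class counts for one sample
resolve_unambiguous <- function(a, b) {
  # a, b = ALT dosage at locus 1, 2. Haplotype = (allele1, allele2) with
  # 0 = REF. For a or b in {0, 2} the assignment is forced.
  h <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  alleles1 <- c(rep(0, 2 - a), rep(1, a))
  alleles2 <- c(rep(0, 2 - b), rep(1, b))
  if (a %in% c(0, 2)) {
    pairs <- rbind(c(alleles1[1], alleles2[1]), c(alleles1[2], alleles2[2]))
  } else {
    # b is 0 or 2 here; locus-2 alleles identical, pairing irrelevant
    pairs <- rbind(c(alleles1[1], alleles2[1]), c(alleles1[2], alleles2[2]))
  }
  for (k in 1:2) {
    cls <- 1L + pairs[k, 1] * 2L + pairs[k, 2]
    h[cls] <- h[cls] + 1
  }
  h
}

# observed-data log-likelihood of a genotype table under haplotype freqs
loglik_genotype_table <- function(cnt, p) {
  ll <- 0
  for (a in 0:2) for (b in 0:2) {
    m <- cnt[a + 1, b + 1]
    if (m == 0) next
    ll <- ll + m * log(genotype_prob(a, b, p))
  }
  ll
}

genotype_prob <- function(a, b, p) {
  # probability of genotype (a, b) under random union of haplotypes
  hap_prob <- function(x, y) {
    p[1L + x * 2L + y]
  }
  pr <- 0
  for (x1 in 0:1) for (y1 in 0:1) for (x2 in 0:1) for (y2 in 0:1) {
    if (x1 + x2 == a && y1 + y2 == b) {
      pr <- pr + hap_prob(x1, y1) * hap_prob(x2, y2)
    }
  }
  unname(pr)
}

#' Squared LD correlation from haplotype frequencies
#'
#' `r^2 = D^2 / (pA pa pB pb)` with `D = pAB - pA pB`; the result is
#' clamped to `[0, 1]` against floating-point overshoot.
#'
#' @param freqs a list with `pAB`, `pAb`, `paB`, `pab` (e.g. from
#'   [haplotype_freqs_em()]).
#' @return r-squared in `[0, 1]`.
#' @export
r_squared <- function(freqs) {
  pAB <- freqs$pAB; pAb <- freqs$pAb; paB <- freqs$paB; pab <- freqs$pab
  tot <- pAB + pAb + paB + pab
  if (abs(tot - 1) > 1e-6) stop("haplotype frequencies must sum to 1")
  pA <- pAB + pAb
  pB <- pAB + paB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    stop("undefined LD: marginal allele frequency is 0 or 1")
  }
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  min(max(r2, 0), 1)
}

#' Expand index SNPs to LD proxies
#'
#' For each index SNP present in the panel, every panel site within
#' `search_window_bp` on the same contig whose r-squared with the index is
#' at least `r2_threshold` becomes a proxy variant carrying `index_rsid`
#' and `r2_to_index`. Index SNPs themselves are retained. A site proxying
#' several index SNPs keeps the link with the largest r-squared; a site that
#' is itself an index SNP stays an index record. Index SNPs absent from the
#' panel, and pairs with undefined LD, are skipped with a message.
#'
#' @param index_snps a `variant_set` of index SNPs.
#' @param panel a `genotype_panel`.
#' @param r2_threshold minimum r-squared (inclusive).
#' @param search_window_bp half-width of the search window.
#' @param tol,max_iter EM controls for unphased panels.
#' @return A `variant_set` of index SNPs followed by proxy SNPs.
#' @export
expand_proxies <- function(index_snps, panel, r2_threshold = 0.8,
                           search_window_bp = 500000L,
                           tol = 1e-8, max_iter = 1000L) {
  proxies <- list()
  n_skipped <- 0L
  for (k in seq_len(nrow(index_snps))) {
    rsid <- index_snps$rsid[k]
    i <- match(rsid, panel$loci$rsid)
    if (is.na(i)) {
      n_skipped <- n_skipped + 1L
      next
    }
    near <- which(
      panel$loci$chrom == panel$loci$chrom[i] &
        abs(panel$loci$pos - panel$loci$pos[i]) <= search_window_bp
    )
    near <- setdiff(near, i)
    for (j in near) {
      r2 <- tryCatch(
        r_squared(haplotype_freqs_em(panel, i, j, tol = tol,
                                     max_iter = max_iter)),
        error = function(e) NA_real_
      )
      if (!is.na(r2) && r2 >= r2_threshold) {
        proxies[[length(proxies) + 1L]] <- data.frame(
          rsid = panel$loci$rsid[j], chrom = panel$loci$chrom[j],
          pos = panel$loci$pos[j], ref = panel$loci$ref[j],
          alt = panel$loci$alt[j], index_rsid = rsid, r2 = r2,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (n_skipped > 0L) {
    message("expand_proxies: ", n_skipped, " index SNP(s) absent from panel")
  }
  if (length(proxies) == 0L) {
    return(index_snps)
  }
  px <- do.call(rbind, proxies)
  # keep the strongest index link per proxy rsid
  px <- px[order(px$rsid, -px$r2), , drop = FALSE]
  px <- px[!duplicated(px$rsid), , drop = FALSE]
  # sites that are themselves index SNPs stay index records
  px <- px[!(px$rsid %in% index_snps$rsid), , drop = FALSE]
  if (nrow(px) == 0L) return(index_snps)
  px <- px[order(px$chrom, px$pos, px$rsid), , drop = FALSE]
  out <- rbind(
    index_snps,
    variant_set(px$rsid, px$chrom, px$pos, px$ref, px$alt,
                source = "proxy", pvalue = NA_real_,
                index_rsid = px$index_rsid, r2_to_index = px$r2,
                reported_genes = "")
  )
  rownames(out) <- NULL
  out
}

#' Write the proxy-expansion table
#'
#' TSV with one row per proxy link: `index_rsid`, `proxy_rsid`, `chrom`,
#' `pos`, `r2`.
#'
#' @param variants output of [expand_proxies()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proxy_table <- function(variants, path) {
  px <- variants[variants$source == "proxy", , drop = FALSE]
  out <- data.frame(index_rsid = px$index_rsid, proxy_rsid = px$rsid,
                    chrom = px$chrom, pos = px$pos, r2 = px$r2_to_index,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
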
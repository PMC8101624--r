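# Independent brute-force oracles the implementation is checked against.

# Maximum-likelihood two-locus haplotype frequencies by 1-d grid search:
# allele-frequency margins are fixed at their observed values and pAB is
# scanned over its feasible range.
grid_ld_oracle <- function(dosage1, dosage2, step = 1e-3) {
  ok <- !is.na(dosage1) & !is.na(dosage2)
  g1 <- dosage1[ok]; g2 <- dosage2[ok]
  n <- length(g1)
  pA <- sum(2 - g1) / (2 * n)
  pB <- sum(2 - g2) / (2 * n)
  grid <- seq(max(0, pA + pB - 1), min(pA, pB), by = step)
  loglik <- vapply(grid, function(pAB) {
    p <- c(AB = pAB, Ab = pA - pAB, aB = pB - pAB, ab = 1 - pA - pB + pAB)
    if (any(p < -1e-12)) return(-Inf)
    p <- pmax(p, 0)
    ll <- 0
    for (i in seq_len(n)) {
      pr <- 0
      for (x1 in 0:1) for (y1 in 0:1) for (x2 in 0:1) for (y2 in 0:1) {
        if (x1 + x2 == g1[i] && y1 + y2 == g2[i]) {
          h <- function(x, y) p[1 + x * 2 + y]
          pr <- pr + h(x1, y1) * h(x2, y2)
        }
      }
      ll <- ll + log(pr)
    }
    ll
  }, numeric(1))
  pAB <- grid[which.max(loglik)]
  list(pAB = pAB, pAb = pA - pAB, paB = pB - pAB,
       pab = 1 - pA - pB + pAB)
}

# naive chromatin-state lookup: linear scan over a BED-style data frame
# (0-based half-open), positions 1-based
naive_state_at <- function(pos, bed0) {
  hit <- which(bed0$start <= pos - 1 & pos - 1 < bed0$end)
  if (length(hit) == 0L) NA_integer_ else bed0$state[hit[1]]
}

naive_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# independent re-implementation of the curation rules
naive_curate <- function(bases, probs, frac, cons_min, partly_min) {
  top_p <- apply(probs, 2, max)
  top_b <- rownames(probs)[apply(probs, 2, which.max)]
  cls <- ifelse(top_p >= cons_min, "c",
                ifelse(top_p >= partly_min, "p", "u"))
  bp <- mapply(function(b, j) probs[b, j], bases, seq_along(bases))
  if (any(cls == "c" & bases != top_b)) return(FALSE)
  if (sum(cls == "p" & bases != top_b & bp >= frac * top_p) > 1) {
    return(FALSE)
  }
  if (any(bp < frac * top_p)) return(FALSE)
  TRUE
}

# independent full scanner over all strand/offset placements
naive_scan <- function(ref_window, alt_window, probs, fold_min = 5,
                       frac = 0.2, cons_min = 0.85, partly_min = 0.5) {
  L <- nchar(ref_window)
  W <- ncol(probs)
  ctr <- (L + 1) %/% 2
  rows <- list()
  for (strand in c("+", "-")) {
    rw <- if (strand == "-") naive_revcomp(ref_window) else ref_window
    aw <- if (strand == "-") naive_revcomp(alt_window) else alt_window
    for (off in seq_len(L - W + 1)) {
      if (!(off <= ctr && ctr <= off + W - 1)) next
      idx <- ctr - off + 1
      rb <- substr(rw, ctr, ctr); ab <- substr(aw, ctr, ctr)
      rp <- probs[rb, idx]; ap <- probs[ab, idx]
      fold <- max(rp, ap) / min(rp, ap)
      favored <- if (ap > rp) "alt" else "ref"
      span <- function(w) strsplit(substr(w, off, off + W - 1), "")[[1]]
      rc <- naive_curate(span(rw), probs, frac, cons_min, partly_min)
      ac <- naive_curate(span(aw), probs, frac, cons_min, partly_min)
      fav <- if (favored == "ref") rc else ac
      dis <- if (favored == "ref") ac else rc
      asf <- fold > fold_min && fav && (!dis || min(rp, ap) < max(rp, ap))
      rows[[length(rows) + 1]] <- data.frame(
        strand = strand, offset = off, fold_change = fold,
        favored_allele = favored, ref_pass = rc, alt_pass = ac,
        allele_specific = asf, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

random_pwm_probs <- function(width) {
  m <- matrix(stats::rgamma(4 * width, shape = 0.6), nrow = 4,
              dimnames = list(c("A", "C", "G", "T")))
  sweep(m, 2, colSums(m), "/")
}

random_window <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# random disjoint 0-based half-open intervals with states
random_disjoint_bed <- function(n, max_pos, max_width = 900) {
  starts <- sort(sample(0:max_pos, n))
  ends <- starts + sample(50:max_width, n, replace = TRUE)
  keep <- logical(n)
  last_end <- -1
  for (i in seq_len(n)) {
    if (starts[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- ends[i]
    }
  }
  data.frame(start = starts[keep], end = ends[keep],
             state = sample(1:18, sum(keep), replace = TRUE))
}
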
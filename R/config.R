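#' Pipeline configuration
#'
#' Collects every tunable threshold of the prioritization pipeline in one
#' validated object. Defaults encode the published protocol: genome-wide
#' significance at `5e-8` for index SNPs, `6.6e-9` for imputed eBMD SNPs,
#' LD proxies at r-squared `>= 0.8`, strong promoter/enhancer chromatin
#' states `{1, 3, 8, 9}` of the 18-state segmentation model, chromatin and
#' H3K27ac sharing with at most 3 of the 12 comparison cell cultures
#' (`k27ac_max_other = 4` is the relaxed protocol), preferential expression
#' at focal/median ratio `> 5` with focal RPKM `> 1`, a TF expression gate
#' at RPKM `>= 0.8`, a 21-base scoring window, and a `> 5`-fold
#' allele-specific position-probability rule.
#'
#' @param gwas_p_threshold p-value cutoff for index SNPs.
#' @param ebmd_imputed_p_threshold p-value cutoff for imputed eBMD SNPs.
#' @param r2_threshold minimum r-squared linking a proxy to its index SNP.
#' @param strong_states integer codes counted as strong regulatory chromatin.
#' @param state_max_other maximum number of comparison cell types allowed to
#'   share strong chromatin at an EnhPro SNP.
#' @param k27ac_max_other maximum number of comparison cell types allowed to
#'   share an H3K27ac narrowPeak at an EnhPro SNP (4 = relaxed protocol).
#' @param expr_ratio_min minimum focal/median-other RPKM ratio (exclusive).
#' @param expr_focal_min_rpkm minimum focal RPKM (exclusive).
#' @param tf_min_rpkm minimum focal RPKM for a predicted TF (inclusive).
#' @param tfbs_window odd length of the SNP-centred scoring window, in bases.
#' @param tfbs_fold_min minimum Ref/Alt position-probability fold change
#'   (exclusive) for an allele-specific call.
#' @param partial_match_min_frac fraction of a PWM position's best
#'   probability below which a base is not even a partial match.
#' @param conserved_prob_min minimum top-base probability classifying a PWM
#'   position as conserved.
#' @param partly_conserved_prob_min minimum top-base probability classifying
#'   a PWM position as partly conserved.
#' @param proxy_search_window_bp half-width of the proxy search window
#'   around an index SNP.
#' @param imputed_locus_buffer_bp buffer around candidate gene spans when
#'   collecting imputed SNPs.
#' @param state_label_window_bp neighbourhood (total width, bp) inspected
#'   around a SNP when composing the display chromatin label
#'   (e.g. "Str enh/prom").
#' @param pwm_pseudocount pseudocount added to each PWM count cell before
#'   row normalization.
#' @param em_tol convergence tolerance of the haplotype-frequency EM.
#' @param em_max_iter iteration cap of the haplotype-frequency EM.
#' @param exclude_genes gene identifiers removed from the candidate set
#'   after selection (e.g. genes already analyzed elsewhere).
#' @param rng_seed optional integer seed recorded with the run.
#'
#' @return An object of class `enhpro_config` (a named list).
#' @examples
#' cfg <- enhpro_config()
#' relaxed <- enhpro_config(k27ac_max_other = 4)
#' @export
enhpro_config <- function(gwas_p_threshold = 5e-8,
                          ebmd_imputed_p_threshold = 6.6e-9,
                          r2_threshold = 0.8,
                          strong_states = c(1L, 3L, 8L, 9L),
                          state_max_other = 3L,
                          k27ac_max_other = 3L,
                          expr_ratio_min = 5,
                          expr_focal_min_rpkm = 1,
                          tf_min_rpkm = 0.8,
                          tfbs_window = 21L,
                          tfbs_fold_min = 5,
                          partial_match_min_frac = 0.2,
                          conserved_prob_min = 0.85,
                          partly_conserved_prob_min = 0.5,
                          proxy_search_window_bp = 500000L,
                          imputed_locus_buffer_bp = 500000L,
                          state_label_window_bp = 200L,
                          pwm_pseudocount = 0.01,
                          em_tol = 1e-8,
                          em_max_iter = 1000L,
                          exclude_genes = character(),
                          rng_seed = NULL) {
  cfg <- list(
    gwas_p_threshold = gwas_p_threshold,
    ebmd_imputed_p_threshold = ebmd_imputed_p_threshold,
    r2_threshold = r2_threshold,
    strong_states = as.integer(strong_states),
    state_max_other = as.integer(state_max_other),
    k27ac_max_other = as.integer(k27ac_max_other),
    expr_ratio_min = expr_ratio_min,
    expr_focal_min_rpkm = expr_focal_min_rpkm,
    tf_min_rpkm = tf_min_rpkm,
    tfbs_window = as.integer(tfbs_window),
    tfbs_fold_min = tfbs_fold_min,
    partial_match_min_frac = partial_match_min_frac,
    conserved_prob_min = conserved_prob_min,
    partly_conserved_prob_min = partly_conserved_prob_min,
    proxy_search_window_bp = as.integer(proxy_search_window_bp),
    imputed_locus_buffer_bp = as.integer(imputed_locus_buffer_bp),
    state_label_window_bp = as.integer(state_label_window_bp),
    pwm_pseudocount = pwm_pseudocount,
    em_tol = em_tol,
    em_max_iter = as.integer(em_max_iter),
    exclude_genes = as.character(exclude_genes),
    rng_seed = rng_seed
  )
  class(cfg) <- "enhpro_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "enhpro_config"))
  positive <- c(
    "gwas_p_threshold", "ebmd_imputed_p_threshold", "r2_threshold",
    "expr_ratio_min", "expr_focal_min_rpkm", "tf_min_rpkm", "tfbs_window",
    "tfbs_fold_min", "partial_match_min_frac", "conserved_prob_min",
    "partly_conserved_prob_min", "proxy_search_window_bp",
    "imputed_locus_buffer_bp", "state_label_window_bp", "pwm_pseudocount",
    "em_tol", "em_max_iter"
  )
  for (nm in positive) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop("config field '", nm, "' must be a single strictly positive number")
    }
  }
  if (cfg$tfbs_window %% 2L != 1L) {
    stop("config field 'tfbs_window' must be odd")
  }
  if (cfg$state_max_other < 0L || cfg$k27ac_max_other < 0L) {
    stop("sharing thresholds must be non-negative")
  }
  if (!all(cfg$strong_states %in% 1:18)) {
    stop("strong_states must be chromatin state codes in 1..18")
  }
  if (cfg$partly_conserved_prob_min >= cfg$conserved_prob_min) {
    stop("partly_conserved_prob_min must be below conserved_prob_min")
  }
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Any field of [enhpro_config()] may appear in the file; unset fields keep
#' their defaults. Unknown keys are an error so that typos do not silently
#' fall back to defaults.
#'
#' @param path path to a YAML key-value file.
#' @return An `enhpro_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(enhpro_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(enhpro_config, raw)
}

#' @export
print.enhpro_config <- function(x, ...) {
  cat("<enhpro_config>\n")
  for (nm in setdiff(names(x), "rng_seed")) {
    cat(sprintf("  %-26s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
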
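# Expensive shared objects (the benchmark fixture, the default synthetic
# bundle and their pipeline runs) are built once per test session.

.enhpro_test_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .enhpro_test_cache)) {
    assign(key, builder(), envir = .enhpro_test_cache)
  }
  get(key, envir = .enhpro_test_cache)
}

fixture_bundle <- function() {
  cached("fixture", function() make_table1_fixture(tempfile("fx_")))
}

fixture_run_default <- function() {
  cached("fx_run_default", function() {
    suppressMessages(suppressWarnings(run_pipeline(fixture_bundle()$dir)))
  })
}

fixture_run_relaxed <- function() {
  cached("fx_run_relaxed", function() {
    suppressMessages(suppressWarnings(
      run_pipeline(fixture_bundle()$dir, enhpro_config(k27ac_max_other = 4))))
  })
}

sim_bundle <- function() {
  cached("sim", function() simulate_bundle(simulation_spec(),
                                           tempfile("sim_")))
}

sim_run <- function() {
  cached("sim_run", function() {
    suppressMessages(suppressWarnings(run_pipeline(sim_bundle()$dir)))
  })
}

# a small unphased genotype panel object assembled directly
make_unphased_panel <- function(dosage, chrom = "chr1",
                                pos = NULL, rsid = NULL) {
  n_loci <- nrow(dosage)
  if (is.null(pos)) pos <- seq_len(n_loci) * 100L
  if (is.null(rsid)) rsid <- paste0("L", seq_len(n_loci))
  structure(list(
    samples = paste0("S", seq_len(ncol(dosage))),
    loci = data.frame(rsid = rsid, chrom = chrom, pos = pos,
                      ref = "A", alt = "G", stringsAsFactors = FALSE),
    hap1 = matrix(NA_integer_, n_loci, ncol(dosage)),
    hap2 = matrix(NA_integer_, n_loci, ncol(dosage)),
    dosage = dosage, phased = FALSE
  ), class = "genotype_panel")
}

make_phased_panel <- function(hap1, hap2, chrom = "chr1",
                              pos = NULL, rsid = NULL) {
  n_loci <- nrow(hap1)
  if (is.null(pos)) pos <- seq_len(n_loci) * 100L
  if (is.null(rsid)) rsid <- paste0("L", seq_len(n_loci))
  structure(list(
    samples = paste0("S", seq_len(ncol(hap1))),
    loci = data.frame(rsid = rsid, chrom = chrom, pos = pos,
                      ref = "A", alt = "G", stringsAsFactors = FALSE),
    hap1 = hap1, hap2 = hap2, dosage = hap1 + hap2, phased = TRUE
  ), class = "genotype_panel")
}
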
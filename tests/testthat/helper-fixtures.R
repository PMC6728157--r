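# Fixture builders shared across test files. Everything is generated in
# code; no stored data files.

vcf_header <- function(samples = character()) {
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(samples) > 0L) cols <- c(cols, "FORMAT", samples)
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"AC\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"AN\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    paste(cols, collapse = "\t"))
}

write_fixture_vcf <- function(body_lines, samples = character(),
                              path = tempfile(fileext = ".vcf")) {
  writeLines(c(vcf_header(samples), body_lines), path)
  path
}

# The worked-example site: nucleotide C at position 32,936,732 on
# chromosome 13 (BRCA2 region), as a one-line sites-only VCF.
example_site_vcf <- function(path = tempfile(fileext = ".vcf")) {
  write_fixture_vcf("13\t32936732\t.\tG\tC\t.\tPASS\tAC=3;AN=200",
                    path = path)
}

# A population whose genotype matrix is set by hand (for oracle checks
# with known dosages).
manual_population <- function(G, f = rep(0.1, ncol(G))) {
  M <- ncol(G)
  structure(list(n_individuals = nrow(G), n_snps = M,
                 frequencies = f, genotypes = G,
                 sites = data.frame(chrom = "1", pos = seq_len(M) * 10L,
                                    ref = rep("A", M), alt = rep("C", M),
                                    stringsAsFactors = FALSE),
                 seed = 0L),
            class = "synthetic_population")
}

# Random allele key over a population's site table; emitted = TRUE draws a
# key matching a site's actual ref/alt, FALSE perturbs position or alt so
# the key cannot be in any index built from the population.
random_site_key <- function(pop, assembly = "GRCh37") {
  j <- sample.int(pop$n_snps, 1L)
  normalize_allele(pop$sites$chrom[j], pop$sites$pos[j], pop$sites$ref[j],
                   pop$sites$alt[j], assembly)
}

random_absent_key <- function(pop, assembly = "GRCh37") {
  j <- sample.int(pop$n_snps, 1L)
  if (runif(1) < 0.5) {
    # off-grid position (sites sit at multiples of 10)
    normalize_allele(pop$sites$chrom[j], pop$sites$pos[j] + 1L, "A", "C",
                     assembly)
  } else {
    # same site, the one alt base that is neither ref nor the emitted alt
    other <- setdiff(c("A", "C", "G", "T"),
                     c(pop$sites$ref[j], pop$sites$alt[j]))[1L]
    normalize_allele(pop$sites$chrom[j], pop$sites$pos[j], pop$sites$ref[j],
                     other, assembly)
  }
}

# Linear-scan oracle for lookup(): walk every record in the index.
scan_lookup <- function(index, key) {
  for (rec in as.list(index$records)) {
    k <- rec$key
    if (identical(k$chromosome, key$chromosome) &&
        k$start == key$start &&
        identical(k$ref_bases, key$ref_bases) &&
        identical(k$alt_bases, key$alt_bases)) {
      return(TRUE)
    }
  }
  FALSE
}

# A beacon serving one generated dataset, for protocol-level tests.
fixture_beacon <- function(pop, member_ids, beacon_id = "fixture-beacon",
                           dataset_id = "ds1", assembly = "GRCh37", ...) {
  path <- tempfile(fileext = ".vcf")
  write_vcf(pop, member_ids, path)
  idx <- ingest_vcf(path, dataset_id, assembly)
  add_dataset(beacon(beacon_id, ...), idx)
}

# Fully populated dataset response with randomized optional fields, for
# redaction monotonicity checks.
random_full_response <- function(beacon_id = "b") {
  dr <- list(dataset_id = paste0("ds", sample.int(100, 1L)),
             exists = runif(1) < 0.5)
  if (runif(1) < 0.8) dr$frequency <- runif(1)
  if (runif(1) < 0.8) dr$allele_count <- sample.int(100, 1L)
  if (runif(1) < 0.8) dr$sample_count <- sample.int(50, 1L)
  if (runif(1) < 0.5) dr$extra_metadata <- list(DP = "40")
  if (runif(1) < 0.3) dr$note <- "note"
  beaconr:::new_allele_response(beacon_id, exists = dr$exists,
                                dataset_responses = list(dr))
}

# Populations shared by the heavier statistical tests, built once per
# session. Sizes are the study conditions stated in the methods vignette.
.pop_cache <- new.env(parent = emptyenv())

cached_population <- function(name) {
  if (is.null(.pop_cache[[name]])) {
    .pop_cache[[name]] <- switch(
      name,
      # mid-size pool for calibration, beacon-size sweeps and rare/common
      mid = simulate_population(2000, 20000, seed = 101),
      # deep pool supporting 10,000-query sessions at beacon size 1,000
      deep = simulate_population(2200, 30000, seed = 102),
      # the pinned re-identification study population
      study = simulate_population(5000, 50000, seed = 103),
      stop("unknown cached population ", name))
  }
  .pop_cache[[name]]
}
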
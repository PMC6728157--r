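# End-to-end wiring tests; every fixture (VCFs, configs, scenarios) is
# generated on the fly.

write_config <- function(dir, datasets, beacon_id = "cli-beacon",
                         token_registry = NULL, budget = NULL) {
  cfg <- list(beacon_id = beacon_id, organization = "test-org",
              description = "test beacon", datasets = datasets)
  if (!is.null(token_registry)) cfg$token_registry <- token_registry
  if (!is.null(budget)) cfg$budget <- budget
  path <- file.path(dir, "beacon.json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, null = "null")
  path
}

example_config <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  vcf <- file.path(dir, "example.vcf")
  example_site_vcf(vcf)
  write_config(dir, list(list(id = "ds1", path = "example.vcf",
                              assembly = "GRCh37")))
}

test_that("service config validation names the offending field", {
  dir <- tempfile(); dir.create(dir)
  expect_error(load_service_config(file.path(dir, "none.json")),
               class = "beacon_config_error")
  bad <- file.path(dir, "bad.json")
  jsonlite::write_json(list(beacon_id = "b", datasets = list(
    list(id = "d1", path = "missing.vcf"))), bad, auto_unbox = TRUE)
  expect_error(load_service_config(bad), "missing.vcf",
               class = "beacon_config_error")
  dup <- file.path(dir, "dup.json")
  jsonlite::write_json(list(beacon_id = "b", datasets = list(
    list(id = "d1", path = "x.vcf"), list(id = "d1", path = "y.vcf"))),
    dup, auto_unbox = TRUE)
  expect_error(load_service_config(dup), "unique",
               class = "beacon_config_error")
})

test_that("build_beacon persists indexes and reuses fresh ones", {
  cfg_path <- example_config()
  cfg <- load_service_config(cfg_path)
  b1 <- build_beacon(cfg)
  index_path <- paste0(cfg$datasets[[1]]$path, ".index.json")
  expect_true(file.exists(index_path))
  mtime1 <- file.mtime(index_path)
  b2 <- build_beacon(cfg)  # reuses the persisted index
  expect_equal(file.mtime(index_path), mtime1)
  expect_equal(record_count(b2$datasets[[1]]$index), 1L)
  # touching the VCF invalidates the index
  Sys.setFileTime(cfg$datasets[[1]]$path, Sys.time() + 5)
  b3 <- build_beacon(cfg)
  expect_gte(as.numeric(file.mtime(index_path)), as.numeric(mtime1))
  expect_true(beacon_query(b3, allele_query("GRCh37", "13", 32936731,
                                            "G", "C"))$exists)
})

test_that("cli ingest summarizes records and fails cleanly on bad paths", {
  cfg_path <- example_config()
  out <- capture.output(status <- cli_ingest(cfg_path), type = "output")
  expect_equal(status, 0L)
  summary <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(summary$records, 1L)

  # empty VCF ingests to a zero-record dataset, exit 0
  dir <- tempfile(); dir.create(dir)
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"),
             file.path(dir, "empty.vcf"))
  cfg2 <- write_config(dir, list(list(id = "e", path = "empty.vcf")))
  out2 <- capture.output(status2 <- cli_ingest(cfg2), type = "output")
  expect_equal(status2, 0L)
  expect_equal(jsonlite::fromJSON(paste(out2, collapse = ""))$records, 0L)

  # missing file: nonzero exit, message names the path
  cfg3 <- file.path(dir, "bad.json")
  jsonlite::write_json(list(beacon_id = "b", datasets = list(
    list(id = "d", path = "gone.vcf"))), cfg3, auto_unbox = TRUE)
  msgs <- capture.output(status3 <- cli_ingest(cfg3), type = "message")
  expect_equal(status3, 2L)
  expect_true(any(grepl("gone.vcf", msgs)))
})

test_that("cli query exit codes encode yes / no / refusal", {
  cfg_path <- example_config()
  quiet_query <- function(...) {
    status <- NULL
    capture.output(status <- cli_query(...), type = "output")
    status
  }
  expect_equal(quiet_query(cfg_path, "GRCh37", "13", 32936731, "G", "C"), 0L)
  expect_equal(quiet_query(cfg_path, "GRCh37", "13", 32936731, "G", "T"), 1L)
  # malformed allele
  expect_equal(suppressMessages(
    quiet_query(cfg_path, "GRCh37", "13", 32936731, "G", "<DEL>")), 2L)

  # budget-locked token: distinct refusal, exit 2
  dir <- tempfile(); dir.create(dir)
  example_site_vcf(file.path(dir, "example.vcf"))
  cfg_b <- write_config(dir, list(list(id = "ds1", path = "example.vcf",
                                       assembly = "GRCh37")),
                        token_registry = list(tok = "registered"),
                        budget = list(threshold_bits = 0.01))
  expect_equal(quiet_query(cfg_b, "GRCh37", "13", 32936731, "G", "C",
                           token = "tok"), 0L)
  # fresh process state per call rebuilds the ledger, so lock it in-process
  bcn <- build_beacon(load_service_config(cfg_b))
  q <- allele_query("GRCh37", "13", 32936731, "G", "C")
  beacon_query(bcn, q, credential("tok"))
  r <- beacon_query(bcn, q, credential("tok"))
  expect_equal(r$error$code, "budget_exhausted")
})

test_that("cli network query aggregates across configured beacons", {
  dir <- tempfile(); dir.create(dir)
  pop <- simulate_population(10, 60, seed = 123)
  for (i in 1:2) {
    sub <- file.path(dir, paste0("b", i)); dir.create(sub)
    write_vcf(pop, if (i == 1) 1:5 else 6:10, file.path(sub, "d.vcf"))
    write_config(sub, list(list(id = paste0("d", i), path = "d.vcf",
                                assembly = "GRCh37")),
                 beacon_id = paste0("net-beacon-", i))
  }
  reg_path <- file.path(dir, "registry.json")
  jsonlite::write_json(list(beacons = list(
    list(config = "b1/beacon.json"), list(config = "b2/beacon.json"))),
    reg_path, auto_unbox = TRUE)

  seg1 <- which(colSums(pop$genotypes[1:5, ]) > 0)
  j <- seg1[1]
  q <- allele_query("GRCh37", "1", pop$sites$pos[j] - 1, pop$sites$ref[j],
                    pop$sites$alt[j])
  out <- capture.output(status <- cli_network_query(reg_path, q),
                        type = "output")
  expect_equal(status, 0L)
  parsed <- jsonlite::fromJSON(paste(out, collapse = ""),
                               simplifyVector = FALSE)
  expect_equal(parsed$yes_count + parsed$no_count, 2L)
  expect_gte(parsed$yes_count, 1L)
})

test_that("cli attack scenarios are reproducible and emit both summaries", {
  dir <- tempfile(); dir.create(dir)
  scenario <- list(
    population = list(n_individuals = 80, n_snps = 500, seed = 11),
    attack = list(attack_kind = "frequency_aware_lrt", n_queries = 60,
                  n_members = 20, n_replicates = 30, seed = 12),
    defense = list(threshold_bits = 30))
  sc_path <- file.path(dir, "scenario.json")
  jsonlite::write_json(scenario, sc_path, auto_unbox = TRUE)

  run <- function(prefix) {
    capture.output(status <- suppressWarnings(
      cli_attack(sc_path, out_prefix = file.path(dir, prefix))),
      type = "output")
    status
  }
  expect_equal(run("a"), 0L)
  expect_equal(run("b"), 0L)
  # same seed twice: byte-identical replicate CSVs
  expect_identical(readLines(file.path(dir, "a_replicates.csv")),
                   readLines(file.path(dir, "b_replicates.csv")))
  summary <- jsonlite::fromJSON(file.path(dir, "a_summary.json"))
  expect_true(all(c("undefended", "defended") %in% names(summary)))
  expect_lte(summary$defended$power, summary$undefended$power)

  # invalid scenario: config error naming the missing field
  bad <- file.path(dir, "bad.json")
  jsonlite::write_json(list(population = list(n_individuals = 10)), bad,
                       auto_unbox = TRUE)
  msgs <- capture.output(status_bad <- cli_attack(bad), type = "message")
  expect_equal(status_bad, 2L)
  expect_true(any(grepl("attack", msgs)))
})

test_that("the service loop answers newline-delimited JSON requests", {
  cfg_path <- example_config()
  requests <- c(
    '{"path": "/"}',
    paste0('{"path": "/query", "params": {"assemblyId": "GRCh37", ',
           '"referenceName": "13", "start": 32936731, ',
           '"referenceBases": "G", "alternateBases": "C"}}'))
  con <- textConnection(requests)
  out <- capture.output(
    suppressMessages(cli_serve(cfg_path, con = con, max_requests = 2)),
    type = "output")
  close(con)
  out <- out[nzchar(trimws(out))]
  info <- jsonlite::fromJSON(out[1])
  expect_equal(info$beacon_id, "cli-beacon")
  ans <- jsonlite::fromJSON(out[2])
  expect_true(ans$exists)
})

test_that("the bundled executable script runs out of process", {
  script <- system.file("cli", "beacon", package = "beaconr")
  expect_true(nzchar(script))
  dir <- tempfile(); dir.create(dir)
  out_vcf <- file.path(dir, "sim.vcf")
  res <- system2("Rscript",
                 c(script, "fixtures", "--n-individuals", "10",
                   "--n-snps", "40", "--seed", "3", "--out", out_vcf),
                 stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  expect_true(file.exists(out_vcf))
  idx <- ingest_vcf(out_vcf, "sim", "GRCh37")
  pop <- simulate_population(10, 40, seed = 3)
  expect_equal(record_count(idx), sum(colSums(pop$genotypes) > 0))
})
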
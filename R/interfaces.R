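# Service wiring: JSON service configuration, index persistence policy,
# and the command-line entry points (light a beacon from VCFs, query it,
# serve it, federate, run attack experiments, write fixtures).
#
# CLI conventions: machine-readable JSON on stdout, logs on stderr; exit
# code 0 for "yes", 1 for "no", 2 for errors and refusals.

#' Load and validate a beacon service configuration
#'
#' The configuration is a JSON object with the beacon identity
#' (`beacon_id`, `organization`, `description`), a `datasets` array
#' (`path`, `id`, `assembly`, optional `consent`
#' (`{primary, disease_term, secondary}`), optional `minimum_tier`), an
#' optional `token_registry` (inline map token -> tier, or a path to one),
#' and an optional `budget` object (`threshold_bits`, `frequency_floor`,
#' `no_response_cost`). Referenced paths must exist at load time and
#' dataset ids must be unique.
#'
#' @param path Path to the JSON configuration.
#' @return A validated `service_config` list.
#' @export
load_service_config <- function(path) {
  if (!file.exists(path)) {
    beacon_abort(sprintf("config file not found: %s", path),
                 "beacon_config_error")
  }
  cfg <- jsonlite::read_json(path)
  if (is.null(cfg$beacon_id) || !nzchar(cfg$beacon_id)) {
    beacon_abort("config field 'beacon_id' is required", "beacon_config_error")
  }
  ids <- vapply(cfg$datasets, function(d) d$id %||% "", "")
  if (anyDuplicated(ids) || any(!nzchar(ids))) {
    beacon_abort("config field 'datasets': ids must be present and unique",
                 "beacon_config_error")
  }
  base <- dirname(normalizePath(path))
  cfg$datasets <- lapply(cfg$datasets, function(d) {
    if (is.null(d$path)) {
      beacon_abort(sprintf("config dataset '%s': field 'path' is required", d$id),
                   "beacon_config_error")
    }
    d$path <- resolve_path(d$path, base)
    if (!file.exists(d$path)) {
      beacon_abort(sprintf("config dataset '%s': file not found: %s",
                           d$id, d$path), "beacon_config_error")
    }
    d
  })
  if (is.character(cfg$token_registry) && length(cfg$token_registry) == 1L) {
    reg_path <- resolve_path(cfg$token_registry, base)
    if (!file.exists(reg_path)) {
      beacon_abort(sprintf("token registry file not found: %s", reg_path),
                   "beacon_config_error")
    }
    cfg$token_registry <- jsonlite::read_json(reg_path)
  }
  structure(cfg, class = "service_config")
}

resolve_path <- function(p, base) {
  if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
}

config_consent <- function(d) {
  if (is.null(d$consent)) return(consent_code("NRES"))
  consent_code(d$consent$primary %||% "NRES",
               disease_term = d$consent$disease_term,
               secondary_requirements = unlist(d$consent$secondary) %||% character())
}

#' Build a beacon from a service configuration
#'
#' Ingests (or reloads) every configured dataset and assembles the beacon
#' with its token registry, budget policy and ledger. Indexes are
#' persisted next to each VCF as `<vcf>.index.json` and reused on
#' subsequent builds unless the VCF is newer than its index.
#'
#' @param cfg A [load_service_config()] result.
#' @param rebuild Force re-ingestion even when a fresh index file exists.
#' @return A [beacon()].
#' @export
build_beacon <- function(cfg, rebuild = FALSE) {
  stopifnot(inherits(cfg, "service_config"))
  budget <- cfg$budget %||% list()
  bcn <- beacon(
    beacon_id = cfg$beacon_id,
    organization = cfg$organization %||% "unknown",
    description = cfg$description %||% "",
    token_registry = cfg$token_registry %||% list(),
    ledger = budget_ledger(budget$threshold_bits %||% 30),
    policy = cost_policy(
      frequency_floor = budget$frequency_floor %||% 1e-4,
      no_response_cost = budget$no_response_cost %||% 0.05))
  for (d in cfg$datasets) {
    index_path <- paste0(d$path, ".index.json")
    fresh <- file.exists(index_path) &&
      file.mtime(index_path) >= file.mtime(d$path)
    index <- if (!rebuild && fresh) {
      index_load(index_path)
    } else {
      idx <- ingest_vcf(d$path, d$id, d$assembly %||% "GRCh37")
      index_save(idx, index_path)
      idx
    }
    bcn <- add_dataset(bcn, index, consent = config_consent(d),
                       minimum_tier = d$minimum_tier %||% "open",
                       name = d$name %||% d$id,
                       description = d$description %||% "")
  }
  bcn
}

cli_log <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...), file = stderr())

#' CLI: ingest configured VCFs into persisted indexes
#'
#' @param config_path Path to a service configuration.
#' @param rebuild Force re-ingestion.
#' @return Exit status: 0 on success, 2 on total failure.
#' @export
cli_ingest <- function(config_path, rebuild = TRUE) {
  res <- tryCatch({
    cfg <- load_service_config(config_path)
    summaries <- lapply(cfg$datasets, function(d) {
      n_warn <- 0L
      idx <- withCallingHandlers(
        ingest_vcf(d$path, d$id, d$assembly %||% "GRCh37"),
        warning = function(w) {
          n_warn <<- n_warn + 1L
          cli_log("warning [%s]: %s", d$id, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      index_save(idx, paste0(d$path, ".index.json"))
      cli_log("ingested '%s': %d records, %s samples, %d warnings",
              d$id, record_count(idx),
              if (is.null(idx$sample_total)) "?" else idx$sample_total, n_warn)
      list(dataset_id = d$id, records = record_count(idx),
           samples = idx$sample_total, warnings = n_warn)
    })
    cat(jsonlite::toJSON(summaries, auto_unbox = TRUE, null = "null"), "\n")
    0L
  }, error = function(e) {
    cli_log("error: %s", conditionMessage(e))
    2L
  })
  res
}

#' CLI: query a beacon (or a network registry) for one allele
#'
#' Prints the JSON response on stdout.
#'
#' @param target Path to a service configuration (single beacon) or to a
#'   network registry file (see [cli_network_query()]).
#' @param assembly,chrom,start,ref,alt The allele (`start` is 0-based).
#' @param token Optional credential token.
#' @param purpose Declared research-purpose category.
#' @param disease_term Disease term for disease-specific purposes.
#' @param include_datasets Request per-dataset detail.
#' @return Exit status: 0 yes, 1 no, 2 error or refusal.
#' @export
cli_query <- function(target, assembly, chrom, start, ref, alt,
                      token = NULL, purpose = "general_research",
                      disease_term = NULL, include_datasets = TRUE) {
  tryCatch({
    q <- allele_query(assembly, chrom, as.numeric(start), ref, alt,
                      purpose = research_purpose(purpose, disease_term),
                      include_dataset_responses = include_datasets)
    cred <- if (is.null(token)) credential() else credential(token)
    cfg <- jsonlite::read_json(target)
    if (!is.null(cfg$beacons)) {
      return(cli_network_query(target, q, cred))
    }
    bcn <- build_beacon(load_service_config(target))
    resp <- beacon_query(bcn, q, cred)
    cat(response_json(resp), "\n")
    if (!is.null(resp$error)) 2L else if (isTRUE(resp$exists)) 0L else 1L
  }, error = function(e) {
    cli_log("error: %s", conditionMessage(e))
    2L
  })
}

#' CLI: fan a query out across a registry of beacons
#'
#' The registry file is JSON: `{"beacons": [{"config": "<path>"}, ...]}`,
#' each entry naming a beacon service configuration.
#'
#' @param registry_path Path to the registry file.
#' @param query An [allele_query()].
#' @param cred A [credential()].
#' @return Exit status: 0 if any beacon answered yes, 1 if none did, 2 on
#'   error.
#' @export
cli_network_query <- function(registry_path, query, cred = credential()) {
  tryCatch({
    reg_cfg <- jsonlite::read_json(registry_path)
    base <- dirname(normalizePath(registry_path))
    registry <- beacon_registry()
    for (entry in reg_cfg$beacons) {
      bcn <- build_beacon(load_service_config(resolve_path(entry$config, base)))
      registry <- register_beacon(registry, bcn)
    }
    resp <- federated_query(registry, query, cred)
    out <- list(yes_count = resp$yes_count, no_count = resp$no_count,
                error_count = resp$error_count,
                beacons = lapply(resp$per_beacon, function(r) {
                  if (inherits(r, "beacon_failure")) list(failure = r$failure)
                  else unclass_deep(r)
                }))
    cat(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null"), "\n")
    if (resp$yes_count > 0) 0L else 1L
  }, error = function(e) {
    cli_log("error: %s", conditionMessage(e))
    2L
  })
}

#' CLI: run an attack scenario end-to-end
#'
#' The scenario file is JSON with a `population` object
#' (`n_individuals`, `n_snps`, `afs_shape`, `f_min`, `seed`), an `attack`
#' object (fields of [attack_config()]), an optional `defense` object
#' (`threshold_bits`, `frequency_floor`, `no_response_cost`) and an
#' optional `power_goal` triggering a [queries_needed()] sweep. Writes
#' `<out_prefix>_replicates.csv` (one row per replicate and arm) and
#' `<out_prefix>_summary.json`; both are reproducible given the seeds.
#'
#' @param scenario_path Path to the scenario JSON.
#' @param out_prefix Output file prefix (default: scenario path sans
#'   extension).
#' @return Exit status: 0 on success, 2 on configuration error.
#' @export
cli_attack <- function(scenario_path, out_prefix = NULL) {
  tryCatch({
    sc <- jsonlite::read_json(scenario_path)
    for (field in c("population", "attack")) {
      if (is.null(sc[[field]])) {
        beacon_abort(sprintf("scenario field '%s' is required", field),
                     "beacon_config_error")
      }
    }
    p <- sc$population
    pop <- simulate_population(
      n_individuals = p$n_individuals %||%
        beacon_abort("scenario field 'population.n_individuals' is required",
                     "beacon_config_error"),
      n_snps = p$n_snps %||%
        beacon_abort("scenario field 'population.n_snps' is required",
                     "beacon_config_error"),
      afs_shape = unlist(p$afs_shape) %||% c(0.5, 0.5),
      f_min = p$f_min %||% 0.001, seed = p$seed %||% 1L)
    a <- sc$attack
    config <- attack_config(
      attack_kind = a$attack_kind %||% "frequency_aware_lrt",
      n_queries = a$n_queries %||%
        beacon_abort("scenario field 'attack.n_queries' is required",
                     "beacon_config_error"),
      n_members = a$n_members %||%
        beacon_abort("scenario field 'attack.n_members' is required",
                     "beacon_config_error"),
      mismatch_rate = a$mismatch_rate %||% 1e-6,
      fpr_target = a$fpr_target %||% 0.05,
      n_replicates = a$n_replicates %||% 100L,
      seed = a$seed %||% 1L,
      freq_range = if (!is.null(a$freq_range)) unlist(a$freq_range),
      null_calibration = isTRUE(a$null_calibration))

    if (is.null(out_prefix)) {
      out_prefix <- tools::file_path_sans_ext(scenario_path)
    }
    summary <- list(scenario = scenario_path,
                    attack_kind = config$attack_kind,
                    n_members = config$n_members,
                    n_queries = config$n_queries,
                    n_replicates = config$n_replicates)
    if (!is.null(sc$defense)) {
      d <- sc$defense
      pair <- evaluate_defense(
        pop, config,
        budget_policy = cost_policy(
          frequency_floor = d$frequency_floor %||% 1e-4,
          no_response_cost = d$no_response_cost %||% 0.05),
        threshold_bits = d$threshold_bits %||% 30)
      result <- pair$defended
      summary$undefended <- list(power = pair$undefended$power,
                                 achieved_fpr = pair$undefended$achieved_fpr)
      summary$defended <- list(
        power = pair$defended$power,
        achieved_fpr = pair$defended$achieved_fpr,
        max_answered = max(pair$defended$answered_members,
                           pair$defended$answered_nonmembers))
    } else {
      result <- run_attack(pop, config)
      summary$power <- result$power
      summary$achieved_fpr <- result$achieved_fpr
    }
    if (!is.null(sc$power_goal)) {
      qn <- queries_needed(pop, config, power_goal = sc$power_goal)
      summary$queries_needed <- if (qn$reached) qn$n_queries else "not reached"
    }
    csv_path <- paste0(out_prefix, "_replicates.csv")
    write.csv(attack_result_table(result), csv_path, row.names = FALSE)
    jsonlite::write_json(summary, paste0(out_prefix, "_summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    cat(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA), "\n")
    cli_log("wrote %s and %s_summary.json", csv_path, out_prefix)
    0L
  }, error = function(e) {
    cli_log("error: %s", conditionMessage(e))
    2L
  })
}

#' CLI: write a fixture VCF from a simulated population
#'
#' @param n_individuals,n_snps,seed Population parameters.
#' @param n_members Individuals exported to the VCF (defaults to all).
#' @param out Output VCF path.
#' @return Exit status 0, or 2 on error.
#' @export
cli_fixture_vcf <- function(n_individuals, n_snps, seed, out,
                            n_members = n_individuals) {
  tryCatch({
    pop <- simulate_population(as.integer(n_individuals),
                               as.integer(n_snps), seed = as.integer(seed))
    write_vcf(pop, seq_len(as.integer(n_members)), out)
    cli_log("wrote %s", out)
    0L
  }, error = function(e) {
    cli_log("error: %s", conditionMessage(e))
    2L
  })
}

#' CLI: serve a beacon over newline-delimited JSON
#'
#' Reads one request per line from `con` — either
#' `{"path": "/", ...}` or `{"path": "/query", "params": {...}}` with the
#' wire parameter names of [handle_request()] — and writes one JSON
#' response line per request. This transport-neutral loop is suitable for
#' inetd-style wiring or piping; an HTTP front end can mount
#' [handle_request()] directly instead.
#'
#' @param config_path Path to a service configuration.
#' @param con Input connection (default stdin).
#' @param max_requests Stop after this many requests (`Inf` to stream).
#' @return Exit status 0.
#' @export
cli_serve <- function(config_path, con = "stdin", max_requests = Inf) {
  bcn <- build_beacon(load_service_config(config_path))
  cli_log("beacon '%s' ready (%d datasets)", bcn$beacon_id,
          length(bcn$datasets))
  if (identical(con, "stdin")) con <- file("stdin", open = "r")
  n <- 0
  while (n < max_requests) {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !nzchar(line)) break
    req <- tryCatch(jsonlite::fromJSON(line, simplifyVector = FALSE),
                    error = function(e) NULL)
    out <- if (is.null(req)) {
      response_json(list(error = protocol_error("bad_request",
                                                "request is not valid JSON")))
    } else {
      handle_request(bcn, req$path %||% "/", req$params %||% list())
    }
    cat(out, "\n")
    n <- n + 1
  }
  0L
}

#' CLI entry point
#'
#' Dispatches the subcommands `ingest`, `serve`, `query`, `network`,
#' `simulate` and `fixtures`; run with no arguments for usage. This is the
#' function behind the `beacon` executable script shipped in
#' `system.file("cli", "beacon", package = "beaconr")`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: beacon <command> [options]",
    "  ingest   --config <file>",
    "  serve    --config <file>",
    "  query    --target <config|registry> --assembly <id> --chrom <name>",
    "           --start <0-based> --ref <bases> --alt <bases> [--token <t>]",
    "           [--purpose <category>] [--disease-term <term>]",
    "  network  --registry <file> --assembly ... (as for query)",
    "  simulate --scenario <file> [--out-prefix <prefix>]",
    "  fixtures --n-individuals <n> --n-snps <m> --seed <s> --out <vcf>",
    sep = "\n")
  if (length(argv) < 1L) { cat(usage, "\n", file = stderr()); return(2L) }
  cmd <- argv[1L]
  opts <- parse_flags(argv[-1L])
  need <- function(flag) {
    if (is.null(opts[[flag]])) {
      cli_log("missing required option --%s", flag)
      cat(usage, "\n", file = stderr())
      NULL
    } else opts[[flag]]
  }
  switch(cmd,
    ingest = {
      cfg <- need("config"); if (is.null(cfg)) return(2L)
      cli_ingest(cfg)
    },
    serve = {
      cfg <- need("config"); if (is.null(cfg)) return(2L)
      cli_serve(cfg)
    },
    query = ,
    network = {
      target <- opts$target %||% opts$registry
      if (is.null(target)) { cli_log("missing --target/--registry"); return(2L) }
      for (flag in c("assembly", "chrom", "start", "ref", "alt")) {
        if (is.null(need(flag))) return(2L)
      }
      cli_query(target, opts$assembly, opts$chrom, opts$start, opts$ref,
                opts$alt, token = opts$token,
                purpose = opts$purpose %||% "general_research",
                disease_term = opts[["disease-term"]])
    },
    simulate = {
      sc <- need("scenario"); if (is.null(sc)) return(2L)
      cli_attack(sc, out_prefix = opts[["out-prefix"]])
    },
    fixtures = {
      for (flag in c("n-individuals", "n-snps", "seed", "out")) {
        if (is.null(need(flag))) return(2L)
      }
      cli_fixture_vcf(opts[["n-individuals"]], opts[["n-snps"]],
                      opts$seed, opts$out,
                      n_members = opts[["n-members"]] %||%
                        opts[["n-individuals"]])
    },
    { cli_log("unknown command '%s'", cmd); cat(usage, "\n", file = stderr()); 2L })
}

parse_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- substring(args[i], 3L)
      if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opts[[key]] <- TRUE
        i <- i + 1L
      }
    } else i <- i + 1L
  }
  opts
}
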
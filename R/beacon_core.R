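# The beacon protocol engine. A beacon serves one or more VCF-backed
# datasets and exposes two functions: info (describe the beacon and its
# datasets) and query (does any served dataset contain this allele?).
# Queries pass a consent gate and an information-budget gate per dataset,
# and responses are redacted to the caller's access tier before return.

#' Construct a beacon
#'
#' @param beacon_id Unique beacon identifier.
#' @param organization Host organization name.
#' @param description Free-text description.
#' @param api_version Protocol version string.
#' @param token_registry Named mapping token -> tier for [resolve_tier()].
#' @param ledger A [budget_ledger()] shared by all of the beacon's
#'   datasets; pass `budget_ledger(Inf)` to disable metering.
#' @param policy A [cost_policy()] pricing each disclosure.
#' @param field_map Tier -> disclosed-field mapping for [redact()].
#' @return An object of class `beacon`. Add datasets with [add_dataset()].
#' @export
beacon <- function(beacon_id, organization = "unknown", description = "",
                   api_version = "v1.0.0", token_registry = list(),
                   ledger = budget_ledger(), policy = cost_policy(),
                   field_map = default_field_map()) {
  stopifnot(nzchar(beacon_id))
  structure(list(beacon_id = beacon_id, organization = organization,
                 description = description, api_version = api_version,
                 datasets = list(), token_registry = token_registry,
                 ledger = ledger, policy = policy, field_map = field_map),
            class = "beacon")
}

#' Add a dataset to a beacon
#'
#' @param bcn A [beacon()].
#' @param index A [ingest_vcf()] dataset index.
#' @param consent A [consent_code()] stating the dataset's use conditions.
#' @param minimum_tier Lowest tier allowed to query this dataset.
#' @param name,description Human-readable dataset metadata.
#' @return The beacon with the dataset attached.
#' @export
add_dataset <- function(bcn, index, consent = consent_code("NRES"),
                        minimum_tier = "open", name = index$dataset_id,
                        description = "") {
  stopifnot(inherits(bcn, "beacon"), inherits(index, "dataset_index"))
  tier_rank(minimum_tier)
  if (index$dataset_id %in% names(bcn$datasets)) {
    beacon_abort(sprintf("duplicate dataset id '%s'", index$dataset_id),
                 "beacon_config_error")
  }
  bcn$datasets[[index$dataset_id]] <-
    list(index = index, consent = consent, minimum_tier = minimum_tier,
         name = name, description = description)
  bcn
}

#' Describe a beacon and the datasets it serves
#'
#' The first of the two protocol functions. Dataset-level variant counts
#' are read live from the underlying indexes, so they always match what
#' [beacon_query()] can see.
#'
#' @param bcn A [beacon()].
#' @return An object of class `beacon_info`.
#' @export
beacon_info <- function(bcn) {
  stopifnot(inherits(bcn, "beacon"))
  datasets <- lapply(bcn$datasets, function(ds) {
    info <- list(
      dataset_id = ds$index$dataset_id, name = ds$name,
      description = ds$description, assembly_id = ds$index$assembly_id,
      variant_count = record_count(ds$index),
      consent_code = ds$consent$primary_category,
      minimum_tier = ds$minimum_tier)
    if (!is.null(ds$index$sample_total)) {
      info$sample_count <- ds$index$sample_total
    }
    info
  })
  structure(list(beacon_id = bcn$beacon_id, organization = bcn$organization,
                 description = bcn$description,
                 api_version = bcn$api_version,
                 datasets = unname(datasets)),
            class = "beacon_info")
}

#' Construct an allele query
#'
#' @param assembly_id Genome assembly of the coordinates.
#' @param chromosome Contig name.
#' @param start 0-based position of the first reference base.
#' @param ref_bases,alt_bases Reference and alternate bases (`[ACGT]+`).
#' @param dataset_ids Datasets to query; `NULL` means every dataset the
#'   caller's tier can see.
#' @param purpose The caller's declared [research_purpose()].
#' @param include_dataset_responses Include per-dataset detail in the
#'   response (subject to tier redaction)?
#' @return An object of class `allele_query`.
#' @export
allele_query <- function(assembly_id, chromosome, start, ref_bases,
                         alt_bases, dataset_ids = NULL,
                         purpose = research_purpose(),
                         include_dataset_responses = FALSE) {
  key <- normalize_allele(chromosome, as.numeric(start) + 1, ref_bases,
                          alt_bases, assembly_id)
  structure(list(key = key, dataset_ids = dataset_ids, purpose = purpose,
                 include_dataset_responses = include_dataset_responses),
            class = "allele_query")
}

protocol_error <- function(code, message) {
  list(code = code, message = message)
}

new_allele_response <- function(beacon_id, exists = NULL,
                                dataset_responses = list(), error = NULL) {
  structure(list(beacon_id = beacon_id, exists = exists,
                 dataset_responses = dataset_responses, error = error),
            class = "allele_response")
}

#' Query a beacon for an allele
#'
#' The second protocol function. For each selected dataset the engine
#' applies, in order: the consent gate ([check_consent()] of the caller's
#' purpose against the dataset's consent code), the tier gate (the
#' dataset's minimum tier), and the information-budget gate
#' ([charge_and_gate()]); only then is the allele looked up. The beacon's
#' `exists` is the OR over datasets that passed every gate; gated-out
#' datasets are reported as denied — with no `exists` field, so a refusal
#' is never mistaken for "allele absent" — and do not enter the OR. The
#' response is redacted to the caller's tier before return.
#'
#' Protocol-level failures (malformed allele, unknown dataset, unknown
#' token, exhausted budget) are returned as a typed `error` object inside
#' the response, with `exists` unset.
#'
#' @param bcn A [beacon()].
#' @param query An [allele_query()], or anything coercible via its fields.
#' @param cred The caller's [credential()].
#' @return An object of class `allele_response`.
#' @export
beacon_query <- function(bcn, query, cred = credential()) {
  stopifnot(inherits(bcn, "beacon"), inherits(cred, "credential"))
  if (!inherits(query, "allele_query")) {
    query <- tryCatch(do.call(allele_query, query), beacon_error = function(e) e)
  }
  if (inherits(query, "beacon_error")) {
    return(new_allele_response(bcn$beacon_id, error = protocol_error(
      "malformed_allele", conditionMessage(query))))
  }
  tier <- tryCatch(resolve_tier(cred, bcn$token_registry),
                   beacon_error = function(e) e)
  if (inherits(tier, "beacon_error")) {
    return(new_allele_response(bcn$beacon_id, error = protocol_error(
      "authentication_error", conditionMessage(tier))))
  }

  if (is.null(query$dataset_ids)) {
    selected <- names(bcn$datasets)
    # default selection: every dataset the caller's tier can see
    selected <- selected[vapply(selected, function(id) {
      tier_rank(tier) >= tier_rank(bcn$datasets[[id]]$minimum_tier)
    }, logical(1L))]
  } else {
    unknown <- setdiff(query$dataset_ids, names(bcn$datasets))
    if (length(unknown) > 0L) {
      return(new_allele_response(bcn$beacon_id, error = protocol_error(
        "unknown_dataset",
        sprintf("unknown dataset id(s): %s", paste(unknown, collapse = ", ")))))
    }
    selected <- query$dataset_ids
  }

  dataset_responses <- list()
  permitted_exists <- logical(0)
  n_budget_denied <- 0L
  n_denied <- 0L
  for (id in selected) {
    ds <- bcn$datasets[[id]]
    dr <- list(dataset_id = id)

    consent <- check_consent(ds$consent, query$purpose)
    if (!consent$allowed) {
      dr$note <- paste0("not authorized for this purpose: ", consent$reason)
      n_denied <- n_denied + 1L
      dataset_responses[[id]] <- dr
      next
    }
    if (tier_rank(tier) < tier_rank(ds$minimum_tier)) {
      dr$note <- sprintf("denied: dataset requires %s access", ds$minimum_tier)
      n_denied <- n_denied + 1L
      dataset_responses[[id]] <- dr
      next
    }
    if (budget_locked(bcn$ledger, cred$identity_key)) {
      dr$note <- "budget exhausted"
      n_budget_denied <- n_budget_denied + 1L
      dataset_responses[[id]] <- dr
      next
    }

    rec <- tryCatch(lookup(ds$index, query$key), beacon_error = function(e) e)
    if (inherits(rec, "beacon_assembly_mismatch")) {
      dr$note <- conditionMessage(rec)
      n_denied <- n_denied + 1L
      dataset_responses[[id]] <- dr
      next
    }
    found <- !is.null(rec)
    freq <- allele_frequency(rec)
    charge_and_gate(bcn$ledger, cred$identity_key,
                    query_cost(freq, found, bcn$policy))

    dr$exists <- found
    if (found) {
      if (!is.null(freq)) dr$frequency <- freq
      dr$allele_count <- rec$allele_count
      if (!is.null(rec$sample_count)) dr$sample_count <- rec$sample_count
      if (length(rec$extra_metadata) > 0L) dr$extra_metadata <- rec$extra_metadata
    }
    permitted_exists <- c(permitted_exists, found)
    dataset_responses[[id]] <- dr
  }

  if (length(permitted_exists) == 0L && n_budget_denied > 0L) {
    return(new_allele_response(bcn$beacon_id, error = protocol_error(
      "budget_exhausted",
      "budget exhausted: cumulative disclosure limit reached for this credential")))
  }
  if (length(permitted_exists) == 0L && n_denied > 0L) {
    return(new_allele_response(bcn$beacon_id, error = protocol_error(
      "not_authorized", "no queried dataset permits this purpose or tier")))
  }

  resp <- new_allele_response(bcn$beacon_id,
                              exists = any(permitted_exists),
                              dataset_responses = unname(dataset_responses))
  if (!isTRUE(query$include_dataset_responses)) resp$dataset_responses <- list()
  redact(resp, tier, bcn$field_map)
}

#' Serialize a response (or info object) to protocol JSON
#'
#' `NULL` fields — notably `exists` on denied dataset entries — are
#' omitted, not rendered as JSON null.
#'
#' @param x An `allele_response`, `beacon_info` or `network_response`.
#' @return A JSON string.
#' @export
response_json <- function(x) {
  as.character(jsonlite::toJSON(unclass_deep(x), auto_unbox = TRUE,
                                digits = NA, null = "null"))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x <- x[!vapply(x, is.null, logical(1L))]  # absent fields stay absent
    lapply(x, unclass_deep)
  } else x
}

#' @export
print.allele_response <- function(x, ...) {
  if (!is.null(x$error)) {
    cat(sprintf("<allele_response> beacon '%s': ERROR [%s] %s\n",
                x$beacon_id, x$error$code, x$error$message))
  } else {
    cat(sprintf("<allele_response> beacon '%s': %s (%d dataset responses)\n",
                x$beacon_id, if (isTRUE(x$exists)) "yes" else "no",
                length(x$dataset_responses)))
  }
  invisible(x)
}

#' @export
print.beacon <- function(x, ...) {
  cat(sprintf("<beacon> '%s' (%s): %d dataset(s)\n", x$beacon_id,
              x$organization, length(x$datasets)))
  invisible(x)
}

## ---- Transport-agnostic HTTP-style route handler --------------------------

#' Handle a protocol request given as a route and query parameters
#'
#' Implements the two wire routes — `GET /` (info) and `GET /query` with
#' parameters `assemblyId`, `referenceName`, `start`, `referenceBases`,
#' `alternateBases`, `datasetIds` (comma-separated),
#' `includeDatasetResponses`, plus `token` for authenticated calls — as a
#' pure function from (path, params) to a JSON body, so any HTTP front end
#' (or the bundled newline-delimited-JSON service loop) can mount it.
#'
#' @param bcn A [beacon()].
#' @param path `"/"` or `"/query"`.
#' @param params Named list of query parameters (strings).
#' @return JSON response body as a string.
#' @export
handle_request <- function(bcn, path, params = list()) {
  if (identical(path, "/")) return(response_json(beacon_info(bcn)))
  if (!identical(path, "/query")) {
    return(response_json(list(error = protocol_error(
      "not_found", sprintf("unknown route '%s'", path)))))
  }
  cred <- if (is.null(params$token)) credential() else credential(params$token)
  purpose <- research_purpose(
    category = params$purpose %||% "general_research",
    disease_term = params$diseaseTerm)
  q <- tryCatch(
    allele_query(
      assembly_id = params$assemblyId, chromosome = params$referenceName,
      start = as.numeric(params$start), ref_bases = params$referenceBases,
      alt_bases = params$alternateBases,
      dataset_ids = if (!is.null(params$datasetIds))
        strsplit(params$datasetIds, ",", fixed = TRUE)[[1]],
      purpose = purpose,
      include_dataset_responses =
        isTRUE(as.logical(params$includeDatasetResponses %||% "false"))),
    beacon_error = function(e) e)
  if (inherits(q, "beacon_error")) {
    return(response_json(new_allele_response(bcn$beacon_id,
      error = protocol_error("malformed_allele", conditionMessage(q)))))
  }
  response_json(beacon_query(bcn, q, cred))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
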
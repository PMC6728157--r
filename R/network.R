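# Beacon-network federation: a registry of beacons, query fan-out with
# per-beacon fault isolation, response aggregation ("who has observed this
# allele?"), and origin-obscuring aggregate beacons.

#' Query a beacon handle
#'
#' Generic over the kinds of handle a registry may hold: an in-process
#' [beacon()], an [make_aggregate()] beacon, or a function
#' `function(query, cred)` wrapping a remote endpoint.
#'
#' @param handle A beacon handle.
#' @param query An [allele_query()].
#' @param cred A [credential()]. Forwarded unchanged: each beacon applies
#'   its own tier policy.
#' @return An `allele_response`.
#' @export
handle_query <- function(handle, query, cred = credential()) {
  UseMethod("handle_query")
}

#' @export
handle_query.beacon <- function(handle, query, cred = credential()) {
  beacon_query(handle, query, cred)
}

#' @export
handle_query.function <- function(handle, query, cred = credential()) {
  handle(query, cred)
}

#' Describe a beacon handle
#'
#' @param handle A beacon handle.
#' @return A `beacon_info`.
#' @export
handle_info <- function(handle) UseMethod("handle_info")

#' @export
handle_info.beacon <- function(handle) beacon_info(handle)

#' @export
handle_info.function <- function(handle) {
  # function handles carry their descriptor as an attribute
  info <- attr(handle, "beacon_info")
  if (is.null(info)) beacon_abort("handle has no reachable info",
                                  "beacon_registration_error")
  info
}

#' Construct an empty beacon registry
#'
#' @return An object of class `beacon_registry`.
#' @export
beacon_registry <- function() {
  structure(list(entries = list()), class = "beacon_registry")
}

#' Register a beacon with the network
#'
#' The handle's `info()` must be reachable at registration time; an
#' unreachable handle or a duplicate beacon id is rejected and the registry
#' is returned unchanged by error.
#'
#' @param registry A [beacon_registry()].
#' @param handle A beacon handle (see [handle_query()]).
#' @param organization Organization label shown in the directory.
#' @return The registry with the beacon added.
#' @export
register_beacon <- function(registry, handle, organization = NULL) {
  stopifnot(inherits(registry, "beacon_registry"))
  info <- tryCatch(handle_info(handle), error = function(e) {
    beacon_abort(sprintf("cannot register unreachable beacon: %s",
                         conditionMessage(e)), "beacon_registration_error")
  })
  id <- info$beacon_id
  if (id %in% names(registry$entries)) {
    beacon_abort(sprintf("beacon id '%s' already registered", id),
                 "beacon_registration_error")
  }
  registry$entries[[id]] <-
    list(handle = handle,
         organization = organization %||% info$organization)
  registry
}

#' Directory listing of registered beacons
#'
#' @param registry A [beacon_registry()].
#' @return Data frame with `beacon_id` and `organization`.
#' @export
registry_directory <- function(registry) {
  data.frame(beacon_id = names(registry$entries),
             organization = vapply(registry$entries, `[[`, "", "organization"),
             row.names = NULL)
}

#' Fan a query out across every registered beacon
#'
#' Answers "who has observed this allele?". Each beacon is queried
#' independently under a per-beacon time limit; one beacon's failure or
#' timeout never aborts the fan-out and is recorded as a failure marker —
#' distinct from a "no", because federation must distinguish absence from
#' unavailability. Yes/no/error counts partition the registry.
#'
#' @param registry A [beacon_registry()].
#' @param query An [allele_query()].
#' @param cred A [credential()], forwarded unchanged to every beacon.
#' @param timeout Per-beacon time limit in seconds.
#' @return An object of class `network_response` with per-beacon outcomes
#'   and aggregate `yes_count`, `no_count`, `error_count`.
#' @export
federated_query <- function(registry, query, cred = credential(),
                            timeout = 5) {
  stopifnot(inherits(registry, "beacon_registry"))
  if (length(registry$entries) == 0L) {
    beacon_abort("no beacons registered", "beacon_no_beacons")
  }
  per_beacon <- lapply(registry$entries, function(entry) {
    tryCatch({
      setTimeLimit(elapsed = timeout, transient = TRUE)
      on.exit(setTimeLimit(elapsed = Inf, transient = TRUE), add = TRUE)
      handle_query(entry$handle, query, cred)
    }, error = function(e) {
      structure(list(failure = conditionMessage(e)), class = "beacon_failure")
    })
  })
  outcome <- vapply(per_beacon, function(r) {
    if (inherits(r, "beacon_failure") || !is.null(r$error)) "error"
    else if (isTRUE(r$exists)) "yes" else "no"
  }, "")
  structure(list(query = query, per_beacon = per_beacon,
                 yes_count = sum(outcome == "yes"),
                 no_count = sum(outcome == "no"),
                 error_count = sum(outcome == "error")),
            class = "network_response")
}

#' @export
print.network_response <- function(x, ...) {
  cat(sprintf("<network_response> %d yes / %d no / %d failed of %d beacons\n",
              x$yes_count, x$no_count, x$error_count, length(x$per_beacon)))
  invisible(x)
}

## ---- Aggregate (origin-obscuring) beacons ---------------------------------

#' Combine beacons into a single origin-obscuring aggregate
#'
#' The aggregate answers yes iff any member answers yes, while its info and
#' its responses never identify the members: queries are forwarded live
#' (no merged index), member dataset detail is discarded, and only the
#' aggregate's own identity appears on the wire. This lets several hosts
#' pool data points while blocking direct access to — or enumeration of —
#' the participating beacons.
#'
#' @param handles List of at least one beacon handle.
#' @param aggregate_id Public identifier of the aggregate.
#' @param organization,description Public metadata of the aggregate.
#' @return An object of class `aggregate_beacon` (usable as a handle).
#' @export
make_aggregate <- function(handles, aggregate_id,
                           organization = "aggregate",
                           description = "aggregate beacon") {
  if (length(handles) < 1L) {
    beacon_abort("an aggregate needs at least one member beacon",
                 "beacon_domain_error")
  }
  structure(list(aggregate_id = aggregate_id, organization = organization,
                 description = description, members = handles),
            class = "aggregate_beacon")
}

#' @export
handle_info.aggregate_beacon <- function(handle) {
  structure(list(beacon_id = handle$aggregate_id,
                 organization = handle$organization,
                 description = handle$description,
                 api_version = "v1.0.0", datasets = list()),
            class = "beacon_info")
}

#' @export
handle_query.aggregate_beacon <- function(handle, query, cred = credential()) {
  answers <- lapply(handle$members, function(m) {
    tryCatch(handle_query(m, query, cred), error = function(e) {
      structure(list(failure = conditionMessage(e)), class = "beacon_failure")
    })
  })
  exists <- vapply(answers, function(r) {
    if (inherits(r, "beacon_failure") || !is.null(r$error)) NA
    else isTRUE(r$exists)
  }, NA)
  if (all(is.na(exists))) {
    return(new_allele_response(handle$aggregate_id, error = protocol_error(
      "aggregate_unavailable", "no member beacon could answer")))
  }
  # OR over members that answered; member identities never leave this frame
  new_allele_response(handle$aggregate_id,
                      exists = any(exists, na.rm = TRUE))
}

#' @export
print.aggregate_beacon <- function(x, ...) {
  cat(sprintf("<aggregate_beacon> '%s' (%d members, unlisted)\n",
              x$aggregate_id, length(x$members)))
  invisible(x)
}
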
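# Tiered access: tier resolution from credentials, consent-code purpose
# gating, and progressive-disclosure redaction of query responses.

#' Access tiers, in increasing order of privilege
#'
#' The three GA4GH-style access levels. Responses disclose strictly more
#' metadata at each successive tier (progressive disclosure).
#'
#' @return Character vector `c("open", "registered", "controlled")`, ordered
#'   from least to most privileged.
#' @export
access_tiers <- function() c("open", "registered", "controlled")

tier_rank <- function(tier) {
  r <- match(tier, access_tiers())
  if (is.na(r)) beacon_abort(sprintf("unknown access tier '%s'", tier),
                             "beacon_domain_error")
  r
}

tier_min <- function(a, b) access_tiers()[min(tier_rank(a), tier_rank(b))]

#' Construct a credential
#'
#' A credential carries an opaque token (absent for anonymous users), an
#' upper bound on the tier the token may confer (`tier_claim`), and a
#' stable `identity_key` used for information-budget accounting. Anonymous
#' credentials share a single budget pool key, so open-access abuse is
#' metered collectively.
#'
#' @param token Opaque token string, or `NULL` for anonymous access.
#' @param tier_claim Highest tier the holder claims; the resolved tier
#'   never exceeds it.
#' @param identity_key Budget-accounting key; defaults to the token, or the
#'   shared `"anonymous"` pool for tokenless credentials.
#' @return An object of class `credential`.
#' @export
credential <- function(token = NULL, tier_claim = "controlled",
                       identity_key = NULL) {
  tier_rank(tier_claim)  # validate
  if (is.null(identity_key)) {
    identity_key <- if (is.null(token)) "anonymous" else token
  }
  stopifnot(nzchar(identity_key))
  structure(list(token = token, tier_claim = tier_claim,
                 identity_key = identity_key),
            class = "credential")
}

#' Resolve a credential to an access tier
#'
#' Anonymous credentials (no token) resolve to `"open"`. A token found in
#' the registry resolves to its registered tier, capped at the credential's
#' `tier_claim` (resolution never escalates). A token absent from the
#' registry is an authentication error, never a silent downgrade to open.
#'
#' @param cred A [credential()].
#' @param token_registry Named list/character vector mapping token -> tier.
#' @return One of [access_tiers()].
#' @export
resolve_tier <- function(cred, token_registry = list()) {
  stopifnot(inherits(cred, "credential"))
  if (is.null(cred$token)) return("open")
  registered <- token_registry[[cred$token]]
  if (is.null(registered)) {
    beacon_abort(sprintf("unknown token '%s'", cred$token), "beacon_auth_error")
  }
  tier_min(registered, cred$tier_claim)
}

## ---- Consent codes --------------------------------------------------------

consent_primary_categories <- c("NRES", "GRU", "HMB", "DS", "POA")
purpose_categories <- c("general_research", "health_medical_biomedical",
                        "disease_specific", "population_origins")

#' Construct a consent code
#'
#' Structured data-use conditions attached to a dataset: a primary category
#' (NRES: no restriction; GRU: general research use; HMB: health, medical
#' or biomedical research; DS: disease-specific research; POA: population
#' origins/ancestry research only) plus optional secondary modifiers, which
#' are carried and displayed but not enforced.
#'
#' @param primary_category One of NRES, GRU, HMB, DS, POA.
#' @param disease_term Required when `primary_category == "DS"`.
#' @param secondary_requirements Character vector of modifier labels.
#' @return An object of class `consent_code`.
#' @export
consent_code <- function(primary_category, disease_term = NULL,
                         secondary_requirements = character()) {
  primary_category <- match.arg(primary_category, consent_primary_categories)
  if (primary_category == "DS" &&
      (is.null(disease_term) || !nzchar(disease_term))) {
    beacon_abort("DS consent requires a disease term", "beacon_domain_error")
  }
  structure(list(primary_category = primary_category,
                 disease_term = disease_term,
                 secondary_requirements = secondary_requirements),
            class = "consent_code")
}

#' Construct a research purpose
#'
#' The purpose a caller declares for a query, matched against dataset
#' consent codes by [check_consent()].
#'
#' @param category One of `general_research`,
#'   `health_medical_biomedical`, `disease_specific`, `population_origins`.
#' @param disease_term Required when `category == "disease_specific"`.
#' @return An object of class `research_purpose`.
#' @export
research_purpose <- function(category = "general_research",
                             disease_term = NULL) {
  category <- match.arg(category, purpose_categories)
  if (category == "disease_specific" &&
      (is.null(disease_term) || !nzchar(disease_term))) {
    beacon_abort("disease_specific purpose requires a disease term",
                 "beacon_domain_error")
  }
  structure(list(category = category, disease_term = disease_term),
            class = "research_purpose")
}

#' Decide whether a research purpose satisfies a dataset's consent code
#'
#' The decision table is total: every (code, purpose) pair yields exactly
#' one decision. NRES allows everything; GRU allows all research
#' categories; HMB allows health/medical/biomedical and disease-specific
#' research; DS allows only disease-specific research whose term matches
#' the consented disease exactly (no ontology expansion); POA allows only
#' population-origins research.
#'
#' @param code A [consent_code()].
#' @param purpose A [research_purpose()].
#' @return A list with `allowed` (logical) and, when denied, `reason`.
#' @export
check_consent <- function(code, purpose) {
  stopifnot(inherits(code, "consent_code"), inherits(purpose, "research_purpose"))
  allow <- function() list(allowed = TRUE, reason = NULL)
  deny <- function(reason) list(allowed = FALSE, reason = reason)
  switch(code$primary_category,
    NRES = allow(),
    GRU = allow(),
    HMB = if (purpose$category %in% c("health_medical_biomedical",
                                      "disease_specific")) allow() else
      deny("dataset consented for health/medical/biomedical research only"),
    DS = if (purpose$category == "disease_specific" &&
             identical(purpose$disease_term, code$disease_term)) allow() else
      deny(sprintf("dataset consented for research on '%s' only",
                   code$disease_term)),
    POA = if (purpose$category == "population_origins") allow() else
      deny("dataset consented for population origins/ancestry research only"))
}

## ---- Progressive-disclosure redaction -------------------------------------

# Fields of a dataset-level response visible at each tier. The chain is a
# strict superset ordering: open < registered < controlled.
default_field_map <- function() {
  list(open = c("dataset_id", "exists", "note"),
       registered = c("dataset_id", "exists", "note", "frequency",
                      "allele_count"),
       controlled = c("dataset_id", "exists", "note", "frequency",
                      "allele_count", "sample_count", "extra_metadata"))
}

#' Redact an allele response for an access tier
#'
#' Implements progressive disclosure: an open-tier caller sees only the
#' yes/no verdict per dataset; registered callers additionally see allele
#' frequency and allele count; controlled callers see everything, including
#' carrier sample counts and extra metadata copied from the source VCF.
#' The disclosed field set at any tier is a superset of every lower tier's.
#'
#' @param response An `allele_response` (see [beacon_query()]).
#' @param tier One of [access_tiers()].
#' @param field_map Tier -> permitted field names; the default implements
#'   the mapping above and can be overridden by beacon configuration.
#' @return The response with per-dataset fields outside the tier's
#'   permitted set removed.
#' @export
redact <- function(response, tier, field_map = default_field_map()) {
  tier_rank(tier)  # validate
  allowed <- field_map[[tier]]
  response$dataset_responses <- lapply(response$dataset_responses, function(dr) {
    dr[intersect(names(dr), allowed)]
  })
  response
}
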
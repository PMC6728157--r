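# Information budgeting: meter cumulative per-credential disclosure in bits
# and refuse service before re-identification confidence is reachable.
#
# A "yes" about an allele of frequency f is worth -log2(f) bits of surprisal
# about the served cohort; rare alleles are far more revealing than common
# ones, so they cost more. "No" answers also inform the frequency-agnostic
# membership attack, so they carry a small constant cost.

#' Construct a disclosure cost policy
#'
#' @param frequency_floor Minimum frequency used in pricing; queries for
#'   alleles rarer than this are charged as if at the floor, bounding the
#'   per-query cost at `-log2(frequency_floor)` bits.
#' @param no_response_cost Bits charged for a "no" answer. Repeated "no"s
#'   still leak membership evidence; set to 0 to meter "yes" answers only.
#' @param unknown_frequency_cost Bits charged for a "yes" whose allele
#'   frequency is unknown; defaults to the worst case, the cost at the
#'   frequency floor.
#' @return An object of class `cost_policy`.
#' @export
cost_policy <- function(frequency_floor = 1e-4, no_response_cost = 0.05,
                        unknown_frequency_cost = NULL) {
  if (frequency_floor <= 0 || frequency_floor >= 1) {
    beacon_abort("frequency_floor must be in (0, 1)", "beacon_domain_error")
  }
  if (no_response_cost < 0) {
    beacon_abort("costs must be >= 0", "beacon_domain_error")
  }
  if (is.null(unknown_frequency_cost)) {
    unknown_frequency_cost <- -log2(frequency_floor)
  }
  if (unknown_frequency_cost < 0) {
    beacon_abort("costs must be >= 0", "beacon_domain_error")
  }
  structure(list(frequency_floor = frequency_floor,
                 no_response_cost = no_response_cost,
                 unknown_frequency_cost = unknown_frequency_cost),
            class = "cost_policy")
}

#' Disclosure cost of one query response, in bits
#'
#' A "yes" for an allele at frequency `f` costs `-log2(max(f, floor))`
#' bits: strictly decreasing in frequency above the floor. A "yes" with
#' unknown frequency costs `unknown_frequency_cost`; a "no" costs
#' `no_response_cost`.
#'
#' @param frequency Allele frequency in `(0, 1]`, or `NULL` when unknown.
#' @param response_is_yes Logical: was the answer "yes"?
#' @param policy A [cost_policy()].
#' @return Cost in bits (nonnegative scalar).
#' @examples
#' query_cost(0.5, TRUE, cost_policy())   # 1 bit
#' query_cost(0.25, TRUE, cost_policy())  # 2 bits
#' @export
query_cost <- function(frequency, response_is_yes, policy = cost_policy()) {
  stopifnot(inherits(policy, "cost_policy"))
  if (!response_is_yes) return(policy$no_response_cost)
  if (is.null(frequency)) return(policy$unknown_frequency_cost)
  if (!is.numeric(frequency) || is.na(frequency) ||
      frequency <= 0 || frequency > 1) {
    beacon_abort("frequency must be in (0, 1]", "beacon_domain_error")
  }
  -log2(max(frequency, policy$frequency_floor))
}

#' Construct a budget ledger
#'
#' Tracks cumulative disclosure per credential identity and locks an
#' identity out once its spend reaches the threshold. The ledger mutates in
#' place (it is environment-backed) so a beacon's state persists across
#' queries.
#'
#' @param threshold_bits Lockout threshold in bits. The default of 30 bits
#'   is roughly the self-information of one individual among the human
#'   population; an attacker held below it cannot accumulate enough
#'   evidence to single a person out with confidence.
#' @return An object of class `budget_ledger`.
#' @export
budget_ledger <- function(threshold_bits = 30) {
  if (threshold_bits <= 0) {
    beacon_abort("threshold_bits must be positive", "beacon_domain_error")
  }
  e <- new.env(parent = emptyenv())
  e$threshold_bits <- threshold_bits
  e$spent <- new.env(parent = emptyenv(), hash = TRUE)
  e$locked <- new.env(parent = emptyenv(), hash = TRUE)
  class(e) <- "budget_ledger"
  e
}

#' Charge a credential's budget and gate the query
#'
#' An already-locked identity is refused without further charging. An
#' unlocked identity is charged, then locked if its cumulative spend
#' reaches the threshold — charge-then-lock, so the query that crosses the
#' threshold is still answered.
#'
#' @param ledger A [budget_ledger()].
#' @param identity_key Budget-accounting key of the caller.
#' @param cost Cost in bits (`>= 0`), from [query_cost()].
#' @return List with `permitted` (logical), `spent` (cumulative bits) and
#'   `locked` (logical, state after this call).
#' @export
charge_and_gate <- function(ledger, identity_key, cost) {
  stopifnot(inherits(ledger, "budget_ledger"), cost >= 0)
  if (isTRUE(ledger$locked[[identity_key]])) {
    return(list(permitted = FALSE,
                spent = budget_spent(ledger, identity_key), locked = TRUE))
  }
  spent <- budget_spent(ledger, identity_key) + cost
  assign(identity_key, spent, envir = ledger$spent)
  # small slack so accumulated floating-point error cannot defer the lock
  locked <- spent >= ledger$threshold_bits - 1e-9
  if (locked) assign(identity_key, TRUE, envir = ledger$locked)
  list(permitted = TRUE, spent = spent, locked = locked)
}

#' Cumulative bits spent by an identity
#'
#' @param ledger A [budget_ledger()].
#' @param identity_key Budget-accounting key.
#' @return Nonnegative scalar (0 for unseen identities).
#' @export
budget_spent <- function(ledger, identity_key) {
  s <- ledger$spent[[identity_key]]
  if (is.null(s)) 0 else s
}

#' Is an identity locked out?
#'
#' @param ledger A [budget_ledger()].
#' @param identity_key Budget-accounting key.
#' @return Logical scalar.
#' @export
budget_locked <- function(ledger, identity_key) {
  isTRUE(ledger$locked[[identity_key]])
}

#' Reset an identity's budget (administrative action)
#'
#' Zeroes the identity's spend and unlocks it; a subsequent charge behaves
#' as for a fresh key. Resetting an unknown key is a no-op.
#'
#' @param ledger A [budget_ledger()].
#' @param identity_key Budget-accounting key.
#' @return The ledger, invisibly.
#' @export
budget_reset <- function(ledger, identity_key) {
  if (exists(identity_key, envir = ledger$spent, inherits = FALSE)) {
    rm(list = identity_key, envir = ledger$spent)
  }
  if (exists(identity_key, envir = ledger$locked, inherits = FALSE)) {
    rm(list = identity_key, envir = ledger$locked)
  }
  message(sprintf("budget ledger: reset identity '%s'", identity_key))
  invisible(ledger)
}

# JSON persistence of ledger state (external interface).
ledger_save <- function(ledger, path) {
  keys <- ls(ledger$spent, all.names = TRUE)
  jsonlite::write_json(
    list(format_version = 1L, threshold_bits = ledger$threshold_bits,
         spent = as.list(setNames(lapply(keys, budget_spent,
                                         ledger = ledger), keys)),
         locked = ls(ledger$locked, all.names = TRUE)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

ledger_load <- function(path) {
  x <- jsonlite::read_json(path)
  ledger <- budget_ledger(x$threshold_bits)
  for (k in names(x$spent)) assign(k, x$spent[[k]], envir = ledger$spent)
  for (k in unlist(x$locked)) assign(k, TRUE, envir = ledger$locked)
  ledger
}
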
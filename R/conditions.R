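# Typed condition helpers. Every error raised by the package carries the
# class "beacon_error" plus a specific subclass so callers (and the query
# engine itself) can distinguish, e.g., an unsupported allele from an
# authentication failure without string-matching messages.

beacon_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "beacon_error")))
}

#' Test whether a condition is a beacon error of a given subclass
#'
#' @param cnd A condition object.
#' @param class Subclass to test for, e.g. `"beacon_unsupported_allele"`.
#' @return Logical scalar.
#' @export
is_beacon_error <- function(cnd, class = "beacon_error") {
  inherits(cnd, class)
}
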
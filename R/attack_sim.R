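# Membership-inference (attribute-disclosure) attack simulation.
#
# The attacker holds the genome of a known target and repeatedly asks a
# beacon about alleles the target carries. Each "yes" is weak evidence the
# target is in the served cohort; accumulated over many queries the
# evidence becomes decisive. Two attacker models are simulated:
#   * frequency-aware LRT — per-query log-likelihood-ratio terms using the
#     population allele frequencies, querying rarest alleles first;
#   * frequency-agnostic count — the plain fraction of "yes" answers over
#     randomly ordered queries, needing no frequency knowledge at all.
# Power is estimated by Monte Carlo over paired member/non-member targets,
# with the decision threshold calibrated empirically to the desired
# false-positive rate on non-members.

#' Simulate a diploid population with a known allele-frequency spectrum
#'
#' Allele frequencies are drawn from a Beta(`afs_shape`) distribution
#' truncated to `[f_min, 0.5]` (the default Beta(0.5, 0.5) concentrates
#' mass near the rare end, mimicking a site-frequency spectrum). Genotypes
#' are alt-allele dosages in {0, 1, 2}, two independent Bernoulli(f) draws
#' per individual per site — sites are unlinked, matching the independence
#' assumption of both attack statistics.
#'
#' @param n_individuals Number of diploid individuals (pool size, not the
#'   beacon size: beacons are formed from subsets).
#' @param n_snps Number of independent biallelic SNPs.
#' @param afs_shape Beta shape parameters `c(a, b)` of the frequency draw.
#' @param f_min Lower truncation of the frequency spectrum.
#' @param seed RNG seed; the same seed reproduces the population exactly.
#' @return An object of class `synthetic_population` with fields
#'   `n_individuals`, `n_snps`, `frequencies`, `genotypes` (individuals x
#'   sites integer matrix), `sites` (chrom/pos/ref/alt table for VCF
#'   export) and `seed`.
#' @export
simulate_population <- function(n_individuals, n_snps,
                                afs_shape = c(0.5, 0.5), f_min = 0.001,
                                seed = 1L) {
  if (n_individuals < 1 || n_snps < 1) {
    beacon_abort("population dimensions must be positive", "beacon_domain_error")
  }
  if (length(afs_shape) != 2L || any(afs_shape <= 0)) {
    beacon_abort("afs_shape must be two positive Beta parameters",
                 "beacon_domain_error")
  }
  if (f_min <= 0 || f_min > 0.5) {
    beacon_abort("f_min must be in (0, 0.5]", "beacon_domain_error")
  }
  set.seed(seed)
  a <- afs_shape[1]; b <- afs_shape[2]
  lo <- pbeta(f_min, a, b); hi <- pbeta(0.5, a, b)
  f <- qbeta(runif(n_snps, lo, hi), a, b)
  f <- pmin(pmax(f, f_min), 0.5)

  # dosages drawn column-chunked to bound peak memory on large populations
  G <- matrix(0L, nrow = n_individuals, ncol = n_snps)
  chunk <- max(1L, floor(2e7 / n_individuals))
  for (start in seq(1L, n_snps, by = chunk)) {
    cols <- start:min(start + chunk - 1L, n_snps)
    G[, cols] <- rbinom(n_individuals * length(cols), 2L,
                        rep(f[cols], each = n_individuals))
  }

  refs <- sample(c("A", "C", "G", "T"), n_snps, replace = TRUE)
  alts <- c("A", "C", "G", "T")[
    (match(refs, c("A", "C", "G", "T")) - 1L +
       sample.int(3L, n_snps, replace = TRUE)) %% 4L + 1L]
  structure(list(n_individuals = n_individuals, n_snps = n_snps,
                 frequencies = f, genotypes = G,
                 sites = data.frame(chrom = "1",
                                    pos = seq_len(n_snps) * 10L,
                                    ref = refs, alt = alts,
                                    stringsAsFactors = FALSE),
                 seed = seed),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("<synthetic_population> %d individuals x %d SNPs, f in [%.4g, %.4g], seed %d\n",
              x$n_individuals, x$n_snps, min(x$frequencies),
              max(x$frequencies), x$seed))
  invisible(x)
}

#' Build a beacon presence oracle from a subset of a population
#'
#' The oracle answers yes for a site iff at least one member carries at
#' least one surviving alt-allele copy there. With `dropout > 0` each alt
#' copy is independently lost with that probability at construction time,
#' modelling the chance that the beacon's copy of a member's genome lacks
#' an allele the attacker knows the member to carry (pipeline differences,
#' missed calls).
#'
#' @param population A [simulate_population()].
#' @param member_ids Integer indices of the individuals the beacon serves
#'   (may be empty: the resulting oracle answers all-no).
#' @param dropout Per-copy loss probability.
#' @return An object of class `beacon_oracle` with the per-site `presence`
#'   vector, surviving `allele_counts` and beacon-cohort `frequencies`.
#' @export
beacon_from_population <- function(population, member_ids, dropout = 0) {
  stopifnot(inherits(population, "synthetic_population"))
  if (length(member_ids) > 0 &&
      (any(member_ids < 1) || any(member_ids > population$n_individuals))) {
    beacon_abort("member_ids outside population", "beacon_domain_error")
  }
  ac <- colSums(population$genotypes[member_ids, , drop = FALSE])
  if (dropout > 0) ac <- rbinom(length(ac), ac, 1 - dropout)
  n <- length(member_ids)
  structure(list(member_ids = member_ids, n_members = n,
                 presence = ac > 0L, allele_counts = ac,
                 frequencies = if (n > 0) ac / (2 * n) else rep(0, length(ac))),
            class = "beacon_oracle")
}

#' Query a beacon oracle at site indexes
#'
#' @param oracle A [beacon_from_population()] oracle.
#' @param snp_index Integer site indexes.
#' @return Logical vector of yes/no answers.
#' @export
oracle_query <- function(oracle, snp_index) {
  stopifnot(inherits(oracle, "beacon_oracle"))
  oracle$presence[snp_index]
}

## ---- Attack statistics ----------------------------------------------------

#' Frequency-aware log-likelihood-ratio membership statistic
#'
#' For responses `x_i` to queries at the target's alt-carried sites with
#' population frequencies `f_i`, against a beacon of `N` individuals:
#' under the null (target not served) a yes has probability
#' `P_out = 1 - (1 - f)^(2N)`; under the alternative (target served, with
#' per-copy mismatch probability `delta`) a no can only arise through
#' mismatch, `P_in = 1 - delta * (1 - f)^(2(N-1))`. The statistic is the
#' sum of per-query log ratios; large values favour membership.
#'
#' @param responses Numeric/logical vector of yes(1)/no(0) answers.
#' @param queried_frequencies Population frequencies of the queried sites.
#' @param N Beacon size (individuals served).
#' @param delta Per-copy mismatch probability; must be positive so the
#'   no-response branch has finite log-likelihood.
#' @return The log-likelihood-ratio sum (0 for zero queries).
#' @export
lrt_statistic <- function(responses, queried_frequencies, N, delta = 1e-6) {
  x <- as.numeric(responses)
  if (length(x) == 0L) return(0)
  if (length(queried_frequencies) != length(x)) {
    beacon_abort("responses and queried_frequencies lengths differ",
                 "beacon_domain_error")
  }
  if (delta <= 0) {
    if (any(x == 0)) {
      beacon_abort("delta = 0 makes a 'no' response impossible for a member; use delta > 0",
                   "beacon_domain_error")
    }
    delta <- .Machine$double.xmin  # all-yes: no-branch never evaluated
  }
  sum(lrt_terms(x, queried_frequencies, N, delta))
}

# Per-query log-ratio terms, evaluated in log space so they stay finite
# when (1 - f)^(2N) underflows: since 1 - P_in = delta (1-f)^(2(N-1)) and
# 1 - P_out = (1-f)^(2N), the no-branch reduces exactly to
# log(delta) - 2 log(1 - f).
lrt_terms <- function(x, f, N, delta) {
  l1mf <- log1p(-f)
  log_pout <- log(-expm1(2 * N * l1mf))
  log_pin <- log1p(-delta * exp(2 * (N - 1) * l1mf))
  x * (log_pin - log_pout) + (1 - x) * (log(delta) - 2 * l1mf)
}

#' Frequency-agnostic count membership statistic
#'
#' The fraction of yes answers among the queries — the simplest attack,
#' requiring no allele-frequency model at all.
#'
#' @param responses Numeric/logical vector of yes(1)/no(0) answers;
#'   must be nonempty.
#' @return The yes-fraction in `[0, 1]`.
#' @export
count_statistic <- function(responses) {
  x <- as.numeric(responses)
  if (length(x) == 0L) {
    beacon_abort("count statistic needs at least one query", "beacon_domain_error")
  }
  mean(x)
}

## ---- Attack configuration & Monte-Carlo engine ----------------------------

#' Configure a membership-inference attack experiment
#'
#' @param attack_kind `"frequency_aware_lrt"` (rarest-first query order,
#'   LRT statistic) or `"frequency_agnostic_count"` (random query order,
#'   yes-fraction statistic).
#' @param n_queries Queries issued per target (truncated, with a warning,
#'   to the target's number of alt-carried sites).
#' @param n_members Beacon size drawn per replicate.
#' @param mismatch_rate Per-copy probability `delta` that the beacon's copy
#'   of a member's genome lacks an allele copy the attacker knows about;
#'   applied as dropout at beacon construction and used in the LRT.
#' @param fpr_target Decision false-positive rate `alpha`; the threshold is
#'   the empirical `(1-alpha)` quantile of non-member statistics, so the
#'   achieved FPR never exceeds `alpha`.
#' @param n_replicates Monte-Carlo replicates (fresh beacon membership and
#'   fresh member/non-member targets each).
#' @param seed RNG seed for the whole experiment.
#' @param freq_range Optional `c(lo, hi)`: restrict queries to sites with
#'   population frequency in this interval (used to compare the
#'   informativeness of rare versus common alleles).
#' @param null_calibration If `TRUE`, beacon membership is resampled
#'   independently of both targets (neither is served), so member and
#'   non-member statistics are exchangeable and estimated power should
#'   match `fpr_target` — a calibration check.
#' @return An object of class `attack_config`.
#' @export
attack_config <- function(attack_kind = c("frequency_aware_lrt",
                                          "frequency_agnostic_count"),
                          n_queries, n_members, mismatch_rate = 1e-6,
                          fpr_target = 0.05, n_replicates = 100L,
                          seed = 1L, freq_range = NULL,
                          null_calibration = FALSE) {
  attack_kind <- match.arg(attack_kind)
  if (n_queries < 1) {
    beacon_abort("n_queries must be >= 1", "beacon_domain_error")
  }
  if (n_members < 1) {
    beacon_abort("n_members must be >= 1", "beacon_domain_error")
  }
  if (mismatch_rate <= 0 || mismatch_rate >= 1) {
    beacon_abort("mismatch_rate must be in (0, 1)", "beacon_domain_error")
  }
  if (fpr_target <= 0 || fpr_target >= 1) {
    beacon_abort("fpr_target must be in (0, 1)", "beacon_domain_error")
  }
  if (n_replicates < 2) {
    beacon_abort("need at least 2 replicates", "beacon_domain_error")
  }
  structure(list(attack_kind = attack_kind, n_queries = as.integer(n_queries),
                 n_members = as.integer(n_members),
                 mismatch_rate = mismatch_rate, fpr_target = fpr_target,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), freq_range = freq_range,
                 null_calibration = isTRUE(null_calibration)),
            class = "attack_config")
}

# One Monte-Carlo pass: for each replicate draw beacon membership and a
# member/non-member target pair, query each target's alt-carried sites in
# the attacker's order, and store the response sequence plus per-site
# frequencies (population f for the LRT, beacon-cohort f for budget
# pricing). Cumulative statistics are precomputed so power can later be
# evaluated at any query count by prefix truncation.
attack_replicates <- function(population, config) {
  stopifnot(inherits(population, "synthetic_population"),
            inherits(config, "attack_config"))
  pool <- population$n_individuals
  need <- config$n_members + 2L
  if (pool < need) {
    beacon_abort(sprintf("population of %d cannot supply %d members plus disjoint targets",
                         pool, config$n_members), "beacon_domain_error")
  }
  set.seed(config$seed)
  f <- population$frequencies
  eligible <- seq_len(population$n_snps)
  if (!is.null(config$freq_range)) {
    eligible <- which(f >= config$freq_range[1] & f <= config$freq_range[2])
    if (length(eligible) == 0L) {
      beacon_abort("no sites in the requested frequency range",
                   "beacon_domain_error")
    }
  }
  truncated <- FALSE
  reps <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    if (config$null_calibration) {
      targets <- sample.int(pool, 2L)
      members <- sample(setdiff(seq_len(pool), targets), config$n_members)
      t_member <- targets[1L]; t_non <- targets[2L]
    } else {
      members <- sample.int(pool, config$n_members)
      t_member <- members[sample.int(config$n_members, 1L)]
      t_non <- sample(setdiff(seq_len(pool), members), 1L)
    }
    oracle <- beacon_from_population(population, members,
                                     dropout = config$mismatch_rate)
    one <- function(target) {
      carried <- eligible[population$genotypes[target, eligible] >= 1L]
      if (length(carried) == 0L) {
        return(list(resp = numeric(0), f_pop = numeric(0),
                    f_beacon = numeric(0)))
      }
      ord <- if (config$attack_kind == "frequency_aware_lrt") {
        carried[order(f[carried])]                       # rarest first
      } else {
        carried[sample.int(length(carried))]             # random order
      }
      ord <- ord[seq_len(min(config$n_queries, length(ord)))]
      if (length(ord) < config$n_queries) truncated <<- TRUE
      list(resp = as.numeric(oracle_query(oracle, ord)), f_pop = f[ord],
           f_beacon = oracle$frequencies[ord])
    }
    reps[[r]] <- list(member = one(t_member), nonmember = one(t_non))
  }
  if (truncated) {
    warning(sprintf("n_queries = %d exceeds some targets' alt-carried sites; truncated",
                    config$n_queries), call. = FALSE)
  }
  reps
}

# Statistic of one target's session truncated to its first n answers.
session_statistic <- function(session, n, config) {
  n_use <- min(n, length(session$resp))
  if (n_use == 0L) return(-Inf)  # an empty session carries no evidence
  idx <- seq_len(n_use)
  if (config$attack_kind == "frequency_agnostic_count") {
    count_statistic(session$resp[idx])
  } else {
    lrt_statistic(session$resp[idx], session$f_pop[idx],
                  N = config$n_members, delta = config$mismatch_rate)
  }
}

# Threshold at the empirical (1 - alpha) quantile of non-member statistics
# using an order statistic, so achieved FPR <= alpha by construction.
calibrate_threshold <- function(nonmember_stats, alpha) {
  s <- sort(nonmember_stats)
  s[ceiling((1 - alpha) * length(s))]
}

new_attack_result <- function(members, nonmembers, config,
                              n_queries_used = config$n_queries, extra = list()) {
  thr <- calibrate_threshold(nonmembers, config$fpr_target)
  structure(c(list(statistics_members = members,
                   statistics_nonmembers = nonmembers,
                   threshold = thr,
                   power = mean(members > thr),
                   achieved_fpr = mean(nonmembers > thr),
                   n_queries = n_queries_used, config = config), extra),
            class = "attack_result")
}

#' Run a membership-inference attack experiment
#'
#' Per replicate: draw a fresh beacon membership and a member and a
#' non-member target, query each target's alt-carried sites in the
#' attacker's order, and compute the configured statistic. The decision
#' threshold is the empirical `(1 - alpha)` quantile of the non-member
#' statistics; power is the fraction of member statistics exceeding it.
#'
#' @param population A [simulate_population()].
#' @param config An [attack_config()].
#' @return An object of class `attack_result` with the per-trial statistic
#'   samples, the calibrated `threshold`, `power` and `achieved_fpr`.
#' @export
run_attack <- function(population, config) {
  reps <- attack_replicates(population, config)
  members <- vapply(reps, function(r)
    session_statistic(r$member, config$n_queries, config), 0)
  nonmembers <- vapply(reps, function(r)
    session_statistic(r$nonmember, config$n_queries, config), 0)
  new_attack_result(members, nonmembers, config)
}

#' @export
print.attack_result <- function(x, ...) {
  cat(sprintf("<attack_result> %s: power %.3f at FPR %.3f (target %.2f), %d queries, %d replicates\n",
              x$config$attack_kind, x$power, x$achieved_fpr,
              x$config$fpr_target, x$n_queries,
              x$config$n_replicates))
  invisible(x)
}

#' Export per-replicate attack statistics as a data frame
#'
#' One row per replicate and arm, suitable for CSV export.
#'
#' @param result An `attack_result`.
#' @return Data frame with `replicate`, `arm`, `statistic`, `exceeds`.
#' @export
attack_result_table <- function(result) {
  stopifnot(inherits(result, "attack_result"))
  R <- length(result$statistics_members)
  data.frame(
    replicate = rep(seq_len(R), 2L),
    arm = rep(c("member", "nonmember"), each = R),
    statistic = c(result$statistics_members, result$statistics_nonmembers),
    exceeds = c(result$statistics_members, result$statistics_nonmembers) >
      result$threshold,
    row.names = NULL)
}

#' Smallest query count reaching a power goal
#'
#' Evaluates power on a single set of Monte-Carlo replicates at increasing
#' prefix lengths of each attack session: query counts are swept by
#' doubling up to `config$n_queries` (the cap), then the first bracketing
#' interval is bisected. Reports the smallest count at which estimated
#' power reaches `power_goal`, or "not reached" at the cap.
#'
#' @param population A [simulate_population()].
#' @param config An [attack_config()]; `n_queries` acts as the sweep cap.
#' @param power_goal Target power in (0, 1).
#' @return List with `reached` (logical), `n_queries` (integer or `NA`),
#'   `power` (estimated power at that count) and `power_at_cap`.
#' @export
queries_needed <- function(population, config, power_goal = 0.95) {
  if (power_goal <= 0 || power_goal >= 1) {
    beacon_abort("power_goal must be in (0, 1)", "beacon_domain_error")
  }
  reps <- attack_replicates(population, config)
  power_at <- function(n) {
    members <- vapply(reps, function(r) session_statistic(r$member, n, config), 0)
    nonmembers <- vapply(reps, function(r) session_statistic(r$nonmember, n, config), 0)
    thr <- calibrate_threshold(nonmembers, config$fpr_target)
    mean(members > thr)
  }
  cap <- config$n_queries
  power_cap <- power_at(cap)
  if (power_cap < power_goal) {
    return(list(reached = FALSE, n_queries = NA_integer_, power = power_cap,
                power_at_cap = power_cap))
  }
  # doubling phase
  n <- 1L
  while (n < cap && power_at(n) < power_goal) n <- min(2L * n, cap)
  # bisection within (n/2, n]
  lo <- max(1L, n %/% 2L)
  hi <- n
  while (lo < hi - 1L) {
    mid <- (lo + hi) %/% 2L
    if (power_at(mid) >= power_goal) hi <- mid else lo <- mid
  }
  best <- if (power_at(lo) >= power_goal) lo else hi
  list(reached = TRUE, n_queries = as.integer(best), power = power_at(best),
       power_at_cap = power_cap)
}

#' Evaluate the information-budget defense against an attack
#'
#' Runs the configured attack twice on identical Monte-Carlo draws: once
#' unmetered, and once with the budget gate in the query path. In the
#' defended run each target session is priced per answer ([query_cost()]
#' with the beacon-cohort allele frequency on "yes") and terminates at the
#' first refusal; charge-then-lock semantics answer the query that crosses
#' the threshold. Statistics and thresholds are then computed from the
#' answered prefixes only.
#'
#' @param population A [simulate_population()].
#' @param config An [attack_config()].
#' @param budget_policy A [cost_policy()].
#' @param threshold_bits Ledger lockout threshold; `Inf` disables the
#'   defense and reproduces the unmetered result exactly.
#' @return List with `undefended` and `defended` `attack_result`s; the
#'   defended result carries `answered_members` / `answered_nonmembers`,
#'   the per-replicate counts of queries answered before lockout.
#' @export
evaluate_defense <- function(population, config,
                             budget_policy = cost_policy(),
                             threshold_bits = 30) {
  reps <- attack_replicates(population, config)
  stat_all <- function(which, n) {
    vapply(reps, function(r) session_statistic(r[[which]], n, config), 0)
  }
  undefended <- new_attack_result(stat_all("member", config$n_queries),
                                  stat_all("nonmember", config$n_queries),
                                  config)

  answered_n <- function(session) {
    if (length(session$resp) == 0L) return(0L)
    yes <- session$resp == 1
    costs <- rep(budget_policy$no_response_cost, length(yes))
    # a yes is priced by the beacon's own cohort frequency of the allele
    costs[yes] <- vapply(session$f_beacon[yes], query_cost, 0,
                         response_is_yes = TRUE, policy = budget_policy)
    spent <- cumsum(costs)
    # charge-then-lock: query i is answered iff spend before it < threshold
    # (same floating-point slack as the ledger's lock test)
    sum(c(0, spent[-length(spent)]) < threshold_bits - 1e-9)
  }
  def_stat <- function(which) {
    vapply(reps, function(r) {
      s <- r[[which]]
      session_statistic(s, answered_n(s), config)
    }, 0)
  }
  answered_members <- vapply(reps, function(r) answered_n(r$member), 0L)
  answered_nonmembers <- vapply(reps, function(r) answered_n(r$nonmember), 0L)
  defended <- new_attack_result(
    def_stat("member"), def_stat("nonmember"), config,
    n_queries_used = config$n_queries,
    extra = list(answered_members = answered_members,
                 answered_nonmembers = answered_nonmembers,
                 threshold_bits = threshold_bits))
  list(undefended = undefended, defended = defended)
}
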
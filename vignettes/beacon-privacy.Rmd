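---
title: "Genomic beacons: protocol, re-identification risk, and information budgeting"
author: "beaconr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic beacons: protocol, re-identification risk, and information budgeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beaconr)
```

## The discovery problem

A *beacon* is a web-accessible service that answers one narrow question
about a genomic dataset: "have you observed this allele?" A query names a
genome assembly, a contig, a position, and reference and alternate bases;
the beacon answers yes or no, optionally attaching metadata such as the
allele frequency. Because the answer aggregates over an entire cohort, a
beacon can make case-level variant collections discoverable without
shipping genotypes — a remote searcher learns that *someone* in the
dataset carries the allele, with no reference to a specific sample.
Beacons federate naturally: many independently hosted services speaking
the same protocol can be searched as one network ("who has observed this
allele?").

This package implements the full stack in R — VCF-backed allele indexes,
the two-function query protocol with tiered disclosure and consent
gating, an information-budget defense, network federation with
origin-obscuring aggregates — together with a Monte-Carlo simulator of
membership-inference attacks that quantifies how much re-identification
risk the yes/no interface actually leaves, and how well budgeting
mitigates it.

## Allele identity and the exact-match contract

Queries and stored records meet on a canonical allele key: assembly,
contig (with any `"chr"` prefix stripped), 0-based start, reference and
alternate bases. VCF records are 1-based; the conversion happens once, at
`normalize_allele()`, and nowhere else. Normalization trims bases shared
by ref and alt — suffix first, then prefix, advancing the start — so that
`CAG>CTG` and `A>T` at the same site collide on one key. Trimming is
reference-free by design: the protocol promises exact-match semantics on
the allele as specified, so no FASTA is consulted and no left-alignment
across homopolymers is attempted. Symbolic alleles (`<DEL>`, breakends)
and `N`-containing alleles are rejected with a typed condition; on
ingest they are skipped with a warning rather than failing the dataset.
Multi-allelic VCF lines are split per alternate allele, and duplicate
normalized keys merge by summing counts. `INFO/AC` and `INFO/AN` take
precedence over genotype-derived counts when both are available, on the
principle that producer-asserted counts are authoritative.

## Tiers, consent, and progressive disclosure

Three ordered access tiers govern how much a response reveals:

| tier | disclosed per dataset |
|------|----------------------|
| open | `exists` (and denial notes) |
| registered | + allele frequency, allele count |
| controlled | + carrier sample count, extra VCF metadata |

The principle is progressive disclosure: the field set at any tier is a
superset of every lower tier's, so passing a stronger authentication
check never loses information. The specific tier-to-field mapping is a
policy default of this package (configurable per beacon via
`field_map`); what is fixed is the superset chain, which the test suite
checks property-style over randomized responses.

Datasets carry structured consent codes (`NRES`, `GRU`, `HMB`, `DS-<term>`,
`POA`) and queries declare a research purpose; `check_consent()`
implements a total decision table, with disease-specific (`DS`) matching
by exact term — ontology expansion is a deliberate extension point, not a
dependency. Secondary consent modifiers are carried and displayed but not
enforced, since their semantics require policy context a library cannot
verify. Two decisions matter for correctness downstream:

* a consent or tier denial is an explicit *refusal marker with no
  `exists` field* — never a fabricated "no", which would corrupt the OR
  performed by federation;
* the beacon's `exists` is the OR only over datasets that passed every
  gate.

## Metering disclosure: the information budget

Each answer about an allele of frequency $f$ is priced in bits as its
surprisal, $-\log_2 \max(f, f_{\min})$ for a yes, with a frequency floor
$f_{\min} = 10^{-4}$ bounding the price of extremely rare alleles, and a
small constant (default 0.05 bits) for a no — repeated "no"s also feed
the frequency-agnostic attack below, so they are not free. The price is
strictly decreasing in frequency above the floor: very rare alleles are
far more revealing than common ones. A per-credential ledger accumulates
spend and locks the credential at a threshold (default 30 bits, roughly
the self-information of singling out one person among the human
population). Semantics are charge-then-lock: the query that crosses the
threshold is still answered, which avoids needing a side-channel-prone
"would this query be free?" oracle. Anonymous callers share one budget
pool. The surprisal form is the simplest monotone disclosure measure
consistent with the inverse-frequency principle; it is not a formal
differential-privacy accountant, and budgets are per-user, not
per-data-subject.

## The attack model

The attacker knows the target's genome and may only ask the beacon
yes/no questions about alleles the target carries. Two attackers are
simulated against a beacon serving $N$ diploid members:

**Frequency-aware LRT.** For a query at population frequency $f_i$
answered $x_i \in \{0,1\}$,
$$\Lambda = \sum_i \left[ x_i \ln\frac{P_{\mathrm{in}}^i}{P_{\mathrm{out}}^i}
 + (1-x_i) \ln\frac{1-P_{\mathrm{in}}^i}{1-P_{\mathrm{out}}^i} \right],$$
with $P_{\mathrm{out}}^i = 1-(1-f_i)^{2N}$ (someone else carries it) and
$P_{\mathrm{in}}^i = 1-\delta\,(1-f_i)^{2(N-1)}$, where $\delta$ is the
per-copy probability that the beacon's copy of the member's genome lacks
the allele (default $10^{-6}$; it must be positive for the no-branch to
be finite). This attacker queries rarest alleles first.

**Frequency-agnostic count.** The plain yes-fraction over queries in
random order — no frequency model needed at all.

Power is estimated by Monte Carlo: each replicate draws a fresh beacon
membership, one member and one non-member target, and a query session
per target. The decision threshold is the empirical $(1-\alpha)$
order statistic of the non-member statistics, so the achieved
false-positive rate never exceeds $\alpha$ by construction; power is the
fraction of member statistics strictly exceeding it. Calibration is
deliberately empirical rather than asymptotic — it stays valid at
desk-scale replicate counts — and a permutation-null mode
(`null_calibration = TRUE`, beacon membership resampled independently of
both targets) verifies that estimated power matches $\alpha$.

## The synthetic populations

`simulate_population()` draws per-site allele frequencies from a
Beta(0.5, 0.5) distribution truncated to $[f_{\min}, 0.5]$ — a rare-heavy
spectrum — and genotypes as two independent Bernoulli($f$) draws per
individual: unlinked sites, matching the independence assumptions of
both statistics. What this deliberately does *not* emulate: linkage
disequilibrium, relatedness between individuals, population structure,
genotyping error beyond the single dropout parameter, and
frequency-spectrum mass below the truncation point. Passing tests
therefore certify the protocol logic and the *qualitative* risk
dependencies (more queries, smaller beacons, rarer alleles all increase
power), not quantitative risk on any real cohort.

The truncation point matters more than it may appear. At
$f_{\min} = 10^{-3}$, a 1,000-member beacon is nearly saturated: the
chance a site is absent is $(1-f)^{2000} \le e^{-2}$ at every site, and
averaging over the spectrum (weighted by the chance the target carries
the site) the per-query "no" probability for a non-member is about
$10^{-5}$. The frequency-agnostic attack's statistic then ties at
yes-fraction 1.0 for the vast majority of non-members, and no threshold
holding the false-positive rate at 5% can deliver high power within —
or indeed anywhere near — the number of positions a target carries. The
acceptance sweep (`scripts/acceptance.R`) measures exactly this: under
these study conditions the 95%-power point is not reached before the
queryable session is exhausted, and the script reports the exhausted
bound. Against smaller beacons (tens to low hundreds of members), or
when queries are restricted to the rare band, the same attack is
decisive within tens to thousands of queries — the regime where
real-world collections with substantial rare-variant content live.

## Defense evaluation

`evaluate_defense()` runs one set of Monte-Carlo draws through the
attack twice: unmetered, and with the budget gate in the query path. In
the defended arm each answer is priced with the beacon's own cohort
frequency, the session ends at the first refusal, and statistics are
computed over the answered prefix only. Pairing on identical draws makes
the comparison sharp: setting the threshold to `Inf` reproduces the
unmetered result bit-for-bit, and a finite threshold can only shorten
sessions. With the default policy the cheapest possible answer costs
0.05 bits, so a 30-bit budget answers at most
$\lceil 30/0.05 \rceil = 600$ queries — and in practice far fewer for
the rarest-first attacker, whose informative answers cost up to 13.3
bits each.

## Numerical and engineering choices

* The LRT is evaluated in log space. Since
  $1-P_{\mathrm{in}} = \delta(1-f)^{2(N-1)}$ and
  $1-P_{\mathrm{out}} = (1-f)^{2N}$, the no-branch reduces exactly to
  $\ln\delta - 2\ln(1-f)$, which stays finite when $(1-f)^{2N}$
  underflows; the yes-branch uses `log1p`/`expm1` forms.
* The ledger lock comparison includes a $10^{-9}$-bit slack so that
  accumulated floating-point error in repeated small charges cannot
  defer a lockout past the threshold.
* Dataset indexes are environment-backed hash maps keyed by the
  canonical allele string; lookups are O(1) and a linear-scan oracle in
  the test suite cross-checks presence/absence verdicts.
* Query fan-out across a registry is sequential with a per-beacon
  elapsed-time cap; a timeout or error is a *failure marker*, never a
  "no", because federation must distinguish absence from unavailability.
* Aggregate beacons forward live queries to members and answer with the
  OR; they keep no merged index, and neither their info nor their
  responses ever name a member.
* The wire layer is a pure function from (route, parameters) to a JSON
  body (`handle_request()`), so any HTTP front end can mount it; the
  bundled CLI serves it over newline-delimited JSON.
* Genotype matrices are generated in column chunks to bound peak memory;
  the largest study population (5,000 x 50,000) occupies about 1 GB as
  an integer matrix.

## Study conditions used by the test suite

The statistical checks run at fixed, seeded conditions chosen once:

* *calibration*: pool 2,000 x 20,000 sites, beacon of 100, LRT
  statistic (continuous, so the empirical quantile is well behaved),
  300 queries, 200 replicates under the permutation null;
* *query-count and beacon-size sweeps*: count statistic; beacon of
  1,000 (pool 2,200 x 30,000) across 100-10,000 queries, and beacons of
  {10, 100, 1,000} (pool 2,000 x 20,000) at 1,000 queries, 100
  replicates each;
* *rare versus common*: beacons of 50, 10 queries restricted to
  $f < 0.01$ versus $f > 0.1$, 200 replicates;
* *defense*: beacon of 1,000, 5,000 queries, 100 replicates, 30-bit
  threshold, paired arms; plus a beacon-of-100 configuration with
  queries restricted to $f \in [0.01, 0.02]$ — a moderate-evidence
  regime where each answer is informative but not decisive, so the
  unmetered attack has power that the budget visibly takes away;
* *re-identification sweep*: pool 5,000 x 50,000, beacon of 1,000,
  count statistic, 200 replicates, query counts by doubling/bisection
  up to the full session.

## Limitations

Beyond the population-model simplifications above: consent matching is
string-exact; tokens are opaque strings resolved against a local
registry, standing in for a real OpenID Connect/OAuth2 flow;
per-data-subject budgets, LD-aware and kinship attacks, and structural
variant queries are out of scope. Budget refusals are deliberately
distinguishable from "no" at the wire level; an operator wanting
indistinguishable refusals needs a different response contract.
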
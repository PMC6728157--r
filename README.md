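# beaconr

Genomic *beacons* are web services that answer a single, deliberately
narrow question about a variant dataset: **"have you observed this
allele?"** — assembly, chromosome, position, reference and alternate
bases in; yes or no (plus optional metadata such as allele frequency)
out. Because the answer aggregates over a whole cohort, beacons make
collections discoverable without shipping genotypes, and many
independently hosted beacons can be federated into one searchable
network ("who has observed this allele?").

`beaconr` is an R implementation of that stack, for data stewards who
want to light a beacon from VCF files and for privacy researchers who
want to measure what the yes/no interface still leaks:

* **allele store** — exact-match allele indexes built from VCF v4.x
  (plain or gzipped), with multi-allelic splitting, suffix/prefix trim
  normalization, and AC/AN- or genotype-derived counts;
* **protocol engine** — the two protocol functions (`beacon_info()`,
  `beacon_query()`), with consent-code purpose gating, tiered
  progressive disclosure (open / registered / controlled), and typed
  refusals that are never confused with "no";
* **information budgeting** — per-credential disclosure metering in
  bits, pricing a "yes" about an allele of frequency *f* at
  −log₂ max(f, 10⁻⁴) bits and locking the credential at a threshold
  (default 30 bits) before re-identification confidence is reachable;
* **federation** — a beacon registry with fault-isolated query fan-out,
  and origin-obscuring aggregate beacons that answer the OR over hidden
  members;
* **attack simulator** — synthetic diploid populations with a known
  allele-frequency spectrum, plus membership-inference attacks
  (frequency-aware likelihood-ratio test and frequency-agnostic
  yes-count) with empirically calibrated power estimates, and paired
  evaluation of the budgeting defense.

The membership-inference model: an attacker who already holds a
target's genome queries alleles the target carries. Against a beacon of
*N* members, a yes has probability 1−(1−f)^(2N) if the target is *not*
served, versus 1−δ(1−f)^(2(N−1)) if they are (δ = per-copy dropout);
accumulating that gap over many queries — or simply counting "no"s —
confirms membership, and with it the sensitive attribute the dataset
represents. Power grows with query count and allele rarity and shrinks
with beacon size; the vignette
(`vignettes/beacon-privacy.Rmd`) derives the statistics and documents
every simulation condition.

## Worked example

Light a beacon from a VCF containing the allele G>C at position
32,936,732 of chromosome 13 (a *BRCA2* site), query it anonymously, and
watch the budget meter refuse a locked credential:

```r
library(beaconr)

vcf <- tempfile(fileext = ".vcf")
writeLines(c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"AC\">",
  "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"AN\">",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
  "13\t32936732\t.\tG\tC\t.\tPASS\tAC=3;AN=200"), vcf)

idx <- ingest_vcf(vcf, "demo-dataset", "GRCh37")
bcn <- add_dataset(beacon("demo-beacon",
                          token_registry = list(r1 = "registered")), idx)

# positions are 0-based at the API boundary (VCF POS 32936732 -> 32936731)
q <- allele_query("GRCh37", "13", 32936731, "G", "C",
                  include_dataset_responses = TRUE)
beacon_query(bcn, q)
#> <allele_response> beacon 'demo-beacon': yes (1 dataset responses)

# a registered credential additionally sees frequency and allele count
r <- beacon_query(bcn, q, credential("r1"))
r$dataset_responses[[1]]$frequency
#> [1] 0.015

cat(response_json(beacon_query(bcn, allele_query(
  "GRCh37", "13", 32936731, "G", "T"))))
#> {"beacon_id":"demo-beacon","exists":false,"dataset_responses":[]}
```

The yes above cost the anonymous pool −log₂(0.015) ≈ 6.1 bits of its
30-bit budget; after enough such answers the beacon returns a typed
`budget_exhausted` refusal (distinct from "no") instead of a verdict.

Simulate a re-identification attack and the budget defense:

```r
pop <- simulate_population(n_individuals = 2000, n_snps = 20000, seed = 101)
# a 100-member beacon, querying alleles at frequency 1-2%: informative
# (a non-member draws a "no" 2-13% of the time per query) but no single
# answer is decisive
cfg <- attack_config("frequency_aware_lrt", n_queries = 2000,
                     n_members = 100, n_replicates = 100, seed = 1,
                     freq_range = c(0.01, 0.02))
pair <- evaluate_defense(pop, cfg, threshold_bits = 30)
pair$undefended$power   # unmetered: the full session accumulates evidence
#> [1] 0.47
pair$defended$power     # 30-bit budget takes roughly half of that away
#> [1] 0.25
range(pair$defended$answered_members)  # sessions end after a few answers
#> [1] 5 6
```

A command-line wrapper (`system.file("cli", "beacon", package =
"beaconr")`) exposes `ingest`, `serve`, `query`, `network`, `simulate`
and `fixtures` subcommands with JSON on stdout and exit codes 0 (yes) /
1 (no) / 2 (error or refusal).

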
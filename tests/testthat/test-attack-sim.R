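test_that("population simulation is seed-reproducible with the stated spectrum", {
  p1 <- simulate_population(10, 100, afs_shape = c(0.5, 0.5),
                            f_min = 0.001, seed = 7)
  p2 <- simulate_population(10, 100, afs_shape = c(0.5, 0.5),
                            f_min = 0.001, seed = 7)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$frequencies, p2$frequencies)
  expect_true(all(p1$frequencies >= 0.001 & p1$frequencies <= 0.5))
  expect_true(all(p1$genotypes %in% 0:2))

  # truncation collapse: f_min = 0.5 pins every frequency at 0.5
  p3 <- simulate_population(10, 50, f_min = 0.5, seed = 8)
  expect_true(all(p3$frequencies == 0.5))

  # a fixed f = 0.5 column over many individuals has mean dosage ~ 2f
  p4 <- simulate_population(10000, 3, f_min = 0.5, seed = 9)
  means <- colMeans(p4$genotypes)
  sd3 <- 3 * sqrt(2 * 0.5 * 0.5 / 10000)
  expect_true(all(abs(means - 1.0) < sd3))

  expect_error(simulate_population(0, 10), class = "beacon_domain_error")
  expect_error(simulate_population(10, 10, f_min = 0),
               class = "beacon_domain_error")
  expect_error(simulate_population(10, 10, afs_shape = c(1, -1)),
               class = "beacon_domain_error")
})

test_that("beacon oracle is the OR over member dosages", {
  # single member, dosages {2, 0, 1} -> yes, no, yes
  pop <- manual_population(matrix(c(2L, 0L, 1L), nrow = 1))
  o <- beacon_from_population(pop, 1L)
  expect_identical(oracle_query(o, 1:3), c(TRUE, FALSE, TRUE))

  # brute-force OR oracle over random instances
  set.seed(91)
  for (i in 1:50) {
    G <- matrix(sample(0:2, 60, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
                nrow = 6)
    pop <- manual_population(G)
    members <- sample.int(6, sample.int(6, 1))
    o <- beacon_from_population(pop, members)
    brute <- apply(G[members, , drop = FALSE] >= 1L, 2, any)
    expect_identical(unname(oracle_query(o, 1:10)), unname(brute))
  }

  # empty beacon answers all-no
  o0 <- beacon_from_population(manual_population(matrix(2L, 2, 4)), integer(0))
  expect_identical(oracle_query(o0, 1:4), rep(FALSE, 4))
})

test_that("LRT statistic matches hand evaluation and a brute-force oracle", {
  # one yes at f = 0.5, N = 1: ln(0.999999 / 0.75)
  expect_equal(lrt_statistic(1, 0.5, N = 1, delta = 1e-6),
               log(0.999999 / 0.75), tolerance = 1e-12)
  expect_equal(lrt_statistic(1, 0.5, N = 1, delta = 1e-6), 0.28768,
               tolerance = 1e-4)
  # one no: ln(1e-6 / 0.25)
  expect_equal(lrt_statistic(0, 0.5, N = 1, delta = 1e-6),
               log(1e-6 / 0.25), tolerance = 1e-9)
  expect_equal(lrt_statistic(numeric(0), numeric(0), N = 5), 0)
  expect_error(lrt_statistic(c(1, 0), c(0.1, 0.2), N = 5, delta = 0),
               class = "beacon_domain_error")
  # delta = 0 is tolerable when every response is yes
  expect_equal(lrt_statistic(1, 0.25, N = 2, delta = 0),
               -log(1 - 0.75^4), tolerance = 1e-12)

  # independent brute-force evaluation of the per-query likelihood terms,
  # in a parameter regime where the direct formula is numerically exact
  set.seed(92)
  for (i in 1:1000) {
    n <- sample.int(6, 1)
    x <- sample(0:1, n, replace = TRUE)
    f <- runif(n, 0.01, 0.3)
    N <- sample.int(10, 1)
    delta <- 10^runif(1, -4, -2)
    brute <- 0
    for (q in seq_len(n)) {
      p_out <- 1 - (1 - f[q])^(2 * N)
      p_in <- 1 - delta * (1 - f[q])^(2 * (N - 1))
      brute <- brute +
        if (x[q] == 1) log(p_in / p_out) else log((1 - p_in) / (1 - p_out))
    }
    expect_equal(lrt_statistic(x, f, N, delta), brute, tolerance = 1e-6)
  }
})

test_that("count statistic is the yes-fraction", {
  expect_equal(count_statistic(rep(1, 100)), 1.0)
  expect_equal(count_statistic(rep(0, 100)), 0.0)
  expect_error(count_statistic(numeric(0)), class = "beacon_domain_error")
  set.seed(93)
  for (i in 1:50) {
    x <- sample(0:1, sample.int(200, 1), replace = TRUE)
    expect_equal(count_statistic(x), mean(x))
  }
})

test_that("attack configuration rejects degenerate settings", {
  expect_error(attack_config("frequency_aware_lrt", n_queries = 0,
                             n_members = 5),
               class = "beacon_domain_error")
  expect_error(attack_config("frequency_aware_lrt", n_queries = 10,
                             n_members = 0),
               class = "beacon_domain_error")
  expect_error(attack_config("frequency_aware_lrt", n_queries = 10,
                             n_members = 5, mismatch_rate = 0),
               class = "beacon_domain_error")
  expect_error(attack_config("frequency_aware_lrt", n_queries = 10,
                             n_members = 5, fpr_target = 1),
               class = "beacon_domain_error")
  # population too small for members plus disjoint targets
  pop <- simulate_population(6, 50, seed = 94)
  cfg <- attack_config("frequency_aware_lrt", n_queries = 5, n_members = 5,
                       n_replicates = 5)
  expect_error(run_attack(pop, cfg), class = "beacon_domain_error")
})

test_that("achieved FPR never exceeds its target, and results are seeded", {
  pop <- simulate_population(60, 400, seed = 95)
  cfg <- attack_config("frequency_aware_lrt", n_queries = 50, n_members = 20,
                       n_replicates = 60, seed = 5)
  r1 <- suppressWarnings(run_attack(pop, cfg))
  r2 <- suppressWarnings(run_attack(pop, cfg))
  expect_identical(r1$statistics_members, r2$statistics_members)
  expect_lte(r1$achieved_fpr, cfg$fpr_target)
  expect_gte(r1$power, 0)
  tab <- attack_result_table(r1)
  expect_equal(nrow(tab), 120L)
  expect_equal(sum(tab$exceeds[tab$arm == "nonmember"]) / 60, r1$achieved_fpr)
})

test_that("a tiny beacon with rare alleles is re-identified within 50 queries", {
  # N = 1 and rare alleles separate members from non-members almost
  # immediately: a non-member's rare alleles are unlikely to be served
  pop <- simulate_population(400, 800, afs_shape = c(0.5, 0.5),
                             f_min = 0.001, seed = 96)
  cfg <- attack_config("frequency_aware_lrt", n_queries = 50, n_members = 1,
                       n_replicates = 60, seed = 6)
  qn <- suppressWarnings(queries_needed(pop, cfg, power_goal = 0.95))
  expect_true(qn$reached)
  expect_lte(qn$n_queries, 50)

  # under the permutation null there is no signal to accumulate
  cfg0 <- attack_config("frequency_aware_lrt", n_queries = 50, n_members = 1,
                        n_replicates = 60, seed = 6, null_calibration = TRUE)
  qn0 <- suppressWarnings(queries_needed(pop, cfg0, power_goal = 0.95))
  expect_false(qn0$reached)
})

test_that("defense evaluation is paired and disabling it is exact", {
  pop <- simulate_population(300, 2000, seed = 97)
  cfg <- attack_config("frequency_aware_lrt", n_queries = 300,
                       n_members = 100, n_replicates = 40, seed = 7)
  off <- suppressWarnings(
    evaluate_defense(pop, cfg, threshold_bits = Inf))
  expect_identical(off$defended$statistics_members,
                   off$undefended$statistics_members)
  expect_identical(off$defended$power, off$undefended$power)

  on <- suppressWarnings(evaluate_defense(pop, cfg, threshold_bits = 30))
  min_cost <- 0.05
  expect_lte(max(on$defended$answered_members,
                 on$defended$answered_nonmembers), ceiling(30 / min_cost))
  expect_lte(on$defended$power, on$undefended$power)
  # pairing: the unmetered arm is identical across the two calls
  expect_identical(on$undefended$statistics_members,
                   off$undefended$statistics_members)
})

test_that("member VCF export is consistent with the genotypes it encodes", {
  pop <- simulate_population(25, 300, seed = 98)
  members <- c(2L, 5L, 9L, 11L)
  path <- tempfile(fileext = ".vcf")
  write_vcf(pop, members, path)

  ac_true <- colSums(pop$genotypes[members, , drop = FALSE])
  seg <- which(ac_true > 0)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), length(seg))

  # AC in INFO equals the sum of member dosages per site; AN is 2 * members
  info <- vapply(strsplit(body, "\t"), `[[`, "", 8L)
  ac_written <- as.integer(sub("^AC=(\\d+);.*$", "\\1", info))
  an_written <- as.integer(sub("^.*AN=(\\d+)$", "\\1", info))
  expect_equal(ac_written, unname(ac_true[seg]))
  expect_true(all(an_written == 2L * length(members)))

  # re-ingest round trip
  idx <- ingest_vcf(path, "rt", "GRCh37")
  expect_equal(record_count(idx), length(seg))
  expect_equal(idx$sample_total, length(members))

  # empty membership: valid header-only file
  p0 <- tempfile(fileext = ".vcf")
  write_vcf(pop, integer(0), p0)
  expect_equal(sum(!startsWith(readLines(p0), "#")), 0L)
  expect_equal(record_count(ingest_vcf(p0, "empty", "GRCh37")), 0L)
})
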
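test_that("observed COG counting expands isoforms and tracks unannotated", {
  cog_table <- tibble::tibble(id = c("a", "b", "c"),
                              cog = c("J", "J", NA))
  obs <- observed_cog_counts(c("a", "b", "c"), cog_table)
  expect_identical(obs$count[obs$cog == "J"], 2L)
  expect_identical(attr(obs, "unannotated"), 1L)

  # a UTR with two isoforms, both COG K, contributes 2
  expansion <- tibble::tibble(utr_id = c("u1", "u1", "u2"),
                              isoform_id = c("i1", "i2", "i3"))
  ct <- tibble::tibble(id = c("i1", "i2", "i3"), cog = c("K", "K", "J"))
  obs2 <- observed_cog_counts("u1", ct, expansion)
  expect_identical(obs2$count[obs2$cog == "K"], 2L)
  # multi-letter assignments count once per letter
  ct3 <- tibble::tibble(id = "x", cog = "JK")
  obs3 <- observed_cog_counts("x", ct3)
  expect_identical(obs3$count, c(1L, 1L))

  expect_error(observed_cog_counts("nope", cog_table), "nope")

  # random tables vs a brute-force tally
  prot <- simulate_proteome(50, 3, p_annotated = 0.8, seed = 60)
  targ <- sample(prot$universe, 20)
  got <- observed_cog_counts(targ, prot$cog_table, prot$expansion)
  iso <- prot$expansion$isoform_id[prot$expansion$utr_id %in% targ]
  cg <- prot$cog_table$cog[match(iso, prot$cog_table$id)]
  brute <- table(unlist(strsplit(cg[!is.na(cg)], "")))
  expect_identical(setNames(got$count, got$cog),
                   setNames(as.integer(brute), names(brute)))
})

test_that("the resampling null is deterministic and respects degeneracy", {
  # degenerate universe: one UTR with one COG-J isoform, n = 5
  ct <- tibble::tibble(id = "u1", cog = "J")
  null <- monte_carlo_null("u1", ct, n_draws = 5, n_reps = 100, seed = 3)
  expect_true(all(null$counts[, "J"] == 5L))

  prot <- simulate_proteome(40, 3, seed = 8)
  n1 <- monte_carlo_null(prot$universe, prot$cog_table, 30, 500, seed = 9,
                         expansion = prot$expansion)
  n2 <- monte_carlo_null(prot$universe, prot$cog_table, 30, 500, seed = 9,
                         expansion = prot$expansion)
  expect_identical(n1$counts, n2$counts)
  # isoform expansion admits more proteins than draws
  expect_true(any(rowSums(n1$counts) > 30))
  expect_error(monte_carlo_null(character(0), ct, 5, 10, 1), "nonempty")
})

test_that("empirical two-tailed p follows the tail-doubling definition", {
  ct <- tibble::tibble(id = "u1", cog = "J")
  const <- monte_carlo_null("u1", ct, n_draws = 5, n_reps = 200, seed = 1)
  # observed equal to every replicate: both tails are 1, p capped at 1
  p1 <- empirical_two_tailed_p(c(J = 5), const)
  expect_equal(p1$p, 1)
  expect_false(p1$p_is_bound)
  # observed beyond every replicate: reported as the bound < 1/R
  pb <- empirical_two_tailed_p(c(J = 7), const)
  expect_true(pb$p_is_bound)
  expect_equal(pb$p, 1 / 200)
  expect_match(pb$p_report, "^< ")

  # invariance to replicate order
  prot <- simulate_proteome(30, 2, seed = 5)
  null <- monte_carlo_null(prot$universe, prot$cog_table, 40, 1000, seed = 2,
                           expansion = prot$expansion)
  perm <- null
  perm$counts <- perm$counts[sample.int(nrow(perm$counts)), , drop = FALSE]
  cc <- colnames(null$counts)[1]
  o <- setNames(10L, cc)
  expect_identical(empirical_two_tailed_p(o, null)$p,
                   empirical_two_tailed_p(o, perm)$p)
})

test_that("empirical p converges to the exact binomial computation", {
  # identity expansion, two categories at 50/50, n = 10 draws: counts are
  # Binomial(10, 1/2); observing 10 has exact doubled-tail p = 2 * 0.5^10
  universe <- sprintf("u%02d", 1:10)
  ct <- tibble::tibble(id = universe, cog = rep(c("J", "K"), 5))
  null <- monte_carlo_null(universe, ct, n_draws = 10, n_reps = 2e4,
                           seed = 11)
  p_hat <- empirical_two_tailed_p(c(J = 10), null)
  exact <- oracle_binom_tails(10, 10, 0.5)
  p_exact <- min(1, 2 * min(exact$tail_low, exact$tail_high))
  se <- sqrt(p_exact / 2 * (1 - p_exact / 2) / 2e4)
  tol <- if (p_hat$p_is_bound) 1 / 2e4 else 0
  expect_lt(abs(p_hat$p - p_exact), 2 * 3 * se + tol)
})

test_that("enrichment reports percent differences against the reference", {
  universe <- sprintf("u%02d", 1:20)
  ct <- tibble::tibble(id = universe, cog = rep(c("J", "K"), each = 10))
  null <- monte_carlo_null(universe, ct, n_draws = 20, n_reps = 2000,
                           seed = 21)
  reference <- observed_cog_counts(universe, ct)
  # targets drawn as the whole universe: observed% = reference%, enrichment 0
  rep0 <- enrichment_report(observed_cog_counts(universe, ct), null,
                            reference)
  expect_equal(rep0$enrichment_pct, c(0, 0))
  # all-J targets: J doubles (+100%), K vanishes (-100%)
  repJ <- enrichment_report(
    observed_cog_counts(universe[1:10], ct), null, reference)
  expect_equal(repJ$enrichment_pct[repJ$cog == "J"], 100)
  expect_equal(repJ$enrichment_pct[repJ$cog == "K"], -100)
  # rows sorted by observed percentage, ascending
  expect_true(!is.unsorted(repJ$observed_pct))

  # significance thresholds equal a brute-force quantile scan
  totals <- rowSums(null$counts)
  for (cc in c("J", "K")) {
    pcts <- sort(100 * null$counts[, cc] / totals)
    qlo <- pcts[max(1, ceiling(0.025 * length(pcts)))]
    qhi <- pcts[ceiling(0.975 * length(pcts))]
    ref_pct <- 50
    expect_equal(
      rep0$threshold_over_pct[rep0$cog == cc],
      (qhi - ref_pct) / ref_pct * 100)
    expect_equal(
      rep0$threshold_under_pct[rep0$cog == cc],
      (qlo - ref_pct) / ref_pct * 100)
  }
})

test_that("tidy, glance and autoplot expose the enrichment fit", {
  prot <- simulate_proteome(60, 3, p_annotated = 0.9, seed = 31)
  enr <- cog_enrichment(prot$universe[1:25], prot$universe, prot$cog_table,
                        expansion = prot$expansion, n_reps = 2000, seed = 7)
  td <- tidy(enr)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "cog_enrichment"))
  gl <- glance(enr)
  expect_identical(gl$n_categories, nrow(td))
  expect_identical(gl$n_reps, 2000)
  pl <- autoplot(enr)
  expect_s3_class(pl, "ggplot")
})
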
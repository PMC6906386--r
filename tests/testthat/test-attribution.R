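lib_pair <- function(seed = 21) {
  generate_genome_set(
    tibble::tibble(name = c("aphid", "plant"),
                   category = c("host_insect", "host_plant"),
                   length = 6000L),
    seed = seed)
}

test_that("exact substrings hit and two substitutions at k=1 do not", {
  gs <- lib_pair()
  subj <- setNames(gs$sequence[1], "aphid")
  read <- substr(gs$sequence[1], 101, 125)
  h <- match_read(read, subj, k_max = 1)
  expect_true(nrow(h) >= 1)
  expect_true(any(h$start == 100 & h$mismatches == 0))

  ch <- strsplit(read, "")[[1]]
  flip <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  ch[3] <- flip(ch[3]); ch[10] <- flip(ch[10])
  mut <- paste(ch, collapse = "")
  h2 <- match_read(mut, subj, k_max = 1)
  expect_false(any(h2$start == 100 & h2$strand == "+"))
})

test_that("an N in the read counts as a mismatch", {
  gs <- lib_pair()
  subj <- setNames(gs$sequence[1], "aphid")
  read <- substr(gs$sequence[1], 201, 222)
  withN <- paste0(substr(read, 1, 5), "N", substr(read, 7, 22))
  expect_true(any(match_read(withN, subj, k_max = 1)$start == 200))
  expect_false(any(match_read(withN, subj, k_max = 0)$start == 200))
})

test_that("matcher equals the brute-force Hamming scan", {
  gs <- lib_pair(seed = 5)
  subj <- setNames(gs$sequence, gs$name)
  set.seed(17)
  src <- tibble::tibble(name = gs$name, sequence = gs$sequence,
                        proportion = c(0.5, 0.5))
  sim0 <- sample_reads(src, 30, seed = 2)
  sim2 <- sample_reads(src, 30, seed = 3, n_mismatches = 2)
  reads <- c(sim0$reads$seq, sim2$reads$seq)
  for (r in reads) {
    expect_identical(as.data.frame(match_read(r, subj, k_max = 1)),
                     as.data.frame(oracle_match(r, subj, k_max = 1)))
  }
})

test_that("partitioning handles exclusive, joint and unmapped reads", {
  gs <- lib_pair(seed = 9)
  # plant-only read
  plant_read <- substr(gs$sequence[2], 501, 525)
  # a read planted in both libraries: splice a shared segment in
  shared <- substr(gs$sequence[1], 1001, 1030)
  gs2 <- gs
  gs2$sequence[2] <- paste0(substr(gs$sequence[2], 1, 3000), shared,
                            substr(gs$sequence[2], 3031, 6000))
  reads <- tibble::tibble(read_id = c("p", "j", "u"),
                          seq = c(plant_read, shared, strrep("ACGT", 6)),
                          sample_id = "S1")
  part_all <- partition_reads(reads, gs2, k_max = 1, mode = "all")
  expect_identical(part_all$category,
                   c("host_plant", "host_insect+host_plant", "unmapped"))
  # cascade: the joint read stops at the insect stage
  part_casc <- partition_reads(reads, gs2, k_max = 1, mode = "cascade")
  expect_identical(part_casc$category,
                   c("host_plant", "host_insect", "unmapped"))

  expect_error(
    partition_reads(reads, dplyr::mutate(gs, name = "x"), k_max = 1),
    "duplicate")
})

test_that("membership sets are conserved and monotone in k_max", {
  gs <- lib_pair(seed = 13)
  src <- tibble::tibble(name = gs$name, sequence = gs$sequence,
                        proportion = c(0.5, 0.5))
  sim <- sample_reads(src, 60, seed = 4, n_mismatches = 1)
  reads <- sim$reads
  reads$sample_id <- "S1"
  p0 <- partition_reads(reads, gs, k_max = 0, mode = "all")
  p1 <- partition_reads(reads, gs, k_max = 1, mode = "all")
  # conservation: every read appears once, mapped or unmapped
  expect_identical(nrow(p1), nrow(reads))
  expect_identical(sum(p1$category == "unmapped") +
                     sum(p1$category != "unmapped"), nrow(reads))
  # monotonicity: raising k_max never shrinks a membership set
  for (i in seq_len(nrow(reads))) {
    expect_true(all(p0$membership[[i]] %in% p1$membership[[i]]))
  }
  # with 1 injected mismatch, k=1 recovers every origin
  cat_of <- c(aphid = "host_insect", plant = "host_plant")
  expect_true(all(purrr::map2_lgl(
    p1$membership, cat_of[sim$labels$origin], ~ .y %in% .x)))
})

test_that("partition summaries aggregate like a hand calculation", {
  part <- tibble::tibble(
    read_id = sprintf("r%d", 1:30),
    sample_id = rep(c("s1", "s2", "s3"), each = 10),
    membership = c(rep(list("host_plant"), 2), rep(list(character(0)), 8),
                   rep(list("host_plant"), 3), rep(list(character(0)), 7),
                   rep(list("host_plant"), 4), rep(list(character(0)), 6)),
    category = c(rep("host_plant", 2), rep("unmapped", 8),
                 rep("host_plant", 3), rep("unmapped", 7),
                 rep("host_plant", 4), rep("unmapped", 6)))
  sm <- summarize_partitions(part)
  row <- sm[sm$category == "host_plant" & sm$kind == "exclusive", ]
  expect_equal(row$mean_prop, 0.3)
  expect_equal(row$sd_prop, 0.1)
  expect_identical(row$n_samples, 3L)
  # absent category reported as 0 +/- 0, retained in the table
  expect_true("any:viral" %in% sm$category)
  expect_equal(sm$mean_prop[sm$category == "any:viral"], 0)
  expect_equal(sm$sd_prop[sm$category == "any:viral"], 0)
  # exclusive proportions sum to 1 within a group
  excl <- sm[sm$kind == "exclusive", ]
  expect_equal(sum(excl$mean_prop), 1)

  # single-sample group: SD undefined, not zero
  one <- summarize_partitions(part[part$sample_id == "s1", ])
  expect_true(is.na(one$sd_prop[one$category == "host_plant" &
                                  one$kind == "exclusive"]))

  # independent recomputation from the per-sample proportions
  props <- c(0.2, 0.3, 0.4)
  expect_equal(row$mean_prop, sum(props) / 3)
  expect_equal(row$sd_prop, sqrt(sum((props - mean(props))^2) / 2))
})
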
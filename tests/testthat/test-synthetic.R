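test_that("genome generation is seeded, sized and alphabet-bounded", {
  spec <- tibble::tibble(
    name = c("a", "b"), category = c("host_insect", "host_plant"),
    length = c(10000L, 10000L), gc = 0.4)
  g1 <- generate_genome_set(spec, seed = 7)
  g2 <- generate_genome_set(spec, seed = 7)
  expect_identical(g1$sequence, g2$sequence)
  g3 <- generate_genome_set(spec, seed = 8)
  expect_false(identical(g1$sequence, g3$sequence))

  tiny <- generate_genome_set(
    tibble::tibble(name = "x", category = "viral", length = 100L, gc = 0.5),
    seed = 1)
  expect_equal(nchar(tiny$sequence), 100L)
  expect_true(grepl("^[ACGT]+$", tiny$sequence))
})

test_that("cross-library shared 17-mers match brute-force enumeration", {
  spec <- tibble::tibble(
    name = c("insect", "symbiont", "plant", "bact", "virus"),
    category = c("host_insect", "obligate_symbiont", "host_plant",
                 "bacterial", "viral"),
    length = 3000L)
  gs <- generate_genome_set(spec, seed = 3, max_shared_kmers = 0L)
  km <- lapply(gs$sequence, function(s) {
    n <- nchar(s)
    unique(c(substring(s, 1:(n - 16), 17:n),
             substring(revcomp(s), 1:(n - 16), 17:n)))
  })
  shared <- 0L
  for (i in 1:4) for (j in (i + 1):5) {
    shared <- shared + length(intersect(km[[i]], km[[j]]))
  }
  expect_identical(shared, 0L)
})

test_that("degenerate genome specs are rejected with a message", {
  expect_error(generate_genome_set(tibble::tibble(), seed = 1),
               "at least one library")
  expect_error(generate_genome_set(
    tibble::tibble(name = c("a", "a"), category = "viral", length = 200L),
    seed = 1), "unique")
  expect_error(generate_genome_set(
    tibble::tibble(name = "a", category = "viral", length = 50L),
    seed = 1), ">= 100")
  expect_error(generate_genome_set(
    tibble::tibble(name = "a", category = "nope", length = 200L),
    seed = 1), "categories")
})

test_that("precursor construction obeys the hairpin geometry contract", {
  p <- generate_precursor(21, 15, 10, 10, n_mismatches = 0, seed = 2)
  expect_equal(nchar(p$sequence), 77L)
  arm1 <- substr(p$sequence, p$arm1_start + 1, p$arm1_end)
  arm2 <- substr(p$sequence, p$arm2_start + 1, p$arm2_end)
  expect_identical(arm2, revcomp(arm1))
  expect_equal(nchar(p$dotbracket), 77L)

  expect_error(generate_precursor(19, 15, seed = 1), "20 and 24")
  expect_error(generate_precursor(24, 250, 10, 10, seed = 1), "300")
})

test_that("injected duplex mismatches equal a base-by-base complement check", {
  for (nm in c(0L, 2L, 4L)) {
    p <- generate_precursor(22, 10, 0, 0, n_mismatches = nm, seed = 5)
    a1 <- strsplit(substr(p$sequence, p$arm1_start + 1, p$arm1_end), "")[[1]]
    a2 <- strsplit(substr(p$sequence, p$arm2_start + 1, p$arm2_end), "")[[1]]
    # arm1 position j pairs arm2 position arm_len - j + 1 (antiparallel)
    non_comp <- sum(vapply(seq_along(a1), function(j) {
      chartr("ACGT", "TGCA", a1[j]) != a2[length(a2) - j + 1]
    }, logical(1)))
    expect_identical(non_comp, as.integer(nm))
  }
})

test_that("read sampling labels every read and draws exact multinomials", {
  gs <- generate_genome_set(
    tibble::tibble(name = c("a", "b"),
                   category = c("host_insect", "host_plant"),
                   length = 5000L),
    seed = 2)
  src <- tibble::tibble(name = gs$name, sequence = gs$sequence,
                        proportion = c(0.5, 0.5))
  sim <- sample_reads(src, 400, seed = 9)
  expect_identical(nrow(sim$reads), 400L)
  expect_identical(sim$reads$read_id, sim$labels$read_id)
  # every zero-noise read is a substring of its labelled origin
  origins <- setNames(gs$sequence, gs$name)
  found <- vapply(seq_len(400), function(i) {
    s <- sim$reads$seq[i]
    if (sim$labels$strand[i] == "-") s <- revcomp(s)
    grepl(s, origins[[sim$labels$origin[i]]], fixed = TRUE)
  }, logical(1))
  expect_true(all(found))
  # byte-identical rerun
  sim2 <- sample_reads(src, 400, seed = 9)
  expect_identical(sim, sim2)
  # n = 0 is empty, not an error
  empty <- sample_reads(src, 0, seed = 1)
  expect_identical(nrow(empty$reads), 0L)
  # proportion and window validation
  expect_error(sample_reads(dplyr::mutate(src, proportion = 0.6), 10, seed = 1),
               "sum to 1")
  expect_error(sample_reads(src, 10, length_range = c(10, 35), seed = 1),
               "17")
})

test_that("truth mirnome encodes duplicates and drives the evidence tree", {
  m <- make_truth_mirnome(10, 2, 6, seed = 4)
  expect_identical(nrow(m$precursors), 10L)
  mir <- enumerate_mirnas(m$precursors)
  expect_lte(nrow(mir), 20L)
  # duplicated loci: identical mature sequences at distinct coordinates
  arm <- function(p, i) substr(p$sequence[i],
                               p$arm1_start[i] + 1, p$arm1_end[i])
  dup <- m$precursors[9:10, ]
  expect_true(any(duplicated(m$precursors$sequence)))
  expect_identical(anyDuplicated(m$precursors$start), 0L)
  # evidence classifies exactly to the planted truth
  cls <- classify_precursor(m$evidence$evalue, m$evidence$coverage,
                            m$evidence$short_evalue_mature,
                            m$evidence$short_evalue_star)
  expect_identical(unname(cls), m$status_truth$status)
  expect_error(make_truth_mirnome(5, 5, 3, seed = 1), "smaller")

  one <- make_truth_mirnome(1, 0, 1, seed = 2)
  expect_lte(nrow(enumerate_mirnas(one$precursors)), 2L)
})

test_that("region-labelled precursor reads are recovered exactly", {
  p <- generate_precursor(22, 30, 18, 18, n_mismatches = 0, seed = 3)
  sim <- sample_precursor_reads(
    p, 500, c(mature = 0.60, star = 0.30, loop = 0.02, fragment = 0.08),
    seed = 5)
  prof <- profile_reads(sim$reads, p)
  expect_identical(nrow(prof), 500L)
  lab <- sim$labels$region[match(prof$read_id, sim$labels$read_id)]
  expect_identical(prof$label, lab)
})
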
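prec_row <- function(id, ref = "c1", start, end, strand = "+",
                     mature_reads, dataset_id = "ds1") {
  tibble::tibble(precursor_id = id, ref = ref, start = start, end = end,
                 strand = strand, mature_reads = mature_reads,
                 dataset_id = dataset_id)
}

test_that("duplicate collapse keeps the highest mature read count", {
  p <- dplyr::bind_rows(
    prec_row("a", start = 100, end = 200, mature_reads = 100,
             dataset_id = "ds2"),
    prec_row("b", start = 100, end = 200, mature_reads = 40,
             dataset_id = "ds1"))
  out <- collapse_duplicates(p)
  expect_identical(out$precursor_id, "a")

  # opposite strands at the same coordinates: both retained
  p2 <- dplyr::bind_rows(
    prec_row("a", start = 100, end = 200, mature_reads = 10),
    prec_row("b", start = 100, end = 200, strand = "-", mature_reads = 10))
  expect_identical(nrow(collapse_duplicates(p2)), 2L)

  # tie: lexicographically smallest dataset id wins, with a warning
  p3 <- dplyr::bind_rows(
    prec_row("a", start = 100, end = 200, mature_reads = 50,
             dataset_id = "ds2"),
    prec_row("b", start = 110, end = 210, mature_reads = 50,
             dataset_id = "ds1"))
  expect_warning(out3 <- collapse_duplicates(p3), "tie")
  expect_identical(out3$precursor_id, "b")
})

test_that("collapse equals argmax per connected overlap component", {
  set.seed(91)
  n <- 60
  p <- tibble::tibble(
    precursor_id = sprintf("p%02d", 1:n),
    ref = sample(c("c1", "c2"), n, TRUE),
    start = sample(0:2000, n, TRUE),
    strand = sample(c("+", "-"), n, TRUE),
    mature_reads = sample(1:500, n, TRUE),
    dataset_id = sample(c("dsA", "dsB", "dsC"), n, TRUE))
  p$end <- p$start + sample(80:160, n, TRUE)
  out <- suppressWarnings(collapse_duplicates(p, min_overlap = 0.5))

  # oracle: adjacency by the reciprocal-overlap definition, igraph components
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (p$ref[i] == p$ref[j] && p$strand[i] == p$strand[j]) {
      w <- max(0, min(p$end[i], p$end[j]) - max(p$start[i], p$start[j]))
      if (w / (p$end[i] - p$start[i]) >= 0.5 &&
          w / (p$end[j] - p$start[j]) >= 0.5) adj[i, j] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "upper")
  comp <- igraph::components(g)$membership
  keep <- unlist(lapply(split(seq_len(n), comp), function(idx) {
    best <- idx[p$mature_reads[idx] == max(p$mature_reads[idx])]
    best[order(p$dataset_id[best])][1]
  }))
  expect_setequal(out$precursor_id, p$precursor_id[keep])
})

test_that("mature/star designation follows read support with a tie warning", {
  expect_identical(assign_mature_star(370, 12), "first")
  expect_identical(assign_mature_star(0, 5), "second")
  expect_warning(res <- assign_mature_star(7, 7), "tie")
  expect_identical(res, "first")
})

test_that("miRNA enumeration collapses identical arms across loci", {
  m <- make_truth_mirnome(8, 2, 8, seed = 6)
  mir <- enumerate_mirnas(m$precursors)
  # set oracle: unique arm sequences
  arms <- c(
    substr(m$precursors$sequence, m$precursors$arm1_start + 1,
           m$precursors$arm1_end),
    substr(m$precursors$sequence, m$precursors$arm2_start + 1,
           m$precursors$arm2_end))
  expect_identical(nrow(mir), length(unique(arms)))
  expect_lte(nrow(mir), 2L * nrow(m$precursors))
  # duplicated loci list every encoding precursor
  shared <- mir[mir$n_precursors > 1, ]
  expect_true(nrow(shared) >= 1)
  for (i in seq_len(nrow(shared))) {
    for (pid in shared$precursors[[i]]) {
      row <- m$precursors[m$precursors$precursor_id == pid, ]
      expect_true(shared$sequence[i] %in% c(
        substr(row$sequence, row$arm1_start + 1, row$arm1_end),
        substr(row$sequence, row$arm2_start + 1, row$arm2_end)))
    }
  }
  # a single non-duplicated precursor with distinct arms gives 2 miRNAs
  p1 <- generate_precursor(21, 12, 5, 5, n_mismatches = 2, seed = 3)
  expect_identical(nrow(enumerate_mirnas(p1)), 2L)
})

test_that("collapse never increases the miRNA count", {
  m <- make_truth_mirnome(10, 3, 10, seed = 12)
  before <- nrow(enumerate_mirnas(m$precursors))
  after <- nrow(enumerate_mirnas(
    suppressWarnings(collapse_duplicates(m$precursors))))
  expect_lte(after, before)
})

test_that("known/novel classification matches the hand-written truth table", {
  grid <- expand.grid(
    evalue = c(1e-12, 1e-10, 1e-6, 1e-3, 1),
    coverage = c(0.59, 0.60, 0.61),
    short = c(1e-11, 1e-10, 1e-9, NA),
    stringsAsFactors = FALSE)
  # hand-derived expectations, tier by tier:
  #  e < 1e-10                -> known, whatever else
  #  e >= 1e-3                -> novel, whatever else
  #  middle tier, cov >= 0.60 -> known
  #  middle tier, cov < 0.60  -> short < 1e-10 known; >= 1e-10 novel; NA unset
  expected <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    e <- grid$evalue[i]; cv <- grid$coverage[i]; sh <- grid$short[i]
    expected[i] <-
      if (e == 1e-12) "known"
      else if (e %in% c(1e-3, 1)) "novel"
      else if (cv >= 0.60) "known"
      else if (is.na(sh)) "unset"
      else if (sh == 1e-11) "known"
      else "novel"
  }
  got <- suppressWarnings(
    classify_precursor(grid$evalue, grid$coverage,
                       short_evalue_mature = grid$short,
                       short_evalue_star = NA_real_))
  expect_identical(as.character(got), expected)

  # aggregation: the minimum over mature/star short e-values decides
  expect_identical(
    classify_precursor(1e-5, 0.4, short_evalue_mature = 1e-2,
                       short_evalue_star = 1e-12), "known")
  # reaching the short branch with no evidence is flagged, not guessed
  expect_warning(u <- classify_precursor(1e-5, 0.4), "no evidence")
  expect_identical(as.character(u), "unset")
})

test_that("precursor validation checks length, arms and duplex pairing", {
  p <- generate_precursor(22, 20, 10, 10, n_mismatches = 0, seed = 7)
  v <- validate_precursor(p)
  expect_true(v$pass)
  expect_equal(v$duplex_pair_frac, 1)

  # duplex fraction equals the construction: (arm - mismatches) / arm
  for (nm in c(2L, 6L)) {
    pm <- generate_precursor(20, 20, 10, 10, n_mismatches = nm, seed = 8)
    vm <- validate_precursor(pm, min_duplex_pair_frac = 0)
    expect_equal(vm$duplex_pair_frac, (20 - nm) / 20)
  }
  # 6/20 mismatches dips below the default 0.75 pairing threshold
  pm <- generate_precursor(20, 20, 10, 10, n_mismatches = 6, seed = 8)
  vfail <- validate_precursor(pm)
  expect_false(vfail$pass)
  expect_true("duplex_pairing" %in% vfail$reasons[[1]])

  # over-long precursor fails with reason "length"
  long <- p
  long$sequence <- paste0(p$sequence, strrep("A", 301 - nchar(p$sequence)))
  long$dotbracket <- paste0(p$dotbracket,
                            strrep(".", 301 - nchar(p$dotbracket)))
  vlong <- validate_precursor(long)
  expect_false(vlong$pass)
  expect_true("length" %in% vlong$reasons[[1]])

  expect_error(parse_dotbracket("(()"), "unbalanced")
  expect_error(parse_dotbracket("())"), "unbalanced")
})

test_that("ShortStack-style tables round into the internal layout", {
  p <- generate_precursor(21, 18, 8, 8, n_mismatches = 1, seed = 10,
                          id = "locusA")
  fa <- tempfile(fileext = ".fa")
  write_fasta(setNames(p$sequence, "locusA"), fa)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "Locus\tName\tStrand\tMajorRNA\tMajorRNAReads\tStar\tStarReads",
    sprintf("chr5:1000-%d\tlocusA\t+\t%s\t320\t%s\t12",
            999 + nchar(p$sequence),
            substr(p$sequence, p$arm1_start + 1, p$arm1_end),
            substr(p$sequence, p$arm2_start + 1, p$arm2_end))), tsv)
  got <- read_shortstack(tsv, fa, dataset_id = "bioproj1")
  expect_identical(got$arm1_start, p$arm1_start)
  expect_identical(got$arm2_end, p$arm2_end)
  expect_identical(got$mature_arm, "first")
  expect_identical(got$mature_reads, 320L)
  expect_identical(got$start, 999L)
})
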
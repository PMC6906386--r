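# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by the most literal method available (position-by-position
# scans, exhaustive enumeration, closed forms) and never call the code paths
# they check.

# Hamming-distance scan of a pattern over every position of a reference
# (forward strand): mismatch count per 0-based start.
hamming_profile <- function(pattern, ref) {
  L <- nchar(pattern)
  n <- nchar(ref)
  if (n < L) return(integer(0))
  p <- utf8ToInt(pattern)
  r <- utf8ToInt(ref)
  mm <- integer(n - L + 1L)
  for (j in seq_len(L)) {
    mm <- mm + (r[j:(n - L + j)] != p[j])
  }
  mm
}

# Oracle for match_read(): all <= k_max substitution hits, both strands.
oracle_match <- function(read, subject, k_max) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  rows <- list()
  for (ref in names(subject)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read else rc
      mm <- hamming_profile(pat, subject[[ref]])
      hit <- which(mm <= k_max)
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          ref = ref, start = hit - 1L, end = hit - 1L + nchar(read),
          strand = strand, mismatches = as.integer(mm[hit]))
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(ref = character(), start = integer(), end = integer(),
                   strand = character(), mismatches = integer())
  dplyr::arrange(out, ref, start, strand)
}

# Oracle for the region rule: position-wise check that the whole interval
# lies within region r extended by 1 nt into each existing neighbour, then
# the stated tie-break (mature/star first, then majority overlap, leftmost).
oracle_region_label <- function(start, end, rmap) {
  pos <- seq.int(start, end - 1L)
  nr <- nrow(rmap)
  eligible <- logical(nr)
  for (r in seq_len(nr)) {
    lo <- rmap$start[r] - (if (r > 1L) 1L else 0L)
    hi <- rmap$end[r] + (if (r < nr) 1L else 0L)
    eligible[r] <- all(pos >= lo & pos < hi)
  }
  if (!any(eligible)) return("fragment")
  cand <- which(eligible)
  is_arm <- rmap$region[cand] %in% c("mature", "star")
  if (any(is_arm)) cand <- cand[is_arm]
  if (length(cand) > 1L) {
    ov <- vapply(cand, function(r) {
      sum(pos >= rmap$start[r] & pos < rmap$end[r])
    }, integer(1))
    cand <- cand[ov == max(ov)][1]
  }
  rmap$region[cand]
}

# Exact two-tailed binomial p under the tail-doubling definition.
oracle_binom_tails <- function(observed, size, prob) {
  list(tail_low = stats::pbinom(observed, size, prob),
       tail_high = stats::pbinom(observed - 1, size, prob,
                                 lower.tail = FALSE))
}

# Oracle for seed-region consensus: all-pairs combination check per
# (miRNA, target), built directly from the definition.
oracle_consensus <- function(predictions, required_tools, seed = c(2L, 8L)) {
  preds <- predictions
  preds$ss <- preds$end - seed[2]
  preds$se <- preds$end - seed[1] + 1L
  preds <- preds[(preds$end - preds$start) >= seed[2], ]
  keys <- unique(paste(preds$mirna_id, preds$target_id, sep = "\r"))
  hits <- character(0)
  for (kk in keys) {
    parts <- strsplit(kk, "\r")[[1]]
    sub <- preds[preds$mirna_id == parts[1] & preds$target_id == parts[2], ]
    lists <- lapply(required_tools,
                    function(t) which(sub$tool == t))
    if (any(lengths(lists) == 0)) next
    grid <- expand.grid(lists)
    found <- FALSE
    for (r in seq_len(nrow(grid))) {
      idx <- as.integer(grid[r, ])
      if (min(sub$se[idx]) - max(sub$ss[idx]) >= 1L) found <- TRUE
    }
    if (found) hits <- c(hits, kk)
  }
  sort(hits)
}

# Small fully random prediction table for intersection/venn tests.
random_predictions <- function(n_pairs, tools, seed) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_pairs)) {
    for (t in tools) {
      if (stats::runif(1) < 0.7) {
        s <- sample(0:60, 1)
        len <- sample(c(6L, 8L, 15L, 22L), 1)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          tool = t, mirna_id = paste0("m", (i %% 4) + 1),
          target_id = sprintf("t%03d", i), start = s, end = s + len)
      }
    }
  }
  dplyr::bind_rows(rows)
}
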
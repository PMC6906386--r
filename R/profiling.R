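#' Region map of a miRNA precursor
#'
#' Derives the five labelled regions (5' end, mature, loop, star, 3' end; the
#' mature/star order depends on which arm is mature) from the precursor's arm
#' coordinates, in 0-based half-open precursor coordinates. Zero-length
#' regions (e.g. a missing 5' end) are dropped.
#'
#' @param precursor One-row precursor tibble.
#' @return Tibble with `precursor_id`, `region`, `start`, `end`; regions are
#'   contiguous, non-overlapping and cover the precursor.
#' @export
region_map <- function(precursor) {
  stopifnot(nrow(precursor) == 1)
  len <- nchar(precursor$sequence)
  first_lab <- if (precursor$mature_arm == "first") "mature" else "star"
  second_lab <- if (precursor$mature_arm == "first") "star" else "mature"
  out <- tibble(
    precursor_id = precursor$precursor_id,
    region = c("five_prime_end", first_lab, "loop", second_lab,
               "three_prime_end"),
    start = as.integer(c(0L, precursor$arm1_start, precursor$arm1_end,
                         precursor$arm2_start, precursor$arm2_end)),
    end = as.integer(c(precursor$arm1_start, precursor$arm1_end,
                       precursor$arm2_start, precursor$arm2_end, len))
  )
  out[out$end > out$start, ]
}

#' Exact alignment of a read to a precursor
#'
#' All exact substring occurrences of the read in the precursor (forward
#' strand), as 0-based half-open intervals. Mismatched or gapped placements
#' are excluded by construction.
#'
#' @param read Read sequence (character scalar).
#' @param precursor_seq Precursor sequence.
#' @return Tibble with `start`, `end` (possibly empty).
#' @export
align_to_precursor <- function(read, precursor_seq) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(read),
                                Biostrings::DNAString(precursor_seq),
                                max.mismatch = 0, with.indels = FALSE,
                                fixed = TRUE)
  tibble(start = Biostrings::start(m) - 1L,
         end = Biostrings::start(m) - 1L + nchar(read))
}

#' Classify an aligned interval into a precursor region
#'
#' A read belongs to region R if its interval lies within R extended by
#' exactly 1 nt into each adjacent region (the at-most-one-nucleotide-overlap
#' rule); any read overlapping two regions by more than one nucleotide is a
#' fragment. When the 1-nt extensions make two regions eligible (only
#' possible for very short intervals), mature/star are checked before
#' loop/ends, and remaining ties are broken toward the region containing the
#' majority of the interval, then leftmost.
#'
#' @param start,end 0-based half-open interval on the precursor (vectorised).
#' @param rmap Region map from [region_map()].
#' @return Character vector of labels (`mature`, `star`, `loop`,
#'   `five_prime_end`, `three_prime_end`, `fragment`).
#' @export
classify_read_region <- function(start, end, rmap) {
  len <- max(rmap$end)
  if (any(start < 0 | end > len | end <= start)) {
    abort("interval outside the precursor")
  }
  nr <- nrow(rmap)
  ext_start <- rmap$start - ifelse(seq_len(nr) == 1L, 0L, 1L)
  ext_end <- rmap$end + ifelse(seq_len(nr) == nr, 0L, 1L)
  priority <- ifelse(rmap$region %in% c("mature", "star"), 1L, 2L)
  vapply(seq_along(start), function(i) {
    ok <- ext_start <= start[i] & end[i] <= ext_end
    if (!any(ok)) return("fragment")
    cand <- which(ok)
    cand <- cand[priority[cand] == min(priority[cand])]
    if (length(cand) > 1L) {
      ov <- interval_overlap(start[i], end[i], rmap$start[cand],
                             rmap$end[cand])
      cand <- cand[ov == max(ov)][1]
    }
    rmap$region[cand]
  }, character(1))
}

#' Profile reads over miRNA precursor regions
#'
#' Aligns each read exactly (no mismatches, no gaps, forward strand) to each
#' precursor, classifies every occurrence with [classify_read_region()], and
#' keeps either the single best occurrence per read (`multi = "best"`: most
#' specific label, mature/star over loop/ends over fragment, ties leftmost)
#' or all occurrences (`multi = "all"`).
#'
#' @param reads Tibble with `read_id`, `seq`.
#' @param precursors Precursor tibble.
#' @param multi "best" (default) or "all".
#' @return Assignment tibble: `read_id`, `precursor_id`, `start`, `end`,
#'   `label`. Reads with no exact occurrence are absent.
#' @export
profile_reads <- function(reads, precursors, multi = c("best", "all")) {
  multi <- match.arg(multi)
  rmaps <- lapply(seq_len(nrow(precursors)),
                  function(i) region_map(precursors[i, ]))
  label_rank <- c(mature = 1L, star = 1L, loop = 2L, five_prime_end = 2L,
                  three_prime_end = 2L, fragment = 3L)
  # identical read sequences share their occurrence set: compute once
  uniq <- unique(reads$seq)
  occ_by_seq <- vector("list", length(uniq))
  for (i in seq_along(uniq)) {
    occ <- list()
    for (j in seq_len(nrow(precursors))) {
      al <- align_to_precursor(uniq[i], precursors$sequence[j])
      if (nrow(al) == 0) next
      al$precursor_id <- precursors$precursor_id[j]
      al$label <- classify_read_region(al$start, al$end, rmaps[[j]])
      al$prec_order <- j
      occ[[length(occ) + 1L]] <- al
    }
    if (!length(occ)) next
    occ <- bind_rows(occ)
    if (multi == "best") {
      occ <- occ[order(label_rank[occ$label], occ$prec_order, occ$start), ]
      occ <- occ[1, ]
    }
    occ_by_seq[[i]] <- occ
  }
  idx <- match(reads$seq, uniq)
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    occ <- occ_by_seq[[idx[i]]]
    if (is.null(occ)) return(NULL)
    occ$read_id <- reads$read_id[i]
    occ
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(tibble(read_id = character(), precursor_id = character(),
                  start = integer(), end = integer(), label = character()))
  }
  out <- bind_rows(rows)
  out[, c("read_id", "precursor_id", "start", "end", "label")]
}

#' Summarise a precursor read profile
#'
#' Percentages of precursor-aligned reads per region label, pooled over all
#' assignments given (pooling samples first and summarising is identical to
#' summarising the concatenation).
#'
#' @param assignments Tibble from [profile_reads()].
#' @return Tibble with `label`, `n`, `pct` (sums to 100 up to rounding);
#'   empty input yields an empty tibble rather than a division error.
#' @export
summarize_profile <- function(assignments) {
  if (nrow(assignments) == 0) {
    return(tibble(label = character(), n = integer(), pct = numeric()))
  }
  out <- count(assignments, label = .data$label)
  out$pct <- 100 * out$n / sum(out$n)
  arrange(out, desc(.data$n))
}

#' Bar plot of the precursor region profile
#'
#' @param summary Tibble from [summarize_profile()].
#' @return A ggplot object.
#' @export
plot_profile <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = stats::reorder(.data$label, -.data$pct),
                               y = .data$pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "% of precursor-aligned reads") +
    ggplot2::theme_minimal()
}
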
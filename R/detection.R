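#' Detect miRNAs in a read set by perfect full-length match
#'
#' A read counts toward a miRNA iff its sequence is exactly identical to the
#' miRNA sequence (full-length equality, forward orientation, by default).
#' Because miRNA sequences are unique, each read counts toward at most one
#' miRNA. A `"substring"` mode (miRNA contained anywhere in the read) and a
#' `"both"`-orientation mode exist for sensitivity analysis.
#'
#' @param reads Tibble with `read_id`, `seq`, and optionally `sample_id`
#'   (counts are then per sample).
#' @param mirnas Tibble with `mirna_id`, `sequence` (sequences must be
#'   unique).
#' @param mode "exact" (default) or "substring".
#' @param orientation "forward" (default) or "both".
#' @return Tibble with `mirna_id`, `sample_id` (if present in `reads`) and
#'   `count`, one row per miRNA x sample including zero counts.
#' @export
detect_mirnas <- function(reads, mirnas, mode = c("exact", "substring"),
                          orientation = c("forward", "both")) {
  mode <- match.arg(mode)
  orientation <- match.arg(orientation)
  reads <- as_tibble(reads)
  mirnas <- as_tibble(mirnas)
  if (nrow(mirnas) == 0) {
    warn("empty miRNA set: no detections possible")
    return(tibble(mirna_id = character(), count = integer()))
  }
  if (anyDuplicated(mirnas$sequence)) abort("miRNA sequences must be unique")
  per_sample <- "sample_id" %in% names(reads)
  if (!per_sample) reads$sample_id <- "sample"

  count_one <- function(mir_seq, read_seqs) {
    hits <- read_seqs == mir_seq
    if (orientation == "both") hits <- hits | read_seqs == revcomp(mir_seq)
    if (mode == "substring") {
      hits <- grepl(mir_seq, read_seqs, fixed = TRUE)
      if (orientation == "both") {
        hits <- hits | grepl(revcomp(mir_seq), read_seqs, fixed = TRUE)
      }
    }
    sum(hits)
  }

  out <- tidyr::expand_grid(mirna_id = mirnas$mirna_id,
                            sample_id = unique(reads$sample_id))
  out <- left_join(out, mirnas[, c("mirna_id", "sequence")], by = "mirna_id")
  out$count <- vapply(seq_len(nrow(out)), function(i) {
    rs <- reads$seq[reads$sample_id == out$sample_id[i]]
    count_one(out$sequence[i], rs)
  }, integer(1))
  out$sequence <- NULL
  if (!per_sample) out$sample_id <- NULL
  out
}

#' Intersect detected miRNA sets across samples
#'
#' A miRNA is detected in a sample iff its count is at least 1; the result is
#' the set detected in every listed sample.
#'
#' @param detections Tibble from [detect_mirnas()] with `sample_id`.
#' @param samples Character vector of sample ids (default: all present).
#' @return Tibble with a single `mirna_id` column (sorted).
#' @export
intersect_across_samples <- function(detections, samples = NULL) {
  samples <- samples %||% unique(detections$sample_id)
  if (length(samples) == 0) abort("`samples` must be nonempty")
  sets <- lapply(samples, function(s) {
    detections$mirna_id[detections$sample_id == s & detections$count >= 1]
  })
  tibble(mirna_id = sort(Reduce(intersect, sets)))
}

#' Map detected miRNAs to their encoding precursors
#'
#' Unions the precursor lists over the given miRNAs, deduplicated, keeping
#' the per-miRNA breakdown. miRNAs with an empty precursor list are flagged
#' with a warning.
#'
#' @param detected Tibble with a `mirna_id` column (or character vector).
#' @param mirnas Tibble from [enumerate_mirnas()] carrying `precursors`
#'   list-column.
#' @return Tibble with `mirna_id`, `precursor_id` (one row per pair);
#'   attribute `precursor_ids` holds the deduplicated union.
#' @export
map_to_precursors <- function(detected, mirnas) {
  ids <- if (is.data.frame(detected)) unique(detected$mirna_id) else
    unique(detected)
  m <- mirnas[mirnas$mirna_id %in% ids, ]
  empties <- m$mirna_id[lengths(m$precursors) == 0]
  if (length(empties)) {
    warn(paste("miRNA(s) with empty precursor list:",
               paste(empties, collapse = ", ")))
  }
  out <- tibble(
    mirna_id = rep(m$mirna_id, lengths(m$precursors)),
    precursor_id = unlist(m$precursors, use.names = FALSE) %||% character(0)
  )
  out <- distinct(out)
  attr(out, "precursor_ids") <- sort(unique(out$precursor_id))
  out
}
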
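#' Seed-region image of a predicted target site
#'
#' Maps miRNA seed positions (default 2-8, 1-based from the miRNA 5' end)
#' onto the target site assuming antiparallel pairing: miRNA position j
#' pairs with target position `site_end - j` (0-based), so the canonical
#' 2-8 seed images to the half-open target interval
#' `[site_end - 8, site_end - 1)`. Sites too short to contain the full seed
#' image are excluded (NA output).
#'
#' @param site_start,site_end 0-based half-open site interval on the target
#'   (vectorised).
#' @param seed Integer pair: first and last miRNA seed position (1-based).
#' @return Tibble with `seed_start`, `seed_end` (NA rows for excluded
#'   sites).
#' @export
seed_interval <- function(site_start, site_end, seed = c(2L, 8L)) {
  stopifnot(length(seed) == 2, seed[1] >= 1, seed[2] >= seed[1])
  s <- site_end - seed[2]
  e <- site_end - seed[1] + 1L
  short <- (site_end - site_start) < seed[2]
  s[short] <- NA_integer_
  e[short] <- NA_integer_
  tibble(seed_start = s, seed_end = e)
}

#' Intersect per-tool target predictions in the seed region
#'
#' A (miRNA, target) pair reaches consensus iff every required tool reports
#' at least one site such that the chosen sites' seed images mutually overlap
#' by at least 1 nt; the consensus interval is the intersection of those seed
#' images. When several site combinations qualify, the widest intersection
#' is reported (ties leftmost). Sites too short to carry a seed image are
#' excluded with a reason (attribute `excluded`).
#'
#' @param predictions Tibble with `tool`, `mirna_id`, `target_id`, `start`,
#'   `end` (0-based half-open site interval), optional `score`.
#' @param required_tools Character vector of tools that must all agree.
#' @param seed Seed definition passed to [seed_interval()].
#' @return Tibble with `mirna_id`, `target_id`, `tools` (list-column),
#'   `seed_start`, `seed_end`.
#' @export
intersect_predictions <- function(predictions, required_tools,
                                  seed = c(2L, 8L)) {
  preds <- as_tibble(predictions)
  missing_tools <- setdiff(required_tools, unique(preds$tool))
  if (length(missing_tools)) {
    abort(paste("required tools absent from predictions:",
                paste(missing_tools, collapse = ", ")))
  }
  si <- seed_interval(preds$start, preds$end, seed)
  preds$seed_start <- si$seed_start
  preds$seed_end <- si$seed_end
  excluded <- preds[is.na(preds$seed_start), ]
  preds <- preds[!is.na(preds$seed_start), ]

  key <- paste(preds$mirna_id, preds$target_id, sep = "\r")
  out <- list()
  for (kk in unique(key)) {
    sub <- preds[key == kk, ]
    per_tool <- lapply(required_tools, function(t) which(sub$tool == t))
    if (any(lengths(per_tool) == 0)) next
    combos <- expand.grid(per_tool, KEEP.OUT.ATTRS = FALSE)
    best <- NULL
    for (r in seq_len(nrow(combos))) {
      idx <- as.integer(combos[r, ])
      s <- max(sub$seed_start[idx])
      e <- min(sub$seed_end[idx])
      if (e - s >= 1L && (is.null(best) || (e - s) > (best[2] - best[1]) ||
                          ((e - s) == (best[2] - best[1]) && s < best[1]))) {
        best <- c(s, e)
      }
    }
    if (is.null(best)) next
    out[[length(out) + 1L]] <- tibble(
      mirna_id = sub$mirna_id[1], target_id = sub$target_id[1],
      tools = list(sort(required_tools)),
      seed_start = best[1], seed_end = best[2])
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(mirna_id = character(), target_id = character(), tools = list(),
           seed_start = integer(), seed_end = integer())
  res <- arrange(res, .data$mirna_id, .data$target_id)
  attr(res, "excluded") <- excluded
  attr(res, "seed") <- seed
  res
}

#' Venn counts of predicted (miRNA, target) pairs per tool combination
#'
#' Tallies distinct (miRNA, target) pairs by the exact set of tools
#' predicting them. Counts over the disjoint regions sum to the total number
#' of distinct pairs (inclusion-exclusion consistent).
#'
#' @param predictions Tibble as in [intersect_predictions()].
#' @param tools Character vector of tools (default: all present; >= 2).
#' @return Tibble with `tool_set` (e.g. "miRanda+PITA"), `n_tools`, `count`,
#'   one row per nonempty tool subset (including zero counts).
#' @export
venn_counts <- function(predictions, tools = NULL) {
  preds <- as_tibble(predictions)
  tools <- sort(tools %||% unique(preds$tool))
  if (length(tools) < 2) abort("at least two tools are required")
  preds <- preds[preds$tool %in% tools, ]
  pair_tools <- preds |>
    distinct(.data$mirna_id, .data$target_id, .data$tool) |>
    group_by(.data$mirna_id, .data$target_id) |>
    summarise(tool_set = paste(sort(unique(.data$tool)), collapse = "+"),
              .groups = "drop")
  subsets <- unlist(lapply(seq_along(tools), function(k) {
    apply(utils::combn(tools, k), 2, paste, collapse = "+")
  }))
  counts <- table(factor(pair_tools$tool_set, levels = subsets))
  tibble(tool_set = subsets,
         n_tools = lengths(strsplit(subsets, "+", fixed = TRUE)),
         count = as.integer(counts))
}

#' Expand UTR-level targets to transcript isoforms
#'
#' Replaces each targeted 3' UTR by all transcript isoforms sharing it,
#' deduplicated. Expansion can exceed the UTR count (one-to-many).
#'
#' @param targets Tibble with a `target_id` column of UTR ids (e.g. the
#'   consensus set), or a character vector.
#' @param utr_table Long tibble with `utr_id`, `transcript_id` (e.g. from
#'   [extract_three_prime_utrs()]).
#' @return Tibble with `target_id`, `transcript_id`; attribute `isoforms`
#'   holds the deduplicated isoform set.
#' @export
expand_utrs <- function(targets, utr_table) {
  ids <- if (is.data.frame(targets)) unique(targets$target_id) else
    unique(targets)
  missing_ids <- setdiff(ids, utr_table$utr_id)
  if (length(missing_ids)) {
    abort(paste("UTR id(s) missing from the table:",
                paste(missing_ids, collapse = ", ")))
  }
  out <- utr_table[utr_table$utr_id %in% ids, c("utr_id", "transcript_id")]
  out <- distinct(rename(out, target_id = "utr_id"))
  attr(out, "isoforms") <- sort(unique(out$transcript_id))
  out
}
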
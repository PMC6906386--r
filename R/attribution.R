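#' Find all near-exact occurrences of a read in a library
#'
#' Reports every ungapped occurrence of `read` in the reference sequences of
#' a library with at most `k_max` substitutions, on both strands. An `N` in
#' the read never matches and therefore counts as a mismatch at that base.
#' Hits are ordered by (reference, position, strand). A minus-strand hit
#' means the reverse complement of the read occurs at the reported position
#' of the forward reference.
#'
#' @param read Read sequence (character scalar, length >= 17).
#' @param subject Named character vector of reference sequences (a single
#'   unnamed sequence is labelled "ref").
#' @param k_max Maximum substitutions (default 1: the "fewer than two
#'   mismatches" rule).
#' @return Tibble with `ref`, `start` (0-based), `end` (half-open), `strand`,
#'   `mismatches`.
#' @export
match_read <- function(read, subject, k_max = 1L) {
  stopifnot(is.character(read), length(read) == 1)
  if (nchar(read) < 17) abort("reads shorter than 17 nt are not matched")
  if (k_max < 0) abort("`k_max` must be >= 0")
  if (is.null(names(subject))) {
    names(subject) <- if (length(subject) == 1) "ref" else
      paste0("ref", seq_along(subject))
  }
  pat_f <- Biostrings::DNAString(read)
  pat_r <- Biostrings::reverseComplement(pat_f)
  rows <- list()
  for (ref in names(subject)) {
    subj <- Biostrings::DNAString(subject[[ref]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pat_f else pat_r
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = k_max,
                                    with.indels = FALSE, fixed = TRUE)
      if (length(m) == 0) next
      st <- Biostrings::start(m)
      mm <- Biostrings::neditStartingAt(pat, subj, starting.at = st,
                                        fixed = TRUE)
      rows[[length(rows) + 1L]] <- tibble(
        ref = ref, start = st - 1L, end = st - 1L + nchar(read),
        strand = strand, mismatches = as.integer(mm))
    }
  }
  if (!length(rows)) {
    return(tibble(ref = character(), start = integer(), end = integer(),
                  strand = character(), mismatches = integer()))
  }
  out <- bind_rows(rows)
  arrange(out, .data$ref, .data$start, .data$strand)
}

# TRUE if the read occurs in any of the library's sequences (either strand)
# with <= k_max substitutions. DNAString patterns are passed in prebuilt.
has_hit <- function(pat_f, pat_r, subjects, k_max) {
  for (subj in subjects) {
    if (Biostrings::countPattern(pat_f, subj, max.mismatch = k_max,
                                 with.indels = FALSE, fixed = TRUE) > 0) {
      return(TRUE)
    }
    if (Biostrings::countPattern(pat_r, subj, max.mismatch = k_max,
                                 with.indels = FALSE, fixed = TRUE) > 0) {
      return(TRUE)
    }
  }
  FALSE
}

#' Partition reads by source library membership
#'
#' Assigns each read the set of source categories whose library it matches
#' with at most `k_max` substitutions (both strands, ungapped). In the
#' default `"cascade"` mode the host-insect and obligate-symbiont libraries
#' are interrogated first and only reads unmapped at that stage are tested
#' against the plant/bacterial/viral libraries (the order used when the
#' insect genomes are the primary references); `"all"` mode tests every read
#' against every library, which is required to resolve joint categories such
#' as insect+plant.
#'
#' @param reads Tibble with `read_id`, `seq`; extra columns (e.g.
#'   `sample_id`) pass through.
#' @param libraries Tibble with `name`, `category`, `sequence`; names must be
#'   unique and categories drawn from the five source categories.
#' @param k_max Maximum substitutions per alignment (default 1).
#' @param mode "cascade" or "all" (see above).
#' @return Tibble with the input identifier columns plus `membership`
#'   (list-column of matched categories, sorted) and `category` (collapsed
#'   exclusive-category string, `"unmapped"` when the membership is empty).
#'   Attributes `mode`, `k_max` and `libraries` record the configuration.
#' @export
partition_reads <- function(reads, libraries, k_max = 1L,
                            mode = c("cascade", "all")) {
  mode <- match.arg(mode)
  reads <- as_tibble(reads)
  libraries <- as_tibble(libraries)
  if (anyDuplicated(libraries$name)) abort("duplicate library names")
  if (!all(libraries$category %in% SOURCE_CATEGORIES)) {
    abort("library categories must be among the five source categories")
  }
  subj <- lapply(libraries$sequence, Biostrings::DNAString)
  stage1 <- libraries$category %in% c("host_insect", "obligate_symbiont")

  membership <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    pat_f <- Biostrings::DNAString(reads$seq[i])
    pat_r <- Biostrings::reverseComplement(pat_f)
    hit_lib <- logical(nrow(libraries))
    test <- function(j) has_hit(pat_f, pat_r, subj[j], k_max)
    if (mode == "cascade") {
      for (j in which(stage1)) hit_lib[j] <- test(j)
      if (!any(hit_lib)) for (j in which(!stage1)) hit_lib[j] <- test(j)
    } else {
      for (j in seq_len(nrow(libraries))) hit_lib[j] <- test(j)
    }
    membership[[i]] <- sort(unique(libraries$category[hit_lib]))
  }
  out <- reads[, setdiff(names(reads), c("seq", "qual")), drop = FALSE]
  out$membership <- membership
  out$category <- vapply(membership, function(m) {
    if (length(m) == 0) "unmapped" else paste(m, collapse = "+")
  }, character(1))
  attr(out, "mode") <- mode
  attr(out, "k_max") <- k_max
  attr(out, "libraries") <- libraries[, c("name", "category")]
  out
}

#' Summarise source partitions across samples
#'
#' Computes, per sample, the proportion of reads in each mutually exclusive
#' category (including `"unmapped"`), then the mean and sample standard
#' deviation (n-1 denominator) across the samples of each group. "Any"
#' roll-ups (the and/or categories, e.g. reads matching the host plant
#' whether or not they also match something else) are reported alongside the
#' exclusive table.
#'
#' @param partition Partition tibble from [partition_reads()] (or several
#'   row-bound together) carrying a `sample_id` column.
#' @param groups Optional tibble with `sample_id` plus grouping columns
#'   (e.g. `tissue`); joined before summarising.
#' @param group_var Name of the grouping column (default `"tissue"`; ignored
#'   when `groups` is NULL, in which case all samples form one group).
#' @return Tibble with `group`, `category`, `kind` ("exclusive" or
#'   "any"), `mean_prop`, `sd_prop` (NA for single-sample groups), `n_samples`.
#'   Exclusive proportions sum to 1 within each sample.
#' @export
summarize_partitions <- function(partition, groups = NULL,
                                 group_var = "tissue") {
  stopifnot("sample_id" %in% names(partition))
  if (!is.null(groups)) {
    partition <- left_join(partition, groups, by = "sample_id")
  } else {
    partition[[group_var]] <- "all"
  }
  if (!group_var %in% names(partition)) {
    abort(sprintf("grouping column '%s' not found", group_var))
  }

  totals <- partition |>
    count(.data$sample_id, name = "total")

  # exclusive categories
  excl <- partition |>
    count(.data$sample_id, .data[[group_var]], .data$category) |>
    left_join(totals, by = "sample_id") |>
    mutate(prop = .data$n / .data$total, kind = "exclusive")

  # any:<category> roll-ups over the raw membership sets
  any_rows <- lapply(SOURCE_CATEGORIES, function(cat) {
    partition |>
      group_by(.data$sample_id, .data[[group_var]]) |>
      summarise(n = sum(vapply(.data$membership, function(m) cat %in% m,
                               logical(1))), .groups = "drop") |>
      mutate(category = paste0("any:", cat))
  })
  anyt <- bind_rows(any_rows) |>
    left_join(totals, by = "sample_id") |>
    mutate(prop = .data$n / .data$total, kind = "any")

  per_sample <- bind_rows(excl, anyt)
  # complete the exclusive table: categories absent from a sample are 0
  cats <- unique(per_sample$category)
  grid <- tidyr::expand_grid(sample_id = unique(partition$sample_id),
                             category = cats)
  meta <- distinct(partition[, c("sample_id", group_var)])
  per_sample <- grid |>
    left_join(meta, by = "sample_id") |>
    left_join(per_sample[, c("sample_id", "category", "prop", "kind")],
              by = c("sample_id", "category")) |>
    mutate(prop = ifelse(is.na(.data$prop), 0, .data$prop),
           kind = ifelse(grepl("^any:", .data$category), "any", "exclusive"))

  per_sample |>
    group_by(group = .data[[group_var]], .data$category, .data$kind) |>
    summarise(
      mean_prop = mean(.data$prop),
      sd_prop = if (n() > 1) sd(.data$prop) else NA_real_,
      n_samples = n(), .groups = "drop") |>
    arrange(.data$group, .data$kind, desc(.data$mean_prop))
}

#' Bar plot of source-partition proportions per group
#'
#' @param summary Tibble from [summarize_partitions()].
#' @param kind Which rows to plot ("exclusive" or "any").
#' @return A ggplot object.
#' @export
plot_partition_summary <- function(summary, kind = "exclusive") {
  dat <- summary[summary$kind == kind, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category, y = .data$mean_prop,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_prop - .data$sd_prop,
                   ymax = .data$mean_prop + .data$sd_prop),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25,
      na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "proportion of filtered reads") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
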
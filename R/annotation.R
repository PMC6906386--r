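#' Collapse duplicate precursor calls across datasets
#'
#' Precursor calls from different datasets whose genomic loci overlap
#' reciprocally by at least `min_overlap` on the same strand form a duplicate
#' group (transitively); from each group the member with the most reads
#' mapped to its mature miRNA is retained. A tie is broken toward the
#' lexicographically smallest `dataset_id`, with a warning.
#'
#' @param precursors Precursor tibble with `precursor_id`, `ref`, `start`,
#'   `end`, `strand`, `mature_reads`, `dataset_id` (plus any other columns).
#' @param min_overlap Reciprocal overlap fraction defining a duplicate
#'   (default 0.5).
#' @return Tibble of retained precursors with an added `dup_group` column;
#'   attribute `groups` maps every input precursor to its group and
#'   retention flag.
#' @export
collapse_duplicates <- function(precursors, min_overlap = 0.5) {
  p <- as_tibble(precursors)
  n <- nrow(p)
  if (n == 0) return(p)
  parent <- uf_new(n)
  gr <- GenomicRanges::GRanges(
    p$ref, IRanges::IRanges(p$start + 1L, p$end), strand = p$strand)
  ov <- GenomicRanges::findOverlaps(gr, ignore.strand = FALSE,
                                    drop.self = TRUE, drop.redundant = TRUE)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  if (length(qi)) {
    w <- interval_overlap(p$start[qi], p$end[qi], p$start[si], p$end[si])
    recip <- w / (p$end[qi] - p$start[qi]) >= min_overlap &
      w / (p$end[si] - p$start[si]) >= min_overlap
    for (k in which(recip)) parent <- uf_union(parent, qi[k], si[k])
  }
  comp <- uf_components(parent)
  keep <- logical(n)
  for (g in unique(comp)) {
    idx <- which(comp == g)
    best <- idx[p$mature_reads[idx] == max(p$mature_reads[idx])]
    if (length(best) > 1L) {
      warn(sprintf(
        "duplicate group %d: mature read-count tie, keeping dataset '%s'",
        g, min(p$dataset_id[best])))
      best <- best[order(p$dataset_id[best])][1]
    }
    keep[best] <- TRUE
  }
  out <- p
  out$dup_group <- comp
  groups <- tibble(precursor_id = p$precursor_id, dup_group = comp,
                   retained = keep)
  out <- out[keep, ]
  attr(out, "groups") <- groups
  out
}

#' Designate mature vs star arm by read support
#'
#' The arm with the higher mapped-read count is the mature miRNA; the other
#' is the star. The designation records the arm index, not the 5p/3p naming
#' convention. Ties go to the first arm with a warning.
#'
#' @param first_count,second_count Non-negative read counts of the two arms
#'   (vectorised).
#' @return Character vector: "first" or "second".
#' @export
assign_mature_star <- function(first_count, second_count) {
  stopifnot(all(first_count >= 0), all(second_count >= 0))
  ties <- first_count == second_count
  if (any(ties)) {
    warn(sprintf("%d arm read-count tie(s): first arm designated mature",
                 sum(ties)))
  }
  ifelse(second_count > first_count, "second", "first")
}

# Arm sequences of a precursor tibble (columns arm{1,2}_{start,end}).
arm_sequences <- function(precursors) {
  tibble(
    precursor_id = precursors$precursor_id,
    first = substr(precursors$sequence, precursors$arm1_start + 1L,
                   precursors$arm1_end),
    second = substr(precursors$sequence, precursors$arm2_start + 1L,
                    precursors$arm2_end),
    mature_arm = precursors$mature_arm
  )
}

#' Enumerate the unique miRNAs encoded by a precursor set
#'
#' One entry per unique arm sequence: identical arms of duplicated loci
#' collapse to one miRNA listing all encoding precursors, and both arms of a
#' precursor are enumerated (so a set of P precursors yields at most 2P
#' miRNAs).
#'
#' @param precursors Precursor tibble (see [generate_precursor()] for the
#'   arm-coordinate columns).
#' @return Tibble with `mirna_id`, `sequence`, `precursors` (list-column of
#'   precursor ids), `arms` (list-column, "first"/"second" per precursor),
#'   `roles` (list-column, "mature"/"star" per precursor), `n_precursors`,
#'   and `status` (initialised to "unset").
#' @export
enumerate_mirnas <- function(precursors) {
  arms <- arm_sequences(precursors)
  long <- bind_rows(
    tibble(precursor_id = arms$precursor_id, arm = "first",
           sequence = arms$first,
           role = ifelse(arms$mature_arm == "first", "mature", "star")),
    tibble(precursor_id = arms$precursor_id, arm = "second",
           sequence = arms$second,
           role = ifelse(arms$mature_arm == "second", "mature", "star"))
  )
  uniq <- unique(long$sequence)
  out <- tibble(
    mirna_id = sprintf("mir_%04d", seq_along(uniq)),
    sequence = uniq,
    precursors = lapply(uniq, function(s) long$precursor_id[long$sequence == s]),
    arms = lapply(uniq, function(s) long$arm[long$sequence == s]),
    roles = lapply(uniq, function(s) long$role[long$sequence == s])
  )
  out$n_precursors <- lengths(out$precursors)
  out$status <- "unset"
  out
}

#' Classify a precursor as known or novel from tiered homology evidence
#'
#' Decision tree over homology-search evidence against a reference miRNA
#' database: precursor e-value < 1e-10 is known; e-value >= 1e-3 is novel;
#' in between, query coverage >= 60% is known, otherwise the minimum
#' short-search e-value over the mature and star sequences decides
#' (< 1e-10 known, else novel). Boundary semantics are literal: an e-value
#' of exactly 1e-10 falls in the middle tier at the first split and is
#' "not known" at the short-search split; coverage of exactly 0.60 is known.
#'
#' @param evalue Precursor search e-value (vectorised).
#' @param coverage Query coverage fraction in \[0,1\].
#' @param short_evalue_mature,short_evalue_star Short-search e-values of the
#'   two arms (NA when the search was not run).
#' @return Character vector: "known", "novel", or "unset" when the tree
#'   reaches the short-search branch with no short-search evidence (an
#'   explicit error record is attached as attribute `errors`).
#' @export
classify_precursor <- function(evalue, coverage = NA_real_,
                               short_evalue_mature = NA_real_,
                               short_evalue_star = NA_real_) {
  n <- length(evalue)
  coverage <- rep_len(coverage, n)
  short_evalue_mature <- rep_len(short_evalue_mature, n)
  short_evalue_star <- rep_len(short_evalue_star, n)
  stopifnot(all(evalue >= 0))
  out <- character(n)
  errors <- integer(0)
  for (i in seq_len(n)) {
    e <- evalue[i]
    if (e < 1e-10) {
      out[i] <- "known"
    } else if (e >= 1e-3) {
      out[i] <- "novel"
    } else if (!is.na(coverage[i]) && coverage[i] >= 0.60) {
      out[i] <- "known"
    } else {
      shorts <- c(short_evalue_mature[i], short_evalue_star[i])
      if (all(is.na(shorts))) {
        out[i] <- "unset"
        errors <- c(errors, i)
      } else {
        out[i] <- if (min(shorts, na.rm = TRUE) < 1e-10) "known" else "novel"
      }
    }
  }
  if (length(errors)) {
    warn(sprintf(
      "%d precursor(s) reached the short-search branch with no evidence: unset",
      length(errors)))
    attr(out, "errors") <- errors
  }
  out
}

#' @rdname classify_precursor
#' @param precursors Precursor tibble.
#' @param evidence Tibble with `precursor_id`, `evalue`, `coverage`,
#'   `short_evalue_mature`, `short_evalue_star`.
#' @return `classify_precursors()`: the precursor tibble with a `status`
#'   column added.
#' @export
classify_precursors <- function(precursors, evidence) {
  p <- left_join(as_tibble(precursors), as_tibble(evidence),
                 by = "precursor_id")
  p$status <- classify_precursor(p$evalue, p$coverage,
                                 p$short_evalue_mature, p$short_evalue_star)
  p
}

#' Parse a dot-bracket secondary structure into a pair table
#'
#' @param db Dot-bracket string over `.`, `(`, `)`.
#' @return Integer vector: position i holds the 1-based partner of base i,
#'   or 0 if unpaired. Unbalanced strings are a parse error.
#' @export
parse_dotbracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  if (!all(ch %in% c(".", "(", ")"))) {
    abort("dot-bracket contains characters other than '.', '(', ')'")
  }
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) abort("unbalanced dot-bracket: unmatched ')'")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) abort("unbalanced dot-bracket: unmatched '('")
  pt
}

#' Validate a precursor call against structural constraints
#'
#' Fails when the precursor exceeds 300 nt, an arm length falls outside
#' 20-24 nt, or fewer than `min_duplex_pair_frac` of mature-arm positions
#' are paired with star-arm positions in the secondary structure.
#'
#' @param precursors Precursor tibble; `dotbracket` column used unless `db`
#'   supplies structures.
#' @param db Optional character vector of dot-bracket strings (recycled
#'   against rows).
#' @param min_duplex_pair_frac Minimum fraction of mature positions paired
#'   into the star arm (default 0.75).
#' @return Tibble with `precursor_id`, `pass`, `reasons` (list-column),
#'   `duplex_pair_frac`.
#' @export
validate_precursor <- function(precursors, db = NULL,
                               min_duplex_pair_frac = 0.75) {
  p <- as_tibble(precursors)
  db <- db %||% p$dotbracket
  db <- rep_len(db, nrow(p))
  res <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    reasons <- character(0)
    len <- nchar(p$sequence[i])
    if (len > 300) reasons <- c(reasons, "length")
    a1 <- p$arm1_end[i] - p$arm1_start[i]
    a2 <- p$arm2_end[i] - p$arm2_start[i]
    if (a1 < 20 || a1 > 24 || a2 < 20 || a2 > 24) {
      reasons <- c(reasons, "arm_length")
    }
    frac <- NA_real_
    if (!is.na(db[i])) {
      if (nchar(db[i]) != len) abort("dot-bracket length != sequence length")
      pt <- parse_dotbracket(db[i])
      mat <- if (p$mature_arm[i] == "first") {
        (p$arm1_start[i] + 1L):p$arm1_end[i]
      } else {
        (p$arm2_start[i] + 1L):p$arm2_end[i]
      }
      star <- if (p$mature_arm[i] == "first") {
        (p$arm2_start[i] + 1L):p$arm2_end[i]
      } else {
        (p$arm1_start[i] + 1L):p$arm1_end[i]
      }
      frac <- mean(pt[mat] %in% star)
      if (frac < min_duplex_pair_frac) reasons <- c(reasons, "duplex_pairing")
    }
    res[[i]] <- tibble(precursor_id = p$precursor_id[i],
                       pass = length(reasons) == 0,
                       reasons = list(reasons), duplex_pair_frac = frac)
  }
  bind_rows(res)
}

#' Read a ShortStack-style precursor results table
#'
#' Ingests the tabular dialect written downstream of ShortStack: one row per
#' precursor with columns `Locus` (ref:start-end, 1-based closed), `Name`,
#' `Strand`, `MajorRNA` (mature sequence), `MajorRNAReads`, `Star`,
#' `StarReads`, together with a FASTA of precursor sequences keyed by
#' `Name`. Arm coordinates are recovered by locating the mature and star
#' sequences within the precursor.
#'
#' @param results_path TSV path.
#' @param fasta_path Precursor FASTA path.
#' @param dataset_id Dataset label attached to every precursor.
#' @return Precursor tibble in the package's internal layout.
#' @export
read_shortstack <- function(results_path, fasta_path, dataset_id = "ds") {
  x <- utils::read.table(results_path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, comment.char = "#")
  fa <- read_fasta(fasta_path)
  seqs <- setNames(fa$seq, fa$id)
  loc <- regmatches(x$Locus, regexec("^(.+):([0-9]+)-([0-9]+)$", x$Locus))
  rows <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    s <- seqs[[x$Name[i]]]
    if (is.null(s)) abort(sprintf("precursor '%s' missing from FASTA",
                                  x$Name[i]))
    m_at <- regexpr(x$MajorRNA[i], s, fixed = TRUE)
    s_at <- regexpr(x$Star[i], s, fixed = TRUE)
    if (m_at == -1 || s_at == -1) {
      abort(sprintf("arm sequence of '%s' not found in its precursor",
                    x$Name[i]))
    }
    first_is_major <- m_at < s_at
    a1 <- if (first_is_major) m_at else s_at
    a1len <- nchar(if (first_is_major) x$MajorRNA[i] else x$Star[i])
    a2 <- if (first_is_major) s_at else m_at
    a2len <- nchar(if (first_is_major) x$Star[i] else x$MajorRNA[i])
    rows[[i]] <- tibble(
      precursor_id = x$Name[i], sequence = s, dotbracket = NA_character_,
      arm1_start = as.integer(a1) - 1L,
      arm1_end = as.integer(a1) - 1L + a1len,
      arm2_start = as.integer(a2) - 1L,
      arm2_end = as.integer(a2) - 1L + a2len,
      mature_arm = if (first_is_major) "first" else "second",
      mature_reads = as.integer(x$MajorRNAReads[i]),
      star_reads = as.integer(x$StarReads[i]),
      ref = loc[[i]][2], start = as.integer(loc[[i]][3]) - 1L,
      end = as.integer(loc[[i]][4]), strand = x$Strand[i],
      dataset_id = dataset_id)
  }
  bind_rows(rows)
}

#' Write an annotated miRNA FASTA
#'
#' Headers carry the known/novel status and the encoding precursor list.
#'
#' @param mirnas Tibble from [enumerate_mirnas()] (with `status` filled in).
#' @param path Output path.
#' @export
write_mirna_fasta <- function(mirnas, path) {
  hdr <- sprintf("%s status=%s precursors=%s", mirnas$mirna_id, mirnas$status,
                 vapply(mirnas$precursors, paste, character(1), collapse = ","))
  write_fasta(setNames(mirnas$sequence, hdr), path)
}
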
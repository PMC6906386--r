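#' Process raw small RNA reads: adapter clip, quality trim, length select
#'
#' Applies, in order: (1) adapter clipping at the leftmost exact match of an
#' adapter prefix of at least 8 nt (read-through model: the match extends to
#' the 3' end of the read or covers the whole adapter); (2) quality handling
#' at `min_phred` (phred+33) - either 3'-end trimming to the longest prefix
#' whose bases are all at or above the threshold (`quality_mode = "trim"`,
#' the default) or dropping any read containing a base below it
#' (`"drop"`); (3) retention of reads whose final length falls inside
#' `length_window`. The two windows used in practice are 17-35 nt for insect
#' tissue libraries and 17-25 nt for plant miRNA annotation.
#'
#' @param reads Tibble with columns `read_id`, `seq`, and optionally `qual`
#'   (phred+33 strings); extra columns (e.g. `sample_id`) pass through.
#' @param adapter Adapter sequence (NULL skips the step; "" skips with a
#'   warning).
#' @param min_phred Quality threshold (default 28).
#' @param length_window Integer pair, closed interval of retained lengths.
#' @param quality_mode "trim" or "drop" (see above).
#' @return Tibble of retained reads (seq/qual updated); attribute
#'   `processing` records input/retained counts and per-reason drop counts.
#' @export
process_reads <- function(reads, adapter = NULL, min_phred = 28L,
                          length_window = c(17L, 35L),
                          quality_mode = c("trim", "drop")) {
  quality_mode <- match.arg(quality_mode)
  reads <- as_tibble(reads)
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  if (!"qual" %in% names(reads)) reads$qual <- NA_character_
  n_in <- nrow(reads)
  dropped <- c(quality = 0L, too_short = 0L, too_long = 0L)

  prior <- attr(reads, "processing")
  already_clipped <- !is.null(prior) && identical(prior$adapter, adapter)
  if (!is.null(adapter) && !already_clipped) {
    if (!nzchar(adapter)) {
      warn("empty adapter sequence: adapter step skipped")
    } else {
      clip <- vapply(reads$seq, adapter_clip_at, integer(1), adapter = adapter,
                     USE.NAMES = FALSE)
      has <- clip > 0L
      reads$seq[has] <- substr(reads$seq[has], 1L, clip[has] - 1L)
      reads$qual[has] <- substr(reads$qual[has], 1L, clip[has] - 1L)
    }
  }

  has_q <- !is.na(reads$qual)
  if (any(has_q)) {
    if (quality_mode == "trim") {
      keep_len <- vapply(reads$qual[has_q], function(q) {
        sc <- phred33(q)
        bad <- which(sc < min_phred)
        if (length(bad)) bad[1] - 1L else length(sc)
      }, integer(1), USE.NAMES = FALSE)
      reads$seq[has_q] <- substr(reads$seq[has_q], 1L, keep_len)
      reads$qual[has_q] <- substr(reads$qual[has_q], 1L, keep_len)
    } else {
      ok <- vapply(reads$qual, function(q) {
        if (is.na(q)) TRUE else all(phred33(q) >= min_phred)
      }, logical(1), USE.NAMES = FALSE)
      dropped["quality"] <- sum(!ok)
      reads <- reads[ok, ]
    }
  }

  len <- nchar(reads$seq)
  dropped["too_short"] <- sum(len < length_window[1])
  dropped["too_long"] <- sum(len > length_window[2])
  out <- reads[len >= length_window[1] & len <= length_window[2], ]
  attr(out, "processing") <- list(
    n_input = n_in, n_retained = nrow(out), dropped = dropped,
    adapter = adapter, min_phred = min_phred,
    length_window = length_window, quality_mode = quality_mode)
  out
}

# Leftmost 1-based position where a >= 8 nt adapter prefix matches the read
# through its 3' end (or the full adapter matches internally); 0 if none.
adapter_clip_at <- function(seq, adapter) {
  ln <- nchar(seq)
  la <- nchar(adapter)
  if (la < 8L || ln < 8L) return(0L)
  a8 <- substr(adapter, 1L, 8L)
  # candidate positions where the first 8 adapter bases match (overlaps kept)
  cand <- which(substring(seq, 1:(ln - 7L), 8:ln) == a8)
  for (p in cand) {
    m <- min(la, ln - p + 1L)
    if (substr(seq, p, p + m - 1L) == substr(adapter, 1L, m)) {
      return(p)
    }
  }
  0L
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings that present sequences as tibbles.
#'
#' @param path File path.
#' @return `read_fasta()`: tibble with `id`, `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = sub(" .*", "", names(x)), desc = names(x),
         seq = unname(as.character(x)))
}

#' @rdname read_fasta
#' @param seqs Named character vector, or tibble with `id` and `seq` columns.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write FASTQ (phred+33)
#'
#' @param path File path.
#' @return `read_fastq()`: tibble with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns internally about dropped metadata columns on FASTQ
  # import; nothing user-meaningful is lost
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble(read_id = sub(" .*", "", names(x)),
         seq = unname(as.character(x)),
         qual = unname(as.character(Biostrings::quality(x))))
}

#' @rdname read_fastq
#' @param reads Tibble with `read_id`, `seq` and optionally `qual` (defaults
#'   to a fixed "I", phred 40).
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual %||% NULL
  if (is.null(qual) || all(is.na(qual))) qual <- strrep("I", nchar(reads$seq))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id)),
    Biostrings::PhredQuality(qual))
  # Biostrings warns about dropped metadata columns; none are meaningful here
  withCallingHandlers(
    Biostrings::writeQualityScaledXStringSet(x, path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  invisible(path)
}

#' Parse alignments from SAM
#'
#' Ingests a SAM file (via Rsamtools), excluding unmapped records, flagging
#' gapped alignments (CIGAR containing I/D/N) and extracting the mismatch
#' count from the NM tag or, failing that, by reconstructing it from the MD
#' tag. Records with neither tag are rejected and counted.
#'
#' @param path SAM file path.
#' @param library_name Library label attached to every record.
#' @return Tibble with `read_id`, `library`, `ref_id`, `start` (0-based),
#'   `strand`, `mismatches`, `gapped`; attribute `n_rejected` counts records
#'   lacking both NM and MD.
#' @export
parse_alignments <- function(path, library_name = "library") {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "cigar"),
    tag = c("NM", "MD"))
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- bitwAnd(r$flag, 4L) == 0L
  nm <- r$tag$NM %||% rep(NA_integer_, length(r$flag))
  md <- r$tag$MD %||% rep(NA_character_, length(r$flag))
  mism <- nm
  use_md <- is.na(mism) & !is.na(md)
  mism[use_md] <- vapply(md[use_md], md_mismatches, integer(1),
                         USE.NAMES = FALSE)
  reject <- mapped & is.na(mism)
  keep <- mapped & !reject
  out <- tibble(
    read_id = r$qname[keep],
    library = library_name,
    ref_id = as.character(r$rname[keep]),
    start = r$pos[keep] - 1L,
    strand = as.character(r$strand[keep]),
    mismatches = mism[keep],
    gapped = grepl("[IDN]", r$cigar[keep])
  )
  attr(out, "n_rejected") <- sum(reject)
  if (any(reject)) {
    warn(sprintf("%d mapped record(s) lacked both NM and MD tags: rejected",
                 sum(reject)))
  }
  out
}

# Substitution count encoded in an MD tag (letters outside ^-deletion runs).
md_mismatches <- function(md) {
  toks <- regmatches(md, gregexpr("\\^[A-Z]+|[A-Z]+|[0-9]+", md))[[1]]
  sum(nchar(toks[grepl("^[A-Z]+$", toks)]))
}

#' Write ungapped alignment records as SAM
#'
#' Companion writer for [parse_alignments()] round trips: emits one record
#' per hit with a full-length match CIGAR and an NM tag.
#'
#' @param hits Tibble with `read_id`, `ref`, `start` (0-based), `strand`,
#'   `mismatches`.
#' @param reads Tibble with `read_id`, `seq` (forward-strand read sequence).
#' @param ref_lengths Named integer vector of reference lengths.
#' @param path Output path.
#' @export
write_sam <- function(hits, reads, ref_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (i in seq_along(ref_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths)[i],
                       ref_lengths[i]), con)
  }
  seqs <- setNames(reads$seq, reads$read_id)
  for (i in seq_len(nrow(hits))) {
    s <- seqs[[hits$read_id[i]]]
    minus <- hits$strand[i] == "-"
    writeLines(paste(
      hits$read_id[i], if (minus) 16L else 0L, hits$ref[i],
      hits$start[i] + 1L, 42L, paste0(nchar(s), "M"), "*", 0L, 0L,
      if (minus) revcomp(s) else s, "*",
      paste0("NM:i:", hits$mismatches[i]), sep = "\t"), con)
  }
  invisible(path)
}

#' Extract 3' UTRs from a gene-model annotation
#'
#' Collects `three_prime_UTR` features from a GFF3 annotation, maps each to
#' its parent transcripts and genes, and merges UTRs with identical
#' coordinates across isoforms into a single UTR identifier listing all
#' parent transcripts. Features lacking a Parent attribute are skipped and
#' counted.
#'
#' @param gff GFF3 file path or a GRanges as returned by
#'   `rtracklayer::import()`.
#' @return Tibble with one row per (UTR, transcript): `utr_id`, `seqname`,
#'   `start` (0-based half-open), `end`, `strand`, `transcript_id`,
#'   `gene_id`; attribute `n_skipped` counts parentless UTR features.
#' @export
extract_three_prime_utrs <- function(gff) {
  gr <- if (is.character(gff)) rtracklayer::import(gff) else gff
  mc <- S4Vectors::mcols(gr)
  is_tx <- as.character(mc$type) %in% c("mRNA", "transcript")
  tx2gene <- setNames(
    vapply(mc$Parent[is_tx], function(p) if (length(p)) p[[1]] else NA_character_,
           character(1)),
    mc$ID[is_tx])
  is_utr <- as.character(mc$type) == "three_prime_UTR"
  utr <- gr[is_utr]
  parents <- S4Vectors::mcols(utr)$Parent
  n_skipped <- sum(lengths(parents) == 0)
  keep <- lengths(parents) > 0
  utr <- utr[keep]
  parents <- parents[keep]
  if (length(utr) == 0) {
    out <- tibble(utr_id = character(), seqname = character(),
                  start = integer(), end = integer(), strand = character(),
                  transcript_id = character(), gene_id = character())
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  long <- tibble(
    seqname = rep(as.character(GenomicRanges::seqnames(utr)), lengths(parents)),
    start = rep(GenomicRanges::start(utr) - 1L, lengths(parents)),
    end = rep(GenomicRanges::end(utr), lengths(parents)),
    strand = rep(as.character(GenomicRanges::strand(utr)), lengths(parents)),
    transcript_id = unlist(parents)
  )
  long <- distinct(long)
  key <- paste(long$seqname, long$start, long$end, long$strand, sep = ":")
  long$utr_id <- sprintf("utr_%05d", match(key, unique(key)))
  long$gene_id <- unname(tx2gene[long$transcript_id])
  out <- long[, c("utr_id", "seqname", "start", "end", "strand",
                  "transcript_id", "gene_id")]
  out <- arrange(out, .data$utr_id, .data$transcript_id)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read BLAST tabular output (outfmt 6, with query coverage)
#'
#' Expects the 12 standard outfmt-6 columns plus a 13th `qcovs` column
#' (query coverage per subject, in percent), as produced by
#' `-outfmt "6 std qcovs"`.
#'
#' @param path File path.
#' @param kind Search kind label: "precursor_blast" or "short_blast".
#' @return Tibble with `query_id`, `subject_id`, `evalue`, `coverage`
#'   (fraction in \[0,1\]) and `kind`.
#' @export
read_blast_outfmt6 <- function(path, kind = c("precursor_blast",
                                              "short_blast")) {
  kind <- match.arg(kind)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore", "qcovs")
  x <- utils::read.table(path, sep = "\t", col.names = cols,
                         stringsAsFactors = FALSE, comment.char = "#")
  tibble(query_id = x$qseqid, subject_id = x$sseqid, evalue = x$evalue,
         coverage = x$qcovs / 100, kind = kind)
}

#' Write a tibble as TSV with commented header lines
#'
#' All coordinate columns in written reports are 1-based closed; internal
#' coordinates are 0-based half-open. The `comments` lines document run
#' parameters (seed, thresholds) at the top of the file, prefixed with `#`.
#'
#' @param x Tibble.
#' @param path Output path.
#' @param comments Character vector of header comment lines (without `#`).
#' @export
write_tsv_report <- function(x, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
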
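#' Generate a set of ground-truth source genomes
#'
#' Creates random nucleotide "genomes" for the five source categories used in
#' cross-kingdom read attribution (host insect, obligate symbiont, host plant,
#' bacterial, viral). Libraries are rejection-sampled so that the number of
#' exact 17-mers shared between any two libraries (counting both strands)
#' stays at or below `max_shared_kmers`, which keeps ground-truth provenance
#' of sampled reads unambiguous.
#'
#' @param libraries Data frame with columns `name`, `category` and `length`,
#'   and optionally `gc` (defaults to 0.5). Categories must come from
#'   `r paste(SOURCE_CATEGORIES, collapse = ", ")`.
#' @param seed Integer seed; generation is bit-for-bit reproducible.
#' @param max_shared_kmers Cap on distinct k-mers shared between any pair of
#'   libraries (default 0, i.e. fully disjoint).
#' @param k K-mer size used for the disjointness check (default 17).
#' @param retry_cap Maximum rejection-sampling retries per library.
#' @return Tibble with columns `name`, `category`, `sequence`; attributes
#'   `seed` and `kmer_k` record the generation parameters.
#' @export
#' @examples
#' gs <- generate_genome_set(
#'   tibble::tibble(name = c("aphid", "plant"),
#'                  category = c("host_insect", "host_plant"),
#'                  length = c(2000, 2000)),
#'   seed = 7)
#' nchar(gs$sequence)
generate_genome_set <- function(libraries, seed, max_shared_kmers = 0L,
                                k = 17L, retry_cap = 100L) {
  libraries <- as_tibble(libraries)
  if (nrow(libraries) == 0) {
    abort("`libraries` must describe at least one library.")
  }
  if (!all(c("name", "category", "length") %in% names(libraries))) {
    abort("`libraries` needs columns `name`, `category`, `length`.")
  }
  if (anyDuplicated(libraries$name)) abort("library names must be unique")
  if (!all(libraries$category %in% SOURCE_CATEGORIES)) {
    abort(paste0("categories must be among: ",
                 paste(SOURCE_CATEGORIES, collapse = ", ")))
  }
  if (any(libraries$length < 100)) abort("library lengths must be >= 100")
  if (!"gc" %in% names(libraries)) libraries$gc <- 0.5
  if (any(libraries$gc <= 0 | libraries$gc >= 1)) abort("gc must be in (0,1)")

  set.seed(seed)
  seqs <- character(nrow(libraries))
  seen_kmers <- character(0)
  for (i in seq_len(nrow(libraries))) {
    ok <- FALSE
    for (try in seq_len(retry_cap)) {
      s <- rand_dna(libraries$length[i], libraries$gc[i])
      km <- unique(c(kmers(s, k), kmers(revcomp(s), k)))
      n_shared <- sum(km %in% seen_kmers)
      if (n_shared <= max_shared_kmers) {
        if (try > 1L) {
          inform(sprintf("library '%s': accepted after %d rejection retries",
                         libraries$name[i], try - 1L))
        }
        seqs[i] <- s
        seen_kmers <- c(seen_kmers, km)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(sprintf(
        "library '%s': could not satisfy the shared %d-mer cap in %d tries",
        libraries$name[i], k, retry_cap))
    }
  }
  out <- tibble(name = libraries$name, category = libraries$category,
                sequence = seqs)
  attr(out, "seed") <- seed
  attr(out, "kmer_k") <- k
  out
}

#' Generate a synthetic hairpin miRNA precursor
#'
#' Builds a precursor as 5' end + first arm + loop + second arm + 3' end,
#' where the second arm is the reverse complement of the first up to
#' `n_mismatches` injected non-complementary positions, together with the
#' matching dot-bracket structure. Arm lengths follow the 20-24 nt mature
#' miRNA size limit and total length is capped at 300 nt.
#'
#' @param arm_len Arm (mature/star) length in nt, 20-24.
#' @param loop_len Loop length in nt (>= 3).
#' @param end5_len,end3_len Lengths of the unpaired 5'/3' end regions.
#' @param n_mismatches Number of non-complementary positions injected into
#'   the mature/star duplex.
#' @param mature_arm Which arm carries the mature miRNA ("first" or "second").
#' @param seed Integer seed.
#' @param id Precursor identifier; defaults to `prec_<seed>`.
#' @return One-row tibble with columns `precursor_id`, `sequence`,
#'   `dotbracket`, 0-based half-open arm coordinates `arm1_start`, `arm1_end`,
#'   `arm2_start`, `arm2_end`, `mature_arm`, and read-count placeholders
#'   `mature_reads`, `star_reads`.
#' @export
generate_precursor <- function(arm_len, loop_len, end5_len = 10L,
                               end3_len = 10L, n_mismatches = 0L,
                               mature_arm = c("first", "second"),
                               seed = 1L, id = NULL) {
  mature_arm <- match.arg(mature_arm)
  arm_len <- as.integer(arm_len)
  loop_len <- as.integer(loop_len)
  end5_len <- as.integer(end5_len)
  end3_len <- as.integer(end3_len)
  n_mismatches <- as.integer(n_mismatches)
  if (arm_len < 20 || arm_len > 24) {
    abort("`arm_len` must be between 20 and 24 (mature miRNA size limit)")
  }
  if (loop_len < 3) abort("`loop_len` must be >= 3")
  if (n_mismatches < 0 || n_mismatches > arm_len) {
    abort("`n_mismatches` must be in [0, arm_len]")
  }
  total <- end5_len + 2L * arm_len + loop_len + end3_len
  if (total > 300) abort("precursor length would exceed the 300 nt limit")

  set.seed(seed)
  arm1 <- rand_dna(arm_len)
  arm2 <- revcomp(arm1)
  mm_arm1 <- sort(sample.int(arm_len, n_mismatches))
  a2 <- strsplit(arm2, "")[[1]]
  for (j in mm_arm1) {
    # arm1 position j pairs with arm2 position arm_len - j + 1
    pos2 <- arm_len - j + 1L
    comp <- a2[pos2]
    a2[pos2] <- sample(setdiff(c("A", "C", "G", "T"), comp), 1L)
  }
  arm2 <- paste(a2, collapse = "")
  seqn <- paste0(rand_dna(end5_len), arm1, rand_dna(loop_len), arm2,
                 rand_dna(end3_len))

  db <- rep(".", total)
  arm1_idx <- end5_len + seq_len(arm_len)
  arm2_idx <- end5_len + arm_len + loop_len + seq_len(arm_len)
  db[arm1_idx] <- "("
  db[arm2_idx] <- ")"
  db[arm1_idx[mm_arm1]] <- "."
  db[arm2_idx[arm_len - mm_arm1 + 1L]] <- "."

  tibble(
    precursor_id = id %||% paste0("prec_", seed),
    sequence = seqn,
    dotbracket = paste(db, collapse = ""),
    arm1_start = end5_len, arm1_end = end5_len + arm_len,
    arm2_start = end5_len + arm_len + loop_len,
    arm2_end = end5_len + 2L * arm_len + loop_len,
    mature_arm = mature_arm,
    mature_reads = NA_integer_, star_reads = NA_integer_
  )
}

#' Sample labelled small RNA reads from source sequences
#'
#' Draws reads from a set of origin sequences at fixed proportions (the
#' per-origin totals are the exact multinomial draw for the seed), as
#' substrings of a random position and length, optionally mutated by a fixed
#' number of substitutions per read and/or reverse-complemented with a fixed
#' probability. Every read receives a truth label.
#'
#' @param sources Data frame with columns `name`, `sequence`, `proportion`
#'   (proportions must sum to 1).
#' @param n Number of reads (0 yields empty tibbles).
#' @param length_range Two integers inside \[17, 35\].
#' @param n_mismatches Substitutions injected into each read.
#' @param revcomp_frac Fraction of reads emitted reverse-complemented.
#' @param seed Integer seed.
#' @param prefix Read-id prefix.
#' @return List with `reads` (tibble: `read_id`, `seq`, `qual` fixed at "I")
#'   and `labels` (tibble: `read_id`, `origin`, `region` (NA here),
#'   `mismatches`, `start`, `strand`).
#' @export
sample_reads <- function(sources, n, length_range = c(17L, 35L),
                         n_mismatches = 0L, revcomp_frac = 0,
                         seed = 1L, prefix = "read") {
  sources <- as_tibble(sources)
  stopifnot(all(c("name", "sequence", "proportion") %in% names(sources)))
  if (abs(sum(sources$proportion) - 1) > 1e-9) {
    abort("source proportions must sum to 1")
  }
  if (length_range[1] < 17 || length_range[2] > 35 ||
      length_range[1] > length_range[2]) {
    abort("`length_range` must lie within [17, 35]")
  }
  empty <- list(
    reads = tibble(read_id = character(), seq = character(),
                   qual = character()),
    labels = tibble(read_id = character(), origin = character(),
                    region = character(), mismatches = integer(),
                    start = integer(), strand = character())
  )
  if (n == 0) return(empty)

  set.seed(seed)
  counts <- as.vector(rmultinom(1, n, sources$proportion))
  origin <- rep(sources$name, counts)
  src_seq <- rep(sources$sequence, counts)
  len <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  max_start <- nchar(src_seq) - len
  if (any(max_start < 0)) abort("a source sequence is shorter than a read")
  start0 <- vapply(max_start, function(m) sample.int(m + 1L, 1L) - 1L,
                   integer(1))
  seqs <- substr(src_seq, start0 + 1L, start0 + len)
  if (n_mismatches > 0) {
    seqs <- vapply(seqs, mutate_read, character(1), k = n_mismatches,
                   USE.NAMES = FALSE)
  }
  is_rc <- stats::runif(n) < revcomp_frac
  if (any(is_rc)) seqs[is_rc] <- revcomp(seqs[is_rc])
  ids <- make_ids(prefix, n)
  list(
    reads = tibble(read_id = ids, seq = seqs,
                   qual = strrep("I", nchar(seqs))),
    labels = tibble(read_id = ids, origin = origin, region = NA_character_,
                    mismatches = as.integer(n_mismatches), start = start0,
                    strand = ifelse(is_rc, "-", "+"))
  )
}

# Inject exactly k substitutions at distinct positions of one read.
mutate_read <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample.int(length(ch), min(k, length(ch)))
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Sample region-labelled reads from a hairpin precursor
#'
#' Plants reads into the regions of a precursor at fixed proportions. For
#' `mature`/`star` the read is an exact copy of the arm; for `loop` and the
#' end regions the read is fully inside the region (with at most 1 nt overlap
#' into a neighbour, chosen uniformly); for `fragment` the read straddles a
#' randomly chosen region boundary by at least 2 nt on each side.
#'
#' @param precursor One-row precursor tibble (see [generate_precursor()]).
#' @param n Number of reads.
#' @param region_props Named numeric proportions over a subset of
#'   `mature`, `star`, `loop`, `five_prime_end`, `three_prime_end`,
#'   `fragment`; must sum to 1.
#' @param seed Integer seed.
#' @param min_len Minimum read length for non-arm regions (default 17).
#' @param prefix Read-id prefix.
#' @return List with `reads` and `labels` tibbles (see [sample_reads()]);
#'   `labels$region` carries the planted region.
#' @export
sample_precursor_reads <- function(precursor, n, region_props, seed = 1L,
                                   min_len = 17L, prefix = "pread") {
  stopifnot(nrow(precursor) == 1)
  if (abs(sum(region_props) - 1) > 1e-9) {
    abort("`region_props` must sum to 1")
  }
  bad <- setdiff(names(region_props), REGION_LABELS)
  if (length(bad)) abort(paste("unknown regions:", paste(bad, collapse = ", ")))
  rmap <- region_map(precursor)
  pseq <- precursor$sequence
  set.seed(seed)
  counts <- as.vector(rmultinom(1, n, region_props))
  names(counts) <- names(region_props)

  one_read <- function(region) {
    if (region %in% c("mature", "star")) {
      r <- rmap[rmap$region == region, ]
      return(c(substr(pseq, r$start + 1L, r$end), region))
    }
    if (region == "fragment") {
      # interior boundaries between consecutive regions
      bnd <- rmap$end[-nrow(rmap)]
      b <- bnd[sample.int(length(bnd), 1L)]
      left <- sample(2:8, 1L)
      len <- max(min_len, left + sample(2:8, 1L))
      start0 <- b - left
      start0 <- max(0L, min(start0, nchar(pseq) - len))
      return(c(substr(pseq, start0 + 1L, start0 + len), "fragment"))
    }
    r <- rmap[rmap$region == region, ]
    if (nrow(r) == 0) abort(paste("precursor has no region", region))
    width <- r$end - r$start
    if (width < min_len) {
      abort(sprintf("region '%s' (%d nt) shorter than min_len %d",
                    region, width, min_len))
    }
    len <- sample(seq(min_len, min(width, 35L)), 1L)
    start0 <- r$start + sample.int(width - len + 1L, 1L) - 1L
    c(substr(pseq, start0 + 1L, start0 + len), region)
  }

  region_vec <- rep(names(counts), counts)
  drawn <- vapply(region_vec, one_read, character(2), USE.NAMES = FALSE)
  ids <- make_ids(prefix, n)
  list(
    reads = tibble(read_id = ids, seq = drawn[1, ],
                   qual = strrep("I", nchar(drawn[1, ]))),
    labels = tibble(read_id = ids, origin = precursor$precursor_id,
                    region = drawn[2, ], mismatches = 0L,
                    start = NA_integer_, strand = "+")
  )
}

#' Generate a ground-truth miRNA complement with homology evidence
#'
#' Builds `n_loci` precursors on a fictitious reference, of which
#' `n_duplicated_loci` are sequence-identical copies of earlier loci placed at
#' distinct coordinates (so they encode identical mature miRNAs), and a
#' homology-evidence table constructed so that `n_known` loci exercise the
#' "known" branches of the classification tree (strong precursor hit,
#' mid-tier hit with high coverage, mid-tier hit rescued by a short search)
#' and the rest exercise the "novel" branches.
#'
#' @param n_loci Number of precursor loci.
#' @param n_duplicated_loci Number of loci that are duplicates of earlier
#'   ones (must be < `n_loci`).
#' @param n_known Number of loci whose evidence should classify as known.
#' @param seed Integer seed.
#' @return List with `precursors` (tibble, one row per locus, including
#'   genomic coordinates and arm read counts), `evidence` (tibble:
#'   `precursor_id`, `evalue`, `coverage`, `short_evalue_mature`,
#'   `short_evalue_star`), and `status_truth` (tibble: `precursor_id`,
#'   `status`).
#' @export
make_truth_mirnome <- function(n_loci, n_duplicated_loci = 0L,
                               n_known = n_loci, seed = 1L) {
  if (n_duplicated_loci >= n_loci && n_loci > 0) {
    abort("`n_duplicated_loci` must be smaller than `n_loci`")
  }
  if (n_known > n_loci) abort("`n_known` must be <= `n_loci`")
  set.seed(seed)
  n_base <- n_loci - n_duplicated_loci
  rows <- vector("list", n_loci)
  pos <- 1000L
  for (i in seq_len(n_base)) {
    p <- generate_precursor(
      arm_len = sample(20:24, 1L), loop_len = sample(15:40, 1L),
      end5_len = sample(5:15, 1L), end3_len = sample(5:15, 1L),
      n_mismatches = sample(0:2, 1L),
      mature_arm = sample(c("first", "second"), 1L),
      seed = sample.int(1e6, 1L), id = sprintf("prec_%03d", i))
    p$ref <- "chrT"
    p$start <- pos
    p$end <- pos + nchar(p$sequence)
    p$strand <- "+"
    pos <- pos + nchar(p$sequence) + 500L
    p$mature_reads <- sample(50:500, 1L)
    p$star_reads <- sample(1:40, 1L)
    p$dataset_id <- "truth"
    rows[[i]] <- p
  }
  for (j in seq_len(n_duplicated_loci)) {
    src <- rows[[sample.int(n_base, 1L)]]
    p <- src
    p$precursor_id <- sprintf("prec_%03d", n_base + j)
    p$start <- pos
    p$end <- pos + nchar(p$sequence)
    pos <- pos + nchar(p$sequence) + 500L
    p$mature_reads <- sample(50:500, 1L)
    p$star_reads <- sample(1:40, 1L)
    rows[[n_base + j]] <- p
  }
  precursors <- bind_rows(rows)

  # Evidence cycling through the branches of the classification tree.
  known_branch <- c("strong", "mid_cov", "mid_short")
  novel_branch <- c("weak", "mid_short_weak")
  status <- c(rep("known", n_known), rep("novel", n_loci - n_known))
  ev <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    if (status[i] == "known") {
      b <- known_branch[(i - 1L) %% 3L + 1L]
      ev[[i]] <- switch(b,
        strong = tibble(evalue = 1e-12, coverage = stats::runif(1, 0.3, 1),
                        short_evalue_mature = NA_real_,
                        short_evalue_star = NA_real_),
        mid_cov = tibble(evalue = 1e-5, coverage = stats::runif(1, 0.60, 0.95),
                         short_evalue_mature = NA_real_,
                         short_evalue_star = NA_real_),
        mid_short = tibble(evalue = 1e-5, coverage = stats::runif(1, 0.1, 0.59),
                           short_evalue_mature = 1e-12,
                           short_evalue_star = 1e-4))
    } else {
      b <- novel_branch[(i - 1L) %% 2L + 1L]
      ev[[i]] <- switch(b,
        weak = tibble(evalue = 0.01, coverage = stats::runif(1, 0, 1),
                      short_evalue_mature = NA_real_,
                      short_evalue_star = NA_real_),
        mid_short_weak = tibble(evalue = 1e-5,
                                coverage = stats::runif(1, 0.1, 0.59),
                                short_evalue_mature = 1e-8,
                                short_evalue_star = 1e-6))
    }
  }
  evidence <- bind_rows(ev)
  evidence$precursor_id <- precursors$precursor_id
  evidence <- evidence[, c("precursor_id", "evalue", "coverage",
                           "short_evalue_mature", "short_evalue_star")]
  list(precursors = precursors, evidence = evidence,
       status_truth = tibble(precursor_id = precursors$precursor_id,
                             status = status))
}

#' Simulate multi-tool target-prediction tables with controlled overlap
#'
#' Plants (miRNA, target) pairs of three kinds: consensus pairs reported by
#' every tool with mutually overlapping seed images; partial pairs reported
#' by a strict subset of tools; and discordant pairs reported by all tools
#' but with disjoint seed images (so they must not reach consensus).
#'
#' @param mirna_ids Character vector of miRNA identifiers.
#' @param tools Character vector of tool names (>= 2).
#' @param n_consensus,n_partial,n_discordant Numbers of planted pairs.
#' @param target_len Length of each synthetic target sequence coordinate
#'   space.
#' @param seed Integer seed.
#' @return List with `predictions` (tibble: `tool`, `mirna_id`, `target_id`,
#'   `start`, `end`, `score`) and `truth` (tibble: `mirna_id`, `target_id`,
#'   `kind`).
#' @export
simulate_target_tables <- function(mirna_ids, tools,
                                   n_consensus = 10L, n_partial = 10L,
                                   n_discordant = 5L, target_len = 500L,
                                   seed = 1L) {
  stopifnot(length(tools) >= 2)
  set.seed(seed)
  n_pairs <- n_consensus + n_partial + n_discordant
  kind <- rep(c("consensus", "partial", "discordant"),
              c(n_consensus, n_partial, n_discordant))
  target_id <- sprintf("utr_%04d", seq_len(n_pairs))
  mirna <- sample(mirna_ids, n_pairs, replace = TRUE)
  preds <- vector("list", n_pairs)
  site_len <- 22L
  for (i in seq_len(n_pairs)) {
    if (kind[i] == "consensus") {
      # same anchor, jittered by at most 2 nt: 7-nt seed images still overlap
      anchor <- sample(50:(target_len - 50), 1L)
      off <- sample(-2:2, length(tools), replace = TRUE)
      preds[[i]] <- tibble(tool = tools, mirna_id = mirna[i],
                           target_id = target_id[i],
                           start = anchor + off,
                           end = anchor + off + site_len,
                           score = round(stats::runif(length(tools), 60, 99), 1))
    } else if (kind[i] == "partial") {
      sub <- sample(tools, sample.int(length(tools) - 1L, 1L))
      anchor <- sample(50:(target_len - 50), 1L)
      preds[[i]] <- tibble(tool = sub, mirna_id = mirna[i],
                           target_id = target_id[i],
                           start = anchor, end = anchor + site_len,
                           score = round(stats::runif(length(sub), 60, 99), 1))
    } else {
      # all tools, but sites spaced > site_len apart: seed images disjoint
      anchors <- 30L + (seq_along(tools) - 1L) * (site_len + 20L)
      preds[[i]] <- tibble(tool = tools, mirna_id = mirna[i],
                           target_id = target_id[i],
                           start = anchors, end = anchors + site_len,
                           score = round(stats::runif(length(tools), 60, 99), 1))
    }
  }
  list(predictions = bind_rows(preds),
       truth = tibble(mirna_id = mirna, target_id = target_id, kind = kind))
}

#' Simulate a COG-annotated reference proteome with isoform structure
#'
#' Builds a reference universe of 3'-UTR identifiers, a one-to-many
#' UTR-to-isoform expansion table, and a COG annotation over isoforms.
#'
#' @param n_utrs Number of UTRs in the universe.
#' @param max_isoforms Maximum isoforms per UTR (drawn uniformly from 1..max).
#' @param cogs Character vector of COG category letters to use.
#' @param p_annotated Probability an isoform carries a COG annotation.
#' @param cog_probs Optional sampling weights over `cogs` (default uniform).
#' @param seed Integer seed.
#' @return List with `universe` (character), `expansion` (tibble: `utr_id`,
#'   `isoform_id`) and `cog_table` (tibble: `id`, `cog`; `cog` is NA for
#'   unannotated isoforms).
#' @export
simulate_proteome <- function(n_utrs, max_isoforms = 3L,
                              cogs = c("J", "K", "L", "E", "T"),
                              p_annotated = 1, cog_probs = NULL, seed = 1L) {
  set.seed(seed)
  utr_id <- sprintf("utr_%05d", seq_len(n_utrs))
  n_iso <- sample.int(max_isoforms, n_utrs, replace = TRUE)
  utr_rep <- rep(utr_id, n_iso)
  expansion <- tibble(
    utr_id = utr_rep,
    isoform_id = paste0(utr_rep, "-R", unlist(lapply(n_iso, seq_len)))
  )
  n_total <- nrow(expansion)
  cog <- sample(cogs, n_total, replace = TRUE, prob = cog_probs)
  cog[stats::runif(n_total) >= p_annotated] <- NA_character_
  list(universe = utr_id, expansion = expansion,
       cog_table = tibble(id = expansion$isoform_id, cog = cog))
}
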
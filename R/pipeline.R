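#' Default all-synthetic demonstration configuration
#'
#' Returns a configuration list for [run_pipeline()] that exercises every
#' stage on generated data: five source genomes (one per category), a
#' ground-truth miRNA complement with duplicated loci and mixed known/novel
#' evidence, reads sampled across sources and precursor regions, multi-tool
#' target tables with planted overlap structure, and a COG-annotated
#' reference proteome with one-to-many isoform expansion.
#'
#' @param seed Integer master seed; each stochastic stage derives its own
#'   sub-seed from it.
#' @return Named list of parameters (see the pipeline vignette for the
#'   meaning and defaults of each).
#' @export
demo_config <- function(seed = 1L) {
  list(
    seed = seed,
    genome_length = 10000L,
    n_samples = 3L,
    n_reads = 600L,
    length_window = c(17L, 35L),
    k_max = 1L,
    attribution_mode = "cascade",
    n_loci = 12L,
    n_duplicated_loci = 3L,
    n_known = 8L,
    min_dup_overlap = 0.5,
    n_profile_reads = 2000L,
    profile_props = c(mature = 0.457, star = 0.457, loop = 0.018,
                      fragment = 0.068),
    tools = c("miRanda", "PITA", "RNAhybrid"),
    n_consensus = 12L, n_partial = 8L, n_discordant = 5L,
    seed_region = c(2L, 8L),
    n_utrs = 400L, max_isoforms = 3L,
    cogs = c("J", "K", "L", "E", "T", "O", "C"),
    n_enrich_reps = 20000L,
    alpha = 0.05
  )
}

# Stable stage sub-seed derived from the master seed (kept below 2^31).
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 97 + as.numeric(k) * 1009) %% 2147483647)
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates, end-to-end: genome simulation, read sampling, read
#' processing, source attribution, precursor annotation (duplicate collapse,
#' mature/star designation, known/novel classification), miRNA detection
#' with cross-sample intersection, precursor region profiling, multi-tool
#' target intersection with Venn counts, and COG enrichment. Each stage
#' writes its tables into `out_dir`, and a manifest of MD5 checksums is
#' written last; a rerun with the same config and seed reproduces identical
#' checksums.
#'
#' @param config Configuration list (see [demo_config()]) or the path of a
#'   YAML file containing one.
#' @param out_dir Output directory (created; must be writable).
#' @return Invisibly, a list with every stage's in-memory result plus the
#'   manifest tibble.
#' @export
run_pipeline <- function(config = demo_config(), out_dir = tempfile("run_")) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- demo_config(seed = config$seed %||% 1L)
  config <- utils::modifyList(defaults, config)
  # validate before any stage runs: every *_path entry must exist
  path_keys <- grep("_path$", names(config), value = TRUE)
  for (k in path_keys) {
    if (!file.exists(config[[k]])) {
      abort(sprintf("config entry '%s' points to a missing file: %s",
                    k, config[[k]]))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(x, name, comments = character(0)) {
    pth <- file.path(out_dir, name)
    for (cl in names(x)[vapply(x, is.list, logical(1))]) {
      x[[cl]] <- vapply(x[[cl]], paste, character(1), collapse = ",")
    }
    write_tsv_report(x, pth, comments = c(
      sprintf("dietmir %s | master seed %d",
              as.character(utils::packageVersion("dietmir")), config$seed),
      "coordinates in this report are 1-based closed unless suffixed '0'",
      comments))
    files <<- c(files, pth)
    pth
  }

  # -- simulate sources and reads ------------------------------------------
  libs <- tibble(
    name = c("aphid", "buchnera", "plant", "bact", "virus"),
    category = c("host_insect", "obligate_symbiont", "host_plant",
                 "bacterial", "viral"),
    length = config$genome_length)
  genomes <- generate_genome_set(libs, seed = stage_seed(config$seed, 1L))
  write_fasta(setNames(genomes$sequence, genomes$name),
              file.path(out_dir, "genomes.fasta"))
  files <- c(files, file.path(out_dir, "genomes.fasta"))

  mirnome <- make_truth_mirnome(config$n_loci, config$n_duplicated_loci,
                                config$n_known,
                                seed = stage_seed(config$seed, 2L))

  sources <- tibble(name = genomes$name, sequence = genomes$sequence,
                    proportion = c(0.35, 0.15, 0.35, 0.1, 0.05))
  sample_ids <- paste0("S", seq_len(config$n_samples))
  reads_all <- list()
  labels_all <- list()
  for (i in seq_along(sample_ids)) {
    sim <- sample_reads(sources, config$n_reads,
                        length_range = config$length_window,
                        seed = stage_seed(config$seed, 10L + i),
                        prefix = paste0(sample_ids[i], "_read"))
    sim$reads$sample_id <- sample_ids[i]
    sim$labels$sample_id <- sample_ids[i]
    reads_all[[i]] <- sim$reads
    labels_all[[i]] <- sim$labels
  }
  reads <- bind_rows(reads_all)
  labels <- bind_rows(labels_all)
  write_fastq(reads, file.path(out_dir, "reads.fastq"))
  files <- c(files, file.path(out_dir, "reads.fastq"))
  put(labels, "truth_labels.tsv")

  # -- process and attribute ------------------------------------------------
  processed <- process_reads(reads, length_window = config$length_window)
  put(processed[, c("read_id", "sample_id", "seq")], "processed_reads.tsv")

  parts <- lapply(sample_ids, function(s) {
    partition_reads(processed[processed$sample_id == s, ], genomes,
                    k_max = config$k_max, mode = config$attribution_mode)
  })
  partition <- bind_rows(parts)
  put(partition |>
        mutate(membership = NULL), "partition_per_read.tsv")
  groups <- tibble(sample_id = sample_ids,
                   tissue = rep_len(c("gut", "bacteriome"),
                                    length(sample_ids)))
  part_summary <- summarize_partitions(partition, groups = groups)
  put(part_summary, "partition_summary.tsv",
      comments = sprintf("attribution mode=%s k_max=%d",
                         config$attribution_mode, config$k_max))

  # -- annotate precursors --------------------------------------------------
  collapsed <- collapse_duplicates(mirnome$precursors,
                                   min_overlap = config$min_dup_overlap)
  classified <- classify_precursors(collapsed, mirnome$evidence)
  mirnas <- enumerate_mirnas(classified)
  prec_status <- setNames(classified$status, classified$precursor_id)
  mirnas$status <- vapply(mirnas$precursors, function(ps) {
    if (any(prec_status[ps] == "known")) "known" else "novel"
  }, character(1))
  put(classified[, c("precursor_id", "ref", "start", "end", "strand",
                     "mature_arm", "mature_reads", "star_reads", "status",
                     "dup_group")],
      "precursor_annotation.tsv")
  write_mirna_fasta(mirnas, file.path(out_dir, "mirnas.fasta"))
  files <- c(files, file.path(out_dir, "mirnas.fasta"))

  # -- detect plant miRNAs in the insect read sets -------------------------
  # plant detection reads: planted copies of a few miRNAs on top of the
  # sample reads, so the detection stage has signal
  set.seed(stage_seed(config$seed, 3L))
  planted <- mirnas[sample.int(nrow(mirnas), min(6L, nrow(mirnas))), ]
  n_ps <- min(3L, length(sample_ids))
  planted_reads <- tibble(
    read_id = paste0("planted_", seq_len(n_ps * nrow(planted))),
    seq = rep(planted$sequence, n_ps),
    sample_id = rep(sample_ids[seq_len(n_ps)], each = nrow(planted))
  )
  det_reads <- bind_rows(processed[, c("read_id", "seq", "sample_id")],
                         planted_reads)
  detections <- detect_mirnas(det_reads, mirnas)
  put(detections, "detection_counts.tsv")
  shared <- intersect_across_samples(detections)
  put(shared, "shared_mirnas.tsv")
  prec_hits <- map_to_precursors(shared, mirnas)
  put(prec_hits, "detected_mirna_precursors.tsv")

  # -- profile reads over one precursor ------------------------------------
  prof_precursor <- generate_precursor(
    arm_len = 22L, loop_len = 30L, end5_len = 12L, end3_len = 12L,
    n_mismatches = 1L, seed = stage_seed(config$seed, 4L),
    id = "prof_prec")
  prof_sim <- sample_precursor_reads(prof_precursor, config$n_profile_reads,
                                     config$profile_props,
                                     seed = stage_seed(config$seed, 5L))
  assignments <- profile_reads(prof_sim$reads, prof_precursor)
  put(assignments, "region_assignments.tsv")
  profile <- summarize_profile(assignments)
  put(profile, "region_profile_summary.tsv")

  # -- target intersection --------------------------------------------------
  tt <- simulate_target_tables(
    mirnas$mirna_id, config$tools, n_consensus = config$n_consensus,
    n_partial = config$n_partial, n_discordant = config$n_discordant,
    seed = stage_seed(config$seed, 6L))
  consensus <- intersect_predictions(tt$predictions, config$tools,
                                     seed = config$seed_region)
  venn <- venn_counts(tt$predictions, config$tools)
  put(consensus, "consensus_targets.tsv",
      comments = sprintf("seed region: miRNA positions %d-%d",
                         config$seed_region[1], config$seed_region[2]))
  put(venn, "venn_counts.tsv")

  # -- COG enrichment -------------------------------------------------------
  prot <- simulate_proteome(config$n_utrs, config$max_isoforms,
                            cogs = config$cogs,
                            seed = stage_seed(config$seed, 7L))
  idx <- as.integer(sub("utr_", "", unique(consensus$target_id)))
  target_utrs <- unique(prot$universe[(idx %% config$n_utrs) + 1L])
  enr <- cog_enrichment(target_utrs, prot$universe, prot$cog_table,
                        expansion = prot$expansion,
                        n_reps = config$n_enrich_reps,
                        seed = stage_seed(config$seed, 8L),
                        alpha = config$alpha)
  put(tidy.cog_enrichment(enr), "cog_enrichment.tsv",
      comments = sprintf("n_reps=%d n_draws=%d alpha=%g",
                         attr(enr, "n_reps"), attr(enr, "n_draws"),
                         attr(enr, "alpha")))

  # -- manifest -------------------------------------------------------------
  manifest <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  write_tsv_report(manifest, file.path(out_dir, "manifest.tsv"),
                   comments = sprintf("master seed %d", config$seed))
  yaml::write_yaml(config, file.path(out_dir, "run_info.yaml"))

  invisible(list(
    config = config, genomes = genomes, reads = reads, labels = labels,
    processed = processed, partition = partition,
    partition_summary = part_summary, precursors = classified,
    mirnas = mirnas, detections = detections, shared = shared,
    profile = profile, assignments = assignments, consensus = consensus,
    venn = venn, enrichment = enr, manifest = manifest, out_dir = out_dir
  ))
}
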
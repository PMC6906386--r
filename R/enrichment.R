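#' Observed COG composition of a target set
#'
#' Expands UTR-level targets to protein isoforms (when an expansion table is
#' given), then tallies COG category letters. Isoforms without a COG count
#' as unannotated; multi-letter assignments count once in every assigned
#' category (so observed and resampled compositions are commensurable).
#'
#' @param targets Character vector of ids, or tibble with `target_id`.
#' @param cog_table Tibble with `id`, `cog` (string of COG letters; NA or ""
#'   means unannotated).
#' @param expansion Optional tibble with `utr_id`, `isoform_id`; when given,
#'   targets are UTR ids and are expanded before counting.
#' @return Tibble with `cog`, `count` (one row per letter observed);
#'   attributes `unannotated` (count) and `n_proteins` (expanded set size).
#' @export
observed_cog_counts <- function(targets, cog_table, expansion = NULL) {
  ids <- if (is.data.frame(targets)) targets$target_id else targets
  if (!is.null(expansion)) {
    missing_ids <- setdiff(ids, expansion$utr_id)
    if (length(missing_ids)) {
      abort(paste("target id(s) outside the universe:",
                  paste(missing_ids, collapse = ", ")))
    }
    ids <- expansion$isoform_id[expansion$utr_id %in% ids]
  }
  missing_ids <- setdiff(ids, cog_table$id)
  if (length(missing_ids)) {
    abort(paste("id(s) absent from the COG table:",
                paste(missing_ids, collapse = ", ")))
  }
  cogs <- cog_table$cog[match(ids, cog_table$id)]
  unann <- sum(is.na(cogs) | cogs == "")
  letters_all <- unlist(strsplit(cogs[!is.na(cogs) & cogs != ""], ""))
  tab <- table(letters_all)
  out <- tibble(cog = names(tab), count = as.integer(tab))
  out <- arrange(out, .data$cog)
  attr(out, "unannotated") <- unann
  attr(out, "n_proteins") <- length(ids)
  out
}

# Per-UTR COG contribution matrix: one row per universe UTR, one column per
# COG letter in the table; entry = number of (isoform, letter) assignments
# the UTR contributes after expansion.
cog_contribution_matrix <- function(universe, cog_table, expansion = NULL) {
  letters_used <- sort(unique(unlist(
    strsplit(cog_table$cog[!is.na(cog_table$cog) & cog_table$cog != ""], ""))))
  M <- matrix(0L, nrow = length(universe), ncol = length(letters_used),
              dimnames = list(universe, letters_used))
  for (i in seq_along(universe)) {
    ids <- if (!is.null(expansion)) {
      expansion$isoform_id[expansion$utr_id == universe[i]]
    } else {
      universe[i]
    }
    cg <- cog_table$cog[match(ids, cog_table$id)]
    cg <- cg[!is.na(cg) & cg != ""]
    if (!length(cg)) next
    tab <- table(unlist(strsplit(cg, "")))
    M[i, names(tab)] <- as.integer(tab)
  }
  M
}

#' Monte Carlo null distributions of COG counts
#'
#' Each replicate draws `n_draws` UTRs uniformly with replacement from the
#' reference universe, expands them into their associated isoforms (so more
#' proteins than draws can enter a replicate), and tallies COG letters. The
#' result is deterministic for a fixed seed. The study-scale setting is
#' 1e6 replicates; 1e5 is a practical desk-scale default.
#'
#' @param universe Character vector of reference UTR ids (the sampling
#'   units).
#' @param cog_table Tibble with `id`, `cog` over isoforms (or over the
#'   universe itself when `expansion` is NULL).
#' @param n_draws Number of UTRs drawn per replicate (>= 1).
#' @param n_reps Number of replicates R (>= 1).
#' @param seed Integer seed.
#' @param expansion Optional `utr_id`/`isoform_id` expansion table.
#' @param chunk Replicates per internal chunk (memory control).
#' @return Object of class `cog_null`: list with `counts` (R x categories
#'   integer matrix), `n_draws`, `n_reps`, `seed`, `universe_size`.
#' @export
monte_carlo_null <- function(universe, cog_table, n_draws, n_reps, seed,
                             expansion = NULL, chunk = 2000L) {
  if (length(universe) == 0) abort("`universe` must be nonempty")
  if (n_draws < 1 || n_reps < 1) abort("`n_draws` and `n_reps` must be >= 1")
  M <- cog_contribution_matrix(universe, cog_table, expansion)
  set.seed(seed)
  counts <- matrix(0L, nrow = n_reps, ncol = ncol(M),
                   dimnames = list(NULL, colnames(M)))
  done <- 0L
  while (done < n_reps) {
    b <- min(chunk, n_reps - done)
    idx <- sample.int(length(universe), b * n_draws, replace = TRUE)
    grp <- rep(seq_len(b), each = n_draws)
    counts[done + seq_len(b), ] <- rowsum(M[idx, , drop = FALSE], grp)
    done <- done + b
  }
  structure(list(counts = counts, n_draws = n_draws, n_reps = n_reps,
                 seed = seed, universe_size = length(universe)),
            class = "cog_null")
}

#' @export
print.cog_null <- function(x, ...) {
  cat(sprintf(
    "<cog_null> %d replicates x %d categories (n_draws = %d, seed = %d)\n",
    x$n_reps, ncol(x$counts), x$n_draws, x$seed))
  invisible(x)
}

#' Empirical two-tailed p-value against a resampling null
#'
#' For observed count o and replicate counts z_1..z_R:
#' `tail_high = #\{z >= o\}/R`, `tail_low = #\{z <= o\}/R`, and
#' `p = min(1, 2 * min(tail_high, tail_low))`. When the smaller tail count
#' is zero the p-value is reported as the bound "< 1/R" rather than 0
#' (at R = 1e6 this prints as "< 1e-06").
#'
#' @param observed Named integer vector of observed counts (names = COG
#'   letters), or a tibble with `cog`, `count`. For a single category a
#'   plain numeric vector of one or more observed values may be given with
#'   `cog` naming the category.
#' @param null A `cog_null` object.
#' @param cog Category letter when `observed` is an unnamed numeric vector.
#' @return Tibble with `cog`, `observed`, `tail_low`, `tail_high`, `p`
#'   (numeric; equal to 1/R when the bound applies), `p_is_bound`,
#'   `p_report` (printable form).
#' @export
empirical_two_tailed_p <- function(observed, null, cog = NULL) {
  stopifnot(inherits(null, "cog_null"))
  if (is.data.frame(observed)) {
    obs <- setNames(observed$count, observed$cog)
    dat <- tibble(cog = names(obs), observed = unname(obs))
  } else if (!is.null(cog)) {
    dat <- tibble(cog = cog, observed = as.numeric(observed))
  } else {
    dat <- tibble(cog = names(observed), observed = unname(observed))
  }
  missing_cogs <- setdiff(unique(dat$cog), colnames(null$counts))
  if (length(missing_cogs)) {
    abort(paste("categories absent from the null:",
                paste(missing_cogs, collapse = ", ")))
  }
  R <- null$n_reps
  res <- lapply(unique(dat$cog), function(cc) {
    z <- sort.int(null$counts[, cc])
    o <- dat$observed[dat$cog == cc]
    n_le <- findInterval(o, z)                 # #{z <= o}
    n_ge <- R - findInterval(o - 1L, z)        # #{z >= o}
    tibble(cog = cc, observed = o, tail_low = n_le / R, tail_high = n_ge / R)
  })
  out <- bind_rows(res)
  min_tail <- pmin(out$tail_low, out$tail_high)
  out$p_is_bound <- min_tail == 0
  out$p <- pmin(1, 2 * min_tail)
  out$p[out$p_is_bound] <- 1 / R
  out$p_report <- ifelse(out$p_is_bound, sprintf("< %g", 1 / R),
                         sprintf("%g", out$p))
  out
}

#' Enrichment report: observed vs resampled COG composition
#'
#' Computes, per category, the observed percentage (of COG-annotated
#' proteins in the target set), the reference percentage, the percent
#' enrichment `(observed% - reference%) / reference% * 100`, the empirical
#' two-tailed p-value, an over/under flag (observed above/below the null
#' median), and the minimum percent enrichment needed for significance at
#' `alpha` on each side (from the null's alpha/2 and 1-alpha/2 empirical
#' quantiles, inverse-ECDF definition, converted to the enrichment scale).
#' Rows are sorted by observed percentage, ascending. A Bonferroni-adjusted
#' column is included for reference but not used for the significance flag.
#'
#' @param observed Tibble from [observed_cog_counts()].
#' @param null A `cog_null` object whose replicates used the same counting
#'   rules.
#' @param reference Tibble with `cog`, `count`: the reference composition
#'   (the whole universe counted identically).
#' @param alpha Significance level (default 0.05).
#' @return Tibble of class `cog_enrichment` with columns `cog`, `observed`,
#'   `observed_pct`, `reference_pct`, `enrichment_pct`, `p`, `p_is_bound`,
#'   `p_report`, `over`, `significant`, `p_bonferroni`,
#'   `threshold_over_pct`, `threshold_under_pct` (enrichment-scale
#'   thresholds; NA where the reference percentage is 0).
#' @export
enrichment_report <- function(observed, null, reference, alpha = 0.05) {
  stopifnot(inherits(null, "cog_null"))
  cogs <- colnames(null$counts)
  miss <- setdiff(cogs, reference$cog)
  if (length(miss)) {
    abort(paste("reference composition lacks categories:",
                paste(miss, collapse = ", ")))
  }
  obs <- setNames(rep(0L, length(cogs)), cogs)
  obs[observed$cog] <- observed$count
  ref <- setNames(reference$count, reference$cog)[cogs]
  obs_pct <- 100 * obs / sum(obs)
  ref_pct <- 100 * ref / sum(ref)
  enr <- ifelse(ref_pct > 0, (obs_pct - ref_pct) / ref_pct * 100, NA_real_)
  undef <- ref_pct == 0 & obs > 0
  if (any(undef)) {
    warn(paste("undefined positive enrichment (reference% = 0):",
               paste(cogs[undef], collapse = ", ")))
  }

  pv <- empirical_two_tailed_p(setNames(as.integer(obs), cogs), null)
  pv <- pv[match(cogs, pv$cog), ]

  # null composition per replicate, on the percentage/enrichment scale
  totals <- rowSums(null$counts)
  P <- 100 * null$counts / totals
  q_lo <- apply(P, 2, ecdf_quantile, q = alpha / 2)
  q_hi <- apply(P, 2, ecdf_quantile, q = 1 - alpha / 2)
  thr_over <- ifelse(ref_pct > 0, (q_hi - ref_pct) / ref_pct * 100, NA_real_)
  thr_under <- ifelse(ref_pct > 0, (q_lo - ref_pct) / ref_pct * 100, NA_real_)

  med <- apply(null$counts, 2, median)
  out <- tibble(
    cog = cogs, observed = as.integer(obs),
    observed_pct = as.numeric(obs_pct), reference_pct = as.numeric(ref_pct),
    enrichment_pct = as.numeric(enr),
    p = pv$p, p_is_bound = pv$p_is_bound, p_report = pv$p_report,
    over = obs > med,
    significant = pv$p < alpha | pv$p_is_bound,
    p_bonferroni = pmin(1, pv$p * length(cogs)),
    threshold_over_pct = as.numeric(thr_over),
    threshold_under_pct = as.numeric(thr_under)
  )
  out <- arrange(out, .data$observed_pct)
  class(out) <- c("cog_enrichment", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "n_reps") <- null$n_reps
  attr(out, "n_draws") <- null$n_draws
  out
}

# Inverse-ECDF (type 1) quantile: smallest value with ECDF >= q.
ecdf_quantile <- function(x, q) {
  xs <- sort.int(x)
  xs[max(1L, ceiling(q * length(xs)))]
}

#' One-call COG enrichment analysis
#'
#' Convenience wrapper: observed counts, reference composition, Monte Carlo
#' null and report in one step.
#'
#' @param targets UTR ids of the target set.
#' @param universe Reference UTR universe.
#' @param cog_table,expansion As in [monte_carlo_null()].
#' @param n_reps Replicates (default 1e5).
#' @param seed Integer seed.
#' @param n_draws Draws per replicate (default: number of targets).
#' @param alpha Significance level.
#' @return A `cog_enrichment` tibble (see [enrichment_report()]).
#' @export
cog_enrichment <- function(targets, universe, cog_table, expansion = NULL,
                           n_reps = 1e5, seed = 1L,
                           n_draws = length(unique(targets)), alpha = 0.05) {
  observed <- observed_cog_counts(targets, cog_table, expansion)
  reference <- observed_cog_counts(universe, cog_table, expansion)
  null <- monte_carlo_null(universe, cog_table, n_draws = n_draws,
                           n_reps = n_reps, seed = seed,
                           expansion = expansion)
  enrichment_report(observed, null, reference, alpha = alpha)
}

#' Tidy a COG enrichment result
#'
#' @param x A `cog_enrichment` object.
#' @param ... Unused.
#' @return The underlying tibble, one row per COG category.
#' @export
tidy.cog_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cog_enrichment")
  as_tibble(out)
}

#' @rdname tidy.cog_enrichment
#' @export
glance.cog_enrichment <- function(x, ...) {
  tibble(
    n_categories = nrow(x),
    n_significant = sum(x$significant),
    n_over = sum(x$significant & x$over),
    n_under = sum(x$significant & !x$over),
    n_reps = attr(x, "n_reps"),
    n_draws = attr(x, "n_draws"),
    alpha = attr(x, "alpha")
  )
}

#' Plot a COG enrichment result
#'
#' Percent-enrichment bars per category with the significance thresholds
#' marked in grey and significant categories starred.
#'
#' @param object A `cog_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cog_enrichment <- function(object, ...) {
  dat <- tidy.cog_enrichment(object)
  dat$cog <- factor(dat$cog, levels = dat$cog[order(dat$observed_pct)])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cog,
                                    y = .data$enrichment_pct)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$significant),
                      show.legend = FALSE, na.rm = TRUE) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$threshold_under_pct,
                   ymax = .data$threshold_over_pct),
      colour = "grey55", width = 0.4, na.rm = TRUE) +
    ggplot2::geom_text(
      data = dat[dat$significant, ],
      ggplot2::aes(label = "*",
                   y = .data$enrichment_pct +
                     5 * sign(.data$enrichment_pct)),
      na.rm = TRUE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey40")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% enrichment vs reference") +
    ggplot2::theme_minimal()
}
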
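#' Score an ensemble of alignments
#'
#' Runs [score_msa()] on each replicate alignment and stacks the per-column
#' records, keyed by replicate index and reference position. Columns where
#' the reference row holds a gap are dropped (their count per replicate is
#' kept in the `dropped_columns` attribute for diagnostics), so every
#' reference position contributes exactly one record per replicate.
#'
#' @param msas List of `sdp_msa` objects (one per replicate).
#' @param threshold Support threshold (default 0.6).
#' @inheritParams group_conservation
#' @return Long tibble of per-replicate records: `replicate`, `position`,
#'   `group`, and the [score_msa()] statistics.
#' @export
score_ensemble <- function(msas, threshold = 0.6,
                           conservation = c("pairs", "self-inclusive")) {
  conservation <- match.arg(conservation)
  stopifnot(is.list(msas), length(msas) >= 1L)
  dropped <- integer(length(msas))
  recs <- lapply(seq_along(msas), function(i) {
    sc <- score_msa(msas[[i]], threshold = threshold, conservation = conservation)
    gap_cols <- is.na(sc$ref_position)
    dropped[i] <<- length(unique(sc$column[gap_cols]))
    sc <- sc[!gap_cols, , drop = FALSE]
    sc$replicate <- i
    sc
  })
  out <- bind_rows(recs)
  out <- rename(out, position = "ref_position")
  out <- out[, c("replicate", "position", "group", "group_conservation", "support",
                 "weight", "group_score", "cons_all", "agree_all", "groupsim_all",
                 "cons_support", "agree_support", "n_support", "support_defined")]
  attr(out, "dropped_columns") <- dropped
  out
}

#' Aggregate per-replicate records by reference position
#'
#' Merges the per-replicate column records of [score_ensemble()] into
#' per-position (and per position x group) ensemble summaries: ensemble-mean
#' group-specific scores with distribution summaries, ensemble-mean
#' conservation per group, support frequency, conservation-agreement
#' projection coordinates (all-groups and support-only variants), and the
#' heterogeneity call.
#'
#' Completeness is enforced: every (replicate, position, group) triple must
#' appear exactly once — the column map guarantees this for any valid
#' replicate, so a duplicate or a hole indicates corrupted input.
#'
#' @param records Tibble from [score_ensemble()] (columns `replicate`,
#'   `position`, `group`, `group_score`, ...).
#' @param het_hi Strict lower bound for a conserved group in the
#'   heterogeneity call (default 0.6).
#' @param het_lo Strict upper bound for a degenerate group (default 0.5).
#' @param het_min_count Minimum number of groups on each extreme (default 6).
#' @return An object of class `sdp_ensemble` with elements `scores`
#'   (position x group tibble), `positions` (per-position tibble),
#'   `n_replicates`, `groups`, and the call parameters.
#' @export
aggregate_ensemble <- function(records, het_hi = 0.6, het_lo = 0.5, het_min_count = 6L) {
  stopifnot(is.data.frame(records),
            all(c("replicate", "position", "group", "group_score") %in% names(records)))
  reps <- sort(unique(records$replicate))
  positions <- sort(unique(records$position))
  groups <- sort(unique(records$group))
  n_rep <- length(reps)

  key <- paste(records$replicate, records$position, records$group, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    d <- records[dup, ][1, ]
    abort(sprintf("duplicate record for replicate %s, position %s, group %s",
                  d$replicate, d$position, d$group))
  }
  expected <- n_rep * length(positions) * length(groups)
  if (nrow(records) != expected) {
    tab <- table(records$position, records$replicate)
    hole <- which(tab != length(groups), arr.ind = TRUE)[1, , drop = TRUE]
    abort(sprintf("missing record(s): position %s, replicate %s",
                  rownames(tab)[hole[1]], colnames(tab)[hole[2]]))
  }

  scores <- records |>
    group_by(.data$position, .data$group) |>
    summarise(
      mean_score = mean(.data$group_score),
      median_score = stats::median(.data$group_score),
      q1 = stats::quantile(.data$group_score, 0.25, names = FALSE),
      q3 = stats::quantile(.data$group_score, 0.75, names = FALSE),
      lo95 = stats::quantile(.data$group_score, 0.025, names = FALSE),
      hi95 = stats::quantile(.data$group_score, 0.975, names = FALSE),
      var_score = stats::var(.data$group_score),
      mean_conservation = mean(.data$group_conservation),
      support_freq = mean(.data$support),
      .groups = "drop"
    )

  het <- scores |>
    group_by(.data$position) |>
    summarise(
      n_conserved = sum(.data$mean_conservation > het_hi),
      n_degenerate = sum(.data$mean_conservation < het_lo),
      .groups = "drop"
    ) |>
    mutate(is_heterogeneous = .data$n_conserved >= het_min_count &
             .data$n_degenerate >= het_min_count)

  proj <- bind_rows(
    project_positions(records, variant = "all"),
    project_positions(records, variant = "support")
  ) |>
    tidyr::pivot_wider(
      id_cols = "position", names_from = "variant",
      values_from = c("x", "y", "n_defined"),
      names_glue = "{.value}_{variant}"
    ) |>
    select(-"n_defined_all")

  positions_tbl <- left_join(het, proj, by = "position")

  structure(
    list(scores = scores, positions = positions_tbl,
         n_replicates = n_rep, groups = groups,
         params = list(het_hi = het_hi, het_lo = het_lo, het_min_count = het_min_count)),
    class = "sdp_ensemble"
  )
}

#' @export
print.sdp_ensemble <- function(x, ...) {
  cat("<sdp_ensemble> ", nrow(x$positions), " reference positions x ",
      length(x$groups), " groups over ", x$n_replicates, " replicates\n", sep = "")
  cat("  heterogeneously conserved positions: ",
      sum(x$positions$is_heterogeneous), "\n", sep = "")
  invisible(x)
}

#' Ensemble-mean group-specific score
#'
#' @param records Tibble from [score_ensemble()].
#' @param position Reference position.
#' @param group Group name.
#' @return Arithmetic mean of the group's score over replicates.
#' @export
ensemble_group_score <- function(records, position, group) {
  sel <- records$position == position & records$group == group
  if (!any(sel)) abort(sprintf("no records for position %s, group %s", position, group))
  mean(records$group_score[sel])
}

#' Distribution summary of a score collection
#'
#' Mean, median, quartiles and the middle-95% band (2.5% / 97.5%
#' percentiles), with linear interpolation between order statistics
#' (`stats::quantile` type 7), so summaries are bit-reproducible.
#'
#' @param values Non-empty numeric vector.
#' @return One-row tibble: `mean`, `median`, `q1`, `q3`, `lo95`, `hi95`.
#' @export
summarize_scores <- function(values) {
  if (length(values) == 0L || all(is.na(values))) abort("summarize_scores: empty input")
  q <- stats::quantile(values, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE, type = 7)
  tibble(mean = mean(values), median = q[3], q1 = q[2], q3 = q[4],
         lo95 = q[1], hi95 = q[5])
}

#' Heterogeneity call from ensemble-mean conservations
#'
#' A position is heterogeneously conserved when at least `min_count` groups
#' have ensemble-mean conservation strictly greater than `hi` and at least
#' `min_count` others strictly less than `lo`.
#'
#' @param mean_conservation Numeric vector of per-group ensemble-mean
#'   conservations (one entry per group).
#' @param hi,lo,min_count Thresholds (defaults 0.6, 0.5, 6).
#' @return One-row tibble: `n_conserved`, `n_degenerate`, `is_heterogeneous`.
#' @export
classify_heterogeneity <- function(mean_conservation, hi = 0.6, lo = 0.5, min_count = 6L) {
  n_cons <- sum(mean_conservation > hi)
  n_deg <- sum(mean_conservation < lo)
  tibble(n_conserved = n_cons, n_degenerate = n_deg,
         is_heterogeneous = n_cons >= min_count & n_deg >= min_count)
}

#' Conservation-agreement projection of reference positions
#'
#' Projects each reference position into the two-dimensional
#' conservation-agreement space: x = ensemble-mean group-wise conservation,
#' y = ensemble-mean between-group agreement, computed either over all
#' groups or over support groups only. For the support-only variant, only
#' replicates where the support statistics are defined (at least two support
#' groups) enter the mean; positions with no defined replicate get an `NA`
#' sentinel row rather than being dropped.
#'
#' @param records Tibble from [score_ensemble()].
#' @param variant `"all"` or `"support"`.
#' @return Tibble: `position`, `x`, `y`, `variant`, `n_defined` (replicates
#'   entering the mean).
#' @export
project_positions <- function(records, variant = c("all", "support")) {
  variant <- match.arg(variant)
  cols <- distinct(records, .data$replicate, .data$position, .keep_all = TRUE)
  if (variant == "all") {
    out <- cols |>
      group_by(.data$position) |>
      summarise(x = mean(.data$cons_all), y = mean(.data$agree_all),
                n_defined = dplyr::n(), .groups = "drop")
  } else {
    out <- cols |>
      group_by(.data$position) |>
      summarise(
        n_defined = sum(.data$support_defined),
        x = if (any(.data$support_defined))
          mean(.data$cons_support[.data$support_defined]) else NA_real_,
        y = if (any(.data$support_defined))
          mean(.data$agree_support[.data$support_defined]) else NA_real_,
        .groups = "drop"
      ) |>
      select("position", "x", "y", "n_defined")
  }
  out$variant <- variant
  out
}

#' Top fraction of scores
#'
#' Returns the `k = floor(fraction * N)` highest-scoring rows of a score
#' table, with deterministic tie-breaking (descending score, then position,
#' then group / remaining key order).
#'
#' @param scores A tibble with a numeric score column.
#' @param fraction Percentile fraction in `(0, 1]` (e.g. 0.075, 0.05, 0.01).
#' @param score_col Name of the score column (default `"mean_score"`).
#' @return The top-k rows, ordered.
#' @export
rank_top <- function(scores, fraction, score_col = "mean_score") {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1L, score_col %in% names(scores))
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]")
  }
  k <- floor(fraction * nrow(scores))
  tie_cols <- intersect(c("position", "group"), names(scores))
  ord <- scores |>
    arrange(desc(.data[[score_col]]),
            across(all_of(tie_cols)))
  slice_head(ord, n = k)
}

#' Amino-acid composition of a group at a reference position
#'
#' Counts, across the ensemble of replicate alignments, the residues of a
#' group's sampled sequences at the alignment column mapped to the given
#' reference position — the count matrix behind a per-group sequence logo.
#' Frequencies are normalized over non-gap, canonical symbols; the gap
#' fraction is reported separately.
#'
#' @param msas List of `sdp_msa` replicates.
#' @param position Reference position (1-based).
#' @param group Group name.
#' @return Tibble with one row per canonical amino acid: `residue`, `count`,
#'   `frequency`; attributes `gap_fraction` and `n_observations`.
#' @export
composition_matrix <- function(msas, position, group) {
  stopifnot(is.list(msas), length(msas) >= 1L)
  counts <- numeric(20L)
  n_gap <- 0L
  n_total <- 0L
  for (msa in msas) {
    cmap <- map_reference_columns(msa)
    col <- cmap$column[match(position, cmap$ref_position)]
    if (is.na(col)) next
    keep <- msa$groups == group & names(msa$rows) != msa$reference_id
    if (!any(keep)) next
    res <- toupper(substr(msa$rows[keep], col, col))
    codes <- residue_codes(res)
    counts <- counts + tabulate(codes, nbins = 20L)
    n_gap <- n_gap + sum(is.na(codes))
    n_total <- n_total + length(res)
  }
  freq <- if (sum(counts) > 0) counts / sum(counts) else rep(NA_real_, 20L)
  out <- tibble(residue = AA20, count = counts, frequency = freq)
  attr(out, "gap_fraction") <- if (n_total > 0) n_gap / n_total else NA_real_
  attr(out, "n_observations") <- n_total
  out
}

#' Long-format composition table over positions and groups
#'
#' @param msas List of `sdp_msa` replicates.
#' @param positions Reference positions (default: all mapped in the first
#'   replicate).
#' @param groups Groups (default: all non-reference groups).
#' @return Long tibble: `position`, `group`, `residue`, `count`,
#'   `frequency`, `gap_fraction`.
#' @export
composition_table <- function(msas, positions = NULL, groups = NULL) {
  stopifnot(is.list(msas), length(msas) >= 1L)
  cmap1 <- map_reference_columns(msas[[1]])
  if (is.null(positions)) positions <- sort(cmap1$ref_position[!is.na(cmap1$ref_position)])
  if (is.null(groups)) {
    groups <- sort(setdiff(unique(msas[[1]]$groups), "reference"))
  }
  grid <- tidyr::expand_grid(position = positions, group = groups)
  purrr::pmap_dfr(grid, function(position, group) {
    cm <- composition_matrix(msas, position, group)
    cm$position <- position
    cm$group <- group
    cm$gap_fraction <- attr(cm, "gap_fraction")
    cm[, c("position", "group", "residue", "count", "frequency", "gap_fraction")]
  })
}

#' @rdname aggregate_ensemble
#' @param x An `sdp_ensemble`.
#' @param ... Unused.
#' @method tidy sdp_ensemble
#' @export
tidy.sdp_ensemble <- function(x, ...) {
  left_join(x$scores,
            select(x$positions, "position", "is_heterogeneous"),
            by = "position")
}

#' @rdname aggregate_ensemble
#' @method glance sdp_ensemble
#' @export
glance.sdp_ensemble <- function(x, ...) {
  tibble(
    n_positions = nrow(x$positions),
    n_groups = length(x$groups),
    n_replicates = x$n_replicates,
    n_heterogeneous = sum(x$positions$is_heterogeneous),
    max_mean_score = max(x$scores$mean_score),
    mean_support_freq = mean(x$scores$support_freq)
  )
}
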
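#' Pipeline configuration
#'
#' Collects every protocol constant in one place, with the published
#' defaults: 200-sequence sub-samples (201 with the reference), per-set
#' allocation between 8 and 13, 5000 replicates, support threshold 0.6,
#' heterogeneity thresholds 0.6 / 0.5 with at least 6 groups on each
#' extreme, and top-score fractions 7.5% / 5% / 1%.
#'
#' @param total Sequences per sub-sample.
#' @param min_per_set,max_per_set Per-set allocation bounds.
#' @param n_replicates Ensemble size.
#' @param support_threshold Inclusive group-conservation threshold for
#'   support membership.
#' @param het_hi,het_lo,het_min_count Heterogeneity-call parameters.
#' @param top_fractions Percentile fractions for SDP calls.
#' @param base_seed Base seed; replicate i uses `base_seed + i - 1`.
#' @param aligner Aligner command template (see [align_replicate()]).
#' @param conservation Conservation convention (see [group_conservation()]).
#' @return A list of class `sdp_config`.
#' @export
sdp_config <- function(total = 200L, min_per_set = 8L, max_per_set = 13L,
                       n_replicates = 5000L, support_threshold = 0.6,
                       het_hi = 0.6, het_lo = 0.5, het_min_count = 6L,
                       top_fractions = c(0.075, 0.05, 0.01), base_seed = 1L,
                       aligner = "mafft --localpair --maxiterate 1000 --quiet --amino {input}",
                       conservation = c("pairs", "self-inclusive")) {
  conservation <- match.arg(conservation)
  stopifnot(min_per_set <= max_per_set,
            support_threshold >= 0, support_threshold <= 1,
            het_hi >= 0, het_hi <= 1, het_lo >= 0, het_lo <= 1,
            all(top_fractions > 0), all(top_fractions <= 1))
  structure(
    list(total = as.integer(total), min_per_set = as.integer(min_per_set),
         max_per_set = as.integer(max_per_set),
         n_replicates = as.integer(n_replicates),
         support_threshold = support_threshold,
         het_hi = het_hi, het_lo = het_lo, het_min_count = as.integer(het_min_count),
         top_fractions = top_fractions, base_seed = as.integer(base_seed),
         aligner = aligner, conservation = conservation),
    class = "sdp_config"
  )
}

#' @export
print.sdp_config <- function(x, ...) {
  cat("<sdp_config>\n")
  for (k in names(x)) cat("  ", k, ": ", paste(x[[k]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Run the full ensemble SDP pipeline
#'
#' Composes the workflow end to end: allocate -> for each replicate: sample,
#' align (or take a supplied pre-aligned replicate), map columns, score ->
#' aggregate by reference position -> classify -> rank -> write output
#' tables. Rerunning with the same config, pool, and pre-aligned inputs
#' reproduces byte-identical tables.
#'
#' Output files in `outdir`: `ensemble_scores.tsv` (per position x group),
#' `heterogeneity.tsv`, `projection.tsv`, `top_flags.tsv`,
#' `composition.tsv`, and `manifest.tsv` (config, seeds, versions).
#'
#' @param pool An `sdp_pool`.
#' @param reference_id Reference sequence id.
#' @param config An [sdp_config()].
#' @param outdir Output directory (created if missing).
#' @param msas Optional list of pre-aligned `sdp_msa` replicates; when
#'   supplied, no aligner is invoked and `n_replicates` is taken from its
#'   length.
#' @param write_composition Whether to write the (larger) composition table
#'   (default TRUE).
#' @return The `sdp_ensemble`, invisibly, with attribute `outdir`.
#' @export
run_pipeline <- function(pool, reference_id, config = sdp_config(), outdir,
                         msas = NULL, write_composition = TRUE) {
  stopifnot(inherits(pool, "sdp_pool"), inherits(config, "sdp_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  if (is.null(msas)) {
    reps <- generate_ensemble(pool, reference_id,
                              n_replicates = config$n_replicates,
                              base_seed = config$base_seed,
                              total = config$total,
                              min_per_set = config$min_per_set,
                              max_per_set = config$max_per_set)
    msas <- lapply(reps, function(rep) {
      tryCatch(
        align_replicate(rep$sequences, reference_id, aligner = config$aligner),
        error = function(e) abort(paste0("alignment stage failed at replicate ",
                                         rep$index, ": ", conditionMessage(e)))
      )
    })
  }

  records <- score_ensemble(msas, threshold = config$support_threshold,
                            conservation = config$conservation)
  ens <- aggregate_ensemble(records, het_hi = config$het_hi, het_lo = config$het_lo,
                            het_min_count = config$het_min_count)

  scores <- ens$scores
  flags <- scores[, c("position", "group", "mean_score")]
  for (f in config$top_fractions) {
    top <- rank_top(scores, f)
    lbl <- paste0("top_", sub("\\.?0+$", "", format(100 * f, trim = TRUE)), "pct")
    flags[[lbl]] <- paste(flags$position, flags$group) %in% paste(top$position, top$group)
  }

  proj <- bind_rows(
    project_positions(records, "all"),
    project_positions(records, "support")
  )

  readr::write_tsv(scores, file.path(outdir, "ensemble_scores.tsv"))
  readr::write_tsv(ens$positions[, c("position", "n_conserved", "n_degenerate",
                                     "is_heterogeneous")],
                   file.path(outdir, "heterogeneity.tsv"))
  readr::write_tsv(proj, file.path(outdir, "projection.tsv"))
  readr::write_tsv(flags, file.path(outdir, "top_flags.tsv"))
  if (write_composition) {
    readr::write_tsv(composition_table(msas), file.path(outdir, "composition.tsv"))
  }

  dropped <- attr(records, "dropped_columns")
  manifest <- tibble(
    key = c("package", "package_version", "r_version", "reference_id",
            "n_replicates", "base_seed", "total", "min_per_set", "max_per_set",
            "support_threshold", "het_hi", "het_lo", "het_min_count",
            "top_fractions", "conservation", "dropped_reference_gap_columns"),
    value = c("sdpensemble",
              as.character(utils::packageVersion("sdpensemble")),
              paste(R.version$major, R.version$minor, sep = "."),
              reference_id,
              length(msas), config$base_seed, config$total,
              config$min_per_set, config$max_per_set,
              config$support_threshold, config$het_hi, config$het_lo,
              config$het_min_count,
              paste(config$top_fractions, collapse = ","),
              config$conservation,
              paste(dropped, collapse = ","))
  )
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"))

  attr(ens, "outdir") <- outdir
  invisible(ens)
}
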
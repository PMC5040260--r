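#' Archetype plan for a simulated pool
#'
#' Describes the planted pattern of every column of a synthetic pool. Kinds:
#' \describe{
#'   \item{GLOBAL_CONSERVED}{one residue shared by every group (no SDP
#'     signal: conservation and agreement both maximal).}
#'   \item{IDEAL_SDP}{each group fixed to its own distinct residue (maximal
#'     signal).}
#'   \item{NEUTRAL}{independent uniform residues (degenerate, no signal).}
#'   \item{PARTIAL_SDP}{distinct residues for the `support` subset of
#'     groups, uniform noise for the rest.}
#'   \item{SHARED_SDP}{one residue shared by the `shared` subset of groups,
#'     distinct residues for the remaining groups (all groups conserved,
#'     elevated between-group agreement).}
#' }
#'
#' @param n_positions Number of columns.
#' @param kinds Character vector recycled over positions (default all
#'   `"NEUTRAL"`).
#' @return Tibble with columns `position`, `kind`, `support` (list),
#'   `shared` (list), `noise`; edit rows to plant specific archetypes.
#' @export
archetype_plan <- function(n_positions, kinds = "NEUTRAL") {
  tibble(
    position = seq_len(n_positions),
    kind = rep_len(kinds, n_positions),
    support = vector("list", n_positions),
    shared = vector("list", n_positions),
    noise = 0
  )
}

ARCHETYPE_KINDS <- c("GLOBAL_CONSERVED", "IDEAL_SDP", "NEUTRAL", "PARTIAL_SDP", "SHARED_SDP")

#' Generate a synthetic grouped sequence pool with planted archetypes
#'
#' Builds a pool of `n_groups` ortholog sets whose columns follow the
#' archetype plan, plus a reference sequence (a copy of the planted
#' consensus, from the first group's perspective), plus the ground truth of
#' which (position, group) pairs were planted as SDPs. All sequences have
#' equal length and no gaps, so the true alignment is the identity.
#' Per-sequence substitution noise replaces a planted residue with a uniform
#' draw from the other 19 canonical residues. Deterministic under `seed`.
#'
#' @param group_sizes Named integer vector of set sizes (or an unnamed
#'   vector, named `G01`, `G02`, ... automatically).
#' @param archetypes Tibble from [archetype_plan()] (columns `position`,
#'   `kind`, `support`, `shared`, `noise`).
#' @param seed Integer seed.
#' @param reference_id Id given to the emitted reference (default `"REF"`).
#' @return List with elements `pool` (an `sdp_pool`) and `truth` (tibble
#'   `position`, `kind`, `group`, `planted`).
#' @export
generate_pool <- function(group_sizes, archetypes, seed = 1L, reference_id = "REF") {
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- sprintf("G%02d", seq_along(group_sizes))
  }
  stopifnot(all(group_sizes >= 2L))
  groups <- names(group_sizes)
  n_groups <- length(groups)
  if (n_groups < 2L) abort("generate_pool needs at least 2 groups")
  stopifnot(is.data.frame(archetypes),
            all(c("position", "kind", "support", "shared", "noise") %in% names(archetypes)))
  bad <- setdiff(archetypes$kind, ARCHETYPE_KINDS)
  if (length(bad) > 0L) abort(paste0("unknown archetype kind(s): ", paste(bad, collapse = ", ")))
  if (any(archetypes$kind %in% c("IDEAL_SDP", "SHARED_SDP")) && n_groups > 20L) {
    abort("IDEAL_SDP/SHARED_SDP need one distinct residue per group: at most 20 groups")
  }
  L <- nrow(archetypes)
  stopifnot(identical(sort(archetypes$position), seq_len(L)))
  archetypes <- archetypes[order(archetypes$position), ]

  n_total <- sum(group_sizes)
  grp_of_row <- rep(groups, group_sizes)

  with_local_seed(seed, {
    # planted consensus residue per (group, position); NA = neutral drift
    consensus <- matrix(NA_character_, nrow = n_groups, ncol = L,
                        dimnames = list(groups, NULL))
    planted <- matrix(FALSE, nrow = n_groups, ncol = L, dimnames = list(groups, NULL))
    for (j in seq_len(L)) {
      kind <- archetypes$kind[j]
      if (kind == "GLOBAL_CONSERVED") {
        consensus[, j] <- sample(AA20, 1L)
      } else if (kind == "IDEAL_SDP") {
        consensus[, j] <- sample(AA20, n_groups)
        planted[, j] <- TRUE
      } else if (kind == "PARTIAL_SDP") {
        supp <- archetypes$support[[j]]
        if (is.null(supp) || length(supp) < 1L || length(supp) >= n_groups) {
          abort(sprintf("PARTIAL_SDP at position %d needs 1 <= |support| < n_groups", j))
        }
        consensus[supp, j] <- sample(AA20, length(supp))
        planted[supp, j] <- TRUE
      } else if (kind == "SHARED_SDP") {
        shared <- archetypes$shared[[j]]
        if (is.null(shared) || length(shared) < 2L) {
          abort(sprintf("SHARED_SDP at position %d needs >= 2 shared groups", j))
        }
        others <- setdiff(groups, shared)
        res <- sample(AA20, 1L + length(others))
        consensus[shared, j] <- res[1]
        if (length(others) > 0L) consensus[others, j] <- res[-1]
        planted[, j] <- TRUE
      }
      # NEUTRAL: consensus stays NA
    }

    # residue matrix, rows = sequences
    M <- matrix(NA_character_, nrow = n_total, ncol = L)
    for (j in seq_len(L)) {
      cons_j <- consensus[grp_of_row, j]
      drift <- is.na(cons_j)
      M[, j] <- cons_j
      if (any(drift)) M[drift, j] <- sample(AA20, sum(drift), replace = TRUE)
      noise <- archetypes$noise[j]
      if (noise > 0) {
        hit <- runif(n_total) < noise
        if (any(hit)) {
          M[hit, j] <- vapply(M[hit, j],
                              function(r) sample(setdiff(AA20, r), 1L),
                              character(1), USE.NAMES = FALSE)
        }
      }
    }

    # reference: the planted consensus seen from the first group; neutral
    # positions get an independent uniform residue
    ref <- consensus[1, ]
    ref[is.na(ref)] <- sample(AA20, sum(is.na(ref)), replace = TRUE)

    ids <- sprintf("%s_s%03d", grp_of_row, unlist(lapply(group_sizes, seq_len)))
    sequences <- tibble(
      id = ids, description = "",
      residues = apply(M, 1L, paste0, collapse = ""),
      group = grp_of_row
    )
    references <- tibble(id = reference_id, description = "synthetic reference",
                         residues = paste0(ref, collapse = ""))
    truth <- tibble(
      position = rep(seq_len(L), each = n_groups),
      kind = rep(archetypes$kind, each = n_groups),
      group = rep(groups, times = L),
      planted = as.vector(planted)
    )
    list(pool = new_sdp_pool(sequences, references), truth = truth)
  })
}

#' Generate a pre-aligned replicate ensemble from a synthetic pool
#'
#' Because synthetic pools are equal-length and gap-free, the identity
#' alignment is the true one; each replicate is a sub-sampled row set plus
#' the reference. Alignment uncertainty is emulated by column jitter: with
#' probability `column_jitter` per (replicate, sequence), one randomly
#' chosen residue is misplaced — its column is gapped for that row and the
#' residue moved to an overflow column appended to the alignment. The
#' overflow column is a reference-gap column (dropped from aggregation), so
#' jitter perturbs the content of exactly one mapped column per affected
#' row. Replicate `i` uses seed `base_seed + i - 1`.
#'
#' @param pool `sdp_pool` from [generate_pool()].
#' @param n_replicates Number of replicates.
#' @param column_jitter Per-(replicate, sequence) misplacement probability.
#' @param base_seed Integer seed.
#' @param plan Allocation tibble (default `allocate(pool, ...)` using the
#'   supplied totals).
#' @param reference_id Reference to include (default: first pool reference).
#' @inheritParams generate_ensemble
#' @return List of `sdp_msa` replicates.
#' @export
generate_prealigned_ensemble <- function(pool, n_replicates, column_jitter = 0,
                                         base_seed = 1L, plan = NULL,
                                         reference_id = NULL,
                                         total = 200L, min_per_set = 8L, max_per_set = 13L) {
  stopifnot(inherits(pool, "sdp_pool"))
  if (is.null(reference_id)) reference_id <- pool$references$id[1]
  lens <- nchar(c(pool$sequences$residues, pool$references$residues))
  if (length(unique(lens)) != 1L) {
    abort("generate_prealigned_ensemble requires an equal-length, gap-free pool")
  }
  L <- lens[1]
  if (is.null(plan)) plan <- allocate(pool, total, min_per_set, max_per_set)
  reps <- generate_ensemble(pool, reference_id, n_replicates = n_replicates,
                            base_seed = base_seed, plan = plan)
  pad <- column_jitter > 0
  lapply(reps, function(rep) {
    rows <- setNames(rep$sequences$residues, rep$sequences$id)
    if (pad) {
      # jitter seed offset keeps the draw stream separate from the sampling
      rows <- with_local_seed(rep$seed + 10000000L, {
        n <- length(rows)
        jitter_row <- c(runif(n - 1L) < column_jitter, FALSE)  # never the reference
        out <- paste0(rows, "-")
        for (i in which(jitter_row)) {
          p <- sample.int(L, 1L)
          ch <- strsplit(out[i], "", fixed = TRUE)[[1]]
          ch[L + 1L] <- ch[p]
          ch[p] <- "-"
          out[i] <- paste0(ch, collapse = "")
        }
        setNames(out, names(rows))
      })
    }
    sdp_msa(rows, setNames(rep$sequences$group, rep$sequences$id), reference_id)
  })
}
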
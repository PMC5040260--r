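#' Per-set sub-sample allocation
#'
#' Apportions a fixed sub-sample total across ortholog sets proportionally to
#' set size, subject to a per-set minimum and maximum. The defaults are the
#' ensemble protocol constants: 200 sequences per sub-sample, at least 8 and
#' at most 13 from any one set.
#'
#' The apportionment is clamped largest-remainder: each set starts at the
#' integer part of its proportional ideal share (clamped to its bounds), and
#' the residual is then placed one unit at a time where the deviation
#' `|count - ideal share|` grows least — i.e. by largest fractional
#' remainder while any set sits below its ideal — with ties broken toward
#' the set currently furthest below its ideal, then the larger set, then set
#' name. The result minimizes the total deviation from proportionality
#' subject to the bounds and is deterministic.
#'
#' @param set_sizes Named integer vector of ortholog-set sizes, or an
#'   `sdp_pool`.
#' @param total Total sequences per sub-sample (default 200).
#' @param min_per_set Minimum allocation per set (default 8).
#' @param max_per_set Maximum allocation per set (default 13).
#' @return A tibble with columns `set`, `size`, `ideal`, `count` (ordered by
#'   set name), with attributes `total`, `min_per_set`, `max_per_set`.
#' @export
allocate <- function(set_sizes, total = 200L, min_per_set = 8L, max_per_set = 13L) {
  if (inherits(set_sizes, "sdp_pool")) set_sizes <- pool_set_sizes(set_sizes)
  stopifnot(is.numeric(set_sizes), length(set_sizes) >= 1L, !is.null(names(set_sizes)))
  set_sizes <- set_sizes[order(names(set_sizes))]
  k <- length(set_sizes)
  if (min_per_set > max_per_set) abort("min_per_set exceeds max_per_set")
  if (k * min_per_set > total) {
    abort(sprintf("infeasible: %d sets x minimum %d exceeds total %d", k, min_per_set, total))
  }
  if (k * max_per_set < total) {
    abort(sprintf("infeasible: %d sets x maximum %d is below total %d", k, max_per_set, total))
  }
  too_small <- set_sizes < min_per_set
  if (any(too_small)) {
    abort(paste0("set(s) smaller than the minimum allocation: ",
                 paste(names(set_sizes)[too_small], collapse = ", ")))
  }
  cap <- pmin(max_per_set, set_sizes)   # cannot draw more than the set holds
  if (sum(cap) < total) {
    abort("infeasible: per-set caps (max allocation / set size) sum below total")
  }

  ideal <- total * set_sizes / sum(set_sizes)
  # start at the clamped integer parts of the ideal shares, then move single
  # units toward the total, always to the set where |count - ideal| grows
  # least (equivalently, largest-remainder order while any set sits below its
  # ideal). The per-set objective is convex, so this greedy is optimal for
  # sum |count - ideal| under the bounds.
  count <- as.integer(pmax(min_per_set, pmin(floor(ideal), cap)))
  tie_rank <- order(order(-set_sizes, names(set_sizes)))  # larger set, then name
  need <- total - sum(count)
  while (need > 0L) {
    open <- which(count < cap)
    cost <- abs(count[open] + 1L - ideal[open]) - abs(count[open] - ideal[open])
    surplus <- count[open] - ideal[open]
    pick <- open[order(cost, surplus, tie_rank[open])][1]
    count[pick] <- count[pick] + 1L
    need <- need - 1L
  }
  while (need < 0L) {
    open <- which(count > min_per_set)
    cost <- abs(count[open] - 1L - ideal[open]) - abs(count[open] - ideal[open])
    surplus <- ideal[open] - count[open]
    pick <- open[order(cost, surplus, tie_rank[open])][1]
    count[pick] <- count[pick] - 1L
    need <- need + 1L
  }
  out <- tibble(set = names(set_sizes), size = as.integer(set_sizes),
                ideal = unname(ideal), count = as.integer(unname(count)))
  attr(out, "total") <- as.integer(total)
  attr(out, "min_per_set") <- as.integer(min_per_set)
  attr(out, "max_per_set") <- as.integer(max_per_set)
  out
}

#' Draw one sub-sample replicate from a pool
#'
#' Draws, for each ortholog set, the planned number of sequence ids uniformly
#' without replacement, using a random generator initialized from `seed`.
#' The same seed always yields the same sample; the global RNG state is left
#' untouched.
#'
#' @param pool An `sdp_pool`.
#' @param plan Allocation tibble from [allocate()].
#' @param seed Integer seed for this replicate.
#' @return Tibble with columns `group`, `id` (attribute `seed`).
#' @export
draw_replicate <- function(pool, plan, seed) {
  stopifnot(inherits(pool, "sdp_pool"), is.data.frame(plan))
  sizes <- pool_set_sizes(pool)
  missing_sets <- setdiff(plan$set, names(sizes))
  if (length(missing_sets) > 0L) {
    abort(paste0("plan names set(s) absent from pool: ", paste(missing_sets, collapse = ", ")))
  }
  over <- plan$count > sizes[plan$set]
  if (any(over)) {
    abort(paste0("allocation exceeds set size for: ", paste(plan$set[over], collapse = ", ")))
  }
  ids_by_set <- split(pool$sequences$id, pool$sequences$group)
  drawn <- with_local_seed(seed, {
    lapply(seq_len(nrow(plan)), function(i) {
      members <- sort(ids_by_set[[plan$set[i]]])
      members[sample.int(length(members), plan$count[i])]
    })
  })
  out <- tibble(group = rep(plan$set, plan$count), id = unlist(drawn, use.names = FALSE))
  attr(out, "seed") <- as.integer(seed)
  out
}

# run expr under a temporary RNG seed, restoring prior global state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Generate an ensemble of sub-sample replicates
#'
#' Replicate `i` (1-based) is drawn with seed `base_seed + i - 1`, so the
#' whole ensemble is reproducible from `base_seed` and any replicate can be
#' replayed in isolation. Each emitted sequence collection is the sampled
#' sequences followed by the reference sequence (appended last, group
#' `"reference"`); with the default 200-sequence plan on a 20-set pool this
#' is 201 sequences per alignment input.
#'
#' @param pool An `sdp_pool`.
#' @param reference_id Id of a sequence in `pool$references`.
#' @param n_replicates Number of replicates (default 5000).
#' @param base_seed Integer base seed.
#' @param plan Allocation tibble; defaults to `allocate(pool)` with protocol
#'   defaults.
#' @param total,min_per_set,max_per_set Passed to [allocate()] when `plan` is
#'   not supplied.
#' @return List of replicates; each element has `index`, `seed`, `sample`
#'   (the [draw_replicate()] tibble) and `sequences` (tibble `id`,
#'   `residues`, `group`, reference last).
#' @export
generate_ensemble <- function(pool, reference_id, n_replicates = 5000L, base_seed = 1L,
                              plan = NULL, total = 200L, min_per_set = 8L,
                              max_per_set = 13L) {
  stopifnot(inherits(pool, "sdp_pool"))
  if (!reference_id %in% pool$references$id) {
    abort(paste0("reference id not among pool references: ", reference_id))
  }
  if (n_replicates == 0L) return(list())
  if (is.null(plan)) plan <- allocate(pool, total, min_per_set, max_per_set)
  ref <- pool$references[pool$references$id == reference_id, ]
  seq_lookup <- setNames(pool$sequences$residues, pool$sequences$id)
  lapply(seq_len(n_replicates), function(i) {
    seed <- as.integer(base_seed + i - 1L)
    smp <- draw_replicate(pool, plan, seed)
    seqs <- tibble(
      id = c(smp$id, ref$id),
      residues = c(unname(seq_lookup[smp$id]), ref$residues),
      group = c(smp$group, "reference")
    )
    list(index = i, seed = seed, sample = smp, sequences = seqs)
  })
}
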
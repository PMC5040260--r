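#' Read unaligned protein sequences from FASTA
#'
#' Reads a FASTA file into a tibble of sequences. Sequence ids are taken from
#' the header line up to the first whitespace; the remainder of the header is
#' kept as the description. Residues are upper-cased. Because the sequence
#' pool must be unaligned, any gap character (`-` or `.`) in a record is an
#' error.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `residues`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA in ", path, ": ", conditionMessage(e)))
  )
  if (length(set) == 0L) {
    return(tibble(id = character(), description = character(), residues = character()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id(s) in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  residues <- unname(toupper(as.character(set)))
  gappy <- grepl("[-.]", residues)
  if (any(gappy)) {
    abort(paste0("record(s) contain gap characters (pool sequences must be unaligned): ",
                 paste(ids[gappy], collapse = ", ")))
  }
  if (any(!nzchar(residues))) {
    abort(paste0("empty sequence record(s): ", paste(ids[!nzchar(residues)], collapse = ", ")))
  }
  tibble(id = ids, description = desc, residues = residues)
}

#' Write sequences to FASTA
#'
#' @param sequences A tibble with columns `id` and `residues` (optionally
#'   `description`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.data.frame(sequences), all(c("id", "residues") %in% names(sequences)))
  headers <- sequences$id
  if ("description" %in% names(sequences)) {
    has_desc <- !is.na(sequences$description) & nzchar(sequences$description)
    headers[has_desc] <- paste(sequences$id[has_desc], sequences$description[has_desc])
  }
  set <- Biostrings::BStringSet(setNames(sequences$residues, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Assemble a grouped sequence pool
#'
#' Partitions sequences into named ortholog sets (specificity groups) and a
#' separate collection of reference sequences. Every sequence id must be
#' assigned to exactly one group or be listed as a reference.
#'
#' @param sequences Tibble with columns `id`, `residues` (and optionally
#'   `description`), e.g. from [read_fasta()].
#' @param groups Either a tibble with columns `id` and `group`, or a named
#'   character vector mapping id to group name.
#' @param reference_ids Character vector of reference sequence ids.
#' @return An object of class `sdp_pool`: a list with tibbles `sequences`
#'   (id, description, residues, group) and `references`.
#' @export
build_pool <- function(sequences, groups, reference_ids = character()) {
  stopifnot(is.data.frame(sequences), all(c("id", "residues") %in% names(sequences)))
  if (!"description" %in% names(sequences)) sequences$description <- ""
  if (is.data.frame(groups)) {
    stopifnot(all(c("id", "group") %in% names(groups)))
    group_map <- setNames(as.character(groups$group), groups$id)
  } else {
    group_map <- groups
  }
  if (anyDuplicated(sequences$id)) {
    abort("duplicate sequence ids in pool input")
  }
  both <- intersect(names(group_map), reference_ids)
  if (length(both) > 0L) {
    abort(paste0("id(s) assigned to both a group and the reference list: ",
                 paste(both, collapse = ", ")))
  }
  assigned <- sequences$id %in% names(group_map) | sequences$id %in% reference_ids
  if (!all(assigned)) {
    abort(paste0("unassigned sequence id(s): ",
                 paste(sequences$id[!assigned], collapse = ", ")))
  }
  missing_ref <- setdiff(reference_ids, sequences$id)
  if (length(missing_ref) > 0L) {
    abort(paste0("reference id(s) absent from sequences: ",
                 paste(missing_ref, collapse = ", ")))
  }
  is_ref <- sequences$id %in% reference_ids
  refs <- sequences[is_ref, c("id", "description", "residues")]
  seqs <- sequences[!is_ref, , drop = FALSE]
  seqs$group <- unname(group_map[seqs$id])
  seqs <- as_tibble(seqs[, c("id", "description", "residues", "group")])
  if (length(unique(seqs$group)) < 2L) {
    abort("a sequence pool needs at least 2 ortholog sets (group-specific scoring is undefined otherwise)")
  }
  new_sdp_pool(seqs, as_tibble(refs))
}

new_sdp_pool <- function(sequences, references) {
  structure(list(sequences = sequences, references = references),
            class = "sdp_pool")
}

#' @export
print.sdp_pool <- function(x, ...) {
  sizes <- pool_set_sizes(x)
  cat("<sdp_pool> ", nrow(x$sequences), " sequences in ", length(sizes),
      " ortholog sets; ", nrow(x$references), " reference(s)\n", sep = "")
  cat("  sets: ", paste0(names(sizes), " (", sizes, ")", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Ortholog-set sizes of a pool
#'
#' @param pool An `sdp_pool`.
#' @return Named integer vector of set sizes, ordered by set name.
#' @export
pool_set_sizes <- function(pool) {
  stopifnot(inherits(pool, "sdp_pool"))
  tab <- table(pool$sequences$group)
  setNames(as.integer(tab), names(tab))
}

.blosum_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.blosum_env$BLOSUM62)) {
    utils::data("BLOSUM62", package = "Biostrings", envir = .blosum_env)
  }
  .blosum_env$BLOSUM62
}

#' Pairwise percent identity between two sequences
#'
#' Globally aligns two unaligned protein sequences (Needleman-Wunsch,
#' BLOSUM62, gap opening 10 / extension 0.5) and returns the fraction of
#' identical aligned pairs over the full alignment length, counting gap
#' columns in the denominator. This conservative, symmetric convention is the
#' one used by the pool-curation filter.
#'
#' @param a,b Sequence strings (or single-row tibbles with a `residues`
#'   column).
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  a <- .as_residue_string(a)
  b <- .as_residue_string(b)
  if (!nzchar(a) || !nzchar(b)) abort("pairwise_identity: empty sequence")
  # BLOSUM62 has no U/O rows; map them to X for alignment purposes
  a <- chartr("UO", "XX", a)
  b <- chartr("UO", "XX", b)
  aln <- tryCatch(
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "global", substitutionMatrix = blosum62(),
      gapOpening = 10, gapExtension = 0.5
    ),
    error = function(e) abort(paste0("pairwise alignment failed: ", conditionMessage(e)))
  )
  Biostrings::pid(aln, type = "PID1") / 100
}

.as_residue_string <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("residues" %in% names(x), nrow(x) == 1L)
    x <- x$residues
  }
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

#' Curate a sequence pool with candidate supplements
#'
#' Applies the two-part supplementation rule, then the minimum-set-size
#' filter. A candidate is added to ortholog set S iff (1) its identity to
#' every member of S is at least `min_identity`, and (2) its lowest identity
#' to any member of S is strictly greater than its identity to every pool
#' sequence outside S. Both rules are evaluated against the original
#' (pre-supplementation) pool, so the result does not depend on candidate
#' order. Finally, any set with fewer than `min_set_size` members is dropped.
#'
#' @param pool An `sdp_pool`.
#' @param candidates Tibble of candidate sequences (`id`, `residues`,
#'   optionally `description`); ids must be disjoint from the pool.
#' @param min_identity Inclusive identity threshold (default 0.35).
#' @param min_set_size Sets smaller than this after supplementation are
#'   dropped (default 20).
#' @param identity_fun Function `(a, b) -> fraction`; defaults to
#'   [pairwise_identity()]. Injectable for testing or for precomputed
#'   identities.
#' @return A curated `sdp_pool`.
#' @export
curate_pool <- function(pool, candidates, min_identity = 0.35, min_set_size = 20,
                        identity_fun = pairwise_identity) {
  stopifnot(inherits(pool, "sdp_pool"))
  if (nrow(candidates) > 0L) {
    if (!"description" %in% names(candidates)) candidates$description <- ""
    clash <- intersect(candidates$id, c(pool$sequences$id, pool$references$id))
    if (length(clash) > 0L) {
      abort(paste0("candidate id(s) already present in pool: ", paste(clash, collapse = ", ")))
    }
    pool_seq <- pool$sequences
    # identity of each candidate to each original pool member
    accepted <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
      cand <- candidates[i, ]
      ident <- vapply(pool_seq$residues, function(r) identity_fun(cand$residues, r),
                      numeric(1), USE.NAMES = FALSE)
      by_set <- split(ident, pool_seq$group)
      min_by_set <- vapply(by_set, min, numeric(1))
      max_by_set <- vapply(by_set, max, numeric(1))
      ok_rule1 <- min_by_set >= min_identity
      dest <- NA_character_
      for (s in names(by_set)[ok_rule1]) {
        outside_max <- suppressWarnings(max(max_by_set[setdiff(names(by_set), s)]))
        if (min_by_set[[s]] > outside_max) dest <- s
      }
      if (is.na(dest)) return(NULL)
      tibble(id = cand$id, description = cand$description,
             residues = cand$residues, group = dest)
    })
    if (nrow(accepted) > 0L) {
      pool <- new_sdp_pool(bind_rows(pool$sequences, accepted), pool$references)
    }
  }
  sizes <- pool_set_sizes(pool)
  keep <- names(sizes)[sizes >= min_set_size]
  if (length(keep) == 0L) {
    abort(paste0("curation dropped every ortholog set (min_set_size = ", min_set_size, ")"))
  }
  dropped <- setdiff(names(sizes), keep)
  if (length(dropped) > 0L) {
    seqs <- pool$sequences[pool$sequences$group %in% keep, , drop = FALSE]
    pool <- new_sdp_pool(as_tibble(seqs), pool$references)
  }
  pool
}
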
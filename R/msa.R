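#' Construct an MSA object
#'
#' A light container for one ensemble replicate's alignment: equal-length
#' gapped rows keyed by sequence id, a group label per row, and the id of the
#' reference row (excluded from scoring, used only to map columns to
#' reference positions).
#'
#' @param rows Named character vector of gapped (aligned) residue strings.
#' @param groups Named character vector mapping row id to group name (the
#'   reference row may be labelled `"reference"`).
#' @param reference_id Id of the reference row.
#' @return An object of class `sdp_msa`.
#' @export
sdp_msa <- function(rows, groups, reference_id) {
  stopifnot(is.character(rows), !is.null(names(rows)))
  if (anyDuplicated(names(rows))) abort("duplicate row ids in MSA")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) abort("ragged alignment: rows of unequal length")
  if (!reference_id %in% names(rows)) {
    abort(paste0("reference row absent from alignment: ", reference_id))
  }
  ids <- names(rows)
  grp <- groups[ids]
  if (any(is.na(grp) & ids != reference_id)) {
    abort(paste0("row(s) without a group label: ",
                 paste(ids[is.na(grp) & ids != reference_id], collapse = ", ")))
  }
  grp[ids == reference_id] <- "reference"
  structure(
    list(rows = rows, groups = setNames(as.character(grp), ids),
         reference_id = reference_id, length = unname(widths[1])),
    class = "sdp_msa"
  )
}

#' @export
print.sdp_msa <- function(x, ...) {
  cat("<sdp_msa> ", length(x$rows), " rows x ", x$length, " columns; reference: ",
      x$reference_id, "\n", sep = "")
  invisible(x)
}

# rows x columns character matrix (uppercase), '.' normalized to '-'
msa_matrix <- function(msa) {
  m <- matrix(unlist(strsplit(toupper(msa$rows), "", fixed = TRUE), use.names = FALSE),
              nrow = length(msa$rows), ncol = msa$length, byrow = TRUE,
              dimnames = list(names(msa$rows), NULL))
  m[m == "."] <- "-"
  m
}

#' Align one replicate with an external aligner
#'
#' Writes the replicate's sequences to a temporary FASTA file, runs the
#' aligner command (default: MAFFT L-INS-i), and parses its aligned-FASTA
#' output from stdout. The command is a template in which `{input}` is
#' replaced by the temporary FASTA path; any aligner that reads FASTA and
#' writes aligned FASTA to stdout can be substituted.
#'
#' @param sequences Tibble with `id`, `residues`, `group` (reference row
#'   labelled `"reference"`), e.g. one element of [generate_ensemble()].
#' @param reference_id Id of the reference sequence.
#' @param aligner Command template (default
#'   `"mafft --localpair --maxiterate 1000 --quiet --amino {input}"`).
#' @return An `sdp_msa`.
#' @export
align_replicate <- function(sequences, reference_id,
                            aligner = "mafft --localpair --maxiterate 1000 --quiet --amino {input}") {
  stopifnot(is.data.frame(sequences), nrow(sequences) >= 2L)
  fa <- tempfile(fileext = ".fasta")
  out <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fa, out)), add = TRUE)
  write_fasta(sequences[, c("id", "residues")], fa)
  cmd <- gsub("{input}", fa, aligner, fixed = TRUE)
  parts <- strsplit(cmd, "\\s+")[[1]]
  errf <- tempfile(fileext = ".log")
  on.exit(unlink(errf), add = TRUE)
  code <- suppressWarnings(
    tryCatch(system2(parts[1], parts[-1], stdout = out, stderr = errf),
             error = function(e) abort(paste0("aligner failed to launch: ", cmd,
                                              " (", conditionMessage(e), ")")))
  )
  if (!identical(as.integer(code), 0L)) {
    err <- if (file.exists(errf)) paste(readLines(errf, warn = FALSE), collapse = "\n") else ""
    abort(paste0("aligner exited with status ", code, ": ", cmd, "\n", err))
  }
  aligned <- Biostrings::readBStringSet(out)
  ids <- sub("\\s.*$", "", names(aligned))
  missing <- setdiff(sequences$id, ids)
  if (length(missing) > 0L) {
    abort(paste0("aligner output missing sequence(s): ", paste(missing, collapse = ", ")))
  }
  rows <- setNames(toupper(as.character(aligned)), ids)[sequences$id]
  stripped <- gsub("[-.]", "", rows)
  if (!identical(unname(stripped), toupper(sequences$residues))) {
    abort("aligner output does not reproduce input sequences after gap removal")
  }
  sdp_msa(rows, setNames(sequences$group, sequences$id), reference_id)
}

#' Load a pre-computed alignment from aligned FASTA
#'
#' @param path Aligned-FASTA file.
#' @param groups Named character vector or tibble (`id`, `group`) with group
#'   labels for every non-reference row.
#' @param reference_id Id of the reference row.
#' @return An `sdp_msa`.
#' @export
load_msa <- function(path, groups, reference_id) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate row id(s) in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (is.data.frame(groups)) groups <- setNames(as.character(groups$group), groups$id)
  rows <- setNames(toupper(as.character(set)), ids)
  sdp_msa(rows, groups, reference_id)
}

#' Write an MSA to aligned FASTA
#'
#' @param msa An `sdp_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  stopifnot(inherits(msa, "sdp_msa"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(msa$rows), path)
  invisible(path)
}

#' Map alignment columns to reference positions
#'
#' The k-th non-gap character of the reference row maps to reference position
#' k (1-based); columns where the reference row holds a gap map to `NA` and
#' are dropped from ensemble aggregation.
#'
#' @param msa An `sdp_msa`.
#' @return Tibble with columns `column` (1-based alignment column) and
#'   `ref_position` (integer or `NA`).
#' @export
map_reference_columns <- function(msa) {
  stopifnot(inherits(msa, "sdp_msa"))
  ref <- strsplit(toupper(msa$rows[[msa$reference_id]]), "", fixed = TRUE)[[1]]
  is_res <- !(ref %in% GAP_CHARS)
  pos <- rep(NA_integer_, length(ref))
  pos[is_res] <- seq_len(sum(is_res))
  tibble(column = seq_along(ref), ref_position = pos)
}

#' Extract one alignment column (reference withheld)
#'
#' Returns the residues of all rows except the reference at the given
#' column, with their group labels. The reference is withheld so it cannot
#' bias the scoring of its own positions.
#'
#' @param msa An `sdp_msa`.
#' @param column 1-based column index.
#' @return Tibble with columns `id`, `residue`, `group`.
#' @export
column_view <- function(msa, column) {
  stopifnot(inherits(msa, "sdp_msa"))
  if (length(column) != 1L || column < 1L || column > msa$length) {
    abort(paste0("column out of range 1..", msa$length))
  }
  keep <- names(msa$rows) != msa$reference_id
  res <- substr(msa$rows[keep], column, column)
  res <- toupper(res)
  res[res == "."] <- "-"
  tibble(id = names(msa$rows)[keep], residue = unname(res),
         group = unname(msa$groups[keep]))
}
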
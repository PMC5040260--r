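#' Identity-matrix residue comparison
#'
#' The elementary pairwise comparison underlying every column statistic:
#' 1 iff both symbols are the same canonical amino acid. Any pair involving a
#' gap or an ambiguity code (X, B, Z, U, O) compares 0, including to itself —
#' gaps and ambiguous residues carry no identity evidence, so heavily gapped
#' groups come out degenerate.
#'
#' @param a,b Single residue symbols (vectorized).
#' @return 0/1 integer vector.
#' @export
residue_comp <- function(a, b) {
  ca <- residue_codes(toupper(a))
  cb <- residue_codes(toupper(b))
  as.integer(!is.na(ca) & !is.na(cb) & ca == cb)
}

# counts of canonical residues (length-20 vector) in a residue character vector
.aa_counts <- function(residues) {
  tabulate(residue_codes(toupper(residues)), nbins = 20L)
}

#' Within-group conservation of an alignment column
#'
#' Mean identity-matrix comparison over all unordered pairs of distinct
#' sequences in the group (the strict-pair convention). With
#' `conservation = "self-inclusive"`, self-pairs are included (pairs over
#' n(n+1)/2), an alternative convention under which a 0.6 threshold on a
#' group of eight corresponds to six identical residues.
#'
#' @param residues Character vector of the group's residues at the column
#'   (gaps included).
#' @param conservation `"pairs"` (default) or `"self-inclusive"`.
#' @return Conservation in `[0, 1]`.
#' @export
group_conservation <- function(residues, conservation = c("pairs", "self-inclusive")) {
  conservation <- match.arg(conservation)
  n <- length(residues)
  if (n < 2L) abort("group_conservation needs at least 2 members")
  cnt <- .aa_counts(residues)
  if (conservation == "pairs") {
    sum(cnt * (cnt - 1)) / (n * (n - 1))
  } else {
    sum(cnt * (cnt + 1)) / (n * (n + 1))
  }
}

#' Group-wise conservation of a column
#'
#' Unweighted mean of per-group conservation over the given groups: groups of
#' unequal sampled size contribute equally.
#'
#' @param residues,groups Parallel vectors: residue symbols and group labels.
#' @param which_groups Groups to average over (default: all present).
#' @inheritParams group_conservation
#' @return Mean conservation in `[0, 1]`.
#' @export
groupwise_conservation <- function(residues, groups, which_groups = NULL,
                                   conservation = c("pairs", "self-inclusive")) {
  conservation <- match.arg(conservation)
  if (is.null(which_groups)) which_groups <- unique(groups)
  if (length(which_groups) == 0L) abort("groupwise_conservation over an empty group set is undefined")
  by_grp <- split(residues, groups)
  missing <- setdiff(which_groups, names(by_grp))
  if (length(missing) > 0L) abort(paste0("unknown group(s): ", paste(missing, collapse = ", ")))
  mean(vapply(which_groups,
              function(g) group_conservation(by_grp[[g]], conservation),
              numeric(1)))
}

#' Between-group agreement of a column
#'
#' For each unordered pair of groups, the mean identity-matrix comparison
#' over all cross pairs of sequences; then the unweighted mean over group
#' pairs.
#'
#' @inheritParams groupwise_conservation
#' @return Mean agreement in `[0, 1]`.
#' @export
between_group_agreement <- function(residues, groups, which_groups = NULL) {
  if (is.null(which_groups)) which_groups <- unique(groups)
  if (length(which_groups) < 2L) {
    abort("between_group_agreement needs at least 2 groups")
  }
  by_grp <- split(residues, groups)
  missing <- setdiff(which_groups, names(by_grp))
  if (length(missing) > 0L) abort(paste0("unknown group(s): ", paste(missing, collapse = ", ")))
  counts <- lapply(by_grp[which_groups], .aa_counts)
  sizes <- vapply(by_grp[which_groups], length, integer(1))
  pair_vals <- c()
  k <- length(which_groups)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      pair_vals <- c(pair_vals,
                     sum(counts[[i]] * counts[[j]]) / (sizes[i] * sizes[j]))
    }
  }
  mean(pair_vals)
}

#' GroupSim-style SDP signal of a column
#'
#' Group-wise conservation minus between-group agreement over all groups.
#' Maximal (1) when every group is fixed to its own distinct residue; 0 both
#' for globally conserved and for fully degenerate columns.
#'
#' @inheritParams between_group_agreement
#' @inheritParams group_conservation
#' @return Signal in `[-1, 1]`.
#' @export
groupsim_score <- function(residues, groups, conservation = c("pairs", "self-inclusive")) {
  conservation <- match.arg(conservation)
  groupwise_conservation(residues, groups, conservation = conservation) -
    between_group_agreement(residues, groups)
}

#' Support set of a column
#'
#' The groups conserved at this column of this alignment: group conservation
#' greater than or equal to `threshold` (inclusive; default 0.6). Only
#' support groups enter the noise-filtered contrast.
#'
#' @inheritParams groupwise_conservation
#' @param threshold Inclusive conservation threshold (default 0.6).
#' @return Character vector of group names (sorted).
#' @export
support_set <- function(residues, groups, threshold = 0.6,
                        conservation = c("pairs", "self-inclusive")) {
  conservation <- match.arg(conservation)
  by_grp <- split(residues, groups)
  cons <- vapply(by_grp, group_conservation, numeric(1), conservation = conservation)
  sort(names(cons)[cons >= threshold])
}

#' Group-specific SDP scores of one alignment column
#'
#' The full per-column record. With support groups S (conservation >=
#' `threshold`) and, when `|S| >= 2`, the noise-filtered contrast
#' `C = groupwise_conservation(S) - between_group_agreement(S)`, the score of
#' group g is `W_g * C` where `W_g = 1` if g is in S and `W_g =` g's
#' conservation otherwise. When fewer than two groups are in support the
#' contrast is undefined and every score is 0 (flagged via
#' `support_defined`).
#'
#' @param view Column tibble with `residue` and `group` columns (see
#'   [column_view()]), or parallel vectors via `residues`/`groups`.
#' @param threshold Support threshold (default 0.6).
#' @inheritParams group_conservation
#' @return A tibble with one row per group: `group`, `group_conservation`,
#'   `support` (logical), `weight`, `group_score`, plus the column-level
#'   statistics repeated on every row: `cons_all`, `agree_all`,
#'   `groupsim_all`, `cons_support`, `agree_support` (NA when undefined),
#'   `n_support`, `support_defined`.
#' @export
score_column <- function(view, threshold = 0.6,
                         conservation = c("pairs", "self-inclusive")) {
  conservation <- match.arg(conservation)
  stopifnot(is.data.frame(view), all(c("residue", "group") %in% names(view)))
  residues <- view$residue
  groups <- view$group
  grp_names <- sort(unique(groups))
  if (length(grp_names) < 2L) abort("score_column needs at least 2 groups")
  by_grp <- split(residues, groups)
  cons <- vapply(by_grp[grp_names], group_conservation, numeric(1),
                 conservation = conservation)
  supp <- names(cons)[cons >= threshold]
  cons_all <- mean(cons)
  agree_all <- between_group_agreement(residues, groups, grp_names)
  if (length(supp) >= 2L) {
    cons_supp <- mean(cons[supp])
    agree_supp <- between_group_agreement(residues, groups, supp)
    contrast <- cons_supp - agree_supp
    defined <- TRUE
  } else {
    cons_supp <- NA_real_
    agree_supp <- NA_real_
    contrast <- NA_real_
    defined <- FALSE
  }
  in_supp <- grp_names %in% supp
  weight <- ifelse(in_supp, 1, cons[grp_names])
  score <- if (defined) weight * contrast else rep(0, length(grp_names))
  tibble(
    group = grp_names,
    group_conservation = unname(cons[grp_names]),
    support = in_supp,
    weight = unname(weight),
    group_score = unname(score),
    cons_all = cons_all,
    agree_all = agree_all,
    groupsim_all = cons_all - agree_all,
    cons_support = cons_supp,
    agree_support = agree_supp,
    n_support = length(supp),
    support_defined = defined
  )
}

#' Score every column of an MSA
#'
#' Vectorized per-alignment scoring engine. Equivalent to calling
#' [score_column()] on every [column_view()], but computed from per-group
#' residue count matrices for speed. The reference row is withheld.
#'
#' @param msa An `sdp_msa`.
#' @param threshold Support threshold (default 0.6).
#' @inheritParams group_conservation
#' @return A tibble with one row per column x group (columns of
#'   [score_column()] plus `column` and `ref_position`).
#' @export
score_msa <- function(msa, threshold = 0.6,
                      conservation = c("pairs", "self-inclusive")) {
  conservation <- match.arg(conservation)
  stopifnot(inherits(msa, "sdp_msa"))
  m <- msa_matrix(msa)
  keep <- rownames(m) != msa$reference_id
  m <- m[keep, , drop = FALSE]
  grp <- msa$groups[rownames(m)]
  grp_names <- sort(unique(grp))
  if (length(grp_names) < 2L) abort("score_msa needs at least 2 groups")
  L <- ncol(m)
  X <- matrix(residue_codes(m), nrow = nrow(m))   # codes, NA for gap/ambiguous
  X[is.na(X)] <- 0L

  sizes <- vapply(grp_names, function(g) sum(grp == g), integer(1))
  if (any(sizes < 2L)) {
    abort(paste0("group(s) with fewer than 2 members: ",
                 paste(grp_names[sizes < 2L], collapse = ", ")))
  }
  # per-group residue counts: list of L x 20 matrices
  counts <- lapply(grp_names, function(g) {
    Mg <- X[grp == g, , drop = FALSE]
    cnt <- vapply(1:20, function(a) colSums(Mg == a), numeric(L))
    matrix(cnt, nrow = L, ncol = 20L)
  })
  names(counts) <- grp_names

  # per-group conservation, G x L
  G <- length(grp_names)
  cons <- matrix(0, nrow = G, ncol = L, dimnames = list(grp_names, NULL))
  for (g in grp_names) {
    cnt <- counts[[g]]
    n <- sizes[[g]]
    cons[g, ] <- if (conservation == "pairs") {
      rowSums(cnt * (cnt - 1)) / (n * (n - 1))
    } else {
      rowSums(cnt * (cnt + 1)) / (n * (n + 1))
    }
  }

  # pairwise between-group agreement, P x L, plus the pair index
  pair_i <- integer(0); pair_j <- integer(0)
  for (i in seq_len(G - 1L)) {
    pair_i <- c(pair_i, rep(i, G - i))
    pair_j <- c(pair_j, seq(i + 1L, G))
  }
  agree_pairs <- matrix(0, nrow = length(pair_i), ncol = L)
  for (p in seq_along(pair_i)) {
    agree_pairs[p, ] <- rowSums(counts[[pair_i[p]]] * counts[[pair_j[p]]]) /
      (sizes[pair_i[p]] * sizes[pair_j[p]])
  }

  cons_all <- colMeans(cons)
  agree_all <- colMeans(agree_pairs)

  supp_mask <- cons >= threshold
  n_supp <- colSums(supp_mask)
  cons_supp <- rep(NA_real_, L)
  agree_supp <- rep(NA_real_, L)
  for (col in seq_len(L)) {
    s <- which(supp_mask[, col])
    if (length(s) >= 2L) {
      cons_supp[col] <- mean(cons[s, col])
      both <- pair_i %in% s & pair_j %in% s
      agree_supp[col] <- mean(agree_pairs[both, col])
    }
  }
  defined <- !is.na(cons_supp)
  contrast <- cons_supp - agree_supp

  weight <- ifelse(supp_mask, 1, cons)                 # G x L
  score <- sweep(weight, 2L, ifelse(defined, contrast, 0), `*`)

  cmap <- map_reference_columns(msa)
  groupsim <- cons_all - agree_all
  out <- tibble(
    column = rep(seq_len(L), each = G),
    group = rep(grp_names, times = L),
    group_conservation = as.vector(cons),
    support = as.vector(supp_mask),
    weight = as.vector(weight),
    group_score = as.vector(score),
    cons_all = rep(cons_all, each = G),
    agree_all = rep(agree_all, each = G),
    groupsim_all = rep(groupsim, each = G),
    cons_support = rep(cons_supp, each = G),
    agree_support = rep(agree_supp, each = G),
    n_support = rep(as.integer(n_supp), each = G),
    support_defined = rep(defined, each = G)
  )
  left_join(out, cmap, by = "column")[, c("column", "ref_position", "group",
                                          "group_conservation", "support", "weight",
                                          "group_score", "cons_all", "agree_all",
                                          "groupsim_all", "cons_support", "agree_support",
                                          "n_support", "support_defined")]
}
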
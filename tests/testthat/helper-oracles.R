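# Independent brute-force oracles: literal nested-loop implementations of the
# column statistics, and an exhaustive search for the allocation problem.
# They share no code with the package's vectorized engine.

AA_CANON <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

oracle_comp <- function(a, b) {
  if (!(a %in% AA_CANON) || !(b %in% AA_CANON)) return(0)
  if (a == b) 1 else 0
}

oracle_group_conservation <- function(residues) {
  n <- length(residues)
  total <- 0
  count <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      total <- total + oracle_comp(residues[i], residues[j])
      count <- count + 1
    }
  }
  total / count
}

oracle_groupwise_conservation <- function(residues, groups, which_groups = unique(groups)) {
  vals <- numeric(0)
  for (g in which_groups) {
    vals <- c(vals, oracle_group_conservation(residues[groups == g]))
  }
  mean(vals)
}

oracle_between_group_agreement <- function(residues, groups, which_groups = unique(groups)) {
  k <- length(which_groups)
  pair_means <- numeric(0)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      ri <- residues[groups == which_groups[i]]
      rj <- residues[groups == which_groups[j]]
      s <- 0
      for (a in ri) for (b in rj) s <- s + oracle_comp(a, b)
      pair_means <- c(pair_means, s / (length(ri) * length(rj)))
    }
  }
  mean(pair_means)
}

oracle_score_column <- function(residues, groups, threshold = 0.6) {
  grp_names <- sort(unique(groups))
  cons <- vapply(grp_names, function(g) oracle_group_conservation(residues[groups == g]),
                 numeric(1))
  supp <- grp_names[cons >= threshold]
  if (length(supp) >= 2) {
    contrast <- oracle_groupwise_conservation(residues, groups, supp) -
      oracle_between_group_agreement(residues, groups, supp)
    score <- ifelse(grp_names %in% supp, 1, cons) * contrast
  } else {
    contrast <- NA_real_
    score <- rep(0, length(grp_names))
  }
  list(group = grp_names, conservation = unname(cons), support = supp,
       contrast = contrast, score = unname(score),
       cons_all = oracle_groupwise_conservation(residues, groups, grp_names),
       agree_all = oracle_between_group_agreement(residues, groups, grp_names))
}

# random column generator: 2..max_groups groups of 2..max_members, residues
# drawn from a small alphabet plus gaps/ambiguity to exercise the 0-compare
# convention
random_column <- function(max_groups = 6, max_members = 8,
                          alphabet = c("A", "C", "D", "G", "-", "X")) {
  k <- sample(2:max_groups, 1)
  sizes <- sample(2:max_members, k, replace = TRUE)
  groups <- rep(sprintf("g%02d", seq_len(k)), sizes)
  residues <- sample(alphabet, length(groups), replace = TRUE)
  tibble::tibble(id = sprintf("s%03d", seq_along(groups)),
                 residue = residues, group = groups)
}

# exhaustive search over feasible integer allocations (<= 5 sets), minimizing
# sum |count - ideal share|
brute_allocate <- function(set_sizes, total, min_per_set, max_per_set) {
  k <- length(set_sizes)
  ideal <- total * set_sizes / sum(set_sizes)
  ranges <- lapply(seq_len(k), function(i) {
    seq(min_per_set, min(max_per_set, set_sizes[i]))
  })
  grid <- as.matrix(expand.grid(ranges))
  grid <- grid[rowSums(grid) == total, , drop = FALSE]
  obj <- apply(grid, 1, function(cnt) sum(abs(cnt - ideal)))
  list(min_objective = min(obj),
       argmins = grid[obj <= min(obj) + 1e-9, , drop = FALSE])
}

# 4-group, 8-position fixture with two partial-SDP columns, used by the
# pipeline and ensemble-degeneracy tests
pipeline_fixture <- function() {
  ap <- sdpensemble::archetype_plan(8)
  ap$kind <- c("GLOBAL_CONSERVED", "IDEAL_SDP", "NEUTRAL", "PARTIAL_SDP",
               "NEUTRAL", "PARTIAL_SDP", "NEUTRAL", "GLOBAL_CONSERVED")
  ap$support[[4]] <- c("G01", "G02")
  ap$support[[6]] <- c("G02", "G03", "G04")
  sdpensemble::generate_pool(stats::setNames(rep(8L, 4), sprintf("G%02d", 1:4)),
                             ap, seed = 61)
}

# small deterministic pool used across test files: 4 groups x 6 sequences,
# length 10, with one ideal-SDP column, one global column, one partial column
make_test_pool <- function(seed = 11, n_groups = 4, size = 6, length = 10,
                           noise = 0) {
  ap <- sdpensemble::archetype_plan(length)
  ap$kind <- rep(c("GLOBAL_CONSERVED", "IDEAL_SDP", "NEUTRAL", "PARTIAL_SDP", "NEUTRAL"),
                 length.out = length)
  for (j in which(ap$kind == "PARTIAL_SDP")) {
    ap$support[[j]] <- sprintf("G%02d", seq_len(max(2, n_groups %/% 2)))
  }
  ap$noise <- noise
  sdpensemble::generate_pool(stats::setNames(rep(size, n_groups),
                                             sprintf("G%02d", seq_len(n_groups))),
                             ap, seed = seed)
}
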
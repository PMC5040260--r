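test_that("identity-matrix comparison matches on canonical residues only", {
  expect_equal(residue_comp("A", "A"), 1L)
  expect_equal(residue_comp("A", "G"), 0L)
  # gaps and ambiguity codes never match, including themselves
  expect_equal(residue_comp("-", "-"), 0L)
  expect_equal(residue_comp("X", "X"), 0L)
  expect_equal(residue_comp("B", "B"), 0L)
  expect_equal(residue_comp("U", "U"), 0L)
  expect_equal(residue_comp("-", "A"), 0L)
  expect_equal(residue_comp(c("A", "C", "-"), c("A", "C", "-")), c(1L, 1L, 0L))
})

test_that("group conservation counts unordered distinct pairs", {
  expect_equal(group_conservation(rep("A", 8)), 1.0)
  expect_equal(group_conservation(c("A", "C", "D", "E", "F", "G", "H", "I")), 0.0)
  # 6 x A + C + D: 15 identical of 28 pairs
  expect_equal(group_conservation(c(rep("A", 6), "C", "D")), 15 / 28)
  # the self-inclusive convention instead gives 23/36
  expect_equal(group_conservation(c(rep("A", 6), "C", "D"), "self-inclusive"), 23 / 36)
  expect_error(group_conservation("A"), "at least 2")
})

test_that("group-wise conservation is the unweighted mean over groups", {
  residues <- c("A", "A", "C", "D")
  groups <- c("g1", "g1", "g2", "g2")
  expect_equal(groupwise_conservation(residues, groups), 0.5)
  expect_equal(groupwise_conservation(residues, groups, "g1"), 1.0)
  # 4 groups with conservations {1, 1, 0.5, 0} -> 0.625
  residues4 <- c("A", "A", "C", "C", "D", "D", "D", "E", "F", "G")
  groups4 <- c("g1", "g1", "g2", "g2", "g3", "g3", "g3", "g3", "g4", "g4")
  # g3: D,D,D,E -> 3/6 = 0.5; g4: F,G -> 0
  expect_equal(groupwise_conservation(residues4, groups4), mean(c(1, 1, 0.5, 0)))
  expect_error(groupwise_conservation(residues, groups, character(0)), "empty")
})

test_that("between-group agreement averages cross-pair identity over group pairs", {
  # every group fixed to the same residue -> 1
  expect_equal(between_group_agreement(rep("A", 6), rep(c("g1", "g2", "g3"), each = 2)), 1)
  # every group fixed to its own residue -> 0
  expect_equal(between_group_agreement(c("A", "A", "C", "C", "D", "D"),
                                       rep(c("g1", "g2", "g3"), each = 2)), 0)
  # groups fixed to A, A, C -> pair agreements {1, 0, 0}
  expect_equal(between_group_agreement(c("A", "A", "A", "A", "C", "C"),
                                       rep(c("g1", "g2", "g3"), each = 2)), 1 / 3)
  expect_error(between_group_agreement(c("A", "A"), c("g1", "g1")), "at least 2")
})

test_that("GroupSim signal separates the three canonical column patterns", {
  groups <- rep(c("g1", "g2", "g3", "g4"), each = 3)
  # each group fixed to a distinct residue: maximal signal 1
  ideal <- rep(c("A", "C", "D", "E"), each = 3)
  expect_equal(groupsim_score(ideal, groups), 1)
  # all sequences identical: 1 - 1 = 0
  expect_equal(groupsim_score(rep("A", 12), groups), 0)
  # fully degenerate (all residues distinct): 0 - 0 = 0
  degenerate <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N")
  expect_equal(groupsim_score(degenerate, groups), 0)
})

test_that("support membership is inclusive at the threshold", {
  # conservation exactly 0.6: 4 identical + 1 odd in a group of 5 -> 6/10
  res <- c(rep("A", 4), "C", rep("D", 5), "E", "F", "G", "H", "I")
  grp <- c(rep("g1", 5), rep("g2", 5), rep("g3", 5))
  expect_equal(group_conservation(res[grp == "g1"]), 0.6)
  expect_setequal(support_set(res, grp), c("g1", "g2"))
  # all degenerate -> empty; all conserved -> all
  expect_length(support_set(c("A", "C", "D", "E"), c("g1", "g1", "g2", "g2")), 0)
  expect_setequal(support_set(rep("A", 4), c("g1", "g1", "g2", "g2")), c("g1", "g2"))
})

test_that("group-specific scores implement the weighted support contrast", {
  # 4 groups: 3 fixed to distinct residues, 1 fully degenerate
  res <- c(rep("A", 4), rep("C", 4), rep("D", 4), "E", "F", "G", "H")
  grp <- rep(c("g1", "g2", "g3", "g4"), each = 4)
  rec <- score_column(tibble::tibble(residue = res, group = grp))
  expect_equal(rec$group_score[rec$group != "g4"], c(1, 1, 1))
  expect_equal(rec$group_score[rec$group == "g4"], 0)
  expect_true(all(rec$support[rec$group != "g4"]))
  expect_false(rec$support[rec$group == "g4"])
  expect_equal(rec$cons_support, rep(1, 4))
  expect_equal(rec$agree_support, rep(0, 4))

  # a non-support group with conservation 0.4 and contrast C scores 0.4 * C
  res2 <- c(rep("A", 5), rep("C", 5), "D", "D", "E", "F", "G")
  grp2 <- rep(c("g1", "g2", "g3"), each = 5)
  rec2 <- score_column(tibble::tibble(residue = res2, group = grp2))
  expect_equal(rec2$group_conservation[rec2$group == "g3"], 0.1)
  C <- rec2$cons_support[1] - rec2$agree_support[1]
  expect_equal(rec2$group_score[rec2$group == "g3"], 0.1 * C)
  expect_equal(rec2$group_score[rec2$group == "g1"], C)  # weight 1 in support

  # fewer than two support groups: contrast undefined, all scores 0, flagged
  res3 <- c(rep("A", 4), "C", "D", "E", "F")
  grp3 <- rep(c("g1", "g2"), each = 4)
  rec3 <- score_column(tibble::tibble(residue = res3, group = grp3))
  expect_false(rec3$support_defined[1])
  expect_equal(rec3$group_score, c(0, 0))
  expect_true(is.na(rec3$cons_support[1]))
})

test_that("all column statistics agree with the brute-force oracle on random columns", {
  set.seed(401)
  for (i in 1:200) {
    col <- random_column()
    rec <- score_column(col)
    oracle <- oracle_score_column(col$residue, col$group)
    expect_equal(rec$group, oracle$group)
    expect_equal(rec$group_conservation, oracle$conservation, tolerance = 1e-12)
    expect_equal(rec$group_score, oracle$score, tolerance = 1e-12)
    expect_equal(rec$cons_all[1], oracle$cons_all, tolerance = 1e-12)
    expect_equal(rec$agree_all[1], oracle$agree_all, tolerance = 1e-12)
    expect_setequal(rec$group[rec$support], oracle$support)
  }
})

test_that("the vectorized MSA engine equals per-column scoring", {
  sim <- make_test_pool(seed = 17, n_groups = 5, size = 5, length = 8, noise = 0.2)
  msas <- generate_prealigned_ensemble(sim$pool, n_replicates = 2, column_jitter = 0.4,
                                       base_seed = 3, plan = allocate(
                                         pool_set_sizes(sim$pool),
                                         total = 15, min_per_set = 3, max_per_set = 3))
  for (msa in msas) {
    fast <- score_msa(msa)
    for (col in seq_len(msa$length)) {
      slow <- score_column(column_view(msa, col))
      fcol <- fast[fast$column == col, ]
      expect_equal(fcol$group_score, slow$group_score, tolerance = 1e-12)
      expect_equal(fcol$group_conservation, slow$group_conservation, tolerance = 1e-12)
      expect_equal(fcol$cons_all, slow$cons_all, tolerance = 1e-12)
      expect_equal(fcol$agree_all, slow$agree_all, tolerance = 1e-12)
      expect_equal(fcol$cons_support, slow$cons_support, tolerance = 1e-12)
      expect_equal(fcol$agree_support, slow$agree_support, tolerance = 1e-12)
    }
  }
})

test_that("statistics are bounded, permutation-invariant, and monotone in the weight", {
  set.seed(402)
  for (i in 1:50) {
    col <- random_column()
    rec <- score_column(col)
    expect_true(all(rec$group_conservation >= 0 & rec$group_conservation <= 1))
    expect_true(all(rec$cons_all >= 0 & rec$cons_all <= 1))
    expect_true(all(rec$agree_all >= 0 & rec$agree_all <= 1))
    expect_true(all(abs(rec$group_score) <= 1))
    expect_equal(rec$groupsim_all, rec$cons_all - rec$agree_all, tolerance = 1e-12)
    # |score| bounded by the support contrast
    if (rec$support_defined[1]) {
      expect_true(all(abs(rec$group_score) <=
                        abs(rec$cons_support - rec$agree_support) + 1e-12))
    }
    # shuffling rows changes nothing
    perm <- sample(nrow(col))
    rec_p <- score_column(col[perm, ])
    expect_equal(rec, rec_p)
    # renaming groups only renames keys
    ren <- col
    ren$group <- paste0("z_", ren$group)
    rec_r <- score_column(ren)
    expect_equal(rec_r$group_score, rec$group_score)
  }
  # for fixed contrast C > 0, a non-support group's score increases with its conservation
  base <- c(rep("A", 6), rep("C", 6))
  grp <- c(rep("g1", 6), rep("g2", 6), rep("g3", 6))
  scores <- vapply(0:2, function(k) {
    # conservation of g3 rises with k (2, 3, 4 copies of D among 6 residues)
    g3 <- c(rep("D", k + 2), c("F", "H", "I", "K")[seq_len(4 - k)])
    rec <- score_column(tibble::tibble(residue = c(base, g3), group = grp))
    expect_false(rec$support[rec$group == "g3"])
    rec$group_score[rec$group == "g3"]
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})
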
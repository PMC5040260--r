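small_records <- function(n_replicates = 3, jitter = 0, seed = 21) {
  sim <- make_test_pool(seed = seed)
  plan <- allocate(pool_set_sizes(sim$pool), total = 12, min_per_set = 3, max_per_set = 3)
  msas <- generate_prealigned_ensemble(sim$pool, n_replicates = n_replicates,
                                       column_jitter = jitter, base_seed = seed,
                                       plan = plan)
  list(sim = sim, msas = msas, records = score_ensemble(msas))
}

test_that("aggregation yields one record per replicate per position and rejects holes", {
  x <- small_records(n_replicates = 3)
  recs <- x$records
  expect_equal(nrow(recs), 3 * 10 * 4)  # replicates x positions x groups
  ens <- aggregate_ensemble(recs)
  expect_equal(nrow(ens$scores), 10 * 4)
  expect_equal(ens$n_replicates, 3L)

  expect_error(aggregate_ensemble(rbind(recs, recs[1, ])), "duplicate")
  expect_error(aggregate_ensemble(recs[-1, ]), "missing")
})

test_that("an ensemble of identical alignments reproduces single-alignment values with zero variance", {
  x <- small_records(n_replicates = 4, jitter = 0)
  single <- score_msa(x$msas[[1]])
  ens <- aggregate_ensemble(x$records)
  joined <- dplyr::inner_join(
    ens$scores,
    dplyr::select(single, position = "ref_position", "group", "group_score"),
    by = c("position", "group")
  )
  expect_equal(joined$mean_score, joined$group_score, tolerance = 1e-12)
  expect_equal(joined$var_score, rep(0, nrow(joined)), tolerance = 1e-15)
  expect_equal(joined$q1, joined$q3, tolerance = 1e-15)
  # a single replicate's ensemble equals that record exactly
  ens1 <- aggregate_ensemble(x$records[x$records$replicate == 1, ])
  expect_equal(ens1$scores$mean_score, ens$scores$mean_score, tolerance = 1e-12)
})

test_that("replicate order does not affect aggregation", {
  x <- small_records(n_replicates = 5, jitter = 0.3)
  recs <- x$records
  shuffled <- recs[rev(seq_len(nrow(recs))), ]
  e1 <- aggregate_ensemble(recs)
  e2 <- aggregate_ensemble(shuffled)
  expect_equal(e1$scores, e2$scores)
  expect_equal(e1$positions, e2$positions)
})

test_that("ensemble mean matches the closed form for intermittent support", {
  # group in support in a fraction f of replicates with constant contrast C
  # and off-support weight w: mean score = C * (f + (1 - f) * w)
  C <- 0.8; w <- 0.4; n <- 10; f <- 0.3
  in_support <- rep(c(TRUE, FALSE), times = c(3, 7))
  scores <- ifelse(in_support, C, w * C)
  recs <- tibble::tibble(
    replicate = 1:n, position = 1L, group = "g1",
    group_score = scores, group_conservation = ifelse(in_support, 1, w),
    support = in_support
  )
  expect_equal(ensemble_group_score(recs, 1, "g1"), C * (f + (1 - f) * w),
               tolerance = 1e-12)
  expect_error(ensemble_group_score(recs, 1, "nope"), "no records")
  # direct simulation agrees with the closed form
  set.seed(77)
  sim_scores <- replicate(20000, if (runif(1) < f) C else w * C)
  expect_equal(mean(sim_scores), C * (f + (1 - f) * w), tolerance = 0.01)
})

test_that("distribution summaries use linear interpolation and keep their ordering", {
  s <- summarize_scores(rep(0.25, 9))
  expect_equal(unlist(s), setNames(rep(0.25, 6), names(unlist(s))))
  s2 <- summarize_scores(1:100)
  expect_equal(s2$median, 50.5)
  expect_equal(s2$q1, 25.75)
  expect_equal(s2$q3, 75.25)
  expect_error(summarize_scores(numeric(0)), "empty")
  set.seed(55)
  for (i in 1:25) {
    v <- rnorm(sample(2:40, 1))
    s <- summarize_scores(v)
    expect_true(s$lo95 <= s$q1 && s$q1 <= s$median &&
                  s$median <= s$q3 && s$q3 <= s$hi95)
  }
})

test_that("heterogeneity calls use strict thresholds and the 6-group rule", {
  # 6 conserved + 6 degenerate + 8 intermediate -> heterogeneous
  cons <- c(rep(0.9, 6), rep(0.3, 6), rep(0.55, 8))
  call <- classify_heterogeneity(cons)
  expect_true(call$is_heterogeneous)
  expect_equal(call$n_conserved, 6)
  expect_equal(call$n_degenerate, 6)
  # all groups fully conserved -> not heterogeneous
  expect_false(classify_heterogeneity(rep(1, 20))$is_heterogeneous)
  # 5 conserved + 15 degenerate fails the conserved clause
  expect_false(classify_heterogeneity(c(rep(0.9, 5), rep(0.3, 15)))$is_heterogeneous)
  # boundary: exactly 0.6 is not "> 0.6"; exactly 0.5 is not "< 0.5"
  expect_equal(classify_heterogeneity(c(rep(0.6, 10), rep(0.5, 10)))$n_conserved, 0)
  expect_equal(classify_heterogeneity(c(rep(0.6, 10), rep(0.5, 10)))$n_degenerate, 0)
})

test_that("projections land archetype positions in the expected corners", {
  x <- small_records(n_replicates = 3)
  recs <- x$records
  truth <- x$sim$truth
  proj_all <- project_positions(recs, "all")
  proj_sup <- project_positions(recs, "support")
  ideal_pos <- unique(truth$position[truth$kind == "IDEAL_SDP"])
  global_pos <- unique(truth$position[truth$kind == "GLOBAL_CONSERVED"])
  # ideal SDP: (1, 0); globally conserved: (1, 1)
  expect_equal(proj_all$x[proj_all$position %in% ideal_pos],
               rep(1, length(ideal_pos)))
  expect_equal(proj_all$y[proj_all$position %in% ideal_pos],
               rep(0, length(ideal_pos)))
  expect_equal(proj_all$x[proj_all$position %in% global_pos],
               rep(1, length(global_pos)))
  expect_equal(proj_all$y[proj_all$position %in% global_pos],
               rep(1, length(global_pos)))
  # support-only x never below all-groups x where defined
  j <- dplyr::inner_join(proj_all, proj_sup, by = "position", suffix = c("_all", "_sup"))
  j <- j[!is.na(j$x_sup), ]
  expect_true(all(j$x_sup >= j$x_all - 1e-12))
})

test_that("rank_top takes floor(fraction * N) rows with deterministic ties", {
  scores <- tibble::tibble(position = rep(1:90, each = 4),
                           group = rep(paste0("g", 1:4), 90),
                           mean_score = 0)
  expect_equal(nrow(rank_top(scores, 0.075)), 27L)   # floor(0.075 * 360)
  expect_equal(nrow(rank_top(scores, 1.0)), 360L)
  expect_error(rank_top(scores, 0), "fraction")
  expect_error(rank_top(scores, 1.5), "fraction")
  # ties broken by position then group: all-zero scores give the first keys
  top <- rank_top(scores, 0.05)  # 18 rows
  expect_equal(top$position, rep(1:5, each = 4)[1:18])
  # 360 x 20 keys at 5% -> 360
  big <- tibble::tibble(position = rep(1:360, each = 20),
                        group = rep(sprintf("g%02d", 1:20), 360),
                        mean_score = seq_len(7200) / 7200)
  expect_equal(nrow(rank_top(big, 0.05)), 360L)
  expect_equal(min(rank_top(big, 0.05)$mean_score), (7200 - 359) / 7200)
})

test_that("composition matrices count residues and normalize over non-gap symbols", {
  x <- small_records(n_replicates = 4)
  truth <- x$sim$truth
  global_pos <- min(truth$position[truth$kind == "GLOBAL_CONSERVED"])
  cm <- composition_matrix(x$msas, global_pos, "G01")
  expect_equal(sum(cm$count > 0), 1L)             # one residue only
  expect_equal(max(cm$frequency), 1.0)
  expect_equal(sum(cm$frequency), 1.0)
  expect_equal(attr(cm, "gap_fraction"), 0)

  # a 50/50 two-residue group: frequencies ~ 0.5 within binomial error
  rows_a <- setNames(c(rep("A", 6), rep("C", 6), rep("G", 12), "A"),
                     c(sprintf("p%02d", 1:12), sprintf("q%02d", 1:12), "REF"))
  msa5050 <- sdp_msa(rows_a,
                     setNames(c(rep("P", 12), rep("Q", 12)),
                              c(sprintf("p%02d", 1:12), sprintf("q%02d", 1:12))),
                     "REF")
  cm2 <- composition_matrix(list(msa5050), 1, "P")
  expect_equal(cm2$frequency[cm2$residue == "A"], 0.5)
  expect_equal(cm2$frequency[cm2$residue == "C"], 0.5)

  tab <- composition_table(x$msas, positions = c(1, 2), groups = c("G01", "G02"))
  expect_equal(nrow(tab), 2 * 2 * 20)
  expect_equal(unique(tab$gap_fraction), 0)
})

test_that("tidy, glance, and autoplot expose the fitted ensemble", {
  x <- small_records(n_replicates = 3)
  ens <- aggregate_ensemble(x$records, het_min_count = 2)
  td <- tidy(ens)
  expect_true(all(c("position", "group", "mean_score", "is_heterogeneous") %in% names(td)))
  expect_equal(nrow(td), 40L)
  gl <- glance(ens)
  expect_equal(gl$n_positions, 10L)
  expect_equal(gl$n_replicates, 3L)
  p <- autoplot(ens)
  expect_s3_class(p, "ggplot")
  p2 <- plot_composition(x$msas, 1, "G01")
  expect_s3_class(p2, "ggplot")
})
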
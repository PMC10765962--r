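prep_pg <- function(s, d) {
  prune(fix_symmetric_squares(fix_common(build_abg(s, d))))
}

test_that("pruning separates 2-cycles and preserves the 6-score", {
  fi <- fig_instance()
  pg <- prep_pg(fi$s, fi$d)
  # square 1 was fixed for its 2-cycle; its masked edges are gone
  expect_false(any(pg$present[1L, 3:4]))
  # the 2-cycle is a resolved component of its own
  cls <- classify_components(pg)
  expect_length(cls$C, 1L)
  expect_length(pg$zero_paths, 2L)

  # a pair sharing nothing prunes to an empty graph (only 0-paths remain)
  pg2 <- prep_pg(g1("[1 2 3 4 5]"), g1("(1 3 5 2 4) (1 3 5 2 4)"))
  expect_equal(sum(pg2$present), 0)
  expect_equal(sum(pg2$dnext > 0), 0)
  expect_length(pg2$comps, 0L)

  # pruning never changes the oracle 6-score
  for (seed in 0:99) {
    inst <- random_small_instance(seed)
    abg <- build_abg(inst$s, inst$d)
    pg <- prune(fix_symmetric_squares(fix_common(abg)))
    expect_equal(oracle_best(pg$abg, 6)$score, oracle_best(abg, 6)$score,
                 info = sprintf("seed %d", seed))
  }
})

test_that("component classification obeys the score formula", {
  for (seed in 0:59) {
    inst <- random_small_instance(seed)
    pg <- prep_pg(inst$s, inst$d)
    cls <- classify_components(pg)
    expect_setequal(c(cls$C, cls$P, cls$M), seq_along(pg$comps))
    amb_score <- 0
    for (cid in cls$M) {
      amb_score <- amb_score + sigmak:::comp_sweep(pg, cid)$score2 / 2
    }
    total <- length(cls$C) + (length(cls$P) + length(cls$zero_paths)) / 2 +
      amb_score
    expect_equal(total, oracle_best(pg$abg, 6)$score,
                 info = sprintf("seed %d", seed))
  }
})

test_that("triplets are detected and scored as stated", {
  sat <- triplet_instance(saturated = TRUE)
  pg <- prep_pg(sat$s, sat$d)
  tr <- detect_triplets(pg)
  expect_length(tr, 1L)
  expect_identical(tr[[1L]]$kind, "saturated")
  expect_equal(tr[[1L]]$score, 2)

  uns <- triplet_instance(saturated = FALSE)
  pg2 <- prep_pg(uns$s, uns$d)
  tr2 <- detect_triplets(pg2)
  expect_length(tr2, 1L)
  expect_identical(tr2[[1L]]$kind, "unsaturated")
  expect_equal(tr2[[1L]]$score, 1)

  # removing two D-edges (not one) from the saturated structure leaves a
  # three-square component that is no longer a triplet
  pg3 <- prep_pg(g1("(1 2 3)"), g1("(1) (2) (2) (3) [1] [3]"))
  expect_length(detect_triplets(pg3), 0L)
})

test_that("straight propagation solves cycle-only components", {
  # balanced and unbalanced bubbles from random circular instances agree
  # with local exhaustion
  found <- 0L
  for (seed in 0:199) {
    cfg <- generator_config(n_families = 6L + seed %% 5L, n_linear = 0L,
                            n_circular = 1L + seed %% 2L,
                            n_dcj = 2L + seed %% 7L, seed = seed)
    inst <- random_instance(cfg)
    pg <- prep_pg(inst$s, inst$d)
    trip <- vapply(detect_triplets(pg), `[[`, integer(1), "comp")
    for (cid in classify_components(pg)$M) {
      if (cid %in% trip) next
      pls <- sigmak:::comp_players(pg, cid)
      if (any(vapply(pls, `[[`, character(1), "type") == "path")) next
      sb <- straight_bubble_solution(pg, cid)
      expect_equal(max(sb$score, sb$score_alt),
                   sigmak:::comp_sweep(pg, cid)$score2 / 2,
                   info = sprintf("seed %d comp %d", seed, cid))
      found <- found + 1L
    }
  }
  expect_gt(found, 5L)
})

test_that("intersection graphs have the stated players and weights", {
  # two disjoint valid 2-paths resolve their square by pruning and are
  # classified as resolved path components, each worth 1/2
  pg <- prep_pg(g1("[1 2]"), g1("[2 2 1 1]"))
  cls <- classify_components(pg)
  expect_length(cls$P, 2L)
  expect_length(cls$M, 0L)
  expect_equal(oracle_best(pg$abg, 6)$score, 1)

  # MWIS weight equals the component 6-score on random instances; every
  # path player enters with weight 1/2 and every cycle with weight 1
  n_paths <- 0L
  for (seed in 0:79) {
    inst <- random_medium_instance(seed)
    pg <- prep_pg(inst$s, inst$d)
    for (cid in classify_components(pg)$M) {
      if (pg$comps[[cid]]$n_amb > 14L) next
      ig <- build_intersection_graph(pg, cid)
      types <- vapply(ig$players, `[[`, character(1), "type")
      expect_identical(ig$w2, ifelse(types == "cycle", 2L, 1L))
      n_paths <- n_paths + sum(types == "path")
      fl <- solve_flows(ig)
      expect_equal(fl$weight, sigmak:::comp_sweep(pg, cid)$score2 / 2,
                   info = sprintf("seed %d comp %d", seed, cid))
      # and the structural MWIS agrees with brute force
      if (length(ig$players) <= 16L) {
        bf <- sigmak:::mwis_brute(length(ig$players), ig$w2, ig$adj)
        expect_equal(fl$weight2, bf$weight2)
      }
    }
  }
  expect_gt(n_paths, 0L)
})

test_that("two 6-cycles sharing a DSD-path intersect in the graph", {
  # unsaturated triplet: four 6-cycles pairwise sharing the same D-edge
  uns <- triplet_instance(saturated = FALSE)
  pg <- prep_pg(uns$s, uns$d)
  cls <- classify_components(pg)
  ig <- build_intersection_graph(pg, cls$M[1L])
  expect_length(ig$players, 4L)
  expect_true(all(ig$w2 == 2L))
  expect_true(all(vapply(seq_along(ig$adj), function(i)
    length(ig$adj[[i]]) == 3L, logical(1))))   # pairwise intersecting
  expect_equal(solve_flows(ig)$weight, 1)
})

test_that("solve_sigma6 equals the oracle on the randomized suite", {
  for (seed in 0:169) {
    inst <- random_small_instance(seed)
    abg <- build_abg(inst$s, inst$d)
    res <- solve_sigma6(abg)
    expect_equal(res$score, oracle_best(abg, 6)$score,
                 info = sprintf("seed %d", seed))
    expect_equal(k_score(abg, res$tau, 6), res$score)
  }
})

test_that("the structural routes agree with the oracle when forced", {
  # a tiny cap pushes every component with three or more ambiguous squares
  # through the straight-bubble or intersection-graph machinery
  for (seed in 1000:1199) {
    inst <- random_medium_instance(seed)
    abg <- build_abg(inst$s, inst$d)
    if (sum(abg$fixed < 0L) > 18L) next
    res <- solve_sigma6(abg, exhaustive_cap = 2L)
    expect_equal(res$score, oracle_best(abg, 6)$score,
                 info = sprintf("seed %d", seed))
  }
})

test_that("sigma scores are monotone across k on every instance", {
  for (seed in 0:59) {
    inst <- random_small_instance(seed)
    abg <- build_abg(inst$s, inst$d)
    s2 <- 2 * abg$n_star - double_distance_sigma2(inst$s, inst$d)
    s4 <- solve_sigma4(abg)$score
    s6 <- solve_sigma6(abg)$score
    expect_true(s2 <= s4 && s4 <= s6)
  }
})
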
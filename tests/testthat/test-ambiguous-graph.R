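test_that("the ambiguous graph of the worked instance has the stated shape", {
  fi <- fig_instance()
  abg <- build_abg(fi$s, fi$d)
  expect_equal(abg$n_star, 3)
  expect_equal(abg$a_star, 2)                      # a* = n* - kappa(S)
  expect_equal(abg$a_star, abg$n_star - abg$kappa_s)
  expect_equal(sum(abg$dnext > 0) / 2, 4)          # four D-edges
  expect_setequal(abg$labels[abg$s_telo], c("1at", "1bt", "3ah", "3bh"))
  expect_setequal(abg$labels[abg$d_telo], c("1at", "1bh", "3bh", "2bh"))
  expect_equal(sum(abg$s_telo), 4 * abg$kappa_s)
  expect_equal(sum(abg$d_telo), 2 * abg$kappa_d)
})

test_that("degenerate ambiguous graphs are handled", {
  # no adjacency in S at all: no squares, no D-edges, isolated vertices
  abg <- build_abg(g1("[1]"), g1("[1] [1]"))
  expect_equal(abg$a_star, 0)
  expect_equal(sum(abg$dnext), 0)
  expect_length(abg$labels, 4L)

  # a single circular gene gives one square and two D-edges
  abg2 <- build_abg(g1("(1)"), g1("(1) (1)"))
  expect_equal(abg2$a_star, 1)
  expect_equal(sum(abg2$dnext > 0) / 2, 2)

  expect_error(build_abg(g1("[1 2]"), g1("[1 1 3 3]")), "differ")
})

test_that("induced graphs decompose as stated for the worked instance", {
  fi <- fig_instance()
  abg <- build_abg(fi$s, fi$d)

  tau <- as_solution(c("parallel", "crossed"), abg)
  cs <- decompose(induce(abg, tau))
  expect_identical(cs$cycle_len, 2L)
  expect_identical(sort(cs$path_len), c(0L, 0L, 2L, 4L))

  tpar <- as_solution(c("parallel", "parallel"), abg)
  cp <- decompose(induce(abg, tpar))
  expect_identical(cp$cycle_len, 2L)
  expect_identical(sort(cp$path_len), c(0L, 0L, 3L, 3L))

  # k-scores derived from those censuses
  expect_equal(k_score(abg, tau, 6), 3)
  expect_equal(k_score(abg, tau, 2), 2)
  expect_equal(k_score(abg, tpar, 6), 2)

  # switching changes exactly one square's edges
  b1 <- induce(abg, tau)
  b2 <- induce(abg, switch_solution(tau, 2L))
  changed <- which(b1$next1 != b2$next1)
  expect_setequal(abg$labels[changed], c("2ah", "2bh", "3at", "3bt"))
  expect_identical(b1$next2, b2$next2)
})

test_that("switching is an involution and full switching complements", {
  abg <- build_abg(fig_instance()$s, fig_instance()$d)
  tau <- as_solution(c("parallel", "crossed"), abg)
  expect_identical(switch_solution(switch_solution(tau, 1L), 1L), tau)
  expect_identical(unclass(switch_solution(as_solution(c(0L, 1L), abg), 1L)),
                   c("crossed", "crossed"))
  flipped <- Reduce(switch_solution, seq_along(tau), tau)
  expect_identical(unclass(flipped), c("crossed", "parallel"))
  expect_error(switch_solution(tau, 3L), "out of range")
})

test_that("induce rejects solutions conflicting with fixed squares", {
  abg <- fix_common(build_abg(fig_instance()$s, fig_instance()$d))
  expect_identical(abg$fix_reason[1L], "common")
  expect_error(induce(abg, as_solution(c("crossed", "parallel"), abg)),
               "conflicts with fixed")
})

test_that("the oracle reproduces the worked-instance optima", {
  fi <- fig_instance()
  abg <- build_abg(fi$s, fi$d)
  expect_equal(oracle_best(abg, 2)$score, 2)
  expect_equal(oracle_best(abg, 4)$score, 2.5)
  expect_equal(oracle_best(abg, 6)$score, 3)
  # distances: 2 n* - score
  expect_equal(double_distance(fi$s, fi$d, 2)$distance, 4)
  expect_equal(double_distance(fi$s, fi$d, 4)$distance, 3.5)
  expect_equal(double_distance(fi$s, fi$d, 6)$distance, 3)
  expect_equal(double_distance(fi$s, fi$d, 6, method = "oracle")$distance, 3)
  # general even k falls back to plain enumeration
  expect_equal(double_distance(fi$s, fi$d, 8, method = "oracle")$distance, 3)
  expect_error(double_distance(fi$s, fi$d, 8), "oracle")
  expect_error(double_distance(fi$s, fi$d, Inf), "oracle")
})

test_that("the oracle refuses oversized instances", {
  cfg <- generator_config(n_families = 24L, n_linear = 1L, n_circular = 1L,
                          n_dcj = 10L, seed = 3L)
  inst <- random_instance(cfg)
  abg <- build_abg(inst$s, inst$d)
  expect_error(oracle_best(abg, 6), "refusing")
  expect_error(oracle_best(abg, 6, max_squares = 5L), "refusing")
})

test_that("a doubling of S is at double distance zero for every k", {
  for (seed in c(1, 5, 9)) {
    s <- random_small_instance(seed)$s
    cfg <- generator_config(n_families = length(family_set(s)),
                            n_linear = 1L, n_circular = 0L,
                            n_dcj = 0L, seed = seed)
    d <- random_duplicated_from(s, cfg)
    for (k in c(2, 4, 6)) {
      expect_equal(double_distance(s, d, k)$distance, 0)
    }
    expect_equal(double_distance(s, d, Inf, method = "oracle")$distance, 0)
  }
})

test_that("the sigma-2 closed formula matches its definition and the oracle", {
  fi <- fig_instance()
  expect_equal(double_distance_sigma2(fi$s, fi$d), 4)
  for (seed in 1:30) {
    inst <- random_small_instance(seed)
    abg <- build_abg(inst$s, inst$d)
    expect_equal(double_distance_sigma2(inst$s, inst$d),
                 2 * abg$n_star - oracle_best(abg, 2)$score)
  }
})

test_that("k-scores agree with the induce/decompose pipeline everywhere", {
  for (seed in 1:15) {
    inst <- random_small_instance(seed)
    abg <- build_abg(inst$s, inst$d)
    tau <- withr::with_seed(seed,
      as_solution(sample(0:1, abg$a_star, replace = TRUE), abg))
    for (k in c(2, 4, 6, Inf)) {
      expect_equal(k_score(abg, tau, k),
                   sigma_score(decompose(induce(abg, tau)), k))
    }
    # cumulative in k
    expect_true(k_score(abg, tau, 2) <= k_score(abg, tau, 4))
    expect_true(k_score(abg, tau, 4) <= k_score(abg, tau, 6))
  }
})

test_that("scores are invariant under the singularization of D", {
  withr::with_seed(42L, {
    for (seed in 1:12) {
      inst <- random_small_instance(seed)
      base <- vapply(c(2, 4, 6), function(k)
        oracle_best(build_abg(inst$s, inst$d), k)$score, numeric(1))
      for (r in 1:3) {
        d2 <- sigmak:::resingularize_random(singularize(inst$d))
        got <- vapply(c(2, 4, 6), function(k)
          oracle_best(build_abg(inst$s, d2), k)$score, numeric(1))
        expect_equal(got, base)
      }
    }
  })
})

test_that("oracle scores never decrease with k", {
  for (seed in 1:25) {
    inst <- random_small_instance(seed)
    abg <- build_abg(inst$s, inst$d)
    sc <- vapply(list(2, 4, 6, Inf), function(k)
      oracle_best(abg, k)$score, numeric(1))
    expect_true(all(diff(sc) >= 0))
  }
})
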
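test_that("the generator is reproducible and honours its configuration", {
  cfg <- generator_config(n_families = 6L, n_linear = 1L, n_circular = 2L,
                          n_dcj = 3L, seed = 42L)
  a <- random_singular_genome(cfg)
  b <- random_singular_genome(cfg)
  expect_identical(format_genome(a), format_genome(b))
  expect_identical(classify_genome(a), "singular")
  expect_equal(sum(!vapply(a$chromosomes, `[[`, logical(1), "circular")), 1)
  expect_equal(sum(vapply(a$chromosomes, `[[`, logical(1), "circular")), 2)
  expect_equal(length(adjacency_multiset(a)) + length(telomere_multiset(a)) / 2,
               6)
  # identical config -> byte-identical files
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_genomes(list(random_instance(cfg)$s, random_instance(cfg)$d), f1)
  write_genomes(list(random_instance(cfg)$s, random_instance(cfg)$d), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(generator_config(n_families = 2L, n_linear = 2L,
                                n_circular = 1L), "at least")
  expect_error(generator_config(n_linear = 0L, n_circular = 0L),
               "at least one chromosome")
})

test_that("generated pairs are valid double-distance instances", {
  for (seed in 1:30) {
    inst <- random_small_instance(seed)
    expect_identical(classify_genome(inst$s), "singular")
    expect_true(classify_genome(inst$d) %in% c("duplicated", "doubled"))
    abg <- build_abg(inst$s, inst$d)     # validates the family sets
    expect_equal(abg$n_star, length(family_set(inst$s)))
  }
})

test_that("DCJ mechanics match the definition", {
  # the classic inversion: cut (1|2) and (3|4), rejoin crosswise
  at <- sigmak:::genome_to_at(singularize(g1("[1 2 3 4] [1 2 3 4]")))
  # find the two cuts on the copy-a chromosome and rejoin them crosswise
  partner <- at$partner
  eid <- function(lab) {
    labs <- paste0(at$genes$family, at$genes$copy)
    2L * match(sub("[ht]$", "", lab), labs) - (substring(lab, nchar(lab)) == "h")
  }
  p <- eid("1ah"); q <- eid("2at"); r <- eid("3ah"); s <- eid("4at")
  expect_equal(partner[p], q)
  expect_equal(partner[r], s)
  partner[p] <- r; partner[r] <- p
  partner[q] <- s; partner[s] <- q
  at$partner <- partner
  got <- sigmak:::at_to_genome(at)
  expect_true(any(vapply(got$chromosomes, function(ch)
    genome_equal(sigmak:::strip_copies(genome(list(ch))),
                 g1("[1 -3 -2 4]")), logical(1))))

  # n_dcj = 0: D is a doubling of S, all double distances are zero
  for (seed in 1:8) {
    cfg <- generator_config(n_families = 5L, n_linear = 1L, n_circular = 1L,
                            n_dcj = 0L, seed = seed)
    inst <- random_instance(cfg)
    expect_identical(classify_genome(inst$d), "doubled")
    for (k in c(2, 4, 6)) expect_equal(double_distance(inst$s, inst$d, k)$distance, 0)
  }

  # each DCJ changes the DCJ double distance by at most one
  for (seed in 1:25) {
    topo <- seed %% 3L
    cfg <- generator_config(n_families = 4L + seed %% 3L,
                            n_linear = c(0L, 2L, 1L)[topo + 1L],
                            n_circular = c(2L, 0L, 1L)[topo + 1L],
                            n_dcj = seed %% 5L, seed = seed)
    inst <- random_instance(cfg)
    dd <- double_distance(inst$s, inst$d, Inf, method = "oracle")$distance
    expect_lte(dd, cfg$n_dcj)
  }
})

test_that("the command line prints exact rationals and round-trips", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "A.txt"); fb <- file.path(dir, "B.txt")
  writeLines("(1 -3 2) [4]", fa)
  writeLines("(1 2) [3 -4]", fb)
  out <- capture.output(status <- cli_main(c("distance", "--k", "2", fa, fb)))
  expect_equal(status, 0L)
  expect_identical(out, "2.5")
  expect_equal(as.numeric(out), sigma_distance(g1("(1 -3 2) [4]"),
                                               g1("(1 2) [3 -4]"), 2))
  out <- capture.output(cli_main(c("distance", "--k", "inf", fa, fb)))
  expect_identical(out, "2")

  fs <- file.path(dir, "S.txt"); fd <- file.path(dir, "D.txt")
  writeLines("[1 2 3]", fs)
  writeLines("[1 2 -3 1] [-3 2]", fd)
  out <- suppressMessages(
    capture.output(cli_main(c("double-distance", "--k", "6", fs, fd))))
  expect_identical(out, "3")

  # generate writes parseable files; distance errors exit non-zero
  suppressMessages(cli_main(c("generate", "--families", "6", "--seed", "5",
                              "--out-s", fs, "--out-d", fd)))
  inst <- list(s = parse_genome(readLines(fs))[[1L]],
               d = parse_genome(readLines(fd))[[1L]])
  expect_identical(classify_genome(inst$s), "singular")
  expect_true(classify_genome(inst$d) %in% c("duplicated", "doubled"))
  expect_equal(suppressMessages(cli_main(c("distance", "--k", "2", fs, fd))), 1L)
  expect_equal(suppressMessages(cli_main(c("nonsense"))), 2L)
})

test_that("DOT export covers all graph kinds", {
  fi <- fig_instance()
  bg <- build_breakpoint_graph(fig_pair()$s1, fig_pair()$s2)
  lines <- write_dot(bg)
  expect_true(any(grepl("color=blue", lines)))
  expect_true(any(grepl("fillcolor=purple", lines)))   # common telomere

  abg <- build_abg(fi$s, fi$d)
  expect_true(any(grepl("color=red", write_dot(abg))))
  pg <- prune(fix_symmetric_squares(fix_common(abg)))
  expect_true(any(grepl("graph pruned_graph", write_dot(pg))))

  uns <- triplet_instance(saturated = FALSE)
  pg2 <- prune(fix_symmetric_squares(fix_common(build_abg(uns$s, uns$d))))
  ig <- build_intersection_graph(pg2, classify_components(pg2)$M[1L])
  dl <- write_dot(ig)
  expect_true(any(grepl("6-cycle", dl)))
  f <- withr::local_tempfile(fileext = ".dot")
  write_dot(bg, f)
  expect_true(file.exists(f))
})
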
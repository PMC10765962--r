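# Shared fixtures: the worked examples used throughout the tests, plus a
# stratified random-instance maker around the seeded generator.

g1 <- function(text) parse_genome(text)[[1L]]

# canonical pair with breakpoint distance 2.5 and DCJ distance 2
fig_pair <- function() list(s1 = g1("(1 -3 2) [4]"), s2 = g1("(1 2) [3 -4]"))

# singular/duplicated pair whose ambiguous graph has two squares
fig_instance <- function() list(s = g1("[1 2 3]"),
                                d = g1("[1 2 -3 1] [-3 2]"))

# triplet components: three squares pairwise joined by paralogous D-edges
triplet_instance <- function(saturated = TRUE) {
  list(s = g1("(1 2 3)"),
       d = if (saturated) g1("(1) (1) (2) (2) (3) (3)")
       else g1("(1) (2) (2) (3) (3) [1]"))
}

# stratified small instance: circular-only / linear-only / mixed by seed
random_small_instance <- function(seed) {
  topo <- seed %% 3L
  cfg <- generator_config(
    n_families = 4L + (seed %% 7L),
    n_linear = c(0L, 2L, 1L)[topo + 1L],
    n_circular = c(2L, 0L, 1L)[topo + 1L],
    n_dcj = seed %% 9L,
    seed = seed)
  random_instance(cfg)
}

# larger mixed instance likely to contain multi-square ambiguous components
random_medium_instance <- function(seed) {
  nl <- seed %% 4L; nc <- (seed %/% 4L) %% 3L
  if (nl + nc == 0L) nl <- 1L
  cfg <- generator_config(
    n_families = 8L + (seed %% 7L), n_linear = nl, n_circular = nc,
    n_dcj = 6L + seed %% 12L, seed = seed)
  random_instance(cfg)
}

random_canonical_pair <- function(seed) {
  cfg1 <- generator_config(n_families = 5L + seed %% 6L,
                           n_linear = seed %% 3L,
                           n_circular = 1L + (seed %/% 3L) %% 2L,
                           seed = seed)
  cfg2 <- cfg1; cfg2$seed <- seed + 7919L
  list(s1 = random_singular_genome(cfg1), s2 = random_singular_genome(cfg2))
}

expect_score <- function(object, expected) {
  expect_equal(object, expected, tolerance = 0)
}
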
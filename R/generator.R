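# Seeded instance generators.  A random singular genome scatters n distinct
# families over the requested linear and circular chromosomes with random
# orientations; a random duplicated genome is obtained by realizing one
# doubling of a singular genome and applying a number of random DCJ
# operations (emulating rearrangement after a whole-genome duplication),
# then stripping the copy labels.

#' Generator configuration
#'
#' @param n_families number of gene families.
#' @param n_linear,n_circular chromosome counts (at least one chromosome in
#'   total; `n_families >= n_linear + n_circular`).
#' @param n_dcj number of random DCJ operations applied after doubling in
#'   [random_duplicated_from()].
#' @param seed integer seed; all generator randomness derives from it.
#' @param format serialization dialect for [write_genomes()].
#' @return A list of class `sigmak_gencfg`.
#' @export
generator_config <- function(n_families = 10L, n_linear = 1L, n_circular = 1L,
                             n_dcj = 5L, seed = 1L,
                             format = c("brackets", "unimog")) {
  format <- match.arg(format)
  n_families <- as.integer(n_families)
  n_linear <- as.integer(n_linear); n_circular <- as.integer(n_circular)
  if (n_linear + n_circular < 1L) stop("need at least one chromosome")
  if (n_families < n_linear + n_circular) {
    stop("n_families must be at least n_linear + n_circular")
  }
  structure(list(n_families = n_families, n_linear = n_linear,
                 n_circular = n_circular, n_dcj = as.integer(n_dcj),
                 seed = as.integer(seed), format = format),
            class = "sigmak_gencfg")
}

#' Generate a random singular genome
#'
#' @param cfg a [generator_config()].
#' @return A singular [genome()] with exactly the configured chromosome
#'   counts; deterministic for a fixed seed.
#' @export
random_singular_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sigmak_gencfg"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_families
    k <- cfg$n_linear + cfg$n_circular
    fams <- sample(as.character(seq_len(n)))
    # split the shuffled families into k non-empty blocks
    cuts <- if (k > 1L) sort(sample(seq_len(n - 1L), k - 1L)) else integer(0)
    starts <- c(1L, cuts + 1L); stops <- c(cuts, n)
    circ <- sample(c(rep(FALSE, cfg$n_linear), rep(TRUE, cfg$n_circular)))
    chroms <- lapply(seq_len(k), function(i) {
      f <- fams[starts[i]:stops[i]]
      new_chromosome(f, sample(c(TRUE, FALSE), length(f), replace = TRUE),
                     circular = circ[i])
    })
    genome(chroms, name = sprintf("S%d", cfg$seed))
  })
}

# realize one doubling of a singular genome: each linear chromosome is
# copied; each circular chromosome is either copied into two circles or
# concatenated into a single circle (chosen by `concat`)
realize_doubling <- function(s, concat = NULL) {
  circ_idx <- which(vapply(s$chromosomes, `[[`, logical(1), "circular"))
  if (is.null(concat)) concat <- rep(FALSE, length(circ_idx))
  stopifnot(length(concat) == length(circ_idx))
  chroms <- list()
  ci <- 0L
  for (ch in s$chromosomes) {
    if (ch$circular) {
      ci <- ci + 1L
      if (concat[ci]) {
        chroms[[length(chroms) + 1L]] <- new_chromosome(
          c(ch$family, ch$family), c(ch$rev, ch$rev),
          c(rep("a", length(ch$family)), rep("b", length(ch$family))),
          circular = TRUE)
        next
      }
    }
    for (cp in c("a", "b")) {
      chroms[[length(chroms) + 1L]] <- new_chromosome(
        ch$family, ch$rev, rep(cp, length(ch$family)), circular = ch$circular)
    }
  }
  genome(chroms, name = s$name)
}

# ---- adjacency/telomere representation for DCJ sampling ----------------
#
# Extremities are integers: gene i (a row of `genes`) has head 2i-1 and
# tail 2i.  `partner[e]` is the extremity adjacent to e, or 0 when e is a
# telomere.  This makes a single DCJ O(1).

genome_to_at <- function(g) {
  fam <- unlist(lapply(g$chromosomes, `[[`, "family"), use.names = FALSE)
  cp <- unlist(lapply(g$chromosomes, `[[`, "copy"), use.names = FALSE)
  genes <- unique(data.frame(family = fam, copy = cp,
                             stringsAsFactors = FALSE))
  genes <- genes[order(genes$family, genes$copy), , drop = FALSE]
  lab <- paste0(genes$family, genes$copy)
  eid <- stats::setNames(seq_len(2L * nrow(genes)),
                         as.vector(rbind(paste0(lab, "h"), paste0(lab, "t"))))
  partner <- integer(2L * nrow(genes))
  ap <- adjacency_pairs(g)
  if (nrow(ap) > 0L) {
    i <- eid[ap[, 1L]]; j <- eid[ap[, 2L]]
    partner[i] <- j; partner[j] <- i
  }
  list(partner = partner, genes = genes)
}

at_to_genome <- function(at, name = NULL) {
  genes <- at$genes
  ng <- nrow(genes)
  partner <- at$partner
  gene_of <- function(e) (e + 1L) %/% 2L
  other <- function(e) if (e %% 2L == 1L) e + 1L else e - 1L
  used <- logical(ng)
  chroms <- list()
  walk <- function(start_ext, circular) {
    gis <- integer(ng); revs <- logical(ng)
    len <- 0L
    ext <- start_ext
    repeat {
      gi <- gene_of(ext)
      used[gi] <<- TRUE
      len <- len + 1L
      gis[len] <- gi
      revs[len] <- ext %% 2L == 1L     # entered at head => reversed
      nx <- partner[other(ext)]
      if (nx == 0L) {
        stopifnot(!circular)
        break
      }
      if (circular && nx == start_ext) break
      ext <- nx
    }
    gis <- gis[seq_len(len)]
    new_chromosome(genes$family[gis], revs[seq_len(len)], genes$copy[gis],
                   circular = circular)
  }
  for (tl in which(partner == 0L)) {      # linear chromosomes
    if (used[gene_of(tl)]) next
    chroms[[length(chroms) + 1L]] <- walk(tl, circular = FALSE)
  }
  for (gi in seq_len(ng)) {               # remaining genes are circular
    if (used[gi]) next
    chroms[[length(chroms) + 1L]] <- walk(2L * gi - 1L, circular = TRUE)
  }
  genome(chroms, name = name)
}

# sample one adjacency-or-telomere element uniformly: rejection over
# extremities (an adjacency would otherwise be drawn twice as often)
sample_element <- function(partner, ne) {
  repeat {
    e <- sample.int(ne, 1L)
    if (partner[e] == 0L) return(e)                 # telomere
    if (stats::runif(1) < 0.5) return(min(e, partner[e]))   # adjacency
  }
}

# one random DCJ: cut two distinct adjacencies or telomeres and rejoin the
# open extremities differently
random_dcj <- function(partner) {
  ne <- length(partner)
  if (ne < 2L) return(partner)
  e1 <- sample_element(partner, ne)
  repeat {
    e2 <- sample_element(partner, ne)
    if (e2 != e1) break
  }
  a1 <- partner[e1] > 0L; a2 <- partner[e2] > 0L
  if (a1 && a2) {
    p <- e1; q <- partner[e1]; r <- e2; s <- partner[e2]
    if (sample(2L, 1L) == 1L) {          # {p,r}, {q,s}
      partner[p] <- r; partner[r] <- p; partner[q] <- s; partner[s] <- q
    } else {                             # {p,s}, {q,r}
      partner[p] <- s; partner[s] <- p; partner[q] <- r; partner[r] <- q
    }
  } else if (!a1 && !a2) {               # fusion of two telomeres
    partner[e1] <- e2; partner[e2] <- e1
  } else {
    if (!a1) { tmp <- e1; e1 <- e2; e2 <- tmp }
    p <- e1; q <- partner[e1]; r <- e2
    if (sample(2L, 1L) == 1L) {          # {p,r}, q telomere
      partner[p] <- r; partner[r] <- p; partner[q] <- 0L
    } else {                             # {q,r}, p telomere
      partner[q] <- r; partner[r] <- q; partner[p] <- 0L
    }
  }
  partner
}

#' Generate a random duplicated genome from a singular one
#'
#' Chooses one doubling of `s` uniformly (each circular chromosome is
#' independently copied or concatenated), applies `cfg$n_dcj` random DCJ
#' operations on the adjacency/telomere representation (cuts sampled
#' uniformly over adjacencies and telomeres, matching the DCJ definition
#' including telomeric cuts), and strips the copy labels.
#'
#' @param s a singular [genome()].
#' @param cfg a [generator_config()]; `cfg$seed` drives the randomness.
#' @return A duplicated [genome()] over the families of `s`.
#' @export
random_duplicated_from <- function(s, cfg) {
  stopifnot(inherits(cfg, "sigmak_gencfg"))
  if (classify_genome(s) != "singular") stop("`s` must be singular")
  withr::with_seed(cfg$seed + 423779L, {
    nc <- n_circular(s)
    b <- realize_doubling(s, concat = sample(c(TRUE, FALSE), nc, replace = TRUE))
    at <- genome_to_at(b)
    for (i in seq_len(cfg$n_dcj)) at$partner <- random_dcj(at$partner)
    strip_copies(at_to_genome(at, name = sprintf("D%d", cfg$seed)))
  })
}

#' Generate a matched singular/duplicated instance
#'
#' @param cfg a [generator_config()].
#' @return List with `s` (singular genome) and `d` (duplicated genome).
#' @export
random_instance <- function(cfg) {
  s <- random_singular_genome(cfg)
  list(s = s, d = random_duplicated_from(s, cfg))
}

#' Write genomes to a file
#'
#' @param genomes list of [genome()] objects.
#' @param path output file.
#' @param format `"brackets"` or `"unimog"`.
#' @return `path`, invisibly.
#' @export
write_genomes <- function(genomes, path, format = c("brackets", "unimog")) {
  format <- match.arg(format)
  lines <- unlist(lapply(genomes, format_genome, format = format))
  writeLines(lines, path)
  invisible(path)
}
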
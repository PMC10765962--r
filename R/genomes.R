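# Genome representation: a genome is a multiset of chromosomes, each an
# ordered sequence of oriented genes, linear or circular.  Internally a
# chromosome is a list with parallel vectors `family` (character), `rev`
# (logical orientation) and `copy` ("" before singularization, "a"/"b"
# after), plus a `circular` flag.

new_chromosome <- function(family, rev, copy = rep("", length(family)),
                           circular = FALSE) {
  stopifnot(length(family) >= 1L, length(rev) == length(family),
            length(copy) == length(family))
  structure(list(family = as.character(family), rev = as.logical(rev),
                 copy = as.character(copy), circular = isTRUE(circular)),
            class = "sigmak_chromosome")
}

#' Construct a genome from chromosomes
#'
#' A genome is a multiset of chromosomes.  Each chromosome is created from a
#' signed gene string such as `"1 -3 2"` together with a topology flag, or
#' taken as an already-built chromosome object (as returned by
#' [parse_genome()] components).
#'
#' @param chromosomes list of chromosomes.
#' @param name optional genome name (single token, no whitespace).
#' @return An object of class `sigmak_genome`.
#' @seealso [parse_genome()] for the text format.
#' @export
genome <- function(chromosomes, name = NULL) {
  stopifnot(is.list(chromosomes))
  for (ch in chromosomes) {
    if (!inherits(ch, "sigmak_chromosome")) {
      stop("all elements of `chromosomes` must be sigmak_chromosome objects")
    }
  }
  structure(list(chromosomes = chromosomes, name = name),
            class = "sigmak_genome")
}

is_genome <- function(x) inherits(x, "sigmak_genome")

#' @export
print.sigmak_genome <- function(x, ...) {
  nm <- if (is.null(x$name)) "<unnamed>" else x$name
  cat(sprintf("genome %s: %d chromosome(s)\n", nm, length(x$chromosomes)))
  cat(format_genome(x), sep = "\n")
  invisible(x)
}

# ---- parsing -----------------------------------------------------------

RESERVED_CHARS_RE <- "[][()>[:space:]-]"

token_ok <- function(tok) {
  nzchar(tok) & !grepl(RESERVED_CHARS_RE, tok)
}

#' Parse genomes from text
#'
#' Reads one or more genomes from a plain-text gene-order description.  In the
#' default `"brackets"` format an optional `">name"` line starts a new genome;
#' chromosomes are whitespace-separated signed gene tokens flanked by square
#' brackets (`[1 -3 2]`, linear) or parentheses (`(4)`, circular).  Reverse
#' orientation is written with a `-` prefix.  Several chromosomes may share a
#' line.  In the `"unimog"` dialect each chromosome line is terminated by `|`
#' (linear) or `)` (circular) instead.
#'
#' @param text character scalar (possibly multi-line) or character vector of
#'   lines with the genome description.
#' @param format `"brackets"` (default) or `"unimog"`.
#' @return A list of [genome()] objects in file order.
#' @examples
#' gs <- parse_genome("[1 -3 2]\n(4)")
#' adjacency_multiset(gs[[1]])
#' @export
parse_genome <- function(text, format = c("brackets", "unimog")) {
  format <- match.arg(format)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  if (format == "unimog") {
    return(parse_genome_unimog(lines))
  }
  genomes <- list()
  cur_name <- NULL
  cur_chroms <- list()
  open <- NULL        # NULL, "[" or "("
  open_line <- NA_integer_
  cur_tokens <- character()
  flush_genome <- function() {
    if (length(cur_chroms) > 0L || !is.null(cur_name)) {
      genomes[[length(genomes) + 1L]] <<- genome(cur_chroms, name = cur_name)
    }
    cur_chroms <<- list()
  }
  close_chrom <- function(circular, lineno) {
    if (length(cur_tokens) == 0L) {
      stop(sprintf("parse error at line %d: empty chromosome", lineno))
    }
    rev <- startsWith(cur_tokens, "-")
    fam <- ifelse(rev, substring(cur_tokens, 2L), cur_tokens)
    bad <- which(!token_ok(fam))
    if (length(bad) > 0L) {
      stop(sprintf("parse error at line %d: bad gene token '%s'",
                   lineno, cur_tokens[bad[1L]]))
    }
    cur_chroms[[length(cur_chroms) + 1L]] <<-
      new_chromosome(fam, rev, circular = circular)
    cur_tokens <<- character()
  }
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    if (grepl("^\\s*>", line)) {
      if (!is.null(open)) {
        stop(sprintf("parse error at line %d: unclosed chromosome opened at line %d",
                     i, open_line))
      }
      flush_genome()
      cur_name <- trimws(sub("^\\s*>", "", line))
      if (!nzchar(cur_name)) cur_name <- NULL
      next
    }
    # surround brackets with spaces, then tokenize
    line <- gsub("([][()])", " \\1 ", line)
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    for (tok in toks) {
      if (tok %in% c("[", "(")) {
        if (!is.null(open)) {
          stop(sprintf("parse error at line %d: nested '%s' (chromosome opened at line %d)",
                       i, tok, open_line))
        }
        open <- tok
        open_line <- i
      } else if (tok %in% c("]", ")")) {
        want <- if (tok == "]") "[" else "("
        if (is.null(open) || open != want) {
          stop(sprintf("parse error at line %d: unmatched '%s'", i, tok))
        }
        close_chrom(circular = (tok == ")"), lineno = i)
        open <- NULL
      } else {
        if (is.null(open)) {
          stop(sprintf("parse error at line %d: gene token '%s' outside a chromosome",
                       i, tok))
        }
        cur_tokens <- c(cur_tokens, tok)
      }
    }
  }
  if (!is.null(open)) {
    stop(sprintf("parse error: chromosome opened at line %d never closed", open_line))
  }
  flush_genome()
  if (length(genomes) == 0L) stop("parse error: no genome found in input")
  genomes
}

parse_genome_unimog <- function(lines) {
  genomes <- list()
  cur_name <- NULL
  cur_chroms <- list()
  flush_genome <- function() {
    if (length(cur_chroms) > 0L || !is.null(cur_name)) {
      genomes[[length(genomes) + 1L]] <<- genome(cur_chroms, name = cur_name)
    }
    cur_chroms <<- list()
  }
  for (i in seq_along(lines)) {
    line <- trimws(sub("#.*$", "", lines[i]))
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush_genome()
      cur_name <- trimws(substring(line, 2L))
      if (!nzchar(cur_name)) cur_name <- NULL
      next
    }
    last <- substring(line, nchar(line))
    if (!last %in% c("|", ")")) {
      stop(sprintf("parse error at line %d: chromosome must end with '|' or ')'", i))
    }
    body <- trimws(substring(line, 1L, nchar(line) - 1L))
    toks <- strsplit(body, "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) {
      stop(sprintf("parse error at line %d: empty chromosome", i))
    }
    rev <- startsWith(toks, "-")
    fam <- ifelse(rev, substring(toks, 2L), toks)
    bad <- which(!token_ok(fam))
    if (length(bad) > 0L) {
      stop(sprintf("parse error at line %d: bad gene token '%s'", i, toks[bad[1L]]))
    }
    cur_chroms[[length(cur_chroms) + 1L]] <-
      new_chromosome(fam, rev, circular = (last == ")"))
  }
  flush_genome()
  if (length(genomes) == 0L) stop("parse error: no genome found in input")
  genomes
}

# signed token of gene j of chromosome ch, with copy suffix if present
signed_tokens <- function(ch) {
  lab <- paste0(ch$family, ifelse(nzchar(ch$copy), paste0("_", ch$copy), ""))
  paste0(ifelse(ch$rev, "-", ""), lab)
}

#' Serialize a genome to its text representation
#'
#' Writes chromosomes in storage order in the default bracket format (or the
#' UniMoG-style dialect).  With `canonical = TRUE` each chromosome is first
#' put into canonical form (lexicographically smallest among its
#' reverse-complement and, for circular chromosomes, all rotations), making
#' output independent of the incidental input orientation.
#'
#' @param g a [genome()].
#' @param format `"brackets"` or `"unimog"`.
#' @param canonical put each chromosome in canonical form first?
#' @return Character vector of lines (header line included when `g` is named).
#' @export
format_genome <- function(g, format = c("brackets", "unimog"),
                          canonical = FALSE) {
  format <- match.arg(format)
  stopifnot(is_genome(g))
  chroms <- g$chromosomes
  if (canonical) chroms <- lapply(chroms, canonical_chromosome)
  out <- character()
  if (!is.null(g$name)) out <- paste0(">", g$name)
  for (ch in chroms) {
    body <- paste(signed_tokens(ch), collapse = " ")
    line <- if (format == "brackets") {
      if (ch$circular) paste0("(", body, ")") else paste0("[", body, "]")
    } else {
      if (ch$circular) paste0(body, " )") else paste0(body, " |")
    }
    out <- c(out, line)
  }
  out
}

# ---- canonical form ----------------------------------------------------

reverse_complement <- function(ch) {
  n <- length(ch$family)
  new_chromosome(rev(ch$family), !ch$rev[n:1], rev(ch$copy),
                 circular = ch$circular)
}

rotate_chrom <- function(ch, k) {
  n <- length(ch$family)
  idx <- ((seq_len(n) + k - 1L) %% n) + 1L
  new_chromosome(ch$family[idx], ch$rev[idx], ch$copy[idx],
                 circular = ch$circular)
}

chrom_key <- function(ch) paste(signed_tokens(ch), collapse = " ")

# Lexicographically smallest representation among reverse-complement and
# (for circular chromosomes) all rotations.
canonical_chromosome <- function(ch) {
  cands <- list(ch, reverse_complement(ch))
  if (ch$circular && length(ch$family) > 1L) {
    n <- length(ch$family)
    more <- c(lapply(seq_len(n - 1L), function(k) rotate_chrom(ch, k)),
              lapply(seq_len(n - 1L), function(k)
                rotate_chrom(reverse_complement(ch), k)))
    cands <- c(cands, more)
  }
  keys <- vapply(cands, chrom_key, character(1))
  cands[[which.min(rank(keys, ties.method = "first"))]]
}

#' Test two genomes for equality up to canonical form
#'
#' Chromosome equality is invariant under reverse-complement and, for
#' circular chromosomes, rotation; genomes are compared as multisets of
#' canonical chromosomes.
#'
#' @param g1,g2 genomes.
#' @return `TRUE` or `FALSE`.
#' @export
genome_equal <- function(g1, g2) {
  k1 <- sort(vapply(lapply(g1$chromosomes, canonical_chromosome),
                    function(ch) paste0(if (ch$circular) "(" else "[",
                                        chrom_key(ch)),
                    character(1)))
  k2 <- sort(vapply(lapply(g2$chromosomes, canonical_chromosome),
                    function(ch) paste0(if (ch$circular) "(" else "[",
                                        chrom_key(ch)),
                    character(1)))
  identical(k1, k2)
}

# ---- extremities, adjacencies, telomeres -------------------------------

# Extremity label: "<family><copy><side>", e.g. "1h", "3t", "1ah" after
# singularization.  The head of gene X is Xh, the tail Xt.
ext_label <- function(family, copy, side) paste0(family, copy, side)

# For each gene, the extremity met first when reading the chromosome left to
# right (`enter`) and the one met last (`leave`).
chrom_walk <- function(ch) {
  lab <- paste0(ch$family, ch$copy)
  list(enter = ext_label(ch$family, ch$copy, ifelse(ch$rev, "h", "t")),
       leave = ext_label(ch$family, ch$copy, ifelse(ch$rev, "t", "h")),
       lab = lab)
}

# adjacency pairs (2-column matrix of extremity labels), genome order
adjacency_pairs <- function(g) {
  e1 <- character(0); e2 <- character(0)
  for (ch in g$chromosomes) {
    w <- chrom_walk(ch)
    n <- length(ch$family)
    if (n > 1L) {
      e1 <- c(e1, w$leave[seq_len(n - 1L)])
      e2 <- c(e2, w$enter[2:n])
    }
    if (ch$circular) {
      e1 <- c(e1, w$leave[n])
      e2 <- c(e2, w$enter[1L])
    }
  }
  cbind(e1, e2, deparse.level = 0)
}

adj_key <- function(e1, e2) {
  paste(pmin(e1, e2), pmax(e1, e2))
}

#' Adjacency multiset of a genome
#'
#' An adjacency is the unordered pair of neighboring gene extremities within
#' a chromosome; a single-gene circular chromosome `(X)` exceptionally has
#' the adjacency between the two extremities of the same gene, `Xh Xt`.
#'
#' @param g a [genome()].
#' @return Character vector (a multiset): one entry per adjacency, each the
#'   two extremity labels in sorted order separated by a space, e.g.
#'   `"1h 3h"`.
#' @examples
#' adjacency_multiset(parse_genome("[1 -3 2]")[[1]])
#' @export
adjacency_multiset <- function(g) {
  ap <- adjacency_pairs(g)
  if (nrow(ap) == 0L) return(character(0))
  adj_key(ap[, 1L], ap[, 2L])
}

#' Telomere multiset of a genome
#'
#' The extremities at the two ends of each linear chromosome.  Circular
#' chromosomes have no telomeres.
#'
#' @param g a [genome()].
#' @return Character vector of extremity labels (a multiset).
#' @export
telomere_multiset <- function(g) {
  out <- character(0)
  for (ch in g$chromosomes) {
    if (!ch$circular) {
      w <- chrom_walk(ch)
      n <- length(ch$family)
      out <- c(out, w$enter[1L], w$leave[n])
    }
  }
  out
}

family_counts <- function(g) {
  fams <- unlist(lapply(g$chromosomes, `[[`, "family"), use.names = FALSE)
  table(fams)
}

#' Gene family set of a genome
#' @param g a [genome()].
#' @return Sorted character vector of distinct family tokens.
#' @export
family_set <- function(g) sort(names(family_counts(g)))

n_linear <- function(g) sum(!vapply(g$chromosomes, `[[`, logical(1), "circular"))
n_circular <- function(g) sum(vapply(g$chromosomes, `[[`, logical(1), "circular"))

#' Classify a genome by family multiplicity
#'
#' A genome is *singular* when every family occurs exactly once, *duplicated*
#' when every family occurs exactly twice, and *doubled* when it is
#' duplicated and additionally every adjacency and every telomere occurs
#' exactly twice (the structure produced by a whole-genome duplication).
#'
#' @param g a [genome()].
#' @return One of `"singular"`, `"duplicated"`, `"doubled"`, `"other"`.
#' @export
classify_genome <- function(g) {
  fc <- family_counts(g)
  if (length(fc) == 0L) return("other")
  if (all(fc == 1L)) return("singular")
  if (all(fc == 2L)) {
    at <- table(adjacency_multiset(g))
    tt <- table(telomere_multiset(g))
    if (all(at == 2L) && all(tt == 2L)) return("doubled")
    return("duplicated")
  }
  "other"
}

#' Adjacency and telomere content of the doubling of a singular genome
#'
#' Doubling duplicates each adjacency and each telomere of a singular genome
#' `s`.  When `s` has `r` circular chromosomes the doubling is realized by
#' `2^r` distinct doubled genomes (each circular chromosome is either copied
#' into two circles or concatenated into one), all sharing the same
#' adjacency and telomere multisets.
#'
#' @param s a singular [genome()].
#' @return List with `adjacencies` (multiset, each adjacency of `s` twice),
#'   `telomeres` (likewise), and `count` (`2^r`, the number of distinct
#'   doubled genomes).
#' @export
doubled_content <- function(s) {
  if (classify_genome(s) != "singular") {
    stop("doubled_content() requires a singular genome")
  }
  a <- adjacency_multiset(s)
  t <- telomere_multiset(s)
  list(adjacencies = c(a, a), telomeres = c(t, t),
       count = 2^n_circular(s))
}

#' Singularize a duplicated genome
#'
#' Adds copy index `a` to the first occurrence of each family and `b` to the
#' second, in deterministic order (chromosomes in storage order, genes left
#' to right).  Any two singularizations of the same duplicated genome yield
#' the same sigma-k double distance, so the deterministic choice is purely
#' for reproducibility.
#'
#' @param d a duplicated [genome()] without copy indices.
#' @return A genome whose genes carry copy labels (`a`/`b`).
#' @export
singularize <- function(d) {
  if (any(unlist(lapply(d$chromosomes, `[[`, "copy")) != "")) {
    stop("genome is already singularized")
  }
  if (!classify_genome(d) %in% c("duplicated", "doubled")) {
    stop("singularize() requires a duplicated genome")
  }
  seen <- new.env(parent = emptyenv())
  chroms <- lapply(d$chromosomes, function(ch) {
    cp <- character(length(ch$family))
    for (j in seq_along(ch$family)) {
      f <- ch$family[j]
      k <- if (is.null(seen[[f]])) 0L else seen[[f]]
      cp[j] <- if (k == 0L) "a" else "b"
      seen[[f]] <- k + 1L
    }
    new_chromosome(ch$family, ch$rev, cp, circular = ch$circular)
  })
  genome(chroms, name = d$name)
}

# re-singularize with a random copy-label permutation (for invariance tests)
resingularize_random <- function(dch) {
  fams <- family_set(dch)
  flip <- stats::setNames(sample(c(TRUE, FALSE), length(fams), replace = TRUE),
                          fams)
  chroms <- lapply(dch$chromosomes, function(ch) {
    cp <- ch$copy
    do_flip <- flip[ch$family]
    cp <- ifelse(do_flip, ifelse(cp == "a", "b", "a"), cp)
    new_chromosome(ch$family, ch$rev, cp, circular = ch$circular)
  })
  genome(chroms, name = dch$name)
}

strip_copies <- function(g) {
  genome(lapply(g$chromosomes, function(ch)
    new_chromosome(ch$family, ch$rev, circular = ch$circular)),
    name = g$name)
}
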
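# Ambiguous breakpoint graph ABG(S, D) of a singular genome S and a
# duplicated genome D (singularized internally).  Vertices are the four
# extremities Xa_h, Xb_h, Xa_t, Xb_t of every family X.  Each adjacency of
# S becomes a *square*: four candidate S-edges in two paralogous pairs,
#   parallel pair  {ga-ba, gb-bb}   (slots 1, 2)
#   crossed pair   {ga-bb, gb-ba}   (slots 3, 4)
# of which exactly one pair is kept by a solution.  Each adjacency of the
# singularized D contributes one fixed D-edge.

# vertex id for family index i, copy ("a"/"b") and side ("h"/"t")
abg_vid <- function(i, copy, side) {
  (i - 1L) * 4L + ifelse(side == "h", 0L, 2L) + ifelse(copy == "a", 1L, 2L)
}

split_ext <- function(lab) {
  # extremity label without copy -> c(family, side); side is the last char
  n <- nchar(lab)
  cbind(substring(lab, 1L, n - 1L), substring(lab, n, n))
}

#' Build the ambiguous breakpoint graph of a singular and a duplicated genome
#'
#' @param s a singular [genome()].
#' @param d a duplicated genome over the same families; it may already carry
#'   copy labels, otherwise it is singularized deterministically with
#'   [singularize()] (the choice does not affect any sigma-k double
#'   distance).
#' @return A `sigmak_abg` object holding the squares, the D-edges and the
#'   telomere annotations; input to [induce()], [k_score()],
#'   [oracle_best()], [solve_sigma4()] and [solve_sigma6()].
#' @examples
#' s <- parse_genome("[1 2 3]")[[1]]
#' d <- parse_genome("[1 2 -3 1] [-3 2]")[[1]]
#' abg <- build_abg(s, d)
#' abg
#' @export
build_abg <- function(s, d) {
  if (classify_genome(s) != "singular") stop("`s` must be a singular genome")
  fs <- family_set(s); fd <- family_set(d)
  if (!identical(fs, fd)) {
    stop(sprintf("family sets differ; only in S: {%s}; only in D: {%s}",
                 paste(setdiff(fs, fd), collapse = ", "),
                 paste(setdiff(fd, fs), collapse = ", ")))
  }
  has_copies <- any(unlist(lapply(d$chromosomes, `[[`, "copy")) != "")
  dch <- if (has_copies) d else singularize(d)

  fams <- fs
  n <- length(fams)
  m <- 4L * n
  fidx <- stats::setNames(seq_len(n), fams)
  labels <- character(m)
  for (cp in c("a", "b")) for (sd in c("h", "t")) {
    labels[abg_vid(seq_len(n), cp, sd)] <- paste0(fams, cp, sd)
  }
  vid <- stats::setNames(seq_len(m), labels)

  # squares from the adjacencies of S, in genome order
  ap <- adjacency_pairs(s)
  a <- nrow(ap)
  sq <- matrix(0L, a, 4L, dimnames = list(NULL, c("ga", "gb", "ba", "bb")))
  if (a > 0L) {
    g <- split_ext(ap[, 1L]); b <- split_ext(ap[, 2L])
    sq[, "ga"] <- abg_vid(fidx[g[, 1L]], "a", g[, 2L])
    sq[, "gb"] <- abg_vid(fidx[g[, 1L]], "b", g[, 2L])
    sq[, "ba"] <- abg_vid(fidx[b[, 1L]], "a", b[, 2L])
    sq[, "bb"] <- abg_vid(fidx[b[, 1L]], "b", b[, 2L])
  }

  # D-edges from the singularized duplicated genome
  dp <- adjacency_pairs(dch)
  dnext <- integer(m)
  if (nrow(dp) > 0L) {
    i <- vid[dp[, 1L]]; j <- vid[dp[, 2L]]
    if (anyNA(i) || anyNA(j)) stop("internal: unknown extremity in D")
    if (any(dnext[i] > 0L) || any(dnext[j] > 0L)) {
      stop("internal: extremity in two adjacencies of the singularized D")
    }
    dnext[i] <- j; dnext[j] <- i
  }

  s_telo <- logical(m)
  st <- telomere_multiset(s)
  if (length(st) > 0L) {
    e <- split_ext(st)
    s_telo[abg_vid(fidx[e[, 1L]], "a", e[, 2L])] <- TRUE
    s_telo[abg_vid(fidx[e[, 1L]], "b", e[, 2L])] <- TRUE
  }
  d_telo <- dnext == 0L

  # slot endpoint matrices: columns are the four candidate-edge slots
  E1 <- cbind(sq[, "ga"], sq[, "gb"], sq[, "ga"], sq[, "gb"])
  E2 <- cbind(sq[, "ba"], sq[, "bb"], sq[, "bb"], sq[, "ba"])

  structure(list(
    fams = fams, n_star = n, a_star = a, m = m,
    labels = labels, sq = sq, E1 = E1, E2 = E2,
    sq_adj = if (a > 0L) adj_key(ap[, 1L], ap[, 2L]) else character(0),
    dnext = dnext, s_telo = s_telo, d_telo = d_telo,
    kappa_s = n_linear(s), kappa_d = n_linear(d),
    fixed = rep(-1L, a), fix_reason = rep(NA_character_, a),
    s = s, dch = dch), class = "sigmak_abg")
}

#' @export
print.sigmak_abg <- function(x, ...) {
  cat(sprintf("ambiguous breakpoint graph: %d families, %d squares, %d D-edges\n",
              x$n_star, x$a_star, sum(x$dnext > 0) / 2))
  cat(sprintf("  S-telomeres: %d, D-telomeres: %d, fixed squares: %d\n",
              sum(x$s_telo), sum(x$d_telo), sum(x$fixed >= 0)))
  invisible(x)
}

# slot endpoints (R side, slots 1..4)
slot_ends_r <- function(abg, i, s) {
  sqr <- abg$sq
  switch(s,
         c(sqr[i, "ga"], sqr[i, "ba"]),
         c(sqr[i, "gb"], sqr[i, "bb"]),
         c(sqr[i, "ga"], sqr[i, "bb"]),
         c(sqr[i, "gb"], sqr[i, "ba"]))
}

all_present <- function(abg) {
  matrix(TRUE, abg$a_star, 4L)
}

# ---- solutions ---------------------------------------------------------

#' Coerce to a solution (one choice per square)
#'
#' A solution resolves every square of an ambiguous breakpoint graph by
#' keeping either its parallel or its crossed pair of paralogous edges.
#'
#' @param x character vector of `"parallel"`/`"crossed"`, or integer vector
#'   of 0 (parallel) / 1 (crossed).
#' @param abg the graph the solution belongs to.
#' @return Character vector of length `a_star` with class `sigmak_solution`.
#' @export
as_solution <- function(x, abg) {
  if (is.numeric(x)) x <- c("parallel", "crossed")[x + 1L]
  x <- unclass(x)
  if (!is.character(x) || !all(x %in% c("parallel", "crossed"))) {
    stop("a solution is a vector of \"parallel\"/\"crossed\" choices")
  }
  if (length(x) != abg$a_star) {
    stop(sprintf("solution has %d choices but the graph has %d squares",
                 length(x), abg$a_star))
  }
  structure(x, class = "sigmak_solution")
}

choice01 <- function(tau) as.integer(unclass(tau) == "crossed")

#' Switch one square of a solution
#'
#' Replaces the chosen pair of square `i` by its complementary pair;
#' switching twice restores the original solution, and switching every
#' square yields the complementary solution.
#'
#' @param tau a solution (character vector of `"parallel"`/`"crossed"`).
#' @param i square index (1-based).
#' @return The modified solution.
#' @export
switch_solution <- function(tau, i) {
  if (any(i < 1L) || any(i > length(tau))) {
    stop(sprintf("square index out of range 1..%d", length(tau)))
  }
  tau[i] <- ifelse(tau[i] == "parallel", "crossed", "parallel")
  tau
}

#' Induce a concrete breakpoint graph from a solution
#'
#' Keeps, for every square, the chosen pair of paralogous S-edges and masks
#' the complementary pair; together with the D-edges this is a simple
#' breakpoint graph of the corresponding doubled genome and the
#' singularized D, decomposable with [decompose()].
#'
#' @param abg a `sigmak_abg`.
#' @param tau a solution; must agree with any fixed squares.
#' @return A `sigmak_bg`.
#' @export
induce <- function(abg, tau) {
  stopifnot(inherits(abg, "sigmak_abg"))
  tau <- as_solution(tau, abg)
  ch <- choice01(tau)
  bad <- which(abg$fixed >= 0L & ch != abg$fixed)
  if (length(bad) > 0L) {
    stop(sprintf("solution conflicts with fixed square(s) %s",
                 paste(bad, collapse = ", ")))
  }
  next1 <- integer(abg$m)
  if (abg$a_star > 0L) {
    sqr <- abg$sq
    par <- ch == 0L
    e1a <- ifelse(par, sqr[, "ba"], sqr[, "bb"])
    e1b <- ifelse(par, sqr[, "bb"], sqr[, "ba"])
    next1[sqr[, "ga"]] <- e1a
    next1[e1a] <- sqr[, "ga"]
    next1[sqr[, "gb"]] <- e1b
    next1[e1b] <- sqr[, "gb"]
  }
  new_bg(abg$labels, next1, abg$dnext, n_star = 2L * abg$n_star,
         genome1 = "2S", genome2 = "D")
}

#' k-score of a solution
#'
#' The k-score of a solution is `sigma_k` of its induced breakpoint graph;
#' the sigma-k double distance is `2 n* - (maximal k-score)`.
#'
#' @inheritParams induce
#' @inheritParams sigma_score
#' @return The score, a multiple of 1/2.
#' @export
k_score <- function(abg, tau, k) {
  sigma_score(decompose(induce(abg, tau)), k)
}

# ---- fixing ------------------------------------------------------------

#' Fix the squares that close 2-cycles (common adjacencies)
#'
#' Every 0-path and every 2-cycle of the ambiguous breakpoint graph is part
#' of every optimal solution, for any k: common adjacencies and common
#' telomeres of the two genomes are always conserved.  This fixes each
#' square having a candidate S-edge that closes a 2-cycle with a parallel
#' D-edge so that the 2-cycle is induced.
#'
#' @param abg a `sigmak_abg`.
#' @return The graph with those squares fixed (reason `"common"`).
#' @export
fix_common <- function(abg) {
  if (abg$a_star == 0L) return(abg)
  for (s in 1:4) {
    hit <- abg$dnext[abg$E1[, s]] == abg$E2[, s]
    want <- if (s <= 2L) 0L else 1L
    if (any(abg$fixed[hit] >= 0L & abg$fixed[hit] != want)) {
      stop("internal: conflicting 2-cycle fixes in one square")
    }
    abg$fixed[hit] <- want
    abg$fix_reason[hit] <- "common"
  }
  abg
}

#' Fix symmetric squares
#'
#' A square is symmetric when (i) a D-edge joins one of its pairs of
#' paralogous vertices, (ii) one pair of paralogous vertices are both
#' D-telomeres, or (iii) the D-edges at one pair of paralogous vertices
#' both lead to S-telomeres.  The two resolutions of such a square always
#' give the same k-score, so it is fixed arbitrarily (to parallel).
#'
#' @param abg a `sigmak_abg`, typically after [fix_common()].
#' @return The graph with symmetric squares fixed (reason `"symmetric"`).
#' @export
fix_symmetric_squares <- function(abg) {
  if (abg$a_star == 0L) return(abg)
  dn <- abg$dnext
  to_stel <- function(v) dn[v] > 0L & abg$s_telo[pmax(dn[v], 1L)]
  ga <- abg$sq[, "ga"]; gb <- abg$sq[, "gb"]
  ba <- abg$sq[, "ba"]; bb <- abg$sq[, "bb"]
  sym <- (dn[ga] == gb) | (dn[ba] == bb) |
    (abg$d_telo[ga] & abg$d_telo[gb]) | (abg$d_telo[ba] & abg$d_telo[bb]) |
    (to_stel(ga) & to_stel(gb)) | (to_stel(ba) & to_stel(bb))
  sym <- sym & abg$fixed < 0L
  abg$fixed[sym] <- 0L
  abg$fix_reason[sym] <- "symmetric"
  abg
}

# ---- oracle ------------------------------------------------------------

#' Exhaustive oracle over all resolutions
#'
#' Enumerates all `2^f` resolutions of the free squares (respecting any
#' fixed ones) and returns the maximal k-score together with one maximizing
#' solution; ties are broken by the lexicographically smallest choice tuple
#' (parallel before crossed, square 1 most significant).  Exponential in the
#' number of free squares; intended as an independent check of the
#' polynomial solvers on small instances.
#'
#' @param abg a `sigmak_abg`.
#' @param k even integer `>= 2` or `Inf`.
#' @param max_squares refuse instances with more free squares than this.
#' @return List with `score` and `tau`.
#' @export
oracle_best <- function(abg, k, max_squares = 20L) {
  stopifnot(inherits(abg, "sigmak_abg"))
  k <- check_k(k)
  nf <- sum(abg$fixed < 0L)
  if (nf > max_squares) {
    stop(sprintf("refusing exhaustive search over 2^%d resolutions (cap %d free squares); raise `max_squares` to override",
                 nf, max_squares))
  }
  ki <- match(k, c(2, 4, 6, Inf))
  if (!is.na(ki)) {
    sw <- abg_sweep_core(abg$m, abg$dnext, abg$sq, abg$fixed, all_present(abg),
                         abg$s_telo, abg$d_telo)
    ch <- list(sw$choice2, sw$choice4, sw$choice6, sw$choiceInf)[[ki]]
    return(list(score = sw$best2[ki] / 2, tau = as_solution(ch, abg)))
  }
  # general even k: plain enumeration through induce()/decompose()
  free <- which(abg$fixed < 0L)
  base <- ifelse(abg$fixed < 0L, 0L, abg$fixed)
  best <- -Inf; best_tau <- NULL
  for (mask in 0:(2^nf - 1)) {
    ch <- base
    if (nf > 0L) {
      bits <- as.integer(intToBits(mask))[seq_len(nf)]
      ch[free] <- rev(bits)   # square 1 most significant
    }
    tau <- as_solution(ch, abg)
    sc <- k_score(abg, tau, k)
    if (sc > best) { best <- sc; best_tau <- tau }
  }
  list(score = best, tau = best_tau)
}

# ---- double distances --------------------------------------------------

#' Breakpoint (sigma-2) double distance, closed formula
#'
#' `2 n* - |A(2S) n A(D)| - |T(2S) n T(D)| / 2` with multiset
#' intersections: every adjacency or telomere of D that occurs in S is
#' fulfilled greedily.
#'
#' @param s a singular genome.
#' @param d a duplicated genome over the same families.
#' @return The distance, a multiple of 1/2.
#' @export
double_distance_sigma2 <- function(s, d) {
  fs <- family_set(s)
  if (!identical(fs, family_set(strip_copies(d)))) {
    stop("family sets of S and D differ")
  }
  dc <- doubled_content(s)
  d0 <- strip_copies(d)
  if (!classify_genome(d0) %in% c("duplicated", "doubled")) {
    stop("`d` must be a duplicated genome")
  }
  minter <- function(x, y) {
    tx <- table(x); ty <- table(y)
    common <- intersect(names(tx), names(ty))
    sum(pmin(tx[common], ty[common]))
  }
  2 * length(fs) -
    minter(dc$adjacencies, adjacency_multiset(d0)) -
    minter(dc$telomeres, telomere_multiset(d0)) / 2
}

#' The sigma-k double distance of a singular and a duplicated genome
#'
#' The minimum sigma-k distance between the duplicated genome and any
#' doubling of the singular genome, equal to `2 n*` minus the maximal
#' k-score over all resolutions of the ambiguous breakpoint graph.
#' Dispatches to the closed sigma-2 formula, the greedy sigma-4 solver, the
#' sigma-6 solver, or (for `method = "oracle"`, any even k or `Inf`) the
#' exhaustive oracle.  The DCJ double distance (`k = Inf`) is NP-hard and
#' only available through the oracle.
#'
#' @inheritParams double_distance_sigma2
#' @param k 2, 4 or 6 for the polynomial algorithms; any even k or `Inf`
#'   with `method = "oracle"`.
#' @param method `"auto"` (default) or `"oracle"`.
#' @param max_squares cap for the oracle, see [oracle_best()].
#' @return List with `distance`, `score` (the maximal k-score), `tau` (an
#'   optimal solution) and `method`.
#' @examples
#' s <- parse_genome("[1 2 3]")[[1]]
#' d <- parse_genome("[1 2 -3 1] [-3 2]")[[1]]
#' double_distance(s, d, 6)$distance
#' @export
double_distance <- function(s, d, k, method = c("auto", "oracle"),
                            max_squares = 20L) {
  method <- match.arg(method)
  k <- check_k(k)
  abg <- build_abg(s, d)
  if (method == "oracle") {
    ob <- oracle_best(abg, k, max_squares = max_squares)
    return(list(distance = 2 * abg$n_star - ob$score, score = ob$score,
                tau = ob$tau, k = k, method = "oracle"))
  }
  if (is.infinite(k) || k >= 8) {
    stop("only k in {2, 4, 6} is supported algorithmically; use method = \"oracle\" for other k")
  }
  if (k == 2) {
    abg <- fix_common(abg)
    ch <- ifelse(abg$fixed < 0L, 0L, abg$fixed)
    tau <- as_solution(ch, abg)
    sc <- k_score(abg, tau, 2)
    dist <- 2 * abg$n_star - sc
    stopifnot(isTRUE(all.equal(dist, double_distance_sigma2(s, d))))
    return(list(distance = dist, score = sc, tau = tau, k = 2,
                method = "formula"))
  }
  res <- if (k == 4) solve_sigma4(abg) else solve_sigma6(abg)
  list(distance = res$distance, score = res$score, tau = res$tau, k = k,
       method = if (k == 4) "greedy" else "structural", ops = res$ops)
}
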
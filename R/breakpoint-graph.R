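# Breakpoint graph of a canonical genome pair: a multigraph on the 2*n
# gene extremities with one genome1-edge per adjacency of the first genome
# and one genome2-edge per adjacency of the second.  Every vertex carries at
# most one edge of each class, so components are alternating even cycles
# and paths.  Internally a `sigmak_bg` stores the two partner arrays
# (`next1`, `next2`, 0 = no partner) over an indexed vertex set.

new_bg <- function(labels, next1, next2, n_star,
                   genome1 = "genome1", genome2 = "genome2") {
  structure(list(labels = labels, next1 = next1, next2 = next2,
                 n_star = n_star, genome1 = genome1, genome2 = genome2),
            class = "sigmak_bg")
}

#' @export
print.sigmak_bg <- function(x, ...) {
  cat(sprintf("breakpoint graph: %d vertices, %d + %d edges (%s / %s)\n",
              length(x$labels), sum(x$next1 > 0) / 2, sum(x$next2 > 0) / 2,
              x$genome1, x$genome2))
  invisible(x)
}

#' Build the breakpoint graph of a canonical genome pair
#'
#' Two genomes form a canonical pair when both are singular and share the
#' same gene families.  The graph has one vertex per extremity (head and
#' tail of each family) and one edge per adjacency of each genome.
#'
#' @param s1,s2 singular genomes over the same family set.
#' @return A `sigmak_bg` object; pass to [decompose()].
#' @examples
#' p <- parse_genome("(1 2) [3 -4]\n(1 -3 2) [4]")
#' decompose(build_breakpoint_graph(p[[1]], p[[2]]))
#' @export
build_breakpoint_graph <- function(s1, s2) {
  if (classify_genome(s1) != "singular" || classify_genome(s2) != "singular") {
    stop("both genomes of a canonical pair must be singular")
  }
  f1 <- family_set(s1); f2 <- family_set(s2)
  if (!identical(f1, f2)) {
    stop(sprintf("not a canonical pair; families only in first: {%s}; only in second: {%s}",
                 paste(setdiff(f1, f2), collapse = ", "),
                 paste(setdiff(f2, f1), collapse = ", ")))
  }
  fams <- f1
  labels <- as.vector(rbind(paste0(fams, "h"), paste0(fams, "t")))
  vid <- stats::setNames(seq_along(labels), labels)
  partner <- function(g) {
    nxt <- integer(length(labels))
    ap <- adjacency_pairs(g)
    if (nrow(ap) > 0L) {
      i <- vid[ap[, 1L]]; j <- vid[ap[, 2L]]
      if (any(nxt[i] > 0L) || any(nxt[j] > 0L)) {
        stop("internal: extremity in two adjacencies of a singular genome")
      }
      nxt[i] <- j; nxt[j] <- i
    }
    nxt
  }
  new_bg(labels, partner(s1), partner(s2), n_star = length(fams),
         genome1 = if (is.null(s1$name)) "genome1" else s1$name,
         genome2 = if (is.null(s2$name)) "genome2" else s2$name)
}

#' Decompose a breakpoint graph into cycles and paths
#'
#' Components of a breakpoint graph are alternating cycles of even length
#' and paths.  An *i*-cycle has *i* edges; a *j*-path has *j* edges, a
#' 0-path being an isolated vertex that is a telomere in both genomes (a
#' common telomere).  An even path has one endpoint that is a telomere of
#' each genome; odd paths have both endpoints in the same genome.
#'
#' @param bg a `sigmak_bg` from [build_breakpoint_graph()] or [induce()].
#' @return A `sigmak_bg_summary` with elements `cycle_len` (edge count per
#'   cycle), `path_len`, `path_ends` (two-column matrix of endpoint labels),
#'   `n_star`, and convenience counts `c` (total cycles) and `p_e` (total
#'   even paths).
#' @export
decompose <- function(bg) {
  stopifnot(inherits(bg, "sigmak_bg"))
  d <- bg_decompose_core(bg$next1, bg$next2)
  pe <- sum(d$path_len %% 2L == 0L)
  stopifnot(pe %% 2L == 0L)   # telomere counts are even in each genome
  structure(list(cycle_len = sort(d$cycle_len),
                 path_len = d$path_len,
                 path_ends = cbind(bg$labels[d$path_end1],
                                   bg$labels[d$path_end2]),
                 n_star = bg$n_star,
                 c = length(d$cycle_len),
                 p_e = pe),
            class = "sigmak_bg_summary")
}

#' @export
print.sigmak_bg_summary <- function(x, ...) {
  ct <- table(x$cycle_len)
  pt <- table(x$path_len)
  cat(sprintf("components of a breakpoint graph on %d families:\n", x$n_star))
  if (length(ct)) {
    cat("  cycles:", paste(sprintf("%sx %s-cycle", ct, names(ct)),
                           collapse = ", "), "\n")
  } else cat("  cycles: none\n")
  if (length(pt)) {
    cat("  paths: ", paste(sprintf("%sx %s-path", pt, names(pt)),
                           collapse = ", "), "\n")
  } else cat("  paths:  none\n")
  invisible(x)
}

check_k <- function(k) {
  if (identical(k, "inf") || identical(k, "INF")) k <- Inf
  if (!is.numeric(k) || length(k) != 1L || is.na(k)) {
    stop("k must be an even integer >= 2 or Inf")
  }
  if (!is.infinite(k) && (k < 2 || k %% 2 != 0)) {
    stop("k must be an even integer >= 2 or Inf")
  }
  k
}

#' Cumulative cycle/path score sigma_k of a decomposition
#'
#' For even `k`, `sigma_k = c2 + c4 + ... + ck + (p0 + p2 + ... + p(k-2))/2`
#' where `ci` counts cycles with `i` edges and `pj` counts paths with `j`
#' edges.  `k = Inf` counts all cycles and all even paths.  Odd paths never
#' contribute.
#'
#' @param cs a `sigmak_bg_summary` from [decompose()].
#' @param k even integer `>= 2`, or `Inf` (the string `"inf"` is accepted).
#' @return The score, a multiple of 1/2.
#' @export
sigma_score <- function(cs, k) {
  stopifnot(inherits(cs, "sigmak_bg_summary"))
  k <- check_k(k)
  even <- cs$path_len %% 2 == 0
  sum(cs$cycle_len <= k) + sum(even & cs$path_len <= k - 2) / 2
}

#' The sigma-k distance of a canonical genome pair
#'
#' `d_sigma_k(S1, S2) = n* - sigma_k`, where `n*` is the number of common
#' gene families.  `k = 2` gives the breakpoint distance and `k = Inf` the
#' DCJ (double-cut-and-join) rearrangement distance; the distance is
#' non-increasing in `k` between these extremes.
#'
#' @inheritParams build_breakpoint_graph
#' @inheritParams sigma_score
#' @return The distance, a multiple of 1/2.
#' @examples
#' p <- parse_genome("(1 -3 2) [4]\n(1 2) [3 -4]")
#' sigma_distance(p[[1]], p[[2]], 2)    # breakpoint distance: 2.5
#' sigma_distance(p[[1]], p[[2]], Inf)  # DCJ distance: 2
#' @export
sigma_distance <- function(s1, s2, k) {
  k <- check_k(k)
  cs <- decompose(build_breakpoint_graph(s1, s2))
  cs$n_star - sigma_score(cs, k)
}
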
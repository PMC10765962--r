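# Exact maximum-weight independent set used to resolve ambiguous components
# of the pruned graph through their intersection graphs.  The structures
# arising there are chains of intersecting players: components of maximum
# degree two (path-lines and cyclic lines) are solved by the classical
# linear alternating DP, everything else (double-lines, plug-connected
# cycle-lines, the bounded exceptional bubbles) by memoized
# branch-and-reduce with component splitting.  Weights are integers in half
# units (path player = 1, cycle player = 2).

mwis_solve <- function(nv, w2, adj) {
  stopifnot(length(w2) == nv, length(adj) == nv)
  if (nv == 0L) return(list(weight2 = 0L, selected = integer(0), nodes = 0L))
  nodes <- 0L
  memo <- new.env(parent = emptyenv())

  deg_in <- function(v, inset) sum(inset[adj[[v]]])

  comps_of <- function(vs) {
    inset <- logical(nv); inset[vs] <- TRUE
    seen <- logical(nv)
    out <- list()
    for (s in vs) {
      if (seen[s]) next
      q <- s; seen[s] <- TRUE; comp <- integer(0)
      while (length(q) > 0L) {
        v <- q[[1L]]; q <- q[-1L]
        comp <- c(comp, v)
        nb <- adj[[v]]
        nb <- nb[inset[nb] & !seen[nb]]
        seen[nb] <- TRUE
        q <- c(q, nb)
      }
      out[[length(out) + 1L]] <- sort(comp)
    }
    out
  }

  # alternating DP on a path of vertices in order
  path_dp <- function(ord) {
    l <- length(ord)
    if (l == 0L) return(list(weight2 = 0L, selected = integer(0)))
    f <- integer(l + 1L)          # f[i+1] = best on first i vertices
    take <- logical(l)
    f[2L] <- w2[ord[1L]]; take[1L] <- TRUE
    if (l >= 2L) {
      for (i in 2:l) {
        skip <- f[i]
        use <- f[i - 1L] + w2[ord[i]]
        take[i] <- use > skip
        f[i + 1L] <- max(skip, use)
      }
    }
    sel <- integer(0)
    i <- l
    while (i >= 1L) {
      if (take[i]) { sel <- c(sel, ord[i]); i <- i - 2L } else i <- i - 1L
    }
    list(weight2 = f[l + 1L], selected = sel)
  }

  line_solve <- function(cvs) {
    inset <- logical(nv); inset[cvs] <- TRUE
    degs <- vapply(cvs, deg_in, integer(1), inset = inset)
    ends <- cvs[degs <= 1L]
    if (length(ends) > 0L) {           # path
      ord <- integer(0)
      prev <- 0L; v <- ends[[1L]]
      while (TRUE) {
        ord <- c(ord, v)
        nb <- adj[[v]]; nb <- nb[inset[nb] & nb != prev]
        if (length(nb) == 0L) break
        prev <- v; v <- nb[[1L]]
      }
      stopifnot(length(ord) == length(cvs))
      return(path_dp(ord))
    }
    # cycle: walk it, then best of (drop v1) and (take v1)
    ord <- integer(0)
    prev <- 0L; v <- cvs[[1L]]
    while (TRUE) {
      ord <- c(ord, v)
      nb <- adj[[v]]; nb <- nb[inset[nb] & nb != prev]
      if (length(nb) == 0L || nb[[1L]] == cvs[[1L]]) break
      prev <- v; v <- nb[[1L]]
    }
    stopifnot(length(ord) == length(cvs))
    l <- length(ord)
    without <- path_dp(ord[-1L])
    with_v <- path_dp(if (l > 3L) ord[3:(l - 1L)] else integer(0))
    if (w2[ord[1L]] + with_v$weight2 > without$weight2) {
      list(weight2 = w2[ord[1L]] + with_v$weight2,
           selected = c(ord[1L], with_v$selected))
    } else without
  }

  comp_solve <- function(cvs) {
    nodes <<- nodes + 1L
    if (length(cvs) == 1L) {
      return(list(weight2 = w2[cvs], selected = cvs))
    }
    inset <- logical(nv); inset[cvs] <- TRUE
    degs <- vapply(cvs, deg_in, integer(1), inset = inset)
    if (all(degs <= 2L)) return(line_solve(cvs))
    key <- paste(cvs, collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- cvs[which.max(degs)]
    nb <- adj[[v]]; nb <- nb[inset[nb]]
    incl <- solve_set(setdiff(cvs, c(v, nb)))
    excl <- solve_set(setdiff(cvs, v))
    res <- if (w2[v] + incl$weight2 >= excl$weight2) {
      list(weight2 = w2[v] + incl$weight2, selected = c(v, incl$selected))
    } else excl
    memo[[key]] <- res
    res
  }

  solve_set <- function(vs) {
    if (length(vs) == 0L) return(list(weight2 = 0L, selected = integer(0)))
    parts <- lapply(comps_of(vs), comp_solve)
    list(weight2 = sum(vapply(parts, `[[`, integer(1), "weight2")),
         selected = unlist(lapply(parts, `[[`, "selected")))
  }

  res <- solve_set(seq_len(nv))
  res$nodes <- nodes
  res
}

# brute-force MWIS for cross-checks in the test suite
mwis_brute <- function(nv, w2, adj) {
  if (nv == 0L) return(list(weight2 = 0L, selected = integer(0)))
  if (nv > 22L) stop("mwis_brute: too many vertices")
  best <- -1L; bsel <- integer(0)
  for (mask in 0:(2^nv - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(nv) - 1L)) > 0L)
    ok <- TRUE
    for (v in sel) if (any(adj[[v]] %in% sel)) { ok <- FALSE; break }
    if (!ok) next
    wgt <- sum(w2[sel])
    if (wgt > best) { best <- wgt; bsel <- sel }
  }
  list(weight2 = as.integer(best), selected = bsel)
}
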
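# Linear-time sigma-6 disambiguation.  Pipeline: fix 2-cycles and symmetric
# squares, prune every edge that cannot lie in a sigma-6 player (valid
# {2,4}-path or {4,6}-cycle), split the pruned graph into components, and
# solve each ambiguous component: bounded components by exhausting their
# square resolutions, larger cycle-only components by straight propagation,
# and larger mixed components through the maximum-weight independent set of
# their player intersection graph.

player_dedge_vertices <- function(pl) {
  if (pl$type == "cycle") pl$vertices else pl$vertices[-1L]
}

#' Prune the ambiguous breakpoint graph for the sigma-6 disambiguation
#'
#' Removes, to a fixpoint, every candidate S-edge and every D-edge that is
#' not part of any sigma-6 player among the surviving edges (path-end
#' validity always consults the original telomere statuses).  Squares whose
#' surviving edges all lie in one paralogous pair are thereby resolved and
#' fixed; fully pruned squares are fixed to parallel.  The 6-score of the
#' pruned graph equals that of the full graph.
#'
#' @param abg a `sigmak_abg` after [fix_common()] and
#'   [fix_symmetric_squares()].
#' @return A `sigmak_pg`: the graph plus surviving-edge masks, the player
#'   list, and the partition into connected components.
#' @export
prune <- function(abg) {
  stopifnot(inherits(abg, "sigmak_abg"))
  pres <- masked_present(abg)
  dn <- abg$dnext
  ops <- 0L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    players <- enumerate_players_core(abg$m, dn, abg$sq, pres,
                                      abg$s_telo, abg$d_telo, 6L)
    ops <- ops + length(players) + abg$a_star + sum(dn > 0L) %/% 2L
    cov_s <- matrix(FALSE, abg$a_star, 4L)
    cov_dv <- logical(abg$m)
    if (length(players) > 0L) {
      cov_s[cbind(unlist(lapply(players, `[[`, "squares")),
                  unlist(lapply(players, `[[`, "slots")))] <- TRUE
      cov_dv[unlist(lapply(players, player_dedge_vertices))] <- TRUE
    }
    del_s <- pres & !cov_s
    del_dv <- dn > 0L & !cov_dv
    if (!any(del_s) && !any(del_dv)) break
    pres[del_s] <- FALSE
    dn[del_dv] <- 0L
  }

  # resolve squares from their preserved-edge pattern
  fixed <- abg$fixed; reason <- abg$fix_reason
  ambiguous <- logical(abg$a_star)
  for (i in seq_len(abg$a_star)) {
    if (fixed[i] >= 0L) next
    par_has <- any(pres[i, 1:2]); cro_has <- any(pres[i, 3:4])
    if (par_has && cro_has) {
      ambiguous[i] <- TRUE
    } else if (cro_has) {
      fixed[i] <- 1L; reason[i] <- "pruned"
    } else {
      fixed[i] <- 0L; reason[i] <- if (par_has) "pruned" else "pruned-out"
    }
  }
  abg$fixed <- fixed; abg$fix_reason <- reason

  # connected components of the preserved graph
  sidx <- which(pres)                      # (square, slot) linear indices
  el <- cbind(abg$E1[sidx], abg$E2[sidx])
  du <- which(dn > seq_along(dn))
  if (length(du) > 0L) el <- rbind(el, cbind(du, dn[du]))
  memb <- if (nrow(el) > 0L) {
    g <- igraph::make_graph(edges = as.vector(t(el)), n = abg$m,
                            directed = FALSE)
    as.integer(igraph::components(g)$membership)
  } else rep(1L, abg$m)

  vert_has_edge <- logical(abg$m)
  if (nrow(el) > 0L) vert_has_edge[as.vector(el)] <- TRUE
  comp_ids <- sort(unique(memb[vert_has_edge]))
  cid2idx <- integer(max(memb))
  cid2idx[comp_ids] <- seq_along(comp_ids)

  ncomp <- length(comp_ids)
  by_pos <- function(x, f) {
    out <- vector("list", ncomp)
    sp <- split(x, f)
    out[as.integer(names(sp))] <- sp
    out
  }
  verts_by_comp <- by_pos(which(vert_has_edge), cid2idx[memb[vert_has_edge]])

  # squares attached to each component through their preserved edges
  sqs_by_comp <- vector("list", ncomp)
  if (length(sidx) > 0L) {
    e_sq <- ((sidx - 1L) %% abg$a_star) + 1L
    e_cmp <- cid2idx[memb[abg$E1[sidx]]]
    pairs <- unique(cbind(e_cmp, e_sq))
    sqs_by_comp <- by_pos(pairs[, 2L], pairs[, 1L])
  }

  comps <- vector("list", ncomp)
  for (j in seq_len(ncomp)) {
    sqs <- sqs_by_comp[[j]]
    sqs <- if (is.null(sqs)) integer(0) else sort(sqs)
    comps[[j]] <- list(
      id = j, vertices = verts_by_comp[[j]], squares = sqs,
      amb_squares = sqs[ambiguous[sqs]],
      n_amb = sum(ambiguous[sqs]))
  }

  # players per component (all edges of a player share one component)
  pcomp <- integer(length(players))
  if (length(players) > 0L) {
    first_v <- vapply(players, function(pl) pl$vertices[1L], integer(1))
    pcomp <- cid2idx[memb[first_v]]
  }
  players_by_comp <- by_pos(seq_along(players), pcomp)

  structure(list(abg = abg, present = pres, dnext = dn,
                 ambiguous = ambiguous, players = players,
                 player_comp = pcomp, players_by_comp = players_by_comp,
                 comps = comps,
                 zero_paths = which(abg$s_telo & abg$d_telo),
                 iterations = iter, ops = ops),
            class = "sigmak_pg")
}

#' @export
print.sigmak_pg <- function(x, ...) {
  cat(sprintf("pruned ambiguous breakpoint graph: %d component(s), %d ambiguous square(s), %d player(s)\n",
              length(x$comps), sum(x$ambiguous), length(x$players)))
  invisible(x)
}

comp_players <- function(pg, cid) {
  idx <- pg$players_by_comp[[cid]]
  if (is.null(idx)) list() else pg$players[idx]
}

#' Classify the components of a pruned graph
#'
#' Components with at least one still-ambiguous square are *ambiguous*; all
#' others are *resolved* and must each be a single player (a valid 2/4/6
#' cycle or a valid 2/4 path; isolated common telomeres are the 0-paths).
#' The 6-score of the pruned graph is
#' `|C| + |P|/2 + sum over ambiguous components of their 6-scores`.
#'
#' @param pg a `sigmak_pg` from [prune()].
#' @return List with component indices `C` (resolved cycles), `P` (resolved
#'   paths), `M` (ambiguous components) and `zero_paths` (vertices).
#' @export
classify_components <- function(pg) {
  stopifnot(inherits(pg, "sigmak_pg"))
  C <- integer(0); P <- integer(0); M <- integer(0)
  for (j in seq_along(pg$comps)) {
    comp <- pg$comps[[j]]
    if (comp$n_amb > 0L) { M <- c(M, j); next }
    pls <- comp_players(pg, j)
    match_ok <- FALSE
    for (pl in pls) {
      if (setequal(pl$vertices, comp$vertices)) {
        match_ok <- TRUE
        if (pl$type == "cycle") C <- c(C, j) else P <- c(P, j)
        break
      }
    }
    if (!match_ok) {
      stop("internal: a resolved component of the pruned graph is not a single player")
    }
  }
  list(C = C, P = P, M = M, zero_paths = pg$zero_paths)
}

# Exhaustively resolve the ambiguous squares of one component and score it
# locally (6-score, half units).  `override` optionally fixes the ambiguous
# squares to given choices instead of sweeping.
comp_sweep <- function(pg, cid, override = NULL) {
  abg <- pg$abg
  comp <- pg$comps[[cid]]
  core <- comp$vertices
  verts <- sort(unique(c(core, as.vector(abg$sq[comp$squares, , drop = FALSE]))))
  loc <- function(x) findInterval(x, verts)   # verts is sorted
  mloc <- length(verts)

  dnl <- integer(mloc)
  w <- pg$dnext[core]
  has <- w > 0L
  dnl[loc(core[has])] <- loc(w[has])
  nsq <- length(comp$squares)
  sql <- matrix(loc(as.vector(abg$sq[comp$squares, , drop = FALSE])), nsq, 4L,
                dimnames = list(NULL, colnames(abg$sq)))
  presl <- pg$present[comp$squares, , drop = FALSE] &
    matrix(as.vector(abg$E1[comp$squares, ]) %in% core, nsq, 4L) &
    matrix(as.vector(abg$E2[comp$squares, ]) %in% core, nsq, 4L)
  fixedl <- abg$fixed[comp$squares]
  if (!is.null(override)) {
    stopifnot(length(override) == length(comp$amb_squares))
    fixedl[match(comp$amb_squares, comp$squares)] <- override
  }
  sw <- abg_sweep_core(mloc, dnl, sql, fixedl, presl,
                       abg$s_telo[verts], abg$d_telo[verts])
  list(score2 = sw$best2[3L],
       choice = sw$choice6[match(comp$amb_squares, comp$squares)],
       squares = comp$amb_squares, n_masks = sw$n_masks)
}

paralog_vertex <- function(abg, i, v) {
  r <- abg$sq[i, ]
  if (v == r["ga"]) r[["gb"]]
  else if (v == r["gb"]) r[["ga"]]
  else if (v == r["ba"]) r[["bb"]]
  else if (v == r["bb"]) r[["ba"]]
  else stop("internal: vertex not in square")
}

#' Detect triplet components
#'
#' A triplet is an ambiguous component made of exactly three connected
#' ambiguous squares in which at most two vertices, necessarily in distinct
#' squares, are pruned out.  In a *saturated* triplet every pair of squares
#' is joined by two D-edges connecting paralogous vertices (6-score 2); if
#' one such D-edge is missing the triplet is *unsaturated* (6-score 1).
#' Each detected triplet is scored and resolved by exhausting its at most
#' `2^3` local resolutions.
#'
#' @param pg a `sigmak_pg` from [prune()].
#' @return List of triplets, each with `comp`, `squares`, `kind`, `score`
#'   and the fixed local `choice`.
#' @export
detect_triplets <- function(pg) {
  stopifnot(inherits(pg, "sigmak_pg"))
  abg <- pg$abg
  out <- list()
  for (j in seq_along(pg$comps)) {
    comp <- pg$comps[[j]]
    if (comp$n_amb != 3L || !setequal(comp$squares, comp$amb_squares)) next
    sqs <- sort(comp$amb_squares)
    vsets <- lapply(sqs, function(i) as.integer(abg$sq[i, ]))
    # pruned-out vertices: square vertices with no preserved S-edge
    pruned <- integer(0)
    pruned_sq <- integer(0)
    for (t in 1:3) {
      i <- sqs[t]
      for (v in vsets[[t]]) {
        slots_at_v <- if (v == abg$sq[i, "ga"]) c(1L, 3L)
        else if (v == abg$sq[i, "gb"]) c(2L, 4L)
        else if (v == abg$sq[i, "ba"]) c(1L, 4L) else c(2L, 3L)
        if (!any(pg$present[i, slots_at_v])) {
          pruned <- c(pruned, v); pruned_sq <- c(pruned_sq, t)
        }
      }
    }
    if (length(pruned) > 2L || anyDuplicated(pruned_sq) > 0L) next
    # D-edges between each pair of squares: a pair is "full" when joined by
    # two D-edges connecting paralogous vertices in both squares, "half"
    # when a single one of those D-edges is missing
    pair_kind <- character(3)
    pair_idx <- 0L
    for (t1 in 1:2) for (t2 in (t1 + 1):3) {
      pair_idx <- pair_idx + 1L
      raw <- 0L; par_cnt <- 0L
      for (v in vsets[[t1]]) {
        w <- pg$dnext[v]
        if (w > 0L && w %in% vsets[[t2]]) {
          raw <- raw + 1L
          vh <- paralog_vertex(abg, sqs[t1], v)
          wh <- paralog_vertex(abg, sqs[t2], w)
          if (pg$dnext[vh] == wh) par_cnt <- par_cnt + 1L
        }
      }
      pair_kind[pair_idx] <- if (raw == 2L && par_cnt == 2L) "full"
      else if (raw == 1L && par_cnt == 0L) "half"
      else "other"
    }
    kind <- if (all(pair_kind == "full") && length(pruned) == 0L) "saturated"
    else if (sum(pair_kind == "full") == 2L && sum(pair_kind == "half") == 1L)
      "unsaturated"
    else next
    cs <- comp_sweep(pg, j)
    out[[length(out) + 1L]] <- list(comp = j, squares = sqs, kind = kind,
                                    score = cs$score2 / 2,
                                    choice = cs$choice)
  }
  out
}

#' Straight solution of a cycle-only ambiguous component
#'
#' In a component whose players are all cycles, every candidate S-edge of an
#' ambiguous square lies in exactly one player, so resolving one square
#' propagates uniquely through its neighbors and resolves the whole
#' component (the straight solution).  Its complement (all ambiguous
#' squares switched) is the only alternative; the component is *balanced*
#' when both have the same 6-score, otherwise the better one wins.
#'
#' @param pg a `sigmak_pg`.
#' @param cid component index (must contain no path player).
#' @return List with `choice` and `choice_alt` (per ambiguous square of the
#'   component), their scores, `balanced`, and the winning `best_choice`.
#' @export
straight_bubble_solution <- function(pg, cid) {
  stopifnot(inherits(pg, "sigmak_pg"))
  abg <- pg$abg
  comp <- pg$comps[[cid]]
  if (comp$n_amb == 0L) stop("component has no ambiguous square")
  pls <- comp_players(pg, cid)
  if (any(vapply(pls, `[[`, character(1), "type") == "path")) {
    stop("straight solution requires a component without path players")
  }
  edge2pl <- new.env(parent = emptyenv())
  for (pi in seq_along(pls)) {
    pl <- pls[[pi]]
    for (jj in seq_along(pl$squares)) {
      key <- sprintf("%d.%d", pl$squares[jj], pl$slots[jj])
      edge2pl[[key]] <- c(edge2pl[[key]], pi)
    }
  }
  ambs <- sort(comp$amb_squares)
  choice <- stats::setNames(rep(NA_integer_, length(ambs)), ambs)
  start <- ambs[1L]
  choice[[as.character(start)]] <- if (any(pg$present[start, 1:2])) 0L else 1L
  queue <- start
  while (length(queue) > 0L) {
    q <- queue[[1L]]; queue <- queue[-1L]
    cq <- choice[[as.character(q)]]
    slots <- if (cq == 0L) 1:2 else 3:4
    for (s in slots[pg$present[q, slots]]) {
      pids <- edge2pl[[sprintf("%d.%d", q, s)]]
      if (length(pids) != 1L) {
        stop("internal: a candidate S-edge of a cycle-only component is not in exactly one player")
      }
      pl <- pls[[pids]]
      for (jj in seq_along(pl$squares)) {
        q2 <- pl$squares[jj]
        want <- if (pl$slots[jj] <= 2L) 0L else 1L
        if (q2 %in% ambs) {
          cur <- choice[[as.character(q2)]]
          if (is.na(cur)) {
            choice[[as.character(q2)]] <- want
            queue <- c(queue, q2)
          } else if (cur != want) {
            stop("internal: straight propagation reached a square with conflicting requirements")
          }
        } else if (abg$fixed[q2] >= 0L && abg$fixed[q2] != want) {
          stop("internal: straight propagation conflicts with a resolved square")
        }
      }
    }
  }
  if (anyNA(choice)) {
    stop("internal: straight propagation did not reach every ambiguous square")
  }
  alt <- 1L - choice
  sc <- comp_sweep(pg, cid, override = unname(choice))$score2
  sc_alt <- comp_sweep(pg, cid, override = unname(alt))$score2
  best <- if (sc >= sc_alt) choice else alt
  list(choice = choice, choice_alt = alt, score = sc / 2, score_alt = sc_alt / 2,
       balanced = sc == sc_alt, best_choice = best,
       squares = ambs)
}

#' Intersection graph of an ambiguous component
#'
#' One vertex per player of the component: weight 1/2 for each valid
#' {2,4}-path and weight 1 for each valid {4,6}-cycle; two players are
#' joined by an edge when they intersect (share a vertex of the pruned
#' graph).  A maximum-weight independent set of this graph is an optimal
#' solution of the component.
#'
#' @inheritParams straight_bubble_solution
#' @return A `sigmak_ig` with `players`, weights `w2` (half units) and
#'   adjacency lists `adj`.
#' @export
build_intersection_graph <- function(pg, cid) {
  stopifnot(inherits(pg, "sigmak_pg"))
  pls <- comp_players(pg, cid)
  np <- length(pls)
  w2 <- ifelse(vapply(pls, `[[`, character(1), "type") == "cycle", 2L, 1L)
  byv <- new.env(parent = emptyenv())
  for (pi in seq_len(np)) {
    for (v in pls[[pi]]$vertices) {
      key <- as.character(v)
      byv[[key]] <- c(byv[[key]], pi)
    }
  }
  adj <- vector("list", np)
  for (key in ls(byv)) {
    here <- byv[[key]]
    if (length(here) > 1L) {
      for (pi in here) adj[[pi]] <- union(adj[[pi]], setdiff(here, pi))
    }
  }
  adj <- lapply(adj, function(x) if (is.null(x)) integer(0) else sort(x))
  structure(list(players = pls, w2 = w2, adj = adj, comp = cid),
            class = "sigmak_ig")
}

#' Solve an intersection graph exactly
#'
#' Maximum-weight independent set over the players of an ambiguous
#' component.  Components of the intersection graph with maximum degree two
#' (path-lines, cyclic lines) are solved by the linear alternating dynamic
#' program, which selects the odd-numbered players of an unsaturated line;
#' the remaining structures (double-lines, plug-connected cycle-lines and
#' the bounded exceptional bubbles) are solved exactly by memoized
#' branch-and-reduce with component splitting.
#'
#' @param ig a `sigmak_ig` from [build_intersection_graph()].
#' @return List with `weight` (the component 6-score), `selected` (player
#'   indices) and `nodes` (search-tree size, for linearity checks).
#' @export
solve_flows <- function(ig) {
  stopifnot(inherits(ig, "sigmak_ig"))
  res <- mwis_solve(length(ig$players), ig$w2, ig$adj)
  list(weight = res$weight2 / 2, weight2 = res$weight2,
       selected = sort(res$selected), nodes = res$nodes)
}

#' Sigma-6 disambiguation
#'
#' Computes the maximal 6-score of the ambiguous breakpoint graph (and so
#' the sigma-6 double distance): [fix_common()], [fix_symmetric_squares()],
#' [prune()], then each ambiguous component is solved — components with at
#' most `exhaustive_cap` ambiguous squares by exhausting their resolutions,
#' larger cycle-only components by [straight_bubble_solution()], larger
#' mixed components through [solve_flows()] on their intersection graph.
#' The assembled solution is independently re-scored with [k_score()] and
#' checked against the structural component account.
#'
#' @param abg a `sigmak_abg` from [build_abg()].
#' @param exhaustive_cap solve ambiguous components with at most this many
#'   ambiguous squares by local exhaustion (default 12).
#' @return List with `score`, `tau`, `distance`, `ops` (operation count for
#'   linearity checks), `components` (the [classify_components()] result)
#'   and `triplets` (the [detect_triplets()] report).
#' @export
solve_sigma6 <- function(abg, exhaustive_cap = 12L) {
  stopifnot(inherits(abg, "sigmak_abg"))
  abg <- fix_common(abg)
  abg <- fix_symmetric_squares(abg)
  pg <- prune(abg)
  abg <- pg$abg
  cls <- classify_components(pg)
  trips <- detect_triplets(pg)
  # inside a triplet a D-edge lies in four players and S-edges in two, so
  # triplets always go through local exhaustion, whatever the cap
  triplet_comps <- vapply(trips, `[[`, integer(1), "comp")
  ops <- pg$ops
  fixed <- abg$fixed; reason <- abg$fix_reason
  comp_scores2 <- integer(0)

  for (cid in cls$M) {
    comp <- pg$comps[[cid]]
    if (comp$n_amb <= exhaustive_cap || cid %in% triplet_comps) {
      cs <- comp_sweep(pg, cid)
      ops <- ops + as.integer(cs$n_masks)
      for (jj in seq_along(cs$squares)) {
        q <- cs$squares[jj]
        if (fixed[q] < 0L) { fixed[q] <- cs$choice[jj]; reason[q] <- "component" }
      }
      comp_scores2 <- c(comp_scores2, cs$score2)
      next
    }
    pls <- comp_players(pg, cid)
    has_path <- any(vapply(pls, `[[`, character(1), "type") == "path")
    if (!has_path) {
      sb <- straight_bubble_solution(pg, cid)
      ops <- ops + length(comp$squares)
      for (jj in seq_along(sb$squares)) {
        q <- sb$squares[jj]
        if (fixed[q] < 0L) { fixed[q] <- sb$best_choice[[jj]]; reason[q] <- "bubble" }
      }
      comp_scores2 <- c(comp_scores2, as.integer(2 * max(sb$score, sb$score_alt)))
    } else {
      ig <- build_intersection_graph(pg, cid)
      fl <- solve_flows(ig)
      ops <- ops + fl$nodes + length(ig$players)
      for (pi in fl$selected) {
        upd <- fix_to_player(fixed, reason, ig$players[[pi]], "flow")
        fixed <- upd$fixed; reason <- upd$reason
      }
      for (q in comp$amb_squares) {
        if (fixed[q] < 0L) { fixed[q] <- 0L; reason[q] <- "flow-rest" }
      }
      comp_scores2 <- c(comp_scores2, fl$weight2)
    }
  }

  ch <- ifelse(fixed < 0L, 0L, fixed)
  tau <- as_solution(ch, abg)
  score <- k_score(abg, tau, 6)
  structural2 <- 2L * length(cls$C) + length(cls$P) + length(cls$zero_paths) +
    sum(comp_scores2)
  if (structural2 != 2 * score) {
    stop(sprintf("internal: structural 6-score %s disagrees with the induced graph score %s",
                 structural2 / 2, score))
  }
  list(score = score, tau = tau, distance = 2 * abg$n_star - score,
       ops = ops, components = cls, triplets = trips, pg = pg)
}
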
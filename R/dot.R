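# Graphviz (DOT) export.  Breakpoint graphs follow the usual styling:
# edges colored by genome, telomere vertices tinted by which genome(s) they
# are telomeric in; ambiguous graphs draw candidate S-edges (squares) in
# one color and D-edges in another; intersection graphs label players with
# their kind and weight.

dot_quote <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")

vertex_color <- function(t1, t2) {
  ifelse(t1 & t2, "purple", ifelse(t1, "blue", ifelse(t2, "gray", "white")))
}

#' Export a graph in Graphviz DOT format
#'
#' Supports breakpoint graphs (`sigmak_bg`), ambiguous breakpoint graphs
#' (`sigmak_abg`), pruned graphs (`sigmak_pg`) and intersection graphs
#' (`sigmak_ig`).
#'
#' @param x the graph object.
#' @param path optional output file; when `NULL` the DOT lines are returned.
#' @param ... unused.
#' @return Character vector of DOT lines (invisibly when `path` is given).
#' @export
write_dot <- function(x, path = NULL, ...) UseMethod("write_dot")

finish_dot <- function(lines, path) {
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' @export
write_dot.sigmak_bg <- function(x, path = NULL, ...) {
  t1 <- x$next1 == 0L; t2 <- x$next2 == 0L
  lines <- c("graph breakpoint_graph {", "  node [shape=circle];")
  lines <- c(lines, sprintf("  %s [style=filled, fillcolor=%s];",
                            dot_quote(x$labels),
                            vertex_color(t1, t2)))
  for (v in seq_along(x$labels)) {
    if (x$next1[v] > v) {
      lines <- c(lines, sprintf("  %s -- %s [color=blue];",
                                dot_quote(x$labels[v]),
                                dot_quote(x$labels[x$next1[v]])))
    }
    if (x$next2[v] > v) {
      lines <- c(lines, sprintf("  %s -- %s [color=black];",
                                dot_quote(x$labels[v]),
                                dot_quote(x$labels[x$next2[v]])))
    }
  }
  finish_dot(c(lines, "}"), path)
}

abg_dot_lines <- function(abg, present, dnext, title) {
  lines <- c(sprintf("graph %s {", title), "  node [shape=circle];")
  lines <- c(lines, sprintf("  %s [style=filled, fillcolor=%s];",
                            dot_quote(abg$labels),
                            vertex_color(abg$s_telo, abg$d_telo)))
  for (i in seq_len(abg$a_star)) {
    for (s in 1:4) {
      if (!present[i, s]) next
      e <- slot_ends_r(abg, i, s)
      lines <- c(lines, sprintf("  %s -- %s [color=red, label=\"Q%d\"];",
                                dot_quote(abg$labels[e[1L]]),
                                dot_quote(abg$labels[e[2L]]), i))
    }
  }
  for (v in seq_along(dnext)) {
    if (dnext[v] > v) {
      lines <- c(lines, sprintf("  %s -- %s [color=black];",
                                dot_quote(abg$labels[v]),
                                dot_quote(abg$labels[dnext[v]])))
    }
  }
  c(lines, "}")
}

#' @export
write_dot.sigmak_abg <- function(x, path = NULL, ...) {
  finish_dot(abg_dot_lines(x, masked_present(x), x$dnext,
                           "ambiguous_breakpoint_graph"), path)
}

#' @export
write_dot.sigmak_pg <- function(x, path = NULL, ...) {
  finish_dot(abg_dot_lines(x$abg, x$present, x$dnext, "pruned_graph"), path)
}

#' @export
write_dot.sigmak_ig <- function(x, path = NULL, ...) {
  np <- length(x$players)
  lines <- c("graph intersection_graph {", "  node [shape=box];")
  for (i in seq_len(np)) {
    pl <- x$players[[i]]
    lines <- c(lines, sprintf("  p%d [label=\"%d-%s (w=%s)\"];",
                              i, pl$len, pl$type,
                              ifelse(x$w2[i] == 2L, "1", "1/2")))
  }
  for (i in seq_len(np)) {
    for (j in x$adj[[i]]) if (j > i) {
      lines <- c(lines, sprintf("  p%d -- p%d;", i, j))
    }
  }
  finish_dot(c(lines, "}"), path)
}
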
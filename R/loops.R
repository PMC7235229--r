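#' Census of signed feedback loops
#'
#' Enumerates every directed simple cycle of the network (self-loops count as
#' length-1 cycles) and classifies each by the product of its edge signs:
#' activation contributes +1, inhibition -1. A cycle with an even number of
#' inhibitory edges is a positive feedback loop — e.g. mutual inhibition
#' between two nodes — and positive loops are the topological feature this
#' package correlates with phenotypic plasticity. A cycle is identified by its
#' edge set, so rotations of the same node sequence are counted once.
#'
#' @param net a [signed_network()].
#' @param include_cycles when `TRUE` (default) the individual cycles are
#'   returned alongside the counts.
#' @return list of class `loop_census` with `n_positive`, `n_negative`,
#'   `n_total`, and (optionally) `cycles`, a data frame with columns `cycle`
#'   (node labels joined by `->`, starting at the cycle's smallest node index),
#'   `length` and `sign` (+1 / -1).
#' @examples
#' count_feedback_loops(builtin_network("GRHL2"))
#' @export
count_feedback_loops <- function(net, include_cycles = TRUE) {
  stopifnot(inherits(net, "signed_network"))
  n <- length(net$nodes)
  idx <- stats::setNames(seq_len(n), net$nodes)
  # adjacency: list of integer successor vectors, parallel sign vectors
  succ <- rep(list(integer()), n)
  sgn <- rep(list(integer()), n)
  if (nrow(net$edges)) {
    for (e in seq_len(nrow(net$edges))) {
      u <- idx[[net$edges$from[e]]]; v <- idx[[net$edges$to[e]]]
      succ[[u]] <- c(succ[[u]], v)
      sgn[[u]] <- c(sgn[[u]], if (net$edges$type[e] == 1L) 1L else -1L)
    }
  }
  cycles_nodes <- list()
  cycles_sign <- integer()
  # DFS rooted at each node s, restricted to nodes >= s, so each cycle is
  # found exactly once, rooted at its smallest node index.
  path <- integer(n + 1L)
  onpath <- logical(n)
  dfs <- function(s, v, depth, signprod) {
    nb <- succ[[v]]; ss <- sgn[[v]]
    for (k in seq_along(nb)) {
      w <- nb[k]
      if (w == s) {
        cycles_nodes[[length(cycles_nodes) + 1L]] <<- path[seq_len(depth)]
        cycles_sign[[length(cycles_sign) + 1L]] <<- signprod * ss[k]
      } else if (w > s && !onpath[w]) {
        path[depth + 1L] <<- w
        onpath[w] <<- TRUE
        dfs(s, w, depth + 1L, signprod * ss[k])
        onpath[w] <<- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    path[1L] <- s
    onpath[s] <- TRUE
    dfs(s, s, 1L, 1L)
    onpath[s] <- FALSE
  }
  res <- list(n_positive = sum(cycles_sign > 0L),
              n_negative = sum(cycles_sign < 0L),
              n_total = length(cycles_sign))
  if (include_cycles) {
    res$cycles <- data.frame(
      cycle = vapply(cycles_nodes, function(p)
        paste(net$nodes[c(p, p[1L])], collapse = "->"), character(1)),
      length = lengths(cycles_nodes),
      sign = cycles_sign)
  }
  class(res) <- "loop_census"
  res
}

#' @export
print.loop_census <- function(x, ...) {
  cat(sprintf("loop_census: %d positive, %d negative feedback loop(s)\n",
              x$n_positive, x$n_negative))
  if (!is.null(x$cycles) && nrow(x$cycles)) {
    tag <- ifelse(x$cycles$sign > 0, "+", "-")
    cat(paste0("  [", tag, "] ", x$cycles$cycle, collapse = "\n"), "\n")
  }
  invisible(x)
}
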
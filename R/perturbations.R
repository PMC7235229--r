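#' Enumerate all single-edge perturbations of a network
#'
#' A single-edge perturbation deletes an existing edge, flips its sign
#' (activation to inhibition or vice versa), or adds a hypothetical edge of
#' either sign at an ordered node pair that currently has none (self-pairs
#' included). For a network with `N` nodes and `E` edges this yields
#' `E + E + 2 * (N^2 - E)` perturbations. Perturbations are named
#' `"Source-Target_old-new"` with type codes 0 (absent), 1 (activation),
#' 2 (inhibition), e.g. `"ZEB-GRHL2_2-1"` for a sign flip from inhibition to
#' activation.
#'
#' @param net a [signed_network()].
#' @return data frame with columns `source`, `target`, `old_type`, `new_type`,
#'   `name`, ordered deletions, then sign flips, then additions, each class
#'   lexicographic by source, target (and new type for additions).
#' @seealso [apply_perturbation()]
#' @export
enumerate_perturbations <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  e <- net$edges
  ord <- order(e$from, e$to)
  deletions <- data.frame(source = e$from[ord], target = e$to[ord],
                          old_type = e$type[ord], new_type = 0L)
  flips <- data.frame(source = e$from[ord], target = e$to[ord],
                      old_type = e$type[ord],
                      new_type = ifelse(e$type[ord] == 1L, 2L, 1L))
  pairs <- expand.grid(target = net$nodes, source = net$nodes,
                       stringsAsFactors = FALSE)[, c("source", "target")]
  present <- paste(e$from, e$to, sep = "\r")
  absent <- pairs[!paste(pairs$source, pairs$target, sep = "\r") %in% present, ]
  absent <- absent[order(absent$source, absent$target), ]
  additions <- data.frame(
    source = rep(absent$source, each = 2L),
    target = rep(absent$target, each = 2L),
    old_type = 0L,
    new_type = rep(c(1L, 2L), nrow(absent)))
  out <- rbind(deletions, flips, additions)
  out$name <- paste0(out$source, "-", out$target, "_",
                     out$old_type, "-", out$new_type)
  rownames(out) <- NULL
  out
}

#' Apply a single-edge perturbation
#'
#' @param net a [signed_network()].
#' @param pert a one-row data frame (or list) with fields `source`, `target`,
#'   `old_type`, `new_type` as produced by [enumerate_perturbations()].
#' @return a new [signed_network()]; the input is untouched. The network name
#'   is the perturbation name.
#' @export
apply_perturbation <- function(net, pert) {
  stopifnot(inherits(net, "signed_network"))
  src <- as.character(pert$source); tgt <- as.character(pert$target)
  old <- as.integer(pert$old_type); new <- as.integer(pert$new_type)
  if (old == new) stop("perturbation must change the edge type")
  cur <- edge_type_of(net, src, tgt)
  if (cur != old) {
    stop(sprintf("perturbation %s-%s_%d-%d inconsistent with network: pair has type %d",
                 src, tgt, old, new, cur))
  }
  if (!all(c(src, tgt) %in% net$nodes)) stop("perturbation endpoints must be existing nodes")
  edges <- net$edges
  if (old == 0L) {
    edges <- rbind(edges, data.frame(from = src, to = tgt, type = new))
  } else if (new == 0L) {
    edges <- edges[!(edges$from == src & edges$to == tgt), ]
  } else {
    edges$type[edges$from == src & edges$to == tgt] <- new
  }
  signed_network(edges, nodes = net$nodes,
                 name = paste0(src, "-", tgt, "_", old, "-", new))
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Repeatedly attempts double-edge swaps `(a -> b, c -> d)` to
#' `(a -> d, c -> b)`, each edge's sign travelling with it. Swaps that would
#' create a duplicate ordered pair or a new self-loop are rejected. Every
#' node's in-degree and out-degree are exactly preserved, while the placement
#' of activating and inhibiting links is shuffled — the null model used to ask
#' whether plasticity trends are specific to the wild-type wiring.
#'
#' @param net a [signed_network()] with at least 2 edges (fewer returns a copy).
#' @param n_swap_attempts number of attempted swaps; default `10 * E`.
#' @param name label for the randomized network.
#' @return a [signed_network()] with identical degree sequences and edge-sign
#'   multiset. Uses the current R RNG (seed with `set.seed()`).
#' @export
degree_preserving_randomize <- function(net, n_swap_attempts = NULL,
                                        name = paste0(net$name, "_rand")) {
  stopifnot(inherits(net, "signed_network"))
  edges <- net$edges
  m <- nrow(edges)
  if (is.null(n_swap_attempts)) n_swap_attempts <- 10L * m
  if (m >= 2L && n_swap_attempts > 0L) {
    key <- new.env(hash = TRUE, size = max(2L * m, 16L))
    for (i in seq_len(m)) assign(paste(edges$from[i], edges$to[i], sep = "\r"), TRUE, envir = key)
    for (att in seq_len(n_swap_attempts)) {
      ij <- sample.int(m, 2L)
      i <- ij[1]; j <- ij[2]
      a <- edges$from[i]; b <- edges$to[i]
      c_ <- edges$from[j]; d <- edges$to[j]
      # proposed: a->d and c->b
      if (a == d || c_ == b) next
      k1 <- paste(a, d, sep = "\r"); k2 <- paste(c_, b, sep = "\r")
      if (exists(k1, envir = key, inherits = FALSE) ||
          exists(k2, envir = key, inherits = FALSE)) next
      rm(list = c(paste(a, b, sep = "\r"), paste(c_, d, sep = "\r")), envir = key)
      assign(k1, TRUE, envir = key); assign(k2, TRUE, envir = key)
      edges$to[i] <- d; edges$to[j] <- b
    }
  }
  signed_network(edges, nodes = net$nodes, name = name)
}
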
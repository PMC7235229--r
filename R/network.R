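#' Signed directed regulatory network
#'
#' Constructs a `signed_network`, the central data structure of the package: a
#' directed graph whose edges are either activating (type 1) or inhibiting
#' (type 2). Nodes with no incoming edge are *input nodes*; they are frozen at
#' their initial value in Boolean dynamics and excluded from reported state
#' labels.
#'
#' @param edges data frame with columns `from`, `to` (character node labels)
#'   and `type` (integer, 1 = activation, 2 = inhibition). At most one edge per
#'   ordered `(from, to)` pair.
#' @param nodes optional character vector fixing node order. Defaults to first
#'   appearance order in `edges` (`from` before `to`, row by row). Extra
#'   isolated nodes may be listed here.
#' @param name label for the network (used in reports).
#' @return An object of class `signed_network`: a list with elements `name`,
#'   `nodes` (ordered character vector) and `edges` (data frame `from`, `to`,
#'   `type`).
#' @seealso [read_topo()], [builtin_network()], [random_signed_network()],
#'   [input_nodes()]
#' @examples
#' toggle <- signed_network(data.frame(from = c("A", "B"), to = c("B", "A"),
#'                                     type = c(2L, 2L)), name = "toggle")
#' input_nodes(toggle)
#' @export
signed_network <- function(edges, nodes = NULL, name = "network") {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(), type = integer())
  }
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      type = as.integer(edges$type),
                      stringsAsFactors = FALSE)
  if (nrow(edges) > 0L && !all(edges$type %in% c(1L, 2L))) {
    stop("edge type codes must be 1 (activation) or 2 (inhibition)")
  }
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate edge for ordered pair(s): ",
         paste(unique(gsub("\r", " -> ", key[duplicated(key)])), collapse = ", "))
  }
  appearance <- unique(as.vector(t(as.matrix(edges[, c("from", "to")]))))
  if (is.null(nodes)) {
    nodes <- appearance
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicated node labels")
    missing <- setdiff(appearance, nodes)
    if (length(missing)) {
      stop("edge endpoint(s) not in node list: ", paste(missing, collapse = ", "))
    }
  }
  structure(list(name = name, nodes = nodes, edges = edges),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("signed_network '%s': %d nodes, %d edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  inp <- input_nodes(x)
  if (length(inp)) cat("  input nodes (in-degree 0):", paste(inp, collapse = ", "), "\n")
  if (nrow(x$edges)) {
    arrow <- ifelse(x$edges$type == 1L, "->", "-|")
    cat("  edges:", paste(x$edges$from, arrow, x$edges$to, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Input nodes of a network
#'
#' Input nodes are derived, not declared: every node with in-degree zero. They
#' act as constant external signals (e.g. SNAIL in the GRHL2 circuit).
#'
#' @param net a [signed_network()].
#' @return character vector of node labels (possibly empty), in node order.
#' @export
input_nodes <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  net$nodes[!net$nodes %in% net$edges$to]
}

#' Per-node degree summary
#'
#' @param net a [signed_network()].
#' @return list with `n_nodes`, `n_edges`, and named integer vectors
#'   `in_degree`, `out_degree` (node order).
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  indeg <- table(factor(net$edges$to, levels = net$nodes))
  outdeg <- table(factor(net$edges$from, levels = net$nodes))
  list(n_nodes = length(net$nodes), n_edges = nrow(net$edges),
       in_degree = stats::setNames(as.integer(indeg), net$nodes),
       out_degree = stats::setNames(as.integer(outdeg), net$nodes))
}

# Edge lookup table keyed "from\rto" -> type (0 when absent)
edge_type_of <- function(net, from, to) {
  key <- paste(net$edges$from, net$edges$to, sep = "\r")
  hit <- match(paste(from, to, sep = "\r"), key)
  ifelse(is.na(hit), 0L, net$edges$type[hit])
}

# Regulator index lists, used by both dynamical engines.
# Returns, for each node, 0-based indices of activating and inhibiting
# regulators (in node order).
regulator_lists <- function(net) {
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  act <- inh <- rep(list(integer()), length(net$nodes))
  if (nrow(net$edges)) {
    for (e in seq_len(nrow(net$edges))) {
      tgt <- idx[[net$edges$to[e]]]
      src <- idx[[net$edges$from[e]]] - 1L
      if (net$edges$type[e] == 1L) act[[tgt]] <- c(act[[tgt]], src)
      else inh[[tgt]] <- c(inh[[tgt]], src)
    }
  }
  list(act = act, inh = inh)
}

#' Number of possible projected discrete states
#'
#' The size of the reported state space: `2 ^ k` where `k` is the number of
#' non-input nodes (8 for the GRHL2 circuit, 16 for the OCT4 circuit).
#'
#' @param net a [signed_network()].
#' @return integer count.
#' @export
n_possible_states <- function(net) {
  2L ^ (length(net$nodes) - length(input_nodes(net)))
}
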
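#' Read a network from `.topo` format
#'
#' Parses the whitespace-delimited edge-list format used by the RACIPE family
#' of tools: one row per edge, columns `Source Target Type` with `Type` 1 for
#' activation and 2 for inhibition; an optional header row. Node order is
#' first-appearance order in the file, which fixes the order used in all state
#' labels and reports.
#'
#' @param file path to a `.topo` file, or a character vector of lines, or a
#'   connection.
#' @param name network label; defaults to the file base name (or "network").
#' @return a [signed_network()].
#' @examples
#' read_topo(c("Source Target Type", "ZEB GRHL2 2"))
#' @export
read_topo <- function(file, name = NULL) {
  if (is.character(file) && length(file) == 1L && file.exists(file)) {
    lines <- readLines(file, warn = FALSE)
    if (is.null(name)) name <- sub("\\.topo$", "", basename(file))
  } else if (is.character(file)) {
    lines <- file
  } else {
    lines <- readLines(file, warn = FALSE)
  }
  if (is.null(name)) name <- "network"
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^source\\s+target\\s+type$", tolower(lines[1]))) {
    lines <- lines[-1]
  }
  if (!length(lines)) {
    return(signed_network(NULL, name = name))
  }
  fields <- strsplit(lines, "\\s+")
  if (any(lengths(fields) != 3L)) {
    stop("malformed .topo row(s): expected 'Source Target Type'")
  }
  m <- do.call(rbind, fields)
  type <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(type) || !all(type %in% c(1L, 2L))) {
    stop("invalid edge type code(s) in .topo input (must be 1 or 2)")
  }
  signed_network(data.frame(from = m[, 1], to = m[, 2], type = type),
                 name = name)
}

#' Write a network in `.topo` format
#'
#' Emits a header line `Source Target Type` followed by one row per edge, in
#' edge order. `read_topo(write_topo(net))` is the identity.
#'
#' @param net a [signed_network()].
#' @param file optional path or connection; when `NULL` the lines are returned.
#' @return character vector of lines, invisibly when written to a file.
#' @export
write_topo <- function(net, file = NULL) {
  stopifnot(inherits(net, "signed_network"))
  lines <- c("Source Target Type",
             if (nrow(net$edges))
               paste(net$edges$from, net$edges$to, net$edges$type))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Built-in EMP network topologies
#'
#' Six small regulatory circuits from the epithelial-mesenchymal plasticity
#' literature, shipped as `.topo` files: `GRHL2` (4 nodes, 7 edges), `GRHL2wa`
#' (GRHL2 plus GRHL2 self-activation; 8 edges), `OVOL` (4 nodes, 9 edges,
#' includes OVOL self-inhibition), `OVOLsi` (OVOL without the self-inhibition;
#' 8 edges), `OCT4` (5 nodes, 10 edges) and `NRF2` (8 nodes, 16 edges). SNAIL
#' (or, for NRF2, an external EMT-inducing signal) is the input node.
#'
#' The GRHL2/GRHL2wa edge lists reproduce the published Boolean stable states
#' of those circuits. The OVOL, OCT4 and NRF2 lists are reconstructions
#' constrained by published properties of the circuits: node and edge counts,
#' the signs along the ZEB-miR145-OCT4-miR200-ZEB cycle
#' (inhibition-inhibition-activation-inhibition), the ZEB/E-cadherin mutual
#' inhibition, the miR200-KEAP1-NRF2-SNAIL positive feedback cycle, and the
#' identity and predominance of the epithelial and mesenchymal stable states.
#'
#' @param name one of `"GRHL2"`, `"GRHL2wa"`, `"OVOL"`, `"OVOLsi"`, `"OCT4"`,
#'   `"NRF2"`.
#' @return a [signed_network()].
#' @examples
#' builtin_network("GRHL2")
#' @export
builtin_network <- function(name) {
  known <- c("GRHL2", "GRHL2wa", "OVOL", "OVOLsi", "OCT4", "NRF2")
  if (length(name) != 1L || !name %in% known) {
    stop("unknown built-in network; available: ", paste(known, collapse = ", "))
  }
  path <- system.file("extdata", "topologies", paste0(name, ".topo"),
                      package = "emplast", mustWork = TRUE)
  read_topo(path, name = name)
}

#' Random signed directed network
#'
#' Synthetic-data generator: samples exactly `n_edges` distinct ordered node
#' pairs uniformly at random, each carrying an inhibitory sign with probability
#' `p_inhibition`. Used to exercise every pipeline stage on networks other than
#' the shipped fixtures. Draws from the current R random number generator, so
#' results are reproducible under `set.seed()`.
#'
#' @param n_nodes number of nodes (labelled `N1`, `N2`, ...).
#' @param n_edges number of edges; at most `n_nodes^2` (self-loops allowed) or
#'   `n_nodes * (n_nodes - 1)` (disallowed).
#' @param p_inhibition probability that an edge is inhibitory (type 2).
#' @param allow_self_loops logical.
#' @param name network label.
#' @return a [signed_network()].
#' @examples
#' set.seed(1)
#' random_signed_network(4, 7)
#' @export
random_signed_network <- function(n_nodes, n_edges, p_inhibition = 0.5,
                                  allow_self_loops = FALSE,
                                  name = "random") {
  stopifnot(n_nodes >= 1, n_edges >= 0, p_inhibition >= 0, p_inhibition <= 1)
  capacity <- if (allow_self_loops) n_nodes^2 else n_nodes * (n_nodes - 1L)
  if (n_edges > capacity) {
    stop(sprintf("n_edges = %d exceeds capacity %d for %d nodes",
                 n_edges, capacity, n_nodes))
  }
  nodes <- paste0("N", seq_len(n_nodes))
  pairs <- expand.grid(to = seq_len(n_nodes), from = seq_len(n_nodes))
  pairs <- pairs[, c("from", "to")]
  if (!allow_self_loops) pairs <- pairs[pairs$from != pairs$to, ]
  pick <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
  type <- ifelse(stats::runif(n_edges) < p_inhibition, 2L, 1L)
  signed_network(data.frame(from = nodes[pick$from], to = nodes[pick$to],
                            type = type),
                 nodes = nodes, name = name)
}
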
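#' Discrete state frequency distribution
#'
#' A named numeric vector of frequencies over binary state labels (bit-strings
#' in node order), summing to 1 over its support. The common currency of the
#' package: both the Boolean engine and the discretized ODE ensemble produce
#' one, and [jsd()] compares two of them.
#'
#' @param freq numeric frequencies (non-negative, summing to 1).
#' @param labels character state labels (e.g. `"101"`).
#' @param nodes node labels in bit order.
#' @param fraction_nonconverged optional fraction of simulation runs excluded
#'   from the distribution.
#' @return named numeric vector of class `state_distribution`.
#' @export
state_distribution <- function(freq, labels, nodes = NULL,
                               fraction_nonconverged = NA_real_) {
  stopifnot(length(freq) == length(labels), all(freq >= 0))
  if (length(freq) && abs(sum(freq) - 1) > 1e-9) {
    stop("state frequencies must sum to 1")
  }
  structure(stats::setNames(as.numeric(freq), labels),
            nodes = nodes, fraction_nonconverged = fraction_nonconverged,
            class = "state_distribution")
}

#' @export
print.state_distribution <- function(x, ...) {
  nodes <- attr(x, "nodes")
  if (!is.null(nodes)) cat("states over:", paste(nodes, collapse = ", "), "\n")
  ord <- order(-unclass(x))
  for (i in ord) cat(sprintf("  %s  %.4f\n", names(x)[i], x[i]))
  fnc <- attr(x, "fraction_nonconverged")
  if (!is.na(fnc) && fnc > 0) cat(sprintf("  (non-converged fraction: %.4f)\n", fnc))
  invisible(x)
}

#' Jensen-Shannon divergence between two state distributions
#'
#' `JSD(P || Q) = D(P || M) / 2 + D(Q || M) / 2` with `M = (P + Q) / 2` and `D`
#' the Kullback-Leibler divergence, evaluated with base-2 logarithms so the
#' value lies in `[0, 1]`: 0 for identical distributions, 1 for disjoint
#' supports. Distributions are aligned on the union of their state labels with
#' the convention `0 * log(0 / x) = 0`.
#'
#' @param p,q [state_distribution()]s or named numeric vectors, each summing
#'   to 1.
#' @return scalar divergence in bits.
#' @examples
#' jsd(c(a = 0.5, b = 0.5, c = 0), c(a = 0, b = 0.5, c = 0.5))  # 0.5
#' @export
jsd <- function(p, q) {
  if (is.null(names(p)) || is.null(names(q))) stop("distributions must be named")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("inputs must be normalized distributions (sum to 1)")
  }
  support <- union(names(p), names(q))
  pv <- stats::setNames(numeric(length(support)), support)
  qv <- pv
  pv[names(p)] <- p
  qv[names(q)] <- q
  m <- (pv + qv) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(pv, m) + kl(qv, m)) / 2
}

#' Normalize continuous steady-state expression levels
#'
#' Maps a steady state onto log2 units relative to each node's parameter-set
#' specific scale: `E_in = log2(E_i / f_i)` with normalization factor
#' `f_i = (g_i / k_i) * prod_j lambda_ij`, the product running over the fold
#' changes of *every* incoming edge of node i (activating and inhibiting).
#' Values are floored at 1e-12 before taking logs.
#'
#' @param state numeric concentration vector in node order (or a matrix with
#'   one state per row).
#' @param params a [sample_parameters()] result.
#' @param net a [signed_network()].
#' @return normalized log2 vector (or matrix) in node order.
#' @export
normalize_expression <- function(state, params, net) {
  f <- normalization_factors(params, net)
  stopifnot(all(f > 0))
  if (is.matrix(state)) {
    log2(pmax(state, 1e-12) / rep(f, each = nrow(state)))
  } else {
    log2(pmax(state, 1e-12) / f)
  }
}

# f_i per node for one parameter set
normalization_factors <- function(params, net) {
  f <- params$G / params$k
  if (nrow(net$edges)) {
    for (e in seq_len(nrow(net$edges))) {
      tgt <- match(net$edges$to[e], net$nodes)
      f[tgt] <- f[tgt] * params$edges$lambda[e]
    }
  }
  f
}

#' Discretize an ODE ensemble into binary expression patterns
#'
#' Normalizes every steady state of every parameter set ([normalize_expression()]),
#' pools the normalized levels of the whole ensemble, converts them per node to
#' z-scores about the pooled mean and spread (population standard deviation),
#' and binarizes by sign: z > 0 is 1 (high), z <= 0 is 0 (low). A node with
#' zero pooled spread is set to 0 everywhere with a warning.
#'
#' @param ensemble a [run_ensemble()] result.
#' @return list of class `discretized_ensemble`: `binary` (0/1 matrix, one row
#'   per steady state, columns = nodes), `zscore` and `normalized` matrices,
#'   and `pset` (parameter-set index of each row).
#' @export
discretize_ensemble <- function(ensemble) {
  stopifnot(inherits(ensemble, "racipe_ensemble"))
  states <- ensemble$states
  if (nrow(states) < 2L) stop("need at least 2 steady states to discretize")
  f <- (ensemble$G / ensemble$K)
  if (ncol(ensemble$LAM)) {
    net <- ensemble$network
    for (e in seq_len(nrow(net$edges))) {
      tgt <- match(net$edges$to[e], net$nodes)
      f[, tgt] <- f[, tgt] * ensemble$LAM[, e]
    }
  }
  ein <- log2(pmax(states, 1e-12) / f[ensemble$state_pset, , drop = FALSE])
  mu <- colMeans(ein)
  sdev <- sqrt(colMeans(sweep(ein, 2L, mu)^2))
  zero <- sdev == 0
  if (any(zero)) {
    warning("zero pooled spread for node(s): ",
            paste(colnames(states)[zero], collapse = ", "), "; set to level 0")
    sdev[zero] <- 1
  }
  z <- sweep(sweep(ein, 2L, mu), 2L, sdev, "/")
  binary <- (z > 0) * 1L
  binary[, zero] <- 0L
  structure(list(binary = binary, zscore = z, normalized = ein,
                 pset = ensemble$state_pset, network = ensemble$network,
                 n_converged_psets = ensemble$n_converged_psets),
            class = "discretized_ensemble")
}

#' State frequencies of a discretized ensemble
#'
#' Each parameter set contributes total weight 1, split equally among its `n`
#' distinct steady states (count `1/n` per state — the equal-stability
#' assumption), then normalized by the number of contributing parameter sets.
#'
#' @param disc a [discretize_ensemble()] result.
#' @param report_nodes nodes forming the state label; default the non-input
#'   nodes of the ensemble's network.
#' @return a [state_distribution()].
#' @export
state_frequencies <- function(disc, report_nodes = NULL) {
  stopifnot(inherits(disc, "discretized_ensemble"))
  net <- disc$network
  if (is.null(report_nodes)) report_nodes <- setdiff(net$nodes, input_nodes(net))
  stopifnot(all(report_nodes %in% net$nodes))
  bits <- disc$binary[, match(report_nodes, net$nodes), drop = FALSE]
  labels <- apply(bits, 1L, paste, collapse = "")
  w <- 1 / as.numeric(table(disc$pset)[as.character(disc$pset)])
  total <- tapply(w, labels, sum)
  n_psets <- length(unique(disc$pset))
  state_distribution(as.numeric(total) / n_psets, names(total),
                     nodes = report_nodes)
}

#' Classify discretized states into EMP phenotypes
#'
#' A steady state's phenotype is read off two marker nodes (miR-200 and ZEB by
#' default): (miR200 = 1, ZEB = 0) is epithelial `E`, (1, 1) hybrid `H`,
#' (0, 1) mesenchymal `M`, and (0, 0) — a cell the published three-class scheme
#' leaves unnamed — is kept distinct as `O`.
#'
#' @param binary 0/1 matrix of discretized states (columns named by node), or a
#'   [discretize_ensemble()] result.
#' @param markers length-2 character vector: the epithelial marker (high in E)
#'   and the mesenchymal marker (high in M).
#' @return character vector of calls in `{"E", "H", "M", "O"}`.
#' @export
classify_phenotype <- function(binary, markers = c("miR200", "ZEB")) {
  if (inherits(binary, "discretized_ensemble")) {
    binary <- structure(binary$binary,
                        dimnames = list(NULL, binary$network$nodes))
  }
  if (is.null(dim(binary))) binary <- matrix(binary, nrow = 1L,
                                             dimnames = list(NULL, names(binary)))
  if (!all(markers %in% colnames(binary))) {
    stop("marker node(s) not present: ", paste(setdiff(markers, colnames(binary)),
                                               collapse = ", "))
  }
  e <- binary[, markers[1L]]
  m <- binary[, markers[2L]]
  ifelse(e == 1L & m == 0L, "E",
         ifelse(e == 1L & m == 1L, "H",
                ifelse(e == 0L & m == 1L, "M", "O")))
}

#' Plasticity score 1: fraction of multistable parameter sets
#'
#' The fraction of converged parameter sets whose kinetics support two or more
#' distinct steady states.
#'
#' @param ensemble a [run_ensemble()] result.
#' @return scalar in `[0, 1]`.
#' @export
ps1 <- function(ensemble) {
  stopifnot(inherits(ensemble, "racipe_ensemble"))
  ns <- ensemble$n_states[ensemble$n_states > 0L]
  if (!length(ns)) return(NA_real_)
  mean(ns >= 2L)
}

#' Plasticity score 2: fraction of multi-phenotype parameter sets
#'
#' The biology-centric plasticity score: the fraction of converged parameter
#' sets whose steady states map to two or more distinct phenotype classes
#' ([classify_phenotype()]). A parameter set with several steady states all
#' classified, say, `E` counts as a monostable phase — so `ps2 <= ps1` always.
#'
#' @param disc a [discretize_ensemble()] result (or a [run_ensemble()] result,
#'   discretized on the fly).
#' @param markers passed to [classify_phenotype()].
#' @return scalar in `[0, 1]`.
#' @export
ps2 <- function(disc, markers = c("miR200", "ZEB")) {
  if (inherits(disc, "racipe_ensemble")) disc <- discretize_ensemble(disc)
  stopifnot(inherits(disc, "discretized_ensemble"))
  calls <- classify_phenotype(disc, markers)
  n_pheno <- tapply(calls, disc$pset, function(x) length(unique(x)))
  n_conv <- disc$n_converged_psets
  sum(n_pheno >= 2L) / n_conv
}
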
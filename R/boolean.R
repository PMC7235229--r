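#' Majority-rule update of a single node
#'
#' The Boolean update rule: a node is set to 1 when the number of its
#' activating regulators currently ON exceeds the number of inhibiting
#' regulators ON, to 0 in the opposite case, and is left unchanged on a tie.
#' A node with no regulators (an input node) always ties at 0 = 0 and is
#' therefore frozen at its initial value.
#'
#' @param net a [signed_network()].
#' @param state integer vector of 0/1 values in node order.
#' @param node node label or index to update.
#' @return the node's updated value (0 or 1); equal to its current value when
#'   the update is a hold.
#' @export
majority_update <- function(net, state, node) {
  stopifnot(inherits(net, "signed_network"), length(state) == length(net$nodes))
  if (is.character(node)) node <- match(node, net$nodes)
  if (is.na(node) || node < 1L || node > length(net$nodes)) stop("unknown node")
  regs <- regulator_lists(net)
  a <- sum(state[regs$act[[node]] + 1L])
  i <- sum(state[regs$inh[[node]] + 1L])
  if (a > i) 1L else if (i > a) 0L else as.integer(state[node])
}

#' Asynchronous simulation to a Boolean fixed point
#'
#' Repeatedly picks one node uniformly at random (with replacement) and applies
#' [majority_update()]. The trajectory is declared converged as soon as the
#' state is a fixed point, i.e. no single-node update would change it; runs
#' still changing after `max_steps` updates are flagged non-converged (limit
#' cycles are not analyzed).
#'
#' @param net a [signed_network()].
#' @param init integer 0/1 vector in node order.
#' @param max_steps cap on update steps; default `1000 * n_nodes`.
#' @return list with `initial`, `final` (0/1 vector), `converged` (logical) and
#'   `steps`. Uses the current R RNG.
#' @export
async_fixed_point <- function(net, init, max_steps = NULL) {
  stopifnot(inherits(net, "signed_network"))
  n <- length(net$nodes)
  stopifnot(length(init) == n, all(init %in% c(0L, 1L)))
  if (is.null(max_steps)) max_steps <- 1000L * n
  regs <- regulator_lists(net)
  res <- boolean_runs_cpp(matrix(as.integer(init), nrow = 1L),
                          regs$act, regs$inh, as.integer(max_steps))
  list(initial = as.integer(init),
       final = stats::setNames(as.integer(res$finals[1L, ]), net$nodes),
       converged = as.logical(res$converged[1L]),
       steps = as.integer(res$steps[1L]))
}

#' Exhaustive enumeration of Boolean fixed points
#'
#' Checks every one of the `2^n` full states: a state is a fixed point iff
#' every node's majority update holds or returns its current value. When
#' projecting, input-node columns are dropped and distinct full states that map
#' to the same projected state are merged — this yields the stable-state space
#' the screens report over (e.g. 4 states for the GRHL2 circuit).
#'
#' @param net a [signed_network()] with at most 20 nodes.
#' @param project_out_inputs drop input-node columns and deduplicate (default
#'   `TRUE`).
#' @return integer 0/1 matrix, one row per fixed point, columns named by the
#'   (projected) nodes; rows sorted by their bit-string label.
#' @export
enumerate_fixed_points <- function(net, project_out_inputs = TRUE) {
  stopifnot(inherits(net, "signed_network"))
  n <- length(net$nodes)
  if (n > 20L) stop("exhaustive enumeration guarded at 20 nodes (2^n states)")
  regs <- regulator_lists(net)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))[, seq_len(n), drop = FALSE]
  colnames(grid) <- net$nodes
  act_sum <- inh_sum <- matrix(0L, nrow(grid), n)
  for (v in seq_len(n)) {
    if (length(regs$act[[v]]))
      act_sum[, v] <- rowSums(grid[, regs$act[[v]] + 1L, drop = FALSE])
    if (length(regs$inh[[v]]))
      inh_sum[, v] <- rowSums(grid[, regs$inh[[v]] + 1L, drop = FALSE])
  }
  updated <- ifelse(act_sum > inh_sum, 1L, ifelse(inh_sum > act_sum, 0L, grid))
  fixed <- rowSums(updated != grid) == 0L
  fp <- grid[fixed, , drop = FALSE]
  if (nrow(fp) == 0L) return(fp)
  if (project_out_inputs) {
    keep <- !net$nodes %in% input_nodes(net)
    fp <- fp[, keep, drop = FALSE]
    fp <- fp[!duplicated(apply(fp, 1L, paste, collapse = "")), , drop = FALSE]
  }
  fp[order(apply(fp, 1L, paste, collapse = "")), , drop = FALSE]
}

#' Boolean steady-state frequency distribution
#'
#' Runs asynchronous majority-rule trajectories from initial conditions sampled
#' uniformly over all `2^n` full states (inputs included, so both input levels
#' are explored) and tabulates the projected converged states. Frequencies are
#' normalized over converged runs; the non-converged fraction is reported as an
#' attribute.
#'
#' @param net a [signed_network()].
#' @param n_init number of random initial conditions (10,000 reproduces the
#'   published study conditions).
#' @param max_steps per-run update cap; default `1000 * n_nodes`.
#' @param report_nodes nodes whose values make up the reported state label;
#'   default all non-input nodes of `net`. Passing the wild-type's non-input
#'   node set keeps labels comparable across perturbed topologies.
#' @return a [state_distribution()]: named frequency vector over bit-string
#'   state labels, with attributes `nodes` and `fraction_nonconverged`.
#' @export
boolean_distribution <- function(net, n_init = 10000L, max_steps = NULL,
                                 report_nodes = NULL) {
  stopifnot(inherits(net, "signed_network"), n_init >= 1L)
  n <- length(net$nodes)
  if (is.null(max_steps)) max_steps <- 1000L * n
  if (is.null(report_nodes)) report_nodes <- setdiff(net$nodes, input_nodes(net))
  stopifnot(all(report_nodes %in% net$nodes))
  regs <- regulator_lists(net)
  inits <- matrix(as.integer(stats::runif(n_init * n) < 0.5), n_init, n)
  res <- boolean_runs_cpp(inits, regs$act, regs$inh, as.integer(max_steps))
  conv <- as.logical(res$converged)
  finals <- res$finals[conv, match(report_nodes, net$nodes), drop = FALSE]
  labels <- apply(finals, 1L, paste, collapse = "")
  tab <- table(labels)
  state_distribution(as.numeric(tab) / sum(conv), names(tab),
                     nodes = report_nodes,
                     fraction_nonconverged = 1 - mean(conv))
}
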
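#' Shifted Hill regulatory multiplier
#'
#' `H(B, B0, n, lambda) = B0^n / (B0^n + B^n) + lambda * B^n / (B0^n + B^n)`:
#' equals 1 at zero regulator concentration and approaches the fold change
#' `lambda` at saturation, with `lambda > 1` for activation and `lambda < 1`
#' for inhibition. Vectorized over `B`.
#'
#' @param B regulator concentration(s), non-negative.
#' @param B0 threshold (positive).
#' @param n Hill coefficient (integer >= 1).
#' @param lambda fold change.
#' @return multiplier in `[min(1, lambda), max(1, lambda)]`.
#' @export
shifted_hill <- function(B, B0, n, lambda) {
  if (any(B0 <= 0)) stop("threshold B0 must be positive")
  stopifnot(all(B >= 0), n >= 1)
  bn <- (B / B0)^n  # scaled to avoid overflow for large B
  (1 + lambda * bn) / (1 + bn)
}

# Table of sampling ranges for the random-parameter ensemble
racipe_ranges <- list(G = c(1, 100), k = c(0.1, 1),
                      lambda_inh = c(0.01, 1), lambda_act = c(1, 100),
                      hill_n = c(1L, 6L), threshold_spread = c(0.02, 1.98))

#' Time derivative of the shifted-Hill ODE system
#'
#' For each node T: `dT/dt = G_T * prod_i [H+(P_i)/lambda_i] * prod_j H-(N_j)
#' - k_T * T`, products over T's activators P and inhibitors N. Note the
#' activator term is the shifted Hill function divided by its fold change, so
#' a fully saturated activator contributes multiplier 1 and an absent one
#' `1/lambda`; a node with no regulators relaxes to `G/k`.
#'
#' @param net a [signed_network()].
#' @param params a [sample_parameters()] result.
#' @param x concentration vector in node order (non-negative).
#' @return derivative vector in node order.
#' @export
racipe_rhs <- function(net, params, x) {
  stopifnot(inherits(net, "signed_network"), length(x) == length(net$nodes))
  prod <- rep(1, length(net$nodes))
  ed <- params$edges
  for (e in seq_len(nrow(ed))) {
    tgt <- match(ed$to[e], net$nodes)
    src <- match(ed$from[e], net$nodes)
    h <- shifted_hill(x[src], ed$B0[e], ed$n[e], ed$lambda[e])
    prod[tgt] <- prod[tgt] * if (ed$type[e] == 1L) h / ed$lambda[e] else h
  }
  params$G * prod - params$k * x
}

#' Sample one random kinetic parameter set
#'
#' Draws production rates `G ~ U(1, 100)`, degradation rates `k ~ U(0.1, 1)`,
#' integer Hill coefficients `n ~ U{1..6}`, and fold changes `lambda` uniform
#' on `(1, 100)` for activating and `(0.01, 1)` for inhibiting edges. Each
#' edge's threshold follows the half-functional rule: it is drawn uniformly on
#' `(0.02 M, 1.98 M)` where `M` is the regulator's reference median level, so
#' the regulator typically sits near half-effect. `M` is the median
#' unregulated level `median(G)/median(k)` scaled, for regulated regulators,
#' by the midpoint effective multiplier of each of their own incoming edges
#' (`(1+l)/(2l)` for activation under the divided-Hill convention, `(1+l)/2`
#' for inhibition, at the midpoint `l` of the fold-change range).
#'
#' @param net a [signed_network()].
#' @return list of class `kinetic_params` with `G`, `k` (named numeric, node
#'   order) and `edges` (edge table with columns `from`, `to`, `type`, `B0`,
#'   `n`, `lambda`). Uses the current R RNG.
#' @export
sample_parameters <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  n <- length(net$nodes)
  m <- nrow(net$edges)
  rg <- racipe_ranges
  G <- stats::setNames(stats::runif(n, rg$G[1], rg$G[2]), net$nodes)
  k <- stats::setNames(stats::runif(n, rg$k[1], rg$k[2]), net$nodes)
  ed <- net$edges
  lam <- ifelse(ed$type == 1L,
                stats::runif(m, rg$lambda_act[1], rg$lambda_act[2]),
                stats::runif(m, rg$lambda_inh[1], rg$lambda_inh[2]))
  hills <- sample(rg$hill_n[1]:rg$hill_n[2], m, replace = TRUE)
  M <- threshold_medians(net)
  Msrc <- M[match(ed$from, net$nodes)]
  B0 <- stats::runif(m, rg$threshold_spread[1] * Msrc, rg$threshold_spread[2] * Msrc)
  ed$B0 <- B0
  ed$n <- as.integer(hills)
  ed$lambda <- lam
  structure(list(G = G, k = k, edges = ed), class = "kinetic_params")
}

# Reference median level per node for the half-functional threshold rule.
threshold_medians <- function(net) {
  rg <- racipe_ranges
  base <- stats::median(rg$G) / stats::median(rg$k)  # 50.5 / 0.55
  lam_mid_act <- mean(rg$lambda_act)
  lam_mid_inh <- mean(rg$lambda_inh)
  f_act <- (1 + lam_mid_act) / (2 * lam_mid_act)
  f_inh <- (1 + lam_mid_inh) / 2
  M <- stats::setNames(rep(base, length(net$nodes)), net$nodes)
  for (e in seq_len(nrow(net$edges))) {
    tgt <- net$edges$to[e]
    M[tgt] <- M[tgt] * if (net$edges$type[e] == 1L) f_act else f_inh
  }
  M
}

#' Steady states of one parameter set from random initial conditions
#'
#' Integrates the shifted-Hill system by forward Euler from `n_init` initial
#' conditions sampled log-uniformly on `[0.01, 1e4]` per node, until the
#' largest derivative magnitude drops below `tol` (converged) or `t_max` is
#' reached. Converged endpoints closer than `dedup_tol` (relative, per node)
#' are merged, yielding the parameter set's distinct stable states.
#'
#' @param net a [signed_network()].
#' @param params a [sample_parameters()] result.
#' @param n_init number of initial conditions (100 reproduces the study
#'   conditions).
#' @param dt Euler step (time units).
#' @param t_max integration horizon.
#' @param tol convergence tolerance on `max |dx/dt|`.
#' @param dedup_tol relative per-node tolerance for merging endpoints.
#' @return numeric matrix, one row per distinct steady state (columns = nodes),
#'   with attribute `n_converged` (number of converged trajectories).
#' @export
find_steady_states <- function(net, params, n_init = 100L, dt = 0.1,
                               t_max = 1000, tol = 1e-6, dedup_tol = 0.01) {
  stopifnot(inherits(net, "signed_network"), n_init >= 1L)
  n <- length(net$nodes)
  x0 <- matrix(10^stats::runif(n_init * n, -2, 4), n_init, n)
  ed <- params$edges
  res <- racipe_integrate_cpp(
    x0, as.numeric(params$G), as.numeric(params$k),
    match(ed$from, net$nodes) - 1L, match(ed$to, net$nodes) - 1L,
    as.integer(ed$type == 1L), as.numeric(ed$B0), as.integer(ed$n),
    as.numeric(ed$lambda), dt, t_max, tol)
  conv <- as.logical(res$converged)
  ends <- res$endpoints[conv, , drop = FALSE]
  states <- dedup_states(ends, dedup_tol)
  colnames(states) <- net$nodes
  attr(states, "n_converged") <- sum(conv)
  states
}

# Greedy merge of near-identical endpoints (first occurrence kept).
dedup_states <- function(ends, dedup_tol) {
  if (nrow(ends) == 0L) return(ends)
  kept <- ends[1L, , drop = FALSE]
  for (i in seq_len(nrow(ends))[-1L]) {
    x <- ends[i, ]
    dup <- FALSE
    for (j in seq_len(nrow(kept))) {
      y <- kept[j, ]
      if (all(abs(x - y) <= dedup_tol * pmax(abs(x), abs(y)) + 1e-8)) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept <- rbind(kept, x)
  }
  rownames(kept) <- NULL
  kept
}

#' Run a random-parameter ODE ensemble
#'
#' The continuous, parameter-agnostic arm of the screen: samples `n_param`
#' kinetic parameter sets ([sample_parameters()]), finds each one's distinct
#' steady states from `n_init` random initial conditions
#' ([find_steady_states()]), and collects the results. Each parameter set uses
#' a deterministic RNG substream derived from `seed`, so the ensemble is
#' bit-reproducible and independent of execution order.
#'
#' @param net a [signed_network()].
#' @param n_param number of parameter sets (the study conditions use 10,000;
#'   2,000 gives stable distributions for the small circuits here).
#' @param n_init initial conditions per parameter set.
#' @param seed integer master seed; `NULL` leaves the current RNG state in
#'   charge of picking one.
#' @param dt,t_max,tol,dedup_tol integration settings, see
#'   [find_steady_states()].
#' @param progress print a progress line every 500 parameter sets.
#' @return list of class `racipe_ensemble` with the network, per-parameter-set
#'   matrices `G`, `K`, `LAM`, `B0`, `N` (rows = parameter sets), pooled
#'   steady-state matrix `states` with parallel index `state_pset`, the count
#'   vector `n_states` (0 = no steady state found), `n_converged_psets`, and
#'   the configuration used.
#' @export
run_ensemble <- function(net, n_param, n_init = 100L, seed = NULL, dt = 0.1,
                         t_max = 1000, tol = 1e-6, dedup_tol = 0.01,
                         progress = FALSE) {
  stopifnot(inherits(net, "signed_network"), n_param >= 1L)
  if (!is.null(seed)) set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max, n_param)
  n <- length(net$nodes)
  m <- nrow(net$edges)
  G <- K <- matrix(NA_real_, n_param, n, dimnames = list(NULL, net$nodes))
  ekey <- paste0(net$edges$from, "_", net$edges$to)
  LAM <- B0 <- matrix(NA_real_, n_param, m, dimnames = list(NULL, ekey))
  NH <- matrix(NA_integer_, n_param, m, dimnames = list(NULL, ekey))
  state_list <- vector("list", n_param)
  n_states <- integer(n_param)
  for (i in seq_len(n_param)) {
    set.seed(subseeds[i])
    params <- sample_parameters(net)
    st <- find_steady_states(net, params, n_init = n_init, dt = dt,
                             t_max = t_max, tol = tol, dedup_tol = dedup_tol)
    G[i, ] <- params$G
    K[i, ] <- params$k
    if (m) {
      LAM[i, ] <- params$edges$lambda
      B0[i, ] <- params$edges$B0
      NH[i, ] <- params$edges$n
    }
    n_states[i] <- nrow(st)
    state_list[[i]] <- st
    if (progress && i %% 500L == 0L) {
      message(sprintf("  parameter set %d / %d", i, n_param))
    }
  }
  states <- do.call(rbind, state_list)
  if (is.null(states)) states <- matrix(numeric(), 0L, n)
  colnames(states) <- net$nodes
  structure(list(network = net, G = G, K = K, LAM = LAM, B0 = B0, N = NH,
                 states = states,
                 state_pset = rep(seq_len(n_param), n_states),
                 n_states = n_states,
                 n_converged_psets = sum(n_states > 0L),
                 n_param = n_param, n_init = n_init, seed = seed,
                 config = list(dt = dt, t_max = t_max, tol = tol,
                               dedup_tol = dedup_tol)),
            class = "racipe_ensemble")
}

#' @export
print.racipe_ensemble <- function(x, ...) {
  cat(sprintf("racipe_ensemble '%s': %d parameter sets x %d initial conditions\n",
              x$network$name, x$n_param, x$n_init))
  cat(sprintf("  converged parameter sets: %d; distinct steady states pooled: %d\n",
              x$n_converged_psets, nrow(x$states)))
  tab <- table(x$n_states)
  cat("  states per set:", paste(names(tab), "->", as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}

#' Export an ensemble as plain tables
#'
#' Serializes a [run_ensemble()] result into two data frames in the spirit of
#' RACIPE's parameter/state output files: one row per parameter set with every
#' sampled quantity, and one row per distinct steady state.
#'
#' @param ensemble a [run_ensemble()] result.
#' @return list of data frames `parameters` and `states`, keyed by `pset`.
#' @export
ensemble_tables <- function(ensemble) {
  stopifnot(inherits(ensemble, "racipe_ensemble"))
  pm <- cbind(ensemble$G, ensemble$K, ensemble$B0, ensemble$N, ensemble$LAM)
  colnames(pm) <- c(paste0("G_", colnames(ensemble$G)),
                    paste0("k_", colnames(ensemble$K)),
                    paste0("B0_", colnames(ensemble$B0)),
                    paste0("n_", colnames(ensemble$N)),
                    paste0("lambda_", colnames(ensemble$LAM)))
  params <- data.frame(pset = seq_len(ensemble$n_param),
                       n_states = ensemble$n_states, pm, check.names = FALSE)
  states <- data.frame(pset = ensemble$state_pset, ensemble$states,
                       check.names = FALSE)
  list(parameters = params, states = states)
}
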
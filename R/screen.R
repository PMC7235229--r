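#' Configuration for a screening run
#'
#' Bundles the knobs shared by the screening pipelines. The published study
#' conditions are 10,000 parameter sets and 10,000 Boolean initial conditions;
#' the defaults here (2,000 / 10,000) give stable distributions for the small
#' EMP circuits at a fraction of the cost.
#'
#' @param n_param ODE-ensemble parameter sets per topology.
#' @param n_init_racipe initial conditions per parameter set.
#' @param n_init_boolean Boolean initial conditions per topology.
#' @param seed integer master seed; every topology gets a deterministic
#'   substream, so results do not depend on evaluation order.
#' @param markers phenotype marker pair for [classify_phenotype()] / [ps2()].
#' @param dt,t_max,tol,dedup_tol integrator settings ([find_steady_states()]).
#' @param n_random number of degree-preserving randomizations
#'   ([randomization_screen()]).
#' @param swap_factor attempted swaps per edge during randomization.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(n_param = 2000L, n_init_racipe = 100L,
                          n_init_boolean = 10000L, seed = 1L,
                          markers = c("miR200", "ZEB"), dt = 0.1,
                          t_max = 1000, tol = 1e-6, dedup_tol = 0.01,
                          n_random = 50L, swap_factor = 10L) {
  stopifnot(n_param >= 1L, n_init_racipe >= 1L, n_init_boolean >= 1L,
            n_random >= 0L, swap_factor >= 1L)
  structure(list(n_param = as.integer(n_param),
                 n_init_racipe = as.integer(n_init_racipe),
                 n_init_boolean = as.integer(n_init_boolean),
                 seed = as.integer(seed), markers = markers, dt = dt,
                 t_max = t_max, tol = tol, dedup_tol = dedup_tol,
                 n_random = as.integer(n_random),
                 swap_factor = as.integer(swap_factor)),
            class = "screen_config")
}

# Deterministic per-topology seed substream.
topology_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max, n)
}

# Simulate one topology with both frameworks and measure everything a screen
# record needs. report_nodes fixes the state-label basis (the wild-type's
# non-input nodes) so distributions stay comparable across topologies.
score_topology <- function(net, config, seed, report_nodes,
                           frameworks = c("boolean", "racipe")) {
  out <- list(name = net$name)
  loops <- count_feedback_loops(net, include_cycles = FALSE)
  out$n_positive_loops <- loops$n_positive
  out$n_total_loops <- loops$n_total
  if ("boolean" %in% frameworks) {
    set.seed(seed)
    out$boolean <- boolean_distribution(net, n_init = config$n_init_boolean,
                                        report_nodes = report_nodes)
  }
  if ("racipe" %in% frameworks) {
    ens <- run_ensemble(net, n_param = config$n_param,
                        n_init = config$n_init_racipe, seed = seed + 1L,
                        dt = config$dt, t_max = config$t_max,
                        tol = config$tol, dedup_tol = config$dedup_tol)
    out$ps1 <- ps1(ens)
    if (nrow(ens$states) >= 2L) {
      disc <- discretize_ensemble(ens)
      out$racipe <- state_frequencies(disc, report_nodes = report_nodes)
      out$ps2 <- if (all(config$markers %in% net$nodes))
        ps2(disc, markers = config$markers) else NA_real_
    } else {
      out$racipe <- NULL
      out$ps2 <- NA_real_
    }
  }
  out
}

#' Quantitative convergence of state-frequency distributions
#'
#' Re-simulates a network at increasing sample sizes, several independent
#' replicates per size, and summarizes how the per-state frequency spread
#' shrinks — the analysis used to pick the study's sample sizes.
#'
#' @param net a [signed_network()].
#' @param sizes ascending sample sizes (Boolean initial conditions or
#'   parameter sets).
#' @param n_reps replicates per size (3 reproduces the study conditions).
#' @param framework `"boolean"` or `"racipe"`.
#' @param config a [screen_config()].
#' @return list with `frequencies` (size, rep, state, frequency) and `summary`
#'   (size, state, mean, sd; `sd` is `NA` when `n_reps == 1`).
#' @export
convergence_analysis <- function(net, sizes = c(100L, 1000L, 10000L),
                                 n_reps = 3L, framework = c("boolean", "racipe"),
                                 config = screen_config()) {
  framework <- match.arg(framework)
  stopifnot(!is.unsorted(sizes), n_reps >= 1L)
  seeds <- topology_seeds(config$seed, length(sizes) * n_reps)
  rows <- list()
  i <- 0L
  for (size in sizes) {
    for (rep in seq_len(n_reps)) {
      i <- i + 1L
      set.seed(seeds[i])
      dist <- if (framework == "boolean") {
        boolean_distribution(net, n_init = size)
      } else {
        ens <- run_ensemble(net, n_param = size, n_init = config$n_init_racipe,
                            seed = seeds[i], dt = config$dt,
                            t_max = config$t_max, tol = config$tol,
                            dedup_tol = config$dedup_tol)
        state_frequencies(discretize_ensemble(ens))
      }
      rows[[i]] <- data.frame(size = size, rep = rep, state = names(dist),
                              frequency = as.numeric(dist))
    }
  }
  freq <- do.call(rbind, rows)
  # absent states are true zero frequencies in a replicate
  full <- expand.grid(state = unique(freq$state), rep = seq_len(n_reps),
                      size = sizes, stringsAsFactors = FALSE)
  freq <- merge(full, freq, all.x = TRUE)
  freq$frequency[is.na(freq$frequency)] <- 0
  agg <- stats::aggregate(frequency ~ size + state, freq,
                          function(x) c(mean = mean(x),
                                        sd = if (length(x) > 1L) stats::sd(x) else NA_real_))
  summary <- data.frame(size = agg$size, state = agg$state,
                        mean = agg$frequency[, "mean"], sd = agg$frequency[, "sd"])
  list(frequencies = freq, summary = summary)
}

#' Screen all single-edge perturbations of a network
#'
#' Simulates the wild-type topology and every perturbation from
#' [enumerate_perturbations()] with both frameworks, and records for each: the
#' Boolean and discretized-ensemble state distributions (labelled over the
#' wild-type's non-input nodes so they remain comparable), the JSD of each
#' from the wild-type, plasticity scores, positive/total feedback-loop counts,
#' and plasticity fold changes versus wild-type. Also returns the full
#' pairwise JSD matrix per framework. Per-topology failures are caught and
#' recorded as missing rather than aborting the screen.
#'
#' @param net the wild-type [signed_network()].
#' @param config a [screen_config()].
#' @param frameworks subset of `c("boolean", "racipe")`.
#' @param progress print one line per topology.
#' @return list of class `perturbation_screen` with `records` (data frame, one
#'   row per topology, wild-type first), `pairwise` (named list of JSD
#'   matrices), `distributions` (per framework, named list of
#'   [state_distribution()]s) and `config`.
#' @export
perturbation_screen <- function(net, config = screen_config(),
                                frameworks = c("boolean", "racipe"),
                                progress = FALSE) {
  stopifnot(inherits(net, "signed_network"))
  perts <- enumerate_perturbations(net)
  topologies <- c(list(net), lapply(seq_len(nrow(perts)), function(i)
    apply_perturbation(net, perts[i, ])))
  names(topologies) <- c("WT", perts$name)
  run_screen(topologies, net, config, frameworks, progress)
}

#' Screen degree-preserving randomizations of a network
#'
#' Same measurements as [perturbation_screen()], on `config$n_random`
#' independent degree-preserving rewirings of the wild-type (each scored
#' against the wild-type distributions, which are recomputed as the first
#' record).
#'
#' @inheritParams perturbation_screen
#' @param n_random number of randomized topologies; defaults to
#'   `config$n_random`.
#' @return list of class `perturbation_screen` (records named `rand_<i>`).
#' @export
randomization_screen <- function(net, config = screen_config(),
                                 n_random = NULL,
                                 frameworks = c("boolean", "racipe"),
                                 progress = FALSE) {
  stopifnot(inherits(net, "signed_network"))
  if (is.null(n_random)) n_random <- config$n_random
  seeds <- topology_seeds(config$seed + 211L, max(n_random, 1L))
  topologies <- list(WT = net)
  for (i in seq_len(n_random)) {
    set.seed(seeds[i])
    topologies[[paste0("rand_", i)]] <-
      degree_preserving_randomize(net,
                                  n_swap_attempts = config$swap_factor * nrow(net$edges),
                                  name = paste0("rand_", i))
  }
  run_screen(topologies, net, config, frameworks, progress)
}

run_screen <- function(topologies, wt, config, frameworks, progress) {
  report_nodes <- setdiff(wt$nodes, input_nodes(wt))
  seeds <- topology_seeds(config$seed, length(topologies))
  scores <- vector("list", length(topologies))
  for (i in seq_along(topologies)) {
    scores[[i]] <- tryCatch(
      score_topology(topologies[[i]], config, seeds[i], report_nodes,
                     frameworks),
      error = function(e) {
        warning(sprintf("topology %s failed: %s", names(topologies)[i],
                        conditionMessage(e)))
        list(name = names(topologies)[i], n_positive_loops = NA_integer_,
             n_total_loops = NA_integer_, ps1 = NA_real_, ps2 = NA_real_)
      })
    if (progress) message(sprintf("  [%d/%d] %s", i, length(topologies),
                                  names(topologies)[i]))
  }
  names(scores) <- names(topologies)
  pairwise <- list()
  dists <- list()
  for (fw in frameworks) {
    dl <- lapply(scores, `[[`, fw)
    dists[[fw]] <- dl
    have <- !vapply(dl, is.null, logical(1))
    mat <- matrix(NA_real_, length(dl), length(dl),
                  dimnames = list(names(dl), names(dl)))
    hv <- which(have)
    for (a in hv) for (b in hv) {
      mat[a, b] <- if (a == b) 0 else jsd(dl[[a]], dl[[b]])
    }
    pairwise[[fw]] <- mat
  }
  getnum <- function(field) vapply(scores, function(s)
    if (is.null(s[[field]])) NA_real_ else as.numeric(s[[field]]), numeric(1))
  records <- data.frame(
    name = names(scores),
    n_positive_loops = getnum("n_positive_loops"),
    n_total_loops = getnum("n_total_loops"),
    jsd_boolean = if ("boolean" %in% frameworks) pairwise$boolean[, 1L] else NA_real_,
    jsd_racipe = if ("racipe" %in% frameworks) pairwise$racipe[, 1L] else NA_real_,
    ps1 = getnum("ps1"),
    ps2 = getnum("ps2"),
    row.names = NULL)
  fold <- function(x) if (is.finite(x[1L]) && x[1L] > 0) x / x[1L] else rep(NA_real_, length(x))
  records$ps1_fold <- fold(records$ps1)
  records$ps2_fold <- fold(records$ps2)
  structure(list(records = records, pairwise = pairwise,
                 distributions = dists, config = config),
            class = "perturbation_screen")
}

#' @export
print.perturbation_screen <- function(x, ...) {
  r <- x$records
  cat(sprintf("screen of %d topologies (first row = wild-type)\n", nrow(r)))
  print(utils::head(r[order(-replace(r$jsd_racipe, is.na(r$jsd_racipe),
                                     r$jsd_boolean[is.na(r$jsd_racipe)])), ], 10L))
  invisible(x)
}

#' Correlation and ANOVA summary of screen records
#'
#' Computes the statistical summaries the screens are read through: Spearman
#' rank correlations (PS1 vs PS2; JSD from wild-type vs plasticity fold
#' change; positive-loop count vs plasticity), and a one-way ANOVA of each
#' plasticity score across positive-loop-count groups (groups with fewer than
#' 3 members are dropped and flagged).
#'
#' @param records the `records` data frame of a [perturbation_screen()] /
#'   [randomization_screen()] result (or such a result itself). Needs at least
#'   4 usable rows.
#' @param framework which JSD column to correlate against (`"racipe"` or
#'   `"boolean"`).
#' @return list with data frames `spearman` (pair, rho, p_value, n) and
#'   `anova` (score, F, p_value, n_groups, dropped_groups).
#' @export
correlation_report <- function(records, framework = c("racipe", "boolean")) {
  framework <- match.arg(framework)
  if (inherits(records, "perturbation_screen")) records <- records$records
  stopifnot(nrow(records) >= 4L)
  jsd_col <- paste0("jsd_", framework)
  sp <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 4L) return(c(NA_real_, NA_real_, sum(ok)))
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                           exact = FALSE))
    c(unname(ct$estimate), ct$p.value, sum(ok))
  }
  pairs <- list(
    ps1_vs_ps2 = sp(records$ps1, records$ps2),
    jsd_vs_ps1_fold = sp(records[[jsd_col]], records$ps1_fold),
    jsd_vs_ps2_fold = sp(records[[jsd_col]], records$ps2_fold),
    pos_loops_vs_ps1 = sp(records$n_positive_loops, records$ps1),
    pos_loops_vs_ps2 = sp(records$n_positive_loops, records$ps2))
  spearman <- data.frame(pair = names(pairs),
                         rho = vapply(pairs, `[`, numeric(1), 1L),
                         p_value = vapply(pairs, `[`, numeric(1), 2L),
                         n = vapply(pairs, `[`, numeric(1), 3L),
                         row.names = NULL)
  anova_row <- function(score) {
    ok <- is.finite(records[[score]]) & is.finite(records$n_positive_loops)
    d <- records[ok, ]
    counts <- table(d$n_positive_loops)
    keep <- names(counts)[counts >= 3L]
    d <- d[d$n_positive_loops %in% as.numeric(keep), ]
    if (length(keep) < 2L || length(unique(d[[score]])) == 1L) {
      if (length(keep) >= 2L) {
        # identical scores in every group: no variance to explain
        return(data.frame(score = score, F = 0, p_value = 1,
                          n_groups = length(keep),
                          dropped_groups = length(counts) - length(keep)))
      }
      return(data.frame(score = score, F = NA_real_, p_value = NA_real_,
                        n_groups = length(keep),
                        dropped_groups = length(counts) - length(keep)))
    }
    fit <- stats::aov(d[[score]] ~ factor(d$n_positive_loops))
    s <- summary(fit)[[1L]]
    data.frame(score = score, F = s$`F value`[1L], p_value = s$`Pr(>F)`[1L],
               n_groups = length(keep),
               dropped_groups = length(counts) - length(keep))
  }
  list(spearman = spearman,
       anova = rbind(anova_row("ps1"), anova_row("ps2")))
}
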
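# Discretization, state frequencies, JSD, phenotypes, plasticity scores

test_that("jsd reproduces closed-form cases exactly", {
  p <- c(a = 0.5, b = 0.5, c = 0)
  q <- c(a = 0, b = 0.5, c = 0.5)
  expect_equal(jsd(p, q), 0.5, tolerance = 1e-12)
  expect_equal(jsd(p, p), 0, tolerance = 1e-12)
  expect_equal(jsd(c(x = 1), c(y = 1)), 1, tolerance = 1e-12)
  expect_error(jsd(c(a = 0.4), c(a = 1)), "normalized")
})

test_that("jsd is symmetric, bounded, and matches a brute-force evaluation", {
  set.seed(60)
  for (r in 1:25) {
    k1 <- sample(2:6, 1); k2 <- sample(2:6, 1)
    labs <- paste0("s", 1:8)
    p <- stats::setNames(as.numeric(stats::rmultinom(1, 500, rep(1, k1))) / 500,
                         sample(labs, k1))
    q <- stats::setNames(as.numeric(stats::rmultinom(1, 500, rep(1, k2))) / 500,
                         sample(labs, k2))
    v <- jsd(p, q)
    expect_equal(v, jsd(q, p))
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, oracle_jsd(p, q), tolerance = 1e-12)
  }
})

test_that("expression normalization follows the f_i = (g/k) prod(lambda) rule", {
  net <- make_net(c("A C 1", "B C 2"), nodes = c("A", "B", "C"))
  params <- structure(list(
    G = c(A = 10, B = 20, C = 30), k = c(A = 0.5, B = 0.5, C = 0.6),
    edges = data.frame(from = c("A", "B"), to = "C", type = c(1L, 2L),
                       B0 = 50, n = 2L, lambda = c(4, 0.25))),
    class = "kinetic_params")
  f <- emplast:::normalization_factors(params, net)
  # f_C includes the lambda of every incoming edge, activating and inhibiting
  expect_equal(unname(f["C"]), 30 / 0.6 * 4 * 0.25)
  expect_equal(unname(f["A"]), 20)
  e <- normalize_expression(c(20, 40, 50), params, net)
  expect_equal(unname(e[1]), 0)            # E = f -> log2 ratio 0
  expect_equal(unname(e[2]), log2(40 / 40))
  ee <- normalize_expression(c(40, 40, 100), params, net)
  expect_equal(unname(ee[1]), 1)           # E = 2f -> 1
})

test_that("discretization pools z-scores and binarizes by sign", {
  net <- toggle_switch()
  ens <- run_ensemble(net, n_param = 30, n_init = 20, seed = 5)
  disc <- discretize_ensemble(ens)
  expect_equal(nrow(disc$binary), nrow(ens$states))
  # pooled z-scores are centered per node
  expect_equal(unname(colMeans(disc$zscore)), c(0, 0), tolerance = 1e-10)
  expect_true(all(disc$binary[disc$zscore > 0] == 1L))
  expect_true(all(disc$binary[disc$zscore <= 0] == 0L))
  # two-state pool at -1/+1 gives z-scores -1/+1 under population scaling
  z <- scale(c(-1, 1), scale = FALSE)
  expect_equal(as.numeric(z) / sqrt(mean(as.numeric(z)^2)), c(-1, 1))
})

test_that("state frequencies weight multistable parameter sets by 1/n", {
  disc <- structure(list(
    binary = rbind(c(1L, 0L), c(0L, 1L), c(1L, 0L)),
    pset = c(1L, 1L, 2L),
    network = toggle_switch(),
    n_converged_psets = 2L), class = "discretized_ensemble")
  fr <- state_frequencies(disc)
  # pset 1 contributes 0.5 to each of its two states; pset 2 gives 1 to "10"
  expect_equal(unname(fr[["10"]]), 0.75)
  expect_equal(unname(fr[["01"]]), 0.25)
  expect_equal(sum(fr), 1)
})

test_that("phenotype classification maps the marker quadrants", {
  b <- rbind(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(0L, 0L))
  colnames(b) <- c("miR200", "ZEB")
  expect_equal(classify_phenotype(b), c("E", "H", "M", "O"))
  expect_error(classify_phenotype(b, markers = c("miR200", "nope")),
               "not present")
})

test_that("plasticity scores count multistable and multi-phenotype sets", {
  # synthetic ensemble scaffold: distinct-state counts [1, 2, 1, 3] -> PS1 0.5
  ens <- structure(list(n_states = c(1L, 2L, 1L, 3L)),
                   class = "racipe_ensemble")
  expect_equal(ps1(ens), 0.5)
  expect_equal(ps1(structure(list(n_states = c(1L, 1L)),
                             class = "racipe_ensemble")), 0)
  expect_equal(ps1(structure(list(n_states = c(2L, 4L)),
                             class = "racipe_ensemble")), 1)
  # a multistable set whose states share one phenotype counts for PS1 only
  net <- make_net(c("SNAIL miR200 2", "miR200 ZEB 2", "ZEB miR200 2"),
                  name = "mini")
  # columns in network node order: SNAIL, miR200, ZEB
  disc <- structure(list(
    binary = rbind(c(0L, 1L, 0L), c(0L, 1L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L)),
    pset = c(1L, 1L, 2L, 2L),
    network = net, n_converged_psets = 2L), class = "discretized_ensemble")
  expect_equal(ps2(disc), 0.5)  # only pset 2 mixes phenotypes
})

test_that("PS2 never exceeds PS1 on simulated ensembles", {
  set.seed(73)
  for (nm in c("GRHL2", "OVOL")) {
    net <- builtin_network(nm)
    ens <- run_ensemble(net, n_param = 120, n_init = 30,
                        seed = sample.int(1e6, 1))
    expect_lte(ps2(ens), ps1(ens))
  }
})

test_that("discretization is invariant to parameter-set order", {
  net <- toggle_switch()
  ens <- run_ensemble(net, n_param = 25, n_init = 20, seed = 8)
  fr1 <- state_frequencies(discretize_ensemble(ens))
  # reverse the parameter-set blocks
  perm <- rev(seq_len(ens$n_param))
  rows <- order(match(ens$state_pset, perm))
  ens2 <- ens
  ens2$states <- ens$states[rows, , drop = FALSE]
  ens2$state_pset <- match(ens$state_pset, perm)[rows]
  ens2$G <- ens$G[perm, , drop = FALSE]
  ens2$K <- ens$K[perm, , drop = FALSE]
  ens2$LAM <- ens$LAM[perm, , drop = FALSE]
  ens2$n_states <- ens$n_states[perm]
  fr2 <- state_frequencies(discretize_ensemble(ens2))
  expect_equal(sort(names(fr1)), sort(names(fr2)))
  expect_equal(as.numeric(fr1[sort(names(fr1))]),
               as.numeric(fr2[sort(names(fr2))]), tolerance = 1e-12)
})
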
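# Random-parameter shifted-Hill ODE ensemble

test_that("shifted Hill function hits its closed-form anchor points", {
  expect_equal(shifted_hill(0, 5, 3, 0.1), 1)
  expect_equal(shifted_hill(1e9, 5, 3, 0.1), 0.1, tolerance = 1e-6)
  expect_equal(shifted_hill(1e9, 5, 3, 40), 40, tolerance = 1e-6)
  for (n in 1:6) expect_equal(shifted_hill(5, 5, n, 0.3), (1 + 0.3) / 2)
  expect_error(shifted_hill(1, -2, 3, 0.1), "positive")
  # bounded between 1 and lambda
  b <- shifted_hill(10^seq(-3, 5, 0.5), 7, 4, 0.02)
  expect_true(all(b >= 0.02 & b <= 1))
})

test_that("rhs matches closed-form limits of the regulation terms", {
  iso <- make_net("A B 1", nodes = c("A", "B", "C"))
  set.seed(4)
  p <- sample_parameters(iso)
  # isolated node C: dC/dt = G - k x, zero at G/k
  xstar <- p$G[["C"]] / p$k[["C"]]
  d <- racipe_rhs(iso, p, c(1, 1, xstar))
  expect_equal(d[[3]], 0, tolerance = 1e-12)
  # absent activator (A = 0): dB/dt = G/lambda - k B
  d0 <- racipe_rhs(iso, p, c(0, 2, 1))
  expect_equal(d0[[2]], p$G[["B"]] / p$edges$lambda[1] - p$k[["B"]] * 2)
  # saturated inhibitor: dB/dt -> G * lambda - k B
  inh <- make_net("A B 2", nodes = c("A", "B"))
  set.seed(4)
  pi_ <- sample_parameters(inh)
  dS <- racipe_rhs(inh, pi_, c(1e12, 3))
  expect_equal(dS[[2]], pi_$G[["B"]] * pi_$edges$lambda[1] - pi_$k[["B"]] * 3,
               tolerance = 1e-6)
})

test_that("sampled parameters respect the published ranges", {
  net <- builtin_network("GRHL2")
  set.seed(8)
  draws <- replicate(400, {
    p <- sample_parameters(net)
    c(range(p$G), range(p$k), range(p$edges$n),
      min(p$edges$lambda[p$edges$type == 2L]),
      max(p$edges$lambda[p$edges$type == 2L]),
      min(p$edges$lambda[p$edges$type == 1L]),
      max(p$edges$lambda[p$edges$type == 1L]),
      min(p$edges$B0))
  })
  expect_gte(min(draws[1, ]), 1);    expect_lte(max(draws[2, ]), 100)
  expect_gte(min(draws[3, ]), 0.1);  expect_lte(max(draws[4, ]), 1)
  expect_gte(min(draws[5, ]), 1);    expect_lte(max(draws[6, ]), 6)
  expect_gte(min(draws[7, ]), 0.01); expect_lte(max(draws[8, ]), 1)
  expect_gte(min(draws[9, ]), 1);    expect_lte(max(draws[10, ]), 100)
  expect_gt(min(draws[11, ]), 0)
  # Hill coefficients are integers
  set.seed(9)
  p <- sample_parameters(net)
  expect_true(all(p$edges$n == round(p$edges$n)))
})

test_that("an isolated node relaxes to G/k from any initial condition", {
  net <- signed_network(NULL, nodes = "A", name = "iso")
  set.seed(2)
  p <- sample_parameters(net)
  st <- find_steady_states(net, p, n_init = 20)
  expect_equal(nrow(st), 1L)
  expect_equal(unname(st[1, "A"]), unname(p$G / p$k), tolerance = 1e-4)
  expect_equal(attr(st, "n_converged"), 20L)
})

test_that("a strongly bistable toggle yields exactly the oracle's two states", {
  tog <- toggle_switch()
  G <- 50; k <- 0.5; B0 <- G / (2 * k); n <- 6; lam <- 0.01
  params <- structure(list(
    G = c(A = G, B = G), k = c(A = k, B = k),
    edges = data.frame(from = c("A", "B"), to = c("B", "A"), type = 2L,
                       B0 = B0, n = n, lambda = lam)), class = "kinetic_params")
  set.seed(31)
  st <- find_steady_states(tog, params, n_init = 100)
  expect_equal(nrow(st), 2L)
  # mirror-asymmetric pair: high/low and low/high
  expect_equal(sort(st[, "A"]), sort(st[, "B"]), tolerance = 1e-3)
  expect_gt(max(st[, "A"]) / min(st[, "A"]), 10)
  # independent oracle: roots of the 1-D self-consistency map; the stable
  # fixed points are the outer two of the three roots
  roots <- oracle_toggle_states(G, k, B0, n, lam)
  expect_equal(length(roots), 3L)
  expect_equal(sort(st[, "A"]), range(roots), tolerance = 1e-3)
})

test_that("Euler endpoints agree with a higher-order integrator", {
  skip_if_not_installed("deSolve")
  tog <- toggle_switch()
  params <- structure(list(
    G = c(A = 40, B = 60), k = c(A = 0.4, B = 0.6),
    edges = data.frame(from = c("A", "B"), to = c("B", "A"), type = 2L,
                       B0 = c(60, 70), n = c(4L, 3L), lambda = c(0.05, 0.2))),
    class = "kinetic_params")
  x0s <- rbind(c(1, 200), c(150, 2), c(10, 10))
  ed <- params$edges
  for (i in seq_len(nrow(x0s))) {
    res <- emplast:::racipe_integrate_cpp(
      x0s[i, , drop = FALSE], as.numeric(params$G), as.numeric(params$k),
      match(ed$from, tog$nodes) - 1L, match(ed$to, tog$nodes) - 1L,
      as.integer(ed$type == 1L), ed$B0, as.integer(ed$n), ed$lambda,
      0.1, 1000, 1e-6)
    expect_true(all(res$converged))
    lsoda_end <- deSolve::lsoda(
      y = x0s[i, ], times = c(0, 2000),
      func = function(t, y, ...) list(racipe_rhs(tog, params, y)),
      rtol = 1e-10, atol = 1e-10)[2, 2:3]
    expect_equal(unname(res$endpoints[1, ]), unname(lsoda_end),
                 tolerance = 1e-5)
  }
})

test_that("steady states obey the monotone G/k multiplier bounds", {
  net <- builtin_network("GRHL2")
  set.seed(14)
  for (r in 1:10) {
    p <- sample_parameters(net)
    st <- find_steady_states(net, p, n_init = 30)
    for (i in seq_len(nrow(st))) {
      for (v in net$nodes) {
        inc <- p$edges[p$edges$to == v, ]
        lo <- hi <- p$G[[v]] / p$k[[v]]
        if (nrow(inc)) {
          mults_lo <- ifelse(inc$type == 1L, 1 / inc$lambda, inc$lambda)
          lo <- lo * prod(pmin(mults_lo, 1))
        }
        expect_gte(st[i, v], lo * (1 - 1e-6))
        expect_lte(st[i, v], hi * (1 + 1e-6))
      }
    }
  }
})

test_that("duplicate endpoints are merged and discovery is monotone in n_init", {
  expect_equal(nrow(emplast:::dedup_states(rbind(c(1, 2), c(1.001, 2.002)),
                                           0.01)), 1L)
  expect_equal(nrow(emplast:::dedup_states(rbind(c(1, 2), c(1.5, 2)),
                                           0.01)), 2L)
  tog <- toggle_switch()
  set.seed(55)
  p <- sample_parameters(tog)
  found <- sapply(c(2, 10, 50), function(ni) {
    set.seed(123)
    nrow(find_steady_states(tog, p, n_init = ni))
  })
  expect_true(all(diff(found) >= 0))
})

test_that("ensembles are reproducible from their master seed", {
  net <- builtin_network("GRHL2")
  a <- run_ensemble(net, n_param = 8, n_init = 20, seed = 99)
  b <- run_ensemble(net, n_param = 8, n_init = 20, seed = 99)
  expect_identical(a$states, b$states)
  expect_identical(a$G, b$G)
  expect_equal(a$n_param, 8L)
  expect_equal(length(a$n_states), 8L)
  tabs <- ensemble_tables(a)
  expect_equal(nrow(tabs$parameters), 8L)
  expect_equal(nrow(tabs$states), nrow(a$states))
})
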
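# Shared fixtures and independent brute-force oracles used across tests.

make_net <- function(rows, nodes = NULL, name = "test") {
  m <- do.call(rbind, strsplit(rows, " "))
  signed_network(data.frame(from = m[, 1], to = m[, 2], type = as.integer(m[, 3])),
                 nodes = nodes, name = name)
}

toggle_switch <- function() {
  make_net(c("A B 2", "B A 2"), name = "toggle")
}

# All permutations of a vector (small n only).
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Brute-force signed simple-cycle census: checks every ordered tuple of
# distinct nodes (all lengths), keeps those whose consecutive edges all exist,
# and deduplicates rotations by keeping tuples starting at their smallest
# element. Deliberately naive; independent of count_feedback_loops().
oracle_cycles <- function(net) {
  n <- length(net$nodes)
  sign_of <- function(a, b) {
    t <- edge_type_of(net, a, b)
    if (t == 0L) 0L else if (t == 1L) 1L else -1L
  }
  cycles <- list()
  signs <- integer()
  for (len in seq_len(n)) {
    for (subset in utils::combn(seq_len(n), len, simplify = FALSE)) {
      for (p in perms(subset)) {
        if (p[1L] != min(p)) next  # canonical rotation
        s <- 1L
        ok <- TRUE
        for (i in seq_along(p)) {
          a <- net$nodes[p[i]]
          b <- net$nodes[p[if (i == length(p)) 1L else i + 1L]]
          e <- sign_of(a, b)
          if (e == 0L) { ok <- FALSE; break }
          s <- s * e
        }
        if (ok) {
          cycles[[length(cycles) + 1L]] <- p
          signs[[length(signs) + 1L]] <- s
        }
      }
    }
  }
  list(n_positive = sum(signs > 0L), n_negative = sum(signs < 0L),
       n_total = length(signs))
}

# Direct evaluation of the Jensen-Shannon divergence over an explicit union
# support, independent of jsd()'s implementation.
oracle_jsd <- function(p, q) {
  support <- union(names(p), names(q))
  pv <- ifelse(support %in% names(p), p[support], 0)
  qv <- ifelse(support %in% names(q), q[support], 0)
  m <- (pv + qv) / 2
  term <- function(a) sum(ifelse(a > 0, a * log2(a / m), 0))
  (term(pv) + term(qv)) / 2
}

# Steady states of a symmetric toggle switch (x' = G H-(y) - k x and
# symmetrically) by scanning the 1-D self-consistency map for roots:
# x must satisfy x = (G/k) H-((G/k) H-(x)).
oracle_toggle_states <- function(G, k, B0, n, lam, grid_n = 20000) {
  hminus <- function(b) (1 + lam * (b / B0)^n) / (1 + (b / B0)^n)
  f <- function(x) (G / k) * hminus((G / k) * hminus(x)) - x
  xs <- seq(0, G / k * 1.05, length.out = grid_n)
  fx <- vapply(xs, f, numeric(1))
  roots <- c()
  for (i in seq_len(grid_n - 1L)) {
    if (fx[i] == 0 || (fx[i] > 0) != (fx[i + 1L] > 0)) {
      r <- stats::uniroot(f, c(xs[i], xs[i + 1L]), tol = 1e-10)$root
      roots <- c(roots, r)
    }
  }
  sort(unique(round(roots, 6)))
}
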
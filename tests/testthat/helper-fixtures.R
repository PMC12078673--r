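# Shared fixtures and independent oracles used across the suite.

# Smallest valid junction: two sources A, B draining into outlet C.
y_network <- function() {
  river_network(data.frame(id = c("A", "B", "C"),
                           downstream_id = c("C", "C", NA)))
}

uniform_so_table <- function(max_so = 8, B = 2, S = 0.01, n = 0.035) {
  data.frame(SO = seq_len(max_so), B_m = B, S = S, n = n)
}

# Independent recursive Strahler oracle: postorder recursion straight from
# the definition, no shared code with compute_strahler().
strahler_oracle <- function(net) {
  rec <- function(id) {
    up <- net$upstream[[id]]
    if (length(up) == 0L) return(1L)
    o <- vapply(up, rec, integer(1))
    if (o[1] == o[2]) o[1] + 1L else max(o)
  }
  vapply(net$order, rec, integer(1))
}

# Independent brute-force bisection of the Manning relation on [lo, hi].
bisect_normal_depth <- function(Q, B, S, n, lo = 1e-9, hi = 100,
                                tol = 1e-9) {
  f <- function(H) (1 / n) * (B * H) * (B * H / (B + 2 * H))^(2 / 3) *
    sqrt(S) - Q
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Dense left-eigenvector oracle for the stationary distribution.
eigen_stationary <- function(P) {
  e <- eigen(t(as.matrix(P)))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# A line of junctions: chain of J junctions each fed by two sources, so the
# network has an unambiguous upstream-downstream axis for directional checks.
ladder_network <- function(n_junctions = 3) {
  child <- character(0); parent <- character(0)
  for (j in seq_len(n_junctions)) {
    jid <- paste0("J", j)
    child <- c(child, paste0("s", j, "a"))
    parent <- c(parent, jid)
    second <- if (j < n_junctions) paste0("J", j + 1) else paste0("s", j, "b")
    child <- c(child, second)
    parent <- c(parent, jid)
  }
  river_network_from_edges(data.frame(child_id = child, parent_id = parent))
}
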
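#' Assemble the node-to-node movement transition kernel
#'
#' Each node's movement probability triple is placed on its graph neighbours:
#' junction rows put `p_up1`, `p_up2` on the upstream neighbours and `p_dn` on
#' the downstream one; source rows put probability 1 on their downstream
#' neighbour. The outlet has no downstream neighbour, so its `p_dn` mass is
#' handled by a boundary policy:
#' * `"reflect"` — the outlet's downstream mass is renormalized away, sending
#'   all of it upstream in proportion to `p_up1 : p_up2` (keeps the chain
#'   irreducible on a tree);
#' * `"absorb-self"` — the outlet's `p_dn` becomes a self-loop.
#'
#' A single-node network gets a unit self-loop under either policy.
#'
#' @param net a `river_network`.
#' @param probs table from [network_bias()].
#' @param boundary `"reflect"` (default) or `"absorb-self"`.
#' @return An object of class `transition_kernel`: list with the sparse
#'   row-stochastic matrix `$P` (rows = from, cols = to), node `$ids` and the
#'   `$boundary` tag.
#' @export
build_transition_matrix <- function(net, probs,
                                    boundary = c("reflect", "absorb-self")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(net, "river_network"))
  ids <- net$order
  missing_p <- setdiff(ids, probs$id)
  if (length(missing_p)) {
    stop("probabilities missing for node(s): ",
         paste(missing_p, collapse = ", "))
  }
  probs <- probs[match(ids, probs$id), , drop = FALSE]
  idx <- stats::setNames(seq_along(ids), ids)
  dn <- stats::setNames(net$nodes$downstream_id, net$nodes$id)[ids]

  i <- integer(0); j <- integer(0); v <- numeric(0)
  for (r in seq_along(ids)) {
    id <- ids[r]
    up <- net$upstream[[id]]
    if (length(up) == 0L && !is.na(dn[r])) {          # source
      i <- c(i, r); j <- c(j, idx[dn[r]]); v <- c(v, 1)
      next
    }
    if (length(up) == 0L && is.na(dn[r])) {           # single-node network
      i <- c(i, r); j <- c(j, r); v <- c(v, 1)
      next
    }
    trip <- c(probs$p_up1[r], probs$p_up2[r], probs$p_dn[r])
    if (any(is.na(trip)) || any(trip < 0) ||
        abs(sum(trip) - 1) > 1e-12) {
      stop("probability row for node ", id, " fails the simplex check")
    }
    if (!is.na(dn[r])) {                              # interior junction
      i <- c(i, r, r, r)
      j <- c(j, idx[up[1]], idx[up[2]], idx[dn[r]])
      v <- c(v, trip)
    } else if (boundary == "reflect") {               # outlet
      pu <- trip[1:2] / sum(trip[1:2])
      i <- c(i, r, r); j <- c(j, idx[up[1]], idx[up[2]]); v <- c(v, pu)
    } else {
      i <- c(i, r, r, r)
      j <- c(j, idx[up[1]], idx[up[2]], r)
      v <- c(v, trip)
    }
  }
  P <- Matrix::sparseMatrix(i = i, j = j, x = v,
                            dims = c(length(ids), length(ids)),
                            dimnames = list(ids, ids))
  rs <- Matrix::rowSums(P)
  if (any(abs(rs - 1) > 1e-12)) {
    stop("kernel row(s) not stochastic: ",
         paste(ids[abs(rs - 1) > 1e-12], collapse = ", "))
  }
  structure(list(P = P, ids = ids, boundary = boundary),
            class = "transition_kernel")
}

#' @export
print.transition_kernel <- function(x, ...) {
  cat("transition_kernel:", length(x$ids), "nodes,",
      Matrix::nnzero(x$P), "transitions, boundary =", x$boundary, "\n")
  invisible(x)
}

#' Simulate independent walkers on the movement kernel
#'
#' Each individual moves once per step according to its current node's
#' transition row. Walkers are independent, so each step draws one
#' multinomial per occupied node. Total population is conserved exactly.
#'
#' @param kernel a `transition_kernel`.
#' @param initial named vector of non-negative integer counts per node
#'   (names matching `kernel$ids`; missing nodes start empty).
#' @param steps number of movement steps (>= 1).
#' @param seed integer RNG seed for reproducibility.
#' @return Integer matrix of occupancy, `(steps + 1)` rows (step 0 = initial)
#'   by node columns.
#' @export
simulate_walkers <- function(kernel, initial, steps, seed = 1L) {
  stopifnot(inherits(kernel, "transition_kernel"), steps >= 1)
  ids <- kernel$ids
  counts <- stats::setNames(integer(length(ids)), ids)
  bad <- setdiff(names(initial), ids)
  if (length(bad)) stop("unknown node(s) in initial: ",
                        paste(bad, collapse = ", "))
  counts[names(initial)] <- as.integer(initial)
  if (any(counts < 0)) stop("initial counts must be non-negative")
  if (sum(counts) == 0) stop("initial population is empty")

  P <- as.matrix(kernel$P)  # networks here are small; dense rows are cheap
  occ <- matrix(0L, nrow = steps + 1L, ncol = length(ids),
                dimnames = list(NULL, ids))
  occ[1L, ] <- counts
  set.seed(as.integer(seed))
  for (s in seq_len(steps)) {
    nxt <- integer(length(ids))
    occupied <- which(occ[s, ] > 0L)
    for (r in occupied) {
      moves <- stats::rmultinom(1L, occ[s, r], P[r, ])
      nxt <- nxt + as.integer(moves)
    }
    occ[s + 1L, ] <- nxt
  }
  occ
}

#' Stationary distribution of the movement kernel
#'
#' Left fixed point pi = pi P, found by power iteration on the lazy chain
#' (P + I)/2, which shares the fixed point but is aperiodic even on bipartite
#' tree walks. Irreducibility of the kernel's sparsity pattern is checked
#' first (strong connectivity); a reducible chain is reported, not solved.
#'
#' @param kernel a `transition_kernel`.
#' @param tol fixed-point residual tolerance (default 1e-12).
#' @param max_iter iteration cap.
#' @return Named probability vector over nodes summing to 1, with
#'   `max |pi P - pi| <= tol`.
#' @export
stationary_distribution <- function(kernel, tol = 1e-12, max_iter = 200000L) {
  stopifnot(inherits(kernel, "transition_kernel"))
  P <- kernel$P
  n <- length(kernel$ids)
  if (n == 1L) return(stats::setNames(1, kernel$ids))

  g <- igraph::graph_from_adjacency_matrix(P > 0, mode = "directed")
  if (!igraph::is_connected(g, mode = "strong")) {
    stop("kernel is reducible under boundary policy '", kernel$boundary,
         "': stationary distribution is not unique/reachable")
  }

  pi_v <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    nxt <- 0.5 * (pi_v + as.numeric(Matrix::crossprod(P, pi_v)))
    nxt <- nxt / sum(nxt)
    if (max(abs(nxt - pi_v)) < tol / 2) {
      pi_v <- nxt
      break
    }
    pi_v <- nxt
  }
  resid <- max(abs(as.numeric(Matrix::crossprod(P, pi_v)) - pi_v))
  if (resid > tol * 100) {
    stop("power iteration did not converge (residual ", signif(resid, 3), ")")
  }
  stats::setNames(pi_v, kernel$ids)
}
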
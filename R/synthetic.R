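#' Generate a synthetic binary river network
#'
#' Builds a dendritic (rooted binary) network with a given number of source
#' reaches. `shape = "balanced"` produces a perfect binary tree (n_sources
#' must be a power of two); `shape = "random"` splits the source count
#' recursively at a seeded uniform point, producing varied Strahler-order
#' distributions. A network with L sources always has 2L - 1 nodes.
#'
#' @param n_sources number of source nodes (>= 1).
#' @param shape `"random"` (default) or `"balanced"`.
#' @param seed integer seed; identical seeds give identical networks.
#' @return A validated `river_network` (attributes unassigned).
#' @export
generate_binary_network <- function(n_sources, shape = c("random", "balanced"),
                                    seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(n_sources >= 1)
  if (shape == "balanced" &&
      abs(log2(n_sources) - round(log2(n_sources))) > 1e-9) {
    stop("balanced networks need n_sources to be a power of two")
  }
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("n%04d", counter)
  }
  edges_child <- character(0)
  edges_parent <- character(0)
  set.seed(as.integer(seed))
  grow <- function(n_src) {
    id <- new_id()
    if (n_src > 1L) {
      left_n <- if (shape == "balanced") n_src %/% 2L
                else sample.int(n_src - 1L, 1L)
      for (child_n in c(left_n, n_src - left_n)) {
        child <- grow(child_n)
        edges_child <<- c(edges_child, child)
        edges_parent <<- c(edges_parent, id)
      }
    }
    id
  }
  root <- grow(as.integer(n_sources))
  if (n_sources == 1L) {
    return(river_network(data.frame(id = root, downstream_id = NA)))
  }
  river_network_from_edges(
    data.frame(child_id = edges_child, parent_id = edges_parent,
               stringsAsFactors = FALSE)
  )
}

#' Generate a Strahler-order attribute table
#'
#' Geometric scaling of width and slope with stream order, emulating the
#' downstream trend of natural rivers from narrow, steep headwaters to wide,
#' mild lowland channels: `B(SO) = B1 * width_factor^(SO-1)`,
#' `S(SO) = S1 * slope_factor^(SO-1)`, with roughness constant or per-order.
#'
#' @param max_so largest Strahler order to tabulate.
#' @param base numeric vector `c(B1, S1, n1)`: width (m), slope (-) and
#'   Manning roughness of first-order reaches.
#' @param width_factor multiplicative width growth per order (> 1 for
#'   realistic networks).
#' @param slope_factor multiplicative slope decay per order (< 1 for
#'   realistic networks).
#' @param n_per_so optional vector of length `max_so` overriding roughness
#'   per order.
#' @return data.frame with columns `SO`, `B_m`, `S`, `n`.
#' @export
generate_so_table <- function(max_so, base = c(2.0, 0.02, 0.04),
                              width_factor = 1.6, slope_factor = 0.6,
                              n_per_so = NULL) {
  stopifnot(max_so >= 1, length(base) == 3)
  if (any(base <= 0) || width_factor <= 0 || slope_factor <= 0) {
    stop("base values and factors must be positive")
  }
  so <- seq_len(max_so)
  n_col <- if (is.null(n_per_so)) rep(base[3], max_so) else {
    stopifnot(length(n_per_so) == max_so, all(n_per_so > 0))
    n_per_so
  }
  data.frame(SO = so,
             B_m = base[1] * width_factor^(so - 1),
             S = base[2] * slope_factor^(so - 1),
             n = n_col)
}

#' Generate noisy habitat-suitability samples from a known curve
#'
#' Draws x uniformly over `x_range`, evaluates the curve, adds Gaussian noise
#' and truncates to `[0, 1]`. With `noise_sd = 0` the samples lie exactly on
#' the curve, which makes refitting a round-trip identity check.
#'
#' @param coeffs an `hsc_coefficients` object.
#' @param n number of samples (>= 8).
#' @param noise_sd standard deviation of additive noise (>= 0).
#' @param x_range length-2 range of the hydraulic variable (cm or cm/s).
#' @param seed integer seed.
#' @return data.frame with columns `x`, `hsi`.
#' @export
generate_hsc_samples <- function(coeffs, n = 100L, noise_sd = 0,
                                 x_range = c(0, 200), seed = 1L) {
  stopifnot(inherits(coeffs, "hsc_coefficients"), n >= 8, noise_sd >= 0)
  if (diff(range(x_range)) <= 0) stop("x_range must be a non-empty interval")
  set.seed(as.integer(seed))
  x <- sort(stats::runif(n, x_range[1], x_range[2]))
  y <- eval_hsc(coeffs, x)
  if (noise_sd > 0) {
    y <- pmin(pmax(y + stats::rnorm(n, 0, noise_sd), 0), 1)
  }
  data.frame(x = x, hsi = y)
}
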
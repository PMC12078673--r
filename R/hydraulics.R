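#' Manning discharge for a rectangular channel
#'
#' Q = (1/n) * Omega * Rh^(2/3) * sqrt(S) with wetted area Omega = B*H and
#' hydraulic radius Rh = B*H / (B + 2*H). Kept as a single internal geometry
#' function so alternative cross-sections could be added later.
#'
#' @param H water depth (m)
#' @param B width (m), `S` slope (-), `n` Manning roughness (s m^-1/3)
#' @noRd
manning_q <- function(H, B, S, n) {
  omega <- B * H
  rh <- omega / (B + 2 * H)
  (1 / n) * omega * rh^(2 / 3) * sqrt(S)
}

#' Solve the normal-flow depth of a rectangular reach
#'
#' Inverts the Manning equation for the water depth H at which the reach
#' conveys discharge `Q` under uniform (normal) flow. The conveyance is
#' strictly increasing in H, so the root is unique; it is bracketed starting
#' from the wide-channel estimate `(n*Q / (B*sqrt(S)))^(3/5)` and refined with
#' a guaranteed bracketing root finder.
#'
#' @param Q discharge (m^3/s), > 0.
#' @param B channel width (m), > 0.
#' @param S bed slope (dimensionless), > 0.
#' @param n Manning roughness coefficient (s m^-1/3), > 0.
#' @param tol relative tolerance on the discharge residual
#'   (default `1e-8`, must lie in (0, 1e-3]).
#' @return Water depth H (m) with |Q - Q_manning(H)| <= tol * Q.
#' @examples
#' solve_normal_depth(Q = 0.4, B = 2, S = 0.01, n = 0.035)
#' @export
solve_normal_depth <- function(Q, B, S, n, tol = 1e-8) {
  if (any(!is.finite(c(Q, B, S, n))) || Q <= 0 || B <= 0 || S <= 0 || n <= 0) {
    stop("Q, B, S and n must all be positive and finite")
  }
  if (tol <= 0 || tol > 1e-3) stop("tol must lie in (0, 1e-3]")

  f <- function(H) manning_q(H, B, S, n) - Q
  h_wide <- (n * Q / (B * sqrt(S)))^(3 / 5)  # Rh ~ H limit
  lo <- 1e-6
  hi <- h_wide * 10
  while (f(hi) < 0) {
    hi <- hi * 4
    if (hi > 1e6) stop("failed to bracket normal depth below 1e6 m; ",
                       "inconsistent hydraulic inputs")
  }
  if (f(lo) > 0) lo <- lo / 1e6  # extremely small discharge

  H <- stats::uniroot(f, lower = lo, upper = hi,
                      tol = .Machine$double.eps / 4, maxiter = 5000L)$root
  if (abs(f(H)) > tol * Q) {
    # fall back on plain bisection of the original bracket
    a <- lo; b <- hi
    for (i in 1:2000) {
      H <- (a + b) / 2
      if (abs(f(H)) <= tol * Q) break
      if (f(H) < 0) a <- H else b <- H
    }
    if (abs(f(H)) > tol * Q) {
      stop("normal-depth solver did not reach requested tolerance")
    }
  }
  H
}

#' Mean flow velocity from continuity
#'
#' U = Q / (B * H) for a rectangular section.
#'
#' @param Q discharge (m^3/s), >= 0.
#' @param B width (m), > 0.
#' @param H depth (m), > 0.
#' @return Velocity U (m/s).
#' @export
flow_velocity <- function(Q, B, H) {
  if (any(B <= 0) || any(H <= 0)) stop("B and H must be positive")
  Q / (B * H)
}

#' Solve reach hydraulics for every node of a network
#'
#' Applies the normal-depth solver independently to each reach using its
#' routed discharge and assigned width, slope and roughness.
#'
#' @param net a `river_network` with attributes assigned
#'   (see [assign_reach_attributes()]).
#' @param q_map named discharge vector from [route_discharge()].
#' @param tol relative tolerance passed to [solve_normal_depth()].
#' @return data.frame with one row per node: `id`, `Q_m3s`, `B_m`, `S`, `n`,
#'   `H_m`, `U_ms`, `Omega_m2` (wetted area), `Rh_m` (hydraulic radius).
#' @export
network_hydraulics <- function(net, q_map, tol = 1e-8) {
  stopifnot(inherits(net, "river_network"))
  nd <- net$nodes
  if (any(is.na(nd$B_m) | is.na(nd$S) | is.na(nd$n))) {
    stop("network has unassigned reach attributes; ",
         "call assign_reach_attributes() first")
  }
  missing_q <- setdiff(nd$id, names(q_map))
  if (length(missing_q)) {
    stop("q_map missing node(s): ", paste(missing_q, collapse = ", "))
  }
  q <- as.numeric(q_map[nd$id])
  H <- vapply(seq_len(nrow(nd)), function(i) {
    tryCatch(
      solve_normal_depth(q[i], nd$B_m[i], nd$S[i], nd$n[i], tol = tol),
      error = function(e) {
        stop("node ", nd$id[i], ": ", conditionMessage(e), call. = FALSE)
      }
    )
  }, numeric(1))
  U <- flow_velocity(q, nd$B_m, H)
  data.frame(
    id = nd$id, Q_m3s = q, B_m = nd$B_m, S = nd$S, n = nd$n,
    H_m = H, U_ms = U,
    Omega_m2 = nd$B_m * H,
    Rh_m = nd$B_m * H / (nd$B_m + 2 * H),
    stringsAsFactors = FALSE
  )
}
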
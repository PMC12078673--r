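#' Movement-bias parameters
#'
#' The movement bias b is the signed difference between the probabilities of
#' moving in and against the preferred direction: negative for adults (who
#' drift downstream toward feeding habitat) and positive for juveniles (who
#' head upstream away from competition and predation). The base magnitude
#' |b0| applies when the habitat on both sides is equally good; habitat
#' contrasts rescale it between `b_min` and `b_max` through a Verhulst
#' logistic in the compound-HSI ratio.
#'
#' `b_min` and `b_max` are specified as multipliers of |b0| so that changing
#' the base bias rescales the whole envelope consistently (defaults 1/2 and
#' 2).
#'
#' @param b0_magnitude base bias magnitude |b0| (default 0.1; the sign is
#'   taken from the age class at evaluation time).
#' @param b_min_mult multiplier giving `b_min = b_min_mult * |b0|`;
#'   must lie in (0, 1).
#' @param b_max_mult multiplier giving `b_max = b_max_mult * |b0|`;
#'   must exceed 1 (and `b_max <= 0.5` so probabilities stay in range).
#' @param a sensitivity exponent on the HSI ratio (> 0, default 2).
#' @param sign_convention `"printed"` applies the signed bias directly in the
#'   upstream-probability formula `P_up = (1 - b)/4`; `"narrative"` flips the
#'   sign there so that a negative (adult) bias lowers upstream probability.
#'   See the methods vignette for why both exist.
#' @param hsi_floor positive floor applied to compound HSI before ratios are
#'   formed (default 1e-6); set to `NULL` to error on zero HSI instead.
#' @return An object of class `bias_parameters` with derived fields `b_min`,
#'   `b_max` and the logistic constant `k`.
#' @export
bias_parameters <- function(b0_magnitude = 0.1, b_min_mult = 0.5,
                            b_max_mult = 2, a = 2,
                            sign_convention = c("printed", "narrative"),
                            hsi_floor = 1e-6) {
  sign_convention <- match.arg(sign_convention)
  if (b0_magnitude <= 0) stop("b0_magnitude must be positive")
  if (a <= 0) stop("sensitivity exponent a must be positive")
  b_min <- b_min_mult * b0_magnitude
  b_max <- b_max_mult * b0_magnitude
  if (!(0 < b_min && b_min < b0_magnitude && b0_magnitude < b_max)) {
    stop("need 0 < b_min < |b0| < b_max (check the multipliers)")
  }
  if (b_max > 0.5) stop("b_max must not exceed 0.5 (probability range)")
  if (!is.null(hsi_floor) && hsi_floor <= 0) {
    stop("hsi_floor must be positive or NULL")
  }
  p <- structure(
    list(b0_magnitude = b0_magnitude, b_min = b_min, b_max = b_max, a = a,
         sign_convention = sign_convention, hsi_floor = hsi_floor),
    class = "bias_parameters"
  )
  p$k <- compute_k(p)
  p
}

#' @export
print.bias_parameters <- function(x, ...) {
  cat("bias_parameters: |b0|=", x$b0_magnitude, ", b_min=", x$b_min,
      ", b_max=", x$b_max, ", a=", x$a, ", k=", signif(x$k, 6),
      ", convention=", x$sign_convention, "\n", sep = "")
  invisible(x)
}

#' Logistic constant of the bias curve
#'
#' k = ((b_max - |b0|) / (b_max - b_min)) * (b_min / |b0|). This choice pins
#' the logistic so that an HSI ratio of exactly 1 returns the base bias |b0|.
#' Under the default multipliers (1/2, 2) it equals 1/3. The parameter
#' ordering 0 < b_min < |b0| < b_max guarantees k in (0, 1), so the term
#' k^(ratio^a) decays as the ratio grows.
#'
#' @param params a `bias_parameters` object (or a bare list with fields
#'   `b0_magnitude`, `b_min`, `b_max`).
#' @return k, dimensionless, in (0, 1).
#' @export
compute_k <- function(params) {
  b0 <- params$b0_magnitude
  b_min <- params$b_min
  b_max <- params$b_max
  if (b_max <= b_min) stop("b_max must exceed b_min")
  if (!(0 < b_min && b_min < b0 && b0 < b_max)) {
    stop("need 0 < b_min < |b0| < b_max")
  }
  ((b_max - b0) / (b_max - b_min)) * (b_min / b0)
}

#' Habitat-weighted movement bias toward one adjacent node
#'
#' Verhulst-logistic rescaling of the base bias by the compound-HSI ratio
#' between the candidate node j and the current node i:
#' `b_j = sign(b0) * b_max / (1 + (b_max/b_min - 1) * k^(ratio^a))`.
#' The magnitude runs from `b_min` (ratio -> 0: the destination is much worse,
#' but individuals stay biased toward their preferred direction) through |b0|
#' at ratio 1 up to `b_max` (ratio -> infinity: the destination is far
#' better).
#'
#' @param ratio `HSI_c(j) / HSI_c(i)`, non-negative (vectorised).
#' @param params a `bias_parameters` object.
#' @param age_class `"adult"` (negative bias) or `"juvenile"` (positive).
#' @return Signed bias b_j with `|b_j|` in `[b_min, b_max]`.
#' @examples
#' weighted_bias(1, bias_parameters(), "adult")   # -0.1
#' @export
weighted_bias <- function(ratio, params, age_class = c("adult", "juvenile")) {
  age_class <- match.arg(age_class)
  stopifnot(inherits(params, "bias_parameters"))
  if (any(ratio < 0)) stop("HSI ratio must be non-negative")
  sgn <- if (age_class == "adult") -1 else 1
  # k^(ratio^a) in log space: huge ratios underflow cleanly to 0 (-> b_max)
  logdecay <- ratio^params$a * log(params$k)
  decay <- ifelse(logdecay < -690, 0, exp(logdecay))
  sgn * params$b_max / (1 + (params$b_max / params$b_min - 1) * decay)
}

#' Movement probability triple from two upstream biases
#'
#' Each upstream neighbour j receives `P_up_j = (1 - b_j)/4` and the
#' downstream neighbour the complement `P_dn = 1 - P_up_1 - P_up_2`. Under
#' the `"narrative"` convention the sign of b is flipped inside the formula so
#' that downstream-preferring (negative-bias) fish get the smaller upstream
#' probabilities.
#'
#' @param b1,b2 signed biases toward the two upstream nodes, `|b| <= 1`.
#' @param sign_convention `"printed"` or `"narrative"`.
#' @return Named numeric vector `c(p_up1, p_up2, p_dn)` summing to 1.
#' @export
movement_probabilities <- function(b1, b2,
                                   sign_convention = c("printed",
                                                       "narrative")) {
  sign_convention <- match.arg(sign_convention)
  if (any(abs(c(b1, b2)) > 1)) stop("|bias| must not exceed 1")
  if (sign_convention == "narrative") {
    b1 <- -b1; b2 <- -b2
  }
  p1 <- (1 - b1) / 4
  p2 <- (1 - b2) / 4
  c(p_up1 = p1, p_up2 = p2, p_dn = 1 - p1 - p2)
}

#' Per-node biases and movement probabilities across a network
#'
#' For every junction node i with upstream neighbours j1, j2, computes the
#' HSI ratios `hsi_c(j)/hsi_c(i)`, the weighted biases and the movement
#' probability triple. Source nodes have no upstream choice and move
#' downstream with probability 1. The outlet's triple is computed like any
#' junction; how its downstream mass is handled is decided by the boundary
#' policy when the transition kernel is assembled.
#'
#' @param net a `river_network`.
#' @param hsi table from [network_hsi()] for one age class.
#' @param params a `bias_parameters` object.
#' @param age_class `"adult"` or `"juvenile"`.
#' @return data.frame: `id`, `age_class`, `hsi_c`, `up1`, `up2`, `b_up1`,
#'   `b_up2`, `p_up1`, `p_up2`, `p_dn` (`NA` upstream fields on sources).
#' @export
network_bias <- function(net, hsi, params = bias_parameters(),
                         age_class = c("adult", "juvenile")) {
  age_class <- match.arg(age_class)
  stopifnot(inherits(net, "river_network"), inherits(params, "bias_parameters"))
  missing_h <- setdiff(net$nodes$id, hsi$id)
  if (length(missing_h)) {
    stop("hsi missing for node(s): ", paste(missing_h, collapse = ", "))
  }
  hsi_c <- stats::setNames(hsi$hsi_c, hsi$id)
  if (!is.null(params$hsi_floor)) {
    hsi_c <- pmax(hsi_c, params$hsi_floor)
  }

  ids <- net$order
  out <- data.frame(
    id = ids, age_class = age_class, hsi_c = as.numeric(hsi_c[ids]),
    up1 = NA_character_, up2 = NA_character_,
    b_up1 = NA_real_, b_up2 = NA_real_,
    p_up1 = NA_real_, p_up2 = NA_real_, p_dn = 1,
    stringsAsFactors = FALSE
  )
  for (r in seq_along(ids)) {
    up <- net$upstream[[ids[r]]]
    if (length(up) == 0L) next
    denom <- hsi_c[ids[r]]
    if (denom == 0) {
      stop("compound HSI is zero at node ", ids[r],
           ": ratio undefined (enable hsi_floor)")
    }
    b <- weighted_bias(as.numeric(hsi_c[up]) / as.numeric(denom),
                       params, age_class)
    p <- movement_probabilities(b[1], b[2], params$sign_convention)
    out$up1[r] <- up[1]; out$up2[r] <- up[2]
    out$b_up1[r] <- b[1]; out$b_up2[r] <- b[2]
    out$p_up1[r] <- p["p_up1"]; out$p_up2[r] <- p["p_up2"]
    out$p_dn[r] <- p["p_dn"]
  }
  out
}
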
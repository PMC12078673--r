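#' Habitat suitability curve coefficients
#'
#' Two parametric families describe how suitability responds to a hydraulic
#' variable:
#' * `gaussian_offset`: `c + A * exp(-((x - mu) / sigma)^2)` — bell-shaped
#'   response used for water depth (x in cm);
#' * `gamma_offset`: `c + A * (e/lam)^lam * ((x + u0)/theta)^lam *
#'   exp(-(x + u0)/theta)` — right-skewed response used for flow velocity
#'   (x in cm/s). The leading `(e/lam)^lam` normalizes the gamma kernel so its
#'   maximum equals `c + A`, attained at `x = lam * theta - u0`.
#'
#' @param family `"gaussian_offset"` or `"gamma_offset"`.
#' @param c offset (suitability floor), >= 0.
#' @param A amplitude; `c + A` must not exceed 1 (suitability is an index).
#' @param mu,sigma gaussian centre and width (cm); `sigma > 0`.
#' @param lam,u0,theta gamma shape (-), shift (cm/s) and scale (cm/s);
#'   `lam > 0`, `theta > 0`.
#' @return An object of class `hsc_coefficients`.
#' @export
hsc_coefficients <- function(family = c("gaussian_offset", "gamma_offset"),
                             c, A, mu = NULL, sigma = NULL,
                             lam = NULL, u0 = NULL, theta = NULL) {
  family <- match.arg(family)
  if (c < 0) stop("offset c must be non-negative")
  if (c + A > 1 + 1e-9) stop("c + A exceeds 1: not a suitability curve")
  co <- list(family = family, c = c, A = A)
  if (family == "gaussian_offset") {
    stopifnot(!is.null(mu), !is.null(sigma))
    if (sigma <= 0) stop("sigma must be positive")
    co$mu <- mu; co$sigma <- sigma
  } else {
    stopifnot(!is.null(lam), !is.null(u0), !is.null(theta))
    if (lam <= 0) stop("lam must be positive")
    if (theta <= 0) stop("theta must be positive")
    co$lam <- lam; co$u0 <- u0; co$theta <- theta
  }
  structure(co, class = "hsc_coefficients")
}

#' @export
print.hsc_coefficients <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat("hsc_coefficients [", x$family, "]: ",
      paste(names(pars), signif(unlist(pars), 6), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Default brown-trout suitability-curve library
#'
#' The four curves fitted to the global brown-trout habitat dataset:
#' gaussian-with-offset for water depth (cm) and normalized
#' gamma-with-offset for mean flow velocity (cm/s), for adults and juveniles.
#' Each curve peaks at exactly 1 at its modal depth/velocity and decays to its
#' offset in poor habitat, keeping the suitability floor positive.
#'
#' @return An object of class `hsc_library`: a list with entries
#'   `adult$depth`, `adult$velocity`, `juvenile$depth`, `juvenile$velocity`.
#' @export
default_hsc_library <- function() {
  lib <- list(
    adult = list(
      depth = hsc_coefficients("gaussian_offset", c = 0.1357, A = 0.8643,
                               mu = 51.78, sigma = 35.87),
      velocity = hsc_coefficients("gamma_offset", c = 0.1, A = 0.9,
                                  lam = 1.421, u0 = 12.08, theta = 25.71)
    ),
    juvenile = list(
      depth = hsc_coefficients("gaussian_offset", c = 0.074, A = 0.926,
                               mu = 45.85, sigma = 45.62),
      velocity = hsc_coefficients("gamma_offset", c = 0.06047, A = 0.93953,
                                  lam = 1.113, u0 = 15.1, theta = 32.95)
    )
  )
  structure(lib, class = "hsc_library")
}

#' Evaluate a habitat suitability curve
#'
#' @param coeffs an `hsc_coefficients` object.
#' @param x depth (cm) or velocity (cm/s); non-negative. For the gamma family
#'   `x + u0` must be non-negative.
#' @return Suitability value(s) clamped to `[0, 1]`.
#' @examples
#' lib <- default_hsc_library()
#' eval_hsc(lib$adult$depth, 51.78)  # modal depth -> 1
#' @export
eval_hsc <- function(coeffs, x) {
  stopifnot(inherits(coeffs, "hsc_coefficients"))
  if (any(x < 0)) stop("x must be non-negative")
  if (coeffs$family == "gaussian_offset") {
    v <- coeffs$c + coeffs$A * exp(-((x - coeffs$mu) / coeffs$sigma)^2)
  } else {
    z <- x + coeffs$u0
    if (any(z < 0)) stop("x + u0 is negative: gamma curve undefined")
    lam <- coeffs$lam
    # log-space gamma kernel: avoids overflow of z^lam at large velocity
    logk <- lam * (1 - log(lam)) + lam * log(z / coeffs$theta) - z / coeffs$theta
    k <- ifelse(z == 0 & lam > 0, 0, exp(logk))
    v <- coeffs$c + coeffs$A * k
  }
  pmin(pmax(v, 0), 1)
}

#' Compound habitat suitability index
#'
#' Geometric mean of the depth-based and velocity-based suitability; symmetric,
#' bounded by its inputs, and zero whenever either factor is zero.
#'
#' @param hsi_h,hsi_u suitability values in `[0, 1]`.
#' @return `sqrt(hsi_h * hsi_u)`.
#' @export
compound_hsi <- function(hsi_h, hsi_u) {
  if (any(hsi_h < 0 | hsi_h > 1) || any(hsi_u < 0 | hsi_u > 1)) {
    stop("suitability inputs must lie in [0, 1]")
  }
  sqrt(hsi_h * hsi_u)
}

#' Per-node habitat suitability for one age class
#'
#' Converts solved reach hydraulics from SI units to the curve units
#' (depth m -> cm, velocity m/s -> cm/s; factor 100, applied exactly once
#' here) and evaluates the depth curve, the velocity curve and their compound
#' index at every node.
#'
#' @param net a `river_network`.
#' @param hyd hydraulics table from [network_hydraulics()].
#' @param lib an `hsc_library` (default [default_hsc_library()]).
#' @param age_class `"adult"` or `"juvenile"`.
#' @return data.frame: `id`, `age_class`, `hsi_h`, `hsi_u`, `hsi_c`.
#' @export
network_hsi <- function(net, hyd, lib = default_hsc_library(),
                        age_class = c("adult", "juvenile")) {
  age_class <- match.arg(age_class)
  stopifnot(inherits(net, "river_network"), inherits(lib, "hsc_library"))
  missing_h <- setdiff(net$nodes$id, hyd$id)
  if (length(missing_h)) {
    stop("hydraulics missing for node(s): ", paste(missing_h, collapse = ", "))
  }
  hyd <- hyd[match(net$nodes$id, hyd$id), , drop = FALSE]
  h_cm <- hyd$H_m * 100
  u_cms <- hyd$U_ms * 100
  hsi_h <- eval_hsc(lib[[age_class]]$depth, h_cm)
  hsi_u <- eval_hsc(lib[[age_class]]$velocity, u_cms)
  data.frame(
    id = hyd$id, age_class = age_class,
    hsi_h = hsi_h, hsi_u = hsi_u,
    hsi_c = compound_hsi(hsi_h, hsi_u),
    stringsAsFactors = FALSE
  )
}

#' Fit a habitat suitability curve to samples
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the chosen family to
#' `(x, hsi)` pairs, with a method-of-moments initial guess plus four
#' deterministic jittered restarts to escape local minima (the gamma family is
#' multimodal in its parameters). The best fit by residual sum of squares is
#' returned.
#'
#' @param samples data.frame with columns `x` and `hsi` (in `[0, 1]`);
#'   at least 8 rows.
#' @param family `"gaussian_offset"` or `"gamma_offset"`.
#' @return list with `coefficients` (an `hsc_coefficients`), `r_squared`,
#'   `std_errors` (named vector) and `n`.
#' @export
fit_hsc <- function(samples, family = c("gaussian_offset", "gamma_offset")) {
  family <- match.arg(family)
  stopifnot(is.data.frame(samples), all(c("x", "hsi") %in% names(samples)))
  x <- as.numeric(samples$x); y <- as.numeric(samples$hsi)
  if (length(x) < 8) stop("need at least 8 samples")
  if (any(y < 0 | y > 1)) stop("hsi samples must lie in [0, 1]")
  if (stats::sd(y) < 1e-12) stop("degenerate samples: hsi is constant")

  cc0 <- max(min(y), 0)
  A0 <- max(max(y) - min(y), 1e-3)
  xmode <- x[which.max(y)]

  if (family == "gaussian_offset") {
    w <- pmax(y - cc0, 0)
    sig0 <- sqrt(sum(w * (x - xmode)^2) / max(sum(w), 1e-12))
    sig0 <- max(sig0, diff(range(x)) / 20)
    starts <- list(
      c(mu = xmode, sigma = sig0),
      c(mu = xmode * 0.8, sigma = sig0 * 0.5),
      c(mu = xmode * 1.2, sigma = sig0 * 2),
      c(mu = xmode + sig0, sigma = sig0),
      c(mu = max(xmode - sig0, min(x)), sigma = sig0 * 1.5)
    )
    form <- hsi ~ cc + A * exp(-((x - mu) / sigma)^2)
    fixed <- c(cc = cc0, A = A0)
    lower <- c(cc = 0, A = 1e-6, mu = -Inf, sigma = 1e-6)
  } else {
    starts <- list(
      c(lam = 1.3, u0 = 10, theta = (xmode + 10) / 1.3),
      c(lam = 0.8, u0 = 5, theta = (xmode + 5) / 0.8),
      c(lam = 2.5, u0 = 20, theta = (xmode + 20) / 2.5),
      c(lam = 1.0, u0 = 1, theta = max(xmode, 1)),
      c(lam = 1.8, u0 = 15, theta = (xmode + 15) / 1.8)
    )
    form <- hsi ~ cc + A * exp(lam * (1 - log(lam)) +
                               lam * log((x + u0) / theta) - (x + u0) / theta)
    fixed <- c(cc = cc0, A = A0)
    lower <- c(cc = 0, A = 1e-6, lam = 1e-3, u0 = 1e-9, theta = 1e-6)
  }

  dat <- data.frame(x = x, hsi = y)
  best <- NULL
  best_rss <- Inf
  errs <- character(0)
  for (st in starts) {
    start <- as.list(c(fixed, st))
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = dat, start = start, lower = lower[names(start)],
        control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-14,
                                             ptol = 1e-14)
      )),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      errs <- c(errs, conditionMessage(fit))
      next
    }
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best_rss) {
      best <- fit
      best_rss <- rss
    }
  }
  if (is.null(best)) {
    stop("fit_hsc failed to converge from any start; last errors: ",
         paste(unique(errs), collapse = " | "))
  }

  est <- stats::coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  r2 <- 1 - best_rss / sum((y - mean(y))^2)

  co <- if (family == "gaussian_offset") {
    hsc_coefficients("gaussian_offset", c = unname(est["cc"]),
                     A = min(unname(est["A"]), 1 - unname(est["cc"])),
                     mu = unname(est["mu"]), sigma = abs(unname(est["sigma"])))
  } else {
    hsc_coefficients("gamma_offset", c = unname(est["cc"]),
                     A = min(unname(est["A"]), 1 - unname(est["cc"])),
                     lam = unname(est["lam"]), u0 = unname(est["u0"]),
                     theta = unname(est["theta"]))
  }
  list(coefficients = co, r_squared = r2,
       std_errors = stats::setNames(as.numeric(se), names(est)), n = length(x))
}

#' Read an HSC library from a YAML config file
#'
#' The file has one block per age class with `depth` and `velocity` entries,
#' each giving `family` and its coefficients (see the shipped default at
#' `system.file("extdata", "hsc_default.yaml", package = "troutmove")`).
#'
#' @param path YAML file path.
#' @return An `hsc_library`.
#' @export
read_hsc_library <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("adult", "juvenile")
  if (!all(need %in% names(raw))) {
    stop("HSC library must define blocks: ", paste(need, collapse = ", "))
  }
  lib <- lapply(raw[need], function(block) {
    if (!all(c("depth", "velocity") %in% names(block))) {
      stop("each age-class block needs 'depth' and 'velocity' entries")
    }
    lapply(block[c("depth", "velocity")], function(e) {
      args <- e
      args$family <- NULL
      do.call(hsc_coefficients, c(list(family = e$family), args))
    })
  })
  structure(lib, class = "hsc_library")
}
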
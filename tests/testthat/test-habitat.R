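lib <- default_hsc_library()

test_that("default curves hit their analytic peaks and asymptotes", {
  # gaussian peak at the modal depth = offset + amplitude
  expect_equal(eval_hsc(lib$adult$depth, 51.78), 0.1357 + 0.8643)
  expect_equal(eval_hsc(lib$juvenile$depth, 45.85), 0.074 + 0.926)
  # gamma peak at x = lam * theta - u0
  expect_equal(eval_hsc(lib$adult$velocity, 1.421 * 25.71 - 12.08), 1.0,
               tolerance = 1e-12)
  expect_equal(eval_hsc(lib$juvenile$velocity, 1.113 * 32.95 - 15.1), 1.0,
               tolerance = 1e-12)
  # tails decay to the offsets
  expect_equal(eval_hsc(lib$adult$depth, 1e6), 0.1357)
  expect_equal(eval_hsc(lib$juvenile$depth, 1e6), 0.074)
  expect_equal(eval_hsc(lib$adult$velocity, 1e6), 0.1)
  expect_equal(eval_hsc(lib$juvenile$velocity, 1e6), 0.06047)
})

test_that("all default curves stay within [0,1] and peak at their argmax", {
  grid <- seq(0, 300, by = 0.1)
  argmax <- list(
    adult_depth = c(lib$adult$depth, 51.78),
    juv_depth = c(lib$juvenile$depth, 45.85),
    adult_vel = c(lib$adult$velocity, 1.421 * 25.71 - 12.08),
    juv_vel = c(lib$juvenile$velocity, 1.113 * 32.95 - 15.1)
  )
  for (cls in c("adult", "juvenile")) {
    for (var in c("depth", "velocity")) {
      v <- eval_hsc(lib[[cls]][[var]], grid)
      expect_true(all(v >= 0 & v <= 1), info = paste(cls, var))
    }
  }
  # maximum attained at the analytic argmax within 1e-6
  for (a in argmax) {
    co <- structure(a[seq_len(length(a) - 1)], class = "hsc_coefficients")
    x_star <- a[[length(a)]]
    expect_equal(eval_hsc(co, x_star), 1, tolerance = 1e-6)
    expect_lte(max(eval_hsc(co, grid)), eval_hsc(co, x_star) + 1e-12)
  }
})

test_that("gamma curve rejects negative shifted arguments", {
  co <- hsc_coefficients("gamma_offset", c = 0.1, A = 0.9,
                         lam = 1.5, u0 = -5, theta = 20)
  expect_error(eval_hsc(co, 1), "undefined")
  expect_error(eval_hsc(lib$adult$depth, -1), "non-negative")
})

test_that("compound HSI is the geometric mean with its algebraic properties", {
  expect_equal(compound_hsi(1, 1), 1)
  expect_equal(compound_hsi(0.25, 1), 0.5)
  expect_equal(compound_hsi(0, 0.9), 0)
  set.seed(11)
  a <- runif(100); b <- runif(100)
  expect_equal(compound_hsi(a, b), compound_hsi(b, a))
  expect_equal(compound_hsi(a, a), a)
  expect_true(all(compound_hsi(a, b) <= pmax(a, b) + 1e-15))
  expect_true(all(compound_hsi(a, b) >= pmin(a, b) - 1e-15))
  expect_error(compound_hsi(1.2, 0.5), "\\[0, 1\\]")
})

test_that("network HSI converts SI units once and is deterministic", {
  y <- assign_reach_attributes(y_network(), uniform_so_table())
  hyd <- network_hydraulics(y, route_discharge(y, 0.2))
  # forge a node with the modal adult depth: H = 0.5178 m -> hsi_h = 1
  hyd$H_m[1] <- 0.5178
  hsi <- network_hsi(y, hyd, lib, "adult")
  expect_equal(hsi$hsi_h[1], 1.0)
  expect_equal(hsi$hsi_u[1], eval_hsc(lib$adult$velocity, hyd$U_ms[1] * 100))
  expect_equal(hsi$hsi_c, compound_hsi(hsi$hsi_h, hsi$hsi_u))
  # identical hydraulics give identical indices
  hyd2 <- hyd; hyd2$H_m[2] <- hyd$H_m[1]; hyd2$U_ms[2] <- hyd$U_ms[1]
  hsi2 <- network_hsi(y, hyd2, lib, "adult")
  expect_equal(hsi2[1, c("hsi_h", "hsi_u", "hsi_c")],
               hsi2[2, c("hsi_h", "hsi_u", "hsi_c")],
               ignore_attr = TRUE)
  expect_error(network_hsi(y, hyd[1:2, ], lib, "adult"), "missing")
})

test_that("raising discharge past both curve modes lowers compound HSI", {
  y <- assign_reach_attributes(y_network(), uniform_so_table())
  lastmean <- Inf
  for (q0 in c(2, 4, 8)) {   # deep/fast enough to sit on both right tails
    hyd <- network_hydraulics(y, route_discharge(y, q0))
    expect_true(all(hyd$H_m * 100 > 51.78))
    expect_true(all(hyd$U_ms * 100 > 1.421 * 25.71 - 12.08))
    m <- mean(network_hsi(y, hyd, lib, "adult")$hsi_c)
    expect_lt(m, lastmean)
    lastmean <- m
  }
})

test_that("fitting recovers known coefficients from noiseless samples", {
  specs <- list(
    list(co = lib$adult$depth, fam = "gaussian_offset",
         true = c(cc = 0.1357, A = 0.8643, mu = 51.78, sigma = 35.87)),
    list(co = lib$juvenile$depth, fam = "gaussian_offset",
         true = c(cc = 0.074, A = 0.926, mu = 45.85, sigma = 45.62)),
    list(co = lib$adult$velocity, fam = "gamma_offset",
         true = c(cc = 0.1, A = 0.9, lam = 1.421, u0 = 12.08, theta = 25.71)),
    list(co = lib$juvenile$velocity, fam = "gamma_offset",
         true = c(cc = 0.06047, A = 0.93953, lam = 1.113, u0 = 15.1,
                  theta = 32.95))
  )
  for (sp in specs) {
    samples <- generate_hsc_samples(sp$co, n = 50, noise_sd = 0,
                                    x_range = c(0, 200), seed = 9)
    fit <- fit_hsc(samples, family = sp$fam)
    est <- unlist(fit$coefficients[setdiff(names(fit$coefficients), "family")])
    names(est)[names(est) == "c"] <- "cc"
    expect_equal(est[names(sp$true)], sp$true, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_gt(fit$r_squared, 1 - 1e-10)
  }
})

test_that("fitting under noise recovers coefficients within 3 standard errors", {
  true <- c(cc = 0.1357, A = 0.8643, mu = 51.78, sigma = 35.87)
  samples <- generate_hsc_samples(lib$adult$depth, n = 200, noise_sd = 0.05,
                                  x_range = c(0, 200), seed = 21)
  fit <- fit_hsc(samples, family = "gaussian_offset")
  est <- unlist(fit$coefficients[c("c", "A", "mu", "sigma")])
  names(est) <- c("cc", "A", "mu", "sigma")
  se <- fit$std_errors[names(true)]
  expect_true(all(abs(est - true) <= 3 * se),
              info = paste(round(abs(est - true) / se, 2), collapse = " "))
})

test_that("degenerate fitting inputs are rejected", {
  flat <- data.frame(x = 1:20, hsi = rep(0.5, 20))
  expect_error(fit_hsc(flat, "gaussian_offset"), "degenerate")
  expect_error(fit_hsc(flat[1:5, ], "gaussian_offset"), "at least 8")
  bad <- data.frame(x = 1:20, hsi = seq(-0.1, 1, length.out = 20))
  expect_error(fit_hsc(bad, "gaussian_offset"), "\\[0, 1\\]")
})

test_that("the shipped YAML library equals the built-in defaults", {
  path <- system.file("extdata", "hsc_default.yaml", package = "troutmove")
  expect_true(nzchar(path))
  from_file <- read_hsc_library(path)
  for (cls in c("adult", "juvenile")) {
    for (var in c("depth", "velocity")) {
      expect_equal(unclass(from_file[[cls]][[var]]),
                   unclass(lib[[cls]][[var]]))
    }
  }
})
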
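unbiased_probs <- function(net) {
  hsi <- data.frame(id = net$order, hsi_c = 0.5)
  network_bias(net, hsi, bias_parameters(), "adult")
}

test_that("kernel rows place probabilities on graph neighbours only", {
  y <- y_network()
  hsi <- data.frame(id = c("A", "B", "C"), hsi_c = 0.5)
  # zero-bias triple via a custom check: use juvenile/adult symmetric case
  probs <- network_bias(y, hsi, bias_parameters(), "adult")
  kern <- build_transition_matrix(y, probs, boundary = "absorb-self")
  P <- as.matrix(kern$P)
  # sources jump downstream with probability 1
  expect_equal(P["A", "C"], 1)
  expect_equal(P["B", "C"], 1)
  # outlet row carries its triple, p_dn as a self-loop
  expect_equal(P["C", "A"], 0.275)
  expect_equal(P["C", "B"], 0.275)
  expect_equal(P["C", "C"], 0.45)

  kern_r <- build_transition_matrix(y, probs, boundary = "reflect")
  Pr <- as.matrix(kern_r$P)
  expect_equal(Pr["C", "A"], 0.5)
  expect_equal(Pr["C", "B"], 0.5)
  expect_equal(Pr["C", "C"], 0)

  # row-stochastic under both policies, sparsity matches adjacency
  for (k in list(kern, kern_r)) {
    expect_equal(as.numeric(Matrix::rowSums(k$P)), rep(1, 3),
                 tolerance = 1e-12)
    expect_true(all(as.matrix(k$P) >= 0))
  }
  net <- generate_binary_network(16, seed = 2)
  kr <- build_transition_matrix(net, unbiased_probs(net), "reflect")
  n_edges <- nrow(net$nodes) - 1
  expect_equal(Matrix::nnzero(kr$P), 2 * n_edges)  # each edge used both ways

  expect_error(build_transition_matrix(y, probs[1:2, ]), "missing")
  bad <- probs; bad$p_dn[bad$id == "C"] <- 0.9
  expect_error(build_transition_matrix(y, bad, "absorb-self"), "simplex")
})

test_that("single-node networks get a unit self-loop", {
  solo <- river_network(data.frame(id = "X", downstream_id = NA))
  probs <- data.frame(id = "X", p_up1 = NA, p_up2 = NA, p_dn = 1)
  kern <- build_transition_matrix(solo, probs, "reflect")
  expect_equal(as.numeric(kern$P["X", "X"]), 1)
})

test_that("walkers are conserved, reproducible and respect the kernel", {
  net <- generate_binary_network(8, seed = 4)
  kern <- build_transition_matrix(net, unbiased_probs(net), "reflect")
  init <- setNames(1000, net$outlet)
  occ <- simulate_walkers(kern, init, steps = 200, seed = 99)
  expect_true(all(rowSums(occ) == 1000))
  occ2 <- simulate_walkers(kern, init, steps = 200, seed = 99)
  expect_identical(occ, occ2)
  expect_error(simulate_walkers(kern, setNames(0, net$outlet), 10), "empty")
  expect_error(simulate_walkers(kern, setNames(10, "nope"), 10), "unknown")
})

test_that("stationary distribution is the left fixed point, matching eigen", {
  # symmetric balanced tree: mirror branches get equal stationary mass
  bal <- generate_binary_network(4, "balanced", seed = 1)
  kern <- build_transition_matrix(bal, unbiased_probs(bal), "reflect")
  pi_v <- stationary_distribution(kern)
  expect_equal(sum(pi_v), 1, tolerance = 1e-12)
  resid <- max(abs(as.numeric(Matrix::crossprod(kern$P, pi_v)) - pi_v))
  expect_lt(resid, 1e-10)
  so <- compute_strahler(bal)
  src <- names(so)[lengths(bal$upstream[names(so)]) == 0]
  expect_equal(max(pi_v[src]) - min(pi_v[src]), 0, tolerance = 1e-10)

  # dense eigen oracle on random kernels up to n = 32
  for (seed in 1:6) {
    net <- generate_binary_network(sample(2:16, 1), seed = seed)
    set.seed(seed)
    hsi <- data.frame(id = net$order, hsi_c = runif(nrow(net$nodes), 0.2, 1))
    probs <- network_bias(net, hsi, bias_parameters(), "juvenile")
    k <- build_transition_matrix(net, probs, "reflect")
    pi_v <- stationary_distribution(k)
    expect_equal(unname(pi_v), eigen_stationary(k$P), tolerance = 1e-9)
  }
})

test_that("long-run occupancy matches the stationary law within MC error", {
  net <- generate_binary_network(4, "random", seed = 8)   # 7 nodes
  kern <- build_transition_matrix(net, unbiased_probs(net), "reflect")
  pi_v <- stationary_distribution(kern)
  n_walkers <- 10000
  occ <- simulate_walkers(kern, setNames(n_walkers, net$outlet),
                          steps = 1000, seed = 31)
  # time-average over the second half to smooth the tree walk's 2-periodicity
  tail_occ <- colMeans(occ[501:1001, ]) / n_walkers
  se <- sqrt(pi_v * (1 - pi_v) / n_walkers)
  expect_true(all(abs(tail_occ - pi_v) <= 3 * pmax(se, 1e-4)),
              info = paste(round((tail_occ - pi_v) / se, 1), collapse = " "))
})

test_that("a reducible kernel is reported instead of solved", {
  y <- y_network()
  probs <- data.frame(id = c("A", "B", "C"),
                      p_up1 = c(NA, NA, 0), p_up2 = c(NA, NA, 0),
                      p_dn = c(1, 1, 1))
  kern <- build_transition_matrix(y, probs, "absorb-self")
  expect_error(stationary_distribution(kern), "reducible")
})

test_that("narrative convention sends adults downstream relative to juveniles", {
  net <- ladder_network(4)
  hsi <- data.frame(id = net$order, hsi_c = 0.5)
  p <- bias_parameters(sign_convention = "narrative")
  masses <- lapply(c("adult", "juvenile"), function(age) {
    probs <- network_bias(net, hsi, p, age)
    stationary_distribution(build_transition_matrix(net, probs, "reflect"))
  })
  # outlet-side mass (junction J1 + outlet neighbours) larger for adults
  out_mass <- vapply(masses, function(m) sum(m[c("J1", "s1a")]), numeric(1))
  expect_gt(out_mass[1], out_mass[2])
})
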
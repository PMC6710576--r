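test_that("diffusion parameters are validated", {
  p <- diffusion_params(T = 2, L = 0.4, E = 0.25)
  expect_s3_class(p, "diffusion_params")
  expect_identical(p$n_steps, 50L)
  expect_error(diffusion_params(T = 0, L = 0.5, E = 0.1), "'T'")
  expect_error(diffusion_params(T = 1, L = 1.2, E = 0.1), "'L'")
  expect_error(diffusion_params(T = 1, L = 0.5, E = -0.1), "'E'")
  expect_error(diffusion_params(T = 1, L = 0.5, E = 0.1, n_steps = 0), "n_steps")
})

test_that("seeding counts are round(E * n), half away from zero", {
  set.seed(31)
  net <- generate_network(40, "light", seed = 4)
  for (E in c(0, 0.05, 0.1, 0.25, 0.5, 1)) {
    expect_identical(sum(seed_knowledge(net, E)), as.integer(floor(E * 40 + 0.5)))
  }
  # half case rounds away from zero: E * n = 2.5 -> 3
  net8 <- path_network(8)
  expect_identical(sum(seed_knowledge(net8, 2.5 / 8)), 3L)
  expect_identical(sum(seed_knowledge(net8, 0)), 0L)
})

test_that("seeding targets the extremes of the degree ordering", {
  set.seed(32)
  for (rep in 1:10) {
    net <- generate_network(40, "high", seed = rep)
    deg <- degree_sequence(net)
    least <- seed_knowledge(net, 0.25, "least_connected")
    best <- seed_knowledge(net, 0.25, "best_connected")
    expect_lte(max(deg[least]), min(deg[!least]))
    expect_gte(min(deg[best]), max(deg[!best]))
  }
})

test_that("degree ties among seeding candidates are broken uniformly", {
  # 4-cycle: all degrees equal; E = 0.25 seeds exactly one of four tied nodes
  net <- cycle_network(4)
  set.seed(33)
  n_draw <- 4000
  picks <- replicate(n_draw, which(seed_knowledge(net, 0.25)))
  freq <- tabulate(picks, nbins = 4) / n_draw
  se <- sqrt(0.25 * 0.75 / n_draw)
  expect_true(all(abs(freq - 0.25) <= 3 * se))
})

test_that("a diffusion step obeys threshold, listening and monotonicity", {
  net <- path_network(5)
  informed <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  # L = 0 freezes the state
  set.seed(41)
  expect_identical(diffusion_step(informed, net, T = 1, L = 0), informed)
  # threshold unmet everywhere freezes the state for any L
  expect_identical(diffusion_step(informed, net, T = 2, L = 1), informed)
  # L = 1, T = 1 is a deterministic flood to neighbours only
  after <- diffusion_step(informed, net, T = 1, L = 1)
  expect_identical(after, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # informed nodes never revert across random steps
  set.seed(42)
  state <- informed
  for (s in 1:20) {
    nxt <- diffusion_step(state, net, T = 1, L = 0.3)
    expect_true(all(nxt[state]))
    state <- nxt
  }
})

test_that("full seeding saturates the AUC at n_steps * n", {
  net <- generate_network(40, "moderate", seed = 9)
  for (Tv in 1:2) {
    tr <- run_diffusion(net, diffusion_params(T = Tv, L = 0.3, E = 1))
    expect_true(all(tr$counts == 40L))
    expect_identical(tr$auc, 2000L)
  }
})

test_that("frozen dynamics give AUC = n_steps * seeds", {
  set.seed(51)
  for (E in c(0.05, 0.25, 0.6)) {
    net <- generate_network(40, "light", seed = 17)
    tr <- run_diffusion(net, diffusion_params(T = 1, L = 0, E = E))
    s <- as.integer(floor(E * 40 + 0.5))
    expect_true(all(tr$counts == s))
    expect_identical(tr$auc, 50L * s)
  }
})

test_that("complex contagion on a star informs the hub but never the leaves", {
  # 5-node star, two leaf seeds, T = 2, L = 1: the hub sees two informed
  # contacts and is informed at step 1; leaves (degree 1) can never meet T = 2
  net <- star_network(5)
  seeds <- c(FALSE, TRUE, TRUE, FALSE, FALSE)
  tr <- run_diffusion(net, diffusion_params(T = 2, L = 1, E = 0),
                      informed = seeds)
  expect_identical(tr$counts, rep(3L, 50))
  expect_identical(tr$auc, 150L)
  # stochastic listening cannot break the structural impossibility
  set.seed(52)
  for (rep in 1:20) {
    tr <- run_diffusion(net, diffusion_params(T = 2, L = 0.7, E = 0),
                        informed = seeds)
    expect_lte(max(tr$counts), 3L)
  }
})

test_that("AUC is the rectangle-rule sum of per-step counts", {
  expect_identical(compute_auc(rep(0L, 50)), 0L)
  expect_identical(compute_auc(rep(40L, 50)), 2000L)
  expect_identical(compute_auc(c(10L, 20L, rep(40L, 48))), 1950L)
})

test_that("trajectories are monotone and bounded", {
  set.seed(61)
  for (rep in 1:15) {
    preset <- sample(c("light", "moderate", "high"), 1)
    p <- diffusion_params(T = sample(1:2, 1), L = runif(1), E = runif(1, 0, 0.5),
                          n_steps = 30)
    net <- generate_network(40, preset)
    tr <- run_diffusion(net, p)
    expect_true(all(diff(tr$counts) >= 0L))
    expect_true(all(tr$counts >= 0L & tr$counts <= 40L))
    expect_identical(tr$auc, sum(tr$counts))
    expect_lte(tr$auc, 30L * 40L)
  }
})

test_that("the per-edge listening variant amplifies with informed contacts", {
  # star hub with 3 informed leaves: per-node P = L, per-edge P = 1-(1-L)^3
  net <- star_network(5)
  seeds <- c(FALSE, TRUE, TRUE, TRUE, FALSE)
  L <- 0.3
  n_rep <- 4000
  set.seed(71)
  hub_node <- mean(replicate(n_rep,
    diffusion_step(seeds, net, T = 1, L = L)[1]))
  set.seed(72)
  hub_edge <- mean(replicate(n_rep,
    diffusion_step(seeds, net, T = 1, L = L, listening_model = "per_edge")[1]))
  se <- sqrt(0.5 * 0.5 / n_rep)
  expect_lt(abs(hub_node - L), 3 * se)
  expect_lt(abs(hub_edge - (1 - (1 - L)^3)), 3 * se)
})
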
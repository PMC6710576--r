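test_that("star networks realise the theoretical extreme of skew", {
  for (n in c(2L, 5L, 40L)) {
    net <- star_network(n)
    expect_equal(edge_count(net), n - 1L)
    expect_equal(sort(degree_sequence(net), decreasing = TRUE),
                 c(n - 1L, rep(1L, n - 1L)))
    expect_true(is_connected_network(net))
  }
  expect_error(star_network(1), "at least 2")
})

test_that("degree sequences respect range, parity and degenerate cases", {
  set.seed(101)
  for (preset in c("light", "moderate", "high")) {
    for (rep in 1:25) {
      d <- generate_degree_sequence(40, preset)
      expect_true(all(d >= 1L & d <= 39L))
      expect_identical(sum(d) %% 2L, 0L)
    }
    expect_identical(generate_degree_sequence(2, preset), c(1L, 1L))
  }
  expect_error(generate_degree_sequence(40, "extreme"))
  expect_error(generate_degree_sequence(1, "light"), "at least 2")
})

test_that("heavy-tail sequences are hub-dominated", {
  set.seed(7)
  d <- generate_degree_sequence(40, "high")
  expect_gt(max(d), stats::median(d))
})

test_that("degree skewness matches the bias-corrected formula", {
  # 5-node star: hand-checkable [4,1,1,1,1]
  expect_equal(degree_skewness(star_network(5)), direct_skewness(c(4, 1, 1, 1, 1)))
  expect_equal(degree_skewness(star_network(5)), 1.5 * sqrt(20) / 3)
  # symmetric multiset has zero skewness
  expect_equal(degree_skewness(c(1, 2, 3)), 0)
  # zero variance or too-short input: flagged sentinel, not an error
  expect_identical(degree_skewness(cycle_network(6)), NA_real_)
  expect_identical(degree_skewness(c(2, 2)), NA_real_)
  # cross-check against an established implementation
  set.seed(5)
  for (rep in 1:10) {
    x <- rpois(30, 5) + 1
    if (stats::var(x) == 0) next
    expect_equal(degree_skewness(x), e1071::skewness(x, type = 2))
  }
})

test_that("mean degree-sequence skewness is strictly ordered across presets", {
  set.seed(2024)
  n_seeds <- 200
  sk <- sapply(c("light", "moderate", "high"), function(p)
    replicate(n_seeds, degree_skewness(generate_degree_sequence(40, p))))
  m <- colMeans(sk)
  se <- apply(sk, 2, stats::sd) / sqrt(n_seeds)
  # strict ordering with a >= 3 standard-error margin
  expect_gt(m["moderate"] - m["light"],
            3 * sqrt(se["light"]^2 + se["moderate"]^2))
  expect_gt(m["high"] - m["moderate"],
            3 * sqrt(se["moderate"]^2 + se["high"]^2))
})

test_that("realisation reproduces the target degree multiset exactly", {
  set.seed(11)
  for (preset in c("light", "moderate", "high")) {
    for (rep in 1:10) {
      d <- generate_degree_sequence(40, preset)
      while (!igraph::is_graphical(d) || sum(d) / 2 < 39)
        d <- generate_degree_sequence(40, preset)
      net <- realize_network(d)
      expect_identical(sort(degree_sequence(net)), sort(d))
      expect_true(is_connected_network(net))
      expect_identical(sum(degree_sequence(net)), 2L * edge_count(net))
    }
  }
})

test_that("forced realisations and degenerate sequences behave", {
  # [1,1] -> the single-edge graph
  net2 <- realize_network(c(1, 1))
  expect_equal(edge_count(net2), 1L)
  # [3,1,1,1] -> the 4-node star (unique simple realisation)
  s4 <- realize_network(c(3, 1, 1, 1))
  expect_identical(sort(degree_sequence(s4), decreasing = TRUE), c(3L, 1L, 1L, 1L))
  expect_true(is_connected_network(s4))
  # invalid sequences
  expect_error(realize_network(c(1, 1, 1)), "even sum")
  expect_error(realize_network(c(3, 3)), "\\[0, n - 1\\]")
  expect_error(realize_network(c(4, 4, 4, 1, 1)), "not graphical")
  # too few edges for connectivity, allowed when enforcement is off
  expect_error(realize_network(c(1, 1, 1, 1)), "too few edges")
  loose <- realize_network(c(1, 1, 1, 1), enforce_connected = FALSE)
  expect_identical(degree_sequence(loose), rep(1L, 4))
})

test_that("generation is deterministic under a seed and labelled", {
  for (preset in c("light", "high")) {
    a <- generate_network(40, preset, seed = 99)
    b <- generate_network(40, preset, seed = 99)
    expect_identical(edge_matrix(a), edge_matrix(b))
    expect_identical(a$structure_label, preset)
    expect_identical(a$generator_seed, 99L)
    # serialized forms agree bit-for-bit
    fa <- tempfile(fileext = ".edgelist"); fb <- tempfile(fileext = ".edgelist")
    write_network(a, fa); write_network(b, fb)
    expect_identical(readBin(fa, "raw", file.size(fa)),
                     readBin(fb, "raw", file.size(fb)))
    unlink(c(fa, fb))
  }
  expect_false(identical(edge_matrix(generate_network(40, "light", seed = 1)),
                         edge_matrix(generate_network(40, "light", seed = 2))))
})

test_that("network constructor rejects invalid graphs", {
  expect_error(social_network(rbind(c(1, 1)), 3), "self-loops")
  expect_error(social_network(rbind(c(1, 2), c(2, 1)), 3), "duplicate")
  expect_error(social_network(rbind(c(1, 4)), 3), "indices")
})

test_that("edge-list and GraphML round trips are lossless", {
  set.seed(21)
  nets <- list(generate_network(40, "moderate", seed = 3),
               star_network(6),
               social_network(rbind(c(1, 2)), 4))  # isolated nodes survive
  for (net in nets) {
    for (fmt in c("edgelist", "graphml")) {
      f <- tempfile(fileext = paste0(".", fmt))
      write_network(net, f)
      back <- read_network(f)
      expect_identical(node_count(back), node_count(net))
      expect_identical(sort(edge_key(edge_matrix(back), node_count(back))),
                       sort(edge_key(edge_matrix(net), node_count(net))))
      unlink(f)
    }
  }
  # malformed files are named
  f <- tempfile()
  writeLines(c("# nodes: 3", "0 1 2"), f)
  expect_error(read_network(f), "malformed")
  writeLines(c("0 1"), f)
  expect_error(read_network(f), "nodes")
  unlink(f)
})
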
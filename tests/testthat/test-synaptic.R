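test_that("synaptic distance is the normalized Hamming distance", {
  a <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(synaptic_distance(a, a), 0)
  expect_equal(synaptic_distance(a, 1 - a), 1)
  b <- a; b[1, 1] <- 0
  expect_equal(synaptic_distance(a, b), 0.25)
  expect_error(synaptic_distance(a, matrix(0, 3, 3)), "mismatch")
})

test_that("synaptic distance is a metric on binary snapshots", {
  set.seed(17)
  for (i in 1:30) {
    x <- matrix(rbinom(20, 1, 0.4), 4)
    y <- matrix(rbinom(20, 1, 0.4), 4)
    z <- matrix(rbinom(20, 1, 0.4), 4)
    expect_equal(synaptic_distance(x, y), synaptic_distance(y, x))
    expect_lte(synaptic_distance(x, z),
               synaptic_distance(x, y) + synaptic_distance(y, z) + 1e-12)
    expect_gte(synaptic_distance(x, y), 0)
  }
})

test_that("shuffled distance matches its closed-form expectation", {
  set.seed(18)
  p1 <- 0.3; p2 <- 0.15
  a <- matrix(rbinom(3000, 1, p1), 50)
  b <- matrix(rbinom(3000, 1, p2), 50)
  q1 <- mean(a); q2 <- mean(b)
  expected <- q1 * (1 - q2) + q2 * (1 - q1)
  mc <- shuffled_distance(a, b, n_shuffles = 200, seed = 19)
  expect_equal(mc, expected, tolerance = 0.02)
  # permuting an all-zero snapshot is a no-op
  zero <- matrix(0, 50, 60)
  expect_equal(shuffled_distance(a, zero, 5, seed = 20), synaptic_distance(a, zero))
})

test_that("relative distance handles its undefined cases", {
  expect_equal(relative_distance(0, 0.5), 1)
  expect_equal(relative_distance(0.3, 0.3), 0)
  expect_true(is.na(relative_distance(0.2, 0)))
  expect_equal(relative_distance(1, 0.5), 1)   # equals 1 also at phi = 2 * phi_shuffled
})

test_that("receptive fields reshape the incoming weight vector", {
  cfg <- tiny_cfg()
  net <- build_network(cfg, seed = 21)
  rf <- receptive_field(net, 2)
  expect_equal(dim(rf$weights), c(5, 5))
  # row-major inverse: image pixel (r, c) maps to source (r-1) * size + c
  expect_equal(rf$weights[1, 2], net$proj$w12$weights[2, 2])
  expect_equal(rf$weights[2, 1], net$proj$w12$weights[6, 2])
  # untrained uniform (0, 0.1) weights carry no strong synapses at 0.7 * 0.3
  expect_false(any(rf$strong))
  net$proj$w12$weights[net$proj$w12$mask] <- cfg$gE_max
  rf2 <- receptive_field(net, 2)
  expect_true(all(rf2$strong[matrix(net$proj$w12$mask[, 2], 5, 5, byrow = TRUE)]))
  expect_error(receptive_field(net, 99), "range")
})

test_that("back-trace graphs are consistent with strong connectivity", {
  cfg <- tiny_cfg()
  net <- build_network(cfg, seed = 22)
  empty_sp <- data.frame(layer = character(0), neuron_id = integer(0),
                         time_ms = numeric(0))
  # no strong synapses anywhere: both graphs empty
  g0 <- backtrace_networks(net, empty_sp, code = rep(2, cfg$M))
  expect_equal(igraph::vcount(g0$structural), 0)
  expect_equal(igraph::ecount(g0$functional), 0)
  # make all readout and recurrent synapses strong
  for (nm in c("w23", "w22ee"))
    net$proj[[nm]]$weights[net$proj[[nm]]$mask] <- cfg$gE_max
  # single neuron spiking alone: functional graph has nodes but no edges
  one <- data.frame(layer = "reservoir_E", neuron_id = 1, time_ms = c(10, 40))
  g1 <- backtrace_networks(net, one, code = rep(2, cfg$M))
  expect_gt(igraph::vcount(g1$structural), 0)
  expect_equal(igraph::ecount(g1$functional), 0)
  # two neurons in causal sequence produce a directed functional edge
  seqs <- data.frame(layer = "reservoir_E", neuron_id = c(1, 2, 1, 2),
                     time_ms = c(10, 15, 60, 70))
  g2 <- backtrace_networks(net, seqs, code = rep(2, cfg$M))
  el <- igraph::as_data_frame(g2$functional)
  expect_true(nrow(el) >= 1)
  expect_equal(el$weight[el$from == "1" & el$to == "2"], 2)
  write_graph_csv(g2$structural, withr::local_tempfile(fileext = ".csv"),
                  withr::local_tempfile(fileext = ".graphml"))
})

test_that("binarization thresholds at 0.7 of the class maximum", {
  cfg <- tiny_cfg()
  net <- build_network(cfg, seed = 23)
  syn <- net$proj$w12
  syn$weights[syn$mask][1] <- 0.25    # above 0.21 = 0.7 * 0.3
  b <- binarize_weights(syn)
  expect_equal(sum(b), 1)
  expect_true(all(b %in% c(0, 1)))
  expect_true(all(b[!syn$mask] == 0))
})
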
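test_that("realized connectivity matches the Bernoulli probabilities", {
  cfg <- snn_config("desk")
  net <- build_network(cfg, seed = 1)
  # 1->2 density within 3 sigma of c12_ee over n = K * N_E trials
  n <- cfg$K * cfg$N_E
  dens <- mean(net$proj$w12$mask)
  expect_lt(abs(dens - cfg$c12_ee), 3 * sqrt(cfg$c12_ee * 0.8 / n))
  # fully-connected sink loop
  expect_true(all(net$proj$w33ei$mask))
  expect_true(all(net$proj$w33ie$mask))
  # no self-connections in recurrent projections
  expect_false(any(diag(net$proj$w22ee$mask)))
  expect_false(any(diag(net$proj$w22ii$mask)))
  # empty projection when probability is zero
  net0 <- build_network(tiny_cfg(c12_ee = 0), seed = 2)
  expect_equal(sum(net0$proj$w12$mask), 0)
  expect_error(build_network(tiny_cfg(N_I = 0)), "layer|integer")
})

test_that("initial weights honour class-specific ranges and bounds", {
  net <- build_network(snn_config("desk"), seed = 3)
  w12 <- net$proj$w12$weights[net$proj$w12$mask]
  expect_true(all(w12 >= 0 & w12 <= 0.1))
  w23 <- net$proj$w23$weights[net$proj$w23$mask]
  expect_true(all(w23 >= 0 & w23 <= 0.2))
  z <- net$proj$w22ie$weights[net$proj$w22ie$mask]
  expect_true(all(z >= 0 & z <= 0.1))
})

test_that("identical seeds give bit-identical runs", {
  cfg <- tiny_cfg()
  pats <- flag_patterns(3, 5, seed = 4, max_overlap = 0.95)
  net <- build_network(cfg, seed = 5)
  sch <- training_schedule(pats, 2000, cfg, seed = 6)
  set.seed(7)
  r1 <- run_network(net, sch, pats, record = "network")
  set.seed(7)
  r2 <- run_network(net, sch, pats, record = "network")
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(lapply(r1$net$proj, `[[`, "weights"),
                   lapply(r2$net$proj, `[[`, "weights"))
})

test_that("frozen plasticity leaves every weight bit-identical", {
  cfg <- tiny_cfg()
  pats <- flag_patterns(3, 5, seed = 4, max_overlap = 0.95)
  net <- build_network(cfg, seed = 5)
  sch <- training_schedule(pats, 3000, cfg, seed = 6)
  set.seed(8)
  r <- run_network(net, sch, pats, plasticity = "none")
  expect_identical(lapply(r$net$proj, `[[`, "weights"),
                   lapply(net$proj, `[[`, "weights"))
  # empty schedule leaves the network untouched
  r0 <- run_network(net, sch[0, ], pats)
  expect_identical(r0$net, net)
  expect_equal(ncol(r0$sink_counts), 0)
})

test_that("the ablation mode keeps inhibitory weights fixed", {
  cfg <- tiny_cfg()
  pats <- flag_patterns(3, 5, seed = 4, max_overlap = 0.95)
  net <- build_network(cfg, seed = 5)
  sch <- training_schedule(pats, 3000, cfg, seed = 6)
  set.seed(9)
  r <- run_network(net, sch, pats, plasticity = "no_istdp")
  for (nm in c("w22ie", "w22ii", "w33ie"))
    expect_identical(r$net$proj[[nm]]$weights, net$proj[[nm]]$weights)
  expect_false(identical(r$net$proj$w12$weights, net$proj$w12$weights))
})

test_that("weights never leave [0, g_max] during plastic runs", {
  cfg <- tiny_cfg()
  pats <- flag_patterns(3, 5, seed = 4, max_overlap = 0.95)
  net <- build_network(cfg, seed = 10)
  sch <- training_schedule(pats, 5000, cfg, seed = 11)
  set.seed(12)
  r <- run_network(net, sch, pats)
  for (nm in names(r$net$proj)) {
    syn <- r$net$proj[[nm]]
    expect_true(all(syn$weights >= 0))
    expect_true(all(syn$weights <= syn$g_max + 1e-12))
    expect_true(all(syn$weights[!syn$mask] == 0))
  }
})

test_that("connectivity shuffles preserve weights and degrees", {
  cfg <- snn_config("desk")
  net <- build_network(cfg, seed = 13)
  for (case in 1:6) {
    sh <- shuffle_connectivity(net, case, seed = case)
    for (nm in names(net$proj)) {
      a <- net$proj[[nm]]; b <- sh$proj[[nm]]
      expect_equal(sum(b$mask), sum(a$mask))
      expect_equal(colSums(b$mask), colSums(a$mask))   # in-degree preserved
      expect_equal(sort(b$weights[b$mask]), sort(a$weights[a$mask]))
    }
  }
  # case 1 rewires only the source projection
  sh1 <- shuffle_connectivity(net, 1, seed = 1)
  expect_false(identical(sh1$proj$w12$mask, net$proj$w12$mask))
  expect_identical(sh1$proj$w22ee, net$proj$w22ee)
  # case 5 rewires only the readout projection
  sh5 <- shuffle_connectivity(net, 5, seed = 1)
  expect_false(identical(sh5$proj$w23$mask, net$proj$w23$mask))
  expect_identical(sh5$proj$w12, net$proj$w12)
  # self-loops remain excluded after shuffling recurrent projections
  sh2 <- shuffle_connectivity(net, 2, seed = 2)
  expect_false(any(diag(sh2$proj$w22ee$mask)))
  expect_error(shuffle_connectivity(net, 9), "unknown")
})

test_that("checkpoints round-trip the full network", {
  net <- build_network(tiny_cfg(), seed = 14)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  expect_identical(load_checkpoint(path), net)
})
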
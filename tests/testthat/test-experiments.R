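test_that("probes are side-effect-free and training is seed-reproducible", {
  cfg <- tiny_cfg()
  pats <- flag_patterns(3, 5, seed = 1, max_overlap = 0.95)
  net <- build_network(cfg, seed = 2)
  w_before <- lapply(net$proj, `[[`, "weights")
  set.seed(3)
  rep <- probe_di(net, pats, cfg, d_s = 0.2, J = 2)
  expect_identical(lapply(net$proj, `[[`, "weights"), w_before)
  expect_s3_class(rep, "snn_di")

  fit1 <- train_network(net, pats, total_s = 4, probe_every_s = 2, seed = 7)
  fit2 <- train_network(net, pats, total_s = 4, probe_every_s = 2, seed = 7)
  expect_identical(coef(fit1), coef(fit2))
  expect_identical(fit1$di_series, fit2$di_series)
  expect_equal(nrow(fit1$di_series), 2)
})

test_that("fit objects expose the modelling-idiom methods", {
  cfg <- tiny_cfg()
  pats <- flag_patterns(3, 5, seed = 1, max_overlap = 0.95)
  fit <- train_network(build_network(cfg, seed = 4), pats, total_s = 3,
                       probe_every_s = Inf, seed = 5)
  expect_s3_class(fit, "snn_fit")
  expect_named(coef(fit), names(fit$net$proj))
  expect_output(print(fit), "snn_fit")
  pred <- predict(fit)
  expect_s3_class(pred, "snn_di")
  sims <- simulate(fit, nsim = 2, seed = 6, d_s = 0.2)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), c(cfg$M, length(pats)))
  pdf(NULL); on.exit(dev.off())
  plot(fit, which = "weights")
})

test_that("ablation driver pairs matched on/off conditions", {
  cfg <- tiny_cfg(g_leak = 1, g_leak_gaba = 1)
  pats <- flag_patterns(3, 5, seed = 1, max_overlap = 0.95)
  ab <- istdp_ablation(cfg, pats, total_s = 4, probe_every_s = 2, seed = 8)
  expect_s3_class(ab, "snn_ablation")
  expect_equal(ab$comparison$condition, c("istdp_on", "istdp_off"))
  # the off condition kept its inhibitory weights at initialization
  net0 <- build_network(cfg, seed = 8)
  expect_identical(ab$off$net$proj$w22ie$weights, net0$proj$w22ie$weights)
  expect_false(identical(ab$on$net$proj$w22ie$weights, net0$proj$w22ie$weights))
})

test_that("stability protocol tracks DI on the union and phi against phase 1", {
  cfg <- tiny_cfg()
  old <- flag_patterns(2, 5, seed = 1, max_overlap = 0.95)
  new <- flag_patterns(2, 5, seed = 2, max_overlap = 0.95)
  st <- stability_plasticity(cfg, old, new, phase_s = 4, mode = "new-only",
                             probe_every_s = 2, phi_every_s = 2, seed = 9)
  expect_s3_class(st, "snn_stability")
  expect_equal(nrow(st$phi_series), 2)
  expect_true(all(st$phi_series$phi >= 0 & st$phi_series$phi <= 1))
  expect_equal(nrow(st$di_series), 2)
  # phase-2 fits can share one phase-1 training
  st2 <- stability_plasticity(cfg, old, new, phase_s = 4, mode = "old+new",
                              probe_every_s = 2, phi_every_s = 2, seed = 9,
                              phase1_fit = st$phase1)
  expect_identical(st2$phase1, st$phase1)
})

test_that("shuffle controls report every requested case", {
  cfg <- tiny_cfg()
  pats <- flag_patterns(3, 5, seed = 1, max_overlap = 0.95)
  fit <- train_network(build_network(cfg, seed = 10), pats, total_s = 3,
                       probe_every_s = Inf, seed = 11)
  tab <- shuffle_controls(fit$net, pats, cases = c(1, 5), n_shuffles = 2,
                          cfg = tiny_cfg(J = 2, d_test = 0.2), seed = 12)
  expect_equal(tab$case, c("unshuffled", "case1", "case5", "code-shuffle"))
  expect_true(all(is.finite(tab$mean_DI)))
})

test_that("parameter sweeps return one row per grid value", {
  cfg <- tiny_cfg()
  pats <- flag_patterns(3, 5, seed = 1, max_overlap = 0.95)
  tab <- parameter_sweep(cfg, pats, param = "C", values = c(2, 3),
                         total_s = 2, n_seeds = 2, seed = 13)
  expect_equal(tab$value, c(2, 3))
  expect_equal(tab$n, c(2, 2))
})
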
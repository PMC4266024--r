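test_that("STDP increments match the closed forms to 1e-12", {
  cfg <- snn_config()
  grid <- c(-50, -20, -10, -5, -1, 0, 1, 5, 10, 20, 50)
  e_expect <- ifelse(grid < 0, 0.005 * exp(grid / 20),
                     -0.00525 * exp(-grid / 20))
  expect_equal(estdp_delta(grid, cfg), e_expect, tolerance = 1e-12)
  i_expect <- ifelse(abs(grid) <= 10, 0.0015 * exp(-abs(grid) / 10),
                     -0.0003 * exp(-abs(grid) / 10))
  expect_equal(istdp_delta(grid, cfg), i_expect, tolerance = 1e-12)
  # spot values
  expect_equal(estdp_delta(-10, cfg), 0.005 * exp(-0.5), tolerance = 1e-12)
  expect_equal(estdp_delta(0, cfg), -0.00525, tolerance = 1e-12)
  expect_equal(estdp_delta(-1e4, cfg), 0)
  expect_equal(istdp_delta(5, cfg), 0.0015 * exp(-0.5), tolerance = 1e-12)
  expect_equal(istdp_delta(20, cfg), -0.0003 * exp(-2), tolerance = 1e-12)
})

test_that("excitatory rule is depression-biased, inhibitory rule is even", {
  cfg <- snn_config()
  dts <- seq(-100, 100, by = 0.1)
  # brute-force expectation over a symmetric window of timing differences
  expect_lt(mean(estdp_delta(dts, cfg)), 0)
  expect_equal(istdp_delta(dts, cfg), istdp_delta(-dts, cfg))
  # the only discontinuity of the excitatory rule is at 0
  eps <- 1e-9
  expect_gt(abs(estdp_delta(-eps, cfg) - estdp_delta(eps, cfg)), 0.005)
  smooth <- abs(diff(estdp_delta(c(-10 - eps, -10 + eps), cfg)))
  expect_lt(smooth, 1e-8)
})

test_that("regime classification agrees with the increment signs", {
  cfg <- snn_config()
  grid <- setdiff(seq(-40, 40, by = 0.5), 0)
  tags <- classify_regime(grid, cfg)
  de <- estdp_delta(grid, cfg)
  di <- istdp_delta(grid, cfg)
  oracle <- ifelse(de > 0 & di > 0, "balance",
            ifelse(de > 0 & di < 0, "accelerated_potentiation",
            ifelse(de < 0 & di > 0, "quiescent", "decelerated_depression")))
  expect_equal(tags, oracle)
  expect_equal(classify_regime(-5, cfg), "balance")
  expect_equal(classify_regime(-15, cfg), "accelerated_potentiation")
  expect_equal(classify_regime(5, cfg), "quiescent")
  expect_equal(classify_regime(15, cfg), "decelerated_depression")
})

test_that("synapse matrices enforce mask and bounds", {
  m <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2)
  w <- matrix(0.1, 2, 2)
  syn <- synapse_matrix(m, w, "E->E", g_max = 0.3)
  expect_equal(syn$weights[1, 2], 0.1)
  expect_equal(syn$weights[2, 1], 0)       # off-mask weights are zeroed
  expect_error(synapse_matrix(m, matrix(1, 2, 2), "E->E", g_max = 0.3),
               "outside")
})

test_that("apply_stdp clips to [0, g_max] and only pairs along the mask", {
  cfg <- snn_config()
  set.seed(42)
  for (rep in 1:20) {
    n_pre <- sample(3:6, 1); n_post <- sample(3:6, 1)
    mask <- matrix(runif(n_pre * n_post) < 0.7, n_pre)
    tag <- sample(c("E->E", "I->E"), 1)
    gmax <- if (tag == "E->E") cfg$gE_max else cfg$gI_max
    syn <- synapse_matrix(mask, matrix(runif(n_pre * n_post, 0, gmax), n_pre) * mask,
                          tag, gmax)
    pre <- runif(n_pre) < 0.5; post <- runif(n_post) < 0.5
    lp <- sample(c(-Inf, 1, 5, 9), n_pre, replace = TRUE)
    lo <- sample(c(-Inf, 2, 8), n_post, replace = TRUE)
    out <- apply_stdp(syn, pre, post, lp, lo, t_now = 10, cfg)
    expect_true(all(out$weights >= 0))
    expect_true(all(out$weights <= gmax + 1e-15))
    expect_true(all(out$weights[!mask] == 0))
  }
})

test_that("weights already at the bounds stay clipped under causal pairs", {
  cfg <- snn_config()
  mask <- matrix(TRUE, 1, 1)
  top <- synapse_matrix(mask, matrix(cfg$gE_max), "E->E", cfg$gE_max)
  out <- apply_stdp(top, FALSE, TRUE, last_pre = 8, last_post = -Inf, 10, cfg)
  expect_equal(out$weights[1, 1], cfg$gE_max)    # causal pair cannot exceed gmax
  bot <- synapse_matrix(mask, matrix(0), "E->E", cfg$gE_max)
  out <- apply_stdp(bot, TRUE, FALSE, last_pre = -Inf, last_post = 8, 10, cfg)
  expect_equal(out$weights[1, 1], 0)             # anti-causal pair cannot go below 0
})
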
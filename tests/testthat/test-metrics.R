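# naive double-loop oracle for the inter-pattern distance
oracle_inter <- function(protos) {
  P <- nrow(protos); M <- ncol(protos)
  per <- numeric(M)
  for (i in seq_len(M)) {
    tot <- 0
    for (p in 1:(P - 1)) for (q in (p + 1):P) tot <- tot + (protos[p, i] != protos[q, i])
    per[i] <- tot / (P * (P - 1) / 2)
  }
  sum(per)
}

# exhaustive maximum of the per-neuron mean pairwise distance over all C^P
# symbol assignments
oracle_max_inter <- function(P, C) {
  grids <- do.call(expand.grid, rep(list(0:(C - 1)), P))
  best <- 0
  for (r in seq_len(nrow(grids))) {
    s <- as.numeric(grids[r, ])
    d <- mean(outer(s, s, "!=")[upper.tri(diag(P))])
    if (d > best) best <- d
  }
  best
}

test_that("rate codes band the count ratios as specified", {
  expect_equal(rate_code(c(40, 36, 16, 4), C = 3), c(2, 2, 1, 0))
  expect_equal(rate_code(rep(7, 5), C = 3), rep(2, 5))     # ratio 1 everywhere
  expect_equal(rate_code(rep(0, 4), C = 3), rep(0L, 4))    # degenerate guard
  expect_equal(rate_code(c(10, 4), C = 2), c(1, 0))        # binary threshold 0.5
  expect_equal(rate_code(c(10, 9.4), C = 3), c(2, 2))      # top band includes 1.0
  expect_equal(rate_code(c(100, 89, 39), C = 3), c(2, 1, 0))
})

test_that("prototype codes are modal with uniform tie-breaking", {
  a <- c(1, 0); b <- c(2, 1); c3 <- c(0, 0)
  expect_equal(prototype_code(rbind(a, a, a)), a)
  expect_equal(prototype_code(rbind(a, a, b)), a)
  set.seed(1)
  picks <- replicate(300, paste(prototype_code(rbind(a, b, c3)), collapse = ""))
  tab <- table(picks)
  expect_setequal(names(tab), c("10", "21", "00"))
  expect_true(all(tab > 60))   # all three chosen, roughly uniformly
})

test_that("inter/intra distances reproduce the brute-force oracle", {
  protos <- rbind(c(0, 0), c(0, 1), c(1, 1))
  out <- inter_pattern_distance(protos)
  expect_equal(out$per_neuron, c(2 / 3, 2 / 3))
  expect_equal(out$D_inter, 4 / 3)
  expect_equal(inter_pattern_distance(rbind(c(1, 2), c(1, 2)))$D_inter, 0)
  expect_equal(inter_pattern_distance(rbind(c(0, 0, 0), c(1, 1, 1)))$D_inter, 3)
  set.seed(7)
  for (i in 1:25) {
    P <- sample(2:6, 1); M <- sample(1:4, 1); C <- sample(2:3, 1)
    pr <- matrix(sample(0:(C - 1), P * M, replace = TRUE), P)
    expect_equal(inter_pattern_distance(pr)$D_inter, oracle_inter(pr))
  }
  expect_error(inter_pattern_distance(matrix(0, 1, 3)), "two")
})

test_that("intra-pattern distance averages pairwise code distances", {
  M <- 4
  same <- matrix(1, 3, M)
  expect_equal(intra_pattern_distance(list(same, same)), 0)
  alldiff <- rbind(rep(0, M), rep(1, M))
  expect_equal(intra_pattern_distance(list(alldiff)), M)
  one_neuron <- rbind(c(0, 0, 0, 0), c(1, 0, 0, 0))
  expect_equal(intra_pattern_distance(list(same, one_neuron)), 0.5)
  expect_error(intra_pattern_distance(list(matrix(0, 1, M))), "two")
})

test_that("printed maximum inter-distance reproduces the worked value", {
  expect_equal(max_inter_distance(15, 2, 8), 15 * 8 * 1 / (2 * 14))
  expect_equal(round(max_inter_distance(15, 2, 8), 2), 4.29)
  # grows linearly in M
  expect_equal(max_inter_distance(15, 2, 16), 2 * max_inter_distance(15, 2, 8))
})

test_that("exact maximum inter-distance equals exhaustive enumeration", {
  for (P in 2:5) for (C in 2:3) for (M in 1:2) {
    expect_equal(max_inter_distance(P, C, M, method = "exact"),
                 M * oracle_max_inter(P, C),
                 info = sprintf("P=%d C=%d M=%d", P, C, M))
  }
})

test_that("discriminability index combines separability and uniqueness", {
  M <- 3
  mk <- function(...) do.call(rbind, list(...))
  # perfectly repeatable, all-unique codes: DI = 1
  codes <- lapply(1:3, function(p) mk(rep(p - 1, M), rep(p - 1, M)))
  rep1 <- discriminability_index(codes)
  expect_equal(rep1$DI, 1)
  expect_equal(rep1$uniqueness, 1)
  expect_equal(rep1$D_intra, 0)
  # all prototypes identical: guarded to DI = 0
  same <- lapply(1:3, function(p) mk(c(1, 1, 1), c(1, 1, 1)))
  rep2 <- discriminability_index(same)
  expect_equal(rep2$DI, 0)
  expect_equal(rep2$uniqueness, 1 / 3)
  # D_intra > D_inter drives separability (and DI) negative
  noisy <- list(mk(c(0, 0, 0), c(0, 0, 0), c(2, 2, 2)),
                mk(c(0, 0, 1), c(0, 0, 1), c(2, 2, 2)))
  rep3 <- discriminability_index(noisy)
  expect_lt(rep3$separability, 0)
  expect_lt(rep3$DI, 0)
  expect_true(rep3$D_inter <= rep3$D_inter_max)
})

test_that("DI is invariant to pattern order but not per-code symbol shuffles", {
  set.seed(21)
  codes <- lapply(1:5, function(p) {
    x <- sample(0:2, 4, TRUE)
    rbind(x, x, sample(0:2, 4, TRUE))   # clear mode, no tie-breaking randomness
  })
  base <- discriminability_index(codes)
  for (i in 1:5) {
    perm <- sample(5)
    expect_equal(discriminability_index(codes[perm])$DI, base$DI)
  }
  shuffled <- lapply(codes, function(m) t(apply(m, 1, sample)))
  expect_false(isTRUE(all.equal(discriminability_index(shuffled)$DI, base$DI)))
})

test_that("DI reports serialize to JSON", {
  codes <- lapply(1:3, function(p) matrix(p %% 3, 2, 4))
  rep <- discriminability_index(codes)
  path <- withr::local_tempfile(fileext = ".json")
  write_di_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$DI, rep$DI)
  write_codes(codes, withr::local_tempfile(fileext = ".csv"))
})
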
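test_that("learning slopes match the closed-form least-squares solution", {
  expect_equal(learning_slope(c(50, 55, 60, 65, 70)), 5)
  expect_equal(learning_slope(c(60, 60, 60, 60, 60)), 0)
  y <- c(55, 52, 61, 58, 66)
  d <- 1:5
  # independent normal-equations oracle
  X <- cbind(1, d)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(learning_slope(y), as.numeric(beta[2, 1]), tolerance = 1e-12)
  expect_error(learning_slope(c(1, NA, 3, 4, 5)), "missing")
})

test_that("planned-contrast scores equal 10 x slope for exactly linear data", {
  b <- 1.7
  dat <- expand.grid(participant = paste0("P", 1:4), day = 1:5)
  dat$key <- "k"
  dat$value <- 40 + b * dat$day
  res <- trend_permutation_by_feature(dat, n_perm = 120, seed = 1)
  expect_equal(res$estimate, 10 * b, tolerance = 1e-9)
  expect_equal(res$direction, 1)
})

test_that("the mixed-model trend test recovers planted slopes", {
  withr::with_seed(2, {
    dat <- expand.grid(participant = paste0("P", 1:12), day = 1:5)
    dat$value <- 55 + 3 * dat$day + rnorm(nrow(dat), 0, 2) +
      rep(rnorm(12, 0, 3), 5)
  })
  res <- planned_contrast_lmm(dat)
  expect_gt(res$F, 10)
  expect_lt(res$p, 0.001)
  expect_lt(res$p_lrt, 0.001)
  expect_equal(res$direction, 1)
  expect_equal(res$estimate, 3, tolerance = 0.5)
  expect_error(planned_contrast_lmm(transform(dat, value = 1)),
               "degenerate|constant")
  expect_error(planned_contrast_lmm(dat[dat$participant == "P1", ]),
               "participants")
})

test_that("the trend test is calibrated under the null", {
  n_rep <- 200
  withr::with_seed(3, {
    pvals <- vapply(seq_len(n_rep), function(i) {
      dat <- expand.grid(participant = paste0("P", 1:8), day = 1:5)
      dat$value <- rnorm(nrow(dat)) + rep(rnorm(8), 5)
      planned_contrast_lmm(dat)$p
    }, numeric(1))
  })
  frac <- mean(pvals < 0.05)
  # binomial 95% margin around 0.05 for 200 draws
  expect_lt(frac, 0.05 + 1.96 * sqrt(0.05 * 0.95 / n_rep) + 1e-9)
  expect_gt(frac, 0.0)
})

test_that("top-k weight sums match a brute-force sort on all cases", {
  u <- matrix(100 / 2135, 61, 35,
              dimnames = list(paste0("ch", 1:61), seq(2, 70, 2)))
  expect_equal(topk_weight_sum(u, 200), 200 * 100 / 2135, tolerance = 1e-12)
  one <- u * 0
  one[5, 7] <- 100
  expect_equal(topk_weight_sum(one, 200), 100)
  withr::with_seed(4, {
    r <- matrix(runif(61 * 35), 61, 35,
                dimnames = list(paste0("ch", 1:61), seq(2, 70, 2)))
    r <- 100 * r / sum(r)
  })
  expect_equal(topk_weight_sum(r, 200),
               sum(sort(as.vector(r), decreasing = TRUE)[1:200]),
               tolerance = 1e-12)
  expect_error(topk_weight_sum(r, 0), "positive")
  expect_error(topk_weight_sum(r, 1e6), "exceeds")
})

test_that("frequency profiles and band topographies match direct means", {
  withr::with_seed(5, {
    m <- matrix(runif(8 * 35), 8, 35,
                dimnames = list(paste0("ch", 1:8), seq(2, 70, 2)))
  })
  prof <- frequency_profile(m)
  expect_equal(unname(prof), unname(apply(m, 2, mean)), tolerance = 1e-12)
  u <- m * 0 + 100 / length(m)
  expect_true(all(abs(frequency_profile(u) - 100 / length(m)) < 1e-12))
  conc <- m * 0
  conc[, "10"] <- 1
  expect_equal(names(which.max(frequency_profile(conc))), "10")
  topo <- band_topography(m, c(8, 16))
  cols <- as.numeric(colnames(m)) >= 8 & as.numeric(colnames(m)) <= 16
  expect_equal(unname(topo), unname(rowMeans(m[, cols])), tolerance = 1e-12)
  expect_error(band_topography(m, c(71, 80)), "empty")
})

test_that("the global change index obeys its metric properties", {
  base <- matrix(1, 4, 5)
  maps <- replicate(5, base, simplify = FALSE)
  expect_equal(global_change_index(maps), 0)
  # consecutive maps differing in one feature by 3 -> index 3
  for (i in 2:5) maps[[i]] <- maps[[i - 1]] + matrix(c(3, rep(0, 19)), 4, 5)
  expect_equal(global_change_index(maps), 3)
  withr::with_seed(6, {
    rnd <- replicate(5, matrix(runif(20), 4, 5), simplify = FALSE)
  })
  oracle <- mean(sapply(1:4, function(i) {
    s <- 0
    for (r in 1:4) for (c in 1:5) {
      s <- s + (rnd[[i + 1]][r, c] - rnd[[i]][r, c])^2
    }
    sqrt(s)
  }))
  expect_equal(global_change_index(rnd), oracle, tolerance = 1e-12)
  # linear scaling
  expect_equal(global_change_index(lapply(rnd, `*`, 7)),
               7 * global_change_index(rnd), tolerance = 1e-12)
  bad <- rnd
  bad[[3]] <- matrix(0, 2, 2)
  expect_error(global_change_index(bad), "mismatch")
  expect_error(global_change_index(rnd[1:3]), "5")
})

test_that("per-key permutation trends detect planted increases and floor p values", {
  withr::with_seed(7, {
    dat <- expand.grid(participant = paste0("P", 1:10), day = 1:5,
                       key = paste0("f", 1:6))
    dat$value <- rnorm(nrow(dat), 0, 0.5)
    up <- dat$key %in% c("f1", "f2")
    dat$value[up] <- dat$value[up] + 0.8 * dat$day[up]
  })
  res <- trend_permutation_by_feature(dat, n_perm = 400, seed = 2)
  sig <- res$key[res$p_perm < 0.05]
  expect_true(all(c("f1", "f2") %in% sig))
  expect_true(all(res$direction[res$key %in% c("f1", "f2")] == 1))
  expect_true(all(res$p_perm >= 1 / 401))
  expect_warning(trend_permutation_by_feature(dat, n_perm = 50, seed = 1),
                 "coarse")
})

test_that("correlations agree with the textbook formula and reject degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x)$r, 1)
  withr::with_seed(8, {
    a <- rnorm(12)
    b <- rnorm(12)
  })
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlate(a, b)$r, r_oracle, tolerance = 1e-12)
  expect_error(correlate(x, rep(1, 5)), "variance")
  expect_error(correlate(1:2, 1:2), "n >= 3")
})
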
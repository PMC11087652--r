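test_that("change stack is element-wise post minus pre", {
  cfg <- tiny_config(n_timepoints = 30)
  b <- generate_bold(cfg)
  pre <- isc_matrix(b$pre[[1]]); post <- isc_matrix(b$post[[1]])
  ch <- change_stack(pre, post)
  expect_equal(ch$values, post$values - pre$values)
  expect_true(all(abs(change_stack(pre, pre)$values) < 1e-15))
  pre_bad <- pre; pre_bad$subject_ids <- rev(pre$subject_ids)
  expect_error(change_stack(pre_bad, post), "subject ids")
})

test_that("pairwise designs have the documented combinatorics", {
  d <- build_design(c("g1", "g1", "g2", "g2", "control"))
  expect_equal(nrow(d$X), 10)                       # C(5,2)
  expect_equal(colnames(d$X), c("intercept", "group:g1", "group:g2"))
  expect_equal(sum(d$X[, "group:g1"]), 1)
  expect_true(all(d$X[, "intercept"] == 1))
  da <- build_design(c("g1", "g1", "g2", "g2", "control"),
                     mode = "all_groups")
  expect_equal(sum(da$X[, "any_group"]), 2)
  # two groups of four: 28 pair rows, six 1s per group column
  d8 <- build_design(rep(c("g1", "g2"), each = 4))
  expect_equal(nrow(d8$X), 28)                      # C(8,2)
  expect_equal(unname(colSums(d8$X)[c("group:g1", "group:g2")]), c(6, 6))
  # concatenation across clips
  d2 <- build_design(rep(c("g1", "g2"), each = 4), clips = 1:3)
  expect_equal(nrow(d2$X), 28 * 3)
  expect_equal(d2$pair_index$clip, rep(1:3, each = 28))
  expect_error(build_design(c("g1", "g1", "g2")), "fewer than 2")
})

test_that("regression betas equal the normal-equation solution", {
  st <- rand_stack(9, 4, seed = 10)
  d <- build_design(c(rep("g1", 3), rep("g2", 3), rep("control", 3)))
  fit <- fit_pairwise_regression(st, d)
  Y <- neuralign:::vectorize_target(st, d)
  for (v in 1:4)
    expect_equal(unname(fit$betas[v, ]), ols_oracle(d$X, Y[, v]),
                 tolerance = 1e-10)
  # intercept-only design recovers the mean
  d1 <- d; d1$X <- d$X[, 1, drop = FALSE]
  fit1 <- fit_pairwise_regression(st, d1)
  expect_equal(unname(fit1$betas[, 1]), unname(colMeans(Y)))
  # rank-deficient design is rejected with the collinear column named
  dd <- d; dd$X <- cbind(d$X, dup = d$X[, "group:g1"])
  expect_error(fit_pairwise_regression(st, dd), "dup")
})

test_that("group betas recover the planted change b_post - b_pre", {
  cfg <- tiny_config(n_timepoints = 1200, a_shared = 0.1,
                     b_group_pre = 0.1, b_group_post = 0.4,
                     affected_fraction = 1, n_controls = 2,
                     group_sizes = c(3, 3), seed = 8)
  b <- generate_bold(cfg)
  ch <- change_stack(isc_matrix(b$pre[[1]]), isc_matrix(b$post[[1]]))
  g1 <- which(cfg$group_labels == "g1")
  m <- matrix(ch$values[, g1, g1], nrow = cfg$n_voxels)
  mean_change <- mean(m[, as.vector(upper.tri(diag(3)))])
  expect_lt(abs(mean_change - 0.3), 0.08)
  d <- build_design(cfg$group_labels, subject_ids = cfg$subject_ids)
  fit <- fit_pairwise_regression(ch, d)
  expect_lt(abs(mean(fit$betas[, "group:g1"]) - 0.3), 0.08)
  expect_lt(abs(mean(fit$betas[, "intercept"])), 0.05)
})

test_that("novel-clip regression uses post ISC as target", {
  st <- rand_stack(8, 3, seed = 11)
  # constant ISC matrix: intercept = the constant, group betas 0
  st$values[] <- 0.42
  for (s in 1:8) st$values[, s, s] <- 1
  d <- build_design(rep(c("g1", "g2"), each = 4))
  fit <- novel_clip_regression(st, d)
  expect_equal(fit$model_tag, "novel_post")
  expect_true(all(abs(fit$betas[, "intercept"] - 0.42) < 1e-12))
  expect_true(all(abs(fit$betas[, -1]) < 1e-12))
})

test_that("betas and exhaustive p-values are invariant to subject order", {
  st <- rand_stack(6, 3, seed = 12)
  labels <- c("g1", "g1", "g1", "g2", "g2", "g2")
  d <- build_design(labels)
  p1 <- subjectwise_permutation(st, d, exhaustive = TRUE)
  perm <- c(4, 2, 6, 1, 3, 5)
  st2 <- st; st2$values <- st$values[, perm, perm]
  d2 <- build_design(labels[perm])
  p2 <- subjectwise_permutation(st2, d2, exhaustive = TRUE)
  expect_equal(sort(colnames(p1$p)), sort(colnames(p2$p)))
  expect_equal(p2$p[, colnames(p1$p)], p1$p, tolerance = 1e-12)
  expect_equal(p2$betas[, colnames(p1$betas)], p1$betas, tolerance = 1e-12)
})

test_that("the same relabeling is applied to rows and columns jointly", {
  # a strong within-group effect must vanish under almost all relabelings:
  # p for the group column should be at the enumeration floor
  values <- array(0, dim = c(1, 6, 6))
  g <- list(1:3, 4:6)
  for (m in g[[1]]) for (n in g[[1]]) if (m != n) values[1, m, n] <- 0.5
  st <- rand_stack(6, 1); st$values <- values
  d <- build_design(c("g1", "g1", "g1", "g2", "g2", "g2"))
  pr <- subjectwise_permutation(st, d, exhaustive = TRUE)
  # exactly the 3!*3! = 36 relabelings preserving {1,2,3} setwise keep all
  # three hot pairs inside the g1 block and reproduce |beta| = 0.5
  expect_equal(unname(pr$p[1, "group:g1"]), 36 / 720)
})

test_that("permutation p-values are calibrated on a null cohort", {
  cfg <- tiny_config(n_subjects = 10, n_groups = 2, n_controls = 2,
                     grid = c(5, 5, 4), n_timepoints = 100,
                     a_shared = 0.1, seed = 21)
  b <- generate_bold(cfg)
  ch <- change_stack(isc_matrix(b$pre[[1]]), isc_matrix(b$post[[1]]))
  d <- build_design(cfg$group_labels, subject_ids = cfg$subject_ids)
  pr <- subjectwise_permutation(ch, d, n_perm = 199, seed = 5)
  frac <- mean(pr$p[, c("group:g1", "group:g2")] < 0.05)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.10)
  expect_error(subjectwise_permutation(ch, d, n_perm = 0), "n_perm")
})

test_that("cluster correction keeps components meeting the extent rule", {
  grid <- c(8, 8, 8); V <- prod(grid)
  betas <- matrix(0.01, V, 1, dimnames = list(NULL, "group:g1"))
  p <- matrix(0.5, V, 1, dimnames = list(NULL, "group:g1"))
  # planted 4x4x4 block of 64 suprathreshold voxels
  mask <- array(FALSE, grid); mask[1:4, 1:4, 1:4] <- TRUE
  p[which(mask), 1] <- 0.001
  betas[which(mask), 1] <- 0.4
  maps <- structure(list(betas = betas, predictors = "group:g1",
                         grid = grid, model_tag = "change"),
                    class = "regression_maps")
  perm <- structure(list(p = p, betas = betas, predictors = "group:g1",
                         n_perm = 999, seed = 1, grid = grid),
                    class = "permutation_result")
  tab <- cluster_correct(maps, perm, min_size = 32)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_voxels, 64)
  expect_equal(tab$sign, "positive")
  expect_equal(tab$mean_beta, 0.4)
  expect_setequal(tab$voxels[[1]], which(mask))
  # two blocks of 30 and 40: only the 40 survives min_size 32
  p2 <- matrix(0.5, V, 1, dimnames = list(NULL, "group:g1"))
  b2 <- matrix(0.01, V, 1, dimnames = list(NULL, "group:g1"))
  m30 <- array(FALSE, grid); m30[1:2, 1:3, 1:5] <- TRUE     # 30
  m40 <- array(FALSE, grid); m40[5:6, 5:8, 4:8] <- TRUE     # 40
  p2[c(which(m30), which(m40)), 1] <- 0.001
  b2[c(which(m30), which(m40)), 1] <- 0.2
  maps$betas <- b2; perm$p <- p2; perm$betas <- b2
  tab2 <- cluster_correct(maps, perm, min_size = 32)
  expect_equal(nrow(tab2), 1)
  expect_equal(tab2$n_voxels, 40)
  # nothing below threshold -> empty table
  perm$p[] <- 0.5
  expect_equal(nrow(cluster_correct(maps, perm, min_size = 32)), 0)
  # missing grid geometry is rejected
  maps$grid <- NULL
  expect_error(cluster_correct(maps, perm), "grid")
})

test_that("whole-brain alignment sums positive change only", {
  st <- rand_stack(3, 5, seed = 13)
  st$values[, 2, 1] <- c(0.1, 0.1, 0.1, -0.5, -0.5)
  st$values[, 1, 2] <- st$values[, 2, 1]
  wba <- whole_brain_alignment(st)
  expect_equal(wba$value[wba$i == 2 & wba$j == 1], 0.3)
  allneg <- st; allneg$values[] <- -abs(allneg$values)
  expect_true(all(whole_brain_alignment(allneg)$value == 0))
  # monotonicity: raising one voxel's change never lowers the score
  st2 <- st; st2$values[1, 2, 1] <- st$values[1, 2, 1] + 0.7
  wba2 <- whole_brain_alignment(st2)
  expect_true(all(wba2$value >= wba$value - 1e-12))
})
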
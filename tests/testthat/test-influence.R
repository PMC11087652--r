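test_that("influence stack matches a brute-force ordered-pair oracle", {
  cfg <- tiny_config(n_subjects = 4, n_groups = 1, grid = c(2, 1, 1),
                     n_timepoints = 40, seed = 14)
  b <- generate_bold(cfg)
  inf <- influence_stack(b$pre[[1]], b$post[[1]])
  for (v in 1:2) for (e in 1:4) for (a in 1:4) {
    if (e == a) {
      expect_true(is.na(inf$values[v, e, a]))
    } else {
      expect_equal(inf$values[v, e, a],
                   pairwise_isc(b$pre[[1]]$data[e, v, ],
                                b$post[[1]]$data[a, v, ]) -
                     pairwise_isc(b$pre[[1]]$data[e, v, ],
                                  b$pre[[1]]$data[a, v, ]))
    }
  }
})

test_that("influence has the documented limiting values", {
  cfg <- tiny_config(n_subjects = 3, n_groups = 1, grid = c(2, 1, 1),
                     n_timepoints = 50, seed = 15)
  b <- generate_bold(cfg)
  # alter_post = alter_pre -> influence 0 everywhere
  inf0 <- influence_stack(b$pre[[1]], b$pre[[1]])
  off <- !is.na(inf0$values)
  expect_true(all(abs(inf0$values[off]) < 1e-12))
  # alter_post = ego_pre -> influence = 1 - ISC(ego_pre, alter_pre)
  post <- b$post[[1]]
  post$data[2, , ] <- b$pre[[1]]$data[1, , ]
  inf1 <- influence_stack(b$pre[[1]], post)
  for (v in 1:2)
    expect_equal(inf1$values[v, 1, 2],
                 1 - pairwise_isc(b$pre[[1]]$data[1, v, ],
                                  b$pre[[1]]$data[2, v, ]))
})

test_that("injected imitation is detected in one direction only", {
  cfg <- tiny_config(n_subjects = 6, n_groups = 2, grid = c(2, 2, 1),
                     n_timepoints = 2500, a_shared = 0, seed = 16)
  b <- generate_bold(cfg)
  set.seed(17)
  post <- inject_influence(b$pre[[1]], b$post[[1]], 1, 2, w = 0.25)
  inf <- influence_stack(b$pre[[1]], post)
  expect_lt(abs(mean(inf$values[, 1, 2]) - 0.5), 0.06)  # sqrt(w)
  expect_lt(abs(mean(inf$values[, 2, 1])), 0.06)        # reverse at null
})

test_that("centrality designs z-score and vectorize ordered pairs", {
  labels <- c("g1", "g1", "g1", "g2", "g2", "control")
  cent <- setNames(c(3, 1, 2, 5, 4, 9), paste0("s", 1:6))
  d <- centrality_design(labels, cent, subject_ids = paste0("s", 1:6))
  # ordered same-group pairs: 3*2 + 2*1 = 8 rows; control excluded
  expect_equal(nrow(d$X), 8)
  expect_true(all(d$pair_index$i != d$pair_index$j))
  expect_false(any(c(d$pair_index$i, d$pair_index$j) == 6))
  expect_equal(colnames(d$X),
               c("intercept", "ego:centrality", "alter:centrality"))
  # z-scoring over included subjects only (not the control)
  incl <- 1:5
  z <- (cent[incl] - mean(cent[incl])) / sd(cent[incl])
  expect_equal(unname(d$X[1, "ego:centrality"]),
               unname(z[d$pair_index$i[1]]))
  expect_error(centrality_design(labels, setNames(rep(1, 6),
                                                  paste0("s", 1:6))),
               "constant")
})

test_that("influence regression equals the normal-equation oracle", {
  st <- rand_ordered_stack(6, 5, seed = 18)
  labels <- c("g1", "g1", "g1", "g2", "g2", "g2")
  set.seed(19)
  cent <- setNames(rnorm(6), paste0("s", 1:6))
  d <- centrality_design(labels, cent, subject_ids = paste0("s", 1:6))
  fit <- fit_influence_regression(st, d)
  Y <- neuralign:::vectorize_target(st, d)
  for (v in 1:5)
    expect_equal(unname(fit$betas[v, ]), ols_oracle(d$X, Y[, v]),
                 tolerance = 1e-10)
})

test_that("alter-centrality effects are recovered when influence tracks centrality", {
  # alters with higher centrality imitate their group egos more strongly
  hits <- 0
  for (seed in 1:10) {
    cfg <- tiny_config(n_subjects = 6, n_groups = 2, grid = c(2, 2, 1),
                       n_timepoints = 300, a_shared = 0, seed = 100 + seed)
    b <- generate_bold(cfg)
    cent <- setNames(c(0, 1, 2, 0, 1, 2), cfg$subject_ids)
    set.seed(200 + seed)
    post <- b$post[[1]]
    for (g in c("g1", "g2")) {
      m <- which(cfg$group_labels == g)
      for (a in m[-1])
        post <- inject_influence(b$pre[[1]], post, ego = m[1], alter = a,
                                 w = 0.2 * cent[a]^2 / 4)
    }
    inf <- influence_stack(b$pre[[1]], post)
    d <- centrality_design(cfg$group_labels, cent,
                           subject_ids = cfg$subject_ids)
    fit <- fit_influence_regression(inf, d)
    if (mean(fit$betas[, "alter:centrality"]) > 0) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("whole-brain influence sums positive values per ordered pair", {
  st <- rand_ordered_stack(3, 5, seed = 20)
  st$values[, 1, 2] <- c(0.2, 0.2, 0.2, 0.2, 0.2)
  st$values[, 2, 1] <- c(-1, -1, -1, -1, -1)
  wbi <- whole_brain_influence(st)
  expect_equal(wbi$value[wbi$ego == 1 & wbi$alter == 2], 1.0)
  expect_equal(wbi$value[wbi$ego == 2 & wbi$alter == 1], 0)
  expect_equal(nrow(wbi), 6)  # ordered pairs of 3 subjects
})
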
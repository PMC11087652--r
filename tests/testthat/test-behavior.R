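test_that("city-block distance is the L1 metric", {
  expect_equal(survey_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(survey_distance(c(1, 2, 3), c(2, 2, 5)), 3)
  expect_error(survey_distance(1:3, 1:4), "equal length")
  set.seed(1)
  for (k in 1:20) {
    a <- sample(1:7, 5, TRUE); b <- sample(1:7, 5, TRUE)
    cc <- sample(1:7, 5, TRUE)
    expect_lte(survey_distance(a, cc),
               survey_distance(a, b) + survey_distance(b, cc))
  }
})

test_that("survey influence is the city-block movement toward the ego", {
  ego <- c(1, 5, 3); alt_pre <- c(4, 2, 6)
  expect_equal(survey_influence(ego, alt_pre, alt_pre), 0)
  expect_equal(survey_influence(ego, alt_pre, ego),
               survey_distance(ego, alt_pre))
  expect_equal(survey_influence(ego, alt_pre, c(2, 4, 5)),
               9 - survey_distance(ego, c(2, 4, 5)))
})

test_that("gini matches the double-sum oracle and is scale invariant", {
  expect_equal(gini(c(0, 1)), 0.5)
  expect_equal(gini(c(5, 5, 5)), 0)
  x <- c(1, 1, 1, 97)
  expect_equal(gini(x), gini_oracle(x))
  # merging two equal values leaves G unchanged in the population form
  expect_equal(gini(c(2, 2, 8, 8)), gini_oracle(c(2, 2, 8, 8)))
  set.seed(2)
  for (k in 1:10) {
    v <- rexp(6)
    expect_equal(gini(3.7 * v), gini(v))
    expect_gte(gini(v), 0); expect_lt(gini(v), 1)
  }
  expect_error(gini(c(0, 0)), "all zero")
  expect_error(gini(c(-1, 2)), "non-negative")
})

test_that("word-stem filters match hand enumeration and are idempotent", {
  # toy corpus: "alpha" frequent+broad; "beta" frequent but 2 speakers;
  # "rare" used 3 times; "narrow" broad speakers but 1 clip
  turns <- data.frame(turn_id = 1:12,
                      speaker_id = rep(paste0("s", 1:4), 3),
                      clip_id = rep(1:3, each = 4))
  tokens <- rbind(
    data.frame(turn_id = 1:12, stem = "alpha"),        # 12x, 4 spk, 3 clips
    data.frame(turn_id = c(1, 5, 9, 1, 5, 9), stem = "beta"),  # 6x, 2 spk
    data.frame(turn_id = c(2, 6, 10), stem = "rare"),  # 3x -> RAREWORD
    data.frame(turn_id = 1:4, stem = "narrow"))        # 4x -> RAREWORD (rare)
  m <- word_stem_matrix(tokens, turns, min_total = 5, min_speakers = 3,
                        min_clips = 3)
  expect_setequal(colnames(m), c("alpha", "RAREWORD"))
  expect_equal(attr(m, "dropped"), "beta")
  expect_equal(unname(m[, "alpha"]), rep(1L, 12))
  expect_equal(sum(m[, "RAREWORD"]), 7)  # 3 rare + 4 narrow
  # idempotence: reapplying the filters to the surviving tokens changes nothing
  surv <- tokens[tokens$stem %in% colnames(m), ]
  m2 <- word_stem_matrix(surv, turns, min_total = 5, min_speakers = 3,
                         min_clips = 3)
  expect_identical(m[, "alpha"], m2[, "alpha"])
  expect_error(word_stem_matrix(tokens[0, ], turns), "empty corpus")
})

test_that("word regression recovers a planted centrality-linked stem", {
  set.seed(3)
  speakers <- paste0("s", 1:12)
  cov <- setNames(c(rep(2, 4), rep(0, 4), rep(-2, 4)), speakers)
  turns <- data.frame(turn_id = 1:120,
                      speaker_id = rep(speakers, each = 10),
                      clip_id = rep(1:3, 40))
  # "elite" used only by high-covariate speakers; "common" by everyone
  tok <- rbind(
    data.frame(turn_id = turns$turn_id[turns$speaker_id %in% speakers[1:4]],
               stem = "elite"),
    data.frame(turn_id = c(1:120, sample(1:120, 50, replace = TRUE)),
               stem = "common"))
  m <- word_stem_matrix(tok, turns, min_total = 5, min_speakers = 3,
                        min_clips = 2)
  fit <- word_regression(m, cov, turns$speaker_id, n_perm = 199, seed = 4)
  expect_gt(fit$beta[fit$stem == "elite"], 0)
  expect_lt(fit$perm_p[fit$stem == "elite"], 0.05)
  # null covariate: permutation p-values are not systematically small
  cov0 <- setNames(rnorm(12), speakers)
  fit0 <- word_regression(m, cov0, turns$speaker_id, n_perm = 99, seed = 5)
  expect_gt(mean(fit0$perm_p), 0.2)
})

test_that("oracle equivalence holds for the word regression solver", {
  set.seed(6)
  X <- matrix(rpois(50 * 8, 1), 50, 8,
              dimnames = list(1:50, paste0("w", 1:8)))
  spk <- sample(paste0("s", 1:10), 50, TRUE)
  cov <- setNames(rnorm(10), paste0("s", 1:10))
  fit <- word_regression(X, cov, spk, n_perm = 0)
  z <- (cov - mean(cov)) / sd(cov)
  b <- ols_oracle(cbind(1, X), as.numeric(z[spk]))
  expect_equal(fit$beta, b[-1], tolerance = 1e-10)
})

test_that("session-by-group model detects survey convergence", {
  cfg <- tiny_config(n_subjects = 12, n_groups = 3, n_controls = 0,
                     group_sizes = c(4, 4, 4), seed = 30)
  s <- generate_surveys(cfg, pull = 1)
  fit <- survey_session_model(s$pre, s$post, cfg$group_labels, n_perm = 60,
                              seed = 7)
  co <- fit$coefficients
  # within-group distances collapse after conversation: the within main
  # effect (at before = 0) is negative, the before:within interaction
  # positive, both clearly detected
  expect_lt(co$beta[co$term == "within"], 0)
  expect_gt(co$beta[co$term == "before:within"], 0)
  expect_lt(co$perm_p[co$term == "before:within"], 0.05)
  expect_gt(fit$marginal_r2, 0.1)
  expect_lt(fit$marginal_r2_p, 0.05)
  # pull = 1: post within-group pair distances are exactly zero
  post_d <- subset(fit$table, before == 0 & within == 1)
  expect_true(all(post_d$distance == 0))
})

test_that("interaction sign is recovered across seeds at moderate pull", {
  hits <- 0
  for (seed in 1:100) {
    cfg <- tiny_config(n_subjects = 12, n_groups = 3, n_controls = 0,
                       group_sizes = c(4, 4, 4), seed = 1000 + seed,
                       n_timepoints = 2)
    s <- generate_surveys(cfg, pull = 0.5)
    N <- 12
    flat <- function(a) matrix(a, nrow = N)
    dpre <- as.matrix(dist(flat(s$pre), method = "manhattan"))
    dpost <- as.matrix(dist(flat(s$post), method = "manhattan"))
    prs <- t(combn(N, 2))
    within <- cfg$group_labels[prs[, 1]] == cfg$group_labels[prs[, 2]]
    tab <- data.frame(before = rep(c(1, 0), each = nrow(prs)),
                      within = rep(as.numeric(within), 2),
                      d = c(dpre[prs], dpost[prs]))
    b <- coef(lm(d ~ before * within, data = tab))["before:within"]
    if (b > 0) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("pairwise correlation test respects pair structure", {
  set.seed(8)
  N <- 12
  prs <- t(combn(N, 2))
  x <- rnorm(nrow(prs))
  res <- pairwise_correlation_test(x, x, data.frame(i = prs[, 1],
                                                    j = prs[, 2]),
                                   n_subjects = N, n_perm = 99)
  expect_equal(res$r, 1)
  expect_lt(res$p, 0.05)
  # independent x, y: small p should appear at roughly the nominal rate
  small <- 0
  for (k in 1:40) {
    set.seed(100 + k)
    y <- rnorm(nrow(prs))
    r0 <- pairwise_correlation_test(rnorm(nrow(prs)), y,
                                    data.frame(i = prs[, 1], j = prs[, 2]),
                                    n_subjects = N, n_perm = 99,
                                    seed = k)
    if (r0$p < 0.05) small <- small + 1
  }
  expect_lte(small, 8)   # binomial(40, 0.05) upper tail
})
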
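#' City-block distance between survey answer vectors
#'
#' `sum(|a_i - b_i|)` over numeric-coded items.
#'
#' @param a,b equal-length numeric vectors.
#' @return non-negative scalar.
#' @export
#' @examples
#' survey_distance(c(1, 2, 3), c(2, 2, 5))  # 3
survey_distance <- function(a, b) {
  if (length(a) != length(b)) stop("answer vectors must have equal length")
  sum(abs(a - b))
}

# pairwise city-block distance over subjects x items matrix
survey_distance_matrix <- function(answers) {
  as.matrix(stats::dist(answers, method = "manhattan"))
}

#' Survey influence of an ego on an alter
#'
#' The behavioral analogue of neural influence:
#' `d(ego_pre, alter_pre) - d(ego_pre, alter_post)` with `d` the city-block
#' distance. Positive values mean the alter's answers moved toward the ego's
#' initial answers.
#'
#' @param ego_pre,alter_pre,alter_post equal-length answer vectors.
#' @return scalar.
#' @export
survey_influence <- function(ego_pre, alter_pre, alter_post) {
  survey_distance(ego_pre, alter_pre) - survey_distance(ego_pre, alter_post)
}

#' Gini coefficient (population form)
#'
#' `G = sum_i sum_j |x_i - x_j| / (2 n^2 mean(x))`, the relative mean
#' absolute difference, without small-sample correction. 0 means perfect
#' equality; values approach 1 as one member holds everything.
#'
#' @param values non-negative numeric vector, not all zero.
#' @return scalar in `[0, 1)`.
#' @export
#' @examples
#' gini(c(0, 1))         # 0.5
#' gini(c(5, 5, 5, 5))   # 0
gini <- function(values) {
  if (any(is.na(values))) stop("values must not contain NA")
  if (any(values < 0)) stop("values must be non-negative")
  if (all(values == 0)) stop("values must not be all zero")
  n <- length(values)
  sum(abs(outer(values, values, "-"))) / (2 * n^2 * mean(values))
}

#' Session-by-comparison-type model of pairwise survey distance
#'
#' Tests whether conversation made within-group survey answers more similar:
#' for every unordered subject pair and both sessions, the city-block
#' distance between their (clip-concatenated) answers is modeled as
#' `distance ~ before * within_group + (1 | pair)` — the effect of session
#' (before vs after conversation), comparison type (within vs between
#' groups), and their interaction, with random intercepts for participant
#' pairs. The mixed model is delegated to `lme4::lmer`; the marginal R^2
#' (fixed-effects-only variance fraction) and its permutation p-value —
#' refitting on `n_perm` random permutations of the distance vector — are
#' computed here, along with permutation p-values per coefficient.
#'
#' @param surveys_pre,surveys_post `subjects x items x clips` arrays (as
#'   from [generate_surveys()]).
#' @param group_labels label per subject; `control_label` pairs count as
#'   between-group.
#' @param control_label reserved label.
#' @param n_perm DV permutations for the p-values (0 skips them).
#' @param seed permutation seed.
#' @return list: `table` (the long data), `fit` (the `lmerMod`),
#'   `coefficients` (beta, 95% Wald CI, permutation p), `marginal_r2`,
#'   `marginal_r2_p`.
#' @export
survey_session_model <- function(surveys_pre, surveys_post, group_labels,
                                 control_label = "control", n_perm = 200,
                                 seed = 1L) {
  N <- dim(surveys_pre)[1]
  flat <- function(a) matrix(a, nrow = N)   # subjects x (items*clips)
  d_pre <- survey_distance_matrix(flat(surveys_pre))
  d_post <- survey_distance_matrix(flat(surveys_post))
  prs <- t(combn(seq_len(N), 2))
  within <- as.numeric(group_labels[prs[, 1]] == group_labels[prs[, 2]] &
                         group_labels[prs[, 1]] != control_label)
  pair_id <- paste0("p", prs[, 1], "_", prs[, 2])
  tab <- data.frame(
    pair = rep(pair_id, 2),
    before = rep(c(1, 0), each = nrow(prs)),
    within = rep(within, 2),
    distance = c(d_pre[prs], d_post[prs]))
  fit <- lme4::lmer(distance ~ before * within + (1 | pair), data = tab,
                    REML = FALSE)
  r2 <- marginal_r2(fit)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  coefs <- data.frame(term = names(fe), beta = unname(fe),
                      ci_lo = unname(fe - 1.96 * se),
                      ci_hi = unname(fe + 1.96 * se),
                      perm_p = NA_real_)
  r2_p <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    null_r2 <- numeric(n_perm)
    exceed <- numeric(length(fe))
    for (r in seq_len(n_perm)) {
      tab$dv_perm <- sample(tab$distance)
      f0 <- suppressMessages(suppressWarnings(
        lme4::lmer(dv_perm ~ before * within + (1 | pair), data = tab,
                   REML = FALSE)))
      null_r2[r] <- marginal_r2(f0)
      exceed <- exceed + (abs(lme4::fixef(f0)) >= abs(fe))
    }
    r2_p <- (1 + sum(null_r2 >= r2)) / (1 + n_perm)
    coefs$perm_p <- (1 + exceed) / (1 + n_perm)
  }
  list(table = tab, fit = fit, coefficients = coefs,
       marginal_r2 = r2, marginal_r2_p = r2_p)
}

#' Marginal R-squared of a mixed-effects model
#'
#' Variance explained by the fixed effects alone:
#' `var(X beta) / (var(X beta) + sum(random-intercept variances) +
#' residual variance)` (the Nakagawa-Schielzeth decomposition for Gaussian
#' responses).
#'
#' @param fit an `lmerMod`.
#' @return scalar in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  var_f <- var(as.numeric(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  var_r <- sum(vapply(vc, function(m) sum(diag(m)), numeric(1)))
  var_e <- attr(vc, "sc")^2
  var_f / (var_f + var_r + var_e)
}

#' Turn-by-stem count matrix with rarity and breadth filters
#'
#' Builds the word-stem count matrix used by the word-level regressions.
#' Filters are applied in order: (1) stems used fewer than `min_total` times
#' across all conversations are folded into the placeholder column
#' `RAREWORD`; (2) surviving stems are kept only if used by at least
#' `min_speakers` distinct speakers and in discussions of at least
#' `min_clips` distinct clips, which drops speaker- and movie-specific
#' terms. The filters are idempotent: reapplying them to their own output
#' changes nothing.
#'
#' @param tokens data.frame with one row per stem use: `turn_id`, `stem`.
#' @param turns data.frame mapping `turn_id` to `speaker_id` and `clip_id`.
#' @param min_total rarity threshold (uses, corpus-wide).
#' @param min_speakers speaker-breadth threshold.
#' @param min_clips clip-breadth threshold.
#' @return integer matrix `turns x stems` (rownames = turn ids; includes a
#'   `RAREWORD` column when any stem was folded), with attribute
#'   `"dropped"` listing stems removed by the breadth filters.
#' @export
word_stem_matrix <- function(tokens, turns, min_total = 5,
                             min_speakers = 10, min_clips = 3) {
  if (!nrow(tokens)) stop("empty corpus")
  tokens <- merge(tokens, turns[c("turn_id", "speaker_id", "clip_id")],
                  by = "turn_id")
  # (1) rarity: fold stems used < min_total times into RAREWORD
  totals <- table(tokens$stem)
  rare <- names(totals)[totals < min_total]
  tokens$stem[tokens$stem %in% rare] <- "RAREWORD"
  # (2) breadth: >= min_speakers speakers and >= min_clips clips
  common <- setdiff(unique(tokens$stem), "RAREWORD")
  n_spk <- vapply(common, function(s)
    length(unique(tokens$speaker_id[tokens$stem == s])), integer(1))
  n_clp <- vapply(common, function(s)
    length(unique(tokens$clip_id[tokens$stem == s])), integer(1))
  keep <- common[n_spk >= min_speakers & n_clp >= min_clips]
  dropped <- setdiff(common, keep)
  tokens <- tokens[tokens$stem %in% c(keep, "RAREWORD"), , drop = FALSE]
  stems <- c(sort(keep), intersect("RAREWORD", unique(tokens$stem)))
  ids <- turns$turn_id
  m <- matrix(0L, length(ids), length(stems),
              dimnames = list(as.character(ids), stems))
  if (nrow(tokens)) {
    cnt <- table(factor(tokens$turn_id, levels = ids),
                 factor(tokens$stem, levels = stems))
    m[] <- as.integer(cnt)
  }
  attr(m, "dropped") <- dropped
  m
}

#' Per-stem regression of a speaker covariate on word use
#'
#' OLS with the z-scored covariate (PCA centrality or perceived status of
#' the turn's speaker) as target and word-stem counts as predictors; betas
#' are interpretable as predicted standard deviations from the
#' population mean per additional use of a stem. Permutation p-values
#' shuffle the covariate across speakers (speaker-level, because the
#' covariate is constant within speaker), preserving the turn structure.
#' Collinear stem columns are dropped and reported.
#'
#' @param stem_matrix from [word_stem_matrix()].
#' @param covariate named numeric vector per speaker (z-scored internally).
#' @param speaker_of_turn speaker id per row of `stem_matrix`.
#' @param n_perm permutations (0 skips p-values).
#' @param seed permutation seed.
#' @return data.frame `stem`, `beta`, `perm_p`; attribute `"dropped"` lists
#'   collinear stems removed.
#' @export
word_regression <- function(stem_matrix, covariate, speaker_of_turn,
                            n_perm = 500, seed = 1L) {
  spk <- as.character(speaker_of_turn)
  z <- (covariate - mean(covariate)) / sd(covariate)
  y <- as.numeric(z[spk])
  X <- cbind(intercept = 1, stem_matrix)
  qx <- qr(X)
  dropped <- character()
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  }
  b <- qr.coef(qr(X), y)
  stems <- setdiff(colnames(X), "intercept")
  exceed <- setNames(numeric(length(stems)), stems)
  if (n_perm > 0) {
    set.seed(seed)
    spk_u <- names(z)
    qrX <- qr(X)
    for (r in seq_len(n_perm)) {
      zp <- setNames(z[sample(length(z))], spk_u)
      bp <- qr.coef(qrX, as.numeric(zp[spk]))
      exceed <- exceed + (abs(bp[stems]) >= abs(b[stems]))
    }
  }
  out <- data.frame(stem = stems, beta = unname(b[stems]),
                    perm_p = if (n_perm > 0)
                      unname((1 + exceed) / (1 + n_perm)) else NA_real_)
  attr(out, "dropped") <- setdiff(dropped, "intercept")
  out
}

#' Correlation of two per-pair quantities with subject-wise permutation p
#'
#' Pearson correlation of two vectors indexed by participant pairs (e.g.
#' survey-answer similarity vs whole-brain alignment), with a permutation
#' p-value that respects the non-independence of pairs: subjects are
#' relabeled and `y` is re-indexed through the permuted pairings, `x` held
#' fixed.
#'
#' @param x,y numeric vectors over the same pairs.
#' @param pair_index data.frame/matrix with columns `i`, `j` (subject
#'   indices; equal `i`,`j` forbidden). Ordered or unordered pairs both
#'   work; for unordered pairs `y` must be supplied for each pair once.
#' @param n_subjects number of subjects being relabeled.
#' @param n_perm permutations.
#' @param seed permutation seed.
#' @return list `r`, `p`, `n_perm`.
#' @export
pairwise_correlation_test <- function(x, y, pair_index, n_subjects,
                                      n_perm = 2000, seed = 1L) {
  pair_index <- as.data.frame(pair_index)
  if (length(x) != length(y) || length(x) != nrow(pair_index))
    stop("x, y and pair_index must have matching lengths")
  r_obs <- cor(x, y)
  ymat <- matrix(NA_real_, n_subjects, n_subjects)
  ymat[cbind(pair_index$i, pair_index$j)] <- y
  # mirror only cells not supplied, so unordered input works and ordered
  # input keeps its direction-specific values
  rev_cells <- cbind(pair_index$j, pair_index$i)
  miss <- is.na(ymat[rev_cells])
  ymat[rev_cells[miss, , drop = FALSE]] <- y[miss]
  set.seed(seed)
  exceed <- 0
  for (r in seq_len(n_perm)) {
    sg <- sample.int(n_subjects)
    yp <- ymat[cbind(sg[pair_index$i], sg[pair_index$j])]
    exceed <- exceed + (abs(cor(x, yp)) >= abs(r_obs))
  }
  list(r = r_obs, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}
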
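# shared fixtures and independent oracles, built in code at test time

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 8, n_groups = 2, grid = c(3, 3, 2),
         n_timepoints = 60, a_shared = 0.15, seed = 42L),
    list(...))
  do.call(sim_config, args)
}

# random symmetric change/isc stack for oracle tests
rand_stack <- function(n_subjects, n_voxels, seed = 1, clip_id = 1,
                       grid = NULL) {
  set.seed(seed)
  values <- array(NA_real_, dim = c(n_voxels, n_subjects, n_subjects))
  for (v in seq_len(n_voxels)) {
    m <- matrix(rnorm(n_subjects^2), n_subjects)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    values[v, , ] <- m
  }
  structure(list(values = values,
                 subject_ids = paste0("s", seq_len(n_subjects)),
                 group_labels = NULL, clip_id = clip_id, grid = grid,
                 session_tag = "change"),
            class = c("change_stack", "isc_stack"))
}

# random non-symmetric stack (influence-like)
rand_ordered_stack <- function(n_subjects, n_voxels, seed = 1, clip_id = 1) {
  set.seed(seed)
  values <- array(rnorm(n_voxels * n_subjects^2),
                  dim = c(n_voxels, n_subjects, n_subjects))
  for (s in seq_len(n_subjects)) values[, s, s] <- NA_real_
  structure(list(values = values,
                 subject_ids = paste0("s", seq_len(n_subjects)),
                 group_labels = NULL, clip_id = clip_id, grid = NULL,
                 session_tag = "influence"),
            class = c("influence_stack", "isc_stack"))
}

# literal Burt constraint: c_i = sum_j (p_ij + sum_q p_iq p_qj)^2 with
# proportional strengths p_ab = (z_ab + z_ba) / sum_q (z_aq + z_qa)
burt_oracle <- function(adj) {
  n <- nrow(adj)
  z <- adj
  p <- function(a, b) {
    tot <- sum(z[a, ] + z[, a])
    if (tot == 0) return(NA_real_)
    (z[a, b] + z[b, a]) / tot
  }
  vapply(seq_len(n), function(i) {
    contacts <- which((z[i, ] + z[, i]) > 0)
    if (!length(contacts)) return(NA_real_)
    sum(vapply(contacts, function(j) {
      ind <- 0
      for (q in setdiff(contacts, j)) ind <- ind + p(i, q) * p(q, j)
      (p(i, j) + ind)^2
    }, numeric(1)))
  }, numeric(1))
}

# gini by the literal double sum
gini_oracle <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# normal-equation OLS oracle
ols_oracle <- function(X, y) as.numeric(solve(t(X) %*% X) %*% t(X) %*% y)
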
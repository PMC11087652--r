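#' Post-minus-pre ISC change stack
#'
#' Subtracts the before-conversation ISC matrix from the after-conversation
#' ISC matrix, voxel by voxel and pair by pair. Entries undefined in either
#' input are undefined in the result.
#'
#' @param pre,post `isc_stack` objects with matching subjects, voxels, clip.
#' @return object of class `change_stack` (same layout as an `isc_stack`,
#'   `session_tag = "change"`).
#' @export
change_stack <- function(pre, post) {
  stopifnot(inherits(pre, "isc_stack"), inherits(post, "isc_stack"))
  if (!identical(pre$subject_ids, post$subject_ids))
    stop("subject ids differ between pre and post")
  if (!identical(dim(pre$values), dim(post$values)))
    stop("voxel dimensions differ between pre and post")
  if (!identical(pre$clip_id, post$clip_id))
    stop("clip ids differ between pre and post")
  structure(list(values = post$values - pre$values,
                 subject_ids = pre$subject_ids,
                 group_labels = pre$group_labels,
                 clip_id = pre$clip_id, grid = pre$grid,
                 session_tag = "change"),
            class = c("change_stack", "isc_stack"))
}

#' Pairwise predictor design over unordered participant pairs
#'
#' Builds the vectorized design used by the change regression. Rows are all
#' unordered subject pairs (strict lower triangle of the pair matrix),
#' repeated for each clip and stacked. Columns are an all-1s intercept —
#' capturing change that occurs whether or not participants conversed, e.g.
#' from watching the clips twice — plus either one indicator column per
#' conversation group (`mode = "per_group"`: 1 iff both pair members are in
#' that group) or a single same-group column (`mode = "all_groups"`).
#' Control-group pairs and between-group pairs are always included as rows;
#' the reserved `control` label never forms a predictor column.
#'
#' @param group_labels label per subject; `control_label` marks
#'   non-conversing subjects.
#' @param mode `"per_group"` or `"all_groups"`.
#' @param clips vector of clip ids to stack (default 1).
#' @param subject_ids optional ids (default `s1, s2, ...`).
#' @param control_label reserved non-group label.
#' @return object of class `pairwise_design`: list with `X` (rows x
#'   predictors), `pair_index` (data.frame `clip`, `i`, `j` with `i > j`,
#'   subject indices), `subject_ids`, `group_labels`, `mode`.
#' @export
#' @examples
#' d <- build_design(c("g1", "g1", "g2", "g2", "control"))
#' dim(d$X)       # 10 pairs x 3 columns
#' colnames(d$X)
build_design <- function(group_labels, mode = c("per_group", "all_groups"),
                         clips = 1, subject_ids = NULL,
                         control_label = "control") {
  mode <- match.arg(mode)
  N <- length(group_labels)
  subject_ids <- subject_ids %||% paste0("s", seq_len(N))
  groups <- setdiff(unique(group_labels), control_label)
  sizes <- table(factor(group_labels[group_labels != control_label],
                        levels = groups))
  small <- names(sizes)[sizes < 2]
  if (length(small))
    stop("group(s) with fewer than 2 members would give an all-zero ",
         "predictor column: ", paste(small, collapse = ", "))
  prs <- t(combn(seq_len(N), 2))          # i < j
  pair1 <- data.frame(i = prs[, 2], j = prs[, 1])  # store i > j (lower tri)
  same <- group_labels[pair1$i] == group_labels[pair1$j] &
    group_labels[pair1$i] != control_label
  if (mode == "per_group") {
    cols <- sapply(groups, function(g)
      as.numeric(same & group_labels[pair1$i] == g))
    X1 <- cbind(intercept = 1, cols)
    colnames(X1) <- c("intercept", paste0("group:", groups))
  } else {
    X1 <- cbind(intercept = 1, any_group = as.numeric(same))
  }
  n_clip <- length(clips)
  X <- X1[rep(seq_len(nrow(X1)), n_clip), , drop = FALSE]
  pair_index <- data.frame(clip = rep(clips, each = nrow(pair1)),
                           i = rep(pair1$i, n_clip),
                           j = rep(pair1$j, n_clip))
  structure(list(X = X, pair_index = pair_index,
                 subject_ids = subject_ids, group_labels = group_labels,
                 mode = mode, control_label = control_label,
                 n_subjects = N, clips = clips, ordered = FALSE),
            class = "pairwise_design")
}

#' @export
print.pairwise_design <- function(x, ...) {
  cat("pairwise_design (", if (x$ordered) "ordered" else "unordered",
      "pairs ):", nrow(x$X), "rows x", ncol(x$X), "predictors [",
      paste(colnames(x$X), collapse = ", "), "]\n")
  invisible(x)
}

# stack one or more isc/change stacks into a full-cell matrix list keyed by
# clip: each element is an (N*N) x V matrix with cell id i + (j-1)*N
full_cell_matrices <- function(stacks) {
  if (inherits(stacks, "isc_stack")) stacks <- list(stacks)
  lapply(stacks, function(s) {
    V <- dim(s$values)[1]; N <- dim(s$values)[2]
    t(matrix(s$values, V, N * N))
  })
}

# extract the target matrix (rows of design) from stacks; rows follow
# design$pair_index. Returns n_rows x V matrix.
vectorize_target <- function(stacks, design) {
  if (inherits(stacks, "isc_stack")) stacks <- list(stacks)
  clip_ids <- vapply(stacks, function(s) s$clip_id[[1]], clips_type(design))
  N <- design$n_subjects
  full <- full_cell_matrices(stacks)
  names(full) <- as.character(clip_ids)
  rows <- lapply(split(design$pair_index, design$pair_index$clip),
                 function(px) {
    m <- full[[as.character(px$clip[1])]]
    if (is.null(m)) stop("no target stack for clip ", px$clip[1])
    m[px$i + (px$j - 1) * N, , drop = FALSE]
  })
  # split() orders by factor level; restore design row order
  ord <- order(design$pair_index$clip)
  Y <- do.call(rbind, rows)
  Y[order(ord), , drop = FALSE]
}

clips_type <- function(design) {
  if (is.character(design$pair_index$clip)) character(1) else numeric(1)
}

check_design_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  invisible(qx)
}

ols_betas <- function(X, Y) {
  # per-voxel OLS, NA target rows dropped per voxel
  check_design_rank(X)
  B <- matrix(NA_real_, ncol(X), ncol(Y))
  bad <- colSums(is.na(Y)) > 0
  if (any(!bad)) {
    XtXi <- solve(crossprod(X))
    B[, !bad] <- XtXi %*% crossprod(X, Y[, !bad, drop = FALSE])
  }
  for (v in which(bad)) {
    ok <- !is.na(Y[, v])
    if (sum(ok) >= ncol(X) && qr(X[ok, , drop = FALSE])$rank == ncol(X))
      B[, v] <- qr.coef(qr(X[ok, , drop = FALSE]), Y[ok, v])
  }
  B
}

#' Voxel-wise multiple regression of pair matrices on a pairwise design
#'
#' Unravels the target stack(s) over the design's pair rows (concatenated
#' across clips) and fits, per voxel, ordinary least squares of the target
#' on the design columns. Target rows undefined at a voxel are dropped for
#' that voxel only.
#'
#' @param target a `change_stack` / `isc_stack` or a list of them (one per
#'   clip in the design).
#' @param design a [build_design()] result.
#' @param model_tag label stored in the result (`"change"` or
#'   `"novel_post"`).
#' @return object of class `regression_maps`: `betas` (voxels x
#'   predictors), `predictors`, `grid`, `model_tag`, plus the design.
#' @export
fit_pairwise_regression <- function(target, design, model_tag = "change") {
  stopifnot(inherits(design, "pairwise_design"))
  Y <- vectorize_target(target, design)
  if (nrow(Y) != nrow(design$X)) stop("target rows do not match design rows")
  B <- ols_betas(design$X, Y)
  rownames(B) <- colnames(design$X)
  grid <- if (inherits(target, "isc_stack")) target$grid else target[[1]]$grid
  structure(list(betas = t(B), predictors = colnames(design$X),
                 grid = grid, model_tag = model_tag, design = design),
            class = "regression_maps")
}

#' Novel-clip regression: after-conversation ISC as the target
#'
#' Tests whether conversation-related alignment extends to stimuli that were
#' never discussed: the same group-membership predictors are used, but the
#' target is the after-conversation ISC matrix of a novel clip rather than a
#' change matrix.
#'
#' @inheritParams fit_pairwise_regression
#' @param post an `isc_stack` (or list) from the post-conversation session.
#' @return a `regression_maps` with `model_tag = "novel_post"`.
#' @export
novel_clip_regression <- function(post, design) {
  fit_pairwise_regression(post, design, model_tag = "novel_post")
}

#' @export
print.regression_maps <- function(x, ...) {
  cat("regression_maps (", x$model_tag, "):", nrow(x$betas), "voxels x",
      length(x$predictors), "predictors\n")
  invisible(x)
}

#' Subject-wise permutation inference for pairwise regressions
#'
#' Builds the permutation null that respects the pairs-and-groups structure
#' of the data: for each draw, one relabeling of subjects is sampled and the
#' rows and columns of every clip's target matrix are permuted identically
#' (the same relabeling across all concatenated clips), the design is held
#' fixed, and the regression is refit. Two-tailed p-values per predictor per
#' voxel are `(1 + #{|b_perm| >= |b_obs|}) / (1 + n_perm)` by default
#' (add-one smoothing avoids p = 0 at finite n_perm); the raw proportion is
#' available with `smoothing = "raw"`.
#'
#' With `exhaustive = TRUE` all `N!` relabelings (identity included) are
#' enumerated instead of sampled and the raw-proportion rule is used, which
#' is then exact; feasible for N <= 8.
#'
#' @param target stack or list of stacks (matrix form, so rows/columns can
#'   be shuffled jointly); for ordered-pair designs pass influence stacks.
#' @param design a [build_design()] or [centrality_design()] result.
#' @param n_perm number of permutations (>= 1); the study default is 2000.
#' @param seed integer seed for the permutation draws.
#' @param smoothing `"add_one"` or `"raw"`.
#' @param exhaustive enumerate all relabelings instead of sampling.
#' @param keep_null keep the full null beta array
#'   (`voxels x predictors x n_perm`), needed by the permutation
#'   max-cluster-extent null in [cluster_correct()].
#' @return object of class `permutation_result`: `p` (voxels x predictors),
#'   `betas` (observed), `n_perm`, `seed`, and optionally `null_betas`.
#' @export
subjectwise_permutation <- function(target, design, n_perm = 2000,
                                    seed = 1L,
                                    smoothing = c("add_one", "raw"),
                                    exhaustive = FALSE,
                                    keep_null = FALSE) {
  stopifnot(inherits(design, "pairwise_design"))
  smoothing <- match.arg(smoothing)
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1")
  if (inherits(target, "isc_stack")) target <- list(target)
  N <- design$n_subjects
  full <- full_cell_matrices(target)
  clip_ids <- vapply(target, function(s) s$clip_id[[1]], clips_type(design))
  names(full) <- as.character(clip_ids)
  px_by_clip <- split(design$pair_index, design$pair_index$clip)
  ord <- order(order(design$pair_index$clip))  # map stacked rows -> design rows

  X <- design$X
  check_design_rank(X)
  PH <- solve(crossprod(X)) %*% t(X)      # predictors x rows

  row_idx <- function(sigma) {
    lapply(px_by_clip, function(px)
      sigma[px$i] + (sigma[px$j] - 1) * N)
  }
  gather <- function(idx_list) {
    Y <- do.call(rbind, Map(function(px, idx) {
      full[[as.character(px$clip[1])]][idx, , drop = FALSE]
    }, px_by_clip, idx_list))
    Y[ord, , drop = FALSE]
  }

  Y_obs <- gather(row_idx(seq_len(N)))
  has_na <- anyNA(Y_obs)
  B_obs <- if (has_na) ols_betas(X, Y_obs) else PH %*% Y_obs

  if (exhaustive) {
    # all N! relabelings, identity included (it guarantees p > 0), with the
    # raw-proportion rule: the null is then exact, no smoothing needed
    perms <- all_permutations(N)
    n_perm <- nrow(perms)
    smoothing <- "raw"
  } else {
    set.seed(seed)
    perms <- t(replicate(n_perm, sample.int(N)))
  }

  P_cnt <- matrix(0, nrow(B_obs), ncol(B_obs))
  na_mask <- is.na(B_obs)
  null_betas <- if (keep_null)
    array(NA_real_, dim = c(ncol(B_obs), nrow(B_obs), n_perm)) else NULL
  for (r in seq_len(n_perm)) {
    Yp <- gather(row_idx(perms[r, ]))
    Bp <- if (anyNA(Yp)) ols_betas(X, Yp) else PH %*% Yp
    # count mathematical ties (relabelings that reproduce the observed
    # statistic exactly) as exceedances despite float summation noise
    P_cnt <- P_cnt + (abs(Bp) - abs(B_obs) >= -1e-10 & !is.na(Bp) & !na_mask)
    if (keep_null) null_betas[, , r] <- t(Bp)
  }
  p <- if (smoothing == "add_one") (1 + P_cnt) / (1 + n_perm)
       else P_cnt / n_perm
  p[na_mask] <- NA_real_
  rownames(p) <- rownames(B_obs) <- colnames(X)
  grid <- target[[1]]$grid
  structure(list(p = t(p), betas = t(B_obs),
                 predictors = colnames(X), n_perm = n_perm, seed = seed,
                 smoothing = smoothing, grid = grid,
                 null_betas = null_betas),
            class = "permutation_result")
}

all_permutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation_result:", nrow(x$p), "voxels x", ncol(x$p),
      "predictors,", x$n_perm, "permutations (seed", x$seed, ")\n")
  invisible(x)
}

# 3-D connected-component labeling by flood fill.
# connectivity: 6 (faces), 18 (+edges), 26 (+corners)
label_components <- function(mask, grid, connectivity = 6) {
  stopifnot(length(mask) == prod(grid))
  offs <- neighbor_offsets(connectivity)
  arr <- array(mask, dim = grid)
  lab <- array(0L, dim = grid)
  cur <- 0L
  idx_all <- which(arr)
  coords <- arrayInd(idx_all, grid)
  rownames(coords) <- as.character(idx_all)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      cv <- arrayInd(v, grid)
      for (r in seq_len(nrow(offs))) {
        nb <- cv + offs[r, ]
        if (any(nb < 1) || any(nb > grid)) next
        ni <- nb[1] + (nb[2] - 1L) * grid[1] + (nb[3] - 1L) * grid[1] * grid[2]
        if (arr[ni] && lab[ni] == 0L) {
          lab[ni] <- cur
          queue <- c(queue, ni)
        }
      }
    }
  }
  as.integer(lab)
}

neighbor_offsets <- function(connectivity = 6) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  d <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d <= 2, "26" = d <= 3,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Cluster-extent correction of voxel-wise permutation maps
#'
#' Thresholds each predictor's p-map at the cluster-forming threshold,
#' separately for positive and negative betas, labels connected components
#' on the 3-D voxel grid, and retains clusters that meet the extent
#' criterion. The default criterion is a fixed minimum size (the study rule:
#' cluster-forming p = 0.01, minimum 32 voxels, giving p < 0.05 corrected);
#' alternatively, if the permutation result was computed with
#' `keep_null = TRUE`, `null = "max_cluster"` retains clusters larger than
#' the 95th percentile of maximum cluster sizes under the subject-wise
#' permutation null.
#'
#' @param maps a `regression_maps` (for betas) — or the `permutation_result`
#'   itself, whose observed betas are then used.
#' @param perm a `permutation_result` aligned with `maps`.
#' @param cluster_forming_p voxel-level two-tailed threshold.
#' @param min_size minimum cluster extent in voxels.
#' @param connectivity 6 (face), 18, or 26 neighborhood.
#' @param null `"fixed"` (default) or `"max_cluster"`.
#' @param n_boot bootstrap resamples for the cluster-mean beta 95% CI.
#' @param seed seed for the bootstrap.
#' @return data.frame, one row per surviving cluster: `predictor`, `sign`,
#'   `n_voxels`, `mean_beta`, `peak_beta`, `ci_lo`, `ci_hi`, and a
#'   list-column `voxels` of member voxel indices.
#' @export
cluster_correct <- function(maps, perm = NULL, cluster_forming_p = 0.01,
                            min_size = 32, connectivity = 6,
                            null = c("fixed", "max_cluster"),
                            n_boot = 500, seed = 1L) {
  null <- match.arg(null)
  if (inherits(maps, "permutation_result") && is.null(perm)) perm <- maps
  betas <- maps$betas
  grid <- maps$grid
  if (is.null(grid)) stop("cluster correction needs 3-D grid geometry")
  if (is.null(perm)) stop("a permutation_result is required")
  p <- perm$p
  preds <- colnames(betas) %||% perm$predictors
  colnames(betas) <- colnames(p) <- preds
  size_crit <- min_size
  rows <- list()
  set.seed(seed)
  for (pr in preds) {
    if (null == "max_cluster") {
      if (is.null(perm$null_betas))
        stop("max_cluster null needs subjectwise_permutation(keep_null = TRUE)")
      size_crit <- max_cluster_criterion(perm, pr, cluster_forming_p,
                                         connectivity, grid)
    }
    for (sgn in c(1, -1)) {
      mask <- !is.na(p[, pr]) & p[, pr] < cluster_forming_p &
        sign(betas[, pr]) == sgn
      if (!any(mask)) next
      lab <- label_components(mask, grid, connectivity)
      for (cl in setdiff(unique(lab), 0L)) {
        vox <- which(lab == cl)
        if (length(vox) < size_crit) next
        b <- betas[vox, pr]
        boot <- replicate(n_boot,
                          mean(b[sample.int(length(b), replace = TRUE)]))
        rows[[length(rows) + 1]] <- data.frame(
          predictor = pr, sign = if (sgn > 0) "positive" else "negative",
          n_voxels = length(vox), mean_beta = mean(b),
          peak_beta = b[which.max(abs(b))],
          ci_lo = unname(quantile(boot, 0.025)),
          ci_hi = unname(quantile(boot, 0.975)))
        rows[[length(rows)]]$voxels <- I(list(vox))
      }
    }
  }
  if (!length(rows))
    return(data.frame(predictor = character(), sign = character(),
                      n_voxels = integer(), mean_beta = numeric(),
                      peak_beta = numeric(), ci_lo = numeric(),
                      ci_hi = numeric()))
  do.call(rbind, rows)
}

# 95th percentile of the max suprathreshold cluster size across permutations
# for one predictor; suprathreshold = |null beta| above the voxel's own
# two-sided (1 - p) null quantile.
max_cluster_criterion <- function(perm, predictor, cluster_forming_p,
                                  connectivity, grid) {
  k <- match(predictor, perm$predictors)
  nb <- perm$null_betas[k, , , drop = TRUE]   # voxels x n_perm
  thr <- apply(abs(nb), 1, quantile, probs = 1 - cluster_forming_p,
               na.rm = TRUE)
  maxes <- vapply(seq_len(dim(nb)[2]), function(r) {
    mask <- !is.na(nb[, r]) & abs(nb[, r]) >= thr
    if (!any(mask)) return(0L)
    lab <- label_components(mask, grid, connectivity)
    max(tabulate(lab))
  }, integer(1))
  max(quantile(maxes, 0.95), 1)
}

#' Whole-brain alignment per participant pair
#'
#' The sum over voxels of unthresholded positive change in ISC, one value
#' per unordered pair (per clip). A coarse but sensitive summary used to
#' relate neural alignment to behavioral convergence.
#'
#' @param change a `change_stack` or list of them.
#' @return data.frame `clip`, `i`, `j` (subject indices, `i > j`),
#'   `subject_i`, `subject_j`, `value`.
#' @export
whole_brain_alignment <- function(change) {
  if (inherits(change, "isc_stack")) change <- list(change)
  do.call(rbind, lapply(change, function(s) {
    N <- dim(s$values)[2]
    prs <- t(combn(seq_len(N), 2))
    val <- vapply(seq_len(nrow(prs)), function(r) {
      x <- s$values[, prs[r, 2], prs[r, 1]]
      sum(pmax(x, 0), na.rm = TRUE)
    }, numeric(1))
    data.frame(clip = s$clip_id, i = prs[, 2], j = prs[, 1],
               subject_i = s$subject_ids[prs[, 2]],
               subject_j = s$subject_ids[prs[, 1]], value = val)
  }))
}
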
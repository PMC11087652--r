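#' Directed ego-to-alter neural influence stack
#'
#' For every ordered pair (ego e, alter a) and voxel, computes
#' `ISC(e_pre, a_post) - ISC(e_pre, a_pre)`: the final-position matrix (ego
#' before conversation vs alter after) minus the initial-position matrix
#' (both before). Positive values mean the alter's activity moved toward the
#' ego's initial time series. Unlike the change analysis, both triangles are
#' used — each pair is tested with each member in the ego and in the alter
#' role — so the stack is not symmetric; the diagonal is undefined.
#'
#' @param pre,post [bold_session()] objects for the same clip and subjects.
#' @return object of class `influence_stack`: `values`
#'   (`voxels x N x N`, entry `[v, e, a]`), `subject_ids`, `group_labels`,
#'   `clip_id`, `grid`.
#' @export
influence_stack <- function(pre, post) {
  stopifnot(inherits(pre, "bold_session"), inherits(post, "bold_session"))
  if (!identical(pre$subject_ids, post$subject_ids))
    stop("subject ids differ between pre and post")
  final <- cross_isc_matrix(pre, post)     # [v, e, a] = cor(e_pre, a_post)
  initial <- isc_matrix(pre)$values        # symmetric
  values <- final - initial
  N <- dim(values)[2]
  for (s in seq_len(N)) values[, s, s] <- NA_real_
  structure(list(values = values, subject_ids = pre$subject_ids,
                 group_labels = pre$group_labels, clip_id = pre$clip_id,
                 grid = pre$grid, session_tag = "influence"),
            class = c("influence_stack", "isc_stack"))
}

#' Centrality-valued design over ordered same-group pairs
#'
#' Builds the design for regressing neural influence on social-network
#' centrality. Rows are ordered (ego, alter) pairs — both triangles,
#' diagonal excluded, in ego-major / alter-minor order — restricted to pairs
#' sharing a conversation group, repeated per clip and stacked. Columns are
#' an intercept plus, for every centrality metric supplied, an ego column
#' (value = centrality of the ego) and an alter column (centrality of the
#' alter). Centrality values are z-scored over the subjects entering the
#' design (the study-participant subsample, not the full cohort network)
#' unless `z_score = FALSE`.
#'
#' @param group_labels label per subject (`control_label` excluded).
#' @param centrality named numeric vector, or data.frame/matrix with one
#'   column per metric and rownames (or a `node` column) identifying
#'   subjects.
#' @param clips clip ids to stack.
#' @param subject_ids subject ids matching `group_labels`.
#' @param control_label reserved non-group label.
#' @param z_score z-score metrics over included subjects.
#' @return a `pairwise_design` with `ordered = TRUE`.
#' @export
centrality_design <- function(group_labels, centrality, clips = 1,
                              subject_ids = NULL,
                              control_label = "control", z_score = TRUE) {
  N <- length(group_labels)
  subject_ids <- subject_ids %||% paste0("s", seq_len(N))
  if (is.vector(centrality) && is.numeric(centrality))
    centrality <- data.frame(centrality = centrality,
                             row.names = names(centrality) %||% subject_ids)
  if (!is.null(centrality$node)) {
    rownames(centrality) <- centrality$node
    centrality$node <- NULL
  }
  cent <- as.matrix(centrality[subject_ids, , drop = FALSE])
  if (anyNA(cent))
    stop("missing centrality for subject(s): ",
         paste(subject_ids[apply(is.na(cent), 1, any)], collapse = ", "))
  cells <- expand.grid(alter = seq_len(N), ego = seq_len(N))  # ego-major
  cells <- cells[order(cells$ego, cells$alter), ]
  cells <- cells[cells$ego != cells$alter, ]
  same <- group_labels[cells$ego] == group_labels[cells$alter] &
    group_labels[cells$ego] != control_label
  cells <- cells[same, ]
  if (!nrow(cells)) stop("no ordered same-group pairs")
  incl <- sort(unique(c(cells$ego, cells$alter)))
  if (z_score) {
    mu <- colMeans(cent[incl, , drop = FALSE])
    sdv <- apply(cent[incl, , drop = FALSE], 2, sd)
    if (any(sdv == 0))
      stop("constant centrality metric(s): ",
           paste(colnames(cent)[sdv == 0], collapse = ", "))
    cent <- sweep(sweep(cent, 2, mu), 2, sdv, "/")
  }
  X1 <- matrix(1, nrow(cells), 1, dimnames = list(NULL, "intercept"))
  for (m in colnames(cent)) {
    X1 <- cbind(X1, cent[cells$ego, m], cent[cells$alter, m])
    colnames(X1)[ncol(X1) - 1:0] <- paste0(c("ego:", "alter:"), m)
  }
  n_clip <- length(clips)
  X <- X1[rep(seq_len(nrow(X1)), n_clip), , drop = FALSE]
  pair_index <- data.frame(clip = rep(clips, each = nrow(cells)),
                           i = rep(cells$ego, n_clip),
                           j = rep(cells$alter, n_clip))
  structure(list(X = X, pair_index = pair_index,
                 subject_ids = subject_ids, group_labels = group_labels,
                 mode = "centrality", control_label = control_label,
                 n_subjects = N, clips = clips, ordered = TRUE,
                 centrality = cent),
            class = "pairwise_design")
}

#' Regress neural influence on ego and alter centrality
#'
#' Per-voxel OLS of the vectorized influence stack on a
#' [centrality_design()]. Supply one metric (e.g. PCA centrality) for the
#' composite model, or both eigenvector centrality and brokerage together to
#' estimate their unique effects in a single model, as OLS betas reflect
#' only the variance unique to each predictor.
#'
#' @param influence an `influence_stack` or list of them (one per clip).
#' @param design a [centrality_design()].
#' @return a `regression_maps` with `model_tag = "influence"`.
#' @export
fit_influence_regression <- function(influence, design) {
  stopifnot(inherits(design, "pairwise_design"), isTRUE(design$ordered))
  fit_pairwise_regression(influence, design, model_tag = "influence")
}

#' Whole-brain neural influence per ordered pair
#'
#' The sum over voxels of positive values in the unthresholded influence
#' maps, one value per ordered (ego, alter) pair per clip.
#'
#' @param influence an `influence_stack` or list of them.
#' @return data.frame `clip`, `ego`, `alter` (indices), `ego_id`,
#'   `alter_id`, `value`.
#' @export
whole_brain_influence <- function(influence) {
  if (inherits(influence, "isc_stack")) influence <- list(influence)
  do.call(rbind, lapply(influence, function(s) {
    N <- dim(s$values)[2]
    cells <- expand.grid(alter = seq_len(N), ego = seq_len(N))
    cells <- cells[order(cells$ego, cells$alter), ]
    cells <- cells[cells$ego != cells$alter, ]
    val <- vapply(seq_len(nrow(cells)), function(r) {
      x <- s$values[, cells$ego[r], cells$alter[r]]
      sum(pmax(x, 0), na.rm = TRUE)
    }, numeric(1))
    data.frame(clip = s$clip_id, ego = cells$ego, alter = cells$alter,
               ego_id = s$subject_ids[cells$ego],
               alter_id = s$subject_ids[cells$alter], value = val,
               row.names = NULL)
  }))
}
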
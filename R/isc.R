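#' BOLD session container
#'
#' Holds one session's (pre- or post-conversation) voxel time series for all
#' subjects watching one clip, as a `subjects x voxels x timepoints` array,
#' together with subject ids, group labels, and the 3-D voxel grid geometry
#' needed later for cluster-extent correction.
#'
#' @param data numeric array `subjects x voxels x timepoints`.
#' @param subject_ids unique subject identifiers, one per row.
#' @param group_labels conversation-group label per subject; the reserved
#'   label `"control"` marks subjects who did not converse.
#' @param clip_id clip identifier.
#' @param grid 3-D grid dims with `prod(grid) == n_voxels`; may be `NULL`
#'   for purely non-spatial use.
#' @param tr_seconds repetition time (metadata only).
#' @return object of class `bold_session`.
#' @export
bold_session <- function(data, subject_ids, group_labels = NULL,
                         clip_id = 1, grid = NULL, tr_seconds = NA_real_) {
  if (length(dim(data)) != 3) stop("data must be subjects x voxels x time")
  if (dim(data)[3] < 2) stop("need at least 2 timepoints")
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  if (length(subject_ids) != dim(data)[1])
    stop("subject_ids length must match dim(data)[1]")
  if (!is.null(group_labels) && length(group_labels) != length(subject_ids))
    stop("group_labels length must match subject_ids")
  if (!is.null(grid) && prod(grid) != dim(data)[2])
    stop("prod(grid) must equal the number of voxels")
  structure(list(data = data, subject_ids = as.character(subject_ids),
                 group_labels = group_labels, clip_id = clip_id,
                 grid = if (is.null(grid)) NULL else as.integer(grid),
                 tr_seconds = tr_seconds),
            class = "bold_session")
}

#' @export
print.bold_session <- function(x, ...) {
  d <- dim(x$data)
  cat("bold_session clip", x$clip_id, ":", d[1], "subjects x", d[2],
      "voxels x", d[3], "TRs\n")
  invisible(x)
}

#' Pairwise inter-subject correlation of two time series
#'
#' ISC is the Pearson correlation of two subjects' time series at the same
#' voxel. A zero-variance series makes the correlation undefined; the
#' undefined-marker is `NA` (never 0, never an error), and such voxels are
#' excluded from downstream regressions and summaries.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return Pearson r, or `NA_real_` if either series has zero variance.
#' @export
#' @examples
#' pairwise_isc(c(1, 2, 3, 4), c(2, 4, 6, 8))   # 1
#' pairwise_isc(c(1, 0, 0, 0), c(0, 1, 0, 0))   # -1/3
pairwise_isc <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length")
  if (length(a) < 2) stop("series must have length >= 2")
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Voxel-wise ISC matrix stack for one session
#'
#' For every voxel, computes the N x N matrix of pairwise Pearson
#' correlations between subjects' time series. The result is symmetric with
#' unit diagonal; rows/columns of subjects whose series has zero variance at
#' a voxel are `NA` at that voxel.
#'
#' @param session a [bold_session()] with >= 2 subjects.
#' @param fisher_z apply the Fisher z-transform `atanh(r)` to off-diagonal
#'   values. Off by default: downstream change scores subtract raw ISC
#'   values, so r is kept on its native scale; the transform exists for
#'   sensitivity analyses only.
#' @return object of class `isc_stack`: list with `values`
#'   (`voxels x N x N`), `subject_ids`, `group_labels`, `clip_id`, `grid`,
#'   `session_tag`.
#' @param session_tag `"pre"`, `"post"`, or other label.
#' @export
isc_matrix <- function(session, session_tag = "pre", fisher_z = FALSE) {
  stopifnot(inherits(session, "bold_session"))
  N <- dim(session$data)[1]
  if (N < 2) stop("ISC needs at least 2 subjects")
  V <- dim(session$data)[2]
  values <- array(NA_real_, dim = c(V, N, N))
  for (v in seq_len(V)) {
    X <- t(session$data[, v, ])            # time x subjects
    sds <- apply(X, 2, sd)
    ok <- sds > 0
    C <- matrix(NA_real_, N, N)
    if (sum(ok) >= 2) C[ok, ok] <- cor(X[, ok, drop = FALSE])
    diag(C)[!ok] <- NA_real_
    if (fisher_z) {
      off <- row(C) != col(C)
      C[off] <- atanh(pmin(pmax(C[off], -1 + 1e-12), 1 - 1e-12))
    }
    values[v, , ] <- C
  }
  structure(list(values = values, subject_ids = session$subject_ids,
                 group_labels = session$group_labels,
                 clip_id = session$clip_id, grid = session$grid,
                 session_tag = session_tag),
            class = "isc_stack")
}

# cross-session correlation stack: values[v, i, j] = cor(pre_i, post_j);
# NOT symmetric. Used by influence_stack().
cross_isc_matrix <- function(pre, post) {
  stopifnot(inherits(pre, "bold_session"), inherits(post, "bold_session"))
  if (!identical(pre$subject_ids, post$subject_ids))
    stop("pre/post subject ids differ")
  N <- dim(pre$data)[1]; V <- dim(pre$data)[2]
  values <- array(NA_real_, dim = c(V, N, N))
  for (v in seq_len(V)) {
    X <- t(pre$data[, v, ]); Y <- t(post$data[, v, ])
    okx <- apply(X, 2, sd) > 0; oky <- apply(Y, 2, sd) > 0
    C <- matrix(NA_real_, N, N)
    if (any(okx) && any(oky))
      C[okx, oky] <- cor(X[, okx, drop = FALSE], Y[, oky, drop = FALSE])
    values[v, , ] <- C
  }
  values
}

#' @export
print.isc_stack <- function(x, ...) {
  d <- dim(x$values)
  cat("isc_stack (", x$session_tag, ") clip", x$clip_id, ":", d[1],
      "voxels x", d[2], "x", d[3], "subjects\n")
  invisible(x)
}

#' Rolling-window group ISC time series
#'
#' Computes, for each window position, the mean pairwise ISC over a set of
#' subject pairs (and optionally a subset of voxels, e.g. a significant
#' cluster), mapped to the TR at the window's center. The window advances by
#' `step` TRs; with step 1 there are `T - window + 1` output points. The
#' center of a window starting at 1-based TR `t0` is `t0 + window %/% 2`
#' in 0-based offset terms, i.e. `t0 + window %/% 2` (for even windows this
#' is the convention `window %/% 2` within the window).
#'
#' @param session a [bold_session()].
#' @param pairs 2-column matrix of subject indices or ids (one pair per
#'   row); default all unordered pairs.
#' @param voxels voxel indices to average over (default all).
#' @param window window length in TRs (>= 3).
#' @param step step size in TRs.
#' @return data.frame with `center_tr` and `isc` (mean over pairs and
#'   voxels; windows where all correlations are undefined give `NA`).
#' @export
windowed_group_isc <- function(session, pairs = NULL, voxels = NULL,
                               window = 10, step = 1) {
  stopifnot(inherits(session, "bold_session"))
  if (window < 3) stop("window must be >= 3 (correlation degenerate)")
  T_ <- dim(session$data)[3]
  if (T_ < window) stop("timepoints must be >= window")
  N <- dim(session$data)[1]
  if (is.null(pairs)) pairs <- t(combn(seq_len(N), 2))
  if (is.character(pairs[1])) {
    pairs <- cbind(match(pairs[, 1], session$subject_ids),
                   match(pairs[, 2], session$subject_ids))
  }
  voxels <- voxels %||% seq_len(dim(session$data)[2])
  starts <- seq(1, T_ - window + 1, by = step)
  out <- vapply(starts, function(t0) {
    idx <- t0:(t0 + window - 1)
    vals <- vapply(seq_len(nrow(pairs)), function(p) {
      mean(vapply(voxels, function(v) {
        a <- session$data[pairs[p, 1], v, idx]
        b <- session$data[pairs[p, 2], v, idx]
        if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  data.frame(center_tr = starts + window %/% 2, isc = out)
}
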
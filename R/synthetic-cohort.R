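#' Simulation configuration for a synthetic conversation cohort
#'
#' Defines the generative model used by [generate_bold()] and
#' [generate_cohort()]. Each subject's voxel time series is a variance-
#' partitioned mixture of independent unit-variance signals,
#' \deqn{x_{s,v,t} = \sqrt{a}\, g_{v,t}
#'       + \sqrt{b_{grp(s),ses}}\, h_{grp(s),v,t}
#'       + \sqrt{1 - a - b}\, \epsilon_{s,v,t},}
#' where `g` is a cohort-wide stimulus signal shared by everyone watching the
#' clip, `h` is a group-specific signal carried only by voxels in a
#' contiguous "affected" block, and `eps` is subject noise. The closed-form
#' expected ISC is `a + b` within a group at affected voxels and `a`
#' elsewhere, which is what makes parameter-recovery tests exact.
#'
#' @param n_subjects total number of subjects including controls.
#' @param n_groups number of conversation groups.
#' @param group_sizes integer vector of conversing-group sizes; defaults to an
#'   even split of the non-control subjects. Must sum to
#'   `n_subjects - n_controls`.
#' @param n_controls number of control subjects (label `"control"`); they
#'   watch the clips twice but carry no group signal.
#' @param grid 3-D voxel grid dimensions `c(nx, ny, nz)`; the number of
#'   voxels is `prod(grid)`. Voxels are flattened in R's native column-major
#'   array order.
#' @param n_timepoints time points (TRs) per clip.
#' @param n_clips number of movie clips.
#' @param a_shared cohort-wide signal variance fraction in `[0, 1)`.
#' @param b_group_pre,b_group_post group-signal variance fraction before and
#'   after the conversation.
#' @param affected_fraction fraction of voxels carrying the group signal; the
#'   affected voxels form a contiguous block (near-cube at the grid origin)
#'   so cluster-level operations have spatial structure to find.
#' @param influence_weight default ego-to-alter imitation weight `w` in
#'   `[0, 1]` (see [inject_influence()]); 0 means no injected influence.
#' @param ar1 optional AR(1) coefficient applied to every latent signal
#'   (marginal variance kept at 1). Real BOLD is temporally autocorrelated;
#'   the default 0 keeps the closed forms above exact.
#' @param n_items survey items per clip (7-point Likert scale).
#' @param scale_max top of the Likert scale.
#' @param tr_seconds repetition time, metadata only.
#' @param seed integer seed; all generators are pure functions of
#'   `(config, seed)`.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 10, n_groups = 2, n_controls = 2,
#'                   grid = c(4, 4, 2), n_timepoints = 50)
#' cfg$group_sizes
sim_config <- function(n_subjects = 20, n_groups = 4, group_sizes = NULL,
                       n_controls = 0, grid = c(8, 8, 8),
                       n_timepoints = 200, n_clips = 1,
                       a_shared = 0.1, b_group_pre = 0, b_group_post = 0,
                       affected_fraction = 0.125, influence_weight = 0,
                       ar1 = 0, n_items = 12, scale_max = 7,
                       tr_seconds = 0.727, seed = 1L) {
  n_conv <- n_subjects - n_controls
  if (is.null(group_sizes)) {
    base <- n_conv %/% n_groups
    group_sizes <- rep(base, n_groups)
    extra <- n_conv - sum(group_sizes)
    if (extra > 0) group_sizes[seq_len(extra)] <- group_sizes[seq_len(extra)] + 1L
  }
  if (sum(group_sizes) != n_conv)
    stop("group_sizes must sum to n_subjects - n_controls (",
         n_conv, "), got ", sum(group_sizes))
  if (any(group_sizes < 1)) stop("group_sizes must be positive")
  if (length(group_sizes) != n_groups)
    stop("length(group_sizes) must equal n_groups")
  fr <- c(a_shared = a_shared, b_group_pre = b_group_pre,
          b_group_post = b_group_post, affected_fraction = affected_fraction,
          influence_weight = influence_weight)
  bad <- names(fr)[fr < 0 | fr > 1]
  if (length(bad)) stop("fractions must lie in [0, 1]: ",
                        paste(bad, collapse = ", "))
  tot <- a_shared + max(b_group_pre, b_group_post) + influence_weight
  if (tot >= 1)
    stop("variance fractions sum to ", signif(tot, 4),
         " >= 1: reduce a_shared, b_group_pre/b_group_post, ",
         "or influence_weight")
  if (length(grid) != 3 || any(grid < 1)) stop("grid must be 3 positive dims")
  if (n_timepoints < 2) stop("n_timepoints must be >= 2")
  if (abs(ar1) >= 1) stop("ar1 must lie in (-1, 1)")
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_groups = as.integer(n_groups),
              group_sizes = as.integer(group_sizes),
              n_controls = as.integer(n_controls),
              grid = as.integer(grid),
              n_voxels = as.integer(prod(grid)),
              n_timepoints = as.integer(n_timepoints),
              n_clips = as.integer(n_clips),
              a_shared = a_shared, b_group_pre = b_group_pre,
              b_group_post = b_group_post,
              affected_fraction = affected_fraction,
              influence_weight = influence_weight, ar1 = ar1,
              n_items = as.integer(n_items),
              scale_max = as.integer(scale_max),
              tr_seconds = tr_seconds, seed = as.integer(seed))
  cfg$subject_ids <- sprintf("sub%02d", seq_len(cfg$n_subjects))
  cfg$group_labels <- c(rep(sprintf("g%d", seq_len(cfg$n_groups)),
                            times = cfg$group_sizes),
                        rep("control", cfg$n_controls))
  cfg$affected_voxels <- affected_block(cfg$grid, affected_fraction)
  class(cfg) <- "sim_config"
  cfg
}

# Contiguous near-cubic block of voxels at the grid origin, flattened in
# column-major order; size is round(frac * V) clipped to the grid.
affected_block <- function(grid, frac) {
  n_target <- max(1L, round(frac * prod(grid)))
  side <- max(1L, round(n_target^(1 / 3)))
  dims <- pmin(grid, side)
  # grow dims greedily until block >= target (or fills the grid)
  while (prod(dims) < n_target && any(dims < grid)) {
    k <- which.min(ifelse(dims < grid, dims, Inf))
    dims[k] <- dims[k] + 1L
  }
  idx <- array(FALSE, dim = grid)
  idx[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <- TRUE
  which(idx)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_subjects, "subjects (", x$n_controls, "controls ),",
      x$n_groups, "groups,", x$n_voxels, "voxels,",
      x$n_timepoints, "TRs x", x$n_clips, "clip(s)\n")
  cat("  a_shared =", x$a_shared, " b_pre =", x$b_group_pre,
      " b_post =", x$b_group_post, " w =", x$influence_weight, "\n")
  invisible(x)
}

# unit-variance white noise, optionally AR(1) with marginal variance 1
rnoise <- function(n_row, n_col, ar1 = 0) {
  m <- matrix(rnorm(n_row * n_col), n_row, n_col)
  if (ar1 != 0) {
    for (t in 2:n_col) m[, t] <- ar1 * m[, t - 1] + sqrt(1 - ar1^2) * m[, t]
  }
  m
}

# one session's data for one clip: subjects x voxels x time
simulate_session <- function(cfg, b_group) {
  V <- cfg$n_voxels; T_ <- cfg$n_timepoints; N <- cfg$n_subjects
  a <- cfg$a_shared
  g <- rnoise(V, T_, cfg$ar1)
  groups <- setdiff(unique(cfg$group_labels), "control")
  h <- lapply(groups, function(gr) rnoise(V, T_, cfg$ar1))
  names(h) <- groups
  x <- array(0, dim = c(N, V, T_))
  aff <- cfg$affected_voxels
  for (s in seq_len(N)) {
    lab <- cfg$group_labels[s]
    b_v <- rep(0, V)
    if (lab != "control" && b_group > 0) b_v[aff] <- b_group
    eps <- rnoise(V, T_, cfg$ar1)
    sig <- sqrt(a) * g + sqrt(1 - a - b_v) * eps
    if (lab != "control" && b_group > 0)
      sig[aff, ] <- sig[aff, ] + sqrt(b_group) * h[[lab]][aff, ]
    x[s, , ] <- sig
  }
  x
}

#' Generate synthetic BOLD sessions before and after conversation
#'
#' Draws, for each clip, an independent pre- and post-conversation
#' [bold_session()] under the variance-partition model described in
#' [sim_config()]. All latent components are redrawn per session and clip, so
#' pre and post series of the same subject are independent; expected
#' within-session ISC is `a + b` at affected voxels within a group and `a`
#' otherwise.
#'
#' @param config a [sim_config()].
#' @return list with elements `pre` and `post`, each a list of
#'   `bold_session` objects (one per clip).
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 6, n_groups = 2, grid = c(3, 3, 1),
#'                   n_timepoints = 40, a_shared = 0.2, b_group_post = 0.3)
#' b <- generate_bold(cfg)
#' dim(b$post[[1]]$data)
generate_bold <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pre <- post <- vector("list", config$n_clips)
  for (k in seq_len(config$n_clips)) {
    pre[[k]] <- bold_session(simulate_session(config, config$b_group_pre),
                             subject_ids = config$subject_ids,
                             group_labels = config$group_labels,
                             clip_id = k, grid = config$grid,
                             tr_seconds = config$tr_seconds)
    post[[k]] <- bold_session(simulate_session(config, config$b_group_post),
                              subject_ids = config$subject_ids,
                              group_labels = config$group_labels,
                              clip_id = k, grid = config$grid,
                              tr_seconds = config$tr_seconds)
  }
  list(pre = pre, post = post)
}

#' Inject directed ego-to-alter imitation into a post session
#'
#' Replaces the alter's post-conversation time series, voxel by voxel, with
#' `sqrt(w) * ego_pre + sqrt(1 - w) * noise`, so that the expected
#' ISC(ego_pre, alter_post) is exactly `sqrt(w)` while the reverse direction
#' is untouched. This is the generative analogue of the neural-influence
#' statistic (how far the alter moved toward the ego's initial position).
#'
#' The replacement noise is drawn from the current RNG stream; seed before
#' calling for reproducibility.
#'
#' @param bold_pre,bold_post `bold_session` objects for the same clip.
#' @param ego,alter subject ids (or indices); must differ.
#' @param w imitation weight in `[0, 1]`.
#' @return the modified post `bold_session`.
#' @export
inject_influence <- function(bold_pre, bold_post, ego, alter, w) {
  stopifnot(inherits(bold_pre, "bold_session"),
            inherits(bold_post, "bold_session"))
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  e <- subject_index(bold_pre, ego)
  a <- subject_index(bold_post, alter)
  if (e == a) stop("ego and alter must be different subjects")
  src <- bold_pre$data[e, , ]
  noise <- matrix(rnorm(length(src)), nrow(src), ncol(src))
  bold_post$data[a, , ] <- sqrt(w) * src + sqrt(1 - w) * noise
  bold_post
}

subject_index <- function(session, id) {
  if (is.numeric(id)) return(as.integer(id))
  i <- match(id, session$subject_ids)
  if (is.na(i)) stop("unknown subject: ", id)
  i
}

#' Generate a synthetic directed friendship network
#'
#' Two models are available. `"random"` draws every ordered pair as an edge
#' independently with probability `p` (an Erdos-Renyi digraph). `"clustered"`
#' plants `n_cliques` mutually-connected cliques joined only through
#' `n_brokers` broker nodes, giving a known high-brokerage ground truth: each
#' broker nominates (and is nominated by) `ties_per_clique` members of every
#' clique, and no other between-clique edges exist.
#'
#' @param n number of nodes (>= 2).
#' @param model `"random"` or `"clustered"`.
#' @param p edge probability for the random model.
#' @param n_cliques,n_brokers,ties_per_clique clustered-model structure.
#' @param seed integer seed.
#' @param ids optional node ids (default `p01 ...`).
#' @return a [social_network()]; for the clustered model the broker ids are
#'   in `attr(net, "brokers")`.
#' @export
generate_network <- function(n, model = c("clustered", "random"), p = 0.3,
                             n_cliques = 2, n_brokers = 1,
                             ties_per_clique = 2, seed = 1L, ids = NULL) {
  if (n < 2) stop("a network needs at least 2 nodes")
  model <- match.arg(model)
  set.seed(seed)
  ids <- ids %||% sprintf("p%02d", seq_len(n))
  if (model == "random") {
    cells <- expand.grid(from = seq_len(n), to = seq_len(n))
    cells <- cells[cells$from != cells$to, ]
    keep <- runif(nrow(cells)) < p
    edges <- data.frame(source = ids[cells$from[keep]],
                        target = ids[cells$to[keep]],
                        stringsAsFactors = FALSE)
    return(social_network(edges, nodes = ids))
  }
  n_cl_nodes <- n - n_brokers
  # small cohorts: shrink the clique count rather than fail
  n_cliques <- max(1L, min(n_cliques, n_cl_nodes %/% 2))
  if (n_cl_nodes < 2)
    stop("not enough nodes for ", n_cliques, " cliques plus brokers")
  clique <- rep(seq_len(n_cliques), length.out = n_cl_nodes)
  clique <- sort(clique)
  edges <- list()
  for (cl in seq_len(n_cliques)) {
    members <- which(clique == cl)
    prs <- t(combn(members, 2))
    edges[[length(edges) + 1]] <-
      data.frame(source = ids[c(prs[, 1], prs[, 2])],
                 target = ids[c(prs[, 2], prs[, 1])])
  }
  brokers <- n_cl_nodes + seq_len(n_brokers)
  for (b in brokers) {
    for (cl in seq_len(n_cliques)) {
      members <- which(clique == cl)
      sel <- members[seq_len(min(ties_per_clique, length(members)))]
      edges[[length(edges) + 1]] <-
        data.frame(source = ids[c(rep(b, length(sel)), sel)],
                   target = ids[c(sel, rep(b, length(sel)))])
    }
  }
  net <- social_network(do.call(rbind, edges), nodes = ids)
  attr(net, "brokers") <- ids[brokers]
  attr(net, "cliques") <- split(ids[seq_len(n_cl_nodes)], clique)
  net
}

#' Generate synthetic Likert surveys that converge within groups
#'
#' Pre-conversation answers are i.i.d. uniform on the integer scale
#' `1..scale_max`, per subject, item, and clip. Post-conversation answers of
#' conversing subjects are pulled toward their group's pre-conversation mean
#' by factor `pull` and re-discretized (`pull = 0` leaves answers unchanged;
#' `pull = 1` collapses every group onto its rounded mean, so within-group
#' city-block distances become 0). Controls are never moved.
#'
#' @param config a [sim_config()].
#' @param pull convergence factor in `[0, 1]`.
#' @return list `pre` / `post` of arrays `subjects x items x clips` with
#'   subject dimnames.
#' @export
generate_surveys <- function(config, pull = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  if (pull < 0 || pull > 1) stop("pull must lie in [0, 1]")
  set.seed(config$seed + 1L)
  N <- config$n_subjects; I <- config$n_items; K <- config$n_clips
  pre <- array(sample.int(config$scale_max, N * I * K, replace = TRUE),
               dim = c(N, I, K),
               dimnames = list(config$subject_ids, NULL, NULL))
  post <- pre
  for (g in setdiff(unique(config$group_labels), "control")) {
    members <- which(config$group_labels == g)
    for (k in seq_len(K)) {
      gm <- colMeans(pre[members, , k, drop = FALSE])
      for (s in members) {
        moved <- pre[s, , k] + pull * (gm - pre[s, , k])
        post[s, , k] <- pmin(pmax(round(moved), 1L), config$scale_max)
      }
    }
  }
  storage.mode(post) <- "integer"
  list(pre = pre, post = post)
}

#' Generate a synthetic turn-taking table with speaker covariates
#'
#' Emulates transcribed group conversations: each group-by-clip discussion
#' yields a sequence of speech turns. Speakers with higher perceived status
#' both take more turns (softmax selection with weight `status_talk`) and
#' speak longer turns. Word stems come from a small vocabulary in which
#' "elite" stems are used preferentially by high-centrality speakers with
#' strength `stem_signal`, so word-level regressions have a recoverable
#' ground truth.
#'
#' @param config a [sim_config()].
#' @param centrality optional named per-subject centrality scores (z-scored
#'   internally); defaults to i.i.d. standard normals.
#' @param status optional named per-subject perceived-status scores; default
#'   i.i.d. standard normals.
#' @param turns_per_clip expected number of turns per group discussion.
#' @param mean_words mean words per turn at status 0.
#' @param status_talk softmax weight of status on speaking probability.
#' @param stem_signal log-odds slope of centrality on elite-stem use.
#' @param n_stems,n_elite vocabulary size and number of centrality-linked
#'   stems.
#' @return list with `turns` (one row per speech turn: `turn_id`,
#'   `speaker_id`, `group_id`, `clip_id`, `n_words`, `status`, `centrality`)
#'   and `tokens` (one row per stem use: `turn_id`, `stem`).
#' @export
generate_turns <- function(config, centrality = NULL, status = NULL,
                           turns_per_clip = 40, mean_words = 20,
                           status_talk = 0.8, stem_signal = 1.5,
                           n_stems = 40, n_elite = 4) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  ids <- config$subject_ids
  centrality <- centrality %||% setNames(rnorm(length(ids)), ids)
  status <- status %||% setNames(rnorm(length(ids)), ids)
  zc <- (centrality - mean(centrality)) / sd(centrality)
  stems <- sprintf("stem%02d", seq_len(n_stems))
  elite <- stems[seq_len(n_elite)]
  turns <- list(); tokens <- list(); tid <- 0L
  for (g in setdiff(unique(config$group_labels), "control")) {
    members <- ids[config$group_labels == g]
    for (k in seq_len(config$n_clips)) {
      nt <- max(2L, rpois(1, turns_per_clip))
      pr <- exp(status_talk * status[members])
      speakers <- sample(members, nt, replace = TRUE, prob = pr / sum(pr))
      for (sp in speakers) {
        tid <- tid + 1L
        nw <- 1L + rpois(1, mean_words * exp(0.3 * status[sp]))
        turns[[tid]] <- data.frame(
          turn_id = tid, speaker_id = sp, group_id = g, clip_id = k,
          n_words = nw, status = unname(status[sp]),
          centrality = unname(centrality[sp]))
        p_elite <- 1 / (1 + exp(-(stem_signal * zc[sp] - 1)))
        n_tok <- max(1L, rpois(1, 4))
        use_elite <- runif(n_tok) < p_elite
        tok <- ifelse(use_elite, sample(elite, n_tok, replace = TRUE),
                      sample(setdiff(stems, elite), n_tok, replace = TRUE))
        tokens[[tid]] <- data.frame(turn_id = tid, stem = tok)
      }
    }
  }
  list(turns = do.call(rbind, turns), tokens = do.call(rbind, tokens))
}

#' Generate a complete synthetic cohort
#'
#' Bundles [generate_bold()], [generate_network()], [generate_surveys()] and
#' [generate_turns()] into one object whose `truth` element records every
#' generating parameter, sufficient to recompute the closed-form expectations
#' used in recovery tests. If `config$influence_weight > 0`,
#' `influence_pairs` ordered pairs (default: the first two members of each
#' group, ego then alter) receive injected imitation via
#' [inject_influence()].
#'
#' @param config a [sim_config()].
#' @param pull survey convergence factor, see [generate_surveys()].
#' @param network_model passed to [generate_network()].
#' @param influence_pairs optional 2-column matrix/data.frame of
#'   (ego, alter) subject ids.
#' @return object of class `synthetic_cohort` with elements `bold_pre`,
#'   `bold_post` (lists per clip), `network`, `surveys_pre`, `surveys_post`,
#'   `turns`, `tokens`, `centrality`, and `truth`.
#' @export
#' @examples
#' coh <- generate_cohort(sim_config(n_subjects = 8, n_groups = 2,
#'                                   grid = c(3, 3, 1), n_timepoints = 30))
#' names(coh)
generate_cohort <- function(config, pull = 0.5,
                            network_model = "clustered",
                            influence_pairs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  bold <- generate_bold(config)
  if (config$influence_weight > 0) {
    if (is.null(influence_pairs)) {
      grs <- setdiff(unique(config$group_labels), "control")
      influence_pairs <- do.call(rbind, lapply(grs, function(g) {
        m <- config$subject_ids[config$group_labels == g]
        c(m[1], m[2])
      }))
    }
    set.seed(config$seed + 3L)
    for (k in seq_along(bold$post)) {
      for (r in seq_len(nrow(influence_pairs))) {
        bold$post[[k]] <- inject_influence(
          bold$pre[[k]], bold$post[[k]],
          ego = influence_pairs[r, 1], alter = influence_pairs[r, 2],
          w = config$influence_weight)
      }
    }
  }
  net <- generate_network(config$n_subjects, model = network_model,
                          seed = config$seed + 4L,
                          ids = config$subject_ids)
  surveys <- generate_surveys(config, pull = pull)
  cent <- centrality_table(net)
  turns <- generate_turns(
    config, centrality = setNames(cent$pca_centrality, cent$node))
  structure(list(bold_pre = bold$pre, bold_post = bold$post,
                 network = net,
                 surveys_pre = surveys$pre, surveys_post = surveys$post,
                 turns = turns$turns, tokens = turns$tokens,
                 centrality = cent,
                 truth = list(config = unclass(config), pull = pull,
                              network_model = network_model,
                              influence_pairs = influence_pairs)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat("synthetic_cohort:", cfg$n_subjects, "subjects,", cfg$n_clips,
      "clip(s),", cfg$n_voxels, "voxels x", cfg$n_timepoints, "TRs\n")
  invisible(x)
}
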
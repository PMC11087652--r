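#' Analysis run configuration
#'
#' All tunable analysis parameters in one validated, serializable object.
#' Unknown keys are rejected. The configuration (and hence every output that
#' embeds its hash) round-trips through JSON.
#'
#' @param ... overrides of the defaults listed below.
#' @return object of class `run_config`.
#' @details Defaults: `n_perm = 2000` permutations; cluster-forming
#'   `cluster_p = 0.01` with `min_cluster = 32` voxels and face
#'   (`connectivity = 6`) adjacency; `cluster_null = "fixed"`; design
#'   `mode = "per_group"`; rolling `window = 10` TRs, `step = 1`;
#'   `fisher_z = FALSE` (raw r is differenced, the transform is for
#'   sensitivity analyses); `smoothing = "add_one"` permutation p rule;
#'   `centrality_mode = "union"` and `constraint_ties = "mutual"` graph
#'   conventions; `survey_n_perm = 200`; `seed = 1`.
#' @export
run_config <- function(...) {
  defaults <- list(n_perm = 2000, cluster_p = 0.01, min_cluster = 32,
                   connectivity = 6, cluster_null = "fixed",
                   mode = "per_group", window = 10, step = 1,
                   fisher_z = FALSE, smoothing = "add_one",
                   centrality_mode = "union", constraint_ties = "mutual",
                   survey_n_perm = 200, seed = 1L)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config (hash", config_hash(x), ")\n")
  for (k in names(x)) cat("  ", k, "=", format(x[[k]]), "\n")
  invisible(x)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON serialization; embedded in every pipeline
#' output for provenance.
#'
#' @param config a [run_config()].
#' @return hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(config_to_json(config), tf)
  unname(tools::md5sum(tf))
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
config_to_json <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
}

#' @rdname run_config
#' @param json JSON string or path.
#' @export
config_from_json <- function(json) {
  if (file.exists(json)) json <- paste(readLines(json), collapse = "\n")
  run_config(jsonlite::fromJSON(json))
}

#' Write a synthetic cohort to disk
#'
#' Serializes a [generate_cohort()] result as the on-disk layout the loader
#' expects: per-subject 4-D NIfTI volumes (`bold/`), a JSON cohort manifest,
#' CSV survey and turn tables, a two-column TSV network edge list
#' (`source<TAB>target`), and the generating truth as JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "bold"), recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$truth$config
  grid <- cfg$grid
  bold_files <- list()
  for (ses in c("pre", "post")) {
    stacks <- if (ses == "pre") cohort$bold_pre else cohort$bold_post
    for (k in seq_along(stacks)) {
      s <- stacks[[k]]
      for (si in seq_along(s$subject_ids)) {
        vol <- array(s$data[si, , ], dim = c(grid, dim(s$data)[3]))
        f <- file.path("bold", sprintf("%s_ses-%s_clip-%d.nii.gz",
                                       s$subject_ids[si], ses, k))
        RNifti::writeNifti(RNifti::asNifti(vol), file.path(dir, f))
        bold_files[[length(bold_files) + 1]] <-
          list(subject = s$subject_ids[si], session = ses, clip = k,
               path = f)
      }
    }
  }
  surveys <- rbind(survey_long(cohort$surveys_pre, "pre"),
                   survey_long(cohort$surveys_post, "post"))
  write.csv(surveys, file.path(dir, "surveys.csv"), row.names = FALSE)
  write.table(cohort$network$edges[c("source", "target")],
              file.path(dir, "network.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.csv(cohort$turns, file.path(dir, "turns.csv"), row.names = FALSE)
  write.csv(cohort$tokens, file.path(dir, "tokens.csv"), row.names = FALSE)
  writeLines(as.character(jsonlite::toJSON(cohort$truth, auto_unbox = TRUE,
                                           digits = NA)),
             file.path(dir, "truth.json"))
  manifest <- list(subject_ids = cfg$subject_ids,
                   group_labels = cfg$group_labels,
                   grid = grid, n_clips = cfg$n_clips,
                   tr_seconds = cfg$tr_seconds,
                   bold = bold_files,
                   surveys = "surveys.csv", network = "network.tsv",
                   turns = "turns.csv", tokens = "tokens.csv",
                   truth = "truth.json", seed = cfg$seed)
  mpath <- file.path(dir, "manifest.json")
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           digits = NA)), mpath)
  invisible(mpath)
}

survey_long <- function(arr, session) {
  dn <- dimnames(arr)[[1]]
  idx <- expand.grid(subject = seq_len(dim(arr)[1]),
                     item = seq_len(dim(arr)[2]),
                     clip = seq_len(dim(arr)[3]))
  data.frame(subject_id = dn[idx$subject], session = session,
             clip_id = idx$clip, item = idx$item,
             answer = arr[as.matrix(idx)])
}

#' Load a cohort from a manifest
#'
#' Reads the layout written by [write_cohort()] back into memory, validating
#' as it goes: every referenced file must exist, every subject appearing in
#' the surveys, turns, or network must be declared in the manifest, and
#' volumes must match the declared grid and be finite.
#'
#' @param manifest_path path to `manifest.json`.
#' @return a list mirroring a `synthetic_cohort` (class `cohort`):
#'   `bold_pre`/`bold_post` lists of [bold_session()], `network`,
#'   `surveys_pre`/`surveys_post`, `turns`, `tokens`, `manifest`.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  root <- dirname(manifest_path)
  man <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = TRUE)
  ids <- man$subject_ids
  grid <- man$grid
  rel <- function(p) file.path(root, p)
  for (f in c(man$surveys, man$network, man$turns, man$tokens))
    if (!file.exists(rel(f))) stop("missing file: ", f)
  bold <- man$bold
  sessions <- list()
  for (ses in c("pre", "post")) {
    stacks <- vector("list", man$n_clips)
    for (k in seq_len(man$n_clips)) {
      rowsk <- bold[bold$session == ses & bold$clip == k, ]
      rowsk <- rowsk[match(ids, rowsk$subject), ]
      if (anyNA(rowsk$subject))
        stop("manifest missing BOLD for subject(s): ",
             paste(ids[is.na(rowsk$subject)], collapse = ", "),
             " (session ", ses, ", clip ", k, ")")
      dat <- NULL
      for (r in seq_len(nrow(rowsk))) {
        f <- rel(rowsk$path[r])
        if (!file.exists(f)) stop("missing file: ", rowsk$path[r])
        vol <- tryCatch(suppressWarnings(RNifti::readNifti(f)),
                        error = function(e)
                          stop("unreadable NIfTI: ", rowsk$path[r]))
        vol <- array(vol, dim = dim(vol))
        if (!identical(dim(vol)[1:3], as.integer(grid)))
          stop("grid mismatch in ", rowsk$path[r])
        if (!all(is.finite(vol))) stop("non-finite values in ", rowsk$path[r])
        if (is.null(dat))
          dat <- array(0, dim = c(length(ids), prod(grid), dim(vol)[4]))
        dat[r, , ] <- matrix(vol, prod(grid), dim(vol)[4])
      }
      stacks[[k]] <- bold_session(dat, subject_ids = ids,
                                  group_labels = man$group_labels,
                                  clip_id = k, grid = grid,
                                  tr_seconds = man$tr_seconds)
    }
    sessions[[ses]] <- stacks
  }
  surveys <- read.csv(rel(man$surveys))
  unknown <- setdiff(unique(surveys$subject_id), ids)
  if (length(unknown))
    stop("survey table references unknown subject(s): ",
         paste(unknown, collapse = ", "))
  net_edges <- read.delim(rel(man$network))
  net <- social_network(net_edges, nodes = union(
    ids, unique(c(net_edges$source, net_edges$target))))
  turns <- read.csv(rel(man$turns))
  unknown <- setdiff(unique(turns$speaker_id), ids)
  if (length(unknown))
    stop("turn table references unknown speaker(s): ",
         paste(unknown, collapse = ", "))
  tokens <- read.csv(rel(man$tokens))
  n_items <- max(surveys$item)
  arr <- function(ses) {
    a <- array(NA_real_, dim = c(length(ids), n_items, man$n_clips),
               dimnames = list(ids, NULL, NULL))
    sv <- surveys[surveys$session == ses, ]
    a[cbind(match(sv$subject_id, ids), sv$item, sv$clip_id)] <- sv$answer
    a
  }
  structure(list(bold_pre = sessions$pre, bold_post = sessions$post,
                 network = net, surveys_pre = arr("pre"),
                 surveys_post = arr("post"), turns = turns,
                 tokens = tokens, manifest = man),
            class = c("cohort", "synthetic_cohort"))
}
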
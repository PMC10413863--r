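# End-to-end orchestration: probe series -> clustering -> pockets ->
# features -> ranking, plus forest training over a set of structures.

#' Run configuration
#'
#' Bundles all tunable parameters; the defaults reproduce the deployment
#' settings (gamma = 0, beta = 0.9, ladder 1.4..3.0 step 0.1, LC >= 50
#' and PC >= 20 hit thresholds). Serializable to/from a YAML-like
#' key:value file via [read_run_config()].
#'
#' @param ladder A [radius_ladder()].
#' @param clustering A [clustering_config()].
#' @param grid_spacing Volume-grid spacing (default 0.3 A).
#' @param oracle_spacing Grid-oracle spacing (default 0.6 A).
#' @param cutoff Contact cutoff for evaluation (default 5 A).
#' @param lc_min,pc_min Hit thresholds in percent (defaults 50, 20).
#' @param n_trees,subsample Forest size (defaults 200 trees, 256).
#' @param replication_scale PC replication constant (default 10).
#' @param seed Master seed for all randomness (default 1).
#' @return Object of class `pp_run_config`.
#' @export
run_config <- function(ladder = radius_ladder(),
                       clustering = clustering_config(),
                       grid_spacing = 0.3, oracle_spacing = 0.6,
                       cutoff = 5.0, lc_min = 50, pc_min = 20,
                       n_trees = 200L, subsample = 256L,
                       replication_scale = 10L, seed = 1L) {
  structure(list(ladder = ladder, clustering = clustering,
                 grid_spacing = grid_spacing,
                 oracle_spacing = oracle_spacing, cutoff = cutoff,
                 lc_min = lc_min, pc_min = pc_min, n_trees = n_trees,
                 subsample = subsample,
                 replication_scale = replication_scale, seed = seed),
            class = "pp_run_config")
}

#' Read a run configuration from a flat key:value file
#' @param path File with `key: value` lines (unknown keys are errors).
#' @return A `pp_run_config`.
#' @export
read_run_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path, warn = FALSE),
                invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*:\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  cfg <- run_config()
  lad <- list(r_min = cfg$ladder$r_min, r_max = cfg$ladder$r_max,
              delta = cfg$ladder$delta)
  cl <- cfg$clustering
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k %in% names(lad)) lad[[k]] <- v
    else if (k %in% names(cl)) cl[[k]] <- v
    else if (k %in% names(cfg)) cfg[[k]] <- v
    else stop("unknown config key: ", k)
  }
  cfg$ladder <- radius_ladder(lad$r_min, lad$r_max, lad$delta)
  cfg$clustering <- clustering_config(cl$gamma, cl$beta, cl$align_threshold,
                                      cl$size_threshold,
                                      cl$entrance_radius_min,
                                      cl$buried_radius, cl$proj_tol)
  cfg
}

#' Detect and rank pockets on one structure
#'
#' Runs the full pipeline: probe series over the radius ladder,
#' hierarchical clustering, pocket/subpocket extraction, feature
#' computation, and ranking -- by the four trained forests when `models`
#' is given, otherwise by volume descending (`rank_by_volume` fallback).
#'
#' @param structure A `pp_structure`.
#' @param config A [run_config()].
#' @param models Optional four-forest list from [train_forests()] /
#'   [pocket_train()].
#' @param rank_by_volume Force the volume fallback (default: `TRUE` iff
#'   no models are given).
#' @param structure_id Label used in output tables.
#' @return Object of class `pp_detection`: list with `pockets`, `features`
#'   (data frame), `ranking` (data frame), `tree`, `series`, `stats`.
#' @export
pocket_detect <- function(structure, config = run_config(), models = NULL,
                          rank_by_volume = is.null(models),
                          structure_id = "structure") {
  if (!rank_by_volume && is.null(models)) {
    stop("no models supplied; pass models or set rank_by_volume = TRUE")
  }
  series <- build_probe_series(structure, config$ladder)
  tree <- run_hierarchical_clustering(series, config$clustering)
  pockets <- extract_pockets_subpockets(tree, config$clustering)
  stats <- list(
    probes_per_level = vapply(series$levels, nrow, 1L),
    n_pockets = length(pockets),
    n_subpockets = sum(vapply(pockets, function(p) length(p$subpockets), 1L)))
  if (length(pockets) == 0L) {
    return(structure(list(pockets = list(), features = NULL, ranking = NULL,
                          tree = tree, series = series, stats = stats),
                     class = "pp_detection"))
  }
  feat <- feature_matrix(pockets, structure, config$clustering,
                         config$grid_spacing, structure_id = structure_id)
  ranking <- if (rank_by_volume) {
    top <- feat[!feat$is_subpocket, , drop = FALSE]
    ord <- order(-top$volume, top$pocket_id)
    data.frame(rank = seq_along(ord), pocket_id = top$pocket_id[ord],
               s = NA_real_, s_geo = NA_real_, s_chem = NA_real_,
               is_master = top$is_master[ord], parent = NA_character_,
               subrank = NA_integer_, volume = top$volume[ord],
               stringsAsFactors = FALSE)
  } else {
    score_and_rank(feat, models)
  }
  structure(list(pockets = pockets, features = feat, ranking = ranking,
                 tree = tree, series = series, stats = stats),
            class = "pp_detection")
}

#' @export
print.pp_detection <- function(x, ...) {
  cat(sprintf("<pp_detection> %d pocket(s), %d subpocket(s), %d probes\n",
              x$stats$n_pockets, x$stats$n_subpockets,
              sum(x$stats$probes_per_level)))
  if (!is.null(x$ranking)) {
    print(utils::head(x$ranking[!is.na(x$ranking$rank), ], 5))
  }
  invisible(x)
}

# pocket in rank order (top-level entries only)
.ranked_pockets <- function(detection) {
  rk <- detection$ranking
  rk <- rk[!is.na(rk$rank), , drop = FALSE]
  ids <- vapply(seq_along(detection$pockets),
                function(i) sprintf("p%02d", i), "")
  detection$pockets[match(rk$pocket_id, ids)]
}

# evaluate every pocket/subpocket of a detection against a ligand
.evaluate_detection <- function(detection, structure, ligand, config) {
  a <- structure$atoms
  heavy_xyz <- as.matrix(a[a$is_heavy, c("x", "y", "z")])
  eval_one <- function(pk) {
    atoms <- a[pk$tangent_atoms, , drop = FALSE]
    atoms <- atoms[atoms$is_heavy, , drop = FALSE]
    cs <- coverage_scores(as.matrix(atoms[, c("x", "y", "z")]), ligand,
                          heavy_xyz, cutoff = config$cutoff)
    data.frame(lc = cs$lc, pc = cs$pc, undefined = cs$undefined,
               hit = !cs$undefined &&
                 is_hit(cs$lc, cs$pc, config$lc_min, config$pc_min))
  }
  rows <- list()
  for (pi in seq_along(detection$pockets)) {
    pk <- detection$pockets[[pi]]
    e <- eval_one(pk)
    e$pocket_id <- sprintf("p%02d", pi)
    rows[[length(rows) + 1L]] <- e
    for (si in seq_along(pk$subpockets)) {
      es <- eval_one(pk$subpockets[[si]])
      es$pocket_id <- sprintf("p%02d.s%d", pi, si)
      rows[[length(rows) + 1L]] <- es
    }
  }
  do.call(rbind, rows)
}

#' Train the four ranking forests on a set of structures with ligands
#'
#' For every (structure, ligand) pair the full generation pipeline is run,
#' every pocket and subpocket is evaluated with the LC/PC metrics, hitting
#' pockets are replicated proportionally to PC, split into the large and
#' small populations, and the four forests are fitted.
#'
#' @param dataset List of entries, each a list with `structure`
#'   (`pp_structure`) and `ligand` (k x 3 matrix); [make_structure()]
#'   fixtures work directly.
#' @param config A [run_config()].
#' @return List with `models` (four `pp_iforest`), `training` (the
#'   replicated training rows) and `manifest` (seed, parameters, row
#'   counts).
#' @export
pocket_train <- function(dataset, config = run_config()) {
  rows <- list()
  for (di in seq_along(dataset)) {
    entry <- dataset[[di]]
    st <- entry$structure
    det <- pocket_detect(st, config, rank_by_volume = TRUE,
                         structure_id = paste0("s", di))
    if (length(det$pockets) == 0L) next
    ev <- .evaluate_detection(det, st, entry$ligand, config)
    m <- merge(det$features, ev, by = "pocket_id")
    rows[[length(rows) + 1L]] <- m
  }
  if (!length(rows)) stop("no pockets generated across the dataset")
  all_rows <- do.call(rbind, rows)
  all_rows$pc_pct <- all_rows$pc          # percent, as printed
  all_rows$pc <- ifelse(is.na(all_rows$pc_pct), 0, all_rows$pc_pct / 100)
  training <- build_training_set(all_rows, config$replication_scale)
  models <- train_forests(training, config$n_trees, config$subsample,
                          config$seed)
  manifest <- list(seed = config$seed, n_trees = config$n_trees,
                   subsample = config$subsample,
                   gamma = config$clustering$gamma,
                   beta = config$clustering$beta,
                   n_large = nrow(training$large),
                   n_small = nrow(training$small),
                   n_structures = length(dataset))
  list(models = models, training = training, manifest = manifest,
       evaluated = all_rows)
}
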
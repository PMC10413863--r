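# Isolation-Forest ranking: anomaly scores for pockets, the four-forest
# scheme (geometric/chemical x large/small populations), PC-weighted
# training-set replication, subpocket subranking and the penalized
# single-pocket expansion.

# average path length of an unsuccessful search in a binary search tree
# over n points; 0 for n <= 1 (path lengths are counted in edges)
.c_factor <- function(n) {
  if (n <= 1) return(0)
  H <- sum(1 / seq_len(n - 1))
  2 * H - 2 * (n - 1) / n
}

.grow_itree <- function(X, idx, depth, hlim) {
  m <- length(idx)
  if (depth >= hlim || m <= 1L) {
    return(list(leaf = TRUE, size = m, adj = .c_factor(m)))
  }
  d <- ncol(X)
  feats <- sample.int(d)
  for (q in feats) {
    lo <- min(X[idx, q]); hi <- max(X[idx, q])
    if (hi > lo) {
      sp <- stats::runif(1, lo, hi)
      left <- idx[X[idx, q] < sp]
      right <- idx[X[idx, q] >= sp]
      return(list(leaf = FALSE, feature = q, split = sp,
                  left = .grow_itree(X, left, depth + 1L, hlim),
                  right = .grow_itree(X, right, depth + 1L, hlim)))
    }
  }
  list(leaf = TRUE, size = m, adj = .c_factor(m))  # all rows identical
}

.itree_path <- function(tree, x) {
  h <- 0
  node <- tree
  while (!node$leaf) {
    node <- if (x[node$feature] < node$split) node$left else node$right
    h <- h + 1
  }
  h + node$adj
}

#' Fit an Isolation Forest
#'
#' Each tree is grown on a uniformly random subsample (without
#' replacement, no bootstrap) by recursively choosing a random feature and
#' a uniform split value, until the height limit `ceil(log2 n)` or
#' singleton/constant leaves. Deployment settings are 10,000 trees with
#' subsample 256; smaller ensembles are statistically equivalent for
#' testing.
#'
#' @param rows Numeric feature matrix (observations x features).
#' @param n_trees Number of trees (default 200).
#' @param subsample Subsample size per tree (default 256, clipped to the
#'   number of rows).
#' @param seed Optional integer seed; the fit is deterministic under a
#'   fixed seed and restores the caller's RNG state.
#' @param feature_block,population Optional tags (`"geometric"`/
#'   `"chemical"`, `"large"`/`"small"`) stored in the model.
#' @return Object of class `pp_iforest`.
#' @export
fit_iforest <- function(rows, n_trees = 200L, subsample = 256L, seed = NULL,
                        feature_block = NA_character_,
                        population = NA_character_) {
  X <- as.matrix(rows)
  if (nrow(X) == 0L) stop("empty training set")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
      get(".Random.seed", envir = .GlobalEnv)
    } else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    }, add = TRUE)
    set.seed(seed)
  }
  n_sub <- min(subsample, nrow(X))
  hlim <- ceiling(log2(max(n_sub, 2L)))
  trees <- lapply(seq_len(n_trees), function(t) {
    idx <- sample.int(nrow(X), n_sub, replace = FALSE)
    .grow_itree(X, idx, 0L, hlim)
  })
  structure(list(trees = trees, n_sub = n_sub, n_trees = n_trees,
                 c_n = .c_factor(n_sub), d = ncol(X),
                 feature_names = colnames(X), seed = seed,
                 feature_block = feature_block, population = population),
            class = "pp_iforest")
}

#' @export
print.pp_iforest <- function(x, ...) {
  cat(sprintf("<pp_iforest> %d trees, subsample %d, %d features (%s/%s)\n",
              x$n_trees, x$n_sub, x$d, x$feature_block, x$population))
  invisible(x)
}

#' Anomaly score of observations under a fitted forest
#'
#' `s(x) = 2^(-E(h(x)) / c(n))` with `h` the path length in edges,
#' extended below non-singleton leaves by `c(leaf size)`, and `c(n)` the
#' average path length of an unsuccessful binary-search-tree search over
#' the subsample size. Scores near 1 flag strong anomalies; scores below
#' 0.5 flag normal samples.
#'
#' @param model A `pp_iforest`.
#' @param x Numeric vector (one observation) or matrix (rows =
#'   observations); the column count must match the fitted feature count.
#' @return Numeric vector of scores in (0, 1).
#' @export
anomaly_score <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != model$d) {
    stop("dimension mismatch: model has ", model$d, " features, input has ",
         ncol(x))
  }
  vapply(seq_len(nrow(x)), function(r) {
    Eh <- mean(vapply(model$trees, .itree_path, 1, x = x[r, ]))
    2^(-Eh / model$c_n)
  }, 1)
}

#' Build the PC-replicated training set
#'
#' Only hitting pockets enter the training set; each row is replicated
#' `max(1, round(replication_scale * PC))` times (PC as a fraction), which
#' biases the forests toward pockets that tightly cover their ligand.
#' Rows are split into the "large" population (master pockets containing
#' more than one subpocket) and the "small" population (everything else,
#' including subpockets).
#'
#' @param evaluated Data frame with at least logical `hit`, numeric `pc`
#'   (fraction in `[0, 1]`), logical `is_master` and integer
#'   `n_subpockets`, plus feature columns.
#' @param replication_scale Proportionality constant (default 10).
#' @return List with data frames `large` and `small` (either may have 0
#'   rows) and the replication counts.
#' @export
build_training_set <- function(evaluated, replication_scale = 10L) {
  hits <- evaluated[which(evaluated$hit), , drop = FALSE]
  if (nrow(hits) == 0L) stop("no hitting pockets: cannot build training set")
  reps <- pmax(1L, as.integer(round(replication_scale * hits$pc)))
  rep_rows <- hits[rep(seq_len(nrow(hits)), reps), , drop = FALSE]
  is_large <- rep_rows$is_master & rep_rows$n_subpockets > 1L
  list(large = rep_rows[is_large, , drop = FALSE],
       small = rep_rows[!is_large, , drop = FALSE],
       replication = reps)
}

#' Train the four ranking forests
#'
#' One geometric and one chemical forest per population (large/small).
#' A population with no training rows falls back to the pooled rows of
#' both populations.
#'
#' @param training Output of [build_training_set()].
#' @param n_trees,subsample,seed Passed to [fit_iforest()] (seeds are
#'   offset per forest for independence).
#' @return Named list of `pp_iforest`: `large_geo`, `large_chem`,
#'   `small_geo`, `small_chem`.
#' @export
train_forests <- function(training, n_trees = 200L, subsample = 256L,
                          seed = 1L) {
  pooled <- rbind(training$large, training$small)
  rows_for <- function(pop) {
    r <- training[[pop]]
    if (nrow(r) == 0L) pooled else r
  }
  gcols <- feature_names("geometric")
  ccols <- feature_names("chemical")
  list(
    large_geo = fit_iforest(rows_for("large")[, gcols], n_trees, subsample,
                            seed, "geometric", "large"),
    large_chem = fit_iforest(rows_for("large")[, ccols], n_trees, subsample,
                             seed + 1L, "chemical", "large"),
    small_geo = fit_iforest(rows_for("small")[, gcols], n_trees, subsample,
                            seed + 2L, "geometric", "small"),
    small_chem = fit_iforest(rows_for("small")[, ccols], n_trees, subsample,
                             seed + 3L, "chemical", "small"))
}

#' Score and rank pockets with the four-forest scheme
#'
#' Every top-level pocket (master or standalone) is scored by the
#' large-population geometric and chemical forests; the final score is
#' their average and the global rank is ascending in it (lower = better).
#' Subpockets are sub-ranked within their master by the small-population
#' forests with the same averaging. Ties break by larger volume first,
#' then pocket id.
#'
#' @param feat Feature matrix from [feature_matrix()].
#' @param models List of four forests from [train_forests()].
#' @return Data frame: `rank`, `pocket_id`, `s`, `s_geo`, `s_chem`,
#'   `is_master`, `parent`, `subrank`, `volume`. Top-level rows carry the
#'   global rank; subpocket rows carry `subrank` and `rank = NA`.
#' @export
score_and_rank <- function(feat, models) {
  need <- c("large_geo", "large_chem", "small_geo", "small_chem")
  if (!all(need %in% names(models))) {
    stop("missing model(s): ", paste(setdiff(need, names(models)),
                                     collapse = ", "))
  }
  gcols <- feature_names("geometric")
  ccols <- feature_names("chemical")
  top <- feat[!feat$is_subpocket, , drop = FALSE]
  sub <- feat[feat$is_subpocket, , drop = FALSE]
  sg <- anomaly_score(models$large_geo, as.matrix(top[, gcols]))
  sc <- anomaly_score(models$large_chem, as.matrix(top[, ccols]))
  top_out <- data.frame(pocket_id = top$pocket_id, s_geo = sg, s_chem = sc,
                        s = (sg + sc) / 2, is_master = top$is_master,
                        parent = NA_character_, subrank = NA_integer_,
                        volume = top$volume, stringsAsFactors = FALSE)
  ord <- order(top_out$s, -top_out$volume, top_out$pocket_id)
  top_out <- top_out[ord, , drop = FALSE]
  top_out$rank <- seq_len(nrow(top_out))
  sub_out <- NULL
  if (nrow(sub)) {
    sg <- anomaly_score(models$small_geo, as.matrix(sub[, gcols]))
    sc <- anomaly_score(models$small_chem, as.matrix(sub[, ccols]))
    sub_out <- data.frame(pocket_id = sub$pocket_id, s_geo = sg, s_chem = sc,
                          s = (sg + sc) / 2, is_master = FALSE,
                          parent = sub$parent_id, subrank = NA_integer_,
                          volume = sub$volume, rank = NA_integer_,
                          stringsAsFactors = FALSE)
    for (p in unique(sub_out$parent)) {
      sel <- which(sub_out$parent == p)
      o <- order(sub_out$s[sel], -sub_out$volume[sel],
                 sub_out$pocket_id[sel])
      sub_out$subrank[sel[o]] <- seq_along(sel)
    }
  }
  out <- rbind(top_out, sub_out)
  rownames(out) <- NULL
  out[, c("rank", "pocket_id", "s", "s_geo", "s_chem", "is_master",
          "parent", "subrank", "volume")]
}

#' Penalized score for a subpocket replacing its master
#'
#' The master's score `s` is penalized proportionally to the subpocket's
#' subranking `R` within its parent: `s_R = 1 - (1 - s) / R`. At `R = 1`
#' the master's score is returned unchanged; the score is non-improving
#' (non-decreasing) in `R` and stays in (0, 1).
#'
#' @param s_master Master pocket score in (0, 1).
#' @param R Integer subranking position, `>= 1`.
#' @return Penalized score.
#' @export
subpocket_penalty <- function(s_master, R) {
  if (any(R < 1)) stop("R must be >= 1")
  stopifnot(all(s_master > 0), all(s_master < 1))
  1 - (1 - s_master) / R
}

#' Expand a ranking into the single-pocket list
#'
#' Each master pocket is replaced by its (at most) three top-ranking
#' subpockets, scored by [subpocket_penalty()] applied to the master's
#' score; non-master pockets pass through unchanged and the list is
#' re-sorted ascending by score.
#'
#' @param ranked Output of [score_and_rank()].
#' @param max_subpockets Subpockets kept per master (default 3).
#' @return Data frame in the same layout, re-ranked.
#' @export
expand_single_pocket_list <- function(ranked, max_subpockets = 3L) {
  top <- ranked[!is.na(ranked$rank), , drop = FALSE]
  sub <- ranked[is.na(ranked$rank), , drop = FALSE]
  rows <- list()
  for (r in seq_len(nrow(top))) {
    if (!top$is_master[r]) {
      rows[[length(rows) + 1L]] <- top[r, , drop = FALSE]
      next
    }
    ss <- sub[!is.na(sub$parent) & sub$parent == top$pocket_id[r], ,
              drop = FALSE]
    ss <- ss[order(ss$subrank), , drop = FALSE]
    ss <- ss[seq_len(min(nrow(ss), max_subpockets)), , drop = FALSE]
    if (nrow(ss) == 0L) {
      rows[[length(rows) + 1L]] <- top[r, , drop = FALSE]
      next
    }
    ss$s <- subpocket_penalty(top$s[r], ss$subrank)
    ss$parent <- top$pocket_id[r]
    rows[[length(rows) + 1L]] <- ss
  }
  out <- do.call(rbind, rows)
  ord <- order(out$s, -out$volume, out$pocket_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
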
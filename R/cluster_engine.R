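# Hierarchical clustering of probe spheres via four event types:
# bottleneck, radial shift, pyramidal aggregation, lateral aggregation.
# Merges are union-find over cluster nodes; the merge history forms a
# binary tree from which pockets, subpockets and entrances are extracted.

#' Clustering configuration
#'
#' @param gamma Maximum surface gap for lateral aggregation (Angstrom).
#'   The gap between probes i, j is `d - (r_i + r_j)`; the default 0 means
#'   probes must touch or overlap.
#' @param beta Maximum surface gap for pyramidal aggregation (default 0.9,
#'   the deployment optimum together with `gamma = 0`).
#' @param align_threshold Significant-alignment threshold: minimum number of
#'   radially aligned probes forming a pseudo-mouth (default 4).
#' @param size_threshold Minimum cluster size for a (sub)pocket (default 100).
#' @param entrance_radius_min Terminal probes with radius above this value
#'   are grouped into entrances (default 2.4).
#' @param buried_radius A subpocket whose terminal sphere radius is below
#'   this value is considered buried (default 2.5).
#' @param proj_tol Coincidence tolerance for bottleneck center projections
#'   (default 0.1 A).
#' @return Object of class `pp_cluster_config`.
#' @export
clustering_config <- function(gamma = 0, beta = 0.9, align_threshold = 4L,
                              size_threshold = 100L,
                              entrance_radius_min = 2.4, buried_radius = 2.5,
                              proj_tol = 0.1) {
  stopifnot(gamma >= 0, beta >= 0, align_threshold >= 1, size_threshold >= 1)
  structure(list(gamma = gamma, beta = beta,
                 align_threshold = as.integer(align_threshold),
                 size_threshold = as.integer(size_threshold),
                 entrance_radius_min = entrance_radius_min,
                 buried_radius = buried_radius, proj_tol = proj_tol),
            class = "pp_cluster_config")
}

.empty_events <- function() {
  data.frame(kind = character(0), i = integer(0), j = integer(0),
             dist = numeric(0), radius = numeric(0), stringsAsFactors = FALSE)
}

# shared atom count between triplets of two probe rows (vectorized over pairs)
.shared_atoms <- function(probes, ii, jj) {
  A <- cbind(probes$a1[ii], probes$a2[ii], probes$a3[ii])
  B <- cbind(probes$a1[jj], probes$a2[jj], probes$a3[jj])
  out <- integer(length(ii))
  for (k in 1:3) out <- out + (A[, k] == B[, 1]) + (A[, k] == B[, 2]) +
      (A[, k] == B[, 3])
  out  # triplets are sorted & distinct so counts are exact
}

# probe b's center relative to probe a's trimming plane: is it on a's side?
.same_side_of <- function(probes, a_idx, b_idx) {
  dn <- (probes$x[b_idx] - probes$px[a_idx]) * probes$nx[a_idx] +
        (probes$y[b_idx] - probes$py[a_idx]) * probes$ny[a_idx] +
        (probes$z[b_idx] - probes$pz[a_idx]) * probes$nz[a_idx]
  sign(dn) == probes$side[a_idx]
}

#' Detect clustering events between probe sets
#'
#' Same-radius pass (`probes_hi = NULL`): bottlenecks (same triplet,
#' opposite sides, center projections coincident within `proj_tol` and
#' inside the triangle of atom centers) and lateral aggregation (equal
#' radii, triplets sharing exactly two atoms, each center on the other's
#' probe side of the other's trimming plane, surface gap `d - (r_i+r_j)`
#' at most `gamma`). Cross-level pass (`probes_hi` one increment above):
#' bottlenecks, radial-shift links (same triplet and side) and pyramidal
#' aggregation (different triplet, gap at most `beta`).
#'
#' @param probes_lo Probe data frame, all at one level.
#' @param probes_hi `NULL` (same-radius pass) or probes at the next level.
#' @param config A [clustering_config()].
#' @return Data frame of events: `kind`, probe ids `i`, `j`, `dist`,
#'   `radius` (the larger probe radius of the pair).
#' @export
detect_events <- function(probes_lo, probes_hi = NULL,
                          config = clustering_config()) {
  if (nrow(probes_lo) > 0 && length(unique(probes_lo$level)) != 1L) {
    stop("contract violation: probes_lo spans multiple levels")
  }
  if (!is.null(probes_hi) && nrow(probes_hi) > 0) {
    if (length(unique(probes_hi$level)) != 1L) {
      stop("contract violation: probes_hi spans multiple levels")
    }
    if (nrow(probes_lo) > 0 &&
        probes_hi$level[1] != probes_lo$level[1] + 1L) {
      stop("contract violation: probes_hi is not one level above probes_lo")
    }
  }
  if (is.null(probes_hi)) .events_same_level(probes_lo, config)
  else .events_cross_level(probes_lo, probes_hi, config)
}

.pair_dist <- function(pa, ia, pb, ib) {
  sqrt((pa$x[ia] - pb$x[ib])^2 + (pa$y[ia] - pb$y[ib])^2 +
       (pa$z[ia] - pb$z[ib])^2)
}

.events_same_level <- function(p, config) {
  m <- nrow(p)
  if (m < 2L) return(.empty_events())
  ev <- list()
  # bottlenecks: same triplet, opposite sides (all cross pairs per triplet)
  kt <- data.frame(idx = seq_len(m), key = p$key, side = p$side,
                   stringsAsFactors = FALSE)
  pr <- merge(kt[kt$side > 0, c("idx", "key")],
              kt[kt$side < 0, c("idx", "key")], by = "key")
  if (nrow(pr)) {
    i <- pr$idx.x; j <- pr$idx.y
    dq <- sqrt((p$qx[i] - p$qx[j])^2 + (p$qy[i] - p$qy[j])^2 +
               (p$qz[i] - p$qz[j])^2)
    keep <- p$inside_tri[i] & p$inside_tri[j] & dq <= config$proj_tol
    if (any(keep)) {
      i <- i[keep]; j <- j[keep]
      ev[[length(ev) + 1L]] <- data.frame(
        kind = "bottleneck", i = p$id[i], j = p$id[j],
        dist = .pair_dist(p, i, p, j),
        radius = pmax(p$radius[i], p$radius[j]), stringsAsFactors = FALSE)
    }
  }
  # lateral: gap <= gamma, exactly two shared atoms, mutual same-side
  cen <- as.matrix(p[, c("x", "y", "z")])
  D <- sqrt(pmax(.cross_dist2(cen, cen), 0))
  lim <- outer(p$radius, p$radius, "+") + config$gamma
  cand <- which(D <= lim & upper.tri(D), arr.ind = TRUE)
  if (nrow(cand)) {
    sh <- .shared_atoms(p, cand[, 1], cand[, 2])
    cand <- cand[sh == 2L, , drop = FALSE]
  }
  if (nrow(cand)) {
    ok <- .same_side_of(p, cand[, 1], cand[, 2]) &
          .same_side_of(p, cand[, 2], cand[, 1])
    cand <- cand[ok, , drop = FALSE]
  }
  if (nrow(cand)) {
    ev[[length(ev) + 1L]] <- data.frame(
      kind = "lateral", i = p$id[cand[, 1]], j = p$id[cand[, 2]],
      dist = D[cand], radius = pmax(p$radius[cand[, 1]], p$radius[cand[, 2]]),
      stringsAsFactors = FALSE)
  }
  if (!length(ev)) .empty_events() else do.call(rbind, ev)
}

.events_cross_level <- function(lo, hi, config) {
  if (nrow(lo) == 0L || nrow(hi) == 0L) return(.empty_events())
  ev <- list()
  # same-triplet pairs: radial shift (same side) or bottleneck (opposite)
  grid <- merge(data.frame(i = seq_len(nrow(lo)), key = lo$key,
                           stringsAsFactors = FALSE),
                data.frame(j = seq_len(nrow(hi)), key = hi$key,
                           stringsAsFactors = FALSE), by = "key")
  if (nrow(grid)) {
    i <- grid$i; j <- grid$j
    d <- .pair_dist(lo, i, hi, j)
    same <- lo$side[i] == hi$side[j]
    if (any(same)) {
      ev[[length(ev) + 1L]] <- data.frame(
        kind = "radial_shift", i = lo$id[i[same]], j = hi$id[j[same]],
        dist = d[same], radius = hi$radius[j[same]],
        stringsAsFactors = FALSE)
    }
    opp <- !same & lo$inside_tri[i] & hi$inside_tri[j]
    if (any(opp)) {
      io <- i[opp]; jo <- j[opp]
      dq <- sqrt((lo$qx[io] - hi$qx[jo])^2 + (lo$qy[io] - hi$qy[jo])^2 +
                 (lo$qz[io] - hi$qz[jo])^2)
      keep <- dq <= config$proj_tol
      if (any(keep)) {
        ev[[length(ev) + 1L]] <- data.frame(
          kind = "bottleneck", i = lo$id[io[keep]], j = hi$id[jo[keep]],
          dist = d[opp][keep], radius = hi$radius[jo[keep]],
          stringsAsFactors = FALSE)
      }
    }
  }
  # pyramidal: different triplet, gap <= beta
  D <- sqrt(pmax(.cross_dist2(as.matrix(lo[, c("x", "y", "z")]),
                              as.matrix(hi[, c("x", "y", "z")])), 0))
  lim <- outer(lo$radius, hi$radius, "+") + config$beta
  cand <- which(D <= lim, arr.ind = TRUE)
  if (nrow(cand)) {
    diff_key <- lo$key[cand[, 1]] != hi$key[cand[, 2]]
    cand <- cand[diff_key, , drop = FALSE]
  }
  if (nrow(cand)) {
    ev[[length(ev) + 1L]] <- data.frame(
      kind = "pyramidal", i = lo$id[cand[, 1]], j = hi$id[cand[, 2]],
      dist = D[cand], radius = hi$radius[cand[, 2]],
      stringsAsFactors = FALSE)
  }
  if (!length(ev)) .empty_events() else do.call(rbind, ev)
}

# order events by ascending distance, ties by (i, j)
.sort_events <- function(ev) ev[order(ev$dist, ev$i, ev$j), , drop = FALSE]

#' Run the hierarchical clustering over a probe series
#'
#' Per ladder level: same-radius bottlenecks, then lateral aggregation;
#' then, between the level and the next: cross-level bottlenecks, then
#' pyramidal aggregation and radial shifts, each pass processing candidate
#' pairs in ascending distance order. Merges are union-find over cluster
#' nodes; each merge creates an internal tree node recording the event.
#' Bottleneck events between probes already in one cluster are recorded on
#' the cluster's current top node.
#'
#' @param series A `pp_probe_series`.
#' @param config A [clustering_config()].
#' @return Object of class `pp_cluster_tree`.
#' @export
run_hierarchical_clustering <- function(series, config = clustering_config()) {
  probes <- series$probes
  n <- if (is.null(probes)) 0L else nrow(probes)
  if (n == 0L) {
    return(structure(list(probes = .empty_probes(), n_leaves = 0L,
                          nodes = NULL, roots = integer(0),
                          chains = NULL, config = config),
                     class = "pp_cluster_tree"))
  }
  stopifnot(identical(probes$id, seq_len(n)))
  maxn <- 2L * n
  nd_left <- integer(maxn); nd_right <- integer(maxn)
  nd_kind <- character(maxn); nd_radius <- numeric(maxn)
  nd_size_l <- integer(maxn); nd_size_r <- integer(maxn)
  nd_parent <- integer(maxn)
  n_nodes <- n                      # leaves are nodes 1..n (probe ids)
  uf <- seq_len(n)                  # union-find over probes
  top <- seq_len(n)                 # top node of the cluster rooted at probe r
  csize <- rep(1L, n)
  uf_find <- function(i) {
    r <- i
    while (uf[r] != r) r <- uf[r]
    while (uf[i] != r) { nxt <- uf[i]; uf[i] <<- r; i <- nxt }
    r
  }
  extra_bn <- list()
  apply_events <- function(ev) {
    ev_i <- ev$i; ev_j <- ev$j; ev_kind <- ev$kind; ev_radius <- ev$radius
    for (r in seq_along(ev_i)) {
      ri <- uf_find(ev_i[r]); rj <- uf_find(ev_j[r])
      if (ri == rj) {
        if (ev_kind[r] == "bottleneck") {
          extra_bn[[length(extra_bn) + 1L]] <<-
            c(node = top[ri], radius = ev_radius[r])
        }
        next
      }
      k <- n_nodes + 1L; n_nodes <<- k
      nd_left[k] <<- top[ri]; nd_right[k] <<- top[rj]
      nd_kind[k] <<- ev_kind[r]; nd_radius[k] <<- ev_radius[r]
      nd_size_l[k] <<- csize[ri]; nd_size_r[k] <<- csize[rj]
      nd_parent[top[ri]] <<- k; nd_parent[top[rj]] <<- k
      # deterministic union: larger cluster wins, ties to smaller root id
      if (csize[ri] < csize[rj] || (csize[ri] == csize[rj] && rj < ri)) {
        tmp <- ri; ri <- rj; rj <- tmp
      }
      uf[rj] <<- ri
      csize[ri] <<- csize[ri] + csize[rj]
      top[ri] <<- k
    }
  }
  L <- length(series$levels)
  for (l in seq_len(L)) {
    p_lo <- series$levels[[l]]
    if (nrow(p_lo) > 1L) {
      ev <- .events_same_level(p_lo, config)
      if (nrow(ev)) {
        apply_events(.sort_events(ev[ev$kind == "bottleneck", , drop = FALSE]))
        apply_events(.sort_events(ev[ev$kind == "lateral", , drop = FALSE]))
      }
    }
    if (l < L) {
      p_hi <- series$levels[[l + 1L]]
      if (nrow(p_lo) && nrow(p_hi)) {
        ev <- .events_cross_level(p_lo, p_hi, config)
        if (nrow(ev)) {
          apply_events(.sort_events(ev[ev$kind == "bottleneck", , drop = FALSE]))
          apply_events(.sort_events(ev[ev$kind != "bottleneck", , drop = FALSE]))
        }
      }
    }
  }
  roots <- unique(top[vapply(seq_len(n), uf_find, 1L)])
  nodes <- list(left = nd_left[seq_len(n_nodes)],
                right = nd_right[seq_len(n_nodes)],
                kind = nd_kind[seq_len(n_nodes)],
                radius = nd_radius[seq_len(n_nodes)],
                size_l = nd_size_l[seq_len(n_nodes)],
                size_r = nd_size_r[seq_len(n_nodes)],
                parent = nd_parent[seq_len(n_nodes)])
  bn <- if (length(extra_bn)) {
    data.frame(node = vapply(extra_bn, `[[`, 1, "node"),
               radius = vapply(extra_bn, `[[`, 1, "radius"))
  } else data.frame(node = integer(0), radius = numeric(0))
  chains <- .build_chains(probes)
  structure(list(probes = probes, n_leaves = n, nodes = nodes,
                 roots = roots, extra_bottlenecks = bn, chains = chains,
                 config = config),
            class = "pp_cluster_tree")
}

#' @export
print.pp_cluster_tree <- function(x, ...) {
  cat(sprintf("<pp_cluster_tree> %d probes, %d roots, %d chains\n",
              x$n_leaves, length(x$roots),
              if (is.null(x$chains)) 0L else nrow(x$chains)))
  invisible(x)
}

# Radial-shift chains: maximal runs of probes over consecutive levels with a
# fixed triplet and side. Depth index = number of probes in the run.
.build_chains <- function(probes) {
  grp <- paste(probes$key, probes$side)
  spl <- split(seq_len(nrow(probes)), grp)
  out <- list()
  for (g in spl) {
    g <- g[order(probes$level[g])]
    lv <- probes$level[g]
    run_id <- cumsum(c(1L, diff(lv) != 1L))
    for (rid in unique(run_id)) {
      run <- g[run_id == rid]
      term <- run[length(run)]
      out[[length(out) + 1L]] <- data.frame(
        key = probes$key[term], side = probes$side[term],
        depth = length(run), terminal_probe = probes$id[term],
        terminal_radius = probes$radius[term],
        level_start = probes$level[run[1]], level_end = probes$level[term],
        stringsAsFactors = FALSE)
      out[[length(out)]]$members <- I(list(probes$id[run]))
    }
  }
  ch <- do.call(rbind, out)
  if (is.null(ch)) {
    ch <- data.frame(key = character(0), side = integer(0), depth = integer(0),
                     terminal_probe = integer(0), terminal_radius = numeric(0),
                     level_start = integer(0), level_end = integer(0))
    ch$members <- I(list())
  }
  rownames(ch) <- NULL
  ch$chain_id <- seq_len(nrow(ch))
  ch
}

# node depths (root = 0); parents always have larger ids than children
.node_depths <- function(tree) {
  K <- length(tree$nodes$parent)
  depth <- integer(K)
  for (k in K:1) {
    p <- tree$nodes$parent[k]
    depth[k] <- if (p == 0L) 0L else depth[p] + 1L
  }
  depth
}

.lca <- function(tree, depth, a, b) {
  while (a != b) {
    if (depth[a] >= depth[b]) a <- tree$nodes$parent[a]
    else b <- tree$nodes$parent[b]
    if (a == 0L || b == 0L) return(0L)
  }
  a
}

# minimal node containing a set of leaves
.containing_node <- function(tree, depth, leaves) {
  Reduce(function(a, b) .lca(tree, depth, a, b), leaves)
}

# leaves (probe ids) in the subtree of a node
.subtree_leaves <- function(tree, node) {
  n <- tree$n_leaves
  stack <- node
  out <- integer(0)
  while (length(stack)) {
    k <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (k <= n) out <- c(out, k)
    else stack <- c(stack, tree$nodes$left[k], tree$nodes$right[k])
  }
  sort(out)
}

# internal nodes in the subtree of a node
.subtree_internal <- function(tree, node) {
  n <- tree$n_leaves
  stack <- node
  out <- integer(0)
  while (length(stack)) {
    k <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (k > n) {
      out <- c(out, k)
      stack <- c(stack, tree$nodes$left[k], tree$nodes$right[k])
    }
  }
  out
}

#' Extract pockets and subpockets from a cluster tree
#'
#' A node qualifies as a (conventional) pocket if it holds at least
#' `size_threshold` probes and contains at least one radial-shift chain of
#' depth at least `align_threshold` (a pseudo-mouth). Pockets are the
#' qualifying cluster roots; subpockets are the minimal descendant nodes
#' that also qualify. A pocket owning one or more subpockets is a master.
#'
#' @param tree A `pp_cluster_tree`.
#' @param config A [clustering_config()] (defaults to the tree's own).
#' @return List of `pp_pocket` objects, largest first. Each has `members`
#'   (probe ids), `probes`, `tangent_atoms`, `chains`, `persistence`,
#'   `aggregation` (data frame), `bottleneck_radii`, `entrances`, `buried`,
#'   `subpockets`, `is_master`, `is_subpocket`, `size`.
#' @export
extract_pockets_subpockets <- function(tree, config = tree$config) {
  if (tree$n_leaves == 0L) return(list())
  n <- tree$n_leaves
  K <- length(tree$nodes$parent)
  depth <- .node_depths(tree)
  chains <- tree$chains
  sig <- chains[chains$depth >= config$align_threshold, , drop = FALSE]
  sig$node <- if (nrow(sig)) {
    vapply(sig$members, function(m) .containing_node(tree, depth, m), 1L)
  } else integer(0)
  # bottom-up totals: subtree size and significant-chain count
  # (children always have smaller node ids than their parent)
  size <- c(rep(1L, n), integer(K - n))
  if (K > n) {
    for (k in (n + 1L):K) {
      size[k] <- size[tree$nodes$left[k]] + size[tree$nodes$right[k]]
    }
  }
  nsig <- integer(K)
  if (nrow(sig)) for (nd in sig$node) nsig[nd] <- nsig[nd] + 1L
  nsig_tot <- nsig
  for (k in seq_len(K)) {
    p <- tree$nodes$parent[k]
    if (p > 0L) nsig_tot[p] <- nsig_tot[p] + nsig_tot[k]
  }
  qualified <- size >= config$size_threshold & nsig_tot >= 1L
  qual_tot <- as.integer(qualified)
  for (k in seq_len(K)) {
    p <- tree$nodes$parent[k]
    if (p > 0L) qual_tot[p] <- qual_tot[p] + qual_tot[k]
  }
  minimal <- qualified & (qual_tot == 1L)
  pockets <- list()
  for (root in tree$roots) {
    if (!qualified[root]) next
    sub_nodes <- setdiff(which(minimal)[vapply(which(minimal), function(k) {
      # is k in the subtree of root?
      while (k != 0L && k != root) k <- tree$nodes$parent[k]
      k == root
    }, logical(1))], root)
    pk <- .make_pocket(tree, root, config, sig, is_subpocket = FALSE)
    pk$subpockets <- lapply(sub_nodes, function(nd) {
      sp <- .make_pocket(tree, nd, config, sig, is_subpocket = TRUE)
      sp$parent_node <- root
      sp
    })
    pk$is_master <- length(pk$subpockets) > 0L
    pockets[[length(pockets) + 1L]] <- pk
  }
  pockets[order(-vapply(pockets, function(p) p$size, 1))]
}

.make_pocket <- function(tree, node, config, sig, is_subpocket = FALSE) {
  members <- .subtree_leaves(tree, node)
  pr <- tree$probes[members, , drop = FALSE]
  internal <- .subtree_internal(tree, node)
  kinds <- tree$nodes$kind[internal]
  agg_sel <- internal[kinds %in% c("lateral", "pyramidal")]
  aggregation <- data.frame(radius = tree$nodes$radius[agg_sel],
                            size_l = tree$nodes$size_l[agg_sel],
                            size_r = tree$nodes$size_r[agg_sel])
  bn_radii <- tree$nodes$radius[internal[kinds == "bottleneck"]]
  xb <- tree$extra_bottlenecks
  if (nrow(xb)) {
    bn_radii <- c(bn_radii, xb$radius[xb$node %in% c(node, internal)])
  }
  in_sub <- if (nrow(sig)) sig$node %in% c(node, internal) else logical(0)
  my_chains <- sig[in_sub, , drop = FALSE]
  pk <- structure(list(
    node = node, members = members, probes = pr, size = length(members),
    tangent_atoms = sort(unique(c(pr$a1, pr$a2, pr$a3))),
    chains = my_chains, persistence = my_chains$depth,
    aggregation = aggregation, bottleneck_radii = bn_radii,
    is_subpocket = is_subpocket, subpockets = list(), is_master = FALSE
  ), class = "pp_pocket")
  ent <- detect_entrances(pk, config)
  pk$entrances <- ent$entrances
  pk$buried <- ent$buried
  pk
}

#' @export
print.pp_pocket <- function(x, ...) {
  cat(sprintf(
    "<pp_pocket>%s %d probes, %d entrance(s)%s, %d subpocket(s), %d tangent atoms\n",
    if (x$is_subpocket) " [subpocket]" else "", x$size,
    length(x$entrances), if (x$buried) " (buried)" else "",
    length(x$subpockets), length(x$tangent_atoms)))
  invisible(x)
}

#' Detect pocket entrances
#'
#' Terminal probes of significant chains (depth at least `align_threshold`)
#' with radius above `entrance_radius_min` are single-linkage clustered
#' with the power-distance orthogonality rule (probes linked when
#' `d^2 <= r_i^2 + r_j^2`). Each entrance records the arithmetic mean of
#' member centers, an effective radius (mean center-to-center distance plus
#' mean member radius), the average chain depth index, and the terminal
#' probes' mean outward normal. A pocket with no qualifying terminal probe
#' is buried; a subpocket is buried when its largest terminal radius is
#' below `buried_radius`.
#'
#' @param pocket A `pp_pocket`.
#' @param config A [clustering_config()].
#' @return List with `entrances` (list of `pp_entrance`) and `buried` flag.
#' @export
detect_entrances <- function(pocket, config = clustering_config()) {
  ch <- pocket$chains
  if (is.null(ch) || nrow(ch) == 0L) {
    return(list(entrances = list(), buried = TRUE))
  }
  term_r <- ch$terminal_radius
  qual <- which(term_r > config$entrance_radius_min)
  buried <- if (pocket$is_subpocket) {
    max(term_r) < config$buried_radius
  } else length(qual) == 0L
  if (!length(qual)) return(list(entrances = list(), buried = buried))
  tp <- match(ch$terminal_probe[qual], pocket$probes$id)
  P <- pocket$probes[tp, , drop = FALSE]
  m <- nrow(P)
  comp <- seq_len(m)
  if (m > 1L) {
    cen <- as.matrix(P[, c("x", "y", "z")])
    d2 <- .cross_dist2(cen, cen)
    lim <- outer(P$radius^2, P$radius^2, "+")
    link <- which(d2 <= lim & upper.tri(d2), arr.ind = TRUE)
    for (r in seq_len(nrow(link))) {
      a <- comp[link[r, 1]]; b <- comp[link[r, 2]]
      if (a != b) comp[comp == b] <- a
    }
  }
  entrances <- lapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    cen <- as.matrix(P[idx, c("x", "y", "z"), drop = FALSE])
    ctr <- colMeans(cen)
    eff <- mean(sqrt(colSums((t(cen) - ctr)^2))) + mean(P$radius[idx])
    nrm <- colSums(cbind(P$nx[idx] * P$side[idx], P$ny[idx] * P$side[idx],
                         P$nz[idx] * P$side[idx]))
    nn <- sqrt(sum(nrm^2))
    structure(list(center = ctr, effective_radius = eff,
                   avg_depth_index = mean(ch$depth[qual][idx]),
                   member_terminal_probes = P$id[idx],
                   normal = if (nn > 0) nrm / nn else c(0, 0, 1)),
              class = "pp_entrance")
  })
  list(entrances = entrances, buried = buried)
}

#' Export a pocket's member probes and tangent atoms
#' @param pocket A `pp_pocket`.
#' @param structure The `pp_structure`.
#' @param prefix Output path prefix; writes `<prefix>_probes.tsv` and
#'   `<prefix>_atoms.tsv`.
#' @export
write_pocket <- function(pocket, structure, prefix) {
  write_probes(pocket$probes, paste0(prefix, "_probes.tsv"))
  a <- structure$atoms[pocket$tangent_atoms, , drop = FALSE]
  utils::write.table(a[, c("index", "elety", "resid", "chain", "resno")],
                     paste0(prefix, "_atoms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
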
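# Independent scalar re-implementation of the pairwise clustering-event
# predicate, used to validate the union-find engine by transitive closure.

brute_event <- function(p, i, j, config) {
  dl <- p$level[j] - p$level[i]
  if (abs(dl) > 1) return(FALSE)
  if (dl < 0) { tmp <- i; i <- j; j <- tmp; dl <- -dl }
  d <- sqrt((p$x[i] - p$x[j])^2 + (p$y[i] - p$y[j])^2 +
            (p$z[i] - p$z[j])^2)
  dq <- sqrt((p$qx[i] - p$qx[j])^2 + (p$qy[i] - p$qy[j])^2 +
             (p$qz[i] - p$qz[j])^2)
  same_key <- p$key[i] == p$key[j]
  shared <- length(intersect(c(p$a1[i], p$a2[i], p$a3[i]),
                             c(p$a1[j], p$a2[j], p$a3[j])))
  side_of <- function(a, b) {   # is b's center on a's probe side of a's plane?
    dn <- (p$x[b] - p$px[a]) * p$nx[a] + (p$y[b] - p$py[a]) * p$ny[a] +
      (p$z[b] - p$pz[a]) * p$nz[a]
    sign(dn) == p$side[a]
  }
  if (dl == 0) {
    if (same_key && p$side[i] != p$side[j]) {
      return(p$inside_tri[i] && p$inside_tri[j] && dq <= config$proj_tol)
    }
    if (!same_key && shared == 2) {
      return(d - (p$radius[i] + p$radius[j]) <= config$gamma &&
             side_of(i, j) && side_of(j, i))
    }
    return(FALSE)
  }
  if (same_key) {
    if (p$side[i] == p$side[j]) return(TRUE)              # radial shift
    return(p$inside_tri[i] && p$inside_tri[j] && dq <= config$proj_tol)
  }
  d - (p$radius[i] + p$radius[j]) <= config$beta          # pyramidal
}

# run the engine and the exhaustive closure on a <=200-probe fixture and
# compare the partitions; cached because both the unit and the acceptance
# suites consume it
partition_equality_check <- function() {
  cached("partition_check", {
    set.seed(17)
    pts <- matrix(stats::runif(45, 0, 9), ncol = 3)
    st <- mk_struct(pts[, 1], pts[, 2], pts[, 3], radius = 1.3)
    series <- build_probe_series(st, radius_ladder(1.4, 1.8, 0.1))
    p <- series$probes
    n <- nrow(p)
    cfg <- clustering_config()
    tree <- run_hierarchical_clustering(series, cfg)
    comp <- seq_len(n)
    find <- function(a) { while (comp[a] != a) a <- comp[a]; a }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (brute_event(p, i, j, cfg)) {
        ra <- find(i); rb <- find(j)
        if (ra != rb) comp[rb] <- ra
      }
    }
    brute_groups <- vapply(seq_len(n), find, 1L)
    tree_groups <- integer(n)
    for (r in seq_along(tree$roots)) {
      tree_groups[probepocket:::.subtree_leaves(tree, tree$roots[r])] <- r
    }
    tab <- table(brute_groups, tree_groups)
    list(n = n,
         n_brute = length(unique(brute_groups)),
         n_tree = length(unique(tree_groups)),
         bijective = all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  })
}
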
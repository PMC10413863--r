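test_that("opposed probes on one triplet give a single bottleneck event", {
  st <- mk_triplet_struct()
  pr <- enumerate_probes(st, 1.4, level = 1L)
  ev <- detect_events(pr)
  bn <- ev[ev$kind == "bottleneck", ]
  expect_equal(nrow(bn), 1)
  expect_setequal(c(bn$i, bn$j), pr$id)
})

test_that("mixed levels in one probe list violate the contract", {
  st <- mk_triplet_struct()
  p1 <- enumerate_probes(st, 1.4, level = 1L)
  p2 <- enumerate_probes(st, 1.5, level = 2L)
  expect_error(detect_events(rbind(p1, p2)), "contract violation")
  expect_error(detect_events(p1, p1), "contract violation")
})

test_that("same-triplet probes across consecutive levels chain radially", {
  st <- mk_triplet_struct(blocker_z = 2.0)
  lad <- radius_ladder(1.4, 1.8, 0.1)           # 5 levels
  series <- build_probe_series(st, lad)
  tree <- run_hierarchical_clustering(series)
  ch <- tree$chains[tree$chains$key == "1-2-3", ]
  expect_equal(max(ch$depth), 5)                # one run over all 5 levels
  expect_equal(ch$terminal_radius[which.max(ch$depth)], 1.8)
})

test_that("a single probe produces no events", {
  st <- mk_triplet_struct(blocker_z = 2.0)
  pr <- enumerate_probes(st, 1.4, level = 1L)
  pr <- pr[pr$key == "1-2-3", ]
  expect_equal(nrow(detect_events(pr)), 0)
})

test_that("disjoint probe clouds stay separate, a pyramidal bridge unites them", {
  cloudA <- mk_probes(1, 1.4, rbind(c(0, 0, 1), c(0, 0, -1)),
                      key = "1-2-3", side = c(1L, -1L))
  cloudB <- mk_probes(1, 1.4, rbind(c(6, 0, 1), c(6, 0, -1)),
                      key = "4-5-6", side = c(1L, -1L))
  lvl1 <- rbind(cloudA, cloudB)
  empty <- lvl1[0, ]
  series <- mk_series(list(lvl1, empty), radius_ladder(1.4, 1.5, 0.1))
  tree <- run_hierarchical_clustering(series)
  expect_length(tree$roots, 2)
  # add a level-2 probe within beta of both clouds
  bridge <- mk_probes(2, 1.5, c(2.9, 0, 0), key = "7-8-9")
  series2 <- mk_series(list(lvl1, bridge), radius_ladder(1.4, 1.5, 0.1))
  tree2 <- run_hierarchical_clustering(series2)
  expect_length(tree2$roots, 1)
  pk <- extract_pockets_subpockets(tree2, clustering_config(
    size_threshold = 1L, align_threshold = 1L))
  agg <- pk[[1]]$aggregation
  expect_equal(nrow(agg), 2)     # two pyramidal merges, sizes before each
  expect_setequal(agg$size_l + agg$size_r, c(3, 5))
})

test_that("every probe belongs to exactly one root (member conservation)", {
  det <- small_shell_detection()
  tree <- det$tree
  all_members <- unlist(lapply(tree$roots, function(r) {
    probepocket:::.subtree_leaves(tree, r)
  }))
  expect_equal(sort(all_members), seq_len(tree$n_leaves))
})

test_that("pyramidal event count is non-decreasing in beta", {
  set.seed(21)
  lo <- mk_probes(1, 1.4, matrix(stats::runif(45, 0, 10), ncol = 3),
                  key = sprintf("%d-%d-%d", 1:15, 16:30, 31:45))
  hi <- mk_probes(2, 1.5, matrix(stats::runif(45, 0, 10), ncol = 3),
                  key = sprintf("%d-%d-%d", 46:60, 61:75, 76:90))
  counts <- vapply(c(0, 0.3, 0.6, 0.9, 1.5), function(b) {
    ev <- detect_events(lo, hi, clustering_config(beta = b))
    sum(ev$kind == "pyramidal")
  }, 1L)
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[5], counts[1])
})

test_that("pocket qualification needs both size and a significant chain", {
  st <- mk_triplet_struct(blocker_z = 2.0)
  lad <- radius_ladder(2.0, 2.3, 0.1)       # 4 levels, one probe each
  series <- build_probe_series(st, lad)
  keep <- series$probes$key == "1-2-3"
  series$levels <- lapply(series$levels, function(l) l[l$key == "1-2-3", ])
  series$probes <- series$probes[keep, , drop = FALSE]
  series$probes$id <- seq_len(nrow(series$probes))
  for (l in seq_along(series$levels)) {
    series$levels[[l]]$id <- which(series$probes$level == l)
  }
  tree <- run_hierarchical_clustering(series)
  expect_length(tree$roots, 1)
  # size 4, chain depth 4: qualifies at the matching thresholds
  pk <- extract_pockets_subpockets(tree, clustering_config(
    size_threshold = 4L, align_threshold = 4L))
  expect_length(pk, 1)
  expect_equal(pk[[1]]$size, 4)
  # one probe short of the size threshold: no pocket
  expect_length(extract_pockets_subpockets(tree, clustering_config(
    size_threshold = 5L, align_threshold = 4L)), 0)
  # alignment one deeper than available: no pocket
  expect_length(extract_pockets_subpockets(tree, clustering_config(
    size_threshold = 4L, align_threshold = 5L)), 0)
})

test_that("a master holding two disjoint qualifying descendants has 2 subpockets", {
  chainA <- rbind(mk_probes(1, 1.4, c(0, 0, 0), key = "1-2-3"),
                  mk_probes(2, 1.5, c(0, 0, 0.1), key = "1-2-3"))
  chainB <- rbind(mk_probes(1, 1.4, c(7, 0, 0), key = "4-5-6"),
                  mk_probes(2, 1.5, c(7, 0, 0.1), key = "4-5-6"))
  bridge <- mk_probes(3, 1.6, c(3.5, 0, 0.1), key = "7-8-9")
  lvl <- function(l, df) df[df$level == l, ]
  all_pr <- rbind(chainA, chainB, bridge)
  series <- mk_series(list(lvl(1, all_pr), lvl(2, all_pr), lvl(3, all_pr)),
                      radius_ladder(1.4, 1.6, 0.1))
  tree <- run_hierarchical_clustering(series)
  expect_length(tree$roots, 1)
  cfg <- clustering_config(size_threshold = 2L, align_threshold = 2L)
  pk <- extract_pockets_subpockets(tree, cfg)
  expect_length(pk, 1)
  expect_true(pk[[1]]$is_master)
  expect_length(pk[[1]]$subpockets, 2)
  sizes <- vapply(pk[[1]]$subpockets, function(s) s$size, 1L)
  expect_equal(sort(sizes), c(2L, 2L))
  # subpocket members are subsets of the master's members
  for (sp in pk[[1]]$subpockets) {
    expect_true(all(sp$members %in% pk[[1]]$members))
  }
})

test_that("entrance grouping follows the power-distance rule", {
  cfg <- clustering_config()
  two_probe_pocket <- function(d) {
    pr <- mk_probes(1, 2.5, rbind(c(0, 0, 0), c(d, 0, 0)), key = "1-2-3")
    pr$id <- 1:2
    mk_pocket(probes = pr, chains = mk_chains(c(5, 5), 1:2, c(2.5, 2.5)))
  }
  # d^2 = 9 <= 2.5^2 + 2.5^2: one entrance
  ent <- detect_entrances(two_probe_pocket(3.0), cfg)
  expect_length(ent$entrances, 1)
  e <- ent$entrances[[1]]
  expect_equal(e$center, c(x = 1.5, y = 0, z = 0), ignore_attr = TRUE)
  expect_equal(e$effective_radius, 1.5 + 2.5)
  expect_equal(e$avg_depth_index, 5)
  # d^2 = 16 > 12.5: two entrances
  ent2 <- detect_entrances(two_probe_pocket(4.0), cfg)
  expect_length(ent2$entrances, 2)
})

test_that("singleton and sub-threshold terminals set entrance and buried flags", {
  cfg <- clustering_config()
  pr <- mk_probes(1, 2.5, c(0, 0, 0), key = "1-2-3")
  pr$id <- 1L
  pk <- mk_pocket(probes = pr, chains = mk_chains(6, 1L, 2.5))
  ent <- detect_entrances(pk, cfg)
  expect_length(ent$entrances, 1)
  expect_equal(ent$entrances[[1]]$effective_radius, 2.5)
  expect_equal(ent$entrances[[1]]$avg_depth_index, 6)
  expect_false(ent$buried)
  # all terminal radii at or below 2.4: buried, no entrances
  pr2 <- mk_probes(1, 2.4, c(0, 0, 0), key = "1-2-3")
  pr2$id <- 1L
  pk2 <- mk_pocket(probes = pr2, chains = mk_chains(6, 1L, 2.4))
  ent2 <- detect_entrances(pk2, cfg)
  expect_length(ent2$entrances, 0)
  expect_true(ent2$buried)
  # subpocket with terminal radius between the two constants:
  # entrance exists but the subpocket still counts as buried
  pr3 <- mk_probes(1, 2.45, c(0, 0, 0), key = "1-2-3")
  pr3$id <- 1L
  pk3 <- mk_pocket(probes = pr3, chains = mk_chains(6, 1L, 2.45),
                   is_subpocket = TRUE)
  ent3 <- detect_entrances(pk3, cfg)
  expect_length(ent3$entrances, 1)
  expect_true(ent3$buried)
})

test_that("clustering partition equals the transitive closure of the pair predicate", {
  chk <- partition_equality_check()
  expect_gt(chk$n, 20)
  expect_lte(chk$n, 200)
  expect_equal(chk$n_brute, chk$n_tree)
  expect_true(chk$bijective)
})
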
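xyz <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)

test_that("the whole protein as a pocket always reaches full ligand coverage", {
  set.seed(19)
  prot <- matrix(stats::runif(90, 0, 12), ncol = 3)
  lig <- prot[4, , drop = FALSE] + 2              # guaranteed contact
  cs <- coverage_scores(prot, lig, prot)
  expect_equal(cs$lc, 100)
  expect_false(cs$undefined)
})

test_that("line fixture scores match a brute-force distance audit", {
  # ligand at x = 0; protein atoms at 3, 4.9, 6; pocket = atoms at 3 and 6
  prot <- xyz(3, 0, 0, 4.9, 0, 0, 6, 0, 0)
  lig <- xyz(0, 0, 0)
  pock <- xyz(3, 0, 0, 6, 0, 0)
  cs <- coverage_scores(pock, lig, prot)
  expect_equal(cs$lc, 100)        # the one ligand atom touches the pocket
  expect_equal(cs$pc, 50)         # only the atom at 3 is within 5
})

test_that("a pocket far from the ligand scores zero on both metrics", {
  prot <- xyz(0, 0, 0, 50, 0, 0)
  cs <- coverage_scores(xyz(50, 0, 0), xyz(1, 0, 0), prot)
  expect_equal(cs$lc, 0)
  expect_equal(cs$pc, 0)
})

test_that("percentages are rounded up at 0.1% resolution", {
  # 1 of 3 pocket atoms in contact: PC = 33.333... -> 33.4
  prot <- xyz(1, 0, 0, 20, 0, 0, 30, 0, 0)
  cs <- coverage_scores(prot, xyz(0, 0, 0), prot)
  expect_equal(cs$pc, 33.4)
})

test_that("undefined LC is flagged when the ligand contacts no protein atom", {
  prot <- xyz(0, 0, 0)
  cs <- coverage_scores(prot, xyz(100, 0, 0), prot)
  expect_true(cs$undefined)
  expect_true(is.na(cs$lc))
})

test_that("residue mode scores set overlaps of residue ids", {
  site <- c("A:1", "A:2", "A:3", "A:4")
  pock <- c("A:3", "A:4", "A:9")
  cs <- coverage_scores(pock, site, mode = "residue")
  expect_equal(cs$lc, 50)
  expect_equal(cs$pc, 66.7)       # 2/3 rounded up at 0.1
})

test_that("coverage symmetry: PC equals LC with the roles swapped", {
  set.seed(23)
  for (rep in 1:5) {
    P <- matrix(stats::runif(30, 0, 15), ncol = 3)
    L <- matrix(stats::runif(12, 0, 15), ncol = 3)
    pc <- coverage_scores(P, L, P)$pc
    # as LC: "ligand" = pocket atoms, pocket = ligand, protein = the
    # pocket itself so every unit counts in the normalization
    lc_swapped <- coverage_scores(L, P, P)$lc
    expect_equal(pc, lc_swapped)
  }
})

test_that("LC grows and PC shrinks as far atoms join the pocket", {
  set.seed(29)
  prot <- rbind(matrix(stats::runif(60, 0, 10), ncol = 3),
                matrix(stats::runif(30, 40, 50), ncol = 3))
  lig <- xyz(5, 5, 5)
  near <- prot[1:5, , drop = FALSE]
  more <- prot[1:25, , drop = FALSE]        # supersets including far atoms
  all_p <- prot
  lcs <- vapply(list(near, more, all_p),
                function(p) coverage_scores(p, lig, prot)$lc, 1)
  pcs <- vapply(list(near, more, all_p),
                function(p) coverage_scores(p, lig, prot)$pc, 1)
  expect_true(all(diff(lcs) >= 0))
  expect_true(all(diff(pcs) <= 0))
})

test_that("hit thresholds are inclusive", {
  expect_true(is_hit(50.0, 20.0))
  expect_false(is_hit(49.9, 90))
  expect_false(is_hit(100, 19.9))
  expect_false(is_hit(NA, 50))
})

site_df <- function(hits, lc = 80, pc = 40, sub_hits = NULL) {
  d <- data.frame(pocket_id = seq_along(hits), hit = hits,
                  lc = rep_len(lc, length(hits)),
                  pc = rep_len(pc, length(hits)))
  if (!is.null(sub_hits)) d$sub_hit <- sub_hits
  d
}

test_that("rank-of-hit counts non-matching pockets above the first match", {
  s1 <- site_df(c(FALSE, TRUE, FALSE))
  sm <- protocol_summary(list(s1))
  expect_equal(unname(sm$top), c(0, 100, 100))
  s2 <- site_df(c(TRUE, FALSE))
  expect_equal(unname(protocol_summary(list(s2))$top), c(100, 100, 100))
  # two sites, hits at effective ranks 0 and 11
  s3 <- site_df(c(rep(FALSE, 11), TRUE))
  sm2 <- protocol_summary(list(s2, s3))
  expect_equal(unname(sm2$top), c(50, 50, 50))
  expect_equal(sm2$n_sites, 2)
})

test_that("top-N percentages are mutually monotone", {
  set.seed(37)
  sites <- lapply(1:20, function(i) site_df(stats::runif(15) < 0.2))
  sm <- protocol_summary(sites)
  expect_true(sm$top["top1"] <= sm$top["top3"])
  expect_true(sm$top["top3"] <= sm$top["top10"])
})

test_that("nested mode credits masters whose subpockets match", {
  s <- site_df(c(FALSE, FALSE), sub_hits = c(TRUE, FALSE))
  expect_equal(unname(protocol_summary(list(s), mode = "standard")$top),
               c(0, 0, 0))
  expect_equal(unname(protocol_summary(list(s), mode = "nested")$top),
               c(100, 100, 100))
})

test_that("raising the PC threshold never improves any top-N figure", {
  set.seed(41)
  sites_raw <- lapply(1:15, function(i) {
    data.frame(pocket_id = 1:12,
               lc = round(stats::runif(12, 30, 100), 1),
               pc = round(stats::runif(12, 5, 95), 1))
  })
  summarize_at <- function(pc_min) {
    sites <- lapply(sites_raw, function(s) {
      s$hit <- is_hit(s$lc, s$pc, 50, pc_min)
      s
    })
    protocol_summary(sites)$top
  }
  t20 <- summarize_at(20)
  t50 <- summarize_at(50)
  expect_true(all(t50 <= t20))
})

test_that("empty lists count as misses; undefined sites are excluded", {
  s_ok <- site_df(TRUE)
  sm <- protocol_summary(list(s_ok, site_df(logical(0))))
  expect_equal(unname(sm$top), c(50, 50, 50))
  s_undef <- site_df(TRUE)
  s_undef$undefined <- TRUE
  expect_warning(sm2 <- protocol_summary(list(s_ok, s_undef)),
                 "undefined LC")
  expect_equal(sm2$n_sites, 1)
  expect_equal(unname(sm2$top), c(100, 100, 100))
})

test_that("mean coverage is averaged over the successful pockets only", {
  s1 <- site_df(c(FALSE, TRUE), lc = c(10, 90), pc = c(5, 60))
  s2 <- site_df(TRUE, lc = 70, pc = 40)
  sm <- protocol_summary(list(s1, s2))
  expect_equal(sm$mean_lc, mean(c(90, 70)))
  expect_equal(sm$mean_pc, mean(c(60, 40)))
})
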
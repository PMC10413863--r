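sphere_df <- function(centers, radius) {
  centers <- matrix(centers, ncol = 3)
  data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
             radius = radius)
}

test_that("single-sphere volume and area match the analytic values", {
  g <- union_volume_area(sphere_df(c(0, 0, 0), 1.4), spacing = 0.2)
  expect_equal(g$V, 4 / 3 * pi * 1.4^3, tolerance = 0.01)   # 11.494
  expect_equal(g$A, 4 * pi * 1.4^2, tolerance = 0.002)      # 24.630
})

test_that("two-sphere union volume converges to the lens formula", {
  truth <- 9 * pi / 4                     # r = 1, d = 1
  sph <- sphere_df(rbind(c(0, 0, 0), c(1, 0, 0)), 1)
  errs <- vapply(c(0.4, 0.2, 0.1), function(h) {
    abs(union_volume_area(sph, spacing = h)$V - truth)
  }, 1)
  expect_lt(errs[2] / truth, 0.02)        # within 2% at 0.2 A
  expect_true(all(diff(errs) <= 0))       # halving the spacing improves
  # area of the same union: 8 pi - 2 * 2 pi r h with h = 1/2
  g <- union_volume_area(sph, spacing = 0.2)
  expect_equal(g$A, 6 * pi, tolerance = 0.01)
})

test_that("disjoint spheres are additive in volume and area", {
  one <- union_volume_area(sphere_df(c(0, 0, 0), 1), spacing = 0.2)
  two <- union_volume_area(sphere_df(rbind(c(0, 0, 0), c(10, 0, 0)), 1),
                           spacing = 0.2)
  expect_equal(two$V, 2 * one$V, tolerance = 0.01)
  expect_equal(two$A, 2 * one$A, tolerance = 0.001)
})

test_that("empty sphere lists are rejected", {
  expect_error(union_volume_area(sphere_df(c(0, 0, 0), 1)[0, ]), "empty")
})

test_that("sphericity matches closed forms", {
  r <- 1.7
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1,
               tolerance = 1e-12)
  expect_equal(sphericity(1, 6), (36 * pi)^(1 / 3) / 6, tolerance = 1e-12)
  expect_equal(sphericity(1, 6), 0.8060, tolerance = 1e-4)
  # two disjoint equal spheres treated as one object
  r0 <- 1
  expect_equal(sphericity(2 * 4 / 3 * pi * r0^3, 2 * 4 * pi * r0^2),
               2^(-1 / 3), tolerance = 1e-12)
  expect_error(sphericity(0, 1), "positive")
  expect_error(sphericity(1, -1), "positive")
})

test_that("clustering scores follow their normalized definitions", {
  agg <- data.frame(radius = rep(2, 10), size_l = rep(20, 10),
                    size_r = rep(30, 10))
  pk <- mk_pocket(size = 100L, persistence = c(5, 7), aggregation = agg,
                  bottleneck_radii = c(1.5, 2.5), buried = FALSE)
  fv <- geometric_features(pk, structure(list(V = 50, A = 80),
                                         class = "pp_geometry"))
  expect_equal(unname(fv["aggregation_score"]), 10 / 100)
  expect_equal(unname(fv["persistence_score"]), 12 / 100)
  expect_equal(unname(fv["clustering_score"]), 0.22)
  expect_equal(unname(fv["n_bottlenecks"]), 2)
  expect_equal(unname(fv["avg_bottleneck_radius"]), 2)
  expect_equal(unname(fv["volume_ratio"]), 0.5)
  expect_equal(unname(fv["size"]), 100)
  expect_equal(unname(fv["ramification"]), stats::sd(c(5, 7)))
})

test_that("large aggregations need both sizes above 10 and a 1:5 ratio", {
  mk <- function(size_l, size_r) {
    pk <- mk_pocket(size = 100L,
                    aggregation = data.frame(radius = 2, size_l = size_l,
                                             size_r = size_r))
    fv <- geometric_features(pk, structure(list(V = 50, A = 80),
                                           class = "pp_geometry"))
    unname(fv["large_aggregation_score"])
  }
  expect_equal(mk(50, 8), 0)        # small side not above 10
  expect_equal(mk(60, 11), 0)       # ratio 11/60 below 1/5
  expect_equal(mk(50, 12), 0.01)    # 12/50 = 0.24 >= 1/5, both > 10
  expect_equal(mk(50, 10), 0)       # boundary: 10 is not above 10
})

test_that("entrance depth at the alignment threshold scores exactly 1", {
  pr <- mk_probes(1, 2.5, c(0, 0, 0), key = "1-2-3")
  pr$id <- 1L
  pk <- mk_pocket(probes = pr, chains = mk_chains(4, 1L, 2.5),
                  persistence = 4)
  ent <- detect_entrances(pk, clustering_config())
  pk$entrances <- ent$entrances
  pk$buried <- ent$buried
  fv <- geometric_features(pk, structure(list(V = 10, A = 30),
                                         class = "pp_geometry"))
  expect_equal(unname(fv["entrance_depth_score"]), 1)
  # protrusion = depth*threshold - mean(persistence) - ramification
  expect_equal(unname(fv["protrusion"]), 4 - 4 - 0)
})

test_that("empty persistence lists zero out the derived features", {
  pk <- mk_pocket(size = 10L, buried = TRUE)
  fv <- geometric_features(pk, structure(list(V = 5, A = 20),
                                         class = "pp_geometry"))
  expect_equal(unname(fv[c("persistence_score", "ramification",
                           "entrance_depth_score", "avg_entrance_radius")]),
               c(0, 0, 0, 0))
  expect_equal(unname(fv["buried_flag"]), 1)
  expect_true(all(is.finite(fv)))
})

test_that("chemical fractions count residues once and handle glycine", {
  st <- mk_struct(1:6, resid = c("LEU", "LEU", "LEU", "LEU", "LEU", "LEU"),
                  resno = c(1, 1, 2, 2, 3, 3))
  pk <- mk_pocket(size = 1L, tangent_atoms = 1:6)
  cv <- chemical_features(pk, st)
  expect_length(cv, 22)
  expect_equal(unname(cv["frac_LEU"]), 1)
  expect_equal(sum(cv[paste0("frac_", probepocket:::.aa20)]), 1)
  expect_equal(unname(cv["hydrophobic_score"]), 1)
  # glycine participates in the normalization but in neither class
  st2 <- mk_struct(1:2, resid = c("GLY", "LEU"), resno = 1:2)
  cv2 <- chemical_features(mk_pocket(size = 1L, tangent_atoms = 1:2), st2)
  expect_equal(unname(cv2["hydrophobic_score"]), 0.5)
  expect_equal(unname(cv2["hydrophilic_score"]), 0)
  st3 <- mk_struct(1:4, resid = c("SER", "LYS", "LEU", "GLY"), resno = 1:4)
  cv3 <- chemical_features(mk_pocket(size = 1L, tangent_atoms = 1:4), st3)
  expect_equal(unname(cv3["hydrophilic_score"]), 0.5)
  expect_equal(unname(cv3["hydrophobic_score"]), 0.25)
  expect_equal(unname(cv3[c("frac_SER", "frac_LYS", "frac_LEU",
                            "frac_GLY")]), rep(0.25, 4))
})

test_that("unknown residues enter the denominator only, with a message", {
  st <- mk_struct(1:2, resid = c("LIG", "LEU"), resno = 1:2)
  expect_message(cv <- chemical_features(mk_pocket(size = 1L,
                                                   tangent_atoms = 1:2), st),
                 "unknown residue")
  expect_equal(unname(cv["frac_LEU"]), 0.5)
  expect_equal(unname(cv["hydrophobic_score"]), 0.5)
})

test_that("feature vectors from the pipeline are complete and finite", {
  det <- small_shell_detection()
  feat <- det$features
  gcols <- feature_names("geometric")
  ccols <- feature_names("chemical")
  expect_length(gcols, 17)
  expect_length(ccols, 22)
  expect_true(all(gcols %in% names(feat)))
  expect_true(all(ccols %in% names(feat)))
  expect_true(all(is.finite(as.matrix(feat[, c(gcols, ccols)]))))
  # Wadell index respects the isoperimetric bound on every computed mesh
  expect_true(all(feat$hw_index <= 1 + 1e-9))
  # residue fractions sum to one for every pocket
  expect_equal(unname(rowSums(feat[, paste0("frac_", probepocket:::.aa20)])),
               rep(1, nrow(feat)))
})

test_that("the mold mesh is exportable as OFF", {
  g <- union_volume_area(sphere_df(c(0, 0, 0), 1.4), spacing = 0.4,
                         mesh = TRUE)
  expect_gt(nrow(g$mesh$vertices), 0)
  f <- tempfile(fileext = ".off")
  write_off(g$mesh, f)
  head <- readLines(f, n = 2)
  expect_equal(head[1], "OFF")
})
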
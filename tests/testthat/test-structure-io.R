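test_that("PQR roundtrip preserves coordinates and radii", {
  st <- mk_struct(c(0, 2, 4), radius = c(1.5, 1.7, 1.2),
                  resid = c("ALA", "ALA", "GLY"), resno = c(1, 1, 2))
  f <- tempfile(fileext = ".pqr")
  write_pqr(st, f)
  rd <- read_structure(f)
  expect_equal(natoms(rd), 3)
  expect_equal(rd$atoms$radius, c(1.5, 1.7, 1.2))
  expect_equal(rd$atoms$x, c(0, 2, 4), tolerance = 1e-3)
  expect_equal(rd$atoms$resid, c("ALA", "ALA", "GLY"))
  expect_true(all(rd$atoms$is_heavy))
})

test_that("PDB reading assigns vdW radii and drops waters by default", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HEADER    TOY",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  N   ALA A   1       2.000   0.000   0.000  1.00  0.00           N",
    "ATOM      3  H   ALA A   1       2.500   0.000   0.000  1.00  0.00           H",
    "HETATM    4  O   HOH A   2       4.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  st <- read_structure(f)
  expect_equal(natoms(st), 3)               # water excluded
  expect_false("HOH" %in% st$atoms$resid)
  expect_equal(st$atoms$radius, unname(vdw_radii()[c("C", "N", "H")]))
  expect_equal(st$atoms$is_heavy, c(TRUE, TRUE, FALSE))
  st2 <- read_structure(f, keep_waters = TRUE)
  expect_equal(natoms(st2), 4)
})

test_that("empty or malformed files raise parse errors", {
  f <- tempfile()
  file.create(f)
  expect_error(read_structure(f, format = "pqr"), "parse error|no ATOM")
  writeLines("ATOM 1 C ALA", f)
  expect_error(read_structure(f, format = "pqr"), "line")
  expect_error(read_structure(tempfile(), format = "pqr"), "not found")
})

test_that("binding regions collect heavy atoms within the cutoff", {
  st <- mk_struct(c(0, 4, 6))
  lig <- matrix(c(0, 0, 0), 1)
  regs <- define_binding_regions(st, list(lig), cutoff = 5)
  expect_length(regs, 1)
  expect_equal(regs[[1]]$region_atoms, c(1L, 2L))
  # brute-force oracle over random configurations
  set.seed(7)
  for (rep in 1:5) {
    pts <- matrix(stats::runif(30, 0, 20), ncol = 3)
    st2 <- mk_struct(pts[, 1], pts[, 2], pts[, 3])
    lg <- matrix(stats::runif(6, 0, 20), ncol = 3)
    reg <- define_binding_regions(st2, list(lg), cutoff = 5)[[1]]
    brute <- which(vapply(seq_len(10), function(i) {
      any(sqrt(colSums((t(lg) - unlist(pts[i, ]))^2)) <= 5)
    }, logical(1)))
    expect_equal(reg$region_atoms, brute)
  }
})

test_that("distant ligands give empty flagged regions, not errors", {
  st <- mk_struct(c(0, 1, 2))
  lig <- matrix(c(100, 0, 0), 1)
  expect_message(regs <- define_binding_regions(st, list(lig)),
                 "empty binding region")
  expect_true(regs[[1]]$empty)
  expect_length(regs[[1]]$region_atoms, 0)
  expect_error(define_binding_regions(st, list(matrix(0, 0, 3))),
               "zero heavy atoms")
})

test_that("region size is monotone non-decreasing in the cutoff", {
  set.seed(11)
  pts <- matrix(stats::runif(60, 0, 15), ncol = 3)
  st <- mk_struct(pts[, 1], pts[, 2], pts[, 3])
  lig <- matrix(c(7, 7, 7), 1)
  sizes <- vapply(c(2, 4, 6, 8, 10), function(cut) {
    length(define_binding_regions(st, list(lig), cutoff = cut)[[1]]$region_atoms)
  }, 1L)
  expect_true(all(diff(sizes) >= 0))
})

mk_region <- function(atoms, idx) {
  structure(list(ligand_id = paste0("lig", idx), ligand_index = idx,
                 region_atoms = atoms, empty = length(atoms) == 0),
            class = "pp_binding_region")
}

test_that("deduplication removes mostly-included and high-Jaccard regions", {
  # B fully inside A: |A&B|/|B| = 100% > 50% -> B removed
  out <- deduplicate_binding_regions(list(mk_region(1:10, 1),
                                          mk_region(1:6, 2)))
  expect_equal(vapply(out, `[[`, "", "ligand_id"), "lig1")
  # symmetric 60%/60% overlap: tie broken by keeping the lower index
  out <- deduplicate_binding_regions(list(mk_region(1:10, 1),
                                          mk_region(5:14, 2)))
  expect_equal(vapply(out, `[[`, "", "ligand_id"), "lig1")
  # disjoint regions survive
  out <- deduplicate_binding_regions(list(mk_region(1:10, 1),
                                          mk_region(20:30, 2)))
  expect_length(out, 2)
})

test_that("deduplicated sets satisfy both pairwise bounds", {
  set.seed(5)
  for (rep in 1:10) {
    regs <- lapply(1:6, function(i) {
      mk_region(sort(sample.int(40, sample(5:25, 1))), i)
    })
    out <- deduplicate_binding_regions(regs)
    expect_gte(length(out), 1)
    if (length(out) > 1) {
      for (i in seq_len(length(out) - 1)) for (j in (i + 1):length(out)) {
        A <- out[[i]]$region_atoms; B <- out[[j]]$region_atoms
        inter <- length(intersect(A, B))
        expect_lte(inter / length(A), 0.5)
        expect_lte(inter / length(B), 0.5)
        expect_lt(inter / length(union(A, B)), 0.3)
      }
    }
  }
})

test_that("solvent exposure distinguishes surface from buried atoms", {
  # a single isolated atom is exposed
  st <- mk_struct(0)
  expect_equal(solvent_exposed_residues(st), "A:1")
  # 3x3x3 dense block: the central atom's residue is buried
  g <- expand.grid(x = c(-1.5, 0, 1.5), y = c(-1.5, 0, 1.5),
                   z = c(-1.5, 0, 1.5))
  resno <- ifelse(g$x == 0 & g$y == 0 & g$z == 0, 99L, 1L)
  st2 <- mk_struct(g$x, g$y, g$z, radius = 1.7, resno = resno)
  exposed <- solvent_exposed_residues(st2)
  expect_true("A:1" %in% exposed)
  expect_false("A:99" %in% exposed)
})

test_that("holo binding residues map onto a shifted apo copy", {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY")
  holo <- mk_struct(seq(0, 21, 3), resid = aa, resno = 1:8)
  # apo: same chain, renumbered residues
  apo <- mk_struct(seq(0, 21, 3), resid = aa, resno = 101:108)
  mapped <- map_apo_residues(holo, apo, c("A:2", "A:5"))
  expect_setequal(mapped, c("A:102", "A:105"))
})
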
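# Synthetic test structures with cavities of known location and shape,
# plus a two-probe grid oracle that flags pocket space independently of
# the probe engine (morphological accessibility test on a distance grid).

#' Generate a synthetic toy structure with a known cavity
#'
#' Atoms are placed on a jittered lattice forming one of four shapes:
#' `shell_with_mouth` (hollow spherical shell with a circular mouth),
#' `channel` (a cylindrical tunnel through a block, two mouths),
#' `dimpled_slab` (a slab with a hemispherical surface dimple) and
#' `convex_blob` (a solid ball, no cavity; the negative control). A
#' pseudo-ligand of a few dummy heavy atoms is placed inside the cavity
#' (on the surface, flagged `shallow`, for the blob). Dummy residue names
#' cycle through the 20 amino acids so chemical features are exercised.
#' Generation is deterministic under `seed`.
#'
#' @param kind Shape name.
#' @param atom_radius Atom radius (default 1.7 A).
#' @param lattice_spacing Lattice spacing (default 1.5 A; dense packing
#'   keeps the walls sealed and smooth at probe scale, as in a protein
#'   interior).
#' @param cavity_radius Free cavity radius (default 6 A; for the channel
#'   the free tunnel radius is half this, for the slab the dimple radius
#'   is half this).
#' @param mouth_width Free aperture width of the shell mouth (default 4 A:
#'   a water-sized probe passes, a 3 A probe does not).
#' @param jitter Uniform jitter amplitude (default 0.05 A).
#' @param seed Integer seed (default 1).
#' @return Object of class `pp_fixture`: list with `structure`
#'   (`pp_structure`), `ligand` (k x 3 matrix), `truth_region` (atom
#'   indices within 5 A of the ligand), `kind`, `shallow`.
#' @export
make_structure <- function(kind = c("shell_with_mouth", "channel",
                                    "dimpled_slab", "convex_blob"),
                           atom_radius = 1.7, lattice_spacing = 1.5,
                           cavity_radius = 6, mouth_width = 4,
                           jitter = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(atom_radius > 0, lattice_spacing > 0, cavity_radius > 0,
            mouth_width > 0)
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)
  shallow <- FALSE
  if (kind == "shell_with_mouth") {
    Rc <- cavity_radius + atom_radius
    hole <- mouth_width / 2 + atom_radius   # mouth_width is the free aperture
    if (hole >= Rc) stop("mouth wider than the shell")
    n <- max(12L, round(4 * pi * Rc^2 / lattice_spacing^2))
    pts <- .fibonacci_sphere(n) * Rc
    theta_mouth <- asin(pmin(1, hole / Rc))
    ang <- acos(pmin(1, pmax(-1, pts[, 3] / Rc)))
    pts <- pts[ang > theta_mouth, , drop = FALSE]   # mouth at +z
    # ligand near the cavity floor (opposite the mouth), in wall contact
    lig <- .tetrahedron(1.0) +
      matrix(c(0, 0, -(cavity_radius - 2)), 4, 3, byrow = TRUE)
  } else if (kind == "channel") {
    half <- max(6, cavity_radius)
    g <- seq(-half, half, by = lattice_spacing)
    pts <- as.matrix(expand.grid(x = g, y = g, z = g))
    tube <- cavity_radius / 2 + atom_radius
    pts <- pts[sqrt(pts[, 1]^2 + pts[, 2]^2) >= tube, , drop = FALSE]
    lig <- cbind(0, 0, c(-1.5, -0.5, 0.5, 1.5))
  } else if (kind == "dimpled_slab") {
    # spherical dimple of free radius cavity_radius/2, recessed below the
    # top face so its mouth stays narrower than the large probe
    rd <- cavity_radius / 2
    zc <- -rd / 2
    half <- max(7, cavity_radius + 1)
    g <- seq(-half, half, by = lattice_spacing)
    gz <- seq(-5 * lattice_spacing, 0, by = lattice_spacing)
    pts <- as.matrix(expand.grid(x = g, y = g, z = gz))
    dctr <- c(0, 0, zc)
    keep <- sqrt(colSums((t(pts) - dctr)^2)) >= rd + atom_radius
    pts <- pts[keep, , drop = FALSE]
    lig <- .tetrahedron(0.8) + matrix(dctr, 4, 3, byrow = TRUE)
  } else {                                          # convex_blob
    half <- max(4, cavity_radius - 1)
    g <- seq(-half, half, by = lattice_spacing)
    pts <- as.matrix(expand.grid(x = g, y = g, z = g))
    pts <- pts[sqrt(rowSums(pts^2)) <= half, , drop = FALSE]
    lig <- .tetrahedron(0.8) +
      matrix(c(0, 0, half + atom_radius + 2), 4, 3, byrow = TRUE)
    shallow <- TRUE
  }
  if (nrow(pts) < 4L) stop("degenerate fixture: fewer than 4 atoms")
  pts <- pts + matrix(stats::runif(length(pts), -jitter, jitter), nrow(pts))
  # overlap sanity: atoms must not sit essentially on top of each other
  if (min(stats::dist(pts)) < 0.5 * atom_radius) {
    stop("fixture parameters produce self-intersecting geometry")
  }
  n <- nrow(pts)
  res_of_atom <- ceiling(seq_len(n) / 4)
  atoms <- data.frame(
    type = "ATOM", eleno = seq_len(n), elety = "C", element = "C",
    resid = .aa20[(res_of_atom - 1L) %% 20L + 1L], chain = "A",
    resno = res_of_atom, x = pts[, 1], y = pts[, 2], z = pts[, 3],
    radius = atom_radius, is_heavy = TRUE, stringsAsFactors = FALSE)
  st <- .new_structure(atoms, source = paste0("synthetic:", kind))
  colnames(lig) <- c("x", "y", "z")
  d2 <- .cross_dist2(as.matrix(atoms[, c("x", "y", "z")]), lig)
  truth <- which(apply(d2, 1, min) <= 25)
  if (kind != "convex_blob" && length(truth) == 0L) {
    stop("fixture construction failed: empty truth region")
  }
  structure(list(structure = st, ligand = lig, truth_region = truth,
                 kind = kind, shallow = shallow, seed = seed),
            class = "pp_fixture")
}

.tetrahedron <- function(scale) {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    scale / sqrt(3)
}

#' @export
print.pp_fixture <- function(x, ...) {
  cat(sprintf("<pp_fixture> %s: %d atoms, %d ligand atoms, %d truth atoms%s\n",
              x$kind, natoms(x$structure), nrow(x$ligand),
              length(x$truth_region), if (x$shallow) " (shallow)" else ""))
  invisible(x)
}

# 6-neighborhood flood fill restricted to mask, seeded from the array faces
# (probe positions reachable from bulk solvent)
.flood_from_boundary <- function(mask) {
  dims <- dim(mask)
  vis <- array(FALSE, dims)
  vis[c(1, dims[1]), , ] <- mask[c(1, dims[1]), , ]
  vis[, c(1, dims[2]), ] <- vis[, c(1, dims[2]), ] | mask[, c(1, dims[2]), ]
  vis[, , c(1, dims[3])] <- vis[, , c(1, dims[3])] | mask[, , c(1, dims[3])]
  repeat {
    g <- vis
    g[-1, , ] <- g[-1, , ] | vis[-dims[1], , ]
    g[-dims[1], , ] <- g[-dims[1], , ] | vis[-1, , ]
    g[, -1, ] <- g[, -1, ] | vis[, -dims[2], ]
    g[, -dims[2], ] <- g[, -dims[2], ] | vis[, -1, ]
    g[, , -1] <- g[, , -1] | vis[, , -dims[3]]
    g[, , -dims[3]] <- g[, , -dims[3]] | vis[, , -1]
    g <- g & mask
    g <- g | vis
    if (identical(g, vis)) break
    vis <- g
  }
  vis
}

# binary dilation of a 3-D logical array by a Euclidean ball, via FFT
# convolution with a ball structuring element (zero-padded, linear)
.dilate_ball <- function(mask, radius, spacing) {
  dims <- dim(mask)
  hw <- ceiling(radius / spacing)
  off <- seq(-hw, hw)
  K <- array(0, dim = rep(2L * hw + 1L, 3))
  og <- as.matrix(expand.grid(off, off, off))
  K[sqrt(rowSums(og^2)) * spacing <= radius + 1e-9] <- 1
  pd <- dims + dim(K) - 1L
  pd <- vapply(pd, stats::nextn, 1, factors = c(2, 3, 5))
  A <- array(0, pd); A[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <-
    as.numeric(mask)
  B <- array(0, pd); B[seq_len(dim(K)[1]), seq_len(dim(K)[2]),
                       seq_len(dim(K)[3])] <- K
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) /
    prod(pd)
  sel <- list(hw + seq_len(dims[1]), hw + seq_len(dims[2]),
              hw + seq_len(dims[3]))
  conv[sel[[1]], sel[[2]], sel[[3]]] > 0.5
}

#' Two-probe grid oracle for pocket space
#'
#' Flags grid points that are inaccessible to a large probe but accessible
#' to a small one: a point lies outside the r-probe molecular envelope iff
#' some clash-free probe sphere of radius r that is reachable from bulk
#' solvent contains it (evaluated morphologically: probe-center
#' accessibility on a distance grid, flood-filled from the box boundary so
#' that sealed interior voids stay inside the envelope, then dilation by
#' the probe radius). Pocket points are inside the large-probe envelope,
#' outside the small-probe envelope and outside the atoms. The test is
#' independent of the probe-sphere engine and serves as a cross-check
#' oracle.
#'
#' @param structure A `pp_structure`.
#' @param r_small Small probe radius (default 1.4).
#' @param r_large Large probe radius (default 3.0).
#' @param spacing Grid spacing, at most 1 A (default 0.6).
#' @return Object of class `pp_grid_oracle`: list with `points` (n x 3
#'   matrix of flagged grid points), `mask` (3-D logical array), grid
#'   metadata and `spacing`.
#' @export
grid_pocket_oracle <- function(structure, r_small = 1.4, r_large = 3.0,
                               spacing = 0.6) {
  stopifnot(spacing <= 1.0, r_small < r_large)
  a <- structure$atoms
  cen <- as.matrix(a[, c("x", "y", "z")])
  rad <- a$radius
  margin <- 2 * r_large + 2 * spacing
  lo <- apply(cen, 2, min) - max(rad) - margin
  hi <- apply(cen, 2, max) + max(rad) + margin
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  G <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  D <- .union_sdf(G, cen, rad)     # distance to the van der Waals surface
  dims <- c(length(gx), length(gy), length(gz))
  arr <- function(v) array(v, dim = dims)
  out_small <- .dilate_ball(.flood_from_boundary(arr(D >= r_small)),
                            r_small, spacing)
  out_large <- .dilate_ball(.flood_from_boundary(arr(D >= r_large)),
                            r_large, spacing)
  mask <- !out_large & out_small & arr(D > 0)
  structure(list(points = G[as.vector(mask), , drop = FALSE], mask = mask,
                 inside_large = !out_large & arr(D > 0),
                 gx = gx, gy = gy, gz = gz, spacing = spacing,
                 r_small = r_small, r_large = r_large),
            class = "pp_grid_oracle")
}

#' @export
print.pp_grid_oracle <- function(x, ...) {
  cat(sprintf("<pp_grid_oracle> %d pocket points at %.2f A spacing (%.1f A^3)\n",
              nrow(x$points), x$spacing, nrow(x$points) * x$spacing^3))
  invisible(x)
}

#' Cross-check a detected pocket against the grid oracle
#'
#' Voxelizes the union of the pocket's probe spheres on the oracle grid
#' and computes the Jaccard index against the oracle's pocket points.
#' The probe cloud is clipped to the structure's large-probe envelope
#' (`clip = TRUE`, the default): probe spheres protrude into bulk solvent,
#' which is not pocket volume under any definition, while the oracle
#' region lies inside that envelope by construction -- the clipped Jaccard
#' compares like with like.
#'
#' @param pocket A `pp_pocket` (typically the top-ranked one).
#' @param oracle A `pp_grid_oracle` computed on the same structure.
#' @param min_jaccard Pass threshold (default 0.3).
#' @param clip Clip the probe cloud to the large-probe envelope?
#' @return List with `jaccard`, `pass`, `n_pocket`, `n_oracle`.
#' @export
cross_check <- function(pocket, oracle, min_jaccard = 0.3, clip = TRUE) {
  G <- as.matrix(expand.grid(x = oracle$gx, y = oracle$gy, z = oracle$gz))
  sph <- pocket$probes
  inside <- rep(FALSE, nrow(G))
  chunk <- max(1L, floor(4e6 / max(nrow(sph), 1L)))
  for (s in seq(1L, nrow(G), by = chunk)) {
    e <- min(nrow(G), s + chunk - 1L)
    d2 <- .cross_dist2(G[s:e, , drop = FALSE],
                       as.matrix(sph[, c("x", "y", "z")]))
    inside[s:e] <- rowSums(d2 <= matrix(sph$radius^2, e - s + 1L,
                                        nrow(sph), byrow = TRUE)) > 0L
  }
  if (clip) inside <- inside & as.vector(oracle$inside_large)
  om <- as.vector(oracle$mask)
  inter <- sum(inside & om)
  uni <- sum(inside | om)
  jac <- if (uni == 0L) 1 else inter / uni   # both empty: vacuous pass
  list(jaccard = jac, pass = jac >= min_jaccard,
       n_pocket = sum(inside), n_oracle = sum(om))
}

#' Write a fixture to disk (PQR + xyz ligand)
#' @param fixture A `pp_fixture`.
#' @param prefix Path prefix; writes `<prefix>.pqr` and `<prefix>_lig.xyz`.
#' @export
write_fixture <- function(fixture, prefix) {
  write_pqr(fixture$structure, paste0(prefix, ".pqr"))
  write_xyz(fixture$ligand, paste0(prefix, "_lig.xyz"))
  invisible(prefix)
}
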
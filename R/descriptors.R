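# Pocket descriptors: union-of-spheres geometry (volume, area, mold mesh),
# sphericity, and the 17 geometric/clustering + 22 chemical features.

# signed distance to the union of spheres at grid points G (m x 3), chunked
.union_sdf <- function(G, centers, radii) {
  m <- nrow(G)
  phi <- rep(Inf, m)
  chunk <- max(1L, floor(4e6 / max(nrow(centers), 1L)))
  for (s in seq(1L, m, by = chunk)) {
    e <- min(m, s + chunk - 1L)
    d <- sqrt(pmax(.cross_dist2(G[s:e, , drop = FALSE], centers), 0))
    phi[s:e] <- apply(d - matrix(radii, e - s + 1L, length(radii),
                                 byrow = TRUE), 1, min)
  }
  phi
}

#' Volume, area and mold mesh of a union of spheres
#'
#' Volume is integrated on a signed-distance grid with a linear smoothed
#' occupancy (voxel weight `clamp(1/2 - phi/h, 0, 1)`), which converges to
#' the analytic value as the spacing shrinks. Surface area is computed by
#' deterministic Fibonacci-lattice sampling of each sphere: each sphere
#' contributes `4 pi r^2` times the fraction of its sample points not
#' buried inside any other sphere (the same exposure-counting scheme used
#' for solvent-accessible areas). The mold mesh is the boundary-voxel quad
#' surface, an export/visualization artifact; volume and area are never
#' read from it.
#'
#' @param spheres Matrix or data frame with columns `x, y, z, radius` (a
#'   probe data frame works directly).
#' @param spacing Grid spacing in Angstrom (default 0.3). For very large
#'   sphere sets the spacing is coarsened so the grid stays tractable, and
#'   a gridded coverage estimator replaces the exact signed-distance /
#'   exposure-sampling path (see Details).
#' @param n_points Sample points per sphere for the area (default 500).
#' @param mesh Build the boundary quad mesh? Default `FALSE`.
#' @param max_exact Above this sphere count the gridded estimator is used
#'   (default 400).
#' @details The exact path evaluates the signed distance to the union at
#'   every grid point (volume, with a linear sub-voxel correction) and
#'   samples every sphere surface for buried/exposed points (area). The
#'   large-set path rasterizes spheres by radius group with FFT ball
#'   dilation (volume) and estimates the area from boundary voxel faces
#'   with the 2/3 isotropic-surface correction; it is used for pocket
#'   clouds of thousands of probes where volume feeds the ranking rather
#'   than any analytic comparison.
#' @return Object of class `pp_geometry`: list with `V` (A^3), `A` (A^2)
#'   and optionally `mesh` (list with `vertices`, `faces`).
#' @export
union_volume_area <- function(spheres, spacing = 0.3, n_points = 500L,
                              mesh = FALSE, max_exact = 400L) {
  sph <- as.data.frame(spheres)
  if (nrow(sph) == 0L) stop("empty sphere list")
  stopifnot(all(c("x", "y", "z", "radius") %in% names(sph)))
  cen <- as.matrix(sph[, c("x", "y", "z")])
  rad <- sph$radius
  h <- spacing
  big <- nrow(sph) > max_exact
  if (big) {
    # keep the grid at or below ~2e5 cells
    ext <- (apply(cen + rad, 2, max) - apply(cen - rad, 2, min)) + 4 * h
    h <- max(h, (prod(ext) / 2e5)^(1 / 3))
  }
  lo <- apply(cen - rad, 2, min) - 2 * h
  hi <- apply(cen + rad, 2, max) + 2 * h
  gx <- seq(lo[1], hi[1], by = h)
  gy <- seq(lo[2], hi[2], by = h)
  gz <- seq(lo[3], hi[3], by = h)
  dims <- c(length(gx), length(gy), length(gz))
  if (big) {
    inside <- .union_mask_fft(cen, rad, gx, gy, gz, h)
    V <- sum(inside) * h^3
    A <- .boundary_face_area(inside, h)
    out <- list(V = V, A = A, spacing = h)
    if (mesh) out$mesh <- .boundary_quad_mesh(inside, gx, gy, gz, h)
    return(structure(out, class = "pp_geometry"))
  }
  G <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  phi <- .union_sdf(G, cen, rad)
  occ <- pmin(pmax(0.5 - phi / h, 0), 1)
  V <- sum(occ) * h^3
  # exposure-sampled area
  pts <- .fibonacci_sphere(n_points)
  A <- 0
  for (i in seq_len(nrow(sph))) {
    p <- pts * rad[i] + matrix(cen[i, ], n_points, 3, byrow = TRUE)
    exposed <- rep(TRUE, n_points)
    others <- setdiff(seq_len(nrow(sph)), i)
    if (length(others)) {
      d <- sqrt(pmax(.cross_dist2(p, cen[others, , drop = FALSE]), 0))
      exposed <- rowSums(d < matrix(rad[others] - 1e-9, n_points,
                                    length(others), byrow = TRUE)) == 0L
    }
    A <- A + 4 * pi * rad[i]^2 * mean(exposed)
  }
  out <- list(V = V, A = A, spacing = h)
  if (mesh) {
    out$mesh <- .boundary_quad_mesh(array(phi <= 0, dim = dims),
                                    gx, gy, gz, h)
  }
  structure(out, class = "pp_geometry")
}

# coverage mask of a union of spheres: splat centers per radius group,
# dilate by the group radius (FFT ball convolution)
.union_mask_fft <- function(cen, rad, gx, gy, gz, h) {
  dims <- c(length(gx), length(gy), length(gz))
  ix <- pmin(pmax(round((cen[, 1] - gx[1]) / h) + 1L, 1L), dims[1])
  iy <- pmin(pmax(round((cen[, 2] - gy[1]) / h) + 1L, 1L), dims[2])
  iz <- pmin(pmax(round((cen[, 3] - gz[1]) / h) + 1L, 1L), dims[3])
  inside <- array(FALSE, dims)
  for (r in unique(round(rad, 6))) {
    sel <- abs(rad - r) < 1e-6
    splat <- array(FALSE, dims)
    splat[cbind(ix[sel], iy[sel], iz[sel])] <- TRUE
    inside <- inside | .dilate_ball(splat, r, h)
  }
  inside
}

# area estimate from boundary voxel faces; the 2/3 factor corrects the
# L1 (staircase) overcount for an isotropically oriented surface
.boundary_face_area <- function(mask, h) {
  dims <- dim(mask)
  faces <- 0L
  shift_out <- function(m, d, s) {
    pad <- array(FALSE, dims)
    if (d == 1) { if (s > 0) pad[-dims[1], , ] <- m[-1, , ] else
      pad[-1, , ] <- m[-dims[1], , ] }
    if (d == 2) { if (s > 0) pad[, -dims[2], ] <- m[, -1, ] else
      pad[, -1, ] <- m[, -dims[2], ] }
    if (d == 3) { if (s > 0) pad[, , -dims[3]] <- m[, , -1] else
      pad[, , -1] <- m[, , -dims[3]] }
    pad
  }
  for (d in 1:3) for (s in c(-1, 1)) {
    faces <- faces + sum(mask & !shift_out(mask, d, s))
  }
  faces * h^2 * (2 / 3)
}

#' @export
print.pp_geometry <- function(x, ...) {
  cat(sprintf("<pp_geometry> V = %.2f A^3, A = %.2f A^2 (h = %.2f)\n",
              x$V, x$A, x$spacing))
  invisible(x)
}

# quad mesh of faces between inside and outside voxels
.boundary_quad_mesh <- function(mask, gx, gy, gz, h) {
  dims <- dim(mask)
  verts <- list(); faces <- list(); nv <- 0L
  add_face <- function(p1, p2, p3, p4) {
    verts[[length(verts) + 1L]] <<- rbind(p1, p2, p3, p4)
    faces[[length(faces) + 1L]] <<- nv + 1:4
    nv <<- nv + 4L
  }
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    ctr <- c(gx[i], gy[j], gz[k])
    nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    for (f in 1:6) {
      ii <- i + nb[f, 1]; jj <- j + nb[f, 2]; kk <- k + nb[f, 3]
      outside <- ii < 1 || ii > dims[1] || jj < 1 || jj > dims[2] ||
        kk < 1 || kk > dims[3] || !mask[ii, jj, kk]
      if (!outside) next
      nrm <- nb[f, ]
      # face center and two in-plane axes
      fc <- ctr + nrm * h / 2
      ax <- if (nrm[1] != 0) rbind(c(0, 1, 0), c(0, 0, 1))
            else if (nrm[2] != 0) rbind(c(1, 0, 0), c(0, 0, 1))
            else rbind(c(1, 0, 0), c(0, 1, 0))
      a <- ax[1, ] * h / 2; b <- ax[2, ] * h / 2
      add_face(fc - a - b, fc + a - b, fc + a + b, fc - a + b)
    }
  }
  list(vertices = do.call(rbind, verts),
       faces = do.call(rbind, faces))
}

#' Write a mold mesh as an OFF file
#' @param mesh List with `vertices` (n x 3) and `faces` (m x 4, 1-based).
#' @param path Output path.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(sprintf("%.4f %.4f %.4f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L,
                     mesh$faces[, 4] - 1L), con)
  invisible(path)
}

#' Wadell sphericity
#'
#' The surface area of a sphere of identical volume divided by the
#' object's actual surface area: `psi = pi^(1/3) (6V)^(2/3) / A`. Equals 1
#' for a perfect sphere and decreases as the object departs from
#' sphericity (isoperimetric inequality).
#'
#' @param V Volume (A^3).
#' @param A Surface area (A^2).
#' @return Sphericity index in (0, 1].
#' @export
sphericity <- function(V, A) {
  if (any(V <= 0) || any(A <= 0)) stop("V and A must be positive")
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

.geo_feature_names <- c(
  "n_entrances", "buried_flag", "avg_entrance_radius",
  "entrance_depth_score", "n_bottlenecks", "avg_bottleneck_radius",
  "avg_large_aggregation_radius", "volume", "size", "aggregation_score",
  "persistence_score", "clustering_score", "large_aggregation_score",
  "volume_ratio", "hw_index", "ramification", "protrusion")

#' Geometric and clustering features of a pocket
#'
#' Seventeen named descriptors: entrance counts/radii/depths, bottleneck
#' statistics, aggregation- and persistence-based clustering scores,
#' volume, size, compactness (volume ratio, Wadell sphericity) and the
#' heuristic ramification/protrusion complexity scores. Scores normalized
#' by cluster size allow comparability of differently sized pockets; the
#' entrance depth score is normalized by the significant-alignment
#' threshold so that 1 corresponds to the minimum pseudo-mouth
#' requirement. Large aggregations are lateral/pyramidal merges whose
#' pre-merge cluster sizes are both above 10 and within a 1:5 ratio.
#' Persistence-derived features are 0 when the persistence list is empty.
#'
#' @param pocket A `pp_pocket`.
#' @param geometry A `pp_geometry` from [union_volume_area()] on the
#'   pocket's member spheres.
#' @param config A [clustering_config()].
#' @return Named numeric vector of length 17.
#' @export
geometric_features <- function(pocket, geometry,
                               config = clustering_config()) {
  ent <- pocket$entrances
  size <- pocket$size
  pers <- pocket$persistence
  if (is.null(pers)) pers <- numeric(0)
  n_ent <- length(ent)
  avg_ent_r <- if (n_ent) mean(vapply(ent, `[[`, 1, "effective_radius")) else 0
  eds <- if (n_ent) {
    w <- vapply(ent, function(e) length(e$member_terminal_probes), 1)
    dpt <- vapply(ent, `[[`, 1, "avg_depth_index")
    sum(w * dpt) / sum(w) / config$align_threshold
  } else 0
  bn <- pocket$bottleneck_radii
  agg <- pocket$aggregation
  large <- agg[pmin(agg$size_l, agg$size_r) > 10 &
               pmin(agg$size_l, agg$size_r) /
               pmax(agg$size_l, agg$size_r) >= 1 / 5, , drop = FALSE]
  avg_large_r <- if (nrow(large)) {
    stats::weighted.mean(large$radius, large$size_l + large$size_r)
  } else 0
  ram <- if (length(pers) > 1L) stats::sd(pers) else 0
  mean_pers <- if (length(pers)) mean(pers) else 0
  out <- c(
    n_entrances = n_ent,
    buried_flag = as.numeric(pocket$buried),
    avg_entrance_radius = avg_ent_r,
    entrance_depth_score = eds,
    n_bottlenecks = length(bn),
    avg_bottleneck_radius = if (length(bn)) mean(bn) else 0,
    avg_large_aggregation_radius = avg_large_r,
    volume = geometry$V,
    size = size,
    aggregation_score = nrow(agg) / size,
    persistence_score = sum(pers) / size,
    clustering_score = nrow(agg) / size + sum(pers) / size,
    large_aggregation_score = nrow(large) / size,
    volume_ratio = geometry$V / size,
    hw_index = sphericity(geometry$V, geometry$A),
    ramification = ram,
    protrusion = eds * config$align_threshold - mean_pers - ram)
  out[.geo_feature_names]
}

.aa20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")

#' Bundled hydropathy classification
#'
#' Binary residue classification used for the hydrophobic/hydrophilic
#' scores; glycine is neutral (it counts in the normalization but in
#' neither class). Override by passing a modified copy to
#' [chemical_features()].
#'
#' @return Named character vector over the 20 amino acids with values
#'   `"hydrophobic"`, `"hydrophilic"` or `"neutral"`.
#' @export
default_hydropathy <- function() {
  phob <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP", "CYS")
  phil <- c("ARG", "LYS", "ASP", "GLU", "ASN", "GLN", "HIS", "SER", "THR",
            "TYR")
  out <- stats::setNames(rep("neutral", 20), .aa20)
  out[phob] <- "hydrophobic"
  out[phil] <- "hydrophilic"
  out
}

#' Chemical features of a pocket
#'
#' A residue belongs to the pocket if at least one of its atoms is tangent
#' to any member probe sphere. The 20 amino-acid fractions are normalized
#' by the total number of distinct pocket residues; the hydrophobic and
#' hydrophilic scores are the class counts over the same denominator, with
#' glycine (and unknown residue codes, which are logged) contributing to
#' the denominator only.
#'
#' @param pocket A `pp_pocket`.
#' @param structure The `pp_structure` the pocket was generated from.
#' @param hydropathy_table Residue classification, see
#'   [default_hydropathy()].
#' @return Named numeric vector of length 22 (20 fractions +
#'   `hydrophobic_score` + `hydrophilic_score`).
#' @export
chemical_features <- function(pocket, structure,
                              hydropathy_table = default_hydropathy()) {
  a <- structure$atoms[pocket$tangent_atoms, , drop = FALSE]
  res <- unique(data.frame(id = .res_ids(a), resid = a$resid,
                           stringsAsFactors = FALSE))
  n <- nrow(res)
  if (n == 0L) stop("pocket has no tangent atoms")
  unknown <- setdiff(unique(res$resid), .aa20)
  if (length(unknown)) {
    message("unknown residue code(s) counted in the denominator only: ",
            paste(unknown, collapse = ", "))
  }
  frac <- vapply(.aa20, function(code) sum(res$resid == code) / n, 1)
  names(frac) <- paste0("frac_", .aa20)
  cls <- hydropathy_table[res$resid]
  c(frac,
    hydrophobic_score = sum(cls == "hydrophobic", na.rm = TRUE) / n,
    hydrophilic_score = sum(cls == "hydrophilic", na.rm = TRUE) / n)
}

#' Full feature vector (17 geometric + 22 chemical) for a pocket
#'
#' @param pocket A `pp_pocket`.
#' @param structure The `pp_structure`.
#' @param config A [clustering_config()].
#' @param spacing Grid spacing for the volume integration.
#' @param hydropathy_table See [default_hydropathy()].
#' @return List with `geometric` (17), `chemical` (22), `geometry`
#'   (`pp_geometry`).
#' @export
pocket_features <- function(pocket, structure,
                            config = clustering_config(), spacing = 0.3,
                            hydropathy_table = default_hydropathy()) {
  geom <- union_volume_area(pocket$probes, spacing = spacing)
  list(geometric = geometric_features(pocket, geom, config),
       chemical = chemical_features(pocket, structure, hydropathy_table),
       geometry = geom)
}

#' Feature matrix for a list of pockets (masters, standalone and subpockets)
#'
#' One row per pocket and per subpocket; subpocket rows carry their
#' parent's id. Columns: identifiers, `is_master`, `is_subpocket`,
#' `n_subpockets`, `volume`, then the 39 named features (geometric columns
#' as-is, chemical columns prefixed `chem_` via their own names).
#'
#' @param pockets List of `pp_pocket` from [extract_pockets_subpockets()].
#' @param structure The `pp_structure`.
#' @param config,spacing,hydropathy_table Passed to [pocket_features()].
#' @param structure_id Identifier stored in the `structure_id` column.
#' @return Data frame.
#' @export
feature_matrix <- function(pockets, structure,
                           config = clustering_config(), spacing = 0.3,
                           hydropathy_table = default_hydropathy(),
                           structure_id = "structure") {
  rows <- list()
  for (pi in seq_along(pockets)) {
    pk <- pockets[[pi]]
    fv <- pocket_features(pk, structure, config, spacing, hydropathy_table)
    rows[[length(rows) + 1L]] <- data.frame(
      structure_id = structure_id,
      pocket_id = sprintf("p%02d", pi), parent_id = NA_character_,
      is_master = pk$is_master, is_subpocket = FALSE,
      n_subpockets = length(pk$subpockets),
      volume = fv$geometry$V,
      t(fv$geometric), t(fv$chemical), stringsAsFactors = FALSE)
    for (si in seq_along(pk$subpockets)) {
      sp <- pk$subpockets[[si]]
      sv <- pocket_features(sp, structure, config, spacing, hydropathy_table)
      rows[[length(rows) + 1L]] <- data.frame(
        structure_id = structure_id,
        pocket_id = sprintf("p%02d.s%d", pi, si),
        parent_id = sprintf("p%02d", pi),
        is_master = FALSE, is_subpocket = TRUE, n_subpockets = 0L,
        volume = sv$geometry$V,
        t(sv$geometric), t(sv$chemical), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Names of the feature columns in a feature matrix
#' @param block `"geometric"`, `"chemical"` or `"all"`.
#' @return Character vector of column names.
#' @export
feature_names <- function(block = c("all", "geometric", "chemical")) {
  block <- match.arg(block)
  chem <- c(paste0("frac_", .aa20), "hydrophobic_score", "hydrophilic_score")
  switch(block,
         geometric = .geo_feature_names,
         chemical = chem,
         all = c(.geo_feature_names, chem))
}
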
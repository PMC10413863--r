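# Probe-sphere enumeration: solvent probes simultaneously tangent to three
# atoms (the generators of concave/re-entrant patches of the solvent-excluded
# surface), computed over a ladder of probe radii.

#' Probe radius ladder
#'
#' The probe radius is stepped from the water radius up to a terminal radius
#' in fixed increments; 17 levels at the defaults (1.4, 1.5, ..., 3.0).
#'
#' @param r_min Smallest probe radius (Angstrom, default 1.4).
#' @param r_max Terminal probe radius (default 3.0).
#' @param delta Increment between successive levels (default 0.1).
#' @return Object of class `pp_ladder` with the vector of radii.
#' @export
radius_ladder <- function(r_min = 1.4, r_max = 3.0, delta = 0.1) {
  stopifnot(r_min > 0, r_min < r_max, delta > 0)
  radii <- seq(r_min, r_max + 1e-9, by = delta)
  structure(list(r_min = r_min, r_max = r_max, delta = delta, radii = radii),
            class = "pp_ladder")
}

#' @export
print.pp_ladder <- function(x, ...) {
  cat(sprintf("<pp_ladder> %d levels: %.2f..%.2f step %.2f A\n",
              length(x$radii), x$r_min, x$r_max, x$delta))
  invisible(x)
}

# Candidate atom triplets: atoms i, j can share a tangent probe of radius rp
# only if |ci - cj| < ri + rj + 2 rp (necessary condition). Returns the
# triplet index matrix plus the pairwise distances needed to re-filter the
# same candidate set at smaller probe radii.
.candidate_triplets <- function(cen, rad, rp) {
  n <- nrow(cen)
  if (n < 3L) {
    return(list(trip = matrix(integer(0), 0, 3), d12 = numeric(0),
                d13 = numeric(0), d23 = numeric(0)))
  }
  D <- sqrt(pmax(.cross_dist2(cen, cen), 0))
  lim <- outer(rad, rad, "+") + 2 * rp
  A <- D < lim
  diag(A) <- FALSE
  ed <- which(A & upper.tri(A), arr.ind = TRUE)
  if (nrow(ed) == 0L) {
    return(list(trip = matrix(integer(0), 0, 3), d12 = numeric(0),
                d13 = numeric(0), d23 = numeric(0)))
  }
  trips <- vector("list", nrow(ed))
  for (e in seq_len(nrow(ed))) {
    i <- ed[e, 1]; j <- ed[e, 2]
    ks <- which(A[i, ] & A[j, ])
    ks <- ks[ks > j]
    if (length(ks)) trips[[e]] <- cbind(i, j, ks, deparse.level = 0)
  }
  trip <- do.call(rbind, trips)
  if (is.null(trip)) trip <- matrix(integer(0), 0, 3)
  list(trip = trip,
       d12 = D[trip[, 1:2, drop = FALSE]],
       d13 = D[trip[, c(1, 3), drop = FALSE]],
       d23 = D[trip[, 2:3, drop = FALSE]])
}

# Coarse grid of distance-to-van-der-Waals-surface values used as a clash
# prefilter: a candidate probe center p is clash-free iff D(p) >= r_p, and
# D at the nearest cell differs from D(p) by at most half the cell
# diagonal, so rejecting only when D_cell < r_p - err never discards a
# valid probe.
.make_clash_grid <- function(cen, rad, r_max, h = 0.5) {
  m <- max(rad) + r_max + 2 * h
  lo <- apply(cen, 2, min) - m
  hi <- apply(cen, 2, max) + m
  gx <- seq(lo[1], hi[1], by = h)
  gy <- seq(lo[2], hi[2], by = h)
  gz <- seq(lo[3], hi[3], by = h)
  G <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  D <- array(.union_sdf(G, cen, rad), dim = c(length(gx), length(gy),
                                              length(gz)))
  list(gx = gx, gy = gy, gz = gz, h = h, D = D, err = h * sqrt(3) / 2)
}

# rowwise cross product of n x 3 matrices
.row_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

.empty_probes <- function() {
  data.frame(id = integer(0), level = integer(0), radius = numeric(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             a1 = integer(0), a2 = integer(0), a3 = integer(0),
             key = character(0), nx = numeric(0), ny = numeric(0),
             nz = numeric(0), px = numeric(0), py = numeric(0),
             pz = numeric(0), qx = numeric(0), qy = numeric(0),
             qz = numeric(0), side = integer(0), inside_tri = logical(0),
             stringsAsFactors = FALSE)
}

#' Enumerate probe spheres tangent to atom triplets
#'
#' For every atom triplet whose pairwise distances admit a common tangent
#' sphere of radius `r_p`, both analytic solutions of the three-sphere
#' tangency system are computed; a candidate is kept iff it is clash-free
#' against all atoms (distance to every atom center at least
#' `radius + r_p - tol`). The trimming plane is the plane through the three
#' atom centers; its normal carries a deterministic canonical sign so the
#' two solutions fall on sides +1 and -1. Probes whose centers coincide
#' within `tol` are merged, keeping the lexicographically smallest triplet.
#'
#' @param structure A `pp_structure`.
#' @param r_p Probe radius (Angstrom).
#' @param tol Tolerance for tangency/clash tests (default 1e-3 A).
#' @param level Integer level index stored in the output (default 1).
#' @param cand Optional precomputed candidate set from a larger radius
#'   (internal reuse across a ladder).
#' @param clash_grid Optional coarse distance grid from
#'   [.make_clash_grid()]: candidates provably clashing are rejected
#'   before the exact test (the safety band guarantees no false
#'   rejection).
#' @return Data frame of probes: center (`x,y,z`), sorted tangent triplet
#'   (`a1,a2,a3`), triplet `key`, canonical plane normal (`nx,ny,nz`),
#'   plane point (`px,py,pz`), in-plane projection of the center
#'   (`qx,qy,qz`), `side` (+1/-1) and `inside_tri` (projection inside the
#'   triangle of atom centers).
#' @export
enumerate_probes <- function(structure, r_p, tol = 1e-3, level = 1L,
                             cand = NULL, clash_grid = NULL) {
  stopifnot(r_p > 0)
  a <- structure$atoms
  if (nrow(a) < 3L) return(.empty_probes())
  cen <- as.matrix(a[, c("x", "y", "z")])
  rad <- a$radius
  if (is.null(cand)) cand <- .candidate_triplets(cen, rad, r_p)
  trip <- cand$trip
  if (nrow(trip) == 0L) return(.empty_probes())
  # re-filter candidates for this radius
  keep <- cand$d12 < rad[trip[, 1]] + rad[trip[, 2]] + 2 * r_p &
          cand$d13 < rad[trip[, 1]] + rad[trip[, 3]] + 2 * r_p &
          cand$d23 < rad[trip[, 2]] + rad[trip[, 3]] + 2 * r_p
  trip <- trip[keep, , drop = FALSE]
  if (nrow(trip) == 0L) return(.empty_probes())

  c1 <- cen[trip[, 1], , drop = FALSE]
  c2 <- cen[trip[, 2], , drop = FALSE]
  c3 <- cen[trip[, 3], , drop = FALSE]
  d1 <- rad[trip[, 1]] + r_p
  d2 <- rad[trip[, 2]] + r_p
  d3 <- rad[trip[, 3]] + r_p
  u <- c2 - c1; v <- c3 - c1
  uu <- rowSums(u * u); vv <- rowSums(v * v); uv <- rowSums(u * v)
  det <- uu * vv - uv * uv
  ok <- det > 1e-9 * pmax(uu * vv, 1e-12)   # collinear triplets dropped
  if (!any(ok)) return(.empty_probes())
  trip <- trip[ok, , drop = FALSE]
  c1 <- c1[ok, , drop = FALSE]; u <- u[ok, , drop = FALSE]
  v <- v[ok, , drop = FALSE]
  d1 <- d1[ok]; d2 <- d2[ok]; d3 <- d3[ok]
  uu <- uu[ok]; vv <- vv[ok]; uv <- uv[ok]; det <- det[ok]

  e1 <- (uu + d1^2 - d2^2) / 2
  e2 <- (vv + d1^2 - d3^2) / 2
  alpha <- (e1 * vv - e2 * uv) / det
  beta  <- (e2 * uu - e1 * uv) / det
  p <- alpha * u + beta * v
  h2 <- d1^2 - rowSums(p * p)
  real <- h2 >= 0
  if (!any(real)) return(.empty_probes())
  trip <- trip[real, , drop = FALSE]
  c1 <- c1[real, , drop = FALSE]; u <- u[real, , drop = FALSE]
  v <- v[real, , drop = FALSE]; p <- p[real, , drop = FALSE]
  alpha <- alpha[real]; beta <- beta[real]
  h <- sqrt(h2[real])
  w <- .row_cross(u, v)
  nrm <- w / sqrt(rowSums(w * w))
  # canonical sign: first component with magnitude > 1e-9 made positive
  flip <- nrm[, 1] < -1e-9 |
    (abs(nrm[, 1]) <= 1e-9 & (nrm[, 2] < -1e-9 |
                              (abs(nrm[, 2]) <= 1e-9 & nrm[, 3] < 0)))
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]

  proj <- c1 + p                       # in-plane projection (both solutions)
  inside <- alpha >= -1e-9 & beta >= -1e-9 & (alpha + beta) <= 1 + 1e-9
  centers <- rbind(proj + h * nrm, proj - h * nrm)
  side <- rep(c(1L, -1L), each = nrow(trip))
  trip2 <- rbind(trip, trip)
  proj2 <- rbind(proj, proj)
  nrm2 <- rbind(nrm, nrm)
  inside2 <- c(inside, inside)
  c1_2 <- rbind(c1, c1)

  # coarse prefilter: reject candidates that provably clash
  if (!is.null(clash_grid)) {
    g <- clash_grid
    ii <- pmin(pmax(round((centers[, 1] - g$gx[1]) / g$h) + 1L, 1L),
               length(g$gx))
    jj <- pmin(pmax(round((centers[, 2] - g$gy[1]) / g$h) + 1L, 1L),
               length(g$gy))
    kk <- pmin(pmax(round((centers[, 3] - g$gz[1]) / g$h) + 1L, 1L),
               length(g$gz))
    ok <- g$D[cbind(ii, jj, kk)] >= r_p - g$err - tol
    centers <- centers[ok, , drop = FALSE]
    trip2 <- trip2[ok, , drop = FALSE]
    proj2 <- proj2[ok, , drop = FALSE]
    nrm2 <- nrm2[ok, , drop = FALSE]
    inside2 <- inside2[ok]
    side <- side[ok]
    c1_2 <- c1_2[ok, , drop = FALSE]
    if (nrow(centers) == 0L) return(.empty_probes())
  }
  # exact clash filter against all atoms (triplet atoms sit at r + r_p)
  m <- nrow(centers)
  keep <- logical(m)
  lim <- (rad + r_p - tol)^2
  chunk <- max(1L, floor(1e7 / nrow(cen)))
  for (s in seq(1L, m, by = chunk)) {
    e <- min(m, s + chunk - 1L)
    d2m <- .cross_dist2(centers[s:e, , drop = FALSE], cen)
    keep[s:e] <- rowSums(d2m < matrix(lim, e - s + 1L, nrow(cen),
                                      byrow = TRUE)) == 0L
  }
  if (!any(keep)) return(.empty_probes())
  centers <- centers[keep, , drop = FALSE]
  trip2 <- trip2[keep, , drop = FALSE]
  proj2 <- proj2[keep, , drop = FALSE]
  nrm2 <- nrm2[keep, , drop = FALSE]
  inside2 <- inside2[keep]
  side <- side[keep]
  c1_2 <- c1_2[keep, , drop = FALSE]

  out <- data.frame(
    id = NA_integer_, level = as.integer(level), radius = r_p,
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    a1 = trip2[, 1], a2 = trip2[, 2], a3 = trip2[, 3],
    key = paste(trip2[, 1], trip2[, 2], trip2[, 3], sep = "-"),
    nx = nrm2[, 1], ny = nrm2[, 2], nz = nrm2[, 3],
    px = c1_2[, 1], py = c1_2[, 2], pz = c1_2[, 3],
    qx = proj2[, 1], qy = proj2[, 2], qz = proj2[, 3],
    side = side, inside_tri = inside2, stringsAsFactors = FALSE)

  # duplicate suppression: same center within tol across triplets
  gk <- paste(round(out$x / tol), round(out$y / tol), round(out$z / tol))
  ord <- order(gk, out$a1, out$a2, out$a3)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(gk[ord]), , drop = FALSE]
  # deterministic order: by triplet, then side
  out <- out[order(out$a1, out$a2, out$a3, -out$side), , drop = FALSE]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Build the probe series over a radius ladder
#'
#' Runs [enumerate_probes()] at every ladder level, with the candidate
#' triplet set computed once at the terminal radius and re-filtered per
#' level. Probe ids are unique across levels.
#'
#' @param structure A `pp_structure`.
#' @param ladder A [radius_ladder()].
#' @param tol Tangency/clash tolerance.
#' @return Object of class `pp_probe_series`: list with `levels` (list of
#'   per-level probe data frames), `probes` (combined data frame), `ladder`.
#' @export
build_probe_series <- function(structure, ladder = radius_ladder(),
                               tol = 1e-3) {
  stopifnot(inherits(ladder, "pp_ladder"))
  cen <- as.matrix(structure$atoms[, c("x", "y", "z")])
  rad <- structure$atoms$radius
  cand <- .candidate_triplets(cen, rad, max(ladder$radii))
  cgrid <- .make_clash_grid(cen, rad, max(ladder$radii))
  levels <- vector("list", length(ladder$radii))
  off <- 0L
  for (l in seq_along(ladder$radii)) {
    pr <- enumerate_probes(structure, ladder$radii[l], tol = tol,
                           level = l, cand = cand, clash_grid = cgrid)
    if (nrow(pr)) pr$id <- pr$id + off
    off <- off + nrow(pr)
    levels[[l]] <- pr
  }
  probes <- do.call(rbind, levels)
  rownames(probes) <- NULL
  structure(list(levels = levels, probes = probes, ladder = ladder),
            class = "pp_probe_series")
}

#' @export
print.pp_probe_series <- function(x, ...) {
  cnt <- vapply(x$levels, nrow, 1L)
  cat(sprintf("<pp_probe_series> %d probes over %d levels (%s)\n",
              sum(cnt), length(cnt), paste(cnt, collapse = ",")))
  invisible(x)
}

#' Export/import probes as TSV
#'
#' The TSV layout (`id, level, radius, x, y, z, a1, a2, a3, nx, ny, nz,
#' side`) doubles as a pluggable-backend contract: any producer of probe
#' instances tangent to atom triplets can feed the clustering stage.
#'
#' @param probes Probe data frame (from [enumerate_probes()] or a series).
#' @param path Output path.
#' @export
write_probes <- function(probes, path) {
  utils::write.table(
    probes[, c("id", "level", "radius", "x", "y", "z",
               "a1", "a2", "a3", "nx", "ny", "nz", "side")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
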
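# Shared builders for hand-made structures, probes and pockets, plus a
# session cache so expensive pipeline runs are computed once per test run.

.pp_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .pp_test_cache)) {
    assign(key, force(expr), envir = .pp_test_cache)
  }
  get(key, envir = .pp_test_cache)
}

# structure from bare coordinates
mk_struct <- function(x, y = 0, z = 0, radius = 1, resid = "ALA",
                      resno = NULL, chain = "A") {
  n <- length(x)
  y <- rep_len(y, n); z <- rep_len(z, n)
  radius <- rep_len(radius, n); resid <- rep_len(resid, n)
  if (is.null(resno)) resno <- seq_len(n)
  atoms <- data.frame(type = "ATOM", eleno = seq_len(n), elety = "C",
                      element = "C", resid = resid,
                      chain = rep_len(chain, n), resno = resno,
                      x = x, y = y, z = z, radius = radius,
                      is_heavy = TRUE, stringsAsFactors = FALSE)
  probepocket:::.new_structure(atoms)
}

# three unit atoms on an equilateral triangle (side 2) in z = 0, plus an
# optional blocker below: hosts exactly one tangent probe pair per radius
mk_triplet_struct <- function(blocker_z = NULL) {
  x <- c(0, 2, 1); y <- c(0, 0, sqrt(3)); z <- c(0, 0, 0)
  if (!is.null(blocker_z)) {
    x <- c(x, 1); y <- c(y, sqrt(3) / 3); z <- c(z, blocker_z)
  }
  mk_struct(x, y, z, radius = 1)
}

# minimal synthetic probe data frame (same columns as enumerate_probes)
mk_probes <- function(level, radius, centers, key, side = 1L,
                      normal = c(0, 0, 1), inside_tri = TRUE) {
  centers <- matrix(centers, ncol = 3)
  n <- nrow(centers)
  key <- rep_len(key, n)
  side <- rep_len(side, n)
  trip <- do.call(rbind, lapply(strsplit(key, "-"), as.integer))
  data.frame(id = NA_integer_, level = as.integer(level), radius = radius,
             x = centers[, 1], y = centers[, 2], z = centers[, 3],
             a1 = trip[, 1], a2 = trip[, 2], a3 = trip[, 3], key = key,
             nx = normal[1], ny = normal[2], nz = normal[3],
             px = centers[, 1], py = centers[, 2], pz = 0,
             qx = centers[, 1], qy = centers[, 2], qz = 0,
             side = side, inside_tri = inside_tri,
             stringsAsFactors = FALSE)
}

# wrap per-level probe frames into a pp_probe_series with global ids
mk_series <- function(levels, ladder = NULL) {
  off <- 0L
  for (l in seq_along(levels)) {
    if (nrow(levels[[l]])) {
      levels[[l]]$id <- off + seq_len(nrow(levels[[l]]))
      off <- off + nrow(levels[[l]])
    }
  }
  probes <- do.call(rbind, levels)
  rownames(probes) <- NULL
  structure(list(levels = levels, probes = probes,
                 ladder = ladder %||% radius_ladder()),
            class = "pp_probe_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built pocket carrying exactly the fields the descriptor and
# entrance code read
mk_pocket <- function(probes = NULL, chains = NULL, size = NULL,
                      persistence = numeric(0),
                      aggregation = data.frame(radius = numeric(0),
                                               size_l = integer(0),
                                               size_r = integer(0)),
                      bottleneck_radii = numeric(0),
                      entrances = list(), buried = FALSE,
                      tangent_atoms = integer(0), is_subpocket = FALSE) {
  if (is.null(size)) size <- if (is.null(probes)) 0L else nrow(probes)
  structure(list(node = 1L, members = seq_len(size), probes = probes,
                 size = size, tangent_atoms = tangent_atoms,
                 chains = chains, persistence = persistence,
                 aggregation = aggregation,
                 bottleneck_radii = bottleneck_radii,
                 entrances = entrances, buried = buried,
                 is_subpocket = is_subpocket, subpockets = list(),
                 is_master = FALSE),
            class = "pp_pocket")
}

# chains table in the layout .build_chains produces
mk_chains <- function(depth, terminal_probe, terminal_radius) {
  ch <- data.frame(key = paste0("k", seq_along(depth)), side = 1L,
                   depth = depth, terminal_probe = terminal_probe,
                   terminal_radius = terminal_radius,
                   level_start = 1L, level_end = depth,
                   stringsAsFactors = FALSE)
  ch$members <- I(lapply(seq_along(depth), function(i) integer(0)))
  ch$chain_id <- seq_along(depth)
  ch
}

# small shell pipeline runs shared by several tests
small_shell_fixture <- function() {
  cached("small_shell_fx",
         make_structure("shell_with_mouth", cavity_radius = 4.5, seed = 2))
}

small_shell_detection <- function() {
  cached("small_shell_det", pocket_detect(small_shell_fixture()$structure))
}
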
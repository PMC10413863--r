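# Bundled van der Waals radii (Angstrom), used when reading plain PDB files.
# PQR radii always take precedence. Values follow the commonly used Bondi set.
.default_vdw <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, B = 1.92,
  ZN = 1.39, MG = 1.73, CA = 2.31, FE = 2.00, MN = 2.05, "NA" = 2.27,
  K = 2.75
)

#' Van der Waals radius lookup table
#'
#' Returns the bundled element-to-radius table used for PDB input
#' (PQR files carry their own radii, which always take precedence).
#'
#' @return Named numeric vector of radii in Angstrom, names are upper-case
#'   element symbols.
#' @export
vdw_radii <- function() .default_vdw

.new_structure <- function(atoms, source = NA_character_) {
  rownames(atoms) <- NULL
  atoms$index <- seq_len(nrow(atoms))
  structure(list(atoms = atoms, source = source), class = "pp_structure")
}

#' @export
print.pp_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<pp_structure> %d atoms (%d heavy), %d residues, %d chain(s)\n",
              nrow(a), sum(a$is_heavy),
              length(unique(paste(a$chain, a$resno))),
              length(unique(a$chain))))
  invisible(x)
}

#' Number of atoms in a structure
#' @param x A `pp_structure`.
#' @param ... Unused.
#' @export
natoms <- function(x, ...) nrow(x$atoms)

# residue identifiers "chain:resno" for a set of atom rows
.res_ids <- function(atoms) paste(atoms$chain, atoms$resno, sep = ":")

#' Read a protein structure from PDB or PQR
#'
#' PDB files are parsed with \pkg{bio3d}; radii are assigned from the bundled
#' van der Waals table by element symbol. PQR files (whitespace-separated
#' ATOM/HETATM records with charge and radius as the last two numeric fields)
#' carry their own radii. Water residues (HOH/WAT/TIP3/SOL) are dropped by
#' default; hydrogens are kept but flagged as non-heavy.
#'
#' @param path File path.
#' @param format `"pdb"` or `"pqr"`. Defaults to the file extension.
#' @param keep_waters Keep water residues? Default `FALSE`.
#' @param keep_hetatm Keep non-water HETATM records? Default `FALSE` (ligands
#'   are supplied separately).
#' @param radii Named radius table for PDB input; see [vdw_radii()].
#' @return A `pp_structure`: a list with an `atoms` data frame
#'   (`index, element, elety, resid, chain, resno, x, y, z, radius, is_heavy`).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "pqr"),
                           keep_waters = FALSE, keep_hetatm = FALSE,
                           radii = vdw_radii()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "pqr") "pqr" else "pdb"
  }
  atoms <- if (format == "pqr") .parse_pqr(path) else .parse_pdb(path, radii)
  if (nrow(atoms) == 0L) stop("no ATOM/HETATM records parsed from ", path)
  waters <- c("HOH", "WAT", "TIP3", "SOL")
  if (!keep_waters) atoms <- atoms[!(atoms$resid %in% waters), , drop = FALSE]
  if (!keep_hetatm) {
    atoms <- atoms[atoms$type == "ATOM" | atoms$resid %in% waters, , drop = FALSE]
  }
  if (nrow(atoms) == 0L) stop("no atoms left after filtering in ", path)
  .new_structure(atoms, source = path)
}

.parse_pqr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM|HETATM)", lines)
  if (!any(keep)) stop("parse error: no ATOM/HETATM records in ", path)
  recs <- lines[keep]
  lineno <- which(keep)
  toks <- strsplit(trimws(recs), "\\s+")
  n <- vapply(toks, length, 1L)
  bad <- which(n < 10L)
  if (length(bad)) {
    stop(sprintf("parse error at line %d of %s: expected >=10 whitespace fields, got %d",
                 lineno[bad[1]], path, n[bad[1]]))
  }
  # Two common layouts: with chain (11 fields) or without (10 fields).
  parse_one <- function(tk, ln) {
    has_chain <- length(tk) >= 11L && is.na(suppressWarnings(as.numeric(tk[5])))
    off <- if (has_chain) 1L else 0L
    num <- suppressWarnings(as.numeric(tk[(5 + off):(9 + off)]))
    if (anyNA(num)) stop(sprintf("parse error at line %d: non-numeric coordinate/charge field", ln))
    list(type = tk[1], eleno = as.integer(tk[2]), elety = tk[3], resid = tk[4],
         chain = if (has_chain) tk[5] else "A",
         resno = as.integer(tk[5 + off]),
         x = num[2], y = num[3], z = num[4],
         charge = num[5],
         radius = suppressWarnings(as.numeric(tk[10 + off])))
  }
  out <- mapply(parse_one, toks, lineno, SIMPLIFY = FALSE)
  atoms <- do.call(rbind, lapply(out, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  if (anyNA(atoms$radius) || any(atoms$radius <= 0)) {
    i <- which(is.na(atoms$radius) | atoms$radius <= 0)[1]
    stop(sprintf("parse error at line %d: missing or non-positive radius", lineno[i]))
  }
  atoms$element <- .element_from_name(atoms$elety)
  atoms$is_heavy <- atoms$element != "H"
  atoms[, c("type", "eleno", "elety", "element", "resid", "chain", "resno",
            "x", "y", "z", "radius", "is_heavy")]
}

.element_from_name <- function(elety) {
  e <- toupper(sub("^[0-9']*", "", elety))
  two <- substr(e, 1, 2)
  one <- substr(e, 1, 1)
  ifelse(two %in% c("CL", "BR", "ZN", "MG", "FE", "MN", "SE"), two, one)
}

.parse_pdb <- function(path, radii) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
  a <- pdb$atom
  elem <- toupper(trimws(a$elesy))
  miss <- is.na(elem) | elem == ""
  if (any(miss)) elem[miss] <- .element_from_name(a$elety[miss])
  r <- unname(radii[elem])
  if (anyNA(r)) {
    bad <- unique(elem[is.na(r)])
    stop("no van der Waals radius for element(s): ", paste(bad, collapse = ", "),
         " (atoms ", paste(a$eleno[is.na(r)], collapse = ", "), ")")
  }
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  data.frame(type = a$type, eleno = a$eleno, elety = trimws(a$elety),
             element = elem, resid = trimws(a$resid), chain = chain,
             resno = a$resno, x = a$x, y = a$y, z = a$z,
             radius = r, is_heavy = elem != "H",
             stringsAsFactors = FALSE)
}

#' Write a structure as a PQR file
#'
#' Whitespace-separated PQR with a chain column; charge written as 0 when
#' absent (this package performs no charge assignment).
#'
#' @param structure A `pp_structure`.
#' @param path Output path.
#' @export
write_pqr <- function(structure, path) {
  a <- structure$atoms
  chg <- if ("charge" %in% names(a)) a$charge else rep(0, nrow(a))
  lines <- sprintf("ATOM  %5d %-4s %-4s %s %4d %8.3f %8.3f %8.3f %7.4f %6.4f",
                   a$index, a$elety, a$resid, a$chain, a$resno,
                   a$x, a$y, a$z, chg, a$radius)
  writeLines(lines, path)
  invisible(path)
}

#' Write ligand coordinates as xyz
#' @param coords Numeric matrix (n x 3) of ligand heavy-atom coordinates.
#' @param path Output path.
#' @param element Element symbol used for every atom (default `"C"`).
#' @export
write_xyz <- function(coords, path, element = "C") {
  coords <- as.matrix(coords)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(coords)), "ligand"), con)
  writeLines(sprintf("%s %10.4f %10.4f %10.4f", element,
                     coords[, 1], coords[, 2], coords[, 3]), con)
  invisible(path)
}

#' Read ligand coordinates from an xyz file
#' @param path xyz file path.
#' @return Numeric matrix (n x 3).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  toks <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  m <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  colnames(m) <- c("x", "y", "z")
  m
}

# squared distances between rows of two n x 3 matrices: n x m matrix
.cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
}

#' Define observed binding regions around ligands
#'
#' For each ligand, the binding region is the set of protein heavy atoms whose
#' centers lie within `cutoff` of any ligand heavy-atom center (center-to-center
#' distances, no radius inflation).
#'
#' @param structure A `pp_structure`.
#' @param ligands A list of numeric matrices (n x 3), one per ligand, of ligand
#'   heavy-atom coordinates. A single matrix is accepted.
#' @param cutoff Contact cutoff in Angstrom (default 5).
#' @return A list of `pp_binding_region` objects with fields `ligand_id`,
#'   `ligand_atoms`, `region_atoms` (atom indices), `region_residues`
#'   (chain:resno strings) and `empty` flag.
#' @export
define_binding_regions <- function(structure, ligands, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  if (is.matrix(ligands) || is.data.frame(ligands)) ligands <- list(ligands)
  a <- structure$atoms
  heavy <- which(a$is_heavy)
  pc <- as.matrix(a[heavy, c("x", "y", "z")])
  lapply(seq_along(ligands), function(i) {
    lig <- as.matrix(ligands[[i]])
    if (nrow(lig) == 0L) stop("ligand ", i, " has zero heavy atoms")
    d2 <- .cross_dist2(pc, lig)
    inreg <- heavy[apply(d2, 1, min) <= cutoff^2]
    reg <- structure(list(
      ligand_id = if (!is.null(names(ligands))) names(ligands)[i] else paste0("lig", i),
      ligand_index = i,
      ligand_atoms = lig,
      region_atoms = inreg,
      region_residues = unique(.res_ids(a[inreg, , drop = FALSE])),
      empty = length(inreg) == 0L
    ), class = "pp_binding_region")
    if (reg$empty) {
      message("ligand ", reg$ligand_id, ": no protein heavy atom within ",
              cutoff, " A (empty binding region)")
    }
    reg
  })
}

#' Deduplicate overlapping binding regions
#'
#' For every pair of regions A, B the inclusion ratios |A&B|/|A| and |A&B|/|B|
#' are computed. If either exceeds 50\%, the region with the higher ratio (the
#' smaller, mostly-included one) is removed. Otherwise, if the Jaccard index
#' is at least 30\%, the region with the higher inclusion ratio is discarded.
#' Pairs are processed in (i, j) order, removals applied greedily with
#' re-checking until no pair violates either rule; exact ties keep the
#' lower-index ligand.
#'
#' @param regions List of `pp_binding_region`.
#' @param overlap_max Inclusion-ratio threshold (fraction, default 0.5).
#' @param jaccard_max Jaccard threshold (fraction, default 0.3).
#' @return Filtered list of regions.
#' @export
deduplicate_binding_regions <- function(regions, overlap_max = 0.5,
                                        jaccard_max = 0.3) {
  stopifnot(length(regions) >= 1L)
  alive <- rep(TRUE, length(regions))
  repeat {
    removed <- FALSE
    idx <- which(alive)
    if (length(idx) < 2L) break
    for (ii in seq_len(length(idx) - 1L)) {
      for (jj in (ii + 1L):length(idx)) {
        i <- idx[ii]; j <- idx[jj]
        if (!alive[i] || !alive[j]) next
        A <- regions[[i]]$region_atoms
        B <- regions[[j]]$region_atoms
        inter <- length(intersect(A, B))
        if (inter == 0L) next
        rA <- inter / length(A)
        rB <- inter / length(B)
        jac <- inter / length(union(A, B))
        drop <- NA_integer_
        if (rA > overlap_max || rB > overlap_max) {
          drop <- if (rA > rB) i else if (rB > rA) j else j  # tie: keep lower index
        } else if (jac >= jaccard_max) {
          drop <- if (rA > rB) i else if (rB > rA) j else j
        }
        if (!is.na(drop)) {
          alive[drop] <- FALSE
          removed <- TRUE
        }
      }
    }
    if (!removed) break
  }
  regions[alive]
}

#' Solvent-exposed residues
#'
#' A residue is exposed if at least one of its atoms can be touched by a
#' solvent probe of the given radius: either the atom is tangent to an
#' accepted triplet probe (see [enumerate_probes()]), or a probe-sized sphere
#' placed tangent to the atom along one of a deterministic set of directions
#' is clash-free (the fallback covers convex regions where no triplet probe
#' exists).
#'
#' @param structure A `pp_structure`.
#' @param probe_radius Probe radius in Angstrom (default 1.4).
#' @param n_dir Number of tangent directions sampled in the convex fallback.
#' @return Character vector of exposed residue ids (`"chain:resno"`).
#' @export
solvent_exposed_residues <- function(structure, probe_radius = 1.4,
                                     n_dir = 64L) {
  a <- structure$atoms
  stopifnot(nrow(a) > 0L)
  probes <- enumerate_probes(structure, probe_radius)
  tangent <- if (nrow(probes) > 0L) {
    unique(c(probes$a1, probes$a2, probes$a3))
  } else integer(0)
  exposed_atom <- logical(nrow(a))
  exposed_atom[tangent] <- TRUE
  # direction-sampled tangency fallback for atoms not touching any triplet probe
  dirs <- .fibonacci_sphere(n_dir)
  cen <- as.matrix(a[, c("x", "y", "z")])
  rad <- a$radius
  todo <- which(!exposed_atom)
  for (i in todo) {
    cand <- cen[rep(i, nrow(dirs)), , drop = FALSE] + dirs * (rad[i] + probe_radius)
    d2 <- .cross_dist2(cand, cen)
    ok <- sqrt(pmax(d2, 0)) >= matrix(rad + probe_radius - 1e-6,
                                      nrow(cand), nrow(cen), byrow = TRUE)
    ok[, i] <- TRUE
    if (any(rowSums(ok) == ncol(ok))) exposed_atom[i] <- TRUE
  }
  unique(.res_ids(a[exposed_atom, , drop = FALSE]))
}

# deterministic Fibonacci sphere directions (n x 3 unit vectors)
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' One-letter residue codes per chain
#' @param structure A `pp_structure`.
#' @return Named list (by chain) of data frames with `resno` and `code`.
#' @keywords internal
.chain_sequences <- function(structure) {
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  aa1 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  a <- structure$atoms
  res <- unique(a[, c("chain", "resno", "resid")])
  res$code <- aa1[match(res$resid, aa3)]
  res$code[is.na(res$code)] <- "X"
  split(res[, c("resno", "code")], res$chain)
}

#' Map holo binding residues onto an apo structure
#'
#' Chains are matched by global sequence alignment (Needleman-Wunsch with
#' affine gaps, via \pkg{Biostrings}); only exact residue matches are mapped.
#' Mapped residues are then filtered to those with at least one
#' solvent-exposed atom in the apo structure.
#'
#' @param holo,apo `pp_structure` objects.
#' @param holo_residues Character vector of holo residue ids (`"chain:resno"`).
#' @param probe_radius Probe radius for the apo exposure test (default 1.4).
#' @return Character vector of apo residue ids.
#' @export
map_apo_residues <- function(holo, apo, holo_residues, probe_radius = 1.4) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("map_apo_residues requires the Biostrings package")
  }
  hs <- .chain_sequences(holo)
  as_ <- .chain_sequences(apo)
  mapped <- character(0)
  for (ch in intersect(names(hs), names(as_))) {
    s1 <- paste(hs[[ch]]$code, collapse = "")
    s2 <- paste(as_[[ch]]$code, collapse = "")
    al <- Biostrings::pairwiseAlignment(s1, s2, type = "global",
                                        gapOpening = 10, gapExtension = 0.5)
    p1 <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    p2 <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    i1 <- 0L; i2 <- 0L
    for (k in seq_along(p1)) {
      if (p1[k] != "-") i1 <- i1 + 1L
      if (p2[k] != "-") i2 <- i2 + 1L
      if (p1[k] != "-" && p2[k] != "-" && p1[k] == p2[k]) {
        hid <- paste(ch, hs[[ch]]$resno[i1], sep = ":")
        if (hid %in% holo_residues) {
          mapped <- c(mapped, paste(ch, as_[[ch]]$resno[i2], sep = ":"))
        }
      }
    }
  }
  exposed <- solvent_exposed_residues(apo, probe_radius)
  intersect(unique(mapped), exposed)
}

#' Export a binding-region table as TSV
#' @param regions List of `pp_binding_region`.
#' @param structure The `pp_structure` the regions refer to.
#' @param path Output TSV path.
#' @export
write_binding_regions <- function(regions, structure, path) {
  rows <- do.call(rbind, lapply(regions, function(r) {
    a <- structure$atoms[r$region_atoms, , drop = FALSE]
    data.frame(ligand_id = r$ligand_id, chain = a$chain, resno = a$resno,
               atom_index = a$index, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
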
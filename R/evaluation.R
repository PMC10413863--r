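# Ligand-coverage / pocket-coverage metrics, hit criteria and the Top-N
# ranking protocols (standard, nested, single-pocket), in atom mode (holo
# structures) and residue mode (apo structures).

# round a percentage up to the first decimal (ceiling at 0.1% resolution)
.ceil1 <- function(x) ceiling(x * 10 - 1e-9) / 10

#' Ligand Coverage and Pocket Coverage scores
#'
#' "Contact" means a center-to-center distance below the cutoff. In atom
#' mode, LC is the fraction of ligand heavy atoms in contact with at least
#' one pocket atom, over those in contact with at least one protein atom;
#' PC is the symmetric score: the fraction of pocket atoms within the
#' cutoff of any ligand heavy atom. In residue mode both scores are set
#' overlaps of residue-id sets (pocket residues against the mapped
#' binding-site residues). Percentages are rounded up to the first
#' decimal.
#'
#' @param pocket_atoms Atom-mode: n x 3 coordinate matrix of pocket heavy
#'   atoms. Residue-mode: character vector of pocket residue ids.
#' @param ligand_atoms Atom-mode: m x 3 ligand heavy-atom coordinates.
#'   Residue-mode: character vector of binding-site residue ids.
#' @param protein_atoms Atom-mode only: all protein heavy-atom
#'   coordinates.
#' @param cutoff Contact cutoff in Angstrom (default 5).
#' @param mode `"atom"` or `"residue"`.
#' @return List with `lc` and `pc` in percent; `lc` is `NA` (flagged
#'   `undefined = TRUE`) when the ligand contacts no protein atom.
#' @export
coverage_scores <- function(pocket_atoms, ligand_atoms, protein_atoms = NULL,
                            cutoff = 5.0, mode = c("atom", "residue")) {
  mode <- match.arg(mode)
  if (mode == "residue") {
    site <- unique(as.character(ligand_atoms))
    pock <- unique(as.character(pocket_atoms))
    if (length(site) == 0L) stop("empty binding-site residue set")
    if (length(pock) == 0L) return(list(lc = 0, pc = 0, undefined = FALSE))
    inter <- length(intersect(site, pock))
    return(list(lc = .ceil1(100 * inter / length(site)),
                pc = .ceil1(100 * inter / length(pock)),
                undefined = FALSE))
  }
  lig <- as.matrix(ligand_atoms)
  pock <- as.matrix(pocket_atoms)
  prot <- as.matrix(protein_atoms)
  if (nrow(lig) == 0L) stop("ligand has zero heavy atoms")
  d_lp <- sqrt(pmax(.cross_dist2(lig, prot), 0))
  in_contact_protein <- apply(d_lp, 1, min) < cutoff
  nL <- sum(in_contact_protein)
  if (nL == 0L) {
    return(list(lc = NA_real_, pc = 0, undefined = TRUE))
  }
  if (nrow(pock) == 0L) return(list(lc = 0, pc = 0, undefined = FALSE))
  d_lq <- sqrt(pmax(.cross_dist2(lig, pock), 0))
  lc_num <- sum(apply(d_lq, 1, min) < cutoff & in_contact_protein)
  pc_num <- sum(apply(d_lq, 2, min) < cutoff)
  list(lc = .ceil1(100 * lc_num / nL),
       pc = .ceil1(100 * pc_num / nrow(pock)),
       undefined = FALSE)
}

#' Hit decision from LC/PC scores
#'
#' A pocket matches a binding site when it reaches at least `lc_min` in
#' Ligand Coverage and at least `pc_min` in Pocket Coverage (thresholds
#' inclusive; defaults 50% and 20%).
#'
#' @param lc,pc Scores in percent (`lc` may be `NA` for undefined sites).
#' @param lc_min,pc_min Thresholds in percent.
#' @return Logical.
#' @export
is_hit <- function(lc, pc, lc_min = 50, pc_min = 20) {
  !is.na(lc) & lc >= lc_min & pc >= pc_min
}

#' Top-N summary over ranked prediction lists
#'
#' One ranked pocket list per binding site. The rank-of-hit for a site is
#' the number of non-matching pockets above the first matching one; a site
#' counts in Top-N when its rank-of-hit is below N. Normalization is by
#' the number of sites (structure-ligand pairs). In nested mode a master
#' pocket matches when itself or any of its (at most three) top-ranked
#' subpockets matches (`sub_hit` column). Mean LC/PC are averaged over the
#' first-matching (successful) pockets. Sites whose LC is undefined
#' (ligand contacting no protein atom) are excluded from the
#' normalization with a warning; sites with an empty list count as
#' misses.
#'
#' @param predictions List of data frames, one per site, ordered by rank,
#'   with columns `hit` (logical), `lc`, `pc`, and for nested mode
#'   `sub_hit` (logical).
#' @param mode `"standard"`, `"nested"` or `"single_pocket"` (the latter
#'   expects lists already expanded by [expand_single_pocket_list()] and
#'   counts like standard).
#' @param top_n Integer vector of N values (default 1, 3, 10).
#' @return Object of class `pp_protocol_summary`: list with `top`
#'   (named percentages), `mean_lc`, `mean_pc`, `n_sites`, `mode`.
#' @export
protocol_summary <- function(predictions,
                             mode = c("standard", "nested", "single_pocket"),
                             top_n = c(1L, 3L, 10L)) {
  mode <- match.arg(mode)
  ranks <- numeric(0)
  lcs <- numeric(0); pcs <- numeric(0)
  n_sites <- 0L
  for (site in predictions) {
    if (!is.null(site) && nrow(site) > 0 &&
        !is.null(site$undefined) && isTRUE(site$undefined[1])) {
      warning("site with undefined LC excluded from normalization")
      next
    }
    n_sites <- n_sites + 1L
    if (is.null(site) || nrow(site) == 0L) {
      ranks <- c(ranks, Inf)
      next
    }
    match_flag <- site$hit
    if (mode == "nested" && !is.null(site$sub_hit)) {
      match_flag <- match_flag | site$sub_hit
    }
    first <- which(match_flag)[1]
    if (is.na(first)) {
      ranks <- c(ranks, Inf)
    } else {
      ranks <- c(ranks, sum(!match_flag[seq_len(first - 1L)]))
      lcs <- c(lcs, site$lc[first])
      pcs <- c(pcs, site$pc[first])
    }
  }
  if (n_sites == 0L) stop("no evaluable sites")
  top <- vapply(top_n, function(N) 100 * sum(ranks < N) / n_sites, 1)
  names(top) <- paste0("top", top_n)
  structure(list(top = top,
                 mean_lc = if (length(lcs)) mean(lcs, na.rm = TRUE) else NA,
                 mean_pc = if (length(pcs)) mean(pcs) else NA,
                 n_sites = n_sites, mode = mode),
            class = "pp_protocol_summary")
}

#' @export
print.pp_protocol_summary <- function(x, ...) {
  cat(sprintf("<pp_protocol_summary> mode=%s, %d site(s)\n", x$mode,
              x$n_sites))
  cat(paste(sprintf("  %s = %.1f%%", names(x$top), x$top), collapse = "\n"),
      "\n")
  cat(sprintf("  mean LC = %.1f%%, mean PC = %.1f%% (successful pockets)\n",
              x$mean_lc, x$mean_pc))
  invisible(x)
}
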
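#' Load a query protein structure from PDB
#'
#' Reads ATOM records with [bio3d::read.pdb()], keeps one chain, drops
#' hydrogens, resolves alternate locations by keeping the highest-occupancy
#' conformer, and validates a query-position-to-residue-number mapping
#' against the query sequence (a residue-name mismatch signals a numbering
#' offset and is a hard error).
#'
#' @param path Path to a PDB file.
#' @param query Query amino-acid sequence (ungapped, one-letter); used to
#'   validate the mapping. `NULL` skips validation.
#' @param chain Chain identifier (default `"A"`).
#' @param offset Residue-number offset: query position `p` maps to PDB
#'   residue number `p + offset` (default 0).
#' @return A `structure_model`: list with `atoms` (data.frame: resno, resid,
#'   elety, x, y, z), `chain`, `offset`, `query`.
#' @export
load_structure <- function(path, query = NULL, chain = "A", offset = 0) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (!nrow(at))
    pc_error(sprintf("no ATOM records for chain '%s'", chain), "mapping_error")
  at <- at[is.na(at$elesy) | at$elesy != "H", , drop = FALSE]
  # altloc: keep highest occupancy per (resno, atom name)
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$resno, at$elety)
    at$o[is.na(at$o)] <- 1
    ord <- order(key, -at$o)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$resno, at$elety)), , drop = FALSE]
    at <- at[order(at$resno), , drop = FALSE]
  }
  model <- structure(list(
    atoms = at[, c("resno", "resid", "elety", "x", "y", "z")],
    chain = chain, offset = offset, query = query),
    class = "structure_model")
  if (!is.null(query)) {
    qchars <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
    for (p in seq_along(qchars)) {
      res <- model$atoms[model$atoms$resno == p + offset, , drop = FALSE]
      if (!nrow(res)) next                       # unresolved residue: tolerated
      letter <- unname(AA_THREE[res$resid[1]])
      if (is.na(letter) || letter != qchars[p])
        pc_error(sprintf(
          "residue mismatch at query position %d: sequence %s vs structure %s (check numbering offset)",
          p, qchars[p], res$resid[1]), "mapping_error")
    }
  }
  model
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: chain %s, %d residues, %d heavy atoms\n",
              x$chain, length(unique(x$atoms$resno)), nrow(x$atoms)))
  invisible(x)
}

residue_atoms <- function(model, position) {
  res <- model$atoms[model$atoms$resno == position + model$offset, , drop = FALSE]
  if (!nrow(res))
    pc_error(sprintf("query position %d not resolved in structure", position),
             "mapping_error")
  res
}

min_atom_dist <- function(a, b) {
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(max(min(d2), 0))
}

#' Minimum heavy-atom distance from a residue to the active site
#'
#' @param model A `structure_model`.
#' @param position Query position (1-based, ungapped).
#' @param active_site Integer vector of query positions declared as the
#'   active site, or a data.frame of ligand atom coordinates with columns
#'   `x`, `y`, `z`.
#' @return Minimum Euclidean distance in Angstrom between any heavy atom of
#'   the residue and any heavy atom of the active-site set.
#' @export
distance_to_active_site <- function(model, position, active_site) {
  if (is.null(active_site) || (!is.data.frame(active_site) && !length(active_site)))
    pc_error("active_site set is empty", "config_error")
  res <- residue_atoms(model, position)
  if (is.data.frame(active_site)) {
    site <- active_site
  } else {
    site <- do.call(rbind, lapply(active_site, function(p) residue_atoms(model, p)))
  }
  min_atom_dist(res, site)
}

BACKBONE <- c("N", "CA", "C", "O", "OXT")
CHARGED_N <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"), HIS = c("ND1", "NE2"))
CARBOXYL_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Detect side-chain hydrogen bonds and salt bridges of a residue
#'
#' Geometric, distance-only detection on heavy atoms. A hydrogen bond is a
#' side-chain N or O of the residue within `hbond_max` (default 3.5 A) of an
#' N or O atom of any other residue — side chain or backbone, since the
#' criterion concerns the candidate's own side chain. A salt bridge pairs a
#' side-chain charged nitrogen (Lys NZ; Arg NH1/NH2/NE; His ND1/NE2) with a
#' side-chain carboxylate oxygen (Asp OD1/OD2; Glu OE1/OE2) within
#' `salt_max` (default 4.0 A), in either direction. Pairs qualifying as salt
#' bridges are reported once, as salt bridges.
#'
#' @param model A `structure_model`.
#' @param position Query position.
#' @param hbond_max,salt_max Distance thresholds in Angstrom.
#' @return data.frame with columns `partner_resno`, `kind` (`"hbond"` or
#'   `"salt_bridge"`), `distance`; zero rows when the side chain makes no
#'   contact (e.g. Gly).
#' @export
detect_sidechain_bonds <- function(model, position, hbond_max = 3.5,
                                   salt_max = 4.0) {
  res <- residue_atoms(model, position)
  resno <- position + model$offset
  side <- res[!res$elety %in% BACKBONE, , drop = FALSE]
  out <- data.frame(partner_resno = integer(0), kind = character(0),
                    distance = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(side)) return(out)
  others <- model$atoms[model$atoms$resno != resno, , drop = FALSE]
  if (!nrow(others)) return(out)

  is_no <- function(a) substr(a$elety, 1, 1) %in% c("N", "O")
  charged_n <- function(a) {
    ok <- logical(nrow(a))
    for (r in names(CHARGED_N)) ok <- ok | (a$resid == r & a$elety %in% CHARGED_N[[r]])
    ok
  }
  carboxyl_o <- function(a) {
    ok <- logical(nrow(a))
    for (r in names(CARBOXYL_O)) ok <- ok | (a$resid == r & a$elety %in% CARBOXYL_O[[r]])
    ok
  }
  for (pr in unique(others$resno)) {
    oa <- others[others$resno == pr, , drop = FALSE]
    osc <- oa[!oa$elety %in% BACKBONE, , drop = FALSE]
    # salt bridge: either direction, side-chain groups only
    sb <- Inf
    a1 <- side[charged_n(side), , drop = FALSE]
    b1 <- osc[carboxyl_o(osc), , drop = FALSE]
    if (nrow(a1) && nrow(b1)) sb <- min(sb, min_atom_dist(a1, b1))
    a2 <- side[carboxyl_o(side), , drop = FALSE]
    b2 <- osc[charged_n(osc), , drop = FALSE]
    if (nrow(a2) && nrow(b2)) sb <- min(sb, min_atom_dist(a2, b2))
    if (is.finite(sb) && sb <= salt_max) {
      out <- rbind(out, data.frame(partner_resno = pr, kind = "salt_bridge",
                                   distance = sb, stringsAsFactors = FALSE))
      next
    }
    hd <- side[is_no(side), , drop = FALSE]
    hb <- oa[is_no(oa), , drop = FALSE]
    if (nrow(hd) && nrow(hb)) {
      d <- min_atom_dist(hd, hb)
      if (d <= hbond_max)
        out <- rbind(out, data.frame(partner_resno = pr, kind = "hbond",
                                     distance = d, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Apply the structural exclusion criteria to candidate sites
#'
#' Each candidate's `filter_status` is set to `"rejected_distance"` when its
#' residue lies within `min_distance` of the active site (catalysis risk),
#' else `"rejected_bonded"` when its side chain makes a hydrogen bond or
#' salt bridge (stability risk), else `"passed"`. Nothing is deleted, so the
#' returned table is a full audit trail; input order is preserved.
#'
#' @param candidates A `candidate_sites` data.frame.
#' @param model A `structure_model`.
#' @param active_site Active-site declaration (see
#'   [distance_to_active_site()]).
#' @param min_distance Exclusion radius in Angstrom; a site must be strictly
#'   farther than this (default 6.0).
#' @param hbond_max,salt_max Bond-detection thresholds, in Angstrom.
#' @return The candidate table with `filter_status` set and added columns
#'   `active_site_distance`, `n_hbonds`, `n_salt_bridges`.
#' @export
apply_structural_filters <- function(candidates, model, active_site,
                                     min_distance = 6.0, hbond_max = 3.5,
                                     salt_max = 4.0) {
  stopifnot(is.data.frame(candidates))
  n <- nrow(candidates)
  dist <- numeric(n); nh <- integer(n); ns <- integer(n)
  status <- character(n)
  for (i in seq_len(n)) {
    p <- candidates$position[i]
    dist[i] <- distance_to_active_site(model, p, active_site)
    bonds <- detect_sidechain_bonds(model, p, hbond_max, salt_max)
    nh[i] <- sum(bonds$kind == "hbond")
    ns[i] <- sum(bonds$kind == "salt_bridge")
    status[i] <- if (dist[i] <= min_distance) "rejected_distance"
      else if (nh[i] + ns[i] > 0) "rejected_bonded"
      else "passed"
  }
  out <- candidates
  out$active_site_distance <- dist
  out$n_hbonds <- nh
  out$n_salt_bridges <- ns
  out$filter_status <- status
  out
}
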
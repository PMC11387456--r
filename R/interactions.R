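#' SIFt interaction-type scheme
#'
#' The classic 9-type structural interaction fingerprint scheme. Bit order is
#' fixed: any contact, backbone contact, side-chain contact, polar,
#' hydrophobic, hydrogen bond with the protein as acceptor (ligand donates),
#' hydrogen bond with the protein as donor, aromatic (ring-ring), charged
#' (salt bridge).
#'
#' @return character vector of interaction type names.
#' @export
sift_scheme <- function() {
  c("contact", "backbone_contact", "sidechain_contact", "polar",
    "hydrophobic", "hb_protein_acceptor", "hb_protein_donor",
    "aromatic", "charged")
}

#' Default geometric cutoffs for interaction detection
#'
#' All distances in angstroms, angles in degrees. These are
#' literature-standard values; every SIFt produced records the cutoff set it
#' was computed with.
#'
#' @return named list: `contact` (heavy-heavy, 4.5), `hydrophobic`
#'   (apolar C-C, 4.5), `polar` (polar-polar, 4.0), `hbond`
#'   (donor-acceptor heavy, 3.5), `hbond_angle` (D-H...A minimum, 120),
#'   `charged` (group centers, 4.0), `aromatic` (ring centroids, 5.5).
#' @export
default_cutoffs <- function() {
  list(contact = 4.5, hydrophobic = 4.5, polar = 4.0,
       hbond = 3.5, hbond_angle = 120, charged = 4.0, aromatic = 5.5)
}

# --- residue feature lookup -------------------------------------------------

# side-chain features per standard amino acid; backbone features
# (N donor except PRO, O/OXT acceptors) are added at detection time
residue_feature_table <- function() {
  list(
    ALA = list(hydroph = "CB"),
    ARG = list(donors = c("NE", "NH1", "NH2"), cation = c("NH1", "NH2", "NE"),
               hydroph = c("CB", "CG")),
    ASN = list(donors = "ND2", acceptors = "OD1", hydroph = "CB"),
    ASP = list(acceptors = c("OD1", "OD2"), anion = c("OD1", "OD2"),
               hydroph = "CB"),
    CYS = list(donors = "SG", hydroph = "CB"),
    GLN = list(donors = "NE2", acceptors = "OE1", hydroph = c("CB", "CG")),
    GLU = list(acceptors = c("OE1", "OE2"), anion = c("OE1", "OE2"),
               hydroph = c("CB", "CG")),
    GLY = list(),
    HIS = list(donors = c("ND1", "NE2"), acceptors = c("ND1", "NE2"),
               rings = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
               hydroph = "CB"),
    ILE = list(hydroph = c("CB", "CG1", "CG2", "CD1")),
    LEU = list(hydroph = c("CB", "CG", "CD1", "CD2")),
    LYS = list(donors = "NZ", cation = "NZ", hydroph = c("CB", "CG", "CD")),
    MET = list(hydroph = "CB"),
    PHE = list(rings = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
               hydroph = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    PRO = list(hydroph = c("CB", "CG")),
    SER = list(donors = "OG", acceptors = "OG"),
    THR = list(donors = "OG1", acceptors = "OG1", hydroph = "CG2"),
    TRP = list(donors = "NE1",
               rings = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
                            c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
               hydroph = c("CB", "CG", "CD2", "CE3", "CZ3", "CH2", "CZ2")),
    TYR = list(donors = "OH", acceptors = "OH",
               rings = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
               hydroph = c("CB", "CG", "CD1", "CD2", "CE1", "CE2")),
    VAL = list(hydroph = c("CB", "CG1", "CG2"))
  )
}

STANDARD_AA <- names(residue_feature_table())

# --- ligand feature perception ---------------------------------------------

standard_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                      Br = 1, I = 1, H = 1)

#' Perceive chemical features on a ligand pose
#'
#' Rule-based typing from the element/bond graph: donors are N/O/S with at
#' least one hydrogen (explicit, or implicit by standard valence); acceptors
#' are N/O with lone-pair availability (excluding positively charged atoms,
#' amide nitrogens, and pyrrole-type aromatic NH); cations are formally
#' positive atoms plus amidinium/guanidinium groups under chargeable-group
#' rules; anions are formally negative oxygens plus carboxylate groups;
#' hydrophobes are carbons with no N/O/S neighbor. Aromatic rings (5- or
#' 6-membered, aromatic-flagged or Kekule-alternating, coplanar within 0.1
#' angstrom) get a centroid and unit normal.
#'
#' @param ligand a `ligand_pose`.
#' @return object of class `feature_set`: atom-index sets `donors`,
#'   `acceptors`, `cations`, `anions`, `hydrophobes`; `cation_groups` /
#'   `anion_groups` (lists with member atoms and center); `rings` (atom
#'   indices, centroid, normal); `has_explicit_h`.
#' @export
perceive_features <- function(ligand) {
  a <- ligand$atoms
  b <- ligand$bonds
  n <- nrow(a)
  nb <- lapply(seq_len(n), function(i)
    c(b$to[b$from == i], b$from[b$to == i]))
  bond_order_sum <- vapply(seq_len(n), function(i) {
    o <- c(b$order[b$from == i], b$order[b$to == i])
    sum(ifelse(o == 4, 1.5, o))
  }, numeric(1))
  expl_h <- vapply(nb, function(j) sum(a$element[j] == "H"), numeric(1))
  val <- standard_valence[a$element]
  val[is.na(val)] <- 4
  # charge raises N capacity (ammonium); anionic O holds one bond, no H
  cap <- val + ifelse(a$element == "N", a$charge, 0)
  cap[a$element == "O" & a$charge < 0] <- 1
  impl_h <- pmax(0, round(cap - bond_order_sum))
  impl_h[expl_h > 0] <- 0  # explicit-H molecules: trust the explicit count
  n_h <- expl_h + impl_h

  heavy <- a$element != "H"
  is_amide_n <- vapply(seq_len(n), function(i) {
    if (a$element[i] != "N") return(FALSE)
    any(vapply(nb[[i]], function(j) {
      a$element[j] == "C" &&
        any(b$order[(b$from == j & a$element[b$to] == "O") |
                    (b$to == j & a$element[b$from] == "O")] == 2)
    }, logical(1)))
  }, logical(1))

  rings <- perceive_rings(a, b, nb)
  arom_atoms <- unique(unlist(lapply(rings, `[[`, "atoms")))
  pyrrole_nh <- a$element == "N" & seq_len(n) %in% arom_atoms & n_h > 0

  # chargeable groups
  cation_groups <- list(); anion_groups <- list()
  for (i in which(a$element == "C" & heavy)) {
    nn <- nb[[i]][a$element[nb[[i]]] != "H"]
    n_nbrs <- nn[a$element[nn] == "N"]
    dbl_n <- any((b$from == i & b$order == 2 & a$element[b$to] == "N") |
                 (b$to == i & b$order == 2 & a$element[b$from] == "N"))
    touches_os <- any(a$element[nn] %in% c("O", "S"))
    if (length(n_nbrs) >= 2 && dbl_n && !touches_os && !(i %in% arom_atoms)) {
      mem <- c(i, n_nbrs)
      cation_groups[[length(cation_groups) + 1L]] <-
        list(atoms = mem, center = colMeans(a[n_nbrs, c("x", "y", "z")]))
    }
    o_nbrs <- nn[a$element[nn] == "O"]
    dbl_o <- any((b$from == i & b$order == 2 & a$element[b$to] == "O") |
                 (b$to == i & b$order == 2 & a$element[b$from] == "O"))
    # carboxylate: C with two O, one double, the single-bonded O bearing no H
    if (length(o_nbrs) == 2 && dbl_o) {
      single_o <- o_nbrs[vapply(o_nbrs, function(j) {
        !any((b$from == i & b$to == j & b$order == 2) |
             (b$to == i & b$from == j & b$order == 2))
      }, logical(1))]
      if (length(single_o) && all(n_h[single_o] == 0 | a$charge[single_o] < 0)) {
        anion_groups[[length(anion_groups) + 1L]] <-
          list(atoms = c(i, o_nbrs), center = colMeans(a[o_nbrs, c("x", "y", "z")]))
      }
    }
  }
  for (i in which(a$charge > 0 & heavy)) {
    in_grp <- any(vapply(cation_groups, function(g) i %in% g$atoms, logical(1)))
    if (!in_grp)
      cation_groups[[length(cation_groups) + 1L]] <-
        list(atoms = i, center = as.numeric(a[i, c("x", "y", "z")]))
  }
  for (i in which(a$charge < 0 & a$element == "O")) {
    in_grp <- any(vapply(anion_groups, function(g) i %in% g$atoms, logical(1)))
    if (!in_grp)
      anion_groups[[length(anion_groups) + 1L]] <-
        list(atoms = i, center = as.numeric(a[i, c("x", "y", "z")]))
  }
  cation_atoms <- unique(unlist(lapply(cation_groups, `[[`, "atoms")))
  anion_atoms <- unique(unlist(lapply(anion_groups, `[[`, "atoms")))

  donors <- which(a$element %in% c("N", "O", "S") & n_h > 0)
  acceptors <- which(
    a$element %in% c("N", "O") & a$charge <= 0 &
      !(a$element == "N" & (is_amide_n | pyrrole_nh)) &
      !(seq_len(n) %in% setdiff(cation_atoms, integer(0)) & a$element == "N")
  )
  acceptors <- setdiff(acceptors, cation_atoms)
  hydrophobes <- which(a$element == "C" & vapply(nb, function(j)
    !any(a$element[j] %in% c("N", "O", "S")), logical(1)))

  structure(list(
    donors = donors, acceptors = acceptors,
    cations = cation_atoms %||% integer(0),
    anions = anion_atoms %||% integer(0),
    cation_groups = cation_groups, anion_groups = anion_groups,
    hydrophobes = hydrophobes, rings = rings,
    n_h = n_h, has_explicit_h = any(a$element == "H")
  ), class = "feature_set")
}

# ring perception: smallest ring through each bond (5- or 6-membered),
# aromatic if bond-flagged or Kekule-alternating, and coplanar
perceive_rings <- function(a, b, nb, planarity_tol = 0.1) {
  n <- nrow(a)
  if (!nrow(b)) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = b$from, to = b$to), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  rings <- list()
  seen <- character(0)
  for (k in seq_len(nrow(b))) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(b$from[k], b$to[k])))
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = as.character(b$from[k]), to = as.character(b$to[k])))
    path <- as.integer(names(sp$vpath[[1]]))
    if (length(path) %in% c(5L, 6L)) {
      key <- paste(sort(path), collapse = "-")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- path
      }
    }
  }
  out <- list()
  for (ring in rings) {
    if (!all(a$element[ring] %in% c("C", "N", "O", "S"))) next
    ring_bonds <- b[(b$from %in% ring & b$to %in% ring), , drop = FALSE]
    arom_flag <- all(ring_bonds$order == 4)
    n_dbl <- sum(ring_bonds$order == 2)
    kekule <- (length(ring) == 6 && n_dbl == 3) ||
      (length(ring) == 5 && n_dbl == 2 &&
         any(a$element[ring] %in% c("N", "O", "S")))
    if (!(arom_flag || kekule)) next
    xyz <- as.matrix(a[ring, c("x", "y", "z")])
    cen <- colMeans(xyz)
    s <- svd(sweep(xyz, 2, cen))
    normal <- s$v[, 3]
    dev <- abs(sweep(xyz, 2, cen) %*% normal)
    if (max(dev) > planarity_tol) next
    out[[length(out) + 1L]] <- list(atoms = ring, centroid = cen,
                                    normal = normal / sqrt(sum(normal^2)))
  }
  out
}

# --- detection --------------------------------------------------------------

#' Detect typed ligand-residue interactions in a complex
#'
#' Applies the geometric criteria of [default_cutoffs()] between perceived
#' ligand features and the per-amino-acid residue feature lookup. Events are
#' deterministic and independent of atom ordering. Nonstandard residues are
#' skipped with a warning (or an error with `on_nonstandard = "error"`).
#' When the ligand carries no explicit hydrogens, hydrogen-bond detection
#' degrades to the distance-only criterion and events carry a
#' `"no-H mode"` note.
#'
#' @param cx a `complex3d`.
#' @param cutoffs cutoff list, see [default_cutoffs()].
#' @param method `"grid"` (cell-list accelerated) or `"brute"` (all pairs);
#'   both produce identical events.
#' @param on_nonstandard `"warn"` or `"error"`.
#' @return data frame of class `interaction_events`: `residue` (label),
#'   `residue_key`, `itype`, `distance`, `angle`, `ligand_atoms`,
#'   `residue_atoms` (list columns), `note`.
#' @export
detect_interactions <- function(cx, cutoffs = default_cutoffs(),
                                method = c("grid", "brute"),
                                on_nonstandard = c("warn", "error")) {
  method <- match.arg(method)
  on_nonstandard <- match.arg(on_nonstandard)
  stopifnot(inherits(cx, "complex3d"))
  feats <- perceive_features(cx$ligand)
  rt <- residue_table(cx$receptor)
  nonstd <- rt$key[!rt$resid %in% STANDARD_AA]
  if (length(nonstd)) {
    msg <- paste("nonstandard residue(s) skipped:", paste(nonstd, collapse = ", "))
    if (on_nonstandard == "error") stop_arg(msg) else warning(msg)
    rt <- rt[rt$resid %in% STANDARD_AA, , drop = FALSE]
  }
  keys <- if (method == "grid") {
    grid_candidate_residues(cx, cutoffs)
  } else {
    rt$key
  }
  keys <- intersect(rt$key, keys)
  events <- list()
  lxyz <- as.matrix(cx$ligand$atoms[, c("x", "y", "z")])
  lelem <- cx$ligand$atoms$element
  ftab <- residue_feature_table()
  ra_all <- cx$receptor$atoms
  rkey_all <- paste(ra_all$chain, ra_all$resno, ra_all$insert, sep = ":")
  for (key in keys) {
    ridx <- which(rkey_all == key)
    ev <- residue_events(ra_all[ridx, , drop = FALSE],
                         rt[rt$key == key, , drop = FALSE],
                         lxyz, lelem, feats, cutoffs, ftab)
    if (length(ev)) events <- c(events, ev)
  }
  as_interaction_events(events)
}

as_interaction_events <- function(events) {
  if (!length(events)) {
    out <- data.frame(residue = character(0), residue_key = character(0),
                      itype = character(0), distance = numeric(0),
                      angle = numeric(0), note = character(0),
                      stringsAsFactors = FALSE)
    out$ligand_atoms <- list(); out$residue_atoms <- list()
  } else {
    out <- data.frame(
      residue = vapply(events, `[[`, character(1), "residue"),
      residue_key = vapply(events, `[[`, character(1), "residue_key"),
      itype = vapply(events, `[[`, character(1), "itype"),
      distance = vapply(events, `[[`, numeric(1), "distance"),
      angle = vapply(events, function(e) e$angle %||% NA_real_, numeric(1)),
      note = vapply(events, function(e) e$note %||% "", character(1)),
      stringsAsFactors = FALSE)
    out$ligand_atoms <- lapply(events, `[[`, "ligand_atoms")
    out$residue_atoms <- lapply(events, `[[`, "residue_atoms")
    out <- out[order(out$residue_key, match(out$itype, sift_scheme())), ]
    rownames(out) <- NULL
  }
  class(out) <- c("interaction_events", "data.frame")
  out
}

# typed events between one residue and the ligand
residue_events <- function(ra, rinfo, lxyz, lelem, feats, cutoffs, ftab) {
  events <- list()
  emit <- function(itype, distance, latoms, ratoms, angle = NULL, note = "") {
    events[[length(events) + 1L]] <<- list(
      residue = rinfo$label, residue_key = rinfo$key, itype = itype,
      distance = distance, ligand_atoms = latoms,
      residue_atoms = ra$elety[ratoms], angle = angle, note = note)
  }
  heavy_r <- which(ra$elesy != "H")
  heavy_l <- which(lelem != "H")
  if (!length(heavy_r) || !length(heavy_l)) return(events)
  d <- cross_dist(ra[heavy_r, c("x", "y", "z")], lxyz[heavy_l, , drop = FALSE])
  rownames(d) <- ra$elety[heavy_r]

  # contact + backbone/side-chain split
  if (min(d) <= cutoffs$contact) {
    hit <- which(d <= cutoffs$contact, arr.ind = TRUE)
    emit("contact", min(d),
         heavy_l[unique(hit[, 2])], heavy_r[unique(hit[, 1])])
    bb <- ra$elety[heavy_r] %in% BACKBONE_ATOMS
    if (any(bb) && min(d[bb, , drop = FALSE]) <= cutoffs$contact)
      emit("backbone_contact", min(d[bb, , drop = FALSE]),
           heavy_l, heavy_r[bb])
    if (any(!bb) && min(d[!bb, , drop = FALSE]) <= cutoffs$contact)
      emit("sidechain_contact", min(d[!bb, , drop = FALSE]),
           heavy_l, heavy_r[!bb])
  }

  f <- ftab[[rinfo$resid]] %||% list()
  has_atom <- function(nms) which(ra$elety[heavy_r] %in% nms)
  # residue polar atoms: side-chain N/O/S plus backbone N and O
  r_polar <- which(ra$elesy[heavy_r] %in% c("N", "O", "S"))
  l_polar <- which(lelem[heavy_l] %in% c("N", "O", "S"))
  if (length(r_polar) && length(l_polar)) {
    dp <- d[r_polar, l_polar, drop = FALSE]
    if (min(dp) <= cutoffs$polar) {
      hit <- which(dp == min(dp), arr.ind = TRUE)[1, ]
      emit("polar", min(dp), heavy_l[l_polar[hit[2]]],
           heavy_r[r_polar[hit[1]]])
    }
  }
  # hydrophobic
  r_hyd <- has_atom(f$hydroph %||% character(0))
  l_hyd <- match(intersect(feats$hydrophobes, heavy_l), heavy_l)
  if (length(r_hyd) && length(l_hyd)) {
    dh <- d[r_hyd, l_hyd, drop = FALSE]
    if (min(dh) <= cutoffs$hydrophobic)
      emit("hydrophobic", min(dh), heavy_l[l_hyd], heavy_r[r_hyd])
  }
  # hydrogen bonds; residue donors include backbone N (except PRO)
  r_donors <- has_atom(c(f$donors %||% character(0),
                         if (rinfo$resid != "PRO") "N"))
  r_accept <- has_atom(c(f$acceptors %||% character(0), "O", "OXT"))
  l_donors <- match(intersect(feats$donors, heavy_l), heavy_l)
  l_accept <- match(intersect(feats$acceptors, heavy_l), heavy_l)
  hb_note <- if (feats$has_explicit_h) "" else "no-H mode"
  if (length(l_donors) && length(r_accept)) {
    dh <- d[r_accept, l_donors, drop = FALSE]
    if (min(dh) <= cutoffs$hbond) {
      ok <- TRUE; ang <- NA_real_
      if (feats$has_explicit_h) {
        hit <- which(dh == min(dh), arr.ind = TRUE)[1, ]
        ang <- best_dha_angle(heavy_l[l_donors[hit[2]]],
                              heavy_r[r_accept[hit[1]]], lxyz, lelem, ra)
        ok <- is.na(ang) || ang >= cutoffs$hbond_angle
      }
      if (ok)
        emit("hb_protein_acceptor", min(dh), heavy_l[l_donors],
             heavy_r[r_accept], angle = ang, note = hb_note)
    }
  }
  if (length(l_accept) && length(r_donors)) {
    dh <- d[r_donors, l_accept, drop = FALSE]
    if (min(dh) <= cutoffs$hbond)
      emit("hb_protein_donor", min(dh), heavy_l[l_accept],
           heavy_r[r_donors], note = "no-H mode")
  }
  # aromatic: every residue ring contributes independently
  if (length(f$rings %||% list()) && length(feats$rings)) {
    for (rring in f$rings) {
      ridx <- which(ra$elety %in% rring & ra$elesy != "H")
      if (length(ridx) < length(rring)) next
      rcen <- colMeans(ra[ridx, c("x", "y", "z")])
      for (lring in feats$rings) {
        dd <- sqrt(sum((rcen - lring$centroid)^2))
        if (dd <= cutoffs$aromatic)
          emit("aromatic", dd, lring$atoms, ridx)
      }
    }
  }
  # charged: opposite chargeable group centers
  r_cat <- has_atom(f$cation %||% character(0))
  r_ani <- has_atom(f$anion %||% character(0))
  charged_pair <- function(r_atoms, l_groups) {
    if (!length(r_atoms) || !length(l_groups)) return(NULL)
    rcen <- colMeans(ra[heavy_r[r_atoms], c("x", "y", "z"), drop = FALSE])
    for (g in l_groups) {
      dd <- sqrt(sum((rcen - g$center)^2))
      if (dd <= cutoffs$charged) return(list(d = dd, atoms = g$atoms))
    }
    NULL
  }
  cp <- charged_pair(r_ani, feats$cation_groups)
  if (!is.null(cp)) emit("charged", cp$d, cp$atoms, heavy_r[r_ani])
  cp <- charged_pair(r_cat, feats$anion_groups)
  if (!is.null(cp)) emit("charged", cp$d, cp$atoms, heavy_r[r_cat])
  events
}

# best D-H...A angle over explicit hydrogens attached to the donor
best_dha_angle <- function(donor_i, acceptor_ri, lxyz, lelem, ra) {
  # hydrogens: ligand atoms within 1.2 A of the donor
  dvec <- lxyz[donor_i, ]
  hs <- which(lelem == "H")
  if (!length(hs)) return(NA_real_)
  dh <- sqrt(rowSums((lxyz[hs, , drop = FALSE] -
                        matrix(dvec, length(hs), 3, byrow = TRUE))^2))
  hs <- hs[dh < 1.3]
  if (!length(hs)) return(NA_real_)
  acc <- as.numeric(ra[acceptor_ri, c("x", "y", "z")])
  max(vapply(hs, function(h) {
    v1 <- dvec - lxyz[h, ]; v2 <- acc - lxyz[h, ]
    cosv <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  }, numeric(1)))
}

# cell-list candidate residues: any residue with an atom in the 27-cell
# neighborhood of any ligand atom; the cell size exceeds the largest
# effective interaction radius (ring centroid reach included)
grid_candidate_residues <- function(cx, cutoffs) {
  cell <- max(unlist(cutoffs[c("contact", "hydrophobic", "polar",
                               "hbond", "charged", "aromatic")])) + 3.0
  ra <- cx$receptor$atoms
  la <- cx$ligand$atoms
  key_of <- function(xyz) paste(floor(xyz[, 1] / cell),
                                floor(xyz[, 2] / cell),
                                floor(xyz[, 3] / cell))
  lig_cells <- unique(do.call(rbind, lapply(seq_len(nrow(la)), function(i) {
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    cbind(floor(la$x[i] / cell) + g$dx, floor(la$y[i] / cell) + g$dy,
          floor(la$z[i] / cell) + g$dz)
  })))
  lig_keys <- paste(lig_cells[, 1], lig_cells[, 2], lig_cells[, 3])
  r_keys <- key_of(as.matrix(ra[, c("x", "y", "z")]))
  near <- r_keys %in% lig_keys
  unique(paste(ra$chain, ra$resno, ra$insert, sep = ":")[near])
}

# --- SIFt encoding ----------------------------------------------------------

#' Encode interaction events as a SIFt
#'
#' Binary residue-panel x interaction-type matrix. The bit hierarchy is
#' enforced at encoding: any typed bit implies the contact bit, and hydrogen
#' bond / charged bits imply the polar bit. Events at residues outside the
#' panel are reported in the `outside_panel` attribute, never silently
#' dropped.
#'
#' @param events `interaction_events` from [detect_interactions()].
#' @param panel ordered residue labels (character) or a panel data frame
#'   from [pocket_panel()].
#' @param scheme ordered interaction types, default [sift_scheme()].
#' @param complex_id identifier stored in the fingerprint.
#' @param cutoffs the cutoff set the events were computed with (recorded as
#'   metadata).
#' @return object of class `sift`: `bits` (0/1 matrix), `panel`, `scheme`,
#'   `complex_id`, `cutoffs`.
#' @export
encode_sift <- function(events, panel, scheme = sift_scheme(),
                        complex_id = "complex", cutoffs = default_cutoffs()) {
  if (is.data.frame(panel)) panel <- panel$label
  panel <- as.character(panel)
  if (!length(panel)) stop_arg("panel must be nonempty")
  bits <- matrix(0L, nrow = length(panel), ncol = length(scheme),
                 dimnames = list(panel, scheme))
  inside <- events$residue %in% panel
  hierarchy <- list(hb_protein_acceptor = "polar", hb_protein_donor = "polar",
                    charged = "polar")
  for (i in which(inside)) {
    r <- events$residue[i]; t <- events$itype[i]
    if (t %in% scheme) bits[r, t] <- 1L
    for (p in hierarchy[[t]] %||% character(0))
      if (p %in% scheme) bits[r, p] <- 1L
    if ("contact" %in% scheme) bits[r, "contact"] <- 1L
  }
  structure(list(bits = bits, panel = panel, scheme = scheme,
                 complex_id = complex_id, cutoffs = cutoffs,
                 outside_panel = unique(events$residue[!inside])),
            class = "sift")
}

#' Compute a SIFt for a complex
#'
#' Convenience wrapper: [detect_interactions()] then [encode_sift()].
#'
#' @inheritParams detect_interactions
#' @inheritParams encode_sift
#' @export
compute_sift <- function(cx, panel, scheme = sift_scheme(),
                         cutoffs = default_cutoffs(),
                         method = c("grid", "brute")) {
  events <- detect_interactions(cx, cutoffs, method = method)
  encode_sift(events, panel, scheme, complex_id = cx$complex_id,
              cutoffs = cutoffs)
}

#' Per-frame SIFts of a trajectory
#'
#' @param frames list of `complex3d` sharing ligand identity.
#' @inheritParams encode_sift
#' @param cutoffs cutoff list.
#' @return list of `sift`, frame order preserved.
#' @export
sift_per_frame <- function(frames, panel, scheme = sift_scheme(),
                           cutoffs = default_cutoffs()) {
  lapply(seq_along(frames), function(k) {
    s <- compute_sift(frames[[k]], panel, scheme, cutoffs)
    s$complex_id <- paste0(frames[[k]]$complex_id, "#", k)
    s
  })
}

#' @export
print.sift <- function(x, ...) {
  cat("SIFt:", x$complex_id, "-", length(x$panel), "residues x",
      length(x$scheme), "types;", sum(x$bits), "bits set\n")
  invisible(x)
}
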
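BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Construct a receptor structure
#'
#' @param atoms data frame with columns `chain`, `resno`, `insert`, `resid`
#'   (3-letter code), `elety` (atom name), `elesy` (element), `x`, `y`, `z`.
#' @param metadata optional list (PDB id, title).
#' @return object of class `receptor_structure`.
#' @export
receptor_structure <- function(atoms, metadata = list()) {
  req <- c("chain", "resno", "insert", "resid", "elety", "elesy", "x", "y", "z")
  stopifnot(all(req %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop_arg("receptor atoms must have finite coordinates")
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$generic <- atoms$generic %||% rep(NA_character_, nrow(atoms))
  structure(list(atoms = atoms, metadata = metadata),
            class = "receptor_structure")
}

#' Construct a ligand pose
#'
#' @param atoms data frame with columns `element`, `x`, `y`, `z`, `charge`
#'   (formal charge, integer).
#' @param bonds data frame with columns `from`, `to`, `order` (1, 2, 3, or 4
#'   for aromatic-flagged).
#' @param pose_id identifier string.
#' @param frame_index optional nonnegative frame number.
#' @return object of class `ligand_pose`.
#' @export
ligand_pose <- function(atoms, bonds, pose_id = "pose", frame_index = NULL) {
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  atoms$charge <- as.integer(atoms$charge %||% rep(0L, nrow(atoms)))
  bonds <- bonds %||% data.frame(from = integer(0), to = integer(0), order = integer(0))
  if (nrow(bonds) && (max(bonds$from, bonds$to) > nrow(atoms) ||
                      min(bonds$from, bonds$to) < 1))
    stop_arg("bond indices out of range")
  structure(list(atoms = atoms, bonds = bonds, pose_id = pose_id,
                 frame_index = frame_index), class = "ligand_pose")
}

#' Construct a ligand-receptor complex
#'
#' Receptor and ligand must share one Cartesian frame (angstroms).
#'
#' @param receptor a `receptor_structure`.
#' @param ligand a `ligand_pose`.
#' @param complex_id identifier.
#' @return object of class `complex3d`.
#' @export
complex3d <- function(receptor, ligand, complex_id = "complex") {
  stopifnot(inherits(receptor, "receptor_structure"),
            inherits(ligand, "ligand_pose"))
  structure(list(receptor = receptor, ligand = ligand, complex_id = complex_id),
            class = "complex3d")
}

#' Read a receptor structure from PDB
#'
#' @param path PDB file.
#' @param keep_het keep HETATM records (default drops them; ligand extraction
#'   goes through [load_complex()]).
#' @return `receptor_structure`.
#' @export
read_receptor <- function(path, keep_het = FALSE) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  if (!keep_het) a <- a[a$type == "ATOM", , drop = FALSE]
  if (!nrow(a)) stop_arg("no ATOM records in ", path)
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid, elety = a$elety,
    elesy = ifelse(is.na(a$elesy) | !nzchar(a$elesy),
                   substr(gsub("[0-9]", "", a$elety), 1, 1), a$elesy),
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE
  )
  receptor_structure(atoms, metadata = list(path = path))
}

#' Read a ligand pose from an SDF file
#'
#' Atom coordinates, bond orders and formal charges (both the atom-block
#' charge field and `M  CHG` property lines) are read.
#'
#' @param path SDF file.
#' @param which molecule index within the file.
#' @return `ligand_pose`.
#' @export
read_ligand_sdf <- function(path, which = 1L) {
  sdfset <- ChemmineR::read.SDFset(path)
  if (length(sdfset) < which) stop_arg("SDF has fewer than ", which, " molecules")
  sdf <- sdfset[[which]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  # old-style atom-block charge codes: 1..3 = +3..+1, 5..7 = -1..-3
  code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  chg_map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
               `5` = -1L, `6` = -2L, `7` = -3L)
  charge <- unname(chg_map[as.character(code)])
  charge[is.na(charge)] <- 0L
  # M  CHG lines override
  mchg <- parse_sdf_mchg(path, which)
  if (length(mchg)) charge[as.integer(names(mchg))] <- as.integer(mchg)
  atoms <- data.frame(element = element,
                      x = ab[, 1], y = ab[, 2], z = ab[, 3],
                      charge = charge, stringsAsFactors = FALSE)
  bonds <- data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  ligand_pose(atoms, bonds, pose_id = basename(path))
}

parse_sdf_mchg <- function(path, which) {
  lines <- readLines(path, warn = FALSE)
  ends <- c(0L, which(grepl("^\\$\\$\\$\\$", lines)))
  if (length(ends) < which + 1L) ends <- c(ends, length(lines) + 1L)
  block <- lines[(ends[which] + 1L):(ends[which + 1L] - 1L)]
  chg <- grep("^M  CHG", block, value = TRUE)
  out <- numeric(0)
  for (ln in chg) {
    f <- as.numeric(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- f[1]
    idx <- f[seq(2, by = 2, length.out = k)]
    val <- f[seq(3, by = 2, length.out = k)]
    out[as.character(idx)] <- val
  }
  out
}

#' Load a ligand-receptor complex
#'
#' The receptor comes from a PDB file. The ligand comes either from a
#' separate SDF/PDB file, or (when `ligand_path` is `NULL`) is extracted from
#' the receptor file's HETATM records by residue name; in the latter case the
#' bond graph is perceived with Open Babel.
#'
#' @param receptor_path PDB file.
#' @param ligand_path optional SDF or PDB file with the ligand pose.
#' @param ligand_resname HETATM residue name for in-file extraction
#'   (default `"LIG"`).
#' @param complex_id identifier.
#' @return a `complex3d`.
#' @export
load_complex <- function(receptor_path, ligand_path = NULL,
                         ligand_resname = "LIG", complex_id = NULL) {
  receptor <- read_receptor(receptor_path)
  ligand <- if (is.null(ligand_path)) {
    extract_het_ligand(receptor_path, ligand_resname)
  } else if (grepl("\\.sdf$", ligand_path, ignore.case = TRUE)) {
    read_ligand_sdf(ligand_path)
  } else {
    extract_het_ligand(ligand_path, ligand_resname)
  }
  complex3d(receptor, ligand,
            complex_id = complex_id %||% basename(receptor_path))
}

# ligand from HETATM records, bond perception via Open Babel
extract_het_ligand <- function(path, resname) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  sel <- a$resid == resname
  if (!any(sel)) stop_arg("no HETATM residue '", resname, "' in ", path)
  a <- a[sel, , drop = FALSE]
  lines <- vapply(seq_len(nrow(a)), function(i) {
    sprintf("HETATM%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, substr(a$elety[i], 1, 4), resname,
            ifelse(is.na(a$chain[i]), "A", a$chain[i]), a$resno[i],
            a$x[i], a$y[i], a$z[i], 1, 0,
            ifelse(is.na(a$elesy[i]) | !nzchar(a$elesy[i]),
                   substr(gsub("[0-9]", "", a$elety[i]), 1, 1), a$elesy[i]))
  }, character(1))
  tp <- tempfile(fileext = ".pdb")
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tp, tf)))
  writeLines(c(lines, "END"), tp)
  ChemmineOB::convertFormatFile("PDB", "SDF", tp, tf)
  lig <- read_ligand_sdf(tf)
  # Open Babel preserves atom order but may emit generated 2D coordinates;
  # the authoritative coordinates are the PDB ones
  elem <- ifelse(is.na(a$elesy) | !nzchar(a$elesy),
                 substr(gsub("[0-9]", "", a$elety), 1, 1), a$elesy)
  if (nrow(lig$atoms) != nrow(a) || !identical(lig$atoms$element, elem))
    stop_arg("bond perception changed the atom list for '", resname, "'")
  lig$atoms$x <- a$x; lig$atoms$y <- a$y; lig$atoms$z <- a$z
  lig$pose_id <- paste0(basename(path), ":", resname)
  lig
}

#' Annotate receptor residues with GPCRdb generic numbers
#'
#' Generic numbering is supplied as data (a mapping table), not computed from
#' sequence. Mapped residues get a `generic` label like `"3x32"`; unmapped
#' residues stay unannotated. Mapping rows that match no residue are reported
#' in the `unmatched` attribute.
#'
#' @param receptor a `receptor_structure`.
#' @param mapping data frame with columns `chain`, `resnum`, `generic`
#'   (pattern `<segment>x<position>`, e.g. `"3x32"`, `"45x52"`).
#' @return annotated `receptor_structure`.
#' @export
map_generic_numbers <- function(receptor, mapping) {
  stopifnot(inherits(receptor, "receptor_structure"),
            all(c("chain", "resnum", "generic") %in% names(mapping)))
  if (nrow(mapping)) {
    bad <- !grepl("^[0-9]+x[0-9]+$", mapping$generic)
    if (any(bad))
      stop_arg("invalid generic label(s): ",
               paste(mapping$generic[bad], collapse = ", "))
    if (anyDuplicated(mapping$generic))
      stop_arg("duplicate generic label(s) in mapping")
  }
  key_atoms <- paste(receptor$atoms$chain, receptor$atoms$resno)
  key_map <- paste(mapping$chain, mapping$resnum)
  idx <- match(key_atoms, key_map)
  receptor$atoms$generic <- ifelse(is.na(idx), NA_character_,
                                   mapping$generic[idx])
  unmatched <- mapping[!key_map %in% key_atoms, , drop = FALSE]
  attr(receptor, "unmatched") <- unmatched
  receptor
}

# residue table: one row per residue with label (generic if present)
residue_table <- function(receptor) {
  a <- receptor$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = ":")
  first <- !duplicated(key)
  r <- data.frame(key = key[first], chain = a$chain[first],
                  resno = a$resno[first], insert = a$insert[first],
                  resid = a$resid[first],
                  generic = a$generic[first], stringsAsFactors = FALSE)
  r$label <- ifelse(is.na(r$generic), r$key, r$generic)
  r
}

#' Binding-pocket residue panel
#'
#' Residues with at least one heavy atom within `cutoff_A` of any ligand
#' heavy atom, ordered by (chain, residue number, insertion code).
#'
#' @param cx a `complex3d`.
#' @param cutoff_A distance cutoff in angstroms (default 6).
#' @return data frame of panel residues (`key`, `chain`, `resno`, `resid`,
#'   `generic`, `label`).
#' @export
pocket_panel <- function(cx, cutoff_A = 6.0) {
  stopifnot(inherits(cx, "complex3d"))
  if (cutoff_A <= 0) return(residue_table(cx$receptor)[0, , drop = FALSE])
  ra <- cx$receptor$atoms
  heavy_r <- ra$elesy != "H"
  la <- cx$ligand$atoms
  heavy_l <- la$element != "H"
  if (!any(heavy_l) || !any(heavy_r)) return(residue_table(cx$receptor)[0, ])
  d <- cross_dist(ra[heavy_r, c("x", "y", "z")], la[heavy_l, c("x", "y", "z")])
  near <- apply(d, 1, min) <= cutoff_A
  keys <- unique(paste(ra$chain, ra$resno, ra$insert, sep = ":")[heavy_r][near])
  rt <- residue_table(cx$receptor)
  out <- rt[rt$key %in% keys, , drop = FALSE]
  out[order(out$chain, out$resno, out$insert), , drop = FALSE]
}

#' RMSD between two poses of the same molecule
#'
#' In-place heavy-atom RMSD (no superposition): the poses must already share
#' a Cartesian frame, as in re-docking comparisons. With
#' `symmetry_aware = TRUE` the minimum over bond-graph automorphisms
#' (element-colored) is returned, so topologically equivalent atoms
#' (e.g. a flipped benzene ring) do not inflate the value. Automorphism
#' enumeration is capped; beyond `automorphism_cap` the naive index matching
#' is used with a warning.
#'
#' @param pose_a,pose_b `ligand_pose` objects of the same molecule.
#' @param symmetry_aware minimize over bond-graph automorphisms.
#' @param automorphism_cap maximum number of automorphisms to consider.
#' @return RMSD in angstroms.
#' @export
pose_rmsd <- function(pose_a, pose_b, symmetry_aware = FALSE,
                      automorphism_cap = 10000L) {
  ha <- which(pose_a$atoms$element != "H")
  hb <- which(pose_b$atoms$element != "H")
  if (length(ha) != length(hb))
    stop_arg("poses differ in heavy-atom count")
  ea <- pose_a$atoms$element[ha]; eb <- pose_b$atoms$element[hb]
  if (!identical(sort(ea), sort(eb)))
    stop_arg("poses differ in heavy-atom element composition")
  A <- as.matrix(pose_a$atoms[ha, c("x", "y", "z")])
  B <- as.matrix(pose_b$atoms[hb, c("x", "y", "z")])
  naive <- if (identical(ea, eb)) sqrt(mean(rowSums((A - B)^2))) else NA_real_
  if (!symmetry_aware) {
    if (is.na(naive)) stop_arg("heavy-atom order differs; use symmetry_aware = TRUE")
    return(naive)
  }
  ga <- heavy_graph(pose_a, ha)
  gb <- heavy_graph(pose_b, hb)
  col_a <- as.integer(factor(ea, levels = sort(unique(c(ea, eb)))))
  col_b <- as.integer(factor(eb, levels = sort(unique(c(ea, eb)))))
  maps <- igraph::isomorphisms(ga, gb, method = "vf2",
                               vertex.color1 = col_a, vertex.color2 = col_b)
  if (!length(maps)) stop_arg("poses have non-isomorphic bond graphs")
  if (length(maps) > automorphism_cap) {
    warning("automorphism count ", length(maps), " exceeds cap; using naive matching")
    if (is.na(naive)) stop_arg("heavy-atom order differs and cap exceeded")
    return(naive)
  }
  min(vapply(maps, function(m) {
    perm <- as.integer(m)
    sqrt(mean(rowSums((A - B[perm, , drop = FALSE])^2)))
  }, numeric(1)))
}

heavy_graph <- function(pose, heavy_idx) {
  map <- match(seq_len(nrow(pose$atoms)), heavy_idx)
  b <- pose$bonds
  keep <- !is.na(map[b$from]) & !is.na(map[b$to])
  igraph::graph_from_data_frame(
    data.frame(from = map[b$from[keep]], to = map[b$to[keep]]),
    directed = FALSE,
    vertices = data.frame(name = seq_along(heavy_idx))
  )
}

#' Superpose trajectory frames onto the first frame
#'
#' Least-squares rigid-body (Kabsch) fit of each frame's reference selection
#' onto frame 1; the resulting proper rotation and translation are applied
#' to all atoms of the frame, ligand included.
#'
#' @param frames list of `complex3d` sharing the same receptor topology.
#' @param selection `"calpha"` (default), `"backbone"`, or `"all"` receptor
#'   atoms used as the reference.
#' @return list with `frames` (aligned) and `transforms` (per-frame list of
#'   `rotation` 3x3 and `translation` length-3).
#' @export
superpose_frames <- function(frames, selection = c("calpha", "backbone", "all")) {
  selection <- match.arg(selection)
  stopifnot(length(frames) >= 1L, all(vapply(frames, inherits, logical(1), "complex3d")))
  sel_idx <- function(cx) {
    a <- cx$receptor$atoms
    switch(selection,
           calpha = which(a$elety == "CA"),
           backbone = which(a$elety %in% BACKBONE_ATOMS),
           all = seq_len(nrow(a)))
  }
  ref_i <- sel_idx(frames[[1]])
  if (length(ref_i) < 3L) stop_arg("need at least 3 reference atoms")
  ref <- as.matrix(frames[[1]]$receptor$atoms[ref_i, c("x", "y", "z")])
  transforms <- vector("list", length(frames))
  out <- frames
  for (k in seq_along(frames)) {
    i <- sel_idx(frames[[k]])
    if (length(i) != length(ref_i))
      stop_arg("frame ", k, " reference selection differs from frame 1")
    mov <- as.matrix(frames[[k]]$receptor$atoms[i, c("x", "y", "z")])
    tr <- kabsch(mov, ref)
    out[[k]] <- apply_rigid(frames[[k]], tr)
    transforms[[k]] <- tr
  }
  list(frames = out, transforms = transforms)
}

# Kabsch: rotation R (3x3, det +1) and translation t such that
# mov %*% t(R) + t approximates fix in least squares
kabsch <- function(mov, fix) {
  cm <- colMeans(mov); cf <- colMeans(fix)
  H <- crossprod(sweep(mov, 2, cm), sweep(fix, 2, cf))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- as.numeric(cf - R %*% cm)
  list(rotation = R, translation = t_vec)
}

apply_rigid <- function(cx, tr) {
  rot <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(tr$rotation)
    df$x <- xyz[, 1] + tr$translation[1]
    df$y <- xyz[, 2] + tr$translation[2]
    df$z <- xyz[, 3] + tr$translation[3]
    df
  }
  cx$receptor$atoms <- rot(cx$receptor$atoms)
  cx$ligand$atoms <- rot(cx$ligand$atoms)
  cx
}

#' Write a complex (or frames of complexes) as PDB
#'
#' Receptor atoms as ATOM records, ligand atoms as HETATM records with
#' residue name `LIG`. A list of complexes is written as a multi-model PDB
#' (one MODEL per frame), the trajectory interchange format used here.
#'
#' @param x a `complex3d` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(x, path) {
  frames <- if (inherits(x, "complex3d")) list(x) else x
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (k in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    cx <- frames[[k]]
    ra <- cx$receptor$atoms
    serial <- 0L
    for (i in seq_len(nrow(ra))) {
      serial <- serial + 1L
      writeLines(pdb_atom_line("ATOM", serial, ra$elety[i], ra$resid[i],
                               ra$chain[i], ra$resno[i],
                               ra$x[i], ra$y[i], ra$z[i], ra$elesy[i]), con)
    }
    la <- cx$ligand$atoms
    lig_chain <- "L"
    for (i in seq_len(nrow(la))) {
      serial <- serial + 1L
      name <- paste0(la$element[i], i)
      writeLines(pdb_atom_line("HETATM", serial, name, "LIG", lig_chain, 1L,
                               la$x[i], la$y[i], la$z[i], la$element[i]), con)
    }
    writeLines(if (multi) "ENDMDL" else "END", con)
  }
  if (multi) writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB trajectory into complex frames
#'
#' Multi-model PDB (one MODEL per frame) is the trajectory interchange
#' format used here. The first model provides the topology (including
#' ligand bond perception); subsequent models only update coordinates.
#'
#' @param path multi-model PDB file.
#' @param ligand_resname HETATM residue name of the ligand.
#' @return list of `complex3d`, one per model.
#' @export
read_frames <- function(path, ligand_resname = "LIG") {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  base <- load_complex(path, ligand_resname = ligand_resname)
  is_lig <- pdb$atom$resid == ligand_resname
  rec_idx <- which(pdb$atom$type == "ATOM" & !is_lig)
  lig_idx <- which(is_lig)
  n_models <- nrow(pdb$xyz)
  lapply(seq_len(n_models), function(k) {
    xyz <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
    cx <- base
    cx$receptor$atoms[, c("x", "y", "z")] <- xyz[rec_idx, , drop = FALSE]
    cx$ligand$atoms[, c("x", "y", "z")] <- xyz[lig_idx, , drop = FALSE]
    cx$complex_id <- paste0(basename(path), "#", k)
    cx
  })
}

pdb_atom_line <- function(type, serial, name, resid, chain, resno, x, y, z, elem) {
  name_fmt <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name_fmt, resid, chain, resno, x, y, z, 1, 0, elem)
}
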
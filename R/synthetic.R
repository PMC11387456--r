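#' Specification for the synthetic-data generators
#'
#' One container for the parameters controlling all generators. Defaults
#' emulate the statistical structure of a curated GPCR bioactivity
#' collection and its docking-derived contact panels: log-normal activity
#' values spanning the nM-to-uM range around the 1000 nM activity threshold,
#' Bernoulli contact panels with a moderate background rate and planted
#' active/inactive differences large enough to matter pharmacologically,
#' and sub-angstrom thermal jitter for trajectories.
#'
#' @param seed integer seed; every generator is deterministic given it.
#' @param n_active,n_inactive group sizes (compounds per group).
#' @param planted_deltas named numeric vector: residue label -> planted
#'   active-inactive contact-frequency difference in `[-1, 1]`.
#' @param null_p background contact probability for unplanted residues.
#' @param jitter_sigma_A per-coordinate Gaussian jitter (angstroms).
#' @param persistence per-frame probability that the ligand occupies the
#'   contact pose in a simulated trajectory.
#' @param lognormal_mu,lognormal_sigma log-scale parameters of activity
#'   values (log nM).
#' @param chemotype_mix named numeric vector of chemotype proportions
#'   (must sum to 1); names must exist in [chemotype_rules()].
#' @return validated `synthetic_spec` object.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_active = 50L, n_inactive = 50L,
                           planted_deltas = c(D1 = 0.4),
                           null_p = 0.3,
                           jitter_sigma_A = 0.2,
                           persistence = 0.7,
                           lognormal_mu = log(500), lognormal_sigma = 1.5,
                           chemotype_mix = c("2-aminoquinoline" = 0.5,
                                             "acylguanidine" = 0.5)) {
  stopifnot(is_scalar_number(seed), n_active >= 0, n_inactive >= 0,
            null_p >= 0, null_p <= 1, jitter_sigma_A >= 0,
            persistence >= 0, persistence <= 1,
            lognormal_sigma >= 0)
  if (length(planted_deltas) && any(abs(planted_deltas) > 1))
    stop_arg("planted deltas must lie in [-1, 1]")
  if (length(planted_deltas) &&
      (null_p + max(planted_deltas) > 1 || null_p + min(planted_deltas) < 0))
    stop_arg("infeasible spec: null_p + delta must stay in [0, 1]")
  if (abs(sum(chemotype_mix) - 1) > 1e-8)
    stop_arg("chemotype_mix proportions must sum to 1")
  if (!all(names(chemotype_mix) %in% chemotype_rules()$name))
    stop_arg("unknown chemotype in chemotype_mix")
  structure(list(seed = as.integer(seed), n_active = as.integer(n_active),
                 n_inactive = as.integer(n_inactive),
                 planted_deltas = planted_deltas, null_p = null_p,
                 jitter_sigma_A = jitter_sigma_A, persistence = persistence,
                 lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
                 chemotype_mix = chemotype_mix),
            class = "synthetic_spec")
}

# substream seeds so adding one generator never shifts another's draws
substream <- function(spec, offset) {
  set.seed((spec$seed * 1009L + offset) %% .Machine$integer.max)
}

# deterministic alkyl decoration for index i: the binary digits of i choose
# between plain and methyl-branched chain units, so distinct indices give
# distinct constitutional isomers. Pure-carbon substituents can never create
# a different chemotype.
gen_alkyl <- function(i) {
  nbits <- max(1L, ceiling(log2(i + 1)))
  bits <- as.integer(intToBits(i))[seq_len(nbits)]
  paste0("C", paste(ifelse(bits == 1L, "C(C)", "C"), collapse = ""))
}

#' Simulate a bioactivity table with planted ground truth
#'
#' Draws compounds from the spec's chemotype mix, decorates each class
#' scaffold with a unique alkyl substituent (so [assign_chemotype()] can
#' recover the planted class), assigns log-normal activity values per
#' parameter type (actives truncated below, inactives above the 1000 nM
#' threshold), and duplicates a fraction of compounds into extra records to
#' exercise deduplication.
#'
#' @param spec a `synthetic_spec`.
#' @param duplicate_fraction fraction of compounds receiving a second
#'   measurement record.
#' @param param_probs probabilities that a compound carries a Ki / IC50 /
#'   EC50 determination (each compound gets at least one).
#' @return list with `table` (raw activity rows suitable for
#'   [validate_activity_records()]) and `truth` (per-compound data frame:
#'   `smiles`, `chemotype`, `active`, `value_nM`; plus `n_compounds`).
#' @export
simulate_activity_table <- function(spec,
                                    duplicate_fraction = 0.15,
                                    param_probs = c(Ki = 0.8, IC50 = 0.15,
                                                    EC50 = 0.25)) {
  substream(spec, 1L)
  n <- spec$n_active + spec$n_inactive
  if (n == 0L) stop_arg("spec has no compounds")
  mix <- spec$chemotype_mix
  classes <- sample(names(mix), n, replace = TRUE, prob = mix)
  rules <- chemotype_rules()
  smiles <- character(n)
  counter <- setNames(integer(length(mix)), names(mix))
  for (i in seq_len(n)) {
    cls <- classes[i]
    counter[cls] <- counter[cls] + 1L
    tmpl <- rules$template[rules$name == cls]
    smiles[i] <- sub("{R}", gen_alkyl(counter[cls]), tmpl, fixed = TRUE)
  }
  active <- c(rep(TRUE, spec$n_active), rep(FALSE, spec$n_inactive))
  thr <- 1000
  draw_value <- function(is_active) {
    if (spec$lognormal_sigma == 0) return(exp(spec$lognormal_mu))
    repeat {
      v <- stats::rlnorm(1, spec$lognormal_mu, spec$lognormal_sigma)
      if ((is_active && v < thr) || (!is_active && v >= thr)) return(v)
    }
  }
  value <- vapply(active, draw_value, numeric(1))
  rows <- list()
  for (i in seq_len(n)) {
    params <- names(param_probs)[stats::runif(3) < param_probs]
    if (!length(params)) params <- "Ki"
    for (p in params) {
      rows[[length(rows) + 1L]] <- data.frame(
        structure = smiles[i], parameter = p, relation = "=",
        value = value[i] * exp(stats::rnorm(1, 0, 0.05)), unit = "nM",
        source = sample(c("chembl", "patent", "pdsp"), 1),
        compound_label = sprintf("SYN%04d", i), stringsAsFactors = FALSE)
    }
  }
  dup <- which(stats::runif(n) < duplicate_fraction)
  for (i in dup) {
    rows[[length(rows) + 1L]] <- data.frame(
      structure = smiles[i], parameter = "Ki", relation = "=",
      value = value[i] * exp(stats::rnorm(1, 0, 0.05)), unit = "nM",
      source = "chembl", compound_label = sprintf("SYN%04d", i),
      stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  truth <- data.frame(smiles = smiles, chemotype = classes, active = active,
                      value_nM = value, stringsAsFactors = FALSE)
  list(table = table, truth = truth,
       n_compounds = length(unique(canonical_smiles(smiles))))
}

#' Simulate labeled SIFt panels with planted differential signal
#'
#' Unplanted residues fire Bernoulli(`null_p`) in both groups; planted
#' residues fire Bernoulli(`null_p + delta`) in actives and
#' Bernoulli(`null_p`) in inactives. Only the contact bit is set.
#'
#' @param spec a `synthetic_spec`.
#' @param panel_size number of panel residues; planted residues are named by
#'   `names(spec$planted_deltas)` and appended to `P01..`-style null labels
#'   if not already among them.
#' @return list with `active` and `inactive` (lists of `sift`) and `truth`
#'   (data frame: `residue`, `p_active`, `p_inactive`, `delta`, `planted`).
#' @export
simulate_sift_panel <- function(spec, panel_size = 31L) {
  substream(spec, 2L)
  deltas <- spec$planted_deltas
  n_null <- panel_size - length(deltas)
  if (n_null < 0) stop_arg("panel_size smaller than number of planted residues")
  panel <- c(names(deltas), sprintf("P%02d", seq_len(n_null)))
  p_act <- c(spec$null_p + deltas, rep(spec$null_p, n_null))
  p_ina <- rep(spec$null_p, panel_size)
  names(p_act) <- names(p_ina) <- panel
  scheme <- sift_scheme()
  make_group <- function(n, p) {
    lapply(seq_len(n), function(k) {
      bits <- matrix(0L, panel_size, length(scheme),
                     dimnames = list(panel, scheme))
      bits[, "contact"] <- stats::rbinom(panel_size, 1, p)
      structure(list(bits = bits, panel = panel, scheme = scheme,
                     complex_id = paste0("syn", k),
                     cutoffs = default_cutoffs(), outside_panel = character(0)),
                class = "sift")
    })
  }
  list(active = make_group(spec$n_active, p_act),
       inactive = make_group(spec$n_inactive, p_ina),
       truth = data.frame(residue = panel, p_active = p_act,
                          p_inactive = p_ina, delta = p_act - p_ina,
                          planted = panel %in% names(deltas),
                          stringsAsFactors = FALSE, row.names = NULL))
}

# --- toy 3D pockets ---------------------------------------------------------

# ideal-geometry residue templates (heavy atoms, angstroms, local frame)
residue_template <- function(resid) {
  bb <- data.frame(elety = c("N", "CA", "C", "O"),
                   x = c(0, 1.46, 2.02, 1.40),
                   y = c(0, 0, 1.33, 2.34), z = c(0, 0, 0, 0))
  sc <- switch(resid,
    ASP = data.frame(elety = c("CB", "CG", "OD1", "OD2"),
                     x = c(1.99, 3.49, 4.15, 4.06),
                     y = c(-0.77, -0.80, 0.20, -1.90),
                     z = c(1.21, 1.30, 1.65, 0.95)),
    SER = data.frame(elety = c("CB", "OG"),
                     x = c(1.99, 3.39), y = c(-0.77, -0.80), z = c(1.21, 1.30)),
    LEU = data.frame(elety = c("CB", "CG", "CD1", "CD2"),
                     x = c(1.99, 3.50, 4.05, 4.10),
                     y = c(-0.77, -0.80, 0.55, -2.00),
                     z = c(1.21, 1.30, 1.95, 2.05)),
    PHE = {
      ring <- hexagon_ring(center = c(4.40, -0.80, 1.30),
                           normal = c(0, 0, 1), radius = 1.39)
      data.frame(elety = c("CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                 x = c(1.99, ring[, 1]), y = c(-0.77, ring[, 2]),
                 z = c(1.21, ring[, 3]))
    },
    GLY = NULL,
    stop_arg("no template for residue ", resid))
  rbind(bb, sc)
}

hexagon_ring <- function(center, normal, radius = 1.39) {
  normal <- normal / sqrt(sum(normal^2))
  u <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- u - sum(u * normal) * normal; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  t(vapply(ang, function(a)
    center + radius * (cos(a) * e1 + sin(a) * e2), numeric(3)))
}

make_pocket <- function(residues, spacing = 14) {
  atoms <- do.call(rbind, lapply(seq_along(residues), function(i) {
    tmpl <- residue_template(residues[i])
    data.frame(chain = "A", resno = i, insert = "", resid = residues[i],
               elety = tmpl$elety,
               elesy = substr(gsub("[0-9]", "", tmpl$elety), 1, 1),
               x = tmpl$x, y = tmpl$y + (i - 1) * spacing, z = tmpl$z,
               stringsAsFactors = FALSE)
  }))
  receptor_structure(atoms, metadata = list(synthetic = TRUE))
}

# benzene ligand parallel to a plane point, Kekule bonds
benzene_ligand <- function(center, normal) {
  ring <- hexagon_ring(center, normal)
  atoms <- data.frame(element = rep("C", 6), x = ring[, 1], y = ring[, 2],
                      z = ring[, 3], charge = 0L, stringsAsFactors = FALSE)
  bonds <- data.frame(from = 1:6, to = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1))
  ligand_pose(atoms, bonds, pose_id = "benzene")
}

#' Simulate a toy complex realizing one interaction archetype
#'
#' Builds a small pseudo-pocket from ideal-geometry amino-acid templates and
#' places a minimal rigid ligand so that exactly the archetype's interaction
#' types (plus the implied contact bits) hold under [default_cutoffs()]:
#' `hbond` (methanol O near a serine OG), `ionic` (methylammonium near an
#' aspartate carboxylate, group separation 3.6 A - inside the 4.0 A charged
#' cutoff, outside the 3.5 A hydrogen-bond cutoff), `aromatic` (benzene
#' stacked 3.8 A above a phenylalanine ring), `hydrophobic` (propane beside
#' a leucine side chain), `no_contact` (ligand displaced far from every
#' residue). Real residue templates are used so feature perception is
#' exercised genuinely.
#'
#' @param archetype one of `"hbond"`, `"ionic"`, `"aromatic"`,
#'   `"hydrophobic"`, `"no_contact"`.
#' @param seed integer; a small random proper rotation + translation is
#'   applied to the whole complex so repeated fixtures differ.
#' @param rotate apply the random rigid motion (default TRUE).
#' @return list with `complex` (a `complex3d`), `target_residue` (panel
#'   label), and `expected_itypes` (ground-truth event types at the target).
#' @export
simulate_complex <- function(archetype = c("hbond", "ionic", "aromatic",
                                           "hydrophobic", "no_contact"),
                             seed = 1L, rotate = TRUE) {
  archetype <- match.arg(archetype)
  set.seed(seed)
  pocket <- make_pocket(c("SER", "ASP", "PHE", "LEU", "GLY"))
  res_atoms <- function(resno, elety) {
    a <- pocket$atoms
    as.numeric(a[a$resno == resno & a$elety == elety, c("x", "y", "z")])
  }
  lig <- switch(archetype,
    hbond = {
      og <- res_atoms(1, "OG")
      o_pos <- og + c(2.9, 0, 0)
      atoms <- data.frame(element = c("O", "C"),
                          x = c(o_pos[1], o_pos[1] + 1.43),
                          y = c(o_pos[2], o_pos[2]),
                          z = c(o_pos[3], o_pos[3]), charge = 0L)
      ligand_pose(atoms, data.frame(from = 1, to = 2, order = 1), "methanol")
    },
    ionic = {
      od1 <- res_atoms(2, "OD1"); od2 <- res_atoms(2, "OD2")
      cg <- res_atoms(2, "CG")
      center <- (od1 + od2) / 2
      axis <- center - cg; axis <- axis / sqrt(sum(axis^2))
      n_pos <- center + 3.6 * axis
      atoms <- data.frame(element = c("N", "C"),
                          x = c(n_pos[1], n_pos[1] + 1.49),
                          y = c(n_pos[2], n_pos[2]),
                          z = c(n_pos[3], n_pos[3]),
                          charge = c(1L, 0L))
      ligand_pose(atoms, data.frame(from = 1, to = 2, order = 1),
                  "methylammonium")
    },
    aromatic = {
      a <- pocket$atoms
      ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      ring <- a[a$resno == 3 & a$elety %in% ring_names, c("x", "y", "z")]
      cen <- colMeans(ring)
      benzene_ligand(cen + c(0, 0, 3.8), c(0, 0, 1))
    },
    hydrophobic = {
      cd1 <- res_atoms(4, "CD1")
      base <- cd1 + c(0, 0, 4.0)
      atoms <- data.frame(element = rep("C", 3),
                          x = base[1] + c(0, 1.54, 2.1),
                          y = base[2] + c(0, 0, 1.3),
                          z = base[3] + c(0, 0, 0), charge = 0L)
      ligand_pose(atoms, data.frame(from = c(1, 2), to = c(2, 3),
                                    order = 1), "propane")
    },
    no_contact = {
      atoms <- data.frame(element = c("N", "C"), x = c(60, 61.49),
                          y = c(0, 0), z = c(0, 0), charge = c(1L, 0L))
      ligand_pose(atoms, data.frame(from = 1, to = 2, order = 1),
                  "distant")
    })
  cx <- complex3d(pocket, lig, complex_id = paste0("syn-", archetype, "-", seed))
  if (rotate) cx <- apply_rigid(cx, random_rigid())
  target <- switch(archetype, hbond = "A:1:", ionic = "A:2:",
                   aromatic = "A:3:", hydrophobic = "A:4:",
                   no_contact = NA_character_)
  expected <- switch(archetype,
    hbond = c("contact", "sidechain_contact", "polar",
              "hb_protein_acceptor", "hb_protein_donor"),
    ionic = c("contact", "sidechain_contact", "polar", "charged"),
    aromatic = c("contact", "sidechain_contact", "hydrophobic", "aromatic"),
    hydrophobic = c("contact", "sidechain_contact", "hydrophobic"),
    no_contact = character(0))
  list(complex = cx, target_residue = target, expected_itypes = expected)
}

random_rigid <- function() {
  # uniform-ish random rotation from QR of a Gaussian matrix, det forced +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rotation = q, translation = stats::rnorm(3, 0, 10))
}

#' Simulate a trajectory with planted contact persistence
#'
#' The receptor stays fixed. Per frame, with probability `spec$persistence`
#' the ligand occupies the base contact pose; otherwise it is displaced 12 A
#' along the pocket exit axis (comfortably beyond every cutoff). Gaussian
#' per-coordinate jitter of `spec$jitter_sigma_A` is added to the ligand in
#' every frame.
#'
#' @param base a `complex3d` (e.g. from [simulate_complex()]).
#' @param spec a `synthetic_spec` (uses `persistence`, `jitter_sigma_A`,
#'   `seed`).
#' @param n_frames number of frames (>= 2).
#' @return list with `frames` (list of `complex3d`) and `in_contact`
#'   (logical ground truth per frame).
#' @export
simulate_trajectory <- function(base, spec, n_frames = 500L) {
  stopifnot(inherits(base, "complex3d"), n_frames >= 2)
  substream(spec, 3L)
  rec_cen <- colMeans(base$receptor$atoms[, c("x", "y", "z")])
  lig_cen <- colMeans(base$ligand$atoms[, c("x", "y", "z")])
  axis <- lig_cen - rec_cen
  nrm <- sqrt(sum(axis^2))
  axis <- if (nrm < 1e-8) c(1, 0, 0) else axis / nrm
  in_contact <- stats::runif(n_frames) < spec$persistence
  frames <- lapply(seq_len(n_frames), function(k) {
    cx <- base
    la <- cx$ligand$atoms
    if (!in_contact[k]) {
      la$x <- la$x + 12 * axis[1]
      la$y <- la$y + 12 * axis[2]
      la$z <- la$z + 12 * axis[3]
    }
    if (spec$jitter_sigma_A > 0) {
      nl <- nrow(la)
      la$x <- la$x + stats::rnorm(nl, 0, spec$jitter_sigma_A)
      la$y <- la$y + stats::rnorm(nl, 0, spec$jitter_sigma_A)
      la$z <- la$z + stats::rnorm(nl, 0, spec$jitter_sigma_A)
    }
    cx$ligand$atoms <- la
    cx$complex_id <- paste0(base$complex_id, "-f", k)
    cx
  })
  list(frames = frames, in_contact = in_contact)
}
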
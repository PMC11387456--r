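# in-code fixture builders shared across test files

# minimal V2000 SDF writer for hand-built ligand fixtures
write_sdf_fixture <- function(atoms, bonds, path, title = "fixture") {
  n <- nrow(atoms); m <- nrow(bonds)
  lines <- c(title, "  gpcrsift", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      atoms$x[i], atoms$y[i], atoms$z[i], atoms$element[i]))
  }
  for (k in seq_len(m)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              bonds$from[k], bonds$to[k], bonds$order[k]))
  }
  chg <- which((atoms$charge %||% rep(0, n)) != 0)
  if (length(chg)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste(sprintf("%4d%4d", chg, atoms$charge[chg]),
                                   collapse = "")))
  }
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 3D ligand from SMILES via Open Babel coordinate generation
gen3d_ligand <- function(smiles) {
  sdf_text <- ChemmineOB::convertFormat(
    "SMI", "SDF", smiles, options = data.frame(names = "gen3D", args = ""))
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdf_text, tf)
  read_ligand_sdf(tf)
}

# plain activity-record data frame builder
activity_rows <- function(structure, parameter = "Ki", relation = "=",
                          value = 10, unit = "nM", source = "chembl") {
  data.frame(structure = structure, parameter = parameter,
             relation = relation, value = value, unit = unit,
             source = source, stringsAsFactors = FALSE)
}

# compound_set stub for operations that only read best_* columns
fake_compound_set <- function(Ki = NULL, IC50 = NULL, EC50 = NULL) {
  n <- max(length(Ki), length(IC50), length(EC50))
  pad <- function(x) if (is.null(x)) rep(NA_real_, n) else c(x, rep(NA_real_, n - length(x)))
  na_col <- rep(NA_real_, n)
  out <- data.frame(canonical_key = sprintf("K%04d", seq_len(n)),
                    n_records = rep(1L, n),
                    best_Ki_nM = pad(Ki), lt_Ki_nM = na_col, gt_Ki_nM = na_col,
                    best_IC50_nM = pad(IC50), lt_IC50_nM = na_col, gt_IC50_nM = na_col,
                    best_EC50_nM = pad(EC50), lt_EC50_nM = na_col, gt_EC50_nM = na_col,
                    chemotype = rep(NA_character_, n), stringsAsFactors = FALSE)
  class(out) <- c("compound_set", "data.frame")
  out
}

# single-bit SIFt builder on an arbitrary panel
make_sift <- function(panel, contact_bits, id = "s") {
  scheme <- sift_scheme()
  bits <- matrix(0L, length(panel), length(scheme),
                 dimnames = list(panel, scheme))
  bits[, "contact"] <- as.integer(contact_bits)
  structure(list(bits = bits, panel = panel, scheme = scheme,
                 complex_id = id, cutoffs = default_cutoffs(),
                 outside_panel = character(0)), class = "sift")
}

rigid_transform_complex <- function(cx, angle = 0.7, axis = c(0, 0, 1),
                                    shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle); C <- 1 - c_
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  R <- matrix(c(x*x*C + c_, x*y*C - z*s_, x*z*C + y*s_,
                y*x*C + z*s_, y*y*C + c_, y*z*C - x*s_,
                z*x*C - y*s_, z*y*C + x*s_, z*z*C + c_), 3, byrow = TRUE)
  move <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1] + shift[1]; df$y <- xyz[, 2] + shift[2]
    df$z <- xyz[, 3] + shift[3]
    df
  }
  cx$receptor$atoms <- move(cx$receptor$atoms)
  cx$ligand$atoms <- move(cx$ligand$atoms)
  cx
}

# residue-level view of an annotated receptor
residue_table_of <- function(receptor) {
  a <- receptor$atoms
  first <- !duplicated(paste(a$chain, a$resno, a$insert))
  data.frame(chain = a$chain[first], resno = a$resno[first],
             generic = a$generic[first], stringsAsFactors = FALSE)
}
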
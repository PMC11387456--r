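check_shared_panel <- function(sifts) {
  if (!length(sifts)) stop_arg("need at least one SIFt (n = 0 is undefined)")
  panel <- sifts[[1]]$panel
  ok <- vapply(sifts, function(s) identical(s$panel, panel) &&
                 identical(s$scheme, sifts[[1]]$scheme), logical(1))
  if (!all(ok)) stop_arg("SIFts do not share panel and scheme")
  panel
}

#' Group contact frequency profile
#'
#' Per-residue fraction of fingerprints with any bit set (collapsed) or
#' per-type fractions.
#'
#' @param sifts list of `sift` sharing panel and scheme.
#' @param collapse_types if `TRUE` (default) a residue counts when any
#'   interaction-type bit is set; otherwise frequencies are per type.
#' @param group_label label stored in the profile.
#' @return a `contact_profile` data frame: `residue`, `f` (in `[0,1]`), `n`,
#'   `group` (collapsed), or additionally `itype` (per-type).
#' @export
contact_frequency <- function(sifts, collapse_types = TRUE,
                              group_label = "group") {
  panel <- check_shared_panel(sifts)
  n <- length(sifts)
  if (collapse_types) {
    any_bit <- sapply(sifts, function(s) as.integer(rowSums(s$bits) > 0))
    any_bit <- matrix(any_bit, nrow = length(panel))
    out <- data.frame(residue = panel, f = rowMeans(any_bit), n = n,
                      group = group_label, stringsAsFactors = FALSE)
  } else {
    acc <- Reduce(`+`, lapply(sifts, `[[`, "bits")) / n
    out <- data.frame(residue = rep(panel, times = ncol(acc)),
                      itype = rep(colnames(acc), each = nrow(acc)),
                      f = as.numeric(acc), n = n, group = group_label,
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("contact_profile", "data.frame")
  out
}

#' Frequent contact positions across groups
#'
#' Residues contacting strictly more than `threshold` of compounds in at
#' least one profile (the ">60% in at least one group" presentation rule).
#'
#' @param profiles list of collapsed `contact_profile`s on one panel.
#' @param threshold frequency threshold, strict inequality (default 0.60).
#' @return character vector of residue labels, panel order.
#' @export
frequent_positions <- function(profiles, threshold = 0.60) {
  if (inherits(profiles, "contact_profile")) profiles <- list(profiles)
  panel <- profiles[[1]]$residue
  for (p in profiles) if (!identical(p$residue, panel))
    stop_arg("profiles do not share a panel")
  keep <- Reduce(`|`, lapply(profiles, function(p) p$f > threshold))
  panel[keep]
}

#' Active/inactive differential contact analysis
#'
#' Per residue, the difference between the fraction of interacting active
#' compounds and the fraction of interacting inactive compounds, ranked by
#' absolute difference (ties broken by panel order).
#'
#' @param active,inactive lists of `sift` on a shared panel.
#' @param top_k optional truncation of the ranked table.
#' @return a `differential_result` data frame: `residue`, `f_active`,
#'   `f_inactive`, `delta`, `abs_delta`, sorted by `abs_delta` descending.
#' @export
differential_contacts <- function(active, inactive, top_k = NULL) {
  if (!length(active) || !length(inactive))
    stop_arg("both groups must be nonempty")
  panel <- check_shared_panel(c(active, inactive))
  fa <- contact_frequency(active, group_label = "active")
  fi <- contact_frequency(inactive, group_label = "inactive")
  out <- data.frame(residue = panel, f_active = fa$f, f_inactive = fi$f,
                    delta = fa$f - fi$f, stringsAsFactors = FALSE)
  out$abs_delta <- abs(out$delta)
  out <- out[order(-out$abs_delta, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- head(out, top_k)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Exclude positions contacted by a reference agonist
#'
#' Retains differential results only for residues at which the given agonist
#' fingerprint has no bit set; ranking is preserved. This reproduces the
#' presentation rule for agonist-vs-inactive comparisons, where positions
#' contacted by the examined agonist are dropped.
#'
#' @param diff a `differential_result`.
#' @param agonist_sift a `sift` on the same panel.
#' @return filtered `differential_result`.
#' @export
agonist_exclusion <- function(diff, agonist_sift) {
  contacted <- agonist_sift$panel[rowSums(agonist_sift$bits) > 0]
  out <- diff[!diff$residue %in% contacted, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(diff)
  out
}

#' Spearman correlation of contact frequency with activity
#'
#' Per residue, the Spearman rank correlation between per-compound contact
#' frequencies and experimental activity values. Ranks use midranks on ties,
#' so any strictly monotone transform of the activities (nM vs log nM)
#' yields the same coefficient. Residues with constant frequency across
#' compounds have an undefined coefficient and are reported as `NA` with
#' `sign_set = "undefined"` (never coerced to zero).
#'
#' @param freqs numeric matrix, compounds x residues (rownames = compound
#'   ids, colnames = residue labels): per-compound contact frequency, either
#'   over trajectory frames or 0/1 single-pose bits.
#' @param activities named numeric vector of activity values (nM), names
#'   matching `rownames(freqs)`.
#' @return a `correlation_result` data frame: `residue`, `rho`, `n`,
#'   `sign_set` in `{"+1", "-1", "other", "undefined"}`.
#' @export
spearman_contact_activity <- function(freqs, activities) {
  freqs <- as.matrix(freqs)
  if (nrow(freqs) < 3L) stop_arg("need at least 3 compounds")
  if (!is.null(names(activities)) && !is.null(rownames(freqs)))
    activities <- activities[rownames(freqs)]
  if (length(activities) != nrow(freqs) || anyNA(activities))
    stop_arg("every compound needs an activity value")
  res <- lapply(seq_len(ncol(freqs)), function(j) {
    x <- freqs[, j]
    if (length(unique(x)) < 2L)
      return(data.frame(residue = colnames(freqs)[j], rho = NA_real_,
                        n = nrow(freqs), sign_set = "undefined",
                        stringsAsFactors = FALSE))
    rho <- stats::cor(x, activities, method = "spearman")
    sign_set <- if (isTRUE(all.equal(rho, 1))) "+1"
      else if (isTRUE(all.equal(rho, -1))) "-1" else "other"
    data.frame(residue = colnames(freqs)[j], rho = rho, n = nrow(freqs),
               sign_set = sign_set, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Ligand RMSF over aligned trajectory frames
#'
#' Root-mean-square fluctuation of each ligand heavy atom around its mean
#' position across frames (which must already be superposed on the receptor,
#' see [superpose_frames()]), and their mean as the ligand-level summary.
#'
#' @param aligned_frames list of `complex3d` (>= 2 frames).
#' @return an `rmsf_result`: `per_atom` (angstroms), `ligand_mean_rmsf`,
#'   `n_frames`.
#' @export
ligand_rmsf <- function(aligned_frames) {
  if (length(aligned_frames) < 2L) stop_arg("need at least 2 frames")
  heavy <- which(aligned_frames[[1]]$ligand$atoms$element != "H")
  coords <- lapply(aligned_frames, function(cx)
    as.matrix(cx$ligand$atoms[heavy, c("x", "y", "z")]))
  arr <- simplify2array(coords)            # atoms x 3 x frames
  mean_pos <- apply(arr, c(1, 2), mean)
  per_atom <- sqrt(vapply(seq_along(heavy), function(i) {
    dev <- t(arr[i, , ]) - matrix(mean_pos[i, ], dim(arr)[3], 3, byrow = TRUE)
    mean(rowSums(dev^2))
  }, numeric(1)))
  structure(list(per_atom = per_atom,
                 ligand_mean_rmsf = mean(per_atom),
                 n_frames = length(aligned_frames)),
            class = "rmsf_result")
}

#' Read a mutagenesis-effect table
#'
#' CSV schema: `generic_label`, `substitution` (e.g. `"E2x64D"`), `effect`
#' (one of increase, decrease, loss, no_change, mixed), optional `ligand`,
#' `source`.
#'
#' @param path CSV file.
#' @return validated data frame of mutation records.
#' @export
read_mutation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("generic_label", "substitution", "effect")
  if (!all(req %in% names(df)))
    stop_arg("mutation table needs columns: ", paste(req, collapse = ", "))
  bad <- !grepl("^[0-9]+x[0-9]+$", df$generic_label)
  if (any(bad)) stop_arg("invalid generic label(s): ",
                         paste(df$generic_label[bad], collapse = ", "))
  effects <- c("increase", "decrease", "loss", "no_change", "mixed")
  if (!all(df$effect %in% effects))
    stop_arg("unknown effect value(s); allowed: ", paste(effects, collapse = ", "))
  df
}

#' Confront flagged positions with mutagenesis data
#'
#' Descriptive table join (no significance testing): for each flagged
#' residue, whether mutation data exist and which effect categories they
#' report. A position is effect-bearing when any of its mutations reports
#' increase, decrease, loss, or mixed.
#'
#' @param flagged character vector of generic residue labels flagged by the
#'   contact analyses.
#' @param mutations mutation table (see [read_mutation_table()]).
#' @return a `concordance_report`: list with `per_residue` data frame
#'   (`residue`, `has_data`, `effects`, `effect_bearing`) and `summary`
#'   counts (`flagged_effectful`, `flagged_no_data`, `effectful_unflagged`).
#' @export
mutagenesis_concordance <- function(flagged, mutations) {
  flagged <- unique(as.character(flagged))
  eff_levels <- c("increase", "decrease", "loss", "mixed")
  per <- do.call(rbind, lapply(flagged, function(r) {
    m <- mutations[mutations$generic_label == r, , drop = FALSE]
    effs <- unique(m$effect)
    data.frame(residue = r, has_data = nrow(m) > 0,
               effects = paste(effs, collapse = ";"),
               effect_bearing = any(effs %in% eff_levels),
               stringsAsFactors = FALSE)
  })) %||% data.frame(residue = character(0), has_data = logical(0),
                      effects = character(0), effect_bearing = logical(0))
  effectful_res <- unique(mutations$generic_label[
    mutations$effect %in% eff_levels])
  summary <- c(flagged_effectful = sum(per$effect_bearing),
               flagged_no_data = sum(!per$has_data),
               effectful_unflagged = length(setdiff(effectful_res, flagged)))
  structure(list(per_residue = per, summary = summary),
            class = "concordance_report")
}

# --- plotting ---------------------------------------------------------------

#' Bar chart of contact-frequency profiles
#'
#' @param profiles list of collapsed `contact_profile`s (or one).
#' @param threshold optional horizontal reference line (e.g. 0.6).
#' @return a ggplot object.
#' @export
plot_contact_profile <- function(profiles, threshold = NULL) {
  if (inherits(profiles, "contact_profile")) profiles <- list(profiles)
  df <- do.call(rbind, profiles)
  df$residue <- factor(df$residue, levels = unique(df$residue))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = residue, y = f, fill = group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "residue (generic numbering)",
                  y = "contact frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  p
}

#' Bar chart of active/inactive contact differentials
#'
#' @param diff a `differential_result`.
#' @param top_k number of top positions to show.
#' @return a ggplot object.
#' @export
plot_differential <- function(diff, top_k = 10) {
  df <- head(as.data.frame(diff), top_k)
  df$residue <- factor(df$residue, levels = df$residue)
  ggplot2::ggplot(df, ggplot2::aes(x = residue, y = delta)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "residue (generic numbering)",
                  y = "f(active) - f(inactive)") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("residue", "f", "group", "delta"))
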
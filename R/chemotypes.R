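#' Built-in chemotype rule library
#'
#' SMARTS substructure rules for the named chemical classes of 5-HT5A
#' receptor ligands. Each rule carries a priority; [assign_chemotype()]
#' reports the highest-priority (lowest number) matching rule. The rules are
#' authored so that each class exemplar scaffold matches exactly its own
#' rule, which is what the unit tests assert. The `template` column is a
#' SMILES pattern with a `{R}` attachment point used by the synthetic
#' activity-table generator to decorate scaffolds without changing class.
#'
#' @return data frame with columns `name`, `smarts`, `priority`, `exemplar`,
#'   `template`.
#' @export
chemotype_rules <- function() {
  df <- data.frame(
    name = c("acylguanidine",
             "N'-benzyl-N-(pyridin-2-yl)guanidine",
             "2-amino-dihydroquinazoline",
             "2-aminoquinoline",
             "1-(quinolin-8-yl)methanamine",
             "isoquinoline amide",
             "quinazoline",
             "benzoxazine",
             "benzimidazole",
             "aminoimidazole",
             "carboline",
             "tryptamine",
             "lysergic acid derivative",
             "arylpiperazine",
             "biarylmethylamine"),
    smarts = c("[NX3]C(=[NX2])[NX3]C(=O)[#6]",
               "[#7]~C(~[#7]Cc1ccccc1)~[#7]c1ccccn1",
               "[NX3]C1=NCc2ccccc2N1",
               "[NX3;!$(N=*)]c1ccc2ccccc2n1",
               "[NX3][CH2]c1cccc2cccnc12",
               "O=C([NX3])c1cc2ccccc2cn1",
               "c1ccc2ncncc2c1",
               "C1COc2ccccc2N1",
               "c1ccc2[nH]cnc2c1",
               "[NX3;!$(N=*)]c1ncc[nH]1",
               "c1ccc2c(c1)[nH]c1ccncc12",
               "[NX3;!R][CH2;!R][CH2;!R]c1c[nH]c2ccccc12",
               "N1CCC2Cc3c[nH]c4cccc(c34)C2C1",
               "c1ccc(cc1)N1CC[NX3]CC1",
               "[NX3][CH2]c1ccc(-c2ccccc2)cc1"),
    exemplar = c("NC(=N)NC(=O)c1ccccc1",
                 "NC(=NCc1ccccc1)Nc1ccccn1",
                 "NC1=NCc2ccccc2N1",
                 "Nc1ccc2ccccc2n1",
                 "NCc1cccc2cccnc12",
                 "CNC(=O)c1cc2ccccc2cn1",
                 "c1ccc2ncncc2c1",
                 "C1COc2ccccc2N1",
                 "c1ccc2[nH]cnc2c1",
                 "Nc1ncc[nH]1",
                 "c1ccc2c(c1)[nH]c1ccncc12",
                 "NCCc1c[nH]c2ccccc12",
                 "CN1CCC2Cc3c[nH]c4cccc(c34)C2C1",
                 "c1ccc(cc1)N1CCNCC1",
                 "NCc1ccc(-c2ccccc2)cc1"),
    template = c("{R}NC(=N)NC(=O)c1ccccc1",
                 "{R}NC(=NCc1ccccc1)Nc1ccccn1",
                 "{R}NC1=NCc2ccccc2N1",
                 "{R}Nc1ccc2ccccc2n1",
                 "{R}NCc1cccc2cccnc12",
                 "{R}NC(=O)c1cc2ccccc2cn1",
                 "{R}c1ncc2ccccc2n1",
                 "{R}C1COc2ccccc2N1",
                 "{R}c1nc2ccccc2[nH]1",
                 "{R}Nc1ncc[nH]1",
                 "{R}c1ccc2c(c1)[nH]c1ccncc12",
                 "{R}NCCc1c[nH]c2ccccc12",
                 "{R}N1CCC2Cc3c[nH]c4cccc(c34)C2C1",
                 "{R}N1CCN(c2ccccc2)CC1",
                 "{R}NCc1ccc(-c2ccccc2)cc1"),
    stringsAsFactors = FALSE
  )
  df$priority <- seq_len(nrow(df))
  validate_chemotype_rules(df)
  df
}

validate_chemotype_rules <- function(rules) {
  stopifnot(is.data.frame(rules),
            all(c("name", "smarts", "priority") %in% names(rules)))
  if (anyDuplicated(rules$name)) stop_arg("chemotype rule names must be unique")
  if (anyDuplicated(rules$priority)) stop_arg("rule priorities must be distinct")
  invisible(rules)
}

#' Assign compounds to chemotype classes
#'
#' Matches each compound against an ordered SMARTS rule library and reports
#' the highest-priority matching class. Compounds matching no rule get `NA`.
#' Structures that fail to parse are reported in the `failed` attribute, not
#' silently dropped.
#'
#' @param x a `compound_set` (from [merge_compounds()]) or a character vector
#'   of SMILES.
#' @param rules rule table, see [chemotype_rules()].
#' @return for a `compound_set`, the set with its `chemotype` column filled;
#'   for a SMILES vector, a character vector of class names (`NA` = no
#'   match). Attribute `failed` lists indices of unparseable structures.
#' @export
assign_chemotype <- function(x, rules = chemotype_rules()) {
  validate_chemotype_rules(rules)
  smiles <- if (is.data.frame(x)) x$canonical_key else as.character(x)
  rules <- rules[order(rules$priority), , drop = FALSE]
  assigned <- rep(NA_character_, length(smiles))
  ok <- !is.na(canonical_smiles(smiles))
  if (any(ok)) {
    sdf <- ChemmineR::smiles2sdf(setNames(smiles[ok], paste0("M", which(ok))))
    remaining <- rep(TRUE, sum(ok))
    for (i in seq_len(nrow(rules))) {
      if (!any(remaining)) break
      hit <- smarts_match(sdf, rules$smarts[i])
      take <- remaining & hit
      assigned[which(ok)[take]] <- rules$name[i]
      remaining <- remaining & !hit
    }
  }
  if (is.data.frame(x)) {
    x$chemotype <- assigned
    attr(x, "chemotype_failed") <- which(!ok)
    x
  } else {
    structure(assigned, failed = which(!ok))
  }
}

#' Cluster compounds by fingerprint similarity (Butina leader clustering)
#'
#' Computes circular fingerprints (Open Babel ECFP4) and runs sphere-exclusion
#' (Butina) clustering on the Tanimoto similarity matrix: compounds are
#' processed in descending neighbor count (ties broken by ascending canonical
#' key); each unassigned leader claims all its unassigned neighbors at
#' `similarity >= similarity_cutoff`. Deterministic for a given input.
#'
#' @param entries a `compound_set` or character vector of SMILES.
#' @param similarity_cutoff Tanimoto similarity threshold in (0, 1).
#' @param fp_type Open Babel fingerprint name (default `"ECFP4"`, radius-2
#'   circular).
#' @return a `cluster_assignment`: list with `assignments` (data frame
#'   `canonical_key`, `cluster_id`), `clusters` (member lists, centroid
#'   first), `centroids`, and `method = "similarity"`.
#' @export
cluster_compounds <- function(entries, similarity_cutoff = 0.4,
                              fp_type = "ECFP4") {
  if (!is_scalar_number(similarity_cutoff) ||
      similarity_cutoff <= 0 || similarity_cutoff >= 1)
    stop_arg("similarity_cutoff must lie in (0, 1)")
  smiles <- if (is.data.frame(entries)) entries$canonical_key else canonical_smiles(entries)
  if (length(smiles) < 1L) stop_arg("need at least one compound")
  if (anyNA(smiles)) stop_arg("entries contain unparseable structures")
  sim <- tanimoto_matrix(smiles, fp_type)
  n <- length(smiles)
  neighbors <- lapply(seq_len(n), function(i)
    setdiff(which(sim[i, ] >= similarity_cutoff), i))
  nn <- lengths(neighbors)
  order_idx <- order(-nn, smiles)
  cluster_id <- rep(NA_integer_, n)
  cid <- 0L
  centroids <- integer(0)
  for (i in order_idx) {
    if (!is.na(cluster_id[i])) next
    cid <- cid + 1L
    members <- c(i, neighbors[[i]][is.na(cluster_id[neighbors[[i]]])])
    cluster_id[members] <- cid
    centroids <- c(centroids, i)
  }
  structure(list(
    assignments = data.frame(canonical_key = smiles, cluster_id = cluster_id,
                             stringsAsFactors = FALSE),
    clusters = split(seq_len(n), cluster_id),
    centroids = centroids,
    method = "similarity",
    similarity_cutoff = similarity_cutoff
  ), class = "cluster_assignment")
}

# Pairwise Tanimoto similarity on Open Babel fingerprints
tanimoto_matrix <- function(smiles, fp_type = "ECFP4") {
  sdf <- ChemmineR::smiles2sdf(setNames(smiles, paste0("M", seq_along(smiles))))
  fp <- ChemmineR::fingerprintOB(sdf, fp_type)
  n <- length(smiles)
  m <- matrix(1, n, n)
  for (i in seq_len(n)) {
    s <- ChemmineR::fpSim(fp[i], fp, method = "Tanimoto", sorted = FALSE)
    m[i, ] <- as.numeric(s)
  }
  # fingerprints of e.g. disconnected/featureless molecules can be all-zero;
  # define self-similarity as 1 and guard NaN from 0/0
  m[!is.finite(m)] <- 0
  diag(m) <- 1
  (m + t(m)) / 2
}

#' Rule-based cluster assignment from chemotype classes
#'
#' Wraps [assign_chemotype()] output in the same container as
#' [cluster_compounds()], so per-class summaries use one code path.
#'
#' @param entries a `compound_set` with (or without) chemotypes assigned.
#' @param rules rule table.
#' @return a `cluster_assignment` with `method = "rule_based"`; unmatched
#'   compounds form the explicit `"unassigned"` cluster.
#' @export
chemotype_clusters <- function(entries, rules = chemotype_rules()) {
  if (all(is.na(entries$chemotype))) entries <- assign_chemotype(entries, rules)
  label <- ifelse(is.na(entries$chemotype), "unassigned", entries$chemotype)
  structure(list(
    assignments = data.frame(canonical_key = entries$canonical_key,
                             cluster_id = label, stringsAsFactors = FALSE),
    clusters = split(seq_len(nrow(entries)), label),
    centroids = NULL,
    method = "rule_based"
  ), class = "cluster_assignment")
}

#' Per-cluster activity summary
#'
#' @param assignment a `cluster_assignment`.
#' @param entries the `compound_set` the assignment was computed on (same
#'   order).
#' @return data frame with one row per cluster: `cluster_id`, `size`,
#'   `median_Ki_nM`, `n_Ki_below_50`, `n_Ki_below_100`.
#' @export
cluster_summary <- function(assignment, entries) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (nrow(assignment$assignments) != nrow(entries))
    stop_arg("assignment does not cover entries")
  ids <- assignment$assignments$cluster_id
  do.call(rbind, lapply(split(seq_len(nrow(entries)), ids), function(idx) {
    ki <- entries$best_Ki_nM[idx]
    data.frame(cluster_id = as.character(ids[idx[1]]),
               size = length(idx),
               median_Ki_nM = if (any(!is.na(ki))) stats::median(ki, na.rm = TRUE) else NA_real_,
               n_Ki_below_50 = sum(!is.na(ki) & ki < 50),
               n_Ki_below_100 = sum(!is.na(ki) & ki < 100),
               stringsAsFactors = FALSE)
  }))
}
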
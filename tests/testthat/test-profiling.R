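test_that("contact frequency counts fingerprints with any bit set", {
  panel <- c("3x32", "5x43", "6x52")
  sifts <- list(make_sift(panel, c(1, 0, 0)), make_sift(panel, c(1, 1, 0)),
                make_sift(panel, c(0, 1, 0)))
  prof <- contact_frequency(sifts)
  expect_equal(prof$f, c(2 / 3, 2 / 3, 0))
  expect_equal(prof$n, rep(3L, 3))
  expect_error(contact_frequency(list()), "n = 0")
  mismatched <- c(sifts, list(make_sift(c("A", "B"), c(1, 0))))
  expect_error(contact_frequency(mismatched), "share panel")
})

test_that("planted Bernoulli contact rates are recovered within 3 SE", {
  spec <- synthetic_spec(seed = 23, n_active = 200, n_inactive = 10,
                         planted_deltas = c(), null_p = 0.6)
  pan <- simulate_sift_panel(spec, panel_size = 10)
  prof <- contact_frequency(pan$active)
  se <- sqrt(0.6 * 0.4 / 200)
  expect_true(all(abs(prof$f - 0.6) < 3 * se + 1e-9))
})

test_that("frequent positions use a strict threshold over any group", {
  panel <- c("A", "B", "C")
  p1 <- contact_frequency(list(make_sift(panel, c(1, 0, 0)),
                               make_sift(panel, c(1, 1, 0)),
                               make_sift(panel, c(1, 1, 0)),
                               make_sift(panel, c(1, 0, 0)),
                               make_sift(panel, c(1, 1, 1))), group_label = "g1")
  # B has f = 0.6 exactly: excluded by the strict inequality
  expect_equal(p1$f[2], 0.6)
  expect_equal(frequent_positions(p1), "A")
  all_on <- contact_frequency(list(make_sift(panel, c(1, 1, 1))))
  expect_equal(frequent_positions(list(p1, all_on)), panel)
  # monotone decreasing in the threshold
  ths <- c(0, 0.2, 0.4, 0.6, 0.8)
  ns <- vapply(ths, function(t) length(frequent_positions(p1, t)), integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("two-group planted positions are flagged only via their group", {
  spec <- synthetic_spec(seed = 29, n_active = 80, n_inactive = 80,
                         planted_deltas = c(A1 = 0.55, B2 = 0.55),
                         null_p = 0.25)
  pan <- simulate_sift_panel(spec, panel_size = 20)
  prof_a <- contact_frequency(pan$active, group_label = "active")
  prof_i <- contact_frequency(pan$inactive, group_label = "inactive")
  freq <- frequent_positions(list(prof_a, prof_i), 0.6)
  expect_setequal(freq, c("A1", "B2"))
})

test_that("differential contacts rank by absolute delta with sign structure", {
  panel <- c("A", "B")
  act <- list(make_sift(panel, c(1, 0)), make_sift(panel, c(1, 0)))
  ina <- list(make_sift(panel, c(0, 0)), make_sift(panel, c(0, 0)))
  d <- differential_contacts(act, ina)
  expect_equal(d$residue[1], "A")
  expect_equal(d$delta[1], 1)
  expect_equal(d$abs_delta, abs(d$delta))
  # identical groups: all deltas zero
  d0 <- differential_contacts(act, act)
  expect_true(all(d0$delta == 0))
  # swapping groups negates delta, preserves the abs ranking
  dsw <- differential_contacts(ina, act)
  expect_equal(dsw$delta, -d$delta)
  expect_equal(dsw$residue, d$residue)
  expect_error(differential_contacts(act, list()), "nonempty")
})

test_that("a planted differential residue is top-ranked", {
  spec <- synthetic_spec(seed = 29, n_active = 50, n_inactive = 50,
                         planted_deltas = c(D1 = 0.4), null_p = 0.3)
  pan <- simulate_sift_panel(spec, panel_size = 31)
  d <- differential_contacts(pan$active, pan$inactive, top_k = 5)
  expect_equal(nrow(d), 5L)
  expect_equal(d$residue[1], "D1")
})

test_that("agonist exclusion removes contacted positions, keeping rank order", {
  panel <- c("A", "B", "C")
  act <- list(make_sift(panel, c(1, 1, 0)))
  ina <- list(make_sift(panel, c(0, 0, 0)))
  d <- differential_contacts(act, ina)
  all_contact <- make_sift(panel, c(1, 1, 1))
  expect_equal(nrow(agonist_exclusion(d, all_contact)), 0L)
  no_contact <- make_sift(panel, c(0, 0, 0))
  expect_equal(agonist_exclusion(d, no_contact), d)
  partial <- make_sift(panel, c(1, 0, 0))
  kept <- agonist_exclusion(d, partial)
  expect_false("A" %in% kept$residue)
  expect_true("B" %in% kept$residue)
})

test_that("Spearman correlation matches the closed form on rank permutations", {
  acts <- c(c1 = 10, c2 = 100, c3 = 1000)
  # perfect anticorrelation
  freqs <- matrix(c(0.9, 0.5, 0.1), 3, 1,
                  dimnames = list(names(acts), "3x32"))
  res <- spearman_contact_activity(freqs, acts)
  expect_equal(res$rho, -1)
  expect_equal(res$sign_set, "-1")
  # all 6 permutations of 3 distinct ranks against fixed activity ranks
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  closed_form <- vapply(perms, function(p)
    1 - 6 * sum((p - 1:3)^2) / (3 * (3^2 - 1)), numeric(1))
  got <- vapply(perms, function(p) {
    f <- matrix(c(0.1, 0.5, 0.9)[p], 3, 1,
                dimnames = list(names(acts), "r"))
    spearman_contact_activity(f, acts)$rho
  }, numeric(1))
  expect_equal(got, closed_form)
  expect_setequal(round(got, 10), c(1, 0.5, -0.5, -1))
})

test_that("constant contact columns are reported undefined, never zero", {
  acts <- c(c1 = 10, c2 = 100, c3 = 1000)
  freqs <- cbind(flat = c(0.5, 0.5, 0.5), up = c(0.1, 0.5, 0.9))
  rownames(freqs) <- names(acts)
  res <- spearman_contact_activity(freqs, acts)
  expect_true(is.na(res$rho[res$residue == "flat"]))
  expect_equal(res$sign_set[res$residue == "flat"], "undefined")
  expect_equal(res$sign_set[res$residue == "up"], "+1")
  expect_error(spearman_contact_activity(freqs[1:2, ], acts[1:2]),
               "at least 3")
})

test_that("Spearman is invariant to monotone transforms of activity", {
  set.seed(41)
  acts <- setNames(rlnorm(8, log(300), 1), paste0("c", 1:8))
  freqs <- matrix(runif(8 * 4), 8, 4,
                  dimnames = list(names(acts), paste0("r", 1:4)))
  r1 <- spearman_contact_activity(freqs, acts)
  r2 <- spearman_contact_activity(freqs, log(acts))
  expect_equal(r1$rho, r2$rho)
})

test_that("ligand RMSF is zero for identical frames and needs 2+ frames", {
  arc <- simulate_complex("hbond", seed = 9, rotate = FALSE)
  frames <- rep(list(arc$complex), 4)
  r <- ligand_rmsf(frames)
  expect_equal(r$ligand_mean_rmsf, 0)
  expect_equal(r$per_atom, rep(0, sum(arc$complex$ligand$atoms$element != "H")))
  expect_error(ligand_rmsf(frames[1]), "at least 2")
})

test_that("isotropic jitter gives per-atom RMSF near sigma * sqrt(3)", {
  arc <- simulate_complex("hbond", seed = 10, rotate = FALSE)
  sigma <- 0.25
  spec <- synthetic_spec(seed = 31, persistence = 1, jitter_sigma_A = sigma)
  tr <- simulate_trajectory(arc$complex, spec, n_frames = 1200)
  r <- ligand_rmsf(tr$frames)
  expect_equal(r$ligand_mean_rmsf, sigma * sqrt(3), tolerance = 0.05)
  # invariant to one rigid transform applied identically to all frames
  moved <- lapply(tr$frames, rigid_transform_complex, angle = 0.9)
  r2 <- ligand_rmsf(moved)
  expect_equal(r2$per_atom, r$per_atom, tolerance = 1e-10)
})

test_that("mutagenesis concordance is a faithful table join", {
  mut <- read_mutation_table(system.file("extdata", "mutations_5ht5a.csv",
                                         package = "gpcrsift"))
  rep1 <- mutagenesis_concordance("3x32", mut)
  expect_true(rep1$per_residue$effect_bearing)
  expect_equal(unname(rep1$summary["flagged_effectful"]), 1L)
  # empty mutation table: every flagged position lacks data
  empty <- mut[0, ]
  rep2 <- mutagenesis_concordance(c("3x32", "6x52"), empty)
  expect_true(all(!rep2$per_residue$has_data))
  expect_equal(unname(rep2$summary["flagged_no_data"]), 2L)
  # synthetic overlap design: counts equal the construction
  design <- data.frame(generic_label = c("1x50", "2x50", "3x50"),
                       substitution = c("A1x50B", "A2x50B", "A3x50B"),
                       effect = c("loss", "no_change", "decrease"),
                       stringsAsFactors = FALSE)
  rep3 <- mutagenesis_concordance(c("1x50", "2x50", "9x99"), design)
  expect_equal(unname(rep3$summary["flagged_effectful"]), 1L)  # 1x50
  expect_equal(unname(rep3$summary["flagged_no_data"]), 1L)    # 9x99
  expect_equal(unname(rep3$summary["effectful_unflagged"]), 1L) # 3x50
})

test_that("profile and differential plots build without error", {
  panel <- c("A", "B")
  prof <- contact_frequency(list(make_sift(panel, c(1, 0))))
  p1 <- plot_contact_profile(prof, threshold = 0.6)
  expect_s3_class(p1, "ggplot")
  d <- differential_contacts(list(make_sift(panel, c(1, 0))),
                             list(make_sift(panel, c(0, 1))))
  expect_s3_class(plot_differential(d), "ggplot")
})
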
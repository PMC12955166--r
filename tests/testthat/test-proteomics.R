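make_pm <- function(x, protein, replicate_of = NULL) {
  peptide_matrix(x, protein, replicate_of = replicate_of)
}

test_that("peptide filtering applies the missingness rule with a strict bound", {
  x <- matrix(10, nrow = 3, ncol = 10,
              dimnames = list(c("p30", "p20", "p0"), sprintf("s%02d", 1:10)))
  x["p30", 1:3] <- NA   # 30% missing -> dropped
  x["p20", 1:2] <- NA   # exactly 20% -> retained
  got <- filter_peptides(make_pm(x, c("A", "B", "C")))
  expect_equal(rownames(got$matrix$intensities), c("p20", "p0"))
  expect_equal(got$report$reason[got$report$peptide_id == "p30"],
               "missing_fraction")
  # fully observed matrix passes through unchanged
  full <- make_pm(matrix(5, 2, 4, dimnames = list(c("a", "b"), NULL)),
                  c("A", "B"))
  expect_equal(filter_peptides(full)$matrix$intensities, full$intensities)
})

test_that("noisy technical replicates trigger the CV filter", {
  set.seed(31)
  x <- matrix(1000, nrow = 2, ncol = 4,
              dimnames = list(c("stable", "noisy"),
                              c("s1", "s1r", "s2", "s2r")))
  x["stable", ] <- c(1000, 1010, 900, 905)     # CV well under 15%
  x["noisy", ] <- c(1000, 1500, 800, 1300)     # CV above 15%
  rep_of <- c(s1 = "s1", s1r = "s1", s2 = "s2", s2r = "s2")
  got <- filter_peptides(make_pm(x, c("A", "B"), rep_of))
  expect_equal(rownames(got$matrix$intensities), "stable")
  expect_equal(got$report$reason[2], "replicate_cv")
})

test_that("losing every peptide of a panel protein raises a warning", {
  x <- matrix(c(NA, NA, NA, NA, 1, 2, 3, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("gpx", "other"), NULL))
  expect_warning(got <- filter_peptides(make_pm(x, c("GPX3", "DECOY"))),
                 "GPX3")
  expect_equal(got$lost_panel_proteins, "GPX3")
})

test_that("median normalization centres each sample and is idempotent", {
  x <- matrix(c(1, 2, 4), nrow = 3,
              dimnames = list(c("a", "b", "c"), "s1"))
  pm <- make_pm(x, c("A", "B", "C"))
  norm <- normalize_peptides(pm)
  expect_equal(unname(norm$intensities[, 1]), c(-1, 0, 1))
  # identical values collapse to zero; a singleton observed value maps to 0
  x2 <- matrix(c(8, 8, 8, NA, NA, 32), nrow = 3,
               dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  n2 <- normalize_peptides(make_pm(x2, c("A", "B", "C")))
  expect_equal(unname(n2$intensities[, 1]), c(0, 0, 0))
  expect_equal(unname(n2$intensities[3, 2]), 0)
  expect_true(is.na(n2$intensities[1, 2]))
  # idempotence
  twice <- normalize_peptides(norm)
  expect_equal(twice$intensities, norm$intensities)
  # nonpositive cells are named in the error
  bad <- make_pm(matrix(c(1, 0), 2, 1,
                        dimnames = list(c("a", "bad"), "s9")),
                 c("A", "B"))
  expect_error(normalize_peptides(bad), "bad.*s9")
})

test_that("protein roll-up averages observed peptides only", {
  # pep1, pep2 belong to P1; pep3 to P2
  x <- matrix(c(1, NA, NA,
                3, 5, NA), nrow = 3,
              dimnames = list(c("pep1", "pep2", "pep3"), c("s1", "s2")))
  pm <- make_pm(x, c("P1", "P1", "P2"))
  pm$normalized <- TRUE  # values already on the normalized scale
  prot <- rollup_proteins(pm)
  expect_equal(prot["P1", "s2"], mean(c(3, 5)))
  expect_equal(prot["P1", "s1"], 1)        # mean over the observed peptide
  expect_true(is.na(prot["P2", "s1"]))     # all peptides missing
})

test_that("candidate screening gives exact small-sample Mann-Whitney p-values", {
  mat <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
                dimnames = list("P", NULL))
  got <- screen_candidates(mat, c("sptb", "sptb", "sptb",
                                  "term", "term", "term"))
  expect_equal(got$p, 0.1)   # U = 0; 2/20 assignments as extreme
  expect_equal(got$p, oracle_mw_exact_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(got$direction, "down")
  # identical distributions: tie-corrected two-sided p = 1
  flat <- matrix(rep(c(1, 2), 4), nrow = 1, dimnames = list("Q", NULL))
  got2 <- screen_candidates(flat, rep(c("sptb", "term"), each = 4))
  expect_equal(got2$p, 1)
  expect_error(screen_candidates(mat, rep("sptb", 6)), "both groups")
})

test_that("U statistic and tie-corrected AUC are two views of one quantity", {
  set.seed(41)
  for (i in 1:10) {
    x <- round(rnorm(12, 1), 1)  # rounding forces ties
    y <- round(rnorm(15), 1)
    mat <- matrix(c(x, y), nrow = 1, dimnames = list("P", NULL))
    labs <- c(rep("sptb", 12), rep("term", 15))
    sc <- screen_candidates(mat, labs)
    expect_equal(sc$u_statistic / (12 * 15),
                 auc_mann_whitney(c(x, y), labs), tolerance = 1e-12)
  }
})

test_that("BH-adjusted q-values are monotone in raw p-value order", {
  set.seed(51)
  mat <- matrix(rnorm(20 * 24), nrow = 20,
                dimnames = list(sprintf("P%02d", 1:20), NULL))
  sc <- screen_candidates(mat, rep(c("sptb", "term"), each = 12))
  ord <- order(sc$p)
  expect_true(all(diff(sc$q[ord]) >= -1e-12))
  expect_true(all(sc$q >= sc$p - 1e-12))
})

test_that("concordance requires matching sign and comparable magnitude", {
  screen <- data.frame(protein = c("A", "B", "C", "D"),
                       effect = c(1.0, 1.0, 1.0, 1.0),
                       stringsAsFactors = FALSE)
  val <- matrix(c(0.9, 0.9, 0.9, 0.9,  0, 0, 0, 0,      # A: clear up
                  -1, -1, -1, -1,      0, 0, 0, 0,      # B: reversed
                  0.4, 0.4, 0.4, 0.4,  0, 0, 0, 0),     # C: too small
                nrow = 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), NULL))
  labs <- rep(c("sptb", "term"), each = 4)
  got <- concordance_check(screen, val, labs)
  expect_equal(got$concordant_in_validation, c(TRUE, FALSE, FALSE, FALSE))
  expect_false(got$evaluable[4])  # D absent from validation entirely
})

test_that("the 21-protein screen funnels down to the three planted markers", {
  specs <- default_cohort_specs(seed = 20260101L)
  uab <- generate_cohort(specs$UAB)
  stan <- generate_cohort(specs$Stanford)
  process <- function(cohort, seed) {
    pep <- generate_peptide_data(cohort, seed = seed)
    filt <- filter_peptides(pep$pm)
    prot <- rollup_proteins(normalize_peptides(filt$matrix))
    keep <- !grepl("_rep$", colnames(prot))
    list(prot = prot[, keep, drop = FALSE],
         labels = pep$labels[colnames(prot)[keep]])
  }
  d <- process(uab, 20260401L)
  v <- process(stan, 20260402L)
  expect_equal(nrow(d$prot), 21)
  screen <- screen_candidates(d$prot, d$labels)
  screen <- concordance_check(screen, v$prot, v$labels)
  validated <- screen$protein[screen$significant &
                                screen$concordant_in_validation]
  expect_setequal(validated, c("GPX3", "NID1", "PAPPA2"))
})
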
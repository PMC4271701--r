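test_that("expected frequency is the ancestry-haplotype product", {
  expect_equal(expected_frequency(0, 0.9), 0)
  expect_equal(expected_frequency(1, 0.37), 0.37)
  # back-solved worked example: ancestry 0.659 x parental frequency 0.44
  expect_equal(round(expected_frequency(0.659, 0.44), 2), 0.29)
  expect_error(expected_frequency(1.2, 0.5), "0, 1")
  expect_error(expected_frequency(0.5, -0.1), "0, 1")
})

test_that("migration difference reproduces the worked-example rows", {
  expect_equal(migration_difference(0.25, 0.05), -0.20)
  expect_equal(migration_difference(0.07, 0.34), 0.27)
  expect_equal(migration_difference(0.4, 0.4), 0)
  expect_error(migration_difference(1.5, 0.2), "0, 1")
})

test_that("standardization matches hand arithmetic and its contract", {
  d <- c(0.1, -0.2, 0.05, 0.3, -0.1, 0, 0.15, -0.25, 0.2, -0.05)
  z <- standardize_scores(d)
  expect_equal(z, (d - mean(d)) / sd(d))     # sample sd, n - 1
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)
  expect_error(standardize_scores(rep(0.3, 5)), "zero variance")
  expect_error(standardize_scores(0.2), ">= 2")
})

test_that("scan scores shared modal haplotypes with per-breed z", {
  sim <- small_sim(71, n_sites = 900, n_admixed = 40)
  grid <- build_windows(sim$parental$map, 30)
  scan <- build_windows(sim$parental$map, 30, 15)
  fld <- ancestry_from_truth(sim$truth, grid)
  rec <- migration_scan(sim$parental, sim$admixed, fld, scan)
  expect_true(all(rec$observed > 0))
  expect_true(all(rec$expected <= rec$freq_parental + 1e-12))
  expect_true(all(rec$expected >= 0 & rec$expected <= 1))
  expect_equal(rec$expected, rec$p_B * rec$freq_parental, tolerance = 1e-12)
  expect_equal(rec$freq_change, rec$observed - rec$expected,
               tolerance = 1e-12)
  for (b in unique(rec$breed)) {
    zb <- rec$z[rec$breed == b]
    expect_lt(abs(mean(zb)), 1e-9)
    expect_lt(abs(sd(zb) - 1), 1e-9)
  }
  # literal printed-formula variant: p(B) * observed - parental frequency
  lit <- migration_scan(sim$parental, sim$admixed, fld, scan,
                        convention = "literal")
  expect_equal(lit$freq_change, lit$p_B * lit$observed - lit$freq_parental,
               tolerance = 1e-12)
})

test_that("windows whose modal parental haplotype is absent are not scored", {
  # two breeds over two windows; the admixed cohort carries only breed A
  # haplotypes, so breed B's modal haplotypes are absent and unscored
  hapA <- matrix(rep(c(0L, 1L), each = 30), 6, 60, byrow = TRUE)
  hapA[5:6, ] <- 1L - hapA[5:6, ]   # minority variant keeps windows polymorphic
  set.seed(72)
  hapB <- matrix(rbinom(6 * 60, 1, 0.5), 6, 60)
  par <- genotype_panel(rbind(hapA, hapB),
                        marker_map("1", seq_len(60) * 1000L),
                        sample_manifest(sprintf("S%d", 1:6),
                                        rep(c("A", "B"), each = 3),
                                        "parental_panel"))
  adm_hap <- hapA[c(1:4, 5:6), ]
  adm_hap[1, 1] <- 1L   # break window symmetry so diffs have variance
  adm <- genotype_panel(adm_hap, par$map,
                        sample_manifest(c("C1", "C2", "C3"), "Cross",
                                        "admixed"))
  grid <- build_windows(par$map, 30)
  post <- array(0.5, c(6, 2, 2))
  fld <- ancestry_field(post, c("A", "B"), grid)
  rec <- migration_scan(par, adm, fld, grid)
  expect_false("B" %in% rec$breed)
  expect_equal(sort(unique(rec$breed)), "A")
})

test_that("outlier calling equals a brute-force filter", {
  set.seed(73)
  rec <- data.table::data.table(breed = "A", window_id = 1:50,
                                chrom = "1", start_bp = 1:50 * 1000L,
                                end_bp = 1:50 * 1000L + 500L,
                                haplotype = "x", freq_parental = 0.5,
                                p_B = 0.5, expected = 0.25,
                                observed = runif(50),
                                freq_change = rnorm(50))
  rec$z <- standardize_scores(rec$freq_change)
  out <- call_migration_outliers(rec, 3)
  expect_equal(nrow(out), sum(abs(rec$z) >= 3))
  expect_true(all(diff(abs(out$z)) <= 0))
  expect_equal(nrow(call_migration_outliers(rec, 0)), nrow(rec))
  low <- rec[abs(rec$z) < 3, ]
  expect_equal(nrow(call_migration_outliers(low, 3)), 0)
})

test_that("overlapping outlier windows merge into regions", {
  rec <- data.table::data.table(
    breed = c("A", "A", "A", "B"), window_id = 1:4, chrom = "1",
    start_bp = c(100L, 600L, 5000L, 100L),
    end_bp = c(1000L, 1500L, 6000L, 1000L),
    haplotype = "x", freq_parental = 0.5, p_B = 0.5, expected = 0.25,
    observed = 0.5, freq_change = c(0.2, 0.3, -0.4, 0.1),
    z = c(3.5, 4.2, -5.0, 3.1))
  reg <- merge_outlier_regions(rec)
  a <- reg[reg$breed == "A", ][order(start_bp)]
  expect_equal(nrow(a), 2)
  expect_equal(a$start_bp, c(100L, 5000L))
  expect_equal(a$end_bp, c(1500L, 6000L))
  expect_equal(a$peak_z[1], 4.2)   # peak window carries the stats
  expect_equal(nrow(reg[reg$breed == "B", ]), 1)
})

test_that("null calibration: few extreme z under truth ancestry", {
  n_ext <- 0L; n_tot <- 0L
  for (s in 1:5) {
    sim <- small_sim(700 + s, n_sites = 1000, n_admixed = 50)
    grid <- build_windows(sim$parental$map, 30)
    scan <- build_windows(sim$parental$map, 30, 15)
    fld <- ancestry_from_truth(sim$truth, grid)
    rec <- migration_scan(sim$parental, sim$admixed, fld, scan)
    n_ext <- n_ext + sum(abs(rec$z) >= 3)
    n_tot <- n_tot + nrow(rec)
  }
  expect_lt(n_ext / n_tot, 0.02)
})
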
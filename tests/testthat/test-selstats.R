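test_that("EHH definition: core value, hand enumeration, monotonicity", {
  # 4 carriers of allele 1 at the core; extending to the second flank two
  # carriers stay identical and two become unique -> EHH = C(2,2)/C(4,2)
  hap <- rbind(c(1L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(1L, 1L, 1L),
               c(0L, 0L, 0L), c(0L, 1L, 1L))
  p <- toy_panel(hap, pops = rep("P", 3))
  e <- ehh(p, 1, 1L, max_extension = 1e9, floor_ehh = 0, max_gap = 1e9)
  curve <- e$curve[e$curve$direction >= 0, ]
  expect_equal(curve$ehh[curve$site == 1], 1)            # EHH at core = 1
  expect_equal(curve$ehh[curve$site == 2], (1 + 1) / 6)  # {1,2} and {3,4}
  expect_equal(curve$ehh[curve$site == 3], 1 / 6)        # only {1,2} left
  expect_true(all(diff(curve$ehh) <= 1e-12))             # non-increasing
  expect_error(ehh(p, 1, 2L), "carriers")
})

test_that("EHH equals brute-force all-pairs homozygosity on random toys", {
  for (s in 1:20) {
    set.seed(900 + s)
    hap <- matrix(rbinom(10 * 50, 1, runif(50, 0.2, 0.8)),
                  10, 50, byrow = TRUE)
    p <- toy_panel(hap, pops = rep("P", 5))
    core <- sample(10:40, 1)
    allele <- if (sum(hap[, core]) >= 2 &&
                  sum(hap[, core] == 0) >= 2) sample(0:1, 1) else
                    as.integer(mean(hap[, core]) > 0.5)
    if (sum(hap[, core] == allele) < 2) next
    e <- ehh(p, core, allele, max_extension = 1e9, floor_ehh = 0,
             max_gap = 1e9)
    for (r in seq_len(nrow(e$curve))) {
      expect_equal(e$curve$ehh[r],
                   brute_ehh_at(hap, core, allele, e$curve$site[r]),
                   info = sprintf("seed %d site %d", s, e$curve$site[r]))
    }
  }
})

test_that("iHS is zero on mirror-symmetric haplotype structure", {
  # ancestral and derived carriers have identical flank patterns
  set.seed(91)
  flank <- matrix(rbinom(4 * 20, 1, 0.5), 4, 20)
  hap <- cbind(rbind(flank[, 1:10], flank[, 1:10]),
               rep(c(0L, 1L), each = 4),
               rbind(flank[, 11:20], flank[, 11:20]))
  p <- toy_panel(hap, pops = rep("P", 4))
  core <- 11L
  ia <- ehh(p, core, 0L, max_extension = 1e9, floor_ehh = 0, max_gap = 1e9)
  id <- ehh(p, core, 1L, max_extension = 1e9, floor_ehh = 0, max_gap = 1e9)
  expect_equal(hapflow:::integrate_curve(ia$curve),
               hapflow:::integrate_curve(id$curve))
})

test_that("iHS standardization is exact within frequency bins", {
  sim <- small_sim(92, n_sites = 1200, n_admixed = 40)
  sc <- ihs(sim$admixed)
  ok <- is.finite(sc$ihs)
  expect_gt(sum(ok), 500)
  bins <- hapflow:::merge_small_bins(pmin(floor(sc$daf[ok] / 0.05), 19L), 10L)
  for (b in unique(bins)) {
    v <- sc$ihs[ok][bins == b]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sd(v) - 1), 1e-9)
  }
  expect_true(all(sc$flag[!is.na(sc$ihs)] == "ok"))
  # low-frequency and edge sites are excluded, not scored
  expect_true(all(is.na(sc$ihs[sc$flag != "ok"])))
})

test_that("an injected common long haplotype is a localized iHS peak", {
  hits <- 0L
  for (s in 1:5) {
    sim <- small_sim(930 + s, n_sites = 1000, n_admixed = 40)
    grid <- build_windows(sim$parental$map, 30, 15)
    w <- grid[30, ]
    inj <- inject_haplotype_selection(sim$admixed, sim$parental, sim$truth,
                                      w, "Holstein", 0.4, seed = s)
    sc <- ihs(inj$panel)
    peak <- sc$pos[which.max(abs(sc$ihs))]
    if (length(peak) &&
        peak >= w$start_bp - (w$end_bp - w$start_bp) &&
        peak <= w$end_bp + (w$end_bp - w$start_bp)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("Rsb is identically zero for a panel against itself", {
  sim <- small_sim(94, n_sites = 400, n_admixed = 20)
  r <- rsb(sim$admixed, sim$admixed)
  expect_true(all(r$raw[is.finite(r$raw)] == 0))
  sim2 <- small_sim(95, n_sites = 400, n_admixed = 20)
  hol <- subset_population(sim2$parental, "Holstein")
  r2 <- rsb(hol, sim2$admixed)
  expect_lt(abs(median(r2$rsb, na.rm = TRUE)), 1e-9)
  expect_error(rsb(sim$admixed, sim2$admixed), "same sites")
})

test_that("a population with an injected shared haplotype has positive Rsb", {
  signs <- integer(0)
  for (s in 1:5) {
    sim <- small_sim(960 + s, n_sites = 800, n_admixed = 40)
    grid <- build_windows(sim$parental$map, 30, 15)
    w <- grid[20, ]
    inj <- inject_haplotype_selection(sim$admixed, sim$parental, sim$truth,
                                      w, "Holstein", 0.5, seed = s)
    r <- rsb(inj$panel, sim$admixed)
    in_w <- r$pos >= w$start_bp & r$pos <= w$end_bp & is.finite(r$rsb)
    if (any(in_w)) signs <- c(signs, sign(max(r$rsb[in_w])))
  }
  expect_true(all(signs == 1L))
})

test_that("F_ST estimator sanity: identity, fixation, hand values", {
  # identical populations: split one random panel in two
  p <- random_panel(100, 2000, seed = 97,
                    pops = rep(c("A", "B"), each = 25))
  same <- fst(p, "A", "B")
  expect_lt(abs(same$mean_raw), 0.01)
  # fixed difference
  hap <- rbind(matrix(0L, 4, 3), matrix(1L, 4, 3))
  pf <- toy_panel(hap, pops = rep(c("A", "B"), each = 2))
  fx <- fst(pf, "A", "B")
  expect_equal(fx$per_snp$fst, rep(1, 3))
  # p_A = 0.2, p_B = 0.8: Nei-style (H_T - H_S)/H_T = (0.5 - 0.32)/0.5
  set.seed(98)
  hA <- matrix(rbinom(400 * 100, 1, 0.2), 400, 100)
  hB <- matrix(rbinom(400 * 100, 1, 0.8), 400, 100)
  pb <- toy_panel(rbind(hA, hB), pops = rep(c("A", "B"), each = 200))
  nei <- fst(pb, "A", "B", estimator = "nei")
  expect_lt(abs(nei$mean_raw - 0.36), 0.03)
  # Hudson closed form at these frequencies: 0.36 / 0.68
  hud <- fst(pb, "A", "B")
  expect_lt(abs(hud$overall - 0.36 / 0.68), 0.05)
  # monomorphic pooled sites are excluded from the mean
  hap2 <- cbind(hap, 0L)
  pm <- toy_panel(hap2, pops = rep(c("A", "B"), each = 2))
  expect_equal(fst(pm, "A", "B")$n_excluded, 1L)
  expect_error(fst(pf, "A", "Z"), "present")
})

test_that("region caller equals brute-force enumeration on random tracks", {
  for (s in 1:30) {
    set.seed(1100 + s)
    n <- 60
    pos <- sort(sample.int(5e6, n))
    score <- rnorm(n, 0, 2)
    got <- candidate_regions(data.frame(chrom = "1", pos = pos, ihs = score),
                             score_threshold = 3, min_hits = 3, span = 1e6)
    want <- brute_regions("1", pos, score, 3, 3, 1e6)
    expect_equal(nrow(got), nrow(want), info = paste("seed", s))
    if (nrow(got)) {
      expect_equal(got$start_bp, want$start_bp)
      expect_equal(got$end_bp, want$end_bp)
      expect_equal(got$n_significant, want$n_significant)
    }
  }
})

test_that("region caller rule instantiation", {
  empty <- candidate_regions(
    data.frame(chrom = "1", pos = c(1e5, 2e5, 3e5), ihs = c(1, 2, -2)))
  expect_equal(nrow(empty), 0)
  one <- candidate_regions(
    data.frame(chrom = "1", pos = c(1e5, 3e5, 5e5, 9e6),
               ihs = c(3.5, -4, 3.2, 1)))
  expect_equal(nrow(one), 1)
  expect_equal(one$start_bp, 1e5)
  expect_equal(one$end_bp, 5e5)
  expect_equal(one$max_score, 4)
  expect_equal(one$peak_pos, 3e5)
})
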
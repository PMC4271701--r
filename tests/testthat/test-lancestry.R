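test_that("emission equals a brute-force sum over panel haplotypes", {
  set.seed(61)
  P <- matrix(rbinom(5 * 8, 1, 0.5), 5, 8)   # 5 panel haplotypes, 8 sites
  Q <- matrix(rbinom(3 * 8, 1, 0.5), 3, 8)
  eps <- 0.01
  model <- list(eps = eps, breeds = "B", panels_w = list(B = P))
  got <- hapflow:::window_emissions(model, Q)
  for (q in seq_len(nrow(Q))) {
    want <- mean(vapply(seq_len(nrow(P)), function(t) {
      d <- sum(Q[q, ] != P[t, ])
      eps^d * (1 - eps)^(ncol(P) - d)
    }, numeric(1)))
    expect_equal(got[q, 1], want, tolerance = 1e-12)
  }
  # a query identical to a panel haplotype is bounded below by its own term
  model2 <- list(eps = eps, breeds = "B", panels_w = list(B = P))
  e_self <- hapflow:::window_emissions(model2, P[1, , drop = FALSE])[1, 1]
  expect_gte(e_self, (1 - eps)^8 / nrow(P))
})

test_that("identical parental panels give posteriors equal to the prior", {
  base <- random_panel(8, 90, seed = 62, pops = rep("X", 4))
  hap2 <- rbind(base$hap, base$hap)
  man <- sample_manifest(sprintf("S%02d", 1:8),
                         rep(c("A", "B"), each = 4), "parental_panel")
  par <- genotype_panel(hap2, base$map, man)
  grid <- build_windows(par$map, 30)
  model <- train_ancestry_model(par, grid, prior = c(0.7, 0.3))
  adm <- genotype_panel(base$hap[1:2, ], base$map,
                        sample_manifest("Q1", "Cross", "admixed"))
  fld <- infer_local_ancestry(adm, model)
  expect_equal(max(abs(fld$post[, , 1] - 0.7)), 0, tolerance = 1e-9)
})

test_that("training contract errors", {
  par <- random_panel(8, 60, seed = 63, pops = rep(c("A", "B"), 2))
  grid <- build_windows(par$map, 30)
  expect_error(train_ancestry_model(par, build_windows(par$map, 30, 15)),
               "non-overlapping")
  one_pop <- random_panel(4, 60, seed = 63, pops = c("A", "A"))
  expect_error(train_ancestry_model(one_pop, grid), ">= 2 parental")
  par2 <- par
  par2$hap[hap_populations(par2) == "A", 1:30] <- NA
  expect_error(train_ancestry_model(par2, grid), "zero complete")
})

test_that("a haplotype copied verbatim from one breed is decoded to it", {
  sim <- small_sim(64, n_sites = 1500, n_admixed = 5, fst = 0.2)
  grid <- build_windows(sim$parental$map, 30)
  model <- train_ancestry_model(sim$parental, grid)
  hp <- hap_populations(sim$parental)
  donors <- sample(which(hp == "Guernsey"), 20, replace = TRUE)
  adm <- genotype_panel(sim$parental$hap[donors, ], sim$parental$map,
                        sample_manifest(sprintf("C%02d", 1:10), "Cross",
                                        "admixed"))
  fld <- infer_local_ancestry(adm, model)
  frac <- mean(fld$viterbi == match("Guernsey", model$breeds))
  expect_gt(frac, 0.95)
})

test_that("ancestry recovery improves with parental divergence", {
  # donors held out of the training panel, else exact haplotype identity
  # saturates recovery at every F
  acc <- vapply(c(0.02, 0.1, 0.2), function(F) {
    cfg <- sim_config(n_per_breed = c(124, 84, 84), n_sites = 1200,
                      n_admixed = 30, fst = F, seed = 65)
    par <- simulate_parental_panels(cfg)
    train <- split_panel(par$panel, TRUE)
    donor <- split_panel(par$panel, FALSE)
    adm <- simulate_admixed(donor, cfg)
    grid <- build_windows(par$panel$map, 30)
    model <- train_ancestry_model(train, grid)
    fld <- infer_local_ancestry(adm$panel, model)
    tf <- ancestry_from_truth(adm$truth, grid)
    mean(fld$viterbi == tf$viterbi)
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
  expect_gt(acc[3], 0.9)
})

test_that("ancestry summaries: mean, exclusivity minimum and undefined flag", {
  grid <- build_windows(marker_map("1", seq_len(60) * 1000L), 30)
  post <- array(0, c(4, 2, 3))
  post[, 1, 1] <- 1                       # window 1: all exclusive to breed 1
  post[, 2, ] <- rep(c(0.5, 0.5, 0), each = 4)   # window 2: never exclusive
  fld <- ancestry_field(post, c("A", "B", "C"), grid)
  m <- ancestry_summaries(fld, "mean")
  mn <- ancestry_summaries(fld, "minimum", tau = 0.95)
  expect_equal(unlist(m[1, c("A", "B", "C")]), c(A = 1, B = 0, C = 0))
  expect_equal(unlist(mn[1, c("A", "B", "C")]), c(A = 1, B = 0, C = 0))
  expect_false(mn$undefined[1])
  expect_true(mn$undefined[2])
  expect_equal(unlist(mn[2, c("A", "B", "C")]), c(A = 0, B = 0, C = 0))
})

test_that("minimum summary stays below mean for the top breed (simulated)", {
  sim <- small_sim(66, n_sites = 900, n_admixed = 20, fst = 0.2)
  grid <- build_windows(sim$parental$map, 30)
  model <- train_ancestry_model(sim$parental, grid)
  fld <- infer_local_ancestry(sim$admixed, model)
  m <- ancestry_summaries(fld, "mean")
  mn <- ancestry_summaries(fld, "minimum")
  for (w in which(!mn$undefined)) {
    top <- names(which.max(m[w, fld$breeds]))
    expect_lte(mn[w, top], m[w, top] + 0.25)
  }
})

test_that("ancestry TSV round trip and substitution into the migration scan", {
  sim <- small_sim(67, n_sites = 600, n_admixed = 15)
  grid <- build_windows(sim$parental$map, 30)
  fld <- ancestry_from_truth(sim$truth, grid)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_ancestry(fld, tf)
  fld2 <- read_external_ancestry(tf, grid)
  expect_equal(fld2$post, fld$post, tolerance = 1e-12)
  scan <- build_windows(sim$parental$map, 30, 15)
  r1 <- migration_scan(sim$parental, sim$admixed, fld, scan)
  r2 <- migration_scan(sim$parental, sim$admixed, fld2, scan)
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-12)
  # malformed row
  lines <- readLines(tf)
  parts <- strsplit(lines[3], "\t")[[1]]
  parts[4] <- "0.9"
  lines[3] <- paste(parts, collapse = "\t")
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, tf2)
  expect_error(read_external_ancestry(tf2, grid), "line 3")
})

test_that("posteriors sum to one and map mismatch is rejected", {
  sim <- small_sim(68, n_sites = 600, n_admixed = 10)
  grid <- build_windows(sim$parental$map, 30)
  model <- train_ancestry_model(sim$parental, grid)
  fld <- infer_local_ancestry(sim$admixed, model)
  sums <- apply(fld$post, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  rs <- rowSums(fld$p_mean)
  expect_lt(max(abs(rs - 1)), 1e-9)
  other <- random_panel(4, 600, seed = 1, pops = c("X", "X"),
                        roles = "admixed")
  expect_error(infer_local_ancestry(other, model), "different marker maps")
})
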
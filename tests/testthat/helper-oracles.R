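# Small fixture builders and independent brute-force oracles.
# Oracles deliberately use naive enumeration so they stay independent of the
# package's optimized code paths.

toy_panel <- function(hap, pos = NULL, pops = NULL, roles = "parental_panel",
                      chrom = "1") {
  hap <- as.matrix(hap)
  n_samp <- nrow(hap) / 2L
  if (is.null(pos)) pos <- seq_len(ncol(hap)) * 1000L
  if (is.null(pops)) pops <- rep("P1", n_samp)
  man <- sample_manifest(sprintf("S%02d", seq_len(n_samp)), pops, roles)
  genotype_panel(hap, marker_map(chrom, pos), man)
}

random_panel <- function(n_hap, n_site, seed, pops = NULL, pos = NULL,
                         roles = "parental_panel") {
  set.seed(seed)
  hap <- matrix(rbinom(n_hap * n_site, 1L, runif(n_site, 0.1, 0.9)),
                nrow = n_hap, byrow = TRUE)
  toy_panel(hap, pos = pos, pops = pops, roles = roles)
}

# per-site allele frequency tally by population, naive loops
brute_maf_keep <- function(panel, threshold, rule = "any") {
  hp <- hap_populations(panel)
  pops <- unique(panel$manifest$population)
  keep <- logical(n_sites(panel))
  for (j in seq_len(n_sites(panel))) {
    pass <- logical(length(pops))
    for (i in seq_along(pops)) {
      a <- panel$hap[hp == pops[i], j]
      a <- a[!is.na(a)]
      f <- if (length(a)) mean(a) else 0
      pass[i] <- min(f, 1 - f) > threshold
    }
    keep[j] <- if (rule == "any") any(pass) else all(pass)
  }
  keep
}

# naive string counting for one window and population
brute_spectrum <- function(panel, i0, i1, pop) {
  hp <- hap_populations(panel)
  rows <- which(hp == pop)
  strs <- character(0)
  for (r in rows) {
    a <- panel$hap[r, i0:i1]
    if (any(is.na(a))) next
    strs <- c(strs, paste(a, collapse = ""))
  }
  if (!length(strs)) return(NULL)
  tab <- table(strs)
  data.frame(haplotype = names(tab), count = as.integer(tab),
             frequency = as.integer(tab) / length(strs),
             stringsAsFactors = FALSE)
}

# all-pairs EHH: fraction of carrier pairs identical (and complete) over
# the span from the core to site j, denominator C(n_c, 2)
brute_ehh_at <- function(hap, core, allele, j) {
  carriers <- which(!is.na(hap[, core]) & hap[, core] == allele)
  n_c <- length(carriers)
  span <- min(core, j):max(core, j)
  same <- 0L
  for (a in seq_len(n_c - 1L)) for (b in (a + 1L):n_c) {
    x <- hap[carriers[a], span]; y <- hap[carriers[b], span]
    if (!anyNA(x) && !anyNA(y) && all(x == y)) same <- same + 1L
  }
  same / choose(n_c, 2)
}

# brute-force region caller: enumerate every run of `min_hits` consecutive
# significant SNPs spanning <= span bp, then merge runs sharing SNPs
brute_regions <- function(chrom, pos, score, threshold = 3, min_hits = 3L,
                          span = 1e6) {
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch & is.finite(score) & abs(score) > threshold)
    if (length(idx) < min_hits) next
    p <- pos[idx]
    windows <- list()
    for (j in seq_len(length(idx) - min_hits + 1L)) {
      if (p[j + min_hits - 1L] - p[j] <= span)
        windows[[length(windows) + 1L]] <- j:(j + min_hits - 1L)
    }
    if (!length(windows)) next
    members <- sort(unique(unlist(windows)))
    grp <- cumsum(c(1L, diff(members) > 1L))
    # runs merge only via shared SNPs: consecutive member indices
    for (g in unique(grp)) {
      mm <- members[grp == g]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = p[mm[1]], end_bp = p[mm[length(mm)]],
        n_significant = length(mm), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(chrom = character(),
                                      start_bp = integer(),
                                      end_bp = integer(),
                                      n_significant = integer()))
  do.call(rbind, out)
}

# split a parental panel into training and held-out donor halves per breed
# (donor haplotypes absent from training make ancestry recovery depend on
# divergence rather than exact identity)
split_panel <- function(par, first) {
  man <- par$manifest
  keep <- sort(unlist(lapply(unique(man$population), function(b) {
    idx <- which(man$population == b)
    if (first) idx[seq_len(length(idx) %/% 2)] else
      idx[-seq_len(length(idx) %/% 2)]
  })))
  rows <- rep(seq_len(nrow(man)) %in% keep, each = 2)
  m2 <- man[keep, ]
  rownames(m2) <- NULL
  class(m2) <- class(man)
  genotype_panel(par$hap[rows, ], par$map, m2)
}

# default small simulated world shared by several tests
small_sim <- function(seed, n_sites = 1000L, n_admixed = 50L, fst = 0.1) {
  cfg <- sim_config(n_sites = n_sites, n_admixed = n_admixed, fst = fst,
                    seed = seed)
  par <- simulate_parental_panels(cfg)
  adm <- simulate_admixed(par$panel, cfg)
  list(cfg = cfg, parental = par$panel, par_truth = par$truth,
       admixed = adm$panel, truth = adm$truth)
}
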
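#' Expected frequency of a parental haplotype in the admixed cohort
#'
#' Under neutral migration, the frequency of a parental breed's most
#' frequent window haplotype expected in the admixed cohort is the product
#' of the local ancestry proportion of that breed at the window, p(B), and
#' the haplotype's frequency within the breed, freq(B).
#'
#' @param p_B local ancestry proportion of the breed at the window, in
#'   `[0, 1]`.
#' @param freq_B frequency of the haplotype within the parental breed, in
#'   `[0, 1]`.
#' @return `p_B * freq_B`.
#' @export
expected_frequency <- function(p_B, freq_B) {
  if (any(p_B < 0 | p_B > 1, na.rm = TRUE) ||
      any(freq_B < 0 | freq_B > 1, na.rm = TRUE))
    stop("p_B and freq_B must lie in [0, 1]")
  p_B * freq_B
}

#' Haplotype-frequency migration difference
#'
#' The signed change in frequency of a parental haplotype between what
#' local ancestry predicts in the admixed cohort and what is observed
#' there: `observed - expected`. Positive values mean the haplotype is more
#' common in the admixed cohort than ancestry alone predicts (a candidate
#' for positive selection after admixture), negative values the opposite.
#'
#' @param expected expected frequency in `[0, 1]`.
#' @param observed observed frequency in `[0, 1]`.
#' @return Signed frequency difference.
#' @export
migration_difference <- function(expected, observed) {
  if (any(expected < 0 | expected > 1, na.rm = TRUE) ||
      any(observed < 0 | observed > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  observed - expected
}

#' Standardize migration differences to z-scores
#'
#' `z = (D - mean(D)) / sd(D)` with the sample (n-1) standard deviation,
#' taken over all scored windows in the scope (by default, per breed across
#' the genome).
#'
#' @param diffs numeric vector of per-window frequency differences.
#' @return z-score vector with mean 0 and sd 1.
#' @export
standardize_scores <- function(diffs) {
  diffs <- diffs[is.finite(diffs)]
  if (length(diffs) < 2L) stop("need >= 2 finite differences to standardize")
  s <- stats::sd(diffs)
  if (s == 0) stop("zero variance: differences are all equal")
  (diffs - mean(diffs)) / s
}

# local ancestry p(B) at each scan window: SNP-overlap-weighted mean of the
# training-window mean posteriors
map_ancestry_to_grid <- function(field, scan_grid) {
  tg <- field$grid
  K <- length(field$breeds)
  out <- matrix(NA_real_, nrow(scan_grid), K,
                dimnames = list(NULL, field$breeds))
  for (i in seq_len(nrow(scan_grid))) {
    same <- tg$chrom == scan_grid$chrom[i]
    ov <- pmin(tg$end_idx, scan_grid$end_idx[i]) -
      pmax(tg$start_idx, scan_grid$start_idx[i]) + 1L
    ov[!same | ov < 0L] <- 0L
    if (sum(ov) == 0L) next
    out[i, ] <- colSums(field$p_mean * ov) / sum(ov)
  }
  out
}

#' Genome-wide haplotype-migration scan
#'
#' For every parental breed and scan window, takes the breed's most
#' frequent window haplotype, looks it up in the admixed cohort, and — when
#' it is present there (absent haplotypes are not scored) — records the
#' parental frequency freq(B), the local ancestry p(B), the expected
#' frequency p(B) x freq(B), the observed admixed frequency, the signed
#' difference and its per-breed genome-wide z-score.
#'
#' Two sign conventions are available: the default `observed - expected`
#' (positive = more frequent in the admixed cohort than expected), and a
#' `literal` variant `p(B) * observed - freq(B)`.
#'
#' @param parental parental [genotype_panel()].
#' @param admixed admixed [genotype_panel()] on the same map.
#' @param ancestry an [ancestry_field()] on the training grid.
#' @param grid scan [build_windows()] grid (default style: size 30,
#'   step 15).
#' @param min_parental_freq minimum parental modal-haplotype frequency for
#'   a window to be scored (default 0).
#' @param convention `"observed-minus-expected"` (default) or `"literal"`.
#' @return `data.table` of migration records, one per (breed, scored
#'   window): `breed`, `window_id`, `chrom`, `start_bp`, `end_bp`,
#'   `haplotype`, `freq_parental`, `p_B`, `expected`, `observed`,
#'   `freq_change`, `z`, `display` (frequency > 0.3 reporting flag).
#' @export
migration_scan <- function(parental, admixed, ancestry, grid,
                           min_parental_freq = 0,
                           convention = c("observed-minus-expected",
                                          "literal")) {
  convention <- match.arg(convention)
  if (n_haplotypes(admixed) == 0L) stop("admixed cohort is empty")
  if (!identical(parental$map$pos, admixed$map$pos))
    stop("parental and admixed panels use different marker maps")
  breeds <- ancestry$breeds
  hp <- hap_populations(parental)
  pB <- map_ancestry_to_grid(ancestry, grid)
  recs <- vector("list", nrow(grid) * length(breeds))
  r <- 0L
  for (w in seq_len(nrow(grid))) {
    i0 <- grid$start_idx[w]; i1 <- grid$end_idx[w]
    s_adm <- window_strings(admixed, i0, i1)
    s_adm <- s_adm[!is.na(s_adm)]
    if (!length(s_adm)) next
    for (k in seq_along(breeds)) {
      s_par <- window_strings(parental, i0, i1, rows = hp == breeds[k])
      s_par <- s_par[!is.na(s_par)]
      if (!length(s_par)) next
      tab <- table(s_par)
      modal <- sort(names(tab)[tab == max(tab)])[1L]
      freq_B <- as.numeric(tab[modal]) / length(s_par)
      if (freq_B < min_parental_freq) next
      observed <- mean(s_adm == modal)
      if (observed == 0) next    # inclusion rule: must be found in admixed
      p_Bk <- pB[w, k]
      if (!is.finite(p_Bk)) next
      expected <- expected_frequency(p_Bk, freq_B)
      fc <- if (convention == "observed-minus-expected")
        migration_difference(expected, observed) else
          p_Bk * observed - freq_B
      r <- r + 1L
      recs[[r]] <- data.table::data.table(
        breed = breeds[k], window_id = grid$window_id[w],
        chrom = grid$chrom[w], start_bp = grid$start_bp[w],
        end_bp = grid$end_bp[w], haplotype = modal,
        freq_parental = freq_B, p_B = p_Bk, expected = expected,
        observed = observed, freq_change = fc)
    }
  }
  out <- data.table::rbindlist(recs[seq_len(r)])
  if (!nrow(out)) stop("no scorable windows (no shared modal haplotypes)")
  out[, z := standardize_scores(freq_change), by = "breed"]
  out[, display := freq_parental > 0.3 | observed > 0.3]
  data.table::setorderv(out, c("breed", "window_id"))
  out[]
}

#' Filter migration records to outliers
#'
#' Keeps records with `|z| >= threshold`, sorted by decreasing `|z|`.
#' @param records output of [migration_scan()].
#' @param threshold absolute z threshold (default 3).
#' @return Filtered, sorted `data.table`.
#' @export
call_migration_outliers <- function(records, threshold = 3) {
  out <- records[abs(records$z) >= threshold, ]
  out[order(-abs(out$z)), ]
}

#' Merge outlier windows into regions
#'
#' Adjacent scan windows share SNPs, so a single signal spans several
#' overlapping windows; this merges, per breed and chromosome, outlier
#' windows whose bp spans overlap into maximal regions and reports the
#' union span with the peak window's statistics.
#'
#' @param outliers output of [call_migration_outliers()].
#' @return `data.table`: `breed`, `chrom`, `start_bp`, `end_bp`, `n_windows`,
#'   `peak_z`, and the peak window's `freq_parental`, `p_B`, `expected`,
#'   `observed`, `freq_change`.
#' @export
merge_outlier_regions <- function(outliers) {
  if (!nrow(outliers))
    return(data.table::data.table(
      breed = character(), chrom = character(), start_bp = integer(),
      end_bp = integer(), n_windows = integer(), peak_z = numeric(),
      freq_parental = numeric(), p_B = numeric(), expected = numeric(),
      observed = numeric(), freq_change = numeric()))
  d <- outliers[order(outliers$breed, outliers$chrom, outliers$start_bp), ]
  out <- list()
  for (key in unique(paste(d$breed, d$chrom))) {
    sub <- d[paste(d$breed, d$chrom) == key, ]
    grp <- cumsum(c(TRUE, sub$start_bp[-1L] > cummax(sub$end_bp)[-nrow(sub)]))
    for (g in unique(grp)) {
      s <- sub[grp == g, ]
      peak <- which.max(abs(s$z))
      out[[length(out) + 1L]] <- data.table::data.table(
        breed = s$breed[1], chrom = s$chrom[1],
        start_bp = min(s$start_bp), end_bp = max(s$end_bp),
        n_windows = nrow(s), peak_z = s$z[peak],
        freq_parental = s$freq_parental[peak], p_B = s$p_B[peak],
        expected = s$expected[peak], observed = s$observed[peak],
        freq_change = s$freq_change[peak])
    }
  }
  data.table::rbindlist(out)
}
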
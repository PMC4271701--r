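#' Extended haplotype homozygosity around a core allele
#'
#' EHH at a flanking site x is the probability that two randomly chosen
#' carriers of the core allele are identical over the whole interval from
#' the core to x: sum over distinct extended haplotypes h of C(n_h, 2),
#' divided by C(n_c, 2) for the n_c carriers. EHH at the core itself is 1.
#' The curve is walked outward in both directions and truncated when it
#' falls below `floor_ehh`, when the extension exceeds `max_extension`, at
#' an inter-SNP gap larger than `max_gap`, or at the chromosome edge (the
#' edge case is flagged so integrals can be excluded).
#'
#' Carriers with a missing call at a flanking site stop contributing pairs
#' from that site outward; the denominator C(n_c, 2) is fixed at the core.
#'
#' @param panel a [genotype_panel()].
#' @param core 1-based site index of the core SNP.
#' @param allele core allele, 0 or 1.
#' @param max_extension maximum extension per side in bp (default 1 Mb).
#' @param floor_ehh truncation floor (default 0.05); the first point below
#'   the floor is retained so integrals cover the crossing.
#' @param max_gap inter-SNP gap (bp) beyond which the curve is truncated
#'   (default 200 kb).
#' @return A list with elements `curve` (data.frame `site`, `pos`, `ehh`,
#'   `direction` in -1/0/1, core included once with direction 0), `n_core`
#'   carriers, and flags `edge` / `gap_truncated`.
#' @export
ehh <- function(panel, core, allele, max_extension = 1e6,
                floor_ehh = 0.05, max_gap = 2e5) {
  hapm <- panel$hap
  pos <- panel$map$pos
  chrom <- panel$map$chrom
  carriers <- which(!is.na(hapm[, core]) & hapm[, core] == allele)
  n_c <- length(carriers)
  if (n_c < 2L)
    stop("core allele has fewer than 2 carriers (monomorphic core?)")
  denom <- choose(n_c, 2)
  walk <- function(dir) {
    groups <- rep(1L, n_c)
    alive <- rep(TRUE, n_c)
    out_site <- integer(0); out_ehh <- numeric(0)
    edge <- FALSE; gap_tr <- FALSE
    j <- core
    last_ehh <- 1
    repeat {
      jn <- j + dir
      if (jn < 1L || jn > ncol(hapm) || chrom[jn] != chrom[core]) {
        edge <- last_ehh >= floor_ehh &&
          abs(pos[j] - pos[core]) < max_extension
        break
      }
      if (abs(pos[jn] - pos[core]) > max_extension) break
      if (abs(pos[jn] - pos[j]) > max_gap) { gap_tr <- TRUE; break }
      a <- hapm[carriers, jn]
      alive <- alive & !is.na(a)
      key <- paste(groups[alive], a[alive])
      groups[alive] <- match(key, unique(key))
      cnt <- tabulate(groups[alive])
      e <- sum(choose(cnt, 2)) / denom
      out_site <- c(out_site, jn); out_ehh <- c(out_ehh, e)
      last_ehh <- e
      j <- jn
      if (e < floor_ehh) break
      if (e == 0) break
    }
    list(site = out_site, ehh = out_ehh, edge = edge, gap = gap_tr)
  }
  L <- walk(-1L); R <- walk(1L)
  curve <- data.frame(
    site = c(rev(L$site), core, R$site),
    pos = pos[c(rev(L$site), core, R$site)],
    ehh = c(rev(L$ehh), 1, R$ehh),
    direction = c(rep(-1L, length(L$site)), 0L, rep(1L, length(R$site))))
  list(curve = curve, n_core = n_c, edge = L$edge || R$edge,
       gap_truncated = L$gap || R$gap)
}

# trapezoidal integral of an EHH curve over bp
integrate_curve <- function(curve) {
  x <- curve$pos; y <- curve$ehh
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

# site EHH over all haplotypes (allele-agnostic), normalized so the core
# value is 1: homozygosity of extended haplotypes (grouped by core allele
# at the core) relative to core-allele homozygosity.
ehhs_curve <- function(panel, core, max_extension = 1e6, floor_ehh = 0.05,
                       max_gap = 2e5) {
  hapm <- panel$hap
  pos <- panel$map$pos
  chrom <- panel$map$chrom
  carriers <- which(!is.na(hapm[, core]))
  n <- length(carriers)
  if (n < 2L) stop("fewer than 2 genotyped haplotypes at core")
  denom <- choose(n, 2)
  g0 <- match(hapm[carriers, core], unique(hapm[carriers, core]))
  h0 <- sum(choose(tabulate(g0), 2)) / denom
  if (h0 == 0) stop("core homozygosity is zero")
  walk <- function(dir) {
    groups <- g0
    alive <- rep(TRUE, n)
    out_site <- integer(0); out_ehh <- numeric(0)
    edge <- FALSE; gap_tr <- FALSE
    j <- core; last_e <- 1
    repeat {
      jn <- j + dir
      if (jn < 1L || jn > ncol(hapm) || chrom[jn] != chrom[core]) {
        edge <- last_e >= floor_ehh &&
          abs(pos[j] - pos[core]) < max_extension
        break
      }
      if (abs(pos[jn] - pos[core]) > max_extension) break
      if (abs(pos[jn] - pos[j]) > max_gap) { gap_tr <- TRUE; break }
      a <- hapm[carriers, jn]
      alive <- alive & !is.na(a)
      key <- paste(groups[alive], a[alive])
      groups[alive] <- match(key, unique(key))
      cnt <- tabulate(groups[alive])
      e <- (sum(choose(cnt, 2)) / denom) / h0
      out_site <- c(out_site, jn); out_ehh <- c(out_ehh, e)
      last_e <- e
      j <- jn
      if (e < floor_ehh || e == 0) break
    }
    list(site = out_site, ehh = out_ehh, edge = edge, gap = gap_tr)
  }
  L <- walk(-1L); R <- walk(1L)
  curve <- data.frame(
    site = c(rev(L$site), core, R$site),
    pos = pos[c(rev(L$site), core, R$site)],
    ehh = c(rev(L$ehh), 1, R$ehh))
  list(curve = curve, edge = L$edge || R$edge,
       gap_truncated = L$gap || R$gap)
}

merge_small_bins <- function(bin, min_bin = 10L) {
  # bin: integer bin index per SNP; merge bins with < min_bin members into
  # their nearest non-empty neighbor (next bin, or previous for the last)
  repeat {
    tab <- table(bin)
    small <- names(tab)[tab < min_bin]
    if (!length(small)) break
    b <- as.integer(small[1])
    lev <- sort(unique(bin))
    tgt <- if (any(lev > b)) min(lev[lev > b]) else max(lev[lev < b])
    if (length(tgt) == 0L || !is.finite(tgt)) break
    bin[bin == b] <- tgt
  }
  bin
}

#' Integrated-EHH selection scan (iHS)
#'
#' For each SNP, integrates the EHH curves of the ancestral and derived
#' core alleles over bp (trapezoid rule) to get iHH_A and iHH_D, forms the
#' raw score ln(iHH_A / iHH_D), and standardizes it to mean 0, sd 1 within
#' derived-allele-frequency bins. Extreme iHS values indicate haplotypes
#' that are unusually long for their frequency, the hallmark of a recent
#' partial sweep.
#'
#' Ancestral-allele assignment drives the sign of iHS and is a documented
#' choice: by default the REF (code 0) allele is taken as ancestral;
#' `ancestral = "major"` uses the panel's major allele; or supply a per-SNP
#' 0/1 vector.
#'
#' SNPs with minor allele frequency below `maf_floor`, with an EHH curve
#' truncated at a chromosome edge, or with a non-finite raw score are
#' excluded (flagged in the output, `ihs = NA`).
#'
#' @param panel a [genotype_panel()].
#' @param ancestral `"ref"`, `"major"`, or an integer vector of ancestral
#'   alleles (0/1) per SNP.
#' @param maf_floor minimum minor allele frequency (default 0.05).
#' @param bin_width derived-allele-frequency bin width (default 0.05).
#' @param min_bin minimum SNPs per bin before merging with a neighbor
#'   (default 10).
#' @param max_extension,floor_ehh,max_gap passed to [ehh()].
#' @return `data.table`: `chrom`, `pos`, `id`, `daf`, `ihh_a`, `ihh_d`,
#'   `raw`, `ihs`, `flag` (`"ok"`, `"maf"`, `"edge"`, `"nonfinite"`).
#' @export
ihs <- function(panel, ancestral = c("ref", "major"), maf_floor = 0.05,
                bin_width = 0.05, min_bin = 10L, max_extension = 1e6,
                floor_ehh = 0.05, max_gap = 2e5) {
  M <- n_sites(panel)
  if (is.character(ancestral)) {
    ancestral <- match.arg(ancestral)
    anc <- if (ancestral == "ref") rep(0L, M) else {
      f <- colMeans(panel$hap, na.rm = TRUE)
      as.integer(f > 0.5)
    }
  } else {
    anc <- as.integer(rep_len(ancestral, M))
  }
  f_alt <- colMeans(panel$hap, na.rm = TRUE)
  daf <- ifelse(anc == 0L, f_alt, 1 - f_alt)
  maf <- pmin(f_alt, 1 - f_alt)
  raw <- rep(NA_real_, M)
  ihh_a <- rep(NA_real_, M); ihh_d <- rep(NA_real_, M)
  flag <- rep("ok", M)
  for (j in seq_len(M)) {
    if (is.na(maf[j]) || maf[j] < maf_floor) { flag[j] <- "maf"; next }
    ca <- ehh(panel, j, anc[j], max_extension, floor_ehh, max_gap)
    cd <- ehh(panel, j, 1L - anc[j], max_extension, floor_ehh, max_gap)
    if (ca$edge || cd$edge) { flag[j] <- "edge"; next }
    ihh_a[j] <- integrate_curve(ca$curve)
    ihh_d[j] <- integrate_curve(cd$curve)
    r <- log(ihh_a[j] / ihh_d[j])
    if (!is.finite(r)) { flag[j] <- "nonfinite"; next }
    raw[j] <- r
  }
  std <- rep(NA_real_, M)
  ok <- which(is.finite(raw))
  if (length(ok)) {
    bin <- pmin(floor(daf[ok] / bin_width), floor(1 / bin_width) - 1L)
    bin <- merge_small_bins(bin, min_bin)
    for (b in unique(bin)) {
      idx <- ok[bin == b]
      m <- mean(raw[idx]); s <- stats::sd(raw[idx])
      std[idx] <- if (length(idx) >= 2L && s > 0) (raw[idx] - m) / s else NA_real_
    }
  }
  data.table::data.table(chrom = panel$map$chrom, pos = panel$map$pos,
                         id = panel$map$id, daf = daf, ihh_a = ihh_a,
                         ihh_d = ihh_d, raw = raw, ihs = std, flag = flag)
}

#' Cross-population EHH scan (Rsb)
#'
#' For each SNP shared by the two panels, integrates the allele-agnostic
#' site EHH (EHHS, normalized to 1 at the core) over bp in each population
#' to get iES_1 and iES_2, forms ln(iES_1 / iES_2), and standardizes
#' genome-wide by median-centering and scaling by the standard deviation.
#' Positive standardized values indicate longer haplotype homozygosity in
#' population 1 than 2 at that site.
#'
#' @param panel_1,panel_2 [genotype_panel()] objects on identical maps.
#' @param maf_floor minimum pooled minor allele frequency (default 0.05).
#' @param max_extension,floor_ehh,max_gap passed to the EHHS walk.
#' @return `data.table`: `chrom`, `pos`, `id`, `ies_1`, `ies_2`, `raw`,
#'   `rsb`, `flag`.
#' @export
rsb <- function(panel_1, panel_2, maf_floor = 0.05, max_extension = 1e6,
                floor_ehh = 0.05, max_gap = 2e5) {
  if (!identical(panel_1$map$pos, panel_2$map$pos) ||
      !identical(panel_1$map$chrom, panel_2$map$chrom))
    stop("the two panels must share the same sites")
  M <- n_sites(panel_1)
  f <- (colSums(panel_1$hap, na.rm = TRUE) + colSums(panel_2$hap, na.rm = TRUE)) /
    (colSums(!is.na(panel_1$hap)) + colSums(!is.na(panel_2$hap)))
  maf <- pmin(f, 1 - f)
  raw <- rep(NA_real_, M)
  ies1 <- rep(NA_real_, M); ies2 <- rep(NA_real_, M)
  flag <- rep("ok", M)
  for (j in seq_len(M)) {
    if (is.na(maf[j]) || maf[j] < maf_floor) { flag[j] <- "maf"; next }
    c1 <- try(ehhs_curve(panel_1, j, max_extension, floor_ehh, max_gap),
              silent = TRUE)
    c2 <- try(ehhs_curve(panel_2, j, max_extension, floor_ehh, max_gap),
              silent = TRUE)
    if (inherits(c1, "try-error") || inherits(c2, "try-error")) {
      flag[j] <- "degenerate"; next
    }
    if (c1$edge || c2$edge) { flag[j] <- "edge"; next }
    ies1[j] <- integrate_curve(c1$curve)
    ies2[j] <- integrate_curve(c2$curve)
    r <- log(ies1[j] / ies2[j])
    if (!is.finite(r)) { flag[j] <- "nonfinite"; next }
    raw[j] <- r
  }
  std <- rep(NA_real_, M)
  ok <- which(is.finite(raw))
  if (length(ok) >= 2L) {
    s <- stats::sd(raw[ok])
    if (s > 0) std[ok] <- (raw[ok] - stats::median(raw[ok])) / s
  }
  data.table::data.table(chrom = panel_1$map$chrom, pos = panel_1$map$pos,
                         id = panel_1$map$id, ies_1 = ies1, ies_2 = ies2,
                         raw = raw, rsb = std, flag = flag)
}

#' Single-marker F_ST between two populations
#'
#' Hudson-style two-population estimator from haplotype allele frequencies
#' and counts:
#'
#'   num = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)
#'   den = p1(1-p2) + p2(1-p1)
#'
#' Per-SNP values are num/den (negative estimates are reported as
#' computed); sites monomorphic in the pooled sample have undefined F_ST
#' and are excluded from the means. Three genome-wide summaries are
#' returned: the mean of per-SNP values (raw and truncated at 0) and the
#' ratio-of-averages `sum(num)/sum(den)`, which is the recommended
#' combination of Hudson per-SNP components. A Nei-style
#' `(H_T - H_S)/H_T` per-SNP variant is available via `estimator`.
#'
#' @param panel a [genotype_panel()] containing both populations.
#' @param pop_A,pop_B population labels.
#' @param estimator `"hudson"` (default) or `"nei"`.
#' @return A list: `per_snp` (`data.table` with `chrom`, `pos`, `id`,
#'   `p_A`, `p_B`, `fst`), `mean_raw`, `mean_truncated`, `overall`
#'   (ratio-of-averages; Hudson only), `n_excluded`.
#' @export
fst <- function(panel, pop_A, pop_B, estimator = c("hudson", "nei")) {
  estimator <- match.arg(estimator)
  hp <- hap_populations(panel)
  if (!any(hp == pop_A) || !any(hp == pop_B))
    stop("both populations must be present in the panel")
  hA <- panel$hap[hp == pop_A, , drop = FALSE]
  hB <- panel$hap[hp == pop_B, , drop = FALSE]
  nA <- colSums(!is.na(hA)); nB <- colSums(!is.na(hB))
  pA <- colMeans(hA, na.rm = TRUE); pB <- colMeans(hB, na.rm = TRUE)
  if (estimator == "hudson") {
    num <- (pA - pB)^2 - pA * (1 - pA) / pmax(nA - 1L, 1L) -
      pB * (1 - pB) / pmax(nB - 1L, 1L)
    den <- pA * (1 - pB) + pB * (1 - pA)
  } else {
    pbar <- (nA * pA + nB * pB) / (nA + nB)
    ht <- 2 * pbar * (1 - pbar)
    hs <- (nA * 2 * pA * (1 - pA) + nB * 2 * pB * (1 - pB)) / (nA + nB)
    num <- ht - hs
    den <- ht
  }
  defined <- den > 0 & is.finite(den)
  f <- ifelse(defined, num / den, NA_real_)
  list(per_snp = data.table::data.table(
    chrom = panel$map$chrom, pos = panel$map$pos, id = panel$map$id,
    p_A = pA, p_B = pB, fst = f),
    mean_raw = mean(f[defined]),
    mean_truncated = mean(pmax(f[defined], 0)),
    overall = if (estimator == "hudson")
      sum(num[defined]) / sum(den[defined]) else NA_real_,
    n_excluded = sum(!defined))
}

#' Call candidate sweep regions from an iHS track
#'
#' A region is a maximal cluster of significant SNPs (|score| >
#' `score_threshold`) in which at least `min_hits` consecutive significant
#' SNPs fall within `span` bp of each other — the "at least 3 continuous
#' significant SNPs per 1 Mb" density rule. Concretely: per chromosome,
#' every run of `min_hits` consecutive significant SNPs spanning <= `span`
#' bp marks its members, and overlapping marked runs are merged. Region
#' bounds are the bp of the first and last significant SNP of the cluster.
#'
#' @param scores `data.frame` with `chrom`, `pos` and a score column.
#' @param score_col name of the score column (default `"ihs"`).
#' @param score_threshold significance threshold on |score| (default 3).
#' @param min_hits minimum run length (default 3).
#' @param span bp span containing the run (default 1 Mb).
#' @return `data.table`: `chrom`, `start_bp`, `end_bp`, `n_significant`,
#'   `max_score` (max |score|), `peak_pos`.
#' @export
candidate_regions <- function(scores, score_col = "ihs",
                              score_threshold = 3, min_hits = 3L,
                              span = 1e6) {
  s <- scores[[score_col]]
  sig <- which(is.finite(s) & abs(s) > score_threshold)
  empty <- data.table::data.table(chrom = character(), start_bp = integer(),
                                  end_bp = integer(),
                                  n_significant = integer(),
                                  max_score = numeric(), peak_pos = integer())
  if (!length(sig)) return(empty)
  out <- list()
  for (ch in unique(scores$chrom[sig])) {
    idx <- sig[scores$chrom[sig] == ch]
    p <- scores$pos[idx]
    m <- length(idx)
    if (m < min_hits) next
    marked <- logical(m)
    for (j in seq_len(m - min_hits + 1L)) {
      if (p[j + min_hits - 1L] - p[j] <= span)
        marked[j:(j + min_hits - 1L)] <- TRUE
    }
    if (!any(marked)) next
    runs <- rle(marked)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      members <- idx[starts[r]:ends[r]]
      peak <- members[which.max(abs(s[members]))]
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = ch, start_bp = scores$pos[members[1]],
        end_bp = scores$pos[members[length(members)]],
        n_significant = length(members),
        max_score = max(abs(s[members])),
        peak_pos = scores$pos[peak])
    }
  }
  if (!length(out)) return(empty)
  data.table::rbindlist(out)
}
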
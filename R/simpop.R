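#' Simulation configuration
#'
#' Describes the synthetic study design: K diverged parental breeds, an
#' admixed cohort with known ancestry tracts, and (optionally, via
#' [inject_haplotype_selection()]) planted haplotype-frequency shifts.
#' Defaults emulate the study design the package targets: three dairy
#' breeds with moderate differentiation (Balding-Nichols F = 0.1), parental
#' panel sizes 62/21/21, a 100-sample admixed cohort with genome-wide
#' ancestry proportions (0.53, 0.32, 0.15), about five generations since
#' admixture, and 50K-chip-like density (about 1 SNP per 50 kb).
#'
#' @param breeds parental breed labels.
#' @param n_per_breed diploid samples per breed.
#' @param n_admixed diploid samples in the admixed cohort.
#' @param n_sites number of SNPs.
#' @param chrom chromosome label (single chromosome by default).
#' @param chrom_length chromosome length in bp.
#' @param fst Balding-Nichols drift parameter F per breed, in (0, 1);
#'   recycled.
#' @param admix_prop ancestry proportions over breeds (simplex).
#' @param generations generations since admixture (>= 1).
#' @param recomb_rate recombination rate in Morgans/bp (default 1e-8,
#'   i.e. a uniform 1 cM/Mb map).
#' @param admixed_label population label of the admixed cohort.
#' @param seed integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(breeds = c("Holstein", "Guernsey", "NorwegianRed"),
                       n_per_breed = c(62L, 21L, 21L),
                       n_admixed = 100L,
                       n_sites = 2000L,
                       chrom = "1",
                       chrom_length = 1e8,
                       fst = 0.1,
                       admix_prop = c(0.53, 0.32, 0.15),
                       generations = 5L,
                       recomb_rate = 1e-8,
                       admixed_label = "Crossbred",
                       seed = 1L) {
  K <- length(breeds)
  n_per_breed <- rep_len(as.integer(n_per_breed), K)
  fst <- rep_len(fst, K)
  if (any(fst <= 0 | fst >= 1)) stop("fst must lie in (0, 1)")
  if (length(admix_prop) != K) stop("admix_prop must have one entry per breed")
  if (abs(sum(admix_prop) - 1) > 1e-8) stop("admix_prop must sum to 1")
  if (generations < 1L) stop("generations must be >= 1")
  cfg <- list(breeds = breeds, n_per_breed = n_per_breed,
              n_admixed = as.integer(n_admixed),
              n_sites = as.integer(n_sites), chrom = as.character(chrom),
              chrom_length = as.numeric(chrom_length), fst = fst,
              admix_prop = admix_prop, generations = as.integer(generations),
              recomb_rate = recomb_rate, admixed_label = admixed_label,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate parental breed panels under the Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn uniform on (0.05, 0.95); each
#' breed's frequencies are Beta(p(1-F)/F, (1-p)(1-F)/F) around the
#' ancestral value; haplotypes are then sampled site-independently within
#' breeds. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return `list(panel =, truth =)` where `truth` holds the marker
#'   positions, ancestral and per-breed allele frequencies.
#' @export
simulate_parental_panels <- function(config) {
  set.seed(config$seed)
  K <- length(config$breeds)
  pos <- sort(sample.int(config$chrom_length, config$n_sites))
  p_anc <- stats::runif(config$n_sites, 0.05, 0.95)
  p_breed <- matrix(NA_real_, config$n_sites, K,
                    dimnames = list(NULL, config$breeds))
  for (k in seq_len(K)) {
    F <- config$fst[k]
    p_breed[, k] <- stats::rbeta(config$n_sites,
                                 p_anc * (1 - F) / F,
                                 (1 - p_anc) * (1 - F) / F)
  }
  hap <- do.call(rbind, lapply(seq_len(K), function(k) {
    nh <- 2L * config$n_per_breed[k]
    matrix(stats::rbinom(nh * config$n_sites, 1L,
                         rep(p_breed[, k], each = nh)),
           nrow = nh)
  }))
  manifest <- sample_manifest(
    sample_id = unlist(lapply(seq_len(K), function(k)
      sprintf("%s_%03d", config$breeds[k], seq_len(config$n_per_breed[k])))),
    population = rep(config$breeds, config$n_per_breed),
    role = "parental_panel")
  map <- marker_map(config$chrom, pos)
  panel <- genotype_panel(hap, map, manifest)
  truth <- structure(list(pos = pos, p_anc = p_anc, p_breed = p_breed,
                          config = config),
                     class = "sim_truth")
  list(panel = panel, truth = truth)
}

#' Simulate an admixed cohort from parental panels
#'
#' Each admixed haplotype is built by a Markov ancestry process along the
#' map: the initial breed is drawn from the admixture proportions; between
#' adjacent sites separated by d Morgans a switch occurs with probability
#' 1 - exp(-g d); at every switch a new breed is drawn from the proportions
#' and a new donor haplotype is chosen uniformly from that breed's panel
#' (one donor per tract, so parental window haplotypes migrate intact).
#' Alleles are copied from the donor. Tracts tile each chromosome exactly.
#'
#' @param parental panel from [simulate_parental_panels()] (any panel whose
#'   manifest populations cover the breeds in `config`).
#' @param config a [sim_config()].
#' @param seed RNG seed for this step (default `config$seed + 1`).
#' @return `list(panel =, truth =)`; `truth$tracts` is a `data.table` with
#'   one row per tract: `hap`, `chrom`, `start_site`, `end_site`,
#'   `start_bp`, `end_bp`, `breed`, `donor`.
#' @export
simulate_admixed <- function(parental, config, seed = config$seed + 1L) {
  missing_breed <- setdiff(config$breeds, parental$manifest$population)
  if (length(missing_breed))
    stop("parental panel lacks breed(s): ",
         paste(missing_breed, collapse = ", "))
  set.seed(seed)
  K <- length(config$breeds)
  pos <- parental$map$pos
  M <- length(pos)
  hp <- hap_populations(parental)
  breed_rows <- lapply(config$breeds, function(b) which(hp == b))
  d <- diff(pos) * config$recomb_rate
  p_switch <- 1 - exp(-config$generations * d)
  n_hap <- 2L * config$n_admixed
  hap <- matrix(NA_integer_, n_hap, M)
  tracts <- vector("list", n_hap)
  for (h in seq_len(n_hap)) {
    sw <- stats::rbinom(M - 1L, 1L, p_switch) == 1L
    starts <- c(1L, which(sw) + 1L)
    ends <- c(which(sw), M)
    nt <- length(starts)
    br <- sample.int(K, nt, replace = TRUE, prob = config$admix_prop)
    donor <- vapply(br, function(k) {
      rows <- breed_rows[[k]]
      rows[sample.int(length(rows), 1L)]
    }, integer(1))
    for (t in seq_len(nt)) {
      hap[h, starts[t]:ends[t]] <- parental$hap[donor[t], starts[t]:ends[t]]
    }
    tracts[[h]] <- data.table::data.table(
      hap = h, chrom = config$chrom,
      start_site = starts, end_site = ends,
      start_bp = c(1L, pos[starts[-1L]]),
      end_bp = c(pos[ends[-nt]], as.integer(config$chrom_length)),
      breed = config$breeds[br], donor = donor)
  }
  tracts <- data.table::rbindlist(tracts)
  manifest <- sample_manifest(
    sprintf("ADM_%03d", seq_len(config$n_admixed)),
    config$admixed_label, "admixed")
  panel <- genotype_panel(hap, parental$map, manifest)
  truth <- structure(list(tracts = tracts, breeds = config$breeds,
                          config = config, seed = seed),
                     class = "sim_truth")
  list(panel = panel, truth = truth)
}

#' Plant a haplotype-frequency shift in the admixed cohort
#'
#' Creates the signal the migration statistic is designed to detect: a
#' fraction `delta` of admixed haplotypes, drawn uniformly from those not
#' already carrying it, have one window's alleles overwritten with the
#' named breed's most frequent window haplotype, so the observed window
#' frequency of that haplotype rises by about `delta`. Truth tracts are
#' relabelled to that breed inside the window (donor recorded as `NA`,
#' meaning "injected").
#'
#' @param admixed admixed [genotype_panel()].
#' @param parental parental [genotype_panel()] (source of the modal window
#'   haplotype).
#' @param truth the `sim_truth` from [simulate_admixed()].
#' @param window one row of a [build_windows()] grid.
#' @param breed parental breed label.
#' @param delta fraction of admixed haplotypes to convert, `>= 0`.
#' @param seed RNG seed.
#' @return `list(panel =, truth =, haplotype =, carriers_before =)`.
#' @export
inject_haplotype_selection <- function(admixed, parental, truth, window,
                                       breed, delta, seed = 1L) {
  if (delta < 0) stop("delta must be >= 0")
  stopifnot(nrow(window) == 1L)
  i0 <- window$start_idx; i1 <- window$end_idx
  if (i1 > n_sites(admixed)) stop("window outside the marker map")
  hp <- hap_populations(parental)
  s_par <- window_strings(parental, i0, i1, rows = hp == breed)
  s_par <- s_par[!is.na(s_par)]
  if (!length(s_par)) stop("breed ", breed, " has no complete haplotypes in window")
  tab <- sort(table(s_par), decreasing = TRUE)
  modal <- names(tab)[tab == max(tab)]
  modal <- sort(modal)[1L]
  alleles <- as.integer(strsplit(modal, "")[[1]])
  s_adm <- window_strings(admixed, i0, i1)
  carriers <- !is.na(s_adm) & s_adm == modal
  n_hap <- n_haplotypes(admixed)
  n_sel <- round(delta * n_hap)
  non <- which(!carriers)
  if (n_sel > length(non))
    stop("delta larger than the available non-carrier fraction")
  panel <- admixed
  tracts <- data.table::copy(truth$tracts)
  if (n_sel > 0L) {
    set.seed(seed)
    sel <- non[sample.int(length(non), n_sel)]
    panel$hap[sel, i0:i1] <- matrix(alleles, n_sel, i1 - i0 + 1L,
                                    byrow = TRUE)
    tracts <- relabel_tracts(tracts, sel, i0, i1, breed,
                             window$start_bp, window$end_bp)
  }
  new_truth <- truth
  new_truth$tracts <- tracts
  new_truth$injection <- list(window_id = window$window_id, breed = breed,
                              delta = delta, haplotype = modal)
  list(panel = panel, truth = new_truth, haplotype = modal,
       carriers_before = mean(carriers))
}

# split tracts of the selected haplotypes so [i0, i1] carries `breed`
relabel_tracts <- function(tracts, haps, i0, i1, breed, bp0, bp1) {
  keep <- tracts[!(tracts$hap %in% haps &
                     tracts$start_site <= i1 & tracts$end_site >= i0), ]
  touched <- tracts[tracts$hap %in% haps &
                      tracts$start_site <= i1 & tracts$end_site >= i0, ]
  pieces <- list(keep)
  for (r in seq_len(nrow(touched))) {
    tr <- touched[r, ]
    if (tr$start_site < i0)
      pieces[[length(pieces) + 1L]] <- data.table::data.table(
        hap = tr$hap, chrom = tr$chrom, start_site = tr$start_site,
        end_site = i0 - 1L, start_bp = tr$start_bp, end_bp = bp0 - 1L,
        breed = tr$breed, donor = tr$donor)
    if (tr$end_site > i1)
      pieces[[length(pieces) + 1L]] <- data.table::data.table(
        hap = tr$hap, chrom = tr$chrom, start_site = i1 + 1L,
        end_site = tr$end_site, start_bp = bp1 + 1L, end_bp = tr$end_bp,
        breed = tr$breed, donor = tr$donor)
  }
  inj <- data.table::data.table(
    hap = haps, chrom = touched$chrom[1], start_site = i0, end_site = i1,
    start_bp = bp0, end_bp = bp1, breed = breed, donor = NA_integer_)
  out <- data.table::rbindlist(c(pieces, list(inj)))
  data.table::setorderv(out, c("hap", "start_site"))
  out
}

#' Genome-wide realized ancestry fractions from simulation truth
#'
#' Fraction of sites (over all admixed haplotypes) whose tract carries each
#' breed.
#' @param truth `sim_truth` from [simulate_admixed()].
#' @return Named numeric vector over breeds.
#' @export
realized_ancestry <- function(truth) {
  tr <- truth$tracts
  n_by_breed <- tapply(tr$end_site - tr$start_site + 1L, tr$breed, sum)
  out <- stats::setNames(numeric(length(truth$breeds)), truth$breeds)
  out[names(n_by_breed)] <- n_by_breed / sum(n_by_breed)
  out
}

#' Write simulation outputs to a directory
#'
#' Emits a phased VCF of parental + admixed samples, a manifest TSV, the
#' truth tracts TSV and the configuration as YAML.
#' @param parental,admixed [genotype_panel()] objects sharing a map.
#' @param truth `sim_truth` from [simulate_admixed()].
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(parental, admixed, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- rbind(parental$manifest, admixed$manifest)
  class(manifest) <- c("sample_manifest", "data.frame")
  merged <- genotype_panel(rbind(parental$hap, admixed$hap),
                           parental$map, manifest)
  write_phased_vcf(merged, file.path(dir, "genotypes.vcf"))
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  data.table::fwrite(truth$tracts, file.path(dir, "truth_tracts.tsv"),
                     sep = "\t")
  cfg <- truth$config
  yaml::write_yaml(unclass(cfg), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
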
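#' Marker map
#'
#' A per-site table of marker coordinates for a genotype panel: chromosome,
#' 1-based bp position (VCF convention), marker id and the two alleles of a
#' biallelic SNP. Sites must be strictly sorted by (chromosome, position) and
#' positions unique within a chromosome.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based bp positions.
#' @param id marker ids; autogenerated as `chrom_pos` when `NULL`.
#' @param ref,alt single-character reference / alternate alleles.
#' @return A `data.frame` with class `marker_map`.
#' @export
marker_map <- function(chrom, pos, id = NULL, ref = "A", alt = "G") {
  n <- length(pos)
  chrom <- as.character(rep_len(chrom, n))
  pos <- as.integer(pos)
  if (anyNA(pos) || any(pos < 1L)) stop("positions must be positive integers")
  if (is.null(id)) id <- paste(chrom, pos, sep = "_")
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L))
    stop("only biallelic SNPs with single-character alleles are supported")
  map <- data.frame(chrom = chrom, pos = pos, id = as.character(id),
                    ref = ref, alt = alt, stringsAsFactors = FALSE)
  # strict sort within chromosome, chromosomes in first-appearance order
  ord <- order(match(map$chrom, unique(map$chrom)), map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  dup <- duplicated(map[, c("chrom", "pos")])
  if (any(dup)) stop("duplicated positions within a chromosome: ",
                     paste(head(map$id[dup], 5), collapse = ", "))
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Sample manifest
#'
#' Assigns each sample to a population and a role: `parental_panel` for
#' reference-breed samples used to train ancestry models, `admixed` for the
#' crossbred cohort.
#'
#' @param sample_id unique sample identifiers.
#' @param population population label per sample (e.g. breed name).
#' @param role `"parental_panel"` or `"admixed"`, recycled.
#' @return A `data.frame` with class `sample_manifest`.
#' @export
sample_manifest <- function(sample_id, population, role) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  role <- rep_len(as.character(role), length(sample_id))
  bad <- setdiff(unique(role), c("parental_panel", "admixed"))
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  m <- data.frame(sample_id = sample_id,
                  population = rep_len(as.character(population), length(sample_id)),
                  role = role, stringsAsFactors = FALSE)
  class(m) <- c("sample_manifest", "data.frame")
  m
}

#' Read a sample manifest TSV
#'
#' Columns: sample_id, population, role.
#' @param path file path.
#' @return A [sample_manifest()].
#' @export
read_manifest <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  sample_manifest(d$sample_id, d$population, d$role)
}

#' Write a sample manifest TSV
#' @param manifest a [sample_manifest()].
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Phased genotype panel
#'
#' The universal substrate: a matrix of phased haplotypes (rows; two
#' consecutive rows per diploid sample, in manifest order) over biallelic
#' sites (columns), with allele codes 0 (ref), 1 (alt) and `NA` for missing
#' calls, plus the marker map and the sample manifest.
#'
#' @param hap integer matrix of 0/1/`NA`, `2 * nrow(manifest)` rows.
#' @param map a [marker_map()] with one row per column of `hap`.
#' @param manifest a [sample_manifest()].
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(hap, map, manifest) {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  if (nrow(hap) != 2L * nrow(manifest))
    stop("haplotype row count must be 2 x sample count")
  if (ncol(hap) != nrow(map))
    stop("haplotype column count must equal site count")
  vals <- hap[!is.na(hap)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    stop("non-missing allele codes must be 0 or 1")
  rownames(hap) <- paste(rep(manifest$sample_id, each = 2L),
                         rep(1:2, nrow(manifest)), sep = "|")
  colnames(hap) <- map$id
  structure(list(hap = hap, map = map, manifest = manifest),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples (%d haplotypes) x %d sites, %d chromosome(s)\n",
              nrow(x$manifest), nrow(x$hap), nrow(x$map),
              length(unique(x$map$chrom))))
  tab <- table(x$manifest$population)
  cat("populations:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname genotype_panel
#' @param panel a `genotype_panel`.
#' @export
n_sites <- function(panel) nrow(panel$map)

#' @rdname genotype_panel
#' @export
n_haplotypes <- function(panel) nrow(panel$hap)

#' Population label of each haplotype row
#' @param panel a [genotype_panel()].
#' @return character vector, length `n_haplotypes(panel)`.
#' @export
hap_populations <- function(panel) rep(panel$manifest$population, each = 2L)

#' Read phased genotypes from a VCF
#'
#' Reads a VCF 4.x file with phased GT fields for the samples listed in the
#' manifest and returns a [genotype_panel()]. Multi-allelic and non-SNP
#' records are skipped (count reported via a message). An unphased genotype
#' for a retained sample is an error.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param manifest a [sample_manifest()]; all of its samples must be present.
#' @return A [genotype_panel()] with haplotype rows in manifest order.
#' @export
read_phased_vcf <- function(path, manifest) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  missing_samples <- setdiff(manifest$sample_id,
                             colnames(VariantAnnotation::geno(vcf)$GT))
  if (length(missing_samples))
    stop("manifest sample(s) absent from VCF: ",
         paste(missing_samples, collapse = ", "))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(n_alt))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    message(n_skipped, " multi-allelic or non-SNP record(s) skipped")
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  gt <- VariantAnnotation::geno(vcf)$GT[keep, manifest$sample_id, drop = FALSE]
  map <- marker_map(chrom = as.character(GenomicRanges::seqnames(rr))[keep],
                    pos = GenomicRanges::start(rr)[keep],
                    id = names(rr)[keep], ref = ref[keep], alt = alt1[keep])
  # readVcf keeps record order; map construction sorts, so track permutation
  ord <- order(match(as.character(GenomicRanges::seqnames(rr))[keep],
                     unique(as.character(GenomicRanges::seqnames(rr))[keep])),
               GenomicRanges::start(rr)[keep])
  gt <- gt[ord, , drop = FALSE]
  unphased <- which(matrix(grepl("/", gt, fixed = TRUE), nrow(gt)),
                    arr.ind = TRUE)
  if (nrow(unphased))
    stop(sprintf("unphased genotype for sample %s at %s:%d",
                 colnames(gt)[unphased[1, 2]],
                 map$chrom[unphased[1, 1]], map$pos[unphased[1, 1]]))
  n_samp <- nrow(manifest)
  n_site <- nrow(map)
  hap <- matrix(NA_integer_, nrow = 2L * n_samp, ncol = n_site)
  code <- function(a) ifelse(a == ".", NA_integer_,
                             suppressWarnings(as.integer(a)))
  for (s in seq_len(n_samp)) {
    parts <- strsplit(gt[, s], "|", fixed = TRUE)
    lens <- lengths(parts)
    if (any(lens != 2L))
      stop(sprintf("malformed GT for sample %s at %s:%d",
                   manifest$sample_id[s], map$chrom[which(lens != 2L)[1]],
                   map$pos[which(lens != 2L)[1]]))
    m <- matrix(unlist(parts), nrow = 2L)
    hap[2L * s - 1L, ] <- code(m[1, ])
    hap[2L * s, ] <- code(m[2, ])
  }
  bad <- hap[!is.na(hap)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("allele codes other than 0/1 found in biallelic records")
  genotype_panel(hap, map, manifest)
}

#' Write a panel as a minimal phased VCF 4.2
#'
#' Lossless for alleles, positions and sample ids; missing calls are emitted
#' as `.` per allele.
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  map <- panel$map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=hapflow",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", panel$manifest$sample_id),
                  collapse = "\t")
  writeLines(header, con)
  if (nrow(map) == 0L || nrow(panel$manifest) == 0L) {
    if (nrow(map) > 0L && nrow(panel$manifest) == 0L) {
      body <- paste(map$chrom, map$pos, map$id, map$ref, map$alt,
                    ".", "PASS", ".", "GT", sep = "\t")
      writeLines(body, con)
    }
    return(invisible(path))
  }
  a <- panel$hap
  ch <- matrix(as.character(a), nrow = nrow(a))
  ch[is.na(ch)] <- "."
  odd <- seq(1L, nrow(a), by = 2L)
  gt <- matrix(paste(ch[odd, , drop = FALSE], ch[odd + 1L, , drop = FALSE],
                     sep = "|"),
               nrow = length(odd))        # samples x sites
  gt_cols <- apply(gt, 2L, paste, collapse = "\t")
  body <- paste(map$chrom, map$pos, map$id, map$ref, map$alt,
                ".", "PASS", ".", "GT", gt_cols, sep = "\t")
  writeLines(body, con)
  invisible(path)
}

per_pop_freq <- function(panel, pops = NULL) {
  hp <- hap_populations(panel)
  if (is.null(pops)) pops <- unique(panel$manifest$population)
  out <- vapply(pops, function(p) {
    colMeans(panel$hap[hp == p, , drop = FALSE], na.rm = TRUE)
  }, numeric(n_sites(panel)))
  matrix(out, nrow = n_sites(panel), dimnames = list(panel$map$id, pops))
}

#' Filter sites on minor allele frequency within populations
#'
#' Retains a site iff its minor allele frequency exceeds `threshold` within
#' at least one population (`rule = "any"`, the default — a site informative
#' in any breed is kept) or within every population (`rule = "all"`).
#'
#' @param panel a [genotype_panel()].
#' @param threshold MAF threshold in `[0, 0.5)`; default 0.01.
#' @param rule `"any"` (OR across populations) or `"all"` (AND).
#' @return Filtered [genotype_panel()]; ids of dropped sites in
#'   `attr(, "dropped")`.
#' @export
filter_maf <- function(panel, threshold = 0.01, rule = c("any", "all")) {
  rule <- match.arg(rule)
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 0.5)
    stop("threshold must lie in [0, 0.5)")
  f <- per_pop_freq(panel)
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0   # all-missing within a population
  pass <- maf > threshold
  keep <- if (rule == "any") rowSums(pass) > 0L else rowSums(pass) == ncol(pass)
  out <- genotype_panel(panel$hap[, keep, drop = FALSE],
                        {
                          m <- panel$map[keep, , drop = FALSE]
                          rownames(m) <- NULL
                          class(m) <- c("marker_map", "data.frame")
                          m
                        },
                        panel$manifest)
  attr(out, "dropped") <- panel$map$id[!keep]
  out
}

#' Restrict a panel to one population
#'
#' @param panel a [genotype_panel()].
#' @param population a population label present in the manifest.
#' @return A [genotype_panel()] with only that population's haplotype rows;
#'   the map is unchanged.
#' @export
subset_population <- function(panel, population) {
  if (!population %in% panel$manifest$population)
    stop("unknown population: ", population)
  keep_s <- panel$manifest$population == population
  keep_h <- rep(keep_s, each = 2L)
  man <- panel$manifest[keep_s, , drop = FALSE]
  rownames(man) <- NULL
  class(man) <- c("sample_manifest", "data.frame")
  genotype_panel(panel$hap[keep_h, , drop = FALSE], panel$map, man)
}
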
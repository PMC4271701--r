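#' Build SNP-index windows along the marker map
#'
#' Windows are enumerated per chromosome from the first site, `size` SNPs
#' wide, starting a new window every `step` SNPs (`step = size` gives the
#' non-overlapping grid used to train the ancestry model, `step = size/2`
#' the half-overlapping migration-scan grid). Trailing windows with fewer
#' than `size` sites are dropped; windows never span chromosomes.
#'
#' @param map a [marker_map()].
#' @param size SNPs per window (default 30).
#' @param step SNPs between window starts, `1 <= step <= size`
#'   (default `size`).
#' @return A `data.frame` of class `window_grid` with columns `window_id`,
#'   `chrom`, `start_idx`, `end_idx` (1-based inclusive global site indices),
#'   `start_bp`, `end_bp`.
#' @export
build_windows <- function(map, size = 30L, step = size) {
  size <- as.integer(size); step <- as.integer(step)
  if (size < 2L) stop("size must be >= 2")
  if (step < 1L || step > size) stop("step must satisfy 1 <= step <= size")
  chroms <- unique(map$chrom)
  rows <- list()
  for (ch in chroms) {
    idx <- which(map$chrom == ch)
    n <- length(idx)
    if (n < size) next   # too few sites: zero windows on this chromosome
    starts <- seq.int(1L, n - size + 1L, by = step)
    rows[[ch]] <- data.frame(
      chrom = ch,
      start_idx = idx[starts],
      end_idx = idx[starts + size - 1L],
      start_bp = map$pos[idx[starts]],
      end_bp = map$pos[idx[starts + size - 1L]],
      stringsAsFactors = FALSE)
  }
  grid <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start_idx = integer(),
               end_idx = integer(), start_bp = integer(),
               end_bp = integer())
  rownames(grid) <- NULL
  grid <- cbind(window_id = seq_len(nrow(grid)), grid)
  attr(grid, "size") <- size
  attr(grid, "step") <- step
  class(grid) <- c("window_grid", "data.frame")
  grid
}

window_strings <- function(panel, start_idx, end_idx, rows = NULL) {
  sub <- panel$hap[if (is.null(rows)) TRUE else rows,
                   start_idx:end_idx, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  s <- rep(NA_character_, nrow(sub))
  if (any(complete))
    s[complete] <- do.call(paste0,
                           as.data.frame(sub[complete, , drop = FALSE]))
  s
}

#' Per-window haplotype frequency spectra
#'
#' For every window and population, counts exact-match window haplotypes
#' (allele strings over the window's sites) and normalizes to frequencies.
#' Haplotypes with one or more missing calls in a window are excluded from
#' both numerator and denominator of that window's spectrum; exclusion
#' counts are kept in `attr(, "n_excluded")`.
#'
#' @param panel a [genotype_panel()].
#' @param grid a [build_windows()] grid.
#' @param populations populations to tabulate (default: all in the manifest).
#' @return A `data.table` of class `haplotype_spectrum` with columns
#'   `window_id`, `population`, `haplotype`, `count`, `frequency`.
#' @export
haplotype_spectrum <- function(panel, grid, populations = NULL) {
  if (nrow(grid) && (max(grid$end_idx) > n_sites(panel) || min(grid$start_idx) < 1L))
    stop("window grid references sites outside the panel")
  hp <- hap_populations(panel)
  if (is.null(populations)) populations <- unique(panel$manifest$population)
  out <- vector("list", nrow(grid))
  n_excluded <- 0L
  for (w in seq_len(nrow(grid))) {
    s <- window_strings(panel, grid$start_idx[w], grid$end_idx[w])
    n_excluded <- n_excluded + sum(is.na(s))
    per_pop <- lapply(populations, function(p) {
      sp <- s[hp == p & !is.na(s)]
      if (!length(sp)) return(NULL)
      tab <- table(sp)
      data.table::data.table(window_id = grid$window_id[w], population = p,
                             haplotype = names(tab),
                             count = as.integer(tab),
                             frequency = as.numeric(tab) / length(sp))
    })
    out[[w]] <- data.table::rbindlist(per_pop)
  }
  spec <- data.table::rbindlist(out)
  if (!nrow(spec))
    spec <- data.table::data.table(window_id = integer(), population = character(),
                                   haplotype = character(), count = integer(),
                                   frequency = numeric())
  data.table::setattr(spec, "grid", grid)
  data.table::setattr(spec, "n_excluded", n_excluded)
  data.table::setattr(spec, "class",
                      c("haplotype_spectrum", class(spec)))
  spec[]
}

#' Most frequent window haplotype in a population
#'
#' Ties are broken by the lexicographically smallest haplotype string so the
#' result is deterministic.
#'
#' @param spectrum a [haplotype_spectrum()].
#' @param window_id window identifier from the grid.
#' @param population population label.
#' @return `list(haplotype =, frequency =)`.
#' @export
most_frequent <- function(spectrum, window_id, population) {
  wid <- window_id; pop <- population
  keep <- which(spectrum$window_id == wid & spectrum$population == pop)
  rows <- as.data.frame(spectrum)[keep, ]
  if (!nrow(rows))
    stop(sprintf("no spectrum entries for window %s in population %s",
                 wid, pop))
  rows <- rows[order(-rows$count, rows$haplotype), ]
  list(haplotype = rows$haplotype[1], frequency = rows$frequency[1])
}

#' Frequency of a specific haplotype string in a population
#'
#' @param spectrum a [haplotype_spectrum()].
#' @param window_id window identifier.
#' @param haplotype allele string of length equal to the window size.
#' @param population population label.
#' @return Frequency in `[0, 1]`; 0 if the haplotype is absent.
#' @export
shared_frequency <- function(spectrum, window_id, haplotype, population) {
  grid <- attr(spectrum, "grid")
  if (!is.null(grid)) {
    w <- grid[grid$window_id == window_id, ]
    if (nrow(w) && nchar(haplotype) != (w$end_idx - w$start_idx + 1L))
      stop("haplotype length does not match window size")
  }
  wid <- window_id; pop <- population; h <- haplotype
  # data.frame subsetting: inside [.data.table the bare argument names
  # would resolve to the spectrum's own columns
  keep <- spectrum$window_id == wid & spectrum$population == pop &
    spectrum$haplotype == h
  if (!any(keep)) 0 else spectrum$frequency[which(keep)[1]]
}

#' Export a haplotype spectrum as TSV
#'
#' Columns: chrom, window_start_bp, window_end_bp, population, haplotype,
#' count, frequency.
#' @param spectrum a [haplotype_spectrum()].
#' @param path output path.
#' @export
write_spectrum <- function(spectrum, path) {
  grid <- attr(spectrum, "grid")
  m <- match(spectrum$window_id, grid$window_id)
  out <- data.table::data.table(
    chrom = grid$chrom[m],
    window_start_bp = grid$start_bp[m],
    window_end_bp = grid$end_bp[m],
    population = spectrum$population,
    haplotype = spectrum$haplotype,
    count = spectrum$count,
    frequency = spectrum$frequency)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
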
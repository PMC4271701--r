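#' Train a window-based ancestry model from parental panels
#'
#' For each non-overlapping training window and each parental breed, the
#' model stores the breed's complete panel haplotypes; the emission
#' probability of an observed admixed window haplotype given ancestry in
#' breed B is a haplotype-copying mixture over that breed's panel,
#'
#'   e(h | B) = (1/|panel_B|) * sum_t eps^mismatch(h,t) (1-eps)^match(h,t),
#'
#' i.e. a Li-Stephens-flavoured emission with per-site copying error `eps`.
#' Between adjacent windows the hidden breed switches with probability
#' `rho`, landing on breed B' with probability proportional to the prior.
#'
#' @param parental a [genotype_panel()] with >= 2 parental populations.
#' @param grid a non-overlapping [build_windows()] grid (step = size).
#' @param eps per-site copying error in (0, 0.5); default 0.01.
#' @param rho ancestry switch probability between adjacent windows, in
#'   (0, 1); default 0.05.
#' @param prior ancestry prior over breeds (default uniform).
#' @return An object of class `ancestry_model`.
#' @export
train_ancestry_model <- function(parental, grid, eps = 0.01, rho = 0.05,
                                 prior = NULL) {
  if (attr(grid, "step") < attr(grid, "size"))
    stop("training grid must be non-overlapping (step = size)")
  breeds <- unique(parental$manifest$population[
    parental$manifest$role == "parental_panel"])
  if (length(breeds) < 2L) stop("need >= 2 parental populations")
  if (eps <= 0 || eps >= 0.5) stop("eps must lie in (0, 0.5)")
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  if (is.null(prior)) prior <- rep(1 / length(breeds), length(breeds))
  if (length(prior) != length(breeds) || abs(sum(prior) - 1) > 1e-8)
    stop("prior must be a simplex over the parental breeds")
  hp <- hap_populations(parental)
  panels <- vector("list", nrow(grid))
  for (w in seq_len(nrow(grid))) {
    i0 <- grid$start_idx[w]; i1 <- grid$end_idx[w]
    panels[[w]] <- lapply(breeds, function(b) {
      sub <- parental$hap[hp == b, i0:i1, drop = FALSE]
      sub <- sub[rowSums(is.na(sub)) == 0L, , drop = FALSE]
      if (nrow(sub) == 0L)
        stop(sprintf("breed %s has zero complete haplotypes in window %d",
                     b, grid$window_id[w]))
      sub
    })
    names(panels[[w]]) <- breeds
  }
  structure(list(breeds = breeds, grid = grid, panels = panels,
                 eps = eps, rho = rho, prior = prior, map = parental$map),
            class = "ancestry_model")
}

# emission probabilities for one window: queries (rows of Q) x breeds.
# Missing query sites are dropped pairwise (match and mismatch both skip).
window_emissions <- function(model, Q) {
  L <- ncol(Q)
  K <- length(model$breeds)
  nq <- nrow(Q)
  out <- matrix(NA_real_, nq, K)
  le <- log(model$eps); l1e <- log1p(-model$eps)
  obs <- !is.na(Q)
  Q0 <- Q; Q0[!obs] <- 0L
  for (k in seq_len(K)) {
    P <- model$panels_w[[k]]
    # mismatches over observed sites: d = sum(q) + sum_obs(t) - 2 q.t
    qt <- Q0 %*% t(P)                       # 1-1 matches
    tsum <- obs %*% t(P)                    # per-pair sum of t over observed q sites
    d <- rowSums(Q0) + tsum - 2 * qt
    n_obs <- rowSums(obs)
    out[, k] <- rowMeans(exp(d * le + (n_obs - d) * l1e))
  }
  out
}

#' Infer local ancestry of admixed haplotypes
#'
#' Runs a forward-backward pass (and Viterbi decoding) over training
#' windows for every admixed haplotype, with hidden state = parental breed,
#' haplotype-copying emissions from the trained model, and transitions
#' stay `1 - rho` / switch `rho * prior(B')` between adjacent windows. All
#' recursions are scaled so no finite input underflows.
#'
#' @param admixed a [genotype_panel()] on the same marker map as training.
#' @param model an [train_ancestry_model()] model.
#' @return An `ancestry_field`: posterior array `post[hap, window, breed]`,
#'   Viterbi labels, and per-window mean ancestry `p_mean[window, breed]`.
#' @export
infer_local_ancestry <- function(admixed, model) {
  if (!identical(admixed$map$chrom, model$map$chrom) ||
      !identical(admixed$map$pos, model$map$pos))
    stop("admixed panel and ancestry model use different marker maps")
  grid <- model$grid
  W <- nrow(grid)
  K <- length(model$breeds)
  n_hap <- n_haplotypes(admixed)
  E <- array(NA_real_, c(n_hap, W, K))
  for (w in seq_len(W)) {
    model$panels_w <- model$panels[[w]]
    E[, w, ] <- window_emissions(
      model, admixed$hap[, grid$start_idx[w]:grid$end_idx[w], drop = FALSE])
  }
  # chromosome breaks: restart the chain at each new chromosome
  new_chrom <- c(TRUE, grid$chrom[-1L] != grid$chrom[-W])
  A <- (1 - model$rho) * diag(K) +
    model$rho * matrix(model$prior, K, K, byrow = TRUE)
  post <- array(NA_real_, c(n_hap, W, K))
  vit <- matrix(NA_integer_, n_hap, W)
  lA <- log(A); lpi <- log(model$prior)
  for (h in seq_len(n_hap)) {
    e <- matrix(E[h, , ], W, K)
    e <- pmax(e, 1e-300)
    alpha <- matrix(0, W, K)
    for (w in seq_len(W)) {
      a <- if (new_chrom[w]) model$prior * e[w, ] else
        as.vector(crossprod(A, alpha[w - 1L, ])) * e[w, ]
      alpha[w, ] <- a / sum(a)
    }
    beta <- matrix(0, W, K)
    beta[W, ] <- 1
    if (W > 1L) for (w in (W - 1L):1L) {
      b <- if (new_chrom[w + 1L]) rep(1, K) else
        as.vector(A %*% (e[w + 1L, ] * beta[w + 1L, ]))
      beta[w, ] <- b / sum(b)
    }
    p <- alpha * beta
    p <- p / rowSums(p)
    post[h, , ] <- p
    # Viterbi in log space
    le <- log(e)
    delta <- matrix(-Inf, W, K)
    psi <- matrix(0L, W, K)
    for (w in seq_len(W)) {
      if (new_chrom[w]) {
        delta[w, ] <- lpi + le[w, ]
      } else {
        for (k in seq_len(K)) {
          cand <- delta[w - 1L, ] + lA[, k]
          psi[w, k] <- which.max(cand)
          delta[w, k] <- cand[psi[w, k]] + le[w, k]
        }
      }
    }
    path <- integer(W)
    path[W] <- which.max(delta[W, ])
    if (W > 1L) for (w in (W - 1L):1L) {
      path[w] <- if (new_chrom[w + 1L]) which.max(delta[w, ]) else
        psi[w + 1L, path[w + 1L]]
    }
    vit[h, ] <- path
  }
  ancestry_field(post, model$breeds, grid,
                 hap_ids = rownames(admixed$hap), viterbi = vit)
}

#' Construct an ancestry field
#'
#' @param post array `[haplotype, window, breed]` of posteriors; each
#'   `[h, w, ]` slice must sum to 1.
#' @param breeds breed labels.
#' @param grid the training [build_windows()] grid.
#' @param hap_ids haplotype row identifiers.
#' @param viterbi optional matrix of Viterbi breed indices (defaults to the
#'   posterior argmax).
#' @return An object of class `ancestry_field`.
#' @export
ancestry_field <- function(post, breeds, grid, hap_ids = NULL,
                           viterbi = NULL) {
  stopifnot(length(dim(post)) == 3L, dim(post)[3] == length(breeds))
  sums <- apply(post, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6))
    stop("ancestry posteriors must sum to 1 per (haplotype, window)")
  if (is.null(viterbi))
    viterbi <- apply(post, c(1, 2), which.max)
  p_mean <- apply(post, c(2, 3), mean)
  dimnames(p_mean) <- list(NULL, breeds)
  structure(list(post = post, viterbi = viterbi, p_mean = p_mean,
                 breeds = breeds, grid = grid,
                 hap_ids = hap_ids %||% as.character(seq_len(dim(post)[1]))),
            class = "ancestry_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-window ancestry summaries
#'
#' `mean` mode averages the posterior over haplotypes (multiple ancestries
#' allowed). `minimum` mode counts only haplotypes assigned near-exclusively
#' to one breed — posterior mass above the exclusivity threshold `tau` —
#' and reports the per-breed fraction among those, normalized over breeds;
#' windows where no haplotype is exclusive get an all-zero row and
#' `undefined = TRUE`.
#'
#' @param field an [ancestry_field()].
#' @param mode `"mean"` or `"minimum"`.
#' @param tau exclusivity threshold in (0.5, 1]; default 0.95.
#' @return `data.frame` with `window_id`, one column per breed, and for
#'   `minimum` mode a logical `undefined` column.
#' @export
ancestry_summaries <- function(field, mode = c("mean", "minimum"),
                               tau = 0.95) {
  mode <- match.arg(mode)
  W <- dim(field$post)[2]
  if (mode == "mean") {
    out <- data.frame(window_id = field$grid$window_id, field$p_mean,
                      check.names = FALSE)
    return(out)
  }
  K <- length(field$breeds)
  res <- matrix(0, W, K, dimnames = list(NULL, field$breeds))
  undef <- logical(W)
  for (w in seq_len(W)) {
    p <- matrix(field$post[, w, ], ncol = K)
    excl <- p > tau
    cnt <- colSums(excl)
    if (sum(cnt) == 0) undef[w] <- TRUE else res[w, ] <- cnt / sum(cnt)
  }
  data.frame(window_id = field$grid$window_id, res, undefined = undef,
             check.names = FALSE)
}

#' Write an ancestry field as TSV
#'
#' One row per (haplotype, window) with posterior columns `prob_<breed>`.
#' @param field an [ancestry_field()].
#' @param path output path.
#' @export
write_ancestry <- function(field, path) {
  n_hap <- dim(field$post)[1]; W <- dim(field$post)[2]
  rows <- expand.grid(hap = seq_len(n_hap), window_id = field$grid$window_id)
  probs <- do.call(cbind, lapply(seq_along(field$breeds), function(k)
    as.vector(field$post[, , k])))
  colnames(probs) <- paste0("prob_", field$breeds)
  out <- cbind(data.frame(hap_id = field$hap_ids[rows$hap],
                          hap = rows$hap, window_id = rows$window_id),
               probs)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read an externally computed ancestry field
#'
#' Accepts the TSV layout of [write_ancestry()] (columns `hap`, `window_id`,
#' `prob_<breed>`); rows whose probabilities do not sum to 1 within 1e-6
#' raise an error naming the line.
#'
#' @param path TSV path.
#' @param grid the training [build_windows()] grid the probabilities refer to.
#' @return An [ancestry_field()].
#' @export
read_external_ancestry <- function(path, grid) {
  d <- data.table::fread(path, sep = "\t")
  pcols <- grep("^prob_", names(d), value = TRUE)
  if (!length(pcols)) stop("no prob_<breed> columns in ", path)
  breeds <- sub("^prob_", "", pcols)
  sums <- rowSums(d[, pcols, with = FALSE])
  bad <- which(abs(sums - 1) > 1e-6)
  if (length(bad))
    stop("ancestry probabilities do not sum to 1 at line ", bad[1] + 1L)
  haps <- sort(unique(d$hap))
  wids <- grid$window_id
  if (!all(d$window_id %in% wids)) stop("window ids not found in grid")
  post <- array(NA_real_, c(length(haps), length(wids), length(breeds)))
  hi <- match(d$hap, haps); wi <- match(d$window_id, wids)
  for (k in seq_along(breeds))
    post[cbind(hi, wi, k)] <- d[[pcols[k]]]
  if (anyNA(post)) stop("missing (haplotype, window) combinations in ", path)
  hap_ids <- if ("hap_id" %in% names(d))
    d$hap_id[match(haps, d$hap)] else as.character(haps)
  ancestry_field(post, breeds, grid, hap_ids = hap_ids)
}

#' One-hot ancestry field from simulation truth
#'
#' Assigns each (haplotype, window) the breed covering the most sites of the
#' window in the true tract decomposition (ties to the earlier breed in
#' `truth$breeds`), as a degenerate posterior. Used as the "oracle ancestry"
#' in calibration experiments.
#'
#' @param truth `sim_truth` from [simulate_admixed()].
#' @param grid a [build_windows()] grid on the simulated map.
#' @return An [ancestry_field()].
#' @export
ancestry_from_truth <- function(truth, grid) {
  tr <- truth$tracts
  breeds <- truth$breeds
  n_hap <- max(tr$hap)
  W <- nrow(grid)
  K <- length(breeds)
  post <- array(0, c(n_hap, W, K))
  for (w in seq_len(W)) {
    i0 <- grid$start_idx[w]; i1 <- grid$end_idx[w]
    sub <- tr[tr$start_site <= i1 & tr$end_site >= i0, ]
    ov <- pmin(sub$end_site, i1) - pmax(sub$start_site, i0) + 1L
    agg <- tapply(ov, list(sub$hap, factor(sub$breed, levels = breeds)),
                  sum, default = 0L)
    top <- apply(agg, 1L, which.max)
    post[cbind(as.integer(rownames(agg)), w, as.integer(top))] <- 1
  }
  ancestry_field(post, breeds, grid)
}

#' Viterbi tract labels as a BED-like table
#'
#' Maximal runs of a constant Viterbi breed per haplotype; coordinates are
#' 0-based half-open bp spans of the constituent windows.
#' @param field an [ancestry_field()].
#' @return `data.table` with `hap_id`, `chrom`, `start`, `end`, `breed`.
#' @export
viterbi_tracts <- function(field) {
  g <- field$grid
  out <- list()
  for (h in seq_len(nrow(field$viterbi))) {
    v <- field$viterbi[h, ]
    brk <- c(TRUE, v[-1L] != v[-length(v)] |
               g$chrom[-1L] != g$chrom[-length(v)])
    seg <- cumsum(brk)
    for (s in unique(seg)) {
      w <- which(seg == s)
      out[[length(out) + 1L]] <- data.table::data.table(
        hap_id = field$hap_ids[h], chrom = g$chrom[w[1]],
        start = g$start_bp[w[1]] - 1L, end = g$end_bp[w[length(w)]],
        breed = field$breeds[v[w[1]]])
    }
  }
  data.table::rbindlist(out)
}
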
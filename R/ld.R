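## Pairwise linkage disequilibrium among multi-band loci with permutation
## significance, background-LD estimation and logarithmic decay fitting.
##
## Band presence/absence is treated haploid-style (individuals as
## gametes): for a band pair, D = p_AB - p_A p_B from the 2x2 presence
## table, r2 = D^2/(p_A(1-p_A) p_B(1-p_B)) and D' = |D|/D_max.  Locus
## level r2/D' are weighted averages over the locus pair's band pairs
## with weights proportional to the product of marginal band frequencies.

#' Mask rare alleles
#'
#' Bands whose presence frequency (computed over non-missing calls) is
#' strictly below the threshold have their presence entries set to
#' missing, mirroring the convention of treating rare alleles
#' (frequency < 0.05) as missing data.
#'
#' @param bands band matrix.
#' @param threshold frequency threshold (strict `<`).
#' @return band matrix with rare presences masked.
#' @export
mask_rare <- function(bands, threshold = 0.05) {
  validate_band_matrix(bands)
  freq <- colMeans(bands == 1L, na.rm = TRUE)
  rare <- which(!is.nan(freq) & freq < threshold & freq > 0)
  for (j in rare) bands[which(bands[, j] == 1L), j] <- NA_integer_
  bands
}

## band-level LD from two 0/1 vectors (no NAs)
band_ld <- function(x, y) {
  pa <- mean(x); pb <- mean(y)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NULL)
  pab <- mean(x * y)
  D <- pab - pa * pb
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb)
          else min(pa * pb, (1 - pa) * (1 - pb))
  dp <- if (dmax > 0) abs(D) / dmax else NA_real_
  c(D = D, r2 = r2, Dprime = dp, w = pa * pb)
}

## locus-level weighted r2 / D' between two band sub-matrices (no NAs)
locus_ld <- function(A, Bm) {
  acc <- matrix(NA_real_, 0, 4)
  for (i in seq_len(ncol(A))) for (j in seq_len(ncol(Bm))) {
    v <- band_ld(A[, i], Bm[, j])
    if (!is.null(v)) acc <- rbind(acc, v)
  }
  if (!nrow(acc)) return(NULL)
  w <- acc[, "w"] / sum(acc[, "w"])
  c(r2 = sum(w * acc[, "r2"]), Dprime = sum(w * acc[, "Dprime"], na.rm = TRUE))
}

#' Pairwise LD between loci with permutation significance
#'
#' For every marker pair, computes the frequency-weighted locus-level r2
#' and D' over all band pairs, the permutation p-value obtained by
#' shuffling one locus's individual labels (`p = (1 + #{r2_perm >=
#' r2_obs}) / (shuffles + 1)`), the inter-marker distance (same-chromosome
#' pairs) and a linked flag (same chromosome).  Pairs with fewer than 4
#' individuals complete at both loci, or monomorphic after masking, are
#' skipped with a warning.
#'
#' @param bands band matrix (apply [mask_rare()] first if desired).
#' @param map marker map.
#' @param shuffles number of permutations.
#' @param seed integer seed.
#' @return data frame of class `ld_pairs`: locusA, locusB, chromA,
#'   chromB, distance_bp (NA for unlinked), r2, Dprime, p_perm, linked.
#' @export
pairwise_ld <- function(bands, map, shuffles = 1000L, seed = 1L) {
  validate_band_matrix(bands)
  validate_marker_map(map)
  map <- map[map$band %in% colnames(bands), , drop = FALSE]
  markers <- unique(map$marker)
  if (length(markers) < 2) stopf("need >= 2 loci for pairwise LD")
  set.seed(seed)
  info <- map[!duplicated(map$marker), c("marker", "chrom", "pos_bp")]
  bands_of <- split(map$band, map$marker)[markers]
  out <- vector("list", length(markers) * (length(markers) - 1) / 2)
  idx <- 0L; skipped <- 0L
  for (i in seq_len(length(markers) - 1)) for (j in (i + 1):length(markers)) {
    ma <- markers[i]; mb <- markers[j]
    A <- bands[, bands_of[[ma]], drop = FALSE]
    Bm <- bands[, bands_of[[mb]], drop = FALSE]
    ok <- stats::complete.cases(cbind(A, Bm))
    if (sum(ok) < 4) { skipped <- skipped + 1L; next }
    A <- A[ok, , drop = FALSE]; Bm <- Bm[ok, , drop = FALSE]
    obs <- locus_ld(A, Bm)
    if (is.null(obs)) { skipped <- skipped + 1L; next }
    ge <- 0L
    for (s in seq_len(shuffles)) {
      perm <- locus_ld(A, Bm[sample.int(nrow(Bm)), , drop = FALSE])
      if (!is.null(perm) && perm[["r2"]] >= obs[["r2"]]) ge <- ge + 1L
    }
    p <- (1 + ge) / (shuffles + 1)
    ca <- info$chrom[info$marker == ma]; cb <- info$chrom[info$marker == mb]
    linked <- ca == cb
    dist <- if (linked) abs(info$pos_bp[info$marker == ma] -
                            info$pos_bp[info$marker == mb]) else NA_real_
    idx <- idx + 1L
    out[[idx]] <- data.frame(locusA = ma, locusB = mb, chromA = ca, chromB = cb,
                             distance_bp = dist, r2 = obs[["r2"]],
                             Dprime = obs[["Dprime"]], p_perm = p,
                             linked = linked, stringsAsFactors = FALSE)
  }
  if (skipped) warnf("%d locus pair(s) skipped (monomorphic or < 4 complete)", skipped)
  res <- do.call(rbind, out[seq_len(idx)])
  if (is.null(res)) res <- data.frame(locusA = character(), locusB = character(),
                                      chromA = integer(), chromB = integer(),
                                      distance_bp = numeric(), r2 = numeric(),
                                      Dprime = numeric(), p_perm = numeric(),
                                      linked = logical())
  class(res) <- c("ld_pairs", class(res))
  res
}

#' Background LD level
#'
#' The 99th percentile (type-7 linear interpolation) of r2 over unlinked
#' (different-chromosome) pairs; linked-pair r2 above this level is taken
#' to reflect physical linkage.
#'
#' @param pairs an `ld_pairs` table.
#' @param prob percentile (default 0.99).
#' @return numeric scalar.
#' @export
background_ld <- function(pairs, prob = 0.99) {
  un <- pairs$r2[!pairs$linked]
  if (!length(un)) stopf("no unlinked pairs to estimate background LD")
  stats::quantile(un, prob, type = 7, names = FALSE)
}

#' Logarithmic LD decay fit
#'
#' Least-squares fit of r2 = a + b ln(distance) over linked, significant
#' pairs (permutation p below `p_max`); zero distances are replaced by
#' 1e-7 before the log transform.  The decay distance solves
#' a + b ln(d) = threshold (NA with a warning when b >= 0 or the curve
#' never reaches the threshold from above).
#'
#' @param pairs `ld_pairs` table.
#' @param threshold r2 threshold (default 0.2).
#' @param p_max permutation-significance cutoff (default 0.001).
#' @param dist_unit distance unit of the fit, `"kb"` (default), `"bp"` or
#'   `"Mb"`.
#' @return list with `a`, `b`, `threshold`, `decay_distance` (in
#'   `dist_unit`), `n_pairs`, `dist_unit`.
#' @export
decay_fit <- function(pairs, threshold = 0.2, p_max = 0.001,
                      dist_unit = c("kb", "bp", "Mb")) {
  dist_unit <- match.arg(dist_unit)
  sel <- pairs[pairs$linked & pairs$p_perm < p_max, , drop = FALSE]
  div <- switch(dist_unit, bp = 1, kb = 1e3, Mb = 1e6)
  d <- sel$distance_bp / div
  if (nrow(sel) < 3 || length(unique(d)) < 3) {
    stopf("decay fit needs >= 3 linked significant pairs at distinct distances")
  }
  d[d == 0] <- 1e-7
  fit <- stats::lm.fit(cbind(1, log(d)), sel$r2)
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  if (!is.finite(b) || b >= 0) {
    warnf("non-decaying LD curve (b >= 0); decay distance undefined")
    dd <- NA_real_
  } else {
    dd <- exp((threshold - a) / b)
    if (a <= threshold) {
      warnf("fitted curve starts below the threshold; decay distance undefined")
      dd <- NA_real_
    }
  }
  list(a = unname(a), b = unname(b), threshold = threshold,
       decay_distance = unname(dd), n_pairs = nrow(sel), dist_unit = dist_unit)
}
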
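## Descriptive statistics, RCBD ANOVA, entry means and multivariate
## summaries of the multi-environment phenotype table.

#' Summary statistics per trait group
#'
#' Min, quartiles (type-7 linear interpolation), max, mean and SD (n-1
#' denominator) of phenotype values, grouped by the given keys.
#'
#' @param pheno phenotype table (see [read_phenotypes()]).
#' @param by grouping columns (default `"trait"`).
#' @return data frame with one row per group and columns `min`, `q1`,
#'   `median`, `q3`, `max`, `mean`, `sd`, `n`.
#' @export
summarize_traits <- function(pheno, by = "trait") {
  miss <- setdiff(by, names(pheno))
  if (length(miss)) stopf("grouping column(s) not found: %s", paste(miss, collapse = ", "))
  key <- interaction(pheno[by], drop = TRUE, sep = ":")
  groups <- split(pheno$value, key)
  keys <- do.call(rbind, strsplit(names(groups), ":", fixed = TRUE))
  stats <- t(vapply(groups, function(v) {
    q <- stats::quantile(v, c(0, .25, .5, .75, 1), type = 7, names = FALSE)
    c(q, mean(v), if (length(v) > 1) stats::sd(v) else 0, length(v))
  }, numeric(8)))
  out <- data.frame(keys, stats, stringsAsFactors = FALSE)
  names(out) <- c(by, "min", "q1", "median", "q3", "max", "mean", "sd", "n")
  rownames(out) <- NULL
  out
}

#' RCBD analysis of variance
#'
#' Randomized-complete-block ANOVA of one trait within each environment
#' (genotype, replication/block, error strata; exact sums-of-squares
#' partition).  The layout must be balanced: each genotype observed once
#' per replicate within an environment.
#'
#' @param pheno phenotype table.
#' @param trait trait code to analyse.
#' @param env_keys columns defining an environment (default location+year).
#' @return data frame with columns `environment`, `source`, `df`, `SS`,
#'   `MS`, `F`, `p`.
#' @export
rcbd_anova <- function(pheno, trait, env_keys = c("location", "year")) {
  d <- pheno[pheno$trait == trait, , drop = FALSE]
  if (!nrow(d)) stopf("no records for trait %s", trait)
  env <- interaction(d[env_keys], drop = TRUE, sep = ":")
  res <- lapply(split(d, env), function(e) {
    g <- factor(e$individual); r <- factor(e$replicate)
    if (nlevels(r) < 2) stopf("RCBD requires replication (>=2 blocks)")
    tab <- table(g, r)
    if (any(tab != 1)) stopf("unbalanced genotype x replicate layout in environment")
    y <- e$value
    n <- length(y); gm <- mean(y)
    ss_tot <- sum((y - gm)^2)
    gmeans <- tapply(y, g, mean); rmeans <- tapply(y, r, mean)
    ss_g <- nlevels(r) * sum((gmeans - gm)^2)
    ss_r <- nlevels(g) * sum((rmeans - gm)^2)
    ss_e <- ss_tot - ss_g - ss_r
    df_g <- nlevels(g) - 1L; df_r <- nlevels(r) - 1L
    df_e <- n - 1L - df_g - df_r
    ms <- c(ss_g / df_g, ss_r / df_r, ss_e / df_e)
    Fv <- if (ms[3] > 0) c(ms[1] / ms[3], ms[2] / ms[3]) else c(NA_real_, NA_real_)
    p <- c(stats::pf(Fv[1], df_g, df_e, lower.tail = FALSE),
           stats::pf(Fv[2], df_r, df_e, lower.tail = FALSE))
    data.frame(source = c("genotype", "replication", "error"),
               df = c(df_g, df_r, df_e), SS = c(ss_g, ss_r, ss_e),
               MS = ms, F = c(Fv, NA), p = c(p, NA),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Map(function(nm, df) cbind(environment = nm, df,
                                                   stringsAsFactors = FALSE),
                            names(res), res))
  rownames(out) <- NULL
  out
}

#' Adjusted entry means per individual and trait
#'
#' `mode = "raw"`: arithmetic mean over all environments/replicates.
#' `mode = "shrunk"`: best-linear-unbiased-prediction-style shrinkage of
#' each entry mean toward the grand mean with weight
#' sigma2_g / (sigma2_g + sigma2_res / r_i), using variance components
#' from the replicated layout (method-of-moments; negative sigma2_g
#' clamped to 0 with a warning).
#'
#' @param pheno phenotype table.
#' @param mode `"raw"` or `"shrunk"`.
#' @return numeric matrix individuals x traits (NA where no records).
#' @export
entry_means <- function(pheno, mode = c("shrunk", "raw")) {
  mode <- match.arg(mode)
  ids <- sort(unique(pheno$individual))
  traits <- intersect(TRAIT_CODES, unique(pheno$trait))
  M <- matrix(NA_real_, length(ids), length(traits),
              dimnames = list(ids, traits))
  for (tr in traits) {
    d <- pheno[pheno$trait == tr, ]
    raw <- tapply(d$value, d$individual, mean)
    ni <- tapply(d$value, d$individual, length)
    if (mode == "raw") { M[names(raw), tr] <- raw; next }
    grand <- mean(d$value)
    within <- tapply(d$value, d$individual, function(v)
      if (length(v) > 1) stats::var(v) else NA_real_)
    s2_res <- mean(within, na.rm = TRUE)
    if (!is.finite(s2_res)) s2_res <- 0
    rbar <- mean(ni)
    s2_g <- stats::var(raw) - s2_res / rbar
    if (is.na(s2_g)) s2_g <- 0
    if (s2_g < 0) { warnf("negative genetic variance for %s clamped to 0", tr); s2_g <- 0 }
    w <- if (s2_res == 0) rep(1, length(raw)) else s2_g / (s2_g + s2_res / ni)
    M[names(raw), tr] <- grand + w * (raw - grand)
  }
  M
}

#' Pairwise trait correlations with significance
#'
#' Pearson correlation on pairwise-complete entry means, with two-sided p
#' from the t transform.  Zero-variance traits yield NA with a warning.
#'
#' @param means entry-mean matrix from [entry_means()].
#' @return list with matrices `r`, `p` and `n`.
#' @export
trait_correlations <- function(means) {
  traits <- colnames(means)
  k <- length(traits)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(means[, c(i, j)])
    nn <- sum(ok); n[i, j] <- nn
    if (nn < 3) next
    vi <- means[ok, i]; vj <- means[ok, j]
    if (stats::sd(vi) == 0 || stats::sd(vj) == 0) {
      warnf("zero-variance trait in correlation (%s, %s)", traits[i], traits[j])
      next
    }
    rr <- stats::cor(vi, vj)
    r[i, j] <- rr
    if (i == j) { p[i, j] <- 0; next }
    tt <- rr * sqrt((nn - 2) / max(1 - rr^2, .Machine$double.eps))
    p[i, j] <- 2 * stats::pt(abs(tt), nn - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n)
}

#' Principal components of the trait space
#'
#' Eigendecomposition of the trait correlation matrix; scores are the
#' standardized data times the loadings.  Sign convention: the
#' largest-magnitude loading of each component is positive.  Constant
#' traits are excluded with a warning.
#'
#' @param means entry-mean matrix from [entry_means()].
#' @return list with `eigenvalues`, `loadings`, `scores`, `percent` and
#'   `cumulative` percent variance.
#' @export
trait_pca <- function(means) {
  means <- means[stats::complete.cases(means), , drop = FALSE]
  if (nrow(means) < 3) stopf("PCA requires >= 3 complete individuals")
  sds <- apply(means, 2, stats::sd)
  if (any(sds == 0)) {
    warnf("constant trait(s) excluded from PCA: %s",
          paste(colnames(means)[sds == 0], collapse = ", "))
    means <- means[, sds > 0, drop = FALSE]
  }
  if (ncol(means) < 2) stopf("PCA requires >= 2 non-constant traits")
  Z <- scale(means)
  R <- stats::cor(means)
  eg <- eigen(R, symmetric = TRUE)
  load <- eg$vectors
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(means), paste0("PC", seq_len(ncol(load))))
  scores <- Z %*% load
  ev <- pmax(eg$values, 0)
  pct <- 100 * ev / sum(ev)
  list(eigenvalues = ev, loadings = load, scores = scores,
       percent = pct, cumulative = cumsum(pct))
}
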
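## Q+K mixed linear model association mapping.
##
## Kinship is simple-matching similarity on band calls, min-rescaled.
## The mixed model y = Xb + u + e, u ~ N(0, sg2 K), e ~ N(0, se2 I) is
## fitted by REML through a single spectral decomposition of K with 1-D
## optimisation of the variance ratio, then every band is tested by
## generalized least squares with the variance components held fixed
## across markers (P3D).

#' Kinship matrix from band data
#'
#' Pairwise simple-matching similarity S over non-missing band calls,
#' rescaled to K = max(0, (S - S_min)/(1 - S_min)) with unit diagonal.
#' If the result is not positive semidefinite a ridge of 1e-6 is added
#' (with a message).
#'
#' @param bands band matrix.
#' @return individuals x individuals kinship matrix.
#' @export
kinship <- function(bands) {
  validate_band_matrix(bands)
  n <- nrow(bands)
  obs <- !is.na(bands)
  if (any(rowSums(obs) == 0)) {
    stopf("individual(s) with all-missing genotype: %s",
          paste(rownames(bands)[rowSums(obs) == 0], collapse = ", "))
  }
  X <- bands; X[!obs] <- 0
  O <- obs * 1
  ## matches = x==1 & y==1 plus x==0 & y==0 (both observed)
  both1 <- X %*% t(X)
  both_obs <- O %*% t(O)
  one1 <- X %*% t(O) + O %*% t(X) - 2 * both1  # exactly one of the pair is 1
  S <- (both_obs - one1) / both_obs
  smin <- min(S)
  K <- if (smin < 1) pmax((S - smin) / (1 - smin), 0) else S
  diag(K) <- 1
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    message("kinship not PSD; adding ridge 1e-6")
    K <- K + diag(1e-6, n)
  }
  dimnames(K) <- list(rownames(bands), rownames(bands))
  K
}

## drop collinear columns of a design matrix (QR with pivoting)
drop_collinear <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    message(sprintf("dropping %d collinear fixed-effect column(s)",
                    ncol(X) - qrX$rank))
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

#' REML fit of the single-random-effect mixed model
#'
#' Eigendecomposes K once and profiles the REML log-likelihood over the
#' variance ratio lambda = se2/sg2 on a log scale in [1e-5, 1e5].
#'
#' @param y phenotype vector (finite).
#' @param X fixed-effect design matrix (intercept plus Q covariates);
#'   collinear columns are dropped with a message.
#' @param K kinship matrix matching `y`.
#' @return object of class `mlm_model`: list with `sigma2_g`, `sigma2_e`,
#'   `lambda`, `loglik` (REML), `eigen` (U, d), `X`, `y`.
#' @export
reml_fit <- function(y, X, K) {
  if (any(!is.finite(y))) stopf("non-finite phenotype value")
  n <- length(y)
  if (stats::var(y) == 0) stopf("constant phenotype; variance components undefined")
  if (nrow(K) != n) stopf("kinship dimension does not match phenotype length")
  X <- drop_collinear(cbind(X))
  p <- ncol(X)
  if (n < p + 2) stopf("need n >= number of fixed effects + 2")
  eg <- eigen(K, symmetric = TRUE)
  U <- eg$vectors; d <- pmax(eg$values, 0)
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)

  reml_obj <- function(loglam) {
    lam <- exp(loglam)
    v <- d + lam                       # Var = sg2 (d + lambda)
    w <- 1 / v
    XtW <- Xt * w
    XtWX <- crossprod(Xt, XtW)
    beta <- solve(XtWX, crossprod(XtW, yt))
    r <- yt - Xt %*% beta
    rss <- sum(r^2 * w)
    sg2 <- rss / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * sg2) + 1) + sum(log(v)) +
              determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(reml_obj, c(log(1e-5), log(1e5)), maximum = TRUE,
                         tol = 1e-8)
  lam <- exp(opt$maximum)
  v <- d + lam; w <- 1 / v
  XtW <- Xt * w
  beta <- solve(crossprod(Xt, XtW), crossprod(XtW, yt))
  rss <- sum((yt - Xt %*% beta)^2 * w)
  sg2 <- rss / (n - p)
  se2 <- sg2 * lam
  structure(list(sigma2_g = sg2, sigma2_e = se2, lambda = lam,
                 loglik = opt$objective, eigen = list(U = U, d = d),
                 X = X, y = y),
            class = "mlm_model")
}

#' @export
print.mlm_model <- function(x, ...) {
  cat(sprintf("mlm_model: sigma2_g = %.4g, sigma2_e = %.4g, lambda = %.4g, REML ll = %.2f\n",
              x$sigma2_g, x$sigma2_e, x$lambda, x$loglik))
  invisible(x)
}

#' Mixed-model association scan over all bands
#'
#' Generalized least squares per band with variance components from a
#' fitted [reml_fit()] model held fixed (P3D).  Missing band calls are
#' mean-imputed per band for the test; monomorphic bands are skipped.
#' Returns the band-term F-test p-value, its -log10, the fraction of
#' generalized residual sum of squares explained (r2) and the signed
#' effect estimate.
#'
#' @param model fitted `mlm_model`.
#' @param bands band matrix over the same individuals (rows aligned to
#'   the phenotype order used in the fit).
#' @param map optional marker map (adds marker and position columns).
#' @return data frame: marker, band, effect, F, p, neglog10p, r2.
#' @export
mlm_scan <- function(model, bands, map = NULL) {
  U <- model$eigen$U; d <- model$eigen$d
  lam <- model$lambda
  n <- length(model$y)
  if (nrow(bands) != n) stopf("band matrix does not match phenotype length")
  w <- 1 / sqrt(d + lam)
  yt <- w * crossprod(U, model$y)
  Xt <- w * crossprod(U, model$X)
  qrX <- qr(Xt)
  ry <- stats::resid(stats::lm.fit(Xt, yt))
  rss0 <- sum(ry^2)
  p <- ncol(Xt)

  G <- bands
  freq <- colMeans(G == 1L, na.rm = TRUE)
  mono <- !is.finite(freq) | freq == 0 | freq == 1
  keep <- which(!mono)
  if (!length(keep)) stopf("no polymorphic band to scan")
  G <- G[, keep, drop = FALSE]
  ## mean imputation of missing calls
  for (j in which(colSums(is.na(G)) > 0)) {
    G[is.na(G[, j]), j] <- mean(G[, j], na.rm = TRUE)
  }
  Gt <- w * crossprod(U, G)
  RB <- qr.resid(qrX, Gt)
  bb <- colSums(RB^2)
  by <- as.numeric(crossprod(RB, ry))
  ok <- bb > 1e-12
  eff <- ifelse(ok, by / bb, NA_real_)
  ssx <- ifelse(ok, by^2 / bb, NA_real_)
  rss1 <- rss0 - ssx
  df2 <- n - p - 1L
  Fv <- ssx / (rss1 / df2)
  pv <- stats::pf(Fv, 1, df2, lower.tail = FALSE)
  pv <- pmin(pmax(pv, .Machine$double.xmin), 1)
  band_ids <- colnames(G)
  res <- data.frame(band = band_ids, effect = eff, F = Fv, p = pv,
                    neglog10p = -log10(pv), r2 = ssx / rss0,
                    stringsAsFactors = FALSE)
  res <- res[ok, , drop = FALSE]
  if (!is.null(map)) {
    res$marker <- map$marker[match(res$band, map$band)]
  } else {
    res$marker <- sub("-[0-9]+$", "", res$band)
  }
  rownames(res) <- NULL
  res[, c("marker", "band", "effect", "F", "p", "neglog10p", "r2")]
}

#' Enumerate the 32 genotype/phenotype combinations
#'
#' The Line x Tester design supports 32 combinations of genotype panel
#' and dependent variable:
#' trait phenotype (11): maternal-line genotypes against each tester's F1
#' phenotypes (5), each F1 set against its own phenotypes (5), and the
#' parental set against its own phenotypes (1); GCA (6): parental set
#' plus the five F1 sets, the GCA of a cross's maternal line serving as
#' the F1's value; SCA (5): each F1 set against its crosses' SCA;
#' heterosis (10): maternal-line genotypes (5) and F1-set genotypes (5)
#' against the five heterosis metrics, each metric scanned separately.
#'
#' @param design an [lxt_design()].
#' @return data frame: combination, variable, geno_panel ("PS" or a
#'   tester id), phen_tester (tester id or NA).
#' @export
combination_table <- function(design) {
  tst <- design$testers
  rbind(
    data.frame(combination = seq_along(tst), variable = "phenotype",
               geno_panel = "PS", phen_tester = tst, stringsAsFactors = FALSE),
    data.frame(combination = length(tst) + seq_along(tst), variable = "phenotype",
               geno_panel = tst, phen_tester = tst, stringsAsFactors = FALSE),
    data.frame(combination = 2L * length(tst) + 1L, variable = "phenotype",
               geno_panel = "PS", phen_tester = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(combination = 2L * length(tst) + 2L, variable = "GCA",
               geno_panel = "PS", phen_tester = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(combination = 2L * length(tst) + 2L + seq_along(tst),
               variable = "GCA", geno_panel = tst, phen_tester = tst,
               stringsAsFactors = FALSE),
    data.frame(combination = 3L * length(tst) + 2L + seq_along(tst),
               variable = "SCA", geno_panel = tst, phen_tester = tst,
               stringsAsFactors = FALSE),
    data.frame(combination = 4L * length(tst) + 2L + seq_along(tst),
               variable = "heterosis", geno_panel = "PS", phen_tester = tst,
               stringsAsFactors = FALSE),
    data.frame(combination = 5L * length(tst) + 2L + seq_along(tst),
               variable = "heterosis", geno_panel = tst, phen_tester = tst,
               stringsAsFactors = FALSE))
}

#' Dependent-variable values for one combination
#'
#' Resolves the genotype panel (individual ids) and the per-individual
#' response values for a combination row, trait and (for heterosis)
#' metric.
#'
#' @param combo one row of [combination_table()].
#' @param design the design.
#' @param means entry-mean matrix.
#' @param ca_list named list of [combining_ability()] results per trait.
#' @param het heterosis table from [heterosis_table()].
#' @param trait trait code.
#' @param metric heterosis metric ("MP","HB","HI","K3","K4"); ignored for
#'   other variables.
#' @return list with `ids` (genotype panel) and `y` (named response).
#' @export
combination_values <- function(combo, design, means, ca_list, het,
                               trait, metric = "MP") {
  crs <- design$crosses
  panel_f1 <- function(t) crs$f1[crs$tester == t]
  panel_line_of <- function(f1s) crs$line[match(f1s, crs$f1)]
  v <- combo$variable
  gp <- combo$geno_panel
  pt <- combo$phen_tester

  if (v == "phenotype") {
    if (gp == "PS" && is.na(pt)) {
      ids <- design$lines; y <- means[ids, trait]
    } else if (gp == "PS") {
      ids <- design$lines
      y <- means[f1_of(design, ids, pt), trait]
    } else {
      ids <- panel_f1(gp); y <- means[ids, trait]
    }
  } else if (v == "GCA") {
    ca <- ca_list[[trait]]
    if (is.null(ca)) stopf("combination %d blocked: combining ability for %s missing",
                           combo$combination, trait)
    if (gp == "PS") {
      ids <- design$lines; y <- ca$gca_line[ids]
    } else {
      ids <- panel_f1(gp); y <- ca$gca_line[panel_line_of(ids)]
    }
  } else if (v == "SCA") {
    ca <- ca_list[[trait]]
    if (is.null(ca)) stopf("combination %d blocked: combining ability for %s missing",
                           combo$combination, trait)
    ids <- panel_f1(gp)
    y <- ca$sca[cbind(panel_line_of(ids), rep(gp, length(ids)))]
  } else if (v == "heterosis") {
    if (is.null(het)) stopf("combination %d blocked: heterosis table missing",
                            combo$combination)
    h <- het[het$trait == trait & het$tester == pt, , drop = FALSE]
    if (gp == "PS") {
      ids <- design$lines
      y <- h[[metric]][match(f1_of(design, ids, pt), h$f1)]
    } else {
      ids <- panel_f1(gp)
      y <- h[[metric]][match(ids, h$f1)]
    }
  } else stopf("unknown variable %s", v)
  list(ids = ids, y = stats::setNames(as.numeric(y), ids))
}

#' Run the full association scan over all combinations
#'
#' For every combination, trait (and heterosis metric), fits the Q+K
#' mixed model on the combination's genotype panel and scans all bands.
#' Kinship is computed once per distinct genotype panel; Q covariates are
#' taken from `Q` (rows subset to the panel, last column dropped to avoid
#' collinearity with the intercept) or omitted when `Q` is NULL (K-only
#' model).
#'
#' @param bands band matrix covering all individuals in the design.
#' @param map marker map.
#' @param design the design.
#' @param means entry-mean matrix.
#' @param ca_list named list of [combining_ability()] per trait.
#' @param het heterosis table.
#' @param traits trait codes to scan.
#' @param metrics heterosis metrics to scan (default all five).
#' @param Q optional full membership matrix (rownames = individual ids).
#' @param combos subset of combination ids (default all).
#' @return data frame of association records: combination, variable,
#'   metric, trait, tester, marker, band, effect, p, neglog10p, r2.
#' @export
run_all <- function(bands, map, design, means, ca_list, het,
                    traits = names(ca_list), metrics = c("MP", "HB", "HI", "K3", "K4"),
                    Q = NULL, combos = NULL) {
  ct <- combination_table(design)
  if (!is.null(combos)) ct <- ct[ct$combination %in% combos, , drop = FALSE]
  panels <- unique(ct$geno_panel)
  Ks <- list(); panel_ids <- list()
  for (gp in panels) {
    ids <- if (gp == "PS") design$lines else design$crosses$f1[design$crosses$tester == gp]
    miss <- setdiff(ids, rownames(bands))
    if (length(miss)) stopf("band matrix missing individual(s): %s",
                            paste(utils::head(miss, 5), collapse = ", "))
    panel_ids[[gp]] <- ids
    Ks[[gp]] <- kinship(bands[ids, , drop = FALSE])
  }
  out <- list(); oi <- 0L
  for (ri in seq_len(nrow(ct))) {
    combo <- ct[ri, ]
    mets <- if (combo$variable == "heterosis") metrics else "value"
    for (tr in traits) for (met in mets) {
      cv <- combination_values(combo, design, means, ca_list, het, tr,
                               metric = if (met == "value") "MP" else met)
      ids <- cv$ids; y <- cv$y
      ok <- is.finite(y)
      if (sum(ok) < 10 || stats::var(y[ok]) == 0) next
      ids <- ids[ok]; y <- y[ok]
      Kp <- Ks[[combo$geno_panel]][ids, ids]
      X <- matrix(1, length(ids), 1)
      if (!is.null(Q)) {
        Qp <- Q[ids, , drop = FALSE]
        if (ncol(Qp) > 1) X <- cbind(X, Qp[, -ncol(Qp), drop = FALSE])
      }
      model <- reml_fit(y, X, Kp)
      sc <- mlm_scan(model, bands[ids, , drop = FALSE], map)
      if (!nrow(sc)) next
      oi <- oi + 1L
      out[[oi]] <- cbind(combination = combo$combination,
                         variable = combo$variable,
                         metric = met, trait = tr,
                         tester = combo$phen_tester %||% NA_character_,
                         sc, stringsAsFactors = FALSE)
    }
  }
  if (!oi) stopf("no scans produced any records")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
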
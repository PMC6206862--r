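## Line x Tester combining ability and the five heterosis statistics.

#' Line x Tester combining-ability decomposition
#'
#' Computes, for one trait, the grand mean mu, general combining abilities
#' g_i (lines) and g_j (testers), and specific combining abilities s_ij,
#' from cross means:
#'   g_i = xbar_i.. - mu,  g_j = xbar_.j. - mu,
#'   s_ij = xbar_ij - xbar_i.. - xbar_.j. + mu,
#' together with the L x T ANOVA (replications, crosses split into lines,
#' testers, line x tester, error) and variance components.  With balanced
#' data mu + g_i + g_j + s_ij reconstructs every cross mean exactly and
#' all g and s sum to zero.
#'
#' Variance components (replicated data only): sigma2_sca =
#' (MS_lxt - MS_error)/r; per-parent-type GCA components from the
#' half-sib covariances (MS_lines - MS_lxt)/(r t) and
#' (MS_testers - MS_lxt)/(r l); the combined sigma2_gca is
#' ((MS_lines + MS_testers)/2 - MS_lxt) / (r (l + t)/2).  Negative
#' estimates are clamped to 0 with a warning.
#'
#' @param x either a phenotype table (long format, replicated) or an
#'   entry-mean matrix from [entry_means()].
#' @param design an [lxt_design()].
#' @param trait trait code.
#' @return object of class `combining_ability`: list with `trait`, `mu`,
#'   `gca_line`, `gca_tester`, `sca` (line x tester matrix), `anova`,
#'   `sigma2_gca`, `sigma2_gca_line`, `sigma2_gca_tester`, `sigma2_sca`,
#'   `r` (effective replications).
#' @export
combining_ability <- function(x, design, trait) {
  if (length(design$testers) < 2) {
    stopf("testers stratum undefined with a single tester")
  }
  crs <- design$crosses
  l <- length(design$lines); t <- length(design$testers)

  if (is.matrix(x)) {
    if (!trait %in% colnames(x)) stopf("trait %s not in entry means", trait)
    cm <- x[, trait]
    missing_f1 <- crs$f1[!(crs$f1 %in% names(cm)) | is.na(cm[crs$f1])]
    if (length(missing_f1)) stopf("missing cross mean(s): %s",
                                  paste(missing_f1, collapse = ", "))
    y <- cm[crs$f1]; blocks <- NULL
  } else {
    d <- x[x$trait == trait & x$individual %in% crs$f1, , drop = FALSE]
    missing_f1 <- setdiff(crs$f1, unique(d$individual))
    if (length(missing_f1)) stopf("missing cross mean(s): %s",
                                  paste(missing_f1, collapse = ", "))
    blocks <- interaction(d$location, d$year, d$replicate, drop = TRUE)
    y <- d$value
  }

  if (is.null(blocks)) {
    cross_mean <- stats::setNames(y, crs$f1)
  } else {
    cross_mean <- tapply(y, factor(d$individual, levels = crs$f1), mean)
  }
  mu <- mean(cross_mean)
  M <- matrix(NA_real_, nrow = l, ncol = t,
              dimnames = list(design$lines, design$testers))
  M[cbind(match(crs$line, design$lines), match(crs$tester, design$testers))] <-
    cross_mean[crs$f1]
  if (anyNA(M)) stopf("design is not a complete line x tester grid")
  gl <- rowMeans(M) - mu
  gt <- colMeans(M) - mu
  S <- M - outer(rowMeans(M), rep(1, t)) - outer(rep(1, l), colMeans(M)) + mu

  ## ANOVA
  ss_l <- t * sum((rowMeans(M) - mu)^2)
  ss_t <- l * sum((colMeans(M) - mu)^2)
  ss_lt <- sum(S^2)
  ss_cr <- ss_l + ss_t + ss_lt
  df_l <- l - 1L; df_t <- t - 1L; df_lt <- df_l * df_t; df_cr <- l * t - 1L

  if (!is.null(blocks)) {
    r <- nlevels(blocks)
    gm_all <- mean(y)
    ss_tot <- sum((y - gm_all)^2)
    bmeans <- tapply(y, blocks, mean)
    ss_rep <- l * t * sum((bmeans - gm_all)^2)
    ## cross SS on plot scale
    ss_cr_plot <- r * sum((cross_mean - mean(cross_mean))^2)
    ss_l_plot <- ss_l * r; ss_t_plot <- ss_t * r; ss_lt_plot <- ss_lt * r
    ss_err <- ss_tot - ss_rep - ss_cr_plot
    df_rep <- r - 1L
    df_err <- length(y) - 1L - df_rep - df_cr
    src <- c("replications", "crosses", "lines", "testers", "line_x_tester", "error")
    dfv <- c(df_rep, df_cr, df_l, df_t, df_lt, df_err)
    ssv <- c(ss_rep, ss_cr_plot, ss_l_plot, ss_t_plot, ss_lt_plot, ss_err)
    msv <- ssv / dfv
    ms_e <- msv[6]
    Fv <- c(msv[1:2] / ms_e, msv[3] / msv[5], msv[4] / msv[5], msv[5] / ms_e, NA)
    dfden <- c(df_err, df_err, df_lt, df_lt, df_err, NA)
    pv <- stats::pf(Fv, dfv, dfden, lower.tail = FALSE)
    anova <- data.frame(source = src, df = dfv, SS = ssv, MS = msv,
                        F = Fv, p = pv, stringsAsFactors = FALSE)
    clamp <- function(v, nm) {
      if (is.finite(v) && v < 0) { warnf("negative %s clamped to 0", nm); 0 } else v
    }
    s2_sca <- clamp((msv[5] - ms_e) / r, "sigma2_sca")
    s2_g_l <- clamp((msv[3] - msv[5]) / (r * t), "sigma2_gca_line")
    s2_g_t <- clamp((msv[4] - msv[5]) / (r * l), "sigma2_gca_tester")
    s2_gca <- clamp(((msv[3] + msv[4]) / 2 - msv[5]) / (r * (l + t) / 2),
                    "sigma2_gca")
  } else {
    r <- 1L
    src <- c("crosses", "lines", "testers", "line_x_tester")
    anova <- data.frame(source = src, df = c(df_cr, df_l, df_t, df_lt),
                        SS = c(ss_cr, ss_l, ss_t, ss_lt),
                        MS = c(ss_cr, ss_l, ss_t, ss_lt) / c(df_cr, df_l, df_t, df_lt),
                        F = c(NA, ss_l / df_l / (ss_lt / df_lt),
                              ss_t / df_t / (ss_lt / df_lt), NA),
                        p = NA_real_, stringsAsFactors = FALSE)
    anova$p[2] <- stats::pf(anova$F[2], df_l, df_lt, lower.tail = FALSE)
    anova$p[3] <- stats::pf(anova$F[3], df_t, df_lt, lower.tail = FALSE)
    s2_sca <- s2_g_l <- s2_g_t <- s2_gca <- NA_real_
  }

  structure(list(trait = trait, mu = mu, gca_line = gl, gca_tester = gt,
                 sca = S, anova = anova, sigma2_gca = s2_gca,
                 sigma2_gca_line = s2_g_l, sigma2_gca_tester = s2_g_t,
                 sigma2_sca = s2_sca, r = r),
            class = "combining_ability")
}

#' @export
print.combining_ability <- function(x, ...) {
  cat(sprintf("Combining ability for %s: mu = %.4g, %d lines, %d testers\n",
              x$trait, x$mu, length(x$gca_line), length(x$gca_tester)))
  print(x$anova, row.names = FALSE)
  invisible(x)
}

#' One heterosis statistic for a single cross
#'
#' MP  = 100 (F1 - MPv)/MPv, MPv = (P1 + P2)/2 (mid-parent heterosis);
#' HB  = 100 (F1 - BP)/BP, BP = better parent in the trait's desired
#'       direction (heterobeltiosis);
#' HI  = 100 F1 / MPv (heterosis index);
#' K3/K4 = 100 (F1 - check)/check (standard heterosis over a check).
#'
#' @param f1 F1 value.
#' @param p1,p2 parent values (line, tester).
#' @param check check value (for metrics K3/K4).
#' @param metric one of "MP", "HB", "HI", "K3", "K4".
#' @param direction +1 if higher values are better, -1 if lower.
#' @return percentage (NA with a warning on zero denominators or missing
#'   inputs).
#' @export
heterosis <- function(f1, p1 = NA, p2 = NA, check = NA,
                      metric = c("MP", "HB", "HI", "K3", "K4"),
                      direction = 1) {
  metric <- match.arg(metric)
  den_na <- function(x) {
    if (is.na(x)) return(NA_real_)
    if (x == 0) { warnf("zero denominator in heterosis metric %s", metric); return(NA_real_) }
    x
  }
  if (metric %in% c("K3", "K4")) {
    chk <- den_na(check)
    if (is.na(f1) || is.na(chk)) return(NA_real_)
    return(100 * (f1 - chk) / chk)
  }
  if (is.na(f1) || is.na(p1) || is.na(p2)) return(NA_real_)
  mpv <- (p1 + p2) / 2
  switch(metric,
         MP = { mpv <- den_na(mpv); if (is.na(mpv)) NA_real_ else 100 * (f1 - mpv) / mpv },
         HI = { mpv <- den_na(mpv); if (is.na(mpv)) NA_real_ else 100 * f1 / mpv },
         HB = {
           bp <- if (direction >= 0) max(p1, p2) else min(p1, p2)
           bp <- den_na(bp)
           if (is.na(bp)) NA_real_ else 100 * (f1 - bp) / bp
         })
}

#' Heterosis table over all crosses and traits
#'
#' Computes MP, HB, HI and standard heterosis over the two checks for
#' every cross x trait.  When a phenotype table is supplied, standard
#' heterosis is environment-matched: K3/K4 are computed per
#' (location, year) against that environment's check mean and then
#' averaged over environments; MP/HB/HI use entry means.  With an
#' entry-mean matrix, overall means are used throughout.
#'
#' @param x phenotype table or entry-mean matrix.
#' @param design an [lxt_design()] with checks K3 and K4.
#' @param directions named direction vector (default [TRAIT_DIRECTIONS]).
#' @param traits trait codes (default: those present).
#' @return data frame (line, tester, f1, trait, MP, HB, HI, K3, K4).
#' @export
heterosis_table <- function(x, design, directions = TRAIT_DIRECTIONS,
                            traits = NULL) {
  pheno <- if (!is.matrix(x)) x else NULL
  means <- if (is.matrix(x)) x else entry_means(x, mode = "raw")
  traits <- traits %||% colnames(means)
  crs <- design$crosses
  have_checks <- all(c("K3", "K4") %in% names(design$checks)) &&
    all(design$checks[c("K3", "K4")] %in% rownames(means))
  if (!have_checks) warnf("check records absent: K3/K4 columns will be NA")

  env_check <- function(tr, chk_id) {
    ## mean of 100*(F1_env - check_env)/check_env over environments
    d <- pheno[pheno$trait == tr, ]
    env <- interaction(d$location, d$year, drop = TRUE)
    cm <- tapply(d$value[d$individual == chk_id],
                 env[d$individual == chk_id], mean)
    fm <- tapply(d$value, list(factor(d$individual), env), mean)
    common <- names(cm)[!is.na(cm) & cm != 0]
    if (!length(common)) return(rep(NA_real_, nrow(crs)))
    vals <- fm[crs$f1, common, drop = FALSE]
    ratios <- sweep(sweep(vals, 2, cm[common], "-"), 2, cm[common], "/") * 100
    rowMeans(ratios, na.rm = TRUE)
  }

  out <- vector("list", length(traits))
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    dirn <- directions[[tr]] %||% 1
    f1v <- means[match(crs$f1, rownames(means)), tr]
    p1v <- means[match(crs$line, rownames(means)), tr]
    p2v <- means[match(crs$tester, rownames(means)), tr]
    mpv <- (p1v + p2v) / 2
    bp <- if (dirn >= 0) pmax(p1v, p2v) else pmin(p1v, p2v)
    MP <- ifelse(is.na(mpv) | mpv == 0, NA, 100 * (f1v - mpv) / mpv)
    HI <- ifelse(is.na(mpv) | mpv == 0, NA, 100 * f1v / mpv)
    HB <- ifelse(is.na(bp) | bp == 0, NA, 100 * (f1v - bp) / bp)
    if (have_checks) {
      if (!is.null(pheno)) {
        K3 <- env_check(tr, design$checks[["K3"]])
        K4 <- env_check(tr, design$checks[["K4"]])
      } else {
        c3 <- means[design$checks[["K3"]], tr]
        c4 <- means[design$checks[["K4"]], tr]
        K3 <- if (is.na(c3) || c3 == 0) rep(NA_real_, length(f1v)) else 100 * (f1v - c3) / c3
        K4 <- if (is.na(c4) || c4 == 0) rep(NA_real_, length(f1v)) else 100 * (f1v - c4) / c4
      }
    } else K3 <- K4 <- rep(NA_real_, length(f1v))
    out[[ti]] <- data.frame(line = crs$line, tester = crs$tester, f1 = crs$f1,
                            trait = tr, MP = MP, HB = HB, HI = HI,
                            K3 = K3, K4 = K4, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
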
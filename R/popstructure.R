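## Admixture-model Bayesian clustering of binary band data.
##
## Each individual's band row is treated as a set of haploid observations
## (one allele draw per band locus), matching the single-row 0/1 coding of
## dominant markers.  The Gibbs sampler alternates:
##   z[i,b] | q, p   ~ Categorical over K (ancestry of each band copy)
##   p[k,b] | z, x   ~ Beta with a correlated-frequency prior around the
##                     sample frequency with drift parameter F
##   q[i,]  | z      ~ Dirichlet(alpha + per-individual ancestry counts)
## LnP(D) is estimated as mean(lnL) - var(lnL)/2 over post-burn-in sweeps.

#' Admixture-model MCMC for one K
#'
#' @param bands band matrix (0/1/NA).
#' @param K number of subpopulations (>= 1).
#' @param burnin burn-in sweeps.
#' @param reps post-burn-in sweeps.
#' @param seed integer seed (runs are deterministic under it).
#' @param alpha Dirichlet concentration of the admixture prior.
#' @param drift drift parameter F of the correlated-frequency prior.
#' @return object of class `structure_run`: list with `K`, `seed`,
#'   `burnin`, `reps`, `LnPD`, `Q` (individuals x K posterior-mean
#'   membership), `loglik` (post-burn-in trace).
#' @export
admixture_mcmc <- function(bands, K, burnin = 1000L, reps = 2000L,
                           seed = 1L, alpha = 1.0, drift = 0.05) {
  validate_band_matrix(bands)
  n <- nrow(bands)
  if (K < 1) stopf("K must be >= 1")
  if (K > n) stopf("K (%d) exceeds number of individuals (%d)", K, n)
  allmiss <- colSums(!is.na(bands)) == 0
  if (any(allmiss)) {
    warnf("dropping %d all-missing band column(s)", sum(allmiss))
    bands <- bands[, !allmiss, drop = FALSE]
  }
  poly <- apply(bands, 2, function(v) length(unique(v[!is.na(v)])) > 1)
  if (K > 1 && sum(poly) < 2) stopf("need >= 2 polymorphic band columns")
  B <- ncol(bands)
  X <- bands; obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0L

  set.seed(seed)
  if (K == 1) {
    ## closed-form degenerate case: Q is a column of ones; LnPD from the
    ## posterior-mean frequencies
    phat <- (colSums(X0) + 0.5) / (colSums(obs) + 1)
    ll <- sum(obs * (X0 * log(phat)[col(X)] + (1 - X0) * log(1 - phat)[col(X)]))
    Q <- matrix(1, n, 1, dimnames = list(rownames(bands), "Q1"))
    return(structure(list(K = 1L, seed = seed, burnin = burnin, reps = reps,
                          LnPD = ll, Q = Q, loglik = ll),
                     class = "structure_run"))
  }

  ## correlated-frequency prior around the observed sample frequency
  u <- pmin(pmax(colSums(X0) / pmax(colSums(obs), 1), 0.02), 0.98)
  a0 <- u * (1 - drift) / drift
  b0 <- (1 - u) * (1 - drift) / drift

  p <- matrix(stats::rbeta(K * B, a0[col(matrix(0, K, B))],
                           b0[col(matrix(0, K, B))]), K, B)
  q <- matrix(stats::rgamma(n * K, alpha, 1), n, K)
  q <- q / rowSums(q)

  Qsum <- matrix(0, n, K)
  lls <- numeric(reps)
  total <- burnin + reps
  W <- vector("list", K)
  for (sweep in seq_len(total)) {
    ## per-component observation weights q_ik * p_kb^x (1-p_kb)^(1-x);
    ## note p^x (1-p)^(1-x) = (1-p) + x (2p - 1) for binary x
    tot <- matrix(0, n, B)
    for (k in seq_len(K)) {
      pk <- pmin(pmax(p[k, ], 1e-9), 1 - 1e-9)
      lik <- sweep(X0, 2, 2 * pk - 1, "*")
      lik <- sweep(lik, 2, 1 - pk, "+")
      W[[k]] <- q[, k] * lik
      tot <- tot + W[[k]]
    }
    ## sample z via inverse CDF across K
    U <- matrix(stats::runif(n * B), n, B) * tot
    z <- matrix(1L, n, B)
    acc <- W[[1]]
    for (k in seq_len(K - 1)) {
      z <- z + (U > acc)
      acc <- acc + W[[k + 1]]
    }
    ## observed-data log-likelihood of the (p, q) state used this sweep
    if (sweep > burnin) lls[sweep - burnin] <- sum(log(tot[obs]))

    ## update p and q from ancestry counts (missing cells contribute none)
    m_ik <- matrix(0, n, K)
    for (k in seq_len(K)) {
      sel <- (z == k) & obs
      n1k <- colSums(sel & (X0 == 1L))
      ntotk <- colSums(sel)
      m_ik[, k] <- rowSums(sel)
      p[k, ] <- stats::rbeta(B, a0 + n1k, b0 + ntotk - n1k)
    }
    g <- matrix(stats::rgamma(n * K, alpha + m_ik, 1), n, K)
    q <- g / rowSums(g)

    if (sweep > burnin) Qsum <- Qsum + q
  }
  Q <- Qsum / reps
  dimnames(Q) <- list(rownames(bands), paste0("Q", seq_len(K)))
  LnPD <- mean(lls) - stats::var(lls) / 2
  structure(list(K = as.integer(K), seed = seed, burnin = burnin, reps = reps,
                 LnPD = LnPD, Q = Q, loglik = lls),
            class = "structure_run")
}

#' @export
print.structure_run <- function(x, ...) {
  cat(sprintf("structure_run: K = %d, LnP(D) = %.2f, %d individuals\n",
              x$K, x$LnPD, nrow(x$Q)))
  invisible(x)
}

#' Evanno delta-K model selection
#'
#' Over replicate runs grouped by K:
#'   L'(K)  = mean LnPD(K) - mean LnPD(K-1)
#'   |L''(K)| = |mean LnPD(K+1) - 2 mean LnPD(K) + mean LnPD(K-1)|
#'   deltaK(K) = |L''(K)| / SD_runs(LnPD(K))
#' The selected K maximizes deltaK; if no deltaK is defined (e.g. LnPD
#' exactly linear in K, or zero SD everywhere) the smallest K is returned
#' with a warning.
#'
#' @param runs list of `structure_run` objects (>= 2 runs per K, >= 3
#'   consecutive K values).
#' @return list with `table` (per-K data frame: K, mean_LnPD, sd_LnPD,
#'   Lprime, Lsecond, deltaK) and `selected_K`.
#' @export
evanno <- function(runs) {
  Ks <- vapply(runs, function(r) r$K, integer(1))
  ln <- vapply(runs, function(r) r$LnPD, numeric(1))
  uk <- sort(unique(Ks))
  if (length(uk) < 3) stopf("Evanno needs >= 3 consecutive K values")
  if (any(diff(uk) != 1)) stopf("K values must be consecutive")
  nruns <- table(factor(Ks, levels = uk))
  if (any(nruns < 2)) stopf("Evanno needs >= 2 runs per K")
  mean_ln <- tapply(ln, factor(Ks, levels = uk), mean)
  sd_ln <- tapply(ln, factor(Ks, levels = uk), stats::sd)
  m <- length(uk)
  lp <- c(NA, diff(mean_ln))
  lpp <- rep(NA_real_, m)
  dk <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    if (i == 1 || i == m) next
    lpp[i] <- abs(mean_ln[i + 1] - 2 * mean_ln[i] + mean_ln[i - 1])
    if (is.finite(sd_ln[i]) && sd_ln[i] > 0) dk[i] <- lpp[i] / sd_ln[i]
    else warnf("SD of LnP(D) is 0 at K = %d; deltaK undefined there", uk[i])
  }
  tab <- data.frame(K = uk, mean_LnPD = as.numeric(mean_ln),
                    sd_LnPD = as.numeric(sd_ln), Lprime = as.numeric(lp),
                    Lsecond = lpp, deltaK = dk)
  if (all(!is.finite(dk)) || max(dk, na.rm = TRUE) == 0) {
    warnf("no deltaK peak; falling back to smallest K")
    sel <- uk[1]
  } else sel <- uk[which.max(dk)]
  list(table = tab, selected_K = as.integer(sel))
}

#' Assign individuals to subpopulations from a Q matrix
#'
#' An individual is assigned to the subpopulation with its largest
#' membership only if that membership exceeds the threshold (strictly);
#' otherwise it is labelled `"admixed"`.
#'
#' @param Q membership matrix (rows sum to 1).
#' @param threshold membership threshold (default 0.5, strict).
#' @return character vector of labels (`"1"`, `"2"`, ... or `"admixed"`).
#' @export
assign_subpops <- function(Q, threshold = 0.5) {
  idx <- max.col(Q, ties.method = "first")
  best <- Q[cbind(seq_len(nrow(Q)), idx)]
  out <- ifelse(best > threshold, as.character(idx), "admixed")
  names(out) <- rownames(Q)
  out
}
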
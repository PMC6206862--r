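test_that("kinship equals a brute-force simple-matching computation", {
  set.seed(12)
  m <- bm(matrix(sample(c(0L, 1L, NA), 25, replace = TRUE, prob = c(.4, .4, .2)),
                 5, 5))
  K <- kinship(m)
  ## brute force
  S <- matrix(1, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    S[i, j] <- mean(m[i, ok] == m[j, ok])
  }
  smin <- min(S)
  Kb <- pmax((S - smin) / (1 - smin), 0); diag(Kb) <- 1
  ## the PSD ridge (1e-6 I) may shift the diagonal marginally
  expect_equal(unname(K), unname(Kb), tolerance = 1e-5)
  ## identical rows have kinship 1; the S_min pair anchors 0
  m2 <- bm(rbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0)))
  K2 <- kinship(m2)
  expect_equal(K2[1, 2], 1)
  expect_equal(min(K2), 0)
  expect_true(isSymmetric(unname(K2)))
  m3 <- bm(rbind(c(1L, 0L), c(NA, NA)))
  expect_error(kinship(m3), "all-missing")
})

test_that("REML with K = identity reduces the scan to the OLS F test", {
  set.seed(101)
  n <- 60
  y <- rnorm(n)
  G <- bm(matrix(rbinom(n * 12, 1, 0.4), n, 12))
  K <- diag(n); dimnames(K) <- list(rownames(G), rownames(G))
  fit <- reml_fit(y, matrix(1, n), K)
  sc <- mlm_scan(fit, G)
  for (j in seq_len(ncol(G))) {
    ols <- summary(lm(y ~ G[, j]))
    p_ols <- ols$coefficients[2, 4]
    expect_equal(sc$p[sc$band == colnames(G)[j]], p_ols, tolerance = 1e-6)
  }
})

test_that("REML recovers a simulated heritability", {
  set.seed(55)
  n <- 200
  G <- bm(matrix(rbinom(n * 120, 1, 0.5), n, 120))
  K <- kinship(G)
  eg <- eigen(K, symmetric = TRUE)
  u <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(n))
  reps <- replicate(5, {
    y <- as.numeric(u) + rnorm(n, 0, sd(u))
    fit <- reml_fit(y, matrix(1, n), K)
    fit$sigma2_g / (fit$sigma2_g + fit$sigma2_e)
  })
  expect_lt(abs(mean(reps) - 0.5), 3 * sd(reps) / sqrt(5) + 0.1)
})

test_that("degenerate inputs are rejected", {
  K <- diag(5); dimnames(K) <- list(letters[1:5], letters[1:5])
  expect_error(reml_fit(rep(1, 5), matrix(1, 5), K), "constant phenotype")
  expect_error(reml_fit(c(1, 2, NA, 4, 5), matrix(1, 5), K), "non-finite")
  set.seed(1)
  y <- rnorm(5)
  expect_message(fit <- reml_fit(y, cbind(1, c(1, 1, 1, 1, 1)), K), "collinear")
  expect_equal(ncol(fit$X), 1)
})

test_that("the combination table enumerates all 32 genotype/phenotype pairs", {
  lines <- sprintf("L%02d", 1:4); testers <- LETTERS[1:5]
  crs <- expand.grid(line = lines, tester = testers, stringsAsFactors = FALSE)
  crs$f1 <- paste0(crs$line, "x", crs$tester)
  d <- lxt_design(lines, testers, crs)
  ct <- combination_table(d)
  expect_equal(nrow(ct), 32)
  expect_equal(ct$combination, 1:32)
  expect_equal(as.vector(table(ct$variable)[c("GCA", "SCA", "heterosis", "phenotype")]),
               c(6L, 5L, 10L, 11L))
  ## combination 11 is parents x parents trait phenotype
  expect_equal(ct$geno_panel[ct$combination == 11], "PS")
  expect_true(is.na(ct$phen_tester[ct$combination == 11]))
  expect_equal(ct$variable[ct$combination == 11], "phenotype")
  ## combination 18 is the first SCA set (F1s of tester A)
  expect_equal(ct$variable[ct$combination == 18], "SCA")
  expect_equal(ct$geno_panel[ct$combination == 18], "A")
  ## total scans: 32 combinations x traits, x5 metrics within heterosis
  n_scans <- sum(ifelse(ct$variable == "heterosis", 5, 1)) * 10
  expect_equal(n_scans, (22 + 50) * 10)
})

test_that("combination values route GCA, SCA and heterosis correctly", {
  cfg <- small_config(seed = 29, n_lines = 8L, n_testers = 3L)
  tr <- simulate_lxt(cfg)
  ph <- simulate_phenotypes(tr, "FL")
  m <- entry_means(ph, "raw")
  ca <- list(FL = combining_ability(ph, tr$design, "FL"))
  het <- heterosis_table(ph, tr$design)
  ct <- combination_table(tr$design)
  ## GCA on an F1 panel: the maternal line's GCA is the F1's value
  combo <- ct[ct$variable == "GCA" & ct$geno_panel == "TA", ]
  cv <- combination_values(combo, tr$design, m, ca, het, "FL")
  f1 <- cv$ids[1]
  line <- tr$design$crosses$line[tr$design$crosses$f1 == f1]
  expect_equal(unname(cv$y[f1]), unname(ca$FL$gca_line[line]))
  ## SCA values match the sca matrix
  combo <- ct[ct$variable == "SCA" & ct$geno_panel == "TB", ]
  cv <- combination_values(combo, tr$design, m, ca, het, "FL")
  expect_equal(unname(cv$y[1]),
               unname(ca$FL$sca[tr$design$crosses$line[
                 tr$design$crosses$f1 == cv$ids[1]], "TB"]))
  ## heterosis with maternal genotypes: line i carries its F1's metric
  combo <- ct[ct$variable == "heterosis" & ct$geno_panel == "PS" &
                ct$phen_tester == "TC", ][1, ]
  cv <- combination_values(combo, tr$design, m, ca, het, "FL", metric = "HB")
  l1 <- cv$ids[1]
  expect_equal(unname(cv$y[l1]),
               het$HB[het$f1 == paste0(l1, "xTC") & het$trait == "FL"])
})

test_that("run_all is deterministic and attributes testers to records", {
  cfg <- small_config(seed = 37, n_lines = 15L, n_testers = 3L,
                      qtl_spec = data.frame(marker = 2, trait = "FL",
                                            a = 1, d = 0.5))
  tr <- simulate_lxt(cfg)
  ph <- simulate_phenotypes(tr, "FL")
  m <- entry_means(ph, "raw")
  ca <- list(FL = combining_ability(ph, tr$design, "FL"))
  het <- heterosis_table(ph, tr$design)
  r1 <- run_all(all_bands(tr), tr$map, tr$design, m, ca, het, traits = "FL")
  r2 <- run_all(all_bands(tr), tr$map, tr$design, m, ca, het, traits = "FL")
  expect_identical(r1, r2)
  expect_true(all(r1$p > 0 & r1$p <= 1))
  expect_true(all(r1$r2 >= 0 & r1$r2 <= 1))
  expect_true(all(is.na(r1$tester[r1$combination %in% c(7, 8)])))
  expect_true(all(!is.na(r1$tester[r1$variable == "SCA"])))
})
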
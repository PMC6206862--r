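## cross means for a 2x2 design laid out as an entry-mean matrix
means_2x2 <- function(vals) {
  crs <- expand.grid(line = c("L1", "L2"), tester = c("T1", "T2"),
                     stringsAsFactors = FALSE)
  crs$f1 <- paste0(crs$line, "x", crs$tester)
  d <- lxt_design(c("L1", "L2"), c("T1", "T2"), crs)
  M <- matrix(vals[crs$f1], ncol = 1, dimnames = list(crs$f1, "FL"))
  list(design = d, means = M)
}

test_that("GCA/SCA match the definitional means on the 2x2 worked example", {
  x <- means_2x2(c(L1xT1 = 10, L1xT2 = 12, L2xT1 = 14, L2xT2 = 20))
  ca <- combining_ability(x$means, x$design, "FL")
  expect_equal(ca$mu, 14)
  expect_equal(unname(ca$gca_line), c(-3, 3))
  expect_equal(unname(ca$gca_tester), c(-2, 2))
  expect_equal(unname(ca$sca), matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12)
})

test_that("combining-ability identities hold on random balanced tables", {
  for (s in 1:25) {
    set.seed(s)
    l <- sample(2:20, 1); t <- sample(2:5, 1)
    lines <- sprintf("L%02d", seq_len(l)); testers <- sprintf("T%d", seq_len(t))
    crs <- expand.grid(line = lines, tester = testers, stringsAsFactors = FALSE)
    crs$f1 <- paste0(crs$line, "x", crs$tester)
    d <- lxt_design(lines, testers, crs)
    M <- matrix(rnorm(l * t, 50, 10), ncol = 1, dimnames = list(crs$f1, "FL"))
    M <- M[crs$f1, , drop = FALSE]
    ca <- combining_ability(M, d, "FL")
    expect_lt(abs(sum(ca$gca_line)), 1e-8)
    expect_lt(abs(sum(ca$gca_tester)), 1e-8)
    expect_true(all(abs(rowSums(ca$sca)) < 1e-8))
    expect_true(all(abs(colSums(ca$sca)) < 1e-8))
    ## exact reconstruction of every cross mean
    recon <- ca$mu + outer(ca$gca_line, ca$gca_tester, "+") + ca$sca
    expect_equal(recon[cbind(crs$line, crs$tester)], unname(M[, 1]),
                 tolerance = 1e-10)
    ## strata sum to SS(crosses)
    ss <- ca$anova$SS
    expect_equal(ss[1], sum(ss[2:4]), tolerance = 1e-8 * max(ss[1], 1))
  }
})

test_that("replicated ANOVA partitions plot-level SS exactly", {
  cfg <- small_config(seed = 13, n_lines = 6L, n_testers = 3L)
  tr <- simulate_lxt(cfg)
  ph <- simulate_phenotypes(tr, "FL")
  ca <- combining_ability(ph, tr$design, "FL")
  a <- ca$anova
  f1 <- ph[ph$individual %in% tr$design$crosses$f1, ]
  expect_equal(sum(a$SS[a$source != "crosses"]),
               sum((f1$value - mean(f1$value))^2), tolerance = 1e-8)
  expect_equal(a$SS[a$source == "crosses"],
               sum(a$SS[a$source %in% c("lines", "testers", "line_x_tester")]),
               tolerance = 1e-8)
  expect_true(all(is.finite(c(ca$sigma2_gca, ca$sigma2_sca))))
  ## all-equal cross means: every g and s is zero
  x <- means_2x2(c(L1xT1 = 7, L1xT2 = 7, L2xT1 = 7, L2xT2 = 7))
  ca0 <- combining_ability(x$means, x$design, "FL")
  expect_true(all(ca0$gca_line == 0) && all(ca0$sca == 0))
  ## single tester: testers stratum undefined
  crs <- data.frame(line = c("L1", "L2"), tester = "T1",
                    f1 = c("L1xT1", "L2xT1"))
  d1 <- lxt_design(c("L1", "L2"), "T1", crs)
  M <- matrix(1:2, ncol = 1, dimnames = list(crs$f1, "FL"))
  expect_error(combining_ability(M, d1, "FL"), "single tester")
})

test_that("line GCA tracks simulated additive dosage", {
  qa <- data.frame(marker = 4, trait = "FL", a = 1, d = 0)
  cfg <- small_config(seed = 17, n_lines = 60L, n_testers = 4L, qtl_spec = qa,
                      env_sd = 0.3, block_sd = 0.2, residual_sd = 0.5)
  tr <- simulate_lxt(cfg)
  ph <- simulate_phenotypes(tr, "FL")
  ca <- combining_ability(ph, tr$design, "FL")
  band <- tr$map$band[match("M004", tr$map$marker)]
  dosage <- tr$lines[, band]
  expect_gt(cor(ca$gca_line[rownames(tr$lines)], dosage), 0.5)
})

test_that("heterosis formulas satisfy their exact identities", {
  expect_equal(heterosis(12, 10, 8, metric = "MP"), 100 * (12 - 9) / 9)
  expect_equal(heterosis(12, 10, 8, metric = "HB", direction = 1), 20)
  ## lower-is-better trait: better parent is the smaller one
  expect_equal(heterosis(7, 10, 8, metric = "HB", direction = -1),
               100 * (7 - 8) / 8)
  expect_equal(heterosis(9, 10, 8, metric = "MP"), 0)
  expect_equal(heterosis(9, 10, 8, metric = "HI"), 100)
  expect_equal(heterosis(10, 10, 8, metric = "HB"), 0)
  expect_equal(heterosis(5, check = 5, metric = "K3"), 0)
  expect_warning(expect_true(is.na(heterosis(5, 1, -1, metric = "MP"))),
                 "zero denominator")
  expect_true(is.na(heterosis(5, NA, 3, metric = "MP")))
})

test_that("heterosis table is exact on a zero-noise simulation", {
  cfg <- small_config(seed = 23, env_sd = 0, block_sd = 0, residual_sd = 0,
                      qtl_spec = data.frame(marker = 1, trait = "FL",
                                            a = 1, d = 0))
  tr <- simulate_lxt(cfg)
  ph <- simulate_phenotypes(tr, "FL")
  het <- heterosis_table(ph, tr$design)
  expect_true(all(abs(het$MP) < 1e-10))       # purely additive
  m <- entry_means(ph, "raw")
  f1 <- het$f1[1]
  chk <- m["check_K3", "FL"]
  expect_equal(het$K3[1], 100 * (m[f1, "FL"] - chk) / chk, tolerance = 1e-10)
})

test_that("missing checks degrade gracefully to NA standard heterosis", {
  x <- means_2x2(c(L1xT1 = 10, L1xT2 = 12, L2xT1 = 14, L2xT2 = 20))
  M <- rbind(x$means,
             matrix(c(9, 11), 2, 1, dimnames = list(c("L1", "L2"), "FL")),
             matrix(c(10, 12), 2, 1, dimnames = list(c("T1", "T2"), "FL")))
  expect_warning(het <- heterosis_table(M, x$design), "check")
  expect_true(all(is.na(het$K3)))
  expect_false(anyNA(het$MP))
})
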
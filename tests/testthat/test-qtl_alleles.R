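## construct an association-record table from a compact spec
rec_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(combination = r$combination %||% 1L,
               variable = r$variable, metric = r$metric %||% "value",
               trait = r$trait %||% "FL", tester = r$tester,
               marker = r$marker, band = paste0(r$marker, "-1"),
               effect = 1, p = 10^(-r$nlp), neglog10p = r$nlp,
               r2 = 0.1, stringsAsFactors = FALSE)
  }))
}

test_that("significance filtering is strictly greater than the threshold", {
  rec <- rec_table(list(variable = "phenotype", tester = "A", marker = "M1", nlp = 3.0),
                   list(variable = "phenotype", tester = "A", marker = "M2", nlp = 3.01),
                   list(variable = "phenotype", tester = "A", marker = "M3", nlp = 2.5))
  out <- filter_significant(rec, 3)
  expect_equal(out$marker, "M2")
  expect_equal(nrow(filter_significant(rec[0, ], 3)), 0)
})

test_that("stable-QTL consensus requires three distinct testers", {
  base <- function(tst, var = "phenotype", met = "value", marker = "M1")
    list(variable = var, metric = met, tester = tst, marker = marker, nlp = 4)
  ## three testers via trait phenotype: retained with count 3
  rec <- rec_table(base("A"), base("B"), base("C"))
  q <- stable_qtls(rec)
  expect_equal(nrow(q), 1); expect_equal(q$n_testers, 3)
  ## only two testers: dropped
  expect_equal(nrow(stable_qtls(rec_table(base("A"), base("B")))), 0)
  ## five testers across GCA and HB: retained, count 5
  rec5 <- rec_table(base("A", "GCA"), base("B", "GCA"),
                    base("C", "heterosis", "HB"), base("D", "heterosis", "HB"),
                    base("E", "heterosis", "HB"))
  q5 <- stable_qtls(rec5)
  expect_equal(q5$n_testers, 5)
  expect_equal(q5$effect_type, "both")   # GCA + HB support
  ## duplicate support from one tester counts once
  recdup <- rec_table(base("A"), base("A", "GCA"), base("B"))
  expect_equal(nrow(stable_qtls(recdup)), 0)
  ## records without tester attribution (parent-only combos) never count
  recna <- rec_table(base(NA), base(NA), base(NA))
  expect_equal(nrow(stable_qtls(recna)), 0)
  ## variable whitelist: the five-variable preset drops SCA-only support
  recsca <- rec_table(base("A", "SCA"), base("B", "SCA"), base("C", "SCA"))
  expect_equal(nrow(stable_qtls(recsca)), 1)
  expect_equal(nrow(stable_qtls(recsca, variables = stable_variable_preset())), 0)
})

test_that("effect typing follows the GCA/dominance variable rules", {
  expect_equal(effect_type("GCA")$type, "additive")
  expect_equal(effect_type(c("SCA", "MP"))$type, "dominance")
  expect_equal(effect_type(c("GCA", "HB"))$type, "both")
  pt <- effect_type("phenotype")
  expect_equal(pt$type, "both"); expect_true(pt$low_confidence)
  ## monotone: adding a supporting variable never removes a type
  all_vars <- c("phenotype", "GCA", "SCA", "HB", "HI", "MP", "K3", "K4")
  set.seed(3)
  for (i in 1:50) {
    v <- sample(all_vars, sample(1:7, 1))
    extra <- sample(setdiff(all_vars, v), 1)
    t1 <- effect_type(v)$type; t2 <- effect_type(c(v, extra))$type
    implies <- function(a, b) switch(a, additive = b %in% c("additive", "both"),
                                     dominance = b %in% c("dominance", "both"),
                                     both = TRUE)
    if (t1 != "both" || !effect_type(v)$low_confidence) {
      expect_true(implies(t1, t2) ||
                    (effect_type(v)$low_confidence))
    }
  }
})

test_that("filter->stable->type pipeline equals brute-force enumeration", {
  set.seed(99)
  vars <- c("phenotype", "GCA", "SCA", "heterosis")
  mets <- c("MP", "HB", "HI", "K3", "K4")
  for (iter in 1:100) {
    n <- sample(5:40, 1)
    v <- sample(vars, n, replace = TRUE)
    rec <- data.frame(
      combination = sample(1:32, n, replace = TRUE),
      variable = v,
      metric = ifelse(v == "heterosis", sample(mets, n, replace = TRUE), "value"),
      trait = sample(c("FL", "FS"), n, replace = TRUE),
      tester = sample(c(LETTERS[1:5], NA), n, replace = TRUE),
      marker = sample(c("M1", "M2", "M3"), n, replace = TRUE),
      band = "b", effect = 1, neglog10p = runif(n, 2, 5),
      stringsAsFactors = FALSE)
    rec$p <- 10^-rec$neglog10p
    thr <- 3
    got <- stable_qtls(filter_significant(rec, thr), min_testers = 3)
    ## brute force
    sig <- rec[rec$neglog10p > thr, ]
    exp_rows <- 0
    for (tr in unique(sig$trait)) for (mk in unique(sig$marker)) {
      sub <- sig[sig$trait == tr & sig$marker == mk, ]
      tst <- unique(sub$tester[!is.na(sub$tester)])
      if (length(tst) >= 3) {
        exp_rows <- exp_rows + 1
        row <- got[got$trait == tr & got$marker == mk, ]
        expect_equal(nrow(row), 1)
        expect_equal(row$n_testers, length(tst))
        sup <- unique(ifelse(sub$variable == "heterosis", sub$metric, sub$variable))
        expect_equal(row$effect_type, effect_type(sup)$type)
      }
    }
    expect_equal(nrow(got), exp_rows)
  }
})

test_that("pleiotropy and subgenome tallies partition chromosomes at 13/14", {
  q <- data.frame(trait = c("FL", "FS", "MIC"), marker = c("M1", "M1", "M2"),
                  n_testers = 3, testers = "A,B,C", variables = "GCA",
                  effect_type = "additive", low_confidence = FALSE,
                  stringsAsFactors = FALSE)
  map <- data.frame(marker = c("M1", "M2", "M3"), chrom = c(5, 20, 25),
                    pos_bp = 1e5, band = c("M1-1", "M2-1", "M3-1"))
  s <- pleiotropy_and_subgenome(q, map)
  expect_equal(s$pleiotropic$marker, "M1")
  expect_equal(s$pleiotropic$traits, "FL,FS")
  expect_equal(unname(s$subgenome[c("A", "D")]), c(1L, 1L))
  ## markers on chromosomes 5, 20, 25 tally A:1 D:2
  q2 <- rbind(q, data.frame(trait = "BW", marker = "M3", n_testers = 3,
                            testers = "A,B,C", variables = "GCA",
                            effect_type = "additive", low_confidence = FALSE))
  expect_equal(unname(pleiotropy_and_subgenome(q2, map)$subgenome[c("A", "D")]),
               c(1L, 2L))
  empty <- stable_qtls(data.frame(
    combination = integer(), variable = character(), metric = character(),
    trait = character(), tester = character(), marker = character(),
    band = character(), neglog10p = numeric(), p = numeric()))
  s0 <- pleiotropy_and_subgenome(empty, map)
  expect_equal(nrow(s0$pleiotropic), 0)
})

test_that("allele effects follow the carrier-vs-overall mean formula", {
  ## worked example: carriers are the accessions valued 30 and 40
  ae <- allele_effect(c(0, 0, 1, 1), c(10, 20, 30, 40))
  expect_equal(ae$ai, 10)
  expect_equal(ae$ni, 2); expect_equal(ae$nk, 4)
  expect_true(ae$favorable)
  ## every accession carries the band: ai = 0
  expect_equal(allele_effect(rep(1, 4), c(10, 20, 30, 40))$ai, 0)
  ## MIC direction: negative effect is favorable
  ae2 <- allele_effect(c(1, 1, 0, 0), c(10, 20, 30, 40), direction = -1)
  expect_equal(ae2$ai, -10); expect_true(ae2$favorable)
  ## frequency-weighted carrier/non-carrier decomposition sums to zero
  set.seed(7)
  v <- rnorm(50); b <- rbinom(50, 1, 0.3)
  a1 <- allele_effect(b, v)$ai
  a0 <- mean(v[b == 0]) - mean(v)
  expect_lt(abs(mean(b) * a1 + (1 - mean(b)) * a0), 1e-8)
  ## missing/edge handling
  expect_warning(na <- allele_effect(rep(NA, 3), 1:3), "all-missing")
  expect_true(is.na(na$ai))
  expect_true(is.na(allele_effect(c(0, 0), c(1, 2))$ai))
})

test_that("favorable-allele mining recovers a planted band effect", {
  set.seed(61)
  n <- 150
  b <- rbinom(n, 1, 0.4)
  y <- 10 + 2 * b + rnorm(n, 0, 1)
  ae <- allele_effect(b, y)
  truth_gap <- 2 * (1 - mean(b))
  se <- sqrt(1 / sum(b) + 1 / n)
  expect_lt(abs(ae$ai - truth_gap), 3 * se + 0.2)
  ## null band: effect near zero
  b0 <- rbinom(n, 1, 0.5)
  ae0 <- allele_effect(b0, 10 + rnorm(n))
  expect_lt(abs(ae0$ai), 3 * sqrt(1 / sum(b0) + 1 / n))
})
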
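## Synthetic Line x Tester populations with known marker architecture.
##
## Parents are fixed inbreds scored with dominant multi-band markers; the
## generator draws per-subpopulation band frequencies from a
## correlated-frequency model, builds F1s by band union, and simulates
## multi-environment RCBD phenotypes from a declared additive/dominance
## QTL architecture so every downstream stage has a ground truth.

#' Simulation configuration
#'
#' Defaults mirror the scale of a large upland-cotton association panel:
#' 284 female lines crossed to 5 elite testers, 203 multi-band SSRs spread
#' over 26 chromosomes, trials in 10 locations x 2 years with 3
#' replicates.  Tests and examples pass smaller sizes.
#'
#' @param n_lines number of female lines.
#' @param n_testers number of testers.
#' @param n_markers number of SSR markers.
#' @param bands_per_marker integer vector of admissible band counts per
#'   marker (sampled uniformly).
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length in bp (uniform marker placement).
#' @param n_subpops number of latent subpopulations among the lines.
#' @param admixture_alpha Dirichlet concentration for individual admixture
#'   proportions (small = near-pure assignment).
#' @param divergence drift parameter F of the correlated-frequency model;
#'   subpopulation band frequencies are Beta(u(1-F)/F, (1-u)(1-F)/F)
#'   around the ancestral frequency u.  Larger F = stronger divergence.
#' @param qtl_spec data frame with columns `marker` (index), `trait`,
#'   `a` (additive effect, trait units), `d` (dominance effect).  The
#'   first band of the marker is the causal presence allele.
#' @param trait_means named numeric vector of trait intercepts.
#' @param env_spec list with `locations`, `years`, `replicates` (counts),
#'   `env_sd` (location-year effect SD), `block_sd` (replicate-within-
#'   environment SD) and `residual_sd`, all in trait units.
#' @param seed integer seed; all generation is deterministic under it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_lines = 284L, n_testers = 5L, n_markers = 203L,
                       bands_per_marker = 2:6, n_chromosomes = 26L,
                       chrom_length_bp = 1e8, n_subpops = 3L,
                       admixture_alpha = 0.2, divergence = 0.15,
                       qtl_spec = NULL,
                       trait_means = c(PH = 100, BW = 5.5, LP = 40, BN = 18,
                                       FL = 29, FS = 29, MIC = 4.5, FU = 84,
                                       FE = 6.5, FUI = 85),
                       env_spec = list(locations = 10L, years = 2L,
                                       replicates = 3L, env_sd = 1,
                                       block_sd = 0.5, residual_sd = 1),
                       seed = 1L) {
  cfg <- list(n_lines = as.integer(n_lines), n_testers = as.integer(n_testers),
              n_markers = as.integer(n_markers),
              bands_per_marker = as.integer(bands_per_marker),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = chrom_length_bp,
              n_subpops = as.integer(n_subpops),
              admixture_alpha = admixture_alpha, divergence = divergence,
              qtl_spec = qtl_spec, trait_means = trait_means,
              env_spec = env_spec, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) if (!ok) stopf("invalid config field '%s': %s", field, why)
  chk(cfg$n_lines >= 1, "n_lines", "must be >= 1")
  chk(cfg$n_testers >= 1, "n_testers", "must be >= 1")
  chk(cfg$n_markers >= 1, "n_markers", "must be >= 1")
  chk(all(cfg$bands_per_marker >= 1), "bands_per_marker", "band counts must be >= 1")
  chk(cfg$n_chromosomes >= 1, "n_chromosomes", "must be >= 1")
  chk(cfg$chrom_length_bp > 0, "chrom_length_bp", "must be > 0")
  chk(cfg$n_subpops >= 1, "n_subpops", "must be >= 1")
  chk(cfg$admixture_alpha > 0, "admixture_alpha", "must be > 0")
  chk(cfg$divergence > 0 && cfg$divergence < 1, "divergence", "must be in (0,1)")
  es <- cfg$env_spec
  chk(all(c("locations", "years", "replicates", "env_sd", "block_sd",
            "residual_sd") %in% names(es)), "env_spec", "incomplete")
  chk(es$env_sd >= 0 && es$block_sd >= 0 && es$residual_sd >= 0,
      "env_spec", "SDs must be >= 0")
  chk(es$replicates >= 2, "env_spec", "replicates must be >= 2 for ANOVA stages")
  if (!is.null(cfg$qtl_spec)) {
    q <- cfg$qtl_spec
    chk(all(c("marker", "trait", "a", "d") %in% names(q)), "qtl_spec", "incomplete")
    chk(all(q$marker >= 1 & q$marker <= cfg$n_markers), "qtl_spec",
        "marker index out of range")
    chk(all(q$trait %in% names(cfg$trait_means)), "qtl_spec",
        "trait without a mean in trait_means")
  }
  invisible(cfg)
}

## Draw a band matrix given per-individual subpop memberships (hard labels)
## and per-subpop x band frequency matrix.
draw_bands <- function(ids, labels, freq) {
  n <- length(ids); B <- ncol(freq)
  p <- freq[labels, , drop = FALSE]
  m <- matrix(as.integer(stats::runif(n * B) < p), n, B,
              dimnames = list(ids, colnames(freq)))
  m
}

#' Simulate parental genotypes
#'
#' Band frequencies follow a correlated-frequency model: an ancestral
#' frequency per band, with subpopulation frequencies drawn Beta around it
#' using drift parameter `divergence`.  Lines are allocated to
#' subpopulations in (approximately) equal blocks; testers are drawn from
#' the ancestral frequencies.  Bands are independent dominant markers.
#'
#' @param config a [sim_config()].
#' @return list with `map` (marker map), `lines`, `testers` (band
#'   matrices), `subpop` (named integer vector of true labels for lines)
#'   and `freq` (subpop x band frequency matrix).
#' @export
simulate_parents <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "parents"))
  nb <- sample(config$bands_per_marker, config$n_markers, replace = TRUE)
  marker <- sprintf("M%03d", seq_len(config$n_markers))
  chrom <- rep_len(seq_len(config$n_chromosomes), config$n_markers)
  pos <- round(stats::runif(config$n_markers, 1, config$chrom_length_bp))
  map <- data.frame(
    marker = rep(marker, nb),
    chrom = rep(chrom, nb),
    pos_bp = rep(pos, nb),
    band = unlist(lapply(seq_along(marker),
                         function(i) paste0(marker[i], "-", seq_len(nb[i])))),
    stringsAsFactors = FALSE)
  validate_marker_map(map, config$n_chromosomes)

  B <- nrow(map)
  u <- stats::runif(B, 0.1, 0.9)                # ancestral band frequencies
  Fst <- config$divergence
  shape1 <- u * (1 - Fst) / Fst
  shape2 <- (1 - u) * (1 - Fst) / Fst
  freq <- matrix(0, config$n_subpops, B, dimnames = list(NULL, map$band))
  for (k in seq_len(config$n_subpops)) {
    freq[k, ] <- if (config$n_subpops == 1) u else stats::rbeta(B, shape1, shape2)
  }
  line_ids <- sprintf("L%03d", seq_len(config$n_lines))
  subpop <- stats::setNames(
    sort(rep_len(seq_len(config$n_subpops), config$n_lines)), line_ids)
  lines <- draw_bands(line_ids, subpop, freq)

  tester_ids <- paste0("T", LETTERS[seq_len(config$n_testers)])
  testers <- matrix(as.integer(stats::runif(config$n_testers * B) <
                                 rep(u, each = config$n_testers)),
                    config$n_testers, B,
                    dimnames = list(tester_ids, map$band))
  list(map = map, lines = lines, testers = testers, subpop = subpop, freq = freq)
}

#' Combine two parental band rows into an F1 band row
#'
#' Dominant scoring: the F1 shows a band if either parent shows it; a call
#' is missing only when both parents are missing; otherwise absent.
#'
#' @param line_bands,tester_bands integer vectors (0/1/NA) over the same
#'   band columns.
#' @return integer vector of F1 band calls.
#' @export
make_f1_bands <- function(line_bands, tester_bands) {
  if (length(line_bands) != length(tester_bands) ||
      !identical(names(line_bands), names(tester_bands))) {
    stopf("parent band rows must share the same band columns")
  }
  out <- integer(length(line_bands))
  either1 <- (!is.na(line_bands) & line_bands == 1L) |
             (!is.na(tester_bands) & tester_bands == 1L)
  bothNA <- is.na(line_bands) & is.na(tester_bands)
  out[either1] <- 1L
  out[bothNA] <- NA_integer_
  names(out) <- names(line_bands)
  out
}

#' Simulate a complete Line x Tester truth set
#'
#' Runs [simulate_parents()], builds the full cross set (every line by
#' every tester), two fixed check genotypes, and records the causal
#' architecture.
#'
#' @param config a [sim_config()].
#' @return object of class `lxt_truth`: list with `map`, `lines`,
#'   `testers`, `f1s`, `checks` (band matrices), `design`
#'   ([lxt_design()]), `subpop`, `config`.
#' @export
simulate_lxt <- function(config) {
  par <- simulate_parents(config)
  set.seed(derive_seed(config$seed, "crosses"))
  line_ids <- rownames(par$lines); tester_ids <- rownames(par$testers)
  crosses <- expand.grid(line = line_ids, tester = tester_ids,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  crosses$f1 <- paste0(crosses$line, "x", crosses$tester)
  f1s <- matrix(NA_integer_, nrow(crosses), ncol(par$lines),
                dimnames = list(crosses$f1, colnames(par$lines)))
  for (i in seq_len(nrow(crosses))) {
    f1s[i, ] <- make_f1_bands(par$lines[crosses$line[i], ],
                              par$testers[crosses$tester[i], ])
  }
  ## two fixed commercial checks drawn from the ancestral pool
  u <- colMeans(par$freq)
  checks <- matrix(as.integer(stats::runif(2 * ncol(f1s)) < rep(u, each = 2)),
                   2, ncol(f1s), dimnames = list(c("check_K3", "check_K4"),
                                                 colnames(f1s)))
  design <- lxt_design(line_ids, tester_ids, crosses,
                       checks = c(K3 = "check_K3", K4 = "check_K4"))
  structure(list(map = par$map, lines = par$lines, testers = par$testers,
                 f1s = f1s, checks = checks, design = design,
                 subpop = par$subpop, freq = par$freq, config = config),
            class = "lxt_truth")
}

## genetic value of one individual for one trait under the truth coding:
## parents/checks contribute 2a per carried causal band; F1s contribute 2a
## when both parents carry, a+d when exactly one does, 0 when neither.
genetic_values <- function(truth, trait) {
  cfg <- truth$config
  ids <- c(rownames(truth$lines), rownames(truth$testers),
           rownames(truth$f1s), rownames(truth$checks))
  g <- stats::setNames(numeric(length(ids)), ids)
  q <- cfg$qtl_spec
  if (is.null(q)) return(g)
  q <- q[q$trait == trait, , drop = FALSE]
  if (!nrow(q)) return(g)
  markers <- unique(truth$map$marker)
  for (r in seq_len(nrow(q))) {
    band <- truth$map$band[match(markers[q$marker[r]], truth$map$marker)]
    a <- q$a[r]; d <- q$d[r]
    for (mat in list(truth$lines, truth$testers, truth$checks)) {
      x <- mat[, band]; x[is.na(x)] <- 0L
      g[rownames(mat)] <- g[rownames(mat)] + 2 * a * x
    }
    lx <- truth$lines[truth$design$crosses$line, band]
    tx <- truth$testers[truth$design$crosses$tester, band]
    lx[is.na(lx)] <- 0L; tx[is.na(tx)] <- 0L
    nc <- lx + tx
    gf <- ifelse(nc == 2L, 2 * a, ifelse(nc == 1L, a + d, 0))
    g[truth$design$crosses$f1] <- g[truth$design$crosses$f1] + gf
  }
  g
}

#' Simulate multi-environment RCBD phenotypes for a truth set
#'
#' value = trait mean + genetic value + location-year effect + block
#' effect + residual.  Environment effects are drawn once per
#' (location, year) and shared across genotypes; block effects once per
#' replicate within environment.  Checks are grown in every environment.
#'
#' @param truth an `lxt_truth` from [simulate_lxt()].
#' @param traits trait codes to simulate (default: all in `trait_means`).
#' @return phenotype data frame (individual, trait, location, year,
#'   replicate, value).
#' @export
simulate_phenotypes <- function(truth, traits = NULL) {
  cfg <- truth$config
  traits <- traits %||% names(cfg$trait_means)
  miss <- setdiff(traits, names(cfg$trait_means))
  if (length(miss)) stopf("invalid config field 'trait_means': no mean for trait %s",
                          paste(miss, collapse = ", "))
  es <- cfg$env_spec
  set.seed(derive_seed(cfg$seed, "phenotypes"))
  locs <- sprintf("LOC%02d", seq_len(es$locations))
  yrs <- sprintf("Y%d", seq_len(es$years))
  ids <- c(rownames(truth$lines), rownames(truth$testers),
           rownames(truth$f1s), rownames(truth$checks))
  env <- expand.grid(location = locs, year = yrs, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out <- vector("list", length(traits))
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    gv <- genetic_values(truth, tr)
    env_eff <- stats::rnorm(nrow(env), 0, es$env_sd)
    blocks <- expand.grid(ei = seq_len(nrow(env)), replicate = seq_len(es$replicates),
                          KEEP.OUT.ATTRS = FALSE)
    blocks$beff <- stats::rnorm(nrow(blocks), 0, es$block_sd)
    rec <- expand.grid(individual = ids, bi = seq_len(nrow(blocks)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ei <- blocks$ei[rec$bi]
    rec_out <- data.frame(
      individual = rec$individual, trait = tr,
      location = env$location[ei], year = env$year[ei],
      replicate = blocks$replicate[rec$bi],
      value = cfg$trait_means[[tr]] + gv[rec$individual] + env_eff[ei] +
        blocks$beff[rec$bi] +
        stats::rnorm(nrow(rec), 0, es$residual_sd),
      stringsAsFactors = FALSE)
    out[[ti]] <- rec_out
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Band matrix of every individual in a truth set
#' @param truth an `lxt_truth`.
#' @return band matrix stacking lines, testers, F1s and checks.
#' @export
all_bands <- function(truth) {
  rbind(truth$lines, truth$testers, truth$f1s, truth$checks)
}
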
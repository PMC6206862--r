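## End-to-end orchestration: simulate (or load) -> phenotype statistics ->
## combining ability & heterosis -> population structure -> LD ->
## association -> stable QTLs & favorable alleles, with every stage's
## tables persisted as TSV and a manifest recording seeds and row counts.

#' Run the full analysis pipeline
#'
#' Stages run in dependency order; stage toggles skip optional stages
#' (structure, LD).  With `structure = FALSE` the association scan runs
#' with a K-only model (no Q covariates), which is logged in the
#' manifest.  All randomness derives from per-stage seeds computed from
#' the master seed.
#'
#' @param truth an `lxt_truth` from [simulate_lxt()], or a list with
#'   elements `map`, `bands` (all individuals), `design`, `pheno`.
#' @param out_dir output directory (created; tables written as TSV).
#' @param seed master seed.
#' @param structure run admixture clustering for Q (logical).
#' @param ld run the LD stage (logical).
#' @param traits trait codes to analyse (default: those phenotyped).
#' @param sig_threshold -log10(p) significance threshold (default 3).
#' @param rare_threshold rare-allele masking frequency (default 0.05).
#' @param ld_threshold LD decay r2 threshold (default 0.2).
#' @param min_testers stable-QTL tester minimum (default 3).
#' @param k_range K values for structure (default 1:4 at desk scale).
#' @param struct_runs runs per K (default 3).
#' @param struct_lengths c(burnin, reps) sweeps (short preset default).
#' @param ld_shuffles LD permutations (default 200 at desk scale; the
#'   field convention is 1000).
#' @return invisible list bundle with every stage's results.
#' @export
run_pipeline <- function(truth, out_dir = NULL, seed = 1L,
                         structure = TRUE, ld = TRUE, traits = NULL,
                         sig_threshold = 3, rare_threshold = 0.05,
                         ld_threshold = 0.2, min_testers = 3,
                         k_range = 1:4, struct_runs = 3L,
                         struct_lengths = c(200L, 400L),
                         ld_shuffles = 200L) {
  if (inherits(truth, "lxt_truth")) {
    map <- truth$map; design <- truth$design
    bands <- all_bands(truth)
    pheno <- simulate_phenotypes(truth, traits = traits)
  } else {
    map <- truth$map; design <- truth$design
    bands <- truth$bands; pheno <- truth$pheno
  }
  traits <- traits %||% intersect(TRAIT_CODES, unique(pheno$trait))
  manifest <- list(seed = seed, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  persist <- function(name, df) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  ## phenostats
  summary_tab <- summarize_traits(pheno, by = "trait")
  means <- entry_means(pheno, mode = "shrunk")
  persist("trait_summary", summary_tab)
  note("phenostats", rows = nrow(summary_tab))

  ## combining ability + heterosis
  ca_list <- stats::setNames(
    lapply(traits, function(tr) combining_ability(pheno, design, tr)), traits)
  het <- heterosis_table(pheno, design)
  ca_tab <- do.call(rbind, lapply(ca_list, function(ca)
    data.frame(trait = ca$trait, mu = ca$mu,
               sigma2_gca = ca$sigma2_gca, sigma2_sca = ca$sigma2_sca)))
  persist("combining_ability", ca_tab)
  persist("heterosis", het)
  note("lxt_heterosis", traits = length(ca_list), crosses = nrow(het))

  ## genotype preprocessing
  masked <- mask_rare(bands, rare_threshold)

  ## population structure
  Qfull <- NULL; ev <- NULL
  if (structure) {
    line_bands <- masked[design$lines, , drop = FALSE]
    runs <- list()
    for (K in k_range) for (r in seq_len(struct_runs)) {
      runs[[length(runs) + 1L]] <- admixture_mcmc(
        line_bands, K, burnin = struct_lengths[1], reps = struct_lengths[2],
        seed = derive_seed(seed, sprintf("structK%dr%d", K, r)))
    }
    ev <- evanno(runs)
    selK <- ev$selected_K
    best <- admixture_mcmc(masked, max(selK, 1),
                           burnin = struct_lengths[1], reps = struct_lengths[2],
                           seed = derive_seed(seed, "structQ"))
    Qfull <- best$Q
    persist("evanno", ev$table)
    persist("q_matrix", data.frame(id = rownames(Qfull), Qfull))
    note("popstructure", selected_K = selK)
  } else note("popstructure", skipped = TRUE, model = "K-only")

  ## LD
  ld_res <- NULL
  if (ld) {
    ld_pairs <- pairwise_ld(masked[design$lines, , drop = FALSE], map,
                            shuffles = ld_shuffles,
                            seed = derive_seed(seed, "ld"))
    bg <- tryCatch(background_ld(ld_pairs), error = function(e) NA_real_)
    fit <- tryCatch(decay_fit(ld_pairs, threshold = ld_threshold),
                    error = function(e) NULL)
    ld_res <- list(pairs = ld_pairs, background = bg, decay = fit)
    persist("ld_pairs", ld_pairs)
    note("ld", pairs = nrow(ld_pairs), background = bg,
         decay = if (is.null(fit)) NA else fit$decay_distance)
  } else note("ld", skipped = TRUE)

  ## association
  records <- run_all(masked, map, design, means, ca_list, het,
                     traits = traits, Q = Qfull)
  persist("associations", records)
  note("association", scans = length(unique(paste(records$combination,
                                                  records$trait, records$metric))),
       records = nrow(records))

  ## stable QTLs and favorable alleles
  sig <- filter_significant(records, sig_threshold)
  qtls <- stable_qtls(sig, min_testers = min_testers)
  summ <- pleiotropy_and_subgenome(qtls, map)
  alle <- favorable_alleles(sig, masked, design, means, ca_list, het)
  persist("significant", sig)
  persist("stable_qtls", qtls)
  if (nrow(alle$effects)) persist("allele_effects", alle$effects)
  note("qtl_alleles", significant = nrow(sig), stable = nrow(qtls),
       favorable = sum(alle$effects$favorable %in% TRUE))

  bundle <- list(manifest = manifest, summary = summary_tab, means = means,
                 combining = ca_list, heterosis = het, evanno = ev,
                 Q = Qfull, ld = ld_res, records = records,
                 significant = sig, stable_qtls = qtls,
                 subgenome = summ, alleles = alle, design = design, map = map)
  if (!is.null(out_dir)) {
    mf <- data.frame(stage = names(manifest$stages),
                     info = vapply(manifest$stages, function(s)
                       paste(names(s), unlist(lapply(s, paste, collapse = ";")),
                             sep = "=", collapse = ", "), character(1)))
    persist("manifest", mf)
  }
  invisible(bundle)
}

#' Human-readable pipeline summary
#'
#' Counts of significant associations by variable class, stable QTLs per
#' trait, subgenome tally and favorable alleles per tester set.
#'
#' @param bundle result of [run_pipeline()].
#' @return character vector of report lines (also printed).
#' @export
pipeline_report <- function(bundle) {
  need <- c("records", "significant", "stable_qtls", "alleles")
  miss <- need[!vapply(need, function(n) !is.null(bundle[[n]]), logical(1))]
  if (length(miss) == length(need)) return(message("no stages in bundle"))
  if (length(miss)) stopf("incomplete bundle; missing stage output(s): %s",
                          paste(miss, collapse = ", "))
  lines <- character()
  addl <- function(...) lines <<- c(lines, sprintf(...))
  byvar <- table(bundle$significant$variable)
  addl("Significant associations (-log10 p > threshold): %d total",
       nrow(bundle$significant))
  for (v in names(byvar)) addl("  %-10s %d", v, byvar[[v]])
  addl("Stable QTLs (>= 3 testers): %d", nrow(bundle$stable_qtls))
  if (nrow(bundle$stable_qtls)) {
    bytr <- table(bundle$stable_qtls$trait)
    for (tr in names(bytr)) addl("  %-4s %d", tr, bytr[[tr]])
    sg <- bundle$subgenome$subgenome
    addl("Subgenome tally: A = %d, D = %d (fraction D = %.2f)",
         sg[["A"]], sg[["D"]], bundle$subgenome$frac_D)
  }
  fav <- bundle$alleles$by_tester
  if (length(fav)) {
    addl("Favorable alleles by tester: %s",
         paste(sprintf("%s=%d", names(fav), fav), collapse = ", "))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
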
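## Post-scan inference: significance filtering, the >=3-tester stable-QTL
## consensus, additive/dominance effect typing, pleiotropy and subgenome
## summaries, and favorable-allele effect mining.

## variable label of a record at metric resolution: "phenotype", "GCA",
## "SCA" or the heterosis metric itself ("MP","HB","HI","K3","K4")
record_variable <- function(records) {
  ifelse(records$variable == "heterosis", records$metric, records$variable)
}

#' Filter association records by significance
#'
#' Keeps records with -log10(p) strictly greater than the threshold
#' (alpha = 0.001 corresponds to threshold 3).
#'
#' @param records association record table.
#' @param threshold -log10(p) threshold (strict `>`).
#' @return filtered records.
#' @export
filter_significant <- function(records, threshold = 3) {
  records[records$neglog10p > threshold, , drop = FALSE]
}

#' Stable-QTL consensus across testers
#'
#' Groups significant records by (trait, marker) and counts the distinct
#' testers whose combinations support the pair (F1-set combinations and
#' maternal-genotype combinations paired with a tester's F1 phenotypes
#' both attribute that tester; parent-only combinations attribute none).
#' Pairs supported by fewer than `min_testers` distinct testers, or only
#' by variables outside the whitelist, are dropped.
#'
#' @param records significant association records (see
#'   [filter_significant()]).
#' @param min_testers minimum distinct testers (default 3).
#' @param variables whitelist of supporting variables at metric
#'   resolution; default all eight ("phenotype", "GCA", "SCA", "HB",
#'   "HI", "MP", "K3", "K4"); `stable_variable_preset()` gives the
#'   five-variable preset ("phenotype", "GCA", "HB", "MP", "K4").
#' @return data frame of class `stable_qtls`: trait, marker, n_testers,
#'   testers, variables, effect_type, low_confidence.
#' @export
stable_qtls <- function(records, min_testers = 3,
                        variables = c("phenotype", "GCA", "SCA", "HB",
                                      "HI", "MP", "K3", "K4")) {
  if (!nrow(records)) {
    return(structure(data.frame(trait = character(), marker = character(),
                                n_testers = integer(), testers = character(),
                                variables = character(), effect_type = character(),
                                low_confidence = logical()),
                     class = c("stable_qtls", "data.frame")))
  }
  rv <- record_variable(records)
  keep <- rv %in% variables
  rec <- records[keep, , drop = FALSE]; rv <- rv[keep]
  if (!nrow(rec)) return(stable_qtls(records[0, , drop = FALSE]))
  key <- paste(rec$trait, rec$marker, sep = "\r")
  groups <- split(seq_len(nrow(rec)), key)
  rows <- lapply(groups, function(ix) {
    tst <- unique(rec$tester[ix])
    tst <- tst[!is.na(tst)]
    if (length(tst) < min_testers) return(NULL)
    vars <- sort(unique(rv[ix]))
    et <- effect_type(vars)
    data.frame(trait = rec$trait[ix[1]], marker = rec$marker[ix[1]],
               n_testers = length(tst),
               testers = paste(sort(tst), collapse = ","),
               variables = paste(vars, collapse = ","),
               effect_type = et$type, low_confidence = et$low_confidence,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trait = character(), marker = character(), n_testers = integer(),
               testers = character(), variables = character(),
               effect_type = character(), low_confidence = logical())
  rownames(out) <- NULL
  class(out) <- c("stable_qtls", class(out))
  out
}

#' @rdname stable_qtls
#' @export
stable_variable_preset <- function() c("phenotype", "GCA", "HB", "MP", "K4")

#' Additive/dominance effect typing from supporting variables
#'
#' GCA support indicates additive gene action; support from SCA or any
#' heterosis metric indicates dominance; both yield "both".  Support by
#' trait phenotype alone cannot separate the two and is classified
#' "both" with a low-confidence flag.
#'
#' @param variables character vector of supporting variables at metric
#'   resolution.
#' @return list with `type` ("additive", "dominance" or "both") and
#'   `low_confidence`.
#' @export
effect_type <- function(variables) {
  dom_vars <- c("SCA", "HB", "HI", "MP", "K3", "K4")
  addv <- "GCA" %in% variables
  domv <- any(dom_vars %in% variables)
  if (addv && domv) list(type = "both", low_confidence = FALSE)
  else if (addv) list(type = "additive", low_confidence = FALSE)
  else if (domv) list(type = "dominance", low_confidence = FALSE)
  else list(type = "both", low_confidence = TRUE)
}

#' Pleiotropy and subgenome summary of stable QTLs
#'
#' A marker is pleiotropic if it is a stable QTL for two or more traits.
#' The subgenome tally uses the upland-cotton convention: A subgenome =
#' chromosomes 1-13, D subgenome = 14-26.
#'
#' @param qtls a `stable_qtls` table.
#' @param map marker map.
#' @return list with `pleiotropic` (marker -> traits), `subgenome`
#'   (counts A/D/unplaced over distinct stable markers) and `frac_D`.
#' @export
pleiotropy_and_subgenome <- function(qtls, map) {
  if (!nrow(qtls)) {
    return(list(pleiotropic = data.frame(marker = character(), traits = character()),
                subgenome = c(A = 0L, D = 0L, unplaced = 0L), frac_D = NA_real_))
  }
  tt <- tapply(qtls$trait, qtls$marker, function(x) sort(unique(x)))
  ple <- tt[vapply(tt, length, integer(1)) >= 2]
  pleio <- data.frame(marker = names(ple),
                      traits = vapply(ple, paste, character(1), collapse = ","),
                      stringsAsFactors = FALSE)
  mk <- unique(qtls$marker)
  chrom <- map$chrom[match(mk, map$marker)]
  unplaced <- sum(is.na(chrom))
  if (unplaced) warnf("%d stable marker(s) not in map counted as unplaced", unplaced)
  nA <- sum(chrom >= 1 & chrom <= 13, na.rm = TRUE)
  nD <- sum(chrom >= 14 & chrom <= 26, na.rm = TRUE)
  list(pleiotropic = pleio,
       subgenome = c(A = nA, D = nD, unplaced = unplaced),
       frac_D = if (nA + nD > 0) nD / (nA + nD) else NA_real_)
}

#' Phenotypic effect of one allele (band)
#'
#' ai = mean phenotype over accessions carrying the band - mean phenotype
#' over all accessions.  An allele is favorable when the sign of ai
#' matches the trait's desired direction.
#'
#' @param band_calls 0/1/NA vector of band calls over accessions.
#' @param values phenotype values over the same accessions.
#' @param direction +1 or -1 desired direction.
#' @return list with `ai`, `ni` (carriers), `nk` (total), `favorable`.
#' @export
allele_effect <- function(band_calls, values, direction = 1) {
  ok <- is.finite(values)
  values <- values[ok]; band_calls <- band_calls[ok]
  nk <- length(values)
  if (!nk) stopf("no accessions with phenotype values")
  if (all(is.na(band_calls))) {
    warnf("all-missing band; allele effect undefined")
    return(list(ai = NA_real_, ni = 0L, nk = nk, favorable = NA))
  }
  carriers <- !is.na(band_calls) & band_calls == 1L
  ni <- sum(carriers)
  if (ni == 0) return(list(ai = NA_real_, ni = 0L, nk = nk, favorable = NA))
  ai <- mean(values[carriers]) - mean(values)
  list(ai = ai, ni = ni, nk = nk,
       favorable = if (ai == 0) FALSE else sign(ai) == sign(direction))
}

#' Favorable-allele mining over significant associations
#'
#' Computes ai for every significantly associated band x trait within its
#' own genotype/phenotype combination, flags favorable alleles by the
#' trait direction table, and reports the per-trait maximum positive and
#' minimum negative effects plus the contribution per tester set.
#'
#' @param records significant association records.
#' @param bands band matrix over all individuals.
#' @param design the design.
#' @param means entry-mean matrix.
#' @param ca_list combining-ability list per trait.
#' @param het heterosis table.
#' @param directions trait direction table (default [TRAIT_DIRECTIONS]).
#' @return list with `effects` (per record: combination, variable,
#'   metric, trait, marker, band, ai, ni, nk, favorable), `extremes`
#'   (per trait max positive / min negative ai) and `by_tester`
#'   (favorable-allele counts per tester).
#' @export
favorable_alleles <- function(records, bands, design, means, ca_list, het,
                              directions = TRAIT_DIRECTIONS) {
  if (!nrow(records)) {
    return(list(effects = data.frame(), extremes = data.frame(),
                by_tester = integer()))
  }
  ct <- combination_table(design)
  eff <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    combo <- ct[ct$combination == rec$combination, ]
    met <- if (rec$variable == "heterosis") rec$metric else "MP"
    cv <- combination_values(combo, design, means, ca_list, het, rec$trait,
                             metric = met)
    ids <- cv$ids[is.finite(cv$y)]
    y <- cv$y[ids]
    ae <- allele_effect(bands[ids, rec$band], y,
                        direction = directions[[rec$trait]] %||% 1)
    eff[[i]] <- data.frame(combination = rec$combination,
                           variable = rec$variable, metric = rec$metric,
                           trait = rec$trait, tester = rec$tester,
                           marker = rec$marker, band = rec$band,
                           ai = ae$ai, ni = ae$ni, nk = ae$nk,
                           favorable = ae$favorable, stringsAsFactors = FALSE)
  }
  effects <- do.call(rbind, eff)
  rownames(effects) <- NULL
  fin <- effects[is.finite(effects$ai), , drop = FALSE]
  extremes <- do.call(rbind, lapply(split(fin, fin$trait), function(d) {
    pos <- d[d$ai > 0, , drop = FALSE]; neg <- d[d$ai < 0, , drop = FALSE]
    data.frame(trait = d$trait[1],
               max_positive_band = if (nrow(pos)) pos$band[which.max(pos$ai)] else NA,
               max_positive_ai = if (nrow(pos)) max(pos$ai) else NA_real_,
               min_negative_band = if (nrow(neg)) neg$band[which.min(neg$ai)] else NA,
               min_negative_ai = if (nrow(neg)) min(neg$ai) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(extremes) <- NULL
  fav <- fin[!is.na(fin$favorable) & fin$favorable & !is.na(fin$tester), ]
  by_tester <- table(factor(fav$tester, levels = design$testers))
  list(effects = effects, extremes = extremes,
       by_tester = stats::setNames(as.integer(by_tester), design$testers))
}
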
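#' Trait codes handled by the pipeline
#'
#' The ten yield and fiber-quality traits: plant height (PH), boll weight
#' (BW), lint percentage (LP), bolls per plant (BN), upper-half-mean fiber
#' length (FL), fiber strength (FS), micronaire (MIC), fiber uniformity
#' (FU), fiber elongation (FE) and fiber uniformity index (FUI).
#'
#' @format Character vector of length 10.
#' @export
TRAIT_CODES <- c("PH", "BW", "LP", "BN", "FL", "FS", "MIC", "FU", "FE", "FUI")

#' Default desired direction per trait
#'
#' +1 means higher values are better, -1 lower.  Micronaire (fiber
#' fineness) is the only trait where breeders prefer lower values; all
#' others are improvement targets in the positive direction.  Used to pick
#' the "better parent" for heterobeltiosis and to flag favorable alleles.
#'
#' @format Named numeric vector (+1/-1) over [TRAIT_CODES].
#' @export
TRAIT_DIRECTIONS <- c(PH = 1, BW = 1, LP = 1, BN = 1, FL = 1,
                      FS = 1, MIC = -1, FU = 1, FE = 1, FUI = 1)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a band matrix
#'
#' A band matrix is an integer matrix with individuals as rows (rownames =
#' ids), band columns (colnames = globally unique band ids) and entries in
#' \{0, 1, NA\}; NA encodes a missing band call.
#'
#' @param x matrix to validate.
#' @return `x`, invisibly, after validation.
#' @export
validate_band_matrix <- function(x) {
  if (!is.matrix(x)) stopf("band matrix must be a matrix")
  if (is.null(rownames(x))) stopf("band matrix must have individual ids as rownames")
  if (is.null(colnames(x))) stopf("band matrix must have band ids as colnames")
  if (anyDuplicated(rownames(x))) {
    stopf("duplicate individual id(s): %s",
          paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) stopf("duplicate band id(s)")
  vals <- x[!is.na(x)]
  if (length(vals) && !all(vals %in% c(0L, 1L))) {
    stopf("band matrix entries must be 0, 1 or NA")
  }
  invisible(x)
}

#' Validate a marker map
#'
#' A marker map is a data frame with one row per band and columns
#' `marker`, `chrom` (integer 1-26), `pos_bp` (non-negative integer) and
#' `band` (globally unique band id).  All bands of a marker share its
#' chromosome and position.
#'
#' @param map data frame to validate.
#' @param n_chrom number of chromosomes (26 for allotetraploid upland cotton).
#' @return `map`, invisibly.
#' @export
validate_marker_map <- function(map, n_chrom = 26L) {
  need <- c("marker", "chrom", "pos_bp", "band")
  miss <- setdiff(need, names(map))
  if (length(miss)) stopf("marker map missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(map$band)) stopf("marker map band ids must be globally unique")
  if (any(!is.finite(map$chrom)) || any(map$chrom < 1 | map$chrom > n_chrom)) {
    stopf("marker map chromosome out of range 1..%d", n_chrom)
  }
  if (any(map$pos_bp < 0)) stopf("marker map positions must be non-negative")
  pos <- tapply(map$pos_bp, map$marker, function(p) length(unique(p)))
  if (any(pos > 1)) stopf("bands of one marker must share its position")
  invisible(map)
}

#' Construct a Line x Tester design
#'
#' @param lines character vector of female line ids.
#' @param testers character vector of tester ids.
#' @param crosses data frame with columns `line`, `tester`, `f1` mapping
#'   each cross to its F1 id; must be injective in (line, tester).
#' @param checks named character vector of check-cultivar ids, e.g.
#'   `c(K3 = "check_K3", K4 = "check_K4")`.
#' @return object of class `lxt_design`.
#' @export
lxt_design <- function(lines, testers, crosses, checks = character()) {
  if (!length(testers)) stopf("design requires at least one tester")
  need <- c("line", "tester", "f1")
  miss <- setdiff(need, names(crosses))
  if (length(miss)) stopf("cross table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(crosses[, c("line", "tester")])) {
    stopf("cross map must be injective in (line, tester)")
  }
  if (anyDuplicated(crosses$f1)) stopf("duplicate F1 id in cross map")
  if (any(crosses$f1 %in% c(lines, testers))) {
    stopf("F1 ids must be disjoint from parent ids")
  }
  bad <- setdiff(crosses$line, lines)
  if (length(bad)) stopf("cross map references unknown line(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(crosses$tester, testers)
  if (length(bad)) stopf("cross map references unknown tester(s): %s", paste(bad, collapse = ", "))
  structure(list(lines = as.character(lines), testers = as.character(testers),
                 crosses = crosses, checks = checks),
            class = "lxt_design")
}

#' @export
print.lxt_design <- function(x, ...) {
  cat(sprintf("Line x Tester design: %d lines x %d testers, %d crosses, %d check(s)\n",
              length(x$lines), length(x$testers), nrow(x$crosses), length(x$checks)))
  invisible(x)
}

#' Look up the F1 id of a (line, tester) pair
#' @param design an [lxt_design()].
#' @param line,tester parent ids (vectorised).
#' @return character vector of F1 ids (NA where the cross is absent).
#' @export
f1_of <- function(design, line, tester) {
  key <- paste(design$crosses$line, design$crosses$tester, sep = "\r")
  design$crosses$f1[match(paste(line, tester, sep = "\r"), key)]
}

## derive a reproducible sub-seed from a master seed and a stage tag,
## kept inside 32-bit integer range
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 2654435.0 + h) %% 2147483647)
}
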
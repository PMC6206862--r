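## On-disk formats.  All files are UTF-8, tab-separated, "#" comment lines
## ignored.  Band matrices come in two dialects that differ only in the
## missing-value token: "structure" uses "-9", "tassel" uses "?".

missing_token <- function(dialect) {
  switch(match.arg(dialect, c("structure", "tassel")),
         structure = "-9", tassel = "?")
}

read_tsv_ <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", quote = "", ...)
}

#' Read a band-presence genotype matrix
#'
#' First column `id` holds individual ids; remaining columns are band ids
#' with entries 1 (band present), 0 (absent) or the dialect's missing
#' token ("-9" for the STRUCTURE dialect, "?" for the TASSEL dialect).
#'
#' @param path file path.
#' @param dialect `"structure"` or `"tassel"`.
#' @return validated band matrix (see [validate_band_matrix()]).
#' @export
read_band_matrix <- function(path, dialect = c("structure", "tassel")) {
  dialect <- match.arg(dialect)
  miss <- missing_token(dialect)
  df <- read_tsv_(path)
  if (!"id" %in% names(df)) stopf("band matrix file must have an 'id' column")
  ids <- df$id
  if (anyDuplicated(ids)) {
    stopf("duplicate individual id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cols <- setdiff(names(df), "id")
  m <- matrix(NA_integer_, length(ids), length(cols),
              dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    tok <- df[[cols[j]]]
    bad <- !(tok %in% c("0", "1", miss))
    if (any(bad)) {
      i <- which(bad)[1]
      stopf("unknown token '%s' at row %d, column '%s' (dialect %s)",
            tok[i], i, cols[j], dialect)
    }
    v <- ifelse(tok == miss, NA_integer_, as.integer(tok))
    m[, j] <- v
  }
  validate_band_matrix(m)
  m
}

#' Write a band-presence genotype matrix
#'
#' @param x band matrix.
#' @param path output path.
#' @param dialect `"structure"` (missing = "-9") or `"tassel"` (missing = "?").
#' @param map optional marker map; when given, columns are written in map
#'   band order.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(x, path, dialect = c("structure", "tassel"),
                              map = NULL) {
  dialect <- match.arg(dialect)
  validate_band_matrix(x)
  if (!is.null(map)) {
    ord <- intersect(map$band, colnames(x))
    if (length(ord) != ncol(x)) stopf("map does not cover all band columns")
    x <- x[, ord, drop = FALSE]
  }
  miss <- missing_token(dialect)
  chr <- matrix(as.character(x), nrow(x), ncol(x))
  chr[is.na(chr)] <- miss
  df <- data.frame(id = rownames(x), chr, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c("id", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a marker map
#'
#' Expects tab-separated columns `marker`, `chrom`, `pos_bp`, `band`
#' (one row per band; bands of a multi-band SSR share marker, chromosome
#' and position, e.g. NAU2631-1, NAU2631-2).
#'
#' @param path file path.
#' @return validated marker-map data frame.
#' @export
read_marker_map <- function(path) {
  df <- read_tsv_(path)
  need <- c("marker", "chrom", "pos_bp", "band")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("marker map missing column(s): %s", paste(miss, collapse = ", "))
  chrom <- suppressWarnings(as.integer(df$chrom))
  pos <- suppressWarnings(as.numeric(df$pos_bp))
  if (anyNA(chrom)) stopf("non-integer chromosome in marker map")
  if (anyNA(pos)) stopf("non-numeric position in marker map")
  map <- data.frame(marker = df$marker, chrom = chrom, pos_bp = pos,
                    band = df$band, stringsAsFactors = FALSE)
  validate_marker_map(map)
  map
}

#' @rdname read_marker_map
#' @param map marker map to write.
#' @export
write_marker_map <- function(map, path) {
  validate_marker_map(map)
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a long-format phenotype table
#'
#' Columns: `individual`, `trait` (one of [TRAIT_CODES]), `location`,
#' `year`, `replicate`, `value`.  The key
#' (individual, trait, location, year, replicate) must be unique.
#'
#' @param path file path.
#' @return validated phenotype data frame.
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_(path)
  need <- c("individual", "trait", "location", "year", "replicate", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("phenotype table missing column(s): %s",
                          paste(miss, collapse = ", "))
  validate_phenotypes(data.frame(
    individual = df$individual, trait = df$trait, location = df$location,
    year = df$year, replicate = df$replicate,
    value = suppressWarnings(as.numeric(df$value)),
    stringsAsFactors = FALSE), raw_value = df$value)
}

#' Validate a phenotype table
#' @param df phenotype data frame.
#' @param raw_value internal; original value tokens for error reporting.
#' @return `df` after validation.
#' @export
validate_phenotypes <- function(df, raw_value = NULL) {
  need <- c("individual", "trait", "location", "year", "replicate", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("phenotype table missing column(s): %s", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$trait), TRAIT_CODES)
  if (length(bad)) stopf("unknown trait code(s): %s", paste(bad, collapse = ", "))
  if (anyNA(df$value) || any(!is.finite(df$value))) {
    i <- which(!is.finite(df$value))[1]
    tok <- if (!is.null(raw_value)) raw_value[i] else as.character(df$value[i])
    stopf("non-numeric or non-finite phenotype value '%s' at record %d", tok, i)
  }
  key <- do.call(paste, c(df[c("individual", "trait", "location", "year", "replicate")],
                          sep = "\r"))
  if (anyDuplicated(key)) {
    stopf("duplicate (individual, trait, location, year, replicate) record")
  }
  df
}

#' @rdname read_phenotypes
#' @param df phenotype table to write.
#' @export
write_phenotypes <- function(df, path) {
  validate_phenotypes(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a Line x Tester design table
#'
#' The file has one row per cross with columns `line`, `tester`, `f1`,
#' plus optional header-comment-free check rows encoded in two extra
#' columns `role` (empty or `check`) — for simplicity checks are written
#' as rows with `line = check name`, `tester = ""`, `f1 = check id`,
#' `role = "check"`.
#'
#' @param path file path.
#' @return an [lxt_design()].
#' @export
read_design <- function(path) {
  df <- read_tsv_(path)
  need <- c("line", "tester", "f1")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("design table missing column(s): %s", paste(miss, collapse = ", "))
  role <- df$role %||% rep("", nrow(df))
  chk <- df[role == "check", , drop = FALSE]
  crs <- df[role != "check", c("line", "tester", "f1"), drop = FALSE]
  checks <- stats::setNames(chk$f1, chk$line)
  lxt_design(lines = unique(crs$line), testers = unique(crs$tester),
             crosses = crs, checks = checks)
}

#' @rdname read_design
#' @param design design to write.
#' @export
write_design <- function(design, path) {
  crs <- design$crosses
  crs$role <- ""
  if (length(design$checks)) {
    crs <- rbind(crs, data.frame(line = names(design$checks), tester = "",
                                 f1 = unname(design$checks), role = "check",
                                 stringsAsFactors = FALSE))
  }
  utils::write.table(crs, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert a band matrix file between missing-value dialects
#'
#' @param infile,outfile input and output paths.
#' @param from,to dialects (`"structure"` or `"tassel"`).
#' @return `outfile`, invisibly.
#' @export
convert_band_matrix <- function(infile, outfile, from, to) {
  write_band_matrix(read_band_matrix(infile, from), outfile, to)
}
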
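## Fixture builders shared by the test files.  Everything is generated in
## code under fixed seeds.

small_config <- function(seed = 1L, n_lines = 12L, n_testers = 3L,
                         n_markers = 10L, n_subpops = 1L, qtl_spec = NULL,
                         env_sd = 0.5, block_sd = 0.25, residual_sd = 0.5,
                         locations = 2L, years = 1L, replicates = 3L) {
  sim_config(n_lines = n_lines, n_testers = n_testers, n_markers = n_markers,
             n_subpops = n_subpops, qtl_spec = qtl_spec,
             env_spec = list(locations = locations, years = years,
                             replicates = replicates, env_sd = env_sd,
                             block_sd = block_sd, residual_sd = residual_sd),
             seed = seed)
}

## band matrix from a plain 0/1/NA matrix with default names
bm <- function(m, ids = NULL, bands = NULL) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  rownames(m) <- ids %||% sprintf("I%02d", seq_len(nrow(m)))
  colnames(m) <- bands %||% sprintf("M%03d-1", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## single-band-per-marker map for a band matrix named M001-1, M002-1, ...
map_for <- function(bands, chrom = NULL, pos = NULL) {
  mk <- sub("-[0-9]+$", "", colnames(bands))
  data.frame(marker = mk,
             chrom = chrom %||% rep_len(1:2, length(mk)),
             pos_bp = pos %||% seq(1e5, by = 1e5, length.out = length(mk)),
             band = colnames(bands), stringsAsFactors = FALSE)
}

## balanced toy phenotype table: g genotypes x r blocks (+ given effects)
toy_rcbd <- function(gmeans, beff, noise = NULL, trait = "FL") {
  g <- length(gmeans); r <- length(beff)
  vals <- outer(gmeans, beff, "+")
  if (!is.null(noise)) vals <- vals + noise
  data.frame(individual = rep(sprintf("G%d", seq_len(g)), r),
             trait = trait, location = "L1", year = "Y1",
             replicate = rep(seq_len(r), each = g),
             value = as.numeric(vals), stringsAsFactors = FALSE)
}
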
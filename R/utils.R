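# internal helpers shared across modules

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# deterministic derived seed, kept inside the 32-bit integer range
derive_seed <- function(seed, salt) {
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(salt)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a plain numeric matrix as TSV
#'
#' Whitespace/tab-delimited matrices (volumes x regions, motion traces,
#' connectomes) are the on-disk interchange format of the pipeline.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `read_matrix_tsv` returns a numeric matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                              comment.char = "#"))
}

#' AAL-90 region labels
#'
#' The 90 cortical/subcortical regions of the automated anatomical labeling
#' atlas (45 per hemisphere, left = odd index, right = even index), used as
#' network nodes throughout.
#'
#' @return data.frame with columns `index`, `abbrev` (e.g. `"AMYG.R"`),
#'   `name`, `hemisphere`.
#' @export
aal90_regions <- function() {
  path <- system.file("extdata", "aal90_regions.tsv", package = "fconn",
                      mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
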
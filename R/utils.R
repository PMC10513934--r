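# internal helpers shared across modules

.assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.assertProportion <- function(x, name, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 &&
    (if (open_upper) x < 1 else x <= 1)
  if (!ok) stop(sprintf("'%s' must be a proportion in [0,1%s", name,
                        if (open_upper) ")" else "]"), call. = FALSE)
  as.numeric(x)
}

# equal-frequency bin assignment; ties keep input order (stable)
.equalFreqBins <- function(x, n_bins) {
  n_bins <- max(1L, min(as.integer(n_bins), length(x)))
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r / length(x) * n_bins))
}

# dense column-major matrix of a (possibly sparse) assay, cells x genes
.denseCellsByGenes <- function(m) {
  if (is(m, "sparseMatrix")) as.matrix(m) else as.matrix(m)
}

# provenance header lines written at the top of every numeric output file
.provenanceHeader <- function(params = list(), seed = NA) {
  p <- paste(names(params), vapply(params, function(v)
    paste(format(v), collapse = ","), ""), sep = "=", collapse = "; ")
  c(sprintf("# isletKit %s", as.character(utils::packageVersion("isletKit"))),
    sprintf("# seed=%s; %s", format(seed), p))
}

#' Write a table with a provenance header
#'
#' All numeric outputs of the pipeline carry a two-line `#` header recording
#' the package version, seed and stage parameters, so that any result file
#' can be traced back to its configuration.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named list of stage parameters to record.
#' @param seed seed in effect for the stage.
#' @return invisibly, the path.
#' @export
writeProvenancedTsv <- function(df, path, params = list(), seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader(params, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that an output file carries a parseable provenance header
#'
#' @param path file to check.
#' @return TRUE invisibly; errors if the header is absent or malformed.
#' @export
checkProvenanceHeader <- function(path) {
  head2 <- readLines(path, n = 2L)
  if (length(head2) < 2L || !startsWith(head2[1L], "# isletKit") ||
      !grepl("^# seed=", head2[2L]))
    stop("missing or malformed provenance header in ", path, call. = FALSE)
  invisible(TRUE)
}
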
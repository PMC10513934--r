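#' Read a CellRanger-style MTX bundle into a SingleCellExperiment
#'
#' Accepts either a single bundle directory (matrix.mtx[.gz],
#' features.tsv[.gz] or genes.tsv[.gz], barcodes.tsv[.gz]) or a directory
#' of such bundles (one per sample, as written by [writeSynthetic()]),
#' optionally with a top-level \code{metadata.tsv} whose rows are matched
#' to barcodes. On disk the matrix is genes x cells; duplicated barcodes
#' are rejected and dimension mismatches raise errors naming the files.
#'
#' @param path bundle directory or parent directory of bundles.
#' @return a \linkS4class{SingleCellExperiment} with a \code{counts}
#'   assay.
#' @export
readExpression <- function(path) {
  find1 <- function(dir, base) {
    for (f in c(base, paste0(base, ".gz")))
      if (file.exists(file.path(dir, f))) return(file.path(dir, f))
    NULL
  }
  is_bundle <- function(dir) !is.null(find1(dir, "matrix.mtx"))
  read_bundle <- function(dir) {
    mtx <- find1(dir, "matrix.mtx")
    feat <- find1(dir, "features.tsv")
    if (is.null(feat)) feat <- find1(dir, "genes.tsv")
    bcs <- find1(dir, "barcodes.tsv")
    if (is.null(mtx) || is.null(feat) || is.null(bcs))
      stop("incomplete MTX bundle in ", dir, call. = FALSE)
    m <- Matrix::readMM(if (endsWith(mtx, ".gz")) gzfile(mtx) else mtx)
    ft <- utils::read.table(feat, sep = "\t", stringsAsFactors = FALSE)
    bc <- readLines(bcs)
    if (nrow(m) != nrow(ft))
      stop(sprintf("matrix has %d rows but %s has %d lines", nrow(m),
                   feat, nrow(ft)), call. = FALSE)
    if (ncol(m) != length(bc))
      stop(sprintf("matrix has %d columns but %s has %d lines", ncol(m),
                   bcs, length(bc)), call. = FALSE)
    dimnames(m) <- list(ft[[1L]], bc)
    methods::as(m, "CsparseMatrix")
  }
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  if (is_bundle(path)) {
    mats <- list(read_bundle(path))
  } else {
    subs <- list.dirs(path, recursive = FALSE)
    subs <- subs[vapply(subs, is_bundle, TRUE)]
    if (length(subs) == 0L)
      stop("no MTX bundles found under ", path, call. = FALSE)
    mats <- lapply(subs, read_bundle)
    ids <- Reduce(intersect, lapply(mats, rownames))
    if (any(vapply(mats, nrow, 0L) != length(ids)))
      stop("bundles under ", path, " disagree on features", call. = FALSE)
  }
  counts <- do.call(cbind, mats)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate barcodes in ", path, call. = FALSE)
  cd <- S4Vectors::DataFrame(barcode = colnames(counts),
                             row.names = colnames(counts))
  meta_path <- file.path(path, "metadata.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    m <- match(colnames(counts), meta$barcode)
    if (anyNA(m))
      stop("metadata.tsv misses ", sum(is.na(m)), " barcodes", call. = FALSE)
    cd <- S4Vectors::DataFrame(meta[m, , drop = FALSE],
                               row.names = colnames(counts))
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, then genes, tab-separated).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "")
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(n)
    paste(c(n, "na", sets[[n]]), collapse = "\t"), ""), path)
  invisible(path)
}
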
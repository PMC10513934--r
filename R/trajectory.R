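#' Graph-diffusion condition density
#'
#' Smooths per-condition cell-membership indicators over the embedding
#' graph with a t-step random walk: the row-stochastic transition matrix
#' P is built from the graph weights and the density of condition c is
#' \eqn{P^t (\mathbf{1}_c / n_c)}. Indicators are divided by the group
#' cell count first so unbalanced designs do not bias downstream ratios.
#'
#' @param graph a \linkS4class{NeighborGraph}.
#' @param condition "healthy"/"diseased" (or any two labels) per cell.
#' @param t_steps diffusion steps (default 3; 0 returns the normalized
#'   indicators unchanged).
#' @return cells x conditions matrix of non-negative densities.
#' @export
conditionDensity <- function(graph, condition, t_steps = 3L) {
  w <- graphWeights(graph)
  lab <- as.character(condition)
  ulab <- if (is.factor(condition)) levels(condition) else sort(unique(lab))
  dens <- vapply(ulab, function(u) {
    ind <- as.numeric(lab == u)
    nc <- sum(ind)
    if (nc == 0L) stop("condition ", u, " has zero cells", call. = FALSE)
    ind / nc
  }, numeric(length(lab)))
  deg <- Matrix::rowSums(w)
  if (any(deg == 0)) deg[deg == 0] <- 1       # isolated nodes keep own mass
  if (t_steps > 0L) for (i in seq_len(t_steps))
    dens <- as.matrix(w %*% dens) / deg
  colnames(dens) <- ulab
  dens
}

#' Continuous healthy-to-diseased process score
#'
#' Per dataset, the score is the smoothed healthy density normalized over
#' healthy plus diseased densities; the final per-cell score is the mean
#' across the datasets covering the cell's comparison, i.e. those with
#' positive total density mass at the cell (a dataset whose cells are
#' nowhere near carries no information there). Cells covered by no
#' dataset score 0.5. Scores lie in [0, 1] with 1 the most healthy-dense
#' region.
#'
#' @param densities either a cells x 2 density matrix with columns
#'   "healthy" and "diseased" (single dataset) or a named list of such
#'   matrices, one per dataset, each covering all cells.
#' @return list with \code{score} (per cell, in [0, 1]),
#'   \code{per_dataset} (matrix of per-dataset scores, NA where a dataset
#'   does not cover a cell; NULL for single-dataset input).
#' @export
processScore <- function(densities) {
  one <- function(d) {
    h <- d[, "healthy"]
    s <- h + d[, "diseased"]
    ifelse(s > 0, h / s, NA_real_)
  }
  if (is.list(densities) && !is.matrix(densities)) {
    per <- vapply(densities, one, numeric(nrow(densities[[1L]])))
    per <- matrix(per, ncol = length(densities),
                  dimnames = list(NULL, names(densities)))
    sc <- rowMeans(per, na.rm = TRUE)
    sc[is.nan(sc)] <- 0.5
    list(score = sc, per_dataset = per)
  } else {
    sc <- one(densities)
    sc[is.na(sc)] <- 0.5
    list(score = sc, per_dataset = NULL)
  }
}
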
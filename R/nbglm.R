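# Negative-binomial GLM core: IRLS with log link, offset, and
# method-of-moments dispersion on Pearson residuals. This one engine backs
# every count-based differential expression test in the package.

# fit a single gene; returns coefficients, covariance, dispersion, flags
.nbFitOne <- function(y, X, offset, max_iter = 50L, tol = 1e-8,
                      phi_floor = 1e-8) {
  n <- length(y)
  p <- ncol(X)
  if (all(y == 0))
    return(list(coef = rep(0, p), se = rep(Inf, p), phi = phi_floor,
                converged = FALSE, degenerate = TRUE, all_zero = TRUE))
  # initialize on shifted log scale
  eta <- log(y + 0.5) - offset
  beta <- tryCatch(qr.coef(qr(X), eta), error = function(e) rep(0, p))
  beta[is.na(beta)] <- 0
  phi <- 0.1
  mom_phi <- function(mu) {
    num <- sum(((y - mu)^2 - mu) / mu^2)
    max(phi_floor, num / max(n - p, 1L))
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    phi <- mom_phi(mu)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients))
      return(list(coef = beta, se = rep(Inf, p), phi = phi,
                  converged = FALSE, degenerate = TRUE, all_zero = FALSE))
    new_beta <- fit$coefficients
    if (max(abs(new_beta - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- new_beta
      converged <- TRUE
      break
    }
    beta <- new_beta
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + phi * mu)
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov))
    return(list(coef = beta, se = rep(Inf, p), phi = phi, converged = FALSE,
                degenerate = TRUE, all_zero = FALSE))
  se <- sqrt(pmax(diag(cov), 0))
  list(coef = beta, se = se, cov = cov, phi = phi, converged = converged,
       degenerate = !converged | any(se < 1e-12), all_zero = FALSE)
}

#' Negative-binomial GLM Wald test for one or many genes
#'
#' Fits, per gene, an NB log-link GLM by iteratively reweighted least
#' squares with \code{log(size factor)} as offset (exposure); the per-gene
#' dispersion is estimated by method of moments on Pearson residuals
#' (floored at 1e-8) and updated within the IRLS loop. The two-sided Wald
#' p-value tests the coefficient named (or indexed) by \code{test_coef};
#' the log fold change is that coefficient divided by \eqn{\ln 2}, i.e.
#' the binary logarithm of the modelled multiplicative change per unit of
#' the covariate.
#'
#' Degenerate fits (non-convergence, or a coefficient standard error below
#' 1e-12, the signature of an unidentifiable coefficient) are flagged so
#' downstream selections can exclude them; all-zero genes are flagged with
#' p = 1.
#'
#' @param counts genes x cells (or pseudobulks) integer matrix, or a
#'   vector for a single gene.
#' @param design model matrix, cells x p (full rank).
#' @param size_factors positive exposure per cell; log(size_factors) is
#'   the model offset.
#' @param test_coef column name or index of the coefficient to test.
#' @return data.frame (one row per gene): gene, stat, p, fdr (BH across
#'   the supplied genes), lfc (log2), coef (natural log), se, dispersion,
#'   converged, degenerate, all_zero.
#' @export
nbGlmWald <- function(counts, design, size_factors = NULL, test_coef = 2L) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  counts <- as.matrix(counts)
  X <- as.matrix(design)
  stopifnot(ncol(counts) == nrow(X))
  if (qr(X)$rank < ncol(X)) stop("design is not full rank", call. = FALSE)
  if (is.null(size_factors)) size_factors <- rep(1, nrow(X))
  stopifnot(all(size_factors > 0))
  offset <- log(size_factors)
  ci <- if (is.character(test_coef)) match(test_coef, colnames(X))
        else as.integer(test_coef)
  if (is.na(ci) || ci < 1L || ci > ncol(X))
    stop("test_coef not found in design", call. = FALSE)

  res <- lapply(seq_len(nrow(counts)), function(g) {
    f <- .nbFitOne(counts[g, ], X, offset)
    if (f$all_zero)
      return(data.frame(stat = 0, p = 1, lfc = 0, coef = 0, se = Inf,
                        dispersion = f$phi, converged = FALSE,
                        degenerate = TRUE, all_zero = TRUE))
    z <- if (is.finite(f$se[ci]) && f$se[ci] > 0) f$coef[ci] / f$se[ci] else 0
    data.frame(stat = z, p = 2 * stats::pnorm(-abs(z)),
               lfc = f$coef[ci] / log(2), coef = f$coef[ci], se = f$se[ci],
               dispersion = f$phi, converged = f$converged,
               degenerate = f$degenerate, all_zero = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(gene = if (!is.null(rownames(counts))) rownames(counts)
               else sprintf("gene%d", seq_len(nrow(counts))), out)
  out$fdr <- bhFdr(out$p)
  rownames(out) <- NULL
  out
}

# joint NB fit returning full coefficient covariance, for contrasts
.nbFitFull <- function(y, X, offset) .nbFitOne(y, X, offset)

#' Wald tests of arbitrary contrasts from a joint NB-GLM
#'
#' Fits one NB-GLM per gene and tests each row of \code{contrasts} (a
#' contrast matrix L with one row per comparison, columns matching the
#' design) via \eqn{z = L\beta / \sqrt{L \Sigma L'}}.
#'
#' @inheritParams nbGlmWald
#' @param contrasts comparisons x p numeric matrix.
#' @return list of data.frames, one per contrast row, each as in
#'   [nbGlmWald()].
#' @export
nbGlmContrasts <- function(counts, design, contrasts, size_factors = NULL) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  counts <- as.matrix(counts)
  X <- as.matrix(design)
  L <- as.matrix(contrasts)
  stopifnot(ncol(L) == ncol(X))
  if (is.null(size_factors)) size_factors <- rep(1, nrow(X))
  offset <- log(size_factors)
  fits <- lapply(seq_len(nrow(counts)), function(g)
    .nbFitFull(counts[g, ], X, offset))
  gene_names <- if (!is.null(rownames(counts))) rownames(counts)
                else sprintf("gene%d", seq_len(nrow(counts)))
  lapply(seq_len(nrow(L)), function(r) {
    rows <- lapply(seq_along(fits), function(g) {
      f <- fits[[g]]
      if (f$all_zero || is.null(f$cov))
        return(data.frame(stat = 0, p = 1, lfc = 0, se = Inf,
                          degenerate = TRUE))
      est <- drop(L[r, ] %*% f$coef)
      se <- sqrt(max(drop(L[r, , drop = FALSE] %*% f$cov %*% L[r, ]), 0))
      z <- if (se > 0) est / se else 0
      data.frame(stat = z, p = 2 * stats::pnorm(-abs(z)), lfc = est / log(2),
                 se = se, degenerate = f$degenerate || se < 1e-12)
    })
    out <- do.call(rbind, rows)
    out <- cbind(gene = gene_names, out)
    out$fdr <- bhFdr(out$p)
    rownames(out) <- NULL
    out
  })
}
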
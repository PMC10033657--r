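# Normalization and nuisance-covariate removal applied to expression
# matrices before training or deployment.

#' Normalize a raw-count expression matrix
#'
#' Converts raw counts to counts-per-million per sample, applies a
#' log2 transform with a pseudocount offset, and removes genes that are
#' not expressed in enough samples. The default recipe —
#' `log2(CPM + 1)`, keeping genes with `log2(CPM + 1) > 1` in at least
#' 20% of samples — is a conventional bulk RNA-seq pipeline; every
#' threshold is an argument so a user can match the preparation of a
#' specific training corpus.
#'
#' Matrices already carrying the `"log_scale"` attribute are refused
#' unless `force = TRUE`, since double log-transformation silently
#' destroys the expression scale.
#'
#' @param counts numeric matrix of nonnegative raw counts, genes x
#'   samples, with dimnames.
#' @param offset pseudocount added before the log2 transform (CPM
#'   units; default 1).
#' @param min_log_expr expression-filter threshold on the log2 scale
#'   (default 1).
#' @param min_fraction minimum fraction of samples in which a gene must
#'   exceed `min_log_expr` to be retained (default 0.2).
#' @param force re-normalize even if the input is flagged as already
#'   log-scale.
#' @return numeric matrix of `log2(CPM + offset)` values restricted to
#'   genes passing the filter, with attribute `log_scale = TRUE`.
#' @export
normalize_expression <- function(counts, offset = 1, min_log_expr = 1,
                                 min_fraction = 0.2, force = FALSE) {
  check_expression_matrix(counts, "counts")
  if (isTRUE(attr(counts, "log_scale")) && !force) {
    ximpute_stop("ximpute_invalid_input",
                 "input is already log-scale normalized; use force = TRUE to override")
  }
  if (any(counts < 0)) {
    ximpute_stop("ximpute_invalid_input", "raw counts must be nonnegative")
  }
  stopifnot(offset > 0, min_fraction >= 0, min_fraction <= 1,
            is.finite(min_log_expr))
  libsize <- colSums(counts)
  if (all(libsize == 0)) {
    ximpute_stop("ximpute_empty_after_filter",
                 "all counts are zero; nothing is expressed")
  }
  if (any(libsize == 0)) {
    ximpute_stop("ximpute_invalid_input",
                 sprintf("samples with zero library size: %s",
                         paste(colnames(counts)[libsize == 0], collapse = ", ")))
  }
  cpm <- sweep(counts, 2L, libsize, "/") * 1e6
  logcpm <- log2(cpm + offset)
  keep <- rowMeans(logcpm > min_log_expr) >= min_fraction
  if (!any(keep)) {
    ximpute_stop("ximpute_empty_after_filter",
                 "no genes pass the expression filter")
  }
  out <- logcpm[keep, , drop = FALSE]
  attr(out, "log_scale") <- TRUE
  out
}

#' Remove covariate effects from an expression matrix
#'
#' Replaces each gene's expression by the residuals of an ordinary
#' least-squares fit on the named covariates (categoricals one-hot
#' encoded with a dropped reference level) plus an intercept, then adds
#' the gene's original mean back so the expression scale is preserved.
#' Used to remove the effects of age, sex, ancestry or other nuisance
#' variables before training or deployment; blood and target-tissue
#' matrices are residualized independently with the same covariate
#' list.
#'
#' @param expr numeric log-scale matrix, genes x samples.
#' @param covariates data.frame of sample covariates with `sample_id`
#'   rownames (see [read_covariates()]).
#' @param names character vector of covariate columns to remove.
#' @return matrix of the same shape; per-gene means are unchanged and
#'   per-gene variance never increases.
#' @export
residualize <- function(expr, covariates, names) {
  check_expression_matrix(expr)
  stopifnot(is.character(names), length(names) >= 1L)
  missing_cov <- setdiff(names, colnames(covariates))
  if (length(missing_cov)) {
    ximpute_stop("ximpute_missing_covariate",
                 sprintf("covariates absent from table: %s",
                         paste(missing_cov, collapse = ", ")))
  }
  samp <- colnames(expr)
  missing_samp <- setdiff(samp, rownames(covariates))
  if (length(missing_samp)) {
    ximpute_stop("ximpute_missing_covariate",
                 sprintf("samples absent from covariate table: %s",
                         paste(utils::head(missing_samp, 5L), collapse = ", ")))
  }
  covs <- covariates[samp, names, drop = FALSE]
  if (anyNA(covs)) {
    ximpute_stop("ximpute_missing_covariate", "missing covariate values")
  }
  X <- stats::model.matrix(~ ., data = covs)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    ximpute_stop("ximpute_collinear_covariates",
                 "covariate design matrix is rank deficient")
  }
  res <- t(qr.resid(qrX, t(expr)))
  out <- res + rowMeans(expr)
  dimnames(out) <- dimnames(expr)
  attr(out, "log_scale") <- attr(expr, "log_scale")
  out
}

#' Align an expression matrix to a gene universe
#'
#' Reorders (and if needed fills) the rows of `expr` so they follow
#' `universe` exactly — the alignment step required before projecting a
#' cohort onto a trained model whose PCA is defined over a fixed gene
#' universe. Matching tolerates version-suffixed identifiers on either
#' side (see [strip_gene_version()]) when `strip_versions = TRUE`.
#'
#' With `policy = "mean-impute"` (the deployment default), universe
#' genes absent from `expr` are filled with `fill` — scalar, or a named
#' vector such as the model's training centers, so that the filled gene
#' contributes zero after centering. With `policy = "intersect"`,
#' absent universe genes are dropped and the caller must cope with a
#' reduced universe.
#'
#' @param expr numeric matrix, genes x samples.
#' @param universe character vector of gene IDs defining the target
#'   order.
#' @param policy `"mean-impute"` or `"intersect"`.
#' @param fill fill value(s) for absent genes under mean-impute: a
#'   scalar or a vector named by universe genes (default 0, i.e. the
#'   training mean on a centered scale).
#' @param strip_versions match IDs after stripping `.N` version
#'   suffixes (default `TRUE`).
#' @param min_coverage fraction of the universe that must be present;
#'   below it a `ximpute_low_coverage` warning (or error) is raised.
#' @param on_low_coverage `"warn"` or `"error"`.
#' @return matrix with rows exactly in `universe` order (byte-equal
#'   IDs); attribute `"coverage"` holds the fraction of universe genes
#'   found in `expr`.
#' @export
align_genes <- function(expr, universe,
                        policy = c("mean-impute", "intersect"),
                        fill = 0, strip_versions = TRUE,
                        min_coverage = 0.5,
                        on_low_coverage = c("warn", "error")) {
  check_expression_matrix(expr)
  policy <- match.arg(policy)
  on_low_coverage <- match.arg(on_low_coverage)
  stopifnot(is.character(universe), length(universe) >= 1L,
            !anyDuplicated(universe))
  key_expr <- if (strip_versions) strip_gene_version(rownames(expr)) else rownames(expr)
  key_univ <- if (strip_versions) strip_gene_version(universe) else universe
  idx <- match(key_univ, key_expr)
  coverage <- mean(!is.na(idx))
  if (coverage == 0) {
    ximpute_stop("ximpute_low_coverage",
                 "no universe genes found in the expression matrix")
  }
  if (coverage < min_coverage) {
    msg <- sprintf("only %.1f%% of the %d universe genes are present",
                   100 * coverage, length(universe))
    if (on_low_coverage == "error") ximpute_stop("ximpute_low_coverage", msg)
    ximpute_warn("ximpute_low_coverage", msg)
  }
  if (policy == "intersect") {
    out <- expr[idx[!is.na(idx)], , drop = FALSE]
    rownames(out) <- universe[!is.na(idx)]
  } else {
    fills <- if (length(fill) == 1L && is.null(names(fill))) {
      rep_len(as.numeric(fill), length(universe))
    } else {
      f <- fill[universe]
      if (anyNA(f)) {
        ximpute_stop("ximpute_invalid_input",
                     "named `fill` must cover every universe gene")
      }
      as.numeric(f)
    }
    out <- matrix(rep(fills, ncol(expr)), nrow = length(universe),
                  dimnames = list(universe, colnames(expr)))
    found <- !is.na(idx)
    out[found, ] <- expr[idx[found], , drop = FALSE]
  }
  attr(out, "coverage") <- coverage
  attr(out, "log_scale") <- attr(expr, "log_scale")
  out
}
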
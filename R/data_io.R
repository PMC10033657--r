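# On-disk formats: expression TSV, covariate TSV, GMT gene sets,
# differential-expression tables, serialized imputation models.

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expression matrices are tab-separated text with a header row; the
#' first column holds row identifiers (gene IDs when
#' `orientation = "genes"`, sample IDs when `orientation = "samples"`).
#' The result is always oriented genes x samples. Scientific notation
#' is accepted; values must be numeric and finite.
#'
#' @param path path to a TSV file.
#' @param orientation `"genes"` if rows of the file are genes (the
#'   default), `"samples"` if rows are samples.
#' @return numeric matrix, genes in rows, samples in columns.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, orientation = c("genes", "samples")) {
  orientation <- match.arg(orientation)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) {
    ximpute_stop("ximpute_empty_input",
                 sprintf("no expression values in '%s'", path))
  }
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    ximpute_stop("ximpute_duplicate_identifier",
                 sprintf("duplicate row identifiers in '%s': %s", path,
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  vals <- tab[, -1L, drop = FALSE]
  num <- vapply(vals, function(col) {
    if (is.numeric(col)) return(as.numeric(col))
    suppressWarnings(as.numeric(col))
  }, numeric(nrow(tab)))
  num <- matrix(num, nrow = nrow(tab),
                dimnames = list(ids, colnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
    ximpute_stop("ximpute_parse_error",
                 sprintf("non-numeric expression values in '%s' (first at row %s)",
                         path, if (nrow(bad)) rownames(num)[bad[1L, 1L]] else "?"))
  }
  if (orientation == "samples") num <- t(num)
  check_expression_matrix(num, "matrix")
  num
}

#' Write a gene-by-sample expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: writes a header row and a
#' first column named `gene_id`. Values are written with full double
#' precision (17 significant digits) so that a write/read round trip
#' reproduces the matrix exactly.
#'
#' @param expr numeric matrix, genes x samples, with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  check_expression_matrix(expr)
  df <- data.frame(gene_id = rownames(expr),
                   format(expr, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample covariate table from TSV
#'
#' The first column must be named `sample_id` and hold unique sample
#' identifiers; remaining columns are covariates (e.g. `study`, `age`,
#' `sex`, `diagnosis`, ancestry components, cell fractions). Character
#' columns are converted to factors.
#'
#' @param path path to a TSV file.
#' @return data.frame with `sample_id` rownames.
#' @export
read_covariates <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(tab)) {
    ximpute_stop("ximpute_parse_error",
                 sprintf("covariate table '%s' lacks a sample_id column", path))
  }
  if (anyDuplicated(tab$sample_id)) {
    ximpute_stop("ximpute_duplicate_identifier",
                 sprintf("duplicate sample identifiers in '%s'", path))
  }
  rownames(tab) <- tab$sample_id
  for (j in seq_along(tab)) {
    if (is.character(tab[[j]]) && colnames(tab)[j] != "sample_id") {
      tab[[j]] <- factor(tab[[j]])
    }
  }
  tab
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated, fields are set name,
#' description, then member gene IDs. Members are de-duplicated within
#' a set; empty member fields are dropped.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors; each element carries its
#'   description in attribute `"description"`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    ximpute_stop("ximpute_empty_input", sprintf("no gene sets in '%s'", path))
  }
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      ximpute_stop("ximpute_parse_error",
                   sprintf("GMT line %d has fewer than 3 fields", i))
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      ximpute_stop("ximpute_parse_error",
                   sprintf("GMT set '%s' has no members", fields[1L]))
    }
    sets[[i]] <- structure(members, description = fields[2L])
    nms[i] <- fields[1L]
  }
  if (anyDuplicated(nms)) {
    ximpute_stop("ximpute_duplicate_identifier", "duplicate gene-set names in GMT")
  }
  names(sets) <- nms
  sets
}

#' Read or write a differential-expression table
#'
#' DGE tables are TSV with columns `gene_id`, `effect` (a t-value or
#' z-score), and optionally `se` and `p`. External effect-size tables
#' (e.g. genetically imputed z-scores) typically carry only `gene_id`
#' and `effect`.
#'
#' @param path file path.
#' @return data.frame with one row per gene.
#' @export
read_dge_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene_id", "effect")
  if (!all(need %in% colnames(tab))) {
    ximpute_stop("ximpute_parse_error",
                 sprintf("DGE table '%s' must have columns gene_id and effect", path))
  }
  if (anyDuplicated(tab$gene_id)) {
    ximpute_stop("ximpute_duplicate_identifier",
                 sprintf("duplicate gene identifiers in '%s'", path))
  }
  if ("p" %in% colnames(tab)) {
    ok <- is.na(tab$p) | (tab$p > 0 & tab$p <= 1)
    if (!all(ok)) {
      ximpute_stop("ximpute_invalid_input",
                   sprintf("p-values outside (0, 1] in '%s'", path))
    }
  }
  tab
}

#' @rdname read_dge_table
#' @param dge data.frame as returned by [dge_mega_analysis()].
#' @export
write_dge_table <- function(dge, path) {
  utils::write.table(dge, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

MODEL_SCHEMA_VERSION <- 1L

#' Save or load a trained imputation model
#'
#' A trained model (see [ximpute()]) is written as a single
#' self-describing archive containing a schema version, the blood PCA
#' (gene universe, centers, optional scales, loadings), the per-gene
#' regression coefficient table, and training metadata (number of
#' components, region label, donor count). One archive corresponds to
#' one target region. Loading verifies the schema version and the
#' structural invariants, so a truncated or foreign file is rejected
#' rather than silently mis-deployed.
#'
#' @param model an object of class `"ximpute"`.
#' @param path file path for the archive.
#' @return `save_model` returns `path` invisibly; `load_model` returns
#'   the restored `"ximpute"` object, whose predictions agree with the
#'   original to full floating-point precision.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "ximpute")) {
    ximpute_stop("ximpute_invalid_input", "`model` must be an ximpute model")
  }
  saveRDS(list(schema_version = MODEL_SCHEMA_VERSION,
               package = "ximpute",
               model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    ximpute_stop("ximpute_incompatible_model",
                 sprintf("cannot read model archive '%s': %s", path,
                         conditionMessage(e)))
  })
  if (!is.list(obj) || !identical(obj$package, "ximpute") ||
      is.null(obj$schema_version)) {
    ximpute_stop("ximpute_incompatible_model",
                 sprintf("'%s' is not an ximpute model archive", path))
  }
  if (!identical(obj$schema_version, MODEL_SCHEMA_VERSION)) {
    ximpute_stop("ximpute_incompatible_model",
                 sprintf("model schema version %s not supported (expected %d)",
                         obj$schema_version, MODEL_SCHEMA_VERSION))
  }
  model <- obj$model
  if (!inherits(model, "ximpute") ||
      !identical(ncol(model$pca$loadings), model$k) ||
      !identical(ncol(model$coefficients), model$k + 1L)) {
    ximpute_stop("ximpute_incompatible_model",
                 sprintf("model archive '%s' fails structural checks", path))
  }
  model
}
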
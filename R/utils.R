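# Internal helpers: classed conditions, RNG scoping, matrix checks.

# All package errors carry a subclass so callers can condition on the
# failure mode rather than matching message text.
ximpute_stop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ximpute_error"), call = call))
}

ximpute_warn <- function(class, msg) {
  warning(warningCondition(msg, class = c(class, "ximpute_warning")))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Validate a genes x samples expression matrix: dimnames present and
# unique, all values finite.
check_expression_matrix <- function(x, arg = "expr") {
  if (!is.matrix(x) || !is.numeric(x)) {
    ximpute_stop("ximpute_invalid_input",
                 sprintf("`%s` must be a numeric matrix (genes x samples)", arg))
  }
  if (nrow(x) == 0L || ncol(x) == 0L) {
    ximpute_stop("ximpute_empty_input", sprintf("`%s` has zero extent", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    ximpute_stop("ximpute_invalid_input",
                 sprintf("`%s` needs gene rownames and sample colnames", arg))
  }
  if (anyDuplicated(rownames(x))) {
    ximpute_stop("ximpute_duplicate_identifier",
                 sprintf("duplicate gene identifiers in `%s`", arg))
  }
  if (anyDuplicated(colnames(x))) {
    ximpute_stop("ximpute_duplicate_identifier",
                 sprintf("duplicate sample identifiers in `%s`", arg))
  }
  if (!all(is.finite(x))) {
    ximpute_stop("ximpute_invalid_input",
                 sprintf("non-finite values in `%s`", arg))
  }
  invisible(x)
}

#' Strip version suffixes from gene identifiers
#'
#' Versioned GENCODE-style identifiers (e.g. `"ENSG00000123456.7"`) are
#' reduced to their unversioned stem so that cohorts annotated with and
#' without version suffixes can be matched. Identifiers without a
#' trailing `.<digits>` suffix are returned unchanged.
#'
#' @param ids character vector of gene identifiers.
#' @return character vector of the same length.
#' @examples
#' strip_gene_version(c("ENSG00000157764.12", "BRAF"))
#' @export
strip_gene_version <- function(ids) {
  sub("\\.[0-9]+$", "", ids)
}
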
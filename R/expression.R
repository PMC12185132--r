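#' Expression matrix with a processing-stage tag
#'
#' A genes x samples numeric matrix wrapped with the stage of the
#' preprocessing chain it has reached.  Stages move strictly forward:
#' `counts -> cpm -> log -> normalized -> adjusted -> standardized`.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param stage one of `"counts"`, `"cpm"`, `"log"`, `"normalized"`,
#'   `"adjusted"`, `"standardized"`.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, stage = "counts") {
  stage <- match.arg(stage, .EXPR_STAGES)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ", paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  structure(list(values = values, stage = stage), class = "ExpressionMatrix")
}

#' @export
#' @method print ExpressionMatrix
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [stage: %s] %d genes x %d samples\n",
              x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

# Enforce the forward-only stage contract when a step emits its output.
.advance_stage <- function(x, to) {
  from_i <- match(x$stage, .EXPR_STAGES)
  to_i <- match(to, .EXPR_STAGES)
  if (is.na(to_i)) stop("unknown stage: ", to)
  if (to_i <= from_i)
    stop(sprintf("stage may only move forward (got %s -> %s)", x$stage, to))
  x$stage <- to
  x
}

.assert_stage <- function(x, stage, op) {
  if (!inherits(x, "ExpressionMatrix"))
    stop(op, " expects an ExpressionMatrix")
  if (!x$stage %in% stage)
    stop(sprintf("%s expects stage %s, got %s", op,
                 paste(stage, collapse = "/"), x$stage))
  invisible(x)
}

#' Sample metadata table
#'
#' Validates the per-sample metadata paired with an expression matrix:
#' one row per sample with its condition and batch labels plus any further
#' covariate columns (e.g. instrument, temperature).  Which extra columns
#' are "unwanted" (to be removed by [eb_adjust()]) versus "retained" is
#' chosen at adjustment time.
#'
#' @param df data.frame with at least columns `sample`, `condition`, `batch`.
#' @param expr optional `ExpressionMatrix`; if given, sample ids must match
#'   its columns and every condition must keep at least 2 samples.
#' @return the validated data.frame (invisibly classed `SampleTable`).
#' @export
sample_table <- function(df, expr = NULL) {
  need <- c("sample", "condition", "batch")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in metadata")
  if (!is.null(expr)) {
    if (!setequal(df$sample, sample_ids(expr)))
      stop("metadata samples do not match expression matrix columns")
    df <- df[match(sample_ids(expr), df$sample), , drop = FALSE]
    tab <- table(df$condition)
    if (any(tab < 2))
      stop("conditions with < 2 samples: ",
           paste(names(tab)[tab < 2], collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("SampleTable", "data.frame")
  df
}
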
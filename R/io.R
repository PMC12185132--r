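#' Read and write count matrices
#'
#' TSV layout: first column `gene`, remaining columns one per sample.
#' MatrixMarket layout: `.mtx` plus sibling `<stem>.genes.txt` and
#' `<stem>.samples.txt` index files.
#'
#' @param x `ExpressionMatrix` (any stage) for writers; file path for
#'   readers.
#' @param path file path.
#' @param stage stage tag to stamp on the matrix read from disk.
#' @name counts_io
NULL

#' @rdname counts_io
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname counts_io
#' @export
read_counts_tsv <- function(path, stage = "counts") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("first column must be 'gene': ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in counts file: ", path)
  rownames(m) <- df$gene
  expression_matrix(m, stage)
}

#' @rdname counts_io
#' @export
write_counts_mtx <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  stem <- sub("\\.mtx$", "", path)
  Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), path)
  writeLines(rownames(x$values), paste0(stem, ".genes.txt"))
  writeLines(colnames(x$values), paste0(stem, ".samples.txt"))
  invisible(path)
}

#' @rdname counts_io
#' @export
read_counts_mtx <- function(path, stage = "counts") {
  stem <- sub("\\.mtx$", "", path)
  m <- as.matrix(Matrix::readMM(path))
  rownames(m) <- readLines(paste0(stem, ".genes.txt"))
  colnames(m) <- readLines(paste0(stem, ".samples.txt"))
  expression_matrix(m, stage)
}

#' Read and write sample metadata
#'
#' TSV with columns `sample`, `condition`, `batch` plus free covariate
#' columns.
#'
#' @param samples data.frame / `SampleTable`.
#' @param path file path.
#' @name metadata_io
NULL

#' @rdname metadata_io
#' @export
write_metadata_tsv <- function(samples, path) {
  write.table(as.data.frame(samples), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' @rdname metadata_io
#' @export
read_metadata_tsv <- function(path) {
  sample_table(read.delim(path, stringsAsFactors = FALSE))
}

#' Read a gene-to-GO annotation map
#'
#' Supports a two/three-column TSV (`gene`, `term`, optional `namespace`;
#' repeated rows per term, with or without a header) and GAF 2.x (`!`
#' comment lines; columns 2, 5, 9 give gene, term, aspect; aspect `P`
#' becomes namespace `BP`).
#'
#' @param path file path.
#' @param format `"auto"` (GAF when the first data line has >= 9 tab fields
#'   or the file starts with `!gaf`), `"tsv"`, or `"gaf"`.
#' @return data.frame `gene`, `term` and, when available, `namespace`.
#' @export
read_go_map <- function(path, format = c("auto", "tsv", "gaf")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto") {
    data1 <- lines[!startsWith(lines, "!")][1]
    format <- if (startsWith(lines[1], "!") ||
                  length(strsplit(data1, "\t", fixed = TRUE)[[1]]) >= 9)
      "gaf" else "tsv"
  }
  if (format == "gaf") {
    rows <- lines[!startsWith(lines, "!") & nzchar(lines)]
    f <- strsplit(rows, "\t", fixed = TRUE)
    ok <- vapply(f, length, 0L) >= 9
    if (!all(ok)) stop("malformed GAF row(s) in ", path)
    df <- data.frame(gene = vapply(f, `[`, "", 2),
                     term = vapply(f, `[`, "", 5),
                     namespace = vapply(f, `[`, "", 9),
                     stringsAsFactors = FALSE)
    df$namespace[df$namespace == "P"] <- "BP"
    df$namespace[df$namespace == "F"] <- "MF"
    df$namespace[df$namespace == "C"] <- "CC"
    return(df[!duplicated(paste(df$gene, df$term)), , drop = FALSE])
  }
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_header <- identical(first[1], "gene")
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header)
    names(df) <- c("gene", "term", "namespace")[seq_len(ncol(df))]
  df
}

#' Read and write network edge lists
#'
#' TSV columns: `gene_a`, `gene_b`, `weight`, `species`, `condition`
#' (plus `conditions` provenance on union networks).  Weights are printed
#' with six decimals so repeated runs are byte-identical.
#'
#' @param net a [network()].
#' @param path file path.
#' @param nodes node universe to use when reading (defaults to edge
#'   endpoints).
#' @name network_io
NULL

#' @rdname network_io
#' @export
write_network_tsv <- function(net, path) {
  e <- net$edges
  df <- data.frame(gene_a = e$gene_a, gene_b = e$gene_b,
                   weight = sprintf("%.6f", e$weight),
                   species = net$species, condition = net$condition,
                   stringsAsFactors = FALSE)
  if ("conditions" %in% names(e)) df$conditions <- e$conditions
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname network_io
#' @export
read_network_tsv <- function(path, nodes = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  species <- if (nrow(df)) df$species[1] else "species"
  condition <- if (nrow(df)) df$condition[1] else "condition"
  edges <- df[, intersect(c("gene_a", "gene_b", "weight", "conditions"),
                          names(df)), drop = FALSE]
  if (is.null(nodes)) nodes <- unique(c(edges$gene_a, edges$gene_b))
  network(species, condition, nodes, edges)
}

#' @rdname network_io
#' @export
write_network_graphml <- function(net, path) {
  g <- .as_igraph(net)
  if (nrow(net$edges))
    igraph::E(g)$weight <- net$edges$weight
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a precision set as a sparse upper-triangle TSV
#'
#' Columns `gene_a`, `gene_b`, `condition`, `theta` for every nonzero
#' (`|theta| > 1e-10`) upper-triangle entry.
#'
#' @param pset a `PrecisionSet`.
#' @param path file path.
#' @export
write_precision_tsv <- function(pset, path) {
  stopifnot(inherits(pset, "PrecisionSet"))
  rows <- lapply(seq_along(pset$theta), function(k) {
    Th <- pset$theta[[k]]
    genes <- rownames(Th)
    idx <- which(upper.tri(Th) & abs(Th) > 1e-10, arr.ind = TRUE)
    data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
               condition = pset$chain[k],
               theta = sprintf("%.8f", Th[idx]), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$condition, df$gene_a, df$gene_b), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a HOG network as TSV
#'
#' Columns `hog_a`, `hog_b`, `provenance` (semicolon-joined
#' `species:condition` entries).
#'
#' @param hog_net a `HogNetwork`.
#' @param path file path.
#' @export
write_hog_network_tsv <- function(hog_net, path) {
  df <- data.frame(hog_a = hog_net$edges$hog_a, hog_b = hog_net$edges$hog_b,
                   provenance = vapply(hog_net$edges$provenance,
                                       paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a ground truth to JSON
#'
#' Supports are written as sorted pair lists; precision matrices as dense
#' row-major arrays.
#'
#' @param truth a `GroundTruth`.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(
    condition_names = truth$condition_names,
    gene_ids = truth$gene_ids,
    shared_support = truth$shared_support,
    specific_support = truth$specific_support,
    precision_set = lapply(truth$precision_set, function(m) unname(m))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
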
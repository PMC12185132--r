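#' Counts per million
#'
#' Rescales each sample column to counts per million:
#' `cpm[g, s] = counts[g, s] / colsum(s) * 1e6`, so every column sums to
#' exactly one million.
#'
#' @param counts `ExpressionMatrix` at stage `"counts"` (all values >= 0).
#' @return `ExpressionMatrix` at stage `"cpm"`.
#' @export
compute_cpm <- function(counts) {
  .assert_stage(counts, "counts", "compute_cpm")
  v <- counts$values
  if (any(v < 0)) stop("counts must be non-negative")
  cs <- colSums(v)
  if (any(cs == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(v)[cs == 0], collapse = ", "))
  out <- sweep(v, 2, cs, "/") * 1e6
  .advance_stage(expression_matrix(out, "counts"), "cpm")
}

#' Gene filtering configuration
#'
#' @param cpm_threshold CPM value below which a sample counts as
#'   low-expression for a gene (default 10).
#' @param sample_fraction a gene is removed when at least
#'   `ceiling(sample_fraction * S)` of its S samples fall below the
#'   threshold (default 0.30).
#' @param require_go_bp drop genes without a biological-process GO term.
#' @param log_prior pseudo-value added before the log2 transform.
#' @return a `GeneFilterConfig` list.
#' @export
gene_filter_config <- function(cpm_threshold = 10, sample_fraction = 0.30,
                               require_go_bp = TRUE, log_prior = 0.5) {
  if (cpm_threshold <= 0) stop("cpm_threshold must be > 0")
  if (sample_fraction <= 0 || sample_fraction > 1)
    stop("sample_fraction must be in (0, 1]")
  if (log_prior <= 0) stop("log_prior must be > 0")
  structure(list(cpm_threshold = cpm_threshold,
                 sample_fraction = sample_fraction,
                 require_go_bp = require_go_bp,
                 log_prior = log_prior), class = "GeneFilterConfig")
}

#' Low-expression and annotation gene filter
#'
#' A gene is removed when its CPM falls below `cfg$cpm_threshold` in at
#' least `ceiling(cfg$sample_fraction * S)` of the S samples, or (when
#' `cfg$require_go_bp`) when it carries no biological-process GO term.
#' The returned ids preserve the input gene order.
#'
#' @param cpm `ExpressionMatrix` at stage `"cpm"`.
#' @param cfg a [gene_filter_config()].
#' @param go_map data.frame with columns `gene`, `term` and optionally
#'   `namespace` (`"BP"` rows select the biological-process domain; without
#'   a namespace column all terms are treated as BP).  May be `NULL` only
#'   when `cfg$require_go_bp` is `FALSE`.
#' @return character vector of kept gene ids.
#' @export
filter_genes <- function(cpm, cfg = gene_filter_config(), go_map = NULL) {
  .assert_stage(cpm, "cpm", "filter_genes")
  v <- cpm$values
  S <- ncol(v)
  low <- rowSums(v < cfg$cpm_threshold)
  keep <- low < ceiling(cfg$sample_fraction * S)
  if (cfg$require_go_bp) {
    if (is.null(go_map)) stop("require_go_bp = TRUE needs a go_map")
    bp_genes <- .bp_genes(go_map)
    keep <- keep & rownames(v) %in% bp_genes
  }
  kept <- rownames(v)[keep]
  if (length(kept) == 0)
    stop("no genes survive filtering; relax cpm_threshold or sample_fraction")
  kept
}

.bp_genes <- function(go_map) {
  stopifnot(all(c("gene", "term") %in% names(go_map)))
  if ("namespace" %in% names(go_map))
    unique(go_map$gene[go_map$namespace %in% c("BP", "P", "biological_process")])
  else unique(go_map$gene)
}

#' Log2 transform with a pseudo-value
#'
#' @param cpm `ExpressionMatrix` at stage `"cpm"`.
#' @param prior positive pseudo-value added before taking log2 (default 0.5,
#'   so a CPM of zero maps to -1).
#' @return `ExpressionMatrix` at stage `"log"`.
#' @export
log_transform <- function(cpm, prior = 0.5) {
  .assert_stage(cpm, "cpm", "log_transform")
  if (prior <= 0) stop("prior must be > 0")
  .advance_stage(expression_matrix(log2(cpm$values + prior), "counts"), "log")
}

#' Smoothed group-aware quantile normalization
#'
#' Quantile normalization that preserves genuine between-group differences:
#' per sample, sorted values are replaced by a convex combination
#' `w * overall quantile profile + (1 - w) * group quantile profile`.  The
#' weight per quantile is the within-group share of total variance across
#' samples at that quantile, `w = 1 - SSB/SST` (1 when group profiles
#' coincide, approaching 0 when between-group differences dominate),
#' smoothed along quantiles with a running median whose window spans
#' `window` of the quantiles.  Ties within a sample receive the average of
#' their reference values; the original per-sample rank order is restored.
#'
#' @param logmat `ExpressionMatrix` at stage `"log"`.
#' @param groups factor/character of length `ncol`, the group (treatment)
#'   label per sample; every group needs >= 2 samples.
#' @param window running-median window as a fraction of the number of
#'   quantiles (default 0.05).
#' @return `ExpressionMatrix` at stage `"normalized"`.
#' @export
smooth_quantile_normalize <- function(logmat, groups, window = 0.05) {
  .assert_stage(logmat, "log", "smooth_quantile_normalize")
  v <- logmat$values
  groups <- as.character(groups)
  if (length(groups) != ncol(v)) stop("one group label per sample required")
  tab <- table(groups)
  if (any(tab < 2))
    stop("groups with a single sample: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  G <- nrow(v); S <- ncol(v)
  Q <- apply(v, 2, sort)                      # G x S sorted columns
  q_ref <- rowMeans(Q)                        # overall quantile profile
  grp <- unique(groups)
  q_grp <- sapply(grp, function(g) rowMeans(Q[, groups == g, drop = FALSE]))

  # variance decomposition across samples at each quantile
  n_g <- as.numeric(tab[grp])
  sst <- rowSums((Q - q_ref)^2)
  ssb <- as.numeric((q_grp - q_ref)^2 %*% n_g)
  w <- ifelse(sst < 1e-12, 1, 1 - ssb / sst)
  w <- pmin(pmax(w, 0), 1)
  k <- max(3L, floor(window * G))
  if (k %% 2 == 0) k <- k + 1L
  if (k < G) w <- as.numeric(runmed(w, k, endrule = "constant"))

  out <- v
  for (s in seq_len(S)) {
    fitted <- w * q_ref + (1 - w) * q_grp[, match(groups[s], grp)]
    ord <- order(v[, s])
    assigned <- numeric(G)
    assigned[ord] <- fitted
    # tied input values share one (averaged) reference value
    out[, s] <- stats::ave(assigned, rank(v[, s], ties.method = "min"),
                           FUN = mean)
  }
  .advance_stage(expression_matrix(out, "counts"), "normalized")
}

#' Empirical-Bayes covariate adjustment
#'
#' Per gene, fits a linear model on all covariates (retained + unwanted,
#' columns of the sample table), shrinks each unwanted-covariate
#' coefficient toward its across-gene mean with weight
#' `tau^2 / (tau^2 + sigma_g^2 * c_jj)` (between-gene variance over between
#' plus the per-gene sampling variance of the coefficient), and subtracts
#' only the unwanted-covariate fitted component.  Covariate columns are
#' centered first so removal leaves each gene's mean untouched; the
#' retained-covariate contribution is never subtracted.
#'
#' @param normalized `ExpressionMatrix` at stage `"normalized"` (stage
#'   `"log"` is also accepted for workflows without group normalization).
#' @param samples `SampleTable` (or data.frame) with the covariate columns.
#' @param unwanted character, metadata columns to remove (default `"batch"`).
#' @param retained character, metadata columns whose variation must survive
#'   (default `"condition"`).
#' @return `ExpressionMatrix` at stage `"adjusted"`.
#' @export
eb_adjust <- function(normalized, samples, unwanted = "batch",
                      retained = "condition") {
  .assert_stage(normalized, c("log", "normalized"), "eb_adjust")
  v <- normalized$values
  if (length(unwanted) == 0 ||
      all(vapply(unwanted, function(u) length(unique(samples[[u]])) < 2, TRUE))) {
    return(.advance_stage(expression_matrix(v, "counts"), "adjusted"))
  }
  miss <- setdiff(c(unwanted, retained), names(samples))
  if (length(miss)) stop("metadata lacks covariates: ", paste(miss, collapse = ", "))
  X_parts <- lapply(c(retained, unwanted), function(cv) {
    x <- samples[[cv]]
    if (is.numeric(x)) {
      m <- matrix(x, ncol = 1, dimnames = list(NULL, cv))
    } else {
      x <- factor(x)
      m <- stats::model.matrix(~x)[, -1, drop = FALSE]
      colnames(m) <- paste0(cv, levels(x)[-1])
    }
    sweep(m, 2, colMeans(m))  # center so removal preserves gene means
  })
  names(X_parts) <- c(retained, unwanted)
  X <- cbind(`(Intercept)` = 1, do.call(cbind, X_parts))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("collinear covariate columns: ", paste(bad, collapse = ", "))
  }
  XtX_inv <- chol2inv(qr.R(qrX))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  B <- t(qr.coef(qrX, t(v)))                       # genes x coefficients
  fitted_all <- B %*% t(X)
  df_res <- ncol(v) - ncol(X)
  sigma2 <- rowSums((v - fitted_all)^2) / max(df_res, 1)

  unw_cols <- unlist(lapply(unwanted, function(cv) colnames(X_parts[[cv]])))
  B_unw <- B[, unw_cols, drop = FALSE]
  for (j in unw_cols) {
    b <- B_unw[, j]
    tau2 <- var(b)
    cjj <- XtX_inv[j, j]
    wgt <- if (is.na(tau2) || tau2 <= 0) rep(0, length(b)) else
      tau2 / (tau2 + sigma2 * cjj)
    B_unw[, j] <- wgt * b + (1 - wgt) * mean(b)
  }
  adj <- v - B_unw %*% t(X[, unw_cols, drop = FALSE])
  .advance_stage(expression_matrix(adj, "counts"), "adjusted")
}

#' Standardize genes to mean 0, variance 1
#'
#' Drops zero-variance genes (their ids are attached as attribute
#' `"dropped"`), then centers every remaining gene row to mean 0 and scales
#' it to unit variance using the population (1/n) convention.
#'
#' @param adjusted `ExpressionMatrix` at stage `"adjusted"`.
#' @return `ExpressionMatrix` at stage `"standardized"`, with attribute
#'   `"dropped"` listing removed gene ids.
#' @export
standardize <- function(adjusted) {
  .assert_stage(adjusted, "adjusted", "standardize")
  v <- adjusted$values
  n <- ncol(v)
  mu <- rowMeans(v)
  sd_pop <- sqrt(rowSums((v - mu)^2) / n)
  drop <- sd_pop < 1e-12
  if (all(drop)) stop("all genes have zero variance")
  out <- (v[!drop, , drop = FALSE] - mu[!drop]) / sd_pop[!drop]
  res <- .advance_stage(expression_matrix(out, "counts"), "standardized")
  attr(res, "dropped") <- rownames(v)[drop]
  res
}

#' Full preprocessing chain
#'
#' Convenience wrapper running [compute_cpm()], [filter_genes()],
#' [log_transform()], [smooth_quantile_normalize()], [eb_adjust()] and
#' [standardize()] in order.
#'
#' @inheritParams compute_cpm
#' @inheritParams filter_genes
#' @inheritParams eb_adjust
#' @param samples `SampleTable` paired with `counts`.
#' @return `ExpressionMatrix` at stage `"standardized"`.
#' @export
preprocess_counts <- function(counts, samples, cfg = gene_filter_config(),
                              go_map = NULL, unwanted = "batch",
                              retained = "condition") {
  samples <- sample_table(as.data.frame(samples), counts)
  cpm <- compute_cpm(counts)
  kept <- filter_genes(cpm, cfg, go_map)
  cpm$values <- cpm$values[kept, , drop = FALSE]
  lg <- log_transform(cpm, cfg$log_prior)
  nm <- smooth_quantile_normalize(lg, samples$condition)
  adj <- eb_adjust(nm, samples, unwanted = unwanted, retained = retained)
  standardize(adj)
}
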
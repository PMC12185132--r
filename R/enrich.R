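#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment
#' (`q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1); a thin wrapper
#' around [stats::p.adjust()] kept as the single adjustment route of the
#' package.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Hypergeometric GO overrepresentation analysis
#'
#' Tests each annotation term for overrepresentation in a query gene set
#' against a background (the genes that entered network construction).
#' Term sizes are computed after projection onto the background; terms with
#' background-projected size outside `[min_size, max_size]` are not tested.
#' `p = P[X >= k]` with `X ~ Hypergeom(N, K, n)`; BH adjustment across
#' tested terms; results filtered to `p <= p_cut` and `q <= q_cut`, sorted
#' by `q`, then `p`, then term id.
#'
#' @param query character vector of genes, must be a subset of `background`.
#' @param background character vector of background genes.
#' @param go_map data.frame `gene`, `term`.
#' @param min_size,max_size background-projected term size bounds.
#' @param p_cut,q_cut significance cutoffs applied to the output.
#' @return data.frame `term`, `k` (query hits), `n` (query size), `K`
#'   (term size in background), `N` (background size), `p`, `q`.
#' @export
ora <- function(query, background, go_map, min_size = 10, max_size = 500,
                p_cut = 0.05, q_cut = 0.05) {
  stopifnot(all(c("gene", "term") %in% names(go_map)))
  query <- unique(query)
  background <- unique(background)
  offenders <- setdiff(query, background)
  if (length(offenders))
    stop("query genes missing from background: ",
         paste(head(offenders, 5), collapse = ", "))
  if (nrow(go_map) == 0) stop("empty annotation map")
  gm <- go_map[go_map$gene %in% background, c("gene", "term")]
  gm <- gm[!duplicated(paste(gm$gene, gm$term)), , drop = FALSE]
  sizes <- table(gm$term)
  terms <- names(sizes)[sizes >= min_size & sizes <= max_size]
  N <- length(background)
  n <- length(query)
  res <- lapply(terms, function(tm) {
    members <- gm$gene[gm$term == tm]
    K <- length(members)
    k <- sum(query %in% members)
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(term = character(0), k = integer(0), n = integer(0),
               K = integer(0), N = integer(0), p = numeric(0),
               stringsAsFactors = FALSE)
  out$q <- if (nrow(out)) bh_adjust(out$p) else numeric(0)
  out <- out[out$p <= p_cut & out$q <= q_cut, , drop = FALSE]
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
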
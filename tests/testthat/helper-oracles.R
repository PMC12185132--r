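# Independent slow oracles used to validate the fast implementations.
# These deliberately use different algorithms than the package.

# 1-D total-variation prox by projected gradient on the dual (box QP).
oracle_tv1d <- function(y, lam, iters = 200000) {
  n <- length(y)
  if (n == 1 || lam <= 0) return(y)
  u <- rep(0, n - 1)
  for (i in seq_len(iters)) {
    x <- y - (c(0, u) - c(u, 0))
    g <- -diff(x)
    u_new <- pmin(pmax(u - 0.25 * g, -lam), lam)
    if (max(abs(u_new - u)) < 1e-14) { u <- u_new; break }
    u <- u_new
  }
  y - (c(0, u) - c(u, 0))
}

# Graphical lasso by projected gradient ascent on the dual:
#   max logdet(W)  s.t. |W_ij - S_ij| <= lam (i != j), W_ii = S_ii,
# with Theta = W^{-1}.  Entirely independent of the ADMM route.
oracle_glasso_dual <- function(S, lam, iters = 50000, tol = 1e-12) {
  p <- nrow(S)
  W <- S + diag(lam, p)
  diag(W) <- diag(S)
  W <- (W + t(W)) / 2
  if (min(eigen(W, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    W <- diag(diag(S))
  obj <- function(W) {
    e <- determinant(W, logarithm = TRUE)
    if (e$sign <= 0) -Inf else as.numeric(e$modulus)
  }
  step <- 0.1
  cur <- obj(W)
  for (i in seq_len(iters)) {
    G <- solve(W)
    Wn <- pmin(pmax(W + step * G, S - lam), S + lam)
    diag(Wn) <- diag(S)
    Wn <- (Wn + t(Wn)) / 2
    on <- obj(Wn)
    if (on < cur) {
      step <- step / 2
      if (step < 1e-14) break
      next
    }
    if (abs(on - cur) < tol && max(abs(Wn - W)) < 1e-10) { W <- Wn; break }
    W <- Wn
    cur <- on
    step <- step * 1.05
  }
  solve(W)
}

# Connected components by flood fill over an edge data.frame.
oracle_components <- function(nodes, edges) {
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  adj <- lapply(setNames(vector("list", length(nodes)), nodes), function(x) character(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  cid <- 0L
  for (v in nodes) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      w <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[w])) next
      comp[w] <- cid
      queue <- c(queue, adj[[w]][is.na(comp[adj[[w]]])])
    }
  }
  comp
}

# Brute-force clade-conservation rule over an explicit species set.
oracle_classify <- function(species_set, clade_map) {
  clades <- unique(unname(clade_map[species_set]))
  has <- function(cl) any(clades == cl)
  if (has("tracheophyte") && has("bryophyte") && has("zygnematophyte"))
    "conserved_ancestral"
  else if (has("tracheophyte") && has("bryophyte"))
    "land_plant"
  else "other"
}

# The nine-species study panel and its clade assignment.
study_clade_map <- c(
  "A. thaliana" = "tracheophyte", "O. sativa" = "tracheophyte",
  "Z. mays" = "tracheophyte", "S. lycopersicum" = "tracheophyte",
  "P. patens" = "bryophyte", "M. polymorpha" = "bryophyte",
  "M. endlicherianum" = "zygnematophyte",
  "Z. circumcarinatum" = "zygnematophyte",
  "C. reinhardtii" = "outgroup")

# Random correlation matrix (PD, unit diagonal).
random_corr <- function(p) {
  A <- matrix(rnorm(p * p), p)
  stats::cov2cor(crossprod(A) + diag(p) * 0.5)
}

# Standardize a latent matrix to the GGM input scale (population variance).
standardize_latent <- function(z) {
  zc <- z - rowMeans(z)
  zs <- zc / sqrt(rowSums(zc^2) / ncol(z))
  em <- expression_matrix(zs, "counts")
  em$stage <- "standardized"
  em
}

# Build a CovarianceSet directly from correlation matrices (test fixture).
cov_set <- function(S_list, n) {
  p <- nrow(S_list[[1]])
  genes <- sprintf("g%03d", seq_len(p))
  S_list <- lapply(S_list, function(S) { dimnames(S) <- list(genes, genes); S })
  structure(list(S = S_list, n = setNames(n, names(S_list)),
                 conditions = names(S_list), gene_ids = genes),
            class = "CovarianceSet")
}
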
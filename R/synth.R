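#' Generate a multi-condition ground-truth precision set
#'
#' Builds K sparse symmetric positive-definite precision matrices over the
#' same p genes: a common backbone of edges shared by every condition plus
#' condition-specific extra edges.  Off-diagonal entries are placed at
#' `+/- magnitude` (shared entries keep the same value in every condition);
#' positive definiteness is then enforced by diagonal repair (adding
#' `|min eigenvalue| + 0.1` to the diagonal when the minimum eigenvalue is
#' not positive).
#'
#' @param p number of genes (>= 3).
#' @param K number of conditions (>= 1).
#' @param shared_density fraction of the p(p-1)/2 gene pairs placed in every
#'   condition's support.
#' @param specific_density fraction of gene pairs added per condition on top
#'   of the shared backbone (disjoint from it).
#' @param magnitude absolute value of planted off-diagonal precision entries.
#' @param seed integer seed; the same seed reproduces the same truth.
#' @return a `GroundTruth` list: `precision_set` (named list of p x p
#'   matrices), `shared_support` and `specific_support` (data.frames of
#'   gene pairs, `gene_a < gene_b`), `condition_names`, `gene_ids`.
#' @export
make_precision_set <- function(p, K, shared_density, specific_density,
                               magnitude = 0.3, seed = 1) {
  if (p < 3) stop("p must be >= 3")
  if (K < 1) stop("K must be >= 1")
  if (shared_density < 0 || specific_density < 0 ||
      shared_density + specific_density >= 0.5)
    stop("densities must be non-negative with shared + specific < 0.5")
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(p))
  conditions <- .condition_names(K)
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)  # i < j
  n_pairs <- nrow(pairs)
  n_shared <- floor(shared_density * n_pairs)
  n_spec <- floor(specific_density * n_pairs)

  shared_idx <- if (n_shared > 0) sort(sample.int(n_pairs, n_shared)) else integer(0)
  shared_vals <- magnitude * sample(c(-1, 1), n_shared, replace = TRUE)
  remaining <- setdiff(seq_len(n_pairs), shared_idx)

  theta <- vector("list", K)
  names(theta) <- conditions
  specific <- vector("list", K)
  names(specific) <- conditions
  for (k in seq_len(K)) {
    spec_idx <- if (n_spec > 0) sort(sample(remaining, n_spec)) else integer(0)
    Th <- diag(p)
    if (n_shared > 0) {
      Th[pairs[shared_idx, , drop = FALSE]] <- shared_vals
    }
    if (n_spec > 0) {
      Th[pairs[spec_idx, , drop = FALSE]] <-
        magnitude * sample(c(-1, 1), n_spec, replace = TRUE)
    }
    Th[lower.tri(Th)] <- t(Th)[lower.tri(Th)]
    ev <- min(eigen(Th, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) {
      diag(Th) <- diag(Th) + abs(ev) + 0.1
      ev <- min(eigen(Th, symmetric = TRUE, only.values = TRUE)$values)
    }
    stopifnot(ev > 0)  # must hold after repair
    dimnames(Th) <- list(genes, genes)
    theta[[k]] <- Th
    specific[[k]] <- .pairs_df(genes, pairs[spec_idx, , drop = FALSE])
  }

  structure(list(
    precision_set = theta,
    shared_support = .pairs_df(genes, pairs[shared_idx, , drop = FALSE]),
    specific_support = specific,
    condition_names = conditions,
    gene_ids = genes,
    magnitude = magnitude
  ), class = "GroundTruth")
}

.condition_names <- function(K) {
  base <- c("control", "heat", "cold", "salt", "drought", "highlight",
            "uv", "aba")
  if (K <= length(base)) base[seq_len(K)] else
    c(base, sprintf("cond%02d", seq_len(K - length(base))))
}

.pairs_df <- function(genes, idx) {
  if (is.null(idx) || nrow(idx) == 0)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  df <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                   stringsAsFactors = FALSE)
  df[order(df$gene_a, df$gene_b), , drop = FALSE]
}

.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Simulate RNA-seq-like counts from a ground-truth precision set
#'
#' Draws latent per-sample expression `z ~ MVN(0, solve(Theta_k))` for each
#' condition, adds a per-gene baseline and an additive batch offset on the
#' latent (log-like) scale, maps through softplus to positive means, rescales
#' means to a library size sampled from `libsize_range`, and draws
#' negative-binomial counts (overdispersion `dispersion`).  Realized counts
#' are rescaled to the sampled library size so each sample's total matches
#' its library size up to rounding.
#'
#' @param truth a `GroundTruth` from [make_precision_set()].
#' @param n_per_condition integer vector, samples per condition (each >= 2).
#' @param batch_offsets numeric vector of additive latent-scale shifts, one
#'   per batch; samples are assigned to batches round-robin within condition.
#' @param libsize_range length-2 positive numeric, uniform sampling range of
#'   per-sample library sizes.
#' @param dispersion negative-binomial dispersion (variance = mu + disp*mu^2).
#' @param baseline_range latent-scale per-gene baseline sampling range.
#' @param seed integer seed.
#' @return list with `counts` (`ExpressionMatrix`, stage `"counts"`),
#'   `samples` (`SampleTable`), `latent` (genes x samples matrix of the raw
#'   MVN draws, before baseline/batch/softplus), and `library_sizes`.
#' @export
simulate_expression <- function(truth, n_per_condition,
                                batch_offsets = c(0, 0),
                                libsize_range = c(5e5, 2e6),
                                dispersion = 0.1,
                                baseline_range = c(2, 6),
                                seed = 1) {
  stopifnot(inherits(truth, "GroundTruth"))
  K <- length(truth$precision_set)
  if (length(n_per_condition) != K)
    stop("n_per_condition must have one entry per condition (K = ", K, ")")
  if (any(n_per_condition < 2)) stop("every condition needs >= 2 samples")
  if (any(libsize_range <= 0) || length(libsize_range) != 2)
    stop("libsize_range must be two positive numbers")
  set.seed(seed)
  p <- length(truth$gene_ids)
  n_batches <- length(batch_offsets)
  baseline <- runif(p, baseline_range[1], baseline_range[2])

  N <- sum(n_per_condition)
  latent <- matrix(NA_real_, p, N)
  counts <- matrix(NA_integer_, p, N)
  cond <- character(N)
  batch <- character(N)
  libs <- numeric(N)
  col <- 0L
  for (k in seq_len(K)) {
    R <- chol(truth$precision_set[[k]])  # Theta = R'R  =>  z = R^-1 eps
    nk <- n_per_condition[k]
    z <- backsolve(R, matrix(rnorm(p * nk), p, nk))
    for (j in seq_len(nk)) {
      col <- col + 1L
      b <- ((j - 1L) %% n_batches) + 1L
      latent[, col] <- z[, j]
      cond[col] <- truth$condition_names[k]
      batch[col] <- sprintf("batch%d", b)
      L <- runif(1, libsize_range[1], libsize_range[2])
      libs[col] <- L
      mu_raw <- .softplus(z[, j] + baseline + batch_offsets[b])
      mu <- mu_raw / sum(mu_raw) * L
      ct <- rnbinom(p, mu = mu, size = 1 / dispersion)
      if (sum(ct) > 0) ct <- round(ct * L / sum(ct))
      counts[, col] <- ct
    }
  }
  samples <- sprintf("s%04d", seq_len(N))
  dimnames(latent) <- list(truth$gene_ids, samples)
  dimnames(counts) <- list(truth$gene_ids, samples)
  meta <- sample_table(data.frame(sample = samples, condition = cond,
                                  batch = batch, stringsAsFactors = FALSE))
  list(counts = expression_matrix(counts, "counts"),
       samples = meta, latent = latent, library_sizes = libs)
}

#' Generate a multi-species orthogroup panel with planted conserved edges
#'
#' Creates a panel of species (each with 1-2 genes per HOG), per-species
#' edge lists, and a planted classification truth: a fraction of HOG pairs
#' is realized in at least one species of each of the tracheophyte,
#' bryophyte and zygnematophyte clades (ancestral-conserved under the
#' clade rule); the rest is split between land-plant-only pairs (>= 1
#' tracheophyte + >= 1 bryophyte, no zygnematophyte) and single-clade
#' pairs, so every non-planted pair violates the conservation rule.
#'
#' @param clade_map named character vector or data.frame (`species`,
#'   `clade`) mapping each species to a clade; must contain at least one
#'   species per required clade (`tracheophyte`, `bryophyte`,
#'   `zygnematophyte`).
#' @param hogs number of HOGs in the panel.
#' @param conserved_fraction fraction of planted HOG pairs that are
#'   ancestral-conserved.
#' @param n_pairs total number of planted HOG pairs.
#' @param conditions condition labels edges are assigned to.
#' @param seed integer seed.
#' @return a `SpeciesPanelTruth` list: `species`, `clade_map`, `hog_ids`,
#'   `hog_map` (per-species data.frame `gene`,`hog`), `edges` (per-species
#'   data.frame `gene_a`,`gene_b`,`condition`,`weight`),
#'   `planted_conserved`, `planted_landplant`, `planted_other`
#'   (data.frames of HOG pairs, `hog_a < hog_b`).
#' @export
make_species_panel <- function(clade_map, hogs = 60, conserved_fraction = 0.2,
                               n_pairs = 30,
                               conditions = c("control", "heat"),
                               seed = 1) {
  cm <- .as_clade_map(clade_map)
  required <- c("tracheophyte", "bryophyte", "zygnematophyte")
  for (cl in required) {
    if (!any(cm$clade == cl))
      stop("clade map has no species for required clade: ", cl)
  }
  if (conserved_fraction < 0 || conserved_fraction > 1)
    stop("conserved_fraction must be in [0, 1]")
  set.seed(seed)
  species <- cm$species
  hog_ids <- sprintf("N0.HOG%07d", seq_len(hogs))

  # 1-2 gene copies per species per HOG
  hog_map <- lapply(setNames(species, species), function(sp) {
    copies <- sample(1:2, hogs, replace = TRUE)
    data.frame(
      gene = unlist(lapply(seq_len(hogs), function(h)
        sprintf("%s_h%03d_%d", sp, h, seq_len(copies[h])))),
      hog = rep(hog_ids, copies),
      stringsAsFactors = FALSE
    )
  })

  all_pairs <- which(upper.tri(diag(hogs)), arr.ind = TRUE)
  if (n_pairs > nrow(all_pairs)) stop("n_pairs exceeds available HOG pairs")
  sel <- sample.int(nrow(all_pairs), n_pairs)
  n_cons <- round(conserved_fraction * n_pairs)
  n_lp <- floor((n_pairs - n_cons) / 2)
  kind <- c(rep("conserved", n_cons), rep("landplant", n_lp),
            rep("other", n_pairs - n_cons - n_lp))

  sp_by_clade <- split(cm$species, cm$clade)
  edges <- lapply(setNames(species, species), function(sp)
    data.frame(gene_a = character(0), gene_b = character(0),
               condition = character(0), weight = numeric(0),
               stringsAsFactors = FALSE))

  pick <- function(clade, nmax = 2) {
    pool <- sp_by_clade[[clade]]
    sample(pool, min(length(pool), sample.int(nmax, 1)))
  }
  realize <- function(sp, h1, h2) {
    m <- hog_map[[sp]]
    ga <- sample(m$gene[m$hog == hog_ids[h1]], 1)
    gb <- sample(m$gene[m$hog == hog_ids[h2]], 1)
    data.frame(gene_a = min(ga, gb), gene_b = max(ga, gb),
               condition = sample(conditions, 1),
               weight = round(runif(1, 0.1, 0.9), 3),
               stringsAsFactors = FALSE)
  }

  for (i in seq_len(n_pairs)) {
    h1 <- all_pairs[sel[i], 1]; h2 <- all_pairs[sel[i], 2]
    sps <- switch(kind[i],
      conserved = unique(c(pick("tracheophyte"), pick("bryophyte"),
                           pick("zygnematophyte"))),
      landplant = unique(c(pick("tracheophyte"), pick("bryophyte"))),
      other = {
        cl <- sample(names(sp_by_clade), 1)
        unique(pick(cl))
      })
    for (sp in sps) edges[[sp]] <- rbind(edges[[sp]], realize(sp, h1, h2))
  }

  pair_frame <- function(kk) {
    idx <- all_pairs[sel[kind == kk], , drop = FALSE]
    df <- data.frame(hog_a = hog_ids[pmin(idx[, 1], idx[, 2])],
                     hog_b = hog_ids[pmax(idx[, 1], idx[, 2])],
                     stringsAsFactors = FALSE)
    df[order(df$hog_a, df$hog_b), , drop = FALSE]
  }

  structure(list(
    species = species, clade_map = cm, hog_ids = hog_ids,
    hog_map = hog_map, edges = edges,
    planted_conserved = pair_frame("conserved"),
    planted_landplant = pair_frame("landplant"),
    planted_other = pair_frame("other")
  ), class = "SpeciesPanelTruth")
}

.as_clade_map <- function(clade_map) {
  if (is.data.frame(clade_map)) {
    stopifnot(all(c("species", "clade") %in% names(clade_map)))
    cm <- data.frame(species = as.character(clade_map$species),
                     clade = as.character(clade_map$clade),
                     stringsAsFactors = FALSE)
  } else if (!is.null(names(clade_map))) {
    cm <- data.frame(species = names(clade_map),
                     clade = as.character(clade_map),
                     stringsAsFactors = FALSE)
  } else stop("clade_map must be a named vector or a species/clade data.frame")
  if (anyDuplicated(cm$species)) stop("duplicate species in clade map")
  cm
}

#' Random gene-to-term annotation map for synthetic runs
#'
#' Assigns genes to GO-like terms (ids `SYN:0000001`, ...) with term sizes
#' drawn from `term_size_range`, optionally seeding the first terms on
#' supplied gene sets (e.g. network neighborhoods) so that enrichment has
#' planted signal.
#'
#' @param genes character vector of gene ids (the annotation universe).
#' @param n_terms number of terms.
#' @param term_size_range length-2 integer range of genes per term.
#' @param planted optional named list of gene sets to use as the first terms.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `term`.
#' @export
make_go_map <- function(genes, n_terms = 15, term_size_range = c(10, 20),
                        planted = NULL, seed = 1) {
  set.seed(seed)
  stopifnot(length(genes) >= max(term_size_range))
  out <- list()
  i <- 0
  for (nm in names(planted)) {
    i <- i + 1
    out[[length(out) + 1]] <- data.frame(gene = planted[[nm]], term = nm,
                                         stringsAsFactors = FALSE)
  }
  while (i < n_terms) {
    i <- i + 1
    size <- sample(term_size_range[1]:term_size_range[2], 1)
    out[[length(out) + 1]] <- data.frame(
      gene = sample(genes, size),
      term = sprintf("SYN:%07d", i),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
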
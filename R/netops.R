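#' Co-expression network object
#'
#' @param species species label.
#' @param condition condition label (or `"union"`).
#' @param nodes character vector of gene ids (isolated nodes allowed and
#'   retained for component statistics).
#' @param edges data.frame with columns `gene_a`, `gene_b`, `weight` (and
#'   optionally `conditions`, a semicolon-joined provenance list on union
#'   networks).
#' @return a `Network` object.
#' @export
network <- function(species, condition, nodes, edges) {
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  if (nrow(edges)) {
    a <- pmin(edges$gene_a, edges$gene_b)
    b <- pmax(edges$gene_a, edges$gene_b)
    edges$gene_a <- a
    edges$gene_b <- b
    if (any(a == b)) stop("self-loops are not allowed")
    if (anyDuplicated(paste(a, b)))
      stop("duplicate edges are not allowed")
    bad <- setdiff(unique(c(a, b)), nodes)
    if (length(bad))
      stop("edge endpoints missing from nodes: ",
           paste(head(bad, 5), collapse = ", "))
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(species = species, condition = condition,
                 nodes = sort(unique(nodes)), edges = edges),
            class = "Network")
}

#' @export
#' @method print Network
print.Network <- function(x, ...) {
  cat(sprintf("Network [%s / %s]: %d nodes, %d edges\n",
              x$species, x$condition, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Precision matrix to thresholded partial-correlation network
#'
#' Converts a precision matrix into a network: edge weight is the partial
#' correlation `r_ij = -theta_ij / sqrt(theta_ii * theta_jj)`, kept when
#' `|r_ij| >= tau`.  All genes stay as nodes so component statistics count
#' isolated genes.
#'
#' @param theta symmetric precision matrix with positive diagonal (gene ids
#'   as dimnames).
#' @param tau truncation threshold on `|partial correlation|`.
#' @param species,condition labels stamped on the network.
#' @return a [network()].
#' @export
precision_to_network <- function(theta, tau = 0.05, species = "species",
                                 condition = "condition") {
  if (!isSymmetric(unname(theta), tol = 1e-8)) stop("theta must be symmetric")
  d <- diag(theta)
  if (any(d <= 0)) stop("precision diagonal must be positive")
  genes <- rownames(theta)
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(theta)))
  r <- -theta / sqrt(outer(d, d))
  idx <- which(upper.tri(r) & abs(r) >= tau, arr.ind = TRUE)
  edges <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                      weight = r[idx], stringsAsFactors = FALSE)
  network(species, condition, genes, edges)
}

#' Union of one species' condition networks
#'
#' Edge set is the union across conditions; each edge keeps the largest
#' absolute weight among its contributing conditions and a semicolon-joined
#' `conditions` provenance column.
#'
#' @param networks list of [network()] objects of one species.
#' @return a [network()] with `condition = "union"`.
#' @export
union_conditions <- function(networks) {
  stopifnot(length(networks) >= 1)
  species <- unique(vapply(networks, function(n) n$species, ""))
  if (length(species) != 1) stop("all networks must share one species")
  nodes <- sort(unique(unlist(lapply(networks, function(n) n$nodes))))
  ed <- do.call(rbind, lapply(networks, function(n) {
    if (nrow(n$edges) == 0)
      return(data.frame(gene_a = character(0), gene_b = character(0),
                        weight = numeric(0), condition = character(0),
                        stringsAsFactors = FALSE))
    data.frame(n$edges[c("gene_a", "gene_b", "weight")],
               condition = n$condition, stringsAsFactors = FALSE)
  }))
  if (nrow(ed) == 0) {
    return(network(species, "union", nodes,
                   data.frame(gene_a = character(0), gene_b = character(0),
                              weight = numeric(0), conditions = character(0),
                              stringsAsFactors = FALSE)))
  }
  key <- paste(ed$gene_a, ed$gene_b, sep = "|")
  keep <- !duplicated(key)
  out <- ed[keep, c("gene_a", "gene_b", "weight")]
  out$weight <- vapply(key[keep], function(k) {
    w <- ed$weight[key == k]
    w[which.max(abs(w))]
  }, 0)
  out$conditions <- vapply(key[keep], function(k)
    paste(sort(unique(ed$condition[key == k])), collapse = ";"), "")
  network(species, "union", nodes, out)
}

#' Forming and dissolving edges between two networks
#'
#' @param net_a,net_b [network()] objects of the same species over the same
#'   node universe.
#' @return list with `forming` (edges in `net_a` only) and `dissolving`
#'   (edges in `net_b` only), both edge data.frames.
#' @export
differential_edges <- function(net_a, net_b) {
  if (!identical(net_a$species, net_b$species))
    stop("differential edges require one species")
  if (!setequal(net_a$nodes, net_b$nodes))
    stop("networks must share a node universe")
  ka <- .pair_key(net_a$edges$gene_a, net_a$edges$gene_b)
  kb <- .pair_key(net_b$edges$gene_a, net_b$edges$gene_b)
  list(forming = net_a$edges[!ka %in% kb, , drop = FALSE],
       dissolving = net_b$edges[!kb %in% ka, , drop = FALSE])
}

.as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
}

#' Basic network statistics
#'
#' @param net a [network()].
#' @param top_n how many hubs (highest degree; ties broken by gene id) to
#'   report.
#' @return list: `edges`, `nodes`, `components`, `largest_component`,
#'   `hubs` (data.frame `gene`, `degree`).
#' @export
network_stats <- function(net, top_n = 10) {
  g <- .as_igraph(net)
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  ord <- order(-deg, names(deg))
  hubs <- data.frame(gene = names(deg)[ord], degree = as.integer(deg[ord]),
                     stringsAsFactors = FALSE)[seq_len(min(top_n, length(deg))), ]
  rownames(hubs) <- NULL
  list(edges = nrow(net$edges), nodes = length(net$nodes),
       components = comp$no,
       largest_component = if (comp$no) max(comp$csize) else 0L,
       hubs = hubs)
}

#' First-degree neighborhood of a seed gene set
#'
#' Guilt-by-association helper: all direct neighbors of any seed gene,
#' excluding the seeds themselves, sorted.
#'
#' @param net a [network()].
#' @param seeds character vector of seed gene ids; unknown ids are skipped
#'   with a warning (an error only when all are unknown).
#' @return sorted character vector of neighbor gene ids.
#' @export
neighborhood_of_set <- function(net, seeds) {
  known <- intersect(seeds, net$nodes)
  unknown <- setdiff(seeds, net$nodes)
  if (length(known) == 0) stop("no seed gene is present in the network")
  if (length(unknown))
    warning("skipping unknown seed gene(s): ",
            paste(unknown, collapse = ", "))
  e <- net$edges
  nb <- c(e$gene_b[e$gene_a %in% known], e$gene_a[e$gene_b %in% known])
  sort(setdiff(unique(nb), known))
}

#' Project a gene network into orthogroup (HOG) space
#'
#' Every edge whose two genes map to two different HOGs becomes a HOG edge
#' carrying `(species, condition)` provenance; parallel gene edges merge
#' into one HOG edge with merged provenance.  Edges with an unmapped gene
#' and within-HOG (paralog) edges are dropped and counted.
#'
#' @param net a [network()]; union networks contribute one provenance entry
#'   per original condition in their `conditions` column.
#' @param hog_map data.frame `gene`, `hog` for the network's species.
#' @return a `HogNetwork`: list with `edges` (data.frame `hog_a`, `hog_b`
#'   plus list-column `provenance` of `"species:condition"` strings),
#'   `dropped_unmapped`, `dropped_self`.
#' @export
project_to_hogs <- function(net, hog_map) {
  stopifnot(all(c("gene", "hog") %in% names(hog_map)))
  if (anyDuplicated(hog_map$gene))
    stop("a gene maps to more than one HOG")
  map <- setNames(hog_map$hog, hog_map$gene)
  e <- net$edges
  prov_of <- function(i) {
    conds <- if ("conditions" %in% names(e))
      strsplit(e$conditions[i], ";", fixed = TRUE)[[1]]
    else net$condition
    paste(net$species, conds, sep = ":")
  }
  ha <- unname(map[e$gene_a])
  hb <- unname(map[e$gene_b])
  unmapped <- is.na(ha) | is.na(hb)
  self <- !unmapped & ha == hb
  keep <- which(!unmapped & !self)
  if (length(keep) == 0) {
    edges <- data.frame(hog_a = character(0), hog_b = character(0),
                        stringsAsFactors = FALSE)
    edges$provenance <- list()
  } else {
    a <- pmin(ha[keep], hb[keep])
    b <- pmax(ha[keep], hb[keep])
    key <- paste(a, b, sep = "|")
    uk <- !duplicated(key)
    edges <- data.frame(hog_a = a[uk], hog_b = b[uk], stringsAsFactors = FALSE)
    edges$provenance <- lapply(key[uk], function(k) {
      idx <- keep[key == k]
      sort(unique(unlist(lapply(idx, prov_of))))
    })
    edges <- edges[order(edges$hog_a, edges$hog_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges,
                 dropped_unmapped = sum(unmapped),
                 dropped_self = sum(self)),
            class = "HogNetwork")
}

#' @export
#' @method print HogNetwork
print.HogNetwork <- function(x, ...) {
  cat(sprintf("HogNetwork: %d HOG edges (%d unmapped, %d self-HOG dropped)\n",
              nrow(x$edges), x$dropped_unmapped, x$dropped_self))
  invisible(x)
}

.hog_key <- function(hn) paste(hn$edges$hog_a, hn$edges$hog_b, sep = "|")

#' Merge HOG networks (edge union, provenance union)
#'
#' @param hog_nets list of `HogNetwork` objects (one per species).
#' @return a `HogNetwork` whose edges are the union, each with the union of
#'   contributing provenances.
#' @export
union_hog_networks <- function(hog_nets) {
  stopifnot(length(hog_nets) >= 1)
  all_e <- do.call(rbind, lapply(hog_nets, function(h)
    h$edges[, c("hog_a", "hog_b"), drop = FALSE]))
  prov <- unlist(lapply(hog_nets, function(h) h$edges$provenance),
                 recursive = FALSE)
  key <- paste(all_e$hog_a, all_e$hog_b, sep = "|")
  uk <- !duplicated(key)
  edges <- all_e[uk, , drop = FALSE]
  edges$provenance <- lapply(key[uk], function(k)
    sort(unique(unlist(prov[key == k]))))
  edges <- edges[order(edges$hog_a, edges$hog_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, dropped_unmapped = 0L, dropped_self = 0L),
            class = "HogNetwork")
}

#' Intersection of HOG networks across species
#'
#' @param hog_nets list of >= 2 `HogNetwork` objects.
#' @return a `HogNetwork` holding only edges present in every input, with
#'   provenance merged across inputs.
#' @export
intersect_across_species <- function(hog_nets) {
  stopifnot(length(hog_nets) >= 2)
  keys <- lapply(hog_nets, .hog_key)
  common <- Reduce(intersect, keys)
  merged <- union_hog_networks(hog_nets)
  keep <- .hog_key(merged) %in% common
  merged$edges <- merged$edges[keep, , drop = FALSE]
  rownames(merged$edges) <- NULL
  merged
}

#' Classify a HOG edge's clade conservation
#'
#' Applies the clade rule to the species supporting an edge:
#' `conserved_ancestral` when the species cover all three of tracheophyte,
#' bryophyte and zygnematophyte; else `land_plant` when they cover
#' tracheophyte and bryophyte; else `other`.  Conditions in the provenance
#' are ignored — presence in any condition counts.
#'
#' @param provenance character vector of `"species:condition"` entries (or
#'   bare species names) supporting one edge.
#' @param clade_map named character vector or `species`/`clade` data.frame.
#' @return list: `label` (one of `"conserved_ancestral"`, `"land_plant"`,
#'   `"other"`), `species`, `clades`.
#' @export
classify_conservation <- function(provenance, clade_map) {
  cm <- .as_clade_map(clade_map)
  sp <- unique(sub(":.*$", "", provenance))
  unknown <- setdiff(sp, cm$species)
  if (length(unknown))
    stop("species without clade assignment: ", paste(unknown, collapse = ", "))
  clades <- unique(cm$clade[match(sp, cm$species)])
  label <- if (all(c("tracheophyte", "bryophyte", "zygnematophyte") %in% clades))
    "conserved_ancestral"
  else if (all(c("tracheophyte", "bryophyte") %in% clades))
    "land_plant"
  else "other"
  list(label = label, species = sort(sp), clades = sort(clades))
}

#' Classify every edge of a HOG network
#'
#' @param hog_net a `HogNetwork`.
#' @param clade_map species-to-clade map.
#' @return data.frame `hog_a`, `hog_b`, `label`, `n_species`, `clades`
#'   (semicolon-joined).
#' @export
classify_hog_edges <- function(hog_net, clade_map) {
  if (nrow(hog_net$edges) == 0)
    return(data.frame(hog_a = character(0), hog_b = character(0),
                      label = character(0), n_species = integer(0),
                      clades = character(0), stringsAsFactors = FALSE))
  res <- lapply(hog_net$edges$provenance, classify_conservation, clade_map)
  data.frame(hog_a = hog_net$edges$hog_a, hog_b = hog_net$edges$hog_b,
             label = vapply(res, `[[`, "", "label"),
             n_species = vapply(res, function(r) length(r$species), 0L),
             clades = vapply(res, function(r) paste(r$clades, collapse = ";"), ""),
             stringsAsFactors = FALSE)
}

#' Shared and exclusive edge tallies per clade combination
#'
#' For every unordered clade pair (X, Y): the number of HOG edges supported
#' by at least one species of X and one of Y.  For every clade X: the
#' number of edges whose supporting species all lie in X ("exclusive";
#' these sets are mutually disjoint across clades).
#'
#' @param hog_nets list of `HogNetwork` objects (per species) or a single
#'   merged `HogNetwork`.
#' @param clade_map species-to-clade map.
#' @return list with `pairs` (data.frame `clade_x`, `clade_y`, `count`) and
#'   `exclusive` (data.frame `clade`, `count`).
#' @export
clade_sharing_tallies <- function(hog_nets, clade_map) {
  cm <- .as_clade_map(clade_map)
  merged <- if (inherits(hog_nets, "HogNetwork")) hog_nets
            else union_hog_networks(hog_nets)
  clade_sets <- lapply(merged$edges$provenance, function(pr) {
    sp <- unique(sub(":.*$", "", pr))
    unknown <- setdiff(sp, cm$species)
    if (length(unknown))
      stop("species without clade assignment: ",
           paste(unknown, collapse = ", "))
    unique(cm$clade[match(sp, cm$species)])
  })
  clades <- sort(unique(cm$clade))
  pairs <- expand.grid(clade_x = clades, clade_y = clades,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$clade_x < pairs$clade_y, , drop = FALSE]
  pairs$count <- vapply(seq_len(nrow(pairs)), function(i)
    sum(vapply(clade_sets, function(cs)
      pairs$clade_x[i] %in% cs && pairs$clade_y[i] %in% cs, TRUE)), 0L)
  exclusive <- data.frame(clade = clades, count = vapply(clades, function(cl)
    sum(vapply(clade_sets, function(cs)
      length(cs) == 1 && cs == cl, TRUE)), 0L),
    stringsAsFactors = FALSE)
  rownames(pairs) <- rownames(exclusive) <- NULL
  list(pairs = pairs, exclusive = exclusive)
}
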
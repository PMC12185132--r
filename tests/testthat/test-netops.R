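path_net <- function() {
  network("sp", "cond", c("a", "b", "c"),
          data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                     weight = c(0.5, -0.4)))
}

test_that("precision-to-network applies truncation on partial correlations", {
  Th <- matrix(c(1, -0.3, -0.3, 1), 2,
               dimnames = list(c("g1", "g2"), c("g1", "g2")))
  net <- precision_to_network(Th, tau = 0.05)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 0.3)

  Th2 <- matrix(c(1, -0.04, -0.04, 1), 2,
                dimnames = list(c("g1", "g2"), c("g1", "g2")))
  expect_equal(nrow(precision_to_network(Th2, tau = 0.05)$edges), 0)

  D <- diag(3); dimnames(D) <- list(letters[1:3], letters[1:3])
  net_d <- precision_to_network(D)
  expect_equal(nrow(net_d$edges), 0)
  expect_equal(network_stats(net_d)$components, 3)

  bad <- Th; bad[1, 1] <- -1
  expect_error(precision_to_network(bad), "diagonal")
})

test_that("condition unions merge edges with provenance and max weight", {
  n1 <- network("sp", "heat", c("a", "b", "c", "d"),
                data.frame(gene_a = "a", gene_b = "b", weight = 0.2))
  n2 <- network("sp", "cold", c("a", "b", "c", "d"),
                data.frame(gene_a = c("c", "a"), gene_b = c("d", "b"),
                           weight = c(0.6, -0.9)))
  u <- union_conditions(list(n1, n2))
  expect_equal(u$condition, "union")
  expect_equal(nrow(u$edges), 2)
  ab <- u$edges[u$edges$gene_a == "a", ]
  expect_equal(ab$weight, -0.9)          # max |weight| wins
  expect_equal(ab$conditions, "cold;heat")

  # idempotence
  u2 <- union_conditions(list(n1, n1))
  expect_equal(u2$edges$gene_a, n1$edges$gene_a)
  expect_equal(nrow(u2$edges), nrow(n1$edges))

  expect_error(union_conditions(list(n1, network("other", "x", "a",
    data.frame(gene_a = character(0), gene_b = character(0),
               weight = numeric(0))))), "one species")
})

test_that("union size is bounded by the sum with equality iff disjoint", {
  set.seed(1)
  nodes <- sprintf("g%02d", 1:8)
  for (rep in 1:20) {
    mk <- function() {
      pairs <- t(combn(nodes, 2))
      sel <- sample(nrow(pairs), sample(3:10, 1))
      network("sp", paste0("c", rep),
              nodes, data.frame(gene_a = pairs[sel, 1], gene_b = pairs[sel, 2],
                                weight = runif(length(sel), 0.1, 1)))
    }
    a <- mk(); b <- mk()
    u <- union_conditions(list(a, b))
    ka <- paste(a$edges$gene_a, a$edges$gene_b)
    kb <- paste(b$edges$gene_a, b$edges$gene_b)
    expect_lte(nrow(u$edges), nrow(a$edges) + nrow(b$edges))
    expect_equal(nrow(u$edges) == nrow(a$edges) + nrow(b$edges),
                 length(intersect(ka, kb)) == 0)
  }
})

test_that("differential edges partition the edge sets", {
  a <- path_net()
  d0 <- differential_edges(a, a)
  expect_equal(nrow(d0$forming), 0)
  expect_equal(nrow(d0$dissolving), 0)

  b <- network("sp", "x", c("a", "b", "c"),
               data.frame(gene_a = character(0), gene_b = character(0),
                          weight = numeric(0)))
  d1 <- differential_edges(a, b)
  expect_equal(nrow(d1$forming), 2)
  expect_equal(nrow(d1$dissolving), 0)

  set.seed(2)
  nodes <- sprintf("g%02d", 1:7)
  for (rep in 1:15) {
    pairs <- t(combn(nodes, 2))
    mk <- function() {
      sel <- sample(nrow(pairs), sample(2:8, 1))
      network("sp", "c", nodes,
              data.frame(gene_a = pairs[sel, 1], gene_b = pairs[sel, 2],
                         weight = runif(length(sel), 0.1, 1)))
    }
    x <- mk(); y <- mk()
    d <- differential_edges(x, y)
    kx <- paste(x$edges$gene_a, x$edges$gene_b)
    ky <- paste(y$edges$gene_a, y$edges$gene_b)
    expect_equal(nrow(d$forming) + length(intersect(kx, ky)), nrow(x$edges))
  }
})

test_that("network statistics match an independent flood-fill oracle", {
  p <- path_net()
  st <- network_stats(p)
  expect_equal(st$edges, 2)
  expect_equal(st$nodes, 3)
  expect_equal(st$components, 1)
  expect_equal(st$largest_component, 3)
  expect_equal(st$hubs$gene[1], "b")
  expect_equal(st$hubs$degree[1], 2)

  empty <- network("sp", "c", letters[1:4],
                   data.frame(gene_a = character(0), gene_b = character(0),
                              weight = numeric(0)))
  expect_equal(network_stats(empty)$components, 4)

  set.seed(3)
  for (rep in 1:10) {
    nodes <- sprintf("g%02d", 1:12)
    pairs <- t(combn(nodes, 2))
    sel <- sample(nrow(pairs), sample(0:15, 1))
    net <- network("sp", "c", nodes,
                   data.frame(gene_a = pairs[sel, 1], gene_b = pairs[sel, 2],
                              weight = rep(0.5, length(sel))))
    st <- network_stats(net)
    comp <- oracle_components(nodes, net$edges)
    expect_equal(st$components, length(unique(comp)))
    expect_equal(st$largest_component,
                 if (length(comp)) max(table(comp)) else 0L)
  }
})

test_that("neighborhoods exclude seeds and tolerate unknown ids", {
  p <- path_net()
  expect_equal(neighborhood_of_set(p, "b"), c("a", "c"))
  expect_warning(nb <- neighborhood_of_set(p, c("b", "zzz")), "zzz")
  expect_equal(nb, c("a", "c"))
  expect_error(neighborhood_of_set(p, "zzz"), "no seed")
  # isolated seed has no neighbors; result never contains seeds
  iso <- network("sp", "c", c("a", "b", "x"),
                 data.frame(gene_a = "a", gene_b = "b", weight = 0.5))
  expect_length(neighborhood_of_set(iso, "x"), 0)
  expect_length(intersect(neighborhood_of_set(p, c("a", "b")), c("a", "b")), 0)
})

test_that("the N0.tsv dialect parses and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "HOG\tOG\tGene Tree Parent Clade\tspeciesA\tspeciesB",
    "N0.HOG0000001\tOG01\tn0\tgeneA1, geneA2\tgeneB1",
    "N0.HOG0000002\tOG02\tn0\t\tgeneB2"), f)
  maps <- parse_hog_map(f)
  expect_named(maps, c("speciesA", "speciesB"))
  expect_equal(maps$speciesA$gene, c("geneA1", "geneA2"))
  expect_equal(maps$speciesA$hog, rep("N0.HOG0000001", 2))
  expect_equal(maps$speciesB$hog, c("N0.HOG0000001", "N0.HOG0000002"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_hog_map(maps, f2)
  expect_equal(parse_hog_map(f2), maps)

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "HOG\tOG\tGene Tree Parent Clade\tspeciesA\tspeciesB",
    "N0.HOG0000001\tOG01\tn0\tgeneA1\tgeneB1",
    "N0.HOG0000002\tOG02\tn0\tgeneA1\t"), f3)
  expect_error(parse_hog_map(f3), "multiple HOGs")
})

test_that("HOG projection collapses paralogs and drops self/unmapped edges", {
  hm <- data.frame(gene = c("a1", "a2", "b1"),
                   hog = c("H1", "H1", "H2"))
  net <- network("sp", "heat", c("a1", "a2", "b1", "x"),
                 data.frame(gene_a = c("a1", "a2", "a1", "b1"),
                            gene_b = c("b1", "b1", "a2", "x"),
                            weight = c(0.5, 0.6, 0.7, 0.8)))
  hn <- project_to_hogs(net, hm)
  expect_equal(nrow(hn$edges), 1)           # a1-b1 and a2-b1 collapse
  expect_equal(hn$edges$hog_a, "H1")
  expect_equal(hn$edges$hog_b, "H2")
  expect_equal(hn$edges$provenance[[1]], "sp:heat")
  expect_equal(hn$dropped_self, 1)          # a1-a2 inside H1
  expect_equal(hn$dropped_unmapped, 1)      # b1-x, x unmapped

  expect_error(project_to_hogs(net, rbind(hm, data.frame(gene = "a1",
                                                         hog = "H9"))),
               "more than one HOG")
})

test_that("HOG set algebra obeys union/intersection laws", {
  mk_hn <- function(pairs, prov) {
    edges <- data.frame(hog_a = pairs[, 1], hog_b = pairs[, 2],
                        stringsAsFactors = FALSE)
    edges$provenance <- rep(list(prov), nrow(edges))
    structure(list(edges = edges, dropped_unmapped = 0L, dropped_self = 0L),
              class = "HogNetwork")
  }
  h1 <- mk_hn(cbind(c("H1", "H2"), c("H3", "H4")), "sp1:c")
  h2 <- mk_hn(cbind(c("H1", "H5"), c("H3", "H6")), "sp2:c")

  ii <- intersect_across_species(list(h1, h1))
  expect_equal(ii$edges[, 1:2], h1$edges[, 1:2])

  id <- intersect_across_species(list(h1, mk_hn(cbind("H7", "H8"), "sp2:c")))
  expect_equal(nrow(id$edges), 0)

  ix <- intersect_across_species(list(h1, h2))
  expect_equal(nrow(ix$edges), 1)
  expect_setequal(ix$edges$provenance[[1]], c("sp1:c", "sp2:c"))
  expect_true(all(paste(ix$edges$hog_a, ix$edges$hog_b) %in%
                  paste(h1$edges$hog_a, h1$edges$hog_b)))

  uu <- union_hog_networks(list(h1, h2))
  expect_equal(nrow(uu$edges), 3)
  # union is commutative
  uu2 <- union_hog_networks(list(h2, h1))
  expect_equal(uu$edges[, 1:2], uu2$edges[, 1:2])
})

test_that("the conservation rule labels the worked species examples", {
  cm <- study_clade_map
  expect_equal(classify_conservation(
    c("O. sativa:heat", "P. patens:heat", "Z. circumcarinatum:heat"),
    cm)$label, "conserved_ancestral")
  expect_equal(classify_conservation(
    c("A. thaliana:cold", "M. polymorpha:cold"), cm)$label, "land_plant")
  expect_equal(classify_conservation(
    c("M. endlicherianum:heat", "Z. circumcarinatum:salt"), cm)$label,
    "other")
  expect_error(classify_conservation("Unknown species:heat", cm),
               "without clade")
})

test_that("clade tallies count shared and exclusive edges as a partition", {
  cm <- c(t1 = "tracheophyte", b1 = "bryophyte", z1 = "zygnematophyte")
  mk <- function(a, b, prov) {
    edges <- data.frame(hog_a = a, hog_b = b, stringsAsFactors = FALSE)
    edges$provenance <- prov
    structure(list(edges = edges, dropped_unmapped = 0L, dropped_self = 0L),
              class = "HogNetwork")
  }
  hn <- mk(c("H1", "H2", "H3", "H4", "H5"),
           c("H6", "H7", "H8", "H9", "HA"),
           list(c("t1:c", "b1:c"), c("t1:c", "b1:c"), c("t1:c", "z1:c"),
                c("t1:c"), c("t1:h")))
  tl <- clade_sharing_tallies(hn, cm)
  tb <- tl$pairs[tl$pairs$clade_x == "bryophyte" &
                 tl$pairs$clade_y == "tracheophyte", "count"]
  expect_equal(tb, 2)
  tz <- tl$pairs[tl$pairs$clade_x == "tracheophyte" &
                 tl$pairs$clade_y == "zygnematophyte", "count"]
  expect_equal(tz, 1)
  expect_equal(tl$exclusive$count[tl$exclusive$clade == "tracheophyte"], 2)
  # partition: exclusives + deduplicated cross-clade = total edges
  cross <- sum(vapply(hn$edges$provenance, function(pr) {
    cl <- unique(cm[sub(":.*", "", pr)])
    length(cl) > 1
  }, TRUE))
  expect_equal(sum(tl$exclusive$count) + cross, nrow(hn$edges))
})
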
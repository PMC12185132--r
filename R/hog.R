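#' Parse an OrthoFinder N0.tsv hierarchical-orthogroup table
#'
#' Reads the N0 dialect: a header row `HOG`, `OG`, `Gene Tree Parent
#' Clade`, then one column per species containing comma-separated gene
#' lists; empty cells mean the species has no gene in that HOG.
#'
#' @param path path to the N0.tsv file.
#' @param species optional character vector restricting which species
#'   columns to parse (default: all columns after the third).
#' @return named list (per species) of data.frames `gene`, `hog`.
#' @export
parse_hog_map <- function(path, species = NULL) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty HOG file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 4 || header[1] != "HOG")
    stop("not an N0.tsv header (need HOG, OG, Gene Tree Parent Clade, species...)")
  all_species <- header[-(1:3)]
  if (is.null(species)) species <- all_species
  miss <- setdiff(species, all_species)
  if (length(miss)) stop("species not in file: ", paste(miss, collapse = ", "))
  out <- lapply(setNames(species, species), function(s)
    list(gene = character(0), hog = character(0)))
  for (i in seq_along(lines)[-1]) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 1 || !nzchar(f[1]))
      stop("malformed row at line ", i, " of ", path)
    length(f) <- length(header)  # right-pad short rows (trailing empty cells)
    hog <- f[1]
    for (s in species) {
      cell <- f[3 + match(s, all_species)]
      if (is.na(cell) || !nzchar(trimws(cell))) next
      genes <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
      genes <- genes[nzchar(genes)]
      out[[s]]$gene <- c(out[[s]]$gene, genes)
      out[[s]]$hog <- c(out[[s]]$hog, rep(hog, length(genes)))
    }
  }
  lapply(out, function(o) {
    df <- data.frame(gene = o$gene, hog = o$hog, stringsAsFactors = FALSE)
    dup <- unique(df$gene[duplicated(df$gene)])
    dup <- dup[vapply(dup, function(g)
      length(unique(df$hog[df$gene == g])) > 1, TRUE)]
    if (length(dup))
      stop("gene(s) assigned to multiple HOGs: ",
           paste(head(dup, 5), collapse = ", "))
    df[!duplicated(df$gene), , drop = FALSE]
  })
}

#' Write per-species HOG maps back to the N0.tsv dialect
#'
#' Inverse of [parse_hog_map()] up to whitespace: one row per HOG, species
#' columns carrying comma-joined gene lists.
#'
#' @param hog_maps named list (per species) of data.frames `gene`, `hog`.
#' @param path output path.
#' @export
write_hog_map <- function(hog_maps, path) {
  species <- names(hog_maps)
  hogs <- sort(unique(unlist(lapply(hog_maps, function(m) m$hog))))
  header <- paste(c("HOG", "OG", "Gene Tree Parent Clade", species),
                  collapse = "\t")
  rows <- vapply(seq_along(hogs), function(i) {
    cells <- vapply(species, function(s) {
      m <- hog_maps[[s]]
      paste(sort(m$gene[m$hog == hogs[i]]), collapse = ", ")
    }, "")
    paste(c(hogs[i], sprintf("OG%07d", i), "n0", cells), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
}
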
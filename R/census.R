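# Seed-based family assignment and conserved-family censuses. Family
# membership is a pure function of mature positions 2-8 (the seed). The
# packaged table carries the standard node structure (Eumetazoa, Bilateria,
# Protostomia, Spiralia, Ecdysozoa, Nematoda) with synthetic placeholder
# seed sequences; census arithmetic depends only on names and nodes.

#' Load a seed-family table
#'
#' Columns: `family` (unique name), `seed` (7 nt, positions 2--8 of the
#' mature), `node` (phylogenetic node of origin). The packaged default,
#' `seed_families_synthetic.tsv`, uses standard family names and node
#' assignments but synthetic seed sequences (a few well-known seeds are
#' real); it is a stand-in for a curated seed catalogue.
#'
#' @param path TSV path; `NULL` loads the packaged table.
#' @return data.frame with columns `family`, `seed`, `node`.
#' @export
read_seed_families <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "seed_families_synthetic.tsv",
                        package = "srnaloci", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("family", "seed", "node") %in% names(tab)))
  tab$seed <- normalize_seq(tab$seed)
  if (anyDuplicated(tab$family)) stop("family names must be unique")
  if (any(nchar(tab$seed) != 7)) stop("seeds must be 7 nt")
  tab
}

#' Assign a mature sequence to conserved families by seed identity
#'
#' @param mature mature miRNA sequence (length >= 8).
#' @param table seed-family table from [read_seed_families()].
#' @return list with `families` (every family whose seed equals mature
#'   positions 2--8, or `"novel"` if none), `novel` and `ambiguous` flags.
#' @export
assign_family <- function(mature, table = read_seed_families()) {
  mature <- normalize_seq(mature)
  if (nchar(mature) < 8) stop("mature sequence must be at least 8 nt")
  seed <- substr(mature, 2, 8)
  hits <- table$family[table$seed == seed]
  if (length(hits) == 0)
    list(families = "novel", seed = seed, novel = TRUE, ambiguous = FALSE)
  else
    list(families = hits, seed = seed, novel = FALSE,
         ambiguous = length(hits) > 1)
}

#' Conserved-family complement of a lineage
#'
#' The union of families whose node of origin lies on the lineage's path,
#' e.g. a spiralian complement spans Eumetazoa + Bilateria + Protostomia +
#' Spiralia.
#'
#' @param table seed-family table.
#' @param nodes character vector of node names.
#' @return character vector of family names.
#' @export
lineage_complement <- function(table, nodes) {
  bad <- setdiff(nodes, unique(table$node))
  if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "))
  sort(table$family[table$node %in% nodes])
}

#' Build a presence/absence matrix
#'
#' @param present named list: taxon -> character vector of present families.
#' @param table seed-family table (defines the columns).
#' @return logical matrix, taxa in rows, families in columns.
#' @export
presence_absence_matrix <- function(present, table = read_seed_families()) {
  fams <- table$family
  m <- matrix(FALSE, nrow = length(present), ncol = length(fams),
              dimnames = list(names(present), fams))
  for (tx in names(present)) {
    unknown <- setdiff(present[[tx]], fams)
    if (length(unknown))
      stop("families not in table for taxon ", tx, ": ",
           paste(unknown, collapse = ", "))
    m[tx, present[[tx]]] <- TRUE
  }
  m
}

#' Per-taxon, per-node complement census
#'
#' For each taxon and node reports how many of the node's families are
#' present, the node total, and the named absent families.
#'
#' @param matrix presence/absence matrix (see [presence_absence_matrix()]).
#' @param table seed-family table.
#' @return data.frame with columns `taxon`, `node`, `present`, `total` and
#'   list-column `absent`.
#' @export
complement_census <- function(matrix, table = read_seed_families()) {
  if (!all(colnames(matrix) %in% table$family))
    stop("matrix families must be drawn from the table")
  nodes <- unique(table$node)
  out <- list()
  for (tx in rownames(matrix)) {
    for (nd in nodes) {
      fams <- table$family[table$node == nd]
      here <- fams[fams %in% colnames(matrix)]
      pres <- here[matrix[tx, here]]
      out[[length(out) + 1L]] <- data.frame(
        taxon = tx, node = nd,
        present = length(pres), total = length(fams),
        absent = I(list(sort(setdiff(fams, pres)))),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Symmetric difference between two family complements
#'
#' @param complement_a,complement_b character vectors of family names.
#' @return list with `count` (size of the symmetric difference) and
#'   `families` (its sorted members).
#' @export
family_set_difference <- function(complement_a, complement_b) {
  a <- unique(complement_a); b <- unique(complement_b)
  diff <- sort(c(setdiff(a, b), setdiff(b, a)))
  list(count = length(diff), families = diff)
}
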
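# PPI-neighborhood annotation enrichment.
#
# A protein's "complex" is its interaction neighborhood (the protein plus
# all partners within a hop limit, default 1). The neighborhood is tested
# against disease / pathway / GO term sets with the upper-tail
# hypergeometric probability; p-values are corrected per category with
# Benjamini-Hochberg (Bonferroni available).

#' PPI neighborhood of a protein
#'
#' The protein plus all nodes within `depth` hops in the interaction
#' network. A protein absent from the network yields just itself.
#'
#' @param protein target id.
#' @param network PPI edge data.frame (columns `a`, `b`), e.g. from
#'   [read_ppi()].
#' @param depth hop limit (default 1).
#' @return character vector of target ids (includes `protein`).
#' @export
ppi_neighborhood <- function(protein, network, depth = 1L) {
  verts <- unique(c(network$a, network$b))
  if (!(protein %in% verts)) return(protein)
  g <- igraph::graph_from_data_frame(network, directed = FALSE,
                                     vertices = verts)
  nb <- igraph::ego(g, order = depth, nodes = protein)[[1]]
  sort(unique(c(protein, names(nb))))
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= overlap) when `neighborhood_size` proteins are drawn without
#' replacement from a universe of `universe_size` proteins of which
#' `set_size` carry the annotation.
#'
#' @param overlap observed overlap count.
#' @param set_size annotated proteins in the universe.
#' @param neighborhood_size size of the drawn set.
#' @param universe_size universe size.
#' @return probability in \[0, 1\].
#' @export
hypergeom_p <- function(overlap, set_size, neighborhood_size, universe_size) {
  stopifnot(overlap >= 0, set_size <= universe_size,
            neighborhood_size <= universe_size,
            overlap <= min(set_size, neighborhood_size))
  stats::phyper(overlap - 1, set_size, universe_size - set_size,
                neighborhood_size, lower.tail = FALSE)
}

#' Annotation enrichment of a protein neighborhood
#'
#' One result per annotation term overlapping the neighborhood, with
#' hypergeometric p-values corrected per category across all tested terms,
#' sorted ascending by adjusted p.
#'
#' @param neighborhood character vector of target ids (must lie in the
#'   universe).
#' @param annotations list of annotation sets from [read_annotations()].
#' @param universe character vector of target ids (e.g. all proteins in the
#'   PPI network).
#' @param method multiple-testing correction, `"BH"` (default) or
#'   `"bonferroni"`.
#' @return data.frame with term_id, category, overlap, set_size,
#'   neighborhood_size, universe_size, p_value, p_adjusted.
#' @export
enrich_neighborhood <- function(neighborhood, annotations, universe,
                                method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  if (!all(neighborhood %in% universe))
    stop("neighborhood contains proteins outside the universe")
  neighborhood <- unique(neighborhood)
  rows <- lapply(annotations, function(a) {
    members <- intersect(unique(a$members), universe)
    ov <- length(intersect(members, neighborhood))
    data.frame(term_id = a$term_id, category = a$category,
               overlap = ov, set_size = length(members),
               neighborhood_size = length(neighborhood),
               universe_size = length(universe),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$set_size > 0L, , drop = FALSE]
  res$p_value <- mapply(hypergeom_p, res$overlap, res$set_size,
                        res$neighborhood_size, res$universe_size)
  # correct across all tested terms within each category
  res$p_adjusted <- NA_real_
  for (cat_ in unique(res$category)) {
    sel <- res$category == cat_
    res$p_adjusted[sel] <- stats::p.adjust(res$p_value[sel],
                                           method = if (method == "BH") "BH"
                                           else "bonferroni")
  }
  res <- res[res$overlap >= 1L, , drop = FALSE]
  res <- res[order(res$p_adjusted, res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
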
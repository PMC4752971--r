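# Hierarchical ring-scaffold decomposition (scaffold tree).
#
# Level 0 is the Murcko framework: ring systems plus linkers, side chains
# removed, exocyclic multiple-bonded atoms retained. Each tree step removes
# exactly one peripheral ring chosen by a condensed, totally ordered variant
# of the classic ring-prioritization rules (macrocycle guard; fewest acyclic
# linker bonds in the parent; remove 3/5/6-rings first; fewest heteroatoms;
# retain N over O over S; smaller rings first; canonical-SMILES tie-break),
# so a k-ring molecule yields a chain of exactly k scaffolds ending in a
# single ring. Acyclic molecules are decomposed by iterative terminal-group
# pruning down to their unbranched carbon backbone and kept in a separate
# partition of the forest.

# Murcko pruning on a molgraph: iteratively drop degree-1 atoms, then
# restore atoms attached to the retained core by a bond of order >= 2.
murcko_core_atoms <- function(mol) {
  keep <- rep(TRUE, mol$n_atoms)
  b <- mol$bonds
  repeat {
    deg <- integer(mol$n_atoms)
    sel <- keep[b[, "a1"]] & keep[b[, "a2"]]
    if (any(sel)) {
      t1 <- tabulate(b[sel, "a1"], nbins = mol$n_atoms)
      t2 <- tabulate(b[sel, "a2"], nbins = mol$n_atoms)
      deg <- t1 + t2
    }
    drop <- keep & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  if (!any(keep)) return(integer(0))
  core <- which(keep)
  # restore exocyclic double/triple-bonded atoms
  for (i in seq_len(nrow(b))) {
    if (b[i, "order"] %in% c(2L, 3L)) {
      a1 <- b[i, "a1"]; a2 <- b[i, "a2"]
      if (keep[a1] && !keep[a2]) core <- c(core, a2)
      if (keep[a2] && !keep[a1]) core <- c(core, a1)
    }
  }
  sort(unique(core))
}

#' Murcko scaffold of a molecule
#'
#' Ring systems plus linkers with all side chains removed; atoms attached to
#' the framework by a double or triple bond are retained. Acyclic molecules
#' have no Murcko scaffold.
#'
#' @param smiles a single SMILES string.
#' @return canonical scaffold SMILES, or `NA` for an acyclic molecule.
#' @examples
#' murcko_scaffold("Cc1ccccc1")  # toluene -> benzene
#' @export
murcko_scaffold <- function(smiles) {
  mol <- parse_smiles(smiles)[[1]]
  if (is.null(mol)) stop("unparsable SMILES: ", smiles)
  core <- murcko_core_atoms(mol)
  if (length(core) == 0L) return(NA_character_)
  mol_to_smiles(mol_subgraph(mol, core))
}

# Properties of one SSSR ring used by the prioritization rules.
ring_props <- function(mol, ring) {
  el <- mol$elements[ring]
  list(size = length(ring),
       n_het = sum(el != "C"),
       n_N = sum(el == "N"), n_O = sum(el == "O"), n_S = sum(el == "S"))
}

# Number of acyclic (linker) bonds in a molgraph: bonds not on any cycle.
n_linker_bonds <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(0L)
  g <- mol_to_igraph(mol)
  length(igraph::bridges(g))
}

#' Parent scaffold: remove one prioritized peripheral ring
#'
#' Removes exactly one ring from a multi-ring scaffold according to the
#' ordered prioritization rules (see package vignette); returns `NA` when a
#' single ring remains. The input must itself be a scaffold (or at least a
#' cyclic molecule; it is Murcko-pruned first).
#'
#' @param scaffold canonical scaffold SMILES with at least one ring.
#' @return parent scaffold SMILES, or `NA` for a single-ring scaffold.
#' @export
scaffold_parent <- function(scaffold) {
  mol <- parse_smiles(scaffold)[[1]]
  if (is.null(mol)) stop("unparsable scaffold SMILES: ", scaffold)
  core <- murcko_core_atoms(mol)
  if (length(core) == 0L) stop("acyclic input has no scaffold parent")
  mol <- mol_subgraph(mol, core)
  rings <- mol_sssr(mol)
  if (length(rings) <= 1L) return(NA_character_)
  in_other <- function(k) {
    cnt <- integer(mol$n_atoms)
    for (r in rings) cnt[r] <- cnt[r] + 1L
    cnt
  }
  ring_count <- in_other()
  cands <- list()
  for (k in seq_along(rings)) {
    ring <- rings[[k]]
    exclusive <- ring[ring_count[ring] == 1L]
    if (length(exclusive) == 0L) next  # fully shared ring: not peripheral
    keep <- setdiff(seq_len(mol$n_atoms), exclusive)
    sub <- mol_subgraph(mol, keep)
    if (sub$n_atoms == 0L) next
    # connectivity guard: removal must not split the scaffold
    if (igraph::count_components(mol_to_igraph(sub)) > 1L) next
    pcore <- murcko_core_atoms(sub)
    if (length(pcore) == 0L) next
    parent <- mol_subgraph(sub, pcore)
    if (mol_n_rings(parent) != length(rings) - 1L) next
    psmi <- mol_to_smiles(parent)
    if (is.na(psmi)) next
    cands[[length(cands) + 1L]] <-
      c(ring_props(mol, ring),
        list(linker_bonds = n_linker_bonds(parent), parent_smiles = psmi))
  }
  if (length(cands) == 0L) return(NA_character_)
  getv <- function(f) vapply(cands, function(c_) as.numeric(c_[[f]]), 0)
  keep <- rep(TRUE, length(cands))
  restrict <- function(keep, cond) if (any(keep & cond)) keep & cond else keep
  minimize <- function(keep, v) keep & (v == min(v[keep]))
  # ordered rules
  keep <- restrict(keep, getv("n_het") > 0 & getv("size") %in% c(3, 5, 6))
  keep <- restrict(keep, getv("size") < 12)
  keep <- minimize(keep, getv("linker_bonds"))
  keep <- restrict(keep, getv("size") %in% c(3, 5, 6))
  keep <- minimize(keep, getv("n_het"))
  keep <- minimize(keep, getv("n_N"))
  keep <- minimize(keep, getv("n_O"))
  keep <- minimize(keep, getv("n_S"))
  keep <- minimize(keep, getv("size"))
  smi <- vapply(cands, `[[`, "", "parent_smiles")
  chosen <- which(keep)[order(smi[keep])][1]
  smi[chosen]
}

#' Scaffold chain of a cyclic molecule
#'
#' Murcko scaffold followed by iterated single-ring removals, leaf to
#' single-ring root. A molecule with k rings yields a chain of length k.
#'
#' @param smiles a single SMILES string (must contain a ring).
#' @return character vector of scaffold SMILES, leaf first.
#' @export
scaffold_chain <- function(smiles) {
  s <- murcko_scaffold(smiles)
  if (is.na(s)) stop("acyclic molecule has no ring-scaffold chain")
  chain <- s
  repeat {
    p <- scaffold_parent(chain[length(chain)])
    if (is.na(p)) break
    chain <- c(chain, p)
  }
  chain
}

#' Decompose an acyclic molecule into a pruning chain
#'
#' Iteratively removes one terminal atom per step - heteroatom terminals
#' first (halogens, then S, O, N), then branch carbons, ties broken by the
#' canonical SMILES of the resulting fragment - until the unbranched carbon
#' backbone remains. Deterministic.
#'
#' @param smiles SMILES of a molecule with zero rings.
#' @return character vector of canonical fragment SMILES, whole molecule
#'   first, carbon-backbone root last.
#' @export
decompose_acyclic <- function(smiles) {
  mol <- parse_smiles(smiles)[[1]]
  if (is.null(mol)) stop("unparsable SMILES: ", smiles)
  if (mol_n_rings(mol) > 0L) stop("cyclic molecule: use the ring-scaffold chain")
  chain <- mol_to_smiles(mol)
  removal_rank <- function(el) {
    if (el %in% c("F", "Cl", "Br", "I")) return(1)
    switch(el, S = 2, O = 3, N = 4, C = 6, 5)
  }
  repeat {
    deg <- mol_degree(mol)
    done_backbone <- all(mol$elements == "C") && all(deg <= 2L)
    if (done_backbone || mol$n_atoms <= 1L) break
    terminals <- which(deg <= 1L)
    if (length(terminals) == 0L) break
    rank <- vapply(mol$elements[terminals], removal_rank, 0)
    # carbon terminals are only pruned while branching or heteroatoms remain
    cand <- terminals[rank == min(rank)]
    frag <- lapply(cand, function(a) mol_subgraph(mol, setdiff(seq_len(mol$n_atoms), a)))
    fsmi <- vapply(frag, mol_to_smiles, "")
    pick <- order(fsmi, cand)[1]
    mol <- frag[[pick]]
    chain <- c(chain, fsmi[pick])
  }
  chain
}

#' Build a scaffold forest from a compound library
#'
#' Every compound's scaffold chain (ring chain, or acyclic pruning chain) is
#' inserted with node merging on identical canonical scaffold SMILES;
#' members are propagated to all ancestors. Ring and acyclic chemistry live
#' in separate partitions.
#'
#' @param compounds compound library data.frame (compound_id, smiles).
#' @return object of class `scaffold_forest`: list with `nodes` (data.frame:
#'   scaffold, level, parent, is_ring), `members` (named list of compound id
#'   vectors) and `leaf_of` (named character: compound id -> leaf scaffold).
#' @export
build_forest <- function(compounds) {
  stopifnot(nrow(compounds) >= 1L)
  nodes <- list()    # scaffold -> list(level, parent, is_ring)
  members <- list()  # scaffold -> compound ids
  leaf_of <- character(0)
  chain_cache <- list()
  for (i in seq_len(nrow(compounds))) {
    smi <- compounds$smiles[i]
    cid <- compounds$compound_id[i]
    chain <- chain_cache[[smi]]
    if (is.null(chain)) {
      mol <- parse_smiles(smi)[[1]]
      if (is.null(mol)) stop("unparsable SMILES for compound ", cid)
      if (mol_n_rings(mol) > 0L) {
        ch <- scaffold_chain(smi)
        chain <- list(scaffolds = ch, levels = rev(seq_along(ch)), ring = TRUE)
      } else {
        ch <- decompose_acyclic(smi)
        chain <- list(scaffolds = ch, levels = rep(0L, length(ch)), ring = FALSE)
      }
      chain_cache[[smi]] <- chain
    }
    ch <- chain$scaffolds
    for (k in seq_along(ch)) {
      s <- ch[k]
      parent <- if (k < length(ch)) ch[k + 1] else NA_character_
      if (is.null(nodes[[s]])) {
        nodes[[s]] <- list(level = chain$levels[k], parent = parent,
                           is_ring = chain$ring)
        members[[s]] <- character(0)
      }
      members[[s]] <- c(members[[s]], cid)
    }
    leaf_of[cid] <- ch[1]
  }
  scaffs <- names(nodes)
  nd <- data.frame(scaffold = scaffs,
                   level = vapply(nodes, function(n) as.integer(n$level), 1L),
                   parent = vapply(nodes, function(n) as.character(n$parent), ""),
                   is_ring = vapply(nodes, function(n) n$is_ring, TRUE),
                   stringsAsFactors = FALSE)
  nd <- nd[order(!nd$is_ring, nd$scaffold), , drop = FALSE]
  rownames(nd) <- NULL
  members <- lapply(members, function(m) sort(unique(m)))
  structure(list(nodes = nd, members = members[nd$scaffold],
                 leaf_of = leaf_of),
            class = "scaffold_forest")
}

#' @export
print.scaffold_forest <- function(x, ...) {
  n_roots <- sum(is.na(x$nodes$parent))
  cat("scaffold_forest:", nrow(x$nodes), "nodes,", n_roots, "roots,",
      length(x$leaf_of), "compounds\n")
  invisible(x)
}

# Children of a node, sorted by canonical scaffold SMILES.
forest_children <- function(forest, scaffold) {
  ch <- forest$nodes$scaffold[!is.na(forest$nodes$parent) &
                                forest$nodes$parent == scaffold]
  sort(ch)
}

#' Root scaffolds of a forest
#'
#' @param forest a `scaffold_forest`.
#' @param ring_only if `TRUE`, only single-ring roots (the ring partition).
#' @return character vector of root scaffold SMILES, sorted.
#' @export
forest_roots <- function(forest, ring_only = FALSE) {
  nd <- forest$nodes
  r <- nd[is.na(nd$parent), , drop = FALSE]
  if (ring_only) r <- r[r$is_ring, , drop = FALSE]
  sort(r$scaffold)
}

#' Depth-first compound order of a scaffold forest
#'
#' Linearizes the forest: ring-partition roots first, siblings sorted by
#' canonical scaffold SMILES; at each node the compounds whose leaf is that
#' node are listed (sorted by compound id) before descending into children.
#' This is the row order of the pharmacological heatmap.
#'
#' @param forest a `scaffold_forest`.
#' @return character vector of compound ids.
#' @export
forest_compound_order <- function(forest) {
  own <- function(s) {
    cids <- names(forest$leaf_of)[forest$leaf_of == s]
    sort(cids)
  }
  visit <- function(s) {
    c(own(s), unlist(lapply(forest_children(forest, s), visit), use.names = FALSE))
  }
  roots <- c(forest_roots(forest, ring_only = TRUE),
             setdiff(forest_roots(forest), forest_roots(forest, ring_only = TRUE)))
  as.character(unlist(lapply(roots, visit), use.names = FALSE))
}

#' Serialize a scaffold forest
#'
#' @param forest a `scaffold_forest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_forest_json <- function(forest, path) {
  nd <- forest$nodes
  rec <- lapply(seq_len(nrow(nd)), function(i) {
    list(scaffold_smiles = nd$scaffold[i], level = nd$level[i],
         parent = if (is.na(nd$parent[i])) NULL else nd$parent[i],
         is_ring = nd$is_ring[i],
         members = as.list(forest$members[[nd$scaffold[i]]]))
  })
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_forest_json
#' @export
forest_newick <- function(forest) {
  quote_lab <- function(s) gsub("[(),;:]", "_", s)
  visit <- function(s) {
    ch <- forest_children(forest, s)
    lab <- quote_lab(s)
    if (length(ch) == 0L) return(lab)
    paste0("(", paste(vapply(ch, visit, ""), collapse = ","), ")", lab)
  }
  roots <- forest_roots(forest)
  paste0("(", paste(vapply(roots, visit, ""), collapse = ","), ");")
}
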
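# Internal molecular-graph layer.
#
# Molecules are parsed from SMILES through OpenBabel (ChemmineOB) into
# SYBYL MOL2 blocks - the one OpenBabel text format that carries explicit
# aromatic bond types - and held here as a plain "molgraph": heavy-atom
# element vector, SYBYL atom types, per-atom hydrogen counts, and a bond
# table with orders 1/2/3 and 4 for aromatic. Scaffold pruning edits the
# graph directly; an edited graph is converted back to canonical SMILES by
# writing a MOL2 block (explicit hydrogens preserved on heteroatoms, so
# pyrrole-type N-H survives ring surgery) and round-tripping it through
# OpenBabel. All structure identity in the package is canonical SMILES
# string equality.

ob_convert <- function(from, to, source, add_h = FALSE) {
  tryCatch(
    suppressWarnings(if (add_h) {
      ChemmineOB::convertFormat(from, to, source,
                                options = data.frame(names = "h", args = ""))
    } else {
      ChemmineOB::convertFormat(from, to, source)
    }),
    error = function(e) ""
  )
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form. Strings that fail to parse
#' are returned as `NA`. Conversion is batched; a failing record aborts the
#' OpenBabel batch, so unconverted survivors are retried individually.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector, same length as the input, canonical SMILES or
#'   `NA` where parsing failed.
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  out <- rep(NA_character_, length(smiles))
  idx <- which(!is.na(smiles) & nzchar(trimws(smiles)))
  if (length(idx) == 0L) return(out)
  parse_batch <- function(input_idx) {
    input <- paste(smiles[input_idx], seq_along(input_idx))
    res <- ob_convert("SMI", "CAN", paste(input, collapse = "\n"))
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(invisible(NULL))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ok <- vapply(parts, length, 1L) >= 2L
    parts <- parts[ok]
    pos <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
    can <- trimws(vapply(parts, `[[`, "", 1L))
    keep <- !is.na(pos) & pos >= 1L & pos <= length(input_idx) & nzchar(can)
    out[input_idx[pos[keep]]] <<- can[keep]
    invisible(NULL)
  }
  parse_batch(idx)
  # a bad record stops the batch: retry the stragglers one by one
  for (i in setdiff(idx, which(!is.na(out)))) parse_batch(i)
  out
}

# --- MOL2 parsing --------------------------------------------------------

BOND_ORDER_FROM_MOL2 <- c("1" = 1L, "2" = 2L, "3" = 3L, am = 1L, ar = 4L,
                          du = 1L, un = 1L, nc = 0L)
BOND_ORDER_TO_MOL2 <- c("1" = "1", "2" = "2", "3" = "3", "4" = "ar")

molgraph <- function(elements, types, n_h, bonds) {
  structure(list(elements = elements, types = types, n_h = as.integer(n_h),
                 bonds = bonds, n_atoms = length(elements)),
            class = "molgraph")
}

empty_bonds <- function() {
  matrix(integer(0), ncol = 3, dimnames = list(NULL, c("a1", "a2", "order")))
}

# Parse one MOL2 block into a heavy-atom molgraph (explicit H folded into
# per-atom counts).
parse_mol2_block <- function(lines) {
  cnt <- strsplit(trimws(lines[3]), "[[:space:]]+")[[1]]
  n_at <- as.integer(cnt[1]); n_bd <- as.integer(cnt[2])
  a0 <- grep("^@<TRIPOS>ATOM", lines)[1]
  b0 <- grep("^@<TRIPOS>BOND", lines)[1]
  if (is.na(a0) || is.na(n_at) || n_at == 0L) return(NULL)
  at <- lines[(a0 + 1L):(a0 + n_at)]
  af <- strsplit(trimws(at), "[[:space:]]+")
  types <- vapply(af, `[[`, "", 6L)
  elements <- sub("\\..*$", "", types)
  if (!is.na(b0) && !is.na(n_bd) && n_bd > 0L) {
    bd <- lines[(b0 + 1L):(b0 + n_bd)]
    bf <- strsplit(trimws(bd), "[[:space:]]+")
    bonds <- cbind(a1 = as.integer(vapply(bf, `[[`, "", 2L)),
                   a2 = as.integer(vapply(bf, `[[`, "", 3L)),
                   order = unname(BOND_ORDER_FROM_MOL2[vapply(bf, `[[`, "", 4L)]))
  } else bonds <- empty_bonds()
  heavy <- which(elements != "H")
  n_h <- integer(length(heavy))
  map <- integer(length(elements)); map[heavy] <- seq_along(heavy)
  keep <- logical(nrow(bonds))
  for (i in seq_len(nrow(bonds))) {
    a1 <- bonds[i, "a1"]; a2 <- bonds[i, "a2"]
    h1 <- elements[a1] == "H"; h2 <- elements[a2] == "H"
    if (h1 && h2) next
    if (h1) { n_h[map[a2]] <- n_h[map[a2]] + 1L; next }
    if (h2) { n_h[map[a1]] <- n_h[map[a1]] + 1L; next }
    keep[i] <- TRUE
  }
  bonds <- bonds[keep, , drop = FALSE]
  if (nrow(bonds) > 0L) {
    bonds[, "a1"] <- map[bonds[, "a1"]]
    bonds[, "a2"] <- map[bonds[, "a2"]]
  }
  molgraph(elements[heavy], types[heavy], n_h, bonds)
}

# Parse a batch of SMILES into molgraph objects. Returns a list parallel to
# `smiles` with NULL where parsing failed.
parse_smiles <- function(smiles) {
  n <- length(smiles)
  out <- vector("list", n)
  if (n == 0L) return(out)
  idx <- which(!is.na(smiles) & nzchar(trimws(smiles)))
  if (length(idx) == 0L) return(out)
  parse_batch <- function(input_idx) {
    input <- paste(smiles[input_idx], seq_along(input_idx))
    res <- ob_convert("SMI", "MOL2", paste(input, collapse = "\n"),
                      add_h = TRUE)
    if (!nzchar(res)) return(invisible(NULL))
    blocks <- strsplit(res, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
    for (blk in blocks[-1]) {
      lines <- strsplit(blk, "\n", fixed = TRUE)[[1]]
      pos <- suppressWarnings(as.integer(trimws(lines[2])))
      if (is.na(pos) || pos < 1L || pos > length(input_idx)) next
      g <- tryCatch(parse_mol2_block(lines), error = function(e) NULL)
      if (!is.null(g)) out[[input_idx[pos]]] <<- g
    }
    invisible(NULL)
  }
  parse_batch(idx)
  done <- which(!vapply(out, is.null, TRUE))
  for (i in setdiff(idx, done)) parse_batch(i)
  out
}

# Write a molgraph as a MOL2 block; hydrogens recorded on heavy atoms are
# written explicitly so aromatic N-H assignments survive the round trip.
mol_to_mol2_text <- function(mol, title = "mol") {
  n_h_total <- sum(mol$n_h)
  atom_lines <- sprintf("%7d %-4s %9.4f %9.4f %9.4f %-6s 1 UNL1 0.0000",
                        seq_len(mol$n_atoms), mol$elements, 0, 0, 0, mol$types)
  bond_rows <- cbind(mol$bonds[, "a1"], mol$bonds[, "a2"],
                     BOND_ORDER_TO_MOL2[as.character(mol$bonds[, "order"])])
  h_id <- mol$n_atoms
  for (i in seq_len(mol$n_atoms)) {
    if (mol$n_h[i] > 0L) {
      for (k in seq_len(mol$n_h[i])) {
        h_id <- h_id + 1L
        atom_lines <- c(atom_lines,
                        sprintf("%7d H    %9.4f %9.4f %9.4f H      1 UNL1 0.0000",
                                h_id, 0, 0, 0))
        bond_rows <- rbind(bond_rows, c(i, h_id, "1"))
      }
    }
  }
  bond_lines <- sprintf("%6d %5d %5d %4s", seq_len(nrow(bond_rows)),
                        as.integer(bond_rows[, 1]), as.integer(bond_rows[, 2]),
                        bond_rows[, 3])
  paste(c("@<TRIPOS>MOLECULE", title,
          sprintf(" %d %d 0 0 0", mol$n_atoms + n_h_total, nrow(bond_rows)),
          "SMALL", "NO_CHARGES", "",
          "@<TRIPOS>ATOM", atom_lines,
          "@<TRIPOS>BOND", bond_lines), collapse = "\n")
}

# Canonical SMILES of a molgraph via OpenBabel round trip.
mol_to_smiles <- function(mol) {
  if (mol$n_atoms == 0L) return(NA_character_)
  res <- ob_convert("MOL2", "CAN", mol_to_mol2_text(mol))
  line <- strsplit(res, "\n", fixed = TRUE)[[1]][1]
  if (is.na(line) || !nzchar(trimws(line))) return(NA_character_)
  trimws(strsplit(line, "\t", fixed = TRUE)[[1]][1])
}

# --- graph utilities -----------------------------------------------------

# Heavy-atom degree per atom.
mol_degree <- function(mol) {
  deg <- integer(mol$n_atoms)
  if (nrow(mol$bonds) > 0L) {
    deg <- tabulate(mol$bonds[, "a1"], nbins = mol$n_atoms) +
      tabulate(mol$bonds[, "a2"], nbins = mol$n_atoms)
  }
  deg
}

mol_to_igraph <- function(mol) {
  edges <- as.integer(t(mol$bonds[, c("a1", "a2"), drop = FALSE]))
  igraph::make_graph(edges = edges, n = mol$n_atoms, directed = FALSE)
}

# Atoms that sit on at least one cycle: endpoints of non-bridge edges.
mol_ring_atoms <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(integer(0))
  g <- mol_to_igraph(mol)
  br <- igraph::bridges(g)
  el <- igraph::as_edgelist(g)
  keep <- setdiff(seq_len(nrow(el)), as.integer(br))
  sort(unique(as.integer(el[keep, ])))
}

mol_n_rings <- function(mol) {
  # cyclomatic number: bonds - atoms + components
  g <- mol_to_igraph(mol)
  nrow(mol$bonds) - mol$n_atoms + igraph::count_components(g)
}

# Smallest set of smallest rings (Horton-style): candidate cycles are the
# shortest cycle through each non-bridge edge; a basis is selected greedily
# by size with GF(2) independence over edge incidence vectors.
mol_sssr <- function(mol) {
  n_rings <- mol_n_rings(mol)
  if (n_rings == 0L) return(list())
  g <- mol_to_igraph(mol)
  el <- igraph::as_edgelist(g)
  br <- as.integer(igraph::bridges(g))
  cyc_edges <- setdiff(seq_len(nrow(el)), br)
  cand <- list()
  for (e in cyc_edges) {
    u <- el[e, 1]; v <- el[e, 2]
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = u, to = v))
    p <- as.integer(sp$vpath[[1]])
    if (length(p) >= 2L) cand[[length(cand) + 1L]] <- p
  }
  if (length(cand) == 0L) return(list())
  cand <- cand[order(vapply(cand, length, 1L))]
  edge_key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  inc <- lapply(cand, function(p) {
    ring <- c(p, p[1])
    k <- paste(pmin(ring[-length(ring)], ring[-1]),
               pmax(ring[-length(ring)], ring[-1]))
    edge_key %in% k
  })
  basis <- list(); rings <- list()
  for (i in seq_along(cand)) {
    v <- inc[[i]]
    for (b in basis) {
      pivot <- which(b)[1]
      if (v[pivot]) v <- xor(v, b)
    }
    if (any(v)) {
      basis[[length(basis) + 1L]] <- v
      rings[[length(rings) + 1L]] <- sort(cand[[i]])
      if (length(rings) == n_rings) break
    }
  }
  rings
}

# Induced subgraph on a set of atoms (1-based indices), renumbered. Kept
# atoms are credited one hydrogen per lost single/aromatic bond (two/three
# for lost double/triple bonds) so the graph stays valence-complete and the
# MOL2 round trip never produces radicals.
mol_subgraph <- function(mol, keep) {
  keep <- sort(unique(keep))
  map <- integer(mol$n_atoms)
  map[keep] <- seq_along(keep)
  b <- mol$bonds
  sel <- b[, "a1"] %in% keep & b[, "a2"] %in% keep
  n_h <- mol$n_h[keep]
  lost <- b[!sel, , drop = FALSE]
  for (i in seq_len(nrow(lost))) {
    credit <- switch(as.character(lost[i, "order"]),
                     "2" = 2L, "3" = 3L, 1L)
    for (a in c(lost[i, "a1"], lost[i, "a2"])) {
      if (map[a] > 0L) n_h[map[a]] <- n_h[map[a]] + credit
    }
  }
  b <- b[sel, , drop = FALSE]
  if (nrow(b) > 0L) {
    b[, "a1"] <- map[b[, "a1"]]
    b[, "a2"] <- map[b[, "a2"]]
  }
  molgraph(mol$elements[keep], mol$types[keep], n_h, b)
}
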
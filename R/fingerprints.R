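# Molecular fingerprints and Tanimoto similarity.
#
# Five variants, all folded to a configurable bit length (default 1024):
#   path1024      - Daylight-style linear paths of 1..7 bonds
#   morgan_r2/r3  - circular (Morgan/ECFP-style) environments, radius 2/3
#   feat_morgan_* - Morgan on pharmacophoric atom features instead of
#                   element identity (donor/acceptor/halogen/ring)
# Hashing is a fixed polynomial hash so vectors are deterministic for a
# given canonical SMILES and variant, across platforms and sessions.

FP_VARIANTS <- c("path1024", "morgan_r2", "morgan_r3",
                 "feat_morgan_r2", "feat_morgan_r3")

FP_HASH_PRIME <- 67108859  # < 2^26 so state * 31 stays exact in doubles

fp_hash <- function(codes) {
  h <- 7
  for (c_ in codes) h <- (h * 31 + c_) %% FP_HASH_PRIME
  h
}

fp_element_code <- function(elements) {
  tbl <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si", "H")
  code <- match(elements, tbl)
  code[is.na(code)] <- length(tbl) + 1L
  code
}

# Adjacency list with bond orders for one molgraph.
fp_adjacency <- function(mol) {
  adj <- vector("list", mol$n_atoms)
  for (i in seq_len(mol$n_atoms)) adj[[i]] <- list(nb = integer(0), bo = integer(0))
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    a1 <- b[i, "a1"]; a2 <- b[i, "a2"]; o <- b[i, "order"]
    adj[[a1]]$nb <- c(adj[[a1]]$nb, a2); adj[[a1]]$bo <- c(adj[[a1]]$bo, o)
    adj[[a2]]$nb <- c(adj[[a2]]$nb, a1); adj[[a2]]$bo <- c(adj[[a2]]$bo, o)
  }
  adj
}

# Hashed identifiers of all linear paths of 1..max_len bonds. Each path is
# encoded as alternating element and bond-order codes; the lexicographically
# smaller of the two directions is hashed, so a path contributes the same
# bit regardless of traversal direction.
fp_path_codes <- function(mol, max_len = 7L) {
  if (nrow(mol$bonds) == 0L) return(numeric(0))
  ec <- fp_element_code(mol$elements)
  adj <- fp_adjacency(mol)
  codes <- numeric(0)
  walk <- function(path_atoms, path_codes) {
    last <- path_atoms[length(path_atoms)]
    nbs <- adj[[last]]
    for (k in seq_along(nbs$nb)) {
      nxt <- nbs$nb[k]
      if (nxt %in% path_atoms) next
      pc <- c(path_codes, 100L + nbs$bo[k], ec[nxt])
      seq_fwd <- pc
      seq_rev <- rev(pc)
      use <- if (paste(seq_fwd, collapse = ",") <= paste(seq_rev, collapse = ","))
        seq_fwd else seq_rev
      codes[[length(codes) + 1L]] <<- fp_hash(use)
      if ((length(pc) - 1L) / 2L < max_len)
        walk(c(path_atoms, nxt), pc)
    }
  }
  for (a in seq_len(mol$n_atoms)) walk(a, ec[a])
  codes
}

# Per-atom initial invariants for the Morgan variants.
fp_atom_invariants <- function(mol, featurized) {
  deg <- mol_degree(mol)
  nh <- mol$n_h
  ring <- seq_len(mol$n_atoms) %in% mol_ring_atoms(mol)
  el <- mol$elements
  if (featurized) {
    donor <- el %in% c("N", "O") & nh > 0
    acceptor <- el %in% c("N", "O")
    halogen <- el %in% c("F", "Cl", "Br", "I")
    inv <- cbind(donor, acceptor, halogen, ring)
  } else {
    inv <- cbind(fp_element_code(el), deg, nh, as.integer(ring))
  }
  apply(inv, 1, function(r) fp_hash(as.numeric(r)))
}

# Hashed identifiers of circular environments up to `radius`.
fp_morgan_codes <- function(mol, radius, featurized) {
  code <- fp_atom_invariants(mol, featurized)
  adj <- fp_adjacency(mol)
  all_codes <- code
  if (radius >= 1L) {
    for (r in seq_len(radius)) {
      new_code <- vapply(seq_len(mol$n_atoms), function(i) {
        nbs <- adj[[i]]
        if (length(nbs$nb) == 0L) return(fp_hash(c(r, code[i])))
        pair <- nbs$bo * FP_HASH_PRIME + code[nbs$nb]
        ord <- order(pair)
        fp_hash(c(r, code[i], as.numeric(rbind(nbs$bo[ord], code[nbs$nb[ord]]))))
      }, 0)
      code <- new_code
      all_codes <- c(all_codes, code)
    }
  }
  all_codes
}

fp_fold <- function(codes, nbits) {
  bits <- logical(nbits)
  if (length(codes) > 0L) bits[(codes %% nbits) + 1L] <- TRUE
  bits
}

fp_bits_for_mol <- function(mol, variant, nbits) {
  codes <- switch(variant,
    path1024 = fp_path_codes(mol),
    morgan_r2 = fp_morgan_codes(mol, 2L, FALSE),
    morgan_r3 = fp_morgan_codes(mol, 3L, FALSE),
    feat_morgan_r2 = fp_morgan_codes(mol, 2L, TRUE),
    feat_morgan_r3 = fp_morgan_codes(mol, 3L, TRUE),
    stop("unknown fingerprint variant: ", variant))
  fp_fold(codes, nbits)
}

#' Fingerprint variants
#'
#' @return character vector of the five supported variants.
#' @export
fingerprint_variants <- function() FP_VARIANTS

#' Compute a molecular fingerprint
#'
#' @param smiles a single SMILES string.
#' @param variant one of [fingerprint_variants()].
#' @param nbits fingerprint length in bits.
#' @param compound_id identifier carried on the result.
#' @return object of class `fingerprint`: list with `bits` (logical vector),
#'   `variant`, `nbits`, `compound_id`.
#' @export
fingerprint <- function(smiles, variant = "path1024", nbits = 1024L,
                        compound_id = NA_character_) {
  variant <- match.arg(variant, FP_VARIANTS)
  mol <- parse_smiles(smiles)[[1]]
  if (is.null(mol)) stop("unparsable SMILES: ", smiles)
  structure(list(bits = fp_bits_for_mol(mol, variant, nbits),
                 variant = variant, nbits = as.integer(nbits),
                 compound_id = compound_id),
            class = "fingerprint")
}

#' Fingerprint matrix for a compound library
#'
#' @param compounds compound library data.frame (compound_id, smiles) or a
#'   character vector of SMILES.
#' @param variant one of [fingerprint_variants()].
#' @param nbits fingerprint length.
#' @return 0/1 integer matrix, one row per compound, rownames = compound_id;
#'   attributes `variant` and `nbits`.
#' @export
fingerprint_matrix <- function(compounds, variant = "path1024", nbits = 1024L) {
  variant <- match.arg(variant, FP_VARIANTS)
  if (is.character(compounds))
    compounds <- data.frame(compound_id = compounds, smiles = compounds,
                            stringsAsFactors = FALSE)
  mols <- parse_smiles(compounds$smiles)
  bad <- vapply(mols, is.null, TRUE)
  if (any(bad))
    stop("unparsable SMILES for: ",
         paste(compounds$compound_id[bad], collapse = ", "))
  m <- t(vapply(mols, function(mol) {
    as.integer(fp_bits_for_mol(mol, variant, nbits))
  }, integer(nbits)))
  rownames(m) <- compounds$compound_id
  attr(m, "variant") <- variant
  attr(m, "nbits") <- as.integer(nbits)
  m
}

#' Tanimoto coefficient between two fingerprints
#'
#' \eqn{|a \wedge b| / |a \vee b|}; defined as 0 when both vectors are
#' all-zero.
#'
#' @param a,b `fingerprint` objects (or logical/0-1 vectors of equal length).
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (inherits(a, "fingerprint") && inherits(b, "fingerprint")) {
    if (a$variant != b$variant || a$nbits != b$nbits)
      stop("fingerprint variant/length mismatch")
    a <- a$bits; b <- b$bits
  }
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  un <- sum(a | b)
  if (un == 0L) return(0)
  sum(a & b) / un
}

# All-pairs Tanimoto between the rows of two 0/1 matrices.
tanimoto_matrix <- function(A, B) {
  common <- A %*% t(B)
  ra <- rowSums(A); rb <- rowSums(B)
  un <- outer(ra, rb, "+") - common
  s <- common / un
  s[un == 0] <- 0
  s
}

#' Tanimoto similarity search against a compound library
#'
#' Returns library compounds whose fingerprint similarity to the query
#' exceeds the threshold (strictly, matching a `> 0.85` search convention;
#' set `inclusive = TRUE` for `>=`). Results are sorted by descending
#' similarity, ties broken by compound_id.
#'
#' @param query a SMILES string.
#' @param library compound library data.frame.
#' @param variant fingerprint variant.
#' @param threshold similarity threshold (default 0.85).
#' @param inclusive include hits exactly at the threshold.
#' @param nbits fingerprint length.
#' @return data.frame with compound_id, tanimoto.
#' @export
similarity_search <- function(query, library, variant = "path1024",
                              threshold = 0.85, inclusive = FALSE,
                              nbits = 1024L) {
  stopifnot(nrow(library) > 0L)
  libm <- fingerprint_matrix(library, variant, nbits)
  qm <- fingerprint_matrix(data.frame(compound_id = "query", smiles = query,
                                      stringsAsFactors = FALSE),
                           variant, nbits)
  sims <- as.numeric(tanimoto_matrix(qm, libm))
  hit <- if (inclusive) sims >= threshold else sims > threshold
  res <- data.frame(compound_id = library$compound_id[hit],
                    tanimoto = sims[hit], stringsAsFactors = FALSE)
  res <- res[order(-res$tanimoto, res$compound_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
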
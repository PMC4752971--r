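# Shared fixture builders, cached per test run (generation goes through
# OpenBabel, so each expensive object is built once).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small default-condition fixture set (library, activities, targets, net).
small_fixture <- function() {
  cached("small", {
    cfg <- fixture_config(n_compounds = 80L, n_targets = 20L, seed = 42L)
    lib <- generate_library(cfg)
    act <- generate_activities(lib, cfg)
    list(cfg = cfg, lib = lib, records = act$records,
         targets = generate_targets(cfg),
         net = generate_network_and_annotations(cfg))
  })
}

# Separable QSAR fixture: clean labels at all three cutoffs.
qsar_fixture <- function(seed = 1L) {
  cached(paste0("qsar", seed), {
    cfg <- fixture_config(n_compounds = 200L, n_targets = 10L,
                          inactive_mean = 3, noise_sd = 0.3, seed = seed)
    lib <- generate_library(cfg)
    act <- generate_activities(lib, cfg)
    list(cfg = cfg, lib = lib, records = act$records)
  })
}

# Random 0/1 fingerprint-like matrix pairs for Tanimoto oracles.
random_bit_vectors <- function(n, nbits = 1024L, seed = 7L, density = 0.1) {
  set.seed(seed)
  matrix(as.integer(runif(n * nbits) < density), nrow = n)
}

# Independent per-bit Tanimoto oracle (deliberately naive loop).
tanimoto_oracle <- function(a, b) {
  inter <- 0L; un <- 0L
  for (k in seq_along(a)) {
    if (a[k] == 1L && b[k] == 1L) inter <- inter + 1L
    if (a[k] == 1L || b[k] == 1L) un <- un + 1L
  }
  if (un == 0L) return(0)
  inter / un
}

# Independent recursive depth-first traversal of a scaffold forest
# (re-implements the row-order contract without forest_compound_order).
forest_order_oracle <- function(forest) {
  nd <- forest$nodes
  kids <- function(s) sort(nd$scaffold[!is.na(nd$parent) & nd$parent == s])
  own <- function(s) sort(names(forest$leaf_of)[forest$leaf_of == s])
  rec <- function(s) {
    out <- own(s)
    for (k in kids(s)) out <- c(out, rec(k))
    out
  }
  ring_roots <- sort(nd$scaffold[is.na(nd$parent) & nd$is_ring])
  acyc_roots <- sort(nd$scaffold[is.na(nd$parent) & !nd$is_ring])
  out <- character(0)
  for (r in c(ring_roots, acyc_roots)) out <- c(out, rec(r))
  out
}

# Exhaustive hypergeometric upper-tail oracle by enumeration of draws.
hypergeom_oracle <- function(overlap, set_size, draw, universe) {
  draws <- utils::combn(universe, draw)
  annotated <- seq_len(set_size)
  hits <- apply(draws, 2, function(d) sum(d %in% annotated))
  mean(hits >= overlap)
}
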
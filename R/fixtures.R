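# Seeded synthetic-data generator.
#
# Produces a compound library from a scaffold grammar (single-ring scaffolds
# decorated with prefix/suffix fragments), an activity table with a planted
# structure-activity signal (compounds carrying a pharmacophore fragment are
# potent on the "active" targets), a target family table, and a PPI network
# with one planted dense module covered exactly by one annotation term.
# Everything is a pure function of the configuration, including its seed.

#' Fixture generator configuration
#'
#' @param n_compounds compounds to generate.
#' @param n_targets number of protein targets.
#' @param n_active_targets targets carrying the planted pharmacophore
#'   signal.
#' @param scaffold_grammar single-ring scaffold SMILES decorated to
#'   enumerate the library.
#' @param prefixes,suffixes decoration fragments (SMILES prefix/suffix
#'   strings).
#' @param planted_pharmacophore prefix fragment whose presence makes a
#'   compound active on the active targets.
#' @param active_mean,inactive_mean oriented-value (-log10 molar) means for
#'   pharmacophore/active-target pairs and for all other pairs.
#' @param noise_sd gaussian noise on oriented values.
#' @param missing_fraction fraction of compound-target pairs omitted.
#' @param module_size size of the planted dense PPI module.
#' @param n_random_terms random annotation terms beside the planted one.
#' @param edge_prob background PPI edge probability.
#' @param seed integer seed.
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(n_compounds = 100L, n_targets = 20L,
                           n_active_targets = 3L,
                           scaffold_grammar = c("c1ccccc1", "c1ccncc1",
                                                "C1CCCCC1", "c1ccsc1",
                                                "C1CCNCC1"),
                           prefixes = c("", "C", "CC", "CCC", "O", "CO",
                                        "CC(=O)N", "N", "CCN", "FC(F)(F)",
                                        "NS(=O)(=O)", "CNS(=O)(=O)",
                                        "CCNS(=O)(=O)", "OC(=O)", "C(=O)N",
                                        "CCO", "CN"),
                           suffixes = c("", "C", "CC", "O", "N", "Cl", "F",
                                        "CO", "C(C)C", "CC(C)C", "C#N",
                                        "C(=O)O", "C(=O)N", "OC", "CN"),
                           planted_pharmacophore = "NS(=O)(=O)",
                           active_mean = 7, inactive_mean = 4,
                           noise_sd = 0.5, missing_fraction = 0.3,
                           module_size = min(8L, n_targets),
                           n_random_terms = 20L,
                           edge_prob = 0.08, seed = 1L) {
  stopifnot(missing_fraction >= 0, missing_fraction < 1, noise_sd >= 0,
            length(scaffold_grammar) > 0L,
            any(grepl(planted_pharmacophore, prefixes, fixed = TRUE)),
            n_active_targets <= n_targets, module_size <= n_targets)
  structure(as.list(environment()), class = "fixture_config")
}

#' Generate the fixture compound library
#'
#' Enumerates prefix x scaffold x suffix combinations, canonicalizes, and
#' takes a seeded sample of `n_compounds`. The returned library carries a
#' `has_pharmacophore` bookkeeping column.
#'
#' @param config a [fixture_config()].
#' @return compound library data.frame (compound_id, smiles, name,
#'   has_pharmacophore).
#' @export
generate_library <- function(config) {
  grid <- expand.grid(prefix = config$prefixes,
                      scaffold = config$scaffold_grammar,
                      suffix = config$suffixes,
                      stringsAsFactors = FALSE)
  capacity <- nrow(grid)
  if (config$n_compounds > capacity)
    stop("requested ", config$n_compounds, " compounds but the grammar ",
         "enumerates only ", capacity)
  pick <- with_seed(config$seed, sample.int(capacity, config$n_compounds))
  grid <- grid[pick, , drop = FALSE]
  raw <- paste0(grid$prefix, grid$scaffold, grid$suffix)
  can <- canonicalize_smiles(raw)
  if (anyNA(can))
    stop("fixture grammar produced unparsable SMILES: ",
         paste(utils::head(raw[is.na(can)], 5), collapse = ", "))
  lib <- data.frame(compound_id = sprintf("C%04d", seq_along(can)),
                    smiles = can, name = NA_character_,
                    has_pharmacophore = grepl(config$planted_pharmacophore,
                                              grid$prefix, fixed = TRUE),
                    stringsAsFactors = FALSE)
  # collapse accidental duplicates from equivalent decorations
  lib[!duplicated(lib$smiles), , drop = FALSE]
}

#' Generate the fixture target family table
#'
#' @param config a [fixture_config()].
#' @return target table data.frame (target_id, family_path, family_levels).
#' @export
generate_targets <- function(config) {
  families <- c("enzyme/kinase/CMGC", "enzyme/kinase/TK", "enzyme/protease",
                "receptor/gpcr/aminergic", "receptor/gpcr/peptide",
                "receptor/nhr", "ion_channel/lgic", "transporter/slc")
  ids <- sprintf("P%05d", seq_len(config$n_targets))
  df <- data.frame(target_id = ids,
                   family_path = rep_len(families, config$n_targets),
                   stringsAsFactors = FALSE)
  df$family_levels <- strsplit(df$family_path, "/", fixed = TRUE)
  df
}

# Active (pharmacophore-carrying) targets of a config.
fixture_active_targets <- function(config) {
  sprintf("P%05d", seq_len(config$n_active_targets))
}

#' Generate the fixture activity table
#'
#' Pairs of a pharmacophore compound and an active target draw oriented
#' values near `active_mean`; every other pair near `inactive_mean`. Values
#' are back-converted to a random data type and unit so the table exercises
#' the full standardization path; `missing_fraction` of pairs is omitted.
#'
#' @param library library from [generate_library()].
#' @param config a [fixture_config()].
#' @return list with `records` (validated activity records) and
#'   `n_rejected` (always 0 for generator output).
#' @export
generate_activities <- function(library, config) {
  targets <- sprintf("P%05d", seq_len(config$n_targets))
  active_t <- fixture_active_targets(config)
  pairs <- expand.grid(compound_id = library$compound_id,
                       target_id = targets, stringsAsFactors = FALSE)
  is_active <- library$has_pharmacophore[match(pairs$compound_id,
                                               library$compound_id)] &
    pairs$target_id %in% active_t
  rows <- with_seed(config$seed + 1L, {
    keep <- stats::runif(nrow(pairs)) >= config$missing_fraction
    pairs <- pairs[keep, , drop = FALSE]
    is_active <- is_active[keep]
    oriented <- stats::rnorm(nrow(pairs),
                             ifelse(is_active, config$active_mean,
                                    config$inactive_mean),
                             config$noise_sd)
    types <- sample(activity_data_types(), nrow(pairs), replace = TRUE)
    units <- sample(c("M", "mM", "uM", "nM"), nrow(pairs), replace = TRUE)
    is_raw <- types %in% ACTIVITY_RAW_TYPES
    is_log <- types %in% ACTIVITY_LOG_TYPES
    value <- oriented
    value[is_raw] <- 10^(9 - oriented[is_raw]) / UNIT_TO_NM[units[is_raw]]
    value[is_log] <- -oriented[is_log]
    data.frame(compound_id = pairs$compound_id, target_id = pairs$target_id,
               data_type = types, value = value,
               unit = ifelse(is_raw, units, ""),
               stringsAsFactors = FALSE)
  })
  as_activity_records(rows)
}

#' Generate the fixture PPI network and annotation sets
#'
#' A random background graph over the targets with one planted dense module
#' (a clique of `module_size` targets); one annotation term covers the
#' module exactly, the remaining terms are random subsets.
#'
#' @param config a [fixture_config()].
#' @return list with `network` (edge data.frame), `annotations` (list of
#'   annotation sets) and `planted_term` (its term_id).
#' @export
generate_network_and_annotations <- function(config) {
  targets <- sprintf("P%05d", seq_len(config$n_targets))
  module <- targets[seq_len(config$module_size)]
  with_seed(config$seed + 2L, {
    all_pairs <- utils::combn(targets, 2)
    in_module <- all_pairs[1, ] %in% module & all_pairs[2, ] %in% module
    bg <- stats::runif(ncol(all_pairs)) < config$edge_prob
    sel <- in_module | bg
    network <- ppi_network(all_pairs[1, sel], all_pairs[2, sel])
    planted <- list(term_id = "TERM_PLANTED", category = "pathway",
                    members = module)
    cats <- c("disease", "pathway", "go_term")
    ann <- c(list(planted), lapply(seq_len(config$n_random_terms), function(i) {
      size <- sample(3:min(10L, config$n_targets), 1)
      list(term_id = sprintf("TERM_%03d", i),
           category = cats[1 + (i %% 3)],
           members = sample(targets, size))
    }))
    list(network = network, annotations = ann, planted_term = "TERM_PLANTED")
  })
}

#' Write a complete fixture set to a directory
#'
#' Writes compounds.smi, activities.tsv, targets.tsv, ppi.tsv and
#' annotations.gmt in the package's standard formats.
#'
#' @param dir output directory (created if needed).
#' @param config a [fixture_config()].
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(dir, config = fixture_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- generate_library(config)
  act <- generate_activities(lib, config)
  tg <- generate_targets(config)
  net <- generate_network_and_annotations(config)
  paths <- c(compounds = file.path(dir, "compounds.smi"),
             activities = file.path(dir, "activities.tsv"),
             targets = file.path(dir, "targets.tsv"),
             ppi = file.path(dir, "ppi.tsv"),
             annotations = file.path(dir, "annotations.gmt"))
  write_compounds(lib, paths["compounds"])
  write_activity_table(act$records[c("compound_id", "target_id", "data_type",
                                     "value", "unit")], paths["activities"])
  write_targets(tg, paths["targets"])
  write_ppi(net$network, paths["ppi"])
  write_annotations(net$annotations, paths["annotations"])
  invisible(paths)
}
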
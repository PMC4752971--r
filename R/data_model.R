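# Domain types and file I/O. Everything downstream consumes the plain
# data.frames defined here: compound libraries, activity tables, target
# family tables, annotation sets and PPI edge lists.

ACTIVITY_RAW_TYPES <- c("IC50", "EC50", "Potency", "AC50", "Kd", "Ki")
ACTIVITY_P_TYPES <- c("pIC50", "pKi", "pEC50")
ACTIVITY_LOG_TYPES <- c("LogKi")

#' Supported bioactivity data types
#'
#' The ten standardized data types: six raw concentration types (stored in
#' nM), three p-scale types (dimensionless, already \eqn{-\log_{10}} molar)
#' and LogKi (\eqn{\log_{10}} molar). Additional p-scale types can be
#' registered through the `extra_p_types` argument of the readers, the
#' extension hook for an eleventh type.
#'
#' @return character vector of data type names.
#' @export
activity_data_types <- function() {
  c(ACTIVITY_RAW_TYPES, ACTIVITY_P_TYPES, ACTIVITY_LOG_TYPES)
}

# nM-per-unit conversion factors for concentration units.
UNIT_TO_NM <- c(M = 1e9, mM = 1e6, uM = 1e3, "µM" = 1e3, nM = 1)

new_compound_library <- function(compound_id, smiles, name = NA_character_) {
  stopifnot(!anyDuplicated(compound_id))
  data.frame(compound_id = as.character(compound_id),
             smiles = as.character(smiles),
             name = as.character(name),
             stringsAsFactors = FALSE)
}

#' Build a compound library from SMILES strings
#'
#' Canonicalizes all SMILES in one batch; unparsable entries are dropped and
#' counted, never silently lost.
#'
#' @param smiles character vector of SMILES.
#' @param compound_id character vector of unique identifiers (defaults to
#'   `cmpd_1 ...`).
#' @param name optional compound names.
#' @return list with `compounds` (data.frame: compound_id, smiles, name) and
#'   `n_failed` (count of unparsable records).
#' @export
compound_library <- function(smiles,
                             compound_id = sprintf("cmpd_%d", seq_along(smiles)),
                             name = NA_character_) {
  stopifnot(length(compound_id) == length(smiles))
  name <- rep_len(as.character(name), length(smiles))
  can <- canonicalize_smiles(smiles)
  ok <- !is.na(can)
  list(compounds = new_compound_library(compound_id[ok], can[ok], name[ok]),
       n_failed = sum(!ok))
}

#' Read compounds from a SMILES list or SDF file
#'
#' SMILES list format: one record per line, SMILES first, optional
#' whitespace-separated identifier second. SDF: V2000 records; the molecule
#' title is the identifier.
#'
#' @param path file path.
#' @param format `"smiles_list"` or `"sdf"`.
#' @return list with `compounds` (canonical SMILES) and `n_failed`.
#' @export
read_compounds <- function(path, format = c("smiles_list", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read compound file: ", path)
  if (format == "smiles_list") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) stop("empty compound library: ", path)
    parts <- strsplit(lines, "[[:space:]]+")
    smi <- vapply(parts, `[[`, "", 1L)
    ids <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, "")
    ids <- ifelse(is.na(ids), sprintf("cmpd_%d", seq_along(smi)), ids)
    res <- compound_library(smi, make.unique(ids, sep = "_"))
  } else {
    sdfs <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdfs)
    ids[is.na(ids) | !nzchar(ids)] <- sprintf("cmpd_%d", which(is.na(ids) | !nzchar(ids)))
    smi <- vapply(seq_along(sdfs), function(i) {
      s <- tryCatch(as.character(ChemmineR::sdf2smiles(sdfs[i])),
                    error = function(e) NA_character_)
      if (length(s) == 0L) NA_character_ else s
    }, "")
    res <- compound_library(smi, make.unique(ids, sep = "_"))
  }
  if (nrow(res$compounds) == 0L)
    stop("no parsable molecules in ", path)
  res
}

#' Write compounds to a SMILES list or SDF file
#'
#' @param compounds compound library data.frame.
#' @param path output path.
#' @param format `"smiles_list"` or `"sdf"`.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(compounds, path, format = c("smiles_list", "sdf")) {
  format <- match.arg(format)
  if (format == "smiles_list") {
    writeLines(paste(compounds$smiles, compounds$compound_id), path)
  } else {
    smi <- compounds$smiles
    names(smi) <- compounds$compound_id
    sdfs <- ChemmineR::smiles2sdf(smi)
    ChemmineR::write.SDF(sdfs, file = path, cid = TRUE)
  }
  invisible(path)
}

#' Read a bioactivity table
#'
#' Tab-separated with header columns `compound_id`, `target_id`,
#' `data_type`, `value`, `unit`. Concentration values are normalized to nM
#' (accepted input units: M, mM, uM/µM, nM); p-scale and LogKi values pass
#' through unchanged. Rows with unknown data types or units, or non-positive
#' concentrations, are rejected and counted. The oriented value
#' (\eqn{-\log_{10}} molar, larger = stronger) is derived on load.
#'
#' @param path file path.
#' @param extra_p_types additional dimensionless p-scale data types to accept
#'   unchanged (extension hook).
#' @return list with `records` (data.frame: compound_id, target_id,
#'   data_type, value, unit, oriented_value, z_score) and `n_rejected`.
#' @export
read_activity_table <- function(path, extra_p_types = character(0)) {
  if (!file.exists(path)) stop("cannot read activity table: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("compound_id", "target_id", "data_type", "value", "unit")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("activity table missing column(s): ", paste(missing, collapse = ", "))
  as_activity_records(df[required], extra_p_types = extra_p_types)
}

#' Validate and normalize raw activity rows
#'
#' @param df data.frame with compound_id, target_id, data_type, value, unit.
#' @param extra_p_types see [read_activity_table()].
#' @return list with `records` and `n_rejected`.
#' @export
as_activity_records <- function(df, extra_p_types = character(0)) {
  known <- c(activity_data_types(), extra_p_types)
  p_like <- c(ACTIVITY_P_TYPES, extra_p_types)
  dt <- as.character(df$data_type)
  value <- as.numeric(df$value)
  unit <- as.character(df$unit)
  ok <- dt %in% known & is.finite(value)
  is_raw <- dt %in% ACTIVITY_RAW_TYPES
  ok[is_raw & !(unit %in% names(UNIT_TO_NM))] <- FALSE
  ok[is_raw & value <= 0] <- FALSE
  value_nm <- value
  conv <- is_raw & ok
  value_nm[conv] <- value[conv] * UNIT_TO_NM[unit[conv]]
  unit_out <- ifelse(is_raw, "nM", "")
  rec <- data.frame(compound_id = as.character(df$compound_id),
                    target_id = as.character(df$target_id),
                    data_type = dt, value = value_nm, unit = unit_out,
                    stringsAsFactors = FALSE)[ok, , drop = FALSE]
  rownames(rec) <- NULL
  rec$oriented_value <- orient_value(rec$data_type, rec$value,
                                     extra_p_types = extra_p_types)
  rec$z_score <- rep(NA_real_, nrow(rec))
  list(records = rec, n_rejected = sum(!ok))
}

#' Write an activity table (with derived columns) to TSV
#'
#' @param records activity record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a target family table
#'
#' Tab-separated with columns `target_id` and `family_path`; the family path
#' is a root-to-leaf protein classification written with `/` separators
#' (e.g. `enzyme/kinase/CMGC`).
#'
#' @param path file path.
#' @return data.frame with target_id, family_path (character) and
#'   family_levels (list column of split paths).
#' @export
read_targets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("target_id", "family_path") %in% names(df)))
    stop("target table must have columns target_id, family_path")
  if (anyDuplicated(df$target_id)) stop("duplicate target_id in ", path)
  if (any(!nzchar(df$family_path))) stop("empty family_path in ", path)
  df$family_levels <- strsplit(df$family_path, "/", fixed = TRUE)
  df
}

#' @rdname read_targets
#' @param targets target table data.frame.
#' @export
write_targets <- function(targets, path) {
  utils::write.table(targets[c("target_id", "family_path")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GMT-like annotation sets
#'
#' Tab-separated, one term per line: `term_id`, `category` (one of
#' `disease`, `pathway`, `go_term`), then member target ids. Terms with no
#' members are rejected.
#'
#' @param path file path.
#' @return list of annotation sets, each `list(term_id, category, members)`.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("annotation line with no members: ", f[1])
    cat_ <- match.arg(f[2], c("disease", "pathway", "go_term"))
    out[[length(out) + 1L]] <- list(term_id = f[1], category = cat_,
                                    members = unique(f[-(1:2)]))
  }
  out
}

#' @rdname read_annotations
#' @param annotations list of annotation sets.
#' @export
write_annotations <- function(annotations, path) {
  lines <- vapply(annotations, function(a) {
    paste(c(a$term_id, a$category, a$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Two tab-separated columns of target ids. Self-loops are dropped and
#' duplicate unordered pairs collapsed.
#'
#' @param path file path.
#' @return data.frame with columns `a`, `b` (a < b lexicographically).
#' @export
read_ppi <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("a", "b"))
  ppi_network(df$a, df$b)
}

#' Construct a PPI network edge table
#'
#' @param a,b character vectors of interacting protein ids.
#' @return normalized edge data.frame (no self-loops, unique unordered pairs).
#' @export
ppi_network <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  keep <- a != b
  lo <- pmin(a[keep], b[keep]); hi <- pmax(a[keep], b[keep])
  df <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

#' @rdname read_ppi
#' @param network PPI edge data.frame.
#' @export
write_ppi <- function(network, path) {
  utils::write.table(network, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
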
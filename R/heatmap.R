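# Pharmacological heatmap matrix assembly.
#
# Rows are compounds in scaffold-forest depth-first order; columns are
# proteins in family-tree depth-first order. Cells hold the strongest
# (maximum) z-score across data types for the pair; empty cells can be
# filled by SEA or QSAR predictions, tagged by origin and never overwriting
# a measured cell. The color legend convention is blue = low (weak),
# orange = high (strong).

#' Depth-first target order over the protein family tree
#'
#' Linearizes the family classification: siblings at every level sorted
#' lexicographically, a node's own targets (sorted by target id) listed
#' before its subfamilies.
#'
#' @param targets target table from [read_targets()].
#' @return character vector of target ids.
#' @export
target_family_order <- function(targets) {
  paths <- targets$family_levels
  if (is.null(paths)) paths <- strsplit(targets$family_path, "/", fixed = TRUE)
  visit <- function(idx, depth) {
    done <- vapply(paths[idx], length, 1L) < depth
    own <- idx[done]
    own <- own[order(targets$target_id[own])]
    rest <- idx[!done]
    if (length(rest) == 0L) return(targets$target_id[own])
    lab <- vapply(paths[rest], `[[`, "", depth)
    out <- targets$target_id[own]
    for (l in sort(unique(lab))) {
      out <- c(out, visit(rest[lab == l], depth + 1L))
    }
    out
  }
  visit(seq_len(nrow(targets)), 1L)
}

#' Assemble the pharmacological heatmap matrix
#'
#' @param records activity record data.frame with `z_score` computed.
#' @param forest scaffold forest of the compound library (defines row
#'   order); every measured compound must be in the forest.
#' @param targets target table (defines column order); every measured
#'   target must be present.
#' @param aggregate how to collapse multiple data types per cell: `"max"`
#'   (strongest evidence, default) or `"mean"`.
#' @return object of class `heatmap_matrix`: `row_order`, `col_order`,
#'   `cells` (data.frame: compound_id, target_id, value, origin, raw) and
#'   `scale` (low/high of the measured values).
#' @export
build_heatmap_matrix <- function(records, forest, targets,
                                 aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(is.finite(records$z_score)))
  bad <- setdiff(unique(records$compound_id), names(forest$leaf_of))
  if (length(bad) > 0L)
    stop("measured compound(s) missing from scaffold forest: ",
         paste(bad, collapse = ", "))
  badt <- setdiff(unique(records$target_id), targets$target_id)
  if (length(badt) > 0L)
    stop("measured target(s) missing from target table: ",
         paste(badt, collapse = ", "))
  key <- paste(records$compound_id, records$target_id, sep = "\r")
  agg <- if (aggregate == "max") max else mean
  val <- tapply(records$z_score, key, agg)
  ids <- strsplit(names(val), "\r", fixed = TRUE)
  cells <- data.frame(compound_id = vapply(ids, `[[`, "", 1L),
                      target_id = vapply(ids, `[[`, "", 2L),
                      value = as.numeric(val), origin = "measured",
                      raw = NA_real_, stringsAsFactors = FALSE)
  rownames(cells) <- NULL
  structure(list(row_order = forest_compound_order(forest),
                 col_order = target_family_order(targets),
                 cells = cells,
                 scale = c(low = min(cells$value), high = max(cells$value))),
            class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat(sprintf("heatmap_matrix: %d x %d, %d cells (%s), scale [%.3g, %.3g] (blue = low, orange = high)\n",
              length(x$row_order), length(x$col_order), nrow(x$cells),
              paste(sprintf("%s: %d", names(table(x$cells$origin)),
                            table(x$cells$origin)), collapse = ", "),
              x$scale["low"], x$scale["high"]))
  invisible(x)
}

#' Fill empty heatmap cells with SEA or QSAR predictions
#'
#' Only empty cells are written; measured cells are immutable. QSAR fills
#' store the \[0, 1\] ensemble prediction in `raw` and a display value
#' rescaled to the matrix scale; SEA fills store the SEA z-score as the
#' display value and the E-value in `raw`.
#'
#' @param matrix a `heatmap_matrix`.
#' @param mode `"sea"` or `"qsar"`.
#' @param predictor for `"qsar"`: a named list of `qsar_ensemble` objects
#'   (by target id; columns without a model are left empty and reported in
#'   the `unfilled_targets` attribute). For `"sea"`: a list with elements
#'   `model` (a `sea_background`), `target_sets` and `compounds` (the
#'   compound library giving structures for the rows).
#' @param compounds compound library data.frame giving structures for the
#'   rows (qsar mode).
#' @return the matrix with predicted cells added.
#' @export
fill_gaps <- function(matrix, mode = c("sea", "qsar"), predictor,
                      compounds = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "heatmap_matrix"))
  have <- paste(matrix$cells$compound_id, matrix$cells$target_id, sep = "\r")
  lo <- matrix$scale[["low"]]; hi <- matrix$scale[["high"]]
  new_cells <- list()
  if (mode == "qsar") {
    stopifnot(!is.null(compounds))
    unfilled <- setdiff(matrix$col_order, names(predictor))
    for (tid in intersect(matrix$col_order, names(predictor))) {
      empty_rows <- matrix$row_order[!(paste(matrix$row_order, tid, sep = "\r") %in% have)]
      if (length(empty_rows) == 0L) next
      sub <- compounds[match(empty_rows, compounds$compound_id), , drop = FALSE]
      pred <- predict_qsar(predictor[[tid]], sub)
      new_cells[[length(new_cells) + 1L]] <-
        data.frame(compound_id = pred$compound_id, target_id = tid,
                   value = lo + pred$prediction * (hi - lo),
                   origin = "qsar", raw = pred$prediction,
                   stringsAsFactors = FALSE)
    }
    attr_unfilled <- unfilled
  } else {
    stopifnot(is.list(predictor), inherits(predictor$model, "sea_background"))
    cmp <- predictor$compounds
    for (cid in matrix$row_order) {
      empty_cols <- matrix$col_order[!(paste(cid, matrix$col_order, sep = "\r") %in% have)]
      empty_cols <- intersect(empty_cols, names(predictor$target_sets))
      if (length(empty_cols) == 0L) next
      q <- cmp[match(cid, cmp$compound_id), , drop = FALSE]
      pred <- sea_predict(q, predictor$target_sets[empty_cols], predictor$model)
      if (nrow(pred) == 0L) next
      new_cells[[length(new_cells) + 1L]] <-
        data.frame(compound_id = cid, target_id = pred$target_id,
                   value = pred$z_score, origin = "sea", raw = pred$e_value,
                   stringsAsFactors = FALSE)
    }
    attr_unfilled <- character(0)
  }
  if (length(new_cells) > 0L)
    matrix$cells <- rbind(matrix$cells, do.call(rbind, new_cells))
  attr(matrix, "unfilled_targets") <- attr_unfilled
  matrix
}

#' Collapse heatmap columns through annotation membership
#'
#' Produces the pathway/disease-mode matrix: one column per annotation
#' term, cell = strongest value over the term's member targets.
#'
#' @param matrix a `heatmap_matrix`.
#' @param annotations list of annotation sets.
#' @param category which category of terms to use.
#' @return a `heatmap_matrix` whose columns are term ids.
#' @export
collapse_columns <- function(matrix, annotations,
                             category = c("pathway", "disease", "go_term")) {
  category <- match.arg(category)
  ann <- Filter(function(a) a$category == category, annotations)
  if (length(ann) == 0L) stop("no annotation terms of category ", category)
  cells <- list()
  for (a in ann) {
    sub <- matrix$cells[matrix$cells$target_id %in% a$members, , drop = FALSE]
    if (nrow(sub) == 0L) next
    val <- tapply(sub$value, sub$compound_id, max)
    cells[[length(cells) + 1L]] <-
      data.frame(compound_id = names(val), target_id = a$term_id,
                 value = as.numeric(val), origin = "measured",
                 raw = NA_real_, stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cells)
  structure(list(row_order = matrix$row_order,
                 col_order = sort(vapply(ann, `[[`, "", "term_id")),
                 cells = cells, scale = matrix$scale),
            class = "heatmap_matrix")
}

fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Export a heatmap matrix
#'
#' TSV: dense grid with row/column headers and blank empty cells, plus a
#' `<path>.origin` sidecar grid of cell origins. JSON: row/column orders,
#' scale, legend and sparse cell records. TSV export -> import -> export is
#' byte-idempotent.
#'
#' @param matrix a `heatmap_matrix`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(matrix, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(row_order = matrix$row_order, col_order = matrix$col_order,
           scale = as.list(matrix$scale),
           legend = list(low = "blue", high = "orange"),
           cells = matrix$cells),
      path, auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(path))
  }
  m <- match(paste(rep(matrix$row_order, each = length(matrix$col_order)),
                   rep(matrix$col_order, length(matrix$row_order)), sep = "\r"),
             paste(matrix$cells$compound_id, matrix$cells$target_id, sep = "\r"))
  vals <- matrix(fmt_num(matrix$cells$value[m]),
                 nrow = length(matrix$row_order), byrow = TRUE)
  orig <- matrix(ifelse(is.na(m), "", matrix$cells$origin[m]),
                 nrow = length(matrix$row_order), byrow = TRUE)
  hdr <- paste(c("compound_id", matrix$col_order), collapse = "\t")
  lines <- c(hdr, vapply(seq_along(matrix$row_order), function(i) {
    paste(c(matrix$row_order[i], vals[i, ]), collapse = "\t")
  }, ""))
  writeLines(lines, path)
  olines <- c(hdr, vapply(seq_along(matrix$row_order), function(i) {
    paste(c(matrix$row_order[i], orig[i, ]), collapse = "\t")
  }, ""))
  writeLines(olines, paste0(path, ".origin"))
  invisible(path)
}

#' Import a heatmap matrix from its TSV export
#'
#' @param path path of the TSV grid (expects the `<path>.origin` sidecar).
#' @return a `heatmap_matrix`.
#' @export
read_heatmap_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  col_order <- hdr[-1]
  opath <- paste0(path, ".origin")
  olines <- if (file.exists(opath)) readLines(opath, warn = FALSE) else NULL
  row_order <- character(0); cells <- list()
  for (i in seq_along(lines[-1])) {
    f <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    f <- c(f, rep("", length(hdr) - length(f)))
    row_order <- c(row_order, f[1])
    of <- if (!is.null(olines)) {
      g <- strsplit(olines[i + 1], "\t", fixed = TRUE)[[1]]
      c(g, rep("", length(hdr) - length(g)))
    } else rep("measured", length(hdr))
    filled <- which(nzchar(f[-1]))
    if (length(filled) > 0L) {
      cells[[length(cells) + 1L]] <-
        data.frame(compound_id = f[1], target_id = col_order[filled],
                   value = as.numeric(f[-1][filled]),
                   origin = ifelse(nzchar(of[-1][filled]), of[-1][filled],
                                   "measured"),
                   raw = NA_real_, stringsAsFactors = FALSE)
    }
  }
  cells <- if (length(cells) > 0L) do.call(rbind, cells) else
    data.frame(compound_id = character(0), target_id = character(0),
               value = numeric(0), origin = character(0), raw = numeric(0))
  measured <- cells$value[cells$origin == "measured"]
  sc <- if (length(measured) > 0L) c(low = min(measured), high = max(measured))
  else c(low = 0, high = 1)
  structure(list(row_order = row_order, col_order = col_order,
                 cells = cells, scale = sc),
            class = "heatmap_matrix")
}
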
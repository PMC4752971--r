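# Minimal hand-built inputs for matrix-shape tests.
tiny_heatmap <- function() {
  lib <- compound_library(c("Cc1ccccc1", "Oc1ccccc1", "CC1CCNCC1"),
                          c("cA", "cB", "cC"))$compounds
  forest <- build_forest(lib)
  targets <- data.frame(
    target_id = c("T1", "T2", "T3"),
    family_path = c("enzyme/kinase", "enzyme/protease", "receptor"),
    stringsAsFactors = FALSE)
  rec <- as_activity_records(data.frame(
    compound_id = c("cA", "cA", "cB", "cC"),
    target_id = c("T1", "T1", "T2", "T3"),
    data_type = c("IC50", "Ki", "pKi", "pIC50"),
    value = c(100, 10, 7, 5), unit = c("nM", "nM", "", "")))$records
  rec$z_score <- c(0.4, 1.2, -0.3, 0.8)  # direct cell values for shape tests
  list(lib = lib, forest = forest, targets = targets, records = rec)
}

test_that("matrix assembly takes the strongest data type per pair", {
  tn <- tiny_heatmap()
  hm <- build_heatmap_matrix(tn$records, tn$forest, tn$targets)
  cell <- hm$cells[hm$cells$compound_id == "cA" & hm$cells$target_id == "T1", ]
  expect_equal(cell$value, 1.2)  # max(0.4, 1.2)
  expect_equal(nrow(hm$cells), 3L)
  expect_true(all(hm$cells$origin == "measured"))
  # mean aggregation on request
  hm2 <- build_heatmap_matrix(tn$records, tn$forest, tn$targets, "mean")
  cell2 <- hm2$cells[hm2$cells$compound_id == "cA" & hm2$cells$target_id == "T1", ]
  expect_equal(cell2$value, 0.8)
  # single-record matrix is 1 cell
  hm1 <- build_heatmap_matrix(tn$records[3, ], tn$forest, tn$targets)
  expect_equal(nrow(hm1$cells), 1L)
})

test_that("unknown compounds or targets are an error naming the offender", {
  tn <- tiny_heatmap()
  bad <- tn$records
  bad$compound_id[1] <- "ghost"
  expect_error(build_heatmap_matrix(bad, tn$forest, tn$targets), "ghost")
  bad2 <- tn$records
  bad2$target_id[1] <- "T9"
  expect_error(build_heatmap_matrix(bad2, tn$forest, tn$targets), "T9")
})

test_that("row order equals the independent forest traversal oracle", {
  fx <- small_fixture()
  z <- compute_zscores(fx$records)$records
  forest <- build_forest(fx$lib)
  hm <- build_heatmap_matrix(z, forest, fx$targets)
  expect_equal(hm$row_order, forest_order_oracle(forest))
  expect_setequal(hm$row_order, fx$lib$compound_id)
})

test_that("column order is a depth-first family-tree walk", {
  targets <- data.frame(
    target_id = c("T5", "T1", "T2", "T4", "T3", "T6"),
    family_path = c("b", "a/x", "a/x", "a/y", "a", "b/z"),
    stringsAsFactors = FALSE)
  # oracle: recursive walk, own targets before subfamilies, sorted siblings
  expect_equal(target_family_order(targets),
               c("T3", "T1", "T2", "T4", "T5", "T6"))
})

test_that("gap filling writes only empty cells and never touches measured ones", {
  fx <- qsar_fixture(1L)
  z <- compute_zscores(fx$records)$records
  forest <- build_forest(fx$lib)
  targets <- generate_targets(fx$cfg)
  hm <- build_heatmap_matrix(z, forest, targets)
  ens <- train_qsar_ensemble(fx$records, "P00001", fx$lib, seed = 1,
                             variants = "path1024")
  filled <- fill_gaps(hm, "qsar", list(P00001 = ens), compounds = fx$lib)
  n_meas <- nrow(hm$cells)
  expect_identical(filled$cells[seq_len(n_meas), ], hm$cells)
  added <- filled$cells[-seq_len(n_meas), ]
  expect_true(all(added$origin == "qsar"))
  expect_true(all(added$target_id == "P00001"))
  expect_true(all(added$raw >= 0 & added$raw <= 1))
  # exactly the empty cells of that column were filled
  measured_there <- hm$cells$compound_id[hm$cells$target_id == "P00001"]
  expect_setequal(added$compound_id, setdiff(hm$row_order, measured_there))
  # second fill pass adds nothing and measured cells stay bit-identical
  again <- fill_gaps(filled, "qsar", list(P00001 = ens), compounds = fx$lib)
  expect_identical(again$cells, filled$cells)
  expect_setequal(attr(filled, "unfilled_targets"),
                  setdiff(targets$target_id, "P00001"))
})

test_that("a fully measured matrix passes through gap filling unchanged", {
  tn <- tiny_heatmap()
  rec <- expand.grid(compound_id = c("cA", "cB", "cC"),
                     target_id = c("T1", "T2", "T3"),
                     stringsAsFactors = FALSE)
  rec$data_type <- "pKi"; rec$value <- 5; rec$unit <- ""
  rec <- as_activity_records(rec)$records
  rec$z_score <- rnorm(9)
  hm <- build_heatmap_matrix(rec, tn$forest, tn$targets)
  filled <- fill_gaps(hm, "qsar", list(), compounds = tn$lib)
  expect_identical(filled$cells, hm$cells)
})

test_that("TSV export is dense, importable and byte-idempotent", {
  tn <- tiny_heatmap()
  hm1 <- build_heatmap_matrix(tn$records[3, ], tn$forest, tn$targets)
  p0 <- withr::local_tempfile(fileext = ".tsv")
  export_heatmap(hm1, p0)
  expect_length(readLines(p0), 1L + length(hm1$row_order))

  fx <- small_fixture()
  z <- compute_zscores(fx$records)$records
  hm <- build_heatmap_matrix(z, build_forest(fx$lib), fx$targets)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  export_heatmap(hm, p1)
  export_heatmap(read_heatmap_tsv(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(paste0(p1, ".origin")),
                   readLines(paste0(p2, ".origin")))
  # values and origins survive the round trip
  back <- read_heatmap_tsv(p1)
  key <- function(m) m$cells[order(m$cells$compound_id, m$cells$target_id),
                             c("compound_id", "target_id", "value", "origin")]
  expect_equal(key(back), key(hm), ignore_attr = TRUE)
})

test_that("JSON export carries the sparse cells and legend", {
  tn <- tiny_heatmap()
  hm <- build_heatmap_matrix(tn$records, tn$forest, tn$targets)
  p <- withr::local_tempfile(fileext = ".json")
  export_heatmap(hm, p, "json")
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(nrow(j$cells), nrow(hm$cells))
  expect_equal(j$legend$low, "blue")
  expect_equal(j$legend$high, "orange")
  expect_equal(j$row_order, hm$row_order)
})

test_that("annotation-mode matrices collapse columns by strongest member", {
  tn <- tiny_heatmap()
  hm <- build_heatmap_matrix(tn$records, tn$forest, tn$targets)
  ann <- list(list(term_id = "PW1", category = "pathway",
                   members = c("T1", "T2")),
              list(term_id = "PW2", category = "pathway", members = "T3"))
  cm <- collapse_columns(hm, ann, "pathway")
  expect_equal(cm$col_order, c("PW1", "PW2"))
  v <- cm$cells[cm$cells$compound_id == "cA" & cm$cells$target_id == "PW1", ]
  expect_equal(v$value, 1.2)
})
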
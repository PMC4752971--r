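test_that("activity labeling uses the strongest measurement and an inclusive cutoff", {
  rec <- as_activity_records(data.frame(
    compound_id = c("c1", "c2", "c2", "c3"),
    target_id = "t1",
    data_type = c("IC50", "IC50", "Ki", "Ki"),
    value = c(1000, 50000, 100000, 100),
    unit = c("nM", "nM", "nM", "uM")))$records
  # c1: oriented 6; c2: best oriented ~4.3; c3: oriented 4
  expect_equal(unname(label_actives(rec, "t1", 6)[c("c1", "c2", "c3")]),
               c("active", "inactive", "inactive"))
  expect_equal(unname(label_actives(rec, "t1", 4)["c3"]), "active")
  l5 <- label_actives(rec, "t1", 5)
  expect_equal(unname(l5[c("c1", "c3")]), c("active", "inactive"))
  expect_length(label_actives(rec, "absent", 5), 0L)
})

test_that("planted potencies give the constructed active counts at each cutoff", {
  fx <- qsar_fixture(1L)
  lab6 <- label_actives(fx$records, "P00001", 6)
  lib <- fx$lib
  truth <- lib$has_pharmacophore[match(names(lab6), lib$compound_id)]
  expect_equal(unname(lab6 == "active"), truth)
  # at cutoff 4 the labels are identical (actives ~7, inactives ~3)
  lab4 <- label_actives(fx$records, "P00001", 4)
  expect_equal(unname(lab4 == "active"), truth)
})

test_that("negative balancing tops up, subsamples, and is seed-stable", {
  pos <- sprintf("p%d", 1:10)
  pool <- sprintf("x%d", 1:30)
  mn <- sprintf("n%d", 1:10)
  expect_equal(balance_negatives(pos, mn, pool, 1), mn)

  few <- mn[1:4]
  got <- balance_negatives(pos, few, pool, 5)
  expect_length(got, 10L)
  expect_true(all(few %in% got))
  expect_length(setdiff(got, few), 6L)
  expect_identical(got, balance_negatives(pos, few, pool, 5))
  expect_false(identical(got, balance_negatives(pos, few, pool, 6)))

  many <- sprintf("n%d", 1:25)
  sub <- balance_negatives(pos, many, pool, 2)
  expect_length(sub, 10L)
  expect_true(all(sub %in% many))

  expect_error(balance_negatives(pos, few, pool[1:3], 1), "cannot balance")
  expect_error(balance_negatives(pos, mn, c(pool, pos[1]), 1), "exclude")
})

test_that("training refuses a target with exactly 20 compounds (> 20 gate)", {
  lib <- small_fixture()$lib
  rec <- as_activity_records(data.frame(
    compound_id = lib$compound_id[1:20], target_id = "tGate",
    data_type = "pKi", value = 7, unit = ""))$records
  expect_error(train_qsar_ensemble(rec, "tGate", lib), "insufficient data")
})

test_that("ensemble training is deterministic and balanced", {
  fx <- qsar_fixture(1L)
  e1 <- train_qsar_ensemble(fx$records, "P00001", fx$lib, seed = 3,
                            variants = c("path1024", "morgan_r2"))
  e2 <- train_qsar_ensemble(fx$records, "P00001", fx$lib, seed = 3,
                            variants = c("path1024", "morgan_r2"))
  expect_identical(vapply(e1$models, `[[`, 0, "weight"),
                   vapply(e2$models, `[[`, 0, "weight"))
  # every trained model used an exactly balanced set
  lab <- lapply(c(4, 5, 6), function(co)
    label_actives(fx$records, "P00001", co))
  for (m in e1$models) {
    if (m$skipped) next
    npos <- sum(lab[[match(m$spec$cutoff, c(4, 5, 6))]] == "active")
    expect_equal(m$n_train, 2L * npos)
  }
  expect_equal(length(e1$models), 6L)  # 2 variants x 3 cutoffs
})

test_that("the separable fixture is learned by every model and the ensemble", {
  fx <- qsar_fixture(1L)
  ens <- train_qsar_ensemble(fx$records, "P00001", fx$lib, seed = 1)
  expect_length(ens$models, 15L)
  aurocs <- vapply(ens$models, function(m) if (m$skipped) NA_real_ else m$cv$auroc, 0)
  expect_true(all(aurocs >= 0.9, na.rm = TRUE))
  expect_gt(ens$n_training_molecules, 20L)
  pred <- predict_qsar(ens, fx$lib)
  expect_true(all(pred$prediction >= 0 & pred$prediction <= 1))
  expect_gte(auroc(pred$prediction, fx$lib$has_pharmacophore), 0.9)
})

test_that("weighted aggregation follows the stated convex formula", {
  # hand-built two-model ensemble producing p = 0.5 and p = 1.0
  mk_fit <- function(logit_prior, nbits = 8L) {
    list(log_p1 = rep(0, nbits), log_q1 = rep(0, nbits),
         log_p0 = rep(0, nbits), log_q0 = rep(0, nbits),
         logit_prior = logit_prior)
  }
  ens <- structure(list(
    target_id = "t", nbits = 8L, n_training_molecules = 42L,
    models = list(
      list(spec = list(fingerprint_variant = "path1024", cutoff = 5),
           weight = 0.2, skipped = FALSE, fit = mk_fit(0)),       # p = 0.5
      list(spec = list(fingerprint_variant = "path1024", cutoff = 6),
           weight = 0.6, skipped = FALSE, fit = mk_fit(1e6)))),   # p = 1.0
    class = "qsar_ensemble")
  p <- predict_qsar(ens, "c1ccccc1")
  expect_equal(p$prediction, (0.2 * 0.5 + 0.6 * 1.0) / 0.8)  # 0.875
  expect_equal(p$n_training_molecules, 42L)
  # endpoints
  for (m in seq_along(ens$models)) ens$models[[m]]$fit$logit_prior <- 1e6
  expect_equal(predict_qsar(ens, "c1ccccc1")$prediction, 1)
  for (m in seq_along(ens$models)) ens$models[[m]]$fit$logit_prior <- -1e6
  expect_equal(predict_qsar(ens, "c1ccccc1")$prediction, 0)
  # all-zero weights refuse to predict
  for (m in seq_along(ens$models)) ens$models[[m]]$weight <- 0
  expect_error(predict_qsar(ens, "c1ccccc1"), "no reliable model")
})

test_that("naive Bayes posteriors agree with the e1071 reference", {
  skip_if_not_installed("e1071")
  set.seed(13)
  X <- matrix(rbinom(40 * 6, 1, 0.5), nrow = 40)
  y <- rep(c(TRUE, FALSE), each = 20)
  X[y, 1] <- rbinom(20, 1, 0.9)  # informative bit
  fit <- chemoprofiler:::nb_fit(X, y)
  mine <- chemoprofiler:::nb_predict(fit, X)
  df <- as.data.frame(lapply(as.data.frame(X), factor, levels = c(0, 1)))
  ref <- e1071::naiveBayes(df, factor(y, levels = c(FALSE, TRUE)), laplace = 1)
  theirs <- stats::predict(ref, df, type = "raw")[, "TRUE"]
  expect_equal(mine, unname(theirs), tolerance = 1e-6)
})

test_that("rank-based AUROC agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(17)
  scores <- runif(60)
  labels <- rbinom(60, 1, plogis(3 * (scores - 0.5)))
  mine <- auroc(scores, labels)
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores)))
  expect_equal(mine, ref)
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
})

test_that("mcc matches its confusion-matrix definition on a worked case", {
  pred <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  act <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  # tp 3, tn 1, fp 1, fn 1
  expect_equal(mcc(pred, act), (3 * 1 - 1 * 1) / sqrt(4 * 4 * 2 * 2))
  expect_equal(mcc(c(TRUE, TRUE), c(TRUE, FALSE)), 0)  # degenerate marginal
})

test_that("ensembles survive a JSON round trip with identical predictions", {
  fx <- qsar_fixture(1L)
  ens <- train_qsar_ensemble(fx$records, "P00001", fx$lib, seed = 2,
                             variants = "path1024")
  p <- withr::local_tempfile(fileext = ".json")
  write_qsar_ensemble(ens, p)
  back <- read_qsar_ensemble(p)
  q <- fx$lib[1:10, ]
  expect_equal(predict_qsar(back, q)$prediction,
               predict_qsar(ens, q)$prediction, tolerance = 1e-12)
})
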
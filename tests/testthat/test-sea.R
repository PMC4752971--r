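test_that("raw score sums above-threshold cross-pair similarities", {
  lib <- compound_library(rep("Cc1ccccc1", 6),
                          sprintf("d%d", 1:6))$compounds
  fp <- fingerprint_matrix(lib)
  # n identical molecules vs themselves: every pair contributes 1
  expect_equal(sea_raw_score(fp[1:3, ], fp[4:6, ], 0.5), 9)
  # all pairs below threshold contribute nothing
  a <- matrix(c(1L, 1L, 0L, 0L), nrow = 1)
  b <- matrix(c(0L, 1L, 1L, 1L), nrow = 1)   # tc = 0.25
  expect_equal(sea_raw_score(a, b, 0.57), 0)
  expect_equal(sea_raw_score(a, b, 0.2), 0.25)
})

test_that("raw score equals an independent double-loop oracle", {
  A <- random_bit_vectors(5, 512L, seed = 11)
  B <- random_bit_vectors(7, 512L, seed = 12, density = 0.12)
  for (thr in c(0, 0.1, 0.57)) {
    acc <- 0
    for (i in 1:5) for (j in 1:7) {
      tc <- tanimoto_oracle(A[i, ], B[j, ])
      if (tc >= thr) acc <- acc + tc
    }
    expect_equal(sea_raw_score(A, B, thr), acc)
  }
  # lowering the threshold never decreases the score
  thr <- seq(1, 0, by = -0.1)
  sc <- vapply(thr, function(t) sea_raw_score(A, B, t), 0)
  expect_true(all(diff(sc) >= 0))
})

test_that("a degenerate identical-molecule library forces the background fit", {
  lib <- compound_library(rep("Cc1ccccc1", 60), sprintf("d%d", 1:60))$compounds
  m <- fit_sea_background(lib, set_sizes = c(2L, 4L), n_samples = 10L, seed = 1)
  # every raw score is exactly n1*n2, so the mean fit is the identity line
  expect_equal(m$slope_mean, 1, tolerance = 1e-9)
  expect_equal(m$intercept_mean, 0, tolerance = 1e-9)
  expect_equal(m$slope_sd, 0, tolerance = 1e-12)
  expect_equal(m$intercept_sd, 0, tolerance = 1e-12)
})

test_that("the background fit is deterministic under a fixed seed", {
  fx <- small_fixture()
  fp <- fingerprint_matrix(fx$lib)
  m1 <- chemoprofiler:::fit_sea_background_fps(fp, c(3L, 6L), 15L, 0.57, 7)
  m2 <- chemoprofiler:::fit_sea_background_fps(fp, c(3L, 6L), 15L, 0.57, 7)
  expect_identical(m1, m2)
  m3 <- chemoprofiler:::fit_sea_background_fps(fp, c(3L, 6L), 15L, 0.57, 8)
  expect_false(identical(m1$slope_mean, m3$slope_mean))
  expect_error(fit_sea_background(fx$lib, set_sizes = 50L, n_samples = 5L),
               "library")
})

test_that("the Gumbel tail matches its closed form", {
  g <- 0.57721566490153286
  expect_equal(gumbel_tail_p(0), 1 - exp(-exp(-g)))
  expect_equal(gumbel_tail_p(0), 0.4296, tolerance = 1e-4)
  # monotone decreasing in z
  z <- seq(-3, 8, by = 0.5)
  expect_true(all(diff(gumbel_tail_p(z)) < 0))
  expect_true(all(gumbel_tail_p(z) >= 0 & gumbel_tail_p(z) <= 1))
})

test_that("prediction gates targets at <= 10 ligands and ranks the true target first", {
  fx <- small_fixture()
  fp_lib <- fx$lib
  # planted case: query identical to one 15-ligand set, rest dissimilar
  pharm <- fp_lib[fp_lib$has_pharmacophore, ][1:12, ]
  plain <- fp_lib[!fp_lib$has_pharmacophore, ]
  sets <- list(match_t = pharm[1:12, ],
               other1 = plain[1:15, ], other2 = plain[16:30, ],
               small = plain[31:35, ])
  bg <- fit_sea_background(fx$lib, set_sizes = c(4L, 8L), n_samples = 15L,
                           seed = 3)
  pred <- sea_predict(pharm[1:8, ], sets, bg)
  expect_equal(attr(pred, "skipped"), "small")
  expect_equal(pred$target_id[1], "match_t")
  expect_true(all(pred$n_target_ligands > 10))
  # e-value ascending, consistent with the stated formula
  expect_true(!is.unsorted(pred$e_value))
  expect_equal(pred$e_value, gumbel_tail_p(pred$z_score) * nrow(pred))

  tiny <- list(a = plain[1:5, ], b = plain[6:10, ])
  empty <- sea_predict(pharm[1:3, ], tiny, bg)
  expect_equal(nrow(empty), 0L)
  expect_setequal(attr(empty, "skipped"), c("a", "b"))
})

test_that("fitted background standardizes fresh random set pairs", {
  fx <- small_fixture()
  fp <- fingerprint_matrix(fx$lib)
  bg <- chemoprofiler:::fit_sea_background_fps(fp, c(4L, 8L), 40L, 0.57, 5)
  set.seed(21)
  zs <- replicate(400, {
    n1 <- sample(c(4L, 8L), 1); n2 <- sample(c(4L, 8L), 1)
    pick <- sample.int(nrow(fp), n1 + n2)
    raw <- sea_raw_score(fp[pick[seq_len(n1)], , drop = FALSE],
                         fp[pick[n1 + seq_len(n2)], , drop = FALSE], 0.57)
    chemoprofiler:::sea_zscore(bg, raw, n1, n2)
  })
  expect_lt(abs(mean(zs)), 0.15)
  expect_gt(sd(zs), 0.75)
  expect_lt(sd(zs), 1.25)
})
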
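# Similarity Ensemble Approach (SEA) target prediction.
#
# A query compound set is scored against each target's ligand set by the raw
# score: the sum of all cross-pair Tanimoto similarities at or above an
# inclusion threshold (default 0.57, the classic optimum for Daylight-style
# fingerprints). Raw scores of random set pairs grow with the set-size
# product n1*n2; a background model fits the mean and standard deviation of
# random raw scores linearly against n1*n2. An observed score is
# standardized with the fitted moments and its significance taken from the
# tail of a zero-mean unit-variance extreme-value (Gumbel) distribution:
#   P(Z > z) = 1 - exp(-exp(-(z*pi/sqrt(6) + gamma)))
# with gamma the Euler-Mascheroni constant. E-value = p * number of targets
# scored. Only targets with more than 10 ligands are scored.

EULER_GAMMA <- 0.57721566490153286

#' Gumbel tail probability for a standardized score
#'
#' Upper-tail probability of a zero-mean, unit-variance extreme-value
#' distribution evaluated at `z`.
#'
#' @param z numeric vector of standardized scores.
#' @return numeric vector of tail probabilities in \[0, 1\].
#' @export
gumbel_tail_p <- function(z) {
  x <- z * pi / sqrt(6) + EULER_GAMMA
  -expm1(-exp(-x))
}

#' SEA raw score between two fingerprint sets
#'
#' Sum over all cross pairs of Tanimoto similarities at or above
#' `tc_threshold`; below-threshold pairs contribute zero.
#'
#' @param fpA,fpB 0/1 fingerprint matrices (rows = compounds) from
#'   [fingerprint_matrix()], same variant and width.
#' @param tc_threshold pair inclusion threshold.
#' @return non-negative raw score.
#' @export
sea_raw_score <- function(fpA, fpB, tc_threshold = 0.57) {
  va <- attr(fpA, "variant"); vb <- attr(fpB, "variant")
  if (!is.null(va) && !is.null(vb) && va != vb)
    stop("fingerprint variant mismatch: ", va, " vs ", vb)
  if (ncol(fpA) != ncol(fpB)) stop("fingerprint length mismatch")
  s <- tanimoto_matrix(fpA, fpB)
  sum(s[s >= tc_threshold])
}

#' Fit the SEA random background model
#'
#' Draws seeded random disjoint set pairs from a compound library for every
#' combination of the given set sizes, computes their raw scores, and fits
#' the mean and standard deviation of the raw score linearly against the
#' set-size product n1*n2.
#'
#' @param library compound library data.frame, at least 10x the largest set
#'   size.
#' @param set_sizes integer vector of set sizes to sample (pairs are all
#'   size combinations with repetition).
#' @param n_samples random pairs per size combination (>= 100 pairs overall
#'   recommended).
#' @param tc_threshold pair inclusion threshold.
#' @param seed integer seed; the fit is deterministic given the seed.
#' @param variant,nbits fingerprint settings.
#' @return object of class `sea_background`: fitted coefficients, threshold,
#'   settings and provenance counts.
#' @export
fit_sea_background <- function(library, set_sizes = c(4L, 8L, 16L),
                               n_samples = 50L, tc_threshold = 0.57,
                               seed = 1L, variant = "path1024",
                               nbits = 1024L) {
  stopifnot(nrow(library) >= 10L * max(set_sizes))
  fps <- fingerprint_matrix(library, variant, nbits)
  model <- fit_sea_background_fps(fps, set_sizes, n_samples, tc_threshold, seed)
  model$variant <- variant
  model$nbits <- as.integer(nbits)
  model
}

# Core fit on a precomputed fingerprint matrix.
fit_sea_background_fps <- function(fps, set_sizes, n_samples, tc_threshold,
                                   seed) {
  if (nrow(fps) < 10L * max(set_sizes))
    stop("library too small: need >= ", 10L * max(set_sizes),
         " compounds for set size ", max(set_sizes))
  combos <- expand.grid(n1 = set_sizes, n2 = set_sizes)
  combos <- combos[combos$n1 <= combos$n2, , drop = FALSE]
  prods <- numeric(0); means <- numeric(0); sds <- numeric(0)
  with_seed(seed, {
    for (i in seq_len(nrow(combos))) {
      n1 <- combos$n1[i]; n2 <- combos$n2[i]
      scores <- vapply(seq_len(n_samples), function(j) {
        pick <- sample.int(nrow(fps), n1 + n2)
        sea_raw_score(fps[pick[seq_len(n1)], , drop = FALSE],
                      fps[pick[n1 + seq_len(n2)], , drop = FALSE],
                      tc_threshold)
      }, 0)
      prods <- c(prods, n1 * n2)
      means <- c(means, mean(scores))
      sds <- c(sds, stats::sd(scores))
    }
  })
  fit_m <- stats::lm.fit(cbind(1, prods), means)$coefficients
  fit_s <- stats::lm.fit(cbind(1, prods), sds)$coefficients
  structure(list(tc_threshold = tc_threshold,
                 intercept_mean = unname(fit_m[1]), slope_mean = unname(fit_m[2]),
                 intercept_sd = unname(fit_s[1]), slope_sd = unname(fit_s[2]),
                 set_sizes = set_sizes,
                 n_samples = as.integer(n_samples) * nrow(combos),
                 seed = as.integer(seed)),
            class = "sea_background")
}

#' @export
print.sea_background <- function(x, ...) {
  cat(sprintf(paste0("sea_background: mean = %.4g + %.4g * n1n2, ",
                     "sd = %.4g + %.4g * n1n2 (tc >= %.2f, %d samples)\n"),
              x$intercept_mean, x$slope_mean, x$intercept_sd, x$slope_sd,
              x$tc_threshold, x$n_samples))
  invisible(x)
}

# Fitted background moments at a set-size product.
sea_expected <- function(model, prod) {
  list(mean = model$intercept_mean + model$slope_mean * prod,
       sd = pmax(model$intercept_sd + model$slope_sd * prod, 1e-9))
}

# Standardize a raw score under the background model.
sea_zscore <- function(model, raw, n1, n2) {
  ex <- sea_expected(model, n1 * n2)
  (raw - ex$mean) / ex$sd
}

#' SEA target prediction for a query compound set
#'
#' Scores the query set against every target ligand set with more than 10
#' ligands, standardizes against the background model and reports Gumbel
#' tail E-values (p-value times the number of targets scored), sorted
#' ascending by E-value. Targets at or below 10 ligands are skipped and
#' listed in the `skipped` attribute.
#'
#' @param query compound library data.frame (the query set).
#' @param target_sets named list: target_id -> compound library data.frame
#'   of that target's ligands.
#' @param model a fitted `sea_background`.
#' @return data.frame with target_id, raw_score, z_score, e_value,
#'   n_target_ligands; attribute `skipped` lists excluded targets.
#' @export
sea_predict <- function(query, target_sets, model) {
  stopifnot(inherits(model, "sea_background"))
  variant <- if (is.null(model$variant)) "path1024" else model$variant
  nbits <- if (is.null(model$nbits)) 1024L else model$nbits
  qfp <- fingerprint_matrix(query, variant, nbits)
  sizes <- vapply(target_sets, nrow, 1L)
  scored <- names(target_sets)[sizes > 10L]
  skipped <- names(target_sets)[sizes <= 10L]
  if (length(scored) == 0L) {
    res <- data.frame(target_id = character(0), raw_score = numeric(0),
                      z_score = numeric(0), e_value = numeric(0),
                      n_target_ligands = integer(0))
    attr(res, "skipped") <- skipped
    return(res)
  }
  raw <- numeric(length(scored)); z <- numeric(length(scored))
  nl <- integer(length(scored))
  for (i in seq_along(scored)) {
    tfp <- fingerprint_matrix(target_sets[[scored[i]]], variant, nbits)
    raw[i] <- sea_raw_score(qfp, tfp, model$tc_threshold)
    nl[i] <- nrow(tfp)
    z[i] <- sea_zscore(model, raw[i], nrow(qfp), nl[i])
  }
  p <- gumbel_tail_p(z)
  res <- data.frame(target_id = scored, raw_score = raw, z_score = z,
                    e_value = p * length(scored), n_target_ligands = nl,
                    stringsAsFactors = FALSE)
  res <- res[order(res$e_value, res$target_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
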
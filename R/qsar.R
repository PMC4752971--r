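# Per-target QSAR ensembles.
#
# For each target with more than 20 measured compounds, fifteen binary
# classifiers are trained: 5 fingerprint variants x 3 activity cutoffs
# (oriented -log10 molar values 4, 5 and 6 separate actives from
# inactives). Each training set is balanced by topping up (or subsampling)
# measured inactives with seeded random library compounds that have no
# measurement on the target. Each classifier is a Bernoulli naive Bayes
# over fingerprint bits with Laplace (add-one) smoothing, assessed by
# stratified 5-fold cross-validation; its ensemble weight is the
# cross-validated MCC clipped at zero. The ensemble prediction is the
# weight-normalized convex combination of the per-model active-class
# posteriors, a value in [0, 1].

QSAR_CUTOFFS <- c(4, 5, 6)

#' Label compounds active/inactive for a target at a cutoff
#'
#' A compound is active iff its strongest (maximum) oriented value on the
#' target is at or above the cutoff; compounds measured only below the
#' cutoff are inactive.
#'
#' @param records activity record data.frame with `oriented_value`.
#' @param target_id target to label for.
#' @param cutoff oriented-scale activity threshold (e.g. 6 = 1 uM).
#' @return named character vector (`"active"`/`"inactive"`), names =
#'   compound ids measured on the target; empty if the target is absent.
#' @export
label_actives <- function(records, target_id, cutoff) {
  rec <- records[records$target_id == target_id, , drop = FALSE]
  if (nrow(rec) == 0L) return(stats::setNames(character(0), character(0)))
  best <- tapply(rec$oriented_value, rec$compound_id, max)
  stats::setNames(as.character(ifelse(best >= cutoff, "active", "inactive")),
                  names(best))
}

#' Balance a QSAR training set
#'
#' Measured negatives are topped up with seeded uniform random pool
#' compounds - or subsampled - until there are exactly as many negatives as
#' positives.
#'
#' @param positives character vector of active compound ids.
#' @param measured_negatives character vector of measured-inactive ids.
#' @param pool character vector of candidate random-negative ids (must
#'   exclude the positives and any compound measured on the target).
#' @param seed integer seed.
#' @return character vector of negative compound ids, length equal to
#'   `length(positives)`.
#' @export
balance_negatives <- function(positives, measured_negatives, pool, seed) {
  n_pos <- length(positives)
  if (any(positives %in% pool))
    stop("pool must exclude positive compounds")
  if (length(measured_negatives) == n_pos) return(measured_negatives)
  if (length(measured_negatives) > n_pos) {
    return(with_seed(seed, measured_negatives[sample.int(length(measured_negatives), n_pos)]))
  }
  short <- n_pos - length(measured_negatives)
  avail <- setdiff(pool, measured_negatives)
  if (length(avail) < short)
    stop("cannot balance: need ", short, " random negatives, pool has ",
         length(avail))
  extra <- with_seed(seed, avail[sample.int(length(avail), short)])
  c(measured_negatives, extra)
}

# --- Bernoulli naive Bayes over fingerprint bits -------------------------

# Fit: X is a 0/1 matrix, y logical (TRUE = active). Laplace add-one.
nb_fit <- function(X, y, laplace = 1) {
  n1 <- sum(y); n0 <- sum(!y)
  p1 <- (colSums(X[y, , drop = FALSE]) + laplace) / (n1 + 2 * laplace)
  p0 <- (colSums(X[!y, , drop = FALSE]) + laplace) / (n0 + 2 * laplace)
  prior1 <- (n1 + laplace) / (n1 + n0 + 2 * laplace)
  list(log_p1 = log(p1), log_q1 = log1p(-p1),
       log_p0 = log(p0), log_q0 = log1p(-p0),
       logit_prior = log(prior1) - log1p(-prior1))
}

# Posterior probability of the active class for each row of X.
nb_predict <- function(fit, X) {
  s1 <- X %*% (fit$log_p1 - fit$log_q1) + sum(fit$log_q1)
  s0 <- X %*% (fit$log_p0 - fit$log_q0) + sum(fit$log_q0)
  stats::plogis(as.numeric(s1 - s0) + fit$logit_prior)
}

# Stratified k-fold assignment (seeded shuffle within each class).
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Cross-validated performance of one NB model on a balanced set.
nb_cross_validate <- function(X, y, k, seed) {
  fold <- stratified_folds(y, k, seed)
  prob <- numeric(length(y))
  for (f in seq_len(k)) {
    test <- fold == f
    if (!any(test) || all(test)) next
    fit <- nb_fit(X[!test, , drop = FALSE], y[!test])
    prob[test] <- nb_predict(fit, X[test, , drop = FALSE])
  }
  list(auroc = auroc(prob, y), mcc = mcc(prob >= 0.5, y), folds = k,
       cv_prob = prob)
}

#' Train a per-target QSAR ensemble
#'
#' Builds the 15 models (5 fingerprint variants x cutoffs 4/5/6) for one
#' target. Refuses targets with 20 or fewer distinct measured compounds.
#' Cutoffs with no actives (or no inactives after labeling) produce a
#' zero-weight skipped spec, recorded in the result.
#'
#' @param records activity record data.frame with `oriented_value`.
#' @param target_id target to model.
#' @param compounds compound library data.frame covering every measured
#'   compound; unmeasured library compounds form the random-negative pool.
#' @param seed integer seed controlling balancing and fold assignment.
#' @param variants fingerprint variants to use.
#' @param cutoffs oriented-scale cutoffs.
#' @param nbits fingerprint length.
#' @param folds number of CV folds.
#' @return object of class `qsar_ensemble`.
#' @export
train_qsar_ensemble <- function(records, target_id, compounds, seed = 1L,
                                variants = fingerprint_variants(),
                                cutoffs = QSAR_CUTOFFS, nbits = 1024L,
                                folds = 5L) {
  measured <- unique(records$compound_id[records$target_id == target_id])
  if (length(measured) <= 20L)
    stop("insufficient data: target ", target_id, " has ", length(measured),
         " measured compounds (need > 20)")
  missing <- setdiff(measured, compounds$compound_id)
  if (length(missing) > 0L)
    stop("no structure for measured compound(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  pool <- setdiff(compounds$compound_id, measured)  # leakage guard
  fp <- lapply(stats::setNames(variants, variants), function(v) {
    fingerprint_matrix(compounds, v, nbits)
  })
  models <- list()
  spec_i <- 0L
  for (cutoff in cutoffs) {
    lab <- label_actives(records, target_id, cutoff)
    positives <- names(lab)[lab == "active"]
    meas_neg <- names(lab)[lab == "inactive"]
    for (v in variants) {
      spec_i <- spec_i + 1L
      spec <- list(fingerprint_variant = v, cutoff = cutoff)
      if (length(positives) == 0L || length(positives) == length(lab)) {
        models[[spec_i]] <- list(spec = spec, weight = 0, skipped = TRUE,
                                 reason = if (length(positives) == 0L)
                                   "no actives at cutoff" else
                                     "no inactives at cutoff",
                                 cv = NULL, fit = NULL)
        next
      }
      negatives <- balance_negatives(positives, meas_neg, pool,
                                     seed + spec_i)
      ids <- c(positives, negatives)
      y <- c(rep(TRUE, length(positives)), rep(FALSE, length(negatives)))
      X <- fp[[v]][ids, , drop = FALSE]
      cv <- nb_cross_validate(X, y, folds, seed + spec_i)
      fit <- nb_fit(X, y)
      models[[spec_i]] <- list(spec = spec, weight = max(cv$mcc, 0),
                               skipped = FALSE, reason = NA_character_,
                               cv = list(auroc = cv$auroc, mcc = cv$mcc,
                                         folds = folds),
                               fit = fit, n_train = length(ids))
    }
  }
  structure(list(target_id = target_id, models = models,
                 n_training_molecules = length(measured),
                 variants = variants, cutoffs = cutoffs,
                 nbits = as.integer(nbits), seed = as.integer(seed)),
            class = "qsar_ensemble")
}

#' @export
print.qsar_ensemble <- function(x, ...) {
  w <- vapply(x$models, `[[`, 0, "weight")
  cat(sprintf("qsar_ensemble for %s: %d models (%d active), n_train = %d\n",
              x$target_id, length(x$models), sum(w > 0),
              x$n_training_molecules))
  invisible(x)
}

#' Ensemble QSAR prediction for compounds
#'
#' Weight-normalized convex combination of the per-model active-class
#' posteriors: \eqn{\sum_i w_i p_i / \sum_i w_i}.
#'
#' @param ensemble a trained `qsar_ensemble`.
#' @param compounds compound library data.frame (or character vector of
#'   SMILES) to predict.
#' @return data.frame with compound_id, prediction (in \[0, 1\]) and
#'   n_training_molecules.
#' @export
predict_qsar <- function(ensemble, compounds) {
  stopifnot(inherits(ensemble, "qsar_ensemble"))
  if (is.character(compounds))
    compounds <- data.frame(compound_id = compounds, smiles = compounds,
                            stringsAsFactors = FALSE)
  w <- vapply(ensemble$models, `[[`, 0, "weight")
  if (all(w == 0))
    stop("no reliable model: all ensemble weights are zero for target ",
         ensemble$target_id)
  used_variants <- unique(vapply(ensemble$models[w > 0],
                                 function(m) m$spec$fingerprint_variant, ""))
  fp <- lapply(stats::setNames(used_variants, used_variants), function(v) {
    fingerprint_matrix(compounds, v, ensemble$nbits)
  })
  num <- numeric(nrow(compounds))
  for (m in ensemble$models) {
    if (m$weight <= 0) next
    p <- nb_predict(m$fit, fp[[m$spec$fingerprint_variant]])
    num <- num + m$weight * p
  }
  data.frame(compound_id = compounds$compound_id,
             prediction = num / sum(w),
             n_training_molecules = ensemble$n_training_molecules,
             stringsAsFactors = FALSE)
}

#' Serialize a QSAR ensemble to JSON (and back)
#'
#' Models are stored as plain JSON (specs, weights, CV performance and the
#' naive Bayes log-parameters) - no binary blobs.
#'
#' @param ensemble a `qsar_ensemble`.
#' @param path JSON file path.
#' @return `path` invisibly, or the restored ensemble.
#' @export
write_qsar_ensemble <- function(ensemble, path) {
  x <- unclass(ensemble)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_qsar_ensemble
#' @export
read_qsar_ensemble <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$models <- lapply(x$models, function(m) {
    if (!is.null(m$fit)) m$fit <- lapply(m$fit, unlist)
    m$weight <- as.numeric(m$weight)
    m
  })
  x$nbits <- as.integer(x$nbits)
  class(x) <- "qsar_ensemble"
  x
}
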
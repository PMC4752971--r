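# Bioactivity standardization: orient heterogeneous data types onto a common
# -log10 molar scale and z-score them per (target, data type) group so that
# one color scale can span the whole interaction matrix.

#' Orient an activity value onto the -log10 molar scale
#'
#' Concentration types (IC50, EC50, Potency, AC50, Kd, Ki; values in nM) are
#' mapped to \eqn{-\log_{10}}(molar); p-scale types pass through unchanged;
#' LogKi (log molar) is negated. On the oriented scale larger always means a
#' stronger interaction.
#'
#' @param data_type character vector of data types.
#' @param value numeric vector (nM for concentration types, dimensionless
#'   otherwise).
#' @param extra_p_types additional p-scale types accepted unchanged.
#' @return numeric vector of oriented values.
#' @examples
#' orient_value("IC50", 1000)  # 1 uM -> 6
#' orient_value("pKi", 8.2)    # unchanged
#' @export
orient_value <- function(data_type, value, extra_p_types = character(0)) {
  data_type <- as.character(data_type)
  n <- max(length(data_type), length(value))
  data_type <- rep_len(data_type, n)
  value <- rep_len(as.numeric(value), n)
  out <- rep(NA_real_, n)
  is_raw <- data_type %in% ACTIVITY_RAW_TYPES
  is_p <- data_type %in% c(ACTIVITY_P_TYPES, extra_p_types)
  is_log <- data_type %in% ACTIVITY_LOG_TYPES
  if (any(is_raw & (!is.finite(value) | value <= 0)))
    stop("non-positive concentration value cannot be log transformed")
  bad <- !(is_raw | is_p | is_log)
  if (any(bad)) stop("unknown data type: ", paste(unique(data_type[bad]), collapse = ", "))
  out[is_raw] <- -log10(value[is_raw] * 1e-9)
  out[is_p] <- value[is_p]
  out[is_log] <- -value[is_log]
  out
}

#' Compute per-target, per-data-type activity z-scores
#'
#' Within each (target_id, data_type) group the oriented values are
#' standardized: \eqn{z = (x - \bar x) / s} with the sample (n-1) standard
#' deviation. Degenerate groups (a single record, or zero spread) get
#' \eqn{z = 0} and are flagged in the group statistics, so every stored
#' interaction still renders on the heatmap. Larger z means a stronger
#' interaction.
#'
#' @param records activity record data.frame with `oriented_value` populated
#'   (as returned by [read_activity_table()]).
#' @return list with `records` (input with `z_score` filled) and `stats`
#'   (data.frame: target_id, data_type, mean, sd, n, degenerate).
#' @export
compute_zscores <- function(records) {
  if (nrow(records) == 0L) {
    return(list(records = records,
                stats = data.frame(target_id = character(0),
                                   data_type = character(0), mean = numeric(0),
                                   sd = numeric(0), n = integer(0),
                                   degenerate = logical(0))))
  }
  stopifnot(all(is.finite(records$oriented_value)))
  key <- paste(records$target_id, records$data_type, sep = "\r")
  grp <- factor(key, levels = unique(key))
  mu <- tapply(records$oriented_value, grp, mean)
  sdv <- tapply(records$oriented_value, grp, stats::sd)  # NA for n = 1
  n <- tapply(records$oriented_value, grp, length)
  degenerate <- is.na(sdv) | sdv == 0
  gi <- as.integer(grp)
  z <- (records$oriented_value - mu[gi]) / sdv[gi]
  z[degenerate[gi]] <- 0
  records$z_score <- as.numeric(z)
  first <- !duplicated(gi)
  stats <- data.frame(target_id = records$target_id[first],
                      data_type = records$data_type[first],
                      mean = as.numeric(mu), sd = as.numeric(sdv),
                      n = as.integer(n), degenerate = as.logical(degenerate),
                      stringsAsFactors = FALSE)
  stats$sd[is.na(stats$sd)] <- 0
  rownames(stats) <- NULL
  list(records = records, stats = stats)
}
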
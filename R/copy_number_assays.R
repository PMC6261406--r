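# Target-specific copy-number quantification: delta-delta-Ct relative
# quantification from qPCR triplicates, and Poisson-corrected droplet
# digital PCR with single-well 95% confidence intervals.

# Half-up integer call with a no-call band: estimates within `band` of a
# half-integer are ambiguous and yield NA.
call_integer_cn <- function(est, band = 0.15) {
  frac <- est - floor(est)
  near_half <- abs(frac - 0.5) < band
  ifelse(near_half, NA_integer_, as.integer(round_half_up(est)))
}

#' Triplicate Ct quality control
#'
#' With at least two finite Ct values: if the replicate range is within
#' `max_range` cycles the mean of all finite replicates is used; otherwise
#' the replicate farthest from the median is dropped and the remaining two
#' averaged. Fewer than two finite values is a sample failure.
#'
#' @param cts numeric vector of (typically three) Ct values; `NA` =
#'   non-amplification.
#' @param max_range maximum tolerated replicate range (cycles).
#' @return list: `mean`, `sd` (of used replicates), `n_used`, `outlier`
#'   (dropped value or `NA`), `failed`.
#' @export
replicate_qc <- function(cts, max_range = 0.5) {
  finite <- cts[is.finite(cts)]
  if (length(finite) < 2) {
    return(list(mean = NA_real_, sd = NA_real_, n_used = length(finite),
                outlier = NA_real_, failed = TRUE))
  }
  if (diff(range(finite)) <= max_range) {
    return(list(mean = mean(finite), sd = stats::sd(finite),
                n_used = length(finite), outlier = NA_real_,
                failed = FALSE))
  }
  drop_i <- which.max(abs(finite - stats::median(finite)))
  used <- finite[-drop_i]
  list(mean = mean(used), sd = stats::sd(used), n_used = length(used),
       outlier = finite[drop_i], failed = FALSE)
}

#' Copy number by delta-delta-Ct relative quantification
#'
#' `dCt = mean(Ct_target) - mean(Ct_reference)`; `ddCt = dCt -
#' calibrator_dct` (the calibrator dCt comes from a known-diploid sample);
#' `CN = 2 * 2^(-ddCt)` assuming perfect amplification efficiency. The
#' replicate standard errors are propagated to a 95% CI on the estimate,
#' and the integer call uses half-up rounding with a no-call band around
#' half-integers. A non-amplified target with an amplified reference is
#' copy number 0.
#'
#' @param target_cts,reference_cts numeric Ct triplicates for the target
#'   and reference genes of one sample.
#' @param calibrator_dct calibrator delta-Ct (cycles).
#' @param sample_id,locus_id identifiers carried into the result.
#' @param max_range triplicate QC range threshold (cycles).
#' @param nocall_band half-integer ambiguity band on the CN estimate.
#' @return one-row data.frame of class `quant_result`: `cn_estimate,
#'   ci_low, ci_high, cn_integer, method, qc_flag`.
#' @export
ddct_copy_number <- function(target_cts, reference_cts, calibrator_dct = 0,
                             sample_id = "sample", locus_id = "locus",
                             max_range = 0.5, nocall_band = 0.15) {
  qt <- replicate_qc(target_cts, max_range)
  qr <- replicate_qc(reference_cts, max_range)
  flag <- c(if (!is.na(qt$outlier)) "target_outlier_dropped",
            if (!is.na(qr$outlier)) "reference_outlier_dropped")
  if (qr$failed) {
    stop("reference gene failed to amplify for sample ", sample_id,
         call. = FALSE)
  }
  if (all(!is.finite(target_cts))) {
    # amplified reference, non-amplified target: homozygous deletion
    out <- data.frame(sample_id = sample_id, locus_id = locus_id,
                      cn_estimate = 0, ci_low = 0, ci_high = 0,
                      cn_integer = 0L, method = "qpcr_ddct",
                      qc_flag = "target_not_amplified",
                      stringsAsFactors = FALSE)
    class(out) <- unique(c("quant_result", class(out)))
    return(out)
  }
  if (qt$failed) stop("fewer than 2 usable target replicates for sample ",
                      sample_id, call. = FALSE)
  dct <- qt$mean - qr$mean
  ddct <- dct - calibrator_dct
  cn <- 2 * 2^(-ddct)
  se_ddct <- sqrt(qt$sd^2 / qt$n_used + qr$sd^2 / qr$n_used)
  ci_low <- 2 * 2^(-(ddct + 1.96 * se_ddct))
  ci_high <- 2 * 2^(-(ddct - 1.96 * se_ddct))
  out <- data.frame(sample_id = sample_id, locus_id = locus_id,
                    cn_estimate = cn, ci_low = ci_low, ci_high = ci_high,
                    cn_integer = call_integer_cn(cn, nocall_band),
                    method = "qpcr_ddct",
                    qc_flag = if (length(flag)) paste(flag, collapse = ";")
                    else "ok",
                    stringsAsFactors = FALSE)
  class(out) <- unique(c("quant_result", class(out)))
  out
}

#' Call copy numbers from a qPCR plate table
#'
#' Applies [ddct_copy_number()] to each sample of a plate in the exchange
#' layout (`sample_id, gene_role, ct1, ct2, ct3`), using a designated
#' known-diploid calibrator sample to anchor the delta-delta-Ct.
#'
#' @param plate plate data.frame.
#' @param calibrator_id sample id of the known-diploid calibrator.
#' @param locus_id locus label for the calls.
#' @param ... passed to [ddct_copy_number()].
#' @return `quant_result` data.frame, one row per non-calibrator sample.
#' @export
qpcr_call_plate <- function(plate, calibrator_id, locus_id = "locus", ...) {
  get_cts <- function(id, role) {
    r <- plate[plate$sample_id == id & plate$gene_role == role, ]
    if (nrow(r) != 1) stop("expected one ", role, " row for sample ", id,
                           call. = FALSE)
    as.numeric(r[, c("ct1", "ct2", "ct3")])
  }
  if (!calibrator_id %in% plate$sample_id) {
    stop("calibrator sample ", calibrator_id, " absent from plate",
         call. = FALSE)
  }
  cal_t <- replicate_qc(get_cts(calibrator_id, "target"))
  cal_r <- replicate_qc(get_cts(calibrator_id, "reference"))
  if (cal_t$failed || cal_r$failed) {
    stop("calibrator sample failed triplicate QC", call. = FALSE)
  }
  calibrator_dct <- cal_t$mean - cal_r$mean
  ids <- setdiff(unique(plate$sample_id), calibrator_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    ddct_copy_number(get_cts(id, "target"), get_cts(id, "reference"),
                     calibrator_dct, sample_id = id, locus_id = locus_id,
                     ...)
  }))
  rownames(out) <- NULL
  out
}

#' Droplet digital PCR concentration with Poisson 95% CI
#'
#' The positive-droplet fraction is Poisson-corrected to a mean copies-
#' per-droplet `lambda = -ln(1 - p)` and divided by the droplet volume to
#' give copies/uL. The single-well 95% CI is the normal-approximation
#' binomial interval on `p` transformed through the same map; with zero
#' positives the concentration is 0 with a one-sided upper bound (rule of
#' three, `p_up = 3/total`). Saturated wells (all droplets positive) error.
#'
#' @param positives,total positive and total accepted droplet counts.
#' @param droplet_volume_nl droplet volume in nL (0.85 nL default,
#'   vendor-standard).
#' @return list: `lambda` (copies/droplet), `concentration` (copies/uL),
#'   `ci_low`, `ci_high`, `p_hat`.
#' @export
ddpcr_concentration <- function(positives, total,
                                droplet_volume_nl = 0.85) {
  stopifnot(length(positives) == 1, length(total) == 1, total > 0,
            positives >= 0, droplet_volume_nl > 0)
  if (positives >= total) {
    stop("saturated well: all droplets positive", call. = FALSE)
  }
  v_ul <- droplet_volume_nl * 1e-3
  p <- positives / total
  lam <- -log(1 - p)
  if (positives == 0) {
    p_up <- min(3 / total, 1 - 1e-12)
    return(list(lambda = 0, concentration = 0, ci_low = 0,
                ci_high = -log(1 - p_up) / v_ul, p_hat = 0))
  }
  se <- sqrt(p * (1 - p) / total)
  p_lo <- max(p - 1.96 * se, 0)
  p_hi <- min(p + 1.96 * se, 1 - 1e-12)
  list(lambda = lam, concentration = lam / v_ul,
       ci_low = -log(1 - p_lo) / v_ul, ci_high = -log(1 - p_hi) / v_ul,
       p_hat = p)
}

#' Copy number from a ddPCR target/reference well pair
#'
#' `CN = 2 * concentration_target / concentration_reference`. The 95% CI
#' treats the two wells as independent Poisson measurements and propagates
#' their variances on the log-ratio scale (delta method,
#' `var(lambda) = p / ((1 - p) N)`). The integer call uses half-up
#' rounding with a no-call band around half-integers.
#'
#' @param target,reference one-row data.frames (or lists) with `positives`,
#'   `total`, `droplet_volume_nl`.
#' @param sample_id,locus_id identifiers carried into the result.
#' @param nocall_band half-integer ambiguity band.
#' @return one-row `quant_result` data.frame.
#' @export
ddpcr_copy_number <- function(target, reference, sample_id = "sample",
                              locus_id = "locus", nocall_band = 0.15) {
  ct <- ddpcr_concentration(target$positives, target$total,
                            target$droplet_volume_nl)
  cr <- ddpcr_concentration(reference$positives, reference$total,
                            reference$droplet_volume_nl)
  if (cr$concentration <= 0) {
    stop("reference well has zero concentration", call. = FALSE)
  }
  cn <- 2 * ct$concentration / cr$concentration
  if (ct$concentration == 0) {
    out <- data.frame(sample_id = sample_id, locus_id = locus_id,
                      cn_estimate = 0, ci_low = 0,
                      ci_high = 2 * ct$ci_high / cr$concentration,
                      cn_integer = 0L, method = "ddpcr",
                      qc_flag = "target_zero_positives",
                      stringsAsFactors = FALSE)
    class(out) <- unique(c("quant_result", class(out)))
    return(out)
  }
  var_loglam <- function(cc, n) cc$p_hat / ((1 - cc$p_hat) * n) / cc$lambda^2
  se_lr <- sqrt(var_loglam(ct, target$total) +
                  var_loglam(cr, reference$total))
  out <- data.frame(sample_id = sample_id, locus_id = locus_id,
                    cn_estimate = cn, ci_low = cn * exp(-1.96 * se_lr),
                    ci_high = cn * exp(1.96 * se_lr),
                    cn_integer = call_integer_cn(cn, nocall_band),
                    method = "ddpcr", qc_flag = "ok",
                    stringsAsFactors = FALSE)
  class(out) <- unique(c("quant_result", class(out)))
  out
}

#' Call copy numbers from a ddPCR well table
#'
#' Applies [ddpcr_copy_number()] to each sample of a well table in the
#' exchange layout (`sample_id, gene_role, positives, total,
#' droplet_volume_nl`).
#'
#' @param wells well data.frame.
#' @param locus_id locus label for the calls.
#' @param ... passed to [ddpcr_copy_number()].
#' @return `quant_result` data.frame, one row per sample.
#' @export
ddpcr_call_wells <- function(wells, locus_id = "locus", ...) {
  ids <- unique(wells$sample_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    t_row <- wells[wells$sample_id == id & wells$gene_role == "target", ]
    r_row <- wells[wells$sample_id == id & wells$gene_role == "reference", ]
    if (nrow(t_row) != 1 || nrow(r_row) != 1) {
      stop("expected one target and one reference well for sample ", id,
           call. = FALSE)
    }
    ddpcr_copy_number(t_row, r_row, sample_id = id, locus_id = locus_id,
                      ...)
  }))
  rownames(out) <- NULL
  out
}

#' Diploid reference-sample run check
#'
#' A run of quantification results passes only if the designated
#' known-diploid reference sample was called as integer copy number 2 at
#' every locus it appears at; a missing reference sample invalidates the
#' run.
#'
#' @param run a `quant_result` data.frame for one run.
#' @param reference_sample_id the internal-control sample id.
#' @return list: `pass` (logical), `reason`.
#' @export
reference_sample_check <- function(run, reference_sample_id) {
  rows <- run[run$sample_id == reference_sample_id, , drop = FALSE]
  if (nrow(rows) == 0) {
    return(list(pass = FALSE, reason = "reference sample missing from run"))
  }
  if (any(is.na(rows$cn_integer)) || any(rows$cn_integer != 2L)) {
    return(list(pass = FALSE,
                reason = "reference sample not called diploid"))
  }
  list(pass = TRUE, reason = "reference sample diploid at all loci")
}
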
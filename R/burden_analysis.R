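# Per-sample / per-chromosome CNV burden summaries and case-control
# comparisons.

#' Summarize per-sample CNV burden
#'
#' One row per manifest sample (samples with zero calls included as
#' all-zero rows): total/loss/gain call counts, summed and mean sizes
#' (bp), plus per-chromosome count and size matrices.
#'
#' @param segments a `cnv_segments` data.frame (single caller).
#' @param samples a `sample_manifest`.
#' @return list of class `burden_summary`: `per_sample` data.frame,
#'   `chrom_counts` and `chrom_size` matrices (samples x chromosomes).
#' @export
summarize_burden <- function(segments, samples) {
  segments <- validate_segments(segments)
  orphan <- setdiff(segments$sample_id, samples$sample_id)
  if (length(orphan)) {
    stop("segments reference sample(s) absent from manifest: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  ids <- samples$sample_id
  size <- segments$end - segments$start + 1
  agg <- function(keep, val) {
    out <- tapply(val[keep], factor(segments$sample_id[keep], levels = ids),
                  sum)
    out[is.na(out)] <- 0
    as.numeric(out)
  }
  is_del <- segments$cnv_type == "loss"
  per_sample <- data.frame(
    sample_id = ids,
    n_total = agg(rep(TRUE, nrow(segments)), rep(1, nrow(segments))),
    n_del = agg(is_del, rep(1, nrow(segments))),
    n_dup = agg(!is_del, rep(1, nrow(segments))),
    size_total = agg(rep(TRUE, nrow(segments)), size),
    size_del = agg(is_del, size),
    size_dup = agg(!is_del, size),
    stringsAsFactors = FALSE
  )
  per_sample$mean_size_del <- ifelse(per_sample$n_del > 0,
                                     per_sample$size_del / per_sample$n_del, 0)
  per_sample$mean_size_dup <- ifelse(per_sample$n_dup > 0,
                                     per_sample$size_dup / per_sample$n_dup, 0)
  sf <- factor(segments$sample_id, levels = ids)
  cf <- factor(segments$chrom, levels = CHROMS)
  chrom_counts <- table(sf, cf)
  chrom_size <- tapply(size, list(sf, cf), sum)
  chrom_size[is.na(chrom_size)] <- 0
  out <- list(per_sample = per_sample,
              chrom_counts = unclass(chrom_counts),
              chrom_size = chrom_size)
  class(out) <- "burden_summary"
  out
}

# Wald summary for one glm coefficient.
wald_row <- function(fit, term) {
  co <- summary(fit)$coefficients
  if (!term %in% rownames(co)) {
    return(list(coef = NA_real_, or = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, p = NA_real_))
  }
  b <- co[term, "Estimate"]
  se <- co[term, "Std. Error"]
  list(coef = b, or = exp(b), ci_low = exp(b - 1.96 * se),
       ci_high = exp(b + 1.96 * se), p = co[term, "Pr(>|z|)"])
}

# Detect (quasi-)separation: fitted probabilities at the boundary or
# exploded standard errors.
glm_separated <- function(fit) {
  eps <- 1e-8
  any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) ||
    any(summary(fit)$coefficients[, "Std. Error"] > 100)
}

#' Compare a CNV burden measure between cases and controls
#'
#' Maximum-likelihood logistic regression of case status on the chosen
#' burden measure, adjusted for sex and one ancestry component (the three
#' admixture proportions sum to 1 and are collinear, so exactly one enters
#' each model). The odds ratio is per unit of the measure (per call, or
#' per bp).
#'
#' @param burdens a `burden_summary` from [summarize_burden()].
#' @param samples the `sample_manifest`.
#' @param measure one of `n_total`, `n_del`, `n_dup`, `size_total`,
#'   `size_del`, `size_dup`.
#' @param ancestry_component `"afr"`, `"eur"` or `"amr"`.
#' @return one-row data.frame of class `burden_test`: measure,
#'   coefficient, odds_ratio, ci_low, ci_high, p_value, covariates,
#'   separation flag.
#' @export
compare_burden <- function(burdens, samples,
                           measure = c("n_total", "n_del", "n_dup",
                                       "size_total", "size_del", "size_dup"),
                           ancestry_component = c("afr", "eur", "amr")) {
  measure <- match.arg(measure)
  ancestry_component <- match.arg(ancestry_component)
  stopifnot(inherits(burdens, "burden_summary"))
  df <- merge(burdens$per_sample, samples, by = "sample_id")
  if (min(table(df$group)) < 2) {
    stop("need >= 2 samples per group", call. = FALSE)
  }
  df$y <- as.integer(df$group == "case")
  df$x <- df[[measure]]
  df$anc <- df[[ancestry_component]]
  fit <- stats::glm(y ~ x + sex + anc, family = stats::binomial(), data = df)
  w <- wald_row(fit, "x")
  out <- data.frame(measure = measure, coefficient = w$coef,
                    odds_ratio = w$or, ci_low = w$ci_low,
                    ci_high = w$ci_high, p_value = w$p,
                    covariates = paste("sex", ancestry_component, sep = "+"),
                    separation = glm_separated(fit),
                    stringsAsFactors = FALSE)
  class(out) <- c("burden_test", class(out))
  out
}

#' Per-chromosome case-control t-tests of CNV burden
#'
#' Two-sample t-tests comparing per-sample call counts and summed sizes on
#' each chromosome between cases and controls. Welch's unequal-variance
#' test is the default; the pooled-variance Student test is available. Raw
#' p-values are reported (no multiplicity correction by default);
#' Benjamini-Hochberg adjusted values can be added.
#'
#' @param burdens a `burden_summary`.
#' @param samples the `sample_manifest`.
#' @param var_equal use the pooled-variance Student test.
#' @param p_adjust also report Benjamini-Hochberg adjusted p-values.
#' @return data.frame with one row per (chromosome, measure): t statistic,
#'   p, group means. Chromosomes with zero variance in both groups yield
#'   `NA` rows.
#' @export
per_chromosome_tests <- function(burdens, samples, var_equal = FALSE,
                                 p_adjust = FALSE) {
  stopifnot(inherits(burdens, "burden_summary"))
  grp <- samples$group[match(rownames(burdens$chrom_counts),
                             samples$sample_id)]
  if (length(unique(grp)) < 2) stop("both groups must be represented",
                                    call. = FALSE)
  if (min(table(grp)) < 2) stop("need >= 2 samples per group", call. = FALSE)
  rows <- list()
  for (m in c("calls", "size")) {
    mat <- if (m == "calls") burdens$chrom_counts else burdens$chrom_size
    for (ch in colnames(mat)) {
      a <- mat[grp == "case", ch]
      b <- mat[grp == "control", ch]
      if (stats::var(a) == 0 && stats::var(b) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ch, measure = m, t_statistic = NA_real_, p_value = NA_real_,
          mean_case = mean(a), mean_control = mean(b),
          stringsAsFactors = FALSE)
        next
      }
      tt <- stats::t.test(a, b, var.equal = var_equal)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, measure = m, t_statistic = unname(tt$statistic),
        p_value = tt$p.value, mean_case = mean(a), mean_control = mean(b),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  rownames(out) <- NULL
  out
}

#' Histogram of CNV sizes by type
#'
#' Counts segments per (type, size bin); bins are left-open, right-closed
#' on `end - start + 1` bp, with values at or below the first edge and
#' above the last edge collected into flanking bins.
#'
#' @param segments a `cnv_segments` data.frame.
#' @param bin_edges strictly increasing numeric vector of bp edges.
#' @return data.frame with columns `cnv_type, bin, count`.
#' @export
size_range_histogram <- function(segments,
                                 bin_edges = c(0, 1e4, 5e4, 1e5, 5e5, 1e6)) {
  segments <- validate_segments(segments)
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing", call. = FALSE)
  }
  edges <- unique(c(-Inf, bin_edges, Inf))
  size <- segments$end - segments$start + 1
  bins <- cut(size, edges)
  tab <- table(factor(segments$cnv_type, levels = c("loss", "gain")), bins)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("cnv_type", "bin", "count")
  out
}
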
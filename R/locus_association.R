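# Single- and joint two-locus copy-number genotype association with
# sex/ancestry adjustment.

#' Classify an integer copy number
#'
#' @param cn non-negative integer copy number(s).
#' @return `"del"` (cn < 2), `"diploid"` (cn = 2) or `"dup"` (cn > 2).
#' @export
classify_genotype <- function(cn) {
  if (any(!is.finite(cn) | cn < 0 | cn != round(cn))) {
    stop("cn must be a non-negative integer", call. = FALSE)
  }
  ifelse(cn < 2, "del", ifelse(cn == 2, "diploid", "dup"))
}

#' Construct per-sample per-locus copy number calls
#'
#' @param sample_id,locus_id identifiers.
#' @param cn non-negative integer copy numbers.
#' @param source `"array"`, `"qpcr"` or `"ddpcr"`.
#' @return data.frame of class `copy_number_calls` with a derived
#'   `cn_class` column.
#' @export
copy_number_calls <- function(sample_id, locus_id, cn, source = "array") {
  stopifnot(all(source %in% c("array", "qpcr", "ddpcr")))
  df <- data.frame(sample_id = as.character(sample_id),
                   locus_id = as.character(locus_id),
                   cn = as.integer(cn),
                   cn_class = classify_genotype(cn),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  class(df) <- unique(c("copy_number_calls", class(df)))
  df
}

#' Joint two-locus genotype categories
#'
#' Combines each sample's copy-number class at two loci into one of eight
#' categories: `diploid_both`, `del_A_only`, `del_B_only`, `del_both`,
#' `dup_A_only`, `dup_B_only`, `dup_both`, and `mixed` (a deletion at one
#' locus with a duplication at the other). Samples missing a call at
#' either locus are excluded and reported.
#'
#' @param calls a `copy_number_calls` table covering both loci.
#' @param locus_a,locus_b the two locus ids (A first).
#' @return data.frame `sample_id, category`, with excluded sample ids in
#'   attribute `excluded`.
#' @export
joint_genotype <- function(calls, locus_a, locus_b) {
  a <- calls[calls$locus_id == locus_a, ]
  b <- calls[calls$locus_id == locus_b, ]
  common <- intersect(a$sample_id, b$sample_id)
  excluded <- setdiff(union(a$sample_id, b$sample_id), common)
  if (length(excluded)) {
    message(length(excluded),
            " sample(s) lack a call at one locus and are excluded")
  }
  ca <- a$cn_class[match(common, a$sample_id)]
  cb <- b$cn_class[match(common, b$sample_id)]
  category <- ifelse(
    ca == "diploid" & cb == "diploid", "diploid_both",
    ifelse(ca == "del" & cb == "diploid", "del_A_only",
    ifelse(ca == "diploid" & cb == "del", "del_B_only",
    ifelse(ca == "del" & cb == "del", "del_both",
    ifelse(ca == "dup" & cb == "diploid", "dup_A_only",
    ifelse(ca == "diploid" & cb == "dup", "dup_B_only",
    ifelse(ca == "dup" & cb == "dup", "dup_both", "mixed")))))))
  out <- data.frame(sample_id = common, category = category,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

joint_categories <- c("diploid_both", "del_A_only", "del_B_only",
                      "del_both", "dup_A_only", "dup_B_only", "dup_both",
                      "mixed")

# Firth's bias-reduced logistic regression (Jeffreys-prior penalty):
# Newton iterations on the modified score U*(b) = X'(y - p + h(1/2 - p)),
# h the hat-matrix diagonal. Used when the ML fit separates.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    XW <- X * sqrt(W)
    I <- crossprod(XW)
    Iinv <- tryCatch(solve(I), error = function(e) NULL)
    if (is.null(Iinv)) return(NULL)
    h <- rowSums((XW %*% Iinv) * XW)
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(Iinv %*% U)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% b)
  p <- 1 / (1 + exp(-eta))
  I <- crossprod(X * sqrt(p * (1 - p)))
  se <- sqrt(diag(solve(I)))
  list(coef = b, se = se)
}

#' Joint-genotype case-control association
#'
#' Fits one multivariable logistic regression of case status on joint
#' genotype category indicators (reference: diploid at both loci) plus sex
#' and one ancestry component. Reports per-category odds ratios with Wald
#' 95% confidence intervals and p-values. Categories absent from the data
#' yield `NA` rows; on separation the fit is flagged and, when
#' `firth = TRUE` (default), refit with Firth's penalized likelihood.
#' `mixed` subjects (deletion at one locus, duplication at the other) are
#' excluded from the model by default and reported in the counts only.
#'
#' @param genotypes data.frame `sample_id, category` from
#'   [joint_genotype()] or [plant_joint_genotypes()].
#' @param samples the `sample_manifest`.
#' @param ancestry_component `"afr"`, `"eur"` or `"amr"`.
#' @param reference reference category.
#' @param include_mixed keep `mixed` subjects as a modeled category.
#' @param firth refit with Firth penalization when the ML fit separates.
#' @return data.frame of class `association_table`: one row per category
#'   with `odds_ratio, ci_low, ci_high, p_value, n_case, n_control,
#'   method`; reference row has OR 1 by construction.
#' @export
fit_association <- function(genotypes, samples,
                            ancestry_component = c("afr", "eur", "amr"),
                            reference = "diploid_both",
                            include_mixed = FALSE, firth = TRUE) {
  ancestry_component <- match.arg(ancestry_component)
  if (!"sample_id" %in% names(genotypes)) {
    genotypes$sample_id <- samples$sample_id[seq_len(nrow(genotypes))]
  }
  df <- merge(genotypes[, c("sample_id", "category")], samples,
              by = "sample_id")
  df$y <- as.integer(df$group == "case")
  counts <- table(factor(df$category, levels = joint_categories), df$group)
  if (sum(df$category == reference & df$y == 1) == 0 ||
      sum(df$category == reference & df$y == 0) == 0) {
    stop("reference category must be present in both groups", call. = FALSE)
  }
  fit_df <- df
  if (!include_mixed) fit_df <- fit_df[fit_df$category != "mixed", ]
  present <- intersect(joint_categories, unique(fit_df$category))
  fit_df$category <- factor(fit_df$category,
                            levels = c(reference,
                                       setdiff(present, reference)))
  fit_df$anc <- fit_df[[ancestry_component]]
  has_sex <- length(unique(fit_df$sex)) > 1
  form <- if (has_sex) y ~ category + sex + anc else y ~ category + anc
  fit <- stats::glm(form, family = stats::binomial(), data = fit_df)
  sep <- glm_separated(fit)
  method <- "ml_logistic"
  co <- summary(fit)$coefficients
  if (sep && firth) {
    X <- stats::model.matrix(form, fit_df)
    ff <- firth_logistic(X, fit_df$y)
    if (!is.null(ff)) {
      z <- ff$coef / ff$se
      co <- cbind(Estimate = ff$coef, `Std. Error` = ff$se, z = z,
                  `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
      rownames(co) <- colnames(X)
      method <- "firth_logistic"
    }
  }
  rows <- lapply(joint_categories, function(cat) {
    n_case <- counts[cat, "case"]
    n_control <- counts[cat, "control"]
    if (cat == reference) {
      return(data.frame(category = cat, odds_ratio = 1, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        n_case = n_case, n_control = n_control,
                        stringsAsFactors = FALSE))
    }
    term <- paste0("category", cat)
    if (!term %in% rownames(co)) {
      return(data.frame(category = cat, odds_ratio = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_, n_case = n_case,
                        n_control = n_control, stringsAsFactors = FALSE))
    }
    b <- co[term, "Estimate"]
    se <- co[term, "Std. Error"]
    data.frame(category = cat, odds_ratio = exp(b),
               ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
               p_value = co[term, "Pr(>|z|)"], n_case = n_case,
               n_control = n_control, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$covariates <- paste(if (has_sex) "sex+" else "", ancestry_component,
                          sep = "")
  out$method <- method
  out$separation <- sep
  rownames(out) <- NULL
  class(out) <- unique(c("association_table", class(out)))
  out
}

#' Per-group copy-number class frequency table
#'
#' Counts and proportions of del/diploid/dup calls per locus per group.
#'
#' @param calls a `copy_number_calls` table.
#' @param samples the `sample_manifest`.
#' @return data.frame `locus_id, group, cn_class, n, proportion`
#'   (proportions sum to 1 within each locus x group).
#' @export
genotype_frequency_table <- function(calls, samples) {
  df <- merge(calls, samples[, c("sample_id", "group")], by = "sample_id")
  if (!nrow(df)) stop("no calls for manifest samples", call. = FALSE)
  tab <- as.data.frame(table(
    locus_id = df$locus_id, group = df$group,
    cn_class = factor(df$cn_class, levels = c("del", "diploid", "dup"))),
    stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n"
  tot <- stats::ave(tab$n, paste(tab$locus_id, tab$group), FUN = sum)
  tab$proportion <- ifelse(tot > 0, tab$n / tot, NA_real_)
  tab
}
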
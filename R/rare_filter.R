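# Four-step rare-CNV identification pipeline: (1) exclusion of variants
# seen in the control cohort, (2) population-frequency panel filter at 1%,
# (3) known-variant panel filter, (4) dual-caller concordance. Plus the
# relaxed-threshold functional gene-list screen.

#' Step 1: retain case segments absent from the control cohort
#'
#' Removes any case segment matching a same-type control segment under the
#' overlap rule (default 50% reciprocal).
#'
#' @param case_segments,control_segments `cnv_segments` tables from the
#'   primary caller.
#' @param rule an [overlap_rule()].
#' @return retained case segments.
#' @export
step1_case_exclusive <- function(case_segments, control_segments,
                                 rule = overlap_rule()) {
  case_segments <- validate_segments(case_segments)
  control_segments <- validate_segments(control_segments)
  hit <- match_segments(case_segments, control_segments, rule,
                        match_type = TRUE)
  out <- case_segments[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Step 2: population-frequency filter
#'
#' Removes segments matching a same-type panel entry whose population
#' frequency is at or above `max_freq` (1% default). Segments matching
#' only entries below the threshold are retained and labeled `"< 1%"`;
#' segments matching no entry are retained and labeled `"-"`. The label is
#' attached as a `pop_freq_label` column.
#'
#' @param segments a `cnv_segments` table.
#' @param panel a `reference_panel` carrying frequencies.
#' @param max_freq rarity threshold on population frequency.
#' @param rule an [overlap_rule()].
#' @return retained segments with a `pop_freq_label` column.
#' @export
step2_population_frequency <- function(segments, panel, max_freq = 0.01,
                                       rule = overlap_rule()) {
  segments <- validate_segments(segments)
  if (nrow(panel) > 0 && all(is.na(panel$frequency))) {
    stop("panel carries no frequencies; use step3_known_variant_filter ",
         "for presence/absence panels", call. = FALSE)
  }
  matches <- match_segments_which(segments, panel, rule, match_type = TRUE)
  label <- character(nrow(segments))
  keep <- logical(nrow(segments))
  thr_lab <- paste0("< ", format(100 * max_freq, trim = TRUE), "%")
  for (i in seq_along(matches)) {
    f <- panel$frequency[matches[[i]]]
    f <- f[!is.na(f)]
    if (!length(f)) {
      keep[i] <- TRUE
      label[i] <- "-"
    } else if (max(f) >= max_freq) {
      keep[i] <- FALSE
    } else {
      keep[i] <- TRUE
      label[i] <- thr_lab
    }
  }
  out <- segments[keep, , drop = FALSE]
  out$pop_freq_label <- label[keep]
  rownames(out) <- NULL
  out
}

#' Step 3: known-variant panel filter
#'
#' Removes segments matching a same-type entry of a known-variant panel
#' (DGV-like; frequencies not required) under the overlap rule.
#'
#' @inheritParams step2_population_frequency
#' @param panel a `reference_panel` of known variants.
#' @return retained segments.
#' @export
step3_known_variant_filter <- function(segments, panel,
                                       rule = overlap_rule()) {
  segments <- validate_segments(segments)
  hit <- match_segments(segments, panel, rule, match_type = TRUE)
  out <- segments[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Step 4: dual-caller concordance filter
#'
#' Retains segments replicated by the secondary caller: a same-sample,
#' same-type match under the overlap rule. Samples absent from the
#' secondary call set lose all their segments (reason `"no secondary
#' calls"`).
#'
#' @param segments a `cnv_segments` table (primary caller).
#' @param second_caller_segments `cnv_segments` with
#'   `caller_id = "secondary_caller"`.
#' @param rule an [overlap_rule()].
#' @return retained segments.
#' @export
step4_caller_concordance <- function(segments, second_caller_segments,
                                     rule = overlap_rule()) {
  segments <- validate_segments(segments)
  second_caller_segments <- validate_segments(second_caller_segments)
  if (nrow(second_caller_segments) &&
      !all(second_caller_segments$caller_id == "secondary_caller")) {
    stop("second call set must be labeled caller_id = secondary_caller",
         call. = FALSE)
  }
  hit <- match_segments(segments, second_caller_segments, rule,
                        match_type = TRUE, same_sample = TRUE)
  out <- segments[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the four-step rare-CNV pipeline
#'
#' Applies, in order: control-cohort exclusion, population-frequency
#' filter (< 1%), known-variant filter, and dual-caller concordance. The
#' report carries the per-step retained sets (nested by construction), the
#' count cascade, per-segment removal reasons, and a final rare-CNV table
#' in the published layout (location, genes, type, size kb, sample,
#' population-frequency label).
#'
#' @param case_segments,control_segments primary-caller call sets.
#' @param freq_panel population-frequency `reference_panel`.
#' @param known_panel known-variant `reference_panel`.
#' @param second_caller_segments secondary-caller call set.
#' @param rule an [overlap_rule()] applied at every step.
#' @param max_freq rarity threshold for step 2.
#' @param genes optional `gene_annotation` used to fill the table's gene
#'   column.
#' @return list of class `rare_cnv_report`: `counts` (named cascade
#'   vector), `steps` (list of retained segment tables), `removal_reasons`
#'   (per input case segment), `table` (final rare-CNV table), `rule`.
#' @export
run_rare_pipeline <- function(case_segments, control_segments, freq_panel,
                              known_panel, second_caller_segments,
                              rule = overlap_rule(), max_freq = 0.01,
                              genes = NULL) {
  case_segments <- validate_segments(case_segments)
  key <- function(df) paste(df$sample_id, df$chrom, df$start, df$end,
                            df$cnv_type)
  reasons <- data.frame(key = key(case_segments),
                        reason = rep("retained", nrow(case_segments)),
                        stringsAsFactors = FALSE)
  mark <- function(before, after, why) {
    gone <- setdiff(key(before), key(after))
    reasons$reason[reasons$key %in% gone & reasons$reason == "retained"] <<- why
    invisible(NULL)
  }
  s1 <- step1_case_exclusive(case_segments, control_segments, rule)
  mark(case_segments, s1, "present in control cohort")
  s2 <- step2_population_frequency(s1, freq_panel, max_freq, rule)
  mark(s1, s2, paste0("population frequency >= ",
                      format(100 * max_freq, trim = TRUE), "%"))
  s3 <- step3_known_variant_filter(s2, known_panel, rule)
  mark(s2, s3, "known variant")
  s4 <- step4_caller_concordance(s3, second_caller_segments, rule)
  mark(s3, s4, "not replicated by secondary caller")

  tab <- data.frame(
    location = sprintf("chr%s:%s-%s", s4$chrom,
                       format(s4$start, scientific = FALSE, trim = TRUE),
                       format(s4$end, scientific = FALSE, trim = TRUE)),
    genes = rep("-", nrow(s4)),
    type = ifelse(s4$cnv_type == "loss", "Del", "Dup"),
    size_kb = if (nrow(s4)) interval_size_kb(s4$start, s4$end) else integer(0),
    sample_id = s4$sample_id,
    pop_freq = if (nrow(s4)) s4$pop_freq_label else character(0),
    stringsAsFactors = FALSE
  )
  if (!is.null(genes) && nrow(s4)) {
    gmatch <- match_segments_which(s4, genes, overlap_rule("any"),
                                   match_type = FALSE)
    tab$genes <- vapply(gmatch, function(j) {
      if (!length(j)) "-" else
        paste(unique(genes$gene_symbol[j]), collapse = ", ")
    }, character(1))
  }
  out <- list(
    counts = c(input = nrow(case_segments), step1 = nrow(s1),
               step2 = nrow(s2), step3 = nrow(s3), step4 = nrow(s4)),
    steps = list(step1 = s1, step2 = s2, step3 = s3, step4 = s4),
    removal_reasons = reasons,
    table = tab,
    rule = rule
  )
  class(out) <- "rare_cnv_report"
  out
}

#' @export
print.rare_cnv_report <- function(x, ...) {
  cat("Rare-CNV pipeline report\n")
  cat("  cascade:", paste(sprintf("%s=%d", names(x$counts), x$counts),
                          collapse = " -> "), "\n")
  cat("  overlap rule:", x$rule$rule,
      if (x$rule$rule == "reciprocal") sprintf("(%.0f%%)", 100 * x$rule$frac)
      else "", "\n")
  invisible(x)
}

#' Functional gene-list screen with relaxed probe thresholds
#'
#' Re-applies the probe filter at the relaxed thresholds (15/15 by
#' default, vs the genome-wide 25/50) and reports every segment
#' overlapping a listed gene, tagged with the gene and its list id.
#'
#' @param segments a `cnv_segments` table.
#' @param genes a `gene_annotation` table (lists 1-3).
#' @param min_probes length-2 vector: relaxed loss/gain probe thresholds.
#' @return data.frame with one row per (segment, overlapped gene).
#' @export
gene_list_screen <- function(segments, genes, min_probes = c(15, 15)) {
  segments <- apply_probe_filter(segments, min_probes[1], min_probes[2])
  hits <- match_segments_which(segments, genes, overlap_rule("any"),
                               match_type = FALSE)
  rows <- list()
  for (i in seq_along(hits)) {
    for (j in hits[[i]]) {
      rows[[length(rows) + 1]] <- cbind(
        segments[i, c("sample_id", "chrom", "start", "end", "cnv_type")],
        data.frame(gene_symbol = genes$gene_symbol[j],
                   list_id = genes$list_id[j], stringsAsFactors = FALSE))
    }
  }
  if (!length(rows)) {
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      cnv_type = character(0), gene_symbol = character(0),
                      list_id = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
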
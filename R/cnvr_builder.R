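# CNV regions: unions of overlapping same-type CNVs across subjects, with
# per-region case-control carrier tests.

#' Build CNV regions (CNVRs)
#'
#' A CNVR is the union of transitively overlapping (>= 1 shared base)
#' same-type CNV segments across subjects on one chromosome; gains and
#' losses are never merged. The union span runs from the minimum member
#' start to the maximum member end; a sample is a carrier if it
#' contributes at least one member segment.
#'
#' @param segments a `cnv_segments` data.frame (primary caller only; mixing
#'   callers errors).
#' @param samples the `sample_manifest`.
#' @param cnvr_type build `"loss"` or `"gain"` regions, or `"both"`.
#' @return data.frame of class `cnvr_table`: `region_id, chrom, start,
#'   end, cnvr_type, n_members, n_carriers, carriers_case,
#'   carriers_control` (carrier columns are comma-separated id strings),
#'   plus a `members` attribute mapping segment rows to regions.
#' @export
build_cnvrs <- function(segments, samples, cnvr_type = c("both", "loss",
                                                         "gain")) {
  cnvr_type <- match.arg(cnvr_type)
  segments <- validate_segments(segments)
  if (length(unique(segments$caller_id)) > 1) {
    stop("CNVRs are built from a single caller's segments", call. = FALSE)
  }
  types <- if (cnvr_type == "both") c("loss", "gain") else cnvr_type
  case_ids <- samples$sample_id[samples$group == "case"]
  rows <- list()
  member_map <- list()
  for (ty in types) {
    sub <- segments[segments$cnv_type == ty, , drop = FALSE]
    for (ch in unique(sub$chrom)) {
      idx <- which(sub$chrom == ch)
      ir <- IRanges::IRanges(sub$start[idx], sub$end[idx])
      # min.gapwidth = 0: merge on >= 1 shared base, never book-ended calls
      red <- IRanges::reduce(ir, min.gapwidth = 0L)
      hit <- IRanges::findOverlaps(ir, red)
      comp <- integer(length(idx))
      comp[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
      for (k in seq_along(red)) {
        mem <- idx[comp == k]
        carriers <- unique(sub$sample_id[mem])
        cc <- carriers[carriers %in% case_ids]
        ck <- setdiff(carriers, cc)
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ch, start = IRanges::start(red)[k],
          end = IRanges::end(red)[k], cnvr_type = ty,
          n_members = length(mem), n_carriers = length(carriers),
          carriers_case = paste(sort(cc), collapse = ","),
          carriers_control = paste(sort(ck), collapse = ","),
          stringsAsFactors = FALSE)
        member_map[[length(rows)]] <- mem
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), cnvr_type = character(0),
                      n_members = integer(0), n_carriers = integer(0),
                      carriers_case = character(0),
                      carriers_control = character(0),
                      stringsAsFactors = FALSE)
  }
  # deterministic order regardless of input segment order
  ord <- order(out$cnvr_type, match(out$chrom, CHROMS), out$start, out$end)
  out <- out[ord, , drop = FALSE]
  member_map <- member_map[ord]
  out$region_id <- sprintf("CNVR_%s_%s_%d", out$cnvr_type, out$chrom,
                           as.integer(stats::ave(seq_len(nrow(out)),
                                                 paste(out$cnvr_type,
                                                       out$chrom),
                                                 FUN = seq_along)))
  rownames(out) <- NULL
  out <- out[, c("region_id", "chrom", "start", "end", "cnvr_type",
                 "n_members", "n_carriers", "carriers_case",
                 "carriers_control")]
  attr(out, "members") <- member_map
  class(out) <- unique(c("cnvr_table", class(out)))
  out
}

#' Test one CNVR's carrier frequency between groups
#'
#' Fits a logistic regression of case status on the carrier indicator
#' adjusted for sex and one ancestry component, and also reports the
#' unadjusted carrier 2x2 table with its cross-product odds ratio
#' (Haldane-Anscombe 0.5 correction on empty cells) and Fisher's exact p.
#'
#' @param cnvr one row of a `cnvr_table`.
#' @param samples the `sample_manifest`.
#' @param ancestry_component `"afr"`, `"eur"` or `"amr"`.
#' @return one-row data.frame: adjusted OR/CI/p, Fisher p, 2x2 OR and
#'   counts, separation/degeneracy flags.
#' @export
test_cnvr <- function(cnvr, samples, ancestry_component = c("afr", "eur",
                                                            "amr")) {
  ancestry_component <- match.arg(ancestry_component)
  stopifnot(nrow(cnvr) == 1)
  carriers <- unlist(strsplit(c(cnvr$carriers_case, cnvr$carriers_control),
                              ",", fixed = TRUE))
  carriers <- carriers[nzchar(carriers)]
  if (length(carriers) < 1) stop("CNVR has no carriers", call. = FALSE)
  df <- samples
  df$y <- as.integer(df$group == "case")
  df$carrier <- as.integer(df$sample_id %in% carriers)
  degenerate <- all(df$carrier == 1)
  a <- sum(df$carrier == 1 & df$y == 1)  # case carriers
  b <- sum(df$carrier == 0 & df$y == 1)
  c_ <- sum(df$carrier == 1 & df$y == 0)
  d <- sum(df$carrier == 0 & df$y == 0)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
  fisher_p <- stats::fisher.test(tab)$p.value
  hald <- if (any(tab == 0)) 0.5 else 0
  or_2x2 <- ((a + hald) * (d + hald)) / ((b + hald) * (c_ + hald))
  if (degenerate) {
    w <- list(coef = NA_real_, or = NA_real_, ci_low = NA_real_,
              ci_high = NA_real_, p = NA_real_)
    sep <- FALSE
  } else {
    df$anc <- df[[ancestry_component]]
    fit <- stats::glm(y ~ carrier + sex + anc, family = stats::binomial(),
                      data = df)
    w <- wald_row(fit, "carrier")
    sep <- glm_separated(fit)
  }
  data.frame(region_id = cnvr$region_id, odds_ratio = w$or,
             ci_low = w$ci_low, ci_high = w$ci_high, p_value = w$p,
             p_fisher = fisher_p, or_2x2 = or_2x2,
             case_carriers = a, case_noncarriers = b,
             control_carriers = c_, control_noncarriers = d,
             covariates = paste("sex", ancestry_component, sep = "+"),
             separation = sep, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Annotate CNVRs with overlapping genes
#'
#' Labels each region with the gene symbols it overlaps, distinguishing
#' genes entirely contained in the region span (`entire`) from genes
#' straddling a region edge (`partial`).
#'
#' @param cnvrs a `cnvr_table`.
#' @param genes a `gene_annotation` table.
#' @return data.frame with one row per (region, overlapping gene):
#'   `region_id, gene_symbol, list_id, overlap` (`entire`/`partial`).
#' @export
annotate_cnvrs <- function(cnvrs, genes) {
  rows <- list()
  for (ch in unique(cnvrs$chrom)) {
    ci <- which(cnvrs$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    cr <- IRanges::IRanges(cnvrs$start[ci], cnvrs$end[ci])
    gr <- IRanges::IRanges(genes$start[gi], genes$end[gi])
    ov <- IRanges::findOverlaps(cr, gr)
    for (k in seq_along(ov)) {
      i <- ci[S4Vectors::queryHits(ov)[k]]
      j <- gi[S4Vectors::subjectHits(ov)[k]]
      entire <- genes$start[j] >= cnvrs$start[i] &&
        genes$end[j] <= cnvrs$end[i]
      rows[[length(rows) + 1]] <- data.frame(
        region_id = cnvrs$region_id[i], gene_symbol = genes$gene_symbol[j],
        list_id = genes$list_id[j],
        overlap = if (entire) "entire" else "partial",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(region_id = character(0), gene_symbol = character(0),
                      list_id = integer(0), overlap = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
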
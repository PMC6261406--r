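# Interval matching between segment sets. All coordinates 1-based
# inclusive; widths computed by IRanges.

#' Overlap rule specification
#'
#' Matching rule used by the rare-CNV filters and panel comparisons.
#' `"reciprocal"` requires the shared bases to cover at least `frac` of
#' BOTH intervals' own lengths (standard CNV-matching practice, default
#' 50%); `"any"` accepts a single shared base.
#'
#' @param rule `"reciprocal"` or `"any"`.
#' @param frac reciprocal-overlap fraction in `(0, 1]`; ignored for
#'   `"any"`.
#' @return list of class `overlap_rule`.
#' @export
overlap_rule <- function(rule = c("reciprocal", "any"), frac = 0.5) {
  rule <- match.arg(rule)
  if (rule == "reciprocal" && (frac <= 0 || frac > 1)) {
    stop("reciprocal fraction must be in (0, 1]", call. = FALSE)
  }
  structure(list(rule = rule, frac = frac), class = "overlap_rule")
}

# Which query rows have >= 1 matching subject row under `rule`?
# Matching requires the same chromosome, optionally the same cnv_type and
# the same sample_id. Returns a logical vector over query rows.
match_segments <- function(query, subject, rule = overlap_rule(),
                           match_type = TRUE, same_sample = FALSE) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  hit <- rep(FALSE, nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (!length(si)) next
    qr <- IRanges::IRanges(query$start[qi], query$end[qi])
    sr <- IRanges::IRanges(subject$start[si], subject$end[si])
    ov <- IRanges::findOverlaps(qr, sr)
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    ok <- rep(TRUE, length(qh))
    if (match_type) {
      ok <- ok & query$cnv_type[qi[qh]] == subject$cnv_type[si[sh]]
    }
    if (same_sample) {
      ok <- ok & query$sample_id[qi[qh]] == subject$sample_id[si[sh]]
    }
    if (rule$rule == "reciprocal") {
      w <- IRanges::width(IRanges::pintersect(qr[qh], sr[sh]))
      ok <- ok & w >= rule$frac * IRanges::width(qr)[qh] &
        w >= rule$frac * IRanges::width(sr)[sh]
    }
    if (any(ok)) hit[qi[unique(qh[ok])]] <- TRUE
  }
  hit
}

# As match_segments, but returns for each query row the indices of matching
# subject rows (list), used where the matched entries matter (frequencies).
match_segments_which <- function(query, subject, rule = overlap_rule(),
                                 match_type = TRUE) {
  out <- vector("list", nrow(query))
  for (i in seq_len(nrow(query))) out[[i]] <- integer(0)
  if (nrow(query) == 0 || nrow(subject) == 0) return(out)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (!length(si)) next
    qr <- IRanges::IRanges(query$start[qi], query$end[qi])
    sr <- IRanges::IRanges(subject$start[si], subject$end[si])
    ov <- IRanges::findOverlaps(qr, sr)
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    ok <- rep(TRUE, length(qh))
    if (match_type) {
      ok <- ok & query$cnv_type[qi[qh]] == subject$cnv_type[si[sh]]
    }
    if (rule$rule == "reciprocal") {
      w <- IRanges::width(IRanges::pintersect(qr[qh], sr[sh]))
      ok <- ok & w >= rule$frac * IRanges::width(qr)[qh] &
        w >= rule$frac * IRanges::width(sr)[sh]
    }
    for (k in which(ok)) {
      qrow <- qi[qh[k]]
      out[[qrow]] <- c(out[[qrow]], si[sh[k]])
    }
  }
  out
}
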
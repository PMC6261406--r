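# Allowed chromosome set: autosomes + X (array calls on Y are not analysed).
CHROMS <- c(as.character(1:22), "X")

round_half_up <- function(x) floor(x + 0.5)

#' Normalize chromosome labels
#'
#' Strips an optional `chr` prefix and validates against the allowed set
#' (autosomes 1-22 and X).
#'
#' @param x character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @keywords internal
normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x))
  x <- toupper(x)
  bad <- !(x %in% CHROMS)
  if (any(bad)) {
    stop("invalid chromosome label(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (allowed: 1-22, X)", call. = FALSE)
  }
  x
}

#' Construct a validated CNV segment table
#'
#' The canonical per-call container used throughout the package: one row per
#' called deletion or duplication in one sample from one caller. Coordinates
#' are 1-based inclusive (GRCh37 array-report convention); segment size is
#' `end - start + 1`.
#'
#' @param sample_id character vector of subject identifiers.
#' @param chrom chromosome labels (1-22, X; `chr` prefix tolerated).
#' @param start,end 1-based inclusive base positions, `end >= start >= 1`.
#' @param cn_state integer copy number (>= 0, never 2: diploid calls are not
#'   CNVs).
#' @param n_probes number of consecutive array probes supporting the call;
#'   `NA` for calls without probe metadata (e.g. simulated or PCR-derived).
#' @param caller_id `"primary_caller"` or `"secondary_caller"`.
#' @return data.frame of class `cnv_segments` with columns `sample_id`,
#'   `chrom`, `start`, `end`, `cn_state`, `cnv_type` (`"loss"`/`"gain"`,
#'   derived from `cn_state`), `n_probes`, `caller_id`.
#' @export
cnv_segments <- function(sample_id, chrom, start, end, cn_state,
                         n_probes = NA_integer_,
                         caller_id = "primary_caller") {
  df <- data.frame(
    sample_id = as.character(sample_id),
    chrom = if (length(chrom)) normalize_chrom(chrom) else character(0),
    start = as.numeric(start),
    end = as.numeric(end),
    cn_state = as.integer(cn_state),
    n_probes = as.integer(n_probes),
    caller_id = as.character(caller_id),
    stringsAsFactors = FALSE
  )
  df$cnv_type <- ifelse(df$cn_state < 2, "loss", "gain")
  df <- df[, c("sample_id", "chrom", "start", "end", "cn_state",
               "cnv_type", "n_probes", "caller_id")]
  validate_segments(df)
}

#' Validate a CNV segment table
#'
#' Enforces the segment invariants: positions 1-based with `end >= start`,
#' `cn_state >= 0` and not 2, `cnv_type` consistent with `cn_state`,
#' `n_probes >= 1` when present, known caller labels. Errors name the
#' offending rows.
#'
#' @param df a data.frame with the `cnv_segments` columns.
#' @return the validated data.frame, classed `cnv_segments`.
#' @export
validate_segments <- function(df) {
  needed <- c("sample_id", "chrom", "start", "end", "cn_state",
              "cnv_type", "n_probes", "caller_id")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("segment table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fail <- function(rows, what) {
    stop("invalid segment row(s) ", paste(utils::head(rows, 5), collapse = ", "),
         if (length(rows) > 5) " ..." else "", ": ", what, call. = FALSE)
  }
  df$chrom <- if (nrow(df)) normalize_chrom(df$chrom) else character(0)
  bad <- which(!is.finite(df$start) | !is.finite(df$end) | df$start < 1)
  if (length(bad)) fail(bad, "start must be >= 1")
  bad <- which(df$end < df$start)
  if (length(bad)) fail(bad, "end < start")
  bad <- which(is.na(df$cn_state) | df$cn_state < 0)
  if (length(bad)) fail(bad, "cn_state must be a non-negative integer")
  bad <- which(df$cn_state == 2)
  if (length(bad)) fail(bad, "cn_state 2 is diploid, not a CNV")
  exp_type <- ifelse(df$cn_state < 2, "loss", "gain")
  bad <- which(df$cnv_type != exp_type)
  if (length(bad)) fail(bad, "cnv_type inconsistent with cn_state")
  bad <- which(!is.na(df$n_probes) & df$n_probes < 1)
  if (length(bad)) fail(bad, "n_probes must be >= 1 when present")
  bad <- which(!df$caller_id %in% c("primary_caller", "secondary_caller"))
  if (length(bad)) fail(bad, "caller_id must be primary_caller or secondary_caller")
  rownames(df) <- NULL
  class(df) <- unique(c("cnv_segments", class(df)))
  df
}

#' Read CNV segment calls from disk
#'
#' Two dialects are supported. `chas_tsv` is the package's tab-delimited
#' exchange format with header columns `sample_id, chrom, start, end,
#' cn_state, n_probes, caller_id` and 1-based inclusive coordinates. `bed`
#' is BED4+ (`chrom, start, end, name[, sample_id]`) with 0-based half-open
#' coordinates, converted to 1-based inclusive on read; the `name` field
#' must be one of `del`, `dup`, `loss`, `gain` (case-insensitive) and maps
#' to copy number 1 / 3.
#'
#' @param path path to the file.
#' @param dialect `"chas_tsv"` or `"bed"`.
#' @param caller_id caller label assigned to BED rows (TSV rows carry their
#'   own).
#' @return a `cnv_segments` data.frame.
#' @export
read_segments <- function(path, dialect = c("chas_tsv", "bed"),
                          caller_id = "primary_caller") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "chas_tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    needed <- c("sample_id", "chrom", "start", "end", "cn_state")
    miss <- setdiff(needed, names(df))
    if (length(miss)) {
      stop("segment TSV missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(df$n_probes)) df$n_probes <- NA_integer_
    if (is.null(df$caller_id)) df$caller_id <- caller_id
    cnv_segments(df$sample_id, df$chrom, df$start, df$end, df$cn_state,
                 df$n_probes, df$caller_id)
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            comment.char = "#")
    if (ncol(df) < 4) stop("BED input needs >= 4 columns", call. = FALSE)
    names(df)[1:4] <- c("chrom", "start", "end", "name")
    type <- tolower(df$name)
    known <- c(del = "loss", loss = "loss", dup = "gain", gain = "gain")
    bad <- which(!type %in% names(known))
    if (length(bad)) {
      stop("BED row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           ": name must be del/dup/loss/gain", call. = FALSE)
    }
    sample_id <- if (ncol(df) >= 5) as.character(df[[5]]) else "unknown"
    # BED 0-based half-open -> 1-based inclusive
    cnv_segments(sample_id, df$chrom, df$start + 1, df$end,
                 ifelse(known[type] == "loss", 1L, 3L),
                 NA_integer_, caller_id)
  }
}

#' Write CNV segments as TSV or BED
#'
#' `write_segments` writes the `chas_tsv` dialect; `write_segments_bed`
#' writes BED4+1 (`chrom, start, end, name, sample_id`) with the `chr`
#' prefix restored and coordinates converted back to 0-based half-open, so
#' that a write/read round trip is the identity.
#'
#' @param segments a `cnv_segments` data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_segments <- function(segments, path) {
  segments <- validate_segments(segments)
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
write_segments_bed <- function(segments, path) {
  segments <- validate_segments(segments)
  bed <- data.frame(
    chrom = paste0("chr", segments$chrom),
    start = format(segments$start - 1, scientific = FALSE, trim = TRUE),
    end = format(segments$end, scientific = FALSE, trim = TRUE),
    name = ifelse(segments$cnv_type == "loss", "del", "dup"),
    sample_id = segments$sample_id,
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a case-control sample manifest
#'
#' TSV with header columns `sample_id, group, sex, afr, eur, amr`. Group
#' labels must be `case`/`control`, sex `F`/`M`. The three admixture
#' proportions (African, European, Amerindian) must lie in `[0, 1]` and sum
#' to 1; sums within 1e-3 of 1 are renormalized, anything further off is
#' rejected.
#'
#' @param path path to the manifest TSV.
#' @return data.frame of class `sample_manifest` with the six columns above.
#' @export
read_sample_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("sample_id", "group", "sex", "afr", "eur", "amr")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sample_manifest(df$sample_id, df$group, df$sex, df$afr, df$eur, df$amr)
}

#' Construct a validated sample manifest
#'
#' @param sample_id subject identifiers (must be unique).
#' @param group `"case"` or `"control"`.
#' @param sex `"F"` or `"M"`.
#' @param afr,eur,amr ancestry proportions in `[0, 1]`, summing to 1 per
#'   subject (renormalized when within 1e-3).
#' @return data.frame of class `sample_manifest`.
#' @export
sample_manifest <- function(sample_id, group, sex, afr, eur, amr) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    group = as.character(group),
    sex = as.character(sex),
    afr = as.numeric(afr), eur = as.numeric(eur), amr = as.numeric(amr),
    stringsAsFactors = FALSE
  )
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) {
    stop("duplicate sample_id in manifest: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad <- which(!df$group %in% c("case", "control"))
  if (length(bad)) {
    stop("unknown group label in manifest row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (expected case/control)", call. = FALSE)
  }
  bad <- which(!df$sex %in% c("F", "M"))
  if (length(bad)) {
    stop("sex must be F or M (row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ")", call. = FALSE)
  }
  anc <- as.matrix(df[, c("afr", "eur", "amr")])
  if (any(!is.finite(anc)) || any(anc < 0) || any(anc > 1)) {
    stop("ancestry proportions must be in [0, 1]", call. = FALSE)
  }
  s <- rowSums(anc)
  bad <- which(abs(s - 1) > 1e-3)
  if (length(bad)) {
    stop("ancestry proportions do not sum to 1 in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  df[, c("afr", "eur", "amr")] <- anc / s
  rownames(df) <- NULL
  class(df) <- unique(c("sample_manifest", class(df)))
  df
}

#' Construct or read a reference CNV panel
#'
#' A panel is an interval table of known variants: a control-cohort call
#' set, a population-frequency panel (HapMap-like), or a known-variant
#' database (DGV-like). Frequencies are optional per entry.
#'
#' @param chrom,start,end intervals, 1-based inclusive.
#' @param cnv_type `"loss"` or `"gain"`.
#' @param frequency population frequency in `[0, 1]`, or `NA`.
#' @param name panel label carried through reports.
#' @return data.frame of class `reference_panel`.
#' @export
reference_panel <- function(chrom, start, end, cnv_type,
                            frequency = NA_real_, name = "panel") {
  df <- data.frame(
    chrom = if (length(chrom)) normalize_chrom(chrom) else character(0),
    start = as.numeric(start), end = as.numeric(end),
    cnv_type = as.character(cnv_type),
    frequency = as.numeric(frequency),
    stringsAsFactors = FALSE
  )
  if (any(df$end < df$start)) stop("panel interval with end < start", call. = FALSE)
  bad <- which(!df$cnv_type %in% c("loss", "gain"))
  if (length(bad)) stop("panel cnv_type must be loss/gain", call. = FALSE)
  f <- df$frequency
  if (any(!is.na(f) & (f < 0 | f > 1))) {
    stop("panel frequencies must be in [0, 1]", call. = FALSE)
  }
  attr(df, "panel_name") <- name
  class(df) <- unique(c("reference_panel", class(df)))
  df
}

#' @rdname reference_panel
#' @param path TSV with header `chrom, start, end, cnv_type[, frequency]`.
#' @export
read_reference_panel <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("chrom", "start", "end", "cnv_type")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("panel missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$frequency)) df$frequency <- NA_real_
  reference_panel(df$chrom, df$start, df$end, df$cnv_type, df$frequency, name)
}

#' Construct or read gene annotation lists
#'
#' Gene interval tables used by the CNVR annotator and the functional
#' gene-list screen. `list_id` distinguishes the three curated lists
#' (1: genes with CNVs previously reported in the disease, 2: linkage/GWAS
#' genes, 3: autoimmunity genes).
#'
#' @param gene_symbol gene symbols; `(gene_symbol, list_id)` must be unique.
#' @param chrom,start,end gene intervals, 1-based inclusive.
#' @param list_id integer list membership (1, 2 or 3).
#' @return data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_symbol, chrom, start, end, list_id = 1L) {
  df <- data.frame(
    gene_symbol = as.character(gene_symbol),
    chrom = if (length(chrom)) normalize_chrom(chrom) else character(0),
    start = as.numeric(start), end = as.numeric(end),
    list_id = as.integer(list_id),
    stringsAsFactors = FALSE
  )
  if (any(df$end < df$start)) stop("gene interval with end < start", call. = FALSE)
  if (any(!df$list_id %in% 1:3)) stop("list_id must be 1, 2 or 3", call. = FALSE)
  key <- paste(df$gene_symbol, df$list_id)
  if (anyDuplicated(key)) {
    stop("duplicate (gene_symbol, list_id): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  class(df) <- unique(c("gene_annotation", class(df)))
  df
}

#' @rdname gene_annotation
#' @param path TSV with header `gene_symbol, chrom, start, end, list_id`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("gene_symbol", "chrom", "start", "end")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("gene list missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$list_id)) df$list_id <- 1L
  gene_annotation(df$gene_symbol, df$chrom, df$start, df$end, df$list_id)
}

#' Filter segments on probe support
#'
#' Array CNV calls are retained only when supported by a minimum number of
#' consecutive probes, with separate thresholds for losses and gains (the
#' stringent genome-wide setting is 25/50; the relaxed gene-screen setting
#' is 15/15). Segments without probe counts (simulated or PCR-derived calls)
#' pass unfiltered with a warning.
#'
#' @param segments a `cnv_segments` data.frame.
#' @param min_probes_loss,min_probes_gain minimum probe counts (>= 1).
#' @return the filtered `cnv_segments`.
#' @export
apply_probe_filter <- function(segments, min_probes_loss = 25,
                               min_probes_gain = 50) {
  segments <- validate_segments(segments)
  if (min_probes_loss < 1 || min_probes_gain < 1) {
    stop("probe thresholds must be >= 1", call. = FALSE)
  }
  no_probe <- is.na(segments$n_probes)
  if (any(no_probe)) {
    warning(sum(no_probe),
            " segment(s) lack probe counts and bypass the probe filter",
            call. = FALSE)
  }
  thr <- ifelse(segments$cnv_type == "loss", min_probes_loss, min_probes_gain)
  keep <- no_probe | segments$n_probes >= thr
  out <- segments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interval size in kilobases
#'
#' Size of a 1-based inclusive interval, `end - start + 1` bp, reported in
#' kb with half-up rounding — the convention under which the published
#' rare-CNV table sizes reproduce from their printed coordinates.
#'
#' @param start,end 1-based inclusive positions (vectors of equal length),
#'   or `start` may be a data.frame with `start`/`end` columns.
#' @return integer vector of sizes in kb.
#' @export
interval_size_kb <- function(start, end = NULL) {
  if (is.data.frame(start)) {
    end <- start$end
    start <- start$start
  }
  if (any(end < start)) stop("end < start", call. = FALSE)
  as.integer(round_half_up((end - start + 1) / 1000))
}
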
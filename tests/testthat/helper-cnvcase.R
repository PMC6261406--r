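# Shared fixture builders and brute-force oracles. The oracles are
# deliberately naive O(n*m) / O(n^2) implementations kept independent of
# the package's IRanges-based code paths.

make_manifest <- function(n_cases, n_controls, seed = 1) {
  set.seed(seed)
  n <- n_cases + n_controls
  g <- matrix(rgamma(3 * n, shape = c(2, 7, 1)), ncol = 3, byrow = TRUE)
  anc <- g / rowSums(g)
  sample_manifest(
    sprintf("S%04d", seq_len(n)),
    c(rep("case", n_cases), rep("control", n_controls)),
    sample(c("F", "M"), n, replace = TRUE),
    anc[, 1], anc[, 2], anc[, 3])
}

random_segments <- function(n, n_samples = 5, chroms = c("1", "2"),
                            max_pos = 1e5, max_len = 2e4) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  cnv_segments(sprintf("S%04d", sample.int(n_samples, n, replace = TRUE)),
               sample(chroms, n, replace = TRUE),
               start, start + len - 1,
               sample(c(0L, 1L, 3L, 4L), n, replace = TRUE))
}

# O(n*m) all-pairs overlap matcher (oracle for match_segments).
brute_match <- function(query, subject, rule = "reciprocal", frac = 0.5,
                        match_type = TRUE, same_sample = FALSE) {
  hit <- rep(FALSE, nrow(query))
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] != subject$chrom[j]) next
      if (match_type && query$cnv_type[i] != subject$cnv_type[j]) next
      if (same_sample && query$sample_id[i] != subject$sample_id[j]) next
      ov <- min(query$end[i], subject$end[j]) -
        max(query$start[i], subject$start[j]) + 1
      if (ov < 1) next
      if (rule == "reciprocal") {
        lq <- query$end[i] - query$start[i] + 1
        ls <- subject$end[j] - subject$start[j] + 1
        if (ov < frac * lq || ov < frac * ls) next
      }
      hit[i] <- TRUE
      break
    }
  }
  hit
}

# Connected components of the pairwise >=1 bp same-chrom same-type overlap
# graph (oracle for build_cnvrs), as a membership vector.
brute_components <- function(seg) {
  n <- nrow(seg)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if (seg$chrom[i] != seg$chrom[j]) next
        if (seg$cnv_type[i] != seg$cnv_type[j]) next
        ov <- min(seg$end[i], seg$end[j]) - max(seg$start[i], seg$start[j]) + 1
        if (ov >= 1 && comp[j] != comp[i]) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

# Canonical representation of a segment partition: sorted span strings.
component_spans <- function(seg, comp) {
  unname(sort(vapply(split(seq_len(nrow(seg)), comp), function(idx) {
    paste(seg$cnv_type[idx[1]], seg$chrom[idx[1]],
          min(seg$start[idx]), max(seg$end[idx]), length(idx))
  }, character(1)), method = "radix"))
}

table1_fixture <- function() {
  read.delim(system.file("extdata", "table1_rare_cnvs.tsv",
                         package = "cnvcase"),
             stringsAsFactors = FALSE, check.names = FALSE)
}

parse_location <- function(loc) {
  m <- regmatches(loc, regexec("^chr([0-9X]+):([0-9]+)-([0-9]+)$", loc))
  data.frame(chrom = vapply(m, `[`, character(1), 2),
             start = as.numeric(vapply(m, `[`, character(1), 3)),
             end = as.numeric(vapply(m, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}
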
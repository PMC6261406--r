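test_that("burden summaries count and size calls per sample", {
  man <- make_manifest(2, 2)
  ids <- man$sample_id
  segs <- cnv_segments(
    c(ids[1], ids[1], ids[2]),
    c("1", "1", "14"),
    c(100, 1000, 5000), c(599, 1499, 5999),
    c(1L, 3L, 1L))
  b <- summarize_burden(segs, man)
  expect_equal(nrow(b$per_sample), 4)        # zero-call samples included
  r1 <- b$per_sample[b$per_sample$sample_id == ids[1], ]
  expect_equal(r1$n_del, 1)
  expect_equal(r1$n_dup, 1)
  expect_equal(r1$size_del, r1$size_dup)     # equal-size del and dup
  r4 <- b$per_sample[b$per_sample$sample_id == ids[4], ]
  expect_equal(r4$n_total, 0)
  expect_equal(r4$size_total, 0)
  # conservation: per-chromosome counts re-aggregate to totals
  expect_equal(unname(rowSums(b$chrom_counts)), b$per_sample$n_total)
  expect_equal(unname(rowSums(b$chrom_size)), b$per_sample$size_total)
  # orphan sample ids error
  bad <- cnv_segments("GHOST", "1", 1, 10, 1L)
  expect_error(summarize_burden(bad, man), "absent from manifest")
})

test_that("average calls per subject reproduce cohort-level arithmetic", {
  # 447 calls over 23 subjects and 2652 over 110: means 19.4 and 24.1
  man <- make_manifest(23, 110)
  set.seed(2)
  owner_case <- sample(man$sample_id[man$group == "case"], 447, TRUE)
  owner_ctrl <- sample(man$sample_id[man$group == "control"], 2652, TRUE)
  start <- sample.int(1e8, 3099)
  segs <- cnv_segments(c(owner_case, owner_ctrl),
                       sample(c(as.character(1:22), "X"), 3099, TRUE),
                       start, start + 999, 1L)
  b <- summarize_burden(segs, man)
  grp <- man$group[match(b$per_sample$sample_id, man$sample_id)]
  expect_equal(mean(b$per_sample$n_total[grp == "case"]), 447 / 23)
  expect_equal(round(mean(b$per_sample$n_total[grp == "case"])), 19)
  expect_equal(mean(b$per_sample$n_total[grp == "control"]), 2652 / 110)
  expect_equal(round(mean(b$per_sample$n_total[grp == "control"])), 24)
})

test_that("burden regression is null-calibrated and recovers planted effects", {
  man <- make_manifest(120, 215)
  sim_burden <- function(or_per_call = 1, seed) {
    set.seed(seed)
    n <- nrow(man)
    n_dup <- rnbinom(n, mu = 7, size = 5)
    eta <- -0.6 + log(or_per_call) * n_dup
    y <- rbinom(n, 1, plogis(eta))
    m2 <- man
    m2$group <- ifelse(y == 1, "case", "control")
    start <- unlist(lapply(n_dup, function(k) sample.int(1e8, k)))
    segs <- cnv_segments(rep(m2$sample_id, n_dup), "2", start,
                         start + 4999, 3L)
    # anchor samples so both groups always have >= 2 members
    list(man = m2, b = summarize_burden(segs, m2))
  }
  # identical groups: OR ~ 1
  d <- sim_burden(1, seed = 5)
  r <- compare_burden(d$b, d$man, "n_dup", "afr")
  expect_lt(abs(log(r$odds_ratio)), 0.1)
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)

  # type-I error at the nominal rate under the null (fixed-seed replicate
  # loop; binomial 2 SE band around 0.05)
  p <- vapply(1:400, function(i) {
    d <- sim_burden(1, seed = 1000 + i)
    compare_burden(d$b, d$man, "n_dup", "afr")$p_value
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 2 * sqrt(0.05 * 0.95 / 400) + 1e-9)

  # planted protective duplication burden (OR 0.7 per call): estimates
  # center on the target and CIs cover it at close to nominal rate
  res <- t(vapply(1:200, function(i) {
    d <- sim_burden(0.7, seed = 2000 + i)
    r <- compare_burden(d$b, d$man, "n_dup", "afr")
    c(r$odds_ratio, r$ci_low, r$ci_high)
  }, numeric(3)))
  expect_lt(abs(median(res[, 1]) - 0.7), 0.05)
  expect_gte(mean(res[, 2] <= 0.7 & 0.7 <= res[, 3]), 0.90)
  # at this sample size the pooled estimate clearly excludes the null
  expect_lt(mean(res[, 1]), 0.8)
})

test_that("per-chromosome t-tests localize a planted chr14 size shift", {
  man <- make_manifest(30, 60)
  set.seed(7)
  mk <- function(id, chrom, n, mu) {
    start <- sample.int(1e7, n)
    cnv_segments(rep(id, n), chrom, start,
                 start + pmax(1, round(rnorm(n, mu, mu / 10))), 1L)
  }
  segs <- do.call(rbind, c(
    lapply(man$sample_id, function(id) mk(id, "1", 3, 5000)),
    lapply(man$sample_id[man$group == "case"],
           function(id) mk(id, "14", 3, 20000)),
    lapply(man$sample_id[man$group == "control"],
           function(id) mk(id, "14", 3, 5000))))
  b <- summarize_burden(segs, man)
  tt <- per_chromosome_tests(b, man)
  chr14_size <- tt[tt$chrom == "14" & tt$measure == "size", ]
  chr1_size <- tt[tt$chrom == "1" & tt$measure == "size", ]
  expect_lt(chr14_size$p_value, 1e-6)
  expect_gt(chr1_size$p_value, 0.01)
  # chromosomes with no calls at all give NA rows
  expect_true(all(is.na(tt$p_value[tt$chrom == "21"])))
  # equal group distributions give t = 0 (one subject per group carries
  # an extra call, so variance is non-zero but identical across groups)
  man2 <- make_manifest(2, 2)
  s2 <- cnv_segments(man2$sample_id[c(1, 1, 2, 3, 3, 4)], "1",
                     c(100, 300, 500, 700, 900, 1100),
                     c(199, 399, 599, 799, 999, 1199), 1L)
  t2 <- per_chromosome_tests(summarize_burden(s2, man2), man2)
  expect_equal(t2$t_statistic[t2$chrom == "1" & t2$measure == "calls"], 0)
  # single-sample groups are refused
  man3 <- make_manifest(1, 3)
  expect_error(per_chromosome_tests(summarize_burden(s2[0, ], man3), man3),
               ">= 2 samples")
})

test_that("size histogram conserves call counts", {
  set.seed(21)
  segs <- random_segments(120)
  h <- size_range_histogram(segs, bin_edges = c(0, 5e3, 1e4, 2e4))
  expect_equal(sum(h$count), nrow(segs))
  expect_equal(sum(h$count[h$cnv_type == "loss"]),
               sum(segs$cnv_type == "loss"))
  # all segments in one bin -> a single nonzero cell per type present
  one <- cnv_segments(c("a", "b"), "1", c(100, 300), c(149, 349), 1L)
  h1 <- size_range_histogram(one, bin_edges = c(0, 100, 1000))
  expect_equal(sum(h1$count > 0), 1)
  expect_equal(sum(h1$count), 2)
  # empty input -> all-zero table; bad edges refused
  h0 <- size_range_histogram(one[0, ], bin_edges = c(0, 100))
  expect_true(all(h0$count == 0))
  expect_error(size_range_histogram(one, bin_edges = c(10, 10)),
               "increasing")
})
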
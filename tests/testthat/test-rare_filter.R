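seg1 <- function(sample, chrom, start, end, cn = 1L,
                 caller = "primary_caller") {
  cnv_segments(sample, chrom, start, end, cn, caller_id = caller)
}

test_that("control-cohort exclusion is type-matched and rule-sensitive", {
  case <- seg1("c1", "1", 100, 200)
  # identical control segment removes the call
  expect_equal(nrow(step1_case_exclusive(case, seg1("k1", "1", 100, 200))),
               0)
  # a control gain never matches a case loss
  expect_equal(nrow(step1_case_exclusive(case, seg1("k1", "1", 150, 300,
                                                    3L))), 1)
  # 51 bp shared = 50.5% of the case call but 20% of the control call:
  # retained under the reciprocal rule, removed under any-overlap
  ctrl <- seg1("k1", "1", 150, 400)
  expect_equal(nrow(step1_case_exclusive(case, ctrl, overlap_rule())), 1)
  expect_equal(nrow(step1_case_exclusive(case, ctrl,
                                         overlap_rule("any"))), 0)
})

test_that("population-frequency filter removes common, labels rare", {
  segs <- seg1(c("a", "b", "c"), c("1", "2", "3"),
               c(100, 100, 100), c(200, 200, 200))
  panel <- reference_panel(c("1", "2"), c(100, 100), c(200, 200),
                           "loss", c(0.05, 0.005))
  out <- step2_population_frequency(segs, panel)
  expect_equal(out$sample_id, c("b", "c"))
  expect_equal(out$pop_freq_label, c("< 1%", "-"))
  # a panel without any frequencies is the wrong input here
  nofreq <- reference_panel("1", 100, 200, "loss", NA_real_)
  expect_error(step2_population_frequency(segs, nofreq), "no frequencies")
})

test_that("known-variant filter respects reciprocal nesting", {
  segs <- seg1(c("a", "b", "c"), c("1", "4", "2"),
               c(100, 100, 1000), c(200, 200, 1099))
  panel <- reference_panel(c("1", "2"), c(100, 500), c(200, 1500), "loss")
  out <- step3_known_variant_filter(segs, panel)
  # exact match removed; absent chromosome retained; a small call nested
  # in a huge known variant (10% of its span) retained under reciprocity
  expect_setequal(out$sample_id, c("b", "c"))
  expect_equal(nrow(step3_known_variant_filter(
    segs, panel, overlap_rule("any"))), 1)
})

test_that("caller concordance requires a same-sample replicate", {
  segs <- seg1(c("a", "b"), "1", c(100, 1000), c(200, 1100))
  second <- seg1(c("a", "z"), "1", c(100, 1000), c(200, 1100),
                 caller = "secondary_caller")
  out <- step4_caller_concordance(segs, second)
  expect_equal(out$sample_id, "a")  # b's match sits in the wrong sample
  # unlabeled second call set is refused
  expect_error(step4_caller_concordance(segs, segs), "secondary_caller")
})

test_that("overlap filters agree with the brute-force all-pairs oracle", {
  set.seed(23)
  for (i in 1:40) {
    nq <- sample(5:80, 1)
    ns <- sample(5:80, 1)
    q <- random_segments(nq, n_samples = 4)
    s <- random_segments(ns, n_samples = 4)
    for (rule in list(overlap_rule("reciprocal", 0.5),
                      overlap_rule("reciprocal", 0.8),
                      overlap_rule("any"))) {
      expect_identical(
        cnvcase:::match_segments(q, s, rule, match_type = TRUE),
        brute_match(q, s, rule$rule, rule$frac, match_type = TRUE))
      expect_identical(
        cnvcase:::match_segments(q, s, rule, match_type = TRUE,
                                 same_sample = TRUE),
        brute_match(q, s, rule$rule, rule$frac, match_type = TRUE,
                    same_sample = TRUE))
    }
  }
})

test_that("pipeline cascade is nested with partitioned removal reasons", {
  co <- simulate_cohort(simulation_config(n_cases = 10, n_controls = 25,
                                          seed = 31, n_pool = 80,
                                          mean_calls_case = 10,
                                          mean_calls_control = 12))
  seg <- co$segments_caller1
  case_ids <- co$samples$sample_id[co$samples$group == "case"]
  rep <- run_rare_pipeline(seg[seg$sample_id %in% case_ids, ],
                           seg[!seg$sample_id %in% case_ids, ],
                           co$panels$frequency, co$panels$known,
                           co$segments_caller2)
  counts <- rep$counts
  expect_true(all(diff(counts) <= 0))
  key <- function(df) paste(df$sample_id, df$chrom, df$start, df$end)
  expect_true(all(key(rep$steps$step2) %in% key(rep$steps$step1)))
  expect_true(all(key(rep$steps$step3) %in% key(rep$steps$step2)))
  expect_true(all(key(rep$steps$step4) %in% key(rep$steps$step3)))
  # removal reasons partition the removed calls
  expect_equal(sum(rep$removal_reasons$reason == "retained"),
               unname(counts["step4"]))
  expect_equal(nrow(rep$removal_reasons), unname(counts["input"]))
  # the final table carries sizes and population-frequency labels
  expect_equal(nrow(rep$table), unname(counts["step4"]))
  expect_true(all(rep$table$pop_freq %in% c("-", "< 1%")))
  expect_true(all(rep$table$type %in% c("Del", "Dup")))
})

test_that("pipeline recovers planted rare segments exactly", {
  co <- simulate_cohort(simulation_config(seed = 47))
  seg <- co$segments_caller1
  case_ids <- co$samples$sample_id[co$samples$group == "case"]
  rep <- run_rare_pipeline(seg[seg$sample_id %in% case_ids, ],
                           seg[!seg$sample_id %in% case_ids, ],
                           co$panels$frequency, co$panels$known,
                           co$segments_caller2)
  truth <- co$ground_truth$rare_segments
  key <- function(df) paste(df$sample_id, df$chrom, df$start, df$end)
  found <- key(rep$steps$step4)
  expect_setequal(found, key(truth[truth$rare, ]))
})

test_that("degenerate pipeline inputs pass through cleanly", {
  empty_panel <- reference_panel(character(0), numeric(0), numeric(0),
                                 character(0), numeric(0))
  case <- seg1(c("a", "b"), "1", c(100, 5000), c(200, 6000))
  second <- case
  second$caller_id <- "secondary_caller"
  rep <- run_rare_pipeline(case, case[0, ], empty_panel, empty_panel,
                           second)
  expect_equal(unname(rep$counts), c(2L, 2L, 2L, 2L, 2L))
  rep0 <- run_rare_pipeline(case[0, ], case, empty_panel, empty_panel,
                            second)
  expect_true(all(rep0$counts == 0))
})

test_that("gene-list screen reports relaxed-threshold hits per list", {
  genes <- gene_annotation(c("G1", "G2"), c("1", "2"), c(150, 150),
                           c(400, 400), c(2L, 3L))
  segs <- cnv_segments(c("a", "b", "c"), c("1", "2", "2"),
                       c(100, 100, 120), c(300, 300, 320),
                       c(1L, 3L, 1L), n_probes = c(16L, 20L, 16L))
  # the 16-probe loss fails the stringent genome-wide thresholds ...
  expect_equal(nrow(apply_probe_filter(segs, 25, 50)), 0)
  # ... but is reported by the relaxed screen, tagged with its list
  hits <- gene_list_screen(segs, genes)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$list_id[hits$sample_id == "a"], 2L)
  # one gene hit by a loss and a gain in different subjects -> two rows
  expect_equal(sum(hits$gene_symbol == "G2"), 2)
  # segments overlapping no listed gene are absent
  far <- cnv_segments("d", "9", 1e6, 2e6, 1L, n_probes = 100L)
  expect_false("d" %in% gene_list_screen(rbind(segs, far), genes)$sample_id)
})
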
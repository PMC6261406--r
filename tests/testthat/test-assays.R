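test_that("triplicate QC means, trims and fails as specified", {
  q <- replicate_qc(c(25.0, 25.1, 25.2))
  expect_equal(q$mean, 25.1)
  expect_equal(q$n_used, 3)
  expect_false(q$failed)
  # a wild replicate is dropped (farthest from the median)
  q2 <- replicate_qc(c(25.0, 25.1, 27.9), max_range = 0.5)
  expect_equal(q2$mean, 25.05)
  expect_equal(q2$outlier, 27.9)
  expect_equal(q2$n_used, 2)
  # fewer than two finite values is a failure
  expect_true(replicate_qc(c(NA, NA, 25.0))$failed)
})

test_that("delta-delta-Ct copy numbers follow the doubling rule", {
  # ddCt = 0 -> CN 2; +1 -> CN 1; -0.585 -> CN 3 (2 * 2^0.585)
  cn_at <- function(ddct) {
    ddct_copy_number(rep(25 + ddct, 3), rep(25, 3), calibrator_dct = 0)
  }
  expect_equal(cn_at(0)$cn_estimate, 2)
  expect_equal(cn_at(0)$cn_integer, 2L)
  expect_equal(cn_at(1)$cn_estimate, 1)
  expect_equal(cn_at(1)$cn_integer, 1L)
  r3 <- cn_at(-0.585)
  expect_equal(r3$cn_estimate, 3, tolerance = 1e-4)
  expect_equal(r3$cn_integer, 3L)
  # non-amplified target with amplified reference is copy number zero
  r0 <- ddct_copy_number(c(NA, NA, NA), rep(25, 3))
  expect_equal(r0$cn_integer, 0L)
  expect_equal(r0$qc_flag, "target_not_amplified")
  # estimates inside the half-integer band are no-calls
  amb <- ddct_copy_number(rep(25 - log2(2.5 / 2), 3), rep(25, 3))
  expect_true(is.na(amb$cn_integer))
})

test_that("plate-level ddCt calls anchor on a diploid calibrator", {
  plate <- simulate_qpcr_plate(c(CAL = 2, A = 1, B = 3, C = 2),
                               noise_sd = 0, seed = 1)
  calls <- qpcr_call_plate(plate, calibrator_id = "CAL")
  got <- setNames(calls$cn_integer, calls$sample_id)
  expect_equal(unname(got[c("A", "B", "C")]), c(1L, 3L, 2L))
  expect_true(all(calls$ci_low <= calls$cn_estimate &
                    calls$cn_estimate <= calls$ci_high, na.rm = TRUE))
  expect_error(qpcr_call_plate(plate, "GHOST"), "absent")
})

test_that("ddPCR concentration matches the Poisson closed form", {
  r <- ddpcr_concentration(1000, 10000, droplet_volume_nl = 0.85)
  expect_equal(r$lambda, -log(0.9), tolerance = 1e-12)
  expect_equal(r$concentration, -log(0.9) / 0.00085, tolerance = 1e-9)
  expect_equal(round(r$concentration, 2), 123.95)
  expect_true(r$ci_low < r$concentration && r$concentration < r$ci_high)
  # zero positives: zero estimate with a one-sided upper bound
  r0 <- ddpcr_concentration(0, 10000)
  expect_equal(r0$concentration, 0)
  expect_gt(r0$ci_high, 0)
  # CI width is monotone decreasing in droplet count at fixed fraction
  w <- vapply(c(1e3, 1e4, 1e5), function(n) {
    ci <- ddpcr_concentration(round(0.1 * n), n)
    ci$ci_high - ci$ci_low
  }, numeric(1))
  expect_true(all(diff(w) < 0))
  expect_error(ddpcr_concentration(100, 100), "saturated")
})

test_that("ddPCR copy number is twice the target/reference ratio", {
  well <- function(pos, tot = 10000, v = 0.85) {
    list(positives = pos, total = tot, droplet_volume_nl = v)
  }
  # equal fractions -> CN 2
  expect_equal(ddpcr_copy_number(well(1900), well(1900))$cn_estimate, 2)
  # lambda_target = lambda_ref / 2 exactly: p_t = 0.10, p_r = 0.19
  r1 <- ddpcr_copy_number(well(1000), well(1900))
  expect_equal(r1$cn_estimate, 1, tolerance = 1e-12)
  expect_equal(r1$cn_integer, 1L)
  # shared droplet volume cancels out of the estimate
  r_a <- ddpcr_copy_number(well(1500), well(1000), "s")
  r_b <- ddpcr_copy_number(well(1500, v = 0.5), well(1000, v = 0.5), "s")
  expect_equal(r_a$cn_estimate, r_b$cn_estimate)
  # zero target positives -> CN 0; zero reference errors
  expect_equal(ddpcr_copy_number(well(0), well(1900))$cn_integer, 0L)
  expect_error(ddpcr_copy_number(well(1000), well(0)), "zero")
})

test_that("single-well CI covers a high-resolution droplet simulation", {
  set.seed(101)
  for (lam in c(0.01, 0.1, 0.5, 1)) {
    n <- 1e6
    pos <- rbinom(1, n, 1 - exp(-lam))
    est <- ddpcr_concentration(pos, n)
    truth <- lam / 0.00085
    expect_true(est$ci_low <= truth && truth <= est$ci_high)
  }
})

test_that("assay callers recover planted integer copy numbers", {
  set.seed(202)
  true_cn <- sample(0:4, 200, replace = TRUE)
  names(true_cn) <- sprintf("S%03d", seq_along(true_cn))
  # qPCR route at default replicate noise
  plate <- simulate_qpcr_plate(c(CAL = 2, true_cn))
  calls_q <- qpcr_call_plate(plate, "CAL")
  acc_q <- mean(calls_q$cn_integer == true_cn[calls_q$sample_id],
                na.rm = FALSE)
  expect_gte(acc_q, 0.99)
  # ddPCR route at the default well size
  wells <- simulate_ddpcr_well(true_cn)
  calls_d <- ddpcr_call_wells(wells)
  acc_d <- mean(calls_d$cn_integer == true_cn[calls_d$sample_id])
  expect_gte(acc_d, 0.99)
})

test_that("the diploid internal-control sample gates a run", {
  run <- data.frame(sample_id = c("REF", "REF", "s1"),
                    locus_id = c("target", "reference", "target"),
                    cn_integer = c(2L, 2L, 1L), stringsAsFactors = FALSE)
  expect_true(reference_sample_check(run, "REF")$pass)
  run_bad <- run
  run_bad$cn_integer[1] <- 1L
  expect_false(reference_sample_check(run_bad, "REF")$pass)
  expect_false(reference_sample_check(run, "GHOST")$pass)
})
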
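test_that("cohort generation is reproducible under a fixed seed", {
  cfg <- simulation_config(n_cases = 6, n_controls = 10, seed = 42,
                           mean_calls_case = 8, mean_calls_control = 8,
                           n_pool = 50)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$segments_caller1, b$segments_caller1)
  expect_identical(a$segments_caller2, b$segments_caller2)
  expect_identical(a$samples, b$samples)
  expect_identical(a$ground_truth$rare_segments, b$ground_truth$rare_segments)
})

test_that("risk-locus genotype planting inverts odds correctly", {
  spec <- risk_locus_spec("L", "1", 1e6, 1.1e6,
                          del_freq_control = 0.10, dup_freq_control = 0.20,
                          target_or_del = 3.6, target_or_dup = 0.2)
  # closed-form case probabilities: odds 0.1111*3.6 = 0.4 -> 0.2857;
  # odds 0.25*0.2 = 0.05 -> 0.0476
  g <- genotype_risk_loci(spec, 2e5, 2e5, seed = 9)
  p_del_case <- mean(g$genotype[g$group == "case"] == "del")
  p_dup_case <- mean(g$genotype[g$group == "case"] == "dup")
  expect_lt(abs(p_del_case - 0.2857143), 0.005)
  expect_lt(abs(p_dup_case - 0.04761905), 0.003)
  # Monte-Carlo carrier OR close to the planted value
  or_hat <- function(class) {
    pc <- mean(g$genotype[g$group == "case"] == class)
    pk <- mean(g$genotype[g$group == "control"] == class)
    (pc / (1 - pc)) / (pk / (1 - pk))
  }
  expect_lt(abs(or_hat("del") - 3.6), 0.15)
  expect_lt(abs(or_hat("dup") - 0.2), 0.02)
  # a neutral OR leaves case frequency at the control frequency
  g0 <- genotype_risk_loci(risk_locus_spec("N", "1", 1, 100,
                                           del_freq_control = 0.10,
                                           target_or_del = 1),
                           1e5, 1e5, seed = 10)
  expect_lt(abs(mean(g0$genotype[g0$group == "case"] == "del") - 0.10),
            0.01)
  # infeasible OR/frequency combinations error
  expect_error(genotype_risk_loci(
    risk_locus_spec("X", "1", 1, 100, del_freq_control = 0.45,
                    dup_freq_control = 0.45, target_or_del = 40,
                    target_or_dup = 40), 10, 10), "infeasible")
})

test_that("joint-category planting recovers target odds ratios", {
  p <- c(diploid_both = 0.70, del_A_only = 0.10, del_B_only = 0.05,
         del_both = 0.05, dup_A_only = 0.05, dup_B_only = 0.05)
  or <- c(diploid_both = 1, del_A_only = 3.6, del_B_only = 1.0,
          del_both = 5.9, dup_A_only = 0.2, dup_B_only = 0.2)
  g <- plant_joint_genotypes(1e5, 1e5, p, or, seed = 5)
  emp_or <- function(cat) {
    qc <- mean(g$category[g$group == "case"] == cat) /
      mean(g$category[g$group == "case"] == "diploid_both")
    pk <- mean(g$category[g$group == "control"] == cat) /
      mean(g$category[g$group == "control"] == "diploid_both")
    qc / pk
  }
  for (cat in setdiff(names(or), "diploid_both")) {
    expect_lt(abs(log(emp_or(cat)) - log(or[[cat]])), 0.12)
  }
})

test_that("call composition follows configured loss fraction and sizes", {
  cfg <- simulation_config(n_cases = 40, n_controls = 40, seed = 8,
                           mean_calls_case = 15, mean_calls_control = 15,
                           risk_loci = list())
  co <- simulate_cohort(cfg)
  seg <- co$segments_caller1
  case_ids <- co$samples$sample_id[co$samples$group == "case"]
  is_case <- seg$sample_id %in% case_ids
  expect_lt(abs(mean(seg$cnv_type[is_case] == "loss") - 0.76), 0.05)
  expect_lt(abs(mean(seg$cnv_type[!is_case] == "loss") - 0.62), 0.05)
  # deletions smaller than duplications on the log scale
  lsize <- log(seg$end - seg$start + 1)
  expect_lt(mean(lsize[seg$cnv_type == "loss"]),
            mean(lsize[seg$cnv_type == "gain"]))
  # X chromosome carries the highest call count
  tab <- table(seg$chrom)
  expect_equal(names(which.max(tab)), "X")
  # secondary caller recall of primary calls near the concordance setting
  k <- function(df) paste(df$sample_id, df$chrom, df$start, df$cnv_type)
  recall <- mean(k(seg) %in% k(co$segments_caller2))
  expect_lt(abs(recall - cfg$caller2_concordance), 0.04)
})

test_that("qPCR plate simulation encodes copy number as Ct shifts", {
  cn <- c(A = 2, B = 1, C = 4, D = 0)
  plate <- simulate_qpcr_plate(cn, noise_sd = 0, seed = 1)
  dct <- function(id) {
    t <- plate[plate$sample_id == id & plate$gene_role == "target",
               c("ct1", "ct2", "ct3")]
    r <- plate[plate$sample_id == id & plate$gene_role == "reference",
               c("ct1", "ct2", "ct3")]
    mean(as.numeric(t)) - mean(as.numeric(r))
  }
  expect_equal(dct("A"), 0)        # diploid: target == reference
  expect_equal(dct("B"), 1)        # one copy: one cycle late
  expect_equal(dct("C"), -1)       # four copies: one cycle early
  expect_true(all(is.na(
    plate[plate$sample_id == "D" & plate$gene_role == "target",
          c("ct1", "ct2", "ct3")])))  # CN 0: no amplification
})

test_that("ddPCR well simulation follows Poisson droplet occupancy", {
  w0 <- simulate_ddpcr_well(c(S = 0), droplets = 5000, seed = 2)
  expect_equal(w0$positives[w0$gene_role == "target"], 0L)
  # planted lambda_ref = 0.2107 (p_ref = 0.19) at CN 1 gives expected
  # target positive fraction 1 - exp(-0.10535) = 0.1000
  set.seed(3)
  w1 <- simulate_ddpcr_well(c(S = 1), droplets = 2e5,
                            ref_copies_per_droplet = 0.2107)
  p_t <- w1$positives[w1$gene_role == "target"] / 2e5
  expect_lt(abs(p_t - 0.100), 0.004)
  # diploid: equal positive fractions in expectation
  set.seed(4)
  w2 <- simulate_ddpcr_well(c(S = 2), droplets = 2e5,
                            ref_copies_per_droplet = 0.5)
  expect_lt(abs(diff(w2$positives)) / 2e5, 0.01)
})
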
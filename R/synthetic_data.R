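# Synthetic admixed case-control cohort generator. Every downstream stage
# (burden, CNVR, rare pipeline, association, assay calling) can be exercised
# against the ground truth this module records.

#' GRCh37 canonical chromosome lengths
#'
#' Named vector of chromosome lengths (bp) for autosomes 1-22 and X,
#' GRCh37/hg19 assembly.
#'
#' @return named numeric vector.
#' @export
grch37_chrom_lengths <- function() {
  c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566, X = 155270560)
}

#' Specify a planted risk locus
#'
#' A two-allele-class copy-number risk locus: carriers of a whole-locus
#' deletion or duplication are planted at stated control frequencies, with
#' case frequencies derived from target per-class odds ratios (carrying the
#' class vs diploid, cases relative to controls).
#'
#' @param locus_id label.
#' @param chrom,start,end locus interval (1-based inclusive).
#' @param del_freq_control,dup_freq_control control carrier frequencies in
#'   `[0, 1)`, with `del + dup < 1`.
#' @param target_or_del,target_or_dup positive odds ratios.
#' @return list of class `risk_locus_spec`.
#' @export
risk_locus_spec <- function(locus_id, chrom, start, end,
                            del_freq_control = 0.10,
                            dup_freq_control = 0.10,
                            target_or_del = 1, target_or_dup = 1) {
  stopifnot(del_freq_control >= 0, dup_freq_control >= 0,
            del_freq_control + dup_freq_control < 1,
            target_or_del > 0, target_or_dup > 0)
  structure(list(locus_id = as.character(locus_id),
                 chrom = normalize_chrom(chrom),
                 start = as.numeric(start), end = as.numeric(end),
                 del_freq_control = del_freq_control,
                 dup_freq_control = dup_freq_control,
                 target_or_del = target_or_del,
                 target_or_dup = target_or_dup),
            class = "risk_locus_spec")
}

default_risk_loci <- function() {
  # Whole-gene analogues of the FCGR3B (chr1) and ADAM3A (chr8) multi-allelic
  # CNV loci; control carrier frequencies are simulation assumptions.
  list(
    risk_locus_spec("FCGR3B_like", "1", 161592986, 161601753,
                    del_freq_control = 0.10, dup_freq_control = 0.10,
                    target_or_del = 3.6, target_or_dup = 0.2),
    risk_locus_spec("ADAM3A_like", "8", 39306235, 39380526,
                    del_freq_control = 0.10, dup_freq_control = 0.10,
                    target_or_del = 1.0, target_or_dup = 0.2)
  )
}

#' Simulation configuration
#'
#' Defaults reproduce the structure of the array-screen cohort: 23 cases
#' and 110 controls; negative-binomial per-sample call counts with means 19
#' (cases) and 24 (controls); losses outnumbering gains (76% of case calls,
#' 62% of control calls); lognormal sizes with mean deletion size about
#' 3.6x smaller than duplications; X-chromosome call enrichment; two
#' planted risk loci.
#'
#' @param n_cases,n_controls cohort sizes (>= 1).
#' @param seed integer RNG seed.
#' @param mean_calls_case,mean_calls_control negative-binomial means.
#' @param call_dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param del_fraction_case,del_fraction_control probability a call is a
#'   loss, per group.
#' @param del_size_logmean,dup_size_logmean,size_logsd lognormal size
#'   parameters (log-bp).
#' @param x_enrichment multiplier on the X chromosome's length weight when
#'   assigning calls to chromosomes.
#' @param risk_loci list of [risk_locus_spec()] objects.
#' @param panel_overlap_fraction fraction of common-pool loci placed in the
#'   population-frequency panel (the remainder go to the known-variant
#'   panel, plus a shared overlap).
#' @param caller2_concordance probability a primary-caller segment is
#'   replicated by the secondary caller.
#' @param ancestry_dirichlet Dirichlet concentration for (afr, eur, amr)
#'   admixture proportions.
#' @param n_pool number of shared polymorphic CNV loci in the population.
#' @param pool_fraction probability a call is drawn from the shared pool
#'   (the remainder are private to one subject).
#' @param caller2_noise_mean mean count of secondary-caller-private calls
#'   per sample.
#' @param female_fraction_case,female_fraction_control probability a
#'   subject is female.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_cases = 23, n_controls = 110, seed = 1L,
                              mean_calls_case = 19, mean_calls_control = 24,
                              call_dispersion = 5,
                              del_fraction_case = 0.76,
                              del_fraction_control = 0.62,
                              del_size_logmean = log(20e3),
                              dup_size_logmean = log(70e3),
                              size_logsd = 0.9,
                              x_enrichment = 6,
                              risk_loci = default_risk_loci(),
                              panel_overlap_fraction = 0.6,
                              caller2_concordance = 0.8,
                              ancestry_dirichlet = c(2, 7, 1),
                              n_pool = 300, pool_fraction = 0.85,
                              caller2_noise_mean = 2,
                              female_fraction_case = 0.9,
                              female_fraction_control = 0.5) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_cases >= 1, cfg$n_controls >= 1,
            cfg$mean_calls_case > 0, cfg$mean_calls_control > 0,
            cfg$call_dispersion > 0,
            cfg$del_fraction_case > 0, cfg$del_fraction_case < 1,
            cfg$del_fraction_control > 0, cfg$del_fraction_control < 1,
            cfg$size_logsd > 0, cfg$x_enrichment > 0,
            cfg$panel_overlap_fraction >= 0, cfg$panel_overlap_fraction <= 1,
            cfg$caller2_concordance >= 0, cfg$caller2_concordance <= 1,
            all(cfg$ancestry_dirichlet > 0),
            cfg$pool_fraction >= 0, cfg$pool_fraction <= 1)
  class(cfg) <- "simulation_config"
  cfg
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              ncol = length(alpha), byrow = TRUE)
  g / rowSums(g)
}

# Chromosome sampler: proportional to GRCh37 length, X weight multiplied.
sample_chrom <- function(n, x_enrichment) {
  len <- grch37_chrom_lengths()
  w <- len
  w["X"] <- w["X"] * x_enrichment
  sample(names(len), n, replace = TRUE, prob = w)
}

# Mutable occupied-interval tracker ensuring all placed intervals are
# pairwise disjoint, so interval-overlap matching coincides with locus
# identity in the generated data.
new_tracker <- function() {
  env <- new.env(parent = emptyenv())
  env$occ <- list()
  env
}

tracker_add <- function(trk, chrom, start, end) {
  cur <- trk$occ[[chrom]]
  r <- IRanges::IRanges(start, end)
  trk$occ[[chrom]] <- if (is.null(cur)) r else c(cur, r)
  invisible(NULL)
}

tracker_free <- function(trk, chrom, start, end) {
  cur <- trk$occ[[chrom]]
  if (is.null(cur)) return(TRUE)
  length(IRanges::findOverlaps(IRanges::IRanges(start, end), cur)) == 0
}

# Place `n` non-overlapping intervals of the given widths; rejection
# sampling over uniform starts (genome occupancy stays low at the scales
# simulated here).
place_intervals <- function(trk, chroms, widths, max_tries = 500) {
  len <- grch37_chrom_lengths()
  n <- length(chroms)
  start <- numeric(n)
  # cap at 1 Mb: keeps genome occupancy low enough for disjoint placement
  # and matches the size range of array-called CNVs
  widths <- pmin(widths, 1e6)
  for (i in seq_len(n)) {
    w <- min(widths[i], len[[chroms[i]]] - 2)
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      s <- sample.int(len[[chroms[i]]] - w, 1)
      if (tracker_free(trk, chroms[i], s, s + w - 1)) {
        tracker_add(trk, chroms[i], s, s + w - 1)
        start[i] <- s
        widths[i] <- w
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place interval on chromosome ", chroms[i],
                      " after ", max_tries, " tries", call. = FALSE)
  }
  data.frame(chrom = chroms, start = start, end = start + widths - 1)
}

#' Plant per-sample genotypes at one risk locus
#'
#' Control genotypes are drawn at the stated carrier frequencies. Case
#' carrier probabilities are obtained by odds inversion: for each class,
#' `odds_case = odds_control * target_or`, `p_case = odds_case / (1 +
#' odds_case)`, with the diploid class as remainder. Infeasible
#' combinations (case probabilities summing to >= 1) error.
#'
#' @param spec a [risk_locus_spec()].
#' @param n_cases,n_controls group sizes.
#' @param seed optional RNG seed.
#' @return data.frame with columns `group` (`case` rows first) and
#'   `genotype` (`del`/`diploid`/`dup`).
#' @export
genotype_risk_loci <- function(spec, n_cases, n_controls, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  odds_inv <- function(p, or) {
    if (p == 0) return(0)
    o <- p / (1 - p) * or
    o / (1 + o)
  }
  p_del_case <- odds_inv(spec$del_freq_control, spec$target_or_del)
  p_dup_case <- odds_inv(spec$dup_freq_control, spec$target_or_dup)
  if (p_del_case + p_dup_case >= 1) {
    stop("infeasible OR/frequency combination at locus ", spec$locus_id,
         ": case carrier probabilities sum to >= 1", call. = FALSE)
  }
  draw <- function(n, p_del, p_dup) {
    sample(c("del", "dup", "diploid"), n, replace = TRUE,
           prob = c(p_del, p_dup, 1 - p_del - p_dup))
  }
  data.frame(
    group = c(rep("case", n_cases), rep("control", n_controls)),
    genotype = c(draw(n_cases, p_del_case, p_dup_case),
                 draw(n_controls, spec$del_freq_control,
                      spec$dup_freq_control)),
    stringsAsFactors = FALSE
  )
}

#' Plant joint two-locus genotype categories
#'
#' Draws each subject's joint genotype category from a multinomial whose
#' case weights are the control probabilities multiplied by the target
#' category odds ratios and renormalized, so that the dummy-coded logistic
#' model's category odds ratios (relative to the reference category) equal
#' the targets in expectation.
#'
#' @param n_cases,n_controls group sizes.
#' @param p_control named probability vector over categories (must include
#'   the reference category and sum to 1).
#' @param target_or named odds-ratio vector over the same categories
#'   (reference = 1).
#' @param reference reference category name.
#' @param seed optional RNG seed.
#' @return data.frame with `group` and `category`.
#' @export
plant_joint_genotypes <- function(n_cases, n_controls, p_control, target_or,
                                  reference = "diploid_both", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(abs(sum(p_control) - 1) < 1e-8,
            setequal(names(p_control), names(target_or)),
            reference %in% names(p_control))
  target_or <- target_or[names(p_control)]
  w <- p_control * target_or / target_or[[reference]]
  q_case <- w / sum(w)
  data.frame(
    group = c(rep("case", n_cases), rep("control", n_controls)),
    category = c(sample(names(p_control), n_cases, TRUE, prob = q_case),
                 sample(names(p_control), n_controls, TRUE,
                        prob = p_control)),
    stringsAsFactors = FALSE
  )
}

#' Simulate an admixed case-control CNV cohort
#'
#' Generates a sample manifest, primary- and secondary-caller CNV call
#' sets, reference panels (population-frequency and known-variant), and
#' ground truth for every downstream analysis stage.
#'
#' Calls are drawn per sample (negative-binomial counts) either from a
#' shared pool of polymorphic CNV loci (with population frequencies) or as
#' subject-private segments; all generated intervals are pairwise
#' non-overlapping so that interval matching coincides with locus identity.
#' Risk-locus carrier segments are injected per planted genotype. The
#' population-frequency and known-variant panels jointly cover the entire
#' shared pool, and a segment's ground-truth rarity label is: population
#' frequency < 1%, carried by no control, absent from the known-variant
#' panel, and replicated by the secondary caller.
#'
#' @param config a [simulation_config()].
#' @return list with elements `samples` (manifest), `segments_caller1`,
#'   `segments_caller2`, `panels` (list `frequency`, `known`), and
#'   `ground_truth` (list `genotypes`, `rare_segments`, `planted_or`,
#'   `pool`).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_cases < 1 || config$n_controls < 1) {
    stop("zero cohort size", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  ids <- c(sprintf("SLE%03d", seq_len(config$n_cases)),
           sprintf("BRZ%03d", seq_len(config$n_controls)))
  group <- c(rep("case", config$n_cases), rep("control", config$n_controls))
  sex <- ifelse(stats::runif(n) < ifelse(group == "case",
                                         config$female_fraction_case,
                                         config$female_fraction_control),
                "F", "M")
  anc <- rdirichlet(n, config$ancestry_dirichlet)
  samples <- sample_manifest(ids, group, sex, anc[, 1], anc[, 2], anc[, 3])

  trk <- new_tracker()
  for (rl in config$risk_loci) tracker_add(trk, rl$chrom, rl$start, rl$end)

  # Shared polymorphic pool: ~69% losses (weighted mean of the two group
  # loss fractions), log-uniform population frequencies spanning rare to
  # common, lognormal sizes.
  p_loss_pool <- mean(c(config$del_fraction_case, config$del_fraction_control))
  pool_type <- ifelse(stats::runif(config$n_pool) < p_loss_pool,
                      "loss", "gain")
  pool_freq <- exp(stats::runif(config$n_pool, log(0.002), log(0.4)))
  pool_w <- round(stats::rlnorm(
    config$n_pool,
    ifelse(pool_type == "loss", config$del_size_logmean,
           config$dup_size_logmean),
    config$size_logsd)) + 1
  pool <- place_intervals(trk, sample_chrom(config$n_pool,
                                            config$x_enrichment), pool_w)
  pool$cnv_type <- pool_type
  pool$frequency <- pool_freq
  pool$locus <- seq_len(config$n_pool)

  seg <- list()   # accumulating caller1 rows
  meta <- list()  # per-row provenance for ground truth
  for (i in seq_len(n)) {
    mu <- if (group[i] == "case") config$mean_calls_case else
      config$mean_calls_control
    p_loss <- if (group[i] == "case") config$del_fraction_case else
      config$del_fraction_control
    n_calls <- stats::rnbinom(1, mu = mu, size = config$call_dispersion)
    if (n_calls == 0) next
    # call type follows the group's loss fraction; pool loci are then
    # drawn conditional on type so the fraction is preserved
    call_type <- ifelse(stats::runif(n_calls) < p_loss, "loss", "gain")
    is_common <- stats::runif(n_calls) < config$pool_fraction
    rows <- NULL
    for (ty in c("loss", "gain")) {
      pool_ty <- which(pool$cnv_type == ty)
      k <- min(sum(is_common & call_type == ty), length(pool_ty))
      if (k > 0) {
        loci <- pool_ty[sample.int(length(pool_ty), k,
                                   prob = pool_freq[pool_ty])]
        rows <- rbind(rows, data.frame(
          chrom = pool$chrom[loci], start = pool$start[loci],
          end = pool$end[loci], cnv_type = pool$cnv_type[loci],
          locus = pool$locus[loci], stringsAsFactors = FALSE))
      }
      is_common[which(is_common & call_type == ty)[seq_len(
        max(0, sum(is_common & call_type == ty) - k))]] <- FALSE
    }
    k_priv <- n_calls - nrow(if (is.null(rows)) data.frame() else rows)
    if (k_priv > 0) {
      ptype <- call_type[!is_common]
      pw <- round(stats::rlnorm(
        k_priv,
        ifelse(ptype == "loss", config$del_size_logmean,
               config$dup_size_logmean),
        config$size_logsd)) + 1
      priv <- place_intervals(trk, sample_chrom(k_priv, config$x_enrichment),
                              pw)
      priv$cnv_type <- ptype
      priv$locus <- NA_integer_
      rows <- rbind(rows, priv)
    }
    rows$sample_id <- ids[i]
    seg[[length(seg) + 1]] <- rows
  }
  seg <- do.call(rbind, seg)

  # Risk-locus carrier segments per planted genotype.
  geno <- list()
  for (rl in config$risk_loci) {
    g <- genotype_risk_loci(rl, config$n_cases, config$n_controls)
    geno[[rl$locus_id]] <- data.frame(
      sample_id = ids, locus_id = rl$locus_id, group = group,
      genotype = g$genotype, stringsAsFactors = FALSE)
    carr <- which(g$genotype != "diploid")
    if (length(carr)) {
      seg <- rbind(seg, data.frame(
        chrom = rl$chrom, start = rl$start, end = rl$end,
        cnv_type = ifelse(g$genotype[carr] == "del", "loss", "gain"),
        locus = NA_integer_, sample_id = ids[carr],
        stringsAsFactors = FALSE))
    }
  }
  geno <- do.call(rbind, geno)
  rownames(geno) <- NULL

  width <- seg$end - seg$start + 1
  cn <- ifelse(seg$cnv_type == "loss",
               ifelse(stats::runif(nrow(seg)) < 0.1, 0L, 1L),
               ifelse(stats::runif(nrow(seg)) < 0.1, 4L, 3L))
  n_probes <- pmax(1L, stats::rpois(nrow(seg), width / 1000))
  segments_caller1 <- cnv_segments(seg$sample_id, seg$chrom, seg$start,
                                   seg$end, cn, n_probes, "primary_caller")
  segments_caller1$.locus <- seg$locus

  # Secondary caller: replicate caller1 calls at the concordance rate, plus
  # caller-private noise in unoccupied genome.
  replicated <- stats::runif(nrow(segments_caller1)) < config$caller2_concordance
  c2 <- segments_caller1[replicated, , drop = FALSE]
  c2$caller_id <- "secondary_caller"
  c2$.locus <- NULL
  n_noise <- stats::rpois(n, config$caller2_noise_mean)
  if (sum(n_noise) > 0) {
    ntype <- ifelse(stats::runif(sum(n_noise)) < p_loss_pool, "loss", "gain")
    nw <- round(stats::rlnorm(
      sum(n_noise),
      ifelse(ntype == "loss", config$del_size_logmean,
             config$dup_size_logmean),
      config$size_logsd)) + 1
    npos <- place_intervals(trk, sample_chrom(sum(n_noise),
                                              config$x_enrichment), nw)
    noise <- cnv_segments(rep(ids, n_noise), npos$chrom, npos$start,
                          npos$end, ifelse(ntype == "loss", 1L, 3L),
                          NA_integer_, "secondary_caller")
    c2 <- rbind(c2, noise)
  }
  rownames(c2) <- NULL
  segments_caller2 <- validate_segments(c2)

  # Panels: every pool locus lands in the frequency panel, the known panel,
  # or both; risk loci enter the frequency panel at their (common) carrier
  # frequencies.
  u <- stats::runif(config$n_pool)
  in_freq <- u < config$panel_overlap_fraction
  in_known <- !in_freq | stats::runif(config$n_pool) < 0.3
  freq_rows <- pool[in_freq, c("chrom", "start", "end", "cnv_type",
                               "frequency")]
  for (rl in config$risk_loci) {
    freq_rows <- rbind(freq_rows, data.frame(
      chrom = rep(rl$chrom, 2), start = rep(rl$start, 2),
      end = rep(rl$end, 2), cnv_type = c("loss", "gain"),
      frequency = c(max(rl$del_freq_control, 0.011),
                    max(rl$dup_freq_control, 0.011))))
  }
  panel_freq <- reference_panel(freq_rows$chrom, freq_rows$start,
                                freq_rows$end, freq_rows$cnv_type,
                                freq_rows$frequency, "population_frequency")
  kp <- pool[in_known, , drop = FALSE]
  panel_known <- reference_panel(kp$chrom, kp$start, kp$end, kp$cnv_type,
                                 NA_real_, "known_variants")

  # Ground-truth rarity for primary-caller case segments.
  is_case_row <- segments_caller1$sample_id %in% ids[group == "case"]
  ctrl_rows <- segments_caller1[!is_case_row, , drop = FALSE]
  ctrl_loci <- unique(ctrl_rows$.locus[!is.na(ctrl_rows$.locus)])
  # risk-locus intervals carried by any control, keyed by chrom:start:type
  ctrl_keys <- unique(paste(ctrl_rows$chrom, ctrl_rows$start,
                            ctrl_rows$cnv_type))
  case_rows <- segments_caller1[is_case_row, , drop = FALSE]
  case_rep <- replicated[is_case_row]
  locus_idx <- case_rows$.locus
  popfreq <- ifelse(is.na(locus_idx), 0, pool_freq[locus_idx])
  in_known_lab <- !is.na(locus_idx) & locus_idx %in% pool$locus[in_known]
  ctrl_carried <- (!is.na(locus_idx) & locus_idx %in% ctrl_loci) |
    (is.na(locus_idx) &
       paste(case_rows$chrom, case_rows$start, case_rows$cnv_type) %in%
       ctrl_keys)
  rare <- popfreq < 0.01 & !ctrl_carried & !in_known_lab & case_rep
  rare_segments <- data.frame(
    sample_id = case_rows$sample_id, chrom = case_rows$chrom,
    start = case_rows$start, end = case_rows$end,
    cnv_type = case_rows$cnv_type, pop_frequency = popfreq,
    replicated = case_rep, rare = rare, stringsAsFactors = FALSE)

  planted_or <- do.call(rbind, lapply(config$risk_loci, function(rl) {
    data.frame(locus_id = rl$locus_id, target_or_del = rl$target_or_del,
               target_or_dup = rl$target_or_dup, stringsAsFactors = FALSE)
  }))

  segments_caller1$.locus <- NULL
  list(samples = samples,
       segments_caller1 = validate_segments(segments_caller1),
       segments_caller2 = segments_caller2,
       panels = list(frequency = panel_freq, known = panel_known),
       ground_truth = list(genotypes = geno, rare_segments = rare_segments,
                           planted_or = planted_or, pool = pool))
}

#' Simulate a qPCR plate of Ct triplicates
#'
#' Target-gene Ct values shift by one cycle per copy-number halving
#' relative to the reference gene (perfect amplification efficiency by
#' default): `Ct_target = ct_ref_mean - log(cn/2) / log(efficiency) +
#' noise` per replicate. Copy number 0 yields the non-amplification
#' sentinel (`NA`).
#'
#' @param true_cn named non-negative integer vector of true copy numbers
#'   (names = sample ids).
#' @param efficiency amplification efficiency (fold per cycle; 2 = perfect
#'   doubling).
#' @param ct_ref_mean mean reference-gene Ct (cycles).
#' @param noise_sd per-replicate Gaussian Ct noise (cycles).
#' @param seed optional RNG seed.
#' @return data.frame with columns `sample_id, gene_role, ct1, ct2, ct3`.
#' @export
simulate_qpcr_plate <- function(true_cn, efficiency = 2, ct_ref_mean = 25,
                                noise_sd = 0.03, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(true_cn >= 0), noise_sd >= 0, efficiency > 1)
  ids <- names(true_cn)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(true_cn))
  one <- function(mu) mu + stats::rnorm(3, 0, noise_sd)
  rows <- lapply(seq_along(true_cn), function(i) {
    ref <- one(ct_ref_mean)
    if (true_cn[i] == 0) {
      tgt <- c(NA_real_, NA_real_, NA_real_)
    } else {
      tgt <- one(ct_ref_mean - log(true_cn[i] / 2) / log(efficiency))
    }
    data.frame(sample_id = rep(ids[i], 2),
               gene_role = c("target", "reference"),
               ct1 = c(tgt[1], ref[1]), ct2 = c(tgt[2], ref[2]),
               ct3 = c(tgt[3], ref[3]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a droplet digital PCR well pair
#'
#' Droplet occupancy is Poisson: a droplet is positive with probability
#' `1 - exp(-lambda)`, where the reference gene has `lambda =
#' ref_copies_per_droplet` and the target `lambda * true_cn / 2`.
#'
#' @param true_cn named non-negative numeric vector of true copy numbers.
#' @param droplets accepted droplets per well (> 0).
#' @param ref_copies_per_droplet mean reference copies per droplet (> 0).
#' @param droplet_volume_nl droplet volume in nL.
#' @param seed optional RNG seed.
#' @return data.frame with columns `sample_id, gene_role, positives, total,
#'   droplet_volume_nl`.
#' @export
simulate_ddpcr_well <- function(true_cn, droplets = 15000,
                                ref_copies_per_droplet = 1.0,
                                droplet_volume_nl = 0.85, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(droplets > 0, ref_copies_per_droplet > 0, all(true_cn >= 0))
  ids <- names(true_cn)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(true_cn))
  rows <- lapply(seq_along(true_cn), function(i) {
    p_ref <- 1 - exp(-ref_copies_per_droplet)
    p_tgt <- 1 - exp(-ref_copies_per_droplet * true_cn[i] / 2)
    data.frame(sample_id = rep(ids[i], 2),
               gene_role = c("target", "reference"),
               positives = c(stats::rbinom(1, droplets, p_tgt),
                             stats::rbinom(1, droplets, p_ref)),
               total = rep(as.integer(droplets), 2),
               droplet_volume_nl = rep(droplet_volume_nl, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
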
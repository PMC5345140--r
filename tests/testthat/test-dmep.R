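## fixed 6-sample design used by the hand-built fixtures
.mk_table <- function(pooled_means, reps = 3L, promoter = "prom1",
                      case_shift = 0) {
  samples <- c(paste0("C", 1:reps), paste0("D", 1:reps))
  groups <- setNames(rep(c("control", "case"), each = reps), samples)
  n <- length(pooled_means)
  df <- data.frame(probe_id = sprintf("p%d", 1:n), promoter_id = promoter,
                   chrom = "chr1", start = (0:(n - 1)) * 100L,
                   end = (1:n) * 100L)
  for (s in samples)
    df[[s]] <- pooled_means + if (startsWith(s, "D")) case_shift else 0
  probe_table(df, groups)
}

test_that("peak assembly finds maximal above-threshold runs per promoter", {
  tab <- .mk_table(c(0.5, 0.6, -0.1, 0.7))
  pk <- assemble_peaks(tab, dmep_params(probe_call_threshold = 0.2,
                                        min_probes_per_peak = 2L))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$probe_idx[[1]], 1:2)

  ## all below threshold: nothing
  pk0 <- assemble_peaks(.mk_table(c(0.1, 0.0, -0.2)))
  expect_equal(nrow(pk0), 0L)

  ## min 1 probe, all above: one peak spanning the whole promoter
  pk1 <- assemble_peaks(.mk_table(c(0.5, 0.6, 0.7)),
                        dmep_params(min_probes_per_peak = 1L))
  expect_equal(nrow(pk1), 1L)
  expect_equal(pk1$probe_idx[[1]], 1:3)

  ## peaks never cross promoter boundaries
  tab2 <- rbind(as.data.frame(.mk_table(c(0.5, 0.5), promoter = "a")),
                within(as.data.frame(.mk_table(c(0.5, 0.5), promoter = "b")), {
                  start <- start + 1000L; end <- end + 1000L
                  probe_id <- paste0(probe_id, "b")
                }))
  tab2 <- probe_table(tab2, attr(tab, "groups"))
  expect_equal(nrow(assemble_peaks(tab2)), 2L)
})

test_that("M' equals the difference of grand means", {
  ## symmetry and closed form
  tab <- .mk_table(c(1, 1), case_shift = 0)
  pk <- assemble_peaks(tab, dmep_params(min_probes_per_peak = 1L))
  expect_equal(m_prime(pk[1, ], tab), 0)

  tab2 <- .mk_table(c(0.25, 0.25, 0.25), case_shift = 0.75)
  pk2 <- assemble_peaks(tab2, dmep_params(min_probes_per_peak = 1L))
  expect_equal(m_prime(pk2[1, ], tab2), 0.75)

  ## random replicate block equals an explicit double-summation oracle
  set.seed(1)
  tab3 <- rand_probe_table(n_prom = 1L, max_probes = 6L, edge_cases = FALSE)
  pk3 <- assemble_peaks(tab3, dmep_params(min_probes_per_peak = 1L,
                                          probe_call_threshold = -Inf))
  g <- attr(tab3, "groups")
  acc_case <- acc_ctrl <- c(0, 0)
  for (r in pk3$probe_idx[[1]]) for (s in names(g)) {
    if (g[[s]] == "case") acc_case <- acc_case + c(tab3[r, s], 1)
    else acc_ctrl <- acc_ctrl + c(tab3[r, s], 1)
  }
  expect_equal(m_prime(pk3[1, ], tab3),
               acc_case[1] / acc_case[2] - acc_ctrl[1] / acc_ctrl[2])
})

test_that("probe CV follows sd/|mean| with the zero-mean degenerate case", {
  expect_equal(probe_cv(c(1, 1, 1)), 0)
  expect_equal(probe_cv(c(1, 2, 3)), 0.5)
  expect_equal(probe_cv(c(-1, 1)), Inf)
  expect_error(probe_cv(1), "2 replicates")
})

test_that("DMEP calling applies the enrichment and CV criteria literally", {
  reps <- 3L
  samples <- c(paste0("C", 1:reps), paste0("D", 1:reps))
  groups <- setNames(rep(c("control", "case"), each = reps), samples)
  mk <- function(ctrl, case) {
    n <- nrow(ctrl)
    df <- data.frame(probe_id = sprintf("p%d", 1:n), promoter_id = "x",
                     chrom = "chr1", start = (0:(n - 1)) * 100L, end = (1:n) * 100L)
    df[paste0("C", 1:reps)] <- ctrl
    df[paste0("D", 1:reps)] <- case
    probe_table(df, groups)
  }
  ## medians (0.35 ctrl, 0.10 case), M' = -0.25, clean CV -> control_higher
  ctrl <- matrix(0.35, 2, 3) + c(-0.01, 0.01)
  case <- matrix(0.10, 2, 3) + c(-0.01, 0.01)
  tab <- mk(ctrl, case)
  cd <- call_dmeps(assemble_peaks(tab, dmep_params(probe_call_threshold = 0)), tab)
  expect_equal(cd$dmep_class, "control_higher")
  expect_equal(cd$m_prime, -0.25)
  expect_true(cd$enrichment_pass && cd$cv_pass)

  ## both medians below 0.3 -> enrichment fail -> none
  tab2 <- mk(matrix(0.2, 2, 3) + c(-0.01, 0.01), matrix(0.2, 2, 3) + c(0.01, -0.01))
  cd2 <- call_dmeps(assemble_peaks(tab2, dmep_params(probe_call_threshold = 0)), tab2)
  expect_equal(cd2$dmep_class, "none")
  expect_false(cd2$enrichment_pass)

  ## only 1 of 4 probes passes CV in one group (fraction 0.25 < 0.5) -> none
  ctrl4 <- matrix(rep(c(0.5, 0.5, 0.5, 0.5), 3), 4, 3)
  ctrl4[2:4, ] <- matrix(c(0.05, 0.9, 0.55), 3, 3, byrow = TRUE)  # CV >> 0.8
  case4 <- matrix(0.6, 4, 3) + seq(-0.01, 0.01, length.out = 3)[col(matrix(0, 4, 3))]
  tab3 <- mk(ctrl4, case4)
  cd3 <- call_dmeps(assemble_peaks(tab3, dmep_params(probe_call_threshold = 0)), tab3)
  expect_lt(cd3$cv_pass_control, 0.5)
  expect_equal(cd3$dmep_class, "none")
  expect_false(cd3$cv_pass)
})

test_that("calls match the brute-force criteria oracle on random promoters", {
  set.seed(99)
  for (rep in 1:6) {
    tab <- rand_probe_table(n_prom = 40L, max_probes = 10L)
    pk <- assemble_peaks(tab)
    cd <- call_dmeps(pk, tab)
    expect_equal(cd$dmep_class, oracle_call_dmeps(pk, tab))
  }
  ## and under non-default parameters, including the one-sided reading
  prm <- dmep_params(median_min = 0.25, cv_max = 0.5, cv_pass_fraction_min = 0.75,
                     m_prime_min = 0.1, one_sided = TRUE)
  tab <- rand_probe_table(n_prom = 40L, max_probes = 10L)
  pk <- assemble_peaks(tab, prm)
  expect_equal(call_dmeps(pk, tab, prm)$dmep_class, oracle_call_dmeps(pk, tab, prm))
})

test_that("swapping group labels negates M' and swaps the class counts", {
  set.seed(5)
  tab <- rand_probe_table(n_prom = 60L)
  cd <- call_dmeps(assemble_peaks(tab), tab)
  tabs <- swap_groups(tab)
  cds <- call_dmeps(assemble_peaks(tabs), tabs)
  expect_equal(cds$m_prime, -cd$m_prime)
  expect_equal(sum(cds$dmep_class == "case_higher"),
               sum(cd$dmep_class == "control_higher"))
  expect_equal(sum(cds$dmep_class == "control_higher"),
               sum(cd$dmep_class == "case_higher"))
})

test_that("tightening thresholds never increases the DMEP count", {
  set.seed(13)
  tab <- rand_probe_table(n_prom = 60L)
  n_dmep <- function(prm) {
    cd <- call_dmeps(assemble_peaks(tab, prm), tab, prm)
    sum(cd$dmep_class != "none")
  }
  base <- dmep_params()
  expect_lte(n_dmep(dmep_params(median_min = 0.5)), n_dmep(base))
  expect_lte(n_dmep(dmep_params(cv_max = 0.4)), n_dmep(base))
  expect_lte(n_dmep(dmep_params(m_prime_min = 0.2)), n_dmep(base))
})

test_that("the DMEP summary counts classes and tests group enrichment", {
  ## zero peaks: zero counts, NA p
  sp0 <- array_sim_spec(n_promoters = 20L, n_probes_total = 160L,
                        methylated_fraction = 0, dmep_fraction = 0, seed = 2L)
  sim0 <- simulate_array(sp0)
  cd0 <- call_dmeps(assemble_peaks(sim0$probes), sim0$probes)
  s0 <- summarize_dmeps(cd0, sim0$probes)
  expect_equal(s0$n_dmep, sum(cd0$dmep_class != "none"))
  if (s0$n_dmep == 0L) expect_true(is.na(s0$t_p))

  ## planted truth with a strong clean effect is recovered as counts
  sp <- array_sim_spec(n_promoters = 600L, n_probes_total = 4800L,
                       methylated_fraction = 0.25, dmep_fraction = 0.25,
                       prop_control_higher = 2 / 3, effect_size = 0.8,
                       probe_noise_sd = 0.1, cv_inflation_fraction = 0,
                       seed = 31L)
  sim <- simulate_array(sp)
  cd <- call_dmeps(assemble_peaks(sim$probes), sim$probes)
  s <- summarize_dmeps(cd, sim$probes)
  truth_counts <- table(sim$truth$class)
  expect_equal(s$n_control_higher, unname(truth_counts["control_higher"]),
               ignore_attr = TRUE)
  expect_equal(s$n_case_higher, unname(truth_counts["case_higher"]),
               ignore_attr = TRUE)
  expect_equal(s$n_total_methylated, nrow(sim$truth))
})
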
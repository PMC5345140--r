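test_that("simulated arrays honour the declared dimensions and determinism", {
  sp <- array_sim_spec(n_promoters = 50L, n_probes_total = 400L, seed = 9L)
  sim <- simulate_array(sp)
  ## ~180,000 / 22,327 = 8 probes per promoter at the default geometry
  expect_equal(nrow(sim$probes), 400L)
  expect_equal(unname(table(sim$probes$promoter_id))[1], 8L, ignore_attr = TRUE)
  expect_equal(array_sim_spec()$n_probes_total %/% array_sim_spec()$n_promoters, 8L)

  ## same seed twice: bit-identical
  sim2 <- simulate_array(sp)
  expect_identical(as.data.frame(sim$probes), as.data.frame(sim2$probes))
  expect_identical(sim$truth, sim2$truth)

  ## no planted signal -> empty truth
  sim0 <- simulate_array(array_sim_spec(n_promoters = 20L, n_probes_total = 160L,
                                        methylated_fraction = 0, dmep_fraction = 0,
                                        seed = 1L))
  expect_equal(nrow(sim0$truth), 0L)

  ## fewer than one probe per promoter is rejected
  expect_error(array_sim_spec(n_promoters = 100L, n_probes_total = 50L),
               "fewer than one probe")
})

test_that("planted group shifts are recoverable from the probe values", {
  sp <- array_sim_spec(n_promoters = 300L, n_probes_total = 2400L,
                       methylated_fraction = 0.2, dmep_fraction = 0.2,
                       effect_size = 0.6, probe_noise_sd = 0.2,
                       cv_inflation_fraction = 0, seed = 21L)
  sim <- simulate_array(sp)
  tr <- sim$truth[sim$truth$class != "none", ]
  g <- attr(sim$probes, "groups")
  vals <- as.matrix(as.data.frame(sim$probes)[, names(g)])
  diffs <- vapply(seq_len(nrow(tr)), function(i) {
    idx <- tr$first_probe[i]:tr$last_probe[i]
    d <- mean(vals[idx, g == "case"]) - mean(vals[idx, g == "control"])
    if (tr$class[i] == "control_higher") -d else d
  }, numeric(1))
  ## mean observed |group difference| ~ effect_size within standard error
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - sp$effect_size), 3 * se + 0.02)
})

test_that("simulated promoter sequences carry their class by construction", {
  ps <- simulate_promoter_sequences(c(HCP = 4L, ICP = 4L, LCP = 4L), seed = 5L)
  expect_equal(nchar(ps$sequences), rep(1800L, 12L), ignore_attr = TRUE)
  cl <- classify_promoters(ps$sequences)
  expect_equal(cl$label, unname(ps$labels))
  ## all-A control is LCP with O/E zero everywhere
  aa <- classify_promoter(strrep("A", 1800L))
  expect_equal(aa$label, "LCP")
  expect_equal(aa$max_oe_window_anywhere$oe, 0)
  ## determinism
  ps2 <- simulate_promoter_sequences(c(4L, 4L, 4L), seed = 5L)
  expect_identical(ps$sequences, ps2$sequences)
})

test_that("bisulfite simulation hits the requested methylation probabilities", {
  ## extreme probabilities, no masking
  m1 <- simulate_bisulfite(5L, 8L, p_meth = 1, p_undetermined = 0, seed = 2L)
  expect_true(all(m1$calls == "M"))
  expect_equal(methylation_ratio(m1), 1)

  ## the two-group crypt design: 68.5% vs 50.8% within binomial error
  bb <- simulate_bisulfite(10L, 16L, p_meth = c(0.685, 0.508), seed = 8L)
  for (nm in c("control", "case")) {
    p <- c(control = 0.685, case = 0.508)[[nm]]
    r <- methylation_ratio(bb[[nm]])
    expect_lt(abs(r - p), 3 * sqrt(p * (1 - p) / 160))
  }
  expect_error(simulate_bisulfite(10L, 0L, p_meth = 0.5), "n_sites")
})

test_that("ChIP peaks land at the exact strand-adjusted offsets", {
  models <- toy_models()
  pk <- simulate_chip_peaks(models, c(gplus = 3011, gminus = -16676))
  ## + strand: summit = tss + offset
  expect_equal(pk$summit[1], models$tss[1] + 3011L)
  ## - strand: genomic summit = tss + |offset| for an upstream peak
  expect_equal(pk$summit[2], models$tss[2] + 16676L)
  expect_equal(nrow(simulate_chip_peaks(models, numeric(0))), 0L)
  ## decoys are far from every gene
  pk2 <- simulate_chip_peaks(models, c(gplus = 0), n_decoys = 2L, seed = 3L)
  expect_true(all(pk2$summit[pk2$name %in% c("decoy_1", "decoy_2")] >
                    max(models$gene_end) + 5e5))
})

test_that("qPCR and luciferase generators recover their truth", {
  ## zero noise: exact closed-form recovery
  q <- simulate_qpcr(c(control = 1, case = 2), noise_sd = 0, seed = 1L)
  f <- ddct_fold(q, reference_condition = "control")
  expect_equal(f$fold[f$condition == "case"], 2)

  ## null truth: folds near 1
  q0 <- simulate_qpcr(c(control = 1, a = 1, b = 1), n_replicates = 8L,
                      noise_sd = 0.1, seed = 4L)
  f0 <- ddct_fold(q0, reference_condition = "control")
  expect_true(all(abs(log2(f0$fold)) < 0.35))

  lf <- simulate_luciferase(c(tab2 = 1.5), n_wells = 4L, cv = 0.1, seed = 6L)
  out <- luciferase_relative(lf)
  ## within 2 SE of truth: log-scale SE ~ cv/sqrt(n) per arm
  expect_lt(abs(out$fold / 1.5 - 1), 2 * 0.1 * sqrt(2 / 4) + 0.05)

  ## reproducible under the same seed
  expect_identical(simulate_luciferase(c(x = 2), seed = 11L),
                   simulate_luciferase(c(x = 2), seed = 11L))
})
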
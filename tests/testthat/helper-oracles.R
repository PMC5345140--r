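# Independent brute-force oracles and fixture builders. These deliberately
# use naive loops / substring scans, separate from the package's vectorized
# implementations.

## random probe table with awkward edge values (ties, zero-mean replicates)
rand_probe_table <- function(n_prom = 10L, max_probes = 10L, reps = 3L,
                             edge_cases = TRUE) {
  samples <- c(paste0("C", seq_len(reps)), paste0("D", seq_len(reps)))
  groups <- setNames(rep(c("control", "case"), each = reps), samples)
  rows <- list()
  pos <- 1000L
  probe <- 0L
  for (p in seq_len(n_prom)) {
    k <- sample.int(max_probes, 1L)
    for (j in seq_len(k)) {
      probe <- probe + 1L
      v <- rnorm(2L * reps, mean = sample(c(0, 0.4, 0.8), 1L), sd = 0.4)
      if (edge_cases && runif(1) < 0.15) v[] <- round(v, 1)       # ties
      if (edge_cases && runif(1) < 0.05) {                        # zero mean
        half <- seq_len(reps)
        v[half] <- c(rep(0.5, reps - 1L), -0.5 * (reps - 1L))
      }
      rows[[probe]] <- c(list(probe_id = sprintf("pr%04d", probe),
                              promoter_id = sprintf("prom%03d", p),
                              chrom = "chr1", start = pos, end = pos + 100L),
                         as.list(setNames(v, samples)))
      pos <- pos + 100L
    }
    pos <- pos + 500L
  }
  df <- do.call(rbind.data.frame, rows)
  probe_table(df, groups)
}

## literal probe-by-probe evaluation of the DMEP filter criteria on each peak
oracle_call_dmeps <- function(peaks, table, params = dmep_params()) {
  groups <- attr(table, "groups")
  ctrl <- names(groups)[groups == "control"]
  case <- names(groups)[groups == "case"]
  cls <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    idx <- peaks$probe_idx[[i]]
    gm_c <- gm_d <- cv_ok_c <- cv_ok_d <- numeric(0)
    all_c <- all_d <- numeric(0)
    for (r in idx) {
      vc <- as.numeric(table[r, ctrl])
      vd <- as.numeric(table[r, case])
      gm_c <- c(gm_c, mean(vc)); gm_d <- c(gm_d, mean(vd))
      all_c <- c(all_c, vc); all_d <- c(all_d, vd)
      cvc <- if (mean(vc) == 0) Inf else sd(vc) / abs(mean(vc))
      cvd <- if (mean(vd) == 0) Inf else sd(vd) / abs(mean(vd))
      cv_ok_c <- c(cv_ok_c, cvc <= params$cv_max)
      cv_ok_d <- c(cv_ok_d, cvd <= params$cv_max)
    }
    mp <- mean(all_d) - mean(all_c)
    med_best <- max(median(gm_c), median(gm_d))
    crit_i <- med_best >= params$median_min &&
      (if (params$one_sided) mp > params$m_prime_min
       else abs(mp) > params$m_prime_min)
    crit_ii <- mean(cv_ok_c) >= params$cv_pass_fraction_min &&
      mean(cv_ok_d) >= params$cv_pass_fraction_min
    cls[i] <- if (crit_i && crit_ii) {
      if (mp > 0) "case_higher" else "control_higher"
    } else "none"
  }
  cls
}

## exhaustive 500-bp substring classification of a promoter sequence
oracle_classify <- function(seq, tss_offset = 1300L, window = 500L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  w <- min(window, n)
  starts <- seq_len(n - w + 1L)
  subs <- substring(seq, starts, starts + w - 1L)
  cnt <- function(ch) nchar(subs) - nchar(gsub(ch, "", subs, fixed = TRUE))
  C <- cnt("C"); G <- cnt("G"); Nn <- cnt("N")
  CG <- vapply(gregexpr("CG", subs, fixed = TRUE),
               function(m) sum(m > 0L), integer(1))
  Leff <- w - Nn
  oe <- ifelse(C > 0L & G > 0L, CG * Leff / (C * G), 0)
  gc <- ifelse(Leff > 0L, (C + G) / Leff, NaN)
  offs <- starts - tss_offset - 1L
  in_core <- offs >= -700L & (offs + w - 1L) <= 200L
  if (w == n) in_core <- rep(TRUE, length(starts))
  if (any(in_core & gc >= 0.55 & oe >= 0.6)) "HCP"
  else if (max(oe) < 0.4) "LCP"
  else "ICP"
}

## random DNA of given length and GC bias, optionally salted with N
rand_dna <- function(n, gc = 0.5, n_frac = 0) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p)
  if (n_frac > 0) x[runif(n) < n_frac] <- "N"
  paste(x, collapse = "")
}

## swap the two groups of a probe table (labels only; data untouched)
swap_groups <- function(table) {
  g <- attr(table, "groups")
  g[] <- ifelse(g == "control", "case", "control")
  probe_table(as.data.frame(table), g)
}

## match called DMEPs against a generator truth table
dmep_recovery <- function(called, truth) {
  called <- called[called$dmep_class != "none", , drop = FALSE]
  tr <- truth[truth$class != "none", , drop = FALSE]
  f <- vapply(called$probe_idx, min, integer(1))
  l <- vapply(called$probe_idx, max, integer(1))
  call_ok <- mapply(function(pr, cl, fi, la) {
    j <- which(tr$promoter_id == pr & tr$class == cl)
    length(j) > 0L && any(tr$first_probe[j] <= la & tr$last_probe[j] >= fi)
  }, called$promoter_id, called$dmep_class, f, l)
  found <- mapply(function(pr, cl, fi, la) {
    j <- which(called$promoter_id == pr & called$dmep_class == cl)
    length(j) > 0L && any(f[j] <= la & l[j] >= fi)
  }, tr$promoter_id, tr$class, tr$first_probe, tr$last_probe)
  list(sensitivity = if (nrow(tr)) mean(found) else NA_real_,
       fdp = if (nrow(called)) mean(!call_ok) else 0,
       n_called = nrow(called))
}

## tiny two-gene model fixture used across chip tests
toy_models <- function() {
  gene_models(data.frame(
    gene_id = c("gplus", "gminus"),
    chrom = "chr1", strand = c("+", "-"),
    gene_start = c(100000L, 900000L),
    gene_end = c(120000L, 960000L),
    exons = I(list(
      rbind(c(100000L, 100500L), c(102800L, 103400L), c(110000L, 112000L)),
      rbind(c(900000L, 902000L), c(950000L, 960000L))
    ))
  ))
}
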
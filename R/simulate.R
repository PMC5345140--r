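## synthetic_data: generators for every input the pipeline consumes, with
## known ground truth. Defaults mirror the study design they emulate:
## a 22,327-promoter tiling array (~180,000 probes, windows -1300..+500 of
## TSS), 3 replicates per group, 14.1% of promoters carrying a methylated
## peak and ~5.45% carrying a group-differential one (62.5% control-higher),
## 10-clone bisulfite matrices, and ChIP peaks planted at given TSS offsets.

#' Specification for a synthetic two-group MeDIP tiling array
#'
#' @param n_promoters Number of promoters (default 22327).
#' @param n_probes_total Total probe count; probes per promoter is
#'   `floor(n_probes_total / n_promoters)` (default 180000, ~8 per promoter).
#' @param promoter_window Window around the TSS tiled by the probes, bp
#'   (default `c(-1300, 500)`).
#' @param replicates_per_group Replicates per group (default 3).
#' @param methylated_fraction Fraction of promoters given a methylated peak
#'   (baseline enrichment in both groups; default 0.141).
#' @param dmep_fraction Fraction of promoters whose methylated peak is
#'   group-differential (subset of `methylated_fraction`; default 0.0545).
#' @param prop_control_higher Among differential peaks, fraction with the
#'   control group higher (default 0.625).
#' @param effect_size Mean log2-ratio shift added to the higher group within a
#'   differential peak (default 0.6).
#' @param peak_base_level Baseline log2 enrichment of a methylated peak in
#'   both groups (default 0.5, comfortably above the 0.3 median criterion).
#' @param probe_noise_sd Per-probe, per-replicate Gaussian noise SD
#'   (default 0.2).
#' @param cv_inflation_fraction Fraction of probes with inflated replicate
#'   variance, emulating poor-quality probes that fail the CV criterion
#'   (default 0.1).
#' @param cv_inflation_factor Multiplier applied to the noise SD of inflated
#'   probes (default 6).
#' @param peak_probes_range Range of consecutive probes a planted peak
#'   occupies (default 4..6, truncated to the probes available).
#' @param seed Integer seed; the whole table is bit-reproducible under it.
#' @return An `array_sim_spec` list.
#' @export
array_sim_spec <- function(n_promoters = 22327L, n_probes_total = 180000L,
                           promoter_window = c(-1300L, 500L),
                           replicates_per_group = 3L,
                           methylated_fraction = 0.141,
                           dmep_fraction = 0.0545,
                           prop_control_higher = 0.625,
                           effect_size = 0.6, peak_base_level = 0.5,
                           probe_noise_sd = 0.2,
                           cv_inflation_fraction = 0.1,
                           cv_inflation_factor = 6,
                           peak_probes_range = c(4L, 6L), seed = 1L) {
  stopifnot(n_promoters >= 1L, n_probes_total >= 1L,
            replicates_per_group >= 1L,
            methylated_fraction >= 0, methylated_fraction <= 1,
            dmep_fraction >= 0, dmep_fraction <= methylated_fraction,
            prop_control_higher >= 0, prop_control_higher <= 1,
            cv_inflation_fraction >= 0, cv_inflation_fraction <= 1,
            probe_noise_sd >= 0, diff(promoter_window) > 0)
  if (n_probes_total < n_promoters)
    .fmt_stop("spec implies fewer than one probe per promoter")
  structure(as.list(environment()), class = "array_sim_spec")
}

#' Simulate a two-group MeDIP promoter tiling array
#'
#' Probes are tiled evenly across each promoter window. Baseline probes draw
#' per-replicate log2 ratios from Normal(0, probe_noise_sd). Within planted
#' methylated peaks both groups are centred at `peak_base_level`, and within
#' differential peaks the higher group is shifted by `effect_size` on top. A
#' fraction of probes has its replicate SD multiplied by
#' `cv_inflation_factor`.
#'
#' @param spec An [array_sim_spec()].
#' @return List with `probes` (a [probe_table()]) and `truth` (one row per
#'   planted peak: promoter, probe span, bp span, and true class in
#'   `{control_higher, case_higher, none}`; `none` rows are methylated but not
#'   differential).
#' @export
simulate_array <- function(spec = array_sim_spec()) {
  stopifnot(inherits(spec, "array_sim_spec"))
  set.seed(spec$seed)
  k <- spec$n_probes_total %/% spec$n_promoters
  if (k < 1L) .fmt_stop("spec implies fewer than one probe per promoter")
  width <- diff(spec$promoter_window)
  probe_w <- width %/% k
  n <- spec$n_promoters * k
  reps <- spec$replicates_per_group
  samples <- c(sprintf("C%d", seq_len(reps)), sprintf("D%d", seq_len(reps)))
  groups <- stats::setNames(rep(c("control", "case"), each = reps), samples)

  prom_ids <- sprintf("P%05d", seq_len(spec$n_promoters))
  tss <- 100000L + (seq_len(spec$n_promoters) - 1L) * (width + 2000L)
  start <- rep(tss + spec$promoter_window[1L], each = k) +
    rep(seq_len(k) - 1L, spec$n_promoters) * probe_w
  df <- data.frame(
    probe_id = sprintf("probe_%07d", seq_len(n)),
    promoter_id = rep(prom_ids, each = k),
    chrom = "chr1",
    start = start,
    end = start + probe_w,
    stringsAsFactors = FALSE
  )

  mu <- matrix(0, nrow = n, ncol = 2L)  # per-group mean: [,1] control [,2] case
  n_meth <- round(spec$methylated_fraction * spec$n_promoters)
  n_diff <- round(spec$dmep_fraction * spec$n_promoters)
  truth <- data.frame(promoter_id = character(), first_probe = integer(),
                      last_probe = integer(), chrom = character(),
                      start = integer(), end = integer(), class = character(),
                      stringsAsFactors = FALSE)
  if (n_meth > 0L) {
    meth_prom <- sort(sample.int(spec$n_promoters, n_meth))
    cls <- rep("none", n_meth)
    if (n_diff > 0L) {
      diff_sel <- sample.int(n_meth, n_diff)
      cls[diff_sel] <- ifelse(
        stats::runif(n_diff) < spec$prop_control_higher,
        "control_higher", "case_higher")
    }
    lo <- min(spec$peak_probes_range[1L], k)
    hi <- min(spec$peak_probes_range[2L], k)
    len <- sample(seq(lo, hi), n_meth, replace = TRUE)
    off <- vapply(len, function(l) sample.int(k - l + 1L, 1L), integer(1))
    first <- (meth_prom - 1L) * k + off
    last <- first + len - 1L
    for (j in seq_len(n_meth)) {
      i <- first[j]:last[j]
      mu[i, ] <- spec$peak_base_level
      if (cls[j] == "control_higher") mu[i, 1L] <- mu[i, 1L] + spec$effect_size
      if (cls[j] == "case_higher") mu[i, 2L] <- mu[i, 2L] + spec$effect_size
    }
    truth <- data.frame(promoter_id = prom_ids[meth_prom],
                        first_probe = first, last_probe = last,
                        chrom = "chr1", start = df$start[first],
                        end = df$end[last], class = cls,
                        stringsAsFactors = FALSE)
  }

  sd_probe <- rep(spec$probe_noise_sd, n)
  inflated <- stats::runif(n) < spec$cv_inflation_fraction
  sd_probe[inflated] <- sd_probe[inflated] * spec$cv_inflation_factor
  vals <- matrix(stats::rnorm(n * 2L * reps), nrow = n) * sd_probe +
    cbind(matrix(rep(mu[, 1L], reps), nrow = n),
          matrix(rep(mu[, 2L], reps), nrow = n))
  colnames(vals) <- samples
  df <- cbind(df, as.data.frame(vals))
  list(probes = probe_table(df, groups), truth = truth)
}

## CG-free AT-rich background of length n (no CG dinucleotide anywhere)
.bg_seq <- function(n) {
  x <- sample(c("A", "T", "C", "G"), n, replace = TRUE,
              prob = c(0.35, 0.35, 0.15, 0.15))
  hit <- which(x[-n] == "C" & x[-1L] == "G")
  if (length(hit)) x[hit + 1L] <- "A"
  x
}

## CpG-island block: CGCG + 2 random bases per 6-bp unit (GC ~0.83, O/E ~1.9)
.island_seq <- function(n) {
  units <- ceiling(n / 6)
  x <- unlist(lapply(seq_len(units), function(i)
    c("C", "G", "C", "G", sample(c("A", "C", "G", "T"), 2L, replace = TRUE))))
  x[seq_len(n)]
}

#' Simulate promoter sequences of known CpG class
#'
#' 1800-bp sequences spanning -1300..+500 of TSS. HCP sequences carry a
#' 600-bp CpG island at -700..-101 (well inside the classifier's core
#' region); ICP sequences carry the same island at -1300..-801 (outside the
#' core, so no HCP window qualifies, but the LCP condition is defeated); LCP
#' sequences are CG-free AT-rich background (O/E 0 everywhere). Construction
#' margins are wide, so labels are guaranteed, not tuned.
#'
#' @param n_per_class Integer vector `c(HCP, ICP, LCP)` (optionally named).
#' @param seed Integer seed.
#' @return List with `sequences` (named character) and `labels` (named
#'   character, same names).
#' @export
simulate_promoter_sequences <- function(n_per_class = c(HCP = 1L, ICP = 1L, LCP = 1L),
                                        seed = 1L) {
  if (length(n_per_class) != 3L || any(n_per_class < 0L))
    .fmt_stop("n_per_class must be three non-negative counts (HCP, ICP, LCP)")
  set.seed(seed)
  L <- 1800L
  make <- function(label) {
    x <- .bg_seq(L)
    if (label == "HCP") x[601:1200] <- .island_seq(600L)   # offsets -700..-101
    if (label == "ICP") x[1:500] <- .island_seq(500L)      # offsets -1300..-801
    paste(x, collapse = "")
  }
  labels <- rep(c("HCP", "ICP", "LCP"), n_per_class)
  seqs <- vapply(labels, make, character(1))
  ids <- sprintf("%s_%03d", labels, stats::ave(seq_along(labels), labels,
                                               FUN = seq_along))
  list(sequences = stats::setNames(seqs, ids),
       labels = stats::setNames(labels, ids))
}

#' Simulate bisulfite clone matrices
#'
#' Each call is an i.i.d. Bernoulli(p_meth) methylated/unmethylated draw,
#' masked to undetermined with probability `p_undetermined`.
#'
#' @param n_clones Clones per group (default 10, the sequenced-colony design).
#' @param n_sites CpG sites per clone (>= 1).
#' @param p_meth Methylation probability; a scalar yields one matrix, a
#'   length-2 vector (control, case) yields a named list of two.
#' @param p_undetermined Probability a call is masked to `"X"` (default 0.05).
#' @param seed Integer seed.
#' @param region_id Region identifier for the output object(s).
#' @return A [bs_clones()] object, or `list(control = , case = )` of two.
#' @export
simulate_bisulfite <- function(n_clones = 10L, n_sites, p_meth,
                               p_undetermined = 0.05, seed = 1L,
                               region_id = "region") {
  if (n_sites < 1L) .fmt_stop("n_sites must be >= 1")
  if (n_clones < 1L) .fmt_stop("n_clones must be >= 1")
  stopifnot(all(p_meth >= 0 & p_meth <= 1),
            p_undetermined >= 0, p_undetermined < 1)
  set.seed(seed)
  one <- function(p, id) {
    m <- matrix(ifelse(stats::runif(n_clones * n_sites) < p, "M", "U"),
                nrow = n_clones)
    m[stats::runif(length(m)) < p_undetermined] <- "X"
    ## guarantee the >=1-determined-call invariant per clone
    allx <- rowSums(m != "X") == 0L
    if (any(allx)) m[allx, 1L] <- ifelse(stats::runif(sum(allx)) < p, "M", "U")
    bs_clones(m, region_id = id, site_positions = seq_len(n_sites) * 10L)
  }
  if (length(p_meth) == 1L) return(one(p_meth, region_id))
  if (length(p_meth) != 2L) .fmt_stop("p_meth must have length 1 or 2")
  list(control = one(p_meth[1L], paste0(region_id, "_control")),
       case = one(p_meth[2L], paste0(region_id, "_case")))
}

#' Simulate ChIP peaks at specified TSS offsets
#'
#' One peak per requested offset, its summit placed exactly at the
#' strand-adjusted offset from the gene's TSS (genomic summit = tss + offset
#' on `+` strand, tss - offset on `-` strand). Optional decoy peaks are
#' placed far from every gene.
#'
#' @param models A [gene_models()] data.frame.
#' @param offsets Named numeric vector of signed bp offsets; names are gene
#'   ids present in `models`. Empty vector yields an empty peak set.
#' @param width Peak width in bp (default 400).
#' @param group_label Label attached to the planted peaks.
#' @param n_decoys Number of intergenic decoy peaks (default 0).
#' @param decoy_gap Distance beyond the last gene at which decoys start
#'   (default 1e6 bp).
#' @param seed Integer seed (used only for decoy jitter).
#' @return A [chip_peaks()] data.frame with a `gene_id` truth column.
#' @export
simulate_chip_peaks <- function(models, offsets, width = 400L,
                                group_label = "case", n_decoys = 0L,
                                decoy_gap = 1e6, seed = 1L) {
  set.seed(seed)
  if (length(offsets) == 0L && n_decoys == 0L) {
    out <- chip_peaks(data.frame(chrom = character(), start = integer(),
                                 end = integer(), summit = integer()))
    out$gene_id <- character(0)
    return(out)
  }
  rows <- list()
  if (length(offsets)) {
    if (is.null(names(offsets)) || !all(names(offsets) %in% models$gene_id))
      .fmt_stop("offsets must be named by gene ids present in the models")
    m <- models[match(names(offsets), models$gene_id), , drop = FALSE]
    summit <- ifelse(m$strand == "+", m$tss + offsets, m$tss - offsets)
    rows$planted <- data.frame(
      chrom = m$chrom, start = as.integer(summit - width %/% 2L),
      end = as.integer(summit - width %/% 2L + width),
      name = sprintf("peak_%s", m$gene_id), score = 100,
      summit = as.integer(summit), group_label = group_label,
      gene_id = m$gene_id, stringsAsFactors = FALSE
    )
  }
  if (n_decoys > 0L) {
    base <- max(models$gene_end) + decoy_gap
    pos <- as.integer(base + (seq_len(n_decoys) - 1L) * decoy_gap +
                        sample.int(1000L, n_decoys, replace = TRUE))
    rows$decoys <- data.frame(
      chrom = models$chrom[1L], start = pos - width %/% 2L,
      end = pos - width %/% 2L + width,
      name = sprintf("decoy_%d", seq_len(n_decoys)), score = 10,
      summit = pos, group_label = group_label,
      gene_id = NA_character_, stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)
  gene_id <- df$gene_id
  out <- chip_peaks(df[, setdiff(names(df), "gene_id")])
  out$gene_id <- gene_id
  out
}

#' Simulate a qPCR Ct table
#'
#' Reference-gene Ct values are drawn around a fixed baseline and target Ct
#' values encode the requested fold change relative to the reference
#' condition (one extra cycle = half the expression).
#'
#' @param folds Named numeric vector of true fold changes per condition; the
#'   first element is taken as the reference condition (its fold should be 1).
#' @param n_replicates Replicates per condition (default 6).
#' @param noise_sd Gaussian Ct noise SD, cycles (default 0.15; 0 gives exact
#'   recovery).
#' @param target Target gene name.
#' @param seed Integer seed.
#' @return data.frame with `sample_id`, `condition`, `target_gene`,
#'   `ct_target`, `ct_reference`.
#' @export
simulate_qpcr <- function(folds, n_replicates = 6L, noise_sd = 0.15,
                          target = "gene", seed = 1L) {
  stopifnot(!is.null(names(folds)), all(folds > 0), n_replicates >= 1L)
  set.seed(seed)
  rows <- lapply(names(folds), function(cond) {
    data.frame(
      sample_id = sprintf("%s_%s_%d", target, cond, seq_len(n_replicates)),
      condition = cond, target_gene = target,
      ct_target = 22 - log2(folds[[cond]]) +
        stats::rnorm(n_replicates, 0, noise_sd),
      ct_reference = 15 + stats::rnorm(n_replicates, 0, noise_sd),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Simulate dual-luciferase readings
#'
#' Firefly/renilla well pairs per construct and condition; the active
#' condition's firefly:renilla ratio is the reference condition's times the
#' requested fold activation, with multiplicative noise of the given CV.
#'
#' @param folds Named numeric vector of true fold activations per construct.
#' @param n_wells Replicate wells per construct and condition (default 4).
#' @param cv Coefficient of variation of the well ratios (default 0.1; 0
#'   gives exact recovery).
#' @param conditions Two condition labels, reference first
#'   (default `c("SOX9_neg", "SOX9_pos")`).
#' @param seed Integer seed.
#' @return data.frame with `construct`, `condition`, `firefly`, `renilla`.
#' @export
simulate_luciferase <- function(folds, n_wells = 4L, cv = 0.1,
                                conditions = c("SOX9_neg", "SOX9_pos"),
                                seed = 1L) {
  stopifnot(!is.null(names(folds)), all(folds > 0), length(conditions) == 2L)
  set.seed(seed)
  rows <- list()
  for (con in names(folds)) {
    for (j in 1:2) {
      ratio <- if (j == 1L) 1 else folds[[con]]
      ren <- stats::rnorm(n_wells, 1000, 50)
      fire <- ren * ratio * (1 + stats::rnorm(n_wells, 0, cv))
      rows[[paste(con, j)]] <- data.frame(
        construct = con, condition = conditions[j],
        firefly = fire, renilla = ren, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
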
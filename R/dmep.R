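## dmep_caller: assemble enrichment peaks from probe-level log2(MeDIP/Input)
## ratios and call differential methylation enrichment peaks (DMEPs).
##
## A peak is a maximal run of consecutive probes within one promoter whose
## pooled-mean log2 ratio exceeds a call threshold. A peak is a DMEP when
##  (i)  at least one group's median enrichment over the peak is >= median_min
##       and the between-group difference M' is non-zero (two-sided by
##       default; `one_sided` restores the literal case-higher-only reading),
##  (ii) in BOTH groups at least `cv_pass_fraction_min` of the peak's probes
##       have a replicate coefficient of variability <= cv_max.
## The sign of M' (case mean minus control mean over probe x replicate values)
## orients the class: positive -> case_higher, negative -> control_higher.

#' DMEP filter and assembly parameters
#'
#' @param median_min Minimum per-group median log2(MeDIP/Input) over the
#'   peak's probes for the enrichment criterion (default 0.3).
#' @param cv_max Maximum replicate coefficient of variability per probe
#'   (default 0.8).
#' @param cv_pass_fraction_min Minimum fraction of peak probes that must pass
#'   the CV criterion in both groups (default 0.5).
#' @param min_probes_per_peak Minimum run length for peak assembly (default 2).
#' @param probe_call_threshold Pooled-mean log2 ratio a probe must exceed to
#'   seed/extend a peak (default 0.2).
#' @param m_prime_min Minimum |M'| for a differential call (default 0, i.e.
#'   any non-zero difference; raise to separate differential from merely
#'   methylated peaks in noisy data).
#' @param one_sided If TRUE, only M' > 0 peaks (case higher) qualify,
#'   the literal reading of the filter; default FALSE applies it
#'   direction-symmetrically so both directions are reported.
#' @param cv_scale Scale on which the CV is computed: `"log2"` (default, on
#'   the log2 ratios as stored) or `"linear"` (on 2^ratio).
#' @param median_over `"probe_group_means"` (default: median over the peak's
#'   probes of per-probe group means) or `"all_values"` (median over all
#'   probe x replicate values).
#' @return A `dmep_params` list.
#' @export
dmep_params <- function(median_min = 0.3, cv_max = 0.8,
                        cv_pass_fraction_min = 0.5, min_probes_per_peak = 2L,
                        probe_call_threshold = 0.2, m_prime_min = 0,
                        one_sided = FALSE,
                        cv_scale = c("log2", "linear"),
                        median_over = c("probe_group_means", "all_values")) {
  stopifnot(is.finite(median_min), is.finite(cv_max), !is.na(probe_call_threshold),
            cv_pass_fraction_min >= 0, cv_pass_fraction_min <= 1,
            min_probes_per_peak >= 1L, m_prime_min >= 0)
  structure(list(median_min = median_min, cv_max = cv_max,
                 cv_pass_fraction_min = cv_pass_fraction_min,
                 min_probes_per_peak = as.integer(min_probes_per_peak),
                 probe_call_threshold = probe_call_threshold,
                 m_prime_min = m_prime_min,
                 one_sided = isTRUE(one_sided),
                 cv_scale = match.arg(cv_scale),
                 median_over = match.arg(median_over)),
            class = "dmep_params")
}

#' Assemble enrichment peaks within promoters
#'
#' Within each promoter, maximal runs of at least `min_probes_per_peak`
#' consecutive probes whose pooled mean log2 ratio (mean over all samples)
#' exceeds `probe_call_threshold` become one peak. Peaks never cross promoter
#' boundaries.
#'
#' @param table A [probe_table()].
#' @param params A [dmep_params()] list.
#' @return An `enrichment_peaks` data.frame with one row per peak and a
#'   `probe_idx` list column of row indices into `table`.
#' @export
assemble_peaks <- function(table, params = dmep_params()) {
  stopifnot(inherits(table, "probe_table"))
  pooled <- rowMeans(pt_values(table))
  above <- pooled > params$probe_call_threshold
  runs <- rle(table$promoter_id)
  prom_end <- cumsum(runs$lengths)
  prom_start <- prom_end - runs$lengths + 1L
  out <- vector("list", length(runs$values))
  for (k in seq_along(runs$values)) {
    i0 <- prom_start[k]
    a <- above[i0:prom_end[k]]
    r <- rle(a)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= params$min_probes_per_peak)
    if (!length(keep)) next
    out[[k]] <- data.frame(
      promoter_id = runs$values[k],
      chrom = table$chrom[i0],
      start = table$start[i0 + starts[keep] - 1L],
      end = table$end[i0 + ends[keep] - 1L],
      n_probes = r$lengths[keep],
      first = i0 + starts[keep] - 1L,
      last = i0 + ends[keep] - 1L,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(promoter_id = character(), chrom = character(),
                      start = integer(), end = integer(), n_probes = integer(),
                      first = integer(), last = integer())
  }
  out$probe_idx <- lapply(seq_len(nrow(out)),
                          function(i) out$first[i]:out$last[i])
  if (!nrow(out)) out$probe_idx <- list()
  out$probe_ids <- lapply(out$probe_idx, function(i) table$probe_id[i])
  rownames(out) <- NULL
  structure(out[, c("promoter_id", "chrom", "start", "end", "n_probes",
                    "probe_idx", "probe_ids")],
            class = c("enrichment_peaks", "data.frame"))
}

#' Between-group enrichment difference M' over a peak
#'
#' Grand mean of the peak's probe x replicate log2 ratios in the case group
#' minus the same mean in the control group.
#'
#' @param peak One-row slice of [assemble_peaks()] output (or anything with a
#'   `probe_idx` list column).
#' @param table The [probe_table()] the peak was assembled from.
#' @param groups Optional group map; defaults to the table's.
#' @return Numeric scalar.
#' @export
m_prime <- function(peak, table, groups = pt_groups(table)) {
  groups <- .check_groups(groups)
  idx <- peak$probe_idx[[1L]]
  ctrl <- names(groups)[groups == "control"]
  case <- names(groups)[groups == "case"]
  if (!length(ctrl) || !length(case))
    .fmt_stop("both groups need at least one replicate")
  mean(pt_values(table, case)[idx, ]) - mean(pt_values(table, ctrl)[idx, ])
}

#' Coefficient of variability of a probe's replicate values
#'
#' Sample standard deviation of the replicate log2 ratios divided by the
#' absolute replicate mean; +Inf when the mean is zero.
#'
#' @param values Numeric vector of replicate values (length >= 2).
#' @return Non-negative numeric (possibly `Inf`).
#' @export
probe_cv <- function(values) {
  if (length(values) < 2L)
    .fmt_stop("CV needs at least 2 replicates")
  m <- mean(values)
  if (m == 0) return(Inf)
  stats::sd(values) / abs(m)
}

## row-wise CV over a values matrix (probes x replicates)
.cv_rows <- function(vals) {
  m <- rowMeans(vals)
  s <- apply(vals, 1L, stats::sd)
  ifelse(m == 0, Inf, s / abs(m))
}

#' Call DMEPs on assembled peaks
#'
#' Applies the enrichment-median and CV filters (see [dmep_params()]) and
#' orients each passing peak by the sign of M'.
#'
#' @param peaks Output of [assemble_peaks()].
#' @param table The [probe_table()] used for assembly.
#' @param params A [dmep_params()] list.
#' @return A `dmep_calls` data.frame: the peaks plus `median_control`,
#'   `median_case`, `m_prime`, `cv_pass_control`, `cv_pass_case` (fractions of
#'   probes passing the CV criterion), flags `enrichment_pass`/`cv_pass`, and
#'   `dmep_class` in `{control_higher, case_higher, none}`.
#' @export
call_dmeps <- function(peaks, table, params = dmep_params()) {
  stopifnot(inherits(table, "probe_table"))
  groups <- pt_groups(table)
  ctrl <- names(groups)[groups == "control"]
  case <- names(groups)[groups == "case"]
  vals_c <- pt_values(table, ctrl)
  vals_d <- pt_values(table, case)
  if (params$cv_scale == "linear") {
    cv_c_all <- .cv_rows(2^vals_c)
    cv_d_all <- .cv_rows(2^vals_d)
  } else {
    cv_c_all <- .cv_rows(vals_c)
    cv_d_all <- .cv_rows(vals_d)
  }
  n <- nrow(peaks)
  med_c <- med_d <- mp <- cvfc <- cvfd <- numeric(n)
  for (i in seq_len(n)) {
    idx <- peaks$probe_idx[[i]]
    if (params$median_over == "all_values") {
      med_c[i] <- stats::median(vals_c[idx, ])
      med_d[i] <- stats::median(vals_d[idx, ])
    } else {
      med_c[i] <- stats::median(rowMeans(vals_c[idx, , drop = FALSE]))
      med_d[i] <- stats::median(rowMeans(vals_d[idx, , drop = FALSE]))
    }
    mp[i] <- mean(vals_d[idx, ]) - mean(vals_c[idx, ])
    cvfc[i] <- mean(cv_c_all[idx] <= params$cv_max)
    cvfd[i] <- mean(cv_d_all[idx] <= params$cv_max)
  }
  diff_ok <- if (params$one_sided) mp > params$m_prime_min else
    abs(mp) > params$m_prime_min
  enrich <- (pmax(med_c, med_d) >= params$median_min) & diff_ok
  cv_ok <- (cvfc >= params$cv_pass_fraction_min) &
    (cvfd >= params$cv_pass_fraction_min)
  cls <- rep("none", n)
  cls[enrich & cv_ok & mp > 0] <- "case_higher"
  cls[enrich & cv_ok & mp < 0] <- "control_higher"
  out <- as.data.frame(peaks)
  out$median_control <- med_c
  out$median_case <- med_d
  out$m_prime <- mp
  out$cv_pass_control <- cvfc
  out$cv_pass_case <- cvfd
  out$enrichment_pass <- enrich
  out$cv_pass <- cv_ok
  out$dmep_class <- cls
  structure(out, params = params, class = c("dmep_calls", "data.frame"))
}

#' @export
print.dmep_calls <- function(x, ...) {
  cat(sprintf("dmep_calls: %d peaks, %d DMEPs (%d control_higher / %d case_higher)\n",
              nrow(x), sum(x$dmep_class != "none"),
              sum(x$dmep_class == "control_higher"),
              sum(x$dmep_class == "case_higher")))
  invisible(x)
}

## two-sided unpaired t test p-value; Student by default (the study's stated
## test), Welch via var_equal = FALSE; NA when degenerate
.ttest_p <- function(a, b, var_equal = TRUE) {
  tryCatch(stats::t.test(a, b, var.equal = var_equal)$p.value,
           error = function(e) NA_real_)
}

#' Group comparison of per-sample mean enrichment
#'
#' For each sample, the mean log2 ratio over the selected probes; the two
#' groups of per-sample means are compared with a two-sided unpaired t test
#' (Student's by default).
#'
#' @param table A [probe_table()].
#' @param probes Optional integer vector of probe row indices (default: all).
#' @param var_equal Assume equal variances (Student's t, default TRUE);
#'   FALSE gives Welch.
#' @return List with `p_value`, `mean_control`, `mean_case` and the
#'   `per_sample` means.
#' @export
enrichment_group_test <- function(table, probes = NULL, var_equal = TRUE) {
  groups <- pt_groups(table)
  vals <- pt_values(table)
  if (!is.null(probes)) vals <- vals[probes, , drop = FALSE]
  per_sample <- colMeans(vals)
  a <- per_sample[groups[colnames(vals)] == "control"]
  b <- per_sample[groups[colnames(vals)] == "case"]
  list(p_value = .ttest_p(a, b, var_equal), mean_control = mean(a),
       mean_case = mean(b), per_sample = per_sample)
}

#' Summarize called DMEPs
#'
#' Counts methylated promoters and DMEPs by direction, per-group mean
#' enrichment over DMEP probes, and a Welch t test comparing per-sample mean
#' enrichment (over the DMEP probes) between groups.
#'
#' @param called Output of [call_dmeps()].
#' @param table The [probe_table()] the calls were made on.
#' @return List with `n_total_methylated` (promoters with at least one peak
#'   whose best group median meets the enrichment threshold),
#'   `n_dmep`, `n_control_higher`, `n_case_higher`,
#'   `mean_enrichment_per_group`, and `t_p` (NA when no DMEPs).
#' @export
summarize_dmeps <- function(called, table) {
  params <- attr(called, "params")
  if (is.null(params)) params <- dmep_params()
  meth <- pmax(called$median_control, called$median_case) >= params$median_min
  n_total_methylated <- length(unique(called$promoter_id[meth]))
  is_dmep <- called$dmep_class != "none"
  n_dmep <- sum(is_dmep)
  res <- list(
    n_total_methylated = n_total_methylated,
    n_dmep = n_dmep,
    n_control_higher = sum(called$dmep_class == "control_higher"),
    n_case_higher = sum(called$dmep_class == "case_higher"),
    mean_enrichment_per_group = c(control = NA_real_, case = NA_real_),
    t_p = NA_real_
  )
  if (n_dmep == 0L) return(res)
  idx <- unlist(called$probe_idx[is_dmep])
  gt <- enrichment_group_test(table, probes = idx)
  res$mean_enrichment_per_group <- c(control = gt$mean_control,
                                     case = gt$mean_case)
  res$t_p <- gt$p_value
  res
}
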
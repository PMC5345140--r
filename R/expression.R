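## expression: relative expression (delta-delta-Ct), dual-luciferase
## normalization, and the activator/repressor caller that integrates peak
## presence with knockdown/overexpression concordance.

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, dCt = ct_target - ct_reference; per condition,
#' ddCt = mean dCt(condition) - mean dCt(reference condition); fold =
#' 2^(-ddCt). The standard error is propagated on the ddCt (log2) scale and
#' exponentiated; a two-sided unpaired t test on the per-sample dCt values
#' gives the p-value against the reference condition.
#'
#' @param records data.frame with `sample_id`, `condition`, `ct_target`,
#'   `ct_reference` and optionally `target_gene`.
#' @param target Optional target gene to filter `records` on.
#' @param reference_condition Condition used as the fold = 1 baseline.
#' @return data.frame with one row per condition: `condition`, `n`,
#'   `ddct`, `fold` (exactly 1 for the reference), `fold_lo`, `fold_hi`
#'   (+/- 1 SE on the log2 scale), `p` (NA for the reference).
#' @export
ddct_fold <- function(records, target = NULL, reference_condition) {
  if (!is.null(target) && "target_gene" %in% names(records))
    records <- records[records$target_gene == target, , drop = FALSE]
  if (!reference_condition %in% records$condition)
    .fmt_stop("reference condition '", reference_condition, "' not present")
  if (any(records$ct_target <= 0 | records$ct_target >= 45 |
            records$ct_reference <= 0 | records$ct_reference >= 45))
    .fmt_stop("Ct values must lie in (0, 45)")
  dct <- records$ct_target - records$ct_reference
  conds <- unique(records$condition)
  ref <- dct[records$condition == reference_condition]
  rows <- lapply(conds, function(con) {
    x <- dct[records$condition == con]
    ddct <- mean(x) - mean(ref)
    se <- if (con == reference_condition) {
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
    } else {
      sqrt((if (length(x) > 1L) stats::var(x) / length(x) else 0) +
             (if (length(ref) > 1L) stats::var(ref) / length(ref) else 0))
    }
    if (con == reference_condition) ddct <- 0  # fold identically 1
    p <- if (con == reference_condition) NA_real_ else .ttest_p(x, ref)
    data.frame(condition = con, n = length(x), ddct = ddct,
               fold = 2^(-ddct), fold_lo = 2^(-(ddct + se)),
               fold_hi = 2^(-(ddct - se)), p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Renilla-normalized luciferase fold activation
#'
#' Each well's firefly reading is normalized to its renilla co-transfection
#' control; the fold per construct is the mean normalized ratio in the active
#' condition over the mean in the reference (empty-vector) condition, with a
#' two-sided unpaired t test across replicate wells. Wells with renilla <= 0 are excluded
#' with a warning.
#'
#' @param readings data.frame with `construct`, `condition`, `firefly`,
#'   `renilla`.
#' @param active_condition,reference_condition The two condition labels
#'   (defaults `"SOX9_pos"` / `"SOX9_neg"`).
#' @return data.frame with one row per construct: `construct`, `fold`, `p`,
#'   `n_active`, `n_reference`.
#' @export
luciferase_relative <- function(readings, active_condition = "SOX9_pos",
                                reference_condition = "SOX9_neg") {
  bad <- readings$renilla <= 0
  if (any(bad)) {
    warning(sum(bad), " well(s) with renilla <= 0 excluded")
    readings <- readings[!bad, , drop = FALSE]
  }
  readings$ratio <- readings$firefly / readings$renilla
  rows <- lapply(split(readings, readings$construct), function(d) {
    a <- d$ratio[d$condition == active_condition]
    r <- d$ratio[d$condition == reference_condition]
    if (!length(a) || !length(r))
      .fmt_stop("construct '", d$construct[1L], "' missing a condition")
    p <- if (length(a) > 1L && length(r) > 1L) .ttest_p(a, r) else NA_real_
    data.frame(construct = d$construct[1L], fold = mean(a) / mean(r), p = p,
               n_active = length(a), n_reference = length(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.direction <- function(fold, p, alpha) {
  if (is.na(fold) || is.na(p)) return(NA_character_)
  if (p < alpha && fold < 1) "down" else if (p < alpha && fold > 1) "up" else "ns"
}

#' Call regulatory direction from perturbation concordance
#'
#' A gene is an activated target when knockdown of the TF lowers it and
#' overexpression raises it; a repressed target shows the mirrored pattern.
#' Significant responses in the same direction in both arms are discordant
#' with either model and yield `no_regulation` with a flag. Genes missing
#' either perturbation arm have their call withheld (NA) with a warning.
#'
#' @param perturbations data.frame with one row per gene: `gene`,
#'   `knockdown_fold`, `knockdown_p`, `overexpression_fold`,
#'   `overexpression_p`, and optionally `peak_in_case`, `peak_in_control`.
#' @param alpha Significance threshold for each arm (default 0.05).
#' @return `regulatory_calls` data.frame: gene, both directions
#'   (`down`/`up`/`ns`), `call` in
#'   `{activated_target, repressed_target, no_regulation}` (NA when
#'   withheld), `discordant` flag, and the peak-presence columns.
#' @export
call_regulation <- function(perturbations, alpha = 0.05) {
  p <- perturbations
  for (col in c("peak_in_case", "peak_in_control"))
    if (is.null(p[[col]])) p[[col]] <- NA
  kd <- vapply(seq_len(nrow(p)), function(i)
    .direction(p$knockdown_fold[i], p$knockdown_p[i], alpha), character(1))
  oe <- vapply(seq_len(nrow(p)), function(i)
    .direction(p$overexpression_fold[i], p$overexpression_p[i], alpha),
    character(1))
  call <- character(nrow(p))
  discordant <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    if (is.na(kd[i]) || is.na(oe[i])) {
      warning("gene '", p$gene[i], "': missing perturbation arm, call withheld")
      call[i] <- NA_character_
      next
    }
    if (kd[i] == "down" && oe[i] == "up") call[i] <- "activated_target"
    else if (kd[i] == "up" && oe[i] == "down") call[i] <- "repressed_target"
    else {
      call[i] <- "no_regulation"
      discordant[i] <- kd[i] != "ns" && kd[i] == oe[i]
    }
  }
  structure(data.frame(
    gene = p$gene, knockdown_direction = kd, overexpression_direction = oe,
    call = call, discordant = discordant,
    peak_in_case = p$peak_in_case, peak_in_control = p$peak_in_control,
    stringsAsFactors = FALSE
  ), class = c("regulatory_calls", "data.frame"))
}

#' @export
print.regulatory_calls <- function(x, ...) {
  cat(sprintf(
    "regulatory_calls: %d genes (%d activated, %d repressed, %d no_regulation)\n",
    nrow(x), sum(x$call == "activated_target", na.rm = TRUE),
    sum(x$call == "repressed_target", na.rm = TRUE),
    sum(x$call == "no_regulation", na.rm = TRUE)))
  print(as.data.frame(x))
  invisible(x)
}
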
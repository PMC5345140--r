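## cpg_classifier: high/intermediate/low CpG-density promoter classes from
## windowed GC fraction and CpG observed/expected ratio.
##
## HCP: some 500-bp window fully inside the core region (-700..+200 of TSS)
##      has GC fraction >= 0.55 AND CpG O/E >= 0.6.
## LCP: no 500-bp window anywhere in the assayed promoter has CpG O/E >= 0.4.
## ICP: everything in between.
## O/E follows the Gardiner-Garden convention: (N_CpG * L) / (N_C * N_G),
## with N bases excluded from all counts and the length reduced accordingly.

.seq_chars <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(ch), c("A", "C", "G", "T", "N"))
  if (length(bad))
    .fmt_stop("sequence contains non-ACGTN characters: ",
              paste(bad, collapse = ""))
  ch
}

#' CpG observed/expected ratio of a sequence
#'
#' `(count of CG dinucleotides x effective length) / (count C x count G)`,
#' where N positions are excluded from all counts and the length is reduced
#' accordingly. Returns 0 when the C or G count is 0.
#'
#' @param seq DNA string (A/C/G/T/N, any case), length >= 2.
#' @return Non-negative numeric.
#' @export
cpg_oe <- function(seq) {
  ch <- .seq_chars(seq)
  if (length(ch) < 2L) .fmt_stop("sequence must have length >= 2")
  nC <- sum(ch == "C")
  nG <- sum(ch == "G")
  if (nC == 0L || nG == 0L) return(0)
  L <- sum(ch != "N")
  ncg <- sum(ch[-length(ch)] == "C" & ch[-1L] == "G")
  ncg * L / (nC * nG)
}

#' GC fraction of a sequence
#'
#' `(C + G) / (A + C + G + T)`; N excluded. `NaN` for an all-N sequence.
#'
#' @param seq DNA string.
#' @return Numeric in `[0, 1]` (or `NaN`).
#' @export
gc_fraction <- function(seq) {
  ch <- .seq_chars(seq)
  L <- sum(ch != "N")
  if (L == 0L) return(NaN)
  sum(ch == "C" | ch == "G") / L
}

## sliding-window GC and O/E over every window start, via cumulative sums
.window_stats <- function(ch, window) {
  L <- length(ch)
  isC <- as.integer(ch == "C")
  isG <- as.integer(ch == "G")
  nonN <- as.integer(ch != "N")
  cg <- c(as.integer(ch[-L] == "C" & ch[-1L] == "G"), 0L)
  csC <- c(0L, cumsum(isC)); csG <- c(0L, cumsum(isG))
  csN <- c(0L, cumsum(nonN)); csCG <- c(0L, cumsum(cg))
  starts <- seq_len(L - window + 1L)
  ends <- starts + window - 1L
  wsum <- function(cs, a, b) cs[b + 1L] - cs[a]
  C <- wsum(csC, starts, ends)
  G <- wsum(csG, starts, ends)
  Leff <- wsum(csN, starts, ends)
  CG <- wsum(csCG, starts, ends - 1L)  # dinucleotides fully inside the window
  oe <- ifelse(C > 0L & G > 0L, CG * Leff / (C * G), 0)
  gc <- ifelse(Leff > 0L, (C + G) / Leff, NaN)
  data.frame(start = starts, gc = gc, oe = oe)
}

#' Classify one promoter sequence by CpG density
#'
#' The sequence is assumed to span a fixed window around the TSS;
#' `tss_offset` gives the number of bases upstream of the TSS at which the
#' sequence begins (1300 for the default -1300..+500 design), so base `i`
#' (1-based) sits at offset `i - tss_offset - 1` from the TSS.
#'
#' @param seq DNA string (typically 1800 bp spanning -1300..+500).
#' @param tss_offset Bases upstream of TSS at the sequence start (default 1300).
#' @param window Window width in bp (default 500).
#' @param step Window step in bp (default 1, the exact scan).
#' @param hcp_region Offsets (from TSS) the HCP window must lie fully inside
#'   (default `c(-700, 200)`, endpoints included).
#' @param gc_min,oe_hcp_min HCP thresholds (defaults 0.55 and 0.6).
#' @param oe_lcp_max LCP threshold: LCP when no window anywhere reaches this
#'   O/E (default 0.4).
#' @return A `promoter_cpg_class` list: `label` (`"HCP"`/`"ICP"`/`"LCP"`, or
#'   NA when >50% of the sequence is N), `best_hcp_window` (offset, gc, oe of
#'   the qualifying window with the highest O/E; NULL otherwise), and
#'   `max_oe_window_anywhere` (offset, oe).
#' @export
classify_promoter <- function(seq, tss_offset = 1300L, window = 500L,
                              step = 1L, hcp_region = c(-700L, 200L),
                              gc_min = 0.55, oe_hcp_min = 0.6,
                              oe_lcp_max = 0.4) {
  ch <- .seq_chars(seq)
  L <- length(ch)
  if (L < 2L) .fmt_stop("sequence must have length >= 2")
  if (mean(ch == "N") > 0.5) {
    warning("more than 50% N: label withheld")
    return(structure(list(label = NA_character_, best_hcp_window = NULL,
                          max_oe_window_anywhere = NULL),
                     class = "promoter_cpg_class"))
  }
  w <- min(window, L)  # shorter promoters: single full-length window
  st <- .window_stats(ch, w)
  sel <- seq(1L, nrow(st), by = step)
  st <- st[sel, , drop = FALSE]
  st$offset <- st$start - tss_offset - 1L
  ## HCP windows must lie fully inside the core region
  in_core <- st$offset >= hcp_region[1L] & (st$offset + w - 1L) <= hcp_region[2L]
  if (w == L) in_core <- rep(TRUE, nrow(st))  # degenerate short promoter
  hcp_ok <- in_core & st$gc >= gc_min & st$oe >= oe_hcp_min
  imax <- which.max(st$oe)
  max_any <- list(offset = st$offset[imax], oe = st$oe[imax])
  if (any(hcp_ok)) {
    cand <- st[hcp_ok, , drop = FALSE]
    b <- cand[which.max(cand$oe), , drop = FALSE]
    return(structure(list(
      label = "HCP",
      best_hcp_window = list(offset = b$offset, gc = b$gc, oe = b$oe),
      max_oe_window_anywhere = max_any
    ), class = "promoter_cpg_class"))
  }
  label <- if (max(st$oe) < oe_lcp_max) "LCP" else "ICP"
  structure(list(label = label, best_hcp_window = NULL,
                 max_oe_window_anywhere = max_any),
            class = "promoter_cpg_class")
}

#' @export
print.promoter_cpg_class <- function(x, ...) {
  cat("promoter CpG class:", x$label, "\n")
  if (!is.null(x$best_hcp_window))
    cat(sprintf("  best HCP window at %+d: GC %.3f, O/E %.3f\n",
                x$best_hcp_window$offset, x$best_hcp_window$gc,
                x$best_hcp_window$oe))
  if (!is.null(x$max_oe_window_anywhere))
    cat(sprintf("  max O/E window at %+d: O/E %.3f\n",
                x$max_oe_window_anywhere$offset, x$max_oe_window_anywhere$oe))
  invisible(x)
}

#' Classify many promoter sequences
#'
#' @param seqs Named character vector (e.g. from [read_fasta()]).
#' @inheritParams classify_promoter
#' @param ... Passed to [classify_promoter()].
#' @return data.frame with `promoter_id`, `label`, and the winning-window
#'   statistics (`hcp_offset`, `hcp_gc`, `hcp_oe`, `max_oe_offset`, `max_oe`).
#' @export
classify_promoters <- function(seqs, ...) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("promoter_%d", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    cl <- classify_promoter(seqs[[i]], ...)
    data.frame(
      promoter_id = ids[i], label = cl$label,
      hcp_offset = if (is.null(cl$best_hcp_window)) NA_integer_ else cl$best_hcp_window$offset,
      hcp_gc = if (is.null(cl$best_hcp_window)) NA_real_ else cl$best_hcp_window$gc,
      hcp_oe = if (is.null(cl$best_hcp_window)) NA_real_ else cl$best_hcp_window$oe,
      max_oe_offset = if (is.null(cl$max_oe_window_anywhere)) NA_integer_ else cl$max_oe_window_anywhere$offset,
      max_oe = if (is.null(cl$max_oe_window_anywhere)) NA_real_ else cl$max_oe_window_anywhere$oe,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Class proportions of HCP/ICP/LCP labels
#'
#' @param labels Character vector of labels (NA labels dropped).
#' @param group Optional grouping vector of the same length; proportions are
#'   then computed per group.
#' @return data.frame with `group` (if given), `label`, `n`, `pct`;
#'   percentages sum to 100 within each group. Zero rows for empty input.
#' @export
class_proportions <- function(labels, group = NULL) {
  keep <- !is.na(labels)
  labels <- labels[keep]
  if (is.null(group)) group <- rep("all", length(labels)) else group <- group[keep]
  if (!length(labels))
    return(data.frame(group = character(), label = character(),
                      n = integer(), pct = numeric()))
  tab <- as.data.frame(table(group = group, label = labels),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "n"
  tot <- stats::ave(tab$n, tab$group, FUN = sum)
  tab$pct <- 100 * tab$n / tot
  tab[order(tab$group, tab$label), , drop = FALSE]
}
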
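## chip_annotation: assign ChIP peaks to genomic elements and signed TSS
## offsets. Element windows follow the promoter/enhancer/extended-enhancer
## usage of TF-binding studies: promoter = +/-2 kb of TSS; enhancer = -50 kb
## upstream of and +5 kb downstream from the gene body (minus body and
## promoter); extended enhancer = the same with -100 kb. Assignment is by
## peak summit, per gene, in precedence order promoter > exon > intron >
## enhancer > extended_enhancer; ties between genes break to the smaller
## |TSS offset|; a peak matching no gene is intergenic.

#' Element window definitions
#'
#' @param promoter Promoter half-width around the TSS, bp (default 2000).
#' @param enhancer_upstream Upstream reach from the gene 5' end, bp
#'   (default 50000).
#' @param enhancer_downstream Downstream reach past the gene 3' end, bp
#'   (default 5000).
#' @param extended_upstream Upstream reach of the extended enhancer, bp
#'   (default 100000).
#' @param extended_downstream Downstream reach of the extended enhancer, bp
#'   (default 5000).
#' @return An `element_windows` list.
#' @export
element_windows <- function(promoter = 2000, enhancer_upstream = 50000,
                            enhancer_downstream = 5000,
                            extended_upstream = 1e5,
                            extended_downstream = 5000) {
  w <- list(promoter = promoter, enhancer_upstream = enhancer_upstream,
            enhancer_downstream = enhancer_downstream,
            extended_upstream = extended_upstream,
            extended_downstream = extended_downstream)
  if (any(unlist(w) < 0)) .fmt_stop("element windows must be non-negative")
  structure(w, class = "element_windows")
}

#' Signed TSS offset of a peak summit
#'
#' Summit position minus TSS in gene orientation: negative is upstream of the
#' TSS for the gene. For `-` strand genes the offset is `tss - summit`.
#'
#' @param peak One-row [chip_peaks()] slice (or list with `summit`).
#' @param gene One-row [gene_models()] slice (or list with `tss`, `strand`).
#' @return Signed integer bp.
#' @export
tss_offset <- function(peak, gene) {
  if (gene$strand == "+") peak$summit - gene$tss else gene$tss - peak$summit
}

## category of a summit for one gene; NA when no window matches
.categorize <- function(summit, gene, windows) {
  off <- if (gene$strand == "+") summit - gene$tss else gene$tss - summit
  if (abs(off) <= windows$promoter) return(list(cat = "promoter", off = off))
  in_body <- summit >= gene$gene_start && summit < gene$gene_end
  if (in_body) {
    ex <- gene$exons[[1L]]
    in_exon <- any(summit >= ex[, 1L] & summit < ex[, 2L])
    return(list(cat = if (in_exon) "exon" else "intron", off = off))
  }
  ## gene-oriented enhancer windows in genomic coordinates
  win <- function(up, down) {
    if (gene$strand == "+") c(gene$gene_start - up, gene$gene_end + down)
    else c(gene$gene_start - down, gene$gene_end + up)
  }
  e <- win(windows$enhancer_upstream, windows$enhancer_downstream)
  if (summit >= e[1L] && summit < e[2L]) return(list(cat = "enhancer", off = off))
  x <- win(windows$extended_upstream, windows$extended_downstream)
  if (summit >= x[1L] && summit < x[2L])
    return(list(cat = "extended_enhancer", off = off))
  NULL
}

.cat_rank <- c(promoter = 1L, exon = 2L, intron = 3L, enhancer = 4L,
               extended_enhancer = 5L, intergenic = 6L)

#' Annotate one ChIP peak with its genomic element
#'
#' @param peak One-row [chip_peaks()] slice.
#' @param models A [gene_models()] data.frame.
#' @param windows An [element_windows()] list.
#' @return List with `gene_id` (NA for intergenic), `category`, `tss_offset`.
#' @export
annotate_peak <- function(peak, models, windows = element_windows()) {
  cand <- models[models$chrom == peak$chrom, , drop = FALSE]
  reach <- max(windows$extended_upstream, windows$extended_downstream,
               windows$promoter)
  cand <- cand[peak$summit >= cand$gene_start - reach &
                 peak$summit < cand$gene_end + reach, , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    hit <- .categorize(peak$summit, cand[i, , drop = FALSE], windows)
    if (is.null(hit)) next
    hit$gene_id <- cand$gene_id[i]
    if (is.null(best) ||
        .cat_rank[[hit$cat]] < .cat_rank[[best$cat]] ||
        (.cat_rank[[hit$cat]] == .cat_rank[[best$cat]] &&
           abs(hit$off) < abs(best$off)))
      best <- hit
  }
  if (is.null(best))
    return(list(gene_id = NA_character_, category = "intergenic",
                tss_offset = NA_integer_))
  list(gene_id = best$gene_id, category = best$cat,
       tss_offset = as.integer(best$off))
}

#' Annotate many ChIP peaks
#'
#' @param peaks A [chip_peaks()] data.frame.
#' @param models A [gene_models()] data.frame.
#' @param windows An [element_windows()] list.
#' @return `element_annotations` data.frame: the peaks plus `gene_id`,
#'   `category`, `tss_offset`.
#' @export
annotate_peaks <- function(peaks, models, windows = element_windows()) {
  ann <- lapply(seq_len(nrow(peaks)), function(i)
    annotate_peak(peaks[i, , drop = FALSE], models, windows))
  out <- as.data.frame(peaks)
  out$gene_id <- vapply(ann, `[[`, character(1), "gene_id")
  out$category <- vapply(ann, `[[`, character(1), "category")
  out$tss_offset <- vapply(ann, `[[`, integer(1), "tss_offset")
  structure(out, class = c("element_annotations", "data.frame"))
}

#' Element distribution of annotated peaks
#'
#' @param annotations Output of [annotate_peaks()].
#' @return data.frame with `category`, `n`, `pct` over all six categories
#'   (zero-count categories included); percentages sum to 100. Zero rows for
#'   empty input.
#' @export
element_distribution <- function(annotations) {
  if (!nrow(annotations))
    return(data.frame(category = character(), n = integer(), pct = numeric()))
  cats <- names(.cat_rank)
  n <- vapply(cats, function(cc) sum(annotations$category == cc), integer(1))
  data.frame(category = cats, n = as.integer(n),
             pct = 100 * n / sum(n), row.names = NULL)
}

#' Intersect annotations with a pathway gene list
#'
#' @param annotations Output of [annotate_peaks()].
#' @param gene_list Character vector of gene ids of interest.
#' @return data.frame `(gene_id, peak, category, tss_offset, group)` of
#'   annotations whose assigned gene is in the list, sorted by |tss_offset|.
#' @export
intersect_gene_list <- function(annotations, gene_list) {
  sel <- !is.na(annotations$gene_id) & annotations$gene_id %in% gene_list
  out <- data.frame(
    gene_id = annotations$gene_id[sel],
    peak = annotations$name[sel],
    category = annotations$category[sel],
    tss_offset = annotations$tss_offset[sel],
    group = annotations$group_label[sel],
    stringsAsFactors = FALSE
  )
  out[order(abs(out$tss_offset)), , drop = FALSE]
}
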
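## io_formats: readers/writers for every external representation the pipeline
## touches. All internal coordinates are 0-based half-open; conversion to and
## from 1-based formats (GFF3) happens only here.

.fmt_stop <- function(...) stop(..., call. = FALSE)

#' Read a sample-to-group assignment from YAML
#'
#' The config lists the sample ids belonging to each of the two groups, e.g.
#' \preformatted{
#' groups:
#'   control: [C1, C2, C3]
#'   case: [D1, D2, D3]
#' }
#'
#' @param path Path to a YAML file.
#' @return Named character vector mapping sample id to `"control"`/`"case"`.
#' @export
read_group_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- if (!is.null(cfg$groups)) cfg$groups else cfg
  if (!all(c("control", "case") %in% names(g)))
    .fmt_stop("group config must name 'control' and 'case' sample lists")
  out <- c(
    stats::setNames(rep("control", length(g$control)), unlist(g$control)),
    stats::setNames(rep("case", length(g$case)), unlist(g$case))
  )
  if (anyDuplicated(names(out)))
    .fmt_stop("a sample id appears in both groups")
  out
}

.check_groups <- function(groups) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    .fmt_stop("group assignment must be a named vector (sample id -> group)")
  if (!setequal(unique(groups), c("control", "case")))
    .fmt_stop("samples must partition into exactly the two groups 'control' and 'case'")
  groups
}

#' Construct and validate a probe table
#'
#' A probe table holds, for each tiling probe, its genomic location (0-based
#' half-open), the promoter it belongs to, and one log2(MeDIP/Input) value per
#' sample. Rows are sorted by (chrom, start) and each promoter's probes must
#' form one contiguous, non-overlapping run.
#'
#' @param df data.frame with columns `probe_id`, `promoter_id`, `chrom`,
#'   `start`, `end` and one numeric column per sample.
#' @param groups Named character vector mapping each sample id to `"control"`
#'   or `"case"` (see [read_group_config()]).
#' @return A `probe_table` (data.frame subclass) with the group map stored in
#'   `attr(, "groups")`.
#' @export
probe_table <- function(df, groups) {
  groups <- .check_groups(groups)
  df <- as.data.frame(df)
  need <- c("probe_id", "promoter_id", "chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .fmt_stop("probe table missing column(s): ", paste(miss, collapse = ", "))
  samples <- names(groups)
  miss_s <- setdiff(samples, names(df))
  if (length(miss_s))
    .fmt_stop("probe table missing sample column(s): ", paste(miss_s, collapse = ", "))
  df <- df[, c(need, samples)]
  for (s in samples) {
    if (!is.numeric(df[[s]]) || anyNA(df[[s]]))
      .fmt_stop("sample column '", s, "' must be numeric with no missing values")
  }
  if (any(df$start >= df$end))
    .fmt_stop("probe intervals must satisfy start < end")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  ## per-promoter checks: one chrom, contiguous run, no overlap
  runs <- rle(df$promoter_id)
  if (anyDuplicated(runs$values))
    .fmt_stop("probes of a promoter must form one contiguous run after sorting")
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    i <- idx_start[k]:idx_end[k]
    if (length(unique(df$chrom[i])) != 1L)
      .fmt_stop("promoter '", runs$values[k], "' spans multiple chromosomes")
    if (length(i) > 1L && any(df$start[i][-1] < df$end[i][-length(i)]))
      .fmt_stop("overlapping or unsorted probes within promoter '", runs$values[k], "'")
  }
  structure(df, groups = groups, class = c("probe_table", "data.frame"))
}

#' @export
print.probe_table <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf(
    "probe_table: %d probes, %d promoters, %d samples (%d control / %d case)\n",
    nrow(x), length(unique(x$promoter_id)), length(g),
    sum(g == "control"), sum(g == "case")
  ))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

## accessors used across modules
pt_groups <- function(x) attr(x, "groups")
pt_samples <- function(x, group = NULL) {
  g <- pt_groups(x)
  if (is.null(group)) names(g) else names(g)[g == group]
}
pt_values <- function(x, samples = pt_samples(x)) {
  as.matrix(as.data.frame(x)[, samples, drop = FALSE])
}

#' Read a probe-level enrichment table
#'
#' Tab-delimited with header `probe_id promoter_id chrom start end <sample...>`
#' (coordinates 0-based half-open).
#'
#' @param path Path to the TSV.
#' @param group_assignment Named character vector (sample -> group) or the path
#'   to a YAML group config.
#' @return A validated [probe_table()].
#' @export
read_probe_table <- function(path, group_assignment) {
  if (is.character(group_assignment) && length(group_assignment) == 1L &&
      is.null(names(group_assignment)) && file.exists(group_assignment))
    group_assignment <- read_group_config(group_assignment)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  probe_table(df, group_assignment)
}

#' Write a probe table as TSV
#' @param x A [probe_table()].
#' @param path Output path.
#' @export
write_probe_table <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE)
  invisible(path)
}

## ---- gene models ------------------------------------------------------

#' Construct and validate gene models
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `strand` (`+`/`-`),
#'   `gene_start`, `gene_end` (0-based half-open gene body) and a list column
#'   `exons` of two-column matrices (start, end). The TSS is derived from
#'   strand: gene_start for `+`, gene_end - 1 for `-`.
#' @return A `gene_models` data.frame with a `tss` column added.
#' @export
gene_models <- function(df) {
  df <- as.data.frame(df)
  need <- c("gene_id", "chrom", "strand", "gene_start", "gene_end", "exons")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .fmt_stop("gene models missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    .fmt_stop("strand must be '+' or '-'")
  if (any(df$gene_start >= df$gene_end))
    .fmt_stop("gene body must satisfy gene_start < gene_end")
  df$tss <- ifelse(df$strand == "+", df$gene_start, df$gene_end - 1L)
  for (i in seq_len(nrow(df))) {
    ex <- df$exons[[i]]
    if (is.null(ex) || nrow(ex) == 0L) {
      df$exons[[i]] <- matrix(c(df$gene_start[i], df$gene_end[i]), ncol = 2L,
                              dimnames = list(NULL, c("start", "end")))
      next
    }
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    colnames(ex) <- c("start", "end")
    if (any(ex[, 1L] >= ex[, 2L]))
      .fmt_stop("exon with non-positive width in gene '", df$gene_id[i], "'")
    if (min(ex[, 1L]) < df$gene_start[i] || max(ex[, 2L]) > df$gene_end[i])
      .fmt_stop("exon outside gene body in gene '", df$gene_id[i], "'")
    if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
      .fmt_stop("overlapping exons in gene '", df$gene_id[i], "'")
    df$exons[[i]] <- ex
  }
  structure(df[, c("gene_id", "chrom", "strand", "tss", "gene_start",
                   "gene_end", "exons")],
            class = c("gene_models", "data.frame"))
}

.gff_like <- function(path) grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)

#' Read gene models from BED12 or GFF3
#'
#' The dialect is auto-detected from the file extension unless `format` is
#' given. GFF3 1-based closed coordinates are converted to the internal
#' 0-based half-open convention; the strand-aware TSS is computed (left end
#' for `+`, right end for `-`).
#'
#' @param path Input path.
#' @param format `"auto"`, `"bed"` or `"gff3"`.
#' @return A [gene_models()] data.frame.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (.gff_like(path)) "gff3" else "bed"
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    exons <- lapply(seq_along(gr), function(i) {
      gs <- GenomicRanges::start(gr)[i] - 1L
      bl <- gr$blocks[[i]]
      if (is.null(bl) || length(bl) == 0L) {
        matrix(c(gs, GenomicRanges::end(gr)[i]), ncol = 2L)
      } else {
        ## blocks are 1-based offsets relative to the feature start
        cbind(gs + IRanges::start(bl) - 1L, gs + IRanges::end(bl))
      }
    })
    df <- data.frame(
      gene_id = gr$name,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      gene_start = GenomicRanges::start(gr) - 1L,
      gene_end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    )
    df$exons <- exons
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gn <- gr[tolower(as.character(gr$type)) == "gene"]
    ex <- gr[tolower(as.character(gr$type)) == "exon"]
    ids <- as.character(gn$ID)
    parent <- vapply(ex$Parent, function(p) as.character(p)[1L], character(1))
    exons <- lapply(ids, function(id) {
      sel <- which(parent == id)
      if (!length(sel)) return(NULL)
      cbind(GenomicRanges::start(ex)[sel] - 1L, GenomicRanges::end(ex)[sel])
    })
    df <- data.frame(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(gn)),
      strand = as.character(GenomicRanges::strand(gn)),
      gene_start = GenomicRanges::start(gn) - 1L,
      gene_end = GenomicRanges::end(gn),
      stringsAsFactors = FALSE
    )
    df$exons <- exons
  }
  gene_models(df)
}

#' Write gene models as BED12 or GFF3
#' @param models A [gene_models()] data.frame.
#' @param path Output path.
#' @param format `"auto"` (from extension), `"bed"` or `"gff3"`.
#' @export
write_gene_models <- function(models, path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (.gff_like(path)) "gff3" else "bed"
  if (format == "bed") {
    gr <- GenomicRanges::GRanges(
      models$chrom,
      IRanges::IRanges(models$gene_start + 1L, models$gene_end),
      strand = models$strand
    )
    gr$name <- models$gene_id
    gr$score <- 0L
    gr$thick <- IRanges::ranges(gr)
    gr$blocks <- IRanges::IRangesList(lapply(seq_len(nrow(models)), function(i) {
      ex <- models$exons[[i]]
      IRanges::IRanges(ex[, 1L] - models$gene_start[i] + 1L,
                       ex[, 2L] - models$gene_start[i])
    }))
    rtracklayer::export(gr, path, format = "bed")
  } else {
    gn <- GenomicRanges::GRanges(
      models$chrom,
      IRanges::IRanges(models$gene_start + 1L, models$gene_end),
      strand = models$strand
    )
    gn$type <- "gene"
    gn$ID <- models$gene_id
    gn$Parent <- IRanges::CharacterList(vector("list", nrow(models)))
    n_ex <- vapply(models$exons, nrow, integer(1))
    gi <- rep(seq_len(nrow(models)), n_ex)
    ex_all <- do.call(rbind, models$exons)
    ex <- GenomicRanges::GRanges(
      models$chrom[gi],
      IRanges::IRanges(ex_all[, 1L] + 1L, ex_all[, 2L]),
      strand = models$strand[gi]
    )
    ex$type <- "exon"
    ex$ID <- sprintf("%s.exon%d", models$gene_id[gi],
                     unlist(lapply(n_ex, seq_len)))
    ex$Parent <- IRanges::CharacterList(as.list(models$gene_id[gi]))
    all <- suppressWarnings(c(gn, ex))
    rtracklayer::export(all, path, format = "gff3")
  }
  invisible(path)
}

## ---- ChIP peaks -------------------------------------------------------

#' Construct and validate ChIP peaks
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `summit` (absolute bp), and optionally `name`, `score`, `group_label`.
#' @return A `chip_peaks` data.frame.
#' @export
chip_peaks <- function(df) {
  df <- as.data.frame(df)
  if (is.null(df$name)) df$name <- sprintf("peak_%d", seq_len(nrow(df)))
  if (is.null(df$score)) df$score <- rep(0, nrow(df))
  if (is.null(df$group_label)) df$group_label <- rep("", nrow(df))
  need <- c("chrom", "start", "end", "summit")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .fmt_stop("chip peaks missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) && any(df$summit < df$start | df$summit >= df$end))
    .fmt_stop("peak summit outside [start, end)")
  structure(df[, c("chrom", "start", "end", "name", "score", "summit",
                   "group_label")],
            class = c("chip_peaks", "data.frame"))
}

#' Read ChIP peaks from BED
#'
#' Standard BED (0-based half-open). When a 7th column is present it is taken
#' as the summit offset from the interval start (MACS convention); otherwise
#' the summit is the interval midpoint.
#'
#' @param path Input BED path.
#' @param group_label Label attached to every peak (e.g. `"case"`).
#' @return A [chip_peaks()] data.frame.
#' @export
read_peaks_bed <- function(path, group_label = "") {
  df <- utils::read.table(path, sep = "", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3L) .fmt_stop("BED file needs at least 3 columns")
  out <- data.frame(
    chrom = as.character(df[[1L]]),
    start = as.integer(df[[2L]]),
    end = as.integer(df[[3L]]),
    stringsAsFactors = FALSE
  )
  out$name <- if (ncol(df) >= 4L) as.character(df[[4L]]) else
    sprintf("peak_%d", seq_len(nrow(df)))
  out$score <- if (ncol(df) >= 5L) as.numeric(df[[5L]]) else 0
  out$summit <- if (ncol(df) >= 7L) out$start + as.integer(df[[7L]]) else
    (out$start + out$end) %/% 2L
  out$group_label <- group_label
  chip_peaks(out)
}

#' Write ChIP peaks as BED6+summit
#' @param peaks A [chip_peaks()] data.frame.
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t.\t%d",
                   peaks$chrom, peaks$start, peaks$end, peaks$name,
                   peaks$score, peaks$summit - peaks$start)
  writeLines(lines, path)
  invisible(path)
}

#' Write called DMEPs as BED
#'
#' Emits one BED6 row per differential peak (class other than `"none"`); the
#' score is |M'| x 1000 capped at 1000, the name carries the promoter id and
#' class.
#'
#' @param called Output of [call_dmeps()].
#' @param path Output path.
#' @export
write_dmeps_bed <- function(called, path) {
  d <- called[called$dmep_class != "none", , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t%d\t.",
                   d$chrom, d$start, d$end, d$promoter_id, d$dmep_class,
                   pmin(1000L, as.integer(round(abs(d$m_prime) * 1000))))
  writeLines(lines, path)
  invisible(path)
}

## ---- sequences --------------------------------------------------------

#' Read a FASTA file of promoter sequences
#'
#' Sequences are upper-cased; ambiguity codes other than A/C/G/T/N are
#' rejected.
#'
#' @param path FASTA path.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  freq <- Biostrings::alphabetFrequency(ss)
  other <- rowSums(freq[, setdiff(colnames(freq), c("A", "C", "G", "T", "N")),
                        drop = FALSE])
  if (any(other > 0))
    .fmt_stop("sequence '", names(ss)[which(other > 0)[1L]],
              "' contains ambiguity codes other than ACGTN")
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' Write named sequences as FASTA
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

## ---- bisulfite clone matrices ----------------------------------------

#' Construct a bisulfite clone matrix
#'
#' Calls are `"M"` (methylated), `"U"` (unmethylated) or `"X"` (undetermined),
#' one row per sequenced clone and one column per CpG site.
#'
#' @param calls Character matrix of `"M"`/`"U"`/`"X"`.
#' @param region_id Region identifier.
#' @param clone_ids Row (clone) identifiers; defaults to `clone_1..n`.
#' @param site_positions Column (CpG site) genomic positions, bp.
#' @return A `bs_clones` object.
#' @export
bs_clones <- function(calls, region_id = "region",
                      clone_ids = NULL, site_positions = NULL) {
  calls <- as.matrix(calls)
  if (!all(calls %in% c("M", "U", "X")))
    .fmt_stop("clone calls must be 'M', 'U' or 'X'")
  if (nrow(calls) < 1L || ncol(calls) < 1L)
    .fmt_stop("clone matrix must have at least one clone and one site")
  if (is.null(clone_ids)) clone_ids <- sprintf("clone_%d", seq_len(nrow(calls)))
  if (is.null(site_positions)) site_positions <- seq_len(ncol(calls))
  if (length(clone_ids) != nrow(calls) || length(site_positions) != ncol(calls))
    .fmt_stop("clone matrix dimensions inconsistent with labels")
  dimnames(calls) <- list(clone_ids, as.character(site_positions))
  structure(list(region_id = region_id, clone_ids = clone_ids,
                 site_positions = site_positions, calls = calls),
            class = "bs_clones")
}

#' @export
print.bs_clones <- function(x, ...) {
  cat(sprintf("bs_clones '%s': %d clones x %d CpG sites (%.1f%% methylated of determined)\n",
              x$region_id, nrow(x$calls), ncol(x$calls),
              100 * methylation_ratio(x)))
  invisible(x)
}

#' Read bisulfite clone matrices from TSV
#'
#' Format: header `region_id clone_id <pos...>` with one M/U/X code per site
#' column; one object is returned per region.
#'
#' @param path Input TSV.
#' @return Named list of [bs_clones()] objects, one per region.
#' @export
read_bisulfite <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("region_id", "clone_id") %in% names(df)))
    .fmt_stop("bisulfite TSV needs 'region_id' and 'clone_id' columns")
  sites <- setdiff(names(df), c("region_id", "clone_id"))
  lapply(split(df, df$region_id), function(d) {
    bs_clones(as.matrix(d[, sites, drop = FALSE]), region_id = d$region_id[1L],
              clone_ids = d$clone_id,
              site_positions = as.integer(sites))
  })
}

#' Write bisulfite clone matrices as TSV
#' @param x A [bs_clones()] object or list of them.
#' @param path Output path.
#' @export
write_bisulfite <- function(x, path) {
  if (inherits(x, "bs_clones")) x <- list(x)
  dfs <- lapply(x, function(m) {
    cbind(data.frame(region_id = m$region_id, clone_id = m$clone_ids,
                     stringsAsFactors = FALSE),
          as.data.frame(m$calls, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, dfs)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
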
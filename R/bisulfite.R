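## bisulfite: score clone x CpG-site call matrices and compare methylation
## between groups. Undetermined calls ("X", the crossed markers of lollipop
## diagrams) are excluded from numerator and denominator, never imputed.

#' Overall methylation ratio of a clone matrix
#'
#' Methylated count / (methylated + unmethylated), undetermined excluded.
#'
#' @param matrix A [bs_clones()] object.
#' @return Numeric in `[0, 1]`.
#' @export
methylation_ratio <- function(matrix) {
  stopifnot(inherits(matrix, "bs_clones"))
  m <- sum(matrix$calls == "M")
  u <- sum(matrix$calls == "U")
  if (m + u == 0L) .fmt_stop("no determined calls in clone matrix")
  m / (m + u)
}

.ratio_vec <- function(mm, uu) ifelse(mm + uu == 0L, NA_real_, mm / (mm + uu))

#' Per-clone methylation ratios
#' @param matrix A [bs_clones()] object.
#' @return Named numeric vector, one ratio per clone (NA when a clone has no
#'   determined call).
#' @export
per_clone_ratios <- function(matrix) {
  stopifnot(inherits(matrix, "bs_clones"))
  stats::setNames(
    .ratio_vec(rowSums(matrix$calls == "M"), rowSums(matrix$calls == "U")),
    matrix$clone_ids)
}

#' Per-site methylation ratios
#' @param matrix A [bs_clones()] object.
#' @return Named numeric vector, one ratio per CpG site (NA when a site has
#'   only undetermined calls; such sites are excluded from summaries).
#' @export
per_site_ratios <- function(matrix) {
  stopifnot(inherits(matrix, "bs_clones"))
  stats::setNames(
    .ratio_vec(colSums(matrix$calls == "M"), colSums(matrix$calls == "U")),
    as.character(matrix$site_positions))
}

#' Compare methylation between two clone matrices
#'
#' Two-sided unpaired t test (Student's by default) on per-clone methylation
#' ratios (the sequenced colonies are the biological replicates); per-site
#' ratios available via `by = "site"`.
#'
#' @param matrix_a,matrix_b Two [bs_clones()] objects.
#' @param by `"clone"` (default) or `"site"`.
#' @param var_equal Assume equal variances (default TRUE); FALSE gives Welch.
#' @return List with `ratio_a`, `ratio_b`, `delta` (a - b), and `t_p`
#'   (NA when both samples are constant).
#' @export
compare_methylation <- function(matrix_a, matrix_b, by = c("clone", "site"),
                                var_equal = TRUE) {
  by <- match.arg(by)
  f <- if (by == "clone") per_clone_ratios else per_site_ratios
  a <- f(matrix_a); a <- a[!is.na(a)]
  b <- f(matrix_b); b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    .fmt_stop("need at least 2 ", by, "s with determined calls per group")
  p <- .ttest_p(a, b, var_equal)
  list(ratio_a = methylation_ratio(matrix_a),
       ratio_b = methylation_ratio(matrix_b),
       delta = mean(a) - mean(b), t_p = p)
}

.lolli_chr <- c(M = "*", U = "o", X = "x")

#' Export a clone matrix as a text lollipop grid
#'
#' One row per clone: `*` methylated, `o` unmethylated, `x` undetermined;
#' the header carries the region id and site positions. [read_lollipop()]
#' parses the format back.
#'
#' @param matrix A [bs_clones()] object.
#' @param path Output path, or NULL to return the lines invisibly printed.
#' @return The text lines, invisibly.
#' @export
lollipop_export <- function(matrix, path = NULL) {
  stopifnot(inherits(matrix, "bs_clones"))
  if (nrow(matrix$calls) == 0L || ncol(matrix$calls) == 0L)
    .fmt_stop("empty clone matrix")
  wid <- max(nchar(matrix$clone_ids))
  header <- sprintf("#region=%s sites=%s", matrix$region_id,
                    paste(matrix$site_positions, collapse = ","))
  body <- vapply(seq_len(nrow(matrix$calls)), function(i) {
    sprintf("%-*s %s", wid, matrix$clone_ids[i],
            paste(.lolli_chr[matrix$calls[i, ]], collapse = ""))
  }, character(1))
  lines <- c(header, body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Parse a text lollipop grid back into a clone matrix
#'
#' @param path Path to a file written by [lollipop_export()] (or a character
#'   vector of its lines).
#' @return A [bs_clones()] object.
#' @export
read_lollipop <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  if (!grepl("^#region=", lines[1L]))
    .fmt_stop("not a lollipop grid: missing '#region=' header")
  header <- lines[1L]
  region <- sub("^#region=(\\S+) sites=.*$", "\\1", header)
  sites <- as.integer(strsplit(sub("^.*sites=", "", header), ",")[[1L]])
  body <- lines[-1L][nzchar(lines[-1L])]
  ids <- sub("\\s+\\S+$", "", body)
  rows <- sub("^.*\\s", "", body)
  inv <- stats::setNames(names(.lolli_chr), .lolli_chr)
  calls <- t(vapply(strsplit(rows, "", fixed = TRUE),
                    function(ch) inv[ch], character(length(sites))))
  if (length(sites) == 1L) calls <- matrix(calls, ncol = 1L)
  bs_clones(calls, region_id = region, clone_ids = trimws(ids),
            site_positions = sites)
}
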
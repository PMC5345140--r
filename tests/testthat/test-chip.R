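test_that("TSS offsets are signed in gene orientation", {
  gp <- list(tss = 100000L, strand = "+")
  gm <- list(tss = 100000L, strand = "-")
  expect_equal(tss_offset(list(summit = 103011L), gp), 3011L)
  expect_equal(tss_offset(list(summit = 120391L), gm), -20391L)
  expect_equal(tss_offset(list(summit = 100000L), gp), 0L)
  expect_equal(tss_offset(list(summit = 100000L), gm), 0L)
})

test_that("peaks are assigned to elements in precedence order", {
  models <- toy_models()
  ## gplus: body 100000..120000 (+), exon3 110000..112000
  mk_peak <- function(summit) list(chrom = "chr1", summit = summit)

  ## inside promoter window beats everything
  expect_equal(annotate_peak(mk_peak(100500L), models)$category, "promoter")
  ## summit in the third exon, beyond the +/-2kb promoter
  a <- annotate_peak(mk_peak(110500L), models)
  expect_equal(a$category, "exon")
  expect_equal(a$gene_id, "gplus")
  ## same summit with the exon context removed becomes intronic context
  no_ex <- models
  no_ex$exons[[1]] <- rbind(c(100000L, 100100L))
  expect_equal(annotate_peak(mk_peak(110500L), no_ex)$category, "intron")
  ## upstream within 50 kb: enhancer
  e <- annotate_peak(mk_peak(100000L - 16676L), models)
  expect_equal(e$category, "enhancer")
  expect_equal(e$tss_offset, -16676L)
  ## beyond 50 kb but within 100 kb: extended enhancer only
  x <- annotate_peak(mk_peak(100000L - 95988L), models)
  expect_equal(x$category, "extended_enhancer")
  ## 1 Mb from every gene: intergenic
  far <- annotate_peak(mk_peak(5000000L), models)
  expect_equal(far$category, "intergenic")
  expect_true(is.na(far$gene_id))

  ## minus-strand gene: upstream is to the right of the gene
  em <- annotate_peak(mk_peak(models$tss[2] + 20391L), models)
  expect_equal(em$gene_id, "gminus")
  expect_equal(em$category, "enhancer")
  expect_equal(em$tss_offset, -20391L)
})

test_that("the promoter category is exactly the +/-2kb offset window", {
  models <- toy_models()
  for (off in c(-2000L, -1999L, 0L, 1999L, 2000L)) {
    a <- annotate_peak(list(chrom = "chr1", summit = models$tss[1] + off), models)
    expect_equal(a$category, "promoter", info = off)
    expect_equal(a$tss_offset, off)
  }
  a <- annotate_peak(list(chrom = "chr1", summit = models$tss[1] - 2001L), models)
  expect_false(a$category == "promoter")
})

test_that("annotation is invariant under translation and strand flip", {
  models <- toy_models()
  peaks <- simulate_chip_peaks(models, c(gplus = -16676, gplus = 3011,
                                         gminus = -20391, gminus = 500),
                               n_decoys = 2L, seed = 2L)
  ann <- annotate_peaks(peaks, models)

  shift <- 123456L
  m2 <- models
  m2$gene_start <- m2$gene_start + shift; m2$gene_end <- m2$gene_end + shift
  m2$tss <- m2$tss + shift
  m2$exons <- lapply(m2$exons, function(e) e + shift)
  p2 <- peaks
  p2$start <- p2$start + shift; p2$end <- p2$end + shift
  p2$summit <- p2$summit + shift
  ann2 <- annotate_peaks(p2, m2)
  expect_equal(ann2$category, ann$category)
  expect_equal(ann2$tss_offset, ann$tss_offset)

  ## mirror the whole locus around a point and flip strands
  M <- 4000000L
  m3 <- models
  m3$strand <- ifelse(models$strand == "+", "-", "+")
  m3$gene_start <- M - models$gene_end
  m3$gene_end <- M - models$gene_start
  m3$tss <- ifelse(m3$strand == "+", m3$gene_start, m3$gene_end - 1L)
  m3$exons <- lapply(models$exons, function(e)
    cbind(M - e[, 2], M - e[, 1])[rev(seq_len(nrow(e))), , drop = FALSE])
  p3 <- peaks
  p3$summit <- M - 1L - peaks$summit
  p3$start <- M - peaks$end; p3$end <- M - peaks$start
  ann3 <- annotate_peaks(p3, m3)
  expect_equal(ann3$category, ann$category)
})

test_that("every peak gets exactly one category and distributions partition", {
  models <- toy_models()
  peaks <- simulate_chip_peaks(models, c(gplus = 0, gplus = 3011,
                                         gplus = -30000, gminus = -95988),
                               n_decoys = 3L, seed = 4L)
  ann <- annotate_peaks(peaks, models)
  dist <- element_distribution(ann)
  expect_equal(sum(dist$n), nrow(peaks))
  expect_equal(sum(dist$pct), 100)
  expect_equal(nrow(element_distribution(ann[0, ])), 0L)

  ## planted categories recovered exactly
  expect_equal(ann$category[1:4],
               c("promoter", "exon", "enhancer", "extended_enhancer"))
  expect_equal(ann$category[5:7], rep("intergenic", 3L))
})

test_that("enhancer and extended enhancer coincide in the window limit", {
  models <- toy_models()
  peaks <- simulate_chip_peaks(models, c(gplus = -40000, gplus = -80000,
                                         gminus = -60000), seed = 1L)
  w_wide <- element_windows(promoter = 0, enhancer_upstream = 1e5)
  ann <- annotate_peaks(peaks, models, w_wide)
  expect_true(all(ann$category == "enhancer"))
})

test_that("gene-list intersection returns only listed genes sorted by |offset|", {
  models <- toy_models()
  peaks <- simulate_chip_peaks(models, c(gplus = -30000, gminus = -20391,
                                         gplus = 3011), n_decoys = 2L, seed = 9L)
  ann <- annotate_peaks(peaks, models)
  out <- intersect_gene_list(ann, c("gminus", "gplus"))
  expect_equal(nrow(out), 3L)
  expect_equal(out$tss_offset, c(3011L, -20391L, -30000L))
  expect_equal(nrow(intersect_gene_list(ann, character(0))), 0L)
  expect_equal(nrow(intersect_gene_list(ann, "absent_gene")), 0L)
})
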
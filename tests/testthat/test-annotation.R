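genes_fixture <- tibble::tibble(
  gene_id = c("gA", "gB"),
  chrom = "chr1",
  strand = c("+", "-"),
  tss = c(10000L, 40000L),
  tx_start = c(10000L, 25001L),
  tx_end = c(20000L, 40001L),
  cds_start = c(10400L, 25400L),
  cds_end = c(19600L, 39600L),
  first_exon_end = c(10900L, 39100L)
)

test_that("nearest-TSS mapping follows distance and tie rules", {
  probes <- tibble::tibble(
    probe_id = c("at_tss", "boundary", "near", "far", "tie"),
    chrom = "chr1",
    pos = c(10000L, 20000L, 10300L, 60000L, 25000L)
  )
  g <- tibble::tibble(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                      tss = c(10000L, 30000L, 20000L))
  out <- map_probes_to_genes(probes, g)
  expect_equal(out$gene_id[out$probe_id == "at_tss"], "gA")
  expect_equal(out$tss_distance[out$probe_id == "at_tss"], 0)
  expect_equal(out$gene_id[out$probe_id == "boundary"], "gC")  # distance 0 to gC
  expect_equal(out$gene_id[out$probe_id == "near"], "gA")      # 300 < 9700
  expect_true(is.na(out$gene_id[out$probe_id == "far"]))
  # equidistant between gC (20000) and gB (30000): lexicographic gB
  expect_equal(out$gene_id[out$probe_id == "tie"], "gB")
})

test_that("a TSS exactly max_dist away does not map", {
  probes <- tibble::tibble(probe_id = "p", chrom = "chr1", pos = 0L)
  g <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 10000L)
  expect_true(is.na(map_probes_to_genes(probes, g)$gene_id))
  g2 <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 9999L)
  expect_equal(map_probes_to_genes(probes, g2)$gene_id, "g")
})

test_that("mapping agrees with the all-pairs oracle on random layouts", {
  withr::with_seed(37, {
    for (i in 1:10) {
      ng <- sample(3:50, 1)
      g <- tibble::tibble(
        gene_id = sprintf("g%02d", seq_len(ng)),
        chrom = sample(c("chr1", "chr2"), ng, replace = TRUE),
        tss = sample.int(2e5, ng)
      )
      probes <- tibble::tibble(
        probe_id = sprintf("p%02d", 1:30),
        chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
        pos = sample.int(2e5, 30)
      )
      expect_equal(map_probes_to_genes(probes, g),
                   nearest_tss_oracle(probes, g))
    }
  })
})

test_that("region classification matches the definitions on both strands", {
  gA <- genes_fixture[1, ]   # plus strand, TSS 10000
  expect_equal(classify_region(9900, gA), "TSS200")
  expect_equal(classify_region(9000, gA), "TSS1500")
  expect_equal(classify_region(10100, gA), "5'UTR")   # before cds_start
  expect_equal(classify_region(10600, gA), "1stExon") # past cds_start
  expect_equal(classify_region(15000, gA), "Body")
  expect_equal(classify_region(19700, gA), "3'UTR")
  expect_equal(classify_region(30000, gA), "IGR")
  gB <- genes_fixture[2, ]   # minus strand, TSS 40000
  expect_equal(classify_region(40100, gB), "TSS200")
  expect_equal(classify_region(41000, gB), "TSS1500")
  expect_equal(classify_region(39800, gB), "5'UTR")
  expect_equal(classify_region(39300, gB), "1stExon")
  expect_equal(classify_region(30000, gB), "Body")
  expect_equal(classify_region(25100, gB), "3'UTR")
  bad <- gA
  bad$cds_end <- bad$tx_end + 10
  expect_error(classify_region(15000, bad), "Malformed")
})

test_that("every position gets exactly one region category", {
  withr::with_seed(41, {
    pos <- sample.int(60000, 500)
  })
  for (i in 1:2) {
    r <- classify_region(pos, genes_fixture[i, ])
    expect_true(all(r %in% c("TSS200", "TSS1500", "5'UTR", "1stExon",
                             "Body", "3'UTR", "IGR")))
    expect_length(r, 500)
  }
})

test_that("CpG context follows the Illumina distance bands", {
  islands <- tibble::tibble(chrom = "chr1", start = 10000L, end = 11000L)
  expect_equal(classify_cpg_context(10500, islands), "island")
  expect_equal(classify_cpg_context(10999, islands), "island")
  expect_equal(classify_cpg_context(11000, islands), "shore")  # half-open end
  expect_equal(classify_cpg_context(8500, islands), "shore")   # 1500 bp away
  expect_equal(classify_cpg_context(7000, islands), "shelf")   # 3000 bp away
  expect_equal(classify_cpg_context(5000, islands), "open_sea") # 5000 bp
  expect_equal(classify_cpg_context(123, islands[0, ]), "open_sea")
})

test_that("genomic distribution percentages are integer-rounded shares", {
  ctx <- tibble::tibble(
    probe_id = paste0("cg", 1:4),
    chrom = "chr1", pos = 1:4, gene_id = NA, tss_distance = NA,
    region = c("Body", "Body", "IGR", "IGR"),
    cpg_context = c("island", "island", "open_sea", "open_sea")
  )
  dmps <- tibble::tibble(probe_id = paste0("cg", 1:4), is_dmp = TRUE)
  out <- summarize_genomic_distribution(ctx, dmps)
  isl <- out[out$dimension == "cpg_context" & out$category == "island", ]
  expect_equal(isl$percent, 50)
  # the published island share: 45 of 925 rounds to 5%
  ctx2 <- tibble::tibble(
    probe_id = paste0("cg", 1:925),
    chrom = "chr1", pos = 1:925, gene_id = NA, tss_distance = NA,
    region = "Body",
    cpg_context = c(rep("island", 45), rep("open_sea", 880))
  )
  out2 <- summarize_genomic_distribution(ctx2)
  isl2 <- out2[out2$dimension == "cpg_context" & out2$category == "island", ]
  expect_equal(isl2$n, 45)
  expect_equal(isl2$percent, 5)
  # percentages sum to 100 within rounding error
  sums <- tapply(out2$percent, out2$dimension, sum)
  expect_true(all(abs(sums - 100) <= 1))
  # empty DMP set: empty table, no division error
  none <- tibble::tibble(probe_id = character(), is_dmp = logical())
  expect_equal(nrow(summarize_genomic_distribution(ctx, none)), 0)
})

test_that("annotate_probes combines mapping, region and context", {
  probes <- tibble::tibble(
    probe_id = c("prom", "body", "lost"),
    chrom = "chr1",
    pos = c(9900L, 14000L, 300000L)
  )
  islands <- tibble::tibble(chrom = "chr1", start = 9500L, end = 10500L)
  out <- annotate_probes(probes, genes_fixture, islands)
  expect_equal(out$gene_id, c("gA", "gA", NA))
  expect_equal(out$region, c("TSS200", "Body", "IGR"))
  expect_equal(out$cpg_context, c("island", "shelf", "open_sea"))
})
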
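test_that("the logit2 transform hits its closed-form anchors and inverts", {
  expect_identical(beta_to_mvalue(0.5), 0)
  expect_equal(beta_to_mvalue(0.8), 2)
  eps <- 1e-6
  expect_equal(beta_to_mvalue(0, epsilon = eps),
               log(eps / (1 - eps)) / log(2), tolerance = 1e-12)
  # bijection on the clipped interval
  b <- seq(1e-5, 1 - 1e-5, length.out = 101)
  expect_equal(mvalue_to_beta(beta_to_mvalue(b)), b, tolerance = 1e-12)
  # strictly increasing
  expect_true(all(diff(beta_to_mvalue(b)) > 0))
  expect_error(beta_to_mvalue(1.2), "outside")
  expect_error(beta_to_mvalue(0.5, epsilon = 0.7), "epsilon")
})

test_that("probe filtering removes two probes per rule, in order, idempotently", {
  mm <- toy_manifest()
  out <- filter_probes(mm, toy_blacklist())
  expect_identical(unname(out$report[c("ch", "sex", "blacklist", "kept")]),
                   c(2L, 2L, 2L, 4L))
  expect_identical(out$matrix$probe_ids, c("cg0001", "cg0002", "cg0003", "cg0004"))
  # the chrX ch. probe was counted under the ch rule only
  expect_identical(unname(out$report[["sex"]]), 2L)
  again <- filter_probes(out$matrix, toy_blacklist())
  expect_identical(again$matrix, out$matrix)
  expect_true(all(again$report[c("ch", "sex", "blacklist")] == 0L))
  # removing everything is allowed but warns
  expect_warning(filter_probes(out$matrix, out$matrix$probe_ids), "all probes")
})

test_that("simple spellings of sex chromosomes are all caught", {
  mm <- methylation_matrix(matrix(0.1, 4, 2,
                                  dimnames = list(paste0("cg", 1:4), NULL)),
                           chrom = c("X", "chrX", "Y", "chrY"),
                           pos = 1:4, scale = "beta")
  expect_warning(out <- filter_probes(mm), "all probes")
  expect_identical(unname(out$report[["sex"]]), 4L)
})

test_that("strand-aware promoter extension matches the hand enumeration", {
  set.seed(1)
  gm <- map_cpgs_to_genes(toy_annotation(), toy_probes_matrix(), upstream = 500L)
  expect_identical(gm$gene, c("A", "B", "C", "D", "E"))
  expect_identical(gm$K, c(2L, 2L, 1L, 2L, 1L))
  expect_identical(sort(gm$probes[[1]]), c("p1", "p2"))
  expect_identical(sort(gm$probes[[2]]), c("p2", "p3"))
  expect_identical(gm$probes[[3]], "p5")
  expect_identical(sort(gm$probes[[4]]), c("p6", "p7"))
  expect_identical(gm$probes[[5]], "p6")
  # plus strand extends upstream of start, minus strand past end
  expect_identical(gm$extended_start[gm$gene == "A"], 500L)
  expect_identical(gm$extended_end[gm$gene == "B"], 3000L)
  # shared probe p2 appears in both overlapping genes: multi-mapping inflates
  expect_gte(sum(gm$K), length(unique(unlist(gm$probes))))
})

test_that("gene-map edge cases error or drop as documented", {
  ann <- toy_annotation()
  bad <- ann; bad$strand[1] <- "*"
  expect_error(map_cpgs_to_genes(bad, toy_probes_matrix()), "strand")
  bad2 <- ann; bad2$start[1] <- 10000L
  expect_error(map_cpgs_to_genes(bad2, toy_probes_matrix()), "start > end")
  # a gene with no probes is excluded and recorded
  lonely <- rbind(ann, data.frame(gene = "F", chrom = "chr9", strand = "+",
                                  start = 1L, end = 10L))
  set.seed(1)
  expect_message(gm <- map_cpgs_to_genes(lonely, toy_probes_matrix()),
                 "zero member probes")
  expect_false("F" %in% gm$gene)
  expect_identical(attr(gm, "dropped"), "F")
})

test_that("BED and GFF3 annotations read back on the 1-based inclusive convention", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tA\t0\t+",
               "chr2\t99\t300\tE\t0\t-"), bed)
  expect_message(ann <- read_annotation(bed), "1-based")
  expect_identical(ann$start, c(1000L, 100L))
  expect_identical(ann$end, c(2000L, 300L))
  expect_identical(ann$gene, c("A", "E"))

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=gene:A;Name=A",
               "chr1\tsrc\texon\t1000\t1200\t.\t+\t.\tID=exon:A.1"), gff)
  ann2 <- read_annotation(gff)
  expect_identical(nrow(ann2), 1L)
  expect_identical(ann2$start, 1000L)
  expect_identical(ann2$gene, "A")
})

test_that("a written study round-trips through the file readers", {
  st <- simulate_study(6, c(H00 = 0.5, H11 = 0.5),
                       sim_scenario("H11", n = 40, K = 3), seed = 90)
  d <- withr::local_tempdir()
  paths <- write_sim_study(st, d)
  mm <- read_methylation(paths[["methylation"]])
  expect_identical(mm$scale, "M")
  expect_equal(mm$values, st$methylation$values, tolerance = 1e-12)
  expect_identical(mm$probe_ids, st$methylation$probe_ids)
  ph <- read_phenotypes(paths[["phenotypes"]])
  expect_equal(ph$outcome, st$phenotypes$outcome, tolerance = 1e-12)
  expect_message(ann <- read_annotation(paths[["annotation"]]), "1-based")
  expect_identical(ann$start, st$gene_map$start)
  expect_identical(ann$end, as.integer(st$gene_map$end))
  # blacklist reader
  bl <- tempfile(); writeLines(c("cg0000001", "", "cg0000002"), bl)
  expect_identical(read_blacklist(bl), c("cg0000001", "cg0000002"))
  expect_identical(read_blacklist(NULL), character())
})
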
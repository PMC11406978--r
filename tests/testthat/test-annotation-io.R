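write_tiny_bundle <- function(dir, gff_lines, fasta_lines,
                              domain_df = NULL, id = "G1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(dir, paste0(id, ".gff3"))
  fa <- file.path(dir, paste0(id, ".faa"))
  writeLines(gff_lines, gff)
  writeLines(fasta_lines, fa)
  dom <- NULL
  if (!is.null(domain_df)) {
    dom <- file.path(dir, paste0(id, ".domains.tsv"))
    write.table(domain_df, dom, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(gff = gff, fa = fa, dom = dom)
}

test_that("an empty genome bundle reads to an empty model", {
  d <- withr::local_tempdir()
  p <- write_tiny_bundle(d, "##gff-version 3", character())
  ann <- read_genome(p$fa, p$gff)
  expect_s3_class(ann, "genome_annotation")
  expect_equal(nrow(ann$contigs), 0L)
  expect_equal(nrow(ann$genes), 0L)
  expect_length(ann$proteins, 0L)
})

test_that("ranks follow coordinate order within a contig", {
  d <- withr::local_tempdir()
  gff <- c("##gff-version 3",
           "##sequence-region ctg 1 2000",
           "ctg\tsrc\tgene\t100\t400\t.\t+\t.\tID=g1",
           "ctg\tsrc\tgene\t500\t900\t.\t-\t.\tID=g2",
           "ctg\tsrc\tgene\t1000\t1200\t.\t+\t.\tID=g3")
  fa <- c(">g1", "MKL", ">g2", "MNP", ">g3", "MQR")
  p <- write_tiny_bundle(d, gff, fa)
  ann <- read_genome(p$fa, p$gff)
  expect_equal(ann$genes$gene_id, c("g1", "g2", "g3"))
  expect_equal(ann$genes$rank, 1:3)
  expect_equal(ann$genes$strand, c("+", "-", "+"))
})

test_that("rank assignment ignores input record order", {
  genes <- data.frame(gene_id = c("b", "a", "c"), contig_id = "ctg",
                      start = c(500L, 100L, 900L),
                      end = c(700L, 300L, 1100L), strand = "+")
  a1 <- genome_annotation("G", genes)
  a2 <- genome_annotation("G", genes[c(3, 1, 2), ])
  expect_identical(a1$genes, a2$genes)
  expect_equal(a1$genes$gene_id[a1$genes$rank], c("a", "b", "c"))
})

test_that("malformed GFF3 lines are reported with their line number", {
  d <- withr::local_tempdir()
  gff <- c("##gff-version 3",
           "ctg\tsrc\tgene\t100\t400\t.\t+\t.\tID=g1",
           "ctg src gene broken-line")
  p <- write_tiny_bundle(d, gff, c(">g1", "MKL"))
  expect_error(read_genome(p$fa, p$gff), "line 3")
})

test_that("protein/gene ID mismatches name the orphans", {
  d <- withr::local_tempdir()
  gff <- c("##gff-version 3",
           "ctg\tsrc\tgene\t100\t400\t.\t+\t.\tID=g1")
  p <- write_tiny_bundle(d, gff, c(">gX", "MKL"))
  expect_error(read_genome(p$fa, p$gff), "gX")
})

test_that("partial attributes and contig-terminus overlap mark genes partial", {
  d <- withr::local_tempdir()
  gff <- c("##gff-version 3",
           "##sequence-region ctg 1 1500",
           "ctg\tsrc\tgene\t100\t400\t.\t+\t.\tID=g1;partial=true",
           "ctg\tsrc\tgene\t500\t900\t.\t+\t.\tID=g2;partial=false",
           "ctg\tsrc\tgene\t1000\t1500\t.\t+\t.\tID=g3;partial=false")
  p <- write_tiny_bundle(d, gff, c(">g1", "MK", ">g2", "ML", ">g3", "MN"))
  ann <- read_genome(p$fa, p$gff)
  expect_equal(ann$genes$partial, c(TRUE, FALSE, TRUE))
})

test_that("generator output survives a write/read round trip", {
  gs <- generate_genome_set(generator_config(n_genomes = 2, seed = 11))
  d <- withr::local_tempdir()
  write_genome_bundle(gs$genomes, d, truth = gs$truth)
  back <- read_genome_bundle(d)
  expect_setequal(names(back), names(gs$genomes))
  for (id in names(gs$genomes)) {
    a <- gs$genomes[[id]]; b <- back[[id]]
    expect_identical(b$genes, a$genes)
    expect_identical(sort(names(b$proteins)), sort(names(a$proteins)))
    expect_identical(b$proteins[names(a$proteins)], a$proteins)
    expect_identical(b$domains[sort(names(b$domains))],
                     a$domains[sort(names(a$domains))])
    expect_identical(b$contigs, a$contigs)
  }
})

test_that("cluster report round-trips and keeps its column contract", {
  d <- withr::local_tempdir()
  path <- file.path(d, "report.tsv")
  write_cluster_report(NULL, path)
  empty <- read.delim(path)
  expect_equal(nrow(empty), 0L)
  expect_equal(names(empty),
               c("genome_id", "contig_id", "anchor", "roles", "subtype",
                 "flags", "retained", "capability", "reasons"))

  one <- data.frame(genome_id = "G", contig_id = "c", anchor = "a1",
                    roles = "ABC", subtype = "II", flags = "D_absent",
                    retained = TRUE, capability = "non_bifurcating",
                    reasons = "")
  write_cluster_report(one, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 1L)
  expect_equal(back$subtype, "II")

  gs <- generate_genome_set(generator_config(n_genomes = 3, seed = 5))
  run <- run_pipeline(gs$genomes)
  write_cluster_report(run$calls, path)
  again <- read.delim(path)
  expect_equal(nrow(again), run$summary$anchors)
})
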
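fixture_genes <- function() {
  data.frame(contig = c("c1", "c1", "c1"),
             start = c(100L, 900L, 2000L), end = c(400L, 1200L, 2300L),
             strand = c("+", "-", "+"),
             id = c("gA", "gB", "gC"),
             product = c("alpha", "beta", "gamma"),
             seq = c("MKL", "MNP", "MQR"), stringsAsFactors = FALSE)
}

test_that("CDS features get consecutive locus_index by ascending start", {
  d <- tempfile(); fx <- write_fixture_genome(d, fixture_genes())
  g <- read_genome(fx$gff, fx$faa, "G1", "Hyphomicrobiales")
  expect_s3_class(g, "Genome")
  expect_equal(g$genes$locus_index, 0:2)
  expect_equal(g$genes$gene_id, c("gA", "gB", "gC"))
  expect_equal(g$genes$protein_seq, c("MKL", "MNP", "MQR"))
  expect_equal(g$genes$strand, c("+", "-", "+"))
})

test_that("locus numbering restarts on each contig", {
  genes <- fixture_genes()
  genes$contig <- c("c1", "c2", "c2")
  d <- tempfile(); fx <- write_fixture_genome(d, genes)
  g <- read_genome(fx$gff, fx$faa, "G1", "Hyphomicrobiales")
  expect_equal(g$genes$locus_index[g$genes$contig_id == "c1"], 0L)
  expect_equal(g$genes$locus_index[g$genes$contig_id == "c2"], 0:1)
})

test_that("a GFF3 with zero CDS features yields an empty genome", {
  gff <- tempfile(fileext = ".gff3"); faa <- tempfile(fileext = ".faa")
  writeLines(c("##gff-version 3",
               "c1\ttest\tgene\t1\t90\t.\t+\t.\tID=rna1"), gff)
  writeLines(character(0), faa)
  g <- suppressMessages(read_genome(gff, faa, "G0", "Rhodobacterales"))
  expect_equal(nrow(g$genes), 0L)
})

test_that("malformed GFF3 lines are reported with their line number", {
  gff <- tempfile(fileext = ".gff3"); faa <- tempfile(fileext = ".faa")
  writeLines(c("##gff-version 3",
               "c1\ttest\tCDS\t1\t90\t.\t+\t0\tID=g1",
               "c1\ttest\tCDS\t100"), gff)
  writeLines(c(">g1", "MK"), faa)
  expect_error(read_genome(gff, faa, "G1", "o"), "line 3")
})

test_that("duplicate gene ids error and unmatched FASTA records warn", {
  genes <- fixture_genes()
  genes$id <- c("gA", "gA", "gC")
  d <- tempfile(); fx <- write_fixture_genome(d, genes)
  expect_error(read_genome(fx$gff, fx$faa, "G1", "o"), "duplicate gene_id")

  genes2 <- fixture_genes()
  d2 <- tempfile(); fx2 <- write_fixture_genome(d2, genes2)
  cat(">orphan\nMWW\n", file = fx2$faa, append = TRUE)
  expect_warning(read_genome(fx2$gff, fx2$faa, "G1", "o"), "orphan")
})

test_that("pseudogenes (CDS without FASTA record) are retained without sequence", {
  genes <- fixture_genes()
  d <- tempfile(); fx <- write_fixture_genome(d, genes)
  fa <- readLines(fx$faa)
  writeLines(fa[1:4], fx$faa)  # drop gC record
  g <- read_genome(fx$gff, fx$faa, "G1", "o")
  expect_equal(nrow(g$genes), 3L)
  expect_true(is.na(g$genes$protein_seq[g$genes$gene_id == "gC"]))
})

test_that("genome collections load per metadata row with order preserved", {
  d <- tempfile(); dir.create(d)
  write_fixture_genome(d, fixture_genes(), "G1")
  write_fixture_genome(d, fixture_genes(), "G2")
  meta <- data.frame(genome_id = c("G2", "G1"),
                     taxon_order = c("Rhodobacterales", "Hyphomicrobiales"),
                     gff3 = c("G2.gff3", "G1.gff3"),
                     faa = c("G2.faa", "G1.faa"), stringsAsFactors = FALSE)
  mp <- file.path(d, "metadata.tsv"); write_table(meta, mp)
  gs <- load_genome_collection(d, mp)
  expect_length(gs, 2L)
  expect_equal(names(gs), c("G2", "G1"))
  expect_equal(gs[["G2"]]$taxon_order, "Rhodobacterales")

  # empty metadata -> empty list
  write_table(meta[0, ], mp)
  expect_length(load_genome_collection(d, mp), 0L)

  # blank taxon_order -> error naming the row
  meta$taxon_order[1] <- ""
  write_table(meta, mp)
  expect_error(load_genome_collection(d, mp), "row 1")

  # missing file -> error listing the row
  meta$taxon_order[1] <- "x"; meta$gff3[1] <- "nope.gff3"
  write_table(meta, mp)
  expect_error(load_genome_collection(d, mp), "missing file")
})

test_that("tables round-trip and reads are permissive about extra columns", {
  tab <- data.frame(taxon_order = c("A", "TOTAL"), n_genomes = c(3L, 3L),
                    n_phnA_hits = c(2L, 2L), stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  write_table(tab, p)
  back <- read_table(p, required_cols = names(tab))
  expect_equal(back, tab)
  p2 <- tempfile(fileext = ".tsv")
  write_table(back, p2)
  expect_identical(readLines(p), readLines(p2))  # byte-identical rewrite

  back$extra <- "keep"
  write_table(back, p2)
  again <- read_table(p2, required_cols = names(tab))
  expect_equal(again$extra, rep("keep", 2))

  expect_error(read_table(p, required_cols = c("nope")), "nope")

  empty <- tab[0, ]
  write_table(empty, p)
  expect_equal(nrow(read_table(p, required_cols = names(tab))), 0L)
})

test_that("a Genome survives the gene-table round trip field by field", {
  d <- tempfile(); fx <- write_fixture_genome(d, fixture_genes())
  g <- read_genome(fx$gff, fx$faa, "G1", "Hyphomicrobiales")
  p <- tempfile(fileext = ".tsv")
  write_gene_table(g, p)
  g2 <- read_gene_table(p)
  expect_equal(g2$genome_id, g$genome_id)
  expect_equal(g2$taxon_order, g$taxon_order)
  expect_equal(g2$genes, g$genes)
})

test_that("genome validation catches broken locus ordering", {
  d <- tempfile(); fx <- write_fixture_genome(d, fixture_genes())
  g <- read_genome(fx$gff, fx$faa, "G1", "o")
  g$genes$locus_index <- c(0L, 2L, 3L)
  expect_error(validate_genome(g), "locus_index")
})
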
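# GenBank/FASTA parsing and the annotated-genome coordinate conventions.

make_gb_file <- function(records, path = tempfile(fileext = ".gbk")) {
  writeLines(unlist(records), path)
  path
}

gb_record <- function(id, len, features, seq = NULL) {
  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     linear   BCT 01-JAN-2000", id, len),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", len),
    features)
  if (!is.null(seq)) {
    lines <- c(lines, "ORIGIN",
               sprintf("%9d %s", 1, tolower(seq)))
  }
  c(lines, "//")
}

cds <- function(loc, product = "hypothetical protein", extra = character()) {
  c(sprintf("     CDS             %s", loc),
    sprintf("                     /product=\"%s\"", product),
    extra)
}

test_that("GenBank coordinates convert to 0-based half-open and genes sort by start", {
  path <- make_gb_file(gb_record("rec1", 1000, c(
    cds("complement(5..10)"),
    cds("2..4"),
    cds("101..400"))))
  g <- read_genbank(path)
  expect_equal(g$genes$start, c(1, 4, 100))
  expect_equal(g$genes$end, c(4, 10, 400))
  expect_equal(g$genes$strand, c("+", "-", "+"))
  expect_equal(g$genes$index, 0:2)
  # length preservation: end-start == gb_end - gb_start + 1
  expect_equal(g$genes$end - g$genes$start, c(4 - 2 + 1, 10 - 5 + 1, 400 - 101 + 1))
})

test_that("multi-record files keep empty contigs with a warning; counts match a text scan", {
  recs <- list(
    gb_record("r1", 5000, unlist(lapply(c("11..100", "201..300", "401..500", "601..700"), cds))),
    gb_record("r2", 2000, character()),
    gb_record("r3", 3000, unlist(lapply(c("21..120", "301..400"), cds))))
  path <- make_gb_file(recs)
  expect_warning(g <- read_genbank(path), "zero CDS")
  expect_equal(nrow(g$contigs), 3)
  n_cds_text <- sum(grepl("^     CDS ", readLines(path)))
  expect_equal(nrow(g$genes), n_cds_text)
  expect_equal(nrow(g$genes), 6)
})

test_that("joined locations collapse to their envelope; origin-wrapping features are skipped", {
  path <- make_gb_file(gb_record("rj", 5000, c(
    cds("join(11..100,201..300)"),
    cds("join(4500..5000,1..50)"))))
  expect_warning(g <- read_genbank(path), "origin-spanning")
  expect_equal(nrow(g$genes), 1)
  expect_equal(c(g$genes$start, g$genes$end), c(10, 300))
})

test_that("missing translations are recomputed with table 11 and round-trip via write_genbank", {
  seq <- paste0("ATGGCTGCAACC", "TAA",
                random_dna_str(85))  # MAAT + stop, then padding
  path <- make_gb_file(gb_record("rt", nchar(seq), cds("1..15"), seq = seq))
  g <- read_genbank(path)
  expect_equal(g$genes$protein_seq, "MAAT")

  # explicit translation qualifier wins over recomputation
  path2 <- make_gb_file(gb_record("rt2", nchar(seq),
                                  cds("1..15", extra = '                     /translation="MKLV"'),
                                  seq = seq))
  expect_equal(read_genbank(path2)$genes$protein_seq, "MKLV")

  out <- tempfile(fileext = ".gbk")
  write_genbank(g, out)
  g2 <- read_genbank(out)
  expect_equal(g2$genes[c("contig_id", "start", "end", "strand", "kind")],
               g$genes[c("contig_id", "start", "end", "strand", "kind")])
  expect_equal(toupper(g2$contigs$sequence), toupper(g$contigs$sequence))
})

test_that("read_fasta uppercases, masks non-ACGTN and rejects duplicates", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">c1 desc", "acgt"), fa)
  contigs <- read_fasta(fa)
  expect_equal(contigs$id, "c1")
  expect_equal(contigs$sequence, "ACGT")
  expect_equal(contigs$length, 4L)

  writeLines(c(">c1", "ACRT"), fa)
  expect_warning(masked <- read_fasta(fa), "masked")
  expect_equal(masked$sequence, "ACNT")

  writeLines(c(">c1", "ACGT", ">c1", "GGGG"), fa)
  expect_error(read_fasta(fa), "duplicate")

  writeLines(character(), fa)
  expect_error(read_fasta(fa))
})

test_that("attach_annotations validates, re-sorts and is order-invariant and idempotent", {
  contigs <- tibble::tibble(id = "c1", sequence = NA_character_, length = 10000)
  genes <- gene_tbl(contig_id = "c1", start = c(100, 2000, 900),
                    end = c(500, 2500, 1500), strand = "+",
                    protein_id = c("a", "b", "c"))
  g1 <- attach_annotations(contigs, annotation_provider_table(genes))
  expect_equal(g1$genes$index, 0:2)
  expect_equal(g1$genes$protein_id, c("a", "c", "b"))

  # out-of-order emission gives the same genome as sorted emission
  g2 <- attach_annotations(contigs, annotation_provider_table(genes[c(3, 1, 2), ]))
  expect_equal(g2$genes, g1$genes)

  # idempotent on already-valid sorted input
  g3 <- attach_annotations(contigs, annotation_provider_table(g1$genes))
  expect_equal(g3$genes, g1$genes)

  bad <- gene_tbl(contig_id = "missing", start = 1, end = 10, strand = "+")
  expect_error(attach_annotations(contigs, annotation_provider_table(bad)),
               "unknown contig")
  bad2 <- gene_tbl(contig_id = "c1", start = 50, end = 50, strand = "+")
  expect_error(attach_annotations(contigs, annotation_provider_table(bad2)),
               "invalid span")
})

test_that("gene features written as GFF3 round-trip through an independent reader", {
  set.seed(41)
  fx <- generate_genome(implant_spec(n_background_genes = 15, n_prophages = 1,
                                     cassette_genes = 6, seed = 41))
  path <- tempfile(fileext = ".gff3")
  write_genes_gff3(fx$genome, path)
  gr <- rtracklayer::import(path)
  back <- tibble::tibble(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,  # back to 0-based half-open
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = as.character(gr$type))
  orig <- fx$genome$genes[c("contig_id", "start", "end", "strand", "kind")]
  expect_equal(back[order(back$start), ], orig[order(orig$start), ],
               ignore_attr = TRUE)
})
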
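# Hit-table parsing, phage-like calling and taxonomy extraction.

hit_row <- function(query, subject = "S1", evalue = 1e-20, bitscore = 200,
                    title = NULL) {
  fields <- c(query, subject, "90.0", "100", "5", "0", "1", "100", "1", "100",
              format(evalue, scientific = TRUE), format(bitscore))
  if (!is.null(title)) fields <- c(fields, title)
  paste(fields, collapse = "\t")
}

test_that("hit tables parse in both dialects, skipping bad rows with a warning", {
  path <- tempfile()
  writeLines(c(
    hit_row("p1", "sp|Q9T0V1|CAPSD_BPT7", 1e-30, 250,
            "Major capsid protein OS=Escherichia virus T7 OX=10760 PE=1"),
    hit_row("p2", "S2", 1e-5, 40, "some protein")), path)
  hits <- read_hit_table(path, "tab13")
  expect_equal(nrow(hits), 2)
  expect_equal(hits$query_id[1], "p1")
  expect_equal(hits$evalue[1], 1e-30)
  expect_equal(hits$bitscore[1], 250)
  expect_match(hits$subject_title[1], "OS=Escherichia virus T7")

  # tab12: same rows without the title column
  writeLines(c(hit_row("p1"), hit_row("p2")), path)
  h12 <- read_hit_table(path, "tab12")
  expect_true(all(is.na(h12$subject_title)))

  # 12-column file parsed as tab13 -> parse error (title column missing)
  expect_error(read_hit_table(path, "tab13"), "dialect")

  # one corrupt numeric row among three -> skipped with warning
  writeLines(c(hit_row("p1"), gsub("1e-20", "not_a_number", hit_row("p2")),
               hit_row("p3")), path)
  expect_warning(h <- read_hit_table(path, "tab12"), "skipped")
  expect_equal(h$query_id, c("p1", "p3"))

  # empty file -> empty tibble with warning
  writeLines(character(), path)
  expect_warning(he <- read_hit_table(path, "tab12"), "empty")
  expect_equal(nrow(he), 0)

  expect_error(read_hit_table(tempfile(), "tab12"), "cannot read")
})

test_that("the e-value ceiling is strict and the best hit follows the tie rule", {
  genes <- gene_tbl(contig_id = "c1", start = c(0, 1000), end = c(900, 1900),
                    strand = "+", protein_id = c("p1", "p2"))
  hits <- tibble::tibble(
    query_id = c("p1", "p1", "p2"),
    subject_id = c("B", "A", "C"),
    percent_identity = 90, align_length = 100, mismatch = 0, gapopen = 0,
    qstart = 1, qend = 100, sstart = 1, send = 100,
    evalue = c(1e-6, 1e-8, 1e-7),
    bitscore = c(50, 100, 60),
    subject_title = NA_character_)
  calls <- call_phage_like(genes, hits, evalue_max = 1e-7)
  # p1 called with its 1e-8 hit; p2 at exactly 1e-7 is NOT called
  expect_equal(calls$protein_id, "p1")
  expect_equal(calls$evalue, 1e-8)
  expect_equal(calls$subject_id, "A")

  # e-value ties break by max bitscore, then lexicographic subject id
  tie <- hits
  tie$evalue <- 1e-9
  tie$bitscore <- c(80, 80, 10)
  calls_tie <- call_phage_like(genes, tie, evalue_max = 1e-7)
  expect_equal(calls_tie$subject_id[calls_tie$protein_id == "p1"], "A")

  # hits for unknown genes are ignored with a warning
  orphan <- hits[1, ]
  orphan$query_id <- "nope"
  expect_warning(none <- call_phage_like(genes, orphan), "no gene")
  expect_equal(nrow(none), 0)
})

test_that("calls match a brute-force per-gene minimum scan on random hit sets", {
  set.seed(101)
  for (rep in 1:20) {
    n_genes <- 30
    genes <- random_layout(n_genes)
    n_hits <- sample(20:120, 1)
    hits <- tibble::tibble(
      query_id = sample(genes$protein_id, n_hits, replace = TRUE),
      subject_id = sprintf("S%02d", sample(1:20, n_hits, replace = TRUE)),
      percent_identity = 90, align_length = 100, mismatch = 0, gapopen = 0,
      qstart = 1, qend = 100, sstart = 1, send = 100,
      evalue = 10^runif(n_hits, -20, -2),
      bitscore = sample(30:300, n_hits, replace = TRUE),
      subject_title = NA_character_)
    ceiling <- 1e-7
    calls <- call_phage_like(genes, hits, evalue_max = ceiling)

    # brute force: for each gene scan all its hits
    for (pid in genes$protein_id) {
      h <- hits[hits$query_id == pid & hits$evalue < ceiling, ]
      if (nrow(h) == 0) {
        expect_false(pid %in% calls$protein_id)
      } else {
        h <- h[order(h$evalue, -h$bitscore, h$subject_id), ]
        row <- calls[calls$protein_id == pid, ]
        expect_equal(nrow(row), 1)
        expect_equal(row$subject_id, h$subject_id[1])
        expect_equal(row$evalue, h$evalue[1])
      }
    }
    # permutation invariance and e-value monotonicity
    perm <- call_phage_like(genes, hits[sample(nrow(hits)), ], evalue_max = ceiling)
    expect_equal(perm, calls)
    fewer <- call_phage_like(genes, hits, evalue_max = ceiling / 100)
    expect_true(all(fewer$protein_id %in% calls$protein_id))
  }
})

test_that("taxonomy extraction handles UniProt OS=, NCBI brackets and fallbacks", {
  expect_equal(extract_taxon("Major capsid protein OS=Escherichia virus T7 OX=10760 PE=1"),
               "Escherichia virus T7")
  expect_equal(extract_taxon("terminase large subunit [Salmonella phage P22]"),
               "Salmonella phage P22")
  expect_equal(extract_taxon("integrase OS=Listeria phage A118"),
               "Listeria phage A118")
  expect_equal(extract_taxon(c("", NA, "no markers here")),
               c("unknown", "unknown", "unknown"))
  # configurable override regex
  expect_equal(extract_taxon("tax:Lambda|rest", taxon_regex = "tax:([^|]+)"),
               "Lambda")
})
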
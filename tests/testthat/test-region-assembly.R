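# Cluster merging, att-site detection and taxonomy voting.

mk_cluster <- function(start, end, members = list(0L), source = "DBSCAN",
                       contig = "c1") {
  tibble::tibble(contig_id = contig, start = start, end = end,
                 n_members = lengths(members),
                 member_indices = members, source = source)
}

test_that("intersecting clusters merge transitively; touching half-open intervals do not", {
  cl <- dplyr::bind_rows(
    mk_cluster(1000, 8000, list(c(1L, 2L)), "DBSCAN"),
    mk_cluster(7000, 12000, list(c(2L, 3L)), "SWA"))
  m <- merge_clusters(cl)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(1000, 12000))
  expect_equal(m$sources[[1]], c("DBSCAN", "SWA"))
  expect_equal(m$member_indices[[1]], 1:3)

  touch <- dplyr::bind_rows(mk_cluster(1000, 2000), mk_cluster(2000, 3000))
  expect_equal(nrow(merge_clusters(touch)), 2)
})

test_that("merging equals brute-force transitive closure, idempotently, in any order", {
  set.seed(31)
  for (rep in 1:100) {
    k <- sample(2:12, 1)
    s <- sample(0:50000, k)
    e <- s + sample(500:15000, k, replace = TRUE)
    cl <- mk_cluster(s, e, members = as.list(seq_len(k)),
                     source = sample(c("DBSCAN", "SWA"), k, replace = TRUE))
    got <- merge_clusters(cl)
    want <- oracle_merge(s, e)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want[, 1])
    expect_equal(got$end, want[, 2])
    # idempotence: merging its own output is a no-op
    again <- merge_clusters(got)
    expect_equal(again$start, got$start)
    expect_equal(again$end, got$end)
    expect_equal(again$member_indices, got$member_indices)
    # permutation invariance
    perm <- merge_clusters(cl[sample(k), ])
    expect_equal(perm, got)
    # pairwise disjoint per contig
    if (nrow(got) > 1) expect_true(all(got$start[-1] >= head(got$end, -1)))
  }
})

# a tiny genome with one integrase and controllable flank sequences
flank_genome <- function(up_seq, down_seq, pad = 40) {
  # layout: [gene A][up_seq][integrase][down_seq][gene B]
  a_len <- 300; int_len <- 300; b_len <- 300
  a_start <- pad
  up_start <- a_start + a_len
  int_start <- up_start + nchar(up_seq)
  down_start <- int_start + int_len
  b_start <- down_start + nchar(down_seq)
  total <- b_start + b_len + pad
  seq <- random_dna_str(total)
  substr(seq, up_start + 1, up_start + nchar(up_seq)) <- up_seq
  substr(seq, down_start + 1, down_start + nchar(down_seq)) <- down_seq
  genes <- gene_tbl(
    contig_id = "c1",
    start = c(a_start, int_start, b_start),
    end = c(a_start + a_len, int_start + int_len, b_start + b_len),
    strand = "+",
    product = c("hypothetical protein", "phage integrase", "hypothetical protein"),
    protein_id = c("pa", "pint", "pb"))
  annotated_genome(tibble::tibble(id = "c1", sequence = seq, length = total),
                   genes)
}

region_over <- function(genome) {
  tibble::tibble(contig_id = "c1", start = min(genome$genes$start),
                 end = max(genome$genes$end),
                 member_indices = list(genome$genes$index),
                 sources = list("DBSCAN"))
}

test_that("a planted 15 bp direct repeat is recovered; 11 bp repeats are rejected", {
  set.seed(37)
  plant <- random_dna_str(15)
  up <- paste0(random_dna_str(150), plant, random_dna_str(150))
  down <- paste0(random_dna_str(100), plant, random_dna_str(200))
  g <- flank_genome(up, down)
  att <- detect_att(region_over(g)[1, ], g, flank_genes = 10, min_len = 12)
  expect_false(is.null(att))
  expect_gte(att$att_length, 15)
  expect_equal(att$att_seq_L, att$att_seq_R)
  expect_true(grepl(plant, att$att_seq_L, fixed = TRUE) ||
                att$att_length > 15)  # a longer chance repeat may outrank it
  expect_lte(att$attL_end, att$attR_start)

  # an 11-bp plant alone stays below the length threshold
  repeat {
    plant11 <- random_dna_str(11)
    up11 <- paste0(random_dna_str(60), plant11, random_dna_str(60))
    down11 <- paste0(random_dna_str(40), plant11, random_dna_str(80))
    # ensure no chance >= 12 bp common substring
    if (is.null(oracle_lcs(up11, down11, 12))) break
  }
  g11 <- flank_genome(up11, down11)
  expect_null(detect_att(region_over(g11)[1, ], g11, flank_genes = 10, min_len = 12))
})

test_that("regions without an integrase or without sequence yield no att pair", {
  g <- flank_genome(random_dna_str(100), random_dna_str(100))
  g$genes$product[2] <- "recombination protein"  # no 'integrase' anywhere
  expect_null(detect_att(region_over(g)[1, ], g))

  g2 <- flank_genome(random_dna_str(100), random_dna_str(100))
  g2$contigs$sequence <- NA_character_
  expect_warning(res <- detect_att(region_over(g2)[1, ], g2), "lacks sequence")
  expect_null(res)
})

test_that("builtin aligner equals the longest-common-substring oracle on random flank pairs", {
  set.seed(43)
  n_with_plant <- 0
  for (rep in 1:50) {
    up <- random_dna_str(sample(80:200, 1))
    down <- random_dna_str(sample(80:200, 1))
    if (rep %% 2 == 0) {  # plant a repeat of length 10-40 in half the cases
      plant <- random_dna_str(sample(10:40, 1))
      iu <- sample(seq_len(nchar(up) - nchar(plant)), 1)
      id <- sample(seq_len(nchar(down) - nchar(plant)), 1)
      substr(up, iu, iu + nchar(plant) - 1) <- plant
      substr(down, id, id + nchar(plant) - 1) <- plant
      if (nchar(plant) >= 12) n_with_plant <- n_with_plant + 1
    }
    m <- align_exact_repeats(up, down, min_len = 12)
    m <- m[m$length >= 12 & m$strand == "+", ]
    best <- if (nrow(m)) m[order(-m$score, -m$length, m$qstart, m$sstart), ][1, ] else NULL
    want <- oracle_lcs(up, down, 12)
    if (is.null(want)) {
      expect_null(best)
    } else {
      expect_false(is.null(best))
      expect_equal(best$length, want$length)
      expect_equal(best$qstart, want$qstart)
      expect_equal(best$sstart, want$sstart)
    }
  }
  expect_gte(n_with_plant, 10)  # the planted cases actually exercised recovery
})

test_that("taxonomy votes follow the counting oracle with lexicographic tie-break", {
  region <- tibble::tibble(contig_id = "c1", start = 0, end = 10000)
  mk_calls <- function(taxa) {
    n <- length(taxa)
    tibble::tibble(contig_id = "c1", start = seq(0, by = 500, length.out = n),
                   end = seq(0, by = 500, length.out = n) + 400, taxon = taxa)
  }
  t1 <- assign_taxonomy(region, mk_calls(c("T7", "T7", "T7", "P22")))
  expect_equal(t1$taxon, "T7")
  expect_equal(t1$fraction, 0.75)
  expect_false(t1$tie)

  t2 <- assign_taxonomy(region, mk_calls(c("unknown", "unknown")))
  expect_equal(t2$taxon, "unassigned")
  expect_equal(t2$fraction, 0)

  t3 <- assign_taxonomy(region, mk_calls(c("B", "A", "A", "B")))
  expect_equal(t3$taxon, "A")
  expect_true(t3$tie)

  # genes outside the region do not vote
  calls <- mk_calls(c("T7", "T7"))
  calls$start[2] <- 20000; calls$end[2] <- 20400
  t4 <- assign_taxonomy(region, calls)
  expect_equal(t4$fraction, 1)

  set.seed(47)
  labels <- c("A", "B", "C", "unknown")
  for (rep in 1:100) {
    taxa <- sample(labels, sample(1:12, 1), replace = TRUE)
    got <- assign_taxonomy(region, mk_calls(taxa))
    want <- oracle_mode(taxa)
    expect_equal(got$taxon, want$taxon)
    expect_equal(got$fraction, want$fraction)
    expect_gte(got$fraction, 0)
    expect_lte(got$fraction, 1)
  }
})

test_that("finalize extends regions to the att pair and numbers them in coordinate order", {
  set.seed(53)
  fx <- generate_genome(implant_spec(n_background_genes = 100, n_prophages = 2,
                                     cassette_genes = 12, seed = 53))
  hits <- generate_hit_table(fx$genome, fx$truth,
                             implant_spec(n_background_genes = 100,
                                          n_prophages = 2, seed = 53))
  calls <- call_phage_like(fx$genome$genes, hits)
  merged <- merge_clusters(cluster_phage_like(calls))
  fin <- finalize_regions(merged, fx$genome, calls)
  expect_equal(fin$region_id,
               paste0("synth_contig_1_prophage_", seq_len(nrow(fin))))
  expect_true(all(diff(fin$start) > 0))
  # att extension: where an att pair exists, region covers it
  has_att <- !is.na(fin$att_length)
  expect_true(any(has_att))
  expect_true(all(fin$start[has_att] <= fin$attL_start[has_att]))
  expect_true(all(fin$end[has_att] >= fin$attR_end[has_att]))
  expect_true(all(fin$att_seq_L[has_att] == fin$att_seq_R[has_att]))
  # member genes lie within the final span
  for (i in seq_len(nrow(fin))) {
    g <- fx$genome$genes[fx$genome$genes$index %in% fin$member_indices[[i]], ]
    expect_true(all(g$start >= fin$start[i] & g$end <= fin$end[i]))
  }
})

test_that("the blastn short-task adapter finds the same planted repeat as the builtin aligner", {
  set.seed(59)
  plant <- random_dna_str(20)
  up <- paste0(random_dna_str(90), plant, random_dna_str(90))
  down <- paste0(random_dna_str(60), plant, random_dna_str(120))
  builtin <- align_exact_repeats(up, down, min_len = 12)
  builtin <- builtin[builtin$length >= 12 & builtin$strand == "+", ][1, ]
  external <- align_blastn(up, down, min_len = 12)
  external <- external[external$length >= 12 & external$strand == "+", ]
  expect_gte(nrow(external), 1)
  top <- external[1, ]
  # blastn may extend slightly differently but must cover the planted copy
  expect_lte(top$qstart, builtin$qstart + 2)
  expect_gte(top$qend, builtin$qend - 2)
  expect_gte(top$length, 18)
})
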
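# Deterministic synthetic genomes with implanted prophage cassettes, used to
# test every stage of the pipeline offline.

HOUSEKEEPING_PRODUCTS <- c(
  "DNA polymerase III subunit alpha", "30S ribosomal protein S4",
  "hypothetical protein", "ABC transporter ATP-binding protein",
  "elongation factor Tu", "citrate synthase", "aminotransferase class I",
  "two-component sensor histidine kinase", "50S ribosomal protein L2",
  "NADH-quinone oxidoreductase subunit"
)

CASSETTE_PRODUCTS <- c(
  "phage portal protein", "terminase large subunit",
  "phage major capsid protein", "phage tail fiber protein",
  "baseplate assembly protein", "phage tail tape measure protein",
  "phage holin", "phage lysozyme", "phage antirepressor protein",
  "major head protein", "virion structural protein"
)

SYNTH_TAXA <- c("Escherichia virus T7", "Salmonella virus P22",
                "Enterobacteria phage lambda")

#' Specification of a synthetic implanted-prophage genome
#'
#' @param n_background_genes Housekeeping genes on the contig.
#' @param n_prophages Implanted prophage cassettes.
#' @param cassette_genes Genes per cassette (1..19; the integrase sits
#'   mid-cassette so both planted att repeats fall within its 10-gene
#'   flanks).
#' @param keyword_fraction Fraction of cassette genes given phage-keyword
#'   products.
#' @param gene_len Gene length in bp.
#' @param intra_gap Gap between consecutive cassette genes (must not exceed
#'   the clustering `max_gap`).
#' @param att_len Planted direct-repeat length (0 = none; otherwise >= 12).
#' @param seed Integer seed; the whole fixture is reproducible from it.
#' @return A validated list of class `implant_spec`.
#' @export
implant_spec <- function(n_background_genes = 100, n_prophages = 1,
                         cassette_genes = 12, keyword_fraction = 0.7,
                         gene_len = 900, intra_gap = 100, att_len = 15,
                         seed = 1) {
  stopifnot(cassette_genes >= 1, cassette_genes <= 19,
            keyword_fraction >= 0, keyword_fraction <= 1,
            att_len == 0 || att_len >= 12,
            gene_len >= 30, intra_gap >= 0, n_prophages >= 0)
  need <- if (n_prophages > 0) 10 + 61 * (n_prophages - 1) else 0
  if (n_background_genes < need) {
    stop("need at least ", need, " background genes to separate ",
         n_prophages, " cassette(s) by more than one scan window")
  }
  structure(list(n_background_genes = n_background_genes,
                 n_prophages = n_prophages, cassette_genes = cassette_genes,
                 keyword_fraction = keyword_fraction, gene_len = gene_len,
                 intra_gap = intra_gap, att_len = att_len,
                 seed = as.integer(seed)),
            class = "implant_spec")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
random_protein <- function(n) paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                                           n, replace = TRUE), collapse = "")

#' Generate a synthetic annotated genome with implanted prophages
#'
#' Background genes carry housekeeping products with intergenic gaps drawn
#' uniformly from 200-800 bp; each cassette is a dense run (`intra_gap`
#' spacing) of `cassette_genes` genes, `keyword_fraction` of which get
#' phage-keyword products. When `att_len > 0` one cassette gene (placed
#' mid-cassette) is an integrase and an identical `att_len`-bp repeat is
#' planted in the intergenic gaps immediately flanking the cassette. Fully
#' reproducible from `spec$seed`; truth regions are separated by more than
#' 3,000 bp so they can never chain together under default clustering.
#'
#' @param spec An [implant_spec()].
#' @return List with `genome` (an [annotated_genome()], `source =
#'   "synthetic"`) and `truth` (tibble: `prophage_id`, `contig_id`, `start`,
#'   `end`, `member_protein_ids` list, `attL_start`, `attL_end`,
#'   `attR_start`, `attR_end`, `taxon`).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "implant_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  n_bg <- spec$n_background_genes
  n_pro <- spec$n_prophages
  # background chunk sizes between/around cassettes: internal chunks exceed
  # one scan window (61 genes) so no sliding window can bridge two cassettes;
  # edge chunks get at least 5 genes
  chunk <- if (n_pro == 0) n_bg else {
    base <- c(5, rep(61, max(0, n_pro - 1)), 5)
    left <- n_bg - sum(base)
    add <- left %/% length(base)
    base <- base + add
    rem <- n_bg - sum(base)
    if (rem > 0) base[seq_len(rem)] <- base[seq_len(rem)] + 1L
    base
  }

  contig <- "synth_contig_1"
  pos <- 500
  rows <- list(); truth <- list()
  gid <- 0L
  emit_bg <- function(k) {
    for (i in seq_len(k)) {
      gap <- sample(200:800, 1)
      gid <<- gid + 1L
      s <- pos + gap
      rows[[length(rows) + 1L]] <<- gene_tbl(
        contig_id = contig, start = s, end = s + spec$gene_len,
        strand = sample(c("+", "-"), 1), kind = "CDS",
        product = sample(HOUSEKEEPING_PRODUCTS, 1),
        protein_id = sprintf("SYNP_%04d", gid),
        protein_seq = random_protein(spec$gene_len %/% 3 - 1))
      pos <<- s + spec$gene_len
    }
  }

  for (p in seq_len(n_pro + 1)) {
    emit_bg(chunk[p])
    if (p > n_pro) break
    cg <- spec$cassette_genes
    n_kw <- round(spec$keyword_fraction * cg)
    int_pos <- if (spec$att_len > 0) (cg %/% 2) + 1L else NA_integer_
    kw_pos <- integer()
    if (n_kw > 0) {
      pool <- if (is.na(int_pos)) seq_len(cg) else c(int_pos, setdiff(seq_len(cg), int_pos))
      kw_pos <- if (is.na(int_pos)) sample(seq_len(cg), n_kw) else
        c(int_pos, sample(setdiff(seq_len(cg), int_pos), max(0, n_kw - 1)))
    }
    taxon <- sample(SYNTH_TAXA, 1)
    att_gap_before <- sample(300:500, 1)
    cass_start <- pos + att_gap_before
    members <- character(cg)
    for (i in seq_len(cg)) {
      gid <- gid + 1L
      s <- if (i == 1) cass_start else pos + spec$intra_gap
      prod <- if (!is.na(int_pos) && i == int_pos) "phage integrase" else
        if (i %in% kw_pos) sample(CASSETTE_PRODUCTS, 1) else "hypothetical protein"
      members[i] <- sprintf("SYNP_%04d", gid)
      rows[[length(rows) + 1L]] <- gene_tbl(
        contig_id = contig, start = s, end = s + spec$gene_len,
        strand = sample(c("+", "-"), 1), kind = "CDS",
        product = prod, protein_id = members[i],
        protein_seq = random_protein(spec$gene_len %/% 3 - 1))
      pos <- s + spec$gene_len
    }
    cass_end <- pos
    att <- if (spec$att_len > 0) {
      list(L = cass_start - sample(60:120, 1) - spec$att_len,
           R = cass_end + sample(60:120, 1))
    } else NULL
    truth[[p]] <- tibble(
      prophage_id = sprintf("truth_prophage_%d", p),
      contig_id = contig, start = cass_start, end = cass_end,
      member_protein_ids = list(members),
      attL_start = if (is.null(att)) NA_real_ else att$L,
      attL_end = if (is.null(att)) NA_real_ else att$L + spec$att_len,
      attR_start = if (is.null(att)) NA_real_ else att$R,
      attR_end = if (is.null(att)) NA_real_ else att$R + spec$att_len,
      taxon = taxon)
    # leave room after the cassette for the attR copy
    pos <- pos + if (is.null(att)) 0 else 200
  }

  genes <- bind_rows(rows)
  total_len <- max(genes$end) + 500
  seq <- random_dna(total_len)
  truth <- bind_rows(truth)
  # plant identical att repeats by overwriting the sequence
  for (t in seq_len(nrow(truth))) {
    if (is.na(truth$attL_start[t])) next
    rep_seq <- random_dna(spec$att_len)
    substr(seq, truth$attL_start[t] + 1, truth$attL_end[t]) <- rep_seq
    substr(seq, truth$attR_start[t] + 1, truth$attR_end[t]) <- rep_seq
  }
  genome <- annotated_genome(
    tibble(id = contig, sequence = seq, length = total_len),
    genes, source = "synthetic")
  list(genome = genome, truth = truth)
}

#' Generate a matching synthetic homology hit table
#'
#' Every cassette gene gets exactly one hit with an e-value drawn log-uniform
#' in \[1e-50, 1e-10\] and a subject title carrying `OS=<truth taxon>`;
#' background genes get decoy hits (e-value log-uniform in \[1e-5, 1e-1\],
#' always above the 1e-7 calling ceiling) at a 5% rate. Deterministic from
#' `spec$seed`.
#'
#' @param genome,truth Output of [generate_genome()].
#' @param spec The same [implant_spec()].
#' @return Hit tibble in the 13-column (subject-title) dialect.
#' @export
generate_hit_table <- function(genome, truth, spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 777L)

  cassette <- tibble(
    query_id = unlist(truth$member_protein_ids),
    taxon = rep(truth$taxon, vapply(truth$member_protein_ids, length, integer(1))))
  rows <- list()
  if (nrow(cassette)) {
    n <- nrow(cassette)
    rows[[1]] <- tibble(
      query_id = cassette$query_id,
      subject_id = sprintf("VP_%05d", sample.int(99999, n)),
      percent_identity = round(runif(n, 40, 99), 1),
      align_length = sample(80:300, n, replace = TRUE),
      mismatch = sample(0:50, n, replace = TRUE),
      gapopen = sample(0:3, n, replace = TRUE),
      qstart = 1, qend = 100, sstart = 1, send = 100,
      evalue = 10^runif(n, -50, -10),
      bitscore = round(runif(n, 120, 400), 1),
      subject_title = paste0("putative phage protein OS=", cassette$taxon,
                             " OX=", sample(10000:99999, n, replace = TRUE),
                             " PE=4 SV=1"))
  }
  bg <- filter(genome$genes, !.data$protein_id %in% cassette$query_id)
  decoy <- bg[runif(nrow(bg)) < 0.05, ]
  if (nrow(decoy)) {
    n <- nrow(decoy)
    rows[[length(rows) + 1L]] <- tibble(
      query_id = decoy$protein_id,
      subject_id = sprintf("VP_%05d", sample.int(99999, n)),
      percent_identity = round(runif(n, 20, 40), 1),
      align_length = sample(30:120, n, replace = TRUE),
      mismatch = sample(10:80, n, replace = TRUE),
      gapopen = sample(0:5, n, replace = TRUE),
      qstart = 1, qend = 50, sstart = 1, send = 50,
      evalue = 10^runif(n, -5, -1),
      bitscore = round(runif(n, 25, 60), 1),
      subject_title = "uncharacterized protein")
  }
  bind_rows(rows)
}

#' One-call synthetic fixture
#'
#' Convenience wrapper producing the genome, truth table and hit table for a
#' spec, optionally writing GenBank/FASTA/hit-table/truth files to `dir`.
#'
#' @param spec An [implant_spec()].
#' @param dir Optional output directory.
#' @return List with `genome`, `truth`, `hits` (and `files` when `dir` is
#'   given).
#' @export
generate_fixture <- function(spec, dir = NULL) {
  gt <- generate_genome(spec)
  hits <- generate_hit_table(gt$genome, gt$truth, spec)
  out <- list(genome = gt$genome, truth = gt$truth, hits = hits)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      genbank = file.path(dir, "genome.gbk"),
      fasta = file.path(dir, "genome.fasta"),
      hits = file.path(dir, "hits.tsv"),
      truth = file.path(dir, "truth.tsv"))
    write_genbank(gt$genome, files$genbank)
    write_contigs_fasta(gt$genome$contigs, files$fasta)
    write_hit_table(hits, files$hits, dialect = "tab13")
    readr::write_tsv(select(gt$truth, -"member_protein_ids"), files$truth)
    out$files <- files
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# ---- GenBank writer ---------------------------------------------------------

#' Write an annotated genome as a GenBank flat file
#'
#' Minimal but standard-conforming flat-file output (LOCUS, FEATURES with
#' CDS/tRNA, ORIGIN), sufficient to round-trip through [read_genbank()].
#' Coordinates are converted back to 1-based inclusive.
#'
#' @param genome An [annotated_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ci in seq_len(nrow(genome$contigs))) {
    ctg <- genome$contigs[ci, ]
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   BCT 01-JAN-2000",
                       ctg$id, ctg$length), con)
    writeLines(sprintf("DEFINITION  %s synthetic bacterial contig.", ctg$id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", ctg$length), con)
    g <- filter(genome$genes, .data$contig_id == ctg$id)
    for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i] + 1, g$end[i])
      if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-15s %s", g$kind[i], loc), con)
      writeLines(wrap_qualifier("product", g$product[i]), con)
      if (!is.na(g$protein_id[i])) {
        writeLines(wrap_qualifier("protein_id", g$protein_id[i]), con)
      }
      if (g$kind[i] == "CDS" && nzchar(g$protein_seq[i])) {
        writeLines(wrap_qualifier("translation", g$protein_seq[i]), con)
      }
    }
    if (!is.na(ctg$sequence)) {
      writeLines("ORIGIN", con)
      s <- tolower(ctg$sequence)
      starts <- seq(1, nchar(s), 60)
      for (st in starts) {
        chunk <- substr(s, st, min(st + 59, nchar(s)))
        blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                            pmin(seq(1, nchar(chunk), 10) + 9, nchar(chunk)))
        writeLines(sprintf("%9d %s", st, paste(blocks, collapse = " ")), con)
      }
    }
    writeLines("//", con)
  }
  invisible(path)
}

wrap_qualifier <- function(name, value, width = 58) {
  text <- paste0("/", name, "=\"", value, "\"")
  pieces <- substring(text, seq(1, nchar(text), width),
                      pmin(seq(1, nchar(text), width) + width - 1, nchar(text)))
  paste0(strrep(" ", 21), pieces)
}
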
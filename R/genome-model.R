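#' Annotated-genome container
#'
#' An `annotated_genome` bundles the contigs of a bacterial genome with its
#' gene map. Coordinates are 0-based half-open internally; every user-facing
#' writer converts to 1-based inclusive (GenBank convention).
#'
#' @param contigs Tibble with columns `id`, `sequence`, `length`. `sequence`
#'   may be `NA` when only the gene map is known (att detection then skips
#'   the contig with a warning).
#' @param genes Tibble of gene features; see [gene_tbl()] for the schema.
#' @param source One of `"genbank"`, `"fasta+provider"`, `"synthetic"`.
#'
#' @return An object of class `annotated_genome`: a list with elements
#'   `contigs`, `genes` (re-sorted and re-indexed) and `source`.
#' @export
annotated_genome <- function(contigs, genes, source = "synthetic") {
  contigs <- as_tibble(contigs)
  stopifnot(all(c("id", "sequence", "length") %in% names(contigs)))
  if (anyDuplicated(contigs$id)) {
    stop("duplicate contig ids: ",
         paste(unique(contigs$id[duplicated(contigs$id)]), collapse = ", "))
  }
  genes <- validate_genes(genes, contigs)
  genes <- sort_and_index_genes(genes, contigs$id)
  structure(list(contigs = contigs, genes = genes, source = source),
            class = "annotated_genome")
}

#' Gene feature table constructor
#'
#' Builds the canonical gene tibble used throughout the package. `start`/`end`
#' are 0-based half-open; `index` is the 0-based ordinal of the gene among all
#' genes on its contig ordered by start (ties by end, then `+` before `-`).
#'
#' @param contig_id,start,end,strand,kind,product,protein_id,protein_seq
#'   Per-gene vectors; `kind` is `"CDS"` or `"tRNA"`, `strand` is `"+"`/`"-"`.
#' @param index Optional precomputed ordinals; recomputed by
#'   [annotated_genome()] in any case.
#' @return A tibble with one row per gene.
#' @export
gene_tbl <- function(contig_id = character(), start = integer(),
                     end = integer(), strand = character(),
                     kind = "CDS", product = "", protein_id = NA_character_,
                     protein_seq = "", index = NA_integer_) {
  tibble(
    contig_id = as.character(contig_id),
    index = as.integer(index),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand),
    kind = as.character(kind),
    product = as.character(product),
    protein_id = as.character(protein_id),
    protein_seq = as.character(protein_seq)
  )
}

validate_genes <- function(genes, contigs) {
  genes <- as_tibble(genes)
  needed <- c("contig_id", "start", "end", "strand", "kind", "product",
              "protein_id", "protein_seq")
  missing_cols <- setdiff(needed, names(genes))
  if (length(missing_cols)) {
    stop("gene table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(genes) == 0) return(gene_tbl())
  unknown <- setdiff(genes$contig_id, contigs$id)
  if (length(unknown)) {
    bad <- which(genes$contig_id %in% unknown)[1]
    stop("gene feature ", bad, " references unknown contig '",
         genes$contig_id[bad], "'")
  }
  bad_span <- which(!(genes$start >= 0 & genes$start < genes$end))
  if (length(bad_span)) {
    stop("gene feature ", bad_span[1], " has invalid span [",
         genes$start[bad_span[1]], ", ", genes$end[bad_span[1]], ")")
  }
  len <- setNames(contigs$length, contigs$id)
  over <- which(genes$end > len[genes$contig_id])
  if (length(over)) {
    stop("gene feature ", over[1], " ends beyond contig '",
         genes$contig_id[over[1]], "' (length ", len[genes$contig_id[over[1]]], ")")
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(genes$kind %in% c("CDS", "tRNA"))) stop("kind must be CDS or tRNA")
  genes
}

sort_and_index_genes <- function(genes, contig_order) {
  if (nrow(genes) == 0) return(genes)
  genes |>
    mutate(.contig = factor(.data$contig_id, levels = contig_order),
           .strand = factor(.data$strand, levels = c("+", "-"))) |>
    arrange(.data$.contig, .data$start, .data$end, .data$.strand) |>
    group_by(.data$contig_id) |>
    mutate(index = row_number() - 1L) |>
    ungroup() |>
    select(-".contig", -".strand") |>
    select("contig_id", "index", "start", "end", "strand", "kind",
           "product", "protein_id", "protein_seq")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome> source:", x$source, "\n")
  cat("  contigs:", nrow(x$contigs), " total",
      format(sum(x$contigs$length), big.mark = ","), "bp\n")
  cat("  genes:  ", nrow(x$genes),
      sprintf(" (%d CDS, %d tRNA)\n", sum(x$genes$kind == "CDS"),
              sum(x$genes$kind == "tRNA")))
  invisible(x)
}

# ---- GenBank flat-file reader -----------------------------------------------

#' Read a (multi-record) GenBank flat file
#'
#' Extracts one contig per record and one gene feature per CDS or tRNA
#' feature. 1-based inclusive GenBank locations become 0-based half-open;
#' compound `join(...)` locations are collapsed to their outer envelope.
#' Features that wrap the circular origin are skipped with a warning. CDS
#' translations come from the `/translation` qualifier when present, else are
#' recomputed from the nucleotide span with translation table 11 (trailing
#' stop removed; internal stops kept as `*` with a warning).
#'
#' @param path GenBank flat file, possibly multi-record.
#' @return An [annotated_genome()] with `source = "genbank"`.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("cannot read GenBank file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines))) {
    stop("not a GenBank flat file (no LOCUS line): ", path)
  }
  ends <- which(trimws(lines) == "//")
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, head(ends, -1) + 1L)
  records <- Map(function(s, e) lines[s:e], starts, ends)
  records <- records[vapply(records, function(x) any(grepl("^LOCUS", x)), logical(1))]
  if (!length(records)) stop("no GenBank records in ", path)

  parsed <- lapply(records, parse_gb_record)
  contigs <- bind_rows(lapply(parsed, `[[`, "contig"))
  genes <- bind_rows(lapply(parsed, `[[`, "genes"))
  empty <- contigs$id[!contigs$id %in% genes$contig_id]
  if (length(empty)) {
    warning("record(s) with zero CDS/tRNA features: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  annotated_genome(contigs, genes, source = "genbank")
}

parse_gb_record <- function(lines) {
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  id <- strsplit(trimws(locus), "\\s+")[[1]][2]

  ori <- grep("^ORIGIN", lines)
  seq <- NA_character_
  if (length(ori)) {
    body <- lines[(ori[1] + 1):length(lines)]
    body <- body[trimws(body) != "//"]
    seq <- toupper(paste(gsub("[^A-Za-z]", "", body), collapse = ""))
    if (!nzchar(seq)) seq <- NA_character_
  }
  feat_start <- grep("^FEATURES", lines)
  feats <- list()
  if (length(feat_start)) {
    stop_at <- if (length(ori)) ori[1] - 1L else length(lines)
    flines <- lines[(feat_start[1] + 1):stop_at]
    flines <- flines[grepl("^\\s", flines) & nzchar(trimws(flines))]
    feats <- parse_gb_features(flines)
  }

  rows <- list()
  for (f in feats) {
    if (!f$key %in% c("CDS", "tRNA")) next
    loc <- parse_gb_location(f$location)
    if (is.null(loc)) {
      warning("skipping origin-spanning feature on ", id, ": ", f$location,
              call. = FALSE)
      next
    }
    prot <- ""
    if (f$key == "CDS") {
      prot <- f$qualifiers[["translation"]] %||% ""
      if (!nzchar(prot) && !is.na(seq) && is.null(f$qualifiers[["pseudo"]])) {
        prot <- translate_span(seq, loc$start, loc$end, loc$strand, id)
      }
    }
    rows[[length(rows) + 1L]] <- gene_tbl(
      contig_id = id, start = loc$start, end = loc$end, strand = loc$strand,
      kind = f$key, product = f$qualifiers[["product"]] %||% "",
      protein_id = f$qualifiers[["protein_id"]] %||%
        f$qualifiers[["locus_tag"]] %||% NA_character_,
      protein_seq = prot
    )
  }
  genes <- if (length(rows)) bind_rows(rows) else gene_tbl()
  contig_len <- if (!is.na(seq)) nchar(seq) else {
    max(c(0, genes$end), as.numeric(sub(".*?(\\d+)\\s*bp.*", "\\1", locus)), na.rm = TRUE)
  }
  list(contig = tibble(id = id, sequence = seq, length = contig_len),
       genes = genes)
}

# split the FEATURES block into (key, location, qualifiers) triples; feature
# keys start at column 6, qualifiers/continuations at column 22
parse_gb_features <- function(flines) {
  is_key <- grepl("^ {1,10}\\S", flines)
  idx <- which(is_key)
  feats <- vector("list", length(idx))
  bounds <- c(idx, length(flines) + 1L)
  for (k in seq_along(idx)) {
    block <- flines[idx[k]:(bounds[k + 1] - 1L)]
    first <- strsplit(trimws(block[1]), "\\s+")[[1]]
    key <- first[1]
    rest <- trimws(block[-1])
    qual_at <- grep("^/", rest)
    loc <- paste(c(first[-1], if (length(qual_at)) head(rest, qual_at[1] - 1L) else rest),
                 collapse = "")
    quals <- list()
    if (length(qual_at)) {
      qlines <- rest[qual_at[1]:length(rest)]
      qstarts <- grep("^/", qlines)
      qb <- c(qstarts, length(qlines) + 1L)
      for (q in seq_along(qstarts)) {
        chunk <- qlines[qstarts[q]:(qb[q + 1] - 1L)]
        joined <- paste(chunk, collapse = if (grepl("^/translation", chunk[1])) "" else " ")
        m <- regmatches(joined, regexec("^/([A-Za-z_0-9]+)(=?)(.*)$", joined))[[1]]
        val <- m[4]
        val <- gsub('^"|"$', "", trimws(val))
        quals[[m[2]]] <- if (m[3] == "") TRUE else val
      }
    }
    feats[[k]] <- list(key = key, location = loc, qualifiers = quals)
  }
  feats
}

# envelope of a GenBank location string; NULL if it wraps the circular origin
parse_gb_location <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  inner <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
  inner <- gsub("[<>]", "", inner)
  segs <- strsplit(inner, ",")[[1]]
  pos <- lapply(segs, function(s) {
    nums <- as.numeric(regmatches(s, gregexpr("[0-9]+", s))[[1]])
    if (!length(nums)) return(NULL)
    c(min(nums), max(nums))
  })
  pos <- pos[!vapply(pos, is.null, logical(1))]
  if (!length(pos)) return(NULL)
  starts <- vapply(pos, `[`, numeric(1), 1)
  if (length(starts) > 1 && any(diff(starts) < 0)) return(NULL)  # origin wrap
  lo <- min(vapply(pos, `[`, numeric(1), 1))
  hi <- max(vapply(pos, `[`, numeric(1), 2))
  list(start = lo - 1, end = hi, strand = strand)
}

translate_span <- function(seq, start, end, strand, contig_id) {
  sub <- substr(seq, start + 1, end)
  n <- nchar(sub) - nchar(sub) %% 3
  if (n < 3) return("")
  dna <- Biostrings::DNAString(substr(sub, 1, n))
  if (strand == "-") dna <- Biostrings::reverseComplement(dna)
  aa <- as.character(Biostrings::translate(
    dna, genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "solve"))
  aa <- sub("\\*$", "", aa)
  if (grepl("\\*", aa)) {
    warning("internal stop codon(s) in recomputed translation on ", contig_id,
            " [", start, ", ", end, ")", call. = FALSE)
  }
  aa
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- FASTA reader -----------------------------------------------------------

#' Read nucleotide contigs from a (multi-)FASTA file
#'
#' Contig id is the first whitespace-delimited token of the header. Sequences
#' are uppercased; characters outside `A,C,G,T,N` are masked to `N` with a
#' warning.
#'
#' @param path FASTA nucleotide file.
#' @return Tibble with columns `id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  n_bad <- sum(vapply(gregexpr("[^ACGTN]", seqs),
                      function(m) sum(m > 0), numeric(1)))
  if (n_bad > 0) {
    warning(n_bad, " non-ACGTN character(s) masked to N", call. = FALSE)
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  tibble(id = ids, sequence = unname(seqs), length = unname(nchar(seqs)))
}

# ---- annotation providers ---------------------------------------------------

#' Attach gene annotations to bare contigs
#'
#' An annotation provider is any function taking the contig tibble and
#' returning a gene table obeying the [gene_tbl()] invariants. Provider output
#' is validated, re-sorted and re-indexed, so emission order does not matter.
#'
#' @param contigs Contig tibble as from [read_fasta()].
#' @param provider `function(contigs) -> gene tibble`.
#' @return An [annotated_genome()] with `source = "fasta+provider"`.
#' @export
attach_annotations <- function(contigs, provider) {
  stopifnot(is.function(provider))
  genes <- provider(contigs)
  annotated_genome(contigs, genes, source = "fasta+provider")
}

#' Fixed-table annotation provider
#'
#' Wraps a precomputed gene table as an annotation provider (used with
#' synthetic fixtures and precomputed external annotations).
#'
#' @param genes Gene tibble.
#' @return A provider function for [attach_annotations()].
#' @export
annotation_provider_table <- function(genes) {
  force(genes)
  function(contigs) genes
}

#' External-command annotation provider
#'
#' Runs a user-supplied annotation command (e.g. a Prokka wrapper) and
#' re-reads its GenBank output. The template must contain `{input}` and
#' `{output}` placeholders; `{input}` receives a FASTA of the contigs.
#' Requires the external tool to be installed; never used by the test suite.
#'
#' @param command_template Shell command template.
#' @return A provider function for [attach_annotations()].
#' @export
annotation_provider_command <- function(command_template) {
  force(command_template)
  function(contigs) {
    fa <- tempfile(fileext = ".fasta")
    gb <- tempfile(fileext = ".gbk")
    on.exit(unlink(c(fa, gb)), add = TRUE)
    write_contigs_fasta(contigs, fa)
    cmd <- sub("{input}", fa, command_template, fixed = TRUE)
    cmd <- sub("{output}", gb, cmd, fixed = TRUE)
    status <- system(cmd)
    if (status != 0) stop("annotation command failed (exit ", status, "): ", cmd)
    read_genbank(gb)$genes
  }
}

write_contigs_fasta <- function(contigs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(contigs))) {
    writeLines(paste0(">", contigs$id[i]), con)
    s <- contigs$sequence[i]
    writeLines(substring(s, seq(1, nchar(s), width),
                         pmin(seq(1, nchar(s), width) + width - 1, nchar(s))),
               con)
  }
  invisible(path)
}
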
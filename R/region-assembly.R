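# Merge the two detectors' minimal clusters, find att sites, vote taxonomy.

#' Merge intersecting minimal clusters
#'
#' Transitively merges clusters (from either detector arm) whose envelopes
#' share at least one base on the same contig. Half-open intervals that
#' merely touch (`end == start`) do not intersect. Member indices and source
#' labels are unioned. Idempotent and invariant to input order.
#'
#' @param clusters Cluster tibble (rows from [cluster_phage_like()] and/or
#'   [scan_windows()]).
#' @return Merged-region tibble: `contig_id`, `start`, `end`,
#'   `member_indices` (list), `sources` (list of character), sorted by
#'   (contig, start) and pairwise disjoint per contig.
#' @export
merge_clusters <- function(clusters) {
  clusters <- as_tibble(clusters)
  if (nrow(clusters) == 0) {
    return(tibble(contig_id = character(), start = numeric(), end = numeric(),
                  member_indices = list(), sources = list()))
  }
  if (!"sources" %in% names(clusters)) {
    clusters$sources <- lapply(clusters$source, identity)
  }
  clusters |>
    arrange(.data$contig_id, .data$start, .data$end) |>
    group_by(.data$contig_id) |>
    dplyr::group_map(function(g, key) {
      run_end <- cummax(g$end)
      new_run <- c(TRUE, g$start[-1] >= run_end[-nrow(g)])  # touch does not merge
      run <- cumsum(new_run)
      purrr::map_dfr(split(seq_len(nrow(g)), run), function(ix) {
        tibble(contig_id = key$contig_id,
               start = min(g$start[ix]), end = max(g$end[ix]),
               member_indices = list(sort(unique(unlist(g$member_indices[ix])))),
               sources = list(sort(unique(unlist(g$sources[ix])))))
      })
    }) |>
    bind_rows() |>
    arrange(.data$contig_id, .data$start)
}

# ---- repeat aligners --------------------------------------------------------

#' Exact-repeat aligner for att-site search
#'
#' Finds all maximal exact common substrings of length at least `min_len`
#' between two nucleotide strings (forward orientation; reverse-complement
#' matches are additionally reported when `revcomp = TRUE`, flagged by the
#' `strand` column). Coordinates are 1-based inclusive within each input
#' string. The score is `2 * length`, mirroring the match reward of
#' short-sequence nucleotide alignment.
#'
#' @param query,subject Nucleotide strings.
#' @param min_len Minimum repeat length.
#' @param revcomp Also report reverse-complement matches?
#' @return Tibble: `qstart`, `qend`, `sstart`, `send`, `length`, `score`,
#'   `strand`.
#' @export
align_exact_repeats <- function(query, subject, min_len = 12, revcomp = FALSE) {
  fwd <- exact_matches(query, subject, min_len)
  fwd$strand <- rep("+", nrow(fwd))
  if (revcomp) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(subject)))
    rev <- exact_matches(query, rc, min_len)
    if (nrow(rev)) {
      slen <- nchar(subject)
      tmp <- slen - rev$send + 1L
      rev$send <- slen - rev$sstart + 1L
      rev$sstart <- tmp
      rev$strand <- "-"
      fwd <- bind_rows(fwd, rev)
    }
  }
  arrange(fwd, desc(.data$score), .data$qstart, .data$sstart)
}

# seed-and-extend with a k-mer index; returns maximal matches, deduplicated
exact_matches <- function(query, subject, k) {
  nq <- nchar(query); ns <- nchar(subject)
  out <- tibble(qstart = integer(), qend = integer(), sstart = integer(),
                send = integer(), length = integer(), score = numeric())
  if (nq < k || ns < k || k < 1) return(out)
  qk <- substring(query, 1:(nq - k + 1), k:nq)
  sk <- substring(subject, 1:(ns - k + 1), k:ns)
  idx <- split(seq_along(qk), qk)
  hits <- which(sk %in% names(idx))
  if (!length(hits)) return(out)
  qc <- strsplit(query, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  seen <- character()
  rows <- list()
  for (j in hits) {
    for (i in idx[[sk[j]]]) {
      # extend the seed [i, i+k-1] x [j, j+k-1] maximally in both directions
      a <- i; b <- j
      while (a > 1 && b > 1 && qc[a - 1] == sc[b - 1]) { a <- a - 1; b <- b - 1 }
      ae <- i + k - 1L; be <- j + k - 1L
      while (ae < nq && be < ns && qc[ae + 1] == sc[be + 1]) { ae <- ae + 1; be <- be + 1 }
      key <- paste(a, b, sep = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- c(a, ae, b, be)
    }
  }
  m <- do.call(rbind, rows)
  tibble(qstart = m[, 1], qend = m[, 2], sstart = m[, 3], send = m[, 4],
         length = m[, 2] - m[, 1] + 1L,
         score = 2 * (m[, 2] - m[, 1] + 1L))
}

#' External blastn repeat aligner
#'
#' Shells out to `blastn -task blastn-short -evalue 1000` (the short-query
#' nucleotide task) and parses its 12-column tabular output into the repeat
#' aligner contract. Requires a `blastn` executable; the builtin
#' [align_exact_repeats()] is the default backend.
#'
#' @inheritParams align_exact_repeats
#' @param blastn_path Path to the blastn executable.
#' @return Same shape as [align_exact_repeats()]; minus-strand subject hits
#'   get `strand = "-"` with `sstart < send` normalised.
#' @export
align_blastn <- function(query, subject, min_len = 12, blastn_path = "blastn") {
  qf <- tempfile(fileext = ".fa"); sf <- tempfile(fileext = ".fa")
  of <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(qf, sf, of)), add = TRUE)
  writeLines(c(">q", query), qf)
  writeLines(c(">s", subject), sf)
  status <- system2(blastn_path,
                    c("-task", "blastn-short", "-evalue", "1000",
                      "-query", qf, "-subject", sf, "-outfmt", "6", "-out", of),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("blastn failed with exit status ", status)
  if (!file.size(of)) {
    return(align_exact_repeats("", "", min_len))
  }
  raw <- utils::read.table(of, sep = "\t", stringsAsFactors = FALSE)
  names(raw) <- HIT12_COLS
  minus <- raw$sstart > raw$send
  tibble(qstart = as.integer(raw$qstart), qend = as.integer(raw$qend),
         sstart = as.integer(ifelse(minus, raw$send, raw$sstart)),
         send = as.integer(ifelse(minus, raw$sstart, raw$send)),
         length = as.integer(raw$align_length),
         score = raw$bitscore,
         strand = ifelse(minus, "-", "+")) |>
    arrange(desc(.data$score), .data$qstart, .data$sstart)
}

# ---- att-site detection -----------------------------------------------------

#' Detect attL/attR direct repeats around integrase anchors
#'
#' For each gene in the region whose product mentions "integrase", the
#' nucleotide spans of the `flank_genes` genes upstream (start of the 10th
#' gene upstream, or the contig start, up to the anchor start) and downstream
#' (anchor end to the end of the 10th gene downstream, or the contig end) are
#' extracted and aligned. Forward-strand matches of length at least `min_len`
#' are candidate attL/attR pairs; the pair with the highest score wins (ties:
#' longer match, then leftmost attL, then leftmost attR), across all anchors.
#'
#' @param region One-row merged-region tibble (`contig_id`, `start`, `end`,
#'   `member_indices`).
#' @param genome [annotated_genome()] whose contigs carry sequence.
#' @param flank_genes Genes per flank (default 10).
#' @param min_len Minimum repeat length (default 12 bp).
#' @param aligner Repeat aligner function
#'   `(query, subject, min_len) -> matches`.
#' @return One-row tibble (`attL_start`, `attL_end`, `attR_start`,
#'   `attR_end`, `att_length`, `att_score`, `att_seq_L`, `att_seq_R`;
#'   0-based half-open genomic coordinates) or `NULL` when the region has no
#'   integrase or no qualifying repeat.
#' @export
detect_att <- function(region, genome, flank_genes = 10, min_len = 12,
                       aligner = align_exact_repeats) {
  genes <- filter(genome$genes, .data$contig_id == region$contig_id)
  members <- genes[genes$index %in% region$member_indices[[1]], ]
  anchors <- members[grepl("integrase", members$product, ignore.case = TRUE), ]
  if (nrow(anchors) == 0) return(NULL)
  seq <- genome$contigs$sequence[genome$contigs$id == region$contig_id]
  if (!length(seq) || is.na(seq)) {
    warning("contig '", region$contig_id,
            "' lacks sequence; att detection skipped", call. = FALSE)
    return(NULL)
  }
  clen <- nchar(seq)
  cand <- purrr::map_dfr(seq_len(nrow(anchors)), function(a) {
    i <- anchors$index[a]
    up_from <- if (i - flank_genes >= 0) genes$start[genes$index == i - flank_genes] else 0
    dn_idx <- i + flank_genes
    dn_to <- if (dn_idx <= max(genes$index)) genes$end[genes$index == dn_idx] else clen
    up0 <- up_from; up1 <- anchors$start[a]
    dn0 <- anchors$end[a]; dn1 <- dn_to
    if (up1 - up0 < min_len || dn1 - dn0 < min_len) return(NULL)
    m <- aligner(substr(seq, up0 + 1, up1), substr(seq, dn0 + 1, dn1), min_len)
    m <- filter(m, .data$length >= min_len, .data$strand == "+")
    if (nrow(m) == 0) return(NULL)
    mutate(m,
           attL_start = up0 + .data$qstart - 1, attL_end = up0 + .data$qend,
           attR_start = dn0 + .data$sstart - 1, attR_end = dn0 + .data$send)
  })
  if (is.null(cand) || nrow(cand) == 0) return(NULL)
  best <- cand |>
    arrange(desc(.data$score), desc(.data$length),
            .data$attL_start, .data$attR_start) |>
    slice(1)
  tibble(attL_start = best$attL_start, attL_end = best$attL_end,
         attR_start = best$attR_start, attR_end = best$attR_end,
         att_length = best$length, att_score = best$score,
         att_seq_L = substr(seq, best$attL_start + 1, best$attL_end),
         att_seq_R = substr(seq, best$attR_start + 1, best$attR_end))
}

# ---- taxonomy ---------------------------------------------------------------

#' Majority-vote taxonomy for a region
#'
#' Each phage-like gene inside the region casts one vote with the taxon of
#' its best hit; `"unknown"` labels abstain. The modal label wins; ties go to
#' the lexicographically smallest modal label and are flagged.
#'
#' @param region One-row region tibble (`contig_id`, `start`, `end`).
#' @param calls Call tibble from [call_phage_like()].
#' @return List with `taxon`, `fraction` (modal count / non-unknown votes),
#'   `tie` (logical). No votes gives `("unassigned", 0, FALSE)`.
#' @export
assign_taxonomy <- function(region, calls) {
  votes <- calls |>
    filter(.data$contig_id == region$contig_id,
           .data$start >= region$start, .data$end <= region$end,
           .data$taxon != "unknown") |>
    pull("taxon")
  if (!length(votes)) return(list(taxon = "unassigned", fraction = 0, tie = FALSE))
  counts <- sort(table(votes), decreasing = TRUE)
  modal <- names(counts)[counts == max(counts)]
  list(taxon = sort(modal)[1],
       fraction = as.numeric(max(counts)) / length(votes),
       tie = length(modal) > 1)
}

# ---- finalization -----------------------------------------------------------

#' Finalize merged regions into prophage calls
#'
#' For each merged region: search for an att pair; when found, extend the
#' region to cover `[attL_start, attR_end)`; re-merge if the extension
#' created overlaps (final output is always pairwise disjoint); vote a
#' taxonomy; number regions `<contig>_prophage_<k>` in coordinate order; and
#' recount genes, phage-like genes and keyword genes over the final span.
#'
#' @param merged Merged-region tibble from [merge_clusters()].
#' @param genome [annotated_genome()].
#' @param calls Call tibble from [call_phage_like()].
#' @param keywords [keyword_set()] used for the keyword recount.
#' @param flank_genes,att_min_len,aligner Passed to [detect_att()].
#' @return Prophage-region tibble; coordinates 0-based half-open, one row per
#'   region, with att columns `NA` when no pair was found.
#' @export
finalize_regions <- function(merged, genome, calls,
                             keywords = default_keywords(),
                             flank_genes = 10, att_min_len = 12,
                             aligner = align_exact_repeats) {
  if (nrow(merged) == 0) return(empty_region_tbl())
  current <- merged
  atts <- NULL
  for (pass in 1:3) {
    atts <- purrr::map(seq_len(nrow(current)), function(r) {
      detect_att(current[r, ], genome, flank_genes, att_min_len, aligner)
    })
    ext <- current
    for (r in seq_len(nrow(ext))) {
      if (!is.null(atts[[r]])) {
        ext$start[r] <- min(ext$start[r], atts[[r]]$attL_start)
        ext$end[r] <- max(ext$end[r], atts[[r]]$attR_end)
      }
    }
    remerged <- merge_clusters(ext)
    if (nrow(remerged) == nrow(current)) { current <- remerged; break }
    current <- remerged
  }
  stopifnot(regions_disjoint(current))

  rows <- purrr::map_dfr(seq_len(nrow(current)), function(r) {
    reg <- current[r, ]
    att <- atts[[r]]
    g <- filter(genome$genes, .data$contig_id == reg$contig_id,
                .data$start >= reg$start, .data$end <= reg$end)
    tax <- assign_taxonomy(reg, calls)
    n_phage <- nrow(filter(calls, .data$contig_id == reg$contig_id,
                           .data$start >= reg$start, .data$end <= reg$end))
    n_kw <- sum(is_phage_keyword(g$product, keywords) & g$kind == "CDS")
    tibble(
      contig_id = reg$contig_id, start = reg$start, end = reg$end,
      n_genes = nrow(g), phage_like_count = n_phage, keyword_count = n_kw,
      sources = paste(reg$sources[[1]], collapse = ","),
      member_indices = list(g$index),
      attL_start = if (is.null(att)) NA_real_ else att$attL_start,
      attL_end = if (is.null(att)) NA_real_ else att$attL_end,
      attR_start = if (is.null(att)) NA_real_ else att$attR_start,
      attR_end = if (is.null(att)) NA_real_ else att$attR_end,
      att_length = if (is.null(att)) NA_real_ else att$att_length,
      att_score = if (is.null(att)) NA_real_ else att$att_score,
      att_seq_L = if (is.null(att)) NA_character_ else att$att_seq_L,
      att_seq_R = if (is.null(att)) NA_character_ else att$att_seq_R,
      taxon = tax$taxon, taxon_fraction = tax$fraction, taxon_tie = tax$tie
    )
  })
  rows |>
    arrange(.data$contig_id, .data$start) |>
    group_by(.data$contig_id) |>
    mutate(region_id = paste0(.data$contig_id, "_prophage_", row_number())) |>
    ungroup() |>
    select("region_id", dplyr::everything())
}

regions_disjoint <- function(regions) {
  if (nrow(regions) < 2) return(TRUE)
  ok <- regions |>
    arrange(.data$contig_id, .data$start) |>
    group_by(.data$contig_id) |>
    summarise(ok = all(.data$start[-1] >= head(.data$end, -1)) || n() == 1,
              .groups = "drop")
  all(ok$ok)
}

empty_region_tbl <- function() {
  tibble(region_id = character(), contig_id = character(),
         start = numeric(), end = numeric(), n_genes = integer(),
         phage_like_count = integer(), keyword_count = integer(),
         sources = character(), member_indices = list(),
         attL_start = numeric(), attL_end = numeric(),
         attR_start = numeric(), attR_end = numeric(),
         att_length = numeric(), att_score = numeric(),
         att_seq_L = character(), att_seq_R = character(),
         taxon = character(), taxon_fraction = numeric(),
         taxon_tie = logical())
}
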
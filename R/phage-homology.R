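# Phage-like gene identification from a protein-vs-viral-database hit table.

HIT12_COLS <- c("query_id", "subject_id", "percent_identity", "align_length",
                "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                "evalue", "bitscore")
HIT_NUM_COLS <- setdiff(HIT12_COLS, c("query_id", "subject_id"))

#' Read a tabular protein-alignment hit table
#'
#' Parses the 12-column tabular output of protein aligners (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore),
#' or the 13-column variant with an appended subject-title column that
#' carries organism/taxonomy annotation. Rows with unparseable numeric
#' fields are skipped with a warning; if more than half the rows are skipped
#' the dialect is presumed wrong and parsing fails.
#'
#' @param path Tab-separated hit table.
#' @param dialect `"tab12"` or `"tab13"` (12 columns + subject title).
#' @return Tibble of hits; `subject_title` is `NA` for the tab12 dialect.
#' @export
read_hit_table <- function(path, dialect = c("tab12", "tab13")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read hit table: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    warning("empty hit table: ", path, call. = FALSE)
    return(empty_hit_tbl())
  }
  need <- if (dialect == "tab13") 13L else 12L
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < need
  if (all(short)) stop("hit table has fewer than ", need, " columns; wrong dialect? ", path)
  mat <- t(vapply(fields[!short], function(f) f[seq_len(need)], character(need)))
  hits <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
  names(hits) <- c(HIT12_COLS, if (need == 13L) "subject_title")
  if (need == 12L) hits$subject_title <- NA_character_
  suppressWarnings(
    hits <- mutate(hits, dplyr::across(dplyr::all_of(HIT_NUM_COLS), as.numeric))
  )
  bad <- rowSums(is.na(hits[HIT_NUM_COLS])) > 0
  n_skipped <- sum(bad) + sum(short)
  if (n_skipped > 0.5 * length(lines)) {
    stop("more than half the rows (", n_skipped, "/", length(lines),
         ") are unparseable; wrong dialect? ", path)
  }
  if (n_skipped > 0) {
    warning(n_skipped, " unparseable row(s) skipped in ", path, call. = FALSE)
  }
  out <- hits[!bad, ]
  attr(out, "n_skipped") <- n_skipped
  out
}

empty_hit_tbl <- function() {
  out <- as_tibble(setNames(rep(list(character()), 2), HIT12_COLS[1:2]))
  for (col in HIT_NUM_COLS) out[[col]] <- numeric()
  out$subject_title <- character()
  out[c(HIT12_COLS, "subject_title")]
}

#' Write a hit table
#'
#' @param hits Hit tibble as from [read_hit_table()].
#' @param path Output path.
#' @param dialect `"tab12"` or `"tab13"`.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path, dialect = c("tab13", "tab12")) {
  dialect <- match.arg(dialect)
  cols <- c(HIT12_COLS, if (dialect == "tab13") "subject_title")
  df <- as.data.frame(hits)[, cols, drop = FALSE]
  df$evalue <- format(df$evalue, scientific = TRUE, trim = TRUE, digits = 3)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract an organism label from a hit's subject title
#'
#' Follows the UniProt `OS=<organism>` convention (truncated at the next
#' `OX=`/`GN=`/`PE=`/`SV=` field marker); falls back to a bracketed organism
#' `[...]` terminating the title (NCBI style); otherwise `"unknown"`.
#'
#' @param title Character vector of subject titles.
#' @param taxon_regex Optional override: a regex whose first capture group is
#'   the taxon label.
#' @return Character vector of taxon labels (never `NA`).
#' @export
extract_taxon <- function(title, taxon_regex = NULL) {
  title <- ifelse(is.na(title), "", title)
  if (!is.null(taxon_regex)) {
    m <- stringr::str_match(title, taxon_regex)[, 2]
    return(ifelse(is.na(m) | !nzchar(trimws(m)), "unknown", trimws(m)))
  }
  os <- stringr::str_match(title, "OS=(.*?)(?:\\s+(?:OX|GN|PE|SV)=.*)?$")[, 2]
  br <- stringr::str_match(title, "\\[([^\\]\\[]+)\\]\\s*$")[, 2]
  out <- dplyr::case_when(
    !is.na(os) & nzchar(trimws(os)) ~ trimws(os),
    !is.na(br) & nzchar(trimws(br)) ~ trimws(br),
    TRUE ~ "unknown"
  )
  out
}

#' Call phage-like genes from homology hits
#'
#' A gene is phage-like when at least one of its hits has an e-value strictly
#' below `evalue_max` (default 1e-7, matching the usual viral-database search
#' ceiling). Exactly one best hit is kept per called gene: minimum e-value,
#' ties broken by maximum bit score, then lexicographic subject id, so the
#' result is invariant to hit-table row order.
#'
#' @param genes Gene tibble (needs `protein_id`).
#' @param hits Hit tibble as from [read_hit_table()].
#' @param evalue_max Strict e-value ceiling (> 0).
#' @param taxon_regex Passed to [extract_taxon()].
#' @return Tibble of calls, one row per phage-like gene, ordered by
#'   (contig, gene index), with the gene columns plus `subject_id`, `evalue`,
#'   `bitscore`, `subject_title`, `taxon`.
#' @export
call_phage_like <- function(genes, hits, evalue_max = 1e-7, taxon_regex = NULL) {
  stopifnot(evalue_max > 0)
  genes <- as_tibble(genes)
  hits <- as_tibble(hits)
  if (nrow(hits) == 0 || nrow(genes) == 0) return(empty_call_tbl(genes))
  known <- genes$protein_id[!is.na(genes$protein_id)]
  orphan <- !(hits$query_id %in% known)
  if (any(orphan)) {
    warning(sum(orphan), " hit(s) with query ids matching no gene were ignored",
            call. = FALSE)
    hits <- hits[!orphan, ]
  }
  hits <- filter(hits, .data$evalue < evalue_max)
  if (nrow(hits) == 0) return(empty_call_tbl(genes))
  best <- hits |>
    arrange(.data$query_id, .data$evalue, desc(.data$bitscore), .data$subject_id) |>
    distinct(.data$query_id, .keep_all = TRUE) |>
    select("query_id", "subject_id", "percent_identity", "align_length",
           "evalue", "bitscore", "subject_title")
  genes |>
    dplyr::inner_join(best, by = c(protein_id = "query_id")) |>
    mutate(taxon = extract_taxon(.data$subject_title, taxon_regex)) |>
    arrange(.data$contig_id, .data$index)
}

empty_call_tbl <- function(genes) {
  out <- genes[0, ]
  out$subject_id <- character()
  out$percent_identity <- numeric()
  out$align_length <- numeric()
  out$evalue <- numeric()
  out$bitscore <- numeric()
  out$subject_title <- character()
  out$taxon <- character()
  out
}
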
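# End-to-end pipeline, configuration, result writers and the tuning harness.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the detector with its default:
#' e-value ceiling 1e-7 (strict), DBSCAN minimal cluster size 6 proteins and
#' neighbour distance 3,000 bp, sliding windows of 60 annotated proteins
#' with at least 6 keyword hits, att search over 10-gene flanks with a
#' 12 bp minimum repeat.
#'
#' @param evalue_max Phage-like call ceiling (strict `<`).
#' @param min_protein_num DBSCAN minimal cluster size.
#' @param protein_density_bp DBSCAN maximal neighbour gap (bp).
#' @param dbscan_mode `"chain"` or `"strict"` (see [cluster_phage_like()]).
#' @param window_size,min_keyword_hits Sliding-window parameters.
#' @param flank_genes,att_min_len Att-search parameters.
#' @param att_aligner `"builtin"` or `"blastn"`.
#' @param blastn_path blastn executable for the `"blastn"` backend.
#' @param keywords A [keyword_set()] or path to a keywords file.
#' @param taxon_regex Optional taxon-extraction override
#'   (see [extract_taxon()]).
#' @param threads Worker processes for per-contig detection (results are
#'   independent of the thread count; forking requires a Unix-alike and is
#'   silently reduced to 1 elsewhere).
#' @param seed Integer seed for any randomised step.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(evalue_max = 1e-7, min_protein_num = 6,
                            protein_density_bp = 3000,
                            dbscan_mode = c("chain", "strict"),
                            window_size = 60, min_keyword_hits = 6,
                            flank_genes = 10, att_min_len = 12,
                            att_aligner = c("builtin", "blastn"),
                            blastn_path = "blastn",
                            keywords = default_keywords(),
                            taxon_regex = NULL, threads = 1L, seed = 1L) {
  stopifnot(evalue_max > 0, min_protein_num >= 1, protein_density_bp >= 0,
            window_size >= 1, min_keyword_hits >= 1, flank_genes >= 1,
            att_min_len >= 1, threads >= 1)
  if (.Platform$OS.type != "unix") threads <- 1L
  if (is.character(keywords)) keywords <- read_keywords(keywords)
  stopifnot(inherits(keywords, "keyword_set"))
  structure(list(
    evalue_max = evalue_max, min_protein_num = min_protein_num,
    protein_density_bp = protein_density_bp,
    dbscan_mode = match.arg(dbscan_mode),
    window_size = window_size, min_keyword_hits = min_keyword_hits,
    flank_genes = flank_genes, att_min_len = att_min_len,
    att_aligner = match.arg(att_aligner), blastn_path = blastn_path,
    keywords = keywords, taxon_regex = taxon_regex,
    threads = as.integer(threads), seed = as.integer(seed)
  ), class = "pipeline_config")
}

config_aligner <- function(config) {
  if (config$att_aligner == "blastn") {
    function(q, s, min_len) align_blastn(q, s, min_len, config$blastn_path)
  } else {
    align_exact_repeats
  }
}

#' Run the full prophage detection pipeline
#'
#' Reads (or accepts) an annotated genome and a homology hit table, runs both
#' detector arms, merges their minimal clusters, searches att sites, votes a
#' taxonomy per region, and optionally writes the result files.
#'
#' @param input Path to a GenBank flat file, or an [annotated_genome()], or a
#'   FASTA path (then `provider` is required).
#' @param hits Hit tibble, or path to a tabular hit table, or `NULL` to run
#'   the sliding-window arm only (with a warning).
#' @param config A [pipeline_config()].
#' @param provider Annotation provider for FASTA input
#'   (see [attach_annotations()]).
#' @param hits_dialect Dialect for a hit-table path
#'   (see [read_hit_table()]).
#' @param output_dir Directory for result files, or `NULL` to skip writing.
#' @param prefix File-name prefix for the writers.
#' @return An object of class `prophage_scan`: list with `regions`
#'   (tibble, see [finalize_regions()]), `genome`, `calls`, `clusters`
#'   (both arms), `config`, `counts` (run summary including skipped-record
#'   tallies) and `files` (written paths, if any). Zero regions is a valid
#'   outcome.
#' @export
run_pipeline <- function(input, hits = NULL, config = pipeline_config(),
                         provider = NULL, hits_dialect = "tab13",
                         output_dir = NULL, prefix = "prophinder") {
  genome <- resolve_genome(input, provider)
  n_hits_skipped <- 0L
  if (is.character(hits)) {
    hits <- read_hit_table(hits, dialect = hits_dialect)
    n_hits_skipped <- attr(hits, "n_skipped") %||% 0L
  }
  if (is.null(hits)) {
    warning("no hit table supplied; running the sliding-window arm only",
            call. = FALSE)
    hits <- empty_hit_tbl()
  }

  calls <- call_phage_like(genome$genes, hits, evalue_max = config$evalue_max,
                           taxon_regex = config$taxon_regex)

  detect_contig <- function(cid) {
    list(
      dbscan = cluster_phage_like(
        filter(calls, .data$contig_id == cid),
        max_gap = config$protein_density_bp,
        min_size = config$min_protein_num, mode = config$dbscan_mode),
      swa = scan_windows(
        filter(genome$genes, .data$contig_id == cid),
        keywords = config$keywords, window_size = config$window_size,
        min_hits = config$min_keyword_hits))
  }
  per_contig <- if (config$threads > 1) {
    parallel::mclapply(genome$contigs$id, detect_contig,
                       mc.cores = config$threads)
  } else {
    lapply(genome$contigs$id, detect_contig)
  }
  cl_dbscan <- bind_rows(purrr::map(per_contig, "dbscan")) |>
    arrange(.data$contig_id, .data$start)
  cl_swa <- bind_rows(purrr::map(per_contig, "swa")) |>
    arrange(.data$contig_id, .data$start)
  if (nrow(cl_dbscan) == 0) cl_dbscan <- empty_cluster_tbl()
  if (nrow(cl_swa) == 0) cl_swa <- empty_cluster_tbl()
  merged <- merge_clusters(bind_rows(cl_dbscan, cl_swa))
  regions <- finalize_regions(merged, genome, calls,
                              keywords = config$keywords,
                              flank_genes = config$flank_genes,
                              att_min_len = config$att_min_len,
                              aligner = config_aligner(config))

  counts <- tibble(
    n_contigs = nrow(genome$contigs),
    n_genes = nrow(genome$genes),
    n_hits = nrow(hits),
    n_hits_skipped = n_hits_skipped,
    n_phage_like = nrow(calls),
    n_clusters_dbscan = nrow(cl_dbscan),
    n_clusters_swa = nrow(cl_swa),
    n_regions = nrow(regions),
    n_att_pairs = sum(!is.na(regions$att_length))
  )
  scan <- structure(list(regions = regions, genome = genome, calls = calls,
                         clusters = bind_rows(cl_dbscan, cl_swa),
                         config = config, counts = counts, files = NULL),
                    class = "prophage_scan")
  if (!is.null(output_dir)) {
    scan$files <- write_scan_results(scan, output_dir, prefix)
  }
  scan
}

resolve_genome <- function(input, provider) {
  if (inherits(input, "annotated_genome")) return(input)
  if (!is.character(input)) stop("input must be a path or an annotated_genome")
  first <- readLines(input, n = 1, warn = FALSE)
  if (length(first) && startsWith(first, ">")) {
    if (is.null(provider)) {
      stop("FASTA input requires an annotation provider ",
           "(see attach_annotations())")
    }
    attach_annotations(read_fasta(input), provider)
  } else {
    read_genbank(input)
  }
}

#' @export
print.prophage_scan <- function(x, ...) {
  cat("<prophage_scan>", x$counts$n_regions, "region(s) on",
      x$counts$n_contigs, "contig(s)\n")
  cat("  genes:", x$counts$n_genes, " phage-like:", x$counts$n_phage_like,
      " clusters DBSCAN/SWA:", x$counts$n_clusters_dbscan, "/",
      x$counts$n_clusters_swa, " att pairs:", x$counts$n_att_pairs, "\n")
  if (nrow(x$regions)) {
    print(select(x$regions, "region_id", "start", "end", "n_genes",
                 "phage_like_count", "sources", "taxon"))
  }
  invisible(x)
}

# ---- result writers (all user-facing coordinates 1-based inclusive) ---------

write_scan_results <- function(scan, output_dir, prefix) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(
    summary = file.path(output_dir, paste0(prefix, "_prophage_summary.tsv")),
    proteins = file.path(output_dir, paste0(prefix, "_prophage_proteins.tsv")),
    gff3 = file.path(output_dir, paste0(prefix, "_prophages.gff3")),
    fasta = file.path(output_dir, paste0(prefix, "_prophages.fasta")),
    html = file.path(output_dir, paste0(prefix, "_report.html"))
  )
  write_summary_tsv(scan, files$summary)
  write_proteins_tsv(scan, files$proteins)
  write_regions_gff3(scan$regions, files$gff3)
  write_regions_fasta(scan, files$fasta)
  write_report_html(scan, files$html)
  files
}

summary_table <- function(scan) {
  r <- scan$regions
  tibble(
    region_id = r$region_id, contig = r$contig_id,
    start = r$start + 1, end = r$end,  # 1-based inclusive
    length = r$end - r$start,
    n_genes = r$n_genes, n_phage_like = r$phage_like_count,
    n_keyword = r$keyword_count, sources = r$sources,
    attL = ifelse(is.na(r$attL_start), "",
                  sprintf("%d..%d", r$attL_start + 1, r$attL_end)),
    attR = ifelse(is.na(r$attR_start), "",
                  sprintf("%d..%d", r$attR_start + 1, r$attR_end)),
    att_sequence = ifelse(is.na(r$att_seq_L), "", r$att_seq_L),
    taxon = r$taxon,
    taxon_fraction = round(r$taxon_fraction, 4)
  )
}

write_summary_tsv <- function(scan, path) {
  readr::write_tsv(summary_table(scan), path)
  invisible(path)
}

write_proteins_tsv <- function(scan, path) {
  r <- scan$regions
  rows <- purrr::map_dfr(seq_len(nrow(r)), function(i) {
    g <- filter(scan$genome$genes, .data$contig_id == r$contig_id[i],
                .data$start >= r$start[i], .data$end <= r$end[i])
    g |>
      left_join(select(scan$calls, "protein_id", "subject_id", "evalue",
                       "bitscore", "taxon"),
                by = "protein_id") |>
      mutate(region_id = r$region_id[i],
             start = .data$start + 1) |>
      select("region_id", "contig_id", "protein_id", "start", "end",
             "strand", "kind", "product", "subject_id", "evalue",
             "bitscore", "taxon")
  })
  readr::write_tsv(rows, path)
  invisible(path)
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x
}

#' Write prophage regions as GFF3
#'
#' @param regions Region tibble from [finalize_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_gff3 <- function(regions, path) {
  lines <- "##gff-version 3"
  if (nrow(regions)) {
    attrs <- sprintf("ID=%s;sources=%s;taxon=%s;taxon_fraction=%s",
                     gff3_escape(regions$region_id),
                     gff3_escape(regions$sources),
                     gff3_escape(regions$taxon),
                     round(regions$taxon_fraction, 4))
    lines <- c(lines, sprintf("%s\tprophinder\tprophage_region\t%d\t%d\t.\t.\t.\t%s",
                              regions$contig_id, as.integer(regions$start + 1),
                              as.integer(regions$end), attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write an annotated genome's gene features as GFF3
#'
#' @param genome An [annotated_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genome, path) {
  g <- genome$genes
  lines <- "##gff-version 3"
  if (nrow(g)) {
    ids <- ifelse(is.na(g$protein_id),
                  paste0(g$contig_id, "_gene_", g$index), g$protein_id)
    attrs <- sprintf("ID=%s;product=%s", gff3_escape(ids),
                     gff3_escape(g$product))
    lines <- c(lines, sprintf("%s\tprophinder\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                              g$contig_id, g$kind, as.integer(g$start + 1),
                              as.integer(g$end),
                              g$strand, ifelse(g$kind == "CDS", "0", "."),
                              attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

write_regions_fasta <- function(scan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  r <- scan$regions
  for (i in seq_len(nrow(r))) {
    seq <- scan$genome$contigs$sequence[scan$genome$contigs$id == r$contig_id[i]]
    if (!length(seq) || is.na(seq)) next
    s <- substr(seq, r$start[i] + 1, r$end[i])
    writeLines(sprintf(">%s %s:%d-%d", r$region_id[i], r$contig_id[i],
                       r$start[i] + 1, r$end[i]), con)
    writeLines(substring(s, seq(1, nchar(s), 70),
                         pmin(seq(1, nchar(s), 70) + 69, nchar(s))), con)
  }
  invisible(path)
}

write_report_html <- function(scan, path) {
  tab <- summary_table(scan)
  cells <- function(x, tag) paste0("<", tag, ">", x, "</", tag, ">")
  header <- paste0("<tr>", paste(cells(names(tab), "th"), collapse = ""), "</tr>")
  body <- vapply(seq_len(nrow(tab)), function(i) {
    paste0("<tr>", paste(cells(unlist(tab[i, ], use.names = FALSE), "td"),
                         collapse = ""), "</tr>")
  }, character(1))
  counts <- scan$counts
  writeLines(c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>prophinder report</title>",
    "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:4px}</style>",
    "</head><body>",
    "<h1>Prophage detection report</h1>",
    sprintf("<p>%d contig(s), %d gene(s), %d phage-like gene(s), %d region(s), %d att pair(s).</p>",
            counts$n_contigs, counts$n_genes, counts$n_phage_like,
            counts$n_regions, counts$n_att_pairs),
    "<table>", header, body, "</table>",
    "</body></html>"), path)
  invisible(path)
}

# ---- tuning harness ---------------------------------------------------------

overlap_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Reciprocal-overlap match between predictions and truth
#'
#' Two intervals match when their shared length is at least `min_frac` of
#' each interval's length.
#'
#' @param pred,truth Tibbles with `contig_id`, `start`, `end`.
#' @param min_frac Reciprocal-overlap fraction (default 0.5).
#' @return List with `recall`, `precision`, `n_truth_matched`,
#'   `n_pred_matched`.
#' @export
match_regions <- function(pred, truth, min_frac = 0.5) {
  if (nrow(truth) == 0) stop("empty truth set")
  match_t <- logical(nrow(truth))
  match_p <- logical(nrow(pred))
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(pred))) {
      if (truth$contig_id[i] != pred$contig_id[j]) next
      ov <- overlap_len(truth$start[i], truth$end[i], pred$start[j], pred$end[j])
      if (ov >= min_frac * (truth$end[i] - truth$start[i]) &&
          ov >= min_frac * (pred$end[j] - pred$start[j])) {
        match_t[i] <- TRUE
        match_p[j] <- TRUE
      }
    }
  }
  list(recall = mean(match_t),
       precision = if (nrow(pred) == 0) NA_real_ else mean(match_p),
       n_truth_matched = sum(match_t), n_pred_matched = sum(match_p))
}

#' Grid search over the density-clustering parameters
#'
#' Re-runs detection over a grid of minimal cluster sizes and neighbour
#' densities (defaults: sizes 6..10 step 1, densities 3,000..10,000 bp step
#' 1,000 — a 5 x 8 = 40-cell grid) against user-supplied truth intervals,
#' reporting region-level recall and precision at >= 50% reciprocal overlap.
#'
#' @param instances List of instances, each a list with `genome`
#'   (an [annotated_genome()]), `hits` (hit tibble) and `truth` (tibble with
#'   `contig_id`, `start`, `end`).
#' @param sizes,densities Grid axes.
#' @param config Base [pipeline_config()] for all other parameters.
#' @param min_frac Reciprocal-overlap fraction.
#' @return Tibble with one row per grid cell: `min_size`, `density_bp`,
#'   `recall`, `precision`, sorted best-first (recall, tie precision).
#' @export
tune_parameters <- function(instances, sizes = 6:10,
                            densities = seq(3000, 10000, by = 1000),
                            config = pipeline_config(), min_frac = 0.5) {
  stopifnot(length(instances) >= 1)
  if (any(vapply(instances, function(x) nrow(x$truth) == 0, logical(1)))) {
    stop("empty truth set")
  }
  grid <- tidyr::expand_grid(min_size = sizes, density_bp = densities)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(k) {
    cfg <- config
    cfg$min_protein_num <- grid$min_size[k]
    cfg$protein_density_bp <- grid$density_bp[k]
    n_t <- 0; n_tm <- 0; n_p <- 0; n_pm <- 0
    for (inst in instances) {
      scan <- run_pipeline(inst$genome, hits = inst$hits, config = cfg)
      m <- match_regions(scan$regions, inst$truth, min_frac)
      n_t <- n_t + nrow(inst$truth); n_tm <- n_tm + m$n_truth_matched
      n_p <- n_p + nrow(scan$regions); n_pm <- n_pm + m$n_pred_matched
    }
    tibble(min_size = grid$min_size[k], density_bp = grid$density_bp[k],
           recall = n_tm / n_t,
           precision = if (n_p == 0) NA_real_ else n_pm / n_p)
  })
  arrange(res, desc(.data$recall), desc(.data$precision))
}
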
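# Similarity of predicted regions to candidate phage genomes.

#' Similarity features between a prophage region and one phage
#'
#' Scores a region against a candidate phage with three features:
#' `prot_hit_fraction` (share of region proteins with a qualifying protein
#' hit, e-value < `prot_evalue_max`), `nt_coverage` (share of region bases
#' covered by the union of qualifying nucleotide alignments, e-value <
#' `nt_evalue_max`) and `mean_identity` (mean percent identity of each
#' region protein's best qualifying hit; 0 when none).
#'
#' @param region One-row region tibble (`region_id`, `contig_id`, `start`,
#'   `end`).
#' @param region_genes Gene tibble restricted to the region.
#' @param prot_hits Protein hits for this region x phage pair (`query_id` =
#'   protein id).
#' @param nt_hits Nucleotide alignments of the region against the phage;
#'   `qstart`/`qend` are 1-based inclusive positions on the region sequence.
#' @param phage_id Candidate phage identifier.
#' @param prot_evalue_max,nt_evalue_max Qualifying-hit e-value ceilings.
#' @return One-row tibble: `region_id`, `phage_id`, `prot_hit_fraction`,
#'   `nt_coverage`, `mean_identity`.
#' @export
compute_similarity_features <- function(region, region_genes, prot_hits,
                                        nt_hits, phage_id,
                                        prot_evalue_max = 1e-7,
                                        nt_evalue_max = 1e-3) {
  prots <- region_genes |>
    filter(.data$kind == "CDS", !is.na(.data$protein_id)) |>
    pull("protein_id")
  if (!length(prots)) stop("region ", region$region_id, " has no proteins; cannot score")
  region_len <- region$end - region$start

  qp <- filter(as_tibble(prot_hits), .data$evalue < prot_evalue_max,
               .data$query_id %in% prots)
  frac <- length(unique(qp$query_id)) / length(prots)
  mean_id <- if (nrow(qp) == 0) 0 else {
    qp |>
      arrange(.data$query_id, .data$evalue, desc(.data$bitscore), .data$subject_id) |>
      distinct(.data$query_id, .keep_all = TRUE) |>
      pull("percent_identity") |>
      mean()
  }

  qn <- filter(as_tibble(nt_hits), .data$evalue < nt_evalue_max)
  cov <- if (nrow(qn) == 0 || region_len <= 0) 0 else {
    lo <- pmax(1, pmin(qn$qstart, qn$qend))
    hi <- pmin(region_len, pmax(qn$qstart, qn$qend))
    keep <- hi >= lo
    if (!any(keep)) 0 else {
      ir <- IRanges::reduce(IRanges::IRanges(start = lo[keep], end = hi[keep]))
      sum(IRanges::width(ir)) / region_len
    }
  }
  tibble(region_id = region$region_id, phage_id = phage_id,
         prot_hit_fraction = frac, nt_coverage = cov, mean_identity = mean_id)
}

#' Rank candidate phages against each prophage region
#'
#' Computes similarity features for every region x phage pair that has at
#' least one qualifying hit and ranks phages per region by descending
#' (`prot_hit_fraction`, `nt_coverage`, `mean_identity`), ties by phage id.
#' The phage a protein hit belongs to is the part of its `subject_id` before
#' the first `|` (or the whole `subject_id`); nucleotide hits use
#' `query_id` = region id and `subject_id` = phage id.
#'
#' @param regions Region tibble from [finalize_regions()].
#' @param genes Gene tibble of the genome.
#' @param prot_hits,nt_hits Hit tibbles (see
#'   [compute_similarity_features()]).
#' @param prot_evalue_max,nt_evalue_max Qualifying-hit ceilings.
#' @return Tibble of matches with a 1-based `rank` per region; regions with
#'   no qualifying hits are absent.
#' @export
annotate_regions <- function(regions, genes, prot_hits,
                             nt_hits = empty_hit_tbl(),
                             prot_evalue_max = 1e-7, nt_evalue_max = 1e-3) {
  if (nrow(regions) == 0) return(empty_match_tbl())
  prot_hits <- mutate(as_tibble(prot_hits),
                      phage_id = sub("\\|.*$", "", .data$subject_id))
  nt_hits <- as_tibble(nt_hits)
  out <- purrr::map_dfr(seq_len(nrow(regions)), function(r) {
    reg <- regions[r, ]
    g <- filter(genes, .data$contig_id == reg$contig_id,
                .data$start >= reg$start, .data$end <= reg$end)
    ph <- filter(prot_hits, .data$evalue < prot_evalue_max,
                 .data$query_id %in% g$protein_id)
    nh <- filter(nt_hits, .data$evalue < nt_evalue_max,
                 .data$query_id == reg$region_id)
    phage_ids <- sort(unique(c(ph$phage_id, nh$subject_id)))
    purrr::map_dfr(phage_ids, function(p) {
      compute_similarity_features(
        reg, g,
        filter(ph, .data$phage_id == p),
        filter(nh, .data$subject_id == p),
        phage_id = p,
        prot_evalue_max = prot_evalue_max, nt_evalue_max = nt_evalue_max)
    })
  })
  if (nrow(out) == 0) return(empty_match_tbl())
  out |>
    group_by(.data$region_id) |>
    arrange(desc(.data$prot_hit_fraction), desc(.data$nt_coverage),
            desc(.data$mean_identity), .data$phage_id, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
}

empty_match_tbl <- function() {
  tibble(region_id = character(), phage_id = character(),
         prot_hit_fraction = numeric(), nt_coverage = numeric(),
         mean_identity = numeric(), rank = integer())
}
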
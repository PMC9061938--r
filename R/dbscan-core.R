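# Density-clustering arm: phage-like genes chained along a contig.

#' Nucleotide gap between two gene intervals
#'
#' The spacing used by the density clusterer: `max(0, later.start -
#' earlier.end)`, i.e. 0 when the genes touch or overlap. Symmetric.
#'
#' @param a,b Gene features (one-row data frames or lists with `contig_id`,
#'   `start`, `end`).
#' @return Gap in bp.
#' @export
gene_gap <- function(a, b) {
  if (a$contig_id != b$contig_id) {
    stop("gene_gap() requires genes on the same contig (got '",
         a$contig_id, "' and '", b$contig_id, "')")
  }
  max(0, max(a$start, b$start) - min(a$end, b$end))
}

#' Cluster phage-like genes into minimal prophage candidates
#'
#' The one-dimensional reduction of DBSCAN used for prophage detection: on
#' each contig, consecutive phage-like genes whose inter-gene gap is at most
#' `max_gap` are chained into maximal runs (single linkage), and runs with at
#' least `min_size` members become minimal clusters. In 1-D with a gap metric
#' this coincides with density-reachability chaining, which the `"chain"`
#' mode implements directly; `"strict"` mode runs classic DBSCAN on gene
#' start coordinates (eps = `max_gap`, minPts = `min_size`) for comparison.
#'
#' Defaults are the tool's calibrated parameters: minimal cluster size 6
#' proteins and maximal neighbour distance 3,000 bp.
#'
#' @param calls Phage-like call tibble from [call_phage_like()] (needs
#'   `contig_id`, `index`, `start`, `end`).
#' @param max_gap Maximal spatial distance between neighbour genes in a
#'   cluster (bp).
#' @param min_size Minimal number of phage-like genes per cluster.
#' @param mode `"chain"` (default) or `"strict"`.
#' @return Cluster tibble: `contig_id`, `start`, `end` (envelope over
#'   members), `n_members`, `member_indices` (list column of gene ordinals),
#'   `source = "DBSCAN"`, ordered by (contig, start).
#' @export
cluster_phage_like <- function(calls, max_gap = 3000, min_size = 6,
                               mode = c("chain", "strict")) {
  mode <- match.arg(mode)
  stopifnot(max_gap >= 0, min_size >= 1)
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) return(empty_cluster_tbl())
  out <- calls |>
    arrange(.data$contig_id, .data$start, .data$end) |>
    group_by(.data$contig_id) |>
    dplyr::group_map(function(g, key) {
      grp <- switch(mode,
                    chain = chain_groups(g$start, g$end, max_gap),
                    strict = dbscan1d_groups(g$start, max_gap, min_size))
      cluster_rows(key$contig_id, g, grp, min_size)
    }) |>
    bind_rows()
  if (nrow(out) == 0) return(empty_cluster_tbl())
  arrange(out, .data$contig_id, .data$start)
}

# maximal runs under neighbour-gap chaining; input sorted by start
chain_groups <- function(start, end, max_gap) {
  n <- length(start)
  if (n == 1) return(1L)
  gap <- pmax(0, start[-1] - cummax(end[-n]))
  cumsum(c(1L, as.integer(gap > max_gap)))
}

# classic DBSCAN on 1-D start coordinates; returns group id per point, NA = noise
dbscan1d_groups <- function(x, eps, min_pts) {
  n <- length(x)
  d <- abs(outer(x, x, "-"))
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  grp <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(grp[i])) next
    cl <- cl + 1L
    queue <- i
    grp[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      reach <- which(nb[j, ] & is.na(grp))
      grp[reach] <- cl
      queue <- c(queue, reach[core[reach]])
    }
  }
  grp
}

cluster_rows <- function(contig_id, g, grp, min_size) {
  keep <- !is.na(grp)
  if (!any(keep)) return(NULL)
  g <- g[keep, ]; grp <- grp[keep]
  sizes <- table(grp)
  ok <- names(sizes)[sizes >= min_size]
  if (!length(ok)) return(NULL)
  purrr::map_dfr(ok, function(id) {
    m <- g[grp == id, ]
    tibble(contig_id = contig_id,
           start = min(m$start), end = max(m$end),
           n_members = nrow(m),
           member_indices = list(sort(m$index)),
           source = "DBSCAN")
  })
}

empty_cluster_tbl <- function() {
  tibble(contig_id = character(), start = numeric(), end = numeric(),
         n_members = integer(), member_indices = list(), source = character())
}
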
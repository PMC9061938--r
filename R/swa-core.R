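# Sliding-window arm: keyword scan over gene product annotations.

#' Phage keyword sets
#'
#' A keyword set holds lowercase include phrases (a product matches when it
#' contains at least one as a substring) and exclude phrases that veto a
#' match. [default_keywords()] loads the packaged list of phage structural,
#' lysis and integration vocabulary; [read_keywords()] reads a plain-text
#' file with one phrase per line, a `-` prefix marking excludes and `#`
#' starting comments.
#'
#' @param include,exclude Character vectors of phrases (lowercased on
#'   construction).
#' @return A list with elements `include` and `exclude`, class `keyword_set`.
#' @export
keyword_set <- function(include, exclude = character()) {
  include <- unique(tolower(trimws(include)))
  exclude <- unique(tolower(trimws(exclude)))
  include <- include[nzchar(include)]
  exclude <- exclude[nzchar(exclude)]
  if (!length(include)) stop("keyword set needs at least one include phrase")
  both <- intersect(include, exclude)
  if (length(both)) {
    stop("phrase(s) in both include and exclude lists: ",
         paste(both, collapse = ", "))
  }
  structure(list(include = include, exclude = exclude), class = "keyword_set")
}

#' @rdname keyword_set
#' @param path Keywords file, one phrase per line.
#' @export
read_keywords <- function(path) {
  if (!file.exists(path)) stop("cannot read keywords file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  excl <- startsWith(lines, "-")
  keyword_set(include = lines[!excl], exclude = sub("^-", "", lines[excl]))
}

#' @rdname keyword_set
#' @export
default_keywords <- function() {
  read_keywords(system.file("extdata", "phage_keywords.txt",
                            package = "prophinder", mustWork = TRUE))
}

#' Does a product annotation look phage-related?
#'
#' Case-insensitive substring matching of the keyword set against the product
#' text; an exclude phrase anywhere in the product vetoes the match. Empty or
#' missing products never match. Vectorised over `product`.
#'
#' @param product Character vector of gene product descriptions.
#' @param keywords A [keyword_set()].
#' @return Logical vector.
#' @export
is_phage_keyword <- function(product, keywords = default_keywords()) {
  p <- tolower(ifelse(is.na(product), "", product))
  hit <- Reduce(`|`, lapply(keywords$include, function(k) {
    stringr::str_detect(p, stringr::fixed(k))
  }), init = rep(FALSE, length(p)))
  if (length(keywords$exclude)) {
    veto <- Reduce(`|`, lapply(keywords$exclude, function(k) {
      stringr::str_detect(p, stringr::fixed(k))
    }), init = rep(FALSE, length(p)))
    hit <- hit & !veto
  }
  hit & nzchar(p)
}

#' Sliding-window scan for keyword-dense gene stretches
#'
#' On each contig a window of `window_size` consecutive annotated genes
#' slides with step 1 (a contig with fewer genes yields a single window of
#' all its genes). Both CDS and tRNA features count toward the window size,
#' but only CDS products are keyword-eligible. Windows containing at least
#' `min_hits` keyword-positive genes emit the minimal sub-region spanning
#' their first through last keyword-positive gene; identical sub-regions from
#' overlapping windows are deduplicated.
#'
#' @param genes Gene tibble of an [annotated_genome()].
#' @param keywords A [keyword_set()].
#' @param window_size Number of annotated genes per window.
#' @param min_hits Minimum keyword-positive genes for a window to qualify.
#' @return Cluster tibble in the same shape as [cluster_phage_like()], with
#'   `source = "SWA"` and members the keyword-positive genes of the window.
#' @export
scan_windows <- function(genes, keywords = default_keywords(),
                         window_size = 60, min_hits = 6) {
  stopifnot(window_size >= 1, min_hits >= 1)
  genes <- as_tibble(genes)
  if (nrow(genes) == 0) return(empty_cluster_tbl())
  out <- genes |>
    group_by(.data$contig_id) |>
    dplyr::group_map(function(g, key) {
      g <- arrange(g, .data$index)
      flag <- is_phage_keyword(g$product, keywords) & g$kind == "CDS"
      scan_contig_windows(key$contig_id, g, flag, window_size, min_hits)
    }) |>
    bind_rows()
  if (nrow(out) == 0) return(empty_cluster_tbl())
  out |>
    mutate(.key = vapply(.data$member_indices, paste, character(1), collapse = ",")) |>
    distinct(.data$contig_id, .data$start, .data$end, .data$.key,
             .keep_all = TRUE) |>
    select(-".key") |>
    arrange(.data$contig_id, .data$start)
}

scan_contig_windows <- function(contig_id, g, flag, window_size, min_hits) {
  n <- nrow(g)
  w <- min(window_size, n)
  starts <- seq_len(n - w + 1L)
  cs <- c(0L, cumsum(flag))
  counts <- cs[starts + w] - cs[starts]
  hits <- starts[counts >= min_hits]
  if (!length(hits)) return(NULL)
  purrr::map_dfr(hits, function(s) {
    pos <- which(flag[s:(s + w - 1L)]) + s - 1L
    tibble(contig_id = contig_id,
           start = g$start[pos[1]], end = max(g$end[pos]),
           n_members = length(pos),
           member_indices = list(g$index[pos]),
           source = "SWA")
  })
}
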
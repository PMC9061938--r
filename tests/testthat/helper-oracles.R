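# Independent brute-force oracles used to check the package's algorithms.
# These deliberately avoid the implementation's code paths.

# connected components of the "gap <= max_gap" graph, filtered by size
oracle_cluster <- function(start, end, max_gap, min_size) {
  n <- length(start)
  if (n == 0) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      gap <- max(0, max(start[i], start[j]) - min(end[i], end[j]))
      adj[i, j] <- gap <= max_gap
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- list()
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) >= min_size) {
      out[[length(out) + 1L]] <- sort(members)
    }
  }
  # order components by leftmost member start
  if (length(out) > 1) {
    out <- out[order(vapply(out, function(m) min(start[m]), numeric(1)))]
  }
  out
}

# exhaustive sliding-window enumeration with set-union dedup;
# returns unique (start, end, members) triples as strings for comparison
oracle_windows <- function(start, end, flag, index, window_size, min_hits) {
  n <- length(start)
  if (n == 0) return(character())
  w <- min(window_size, n)
  keys <- character()
  for (s in seq_len(n - w + 1L)) {
    win <- s:(s + w - 1L)
    pos <- win[flag[win]]
    if (length(pos) >= min_hits) {
      keys <- c(keys, paste(start[pos[1]], max(end[pos]),
                            paste(index[pos], collapse = ","), sep = "|"))
    }
  }
  sort(unique(keys))
}

# longest common substring of length >= min_len via full DP;
# ties: longest, then leftmost in a, then leftmost in b. NULL if none.
oracle_lcs <- function(a, b, min_len) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  if (na == 0 || nb == 0) return(NULL)
  best_len <- 0L; best_qa <- NA_integer_; best_qb <- NA_integer_
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    eq <- ca[i] == cb
    cur[eq] <- c(0L, prev[-nb])[eq] + 1L
    for (j in which(cur > 0)) {
      len <- cur[j]
      qa <- i - len + 1L; qb <- j - len + 1L
      if (len > best_len ||
          (len == best_len && (qa < best_qa || (qa == best_qa && qb < best_qb)))) {
        best_len <- len; best_qa <- qa; best_qb <- qb
      }
    }
    prev <- cur
  }
  if (best_len < min_len) return(NULL)
  list(length = best_len, qstart = best_qa, qend = best_qa + best_len - 1L,
       sstart = best_qb, send = best_qb + best_len - 1L)
}

# union length of 1-based inclusive intervals via sort-and-sweep
oracle_union_len <- function(lo, hi) {
  if (length(lo) == 0) return(0)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  total <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= cur_hi + 1) {
      cur_hi <- max(cur_hi, hi[i])
    } else {
      total <- total + cur_hi - cur_lo + 1
      cur_lo <- lo[i]; cur_hi <- hi[i]
    }
  }
  total + cur_hi - cur_lo + 1
}

# modal label with lexicographic tie-break, plus modal fraction
oracle_mode <- function(votes) {
  votes <- votes[votes != "unknown"]
  if (!length(votes)) return(list(taxon = "unassigned", fraction = 0))
  tab <- table(votes)
  modal <- sort(names(tab)[tab == max(tab)])[1]
  list(taxon = modal, fraction = as.numeric(max(tab)) / length(votes))
}

# transitive closure of pairwise interval overlap via igraph components
oracle_merge <- function(start, end) {
  n <- length(start)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- min(end[i], end[j]) > max(start[i], start[j])  # > 0 shared bp
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- lapply(unique(comp), function(cid) {
    m <- which(comp == cid)
    c(min(start[m]), max(end[m]))
  })
  mat <- do.call(rbind, out)
  mat[order(mat[, 1]), , drop = FALSE]
}

# random gene layout on one contig: n genes, random lengths and gaps
random_layout <- function(n, contig = "c1", max_len = 1200, max_gap = 4000) {
  lens <- sample(100:max_len, n, replace = TRUE)
  gaps <- sample(0:max_gap, n, replace = TRUE)
  starts <- cumsum(gaps) + cumsum(c(0, lens[-n]))
  gene_tbl(contig_id = contig, start = starts, end = starts + lens,
           strand = sample(c("+", "-"), n, replace = TRUE),
           product = "hypothetical protein",
           protein_id = sprintf("P%04d", seq_len(n)),
           protein_seq = "M")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# calls tibble for a layout: every gene phage-like with a dummy hit
layout_as_calls <- function(genes) {
  dplyr::mutate(genes,
                index = dplyr::row_number() - 1L,
                subject_id = "S1", percent_identity = 90,
                align_length = 100, evalue = 1e-20, bitscore = 200,
                subject_title = NA_character_, taxon = "unknown")
}
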
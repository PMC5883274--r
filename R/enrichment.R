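#' Common universe of assessed genes across contrasts
#'
#' Because each experiment assesses a different subset of genes, shared
#' markers can only be sought among genes assessed in every contrast.
#'
#' @param assessed named list of character vectors (assessed genes per
#'   contrast).
#' @return character vector: the intersection of all assessed sets.
#' @export
common_universe <- function(assessed) {
  stopifnot(is.list(assessed), length(assessed) >= 2L)
  Reduce(intersect, assessed)
}

#' Venn partition of marker sets across contrasts
#'
#' Restricts each marker set to the common universe, then partitions the
#' union of markers into the 2^k - 1 disjoint membership regions (15 regions
#' for four contrasts). Region names join the member contrasts with `&`.
#' The partition is exact: regions are disjoint and their sizes sum to the
#' size of the union.
#'
#' @param markers named list of marker gene sets, one per contrast.
#' @param universe common universe of assessed genes; markers outside it are
#'   dropped before partitioning.
#' @return list of class `venn_partition`: `regions` (named list region ->
#'   genes), `counts`, `contrasts`, `universe_size`.
#' @export
venn_partition <- function(markers, universe) {
  stopifnot(is.list(markers), length(markers) >= 2L, !is.null(names(markers)))
  k <- length(markers)
  restricted <- lapply(markers, intersect, universe)
  all_genes <- sort(unique(unlist(restricted)))
  membership <- vapply(restricted, function(s) all_genes %in% s,
                       logical(length(all_genes)))
  if (length(all_genes) == 1L) membership <- matrix(membership, nrow = 1L)
  patterns <- apply(membership, 1L, function(b) {
    paste(names(markers)[b], collapse = "&")
  })
  # all 2^k - 1 possible regions, even when empty
  region_names <- unlist(lapply(seq_len(k), function(m) {
    apply(utils::combn(names(markers), m), 2L, paste, collapse = "&")
  }))
  regions <- setNames(vector("list", length(region_names)), region_names)
  for (rn in region_names) regions[[rn]] <- character(0)
  found <- split(all_genes, patterns)
  regions[names(found)] <- found
  structure(list(regions = regions,
                 counts = vapply(regions, length, integer(1)),
                 contrasts = names(markers),
                 universe_size = length(universe)),
            class = "venn_partition")
}

#' Genes shared among a given subset of contrasts
#'
#' Aggregate view over a [venn_partition()]: all genes that are markers in
#' every one of `contrasts` (regardless of membership elsewhere), e.g. the
#' nuclei of the direct motor pathway or the telencephalic song nuclei.
#'
#' @param vp a `venn_partition`.
#' @param contrasts character vector of contrast names.
#' @return character vector of shared marker genes.
#' @export
shared_markers <- function(vp, contrasts) {
  stopifnot(inherits(vp, "venn_partition"),
            all(contrasts %in% vp$contrasts))
  hit <- vapply(names(vp$regions), function(rn) {
    members <- strsplit(rn, "&", fixed = TRUE)[[1]]
    all(contrasts %in% members)
  }, logical(1))
  sort(unique(unlist(vp$regions[hit])))
}

#' Hypergeometric over-representation analysis against a gene-set collection
#'
#' For each gene set, intersected with the assessed-gene universe, tests
#' whether the query (marker) list overlaps it more than expected by chance:
#' p = P(X >= k) under the hypergeometric distribution with universe size N,
#' set size K, query size n, overlap k. Sets overlapping the query in fewer
#' than `min_overlap` genes are not tested. Benjamini-Hochberg q-values are
#' computed across all tested sets; the returned table keeps rows with
#' p <= `p_cutoff` (set `report_all = TRUE` for every tested set) and flags
#' rows with q < 0.05, the conventional reporting filter.
#'
#' @param query character vector of query genes (must lie in `universe`).
#' @param universe character vector: assessed-gene universe.
#' @param gene_sets named list of character vectors.
#' @param min_overlap minimum query overlap for a set to be tested.
#' @param p_cutoff retention cutoff on the nominal p-value.
#' @param report_all return every tested set, not only p <= p_cutoff.
#' @return data.frame: `set`, `K` (set size in universe), `N`, `n`, `k`,
#'   `p`, `q`, `reportable` (q < 0.05), sorted by p.
#' @export
ora <- function(query, universe, gene_sets, min_overlap = 2,
                p_cutoff = 0.01, report_all = FALSE) {
  query <- unique(query)
  universe <- unique(universe)
  if (length(query) == 0L || length(universe) == 0L)
    stop("query and universe must be non-empty")
  if (!all(query %in% universe))
    stop("query genes must be a subset of the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(s) {
    set <- intersect(unique(gene_sets[[s]]), universe)
    K <- length(set)
    k <- length(intersect(set, query))
    if (k < min_overlap) return(NULL)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, K = K, N = N, n = n, k = k, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(set = character(0), K = integer(0), N = integer(0),
                      n = integer(0), k = integer(0), p = numeric(0),
                      q = numeric(0), reportable = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$reportable <- out$q < 0.05
  if (!report_all) out <- out[out$p <= p_cutoff, , drop = FALSE]
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summary table of marker counts per contrast
#'
#' One row per contrast: number of genes assessed, up-regulated (enriched)
#' markers, down-regulated (impoverished) markers, and their total.
#'
#' @param scores named list of gene score tables ([score_genes()]), one per
#'   contrast.
#' @return data.frame: `contrast`, `assessed`, `up`, `down`, `total`.
#' @export
summarize_markers <- function(scores) {
  rows <- lapply(names(scores), function(cn) {
    s <- scores[[cn]]
    assessed <- sum(s$status %in% c("differential", "nondifferential"))
    up <- sum(s$status == "differential" & s$direction == "up")
    down <- sum(s$status == "differential" & s$direction == "down")
    data.frame(contrast = cn, assessed = assessed, up = up, down = down,
               total = up + down, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
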
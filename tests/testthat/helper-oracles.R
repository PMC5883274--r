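# Independent oracles used across tests. These deliberately reimplement the
# checked operations by the most transparent route available (exhaustive
# enumeration, plain interval arithmetic, closed forms) and never call the
# package functions they verify.

# Scan every T-run in a sequence and report whether any run of >= 15 T's
# starts at positions 1..5 (1-based).
oracle_polyt <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  r <- rle(chars)
  starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  any(r$values == "T" & r$lengths >= 15L & starts <= 5L)
}

# Upper-tail hypergeometric by direct summation of the pmf from binomial
# coefficients.
oracle_hyper_upper <- function(k, K, N, n) {
  j <- seq(k, min(K, n))
  if (length(j) == 0L) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Upper-tail hypergeometric by full enumeration of all C(N, n) draws.
oracle_hyper_enumerate <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Venn region assignment by per-gene membership lookup.
oracle_venn <- function(markers, universe) {
  restricted <- lapply(markers, intersect, universe)
  genes <- sort(unique(unlist(restricted)))
  patterns <- vapply(genes, function(g) {
    paste(names(markers)[vapply(restricted, function(s) g %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  split(genes, patterns)
}

# Majority-rule gene scoring recomputed from scratch: transitive closure of
# the >75% reciprocal-overlap relation via boolean matrix powers, then group
# averaging and the >= 50% rule.
oracle_score <- function(probes, cutoff) {
  n <- nrow(probes)
  adj <- diag(n) > 0
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      if (is.na(probes$start[a]) || is.na(probes$start[b])) next
      if (probes$chrom[a] != probes$chrom[b] ||
          probes$strand[a] != probes$strand[b]) next
      ov <- min(probes$end[a], probes$end[b]) -
        max(probes$start[a], probes$start[b])
      shorter <- min(probes$end[a] - probes$start[a],
                     probes$end[b] - probes$start[b])
      if (shorter > 0 && ov / shorter > 0.75) adj[a, b] <- TRUE
    }
  }
  reach <- adj
  for (i in seq_len(n)) reach <- (reach %*% reach) > 0  # transitive closure
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (a in seq_len(n)) {
    if (is.na(comp[a])) {
      cid <- cid + 1L
      comp[which(reach[a, ])] <- cid
    }
  }
  pbar <- tapply(probes$p, comp, mean)
  mbar <- tapply(probes$M, comp, mean)
  sig <- pbar <= cutoff
  status <- if (mean(sig) >= 0.5) "differential" else "nondifferential"
  direction <- if (status != "differential") "none"
  else {
    ms <- mbar[sig]
    if (all(ms > 0)) "up" else if (all(ms < 0)) "down" else "conflict"
  }
  list(status = status, direction = direction,
       n_sig = sum(sig), n_nonsig = sum(!sig))
}

# Random probe configuration for one gene (<= max_probes probes).
random_probe_config <- function(max_probes = 8L) {
  k <- sample(1:max_probes, 1L)
  start <- sample(0:500, k, replace = TRUE)
  len <- sample(c(60L, 80L, 100L), k, replace = TRUE)
  data.frame(
    probe_id = sprintf("p%02d", seq_len(k)),
    chrom = sample(c("chr1", "chr1", "chr2"), k, replace = TRUE),
    strand = sample(c("+", "+", "-"), k, replace = TRUE),
    start = start, end = start + len,
    p = round(runif(k), 3),
    M = round(runif(k, -2, 2), 2),
    stringsAsFactors = FALSE
  )
}

# Ordinary pooled two-sample t computed the textbook way.
oracle_two_sample_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  t <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Small default config for fast tests; callers may override any field.
quick_config <- function(...) {
  args <- utils::modifyList(list(n_genes = 120L, n_pairs = 4L), list(...))
  do.call(sim_config, args)
}
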
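#' @keywords internal
"_PACKAGE"

#' @importFrom stats median phyper pt rnorm runif sd setNames p.adjust var
#' @importFrom utils read.delim write.table
NULL

# Derive a reproducible substream seed from a master seed and a stage label.
# Keeps seeds well inside 32-bit integer range.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587)
}

run_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# simple union-find for single-linkage grouping
uf_groups <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1L]); b <- find(pairs[r, 2L])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, integer(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_fraction <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

stop_nucmark <- function(msg, class) {
  stop(structure(class = c(class, "nucmark_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
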
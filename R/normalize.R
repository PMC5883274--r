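#' Background-correct one channel with the "half" rule
#'
#' Subtracts the local background estimate from the foreground; any zero or
#' negative difference is set to 0.5 so no spot is lost to the log transform.
#' Positive differences are returned unchanged.
#'
#' @param fg,bg non-negative foreground and background intensities.
#' @return corrected intensities, all strictly positive.
#' @export
background_correct_half <- function(fg, bg) {
  if (any(fg < 0, na.rm = TRUE) || any(bg < 0, na.rm = TRUE))
    stop("foreground and background intensities must be non-negative")
  d <- fg - bg
  ifelse(d > 0, d, 0.5)
}

#' M and A values for one two-channel array
#'
#' @param cy5,cy3 background-corrected channel intensities.
#' @return list with `M` = log2(Cy5/Cy3) and `A` = mean log2 intensity.
#' @export
compute_ma <- function(cy5, cy3) {
  list(M = log2(cy5) - log2(cy3), A = (log2(cy5) + log2(cy3)) / 2)
}

#' Print-tip loess normalization of one array
#'
#' Removes intensity-dependent dye bias within each print-tip group by
#' subtracting a robust loess curve of M on A (span 0.3, degree 1, 3
#' robustness iterations). Tip groups with fewer than 10 probes fall back to
#' the global loess curve; a group whose A values are all identical (loess
#' undefined) has its median M subtracted instead.
#'
#' @param M,A per-probe M and A values of one array.
#' @param tip integer print-tip group per probe; a single group reproduces
#'   the global fit.
#' @return normalized M values.
#' @export
normalize_within_array <- function(M, A, tip = rep(1L, length(M))) {
  stopifnot(length(M) == length(A), length(tip) == length(M))
  fit_curve <- function(idx) {
    a <- A[idx]
    if (length(unique(a)) == 1L) return(rep(median(M[idx]), length(idx)))
    limma::loessFit(M[idx], a, span = 0.3, iterations = 3L)$fitted
  }
  out <- M
  groups <- split(seq_along(M), tip)
  small <- vapply(groups, length, integer(1)) < 10L
  global_fit <- NULL
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    if (small[gi]) {
      if (is.null(global_fit)) global_fit <- fit_curve(seq_along(M))
      out[idx] <- M[idx] - global_fit[idx]
    } else {
      out[idx] <- M[idx] - fit_curve(idx)
    }
  }
  out
}

#' Orient a log-ratio as log2(sample/reference)
#'
#' In a dye-balanced common-reference design half of the arrays carry the
#' sample in Cy5 and half in Cy3. M values are log2(Cy5/Cy3); orienting them
#' as log2(sample/reference) leaves M unchanged when the sample is in Cy5
#' and negates it when the sample is in Cy3, making all arrays directly
#' comparable.
#'
#' @param M normalized M values of one array.
#' @param dye_of_sample `"Cy5"` or `"Cy3"`.
#' @return oriented log-ratios.
#' @export
to_sample_over_reference <- function(M, dye_of_sample) {
  if (length(dye_of_sample) != 1L || !dye_of_sample %in% c("Cy5", "Cy3"))
    stop("unknown dye orientation: ", paste(dye_of_sample, collapse = ","))
  if (dye_of_sample == "Cy5") M else -M
}

#' Process all arrays of a two-channel contrast into oriented log-ratios
#'
#' Background-corrects each channel with the "half" rule, computes M/A,
#' print-tip-loess-normalizes each array, and orients every M as
#' log2(sample/reference).
#'
#' @param intensities two-channel result of [generate_intensities()] or an
#'   equivalent list with `arrays`, `design`, `tip`.
#' @return list with `M` (probes x arrays matrix of oriented log-ratios) and
#'   `A` (matrix of A values).
#' @export
process_two_channel <- function(intensities) {
  stopifnot(intensities$platform == "two_channel")
  design <- intensities$design
  arrays <- intensities$arrays
  probe_id <- arrays[[1L]]$probe_id
  tip <- intensities$tip[probe_id]
  Mmat <- matrix(NA_real_, length(probe_id), nrow(design),
                 dimnames = list(probe_id, design$array_id))
  Amat <- Mmat
  for (j in seq_len(nrow(design))) {
    tab <- arrays[[design$array_id[j]]]
    cy5 <- background_correct_half(tab$F_Cy5, tab$B_Cy5)
    cy3 <- background_correct_half(tab$F_Cy3, tab$B_Cy3)
    ma <- compute_ma(cy5, cy3)
    mnorm <- normalize_within_array(ma$M, ma$A, tip)
    Mmat[, j] <- to_sample_over_reference(mnorm, design$dye_of_sample[j])
    Amat[, j] <- ma$A
  }
  list(M = Mmat, A = Amat)
}
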
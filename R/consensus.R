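#' Weighted residue frequencies at every query position
#'
#' For each alignment column where the query carries a residue, computes the
#' weight-normalized frequency of each of the 20 amino acids among the
#' weighted sequences, plus the weighted mass of gaps. `X` (unknown residue)
#' is pooled with the gap mass: it is never a consensus candidate and never
#' counts toward a residue's frequency, so the 20 residue frequencies plus
#' `gap_mass` always sum to one.
#'
#' @param family An [aligned_family].
#' @param weights Named weights from [branch_weights()]; names must be a
#'   subset of the family's ids (typically everything except the outgroup).
#' @return A `consensus_profile`: list with `freq` (positions x 20 matrix),
#'   `gap_mass`, `position` (1-based ungapped query coordinates), `column`
#'   (underlying alignment columns), `query_residue`, and `query_id`.
#' @export
column_frequencies <- function(family, weights) {
  stopifnot(inherits(family, "aligned_family"))
  ids <- intersect(names(weights), names(family$seqs))
  if (!length(ids))
    pc_error("no overlap between weight ids and family ids", "validation_error")
  w <- weights[ids]
  w <- w / sum(w)
  chars <- seq_chars(family)[ids, , drop = FALSE]
  qchars <- strsplit(family$seqs[[family$query_id]], "", fixed = TRUE)[[1]]
  cols <- which(qchars != "-")
  if (!length(cols))
    pc_error("query has no non-gap columns", "validation_error")
  npos <- length(cols)
  freq <- matrix(0, npos, 20, dimnames = list(NULL, AA_ALPHABET))
  gap_mass <- numeric(npos)
  for (p in seq_len(npos)) {
    col <- chars[, cols[p]]
    for (aa in AA_ALPHABET) freq[p, aa] <- sum(w[col == aa])
    gap_mass[p] <- sum(w[col == "-" | col == "X"])
  }
  structure(list(freq = freq, gap_mass = gap_mass,
                 position = seq_len(npos), column = cols,
                 query_residue = qchars[cols], query_id = family$query_id),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("consensus_profile: %d query positions (query: %s)\n",
              length(x$position), x$query_id))
  invisible(x)
}

#' Nominate candidate consensus substitutions
#'
#' At each query position, finds the most frequent residue (gaps excluded
#' from the argmax). A candidate substitution is emitted when that residue
#' differs from the query's and its frequency exceeds the cutoff. An exact
#' tie for the top residue yields no candidate (ambiguous consensus). The
#' frequency tested is, by default, relative to the total weight including
#' the gap mass, so a residue must clear the cutoff absolutely; set
#' `denominator = "nongap"` to test among residue-bearing sequences only.
#'
#' @param profile A `consensus_profile` from [column_frequencies()].
#' @param cutoff Frequency cutoff in percent (default 40: a candidate must
#'   appear in more than 40% of the weighted family).
#' @param denominator `"total"` (include gap mass, default) or `"nongap"`.
#' @return A data.frame of class `candidate_sites` with columns `position`,
#'   `query_residue`, `consensus_residue`, `frequency_pct`, `label` (e.g.
#'   `"D17V"`), `filter_status` (`"candidate"`), sorted by descending
#'   frequency. Zero rows is a valid result.
#' @export
candidate_sites <- function(profile, cutoff = 40,
                            denominator = c("total", "nongap")) {
  stopifnot(inherits(profile, "consensus_profile"))
  denominator <- match.arg(denominator)
  if (cutoff <= 0 || cutoff >= 100)
    pc_error("cutoff must be in (0, 100) percent", "validation_error")
  rows <- list()
  for (p in profile$position) {
    f <- profile$freq[p, ]
    top <- max(f)
    if (top <= 0) next
    winners <- names(f)[f >= top - 1e-12]
    if (length(winners) != 1L) next        # ambiguous consensus
    cstar <- winners
    if (cstar == profile$query_residue[p]) next
    fr <- if (denominator == "total") top else top / max(1 - profile$gap_mass[p], .Machine$double.eps)
    if (fr * 100 > cutoff) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = p,
        query_residue = profile$query_residue[p],
        consensus_residue = cstar,
        frequency_pct = fr * 100,
        label = paste0(profile$query_residue[p], p, cstar),
        filter_status = "candidate",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0), query_residue = character(0),
               consensus_residue = character(0), frequency_pct = numeric(0),
               label = character(0), filter_status = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(-out$frequency_pct, out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_sites", "data.frame")
  out
}

#' Write a consensus profile or candidate table as TSV
#'
#' @param x A `consensus_profile` or `candidate_sites` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus_tsv <- function(x, path) {
  if (inherits(x, "consensus_profile")) {
    top_idx <- apply(x$freq, 1, which.max)
    df <- data.frame(position = x$position,
                     query_res = x$query_residue,
                     top_res = AA_ALPHABET[top_idx],
                     top_freq_pct = 100 * x$freq[cbind(x$position, top_idx)],
                     gap_mass = x$gap_mass)
  } else {
    df <- as.data.frame(x)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
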
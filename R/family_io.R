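#' @keywords internal
"_PACKAGE"

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_THREE <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
              GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
              MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
              SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")

pc_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "phyloconsensus_error")))
}
pc_warning <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "phyloconsensus_warning")))
}

#' Construct an aligned protein family
#'
#' An `aligned_family` holds a protein multiple sequence alignment together
#' with the identifier of the query (design target) row. All downstream
#' steps — distances, tree, weights, consensus — derive from this object.
#'
#' @param seqs Named character vector of aligned sequences (equal lengths;
#'   characters from the 20-letter amino-acid alphabet plus `X` and the gap
#'   `-`). Names are the sequence identifiers.
#' @param query_id Identifier of the query sequence; must name exactly one
#'   record.
#' @return An object of class `aligned_family`: a list with elements
#'   `seqs` (named character vector), `query_id` and `alignment_length`.
#' @examples
#' fam <- aligned_family(c(q = "MKL-A", h1 = "MKLTA", h2 = "MRLTA"), "q")
#' fam$alignment_length
#' @export
aligned_family <- function(seqs, query_id) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    pc_error("all sequences must be named", "validation_error")
  seqs <- toupper(vapply(seqs, as.character, character(1)))
  ids <- names(seqs)
  if (anyDuplicated(ids))
    pc_error(sprintf("duplicate sequence ids: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "validation_error")
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    pc_error(sprintf("aligned sequences differ in length (%s)",
                     paste(range(lens), collapse = "-")),
             "alignment_error")
  ok <- c(AA_ALPHABET, "X", "-")
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% ok)
    if (length(bad))
      pc_error(sprintf("illegal character '%s' in record '%s' at column %d",
                       ch[bad[1]], ids[i], bad[1]),
               "validation_error")
  }
  if (sum(ids == query_id) != 1L)
    pc_error(sprintf("query_id '%s' does not name exactly one record", query_id),
             "validation_error")
  structure(list(seqs = seqs, query_id = query_id,
                 alignment_length = unname(lens[1])),
            class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("aligned_family: %d sequences x %d columns (query: %s)\n",
              length(x$seqs), x$alignment_length, x$query_id))
  invisible(x)
}

#' @export
length.aligned_family <- function(x) length(x$seqs)

ungap <- function(s) gsub("-", "", s, fixed = TRUE)

seq_chars <- function(family) {
  m <- do.call(rbind, strsplit(family$seqs, "", fixed = TRUE))
  rownames(m) <- names(family$seqs)
  m
}

#' Read a protein family alignment
#'
#' Reads a multiple sequence alignment in FASTA or Clustal format and
#' validates it (equal row lengths, unique ids, legal residue characters).
#' Parsing is delegated to [Biostrings::readAAStringSet()] /
#' [Biostrings::readAAMultipleAlignment()]; this function layers the family
#' invariants and query designation on top.
#'
#' @param path Path to the alignment file.
#' @param query_id Identifier of the query sequence in the file.
#' @param format `"fasta"` or `"clustal"`.
#' @return An [aligned_family].
#' @export
read_alignment <- function(path, query_id, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path))
    pc_error(sprintf("file not found: %s", path), "validation_error")
  if (format == "fasta") {
    # readAAStringSet tolerates ragged rows, so length validation stays ours
    ss <- Biostrings::readAAStringSet(path)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    seqs <- as.character(Biostrings::unmasked(aln))
  }
  if (!length(seqs))
    pc_error(sprintf("no sequences in %s", path), "validation_error")
  aligned_family(seqs, query_id)
}

#' Write an aligned family to FASTA
#'
#' @param family An [aligned_family].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(family, path) {
  ss <- Biostrings::AAStringSet(family$seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Percent identity between two rows of an alignment
#'
#' Matches over mutually non-gap columns divided by the count of mutually
#' non-gap columns. `X` never counts as a match.
#' @noRd
alignment_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  both <- ca != "-" & cb != "-"
  if (!any(both)) return(0)
  match_ok <- ca == cb & ca != "X"
  sum(match_ok & both) / sum(both)
}

#' Pre-filter a homolog family
#'
#' Removes, in order: (a) records whose ungapped sequence is byte-identical
#' to an earlier record (the query is never removed; it takes priority over
#' any duplicate of itself), (b) records whose ungapped length falls outside
#' `(1 - length_tolerance, 1 + length_tolerance)` times the query's ungapped
#' length, and (c) records whose identity to the query (matches over mutually
#' non-gap columns) is below `min_identity`.
#'
#' @param family An [aligned_family].
#' @param min_identity Minimum fraction identity to the query, in (0, 1].
#' @param length_tolerance Allowed fractional deviation of ungapped length
#'   from the query's (default 0.2).
#' @param report_path Optional path; if given, a TSV of removed records
#'   (`id`, `reason_removed`) is written there.
#' @return A new [aligned_family]; the removal audit is attached as
#'   attribute `"filter_report"` (a data.frame with columns `id`, `reason`).
#' @export
filter_homologs <- function(family, min_identity = 0.5, length_tolerance = 0.2,
                            report_path = NULL) {
  stopifnot(inherits(family, "aligned_family"))
  if (min_identity <= 0 || min_identity > 1)
    pc_error("min_identity must be in (0, 1]", "validation_error")
  ids <- names(family$seqs)
  qid <- family$query_id
  ug <- vapply(family$seqs, ungap, character(1))
  qlen <- nchar(ug[[qid]])
  removed <- character(0); reason <- character(0)
  drop <- function(id, why) {
    removed <<- c(removed, id); reason <<- c(reason, why)
  }

  # dedupe: query first in priority order, then file order
  order_ids <- c(qid, setdiff(ids, qid))
  seen <- character(0)
  for (id in order_ids) {
    if (ug[[id]] %in% seen) drop(id, "duplicate") else seen <- c(seen, ug[[id]])
  }
  keep <- setdiff(ids, removed)

  lo <- (1 - length_tolerance) * qlen
  hi <- (1 + length_tolerance) * qlen
  for (id in setdiff(keep, qid)) {
    n <- nchar(ug[[id]])
    if (n < lo || n > hi) drop(id, "length")
  }
  keep <- setdiff(ids, removed)

  q <- family$seqs[[qid]]
  for (id in setdiff(keep, qid)) {
    if (alignment_identity(family$seqs[[id]], q) < min_identity)
      drop(id, "low_identity")
  }
  keep <- setdiff(ids, removed)

  if (length(keep) < 3L)
    pc_error(sprintf("only %d sequences survive filtering; a consensus needs >= 3",
                     length(keep)),
             "insufficient_family_error")
  out <- aligned_family(family$seqs[keep], qid)
  rep <- data.frame(id = removed, reason = reason, stringsAsFactors = FALSE)
  attr(out, "filter_report") <- rep
  if (!is.null(report_path))
    utils::write.table(rep, report_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
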
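#' Canonicalize unordered protein pairs
#'
#' Stores each unordered pair in a single canonical form: `protein_a` is the
#' lexicographically smaller identifier. Ordering is byte-wise (C locale,
#' via radix sorting), so it does not depend on the session locale.
#'
#' @param a,b character vectors of protein identifiers.
#' @return data.frame with columns `protein_a`, `protein_b` (a < b).
#' @export
canonical_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  lev <- sort(unique(c(a, b)), method = "radix")
  swap <- match(a, lev) > match(b, lev)
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  data.frame(protein_a = a, protein_b = b, stringsAsFactors = FALSE)
}

#' Load tab-delimited interaction records
#'
#' One row per literature report of a physical interaction:
#' `protein_a<TAB>protein_b<TAB>publication_id[<TAB>source_db]`. Lines
#' starting with `#` are ignored. Identifiers are whitespace-trimmed and the
#' pair is stored canonically (smaller identifier first). Self-reports
#' (A == B after trimming) are dropped with a warning; the number dropped is
#' returned in the `"dropped_self"` attribute. Rows without a publication
#' identifier are rejected: a record is one report in one publication.
#'
#' @param path path to a records file.
#' @param format input dialect; only `"tsv"` is supported.
#' @return data.frame of records with columns `protein_a`, `protein_b`,
#'   `publication_id`, `source_db` and attribute `dropped_self`.
#' @export
load_records <- function(path, format = "tsv") {
  format <- match.arg(format, "tsv")
  if (!file.exists(path)) stop("records file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty records file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- lineno[which(nf < 3L)[1L]]
    stop("malformed record (fewer than 3 columns) at line ", bad,
         " of ", path)
  }
  a <- trimws(vapply(fields, `[[`, "", 1L))
  b <- trimws(vapply(fields, `[[`, "", 2L))
  pub <- trimws(vapply(fields, `[[`, "", 3L))
  src <- trimws(vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "", ""))
  if (any(pub == "")) {
    bad <- lineno[which(pub == "")[1L]]
    stop("record without publication identifier at line ", bad, " of ", path)
  }
  if (any(a == "" | b == "")) {
    bad <- lineno[which(a == "" | b == "")[1L]]
    stop("record with empty protein identifier at line ", bad, " of ", path)
  }
  self <- a == b
  n_self <- sum(self)
  if (n_self > 0L)
    warning("dropped ", n_self, " self-interaction record(s)")
  pairs <- canonical_pairs(a[!self], b[!self])
  out <- data.frame(pairs,
                    publication_id = pub[!self],
                    source_db = src[!self],
                    stringsAsFactors = FALSE)
  attr(out, "dropped_self") <- n_self
  out
}

#' Remove redundant record copies
#'
#' Different source databases index overlapping literature, so the same
#' (pair, publication) report can appear several times. Keeps the first
#' occurrence of each (canonical pair, publication_id) key; `source_db` is
#' ignored for the purpose of identity. Idempotent.
#'
#' @param records data.frame as returned by [load_records()].
#' @return deduplicated records, original order preserved.
#' @export
deduplicate <- function(records) {
  key <- paste(records$protein_a, records$protein_b,
               records$publication_id, sep = "\r")
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate records into an occurrence-weighted network
#'
#' Collapses deduplicated records into unique unordered pairs with
#' occurrence counts O_ij (number of distinct reports of the pair),
#' per-protein report counts N_i (total reports involving protein i,
#' counting multiplicity) and total record count N. Note N_i is not the
#' degree: repeated reports of one partner inflate N_i but not the degree.
#'
#' @param records deduplicated records data.frame.
#' @return object of class `ppi_network`: list with `pairs` (data.frame
#'   `protein_a`, `protein_b`, `occurrence`), `protein_occurrence` (named
#'   integer vector N_i) and `total_records` (N).
#' @export
aggregate_records <- function(records) {
  if (nrow(records) == 0L) stop("no records to aggregate")
  if (any(records$protein_a == records$protein_b))
    stop("self-pairs must be dropped before aggregation")
  records[c("protein_a", "protein_b")] <-
    canonical_pairs(records$protein_a, records$protein_b)
  key <- paste(records$protein_a, records$protein_b, sep = "\r")
  tab <- table(key)
  first <- !duplicated(key)
  pairs <- records[first, c("protein_a", "protein_b"), drop = FALSE]
  pairs$occurrence <- as.integer(tab[paste(pairs$protein_a, pairs$protein_b,
                                           sep = "\r")])
  ord <- order(pairs$protein_a, pairs$protein_b, method = "radix")
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  occ <- c(rep(pairs$protein_a, pairs$occurrence),
           rep(pairs$protein_b, pairs$occurrence))
  ni <- table(occ)
  protein_occurrence <- setNames(as.integer(ni), names(ni))
  structure(list(pairs = pairs,
                 protein_occurrence = protein_occurrence,
                 total_records = sum(pairs$occurrence)),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$protein_occurrence), "proteins,",
      nrow(x$pairs), "unique pairs,", x$total_records, "records\n")
  invisible(x)
}

#' Number of distinct interaction partners of a protein
#'
#' @param network a `ppi_network`.
#' @param protein protein identifier present in the network.
#' @return integer degree (always <= the protein's report count N_i).
#' @export
network_degree <- function(network, protein) {
  if (!protein %in% names(network$protein_occurrence))
    stop("unknown protein: ", protein)
  sum(network$pairs$protein_a == protein | network$pairs$protein_b == protein)
}

#' Degree distribution of a set of unordered pairs
#'
#' @param pairs data.frame with columns `protein_a`, `protein_b` (unique
#'   unordered pairs), or a `ppi_network`.
#' @return named integer vector mapping degree to protein count. Satisfies
#'   the handshake identity sum(degree * count) == 2 * nrow(pairs).
#' @export
degree_distribution <- function(pairs) {
  if (inherits(pairs, "ppi_network")) pairs <- pairs$pairs
  deg <- table(c(pairs$protein_a, pairs$protein_b))
  dist <- table(as.integer(deg))
  setNames(as.integer(dist), names(dist))
}

#' Write / read an aggregated network as TSV
#'
#' Columns `protein_a`, `protein_b`, `occurrence`. Reading re-derives N_i
#' and N, so a write/read round trip reproduces the network exactly.
#'
#' @param network a `ppi_network`.
#' @param path output / input path.
#' @return `read_network` returns a `ppi_network`; `write_network` its path,
#'   invisibly.
#' @export
write_network <- function(network, path) {
  write.table(network$pairs, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  recs <- data.frame(
    protein_a = rep(df$protein_a, df$occurrence),
    protein_b = rep(df$protein_b, df$occurrence),
    stringsAsFactors = FALSE)
  recs$publication_id <- sprintf("ROW%06d", seq_len(nrow(recs)))
  recs$source_db <- ""
  aggregate_records(recs)
}

#' Write records to TSV (ground-truth labels, if present, are stripped)
#'
#' @param records records data.frame.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  cols <- intersect(c("protein_a", "protein_b", "publication_id",
                      "source_db"), names(records))
  write.table(records[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
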
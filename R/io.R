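# Table and FASTA ingestion. CSV is the default dialect; tab-separated
# input is auto-detected from the .tsv/.tab extension.

.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Read a species-to-ecological-group table
#'
#' Expected columns: \code{species}, \code{group} (tokens I..V or NA)
#' and optionally \code{phylum}, \code{genus}, \code{family},
#' \code{order}, \code{class}. Duplicate species rows with consistent
#' groups are deduplicated with a warning; conflicting duplicates are
#' an error.
#'
#' @param path CSV/TSV file path.
#' @return an \code{\link{eg_map}}.
#' @export
read_eg_table <- function(path) {
  df <- .read_table(path)
  need <- c("species", "group")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  }
  extra <- intersect(c("genus", "family", "order", "class"), names(df))
  eg_map(
    species = df$species,
    group = df$group,
    phylum = if ("phylum" %in% names(df)) df$phylum else "unknown",
    taxonomy = if (length(extra) > 0) df[, extra, drop = FALSE] else NULL
  )
}

#' Write an ecological-group map to CSV
#'
#' @param eg an \code{\link{eg_map}}.
#' @param path output file.
#' @export
write_eg_table <- function(eg, path) {
  df <- as.data.frame(eg)
  df$group <- as.character(df$group)
  df$group[df$group == "UNASSIGNED"] <- "NA"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a station-by-species abundance matrix
#'
#' First column is the station id; remaining columns are species counts
#' (non-negative integers). All-zero rows are legitimate azoic stations.
#'
#' @param path CSV/TSV file path.
#' @return stations x species numeric matrix (see
#'   \code{\link{as_station_matrix}}).
#' @export
read_abundance_matrix <- function(path) {
  df <- .read_table(path)
  if (ncol(df) < 2) stop("abundance matrix needs a station column plus species columns")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  as_station_matrix(m)
}

#' Write a station matrix to CSV
#'
#' @param mat stations x species matrix.
#' @param path output file.
#' @export
write_abundance_matrix <- function(mat, path) {
  df <- data.frame(station_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an annotated FASTA file
#'
#' Headers follow the dialect \code{>id|species|phylum} (delimiter
#' configurable). Multi-line sequences are joined and upper-cased;
#' every sequence must be non-empty and strictly IUPAC nucleotide
#' (violations are reported with their offset).
#'
#' @param path FASTA file.
#' @param delim header field delimiter (default \code{"|"}).
#' @param marker marker label attached to every record.
#' @return data.frame with columns \code{id}, \code{species},
#'   \code{phylum}, \code{seq}, \code{length}, \code{marker}.
#' @export
read_fasta <- function(path, delim = "|", marker = NA_character_) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no records in ", path)
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for record '", names(set)[nchar(seqs) == 0][1], "'")
  }
  validate_iupac(seqs, "record")
  fields <- strsplit(names(set), delim, fixed = TRUE)
  get <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) trimws(f[i]) else NA_character_
  }, character(1))
  data.frame(id = get(1), species = normalize_species(get(2)),
             phylum = get(3), seq = unname(seqs),
             length = unname(nchar(seqs)), marker = marker,
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param records data.frame with \code{id}, \code{species},
#'   \code{phylum}, \code{seq}.
#' @param path output file.
#' @param delim header field delimiter.
#' @export
write_fasta <- function(records, path, delim = "|") {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- paste(records$id, records$species, records$phylum,
                      sep = delim)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a primer-pair definition table
#'
#' TSV/CSV with columns \code{name}, \code{forward}, \code{reverse} and
#' optionally \code{marker}.
#'
#' @param path file path.
#' @return list of \code{\link{primer_pair}} objects.
#' @export
read_primer_table <- function(path) {
  df <- .read_table(path)
  need <- c("name", "forward", "reverse")
  if (!all(need %in% names(df))) {
    stop("primer table needs columns name, forward, reverse")
  }
  lapply(seq_len(nrow(df)), function(i) {
    primer_pair(df$name[i], df$forward[i], df$reverse[i],
                marker = if ("marker" %in% names(df)) df$marker[i] else NA)
  })
}
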
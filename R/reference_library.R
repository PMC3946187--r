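#' Deduplicate per-species sequences by greedy clustering
#'
#' Within each species, sequences are sorted longest first and clustered
#' greedily: a sequence joins the first existing cluster whose
#' representative it matches at or above the similarity threshold,
#' otherwise it founds a new cluster. The representative is always the
#' cluster founder (the longest member). Identity is the best ungapped
#' full-overlap offset alignment normalized by the shorter length;
#' sequences from different species never co-cluster.
#'
#' @param records data.frame with columns \code{id}, \code{species} and
#'   \code{seq} (see \code{\link{read_fasta}}).
#' @param threshold similarity threshold in (0, 1] (default 0.9).
#' @return data.frame of representative records (one per cluster) with
#'   column \code{cluster_size} added and attribute \code{members}
#'   (named list: representative id -> member ids).
#' @export
dedup_cluster <- function(records, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(records) == 0) {
    out <- records
    out$cluster_size <- integer(0)
    attr(out, "members") <- list()
    return(out)
  }
  validate_iupac(records$seq, "record")
  reps <- list()
  members <- list()
  for (sp in unique(records$species)) {
    rs <- records[records$species == sp, , drop = FALSE]
    rs <- rs[order(-nchar(rs$seq), rs$id), , drop = FALSE]
    sp_reps <- integer(0)   # row indices into rs of cluster founders
    for (i in seq_len(nrow(rs))) {
      placed <- FALSE
      for (r in sp_reps) {
        if (seq_identity(rs$seq[i], rs$seq[r]) >= threshold) {
          members[[rs$id[r]]] <- c(members[[rs$id[r]]], rs$id[i])
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        sp_reps <- c(sp_reps, i)
        members[[rs$id[i]]] <- rs$id[i]
      }
    }
    reps[[sp]] <- rs[sp_reps, , drop = FALSE]
  }
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  out$cluster_size <- vapply(members[out$id], length, 0L)
  attr(out, "members") <- members[out$id]
  out
}

#' Barcode coverage of a species list
#'
#' For each marker library, which listed species have at least one
#' sequence, broken down by phylum, plus the cross-marker overlap.
#' Species present in a library but absent from the list are reported
#' separately, not treated as an error.
#'
#' @param eg an \code{\link{eg_map}} (the species list, with phyla).
#' @param libraries named list of record data.frames, one per marker
#'   (names are marker labels, e.g. \code{"CO1"}, \code{"18S"}).
#' @return list of class \code{"coverage_report"}: \code{species}
#'   (named list of covered species per marker), \code{by_phylum}
#'   (data.frame: phylum, n_species, then per marker n_<m> and
#'   prop_<m>), \code{overlap} (species covered by every marker),
#'   \code{unlisted} (library species not on the list, per marker) and
#'   \code{total_proportion} (fraction of the list sequenced for at
#'   least one marker).
#' @export
coverage_report <- function(eg, libraries) {
  stopifnot(inherits(eg, "eg_map"), is.list(libraries),
            !is.null(names(libraries)))
  listed <- eg$species
  covered <- lapply(libraries, function(rec) {
    intersect(listed, unique(normalize_species(rec$species)))
  })
  unlisted <- lapply(libraries, function(rec) {
    setdiff(unique(normalize_species(rec$species)), listed)
  })
  by_phylum <- data.frame(table(phylum = eg$phylum), stringsAsFactors = FALSE)
  names(by_phylum)[2] <- "n_species"
  by_phylum$phylum <- as.character(by_phylum$phylum)
  for (m in names(libraries)) {
    hit <- eg$species %in% covered[[m]]
    nm <- tapply(hit, eg$phylum, sum)[as.character(by_phylum$phylum)]
    by_phylum[[paste0("n_", m)]] <- as.integer(nm)
    by_phylum[[paste0("prop_", m)]] <- as.numeric(nm) / by_phylum$n_species
  }
  overlap <- Reduce(intersect, covered)
  any_cov <- unique(unlist(covered))
  res <- list(species = covered, by_phylum = by_phylum,
              overlap = overlap, unlisted = unlisted,
              total_proportion = length(any_cov) / length(listed))
  class(res) <- "coverage_report"
  res
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Barcode coverage: %.1f%% of %d listed species sequenced for >=1 marker\n",
              100 * x$total_proportion, sum(x$by_phylum$n_species)))
  for (m in names(x$species)) {
    cat(sprintf("  %s: %d species (%d not on the list)\n",
                m, length(x$species[[m]]), length(x$unlisted[[m]])))
  }
  cat("  both/all markers:", length(x$overlap), "species\n")
  invisible(x)
}

#' Species of a station matrix having barcode sequences
#'
#' Subset of the matrix species with at least one record in the library;
#' feeds \code{\link{subset_agreement}} to measure how well the
#' currently sequenced species reproduce the full classification.
#'
#' @param mat stations x species count matrix.
#' @param records library record data.frame for one marker.
#' @return character vector of matrix species names with sequences.
#' @export
sequenced_species_filter <- function(mat, records) {
  mat <- as_station_matrix(mat)
  seq_sp <- unique(normalize_species(records$species))
  keep <- intersect(colnames(mat), seq_sp)
  if (length(keep) == 0) {
    stop(sprintf("no overlap: %d matrix species vs %d sequenced species",
                 ncol(mat), length(seq_sp)))
  }
  keep
}
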
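#' Ecological group tokens
#'
#' The five pollution-tolerance ecological groups (EG) used by the AMBI,
#' from GI (sensitive to organic enrichment) to GV (first-order
#' opportunists), plus the sentinel \code{"UNASSIGNED"} for species with
#' no group on the list.
#'
#' @return Character vector of the six group tokens.
#' @export
eg_levels <- function() c("I", "II", "III", "IV", "V", "UNASSIGNED")

#' AMBI group weights
#'
#' Pollution-tolerance weights applied to the percentage of each
#' ecological group: 0, 1.5, 3, 4.5 and 6 for GI..GV.
#'
#' @return Named numeric vector of length 5.
#' @export
eg_weights <- function() c(I = 0, II = 1.5, III = 3, IV = 4.5, V = 6)

#' Normalize a species name for matching
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs
#' to a single space and lower-cases. No fuzzy matching is performed:
#' near-miss spellings stay distinct so that misassignments are never
#' silent.
#'
#' @param x character vector of species names.
#' @return character vector of normalized names.
#' @export
normalize_species <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

#' Construct a species-to-ecological-group map
#'
#' The map plays the role of the AMBI species list: each species carries
#' a phylum and an ecological group (GI..GV) or \code{"UNASSIGNED"}.
#' Species names are normalized (see \code{\link{normalize_species}})
#' and must be unique after normalization.
#'
#' @param species character vector of species names.
#' @param group character vector of group tokens; \code{"I".."V"},
#'   \code{"UNASSIGNED"}, or \code{NA}/\code{"NA"} (mapped to
#'   \code{"UNASSIGNED"}).
#' @param phylum character vector of phylum names (recycled if length 1).
#' @param taxonomy optional data.frame of extra ranks (genus, family,
#'   order, class) aligned with \code{species}; kept as additional
#'   columns for \code{\link{eg_heterogeneity_by_rank}}.
#' @return A data.frame of class \code{"eg_map"} with columns
#'   \code{species} (normalized, unique), \code{phylum}, \code{group}
#'   (factor over \code{\link{eg_levels}}) and any taxonomy columns.
#' @export
eg_map <- function(species, group, phylum = "unknown", taxonomy = NULL) {
  species <- normalize_species(species)
  group <- as.character(group)
  group[is.na(group) | group %in% c("NA", "na", "")] <- "UNASSIGNED"
  group <- toupper(group)
  bad <- setdiff(unique(group), eg_levels())
  if (length(bad) > 0) {
    stop("unparseable ecological group token(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(species)) {
    dups <- unique(species[duplicated(species)])
    # consistent duplicates collapse; conflicting ones are an error
    conflict <- vapply(dups, function(s) {
      length(unique(group[species == s])) > 1L
    }, logical(1))
    if (any(conflict)) {
      stop("conflicting ecological groups for species: ",
           paste(dups[conflict], collapse = ", "))
    }
    warning("dropping ", sum(duplicated(species)),
            " duplicate species row(s) with consistent groups")
    keep <- !duplicated(species)
    species <- species[keep]
    group <- group[keep]
    if (length(phylum) > 1L) phylum <- phylum[keep]
    if (!is.null(taxonomy)) taxonomy <- taxonomy[keep, , drop = FALSE]
  }
  out <- data.frame(
    species = species,
    phylum = rep_len(as.character(phylum), length(species)),
    group = factor(group, levels = eg_levels()),
    stringsAsFactors = FALSE
  )
  if (!is.null(taxonomy)) out <- cbind(out, taxonomy)
  class(out) <- c("eg_map", "data.frame")
  out
}

#' @export
print.eg_map <- function(x, ...) {
  cat("Ecological group map:", nrow(x), "species,",
      length(unique(x$phylum)), "phyla\n")
  print(table(group = x$group))
  invisible(x)
}

#' Look up ecological groups for species names
#'
#' Species absent from the map are treated as \code{"UNASSIGNED"} with a
#' warning (once per call), mirroring how unlisted taxa are handled when
#' computing the index.
#'
#' @param species character vector (normalized internally).
#' @param eg an \code{\link{eg_map}}.
#' @param warn warn about unmatched species (default TRUE).
#' @return factor of group tokens aligned with \code{species}.
#' @export
eg_lookup <- function(species, eg, warn = TRUE) {
  stopifnot(inherits(eg, "eg_map"))
  idx <- match(normalize_species(species), eg$species)
  out <- eg$group[idx]
  if (anyNA(idx)) {
    if (warn) {
      warning(sum(is.na(idx)), " species not on the ecological group list; ",
              "treated as UNASSIGNED")
    }
    out[is.na(idx)] <- "UNASSIGNED"
  }
  out
}

#' Ecological-group heterogeneity by taxonomic rank
#'
#' For each taxonomic rank, groups the assigned species by taxon name
#' and counts how many distinct ecological groups the member species
#' span. Taxa whose species all share one group could in principle be
#' identified at that rank; any spread beyond one group means
#' species-level identification is required for index calculation.
#'
#' @param eg an \code{\link{eg_map}} whose columns include the requested
#'   ranks (e.g. \code{genus}, \code{family}, \code{order},
#'   \code{class}, \code{phylum}).
#' @param ranks character vector of rank column names to tabulate.
#' @return data.frame with columns \code{rank}, \code{n_groups} (1..5)
#'   and \code{n_taxa}; empty map gives a zero-row table. UNASSIGNED
#'   species are excluded.
#' @export
eg_heterogeneity_by_rank <- function(eg, ranks = intersect(
    c("genus", "family", "order", "class", "phylum"), names(eg))) {
  stopifnot(inherits(eg, "eg_map"))
  missing_ranks <- setdiff(ranks, names(eg))
  if (length(missing_ranks) > 0) {
    stop("rank column(s) absent from map: ", paste(missing_ranks, collapse = ", "))
  }
  assigned <- eg[eg$group != "UNASSIGNED", , drop = FALSE]
  out <- lapply(ranks, function(r) {
    if (nrow(assigned) == 0) {
      return(data.frame(rank = character(), n_groups = integer(),
                        n_taxa = integer()))
    }
    spread <- tapply(as.character(assigned$group), assigned[[r]],
                     function(g) length(unique(g)))
    tab <- table(factor(spread, levels = 1:5))
    data.frame(rank = r, n_groups = 1:5, n_taxa = as.integer(tab))
  })
  do.call(rbind, out)
}
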
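#' Rank species by occurrence frequency
#'
#' Occurrence frequency is the number of stations where a species is
#' present (count >= 1). Ranking is by descending frequency with ties
#' broken by species name ascending, so ranks are deterministic.
#'
#' @param mat stations x species count matrix (see
#'   \code{\link{as_station_matrix}}).
#' @return data.frame with columns \code{species}, \code{occurrences},
#'   \code{relative_frequency} (occurrences / n stations) and
#'   \code{rank} (1 = most frequent), sorted by rank.
#' @export
species_frequency_ranking <- function(mat) {
  mat <- as_station_matrix(mat)
  if (all(rowSums(mat) == 0)) stop("all stations are azoic")
  occ <- colSums(mat > 0)
  ord <- order(-occ, colnames(mat))
  data.frame(
    species = colnames(mat)[ord],
    occurrences = as.integer(occ[ord]),
    relative_frequency = as.numeric(occ[ord]) / nrow(mat),
    rank = seq_along(ord),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Most frequent species for a given fraction
#'
#' @param mat stations x species count matrix.
#' @param fraction fraction x of the species pool to keep, in (0, 1];
#'   subset size is \code{round(x * S)}, at least 1.
#' @return character vector of the top-ranked species names.
#' @export
top_frequent_species <- function(mat, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  rk <- species_frequency_ranking(mat)
  k <- max(1L, round(fraction * nrow(rk)))
  rk$species[seq_len(k)]
}

#' Restrict a station matrix to a species subset
#'
#' Drops all species outside \code{keep}. Stations that lose all their
#' individuals under the restriction are flagged as newly azoic (they
#' are retained in the matrix; downstream agreement excludes them
#' pairwise).
#'
#' @param mat stations x species count matrix.
#' @param keep character vector of species names to retain (normalized
#'   internally).
#' @return restricted matrix with attribute \code{newly_azoic}
#'   (character vector of station ids that had individuals before but
#'   none after).
#' @export
restrict_samples <- function(mat, keep) {
  mat <- as_station_matrix(mat)
  if (length(keep) == 0) stop("empty species subset")
  keep <- normalize_species(keep)
  cols <- intersect(colnames(mat), keep)
  if (length(cols) == 0) stop("species subset is disjoint from the matrix species")
  out <- mat[, cols, drop = FALSE]
  newly <- rownames(mat)[rowSums(mat) > 0 & rowSums(out) == 0]
  attr(out, "newly_azoic") <- newly
  out
}

#' Agreement between full-set and subset p/a AMBI classifications
#'
#' Classification A is the p/a AMBI quality class of each station using
#' all species; classification B uses only the species in \code{keep}.
#' Azoic stations, stations emptied by the restriction and stations
#' whose restricted sample is entirely unassigned are excluded pairwise.
#'
#' @param mat stations x species count matrix.
#' @param eg an \code{\link{eg_map}}.
#' @param keep species subset (character vector).
#' @param mode index mode for both classifications (default
#'   \code{"presence"}, the p/a AMBI).
#' @return a \code{\link{cohens_kappa}} result with extra fields
#'   \code{n_excluded} (stations dropped pairwise) and
#'   \code{confusion} (the \code{\link{confusion_matrix}}).
#' @export
subset_agreement <- function(mat, eg, keep, mode = "presence") {
  mat <- as_station_matrix(mat)
  full <- ambi(mat, eg, mode = mode, warn_unmatched = FALSE)
  sub <- ambi(restrict_samples(mat, keep), eg, mode = mode,
              warn_unmatched = FALSE)
  usable <- !full$azoic & !sub$azoic &
    !is.na(full$quality_class) & !is.na(sub$quality_class)
  if (sum(usable) < 1) stop("no comparable station after exclusions")
  cm <- confusion_matrix(full$quality_class[usable], sub$quality_class[usable])
  res <- cohens_kappa(cm)
  res$n_excluded <- as.integer(sum(!usable))
  res$confusion <- cm
  res
}

#' Null distribution of kappa under random species subsets
#'
#' Draws \code{n_replicates} random subsets of \code{round(x * S)}
#' species without replacement from the species observed in the matrix,
#' computes the p/a AMBI agreement of each against the full species
#' set, and returns the vector of kappas. Replicates where agreement is
#' not computable (e.g. the subset empties every station) are recorded
#' as \code{NA}, never silently dropped.
#'
#' Reproducibility: the top-level \code{seed} deterministically derives
#' one sub-seed per replicate (via \code{sample.int} under the
#' top-level seed), so replicate i can be re-run in isolation with its
#' own sub-seed.
#'
#' @param mat stations x species count matrix.
#' @param eg an \code{\link{eg_map}}.
#' @param fraction subset fraction x in (0, 1].
#' @param n_replicates number of random subsets (default 100).
#' @param seed integer seed.
#' @param mode index mode (default \code{"presence"}).
#' @return numeric vector of null kappas (length \code{n_replicates},
#'   possibly with NAs), with attribute \code{subset_size}.
#' @export
random_subset_null <- function(mat, eg, fraction, n_replicates = 100,
                               seed = 1, mode = "presence") {
  if (n_replicates < 2) stop("need at least 2 replicates")
  stopifnot(fraction > 0, fraction <= 1)
  mat <- as_station_matrix(mat)
  species <- colnames(mat)
  k <- max(1L, round(fraction * length(species)))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_replicates)
  kappas <- vapply(seq_len(n_replicates), function(i) {
    set.seed(sub_seeds[i])
    keep <- sample(species, k)
    tryCatch(subset_agreement(mat, eg, keep, mode = mode)$kappa,
             error = function(e) NA_real_)
  }, numeric(1))
  attr(kappas, "subset_size") <- k
  kappas
}

#' P-value of an observed kappa against a resampling null
#'
#' The primary p-value is parametric: the upper-tail probability of the
#' observed kappa under a normal distribution fitted to the null kappas
#' (mean, sd with n-1 denominator). This is the only construction that
#' can produce p-values far below the 1/replicates floor of an
#' empirical count, as seen with 100-replicate nulls. The empirical
#' companion is (1 + #(null >= observed)) / (n + 1).
#'
#' @param observed observed kappa.
#' @param null vector of null kappas (NAs ignored, counted as missing).
#' @return list with \code{p_parametric}, \code{p_empirical},
#'   \code{null_mean}, \code{null_sd}, \code{n_null}, \code{n_missing}
#'   and \code{degenerate} (TRUE when the null has zero spread).
#' @export
subset_pvalue <- function(observed, null) {
  missing <- sum(is.na(null))
  null <- null[!is.na(null)]
  if (length(null) < 2) stop("need at least 2 non-missing null values")
  m <- mean(null)
  s <- stats::sd(null)
  degenerate <- s == 0
  p_par <- if (degenerate) {
    if (observed > m) 0 else if (observed < m) 1 else 0.5
  } else {
    stats::pnorm(observed, mean = m, sd = s, lower.tail = FALSE)
  }
  p_emp <- (1 + sum(null >= observed)) / (length(null) + 1)
  list(p_parametric = p_par, p_empirical = p_emp,
       null_mean = m, null_sd = s,
       n_null = length(null), n_missing = missing,
       degenerate = degenerate)
}

#' Full subset-agreement report for frequent-species fractions
#'
#' For each fraction x, computes the observed kappa between the full
#' p/a AMBI classification and the one restricted to the x most
#' frequent species, the 100-replicate (configurable) random-subset
#' null, and both p-values.
#'
#' @param mat stations x species count matrix.
#' @param eg an \code{\link{eg_map}}.
#' @param fractions numeric vector of fractions (default 0.10, 0.25,
#'   0.50).
#' @param n_replicates null replicates per fraction (default 100).
#' @param seed integer seed.
#' @return data.frame with one row per fraction: observed kappa and
#'   interpretation, null mean/sd, parametric and empirical p-values;
#'   the null vectors are attached as attribute \code{nulls} (a named
#'   list).
#' @export
frequent_subset_report <- function(mat, eg, fractions = c(0.10, 0.25, 0.50),
                                   n_replicates = 100, seed = 1) {
  mat <- as_station_matrix(mat)
  nulls <- list()
  rows <- lapply(seq_along(fractions), function(i) {
    x <- fractions[i]
    keep <- top_frequent_species(mat, x)
    obs <- subset_agreement(mat, eg, keep)
    null <- random_subset_null(mat, eg, x, n_replicates = n_replicates,
                               seed = seed + i - 1L)
    pv <- subset_pvalue(obs$kappa, null)
    nulls[[as.character(x)]] <<- null
    data.frame(fraction = x, subset_size = attr(null, "subset_size"),
               kappa = obs$kappa, interpretation = obs$interpretation,
               null_mean = pv$null_mean, null_sd = pv$null_sd,
               p_parametric = pv$p_parametric, p_empirical = pv$p_empirical,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "nulls") <- nulls
  out
}

#' Ecological-group distribution of a species subset
#'
#' Proportion of each ecological group within a species subset,
#' optionally weighted by station-occurrence frequency (the default,
#' matching how sequenced-species pools are compared against the full
#' list). Unassigned species are dropped.
#'
#' @param species character vector of species names.
#' @param eg an \code{\link{eg_map}}.
#' @param weights optional numeric occurrence weights aligned with
#'   \code{species}; NULL for the unweighted variant.
#' @return named numeric vector of 5 proportions (I..V) summing to 1.
#' @export
eg_distribution <- function(species, eg, weights = NULL) {
  if (length(species) == 0) stop("empty species subset")
  if (is.null(weights)) weights <- rep(1, length(species))
  stopifnot(length(weights) == length(species), all(weights >= 0))
  grp <- eg_lookup(species, eg, warn = FALSE)
  assigned <- grp != "UNASSIGNED"
  if (!any(assigned)) stop("all species in the subset are unassigned")
  tot <- tapply(weights[assigned],
                factor(as.character(grp[assigned]), levels = names(eg_weights())),
                sum)
  tot[is.na(tot)] <- 0
  p <- as.numeric(tot) / sum(tot)
  names(p) <- names(eg_weights())
  p
}
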
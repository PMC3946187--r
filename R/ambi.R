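#' Pollution quality class labels
#'
#' Ordered categorical pollution levels obtained by binning the index
#' value.
#'
#' @return character vector of the five class labels, benign to degraded.
#' @export
quality_classes <- function() {
  c("unpolluted", "slightly polluted", "moderately polluted",
    "heavily polluted", "extremely polluted")
}

#' Classify an index value into a pollution quality class
#'
#' Binning is continuous and half-open on the unrounded value:
#' value <= 1.2 unpolluted, <= 3.3 slightly polluted, <= 5 moderately
#' polluted, <= 6 heavily polluted, > 6 extremely polluted. The
#' published thresholds show gaps (1.2 then 1.3) only because index
#' values are conventionally reported to one decimal; classification
#' here uses the full-precision value.
#'
#' @param value numeric vector of index values in [0, 7].
#' @return factor over \code{\link{quality_classes}}.
#' @export
classify_pollution <- function(value) {
  if (any(is.na(value)) || any(value < 0 | value > 7)) {
    stop("index value outside [0, 7]")
  }
  cut(value, breaks = c(0, 1.2, 3.3, 5, 6, 7),
      labels = quality_classes(),
      include.lowest = TRUE, right = TRUE)
}

#' Ecological-group percentages of a station sample
#'
#' Percentages of individuals (abundance mode) or of species present
#' (presence mode) falling in each ecological group GI..GV. Species
#' without an assigned group are excluded from both numerator and
#' denominator; the excluded fraction is reported as an attribute.
#'
#' @param sample named numeric vector of non-negative counts (names are
#'   species).
#' @param eg an \code{\link{eg_map}}.
#' @param mode \code{"abundance"} or \code{"presence"}.
#' @param warn_unmatched warn about species missing from the map.
#' @return numeric vector of length 5 (named I..V) summing to 100, with
#'   attributes \code{unassigned_fraction} (fraction of individuals or
#'   species excluded) and \code{n_taxa_used}.
#' @export
group_percentages <- function(sample, eg, mode = c("abundance", "presence"),
                              warn_unmatched = TRUE) {
  mode <- match.arg(mode)
  if (is.null(names(sample)) || any(sample < 0) ||
      any(sample != floor(sample))) {
    stop("sample must be a named vector of non-negative integer counts")
  }
  present <- sample[sample > 0]
  if (length(present) == 0) {
    stop("azoic sample: no individuals; use compute_index() for the azoic convention")
  }
  grp <- eg_lookup(names(present), eg, warn = warn_unmatched)
  w <- if (mode == "abundance") as.numeric(present) else rep(1, length(present))
  assigned <- grp != "UNASSIGNED"
  if (!any(assigned)) {
    stop("index not computable: no species in the sample has an assigned ecological group")
  }
  tot <- sum(w)
  totals <- tapply(w[assigned], factor(as.character(grp[assigned]),
                                       levels = names(eg_weights())), sum)
  totals[is.na(totals)] <- 0
  pct <- 100 * totals / sum(totals)
  attr(pct, "unassigned_fraction") <- sum(w[!assigned]) / tot
  attr(pct, "n_taxa_used") <- sum(assigned)
  pct
}

#' Compute the AMBI or p/a AMBI for one station sample
#'
#' The index is the weighted mean of the ecological-group percentages,
#' value = (0 pGI + 1.5 pGII + 3 pGIII + 4.5 pGIV + 6 pGV) / 100,
#' giving a value in [0, 6] for non-azoic samples. An azoic sample
#' (zero individuals) is assigned the conventional maximum of 7,
#' "extremely polluted", with its \code{azoic} flag set.
#'
#' @inheritParams group_percentages
#' @param unassigned_warn_at warn when the excluded (unassigned)
#'   fraction exceeds this value (default 0.2); reliability guardrail.
#' @return object of class \code{"ambi_result"}: a list with
#'   \code{value}, \code{mode}, \code{percentages}, \code{quality_class},
#'   \code{azoic}, \code{unassigned_fraction} and \code{n_taxa_used}.
#' @export
compute_index <- function(sample, eg, mode = c("abundance", "presence"),
                          warn_unmatched = TRUE, unassigned_warn_at = 0.2) {
  mode <- match.arg(mode)
  if (sum(sample) == 0) {
    res <- list(value = 7, mode = mode, percentages = NULL,
                quality_class = factor("extremely polluted",
                                       levels = quality_classes()),
                azoic = TRUE, unassigned_fraction = NA_real_,
                n_taxa_used = 0L)
    class(res) <- "ambi_result"
    return(res)
  }
  pct <- group_percentages(sample, eg, mode, warn_unmatched = warn_unmatched)
  uf <- attr(pct, "unassigned_fraction")
  nt <- attr(pct, "n_taxa_used")
  if (uf > unassigned_warn_at) {
    warning(sprintf("%.0f%% of the sample is unassigned; index reliability reduced",
                    100 * uf))
  }
  if (nt <= 3) {
    warning("3 or fewer assigned taxa; index may be unreliable at very low richness")
  }
  value <- sum(eg_weights() * as.numeric(pct)) / 100
  res <- list(value = value, mode = mode, percentages = as.numeric(pct),
              quality_class = classify_pollution(value),
              azoic = FALSE, unassigned_fraction = uf, n_taxa_used = nt)
  class(res) <- "ambi_result"
  res
}

#' @export
print.ambi_result <- function(x, ...) {
  cat(sprintf("%s AMBI = %.1f (%s)%s\n",
              if (x$mode == "presence") "p/a" else "",
              x$value, as.character(x$quality_class),
              if (x$azoic) " [azoic]" else ""))
  invisible(x)
}

#' Compute the index for every station of an abundance matrix
#'
#' Vectorized station-wise AMBI / p/a AMBI. Internally uses a single
#' matrix product over a group indicator matrix, so it scales to
#' thousands of stations; results match \code{\link{compute_index}}
#' applied row by row.
#'
#' @param mat stations x species matrix of non-negative integer counts
#'   with station ids as rownames and species as colnames.
#' @param eg an \code{\link{eg_map}}.
#' @param mode \code{"abundance"} or \code{"presence"}.
#' @param warn_unmatched warn once about species absent from the map.
#' @return data.frame with one row per station: \code{station_id},
#'   \code{mode}, \code{value}, \code{quality_class}, \code{azoic},
#'   \code{unassigned_fraction}, \code{n_taxa_used}. Stations whose
#'   present species are all unassigned get \code{NA} value and class.
#' @export
ambi <- function(mat, eg, mode = c("abundance", "presence"),
                 warn_unmatched = TRUE) {
  mode <- match.arg(mode)
  mat <- as_station_matrix(mat)
  grp <- eg_lookup(colnames(mat), eg, warn = warn_unmatched)
  w <- if (mode == "presence") (mat > 0) + 0 else mat
  # one-hot species x group indicator; UNASSIGNED dropped
  gi <- outer(as.character(grp), names(eg_weights()), "==") + 0
  totals <- w %*% gi                       # stations x 5
  assigned_tot <- rowSums(totals)
  all_tot <- rowSums(w)
  azoic <- all_tot == 0
  value <- as.numeric(totals %*% eg_weights()) / assigned_tot
  value[azoic] <- 7
  value[!azoic & assigned_tot == 0] <- NA
  qc <- factor(rep(NA_character_, nrow(mat)), levels = quality_classes())
  ok <- !is.na(value)
  qc[ok] <- classify_pollution(value[ok])
  pres <- (mat > 0) %*% (as.character(grp) != "UNASSIGNED")
  data.frame(
    station_id = rownames(mat),
    mode = mode,
    value = value,
    quality_class = qc,
    azoic = azoic,
    unassigned_fraction = ifelse(azoic, NA, 1 - assigned_tot / all_tot),
    n_taxa_used = as.integer(pres),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Coerce to a station-by-species count matrix
#'
#' @param x matrix or data.frame of non-negative integer counts; rows
#'   stations, columns species. Species names are normalized.
#' @return numeric matrix with rownames (station ids) and normalized
#'   colnames.
#' @export
as_station_matrix <- function(x) {
  m <- as.matrix(x)
  if (is.null(colnames(m))) stop("station matrix must have species column names")
  if (is.null(rownames(m))) rownames(m) <- paste0("st", seq_len(nrow(m)))
  storage.mode(m) <- "numeric"
  if (anyNA(m)) stop("station matrix contains missing cells")
  if (any(m < 0) || any(m != floor(m))) {
    bad <- which(m < 0 | m != floor(m), arr.ind = TRUE)[1, ]
    stop(sprintf("invalid count at station '%s', species '%s': cells must be non-negative integers",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  colnames(m) <- normalize_species(colnames(m))
  if (anyDuplicated(colnames(m))) stop("duplicate species columns after name normalization")
  m
}
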
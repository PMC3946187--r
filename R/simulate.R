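# Synthetic inputs with the statistical structure of coastal benthic
# monitoring data: an ecological-group species list dominated by a few
# phyla, communities whose group composition turns over along a
# pollution gradient, long-tailed species occurrence frequencies, and a
# partial barcode library.

#' Logistic ecological-group response curves
#'
#' Occupancy multiplier p_g(pressure) = plogis(a_g + b_g * pressure)
#' for each group: GI decreases steeply with pressure (sensitive
#' species), GII decreases mildly (indifferent), GIII is flat
#' (tolerant), GIV increases (second-order opportunists) and GV
#' increases steeply (first-order opportunists). With the defaults the
#' group ordering p_V >= p_IV >= p_III >= p_II >= p_I holds at
#' pressure 1 and reverses at pressure 0.
#'
#' @param intercepts,slopes numeric length-5 vectors (GI..GV) of
#'   logistic parameters.
#' @return function(group, pressure) -> occupancy probability in [0,1].
#' @export
eg_response_curves <- function(intercepts = c(1.5, 0.5, 0, -1.5, -4),
                               slopes = c(-4, -1.5, 0, 2.5, 6)) {
  stopifnot(length(intercepts) == 5, length(slopes) == 5)
  a <- stats::setNames(intercepts, names(eg_weights()))
  b <- stats::setNames(slopes, names(eg_weights()))
  function(group, pressure) {
    g <- as.character(group)
    p <- stats::plogis(a[g] + b[g] * pressure)
    p[g == "UNASSIGNED"] <- 0.5   # unassigned taxa: no gradient response
    unname(p)
  }
}

#' Generate a synthetic species-to-ecological-group list
#'
#' Stand-in for a curated biotic-index species list: species spread
#' over a few dominant phyla (defaults follow the typical soft-bottom
#' macroinvertebrate breakdown, ~90% in Annelida, Mollusca, Arthropoda,
#' Echinodermata and Cnidaria) with a multinomial ecological-group
#' assignment and a small unassigned fraction. A nested synthetic
#' taxonomy (genus/family/order/class) is attached so rank-level
#' heterogeneity analyses run on generated data.
#'
#' @param n_species number of species.
#' @param eg_proportions length-5 probability vector for GI..GV among
#'   assigned species (default uneven, tolerant group largest).
#' @param unassigned_fraction fraction of species with no group
#'   (default 0.05).
#' @param phylum_proportions named probability vector over phyla.
#' @param seed integer seed.
#' @return an \code{\link{eg_map}} with taxonomy columns.
#' @export
generate_eg_map <- function(n_species,
                            eg_proportions = c(0.20, 0.25, 0.30, 0.15, 0.10),
                            unassigned_fraction = 0.05,
                            phylum_proportions = c(
                              Annelida = 0.36, Mollusca = 0.25,
                              Arthropoda = 0.24, Echinodermata = 0.03,
                              Cnidaria = 0.02, Other = 0.10),
                            seed = 1) {
  stopifnot(n_species >= 1, length(eg_proportions) == 5,
            all(eg_proportions >= 0))
  if (sum(eg_proportions) == 0) stop("all ecological-group proportions are zero")
  eg_proportions <- eg_proportions / sum(eg_proportions)
  set.seed(seed)
  grp <- sample(names(eg_weights()), n_species, replace = TRUE,
                prob = eg_proportions)
  grp[stats::runif(n_species) < unassigned_fraction] <- "UNASSIGNED"
  phyl <- sample(names(phylum_proportions), n_species, replace = TRUE,
                 prob = phylum_proportions)
  # nested taxonomy: ~3 species per genus, ~3 genera per family, ...
  genus <- sprintf("genus_%04d", ceiling(seq_len(n_species) / 3))
  family <- sprintf("family_%04d", ceiling(seq_len(n_species) / 9))
  ord <- sprintf("order_%04d", ceiling(seq_len(n_species) / 27))
  klass <- sprintf("class_%04d", ceiling(seq_len(n_species) / 81))
  eg_map(
    species = sprintf("species_%05d", seq_len(n_species)),
    group = grp, phylum = phyl,
    taxonomy = data.frame(genus = genus, family = family, order = ord,
                          class = klass, stringsAsFactors = FALSE)
  )
}

#' Simulate station communities along a pollution gradient
#'
#' Occupancy and abundance are generated independently: species s is
#' present at a station with probability base_freq_s * p_g(s)(pressure),
#' where base_freq_s is a long-tailed (log-normal, capped at 1) baseline
#' occurrence frequency and p_g the group response curve; present
#' species receive a shifted-geometric abundance with the requested
#' mean. Stations where no species draws present come out azoic, with
#' no special forcing.
#'
#' @param eg an \code{\link{eg_map}}.
#' @param n_stations number of stations.
#' @param pressure per-station pressure in [0, 1]; default an even ramp
#'   over the gradient.
#' @param frequency_shape log-normal sdlog of the baseline occurrence
#'   frequency (default 1.5; larger = longer tail of rare species).
#' @param frequency_scale median baseline occurrence frequency
#'   (default 0.10).
#' @param abundance_scale mean individuals per present species
#'   (default 20).
#' @param curves response curves from \code{\link{eg_response_curves}}.
#' @param seed integer seed.
#' @return list with \code{matrix} (stations x species counts),
#'   \code{pressure} (named numeric) and \code{base_frequency}.
#' @export
generate_gradient_communities <- function(eg, n_stations = 200,
                                          pressure = NULL,
                                          frequency_shape = 1.5,
                                          frequency_scale = 0.10,
                                          abundance_scale = 20,
                                          curves = eg_response_curves(),
                                          seed = 1) {
  stopifnot(inherits(eg, "eg_map"), n_stations >= 1)
  if (is.null(pressure)) {
    pressure <- seq(0, 1, length.out = n_stations)
  }
  stopifnot(length(pressure) == n_stations, all(pressure >= 0 & pressure <= 1))
  set.seed(seed)
  S <- nrow(eg)
  base <- pmin(1, stats::rlnorm(S, meanlog = log(frequency_scale),
                                sdlog = frequency_shape))
  occ_prob <- outer(seq_len(n_stations), seq_len(S), function(i, j) {
    base[j] * curves(eg$group[j], pressure[i])
  })
  present <- matrix(stats::rbinom(length(occ_prob), 1, occ_prob),
                    nrow = n_stations)
  counts <- present * (1L + stats::rgeom(length(present),
                                         prob = 1 / abundance_scale))
  dimnames(counts) <- list(sprintf("station_%03d", seq_len(n_stations)),
                           eg$species)
  names(pressure) <- rownames(counts)
  list(matrix = counts, pressure = pressure, base_frequency = base)
}

#' Draw one concrete sequence from a degenerate IUPAC string
#'
#' Each ambiguous position is resolved by sampling uniformly from its
#' expansion set (uses the current RNG state).
#'
#' @param x IUPAC string.
#' @return plain ACGT string.
#' @export
realize_iupac <- function(x) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  validate_iupac(x, "primer")
  chars <- strsplit(toupper(x), "")[[1]]
  paste(vapply(chars, function(ch) {
    s <- sets[[ch]]
    if (length(s) == 1) s else sample(s, 1)
  }, character(1)), collapse = "")
}

# random ACGT string
.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute bases at a per-site rate (always to a different base)
.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a partial barcode reference library
#'
#' Selects a covered subset of the species list (uniformly, biased
#' toward frequent species, or skewed toward tolerant GIII species) and
#' emits per-species sequences derived from a common marker reference
#' by per-site substitution, so primer annealing sites are present at
#' known positions. When a primer pair is supplied, one concrete
#' realization of each primer is planted near the reference ends
#' (forward at offset 10, reverse-complement site ending 10 bases from
#' the 3' end). A fraction of records can be truncated to emulate
#' partial database entries.
#'
#' @param eg an \code{\link{eg_map}}.
#' @param coverage_fraction fraction of listed species with sequences
#'   (default 0.15, the typical state of benthic barcode libraries).
#' @param bias \code{"none"} (uniform), \code{"frequent"}
#'   (selection probability proportional to occurrence frequency) or
#'   \code{"eg-skewed"} (GIII species four times as likely).
#' @param frequencies named occurrence counts per species (required for
#'   \code{bias = "frequent"}).
#' @param marker marker label stored on the records.
#' @param pair optional \code{\link{primer_pair}} whose sites are
#'   planted on the reference.
#' @param seq_length reference length (default 658, the classic COI
#'   barcode fragment).
#' @param mutation_rate per-site substitution rate between the
#'   reference and each species sequence (default 0.02).
#' @param max_seqs_per_species records per covered species are drawn
#'   uniformly from 1..this (default 2).
#' @param truncation_prob probability that a record is 5'- or
#'   3'-truncated by up to 40% of its length (default 0).
#' @param seed integer seed.
#' @return list: \code{records} (data.frame id, species, phylum, seq),
#'   \code{covered} (character vector, the truth mask),
#'   \code{reference} (the reference sequence string).
#' @export
generate_barcode_library <- function(eg, coverage_fraction = 0.15,
                                     bias = c("none", "frequent", "eg-skewed"),
                                     frequencies = NULL,
                                     marker = "CO1", pair = NULL,
                                     seq_length = 658,
                                     mutation_rate = 0.02,
                                     max_seqs_per_species = 2,
                                     truncation_prob = 0,
                                     seed = 1) {
  bias <- match.arg(bias)
  stopifnot(inherits(eg, "eg_map"),
            coverage_fraction >= 0, coverage_fraction <= 1)
  set.seed(seed)
  S <- nrow(eg)
  n_cov <- round(coverage_fraction * S)
  w <- switch(bias,
    none = rep(1, S),
    frequent = {
      if (is.null(frequencies)) stop("bias = 'frequent' needs occurrence frequencies")
      f <- frequencies[eg$species]
      f[is.na(f)] <- 0
      as.numeric(f) + 1e-6
    },
    `eg-skewed` = ifelse(eg$group == "III", 4, 1)
  )
  covered <- if (n_cov == 0) character(0) else {
    eg$species[sample.int(S, n_cov, prob = w)]
  }
  reference <- .random_seq(seq_length)
  if (!is.null(pair)) {
    fwd <- realize_iupac(pair$forward)
    rev_site <- revcomp(realize_iupac(pair$reverse))
    if (seq_length < nchar(fwd) + nchar(rev_site) + 40) {
      stop("reference too short to plant both primer sites")
    }
    substr(reference, 11, 10 + nchar(fwd)) <- fwd
    r_at <- seq_length - 10 - nchar(rev_site) + 1
    substr(reference, r_at, r_at + nchar(rev_site) - 1) <- rev_site
  }
  recs <- list()
  for (sp in covered) {
    n_rec <- sample.int(max_seqs_per_species, 1)
    for (j in seq_len(n_rec)) {
      s <- .mutate_seq(reference, mutation_rate)
      if (truncation_prob > 0 && stats::runif(1) < truncation_prob) {
        cut <- sample.int(floor(0.4 * nchar(s)), 1)
        s <- if (stats::runif(1) < 0.5) substr(s, cut + 1, nchar(s))
             else substr(s, 1, nchar(s) - cut)
      }
      recs[[length(recs) + 1]] <- data.frame(
        id = sprintf("%s_%s_%d", marker, sp, j),
        species = sp,
        phylum = eg$phylum[match(sp, eg$species)],
        seq = s, stringsAsFactors = FALSE)
    }
  }
  records <- if (length(recs) == 0) {
    data.frame(id = character(), species = character(),
               phylum = character(), seq = character(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, recs)
  list(records = records, covered = covered, reference = reference)
}

#' Example degenerate COI primer pairs
#'
#' A few published wide-range primer pairs for the ~658 bp COI barcode
#' fragment (Folmer region): the classic LCO1490/HCO2198 pair, its
#' degenerate variant, and a shorter-amplicon internal forward primer
#' combined with each reverse.
#'
#' @return list of \code{\link{primer_pair}} objects.
#' @export
example_primer_pairs <- function() {
  list(
    primer_pair("LCO1490xHCO2198",
                "GGTCAACAAATCATAAAGATATTGG",
                "TAAACTTCAGGGTGACCAAAAAATCA", marker = "CO1"),
    primer_pair("dgLCO1490xdgHCO2198",
                "GGTCAACAAATCATAAAGAYATYGG",
                "TAAACTTCAGGGTGACCAAARAAYCA", marker = "CO1"),
    primer_pair("mlCOIintFxHCO2198",
                "GGWACWGGWTGAACWGTWTAYCCYCC",
                "TAAACTTCAGGGTGACCAAAAAATCA", marker = "CO1"),
    primer_pair("mlCOIintFxdgHCO2198",
                "GGWACWGGWTGAACWGTWTAYCCYCC",
                "TAAACTTCAGGGTGACCAAARAAYCA", marker = "CO1")
  )
}
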
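#' Primer scoring configuration
#'
#' Position-weighted mismatch penalties for primer-template binding.
#' Mismatches near the 3' end compromise polymerase extension far more
#' than 5' mismatches, so the last base carries the heaviest penalty,
#' the remaining bases of the 3'-terminal window an intermediate one,
#' and all other positions a light one. A site is callable (can prime)
#' when its total score does not exceed \code{amplify_threshold}.
#'
#' @param penalty_non3_mismatch penalty per mismatch outside the 3'
#'   window (default 0.4).
#' @param penalty_3prime_mismatch penalty per mismatch inside the 3'
#'   window, excluding the terminal base (default 1.0).
#' @param penalty_final_base_mismatch penalty for a 3'-terminal
#'   mismatch (default 3.0).
#' @param three_prime_window length of the 3' window in bases,
#'   terminal base included (default 5).
#' @param amplify_threshold maximal score at which a site still primes
#'   (default 1.0).
#' @return list of class \code{"primer_scoring_config"}.
#' @export
primer_scoring_config <- function(penalty_non3_mismatch = 0.4,
                                  penalty_3prime_mismatch = 1.0,
                                  penalty_final_base_mismatch = 3.0,
                                  three_prime_window = 5L,
                                  amplify_threshold = 1.0) {
  cfg <- list(penalty_non3_mismatch = penalty_non3_mismatch,
              penalty_3prime_mismatch = penalty_3prime_mismatch,
              penalty_final_base_mismatch = penalty_final_base_mismatch,
              three_prime_window = as.integer(three_prime_window),
              amplify_threshold = amplify_threshold)
  if (any(unlist(cfg[1:3]) < 0)) stop("penalties must be non-negative")
  class(cfg) <- "primer_scoring_config"
  cfg
}

#' Define a primer pair
#'
#' Both primers are written 5' to 3'. The reverse primer anneals to the
#' plus strand as its reverse complement; that complement is computed
#' once here and all downstream matching happens on the template's
#' forward strand.
#'
#' @param name pair label.
#' @param forward,reverse IUPAC primer strings (5'->3'), length >= 10.
#' @param marker optional marker label (\code{"CO1"}, \code{"18S"}, ...).
#' @return list of class \code{"primer_pair"} with fields \code{name},
#'   \code{forward}, \code{reverse}, \code{reverse_rc}, \code{marker}
#'   and (once located) \code{ref_start}/\code{ref_end} (0-based
#'   half-open coordinates on the reference).
#' @export
primer_pair <- function(name, forward, reverse, marker = NA_character_) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  validate_iupac(c(forward, reverse), "primer")
  if (nchar(forward) < 10 || nchar(reverse) < 10) {
    stop("primers must be at least 10 bases long")
  }
  p <- list(name = name, forward = forward, reverse = reverse,
            reverse_rc = revcomp(reverse), marker = marker,
            ref_start = NA_integer_, ref_end = NA_integer_)
  class(p) <- "primer_pair"
  p
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("Primer pair %s [%s]: %s / %s", x$name,
              ifelse(is.na(x$marker), "?", x$marker), x$forward, x$reverse))
  if (!is.na(x$ref_start)) {
    cat(sprintf("  reference span [%d, %d)", x$ref_start, x$ref_end))
  }
  cat("\n")
  invisible(x)
}

# per-position penalty vector for a primer of length k (position k is 3')
.position_penalties <- function(k, config) {
  pen <- rep(config$penalty_non3_mismatch, k)
  win <- min(config$three_prime_window, k)
  if (win > 1) {
    pen[(k - win + 1):(k - 1)] <- config$penalty_3prime_mismatch
  }
  pen[k] <- config$penalty_final_base_mismatch
  pen
}

#' Score a primer against an equal-length template window
#'
#' A primer base matches a template base iff their IUPAC expansion sets
#' intersect (so template ambiguity codes are called liberally). The
#' score is the sum of position-dependent mismatch penalties; 0 is a
#' perfect match.
#'
#' @param primer IUPAC primer string (5'->3', plus-strand orientation).
#' @param site template window of the same length.
#' @param config a \code{\link{primer_scoring_config}}.
#' @return numeric score >= 0.
#' @export
score_primer_binding <- function(primer, site,
                                 config = primer_scoring_config()) {
  pm <- seq_to_mask(primer)
  sm <- seq_to_mask(site)
  if (anyNA(pm) || anyNA(sm)) stop("non-IUPAC character in primer or site")
  if (length(pm) != length(sm)) stop("site length must equal primer length")
  mism <- bitwAnd(pm, sm) == 0L
  sum(.position_penalties(length(pm), config)[mism])
}

# score every window of the template for one primer (plus strand);
# returns numeric vector of length L - k + 1 (0-length if template too
# short). Vectorized over windows: one pass per primer position.
scan_primer <- function(primer, template_mask,
                        config = primer_scoring_config()) {
  pm <- seq_to_mask(primer)
  k <- length(pm)
  L <- length(template_mask)
  ns <- L - k + 1L
  if (ns < 1L) return(numeric(0))
  pen <- .position_penalties(k, config)
  scores <- numeric(ns)
  for (j in seq_len(k)) {
    mism <- bitwAnd(pm[j], template_mask[j:(j + ns - 1L)]) == 0L
    scores <- scores + pen[j] * mism
  }
  scores
}

#' Locate a primer pair on a reference sequence
#'
#' Scans the reference for the minimal-score annealing window of the
#' forward primer and of the reverse-complemented reverse primer, and
#' records the outermost coordinates spanning both sites (0-based,
#' half-open). These coordinates define the region a library sequence
#' must cover to be testable for the pair.
#'
#' @param reference reference sequence (character string) or a record
#'   data.frame row with a \code{seq} column.
#' @param pair a \code{\link{primer_pair}}.
#' @param config a \code{\link{primer_scoring_config}}.
#' @return the pair with \code{ref_start} and \code{ref_end} filled in.
#' @export
locate_primer_region <- function(reference, pair,
                                 config = primer_scoring_config()) {
  seq <- if (is.character(reference)) reference else reference$seq
  validate_iupac(seq, "reference")
  tm <- seq_to_mask(seq)
  fs <- scan_primer(pair$forward, tm, config)
  rs <- scan_primer(pair$reverse_rc, tm, config)
  if (length(fs) == 0 || length(rs) == 0) {
    stop("reference shorter than a primer")
  }
  if (min(fs) > config$amplify_threshold ||
      min(rs) > config$amplify_threshold) {
    stop(sprintf("primer pair '%s' not locatable on reference (best scores %.2f / %.2f)",
                 pair$name, min(fs), min(rs)))
  }
  f_start <- which(fs == min(fs))[1]                    # leftmost best forward
  r_cand <- which(rs == min(rs))
  r_start <- r_cand[length(r_cand)]                     # rightmost best reverse
  pair$ref_start <- f_start - 1L
  pair$ref_end <- r_start - 1L + nchar(pair$reverse_rc)
  if (pair$ref_start >= pair$ref_end) {
    stop("reverse site does not lie downstream of the forward site on the reference")
  }
  pair
}

# Ungapped seed-and-extend local alignment of a query against a
# reference: exact 11-mer seeds define candidate diagonals; on each
# diagonal the maximal-scoring segment (match +1 / mismatch -1) is
# found exactly; the best segment across diagonals is returned as
# (score, ref_start, ref_end) in 0-based half-open reference
# coordinates, or NULL when no seed matches.
align_to_reference <- function(query, reference, word = 11L) {
  q <- utf8ToInt(toupper(query))
  r <- utf8ToInt(toupper(reference))
  nq <- length(q); nr <- length(r)
  if (nq < word || nr < word) return(NULL)
  r_words <- vapply(seq_len(nr - word + 1L), function(i) {
    intToUtf8(r[i:(i + word - 1L)])
  }, character(1))
  r_index <- split(seq_along(r_words), r_words)
  diags <- integer(0)
  for (i in seq_len(nq - word + 1L)) {
    w <- intToUtf8(q[i:(i + word - 1L)])
    hits <- r_index[[w]]
    if (!is.null(hits)) diags <- c(diags, hits - i)
  }
  if (length(diags) == 0) return(NULL)
  diags <- unique(diags)
  best <- NULL
  for (d in diags) {
    qi <- max(1L, 1L - d):min(nq, nr - d)
    sc <- ifelse(q[qi] == r[qi + d], 1, -1)
    # maximal-scoring contiguous segment (Kadane with position tracking)
    run <- 0; run_start <- 1L
    seg <- -Inf; seg_q <- c(NA_integer_, NA_integer_)
    for (t in seq_along(sc)) {
      if (run <= 0) { run <- sc[t]; run_start <- t } else run <- run + sc[t]
      if (run > seg) { seg <- run; seg_q <- c(run_start, t) }
    }
    if (is.null(best) || seg > best$score) {
      best <- list(score = seg,
                   ref_start = qi[seg_q[1]] + d - 1L,
                   ref_end = qi[seg_q[2]] + d,
                   query_start = qi[seg_q[1]] - 1L,
                   query_end = qi[seg_q[2]])
    }
  }
  best
}

#' Select the sequences testable for a primer pair
#'
#' A record is testable iff its best local alignment to the reference
#' covers the pair's full annealing span \code{[ref_start, ref_end)}.
#' Partial sequences missing a primer site are excluded so that a
#' failed amplification call always reflects primer-template mismatch,
#' never a truncated record (avoiding false negatives).
#'
#' @param records record data.frame (columns \code{id}, \code{seq}, ...).
#' @param pair a located \code{\link{primer_pair}} (with reference
#'   coordinates).
#' @param reference reference sequence string.
#' @param word seed word length for the local alignment (default 11).
#' @return the subset of \code{records} that is testable (possibly
#'   zero rows).
#' @export
testable_sequences <- function(records, pair, reference, word = 11L) {
  if (is.na(pair$ref_start)) {
    stop("primer pair has no reference coordinates; run locate_primer_region() first")
  }
  seq <- if (is.character(reference)) reference else reference$seq
  ok <- vapply(records$seq, function(s) {
    aln <- align_to_reference(s, seq, word = word)
    !is.null(aln) &&
      aln$ref_start <= pair$ref_start && aln$ref_end >= pair$ref_end
  }, logical(1), USE.NAMES = FALSE)
  records[ok, , drop = FALSE]
}

#' Predict amplification of one template by a primer pair
#'
#' Finds the best-scoring forward site and reverse(-complement) site on
#' the template's plus strand. The template amplifies iff both sites
#' score at or below the threshold and the forward site lies upstream
#' of the reverse site; the amplicon spans the outer coordinates of the
#' two sites.
#'
#' @param pair a \code{\link{primer_pair}}.
#' @param template template sequence string (plus strand).
#' @param config a \code{\link{primer_scoring_config}}.
#' @return list: \code{forward_score}, \code{reverse_score},
#'   \code{amplifies}, and when amplifying \code{amplicon_start},
#'   \code{amplicon_end} (0-based half-open) and
#'   \code{amplicon_length}.
#' @export
predict_amplification <- function(pair, template,
                                  config = primer_scoring_config()) {
  validate_iupac(template, "template")
  tm <- seq_to_mask(template)
  fs <- scan_primer(pair$forward, tm, config)
  rs <- scan_primer(pair$reverse_rc, tm, config)
  kf <- nchar(pair$forward); kr <- nchar(pair$reverse_rc)
  neg <- list(forward_score = if (length(fs)) min(fs) else Inf,
              reverse_score = if (length(rs)) min(rs) else Inf,
              amplifies = FALSE, amplicon_start = NA_integer_,
              amplicon_end = NA_integer_, amplicon_length = NA_integer_)
  f_ok <- which(fs <= config$amplify_threshold)
  r_ok <- which(rs <= config$amplify_threshold)
  if (length(f_ok) == 0 || length(r_ok) == 0) return(neg)
  f <- f_ok[1]                                  # leftmost priming forward site
  r <- r_ok[length(r_ok)]                       # rightmost priming reverse site
  if (f + kf - 1L > r - 1L) return(neg)         # reverse must lie downstream
  list(forward_score = fs[f], reverse_score = rs[r], amplifies = TRUE,
       amplicon_start = f - 1L, amplicon_end = r - 1L + kr,
       amplicon_length = (r - 1L + kr) - (f - 1L))
}

#' Amplification calls for a set of records
#'
#' @param pair a \code{\link{primer_pair}}.
#' @param records record data.frame (columns \code{id}, \code{species},
#'   \code{phylum}, \code{seq}).
#' @param config a \code{\link{primer_scoring_config}}.
#' @return data.frame of calls: id, species, phylum, forward_score,
#'   reverse_score, amplifies.
#' @export
amplification_calls <- function(pair, records,
                                config = primer_scoring_config()) {
  calls <- lapply(seq_len(nrow(records)), function(i) {
    a <- predict_amplification(pair, records$seq[i], config)
    data.frame(id = records$id[i], species = records$species[i],
               phylum = records$phylum[i],
               forward_score = a$forward_score,
               reverse_score = a$reverse_score,
               amplifies = a$amplifies, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(calls, list(make.row.names = FALSE)))
}

#' Per-species and per-phylum amplification summary
#'
#' A species is positive when at least one of its tested sequences
#' amplifies. Phyla are summarized as the percentage of positive
#' species among those tested, alongside the number tested; a phylum
#' with no testable species is reported as untested (\code{NA}
#' percentage), not as 0%.
#'
#' @param calls data.frame from \code{\link{amplification_calls}}.
#' @param all_phyla optional character vector of phyla that should
#'   appear in the summary even when none of their species was testable
#'   (reported with \code{n_tested = 0} and \code{NA} percentage).
#' @return list with \code{by_species} (species, phylum, positive,
#'   n_sequences) and \code{by_phylum} (phylum, n_tested,
#'   pct_amplified).
#' @export
species_amplification_summary <- function(calls, all_phyla = NULL) {
  if (nrow(calls) == 0) {
    return(list(
      by_species = data.frame(species = character(), phylum = character(),
                              positive = logical(), n_sequences = integer()),
      by_phylum = data.frame(phylum = as.character(all_phyla),
                             n_tested = rep(0L, length(all_phyla)),
                             pct_amplified = rep(NA_real_, length(all_phyla)))))
  }
  sp <- unique(calls[, c("species", "phylum")])
  sp$positive <- vapply(sp$species, function(s) {
    any(calls$amplifies[calls$species == s])
  }, logical(1), USE.NAMES = FALSE)
  sp$n_sequences <- vapply(sp$species, function(s) {
    sum(calls$species == s)
  }, integer(1), USE.NAMES = FALSE)
  ph <- data.frame(phylum = union(unique(sp$phylum), all_phyla),
                   stringsAsFactors = FALSE)
  ph$n_tested <- vapply(ph$phylum, function(p) sum(sp$phylum == p), 0L)
  ph$pct_amplified <- vapply(ph$phylum, function(p) {
    pos <- sp$positive[sp$phylum == p]
    if (length(pos) == 0) NA_real_ else 100 * mean(pos)
  }, numeric(1))
  rownames(sp) <- NULL
  list(by_species = sp, by_phylum = ph)
}
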
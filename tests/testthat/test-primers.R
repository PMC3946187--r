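cfg <- primer_scoring_config()

test_that("IUPAC machinery: validation, reverse complement, degeneracy", {
  expect_error(validate_iupac("ACGJ"), "offset 4")
  expect_silent(validate_iupac("acgtryswkmbdhvnu"))
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AACCGR"), "YCGGTT")
  expect_equal(degeneracy("ACGT"), 1L)
  expect_equal(degeneracy("ACGN"), 4L)
  expect_equal(degeneracy("RYN"), 16L)
  expect_setequal(expand_iupac("AR"), c("AA", "AG"))
})

test_that("score_primer_binding applies position-weighted penalties", {
  p <- "ACGTACGTACGT"   # length 12; 3' window = last 5, terminal special
  expect_equal(score_primer_binding(p, p, cfg), 0)

  # one mismatch outside the 3' window -> 0.4
  site <- p; substr(site, 1, 1) <- "T"
  expect_equal(score_primer_binding(p, site, cfg), 0.4)

  # one mismatch inside the 3' window (not terminal) -> 1.0
  site <- p; substr(site, 9, 9) <- "C"
  expect_equal(score_primer_binding(p, site, cfg), 1.0)

  # terminal 3' mismatch -> 3.0, fails default threshold 1.0
  site <- p; substr(site, 12, 12) <- "A"
  expect_equal(score_primer_binding(p, site, cfg), 3.0)
  expect_gt(score_primer_binding(p, site, cfg), cfg$amplify_threshold)

  # penalties accumulate; adding a mismatch never decreases the score
  site2 <- p; substr(site2, 1, 1) <- "T"; substr(site2, 2, 2) <- "G"
  expect_equal(score_primer_binding(p, site2, cfg), 0.8)
  expect_gte(score_primer_binding(p, site2, cfg),
             score_primer_binding(p, sub("^T", "A", site2), cfg))

  expect_error(score_primer_binding(p, "ACG", cfg), "length")
})

test_that("degenerate matching equals brute-force expansion", {
  set.seed(11)
  # primers with <= 4 degenerate positions, random templates
  primers <- c("ACGTRYACGTAC", "NACGTACGTAWS", "ACGKACGTMCGT")
  for (pr in primers) {
    expansions <- expand_iupac(pr)
    for (i in 1:20) {
      site <- random_seq(nchar(pr))
      got <- score_primer_binding(pr, site, cfg)
      # oracle: best (minimal) score over all exact expansions
      best <- min(vapply(expansions,
                         function(e) score_primer_binding(e, site, cfg), 0))
      expect_equal(got, best)
    }
  }
})

test_that("locate_primer_region recovers planted annealing sites", {
  set.seed(5)
  fwd <- "GGTCAACAAATCATAAAGATATTGG"
  rev <- "TAAACTTCAGGGTGACCAAAAAATCA"
  pair <- primer_pair("folmer", fwd, rev, marker = "CO1")

  ref <- paste0(random_seq(50), fwd, random_seq(400), revcomp(rev),
                random_seq(30))
  located <- locate_primer_region(ref, pair)
  expect_equal(located$ref_start, 50L)
  expect_equal(located$ref_end, 50L + 25L + 400L + 26L)

  # degenerate primer whose expansion contains the planted site
  dpair <- primer_pair("dg", "GGTCAACAAATCATAAAGAYATYGG", rev)
  expect_equal(locate_primer_region(ref, dpair)$ref_start, 50L)

  # unlocatable on a random reference
  expect_error(locate_primer_region(random_seq(300), pair), "not locatable")
})

test_that("testable_sequences keeps only records covering the primer span", {
  set.seed(6)
  fwd <- "GGTCAACAAATCATAAAGATATTGG"
  rev <- "TAAACTTCAGGGTGACCAAAAAATCA"
  pair <- primer_pair("folmer", fwd, rev)
  ref <- paste0(random_seq(40), fwd, random_seq(300), revcomp(rev),
                random_seq(40))
  pair <- locate_primer_region(ref, pair)

  recs <- data.frame(
    id = c("full", "no_fwd", "no_rev", "unrelated"),
    species = paste("sp", 1:4), phylum = "Annelida",
    seq = c(ref,
            substr(ref, 80, nchar(ref)),        # starts inside the fwd site
            substr(ref, 1, 330),                # ends before the rev site
            random_seq(400)),
    stringsAsFactors = FALSE)
  kept <- testable_sequences(recs, pair, ref)
  expect_equal(kept$id, "full")

  # known truncation points from the generator match the construction
  eg <- generate_eg_map(60, seed = 7)
  lib <- generate_barcode_library(eg, coverage_fraction = 0.5, pair = pair,
                                  mutation_rate = 0, truncation_prob = 0,
                                  seed = 8)
  p2 <- locate_primer_region(lib$reference, pair)
  expect_equal(nrow(testable_sequences(lib$records, p2, lib$reference)),
               nrow(lib$records))
})

test_that("predict_amplification honors threshold and orientation", {
  set.seed(9)
  fwd <- "GGTCAACAAATCATAAAGATATTGG"
  rev <- "TAAACTTCAGGGTGACCAAAAAATCA"
  pair <- primer_pair("folmer", fwd, rev)

  tpl <- paste0(random_seq(20), fwd, random_seq(300), revcomp(rev),
                random_seq(20))
  call <- predict_amplification(pair, tpl, cfg)
  expect_true(call$amplifies)
  expect_equal(call$forward_score, 0)
  expect_equal(call$amplicon_start, 20L)
  expect_equal(call$amplicon_length, 25L + 300L + 26L)

  # destroyed 3' terminal base of the forward site -> no amplification
  tpl2 <- tpl
  last_fwd <- substr(fwd, 25, 25)
  substr(tpl2, 45, 45) <- chartr("ACGT", "CGTA", last_fwd)
  call2 <- predict_amplification(pair, tpl2, cfg)
  expect_false(call2$amplifies)
  expect_gte(call2$forward_score, 3.0)

  # reverse site upstream of the forward site -> negative call
  tpl3 <- paste0(random_seq(20), revcomp(rev), random_seq(50), fwd,
                 random_seq(20))
  expect_false(predict_amplification(pair, tpl3, cfg)$amplifies)
})

test_that("species summary uses the any-sequence-amplifies rule", {
  set.seed(10)
  fwd <- "GGTCAACAAATCATAAAGATATTGG"
  rev <- "TAAACTTCAGGGTGACCAAAAAATCA"
  pair <- primer_pair("folmer", fwd, rev)
  good <- function() paste0(random_seq(15), fwd, random_seq(200),
                            revcomp(rev), random_seq(15))
  bad <- function() random_seq(280)

  recs <- data.frame(
    id = paste0("r", 1:6),
    species = c("sp one", "sp one", "sp two", "sp two", "sp three", "sp four"),
    phylum = c("Annelida", "Annelida", "Annelida", "Annelida",
               "Mollusca", "Mollusca"),
    seq = c(good(), bad(),    # sp one: one of two amplifies -> positive
            bad(), bad(),     # sp two: negative
            good(), bad()),
    stringsAsFactors = FALSE)
  calls <- amplification_calls(pair, recs, cfg)
  summ <- species_amplification_summary(calls, all_phyla = c("Annelida",
                                                             "Mollusca",
                                                             "Cnidaria"))
  bs <- summ$by_species
  expect_true(bs$positive[bs$species == "sp one"])
  expect_false(bs$positive[bs$species == "sp two"])
  bp <- summ$by_phylum
  expect_equal(bp$pct_amplified[bp$phylum == "Annelida"], 50)
  expect_equal(bp$pct_amplified[bp$phylum == "Mollusca"], 50)
  expect_equal(bp$n_tested[bp$phylum == "Cnidaria"], 0L)
  expect_true(is.na(bp$pct_amplified[bp$phylum == "Cnidaria"]))

  # robustness of the any-rule: dropping one of >= 2 amplifying records
  # keeps the species positive
  recs2 <- recs
  recs2$seq[2] <- good()   # sp one now has two amplifying records
  calls2 <- amplification_calls(pair, recs2, cfg)
  expect_true(species_amplification_summary(calls2)$by_species$positive[1])
  calls2_dropped <- calls2[-1, ]
  expect_true(species_amplification_summary(
    calls2_dropped)$by_species$positive[
      species_amplification_summary(calls2_dropped)$by_species$species == "sp one"])
})
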
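test_that("group percentages follow the exclusion rule and sum to 100", {
  eg <- toy_eg()

  # single-group sample, abundance mode
  p <- group_percentages(c("alpha one" = 10), eg, "abundance")
  expect_equal(as.numeric(p), c(100, 0, 0, 0, 0))

  # uniform presence across the five groups
  s <- setNames(c(3, 1, 7, 2, 5), eg$species)
  p <- group_percentages(s, eg, "presence")
  expect_equal(as.numeric(p), rep(20, 5))

  # unassigned species excluded from numerator and denominator
  eg3 <- eg_map(c("A", "B", "C"), c("I", "III", "NA"))
  p <- group_percentages(c(A = 30, B = 60, C = 10), eg3, "abundance")
  expect_equal(as.numeric(p), c(100 * 30 / 90, 0, 100 * 60 / 90, 0, 0))
  expect_equal(attr(p, "unassigned_fraction"), 0.1)
  expect_equal(attr(p, "n_taxa_used"), 2L)

  # always sums to 100 when defined
  for (seed in 1:5) {
    set.seed(seed)
    s <- setNames(rpois(5, 4), eg$species)
    if (sum(s) == 0) next
    expect_equal(sum(group_percentages(s, eg, "abundance")), 100, tolerance = 1e-9)
  }

  expect_error(group_percentages(setNames(0, "alpha one"), eg), "azoic")
  expect_error(group_percentages(c(C = 5), eg_map("C", "NA"), "presence"),
               "not computable")
})

test_that("compute_index matches the weighted formula and its endpoints", {
  eg <- toy_eg()

  # all group V -> 6; all group I -> 0
  egV <- eg_map(letters[1:7], rep("V", 7))
  expect_equal(compute_index(setNames(rep(1, 7), letters[1:7]), egV,
                             "presence", unassigned_warn_at = 1)$value, 6)
  egI <- eg_map(letters[1:4], rep("I", 4))
  expect_equal(compute_index(setNames(rep(2, 4), letters[1:4]), egI,
                             "presence")$value, 0)

  # equal presence across groups -> mean of the weights
  s <- setNames(rep(1, 5), eg$species)
  expect_equal(compute_index(s, eg, "presence")$value, 3.0)

  # azoic convention: value 7, class extremely polluted, flag set
  r <- compute_index(setNames(rep(0, 5), eg$species), eg, "abundance")
  expect_true(r$azoic)
  expect_equal(r$value, 7)
  expect_equal(as.character(r$quality_class), "extremely polluted")

  # random samples agree with an independent hand-rolled oracle
  groups <- setNames(as.character(eg$group), eg$species)
  for (seed in 1:10) {
    set.seed(seed)
    s <- setNames(rpois(5, 3), eg$species)
    if (sum(s) == 0) next
    for (mode in c("abundance", "presence")) {
      expect_equal(suppressWarnings(compute_index(s, eg, mode))$value,
                   oracle_index(s, groups, mode))
    }
  }

  # unknown species -> UNASSIGNED with warning
  expect_warning(
    expect_warning(
      r <- compute_index(c("alpha one" = 5, "mystery sp" = 5), eg, "abundance",
                         unassigned_warn_at = 1),
      "UNASSIGNED"),
    "low richness")
  expect_equal(r$value, 0)
  expect_equal(r$unassigned_fraction, 0.5)
})

test_that("classify_pollution uses half-open continuous bins", {
  expect_equal(as.character(classify_pollution(c(0, 0.5, 1.2))),
               rep("unpolluted", 3))
  expect_equal(as.character(classify_pollution(c(1.2000001, 3.3))),
               rep("slightly polluted", 2))
  expect_equal(as.character(classify_pollution(c(3.4, 5))),
               rep("moderately polluted", 2))
  expect_equal(as.character(classify_pollution(c(5.1, 6))),
               rep("heavily polluted", 2))
  expect_equal(as.character(classify_pollution(c(6.1, 6.5, 7))),
               rep("extremely polluted", 3))
  expect_error(classify_pollution(-0.1), "outside")
  expect_error(classify_pollution(7.5), "outside")
  # total over the whole valid range
  expect_false(anyNA(classify_pollution(seq(0, 7, by = 0.01))))
})

test_that("index invariances hold on generated samples", {
  eg <- generate_eg_map(40, unassigned_fraction = 0, seed = 11)
  groups <- setNames(as.character(eg$group), eg$species)
  for (seed in 1:8) {
    set.seed(seed)
    s <- setNames(rpois(40, 1.2), eg$species)
    if (sum(s) == 0) next
    r <- suppressWarnings(compute_index(s, eg, "abundance"))
    expect_gte(r$value, 0); expect_lte(r$value, 6)
    # abundance-mode invariance under positive scaling
    expect_equal(suppressWarnings(compute_index(s * 7L, eg, "abundance"))$value,
                 r$value)
    # presence mode ignores counts entirely
    expect_equal(suppressWarnings(compute_index((s > 0) * 1L, eg, "presence"))$value,
                 suppressWarnings(compute_index(s * 3L, eg, "presence"))$value)
  }

  # monotonicity: adding a GV species never decreases p/a AMBI,
  # adding a GI species never increases it
  egx <- eg_map(c("s1", "s2", "gv new", "gi new"), c("II", "IV", "V", "I"))
  base <- c(s1 = 1, s2 = 1)
  v0 <- suppressWarnings(compute_index(base, egx, "presence"))$value
  expect_gte(suppressWarnings(
    compute_index(c(base, "gv new" = 1), egx, "presence"))$value, v0)
  expect_lte(suppressWarnings(
    compute_index(c(base, "gi new" = 1), egx, "presence"))$value, v0)
})

test_that("matrix-level ambi() agrees with per-sample compute_index", {
  eg <- toy_eg()
  m <- toy_matrix()
  for (mode in c("abundance", "presence")) {
    tab <- ambi(m, eg, mode)
    for (i in seq_len(nrow(m))) {
      r <- suppressWarnings(compute_index(m[i, ], eg, mode))
      expect_equal(tab$value[i], r$value)
      expect_equal(as.character(tab$quality_class[i]),
                   as.character(r$quality_class))
      expect_equal(tab$azoic[i], r$azoic)
    }
  }
  # larger randomized cross-check
  eg2 <- generate_eg_map(60, seed = 3)
  com <- generate_gradient_communities(eg2, n_stations = 25, seed = 4)
  tab <- ambi(com$matrix, eg2, "abundance")
  idx <- c(1, 10, 25)
  for (i in idx) {
    expect_equal(tab$value[i],
                 suppressWarnings(compute_index(com$matrix[i, ], eg2,
                                                "abundance"))$value)
  }
})

test_that("eg_heterogeneity_by_rank counts distinct groups per taxon", {
  # 6 species / 3 genera with known group spreads:
  #   genus g1: I, I        -> 1 group
  #   genus g2: I, V        -> 2 groups
  #   genus g3: II, III     -> 2 groups
  eg <- eg_map(paste("sp", 1:6), c("I", "I", "I", "V", "II", "III"),
               taxonomy = data.frame(
                 genus = c("g1", "g1", "g2", "g2", "g3", "g3"),
                 family = c("f1", "f1", "f1", "f1", "f2", "f2")))
  tab <- eg_heterogeneity_by_rank(eg, ranks = c("genus", "family"))
  gen <- tab[tab$rank == "genus", ]
  expect_equal(gen$n_taxa[gen$n_groups == 1], 1L)
  expect_equal(gen$n_taxa[gen$n_groups == 2], 2L)
  expect_equal(sum(gen$n_taxa), 3L)
  fam <- tab[tab$rank == "family", ]
  # f1 spans {I, V} = 2 groups; f2 spans {II, III} = 2 groups
  expect_equal(fam$n_taxa[fam$n_groups == 2], 2L)

  # unassigned species are excluded
  eg2 <- eg_map(c("x1", "x2"), c("I", "NA"),
                taxonomy = data.frame(genus = c("g", "g")))
  tab2 <- eg_heterogeneity_by_rank(eg2, ranks = "genus")
  expect_equal(tab2$n_taxa[tab2$n_groups == 1], 1L)

  # empty map -> empty table
  eg0 <- eg_map(character(0), character(0),
                taxonomy = data.frame(genus = character(0)))
  expect_equal(nrow(eg_heterogeneity_by_rank(eg0, ranks = "genus")), 0L)
})

test_that("eg_map validates groups and rejects conflicting duplicates", {
  expect_error(eg_map("a", "VI"), "unparseable")
  expect_error(eg_map(c("a", "A "), c("I", "V")), "conflicting")
  expect_warning(m <- eg_map(c("a", "a"), c("I", "I")), "duplicate")
  expect_equal(nrow(m), 1L)
  expect_equal(as.character(eg_map("a", NA)$group), "UNASSIGNED")
})
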
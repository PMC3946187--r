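# Shared toy fixtures and independent oracles, built in code.

# five species, one per ecological group
toy_eg <- function() {
  eg_map(c("alpha one", "beta two", "gamma three", "delta four", "epsilon five"),
         c("I", "II", "III", "IV", "V"),
         phylum = c("Annelida", "Annelida", "Mollusca", "Mollusca", "Arthropoda"))
}

# 4 stations x 5 species toy matrix (station d azoic)
toy_matrix <- function() {
  m <- rbind(
    a = c(10, 0, 5, 0, 0),
    b = c(0, 2, 2, 2, 0),
    c = c(0, 0, 0, 3, 9),
    d = c(0, 0, 0, 0, 0)
  )
  colnames(m) <- toy_eg()$species
  m
}

# Independent kappa oracle: computed from raw label pairs, never from
# a confusion matrix. p_e uses the empirical marginal proportions.
oracle_kappa <- function(a, b, classes = sort(unique(c(a, b)))) {
  stopifnot(length(a) == length(b))
  p_o <- mean(a == b)
  p_e <- sum(vapply(classes, function(k) mean(a == k) * mean(b == k), 0))
  if (p_e >= 1) return(if (p_o == 1) 1 else NA_real_)
  (p_o - p_e) / (1 - p_e)
}

# Independent index oracle: direct weighted sum over a named count
# vector and a plain species -> group lookup table (no package code).
oracle_index <- function(counts, groups, mode) {
  w <- c(I = 0, II = 1.5, III = 3, IV = 4.5, V = 6)
  counts <- counts[counts > 0]
  g <- groups[names(counts)]
  keep <- !is.na(g) & g != "UNASSIGNED"
  x <- if (mode == "presence") rep(1, sum(keep)) else counts[keep]
  sum(w[g[keep]] * x) / sum(x)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
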
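#' Confusion matrix of two quality-class classifications
#'
#' Cross-tabulates two classifications of the same stations over the
#' five pollution quality classes. All five classes are always present
#' on both axes, even when empty, so downstream kappa and per-class
#' summaries have a stable shape.
#'
#' @param classes_a,classes_b vectors of quality-class labels (character
#'   or factor over \code{\link{quality_classes}}), equal length,
#'   aligned by station.
#' @param classes class vocabulary; defaults to the five quality
#'   classes.
#' @return object of class \code{"confusion_matrix"}: an integer k x k
#'   matrix (rows = A, columns = B) with attribute \code{n}.
#' @export
confusion_matrix <- function(classes_a, classes_b,
                             classes = quality_classes()) {
  if (length(classes_a) != length(classes_b)) {
    stop("classifications have different lengths")
  }
  if (length(classes_a) == 0) stop("empty classifications")
  a <- as.character(classes_a)
  b <- as.character(classes_b)
  unknown <- setdiff(unique(c(a, b)), classes)
  if (length(unknown) > 0 || anyNA(a) || anyNA(b)) {
    stop("unknown class token(s): ",
         paste(c(unknown, if (anyNA(a) || anyNA(b)) "NA"), collapse = ", "))
  }
  cm <- table(factor(a, levels = classes), factor(b, levels = classes))
  cm <- unclass(as.matrix(cm))
  names(dimnames(cm)) <- c("A", "B")
  attr(cm, "n") <- length(a)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Cohen's kappa from a confusion matrix
#'
#' Unweighted chance-corrected agreement: kappa = (p_o - p_e)/(1 - p_e)
#' where p_o is the observed agreement (trace / n) and p_e the expected
#' agreement under independent raters with the observed marginals. When
#' both classifications are constant and identical (p_e = 1), kappa is
#' defined as 1.
#'
#' @param cm a \code{\link{confusion_matrix}} or plain square count
#'   matrix.
#' @return object of class \code{"kappa_result"}: list with
#'   \code{kappa}, \code{p_observed}, \code{p_expected}, \code{n} and
#'   \code{interpretation} (Monserud-Leemans verbal label).
#' @export
cohens_kappa <- function(cm) {
  m <- unclass(as.matrix(cm))
  if (nrow(m) != ncol(m) || any(m < 0)) stop("need a square non-negative count matrix")
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix")
  p_o <- sum(diag(m)) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  kappa <- if (p_e >= 1) {
    if (p_o == 1) 1 else stop("degenerate marginals with imperfect agreement")
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  res <- list(kappa = kappa, p_observed = p_o, p_expected = p_e,
              n = as.integer(n), interpretation = interpret_kappa(kappa))
  class(res) <- "kappa_result"
  res
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s); p_o = %.3f, p_e = %.3f, n = %d\n",
              x$kappa, x$interpretation, x$p_observed, x$p_expected, x$n))
  invisible(x)
}

#' Verbal interpretation of a kappa value
#'
#' Monserud-Leemans scale with lower-inclusive half-open bins:
#' below 0.05 no agreement; [0.05, 0.20) very poor; [0.20, 0.40) poor;
#' [0.40, 0.55) fair; [0.55, 0.70) good; [0.70, 0.85) very good;
#' [0.85, 1) excellent; exactly 1 perfect.
#'
#' @param kappa numeric in [-1, 1] (vectorized).
#' @return character vector of verbal labels.
#' @export
interpret_kappa <- function(kappa) {
  if (any(is.na(kappa)) || any(kappa < -1 | kappa > 1)) {
    stop("kappa outside [-1, 1]")
  }
  labels <- c("no agreement", "very poor", "poor", "fair", "good",
              "very good", "excellent", "perfect")
  idx <- findInterval(kappa, c(0.05, 0.20, 0.40, 0.55, 0.70, 0.85, 1)) + 1L
  labels[idx]
}

#' Per-class percent agreement
#'
#' For each class, the percentage of stations classified into that class
#' by A that received the same class from B (the diagonal cell over its
#' row total). Classes with an empty row are undefined (\code{NA}).
#'
#' @param cm a \code{\link{confusion_matrix}}.
#' @return named numeric vector of percentages with NA for empty rows.
#' @export
per_class_agreement <- function(cm) {
  m <- unclass(as.matrix(cm))
  if (nrow(m) != ncol(m)) stop("need a square matrix")
  rt <- rowSums(m)
  out <- ifelse(rt > 0, 100 * diag(m) / rt, NA_real_)
  names(out) <- rownames(m)
  out
}
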
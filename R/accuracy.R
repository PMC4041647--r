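#' Error confusion matrix
#'
#' Cross-tabulates reference against predicted class labels: rows are the
#' reference classes, columns the predicted classes, over the union of
#' observed labels (sorted). Both overall accuracy and Cohen's kappa are
#' invariant to this orientation.
#'
#' @param reference vector of reference (ground-truth) labels.
#' @param predicted vector of predicted (mapped) labels, same length.
#' @return a k x k integer matrix of class \code{"ConfusionMatrix"}.
#' @examples
#' cm <- confusionMatrix(c("A", "A", "B"), c("A", "B", "B"))
#' overallAccuracy(cm)
#' @export
confusionMatrix <- function(reference, predicted) {
  if (length(reference) != length(predicted))
    stop("reference and predicted must have the same length")
  if (length(reference) == 0)
    stop("empty label sequences")
  classes <- sort(unique(c(as.character(reference),
                           as.character(predicted))))
  m <- table(factor(reference, levels = classes),
             factor(predicted, levels = classes))
  m <- unclass(as.matrix(m))
  names(dimnames(m)) <- c("reference", "predicted")
  structure(m, class = c("ConfusionMatrix", class(m)))
}

#' Overall accuracy of a confusion matrix
#'
#' The fraction of agreeing observations: trace over total.
#'
#' @param cm a confusion matrix (square numeric matrix).
#' @return fraction in [0, 1].
#' @export
overallAccuracy <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix has no observations")
  sum(diag(cm)) / total
}

#' Cohen's kappa
#'
#' Chance-corrected agreement:
#' \deqn{\kappa = (p_o - p_e) / (1 - p_e)}
#' with observed agreement \eqn{p_o} = trace/total and expected agreement
#' \eqn{p_e = \sum_i row_i \cdot col_i / total^2}. A degenerate matrix
#' whose margins force \eqn{p_e = 1} returns 1 under perfect agreement and
#' is an error otherwise (kappa undefined).
#'
#' @param cm a confusion matrix (square numeric matrix).
#' @return kappa in [-1, 1].
#' @examples
#' cohensKappa(matrix(c(40, 20, 10, 30), 2))  # 0.40
#' @export
cohensKappa <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix has no observations")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (pe >= 1 - .Machine$double.eps^0.5) {
    if (po >= 1 - .Machine$double.eps^0.5) return(1)
    stop("kappa is undefined: degenerate margins with imperfect agreement")
  }
  (po - pe) / (1 - pe)
}

#' Verbal quality of a kappa value
#'
#' Reports the agreement adjective under two published grading scales for
#' kappa, as metadata strings.
#'
#' @param kappa a kappa statistic.
#' @return named character vector with elements \code{monserud} and
#'   \code{landis_koch}.
#' @export
kappaQuality <- function(kappa) {
  monserud <- cut(kappa, c(-Inf, 0.2, 0.4, 0.55, 0.7, 0.85, 0.99, Inf),
                  labels = c("no", "poor", "fair", "good", "very good",
                             "excellent", "perfect"))
  landis <- cut(kappa, c(-Inf, 0, 0.2, 0.4, 0.6, 0.8, Inf),
                labels = c("poor", "slight", "fair", "moderate",
                           "substantial", "almost perfect"))
  c(monserud = as.character(monserud), landis_koch = as.character(landis))
}

#' Read or write a confusion matrix as labelled CSV
#'
#' @param cm a confusion matrix.
#' @param path file path.
#' @return \code{readConfusionMatrix} returns a \code{ConfusionMatrix}.
#' @export
writeConfusionMatrix <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeConfusionMatrix
#' @export
readConfusionMatrix <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  names(dimnames(m)) <- c("reference", "predicted")
  structure(m, class = c("ConfusionMatrix", class(m)))
}
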
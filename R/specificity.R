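## Expression panels are SummarizedExperiment objects: assay "fpkm"
## (features x samples, non-negative) and colData$condition giving the tissue
## or developmental stage of each sample.

#' Build an expression panel
#'
#' @param fpkm Numeric matrix of FPKM values, features x samples, with
#'   dimnames.
#' @param condition Character/factor vector, one condition (tissue or stage)
#'   per sample.
#' @return A \code{SummarizedExperiment} with assay \code{fpkm}.
#' @export
makeExpressionPanel <- function(fpkm, condition) {
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  if (is.null(rownames(fpkm)) || is.null(colnames(fpkm)))
    stop("fpkm needs row and column names")
  if (anyDuplicated(rownames(fpkm))) stop("duplicated feature ids")
  if (length(condition) != ncol(fpkm))
    stop("condition must cover every sample")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = fpkm),
    colData = DataFrame(condition = as.character(condition),
                        row.names = colnames(fpkm)))
}

.fpkm <- function(se) SummarizedExperiment::assay(se, "fpkm")
.conditions <- function(se)
  as.character(SummarizedExperiment::colData(se)$condition)

## features x conditions matrix of condition-mean FPKM
.conditionMeans <- function(se) {
  f <- .fpkm(se)
  cond <- .conditions(se)
  lev <- unique(cond)
  out <- vapply(lev, function(cc)
    rowMeans(f[, cond == cc, drop = FALSE]), numeric(nrow(f)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(f),
                                       dimnames = list(rownames(f), lev))
  out
}

#' Detection breadth across conditions
#'
#' Number of conditions in which a feature is detected, where detection means
#' condition-mean FPKM strictly greater than \code{threshold}.
#'
#' @param se Expression panel from [makeExpressionPanel()].
#' @param threshold Detection threshold (default 0.1 FPKM, strict).
#' @return Integer vector per feature.
#' @export
detectionBreadth <- function(se, threshold = 0.1) {
  cm <- .conditionMeans(se)
  out <- rowSums(cm > threshold)
  storage.mode(out) <- "integer"
  out
}

## Shannon entropy (base 2) of a probability vector; 0 log 0 = 0
.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon distance between two probability vectors
#'
#' Square root of the Jensen-Shannon divergence with base-2 entropy; lies in
#' [0, 1] and is symmetric.
#'
#' @param p,q Non-negative vectors summing to 1.
#' @return Numeric distance.
#' @export
jsDistance <- function(p, q) {
  m <- (p + q) / 2
  jsd <- .entropy2(m) - (.entropy2(p) + .entropy2(q)) / 2
  sqrt(max(jsd, 0))
}

#' Jensen-Shannon tissue-specificity scores
#'
#' For each feature, the expression density p over conditions is the
#' normalized vector of log10(condition-mean FPKM + 1); the specificity score
#' against condition t is 1 - JSdist(p, e_t) with e_t the unit vector of t.
#' The reported specificity is the maximum over conditions, attained at the
#' condition of maximal density. Features with all-zero expression are
#' undefined (NA) and excluded from summaries.
#'
#' @param se Expression panel with >= 2 conditions.
#' @return \code{data.frame}: \code{feature_id}, \code{max_score},
#'   \code{specific_condition}, plus the full per-condition score matrix in
#'   attribute \code{"scores"} and the density matrix in attribute
#'   \code{"density"}.
#' @export
specificityScore <- function(se) {
  cm <- .conditionMeans(se)
  if (ncol(cm) < 2L) stop("specificity needs at least two conditions")
  dens <- log10(cm + 1)
  tot <- rowSums(dens)
  p <- dens / ifelse(tot > 0, tot, NA)
  nc <- ncol(cm)
  scores <- matrix(NA_real_, nrow(cm), nc, dimnames = dimnames(cm))
  for (t in seq_len(nc)) {
    e <- numeric(nc); e[t] <- 1
    ok <- which(tot > 0)
    scores[ok, t] <- vapply(ok, function(i) 1 - jsDistance(p[i, ], e),
                            numeric(1))
  }
  maxI <- apply(scores, 1, function(r) if (all(is.na(r))) NA_integer_
                else which.max(r))
  data.frame(
    feature_id = rownames(cm),
    max_score = ifelse(is.na(maxI), NA_real_,
                       scores[cbind(seq_len(nrow(cm)), maxI)]),
    specific_condition = ifelse(is.na(maxI), NA_character_,
                                colnames(cm)[maxI]),
    row.names = NULL) |>
    structure(scores = scores, density = p)
}
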
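## Coding-potential features: longest ORF, Fickett TESTCODE score, hexamer
## usage log-likelihood ratio, and a logistic model combining them. These
## replace external coding-potential callers with a self-contained scorer
## trained on user-supplied (or simulated) coding/noncoding sequence sets.

.STOPS <- c("TAA", "TAG", "TGA")

## character conversion that keeps names (as.character drops them for
## character input; Biostrings keeps them for XStringSet input)
.asSeqChar <- function(x) {
  if (is.character(x)) return(x)
  as.character(x)
}

#' Longest open reading frame on the sense strand
#'
#' Scans the three sense frames for the longest ATG-initiated,
#' stop-terminated ORF. The reported length includes the stop codon. ORFs
#' whose span contains an N are skipped; a sequence with no complete ORF
#' reports length 0.
#'
#' @param sequence A single character string or \code{DNAString} over ACGTN.
#' @return List with \code{frame} (0-2, NA if none), \code{start} (1-based
#'   offset of the ATG, NA if none) and \code{length} (nt, 0 if none).
#' @examples
#' longestOrf("ATGAAATAG")$length  # 9
#' @export
longestOrf <- function(sequence) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  best <- list(frame = NA_integer_, start = NA_integer_, length = 0L)
  if (n < 6L) return(best)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 2L) next
    idx <- f + seq_len(ncod * 3L)
    cod <- paste0(chars[idx[c(TRUE, FALSE, FALSE)]],
                  chars[idx[c(FALSE, TRUE, FALSE)]],
                  chars[idx[c(FALSE, FALSE, TRUE)]])
    starts <- which(cod == "ATG")
    stops <- which(cod %in% .STOPS)
    if (!length(starts) || !length(stops)) next
    ## first stop at or after each start codon
    k <- findInterval(starts - 1L, stops) + 1L
    ok <- k <= length(stops)
    if (!any(ok)) next
    starts <- starts[ok]
    ends <- stops[k[ok]]
    len <- (ends - starts + 1L) * 3L
    ## drop ORFs containing N
    hasN <- vapply(seq_along(starts), function(i) {
      span <- chars[(f + (starts[i] - 1L) * 3L + 1L):(f + ends[i] * 3L)]
      any(span == "N")
    }, logical(1))
    len[hasN] <- 0L
    if (max(len) > best$length) {
      i <- which.max(len)
      best <- list(frame = f, start = f + (starts[i] - 1L) * 3L + 1L,
                   length = as.integer(max(len)))
    }
  }
  best
}

## Fickett (1982) TESTCODE lookup tables: probability that a sequence with a
## given position/composition parameter value is coding, and the weights of
## the eight parameters. Thresholds are descending; the first threshold less
## than or equal to the value selects the probability.
.FICKETT <- local({
  posProb <- list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  posWeight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  posThresh <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
  cmpProb <- list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  cmpWeight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  cmpThresh <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.17, 0.17, 0.0)
  list(posProb = posProb, posWeight = posWeight, posThresh = posThresh,
       cmpProb = cmpProb, cmpWeight = cmpWeight, cmpThresh = cmpThresh)
})

.fickettLookup <- function(value, thresh, prob) {
  prob[which(value >= thresh)[1]]
}

#' Fickett TESTCODE score
#'
#' Combines four base-position parameters (for each base, the ratio of its
#' maximum to minimum count over the three codon positions, min + 1 in the
#' denominator) and four base-composition parameters through the published
#' TESTCODE probability tables and weights. Higher scores indicate
#' coding-like period-3 bias and composition.
#'
#' @param sequence Character string or \code{DNAString}. Lengths below 200 nt
#'   are allowed with a warning (the statistic is noisy there). Non-ACGT
#'   content above 10\% is an error.
#' @return Numeric score.
#' @export
fickettScore <- function(sequence) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  if (n == 0) stop("empty sequence")
  if (n < 200) warning("Fickett score on sequence shorter than 200 nt")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  keep <- chars %in% c("A", "C", "G", "T")
  if (mean(!keep) > 0.10) stop("more than 10% non-ACGT characters")
  score <- 0
  tb <- .FICKETT
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(p) {
      idx <- seq(p + 1L, n, by = 3L)
      sum(chars[idx] == b)
    }, numeric(1))
    posVal <- max(cnt) / (min(cnt) + 1)
    cmpVal <- sum(cnt) / max(sum(keep), 1)
    score <- score +
      .fickettLookup(posVal, tb$posThresh, tb$posProb[[b]]) * tb$posWeight[[b]] +
      .fickettLookup(cmpVal, tb$cmpThresh, tb$cmpProb[[b]]) * tb$cmpWeight[[b]]
  }
  unname(score)
}

## Extract hexamer strings from a sequence: in-frame (step 3) within the
## longest ORF when one of >= 6 nt exists, else sliding (step 1) over the
## full sequence. Hexamers containing N are dropped.
.hexamers <- function(s) {
  s <- toupper(as.character(s))
  n <- nchar(s)
  if (n < 6L) return(character())
  orf <- longestOrf(s)
  if (orf$length >= 6L) {
    sub <- substr(s, orf$start, orf$start + orf$length - 1L)
    starts <- seq(1L, nchar(sub) - 5L, by = 3L)
    hx <- substring(sub, starts, starts + 5L)
  } else {
    starts <- seq_len(n - 5L)
    hx <- substring(s, starts, starts + 5L)
  }
  hx[!grepl("N", hx, fixed = TRUE)]
}

.HEXAMER_NAMES <- local({
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  sort(apply(g, 1, paste0, collapse = ""))
})

#' Train a hexamer usage table
#'
#' Counts hexamers (in-frame within the longest ORF where available, sliding
#' otherwise) in a coding and a noncoding training set and returns per-hexamer
#' log-likelihood ratios log(f_coding / f_noncoding) with pseudocounts.
#'
#' @param coding,noncoding Character vectors or \code{DNAStringSet}s of
#'   training sequences (at least one each).
#' @param pseudocount Added to every hexamer count in both classes.
#' @return Named numeric vector of length 4096 (all ACGT hexamers).
#' @export
trainHexamerTable <- function(coding, noncoding, pseudocount = 1) {
  if (!length(coding) || !length(noncoding))
    stop("need at least one sequence per class")
  countClass <- function(seqs) {
    hx <- unlist(lapply(as.character(seqs), .hexamers), use.names = FALSE)
    tab <- table(factor(hx, levels = .HEXAMER_NAMES))
    as.numeric(tab) + pseudocount
  }
  cc <- countClass(coding); nc <- countClass(noncoding)
  llr <- log(cc / sum(cc)) - log(nc / sum(nc))
  names(llr) <- .HEXAMER_NAMES
  llr
}

#' Mean hexamer log-likelihood ratio of a sequence
#'
#' @param sequence Character string or \code{DNAString}.
#' @param table A table from [trainHexamerTable()].
#' @return Mean of table entries over the sequence's hexamers; 0 (with
#'   attribute \code{too_short = TRUE}) for sequences shorter than 6 nt.
#' @export
hexamerScore <- function(sequence, table) {
  hx <- .hexamers(sequence)
  if (!length(hx)) {
    out <- 0
    attr(out, "too_short") <- TRUE
    return(out)
  }
  mean(table[hx])
}

#' Coding-potential feature matrix
#'
#' @param sequences Character vector or \code{DNAStringSet}, named by
#'   transcript id.
#' @param hexamerTable A table from [trainHexamerTable()].
#' @return \code{data.frame}: \code{orf_length}, \code{orf_coverage},
#'   \code{fickett}, \code{hexamer}, row-named by transcript id.
#' @export
codingFeatures <- function(sequences, hexamerTable) {
  seqs <- .asSeqChar(sequences)
  orf <- vapply(seqs, function(s) longestOrf(s)$length, numeric(1))
  len <- nchar(seqs)
  fk <- vapply(seqs, function(s)
    suppressWarnings(fickettScore(s)), numeric(1))
  hx <- vapply(seqs, function(s) as.numeric(hexamerScore(s, hexamerTable)),
               numeric(1))
  data.frame(orf_length = orf,
             orf_coverage = ifelse(len > 0, orf / len, 0),
             fickett = fk, hexamer = hx,
             row.names = names(seqs))
}

#' Train the logistic coding-potential model
#'
#' Fits a logistic regression of coding status on the four coding-potential
#' features. The fitted model plus its decision threshold travels with every
#' classification report.
#'
#' @param features \code{data.frame} from [codingFeatures()].
#' @param labels Logical (or 0/1) vector: \code{TRUE} = coding.
#' @param threshold Decision threshold on the coding probability.
#' @return An object of class \code{codingModel}: list with the \code{glm}
#'   fit, \code{threshold}, and feature names.
#' @export
trainCodingModel <- function(features, labels, threshold = 0.5) {
  y <- as.logical(labels)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  dat <- cbind(features, .y = y)
  fit <- stats::glm(.y ~ orf_length + orf_coverage + fickett + hexamer,
                    data = dat, family = stats::binomial())
  structure(list(fit = fit, threshold = threshold,
                 features = c("orf_length", "orf_coverage", "fickett",
                              "hexamer")),
            class = "codingModel")
}

#' @export
print.codingModel <- function(x, ...) {
  cat("codingModel: logistic over", paste(x$features, collapse = ", "),
      "| threshold", x$threshold, "\n")
  print(stats::coef(x$fit))
  invisible(x)
}

#' Coding probability under a trained model
#'
#' @param features \code{data.frame} from [codingFeatures()].
#' @param model A \code{codingModel} from [trainCodingModel()].
#' @return Numeric vector of probabilities in (0, 1).
#' @export
codingProbability <- function(features, model) {
  p <- stats::predict(model$fit, newdata = features, type = "response")
  unname(pmin(pmax(p, .Machine$double.eps), 1 - .Machine$double.eps))
}

#' Serialize / restore a coding model
#'
#' Writes coefficients, threshold and the hexamer table to JSON so a
#' classification run can be reproduced without the training sequences.
#'
#' @param model A \code{codingModel}.
#' @param hexamerTable The hexamer table used to build its features.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeCodingModel <- function(model, hexamerTable, path) {
  obj <- list(coefficients = as.list(stats::coef(model$fit)),
              threshold = model$threshold,
              hexamer_table = as.list(hexamerTable))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
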
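## Neighbour-gene cis-correlation analysis: Pearson correlation of
## log2(FPKM + 0.05) profiles for neighbouring pairs, a seeded random-pair
## null, TSS-distance profiles, and ddCt fold-change quantification.

## run code under a temporary RNG state so callers' streams are untouched
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Pearson correlations of expression for feature pairs
#'
#' Correlates log2(FPKM + 0.05) profiles across samples for each pair.
#' Pairs with a member absent from the matrix are reported with NA and
#' flagged, not silently dropped; zero-variance members likewise.
#'
#' @param se Expression panel (>= 3 samples).
#' @param pairs \code{data.frame} with columns \code{id_a}, \code{id_b} and
#'   optionally \code{class}; extra columns (e.g. \code{gap},
#'   \code{tss_distance}) are carried through.
#' @param offset Added to FPKM before log2 (default 0.05).
#' @return \code{data.frame}: the input pairs plus \code{r} and \code{flag}
#'   (\code{ok}, \code{missing_feature}, \code{zero_variance}).
#' @export
pairCorrelations <- function(se, pairs, offset = 0.05) {
  f <- .fpkm(se)
  if (ncol(f) < 3L) stop("need at least 3 samples for pair correlations")
  lg <- log2(f + offset)
  out <- pairs
  out$r <- NA_real_
  out$flag <- "ok"
  present <- pairs$id_a %in% rownames(lg) & pairs$id_b %in% rownames(lg)
  out$flag[!present] <- "missing_feature"
  idx <- which(present)
  if (length(idx)) {
    a <- lg[pairs$id_a[idx], , drop = FALSE]
    b <- lg[pairs$id_b[idx], , drop = FALSE]
    va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
    zero <- va == 0 | vb == 0
    out$flag[idx[zero]] <- "zero_variance"
    good <- idx[!zero]
    if (length(good))
      out$r[good] <- vapply(seq_along(good), function(k)
        stats::cor(a[which(!zero)[k], ], b[which(!zero)[k], ]), numeric(1))
  }
  out
}

#' Seeded random feature-pair null
#'
#' Uniformly samples unordered feature pairs without replacement, excluding
#' a supplied set of genuine neighbour pairs, and correlates them like
#' [pairCorrelations()].
#'
#' @param se Expression panel.
#' @param nPairs Number of random pairs.
#' @param seed Integer seed (the sampling is reproducible and leaves the
#'   caller's RNG stream untouched).
#' @param exclude Optional \code{data.frame} with \code{id_a}, \code{id_b}:
#'   pairs never to emit (order-insensitive).
#' @param offset log2 offset, as in [pairCorrelations()].
#' @return As [pairCorrelations()], with \code{class = "random"}.
#' @export
randomPairNull <- function(se, nPairs, seed, exclude = NULL, offset = 0.05) {
  ids <- rownames(.fpkm(se))
  n <- length(ids)
  if (n < 2L) stop("need at least two features")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  bad <- if (is.null(exclude)) character() else
    key(as.character(exclude$id_a), as.character(exclude$id_b))
  nAvail <- n * (n - 1) / 2 - length(unique(bad))
  if (nPairs > nAvail)
    stop("nPairs exceeds the ", nAvail, " available non-neighbour pairs")
  pairs <- .withSeed(seed, {
    chosen <- character(0)
    out <- matrix(character(), 0, 2)
    while (nrow(out) < nPairs) {
      need <- nPairs - nrow(out)
      a <- sample(ids, need * 2, replace = TRUE)
      b <- sample(ids, need * 2, replace = TRUE)
      ok <- a != b
      a <- a[ok]; b <- b[ok]
      k <- key(a, b)
      keep <- !(k %in% bad) & !(k %in% chosen) & !duplicated(k)
      a <- a[keep]; b <- b[keep]; k <- k[keep]
      take <- seq_len(min(length(a), need))
      out <- rbind(out, cbind(a[take], b[take]))
      chosen <- c(chosen, k[take])
    }
    out
  })
  df <- data.frame(id_a = pairs[, 1], id_b = pairs[, 2], class = "random")
  pairCorrelations(se, df, offset = offset)
}

#' TSS-distance profile of neighbour pairs
#'
#' Bins pairs by TSS distance into equal-width bins within a window
#' (strictly below \code{window}) and reports per-class bin fractions.
#'
#' @param pairs \code{data.frame} with \code{tss_distance} and \code{class}.
#' @param window Window in bp (default 4000; pairs at exactly the window
#'   boundary are excluded).
#' @param bin Bin width in nt (default 400; must divide \code{window}).
#' @return \code{data.frame}: \code{class}, \code{bin_start}, \code{bin_end},
#'   \code{count}, \code{fraction} (fractions sum to 1 within each class).
#' @export
tssDistanceProfile <- function(pairs, window = 4000, bin = 400) {
  if (window %% bin != 0) stop("bin width must divide the window")
  d <- pairs$tss_distance
  keep <- !is.na(d) & d < window
  cls <- if (is.null(pairs$class)) rep("all", nrow(pairs)) else
    as.character(pairs$class)
  d <- d[keep]; cls <- cls[keep]
  nb <- window %/% bin
  starts <- (seq_len(nb) - 1L) * bin
  b <- pmin(d %/% bin, nb - 1L)  # d < window so always < nb
  out <- do.call(rbind, lapply(unique(cls), function(cc) {
    cnt <- tabulate(b[cls == cc] + 1L, nbins = nb)
    data.frame(class = cc, bin_start = starts, bin_end = starts + bin,
               count = cnt, fraction = cnt / sum(cnt))
  }))
  rownames(out) <- NULL
  out
}

#' Relative qPCR quantification (2^-ddCt)
#'
#' dCt = Ct(target) - Ct(reference) per sample; ddCt = dCt(sample) -
#' dCt(calibrator); fold change = 2^-ddCt, so the calibrator has fold 1.
#'
#' @param measurements \code{data.frame} with columns \code{sample},
#'   \code{ct_target}, \code{ct_reference}.
#' @param calibrator Sample id used as the calibrator.
#' @return \code{data.frame}: \code{sample}, \code{dct}, \code{ddct},
#'   \code{fold_change}.
#' @export
ddctFoldChange <- function(measurements, calibrator) {
  req <- c("sample", "ct_target", "ct_reference")
  if (!all(req %in% names(measurements)))
    stop("measurements needs columns: ", paste(req, collapse = ", "))
  if (anyNA(measurements$ct_reference))
    stop("missing reference Ct value(s)")
  if (!calibrator %in% measurements$sample)
    stop("calibrator sample not found: ", calibrator)
  dct <- measurements$ct_target - measurements$ct_reference
  ddct <- dct - dct[match(calibrator, measurements$sample)]
  data.frame(sample = measurements$sample, dct = dct, ddct = ddct,
             fold_change = 2^(-ddct))
}
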
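#' Structural statistics per transcript
#'
#' Exon count, exon lengths and spliced transcript length (sum of exon
#' lengths, not genomic span) for every transcript — the quantities behind
#' exon-count and length comparisons between lincRNAs and mRNAs.
#'
#' @param catalog A [TranscriptCatalog-class].
#' @return A \code{data.frame} with columns \code{transcript_id},
#'   \code{gene_id}, \code{exon_count}, \code{transcript_length} and a list
#'   column \code{exon_lengths}.
#' @export
transcriptStats <- function(catalog) {
  ex <- exonsByTx(catalog)
  w <- IRanges::width(ex)
  data.frame(
    transcript_id = txIds(catalog),
    gene_id = geneIds(catalog),
    exon_count = lengths(ex),
    transcript_length = vapply(w, sum, numeric(1)),
    exon_lengths = I(as.list(w)),
    row.names = NULL)
}

## chrom:strand:intron-chain signature used for known-transcript matching.
## Single-exon transcripts have no introns; they get a span signature instead
## so that only an identical single-exon reference can match them.
.chainSignature <- function(exons) {
  vapply(seq_along(exons), function(i) {
    e <- exons[[i]]
    chr <- as.character(GenomicRanges::seqnames(e)[1])
    str <- as.character(GenomicRanges::strand(e)[1])
    if (length(e) == 1L)
      return(paste0("SE|", chr, str, "|", GenomicRanges::start(e), "-",
                    GenomicRanges::end(e)))
    intr <- IRanges::gaps(IRanges::ranges(e))
    paste0(chr, str, "|", paste(GenomicRanges::start(intr),
                                GenomicRanges::end(intr),
                                sep = "-", collapse = ","))
  }, character(1))
}

#' Classify catalog transcripts against a reference annotation
#'
#' Mirrors the "remove potential known transcripts" step: a transcript is a
#' \code{known_match} when its intron chain is identical to some reference
#' transcript on the same chromosome and strand (terminal-exon extensions are
#' ignored; a single-exon transcript matches only an identical single-exon
#' reference). Otherwise it is an \code{exonic_overlap} when at least one
#' exonic base overlaps a reference exon on the same strand; otherwise
#' \code{novel}. Antisense overlap is deliberately not "known" — such
#' transcripts fall to the strand-agnostic distance filter downstream.
#'
#' @param catalog,reference [TranscriptCatalog-class] objects.
#' @return \code{data.frame} with columns \code{transcript_id},
#'   \code{status} (factor: \code{known_match}, \code{exonic_overlap},
#'   \code{novel}) and \code{evidence} (matched reference transcript id, or
#'   overlap width in bp, or \code{NA}).
#' @export
classifyNovelty <- function(catalog, reference) {
  if (!length(catalog) || !length(reference))
    stop("catalog and reference must be non-empty")
  sig <- .chainSignature(exonsByTx(catalog))
  refSig <- .chainSignature(exonsByTx(reference))
  hit <- match(sig, refSig)
  status <- ifelse(!is.na(hit), "known_match", NA)
  evidence <- ifelse(!is.na(hit), txIds(reference)[hit], NA)

  ## same-strand exonic overlap for the rest
  rest <- which(is.na(hit))
  if (length(rest)) {
    catEx <- exonsByTx(catalog)[rest]
    flat <- unlist(catEx, use.names = FALSE)
    grp <- rep(seq_along(catEx), lengths(catEx))
    refFlat <- unlist(exonsByTx(reference), use.names = FALSE)
    ov <- GenomicRanges::findOverlaps(flat, refFlat, ignore.strand = FALSE)
    if (length(ov)) {
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(flat)[S4Vectors::queryHits(ov)],
        IRanges::ranges(refFlat)[S4Vectors::subjectHits(ov)]))
      bp <- tapply(w, grp[S4Vectors::queryHits(ov)], sum)
      idx <- rest[as.integer(names(bp))]
      status[idx] <- "exonic_overlap"
      evidence[idx] <- as.character(bp)
    }
  }
  status[is.na(status)] <- "novel"
  data.frame(transcript_id = txIds(catalog),
             status = factor(status,
                             levels = c("known_match", "exonic_overlap",
                                        "novel")),
             evidence = evidence, row.names = NULL)
}

#' Distance from each transcript to the nearest annotated gene
#'
#' Strand-agnostic gap in bp between the transcript's genomic span and the
#' nearest reference gene locus span; 0 when the spans overlap. Gene loci are
#' the union span of all transcripts sharing a \code{gene_id}. An empty
#' reference yields \code{Inf}.
#'
#' @param catalog A [TranscriptCatalog-class] (or \code{GRanges} of spans).
#' @param reference A [TranscriptCatalog-class] for the annotation.
#' @return Numeric vector of distances, named by transcript id.
#' @export
distanceToNearestGene <- function(catalog, reference) {
  spans <- if (is(catalog, "TranscriptCatalog")) txSpans(catalog) else catalog
  if (!length(reference)) {
    d <- rep(Inf, length(spans)); names(d) <- names(spans); return(d)
  }
  genes <- geneSpans(reference)
  hit <- GenomicRanges::distanceToNearest(spans, genes, ignore.strand = TRUE)
  d <- rep(Inf, length(spans))
  d[S4Vectors::queryHits(hit)] <- mcols(hit)$distance
  names(d) <- names(spans)
  d
}

#' Transcription start sites
#'
#' The first transcribed base of each transcript: span start on \code{+},
#' span end on \code{-}. Unstranded transcripts are an error.
#'
#' @param catalog A [TranscriptCatalog-class] or a stranded \code{GRanges} of
#'   transcript spans.
#' @return Integer vector of TSS genomic positions (1-based), named by
#'   transcript id, with chromosome names in attribute \code{"chrom"}.
#' @export
tssPositions <- function(catalog) {
  spans <- if (is(catalog, "TranscriptCatalog")) txSpans(catalog) else catalog
  str <- as.character(GenomicRanges::strand(spans))
  if (any(str == "*"))
    stop("TSS undefined for unstranded transcript(s): ",
         paste(utils::head(names(spans)[str == "*"], 5), collapse = ", "))
  pos <- ifelse(str == "+", GenomicRanges::start(spans),
                GenomicRanges::end(spans))
  names(pos) <- names(spans)
  attr(pos, "chrom") <- as.character(GenomicRanges::seqnames(spans))
  pos
}

#' TSS distance between two transcripts
#'
#' @param a,b Single-transcript [TranscriptCatalog-class] subsets or stranded
#'   single-range \code{GRanges}.
#' @return Absolute distance in bp between the two TSS positions; \code{NA}
#'   if the transcripts sit on different chromosomes.
#' @export
tssDistance <- function(a, b) {
  pa <- tssPositions(a); pb <- tssPositions(b)
  if (attr(pa, "chrom")[1] != attr(pb, "chrom")[1]) return(NA_real_)
  abs(as.numeric(pa[1]) - as.numeric(pb[1]))
}

#' Neighbouring feature pairs within a genomic distance
#'
#' All cross pairs between two span sets whose gene-body gap (0 when spans
#' overlap) is strictly below \code{maxGap}, ignoring strand — orientation is
#' reported, not filtered. Each pair carries the body gap and, when both
#' members are stranded, the TSS distance.
#'
#' @param a,b Named \code{GRanges} of feature spans (e.g. [txSpans()] or
#'   [geneSpans()] output) or [TranscriptCatalog-class] objects (spans used).
#' @param maxGap Pairs with gap < \code{maxGap} bp are kept (default 10 kb).
#' @return \code{data.frame}: \code{id_a}, \code{id_b}, \code{chrom},
#'   \code{gap}, \code{tss_distance}, sorted by chromosome, coordinate and
#'   ids.
#' @export
neighborPairs <- function(a, b, maxGap = 10000) {
  ga <- if (is(a, "TranscriptCatalog")) txSpans(a) else a
  gb <- if (is(b, "TranscriptCatalog")) txSpans(b) else b
  ov <- GenomicRanges::findOverlaps(ga, gb, maxgap = maxGap - 1L,
                                    ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  if (!length(qh))
    return(data.frame(id_a = character(), id_b = character(),
                      chrom = character(), gap = numeric(),
                      tss_distance = numeric()))
  gap <- GenomicRanges::distance(ga[qh], gb[sh], ignore.strand = TRUE)
  strA <- as.character(GenomicRanges::strand(ga[qh]))
  strB <- as.character(GenomicRanges::strand(gb[sh]))
  tssA <- ifelse(strA == "+", GenomicRanges::start(ga[qh]),
                 GenomicRanges::end(ga[qh]))
  tssB <- ifelse(strB == "+", GenomicRanges::start(gb[sh]),
                 GenomicRanges::end(gb[sh]))
  tssD <- ifelse(strA == "*" | strB == "*", NA_real_, abs(tssA - tssB))
  out <- data.frame(id_a = names(ga)[qh], id_b = names(gb)[sh],
                    chrom = as.character(GenomicRanges::seqnames(ga))[qh],
                    gap = as.numeric(gap), tss_distance = tssD)
  ord <- order(out$chrom, GenomicRanges::start(ga)[qh], out$id_a, out$id_b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
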
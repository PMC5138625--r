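#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList
NULL

#' TranscriptCatalog: exon-resolved transcript models
#'
#' Container for a set of transcript models, each an ordered, disjoint set of
#' exons on one chromosome and strand. Backs both the reference annotation and
#' the merged assembly catalog that the lincRNA funnel consumes.
#'
#' @slot exons A \code{GRangesList}, one element per transcript (named by
#'   transcript id), holding its exons sorted by coordinate.
#' @slot txData A \code{DataFrame} with one row per transcript, columns
#'   \code{transcript_id} and \code{gene_id}, parallel to \code{exons}.
#'
#' @seealso [readTranscriptGTF()], [classifyNovelty()], [transcriptStats()]
#' @export
setClass("TranscriptCatalog",
         slots = c(exons = "GRangesList", txData = "DataFrame"))

setValidity("TranscriptCatalog", function(object) {
  msg <- character()
  if (length(object@exons) != nrow(object@txData))
    msg <- c(msg, "exons and txData lengths differ")
  nm <- names(object@exons)
  if (is.null(nm)) nm <- character()
  if (!identical(nm, as.character(object@txData$transcript_id)))
    msg <- c(msg, "names(exons) must equal txData$transcript_id")
  if (anyDuplicated(names(object@exons)))
    msg <- c(msg, "duplicated transcript ids")
  if (length(object@exons)) {
    nchr <- lengths(unique(GenomicRanges::seqnames(object@exons)))
    nstr <- lengths(unique(GenomicRanges::strand(object@exons)))
    if (any(nchr != 1L) || any(nstr != 1L))
      msg <- c(msg, "each transcript must sit on one chromosome and strand")
    if (!all(vapply(object@exons, IRanges::isDisjoint, logical(1))))
      msg <- c(msg, "exons overlap within a transcript")
  }
  if (length(msg)) msg else TRUE
})

#' Build a TranscriptCatalog from an exon GRangesList
#'
#' Exons are sorted within each transcript; transcripts are kept in the order
#' given.
#'
#' @param exons Named \code{GRangesList} of exons, one element per transcript.
#' @param geneIds Character vector of gene ids parallel to \code{exons}.
#' @return A [TranscriptCatalog-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 301), c(200, 450)), "+")
#' cat1 <- TranscriptCatalog(GenomicRanges::GRangesList(t1 = gr), geneIds = "g1")
#' transcriptStats(cat1)
#' @export
TranscriptCatalog <- function(exons, geneIds) {
  if (is.null(names(exons)))
    stop("exons must be a named GRangesList (names = transcript ids)")
  exons <- GRangesList(lapply(exons, GenomicRanges::sort))
  new("TranscriptCatalog", exons = exons,
      txData = DataFrame(transcript_id = names(exons),
                         gene_id = as.character(geneIds)))
}

setMethod("show", "TranscriptCatalog", function(object) {
  cat("TranscriptCatalog with", length(object@exons), "transcripts from",
      length(unique(object@txData$gene_id)), "genes\n")
  if (length(object@exons)) {
    chr <- unique(as.character(unlist(GenomicRanges::seqnames(object@exons),
                                      use.names = FALSE)))
    cat("  seqnames:", paste(utils::head(chr, 6), collapse = " "),
        if (length(chr) > 6) "..." else "", "\n")
  }
})

#' @describeIn TranscriptCatalog Number of transcripts.
#' @param x,object A TranscriptCatalog.
#' @export
setMethod("length", "TranscriptCatalog", function(x) length(x@exons))

#' Accessors for TranscriptCatalog
#'
#' \code{txIds} and \code{geneIds} return the transcript/gene id vectors;
#' \code{exonsByTx} the exon \code{GRangesList}; \code{txSpans} one
#' \code{GRanges} per transcript spanning first to last exon (with
#' \code{gene_id} metadata); \code{geneSpans} one strand-agnostic range per
#' gene locus (union span of its transcripts).
#'
#' @param x A [TranscriptCatalog-class].
#' @return See description.
#' @name catalog-accessors
NULL

#' @rdname catalog-accessors
#' @export
setGeneric("txIds", function(x) standardGeneric("txIds"))
#' @rdname catalog-accessors
#' @export
setMethod("txIds", "TranscriptCatalog", function(x)
  as.character(x@txData$transcript_id))

#' @rdname catalog-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname catalog-accessors
#' @export
setMethod("geneIds", "TranscriptCatalog", function(x)
  as.character(x@txData$gene_id))

#' @rdname catalog-accessors
#' @export
setGeneric("exonsByTx", function(x) standardGeneric("exonsByTx"))
#' @rdname catalog-accessors
#' @export
setMethod("exonsByTx", "TranscriptCatalog", function(x) x@exons)

#' @rdname catalog-accessors
#' @export
setGeneric("txSpans", function(x) standardGeneric("txSpans"))
#' @rdname catalog-accessors
#' @export
setMethod("txSpans", "TranscriptCatalog", function(x) {
  sp <- unlist(range(x@exons), use.names = TRUE)
  mcols(sp)$gene_id <- geneIds(x)
  sp
})

#' @rdname catalog-accessors
#' @export
setGeneric("geneSpans", function(x) standardGeneric("geneSpans"))
#' @rdname catalog-accessors
#' @export
setMethod("geneSpans", "TranscriptCatalog", function(x) {
  sp <- txSpans(x)
  spl <- S4Vectors::split(sp, mcols(sp)$gene_id)
  out <- unlist(range(spl, ignore.strand = TRUE), use.names = TRUE)
  out
})

#' @describeIn TranscriptCatalog Subset by index, logical, or transcript id.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "TranscriptCatalog", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    miss <- setdiff(i, txIds(x))
    if (length(miss))
      stop("unknown transcript ids: ", paste(miss, collapse = ", "))
    i <- match(i, txIds(x))
  }
  new("TranscriptCatalog", exons = x@exons[i], txData = x@txData[i, ])
})

#' SyntheticTruth: planted ground truth behind a simulated data set
#'
#' Records the labels planted by the synthetic-data generator so that every
#' downstream stage (funnel, specificity, cis correlation, modules, hubs) can
#' be scored against known truth.
#'
#' @slot transcripts \code{DataFrame}: per catalog transcript, its planted
#'   class, novelty label (\code{known}/\code{overlapping}/\code{intergenic}),
#'   coding label, the funnel stage it is designed to fail (\code{none} for
#'   true lincRNAs), and its specific tissue (\code{none} if broad or absent
#'   from the tissue panel).
#' @slot cisPairs \code{DataFrame}: planted neighbour pairs
#'   (\code{lincrna_id}, \code{mrna_id}, target Pearson \code{rho},
#'   \code{tss_distance} in bp).
#' @slot modules \code{DataFrame}: per stage-panel gene, its planted module
#'   (\code{noise} for unstructured genes), hub flag, and lincRNA flag.
#' @slot stageOfModule Named character: module id -> developmental stage whose
#'   samples carry the module's expression pulse.
#' @slot tissueFeatures \code{DataFrame}: features of the tissue panel with
#'   type (\code{lincRNA}/\code{mRNA}) and specific tissue (\code{none} =
#'   broadly expressed).
#' @export
setClass("SyntheticTruth",
         slots = c(transcripts = "DataFrame", cisPairs = "DataFrame",
                   modules = "DataFrame", stageOfModule = "character",
                   tissueFeatures = "DataFrame"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  m <- object@modules
  if (nrow(m)) {
    if (any(m$is_hub & m$module == "noise"))
      msg <- c(msg, "hub genes must belong to a module")
    planted <- setdiff(unique(m$module), "noise")
    if (!all(planted %in% names(object@stageOfModule)))
      msg <- c(msg, "every planted module needs a stage assignment")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@transcripts), "catalog transcripts;",
      nrow(object@cisPairs), "cis pairs;",
      nrow(object@modules), "stage-panel genes in",
      length(object@stageOfModule), "modules\n")
})

#' FilterReport: per-stage accounting of the lincRNA funnel
#'
#' The lincRNA filter funnel applies five stages in a fixed order:
#' removal of known/overlapping transcripts, the multi-exon rule (>= 2 exons),
#' the minimum spliced length rule (>= 200 nt), the minimum distance rule
#' (>= 500 bp from any annotated gene), and the coding-potential rule
#' (probability below threshold). The report records input/passed/removed
#' counts per stage and a per-transcript verdict with the first failing stage.
#'
#' @slot stages \code{data.frame} with columns \code{stage}, \code{input},
#'   \code{passed}, \code{removed}, one row per funnel stage in order.
#' @slot verdicts \code{DataFrame}: per transcript, \code{status}
#'   (\code{lincRNA} or \code{removed}) and \code{first_fail} stage
#'   (\code{none} for calls).
#' @slot thresholds Named numeric vector of the thresholds used.
#' @export
setClass("FilterReport",
         slots = c(stages = "data.frame", verdicts = "DataFrame",
                   thresholds = "numeric"))

setValidity("FilterReport", function(object) {
  st <- object@stages
  msg <- character()
  if (nrow(st)) {
    if (any(st$input != st$passed + st$removed))
      msg <- c(msg, "stage conservation violated: input != passed + removed")
    if (nrow(st) > 1 && any(st$passed[-nrow(st)] != st$input[-1]))
      msg <- c(msg, "passed(stage k) must equal input(stage k+1)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:", object@stages$input[1], "transcripts in ->",
      finalCount(object), "lincRNAs\n")
  print(object@stages, row.names = FALSE)
})

#' @describeIn FilterReport The per-stage count table.
#' @param x,object A FilterReport.
#' @export
setGeneric("filterStages", function(x) standardGeneric("filterStages"))
#' @rdname FilterReport-class
#' @export
setMethod("filterStages", "FilterReport", function(x) x@stages)

#' @describeIn FilterReport Per-transcript verdicts.
#' @export
setGeneric("filterVerdicts", function(x) standardGeneric("filterVerdicts"))
#' @rdname FilterReport-class
#' @export
setMethod("filterVerdicts", "FilterReport", function(x) x@verdicts)

#' @describeIn FilterReport Number of transcripts passing the whole funnel.
#' @export
setGeneric("finalCount", function(x) standardGeneric("finalCount"))
#' @rdname FilterReport-class
#' @export
setMethod("finalCount", "FilterReport", function(x)
  x@stages$passed[nrow(x@stages)])

#' @describeIn FilterReport Transcript ids called as lincRNAs.
#' @export
setGeneric("lincRNAIds", function(x) standardGeneric("lincRNAIds"))
#' @rdname FilterReport-class
#' @export
setMethod("lincRNAIds", "FilterReport", function(x)
  as.character(x@verdicts$transcript_id[x@verdicts$status == "lincRNA"]))
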
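#' Read a transcript catalog from a GTF file
#'
#' Parses exon features, groups them by \code{transcript_id}, and assembles a
#' [TranscriptCatalog-class]. Exon lines may appear in any order; coordinates
#' follow the GTF convention (1-based, inclusive) and are held as
#' \code{GRanges}.
#'
#' @param path Path to a GTF file with \code{exon} features carrying
#'   \code{transcript_id} and \code{gene_id} attributes.
#' @return A [TranscriptCatalog-class].
#' @examples
#' cfg <- simulationConfig(seed = 7, n_reference_genes = 4)
#' ann <- simulateAnnotation(cfg)
#' f <- tempfile(fileext = ".gtf")
#' writeTranscriptGTF(ann$reference, f)
#' readTranscriptGTF(f)
#' @export
readTranscriptGTF <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features in ", path)
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id)) {
    bad <- if (is.null(gr$transcript_id)) seq_along(gr) else
      which(is.na(gr$transcript_id))
    stop("exon feature(s) without transcript_id (record ",
         paste(utils::head(bad, 5), collapse = ", "), ")")
  }
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("exon feature(s) without gene_id")
  ex <- GenomicRanges::split(GenomicRanges::granges(gr),
                             factor(gr$transcript_id,
                                    levels = unique(gr$transcript_id)))
  gid <- vapply(split(as.character(gr$gene_id), factor(
    gr$transcript_id, levels = unique(gr$transcript_id))),
    function(g) g[1], character(1))
  TranscriptCatalog(ex, geneIds = gid)
}

#' Write a transcript catalog to a GTF file
#'
#' Emits one \code{exon} line per exon in transcript order, suitable for
#' round-tripping through [readTranscriptGTF()].
#'
#' @param catalog A [TranscriptCatalog-class].
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return \code{path}, invisibly.
#' @export
writeTranscriptGTF <- function(catalog, path, source = "lincnet") {
  ex <- exonsByTx(catalog)
  flat <- unlist(ex, use.names = FALSE)
  n <- lengths(ex)
  mcols(flat) <- DataFrame(
    source = source, type = "exon",
    gene_id = rep(geneIds(catalog), n),
    transcript_id = rep(txIds(catalog), n))
  rtracklayer::export(flat, path, format = "gtf")
  invisible(path)
}
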
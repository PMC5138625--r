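#' The lincRNA filter funnel
#'
#' Applies the five-stage intergenic-lncRNA filter in fixed order:
#' \enumerate{
#'   \item \code{known_removal}: drop transcripts classified
#'     \code{known_match} or \code{exonic_overlap} against the reference
#'     (see [classifyNovelty()]);
#'   \item \code{multi_exon}: keep transcripts with >= \code{minExons} exons;
#'   \item \code{min_length}: keep spliced length >= \code{minLength} nt;
#'   \item \code{min_distance}: keep transcripts >= \code{minDistance} bp
#'     away from every annotated gene locus (strand-agnostic span distance);
#'   \item \code{noncoding}: keep transcripts whose coding probability under
#'     \code{model} is below the model's threshold.
#' }
#' The order matters and is part of the contract: counts at each stage are
#' reported, and each transcript's verdict records the first stage it failed.
#'
#' @param catalog Merged-assembly [TranscriptCatalog-class].
#' @param reference Annotation [TranscriptCatalog-class].
#' @param sequences Named character vector or \code{DNAStringSet} of
#'   transcript sequences covering every catalog transcript.
#' @param model A \code{codingModel} from [trainCodingModel()].
#' @param hexamerTable Hexamer table used for the model's features.
#' @param minExons,minLength,minDistance Funnel thresholds (defaults 2 exons,
#'   200 nt, 500 bp).
#' @return A list with \code{calls} (a [TranscriptCatalog-class] of the
#'   transcripts passing all stages) and \code{report}
#'   (a [FilterReport-class]).
#' @export
classifyLincRNAs <- function(catalog, reference, sequences, model,
                             hexamerTable, minExons = 2L, minLength = 200L,
                             minDistance = 500L) {
  ids <- txIds(catalog)
  seqs <- .asSeqChar(sequences)
  missing <- setdiff(ids, names(seqs))
  if (length(missing))
    stop("transcripts missing from the sequence set: ",
         paste(utils::head(missing, 10), collapse = ", "))
  seqs <- seqs[ids]

  alive <- rep(TRUE, length(ids))
  firstFail <- rep("none", length(ids))
  stageNames <- c("known_removal", "multi_exon", "min_length",
                  "min_distance", "noncoding")
  input <- passed <- integer(length(stageNames))

  fail <- function(stage, bad) {
    firstFail[alive & bad] <<- stage
    alive <<- alive & !bad
  }

  nov <- classifyNovelty(catalog, reference)
  st <- transcriptStats(catalog)
  dist <- distanceToNearestGene(catalog, reference)

  stageFail <- list(
    known_removal = nov$status != "novel",
    multi_exon = st$exon_count < minExons,
    min_length = st$transcript_length < minLength,
    min_distance = dist < minDistance)

  for (k in seq_along(stageFail)) {
    input[k] <- sum(alive)
    fail(stageNames[k], stageFail[[k]])
    passed[k] <- sum(alive)
  }

  ## coding potential only for survivors (verdicts are unaffected: earlier
  ## failures already carry their first failing stage)
  input[5] <- sum(alive)
  if (any(alive)) {
    fx <- codingFeatures(seqs[alive], hexamerTable)
    p <- codingProbability(fx, model)
    coding <- rep(FALSE, length(ids))
    coding[alive] <- p >= model$threshold
    fail("noncoding", coding)
  }
  passed[5] <- sum(alive)

  report <- new("FilterReport",
                stages = data.frame(stage = stageNames, input = input,
                                    passed = passed,
                                    removed = input - passed),
                verdicts = DataFrame(
                  transcript_id = ids,
                  status = ifelse(alive, "lincRNA", "removed"),
                  first_fail = firstFail),
                thresholds = c(min_exons = minExons, min_length = minLength,
                               min_distance = minDistance,
                               coding_threshold = model$threshold))
  list(calls = catalog[which(alive)], report = report)
}

#' Write a FilterReport to TSV and JSON
#'
#' @param report A [FilterReport-class].
#' @param prefix Output path prefix; writes \code{<prefix>_stages.tsv},
#'   \code{<prefix>_verdicts.tsv} and \code{<prefix>.json}.
#' @return Invisibly, the written paths.
#' @export
writeFilterReport <- function(report, prefix) {
  stagesPath <- paste0(prefix, "_stages.tsv")
  verdictsPath <- paste0(prefix, "_verdicts.tsv")
  jsonPath <- paste0(prefix, ".json")
  utils::write.table(filterStages(report), stagesPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(filterVerdicts(report)), verdictsPath,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(stages = filterStages(report),
         thresholds = as.list(report@thresholds),
         lincRNA_count = finalCount(report)),
    jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(stagesPath, verdictsPath, jsonPath))
}
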
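#' Fisher-exact term enrichment of a gene list
#'
#' For each annotation term, tests over-representation of the term's genes in
#' the module list against a background universe with a one-sided (greater)
#' Fisher exact test — the hypergeometric tail P(X >= k) for the 2x2 table
#' (k in-module annotated, n module size, K background annotated,
#' N background size). P-values are Benjamini-Hochberg adjusted within each
#' term category.
#'
#' @param moduleGenes Character vector of genes of interest (must be a subset
#'   of \code{background}).
#' @param background Character vector: the gene universe.
#' @param annotations \code{data.frame} with columns \code{term} and
#'   \code{gene}; genes outside the background are ignored.
#' @param termMeta Optional \code{data.frame} with columns \code{term},
#'   \code{name}, \code{category} (e.g. BP/MF/CC). Without it, all terms
#'   share one category.
#' @param adjust Apply BH adjustment (default TRUE).
#' @return \code{data.frame}: \code{term}, \code{name}, \code{category},
#'   \code{k}, \code{n}, \code{K}, \code{N}, \code{fold_enrichment},
#'   \code{p}, \code{p_adjusted}, sorted by p then term; terms with no
#'   annotated background gene are skipped (recorded in attribute
#'   \code{"skipped"}).
#' @examples
#' ann <- data.frame(term = rep("T1", 10), gene = paste0("g", 1:10))
#' fisherEnrichment(paste0("g", 1:10), paste0("g", 1:100), ann)
#' @export
fisherEnrichment <- function(moduleGenes, background, annotations,
                             termMeta = NULL, adjust = TRUE) {
  moduleGenes <- unique(as.character(moduleGenes))
  background <- unique(as.character(background))
  if (!length(moduleGenes)) stop("empty module gene list")
  out <- setdiff(moduleGenes, background)
  if (length(out))
    stop("module genes missing from background: ",
         paste(utils::head(out, 5), collapse = ", "))
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(moduleGenes)
  termGenes <- split(unique(ann[c("term", "gene")])$gene,
                     unique(ann[c("term", "gene")])$term)
  skipped <- setdiff(unique(as.character(annotations$term)),
                     names(termGenes))
  res <- do.call(rbind, lapply(names(termGenes), function(tm) {
    g <- termGenes[[tm]]
    K <- length(g)
    k <- sum(moduleGenes %in% g)
    ## one-sided hypergeometric upper tail P(X >= k)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N), p = p)
  }))
  if (is.null(res))
    res <- data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(),
                      fold_enrichment = numeric(), p = numeric())
  if (!is.null(termMeta)) {
    m <- match(res$term, termMeta$term)
    res$name <- termMeta$name[m]
    res$category <- termMeta$category[m]
  } else {
    res$name <- res$term
    res$category <- "all"
  }
  res$p_adjusted <- res$p
  if (adjust && nrow(res))
    for (cc in unique(res$category)) {
      i <- res$category == cc
      res$p_adjusted[i] <- stats::p.adjust(res$p[i], method = "BH")
    }
  res <- res[order(res$p, res$term),
             c("term", "name", "category", "k", "n", "K", "N",
               "fold_enrichment", "p", "p_adjusted")]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
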
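## Signed weighted co-expression network, built from scratch: pretreatment,
## soft-threshold selection against scale-free topology, signed adjacency,
## topological overlap, average-linkage clustering with a static branch cut,
## module eigengenes, eigengene-correlation module merging, module-stage
## association, and kME-based hub extraction.

#' Pretreat an FPKM stage panel for network construction
#'
#' Three steps: (1) drop genes whose maximum FPKM across samples is below
#' \code{minMaxFpkm}; (2) of the remainder, keep the top
#' \code{varianceQuantileKept} fraction by variance (computed on the log
#' scale); (3) transform to log2(FPKM + \code{offset}).
#'
#' @param se Expression panel from [makeExpressionPanel()].
#' @param minMaxFpkm Maximum-expression floor (default 0.05).
#' @param varianceQuantileKept Fraction of genes kept by variance
#'   (default 0.75).
#' @param offset Added before log2 (default 1).
#' @return Numeric matrix genes x samples of log2(FPKM + offset), with
#'   attribute \code{"dropped"} = c(low_expression = ..., low_variance = ...).
#' @export
preprocessExpression <- function(se, minMaxFpkm = 0.05,
                                 varianceQuantileKept = 0.75, offset = 1) {
  stopifnot(varianceQuantileKept > 0, varianceQuantileKept <= 1)
  f <- .fpkm(se)
  keep1 <- apply(f, 1, max) >= minMaxFpkm
  f1 <- f[keep1, , drop = FALSE]
  if (!nrow(f1)) stop("all genes removed by the expression floor")
  lg <- log2(f1 + offset)
  v <- apply(lg, 1, stats::var)
  nKeep <- ceiling(varianceQuantileKept * length(v))
  keep2 <- rank(-v, ties.method = "first") <= nKeep
  out <- lg[keep2, , drop = FALSE]
  attr(out, "dropped") <- c(low_expression = sum(!keep1),
                            low_variance = sum(!keep2))
  out
}

#' Signed adjacency matrix
#'
#' a_ij = ((1 + cor_ij) / 2)^beta with Pearson correlation across samples —
#' the signed soft-thresholding transform (cor 1 -> 1, cor -1 -> 0,
#' cor 0 -> 0.5^beta).
#'
#' @param expr Matrix genes x samples (typically [preprocessExpression()]
#'   output).
#' @param beta Soft-thresholding power (>= 1).
#' @return Symmetric genes x genes matrix in [0, 1], diagonal 1.
#' @export
signedAdjacency <- function(expr, beta = 13) {
  stopifnot(beta >= 1)
  v <- apply(expr, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "),
         " (remove in preprocessing)")
  a <- ((1 + stats::cor(t(expr))) / 2)^beta
  diag(a) <- 1
  a
}

## connectivity: row sums of adjacency excluding the diagonal
.connectivity <- function(a) rowSums(a) - diag(a)

#' Pick a soft-thresholding power by scale-free topology fit
#'
#' For each candidate power, builds the signed adjacency, computes
#' connectivity k, bins k into \code{nBins} equal-width bins over its range,
#' regresses log10(bin frequency) on log10(bin mean k), and takes the signed
#' fit R^2 x sign(-slope) — the standard scale-free topology index. The
#' chosen power is the smallest reaching \code{targetR2}; if none does, the
#' power with maximal signed fit is returned with a warning.
#'
#' @param expr Matrix genes x samples.
#' @param powers Candidate powers (default 1:20).
#' @param targetR2 Scale-free fit target (default 0.9).
#' @param nBins Number of connectivity bins (default 10).
#' @return List: \code{beta}, \code{reached} (logical), \code{fit}
#'   (data.frame power / r_squared / slope / mean_k).
#' @export
pickSoftThreshold <- function(expr, powers = 1:20, targetR2 = 0.9,
                              nBins = 10) {
  corr <- stats::cor(t(expr))
  base <- (1 + corr) / 2
  fit <- data.frame(power = powers, r_squared = NA_real_,
                    slope = NA_real_, mean_k = NA_real_)
  for (i in seq_along(powers)) {
    a <- base^powers[i]
    diag(a) <- 1
    k <- .connectivity(a)
    fit$mean_k[i] <- mean(k)
    if (stats::sd(k) == 0) next  # degenerate: fit undefined, recorded as NA
    bins <- cut(k, breaks = nBins, include.lowest = TRUE)
    dk <- tapply(k, bins, mean)
    pk <- tapply(k, bins, length) / length(k)
    ok <- !is.na(dk) & dk > 0
    if (sum(ok) < 3) next
    lmfit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
    r2 <- summary(lmfit)$r.squared
    sl <- stats::coef(lmfit)[2]
    fit$slope[i] <- sl
    fit$r_squared[i] <- r2 * sign(-sl)
  }
  hits <- which(!is.na(fit$r_squared) & fit$r_squared >= targetR2)
  if (length(hits)) {
    list(beta = powers[hits[1]], reached = TRUE, fit = fit)
  } else {
    warning("no candidate power reaches the scale-free target R^2 = ",
            targetR2, "; returning the best fit")
    best <- which.max(fit$r_squared)
    list(beta = powers[best], reached = FALSE, fit = fit)
  }
}

#' Topological overlap matrix
#'
#' t_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij), with
#' l_ij = sum_u a_iu a_uj over u != i, j, the unsigned TOM of a weighted
#' network; diagonal set to 1.
#'
#' @param a Adjacency matrix from [signedAdjacency()].
#' @return Symmetric matrix in [0, 1] with unit diagonal.
#' @export
tomSimilarity <- function(a) {
  stopifnot(nrow(a) == ncol(a))
  adj <- a
  diag(adj) <- 0
  l <- adj %*% adj          # includes no i/j terms since diagonal is 0
  k <- rowSums(adj)
  kmin <- outer(k, k, pmin)
  t <- (l + adj) / (kmin + 1 - adj)
  diag(t) <- 1
  dimnames(t) <- dimnames(a)
  t
}

#' Detect modules on the TOM dendrogram
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM,
#' followed by a static branch cut at a quantile of the merge heights;
#' branches smaller than \code{minModuleSize} are labelled
#' \code{"unassigned"}. Modules are labelled \code{M1}, \code{M2}, ... in
#' decreasing size order (ties broken by first member). The default cut
#' quantile of 0.90 places the cut below the late merges at which
#' unstructured genes join the tree, so noise stays unassigned rather than
#' being absorbed into the last surviving branches.
#'
#' @param tom TOM matrix from [tomSimilarity()].
#' @param minModuleSize Minimum branch size to become a module (default 30).
#' @param cutHeightQuantile Quantile of dendrogram merge heights at which to
#'   cut (default 0.90).
#' @return List: \code{assignment} (named character vector), \code{dendro}
#'   (hclust object), \code{cut_height}.
#' @export
cutModules <- function(tom, minModuleSize = 30, cutHeightQuantile = 0.90) {
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  if (nrow(tom) <= minModuleSize) {
    warning("fewer genes than minModuleSize; all genes unassigned")
    assignment <- rep("unassigned", nrow(tom))
    names(assignment) <- rownames(tom)
    return(list(assignment = assignment, dendro = hc, cut_height = NA_real_))
  }
  h <- as.numeric(stats::quantile(hc$height, cutHeightQuantile))
  raw <- stats::cutree(hc, h = h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= minModuleSize]
  assignment <- rep("unassigned", length(raw))
  names(assignment) <- rownames(tom)
  if (length(keep)) {
    ord <- order(-sizes[keep], vapply(keep, function(g)
      min(which(raw == as.integer(g))), numeric(1)))
    for (j in seq_along(ord)) {
      g <- keep[ord[j]]
      assignment[raw == as.integer(g)] <- paste0("M", j)
    }
  }
  list(assignment = assignment, dendro = hc, cut_height = h)
}

#' Module eigengenes
#'
#' The first principal component of each module's standardized expression,
#' as a unit-norm vector over samples, sign-oriented so that its correlation
#' with the module's mean expression profile is non-negative. The
#' explained-variance fraction is reported per module.
#'
#' @param expr Matrix genes x samples.
#' @param assignment Named module labels from [cutModules()];
#'   \code{"unassigned"} is skipped.
#' @return List: \code{eigengenes} (samples x modules matrix),
#'   \code{var_explained} (named numeric).
#' @export
moduleEigengenes <- function(expr, assignment) {
  mods <- setdiff(sort(unique(assignment)), "unassigned")
  if (!length(mods)) stop("no modules to summarize")
  E <- matrix(NA_real_, ncol(expr), length(mods),
              dimnames = list(colnames(expr), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- names(assignment)[assignment == m]
    if (length(genes) < 2L)
      stop("module ", m, " has fewer than 2 genes")
    x <- scale(t(expr[genes, , drop = FALSE]))  # samples x genes
    sv <- svd(x, nu = 1, nv = 0)
    e <- sv$u[, 1]
    meanProf <- rowMeans(x)
    if (stats::cor(e, meanProf) < 0) e <- -e
    E[, m] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = E, var_explained = ve)
}

#' Merge modules with correlated eigengenes
#'
#' Iteratively merges the module pair with the highest eigengene correlation
#' above \code{threshold} (ties broken by label order), recomputing
#' eigengenes after every merge, until no pair exceeds the threshold.
#' Idempotent at the fixpoint.
#'
#' @param expr Matrix genes x samples.
#' @param assignment Named module labels.
#' @param threshold Merge when eigengene correlation > threshold
#'   (default 0.7, strict).
#' @return Updated named assignment vector (merged modules keep the
#'   alphabetically first of the two labels).
#' @export
mergeModules <- function(expr, assignment, threshold = 0.7) {
  repeat {
    mods <- setdiff(sort(unique(assignment)), "unassigned")
    if (length(mods) < 2L) return(assignment)
    E <- moduleEigengenes(expr, assignment)$eigengenes[, mods, drop = FALSE]
    cc <- stats::cor(E)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)
    if (max(cc) <= threshold) return(assignment)
    ## deterministic tie-break: smallest row label, then column label
    best <- best[order(rownames(cc)[best[, 1]], colnames(cc)[best[, 2]]), ,
                 drop = FALSE]
    a <- rownames(cc)[best[1, 1]]; b <- colnames(cc)[best[1, 2]]
    keepLab <- min(a, b); dropLab <- max(a, b)
    assignment[assignment == dropLab] <- keepLab
  }
}

#' Module-stage association statistics
#'
#' Correlates each module eigengene with a one-hot indicator of each stage
#' (1 for samples of that stage, 0 otherwise); the p-value is the two-sided
#' Student-t test of the correlation with n - 2 degrees of freedom.
#'
#' @param eigengenes Samples x modules matrix from [moduleEigengenes()].
#' @param stages Character/factor vector of stage per sample (>= 4 samples,
#'   > 2 required).
#' @return \code{data.frame}: \code{module}, \code{stage}, \code{r},
#'   \code{p}.
#' @export
moduleStageStats <- function(eigengenes, stages) {
  n <- nrow(eigengenes)
  if (n <= 2L) stop("need more than 2 samples for correlation p-values")
  stages <- as.character(stages)
  if (length(stages) != n) stop("stages must cover every sample")
  lev <- unique(stages)
  out <- expand.grid(module = colnames(eigengenes), stage = lev,
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    ind <- as.numeric(stages == out$stage[i])
    r <- stats::cor(eigengenes[, out$module[i]], ind)
    tval <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    out$r[i] <- r
    out$p[i] <- min(2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE), 1)
  }
  out
}

#' Stage-specific modules
#'
#' A module is specific to a stage when its eigengene-stage correlation
#' exceeds \code{rThreshold} with p below \code{pThreshold}.
#'
#' @param stats Output of [moduleStageStats()].
#' @param rThreshold Correlation threshold (default 0.7, strict).
#' @param pThreshold P-value threshold (default 1e-4, strict).
#' @return \code{data.frame} of the qualifying module/stage rows.
#' @export
stageSpecificModules <- function(stats, rThreshold = 0.7, pThreshold = 1e-4) {
  out <- stats[stats$r > rThreshold & stats$p < pThreshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Module membership (kME) and hub genes
#'
#' kME of gene i for module q is the Pearson correlation of the gene's
#' expression profile with the module eigengene. Hubs are the \code{topN}
#' module members by kME (descending, ties by gene id). When a module has
#' fewer members than \code{topN} the whole module is emitted with a note.
#'
#' @param expr Matrix genes x samples.
#' @param eigengenes Samples x modules matrix.
#' @param assignment Named module labels.
#' @param topN Hub count per module (default 100).
#' @param isLinc Optional named logical flagging lincRNA genes.
#' @return List: \code{kme} (genes x modules matrix), \code{hubs}
#'   (data.frame module / gene_id / kme / rank / is_linc), \code{notes}.
#' @export
kmeHubs <- function(expr, eigengenes, assignment, topN = 100,
                    isLinc = NULL) {
  kme <- stats::cor(t(expr), eigengenes)
  mods <- colnames(eigengenes)
  notes <- character()
  hubs <- do.call(rbind, lapply(mods, function(m) {
    members <- names(assignment)[assignment == m]
    if (!length(members)) return(NULL)
    v <- kme[members, m]
    ord <- order(-v, members)
    n <- min(topN, length(members))
    if (length(members) < topN)
      notes <<- c(notes, paste0(m, ": only ", length(members),
                                " members (topN = ", topN, ")"))
    g <- members[ord[seq_len(n)]]
    data.frame(module = m, gene_id = g, kme = v[ord[seq_len(n)]],
               rank = seq_len(n),
               is_linc = if (is.null(isLinc)) NA else
                 unname(isLinc[g]))
  }))
  rownames(hubs) <- NULL
  list(kme = kme, hubs = hubs, notes = notes)
}

#' Pairwise network weights among selected genes
#'
#' Reports the signed-adjacency weight for every pair of the given genes —
#' the "weight" used when describing a hub gene's strongest neighbours.
#'
#' @param adjacency Matrix from [signedAdjacency()].
#' @param genes Gene ids to report.
#' @return \code{data.frame}: \code{gene_a}, \code{gene_b}, \code{weight},
#'   sorted by decreasing weight.
#' @export
hubNeighborWeights <- function(adjacency, genes) {
  genes <- intersect(genes, rownames(adjacency))
  if (length(genes) < 2L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      weight = numeric()))
  idx <- t(utils::combn(genes, 2))
  w <- adjacency[idx]
  out <- data.frame(gene_a = idx[, 1], gene_b = idx[, 2], weight = w)
  out[order(-out$weight, out$gene_a, out$gene_b), , drop = FALSE] |>
    (\(x) {rownames(x) <- NULL; x})()
}
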
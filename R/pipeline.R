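#' Simulate a term-to-gene annotation for enrichment
#'
#' Synthetic functional terms over the stage-panel genes: one marker term per
#' planted module (a fraction of its genes plus background contamination) and
#' a set of unstructured terms, so the Fisher-enrichment stage can be
#' exercised and scored.
#'
#' @param truth [SyntheticTruth-class] with module slots filled.
#' @param config The [simulationConfig()].
#' @param coverage Fraction of a module's genes carrying its marker term.
#' @param contamination Fraction of background genes carrying it.
#' @param nRandomTerms Unstructured terms drawn uniformly from all genes.
#' @return List: \code{annotations} (data.frame term/gene), \code{meta}
#'   (data.frame term/name/category).
#' @export
simulateTermAnnotation <- function(truth, config, coverage = 0.6,
                                   contamination = 0.05,
                                   nRandomTerms = 10) {
  mods <- as.data.frame(truth@modules)
  if (!nrow(mods)) stop("truth has no module table")
  .withSeed(config$seed + 4000003L, {
    rows <- list()
    planted <- setdiff(unique(mods$module), "noise")
    for (m in planted) {
      genes <- mods$gene_id[mods$module == m]
      others <- mods$gene_id[mods$module != m]
      hit <- sample(genes, round(coverage * length(genes)))
      noise <- sample(others, round(contamination * length(others)))
      rows[[m]] <- data.frame(term = paste0("TERM_", m),
                              gene = c(hit, noise))
    }
    for (i in seq_len(nRandomTerms)) {
      sz <- sample(10:40, 1)
      rows[[paste0("r", i)]] <- data.frame(
        term = sprintf("TERM_RAND%02d", i),
        gene = sample(mods$gene_id, sz))
    }
    ann <- do.call(rbind, rows)
    rownames(ann) <- NULL
    terms <- unique(ann$term)
    meta <- data.frame(term = terms, name = terms,
                       category = "BP")
    list(annotations = ann, meta = meta)
  })
}

#' Run the full analysis on simulated data
#'
#' End-to-end orchestration: simulate inputs, train the coding-potential
#' model, run the lincRNA funnel, score tissue specificity and detection
#' breadth, correlate planted cis pairs against a seeded random null, build
#' the co-expression network (preprocess, soft threshold, adjacency, TOM,
#' modules, merging, eigengenes), call stage-specific modules, extract kME
#' hubs, and test module term enrichment. All thresholds default to the
#' pipeline's canonical values (2 exons, 200 nt, 500 bp, coding 0.5,
#' 0.1 FPKM, 10 kb, 4 kb / 400 nt bins, 0.05 max-FPKM floor, top 75\%
#' variance, merge 0.7, stage rule r > 0.7 & p < 1e-4, top 100 hubs).
#'
#' @param config A [simulationConfig()]; its seed drives every stage.
#' @param outDir Optional directory: when given, artifacts and a JSON run
#'   manifest are written there.
#' @param softPower Soft-thresholding power (default 13, the canonical
#'   signed-network power), or \code{NULL} to select by scale-free fit.
#' @param minModuleSize Minimum module size for the tree cut (default 10,
#'   sized to the synthetic panel).
#' @param topHubs Hubs per stage-specific module (default 100).
#' @param codingThreshold Decision threshold of the coding model.
#' @return A list with every stage's result plus \code{manifest}.
#' @export
runPipeline <- function(config = simulationConfig(), outDir = NULL,
                        softPower = 13, minModuleSize = 10,
                        topHubs = 100, codingThreshold = 0.5) {
  sim <- simulatePipelineData(config, dir = outDir)

  ## coding model trained on generator sequences
  train <- simulateTrainingSequences(config, nPerClass = 300)
  hex <- trainHexamerTable(train$coding, train$noncoding)
  feats <- codingFeatures(c(train$coding, train$noncoding), hex)
  labels <- rep(c(TRUE, FALSE), each = 300)
  model <- trainCodingModel(feats, labels, threshold = codingThreshold)

  ## funnel
  cls <- classifyLincRNAs(sim$catalog, sim$reference, sim$sequences, model,
                          hex)

  ## expression specificity on the tissue panel
  breadth <- detectionBreadth(sim$tissues)
  spec <- specificityScore(sim$tissues)

  ## cis correlation: planted pairs, all mRNA:mRNA neighbour pairs, random
  lincCalls <- cls$calls
  pairsLM <- neighborPairs(lincCalls, geneSpans(sim$reference))
  cisPlanted <- as.data.frame(sim$truth@cisPairs)
  pl <- data.frame(id_a = cisPlanted$lincrna_id, id_b = cisPlanted$mrna_id,
                   class = "linc_mRNA")
  corCis <- pairCorrelations(sim$tissues, pl)
  corRandom <- randomPairNull(sim$tissues, nPairs = nrow(pl),
                              seed = config$seed + 5000003L,
                              exclude = pl)

  ## network on the stage panel
  expr <- preprocessExpression(sim$stages)
  sft <- if (is.null(softPower))
    pickSoftThreshold(expr) else list(beta = softPower, reached = NA,
                                      fit = NULL)
  adj <- signedAdjacency(expr, beta = sft$beta)
  tom <- tomSimilarity(adj)
  cut <- cutModules(tom, minModuleSize = minModuleSize)
  assignment <- mergeModules(expr, cut$assignment)
  eig <- moduleEigengenes(expr, assignment)
  stageStats <- moduleStageStats(eig$eigengenes, .conditions(sim$stages))
  specific <- stageSpecificModules(stageStats)
  isLinc <- stats::setNames(as.data.frame(sim$truth@modules)$is_linc,
                            as.data.frame(sim$truth@modules)$gene_id)
  hubs <- kmeHubs(expr, eig$eigengenes, assignment, topN = topHubs,
                  isLinc = isLinc)

  ## enrichment of each detected module against the preprocessed background
  termAnn <- simulateTermAnnotation(sim$truth, config)
  background <- rownames(expr)
  enrich <- lapply(setdiff(sort(unique(assignment)), "unassigned"),
                   function(m) fisherEnrichment(
                     names(assignment)[assignment == m], background,
                     termAnn$annotations, termAnn$meta))
  names(enrich) <- setdiff(sort(unique(assignment)), "unassigned")

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("lincnet")),
    catalog_size = length(sim$catalog),
    funnel = filterStages(cls$report),
    lincRNA_count = finalCount(cls$report),
    soft_power = sft$beta,
    soft_power_reached_target = sft$reached,
    genes_in_network = nrow(expr),
    modules_detected = length(setdiff(unique(assignment), "unassigned")),
    stage_specific_modules = nrow(specific),
    thresholds = list(min_exons = 2, min_length = 200, min_distance = 500,
                      coding_threshold = codingThreshold,
                      detection_fpkm = 0.1, neighbor_max_gap = 10000,
                      tss_window = 4000, tss_bin = 400,
                      preprocess_min_max_fpkm = 0.05,
                      preprocess_variance_kept = 0.75,
                      merge_threshold = 0.7, stage_r = 0.7, stage_p = 1e-4,
                      top_hubs = topHubs,
                      min_module_size = minModuleSize))
  res <- list(sim = sim, model = model, hexamerTable = hex,
              classification = cls, breadth = breadth, specificity = spec,
              neighborPairs = pairsLM, cisCorrelations = corCis,
              randomCorrelations = corRandom, expr = expr,
              softThreshold = sft, assignment = assignment,
              eigengenes = eig, stageStats = stageStats,
              stageSpecific = specific, hubs = hubs, enrichment = enrich,
              manifest = manifest)
  if (!is.null(outDir)) {
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    writeFilterReport(cls$report, file.path(outDir, "filter_report"))
    utils::write.table(
      data.frame(gene_id = names(assignment), module = assignment),
      file.path(outDir, "module_assignment.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(hubs$hubs, file.path(outDir, "hub_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(stageStats, file.path(outDir, "module_stage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
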
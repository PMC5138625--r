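test_that("generator is deterministic: same config gives identical files", {
  cfg <- simulationConfig(seed = 5, n_reference_genes = 8,
                          n_known_transcripts = 6, n_overlapping_novel = 6,
                          n_intergenic_noncoding = 8, n_intergenic_coding = 5,
                          n_decoy_single_exon = 3, n_decoy_short = 3,
                          n_decoy_close = 3, n_cis_pairs = 3)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  f1 <- simulatePipelineData(cfg, dir = d1)$files
  f2 <- simulatePipelineData(cfg, dir = d2)$files
  for (nm in names(f1))
    expect_identical(readBin(f1[[nm]], "raw", file.size(f1[[nm]])),
                     readBin(f2[[nm]], "raw", file.size(f2[[nm]])),
                     label = paste("bytes of", nm))
})

test_that("annotation respects gene counts and the intergenic gap floor", {
  cfg <- simulationConfig(seed = 2, n_reference_genes = 20,
                          intergenic_gap_range = c(1000, 50000))
  ann <- simulateAnnotation(cfg)
  expect_equal(length(unique(geneIds(ann$reference))), 20)
  ## independent interval sweep: scan gene spans per chromosome
  sp <- geneSpans(ann$reference)
  for (chr in unique(as.character(seqnames(sp)))) {
    s <- sp[seqnames(sp) == chr]
    s <- s[order(start(s))]
    if (length(s) > 1) {
      gaps <- start(s)[-1] - end(s)[-length(s)] - 1
      expect_true(all(gaps >= 1000))
    }
  }
  ## genome long enough for all genes
  chromLen <- setNames(Biostrings::width(ann$genome), names(ann$genome))
  expect_true(all(end(sp) <= chromLen[as.character(seqnames(sp))]))
})

test_that("zero reference genes give an empty annotation", {
  cfg <- simulationConfig(seed = 3, n_reference_genes = 0,
                          n_known_transcripts = 0, n_overlapping_novel = 0)
  ann <- simulateAnnotation(cfg)
  expect_equal(length(ann$reference), 0)
})

test_that("impossible placements raise explicit errors", {
  cfg <- simulationConfig(seed = 4, n_reference_genes = 2,
                          n_chromosomes = 1,
                          intergenic_gap_range = c(1200, 1500),
                          n_known_transcripts = 0, n_overlapping_novel = 0,
                          n_intergenic_noncoding = 10, n_cis_pairs = 0,
                          n_intergenic_coding = 0, n_decoy_single_exon = 0,
                          n_decoy_short = 0, n_decoy_close = 0)
  ann <- simulateAnnotation(cfg)
  expect_error(simulateTranscriptCatalog(ann, cfg), "placement impossible")
})

test_that("planted catalog classes have the structures they claim", {
  sim <- defaultSim()
  truth <- as.data.frame(sim$truth@transcripts)
  st <- transcriptStats(sim$catalog)
  nov <- classifyNovelty(sim$catalog, sim$reference)
  d <- distanceToNearestGene(sim$catalog, sim$reference)

  ## known transcripts carry a reference intron chain
  kn <- truth$transcript_id[truth$class == "known"]
  expect_true(all(nov$status[match(kn, nov$transcript_id)] == "known_match"))
  ## overlapping novels overlap on the same strand
  ov <- truth$transcript_id[truth$class == "overlapping"]
  expect_true(all(nov$status[match(ov, nov$transcript_id)] ==
                    "exonic_overlap"))
  ## lincRNAs: multi-exon, >= 200 nt, >= 500 bp away, intergenic
  li <- truth$transcript_id[truth$class == "lincRNA"]
  idx <- match(li, st$transcript_id)
  expect_true(all(st$exon_count[idx] >= 2))
  expect_true(all(st$transcript_length[idx] >= 200))
  expect_true(all(d[li] >= 500))
  expect_true(all(nov$status[match(li, nov$transcript_id)] == "novel"))
  ## decoys fail exactly their designed stage
  expect_true(all(st$exon_count[match(
    truth$transcript_id[truth$class == "decoy_single_exon"],
    st$transcript_id)] == 1))
  expect_true(all(st$transcript_length[match(
    truth$transcript_id[truth$class == "decoy_short"],
    st$transcript_id)] < 200))
  close <- truth$transcript_id[truth$class == "decoy_close"]
  expect_true(all(d[close] < 500 & d[close] > 0))
  ## both < 500 bp and >= 500 bp intergenic cases are represented
  interg <- truth$transcript_id[truth$novelty_label == "intergenic"]
  expect_true(any(d[interg] < 500) && any(d[interg] >= 500))
})

test_that("planted coding transcripts carry ORFs in range; noncoding are capped", {
  sim <- defaultSim()
  truth <- as.data.frame(sim$truth@transcripts)
  seqs <- as.character(sim$sequences)
  cod <- truth$transcript_id[truth$class == "intergenic_coding"]
  orfs <- vapply(seqs[cod], bruteLongestOrf, numeric(1))
  expect_true(all(orfs >= 300))
  non <- truth$transcript_id[truth$class == "lincRNA"]
  orfsN <- vapply(seqs[non], bruteLongestOrf, numeric(1))
  expect_true(all(orfsN <= 150))
})

test_that("transcript FASTA matches the genome at exon coordinates", {
  sim <- defaultSim()
  ids <- txIds(sim$catalog)[c(3, 80, 150)]
  for (id in ids) {
    ex <- exonsByTx(sim$catalog)[[id]]
    chr <- as.character(seqnames(ex)[1])
    pieces <- Biostrings::extractAt(sim$genome[[chr]], ranges(ex))
    s <- paste(as.character(pieces), collapse = "")
    if (as.character(strand(ex)[1]) == "-")
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    expect_identical(s, as.character(sim$sequences[[id]]))
  }
})

test_that("tissue panel realizes planted detection patterns", {
  sim <- defaultSim()
  tf <- as.data.frame(sim$truth@tissueFeatures)
  br <- detectionBreadth(sim$tissues)
  spec1 <- tf$feature_id[tf$specific_tissue != "none"]
  expect_true(all(br[spec1] == 1))
  broad <- tf$feature_id[tf$specific_tissue == "none"]
  expect_true(all(br[broad] == ncol(SummarizedExperiment::assay(sim$tissues))))
})

test_that("planted cis pairs achieve the target correlation on average", {
  rs <- vapply(1:100, function(s) {
    cfg <- simulationConfig(seed = s, n_tissues = 12)
    tp <- simulateTissuePanel(cfg)
    pl <- data.frame(id_a = tp$cisPairs$lincrna_id,
                     id_b = tp$cisPairs$mrna_id)
    mean(pairCorrelations(tp$panel, pl)$r)
  }, numeric(1))
  expect_true(abs(mean(rs) - 0.9) < 0.25)
})

test_that("doubling module noise lowers within-module correlation", {
  meanWithinCor <- function(noiseSd, seed) {
    cfg <- simulationConfig(seed = seed, module_noise_sd = noiseSd,
                            n_modules = 2, genes_per_module = 20,
                            n_noise_genes = 0)
    sp <- simulateStagePanel(cfg)
    lg <- log2(SummarizedExperiment::assay(sp$panel) + 1)
    mean(vapply(unique(sp$modules$module), function(m) {
      cc <- cor(t(lg[sp$modules$gene_id[sp$modules$module == m], ]))
      mean(cc[upper.tri(cc)])
    }, numeric(1)))
  }
  lo <- vapply(1:8, function(s) meanWithinCor(0.5, s), numeric(1))
  hi <- vapply(1:8, function(s) meanWithinCor(1.0, s), numeric(1))
  expect_true(all(hi < lo))
})

test_that("noise genes are mutually uncorrelated on average", {
  rs <- vapply(1:20, function(s) {
    cfg <- simulationConfig(seed = s, n_modules = 0, genes_per_module = 0,
                            n_noise_genes = 40)
    sp <- simulateStagePanel(cfg)
    lg <- log2(SummarizedExperiment::assay(sp$panel) + 1)
    cc <- cor(t(lg))
    mean(cc[upper.tri(cc)])
  }, numeric(1))
  se <- sd(rs) / sqrt(length(rs))
  expect_true(abs(mean(rs)) < 3 * se + 0.02)
})

test_that("hub genes belong to their modules and stages cover all modules", {
  sim <- defaultSim()
  mods <- as.data.frame(sim$truth@modules)
  expect_true(all(mods$module[mods$is_hub] != "noise"))
  expect_setequal(names(sim$truth@stageOfModule),
                  setdiff(unique(mods$module), "noise"))
  ## every truth id exists in the emitted panels / catalog
  expect_true(all(mods$gene_id %in%
                    rownames(SummarizedExperiment::assay(sim$stages))))
  tf <- as.data.frame(sim$truth@tissueFeatures)
  expect_true(all(tf$feature_id %in%
                    rownames(SummarizedExperiment::assay(sim$tissues))))
  expect_true(all(as.data.frame(sim$truth@transcripts)$transcript_id %in%
                    txIds(sim$catalog)))
})
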
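## Synthetic-data generator: emits a toy genome annotation, a merged-assembly
## style transcript catalog with planted coding/noncoding/decoy transcripts,
## tissue and developmental-stage FPKM panels with planted tissue-specific
## features, cis-correlated neighbour pairs and stage-specific co-expression
## modules with designated hubs — all with a SyntheticTruth record so every
## downstream stage can be scored.

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator, with defaults defining the
#' study conditions used throughout the package's tests. Counts are
#' per-catalog totals; ranges are inclusive.
#'
#' @param seed Integer master seed; all sub-generators derive from it, so a
#'   fixed config yields byte-identical outputs.
#' @param n_chromosomes,n_reference_genes Genome layout.
#' @param intergenic_gap_range bp range for gaps between reference genes.
#' @param n_known_transcripts Catalog copies of reference transcripts
#'   (terminal exons may be extended).
#' @param n_overlapping_novel Novel transcripts sharing exonic bases with a
#'   reference gene on the same strand.
#' @param n_intergenic_noncoding True lincRNAs: multi-exon, >= 200 nt spliced,
#'   >= \code{min_gene_distance} from every gene, noncoding.
#' @param n_intergenic_coding Intergenic transcripts carrying a planted ORF.
#' @param n_decoy_single_exon,n_decoy_short,n_decoy_close Decoys failing,
#'   respectively, the multi-exon, minimum-length and minimum-distance rules
#'   (and nothing earlier).
#' @param orf_length_range_coding nt range (multiples of 3 are drawn) for
#'   planted ORFs.
#' @param noncoding_orf_cap Longest residual ORF allowed in a noncoding
#'   sequence; longer chance ORFs are interrupted with stop codons.
#' @param min_gene_distance The distance rule the survivors satisfy (bp).
#' @param n_tissues Number of tissues (one library per tissue).
#' @param tissue_specific_fraction_linc,tissue_specific_fraction_mrna
#'   Fractions of (non-cis) lincRNAs/mRNAs planted as single-tissue specific.
#' @param n_cis_pairs Planted lincRNA:mRNA neighbour pairs with correlated
#'   expression.
#' @param cis_pair_correlation Target Pearson rho of planted pairs, in [0,1].
#' @param n_stages,replicates_per_stage Stage-panel design.
#' @param n_modules,genes_per_module,n_noise_genes Stage-panel structure.
#' @param module_noise_sd Gaussian noise sd (log2 units) around the module
#'   pulse profile.
#' @param hub_fraction Fraction of each module designated as hubs.
#' @param hub_noise_factor Hub noise sd = hub_noise_factor * module_noise_sd.
#' @return A classed list (\code{simulationConfig}).
#' @export
simulationConfig <- function(seed = 1L,
                             n_chromosomes = 3L,
                             n_reference_genes = 30L,
                             intergenic_gap_range = c(12000L, 40000L),
                             n_known_transcripts = 30L,
                             n_overlapping_novel = 30L,
                             n_intergenic_noncoding = 35L,
                             n_intergenic_coding = 30L,
                             n_decoy_single_exon = 20L,
                             n_decoy_short = 15L,
                             n_decoy_close = 20L,
                             orf_length_range_coding = c(300L, 900L),
                             noncoding_orf_cap = 150L,
                             min_gene_distance = 500L,
                             n_tissues = 8L,
                             tissue_specific_fraction_linc = 0.4,
                             tissue_specific_fraction_mrna = 0.1,
                             n_cis_pairs = 15L,
                             cis_pair_correlation = 0.9,
                             n_stages = 6L,
                             replicates_per_stage = 2L,
                             n_modules = 4L,
                             genes_per_module = 50L,
                             n_noise_genes = 100L,
                             module_noise_sd = 0.5,
                             hub_fraction = 0.1,
                             hub_noise_factor = 0.2) {
  cfg <- as.list(environment())
  counts <- c("n_chromosomes", "n_reference_genes", "n_known_transcripts",
              "n_overlapping_novel", "n_intergenic_noncoding",
              "n_intergenic_coding", "n_decoy_single_exon", "n_decoy_short",
              "n_decoy_close", "n_tissues", "n_cis_pairs", "n_stages",
              "replicates_per_stage", "n_modules", "genes_per_module",
              "n_noise_genes")
  for (nm in counts)
    if (cfg[[nm]] < 0) stop(nm, " must be >= 0")
  if (cfg$cis_pair_correlation < 0 || cfg$cis_pair_correlation > 1)
    stop("cis_pair_correlation must lie in [0, 1]")
  if (diff(intergenic_gap_range) < 0 || intergenic_gap_range[1] < 1)
    stop("invalid intergenic_gap_range")
  if (cfg$n_cis_pairs > cfg$n_intergenic_noncoding)
    stop("n_cis_pairs cannot exceed n_intergenic_noncoding")
  structure(cfg, class = "simulationConfig")
}

#' @export
print.simulationConfig <- function(x, ...) {
  cat("simulationConfig (seed ", x$seed, "): ",
      x$n_reference_genes, " reference genes on ", x$n_chromosomes,
      " chromosomes; catalog of ",
      x$n_known_transcripts + x$n_overlapping_novel +
        x$n_intergenic_noncoding + x$n_intergenic_coding +
        x$n_decoy_single_exon + x$n_decoy_short + x$n_decoy_close,
      " transcripts (", x$n_intergenic_noncoding, " true lincRNAs)\n",
      sep = "")
  invisible(x)
}

.BASES <- c("A", "C", "G", "T")

## deterministic skewed codon usage over the 61 non-stop codons: gives
## in-frame hexamers a real coding signal without an external corpus
.CODON_TABLE <- local({
  cods <- apply(expand.grid(.BASES, .BASES, .BASES,
                            stringsAsFactors = FALSE)[, 3:1],
                1, paste0, collapse = "")
  cods <- sort(cods)
  cods <- setdiff(cods, c("TAA", "TAG", "TGA"))
  w <- seq(0.2, 5, length.out = length(cods))
  w / sum(w)
  list(codons = cods, weights = w / sum(w))
})

.randSeq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                              collapse = "")

## coding sequence: UTR5 + ATG + biased codons + stop + UTR3
.makeCodingSeq <- function(total, orfLen) {
  stopifnot(orfLen %% 3 == 0, orfLen >= 9, total >= orfLen + 6)
  utr5 <- sample(3:(total - orfLen - 3), 1)
  utr3 <- total - orfLen - utr5
  body <- paste(sample(.CODON_TABLE$codons, orfLen / 3 - 2, replace = TRUE,
                       prob = .CODON_TABLE$weights), collapse = "")
  paste0(.randSeq(utr5), "ATG", body, sample(.STOPS, 1), .randSeq(utr3))
}

## noncoding sequence: uniform random with chance ORFs longer than the cap
## interrupted by stop codons in the ORF's own frame. "TAA" is used for the
## interruptions: it contains no G, so an insertion can never create a new
## ATG; residual cross-frame effects are handled by re-scanning until the
## longest ORF is below the cap.
.makeNoncodingSeq <- function(total, cap) {
  for (attempt in 1:20) {
    s <- .randSeq(total)
    for (iter in 1:100) {
      orf <- longestOrf(s)
      if (orf$length <= cap) return(s)
      ## random internal codon: a fixed insertion point can ping-pong
      ## between overlapping reading frames
      ncod <- orf$length / 3
      pos <- orf$start + 3 * sample(ncod - 2, 1)
      substr(s, pos, pos + 2) <- "TAA"
    }
  }
  stop("could not interrupt ORFs below ", cap, " nt in a ", total,
       " nt sequence")
}

## exon scaffold helpers -----------------------------------------------------

## place an exon chain starting at genomic position `start`
.exonChain <- function(chrom, start, widths, introns, strand) {
  starts <- start + cumsum(c(0, widths[-length(widths)] +
                               if (length(introns)) introns else integer()))
  GRanges(chrom, IRanges(start = starts, width = widths), strand = strand)
}

## split a spliced length into n exon widths (each >= 50 when possible)
.splitWidths <- function(total, n) {
  if (n == 1L) return(total)
  base <- total %/% n
  w <- rep(base, n)
  w[1] <- w[1] + total %% n
  w
}

## write a spliced sequence into the genome across an exon chain
.writeTxSeq <- function(genome, exons, spliced) {
  chrom <- as.character(GenomicRanges::seqnames(exons)[1])
  if (as.character(GenomicRanges::strand(exons)[1]) == "-")
    spliced <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(spliced)))
  offs <- cumsum(c(0, IRanges::width(exons)))
  s <- genome[[chrom]]
  for (i in seq_along(exons)) {
    piece <- substr(spliced, offs[i] + 1, offs[i + 1])
    s <- Biostrings::replaceAt(
      s, IRanges(GenomicRanges::start(exons)[i],
                 GenomicRanges::end(exons)[i]), piece)
  }
  genome[[chrom]] <- s
  genome
}

## extract the spliced sequence of an exon chain from the genome
.extractTxSeq <- function(genome, exons) {
  chrom <- as.character(GenomicRanges::seqnames(exons)[1])
  pieces <- Biostrings::extractAt(genome[[chrom]], IRanges::ranges(exons))
  s <- paste(as.character(pieces), collapse = "")
  if (as.character(GenomicRanges::strand(exons)[1]) == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Simulate a reference annotation and genome
#'
#' Places multi-exon reference genes chromosome by chromosome, separated by
#' intergenic gaps drawn from \code{intergenic_gap_range}, and emits a random
#' genome long enough to hold them, with a designed coding sequence written
#' into each gene's exons.
#'
#' @param config A [simulationConfig()].
#' @return List: \code{reference} ([TranscriptCatalog-class]), \code{genome}
#'   (\code{DNAStringSet}), \code{gaps} (\code{GRanges} of intergenic gaps
#'   with flanking gene ids in \code{mcols}).
#' @export
simulateAnnotation <- function(config) {
  .withSeed(config$seed, {
    nGenes <- config$n_reference_genes
    exList <- list(); gid <- character()
    gapRows <- list()
    chromLens <- integer(config$n_chromosomes)
    names(chromLens) <- sprintf("chr%d", seq_len(config$n_chromosomes))
    perChrom <- if (nGenes > 0)
      table(factor(rep(seq_len(config$n_chromosomes), length.out = nGenes),
                   levels = seq_len(config$n_chromosomes)))
    else integer(config$n_chromosomes)
    geneIdx <- 0L
    drawGap <- function() sample(
      seq(config$intergenic_gap_range[1], config$intergenic_gap_range[2]), 1)
    for (ci in seq_len(config$n_chromosomes)) {
      chrom <- names(chromLens)[ci]
      pos <- 1L
      prevGene <- NA_character_
      for (gi in seq_len(perChrom[ci])) {
        gap <- drawGap()
        gapRows[[length(gapRows) + 1L]] <- data.frame(
          chrom = chrom, start = pos, end = pos + gap - 1L,
          left_gene = prevGene, right_gene = NA_character_)
        geneStart <- pos + gap
        geneIdx <- geneIdx + 1L
        id <- sprintf("G%04d", geneIdx)
        gapRows[[length(gapRows)]]$right_gene <- id
        nEx <- sample(4:9, 1)
        widths <- sample(120:400, nEx, replace = TRUE)
        introns <- sample(500:3000, max(nEx - 1, 0), replace = TRUE)
        strand <- sample(c("+", "-"), 1)
        ex <- .exonChain(chrom, geneStart, widths, introns, strand)
        exList[[paste0(id, ".T1")]] <- ex
        gid <- c(gid, id)
        pos <- max(GenomicRanges::end(ex)) + 1L
        prevGene <- id
      }
      gap <- drawGap()
      gapRows[[length(gapRows) + 1L]] <- data.frame(
        chrom = chrom, start = pos, end = pos + gap - 1L,
        left_gene = prevGene, right_gene = NA_character_)
      chromLens[ci] <- pos + gap - 1L
    }
    genome <- Biostrings::DNAStringSet(vapply(chromLens, .randSeq,
                                              character(1)))
    names(genome) <- names(chromLens)
    reference <- if (length(exList))
      TranscriptCatalog(GRangesList(exList), geneIds = gid)
    else
      new("TranscriptCatalog", exons = GRangesList(),
          txData = DataFrame(transcript_id = character(),
                             gene_id = character()))
    ## designed coding content for each reference transcript
    for (i in seq_along(exList)) {
      L <- sum(IRanges::width(exList[[i]]))
      orfLen <- 3 * sample(50:floor((L - 80) / 3), 1)
      orfLen <- min(orfLen, 3 * floor((L - 80) / 3))
      genome <- .writeTxSeq(genome, exList[[i]], .makeCodingSeq(L, orfLen))
    }
    gapsDf <- if (length(gapRows)) do.call(rbind, gapRows) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 left_gene = character(), right_gene = character())
    gaps <- GRanges(gapsDf$chrom, IRanges(gapsDf$start, gapsDf$end))
    mcols(gaps)$left_gene <- gapsDf$left_gene
    mcols(gaps)$right_gene <- gapsDf$right_gene
    list(reference = reference, genome = genome, gaps = gaps)
  })
}

## interval allocator inside intergenic gaps ---------------------------------

## occupied: per-gap list of matrices [start, end]; returns slot or NULL
.fitInGap <- function(gapStart, gapEnd, occ, width, margin, spacing = 150) {
  s <- gapStart + margin
  lim <- gapEnd - margin
  occ <- occ[order(occ[, 1]), , drop = FALSE]
  for (i in seq_len(nrow(occ) + 1)) {
    e <- s + width - 1
    if (e > lim) return(NULL)
    blocked <- FALSE
    if (nrow(occ)) {
      hit <- which(occ[, 1] <= e + spacing & occ[, 2] >= s - spacing)
      if (length(hit)) {
        s <- max(occ[hit, 2]) + spacing + 1
        blocked <- TRUE
      }
    }
    if (!blocked) return(c(s, e))
  }
  NULL
}

#' Simulate a merged transcript catalog with planted truth
#'
#' Builds the catalog the lincRNA funnel consumes: known copies of reference
#' transcripts (with extended terminal exons), same-strand exonic-overlap
#' novels, true intergenic noncoding lincRNAs (a subset planted as cis
#' neighbours of reference genes), intergenic coding transcripts, and decoys
#' engineered to fail exactly one funnel stage each. Designed transcript
#' sequences are written into the genome so genome, catalog GTF and
#' transcript FASTA agree.
#'
#' @param annotation Output of [simulateAnnotation()].
#' @param config The same [simulationConfig()].
#' @return List: \code{catalog} ([TranscriptCatalog-class]),
#'   \code{sequences} (\code{DNAStringSet}, spliced, sense strand),
#'   \code{truth} ([SyntheticTruth-class] — module slots filled by
#'   [simulateExpression()]), \code{genome} (updated \code{DNAStringSet}).
#' @export
simulateTranscriptCatalog <- function(annotation, config) {
  reference <- annotation$reference
  if (!length(reference) &&
      (config$n_known_transcripts > 0 || config$n_overlapping_novel > 0))
    stop("reference must be non-empty to draw known/overlapping transcripts")
  .withSeed(config$seed + 1000003L, {
    genome <- annotation$genome
    gaps <- annotation$gaps
    occ <- lapply(seq_along(gaps), function(i) matrix(numeric(), 0, 2))
    exList <- list(); gid <- character()
    classRows <- list()
    cisRows <- list()
    designedSeq <- list()   # tx id -> spliced sequence (for intergenic)
    txCounter <- 0L
    nextId <- function() {
      txCounter <<- txCounter + 1L
      sprintf("TCONS_%05d", txCounter)
    }
    refEx <- exonsByTx(reference)
    refSpans <- if (length(reference)) txSpans(reference) else GRanges()
    geneSpan <- if (length(reference)) geneSpans(reference) else GRanges()

    addTx <- function(id, ex, gene, class, novelty, codingLab, stage,
                      seq = NULL) {
      exList[[id]] <<- GenomicRanges::sort(ex)
      gid <<- c(gid, gene)
      classRows[[id]] <<- data.frame(
        transcript_id = id, class = class, novelty_label = novelty,
        coding_label = codingLab, expected_stage = stage)
      if (!is.null(seq)) designedSeq[[id]] <<- seq
    }

    ## -- known copies (terminal exons may be extended) ----------------------
    if (config$n_known_transcripts > 0) {
      pick <- sample(length(reference), config$n_known_transcripts,
                     replace = config$n_known_transcripts > length(reference))
      for (j in pick) {
        ex <- refEx[[j]]
        ext5 <- sample(0:100, 1); ext3 <- sample(0:100, 1)
        GenomicRanges::start(ex)[1] <-
          max(1, GenomicRanges::start(ex)[1] - ext5)
        GenomicRanges::end(ex)[length(ex)] <-
          GenomicRanges::end(ex)[length(ex)] + ext3
        addTx(nextId(), ex, geneIds(reference)[j], "known", "known",
              "coding", "known_removal")
      }
    }

    ## -- same-strand exonic-overlap novels ---------------------------------
    if (config$n_overlapping_novel > 0) {
      for (j in sample(length(reference), config$n_overlapping_novel,
                       replace = config$n_overlapping_novel >
                         length(reference))) {
        ex <- refEx[[j]]
        k <- sample(length(ex) - 1, 1)  # exon with a following intron
        e1 <- ex[k]
        GenomicRanges::start(e1) <- GenomicRanges::start(e1) + 10
        GenomicRanges::end(e1) <- GenomicRanges::end(e1) - 10
        intronStart <- GenomicRanges::end(ex[k]) + 1
        intronEnd <- GenomicRanges::start(ex[k + 1]) - 1
        w2 <- sample(80:200, 1)
        s2 <- intronStart + sample(50:150, 1)
        e2 <- GRanges(GenomicRanges::seqnames(e1),
                      IRanges(s2, min(s2 + w2 - 1, intronEnd - 20)),
                      strand = GenomicRanges::strand(e1))
        id <- nextId()
        addTx(id, c(e1, e2), paste0("NOVG_", id),
              "overlapping", "overlapping", "coding", "known_removal")
      }
    }

    ## -- intergenic placements ---------------------------------------------
    gapStartV <- GenomicRanges::start(gaps)
    gapEndV <- GenomicRanges::end(gaps)
    gapChrom <- as.character(GenomicRanges::seqnames(gaps))
    minD <- config$min_gene_distance

    placeFree <- function(spanWidth, margin) {
      ord <- sample(length(gaps))  # random but seeded gap order
      for (g in ord) {
        slot <- .fitInGap(gapStartV[g], gapEndV[g], occ[[g]], spanWidth,
                          margin)
        if (!is.null(slot)) {
          occ[[g]] <<- rbind(occ[[g]], slot)
          return(list(gap = g, start = slot[1]))
        }
      }
      stop("placement impossible: no intergenic gap can host a ", spanWidth,
           " bp transcript at margin ", margin,
           " (intergenic_gap_range too small for the requested catalog)")
    }

    ## cis lincRNAs: anchored next to the TSS side of a reference gene
    cisTargets <- if (config$n_cis_pairs > 0)
      sample(length(reference), config$n_cis_pairs) else integer()
    lincIds <- character()
    makeLincStructure <- function(compact = FALSE) {
      nEx <- if (compact) sample(2:3, 1) else sample(2:4, 1)
      widths <- sample(if (compact) 150:300 else 150:400, nEx,
                       replace = TRUE)
      introns <- sample(if (compact) 200:500 else 200:700, nEx - 1,
                        replace = TRUE)
      list(widths = widths, introns = introns,
           span = sum(widths) + sum(introns))
    }
    for (i in seq_along(cisTargets)) {
      j <- cisTargets[i]
      gene <- geneIds(reference)[j]
      gStrand <- as.character(GenomicRanges::strand(refSpans[j]))
      st <- makeLincStructure(compact = TRUE)
      ## bimodal anchor distances: near-TSS group and a 2.5-3.4 kb group
      d <- if (i %% 2 == 0) sample(600:900, 1) else sample(2500:3400, 1)
      if (gStrand == "+") {
        g <- which(mcols(gaps)$right_gene == gene)
        anchorEnd <- GenomicRanges::start(refSpans[j]) - d - 1
        slot <- c(anchorEnd - st$span + 1, anchorEnd)
        lincStrand <- "-"   # TSS (its right end) faces the gene TSS
      } else {
        g <- which(mcols(gaps)$left_gene == gene)
        slot <- c(GenomicRanges::end(refSpans[j]) + d + 1,
                  GenomicRanges::end(refSpans[j]) + d + st$span)
        lincStrand <- "+"
      }
      if (length(g) != 1 || slot[1] < gapStartV[g] + minD ||
          slot[2] > gapEndV[g] - minD ||
          (nrow(occ[[g]]) && any(occ[[g]][, 1] <= slot[2] + 150 &
                                   occ[[g]][, 2] >= slot[1] - 150)))
        stop("placement impossible for cis lincRNA near gene ", gene)
      occ[[g]] <- rbind(occ[[g]], slot)
      id <- nextId()
      ex <- .exonChain(gapChrom[g], slot[1], st$widths, st$introns,
                       lincStrand)
      addTx(id, ex, paste0("LINCG_", txCounter), "lincRNA", "intergenic",
            "noncoding", "none",
            seq = .makeNoncodingSeq(sum(st$widths),
                                    config$noncoding_orf_cap))
      lincIds <- c(lincIds, id)
      cisRows[[length(cisRows) + 1L]] <- data.frame(
        lincrna_id = id, mrna_id = gene, rho = config$cis_pair_correlation,
        tss_distance = d + 1)
    }

    ## remaining free lincRNAs
    nFree <- config$n_intergenic_noncoding - config$n_cis_pairs
    for (i in seq_len(nFree)) {
      st <- makeLincStructure()
      pl <- placeFree(st$span, minD)
      id <- nextId()
      ex <- .exonChain(gapChrom[pl$gap], pl$start, st$widths, st$introns,
                       sample(c("+", "-"), 1))
      addTx(id, ex, paste0("LINCG_", txCounter), "lincRNA", "intergenic",
            "noncoding", "none",
            seq = .makeNoncodingSeq(sum(st$widths),
                                    config$noncoding_orf_cap))
      lincIds <- c(lincIds, id)
    }

    ## intergenic coding transcripts (fail the coding-potential stage)
    for (i in seq_len(config$n_intergenic_coding)) {
      orfLen <- 3 * sample(ceiling(config$orf_length_range_coding[1] / 3):
                             floor(config$orf_length_range_coding[2] / 3), 1)
      L <- orfLen + sample(80:240, 1)
      nEx <- sample(2:3, 1)
      widths <- .splitWidths(L, nEx)
      introns <- sample(200:700, nEx - 1, replace = TRUE)
      pl <- placeFree(sum(widths) + sum(introns), minD)
      id <- nextId()
      ex <- .exonChain(gapChrom[pl$gap], pl$start, widths, introns,
                       sample(c("+", "-"), 1))
      addTx(id, ex, paste0("ICODG_", txCounter), "intergenic_coding",
            "intergenic", "coding", "noncoding",
            seq = .makeCodingSeq(L, orfLen))
    }

    ## decoys: single-exon (fail multi_exon)
    for (i in seq_len(config$n_decoy_single_exon)) {
      w <- sample(300:800, 1)
      pl <- placeFree(w, minD)
      id <- nextId()
      ex <- GRanges(gapChrom[pl$gap], IRanges(pl$start, width = w),
                    strand = sample(c("+", "-"), 1))
      addTx(id, ex, paste0("DSEG_", txCounter), "decoy_single_exon",
            "intergenic", "noncoding", "multi_exon",
            seq = .makeNoncodingSeq(w, config$noncoding_orf_cap))
    }

    ## decoys: short spliced length (fail min_length)
    for (i in seq_len(config$n_decoy_short)) {
      widths <- sample(60:95, 2, replace = TRUE)
      intron <- sample(200:500, 1)
      pl <- placeFree(sum(widths) + intron, minD)
      id <- nextId()
      ex <- .exonChain(gapChrom[pl$gap], pl$start, widths, intron,
                       sample(c("+", "-"), 1))
      addTx(id, ex, paste0("DSHG_", txCounter), "decoy_short", "intergenic",
            "noncoding", "min_length",
            seq = .makeNoncodingSeq(sum(widths), config$noncoding_orf_cap))
    }

    ## decoys: too close to a gene (fail min_distance); anchored at the
    ## right end of a gap, 100-480 bp from the right-flanking gene
    closeGaps <- which(!is.na(mcols(gaps)$right_gene))
    usedClose <- logical(length(gaps))
    for (i in seq_len(config$n_decoy_close)) {
      st <- makeLincStructure(compact = TRUE)
      d <- sample(100:480, 1)
      placed <- FALSE
      for (g in closeGaps[sample.int(length(closeGaps))]) {
        if (usedClose[g]) next
        slot <- c(gapEndV[g] - d - st$span + 1, gapEndV[g] - d)
        if (slot[1] < gapStartV[g] + minD ||
            (nrow(occ[[g]]) && any(occ[[g]][, 1] <= slot[2] + 150 &
                                     occ[[g]][, 2] >= slot[1] - 150)))
          next
        occ[[g]] <- rbind(occ[[g]], slot)
        usedClose[g] <- TRUE
        id <- nextId()
        ex <- .exonChain(gapChrom[g], slot[1], st$widths, st$introns,
                         sample(c("+", "-"), 1))
        addTx(id, ex, paste0("DCLG_", txCounter), "decoy_close",
              "intergenic", "noncoding", "min_distance",
              seq = .makeNoncodingSeq(sum(st$widths),
                                      config$noncoding_orf_cap))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("placement impossible: no gap left for a close decoy ",
             "(intergenic_gap_range too small or too few reference genes)")
    }

    ## write designed sequences into the genome, then extract all
    for (id in names(designedSeq))
      genome <- .writeTxSeq(genome, exList[[id]], designedSeq[[id]])
    catalog <- if (length(exList))
      TranscriptCatalog(GRangesList(exList), geneIds = gid)
    else
      new("TranscriptCatalog", exons = GRangesList(),
          txData = DataFrame(transcript_id = character(),
                             gene_id = character()))
    seqs <- vapply(names(exList), function(id)
      .extractTxSeq(genome, exList[[id]]), character(1))
    sequences <- Biostrings::DNAStringSet(seqs)

    ## tissue-panel feature table + specific-tissue assignment
    tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
    cisDf <- if (length(cisRows)) do.call(rbind, cisRows) else
      data.frame(lincrna_id = character(), mrna_id = character(),
                 rho = numeric(), tss_distance = numeric())
    mrnaIds <- unique(geneIds(reference))
    feats <- data.frame(
      feature_id = c(lincIds, mrnaIds),
      type = c(rep("lincRNA", length(lincIds)),
               rep("mRNA", length(mrnaIds))))
    feats$specific_tissue <- "none"
    freeLinc <- setdiff(lincIds, cisDf$lincrna_id)
    freeMrna <- setdiff(mrnaIds, cisDf$mrna_id)
    nSpecL <- round(config$tissue_specific_fraction_linc * length(freeLinc))
    nSpecM <- round(config$tissue_specific_fraction_mrna * length(freeMrna))
    if (config$n_tissues >= 2) {
      specL <- if (nSpecL > 0) sample(freeLinc, nSpecL) else character()
      specM <- if (nSpecM > 0) sample(freeMrna, nSpecM) else character()
      feats$specific_tissue[match(c(specL, specM), feats$feature_id)] <-
        sample(tissues, nSpecL + nSpecM, replace = TRUE)
    }

    txDf <- do.call(rbind, classRows)
    txDf$specific_tissue <- feats$specific_tissue[
      match(txDf$transcript_id, feats$feature_id)]
    txDf$specific_tissue[is.na(txDf$specific_tissue)] <- "none"

    truth <- new("SyntheticTruth",
                 transcripts = DataFrame(txDf),
                 cisPairs = DataFrame(cisDf),
                 modules = DataFrame(gene_id = character(),
                                     module = character(),
                                     is_hub = logical(),
                                     is_linc = logical()),
                 stageOfModule = character(),
                 tissueFeatures = DataFrame(feats))
    list(catalog = catalog, sequences = sequences, truth = truth,
         genome = genome)
  })
}

#' Simulate expression panels with planted structure
#'
#' Emits two FPKM panels: a tissue panel (one library per tissue) in which
#' planted tissue-specific features exceed 0.1 FPKM only in their tissue and
#' planted cis pairs share correlated profiles at the target rho; and a
#' developmental-stage panel in which each module's genes follow a pulse
#' profile (high at the module's stage, baseline elsewhere) plus Gaussian
#' noise, hubs with the smallest noise, and noise genes without structure.
#' The returned truth has the module slots filled in.
#'
#' @param truth [SyntheticTruth-class] from [simulateTranscriptCatalog()].
#' @param config The same [simulationConfig()].
#' @return List: \code{tissues}, \code{stages} (both
#'   \code{SummarizedExperiment}), \code{truth} (updated).
#' @export
simulateExpression <- function(truth, config) {
  if (config$replicates_per_stage < 2)
    warning("fewer than 2 replicates per stage: ",
            "correlation p-values will be degenerate")
  .withSeed(config$seed + 2000003L, {
    seTissue <- .tissuePanel(config, as.data.frame(truth@tissueFeatures),
                             as.data.frame(truth@cisPairs))

    ## ---- stage panel ----
    sp <- .stagePanel(config)
    truth@modules <- DataFrame(sp$modules)
    truth@stageOfModule <- sp$stageOfModule
    methods::validObject(truth)
    list(tissues = seTissue, stages = sp$panel, truth = truth)
  })
}

## tissue-panel builder (RNG state of the caller is used): planted
## tissue-specific features are detectable only in their tissue; cis pairs
## share a latent log2 profile at the target rho; everything else is broad
.tissuePanel <- function(config, tf, cis) {
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
  nT <- length(tissues)
  fpkmT <- matrix(0, nrow(tf), nT,
                  dimnames = list(tf$feature_id, tissues))
  cisLinc <- cis$lincrna_id; cisMrna <- cis$mrna_id
  zMrna <- list()
  for (i in seq_len(nrow(tf))) {
    id <- tf$feature_id[i]
    if (tf$specific_tissue[i] != "none") {
      fpkmT[i, ] <- stats::runif(nT, 0, 0.08)
      fpkmT[i, tf$specific_tissue[i]] <- 2^stats::rnorm(1, 4, 0.5)
    } else if (id %in% cisMrna) {
      z <- stats::rnorm(nT)
      zMrna[[id]] <- z
      fpkmT[i, ] <- pmax(2^(2.5 + z), 0.2)
    } else if (!(id %in% cisLinc)) {
      fpkmT[i, ] <- pmax(2^stats::rnorm(nT, 2.5, 1), 0.2)
    }
  }
  rho <- config$cis_pair_correlation
  for (k in seq_len(nrow(cis))) {
    z <- zMrna[[cis$mrna_id[k]]]
    x <- 2.5 + rho * z + sqrt(1 - rho^2) * stats::rnorm(nT)
    fpkmT[cis$lincrna_id[k], ] <- pmax(2^x, 0.2)
  }
  makeExpressionPanel(fpkmT, tissues)
}

#' Simulate only the tissue panel
#'
#' The tissue FPKM panel with planted tissue-specific features and
#' cis-correlated pairs, using free-standing feature ids instead of a
#' simulated genome — convenient for specificity and cis-correlation
#' simulations over many seeds.
#'
#' @param config A [simulationConfig()].
#' @return List: \code{panel} (\code{SummarizedExperiment}), \code{features}
#'   (data.frame feature_id / type / specific_tissue), \code{cisPairs}
#'   (data.frame lincrna_id / mrna_id / rho).
#' @export
simulateTissuePanel <- function(config) {
  .withSeed(config$seed + 2000003L, {
    tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
    lincIds <- sprintf("LINC%04d", seq_len(config$n_intergenic_noncoding))
    mrnaIds <- sprintf("G%04d", seq_len(config$n_reference_genes))
    nCis <- min(config$n_cis_pairs, length(lincIds), length(mrnaIds))
    cis <- data.frame(lincrna_id = lincIds[seq_len(nCis)],
                      mrna_id = mrnaIds[seq_len(nCis)],
                      rho = rep(config$cis_pair_correlation, nCis))
    feats <- data.frame(
      feature_id = c(lincIds, mrnaIds),
      type = c(rep("lincRNA", length(lincIds)),
               rep("mRNA", length(mrnaIds))))
    feats$specific_tissue <- "none"
    freeLinc <- setdiff(lincIds, cis$lincrna_id)
    freeMrna <- setdiff(mrnaIds, cis$mrna_id)
    nSpecL <- round(config$tissue_specific_fraction_linc * length(freeLinc))
    nSpecM <- round(config$tissue_specific_fraction_mrna * length(freeMrna))
    if (config$n_tissues >= 2 && nSpecL + nSpecM > 0) {
      spec <- c(if (nSpecL > 0) sample(freeLinc, nSpecL) else character(),
                if (nSpecM > 0) sample(freeMrna, nSpecM) else character())
      feats$specific_tissue[match(spec, feats$feature_id)] <-
        sample(tissues, length(spec), replace = TRUE)
    }
    list(panel = .tissuePanel(config, feats, cis), features = feats,
         cisPairs = cis)
  })
}

## stage-panel builder (RNG state of the caller is used)
.stagePanel <- function(config) {
  stages <- sprintf("stage%d", seq_len(config$n_stages))
  samples <- as.vector(vapply(stages, function(s)
    paste0(s, "_rep", seq_len(config$replicates_per_stage)),
    character(config$replicates_per_stage)))
  sampleStage <- rep(stages, each = config$replicates_per_stage)
  nS <- length(samples)
  nMod <- config$n_modules
  gpm <- config$genes_per_module
  nHub <- ceiling(config$hub_fraction * gpm)
  modNames <- sprintf("PM%02d", seq_len(nMod))
  stageOfModule <- stats::setNames(
    stages[((seq_len(nMod) - 1) %% config$n_stages) + 1], modNames)
  geneRows <- list()
  exprRows <- list()
  gCount <- 0L
  baseline <- 1; peak <- 6
  for (m in seq_len(nMod)) {
    pulse <- ifelse(sampleStage == stageOfModule[modNames[m]], peak,
                    baseline)
    for (g in seq_len(gpm)) {
      gCount <- gCount + 1L
      id <- sprintf("SG%04d", gCount)
      isHub <- g <= nHub
      sdg <- config$module_noise_sd * if (isHub)
        config$hub_noise_factor else 1
      x <- pulse + stats::rnorm(nS, 0, sdg)
      exprRows[[id]] <- pmax(2^x - 1, 0)
      geneRows[[id]] <- data.frame(gene_id = id, module = modNames[m],
                                   is_hub = isHub)
    }
  }
  for (g in seq_len(config$n_noise_genes)) {
    gCount <- gCount + 1L
    id <- sprintf("SG%04d", gCount)
    mu <- stats::runif(1, 1, 2.5)
    exprRows[[id]] <- pmax(2^(mu + stats::rnorm(nS, 0, 1.2)) - 1, 0)
    geneRows[[id]] <- data.frame(gene_id = id, module = "noise",
                                 is_hub = FALSE)
  }
  fpkmS <- do.call(rbind, exprRows)
  dimnames(fpkmS) <- list(names(exprRows), samples)
  modDf <- do.call(rbind, geneRows)
  rownames(modDf) <- NULL
  ## a fraction of stage-panel genes flagged as lincRNAs (hubs included)
  modDf$is_linc <- FALSE
  if (nrow(modDf))
    modDf$is_linc[sample(nrow(modDf), round(0.17 * nrow(modDf)))] <- TRUE
  list(panel = makeExpressionPanel(fpkmS, sampleStage), modules = modDf,
       stageOfModule = stageOfModule)
}

#' Simulate only the developmental-stage panel
#'
#' The stage panel with planted modules and hubs, without building a genome
#' or catalog — convenient for module-recovery simulations over many seeds.
#'
#' @param config A [simulationConfig()].
#' @return List: \code{panel} (\code{SummarizedExperiment}), \code{modules}
#'   (data.frame gene_id / module / is_hub / is_linc), \code{stageOfModule}
#'   (named character).
#' @export
simulateStagePanel <- function(config) {
  if (config$replicates_per_stage < 2)
    warning("fewer than 2 replicates per stage: ",
            "correlation p-values will be degenerate")
  .withSeed(config$seed + 2000003L, .stagePanel(config))
}

#' Simulate coding/noncoding training and evaluation sequences
#'
#' Free-standing sequence sets from the same sequence models as the catalog
#' (codon-usage-biased planted ORFs vs stop-interrupted noncoding), for
#' training and evaluating the coding-potential model.
#'
#' @param config A [simulationConfig()].
#' @param nPerClass Sequences per class.
#' @param seedOffset Offset added to the master seed (use different offsets
#'   for disjoint training/held-out sets).
#' @return List of character vectors \code{coding} and \code{noncoding},
#'   named by sequence id.
#' @export
simulateTrainingSequences <- function(config, nPerClass = 300,
                                      seedOffset = 3000003L) {
  .withSeed(config$seed + seedOffset, {
    coding <- vapply(seq_len(nPerClass), function(i) {
      orfLen <- 3 * sample(ceiling(config$orf_length_range_coding[1] / 3):
                             floor(config$orf_length_range_coding[2] / 3), 1)
      .makeCodingSeq(orfLen + sample(80:400, 1), orfLen)
    }, character(1))
    noncoding <- vapply(seq_len(nPerClass), function(i)
      .makeNoncodingSeq(sample(300:1500, 1), config$noncoding_orf_cap),
      character(1))
    names(coding) <- sprintf("coding_%04d", seq_len(nPerClass))
    names(noncoding) <- sprintf("noncoding_%04d", seq_len(nPerClass))
    list(coding = coding, noncoding = noncoding)
  })
}

#' Run the whole generator
#'
#' Convenience wrapper: annotation, catalog, expression, and (optionally)
#' files on disk via [writeSimulation()].
#'
#' @param config A [simulationConfig()].
#' @param dir Optional output directory; when given, all artifacts are
#'   written there.
#' @return List: \code{reference}, \code{genome}, \code{catalog},
#'   \code{sequences}, \code{truth}, \code{tissues}, \code{stages},
#'   \code{config}, and (when written) \code{files}.
#' @export
simulatePipelineData <- function(config = simulationConfig(), dir = NULL) {
  ann <- simulateAnnotation(config)
  cat_ <- simulateTranscriptCatalog(ann, config)
  ex <- simulateExpression(cat_$truth, config)
  out <- list(reference = ann$reference, genome = cat_$genome,
              catalog = cat_$catalog, sequences = cat_$sequences,
              truth = ex$truth, tissues = ex$tissues, stages = ex$stages,
              config = config)
  if (!is.null(dir)) out$files <- writeSimulation(out, dir)
  out
}

#' Write every simulated artifact to disk
#'
#' Reference and catalog GTF, genome and transcript FASTA, the two FPKM TSVs
#' (features x samples, header = sample ids), the design TSVs, and the truth
#' tables as TSV + JSON.
#'
#' @param sim Output of [simulatePipelineData()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeTranscriptGTF(sim$reference, p("reference.gtf"))
  writeTranscriptGTF(sim$catalog, p("catalog.gtf"))
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  Biostrings::writeXStringSet(sim$sequences, p("transcripts.fa"))
  writeTsv <- function(df, f)
    utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  fpkmOut <- function(se, f) {
    m <- .fpkm(se)
    writeTsv(data.frame(feature_id = rownames(m), m, check.names = FALSE),
             f)
  }
  fpkmOut(sim$tissues, "fpkm_tissues.tsv")
  fpkmOut(sim$stages, "fpkm_stages.tsv")
  writeTsv(data.frame(sample = colnames(.fpkm(sim$tissues)),
                      tissue = .conditions(sim$tissues)),
           "design_tissues.tsv")
  writeTsv(data.frame(sample = colnames(.fpkm(sim$stages)),
                      stage = .conditions(sim$stages)),
           "design_stages.tsv")
  tr <- sim$truth
  writeTsv(as.data.frame(tr@transcripts), "truth_transcripts.tsv")
  writeTsv(as.data.frame(tr@cisPairs), "truth_cis_pairs.tsv")
  writeTsv(as.data.frame(tr@modules), "truth_modules.tsv")
  writeTsv(as.data.frame(tr@tissueFeatures), "truth_tissue_features.tsv")
  jsonlite::write_json(
    list(stage_of_module = as.list(tr@stageOfModule),
         seed = sim$config$seed),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  files <- c("reference.gtf", "catalog.gtf", "genome.fa", "transcripts.fa",
             "fpkm_tissues.tsv", "fpkm_stages.tsv", "design_tissues.tsv",
             "design_stages.tsv", "truth_transcripts.tsv",
             "truth_cis_pairs.tsv", "truth_modules.tsv",
             "truth_tissue_features.tsv", "truth.json")
  invisible(stats::setNames(file.path(dir, files), files))
}
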
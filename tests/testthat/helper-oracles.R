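## Independent oracles and shared fixtures. Oracles deliberately use naive
## algorithms (substring scans, triple loops, O(n^2) pair scans, direct
## entropy/choose() arithmetic) so they stay independent of the package's
## implementation paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

## memoized default simulation shared across test files
.fixtureEnv <- new.env(parent = emptyenv())

defaultSim <- function(seed = 101) {
  key <- paste0("sim", seed)
  if (is.null(.fixtureEnv[[key]]))
    .fixtureEnv[[key]] <- simulatePipelineData(simulationConfig(seed = seed))
  .fixtureEnv[[key]]
}

defaultRun <- function(seed = 91) {
  key <- paste0("run", seed)
  if (is.null(.fixtureEnv[[key]])) {
    dir <- file.path(tempdir(), paste0("lincnet-run", seed))
    .fixtureEnv[[key]] <- runPipeline(simulationConfig(seed = seed),
                                      outDir = dir)
    .fixtureEnv[[key]]$outDir <- dir
  }
  .fixtureEnv[[key]]
}

defaultModel <- function(seed = 101) {
  key <- paste0("model", seed)
  if (is.null(.fixtureEnv[[key]])) {
    cfg <- simulationConfig(seed = seed)
    train <- simulateTrainingSequences(cfg, nPerClass = 300)
    hex <- trainHexamerTable(train$coding, train$noncoding)
    feats <- codingFeatures(c(train$coding, train$noncoding), hex)
    model <- trainCodingModel(feats, rep(c(TRUE, FALSE), each = 300))
    .fixtureEnv[[key]] <- list(hex = hex, model = model, train = train)
  }
  .fixtureEnv[[key]]
}

## naive longest-ORF scan over every (start, frame) substring
bruteLongestOrf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(max(n - 5, 0))) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i + 3
    while (j + 2 <= n) {
      cod <- substr(s, j, j + 2)
      if (cod %in% stops) {
        orf <- substr(s, i, j + 2)
        if (!grepl("N", orf, fixed = TRUE))
          best <- max(best, nchar(orf))
        break
      }
      j <- j + 3
    }
  }
  best
}

## triple-loop TOM
bruteTom <- function(a) {
  n <- nrow(a)
  adj <- a; diag(adj) <- 0
  k <- rowSums(adj)
  t <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { t[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
    t[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  t
}

## direct entropy-arithmetic JS specificity (score of p against unit vector)
jsScoreOracle <- function(p, t) {
  e <- numeric(length(p)); e[t] <- 1
  m <- (p + e) / 2
  H <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  1 - sqrt(H(m) - (H(p) + H(e)) / 2)
}

## exact hypergeometric upper tail via choose()
fisherTailOracle <- function(k, K, N, n) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

## O(n^2) neighbour-pair scan on span GRanges (gap < maxGap, strand ignored)
bruteNeighborPairs <- function(a, b, maxGap = 10000) {
  out <- list()
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (as.character(seqnames(a)[i]) != as.character(seqnames(b)[j])) next
    gap <- max(start(b)[j] - end(a)[i] - 1, start(a)[i] - end(b)[j] - 1, 0)
    if (gap < maxGap)
      out[[length(out) + 1]] <- data.frame(
        id_a = names(a)[i], id_b = names(b)[j], gap = gap)
  }
  if (!length(out)) return(data.frame(id_a = character(),
                                      id_b = character(), gap = numeric()))
  do.call(rbind, out)
}

## O(n^2) minimum span distance to any gene
bruteMinDistance <- function(spans, genes) {
  vapply(seq_along(spans), function(i) {
    d <- Inf
    for (j in seq_along(genes)) {
      if (as.character(seqnames(spans)[i]) !=
          as.character(seqnames(genes)[j])) next
      gap <- max(start(genes)[j] - end(spans)[i] - 1,
                 start(spans)[i] - end(genes)[j] - 1, 0)
      d <- min(d, gap)
    }
    d
  }, numeric(1))
}

## independent Fickett TESTCODE implementation (same published tables,
## different code path: explicit loops and threshold walks)
fickettOracle <- function(s) {
  s <- toupper(s)
  chars <- strsplit(s, "")[[1]]
  posProb <- list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  posW <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  posT <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
  cmpProb <- list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  cmpW <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  cmpT <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.17, 0.17, 0.0)
  total <- 0
  nACGT <- sum(chars %in% c("A", "C", "G", "T"))
  for (b in c("A", "C", "G", "T")) {
    cnt <- c(0, 0, 0)
    for (i in seq_along(chars))
      if (chars[i] == b) cnt[(i - 1) %% 3 + 1] <- cnt[(i - 1) %% 3 + 1] + 1
    pv <- max(cnt) / (min(cnt) + 1)
    cv <- sum(cnt) / nACGT
    pi <- 1; while (pv < posT[pi]) pi <- pi + 1
    ci <- 1; while (cv < cmpT[ci]) ci <- ci + 1
    total <- total + posProb[[b]][pi] * posW[[b]] + cmpProb[[b]][ci] * cmpW[[b]]
  }
  total
}

## rank-based AUROC (Mann-Whitney U)
aurocRank <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## random spliced transcript as a small GRangesList element
randomTx <- function(chrom, start, widths, introns, strand) {
  starts <- start + cumsum(c(0, head(widths, -1) + introns))
  GRanges(chrom, IRanges(starts, width = widths), strand = strand)
}
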
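.exprPanel <- function(mat) {
  dimnames(mat) <- list(paste0("g", seq_len(nrow(mat))),
                        paste0("s", seq_len(ncol(mat))))
  makeExpressionPanel(mat, paste0("c", seq_len(ncol(mat))))
}

test_that("preprocessing applies the floor, variance rule and log transform", {
  set.seed(51)
  m <- matrix(2^rnorm(10 * 8, 2, 1), 10, 8)
  m[1, ] <- 0.04                      # below the 0.05 max-FPKM floor
  m[2, ] <- 3                         # lowest variance of the survivors
  m[3, ] <- 3 + c(0.001, rep(0, 7))   # second lowest
  se <- .exprPanel(m)
  out <- preprocessExpression(se)
  expect_false("g1" %in% rownames(out))
  ## 9 post-floor genes -> ceiling(0.75 * 9) = 7 kept
  expect_equal(nrow(out), 7)
  expect_equal(unname(attr(out, "dropped")), c(1, 2))
  expect_false(any(c("g2", "g3") %in% rownames(out)))
  ## log2(FPKM + 1): FPKM 3 -> 2
  se2 <- .exprPanel(matrix(3, 4, 4))
  out2 <- preprocessExpression(se2, varianceQuantileKept = 1)
  expect_true(all(out2 == 2))
  ## 8 genes post-drop -> 6 kept under the default 75% rule
  se3 <- .exprPanel(matrix(2^rnorm(8 * 6, 2, 1), 8, 6))
  expect_equal(nrow(preprocessExpression(se3)), 6)
  expect_error(preprocessExpression(.exprPanel(matrix(0.01, 3, 3))),
               "floor")
})

test_that("signed adjacency hits its analytic anchors", {
  n <- 6
  x <- matrix(rnorm(n * 10), n, 10)
  x[2, ] <- x[1, ]            # cor +1
  x[3, ] <- -x[1, ]           # cor -1
  dimnames(x) <- list(paste0("g", 1:n), paste0("s", 1:10))
  a <- signedAdjacency(x, beta = 13)
  expect_equal(a[1, 2], 1)
  expect_equal(a[1, 3], 0)
  ## cor 0 -> 0.5^13 exactly (forced analytically)
  expect_equal(((1 + 0) / 2)^13, 0.0001220703125)
  expect_true(isSymmetric(a))
  expect_true(all(a >= 0 & a <= 1))
  bad <- x; bad[4, ] <- 7
  expect_error(signedAdjacency(bad, 13), "zero-variance")
})

test_that("mean connectivity decreases with the soft power", {
  set.seed(52)
  x <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:12)))
  k <- vapply(c(1, 4, 8, 13, 20), function(b)
    mean(rowSums(signedAdjacency(x, b)) - 1), numeric(1))
  expect_true(all(diff(k) < 0))
})

test_that("soft-threshold selection finds scale-free decay when present", {
  ## heterogeneous single-factor design: gene-factor correlations spread
  ## over [0,1] give a decaying connectivity distribution
  set.seed(53)
  ns <- 12; n <- 300
  f <- rnorm(ns)
  r <- runif(n)
  x <- t(vapply(r, function(ri) ri * f + sqrt(1 - ri^2) * rnorm(ns),
                numeric(ns)))
  dimnames(x) <- list(paste0("g", 1:n), paste0("s", 1:ns))
  sft <- pickSoftThreshold(x)
  expect_true(sft$reached)
  expect_lte(sft$beta, 20)
  expect_gte(sft$fit$r_squared[sft$fit$power == sft$beta], 0.9)
  ## smallest qualifying power is chosen
  earlier <- sft$fit$r_squared[sft$fit$power < sft$beta]
  expect_true(all(is.na(earlier) | earlier < 0.9))

  ## pure noise: warning path, best-fit beta returned
  set.seed(54)
  xn <- matrix(rnorm(150 * 12), 150, 12,
               dimnames = list(paste0("g", 1:150), paste0("s", 1:12)))
  expect_warning(sftN <- pickSoftThreshold(xn), "best fit")
  expect_false(sftN$reached)
})

test_that("TOM matches the brute-force triple sum and its anchors", {
  ## complete graph: all TOM entries 1
  n <- 7
  a1 <- matrix(1, n, n)
  expect_true(all(abs(tomSimilarity(a1) - 1) < 1e-12))
  ## empty graph: off-diagonal 0
  a0 <- diag(n)
  t0 <- tomSimilarity(a0)
  expect_true(all(t0[upper.tri(t0)] == 0))
  expect_true(all(diag(t0) == 1))
  ## 20 random small adjacencies vs O(n^3) oracle
  set.seed(55)
  for (i in 1:20) {
    nn <- sample(6:10, 1)
    a <- matrix(runif(nn * nn), nn, nn)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    expect_lt(max(abs(tomSimilarity(a) - bruteTom(a))), 1e-12)
  }
})

test_that("two planted blocks are recovered perfectly by the tree cut", {
  set.seed(56)
  ns <- 12
  f1 <- rnorm(ns); f2 <- rnorm(ns)
  x <- rbind(t(vapply(1:15, function(i) f1 + rnorm(ns, 0, 0.01),
                      numeric(ns))),
             t(vapply(1:15, function(i) f2 + rnorm(ns, 0, 0.01),
                      numeric(ns))))
  dimnames(x) <- list(paste0("g", 1:30), paste0("s", 1:ns))
  tom <- tomSimilarity(signedAdjacency(x, 13))
  ## noise-free two-block fixture: the only high merge is the block join,
  ## so the cut must sit above the 28/29 within-block merges
  cut <- cutModules(tom, minModuleSize = 10, cutHeightQuantile = 0.99)
  truthLab <- rep(c("A", "B"), each = 15)
  expect_equal(length(setdiff(unique(cut$assignment), "unassigned")), 2)
  expect_equal(mclust::adjustedRandIndex(truthLab, cut$assignment), 1)
  ## all genes one profile -> a single module
  x1 <- t(vapply(1:20, function(i) f1 + rnorm(ns, 0, 0.01), numeric(ns)))
  dimnames(x1) <- list(paste0("g", 1:20), paste0("s", 1:ns))
  tom1 <- tomSimilarity(signedAdjacency(x1, 13))
  cut1 <- cutModules(tom1, minModuleSize = 10, cutHeightQuantile = 0.99)
  expect_equal(length(setdiff(unique(cut1$assignment), "unassigned")), 1)
  ## fewer genes than the minimum size -> everything unassigned, warning
  expect_warning(tiny <- cutModules(tom1[1:5, 1:5], minModuleSize = 10),
                 "unassigned")
  expect_true(all(tiny$assignment == "unassigned"))
})

test_that("eigengenes are unit-norm, oriented, and match an SVD oracle", {
  set.seed(57)
  ns <- 10
  f <- rnorm(ns)
  x <- t(vapply(1:12, function(i) 2 * f + rnorm(ns, 0, 0.3), numeric(ns)))
  dimnames(x) <- list(paste0("g", 1:12), paste0("s", 1:ns))
  asg <- setNames(rep("M1", 12), rownames(x))
  eig <- moduleEigengenes(x, asg)
  e <- eig$eigengenes[, "M1"]
  expect_equal(sum(e^2), 1)
  expect_gte(cor(e, colMeans(x)), 0)
  expect_gt(eig$var_explained[["M1"]], 0.9)
  ## identical profiles: |cor| = 1
  xid <- matrix(rep(f, each = 5), 5, ns, byrow = FALSE)
  dimnames(xid) <- list(paste0("g", 1:5), paste0("s", 1:ns))
  eid <- moduleEigengenes(xid, setNames(rep("M1", 5), rownames(xid)))
  expect_equal(abs(cor(eid$eigengenes[, 1], f)), 1, tolerance = 1e-10)
  ## sign symmetry: flipping all profiles flips the eigengene back positive
  eneg <- moduleEigengenes(-x, asg)
  expect_gte(cor(eneg$eigengenes[, 1], colMeans(-x)), 0)
  ## independent decomposition oracle (up to sign)
  sv <- svd(scale(t(x)))
  expect_equal(abs(cor(e, sv$u[, 1])), 1, tolerance = 1e-10)
})

test_that("module merging joins correlated eigengenes and is idempotent", {
  set.seed(58)
  ns <- 12
  f1 <- rnorm(ns)
  f2 <- f1 + rnorm(ns, 0, 0.3)      # eigengene cor ~0.95 with f1
  f3 <- rnorm(ns)                   # independent
  mk <- function(f, k) t(vapply(1:k, function(i) f + rnorm(ns, 0, 0.05),
                                numeric(ns)))
  x <- rbind(mk(f1, 10), mk(f2, 10), mk(f3, 10))
  dimnames(x) <- list(paste0("g", 1:30), paste0("s", 1:ns))
  asg <- setNames(rep(c("M1", "M2", "M3"), each = 10), rownames(x))
  merged <- mergeModules(x, asg)
  expect_equal(unname(merged[1]), unname(merged[11]))    # M1+M2 joined
  expect_false(unname(merged[1]) == unname(merged[21]))  # M3 separate
  expect_identical(mergeModules(x, merged), merged)      # fixpoint
  ## low correlation: nothing merges
  asg2 <- setNames(rep(c("M1", "M3"), each = 10),
                   rownames(x)[c(1:10, 21:30)])
  expect_identical(mergeModules(x[c(1:10, 21:30), ], asg2), asg2)
})

test_that("module-stage statistics match the t-distribution oracle", {
  ## r = 0.9, n = 12 -> t = 6.53, p ~ 6e-5 < 1e-4
  r <- 0.9; n <- 12
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(tval, df = n - 2, lower.tail = FALSE)
  expect_equal(tval, 6.529, tolerance = 1e-3)
  expect_lt(p, 1e-4)
  expect_gt(p, 1e-5)

  stages <- rep(paste0("st", 1:6), each = 2)
  ind <- as.numeric(stages == "st2")
  E <- cbind(M1 = ind, M2 = rnorm(12))
  rownames(E) <- paste0("s", 1:12)
  st <- moduleStageStats(E, stages)
  hit <- st[st$module == "M1" & st$stage == "st2", ]
  expect_equal(hit$r, 1)
  expect_lt(hit$p, 1e-12)
  sel <- stageSpecificModules(st)
  expect_true(all(sel$r > 0.7 & sel$p < 1e-4))
  expect_true(any(sel$module == "M1" & sel$stage == "st2"))
  ## oracle check on every row
  for (i in seq_len(nrow(st))) {
    ind <- as.numeric(stages == st$stage[i])
    rr <- cor(E[, st$module[i]], ind)
    tt <- rr * sqrt(10) / sqrt(1 - rr^2)
    expect_equal(st$p[i], min(2 * pt(abs(tt), 10, lower.tail = FALSE), 1),
                 tolerance = 1e-12)
  }
  expect_error(moduleStageStats(E[1:2, ], stages[1:2]), "more than 2")
})

test_that("kME anchors hold and hubs rank by module membership", {
  set.seed(59)
  ns <- 12
  f <- rnorm(ns)
  x <- t(vapply(1:20, function(i) f + rnorm(ns, 0, 0.2), numeric(ns)))
  dimnames(x) <- list(paste0("g", 1:20), paste0("s", 1:ns))
  asg <- setNames(rep("M1", 20), rownames(x))
  eig <- moduleEigengenes(x, asg)
  e <- eig$eigengenes[, 1]
  ## a gene equal to the eigengene has kME 1; orthogonal ~ 0
  x2 <- rbind(x, gE = e, gO = residuals(lm(rnorm(ns) ~ e)))
  asg2 <- setNames(c(rep("M1", 20), "M1", "M1"), rownames(x2))
  hub <- kmeHubs(x2, eig$eigengenes, asg2, topN = 5)
  expect_equal(unname(hub$kme["gE", "M1"]), 1, tolerance = 1e-10)
  expect_lt(abs(hub$kme["gO", "M1"]), 1e-6)
  expect_equal(nrow(hub$hubs), 5)
  expect_equal(hub$hubs$gene_id[1], "gE")
  expect_true(all(diff(hub$hubs$kme) <= 0))
  ## topN beyond module size emits the whole module with a note
  hubAll <- kmeHubs(x2, eig$eigengenes, asg2, topN = 100)
  expect_equal(nrow(hubAll$hubs), 22)
  expect_match(hubAll$notes, "only 22 members")
  ## neighbour weights come from the adjacency, sorted
  adj <- signedAdjacency(x2, 13)
  w <- hubNeighborWeights(adj, hub$hubs$gene_id)
  expect_equal(nrow(w), choose(5, 2))
  expect_true(all(diff(w$weight) <= 0))
  expect_equal(w$weight[1],
               adj[w$gene_a[1], w$gene_b[1]])
})

test_that("network pipeline is deterministic for a fixed input", {
  sp <- simulateStagePanel(simulationConfig(seed = 61))
  run <- function() {
    expr <- preprocessExpression(sp$panel)
    tom <- tomSimilarity(signedAdjacency(expr, 13))
    cut <- cutModules(tom, minModuleSize = 10)
    asg <- mergeModules(expr, cut$assignment)
    eig <- moduleEigengenes(expr, asg)
    list(asg = asg, hubs = kmeHubs(expr, eig$eigengenes, asg, topN = 10))
  }
  expect_identical(run(), run())
})

test_that("planted eigengene variance beats same-size random gene sets", {
  wins <- vapply(1:10, function(s) {
    sp <- simulateStagePanel(simulationConfig(seed = 400 + s))
    expr <- preprocessExpression(sp$panel)
    mods <- sp$modules
    genes <- intersect(mods$gene_id[mods$module == "PM01"], rownames(expr))
    asg <- setNames(rep("M", length(genes)), genes)
    vePlanted <- moduleEigengenes(expr[genes, ], asg)$var_explained
    set.seed(s)
    rnd <- sample(rownames(expr), length(genes))
    asgR <- setNames(rep("M", length(rnd)), rnd)
    veRandom <- moduleEigengenes(expr[rnd, ], asgR)$var_explained
    vePlanted > veRandom
  }, logical(1))
  expect_true(all(wins))
})
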
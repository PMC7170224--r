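blockData <- function(n_blocks, genes_per_block, n_samples, r, seed) {
  set.seed(seed)
  lat <- matrix(rnorm(n_blocks * n_samples), n_blocks)
  X <- do.call(rbind, lapply(seq_len(n_blocks), function(b)
    t(sapply(seq_len(genes_per_block), function(i)
      sqrt(r) * lat[b, ] + sqrt(1 - r) * rnorm(n_samples)))))
  rownames(X) <- paste0("g", seq_len(nrow(X)))
  X
}

test_that("TOM matches its formula on small and random networks", {
  a <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(computeTOM(a)[1, 2], 0.5)

  # identical 0/1 rows with a_ij = 1 overlap maximally
  a2 <- matrix(0, 4, 4)
  a2[1, 2] <- a2[2, 1] <- 1
  a2[1, 3] <- a2[3, 1] <- a2[2, 3] <- a2[3, 2] <- 1
  diag(a2) <- 1
  expect_equal(computeTOM(a2)[1, 2], 1)

  set.seed(19)
  a3 <- matrix(runif(36, 0, 0.9), 6)
  a3 <- (a3 + t(a3)) / 2
  diag(a3) <- 1
  expect_equal(unname(computeTOM(a3)), oracleTOM(a3), tolerance = 1e-12)

  tom <- computeTOM(a3)
  expect_true(isSymmetric(tom))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(unname(diag(tom)), rep(1, 6))
  a_bad <- a3
  a_bad[1, 2] <- 0.99
  expect_error(computeTOM(a_bad), "symmetric")
  expect_error(computeTOM(a3 * 2), "\\[0, 1\\]")
})

test_that("soft power selection is reproducible and matches a re-scan", {
  X <- blockData(3, 12, 24, 0.85, seed = 5)
  b1 <- suppressWarnings(pickSoftPower(X))
  b2 <- suppressWarnings(pickSoftPower(X))
  expect_identical(as.integer(b1), as.integer(b2))
  # brute-force re-scan with the published rule over the same grid
  fit <- attr(b1, "fit")
  ok <- which(fit$r2 >= 0.8)
  expected <- if (length(ok)) fit$power[ok[1]]
              else fit$power[which.max(fit$r2)]
  expect_identical(as.integer(b1), as.integer(expected))
  # the default grid starts at the background-suppression floor
  expect_gte(min(fit$power), ceiling(log(0.01) / log(2 / sqrt(24))))

  # duplicated genes keep adjacency 1 at any power
  Xd <- rbind(X[1, ], X[1, ], X[2, ])
  for (beta in c(1, 6, 12))
    expect_equal(adjacencyMatrix(Xd, beta)[1, 2], 1)

  # mean adjacency of independent genes decreases in beta
  set.seed(6)
  Xi <- matrix(rnorm(50 * 40), 50)
  means <- vapply(1:10, function(b) {
    a <- adjacencyMatrix(Xi, b)
    mean(a[upper.tri(a)])
  }, 0)
  expect_true(all(diff(means) < 0))

  # constant rows are dropped with a warning
  Xc <- rbind(X, const = rep(1, ncol(X)))
  w <- capture_warnings(pickSoftPower(Xc))
  expect_true(any(grepl("constant", w)))
})

test_that("module cutting recovers planted blocks and rejects noise", {
  # two blocks of duplicated genes: exactly two perfect modules
  set.seed(55)
  prof1 <- rnorm(20)
  prof2 <- rnorm(20)
  X <- rbind(matrix(rep(prof1, each = 6), 6, byrow = FALSE),
             matrix(rep(prof2, each = 6), 6, byrow = FALSE))
  X <- X + matrix(rnorm(length(X), 0, 1e-6), nrow(X))
  rownames(X) <- paste0("g", 1:12)
  m <- cutModules(computeTOM(adjacencyMatrix(X, 6)), min_module_size = 5)
  expect_equal(length(setdiff(unique(m), 0L)), 2L)
  expect_equal(length(unique(m[1:6])), 1L)
  expect_equal(length(unique(m[7:12])), 1L)
  expect_true(m[1] != m[7])

  # independent genes: nothing survives the minimum module size
  set.seed(10)
  Xi <- matrix(rnorm(60 * 20), 60)
  rownames(Xi) <- paste0("h", 1:60)
  bi <- suppressWarnings(pickSoftPower(Xi))
  mi <- cutModules(computeTOM(adjacencyMatrix(Xi, as.integer(bi))),
                   min_module_size = 10)
  expect_true(all(mi == 0L))

  # three r = 0.9 blocks of 15 genes: assignment close to the truth
  Xb <- blockData(3, 15, 20, 0.9, seed = 9)
  bb <- suppressWarnings(pickSoftPower(Xb))
  mb <- cutModules(computeTOM(adjacencyMatrix(Xb, as.integer(bb))),
                   min_module_size = 10)
  truth <- rep(1:3, each = 15)
  expect_gte(adjRandIndex(truth, mb), 0.8)
  expect_equal(adjRandIndex(truth, mb),
               mclust::adjustedRandIndex(truth, mb), tolerance = 1e-12)
})

test_that("module eigengenes are unit-norm, sign-fixed sample profiles", {
  set.seed(61)
  prof <- rnorm(15)
  X <- rbind(g1 = prof, g2 = prof, g3 = prof)
  colnames(X) <- paste0("s", 1:15)
  e <- moduleEigengene(X, c("g1", "g2", "g3"))
  expect_equal(sum(e^2), 1)
  expect_equal(abs(cor(e, scale(prof)[, 1])), 1, tolerance = 1e-8)
  expect_gt(cor(e, colMeans(t(scale(t(X))))), 0)

  # a perfectly anti-correlated pair still loads both genes fully
  X2 <- rbind(g1 = prof, g2 = -prof)
  colnames(X2) <- paste0("s", 1:15)
  e2 <- moduleEigengene(X2, c("g1", "g2"))
  expect_equal(abs(cor(e2, prof)), 1, tolerance = 1e-8)

  # sign invariant holds across random modules
  set.seed(62)
  for (i in 1:10) {
    Xr <- matrix(rnorm(4 * 12), 4, dimnames = list(paste0("g", 1:4),
                                                   paste0("s", 1:12)))
    er <- moduleEigengene(Xr, rownames(Xr))
    expect_gt(cor(er, colMeans(t(scale(t(Xr))))), 0)
  }
})

test_that("detectModules runs end-to-end on the fixture", {
  fx <- defaultFixture()
  mod <- suppressWarnings(suppressMessages(detectModules(fx$pas, fx$cfg)))
  expect_true(mod$beta >= 1 && mod$beta <= 20)
  expect_true(length(setdiff(unique(mod$modules), 0L)) >= 1)
  sizes <- table(mod$modules[mod$modules != 0])
  expect_true(all(sizes >= fx$cfg$min_module_size))
  expect_equal(ncol(mod$eigengenes), 20L)  # T24 samples
})
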
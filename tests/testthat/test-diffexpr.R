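test_that("size factors match the brute-force median-of-ratios oracle", {
  set.seed(11)
  m <- matrix(rpois(15, 50) + 1, 5, 3,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))

  # brute force: per sample, median over genes of count / geometric mean
  geo <- apply(m, 1, function(x) exp(mean(log(x))))
  oracle <- apply(m, 2, function(col) median(col / geo))
  expect_equal(size_factors(m), oracle)

  # identical columns get factor 1
  m1 <- matrix(rep(c(10, 20, 400, 3, 70), 4), 5, 4,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_equal(unname(size_factors(m1)), rep(1, 4))

  # doubling a column doubles its factor
  m2 <- cbind(m, s4 = 2 * m[, 1])
  sf <- size_factors(m2)
  expect_equal(unname(sf["s4"] / sf["s1"]), 2)

  # no gene expressed everywhere
  m3 <- matrix(c(0, 5, 5, 0), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors(m3), "pseudo-reference")
})

test_that("a gene with identical counts in both groups is a clean null", {
  # every gene constant across samples: size factors are exactly 1 and each
  # gene is its own perfect null
  vals <- c(77L, 120L, 31L, 250L, 64L, 1005L, 9L, 480L, 55L, 143L)
  m <- matrix(rep(vals, 8), ncol = 8,
              dimnames = list(paste0("g", seq_along(vals)), paste0("s", 1:8)))
  cc <- toy_counts(m, rep(c("A", "B"), each = 4))
  de <- test_contrast(normalize_counts(cc), "A", "B")
  expect_true(all(abs(de$log2fc) < 1e-9))
  expect_true(all(de$p == 1))
})

test_that("swapping contrast groups negates log2fc and preserves p", {
  sim <- default_sim()
  norm <- normalize_counts(sim$counts)
  ab <- test_contrast(norm, "ESC", "fibroblast_naive")
  ba <- test_contrast(norm, "fibroblast_naive", "ESC")
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$q, ba$q)
  expect_equal(ab$mean_a, ba$mean_b)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  # hand example
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  # all p-vectors of length <= 6 over a grid
  grid <- c(0.001, 0.02, 0.2, 0.9)
  for (len in 1:6) {
    combos <- as.matrix(expand.grid(rep(list(grid), len)))
    for (i in seq_len(nrow(combos))) {
      p <- combos[i, ]
      expect_equal(unname(p.adjust(p, "BH")), unname(bh_oracle(p)))
    }
  }

  # random vectors, mixed magnitudes
  set.seed(9)
  for (len in c(3, 5, 6)) {
    for (rep in 1:20) {
      p <- runif(len)^3
      expect_equal(unname(p.adjust(p, "BH")), unname(bh_oracle(p)))
    }
  }
})

test_that("q is never below p and is monotone along sorted p", {
  sim <- default_sim()
  de <- test_contrast(normalize_counts(sim$counts), "ESC",
                      "fibroblast_naive")
  ok <- !is.na(de$p)
  expect_true(all(de$q[ok] >= de$p[ok] - 1e-12))
  o <- order(de$p[ok])
  expect_true(all(diff(de$q[ok][o]) >= -1e-12))
  # sign of log2fc follows the means
  both <- ok & de$mean_a > 0 & de$mean_b > 0 & de$mean_a != de$mean_b
  expect_true(all(sign(de$log2fc[both]) ==
                    sign(de$mean_a[both] - de$mean_b[both])))
})

test_that("all-zero genes are untested, zero-in-one-group genes use the pseudocount", {
  m <- rbind(
    allzero = rep(0L, 8),
    halfzero = c(0L, 0L, 0L, 0L, 40L, 44L, 38L, 42L),
    matrix(rep(c(100L, 90L, 110L, 105L), 2 * 9), ncol = 8, byrow = TRUE,
           dimnames = list(paste0("bg", 1:9), NULL)))
  colnames(m) <- paste0("s", 1:8)
  cc <- toy_counts(m, rep(c("A", "B"), each = 4))
  de <- test_contrast(normalize_counts(cc), "A", "B")
  expect_true(is.na(de$p[de$gene == "allzero"]))
  expect_true(is.na(de$q[de$gene == "allzero"]))
  hz <- de[de$gene == "halfzero", ]
  expect_false(is.na(hz$p))
  expect_lt(hz$log2fc, -5)  # log2(0.5 / 40.5)-ish
})

test_that("power rises monotonically with planted fold change", {
  set.seed(5)
  n <- 4; mu0 <- 200; folds <- c(1.5, 2, 3, 4); nb <- 500; nnull <- 4000
  m <- rbind(
    cbind(matrix(rnbinom(nnull * n, mu = mu0, size = 20), nnull),
          matrix(rnbinom(nnull * n, mu = mu0, size = 20), nnull)),
    do.call(rbind, lapply(folds, function(f)
      cbind(matrix(rnbinom(nb * n, mu = mu0 * f, size = 20), nb),
            matrix(rnbinom(nb * n, mu = mu0, size = 20), nb)))))
  rownames(m) <- sprintf("g%05d", seq_len(nrow(m)))
  colnames(m) <- c(paste0("A", 1:n), paste0("B", 1:n))
  cc <- toy_counts(m, rep(c("A", "B"), each = n))
  de <- test_contrast(normalize_counts(cc), "A", "B")
  blk <- c(rep(0, nnull), rep(folds, each = nb))
  power <- vapply(folds, function(f)
    mean(de$p[blk == f] < 0.01, na.rm = TRUE), numeric(1))
  expect_true(all(diff(power) >= 0))
  expect_gt(power[length(power)], power[1] + 0.5)
})

test_that("imported DE tables feed the classifiers like native results", {
  sim <- default_sim()
  norm <- normalize_counts(sim$counts)
  de <- test_contrast(norm, "ESC", "fibroblast_naive")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_de_table(de, path)
  imp <- import_de_table(path)
  expect_equal(nrow(imp), nrow(de))

  genes <- sim$truth$gene[sim$truth$is_tf]
  s1 <- classify_state(de, norm, "ESC", "fibroblast_naive", genes = genes)
  s2 <- classify_state(imp, norm, "ESC", "fibroblast_naive", genes = genes)
  expect_equal(as.character(s1$category), as.character(s2$category))

  # toy table and missing-column error
  toy <- tibble::tibble(gene = c("a", "b", "c"), log2fc = c(1, -2, 0),
                        q = c(0.001, 0.2, 0.9))
  expect_equal(nrow(import_de_table(toy)), 3)
  expect_error(import_de_table(toy[, c("gene", "log2fc")]), "q")
})

test_that("fewer than two replicates per group is an error", {
  m <- matrix(rpois(30, 50), 10, 3,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  cc <- toy_counts(m, c("A", "A", "B"))
  expect_error(test_contrast(normalize_counts(cc), "A", "B"),
               ">= 2 replicates")
})

test_that("the engine agrees with an independent genome-scale implementation", {
  spec <- sim_spec(class_sizes = c(activatome = 30, erasome = 30,
                                   upreprogramome_enriched = 40,
                                   downreprogramome_enriched = 40,
                                   equal_active = 40, inactive_both = 30,
                                   marginal = 10),
                   n_background = 1500, plant_factors = FALSE)
  sim <- simulate_reprogramome(spec, seed = 42)
  norm <- normalize_counts(sim$counts)
  de <- test_contrast(norm, "ESC", "fibroblast_naive")

  suppressMessages(requireNamespace("DESeq2", quietly = TRUE))
  keep <- sim$counts$design$group %in% c("ESC", "fibroblast_naive")
  cd <- data.frame(condition = factor(sim$counts$design$group[keep],
                                      levels = c("fibroblast_naive", "ESC")))
  dds <- DESeq2::DESeqDataSetFromMatrix(sim$counts$counts[, keep], cd,
                                        ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  idx <- match(de$gene, rownames(res))
  ok <- !is.na(de$p) & !is.na(res$pvalue[idx]) & (de$mean_a + de$mean_b > 20)

  expect_gt(cor(de$log2fc[ok], res$log2FoldChange[idx][ok]), 0.99)
  expect_gt(cor(normalize_counts(sim$counts)$size_factors[keep],
                DESeq2::sizeFactors(dds)), 0.99)
  mine_sig <- ok & de$q < 0.01 & abs(de$log2fc) >= 1
  confirmed <- res$padj[idx][mine_sig] < 0.05 &
    sign(res$log2FoldChange[idx][mine_sig]) == sign(de$log2fc[mine_sig])
  expect_gt(mean(confirmed, na.rm = TRUE), 0.95)
})
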
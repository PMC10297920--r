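test_that("size factors follow the median-of-ratios conventions", {
  m <- matrix(rpois(400, 50) + 1, 100, 4)
  m2 <- cbind(m[, 1], m[, 1])
  expect_equal(unname(size_factors(m2)), c(1, 1))

  m3 <- cbind(m[, 1], 2 * m[, 1])
  sf <- unname(size_factors(m3))
  expect_equal(sf[2] / sf[1], 2)
  expect_equal(exp(mean(log(size_factors(m)))), 1)

  # invariant to gene order
  withr::with_seed(1, perm <- sample(nrow(m)))
  expect_equal(size_factors(m[perm, ]), size_factors(m))

  zeroes <- rbind(c(0, 5), c(3, 0))
  expect_error(size_factors(zeroes), "nonzero")
})

test_that("size factors recover planted depth factors", {
  sheet <- sheep_sample_sheet(1, 1, 1, stages = c("D3", "M3", "M6"))
  depths <- rep(c(1, 1.5, 3), 3)
  sim <- simulate_counts(2000, sheet, depth_factors = depths,
                         nb_dispersion = 0.02, seed = 2)
  sf <- size_factors(sim$counts)
  expected <- depths / exp(mean(log(depths)))
  expect_lt(max(abs(sf / expected - 1)), 0.05)
})

test_that("the NB Wald test is calibrated and powerful", {
  sheet <- sheep_sample_sheet(5, 2, 5, stages = "M3")
  sim <- simulate_counts(1500, sheet, nb_dispersion = 0.05, seed = 3)
  de <- de_test(sim$counts, sim$sheet, c("H", "D"))
  rate <- mean(de$p_value[de$tested] < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.025)
  expect_lt(rate, 0.075)

  sheet6 <- sheep_sample_sheet(6, 2, 6, stages = "M3")
  planted <- tibble::tibble(gene = 1:150, group = "D", log2fc = 2)
  simp <- simulate_counts(600, sheet6, baseline = rep(200, 600),
                          nb_dispersion = 0.05, planted_de = planted, seed = 4)
  dep <- de_test(simp$counts, simp$sheet, c("H", "D"))
  expect_gt(mean(simp$truth$de$gene_id %in% significant_genes(dep)), 0.9)
  # planted direction: D over H, positive log2 fold change
  expect_gt(median(dep$log2_fold_change[1:150]), 1.5)
})

test_that("contrast direction only flips the sign of the fold change", {
  sheet <- sheep_sample_sheet(3, 2, 3, stages = "M3")
  sim <- simulate_counts(300, sheet, nb_dispersion = 0.05, seed = 5)
  d1 <- de_test(sim$counts, sim$sheet, c("H", "D"))
  d2 <- de_test(sim$counts, sim$sheet, c("D", "H"))
  expect_equal(d1$log2_fold_change, -d2$log2_fold_change)
  expect_equal(d1$p_value, d2$p_value)
})

test_that("low-count genes are excluded, never NaN", {
  sheet <- sheep_sample_sheet(3, 2, 3, stages = "M3")
  sim <- simulate_counts(100, sheet, nb_dispersion = 0.05, seed = 6)
  sim$counts[1, ] <- 0L
  de <- de_test(sim$counts, sim$sheet, c("H", "D"))
  expect_false(de$tested[1])
  expect_true(is.na(de$p_value[1]))
  expect_false(any(is.nan(de$p_value[de$tested])))
  expect_true(all(de$p_adjust[de$tested] >= de$p_value[de$tested]))
  expect_error(de_test(sim$counts, sim$sheet, c("H", "X")), "absent")
})

test_that("fold changes agree with an independent NB implementation", {
  skip_if_not_installed("DESeq2")
  sheet <- sheep_sample_sheet(4, 2, 4, stages = "M3")
  planted <- tibble::tibble(gene = 1:40,
                            group = rep(c("H", "D"), 20),
                            log2fc = rep(c(1.5, -1.5), 20))
  sim <- simulate_counts(400, sheet, nb_dispersion = 0.05,
                         planted_de = planted, seed = 7)
  de <- de_test(sim$counts, sim$sheet, c("H", "D"))

  use <- sheet$breed %in% c("H", "D")
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      sim$counts[, sheet$sample_id[use]],
      data.frame(breed = factor(sheet$breed[use], levels = c("H", "D"))),
      ~breed)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds, contrast = c("breed", "D", "H"))
  })
  ok <- de$tested & !is.na(ref$log2FoldChange)
  expect_gt(cor(de$log2_fold_change[ok], ref$log2FoldChange[ok]), 0.95)
  # size factors agree after matching normalization conventions
  sf_ref <- DESeq2::estimateSizeFactorsForMatrix(sim$counts[, sheet$sample_id[use]])
  sf_ref <- sf_ref / exp(mean(log(sf_ref)))
  expect_lt(max(abs(attr(de, "size_factors") - sf_ref)), 1e-6)
})

test_that("BH adjustment equals its brute-force definition", {
  withr::with_seed(8, {
    for (i in 1:50) {
      p <- runif(sample(5:200, 1))
      expect_equal(p.adjust(p, "BH"), bh_brute_force(p))
    }
  })
})

test_that("hypergeometric enrichment matches closed forms", {
  u <- paste0("g", 1:10)
  res <- enrich_hypergeometric(u[1:4], list(s = u[1:5]), u)
  expect_lt(abs(res$p_value[1] - 5 / 210), 1e-12)

  # saturation: selecting the whole universe gives p = 1
  res2 <- enrich_hypergeometric(u, list(s = u[1:5]), u)
  expect_equal(res2$p_value[1], 1)

  # sets that vanish after universe intersection are skipped with a note
  res3 <- enrich_hypergeometric(u[1:3], list(s = c("zz", "yy")), u)
  expect_true(is.na(res3$p_value[1]))
  expect_match(res3$note[1], "empty")

  expect_error(enrich_hypergeometric(character(), list(s = u), u), "empty")
  expect_error(enrich_hypergeometric(c("nope"), list(s = u), u), "subset")
})

test_that("GMT files round-trip into named gene-set lists", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg9"), path)
  sets <- read_gmt(path)
  expect_identical(names(sets), c("setA", "setB"))
  expect_identical(sets$setB, c("g2", "g9"))
  res <- enrich_hypergeometric(c("g1", "g2"), path, paste0("g", 1:9))
  expect_identical(res$overlap_count[1], 2L)
})

test_that("stage-specific DEG sets follow exclusive set algebra", {
  fake_de <- function(sig, universe) {
    structure(tibble::tibble(
      gene_id = universe,
      base_mean = 10, log2_fold_change = 1, lfc_se = 1, stat = 1,
      p_value = ifelse(universe %in% sig, 0.001, 0.8),
      p_adjust = ifelse(universe %in% sig, 0.01, 0.9),
      tested = TRUE), class = c("de_result", "tbl_df", "tbl", "data.frame"))
  }
  u <- paste0("g", 1:20)
  des <- list(M3 = fake_de(c("g1", "g2", "g3"), u),
              M6 = fake_de(c("g3", "g4"), u),
              M12 = fake_de(c("g5"), u))
  out <- stage_specific_degs(des)
  expect_setequal(out$gene_id[out$stage == "M3"], c("g1", "g2"))
  expect_setequal(out$gene_id[out$stage == "M6"], "g4")
  expect_setequal(out$gene_id[out$stage == "M12"], "g5")
  expect_false("g3" %in% out$gene_id)

  # brute-force double loop over stages x genes gives the same sets
  sig <- lapply(des, significant_genes)
  for (st in names(des)) {
    brute <- character()
    for (g in u) {
      if (g %in% sig[[st]] &&
          !any(vapply(setdiff(names(des), st),
                      function(o) g %in% sig[[o]], logical(1))))
        brute <- c(brute, g)
    }
    expect_setequal(out$gene_id[out$stage == st], brute)
  }

  des_bad <- des
  des_bad$M6$gene_id[1] <- "other"
  expect_error(stage_specific_degs(des_bad), "universes")
})
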
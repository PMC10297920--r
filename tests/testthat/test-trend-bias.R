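test_that("quantile normalization equalizes sample distributions", {
  withr::with_seed(1, v <- rpois(50, 20))
  m <- cbind(a = v, b = sample(v))
  out <- normalize_to_normal(m, standardize = FALSE)
  expect_equal(sort(out[, 1]), sort(out[, 2]))
  expect_equal(mean(out[, 1]), mean(out[, 2]))

  # tie-free values: columns share one distribution, hence exact equal means
  withr::with_seed(2, cont <- matrix(rgamma(600, 5, 0.1), 100, 6))
  qn <- normalize_to_normal(cont, standardize = FALSE)
  expect_lt(diff(range(colMeans(qn))), 1e-8)
  expect_equal(sort(qn[, 1]), sort(qn[, 6]))

  # integer counts carry ties; averaged tied ranks keep means near-equal
  withr::with_seed(2, big <- matrix(rnbinom(600, mu = 50, size = 10), 100, 6))
  qnc <- normalize_to_normal(big, standardize = FALSE)
  expect_lt(diff(range(colMeans(qnc))) / mean(qnc), 0.01)

  z <- normalize_to_normal(big)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_error(normalize_to_normal(big[, 1, drop = FALSE]), "2 samples")
  expect_error(normalize_to_normal(-big), "nonnegative")
})

test_that("corrected NB expression looks roughly normal per gene", {
  # the study's per-stage scale: 14 animals, typical dispersion 0.05
  withr::with_seed(3, m <- matrix(rnbinom(300 * 14, mu = 100, size = 20), 300, 14))
  z <- normalize_to_normal(m)
  sh <- apply(z, 1, function(x) stats::shapiro.test(x)$p.value)
  # descriptive: no gross excess of rejections over the nominal rate
  expect_lt(mean(sh < 0.05), 0.15)
})

test_that("fuzzy c-means satisfies its defining constraints", {
  withr::with_seed(4, x <- matrix(rnorm(60 * 4), 60, 4))
  fit <- fcm_cluster(x, c = 3, m = 2, seed = 5)
  expect_lt(max(abs(rowSums(fit$membership) - 1)), 1e-9)
  expect_true(all(fit$membership >= 0 & fit$membership <= 1))
  expect_true(all(diff(fit$objective) <= 1e-9))
  expect_true(all(is.finite(fit$centers)))

  # stationarity: memberships reproduce from the final centers
  d2 <- vapply(1:3, function(j) rowSums(sweep(x, 2, fit$centers[j, ])^2),
               numeric(60))
  u <- 1 / (d2 * rowSums(1 / d2))
  expect_lt(max(abs(u - fit$membership)), 1e-3)

  expect_identical(fcm_cluster(x, c = 3, seed = 9)$membership,
                   fcm_cluster(x, c = 3, seed = 9)$membership)
  expect_error(fcm_cluster(x, c = 61), "more clusters")
  expect_error(fcm_cluster(x, c = 2, m = 1), "fuzzifier")
})

test_that("coincident points and centers never produce NaN memberships", {
  # duplicated rows guarantee that initial centers (drawn from the data)
  # coincide exactly with some genes, exercising the singularity rule
  x <- rbind(matrix(0, 6, 2), matrix(5, 6, 2))
  fit <- fcm_cluster(x, c = 2, seed = 1)
  expect_false(any(is.nan(fit$membership)))
  expect_lt(max(abs(rowSums(fit$membership) - 1)), 1e-9)
  expect_identical(length(unique(fit$cluster[1:6])), 1L)
  expect_false(fit$cluster[1] == fit$cluster[7])
  # centers converge onto the two point masses, giving memberships 1 exactly
  expect_equal(max(fit$membership[1, ]), 1)
})

test_that("two opposite planted trends separate perfectly", {
  up <- matrix(rep(c(-1, -0.33, 0.33, 1), each = 30), 30)
  down <- -up
  withr::with_seed(6, x <- rbind(up, down) + matrix(rnorm(240, sd = 0.05), 60, 4))
  fit <- fcm_cluster(x, c = 2, m = 2, seed = 7)
  expect_gt(min(apply(fit$membership, 1, max)), 0.95)
  expect_identical(length(unique(fit$cluster[1:30])), 1L)
  expect_identical(length(unique(fit$cluster[31:60])), 1L)
  expect_false(fit$cluster[1] == fit$cluster[31])
})

test_that("fcm agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  up <- matrix(rep(c(-1, 0, 1), each = 40), 40)
  down <- -up
  withr::with_seed(8, x <- rbind(up, down) + matrix(rnorm(240, sd = 0.1), 80, 3))
  ours <- fcm_cluster(x, c = 2, m = 2, seed = 9)
  set.seed(10)
  ref <- e1071::cmeans(x, centers = 2, m = 2, iter.max = 200)
  expect_equal(mclust::adjustedRandIndex(ours$cluster, ref$cluster), 1)
  ord <- if (sum((ours$centers[1, ] - ref$centers[1, ])^2) <
             sum((ours$centers[1, ] - ref$centers[2, ])^2)) 1:2 else 2:1
  expect_lt(max(abs(ours$centers - ref$centers[ord, ])), 0.05)
})

test_that("trend-pattern classification flags discordant genes", {
  stages <- 4
  csa <- list(H = c(1, 2, 3, 4), HD = c(1, 2.5, 3.5, 4.5), D = c(1, 3, 4, 5))
  n_conc <- 250; n_disc <- 24
  shape <- seq(-1, 1, length.out = stages)
  make_breed <- function(flip_disc) {
    withr::with_seed(11 + flip_disc, {
      conc <- matrix(shape, n_conc, stages, byrow = TRUE)
      disc <- matrix(if (flip_disc) -shape else shape, n_disc, stages,
                     byrow = TRUE)
      rbind(conc, disc) + matrix(rnorm((n_conc + n_disc) * stages, sd = 0.2),
                                 n_conc + n_disc)
    })
  }
  trends <- list(H = make_breed(FALSE), HD = make_breed(FALSE),
                 D = make_breed(TRUE))
  rownames(trends$H) <- rownames(trends$HD) <- rownames(trends$D) <-
    sprintf("g%03d", seq_len(n_conc + n_disc))
  out <- classify_trend_patterns(trends, csa, c = 2, seed = 12)
  truth_disc <- c(rep(FALSE, n_conc), rep(TRUE, n_disc))
  expect_gte(mean(out$discordant[truth_disc]), 0.9)
  expect_lt(mean(out$discordant[!truth_disc]), 0.1)

  # a perfect tracker in every breed is concordant and positive everywhere
  expect_true(all(out$sign_H[!truth_disc] == out$sign_D[!truth_disc]))

  bad <- trends; bad$D <- bad$D[, 1:3]
  expect_error(classify_trend_patterns(bad, csa, seed = 1), "stage grid")
})

test_that("confidence intervals match the t closed form", {
  ci <- confidence_interval(c(5, 5, 5, 5))
  expect_identical(c(ci$lower, ci$mean, ci$upper), c(5, 5, 5))

  ci2 <- confidence_interval(c(0, 2), 0.95)
  expect_equal(ci2$mean, 1)
  expect_lt(abs((ci2$upper - ci2$mean) - 12.7062047), 1e-3)
  expect_lt(abs(ci2$lower + 11.7062047), 1e-2)

  withr::with_seed(13, v <- rnorm(10))
  wide <- confidence_interval(v, 0.99)
  narrow <- confidence_interval(v, 0.95)
  expect_lt(wide$lower, narrow$lower)
  expect_gt(wide$upper, narrow$upper)
  expect_error(confidence_interval(3), "n >= 2")
  expect_error(confidence_interval(c(1, 2), level = 1.2), "level")
})

test_that("bias calls follow the two-interval decision rule", {
  vH <- c(10, 11, 9, 10.5, 9.5, 10)
  vD <- c(20, 21, 19)
  expect_identical(call_bias(vH, vD, 20)$call, "toward_D")
  expect_identical(call_bias(vH, vD, 10)$call, "toward_H")

  overlap_H <- c(9, 10, 11); overlap_D <- c(10, 11, 12)
  expect_identical(call_bias(overlap_H, overlap_D, 10.5)$call, "unbiased")

  far <- call_bias(c(0, 0.1, -0.1), c(10, 10.1, 9.9), 5.2)
  expect_identical(far$call, "toward_D")
  tie <- call_bias(c(0, 0.1, -0.1), c(10, 10.1, 9.9), 5.0)
  expect_identical(tie$call, "ambiguous")

  pooled <- call_bias(vH, vD, 40, mode = "pooled_ci")
  expect_identical(pooled$call, "toward_D")
  expect_error(call_bias(c(1), vD, 1), "H needs")
})

test_that("bias calls are equivariant under affine transforms", {
  withr::with_seed(14, {
    for (i in 1:25) {
      vH <- rnorm(6); vD <- rnorm(3, mean = 2); hd <- rnorm(1, mean = 1)
      a <- runif(1, 0.2, 5); b <- rnorm(1, sd = 10)
      c0 <- call_bias(vH, vD, hd)$call
      c1 <- call_bias(a * vH + b, a * vD + b, a * hd + b)$call
      expect_identical(c1, c0)
    }
  })
})

test_that("the biased-gene count decreases as the level rises", {
  sim <- simulate_counts(400, sheep_sample_sheet(6, 5, 3),
    nb_dispersion = 0.05,
    planted_bias = tibble::tibble(gene = 1:40,
      scenario = rep(c("toward_D", "unbiased"), 20)),
    seed = 15)
  corr <- normalize_to_normal(sim$counts)
  genes <- sim$truth$bias$gene_id
  n_biased <- vapply(c(0.5, 0.8, 0.95, 0.999), function(lv) {
    bc <- call_bias_table(corr, sim$sheet, genes, level = lv)
    sum(bc$by_stage$call %in% c("toward_D", "toward_H"))
  }, numeric(1))
  expect_true(all(diff(n_biased) <= 0))
})

test_that("per-stage calls aggregate by majority with ambiguous ties", {
  expect_identical(ovimyo:::majority_call(c("toward_D", "toward_D", "unbiased")),
                   "toward_D")
  expect_identical(ovimyo:::majority_call(c("toward_D", "toward_H")),
                   "ambiguous")
  expect_identical(ovimyo:::majority_call("unbiased"), "unbiased")
})

test_that("planted bias scenarios are recovered at the study design", {
  plant <- tibble::tibble(gene = 1:130,
    scenario = c(rep("toward_D", 30), rep("toward_H", 30),
                 rep("unbiased", 70)))
  sim <- simulate_counts(1000, sheep_sample_sheet(6, 5, 3),
                         nb_dispersion = 0.05, planted_bias = plant,
                         bias_lfc = 2, seed = 16)
  corr <- normalize_to_normal(sim$counts)
  bc <- call_bias_table(corr, sim$sheet, genes = sim$truth$bias$gene_id)
  j <- dplyr::left_join(bc$overall, sim$truth$bias, by = "gene_id")
  expect_gte(mean(j$call[j$scenario == "toward_D"] == "toward_D"), 0.8)
  expect_gte(mean(j$call[j$scenario == "toward_H"] == "toward_H"), 0.8)
  expect_lte(mean(j$call[j$scenario == "unbiased"] %in%
                    c("toward_D", "toward_H")), 0.1)

  # per-animal voting mode returns the same call families
  bc2 <- call_bias_table(corr, sim$sheet,
                         genes = sim$truth$bias$gene_id[1:10],
                         per_animal = TRUE)
  expect_true(all(bc2$overall$call %in%
                    c("toward_D", "toward_H", "unbiased", "ambiguous")))
})

test_that("hypertrophy screening is a plain, order-stable intersection", {
  sim <- simulate_module_expression(2, 25, 10, 10, noise_sd = 0.3, seed = 17)
  fit <- build_modules(sim$expr, coexpression_config())
  mod <- names(fit$module_sizes)[names(fit$module_sizes) != "grey"][1]
  members <- fit$genes$gene_id[fit$genes$module == mod]

  expect_identical(hypertrophy_gene_screen(c("zz1", "zz2"), fit, mod),
                   character(0))
  expect_identical(hypertrophy_gene_screen(members[1:5], fit, mod),
                   sort(members[1:5]))
  degs <- list(a = members[1:3], b = c(members[3:6], "zz"))
  expect_identical(hypertrophy_gene_screen(degs, fit, mod),
                   sort(intersect(unique(unlist(degs)), members)))
  expect_error(hypertrophy_gene_screen(members, fit, "puce"), "unknown module")
})
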
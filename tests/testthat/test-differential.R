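make_pc <- function(count_list, conditions = c("A", "A", "B", "B"),
                    L = length(count_list[[1]])) {
  ref <- rrna_reference(c(x = strrep("A", L)))
  design <- tibble::tibble(sample_id = names(count_list),
                           condition = conditions)
  positional_counts(count_list, design, ref)
}

test_that("size factors implement median-of-ratios", {
  set.seed(41)
  base <- as.integer(rpois(200, 20) + 1)
  pc_id <- make_pc(list(a = base, b = base, c = base, d = base))
  expect_equal(unname(estimate_size_factors(pc_id)), rep(1, 4))

  # pure depth difference: factors proportional to depth
  pc_depth <- make_pc(list(a = base, b = 2L * base, c = base, d = 2L * base))
  sf <- estimate_size_factors(pc_depth)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)

  # brute-force median-of-ratios oracle on a random 3-sample matrix
  cl <- list(a = as.integer(rpois(150, 30)), b = as.integer(rpois(150, 60)),
             c = as.integer(rpois(150, 15)))
  pc3 <- suppressWarnings(make_pc(cl, conditions = c("A", "A", "B")))
  m <- do.call(rbind, cl)
  geo <- apply(m, 2, function(x) exp(mean(log(x))))
  ok <- is.finite(geo) & geo > 0
  manual <- apply(sweep(m[, ok], 2, geo[ok], "/"), 1, median)
  expect_equal(unname(estimate_size_factors(pc3)), unname(manual))

  # cross-check against the reference implementation (which takes the median
  # on the log scale, hence the loose tolerance on even-length medians)
  ds <- DESeq2::estimateSizeFactorsForMatrix(t(m))
  expect_equal(unname(estimate_size_factors(pc3)), unname(ds),
               tolerance = 1e-3)

  # scaling one sample's raw counts leaves normalized counts unchanged up to
  # one global constant (the scaled sample shifts every geometric mean)
  cl2 <- cl; cl2$b <- 3L * cl2$b
  pc3b <- suppressWarnings(make_pc(cl2, conditions = c("A", "A", "B")))
  n1 <- sweep(do.call(rbind, cl), 1, estimate_size_factors(pc3), "/")
  n2 <- sweep(do.call(rbind, cl2), 1, estimate_size_factors(pc3b), "/")
  ratio <- n2 / n1
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-10)
  expect_equal(unique(round(as.vector(ratio), 10)), 3^(1/3))

  # all-zero overlap triggers the library-size fallback
  pc0 <- make_pc(list(a = c(2L, 0L, 0L, 0L), b = c(0L, 4L, 0L, 0L),
                      c = c(0L, 0L, 6L, 0L), d = c(0L, 0L, 0L, 8L)))
  expect_warning(sf0 <- estimate_size_factors(pc0), "library-size")
  expect_true(all(sf0 > 0))
})

test_that("dispersion estimates track the simulation truth", {
  ref <- rrna_reference(c(r = strrep("A", 2000)))
  # Poisson counts: fitted dispersions collapse towards zero
  simP <- simulate_positional_counts(ref, n_per_group = 3, depth = 50,
                                     dispersion = 0, seed = 4)
  dP <- fit_dispersions(filter_low_counts(simP$pc))
  expect_lt(median(dP), 0.05)

  # NB dispersion 0.5 recovered near the truth
  sim5 <- simulate_positional_counts(ref, n_per_group = 3, depth = 50,
                                     dispersion = 0.5, seed = 3)
  d5 <- fit_dispersions(filter_low_counts(sim5$pc))
  expect_gt(median(d5), 0.3)
  expect_lt(median(d5), 0.7)

  # constant counts across samples sit at the floor
  pcC <- make_pc(list(a = rep(5L, 100), b = rep(5L, 100),
                      c = rep(5L, 100), d = rep(5L, 100)))
  expect_equal(unname(median(fit_dispersions(pcC))), 1e-8, tolerance = 1e-3)

  # single-replicate designs use the flagged conservative fallback
  suppressWarnings(
    pc1 <- make_pc(list(a = rpois(50, 10), b = rpois(50, 10)),
                   conditions = c("A", "B"))
  )
  d1 <- fit_dispersions(pc1)
  expect_true(attr(d1, "fallback"))
  expect_equal(unname(unique(d1)), 0.1)
})

test_that("the closed-form Wald fit agrees with an IRLS NB GLM", {
  ref <- rrna_reference(c(r = strrep("A", 40)))
  sim <- simulate_positional_counts(ref, n_per_group = 3, depth = 50,
                                    dispersion = 0.2, seed = 12)
  pc <- filter_low_counts(sim$pc)
  sf <- estimate_size_factors(pc)
  disp <- rep(0.2, sum(pc$retained))
  dt <- wald_test(pc, sf, disp)
  cond <- pc$design$condition
  for (i in sample(nrow(dt), 10)) {
    y <- pc$counts[, dt$concat0[i] + 1L]
    if (any(tapply(y, cond, sum) == 0)) next  # continuity-corrected case
    fit <- suppressWarnings(
      glm(y ~ cond + offset(log(sf)), family = MASS::negative.binomial(1 / 0.2))
    )
    sm <- summary(fit, dispersion = 1)$coefficients
    expect_equal(dt$log2FC[i], unname(sm[2, 1]) / log(2), tolerance = 1e-4)
    expect_equal(dt$pvalue[i],
                 2 * pnorm(-abs(unname(sm[2, 1] / sm[2, 2]))), tolerance = 1e-3)
  }
})

test_that("the Wald test is calibrated under the null and recovers effects", {
  ref <- rrna_reference(c(r = strrep("A", 2000)))
  sim <- simulate_positional_counts(ref, n_per_group = 3, depth = 50,
                                    dispersion = 0.1, seed = 101)
  d <- differential_abundance(filter_low_counts(sim$pc))
  t1 <- mean(d$result$pvalue < 0.05, na.rm = TRUE)
  expect_gte(t1, 0.03)
  expect_lte(t1, 0.07)

  # true log2FC = 1 at 200 positions is recovered within +- 0.2
  spiked <- sort(sample(0:1999, 200))
  sets <- tibble::tibble(rp_id = "RPX", rank = seq_along(spiked),
                         rrna_id = "r", pos = spiked + 1L,
                         concat0 = spiked, distance = 1)
  csc <- structure(list(sets = sets, backgrounds = list(), tau = 1, cap = 400L,
                        shift = 20L, n_background = 0L, total_length = 2000L),
                   class = "contact_set_collection")
  sim2 <- simulate_positional_counts(ref, csc, target_rp = "RPX",
                                     effect_log2fc = 1, effect_fraction = 1,
                                     seed = 5)
  d2 <- differential_abundance(filter_low_counts(sim2$pc))
  est <- d2$result$log2FC[d2$result$concat0 %in% sim2$truth$concat0]
  expect_equal(mean(est), 1, tolerance = 0.2)

  # extreme separation: all-zero A vs large B gives a large positive log2FC
  # and a small p (sign convention: second level vs first)
  pcx <- make_pc(list(a = c(0L, 10L), b = c(0L, 12L),
                      c = c(200L, 9L), d = c(180L, 11L)))
  dx <- wald_test(pcx, dispersions = rep(0.05, 2))
  expect_gt(dx$log2FC[1], 5)
  expect_lt(dx$pvalue[1], 1e-4)
})

test_that("label swap negates fold changes and preserves p-values", {
  set.seed(52)
  cl <- lapply(1:6, function(i) as.integer(rpois(300, 25)))
  names(cl) <- paste0("s", 1:6)
  pcA <- make_pc(cl, conditions = factor(rep(c("A", "B"), each = 3),
                                         levels = c("A", "B")))
  pcB <- make_pc(cl, conditions = factor(rep(c("B", "A"), each = 3),
                                         levels = c("A", "B")))
  # same dispersions on both to isolate the contrast
  sf <- estimate_size_factors(pcA)
  disp <- fit_dispersions(pcA, sf)
  dA <- wald_test(pcA, sf, disp)
  dB <- wald_test(pcB, sf, disp)
  expect_equal(dA$log2FC, -dB$log2FC)
  expect_equal(dA$pvalue, dB$pvalue)

  # BH is monotone: ordering by p equals ordering by padj up to ties
  expect_equal(order(dA$pvalue, dA$concat0), order(dA$padj, dA$pvalue, dA$concat0))
})

test_that("the ranking score implements the published floor formula", {
  dt <- tibble::tibble(
    rrna_id = "r", pos = 1:6, concat0 = 0:5, baseMean = 1,
    log2FC = c(2, 0, 1, 0.3, -1.5, 4),
    pvalue = c(0.001, 0.5, 1e-9, 0.2, 1e-3, NA),
    padj = c(0.01, 0.9, 1e-8, 0.6, 0.04, NA)
  )
  sc <- ranking_scores(dt)
  expect_equal(sc$rank_score[1], 2 * 5)        # -log10(0.01) = 2 -> floor 5
  expect_equal(sc$rank_score[2], 0)            # zero fold change
  expect_equal(sc$rank_score[3], 1 * 8)        # -log10(1e-8) = 8 > 5
  expect_equal(sc$rank_score[5], 1.5 * 5)      # |log2FC| enters as magnitude
  expect_equal(sc$rank_score[6], 4 * 5)        # missing padj counts as 1

  # for padj >= 1e-5 the multiplier is exactly 5
  expect_true(all(sc$rank_score[sc$padj >= 1e-5 & !is.na(sc$padj)] ==
                    5 * abs(sc$log2FC[sc$padj >= 1e-5 & !is.na(sc$padj)])))

  # padj clamp keeps scores finite
  tiny <- ranking_scores(dplyr::mutate(dt[3, ], padj = 0))
  expect_equal(tiny$rank_score, 1 * 300)

  # the cap variant bounds the multiplier instead
  expect_equal(ranking_scores(dt, score_mode = "cap")$rank_score[3], 1 * 5)
  expect_equal(ranking_scores(dt, score_mode = "cap")$rank_score[1], 2 * 2)
})

test_that("sample PCA separates groups and reports variance fractions", {
  set.seed(61)
  profile1 <- rpois(400, 30); profile2 <- rpois(400, 30)
  noisy <- function(p) as.integer(pmax(p + rpois(400, 2) - 2, 0))
  pc <- make_pc(list(a = noisy(profile1), b = noisy(profile1),
                     c = noisy(profile2), d = noisy(profile2)))
  pca <- sample_pca(pc)
  ve <- attr(pca, "var_explained")
  expect_true(all(diff(ve) <= 1e-12))
  expect_lte(sum(ve), 1 + 1e-8)
  # PC1 separates the two groups
  expect_gt(min(abs(pca$PC1[1:2] - pca$PC1[3:4])), 0)
  expect_true(all(sign(pca$PC1[1:2]) != sign(pca$PC1[3:4])))

  # identical samples get identical coordinates
  pc_id <- make_pc(list(a = profile1, b = profile1,
                        c = profile1, d = profile1))
  pca_id <- sample_pca(pc_id)
  expect_equal(pca_id$PC1, rep(pca_id$PC1[1], 4))
})
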
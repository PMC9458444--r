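#' Median-of-ratios size factors
#'
#' Sequencing-depth normalization across samples: each sample's factor is the
#' median, over reference positions, of the ratio between its count and the
#' position's geometric mean across samples.  Reference positions are the
#' retained positions with a non-zero count in every sample.  Identical
#' samples get factors of 1, and scaling one sample's raw counts by a
#' constant scales its factor by the same constant, leaving normalized
#' counts unchanged.  When no position is non-zero in all samples the
#' factors fall back to relative library size over retained positions, with
#' a warning.
#'
#' @param pc A `positional_counts` object.
#' @return Named numeric vector of positive per-sample factors.
#' @export
estimate_size_factors <- function(pc) {
  stopifnot(inherits(pc, "positional_counts"))
  m <- pc$counts[, pc$retained, drop = FALSE]
  geo <- exp(colMeans(log(m)))            # -Inf logs make zero-count cols NaN/0
  ok <- is.finite(geo) & geo > 0
  if (!any(ok)) {
    warn("no position has non-zero counts in all samples; falling back to library-size factors")
    totals <- rowSums(m)
    sf <- totals / geom_mean(totals)
  } else {
    ratios <- sweep(m[, ok, drop = FALSE], 2, geo[ok], "/")
    sf <- apply(ratios, 1, median)
  }
  if (any(!is.finite(sf) | sf <= 0)) {
    stop_ribohet("could not compute positive size factors", "ribohet_validation_error")
  }
  setNames(sf, rownames(pc$counts))
}

#' Per-position negative-binomial dispersions
#'
#' Each retained position gets a maximum a posteriori (MAP) dispersion: the
#' NB likelihood at the fitted group means, combined with a log-normal prior
#' centered on a mean-dispersion trend.  The trend `a0 + a1/mu` is fitted
#' across positions by a gamma GLM to method-of-moments estimates (pooled
#' within-condition variance, shot noise subtracted); the prior width is the
#' spread of the position-wise estimates around the trend in excess of their
#' sampling noise (`trigamma(df/2)`), floored at 0.25.  This shrinks noisy
#' position-wise estimates toward the trend - strongly when positions share a
#' common dispersion, weakly when dispersion genuinely varies - and keeps the
#' per-position Wald tests calibrated at small replicate numbers.  Everything
#' is floored at 1e-8.  Designs with a single replicate in a condition get a
#' fixed conservative dispersion of 0.1 (flagged via the `"fallback"`
#' attribute).
#'
#' @param pc A `positional_counts`.
#' @param sf Size factors from [estimate_size_factors()].
#' @return Numeric vector over retained positions (named by position label),
#'   with attributes `trend` (function of mu) and `fallback` (logical).
#' @export
fit_dispersions <- function(pc, sf = estimate_size_factors(pc)) {
  stopifnot(inherits(pc, "positional_counts"))
  floor_disp <- 1e-8
  m <- pc$counts[, pc$retained, drop = FALSE]
  labels <- colnames(m)
  if (isTRUE(pc$single_replicate)) {
    out <- setNames(rep(0.1, ncol(m)), labels)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  norm <- sweep(m, 1, sf, "/")
  cond <- pc$design$condition
  xim <- mean(1 / sf)
  mu <- colMeans(norm)
  # pooled within-condition variance
  ss <- 0
  for (lv in levels(cond)) {
    sub <- norm[cond == lv, , drop = FALSE]
    ss <- ss + colSums(sweep(sub, 2, colMeans(sub))^2)
  }
  v <- ss / (nrow(norm) - nlevels(cond))
  mom <- (v - xim * mu) / mu^2
  mom[!is.finite(mom)] <- floor_disp
  mom <- pmax(mom, floor_disp)

  # parametric trend a0 + a1/mu (gamma GLM, identity link), median fallback
  use <- mom > 1e-6 & mu > 0
  trend_fun <- NULL
  if (sum(use) >= 10) {
    fit <- tryCatch(
      glm(mom[use] ~ I(1 / mu[use]),
          family = stats::Gamma(link = "identity"),
          start = c(pmax(median(mom[use]), 1e-4), 1)),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(fit) && all(is.finite(coef(fit))) && coef(fit)[1] > 0) {
      a <- coef(fit)
      trend_fun <- function(x) pmax(a[1] + a[2] / x, floor_disp)
    }
  }
  if (is.null(trend_fun)) {
    med <- pmax(median(mom), floor_disp)
    trend_fun <- function(x) rep(med, length(x))
  }

  # prior width: spread of log position-wise estimates around the trend in
  # excess of their sampling noise (~ trigamma(df/2) for df residual df)
  lt <- log(trend_fun(mu))
  var_samp <- trigamma(max(nrow(norm) - nlevels(cond), 2) / 2)
  var_prior <- if (sum(use) >= 10) {
    max((stats::mad(log(mom[use]) - lt[use]))^2 - var_samp, 0.25)
  } else 0.25

  # MAP: NB log-likelihood at the fitted group means plus the log-normal
  # trend prior, maximized in log dispersion
  ga <- cond == levels(cond)[1]
  qa <- colSums(m[ga, , drop = FALSE]) / sum(sf[ga])
  qb <- colSums(m[!ga, , drop = FALSE]) / sum(sf[!ga])
  out <- vapply(seq_len(ncol(m)), function(i) {
    mu_j <- pmax(sf * ifelse(ga, qa[i], qb[i]), 1e-8)
    y <- m[, i]
    neg_post <- function(la) {
      -sum(dnbinom(y, mu = mu_j, size = exp(-la), log = TRUE)) -
        stats::dnorm(la, lt[i], sqrt(var_prior), log = TRUE)
    }
    exp(stats::optimize(neg_post, c(-25, 5))$minimum)
  }, numeric(1))
  out <- setNames(pmax(out, floor_disp), labels)
  attr(out, "trend") <- trend_fun
  attr(out, "fallback") <- FALSE
  out
}

#' Per-position Wald test for differential rRNA fragment abundance
#'
#' Fits, at every retained position, the negative-binomial GLM with log link
#' `count ~ condition` with the log size factor as offset and the supplied
#' per-position dispersion, and tests the condition coefficient with a Wald
#' test.  For a saturated two-group design the maximum-likelihood fit is the
#' offset-weighted group mean, so the fit is closed-form: `beta = log(mB/mA)`
#' with `m_g = sum(counts)/sum(sf)` within group, standard error from the
#' Fisher information `I_g = sum(mu_j / (1 + disp * mu_j))` evaluated at the
#' fitted means.  A group with an all-zero total gets a 0.5 continuity
#' correction on its summed count so the fold change stays finite.  P-values
#' are two-sided normal; adjustment is Benjamini-Hochberg across retained
#' positions.  Positions where both groups are all zero get `NA` p-values and
#' are excluded from the adjustment.
#'
#' @param pc A `positional_counts`.
#' @param sf Size factors.
#' @param dispersions Per-retained-position dispersions
#'   ([fit_dispersions()]), or a single value recycled.
#' @return A tibble with one row per retained position: `rrna_id`, `pos`,
#'   `concat0`, `baseMean`, `log2FC` (second condition level vs first),
#'   `pvalue`, `padj`.
#' @export
wald_test <- function(pc, sf = estimate_size_factors(pc),
                      dispersions = fit_dispersions(pc, sf)) {
  stopifnot(inherits(pc, "positional_counts"))
  m <- pc$counts[, pc$retained, drop = FALSE]
  disp <- rep_len(as.numeric(dispersions), ncol(m))
  cond <- pc$design$condition
  ga <- cond == levels(cond)[1]
  gb <- !ga

  # MLE of the group mean on the common scale: m_g solves the NB score
  # equation sum_j (y_j - s_j m) / (1 + disp * s_j m) = 0.  The depth-ratio
  # estimate sum(y)/sum(s) is exact for equal size factors and is refined by
  # Newton steps otherwise.  All-zero groups get a 0.5 continuity correction
  # so the fold change stays finite.
  group_mean <- function(idx) {
    y <- m[idx, , drop = FALSE]
    s <- sf[idx]
    tot <- colSums(y)
    est <- pmax(tot, 0.5) / sum(s)
    for (it in 1:25) {
      mu <- outer(s, est)
      denom <- 1 + sweep(mu, 2, disp, "*")
      f <- colSums((y - mu) / denom)
      fp <- colSums(sweep((1 + sweep(y, 2, disp, "*")) / denom^2, 1, s, "*"))
      step <- f / fp
      est_new <- pmax(est + step, 1e-12)
      conv <- max(abs(step) / pmax(est, 1e-8))
      est <- est_new
      if (conv < 1e-10) break
    }
    est[tot == 0] <- 0.5 / sum(s)
    est
  }
  sum_a <- colSums(m[ga, , drop = FALSE])
  sum_b <- colSums(m[gb, , drop = FALSE])
  both_zero <- sum_a == 0 & sum_b == 0
  qa <- group_mean(ga)
  qb <- group_mean(gb)
  beta <- log(qb / qa)

  info_g <- function(mg, sfs) {
    mu <- outer(sfs, mg)                      # samples x positions
    colSums(mu / (1 + sweep(mu, 2, disp, "*")))
  }
  se <- sqrt(1 / info_g(qa, sf[ga]) + 1 / info_g(qb, sf[gb]))
  z <- beta / se
  pvalue <- 2 * pnorm(-abs(z))
  pvalue[both_zero] <- NA_real_
  log2fc <- beta / log(2)
  log2fc[both_zero] <- 0

  idx0 <- unname(which(pc$retained)) - 1L
  loc <- from_concatenated(pc$reference, idx0)
  tibble::tibble(
    rrna_id = loc$rrna_id,
    pos = loc$pos_1based,
    concat0 = idx0,
    baseMean = unname(colMeans(sweep(m, 1, sf, "/"))),
    log2FC = unname(log2fc),
    pvalue = unname(pvalue),
    padj = unname(p.adjust(pvalue, method = "BH"))
  )
}

#' Enrichment ranking score
#'
#' Adds the score that orders rRNA positions for the set-enrichment walk:
#' `abs(log2FC) * max(-log10(padj), 5)`.  Note the `max()` acts as a floor -
#' every position with `padj >= 1e-5` gets the multiplier 5, so among those
#' the ordering is by `abs(log2FC)` alone.  `score_mode = "cap"` replaces the
#' floor with a cap (`min(-log10(padj), 5)`) for users who prefer bounded
#' p-value influence; the default is the floor.  Missing `padj` counts as 1;
#' `padj` is clamped at 1e-300 before the log so the score stays finite.
#'
#' @param dt A differential tibble from [wald_test()].
#' @param score_mode `"floor"` (default) or `"cap"`.
#' @return `dt` with a `rank_score` column added.
#' @export
ranking_scores <- function(dt, score_mode = c("floor", "cap")) {
  score_mode <- match.arg(score_mode)
  padj <- pmin(pmax(dt$padj, 1e-300), 1)
  padj[is.na(padj)] <- 1
  nl <- -log10(padj)
  mult <- if (score_mode == "floor") pmax(nl, 5) else pmin(nl, 5)
  dplyr::mutate(dt, rank_score = abs(.data$log2FC) * mult)
}

#' Differential positional abundance, end to end
#'
#' Chains [estimate_size_factors()], [fit_dispersions()], [wald_test()] and
#' [ranking_scores()] into the fitted object the enrichment step consumes.
#'
#' @param pc A `positional_counts` (run [filter_low_counts()] first).
#' @param score_mode Passed to [ranking_scores()].
#' @return An object of class `rrna_differential`: list with `result` (the
#'   per-position tibble), `size_factors`, `dispersions`, `design`,
#'   `reference`.
#' @export
differential_abundance <- function(pc, score_mode = c("floor", "cap")) {
  stopifnot(inherits(pc, "positional_counts"))
  sf <- estimate_size_factors(pc)
  disp <- fit_dispersions(pc, sf)
  res <- ranking_scores(wald_test(pc, sf, disp), score_mode = score_mode)
  structure(
    list(result = res, size_factors = sf, dispersions = disp,
         design = pc$design, reference = pc$reference),
    class = "rrna_differential"
  )
}

#' @export
print.rrna_differential <- function(x, ...) {
  n_sig <- sum(x$result$padj < 0.05 & abs(x$result$log2FC) > 0.5, na.rm = TRUE)
  cat("<rrna_differential> ", nrow(x$result), " positions tested; ",
      n_sig, " significant (padj < 0.05 & |log2FC| > 0.5); contrast ",
      levels(x$design$condition)[2], " vs ",
      levels(x$design$condition)[1], "\n", sep = "")
  invisible(x)
}

#' @rdname differential_abundance
#' @param x An `rrna_differential`.
#' @param ... Unused.
#' @export
tidy.rrna_differential <- function(x, ...) x$result

#' @rdname differential_abundance
#' @export
glance.rrna_differential <- function(x, ...) {
  tibble::tibble(
    n_positions = nrow(x$result),
    n_significant = sum(x$result$padj < 0.05 & abs(x$result$log2FC) > 0.5,
                        na.rm = TRUE),
    n_untested = sum(is.na(x$result$pvalue)),
    median_dispersion = median(x$dispersions),
    dispersion_fallback = isTRUE(attr(x$dispersions, "fallback"))
  )
}

#' Write the differential table as TSV
#'
#' @param dt An `rrna_differential` or its tidy tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(dt, path) {
  if (inherits(dt, "rrna_differential")) dt <- dt$result
  utils::write.table(dt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample similarity by PCA of positional abundance
#'
#' Log-transformed normalized counts (`log2(count/sf + 1)`) on retained
#' positions, centered per position, then PCA.  Mirrors the sample-level QC
#' view that replicate libraries cluster and conditions separate.
#'
#' @param pc A `positional_counts`.
#' @param sf Size factors (default [estimate_size_factors()]).
#' @return An object of class `rrna_pca`: tibble with `sample_id`,
#'   `condition` and PC coordinate columns; attribute `var_explained` holds
#'   the explained-variance fractions.
#' @export
sample_pca <- function(pc, sf = estimate_size_factors(pc)) {
  stopifnot(inherits(pc, "positional_counts"))
  if (nrow(pc$counts) < 2) {
    stop_ribohet("PCA needs at least two samples", "ribohet_validation_error")
  }
  lt <- log2(sweep(pc$counts[, pc$retained, drop = FALSE], 1, sf, "/") + 1)
  p <- prcomp(lt, center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  k <- ncol(p$x)
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(pc$counts),
                   condition = pc$design$condition),
    tibble::as_tibble(p$x[, seq_len(k), drop = FALSE])
  )
  attr(out, "var_explained") <- ve
  class(out) <- c("rrna_pca", class(out))
  out
}

#' @rdname sample_pca
#' @param object An `rrna_pca`.
#' @param ... Unused.
#' @export
autoplot.rrna_pca <- function(object, ...) {
  ve <- attr(object, "var_explained")
  ggplot2::ggplot(object, ggplot2::aes(.data$PC1, .data$PC2,
                                       colour = .data$condition)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
      colour = "condition",
      title = "Sample similarity from positional rRNA fragment abundance"
    ) +
    ggplot2::theme_minimal()
}
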
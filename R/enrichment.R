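#' Rank rRNA positions for the enrichment walk
#'
#' Orders positions by decreasing `rank_score`
#' (`abs(log2FC) * max(-log10(padj), 5)`), breaking ties by ascending
#' concatenated position so the ranking is deterministic.
#'
#' @param dt An `rrna_differential` or its tidy tibble (needs `concat0` and
#'   `rank_score`).
#' @return A tibble with columns `concat0` and `rank_score`, best first.
#' @export
rank_positions <- function(dt) {
  if (inherits(dt, "rrna_differential")) dt <- dt$result
  stopifnot(all(c("concat0", "rank_score") %in% names(dt)))
  dplyr::arrange(dt, dplyr::desc(.data$rank_score), .data$concat0) |>
    dplyr::select("concat0", "rank_score")
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The classic pre-ranked set-enrichment running sum with weight exponent 1:
#' walking down the ranking, a position in the set increments the sum by its
#' score divided by the summed scores of all in-set positions, a position
#' outside the set decrements it by `1/(N - m)`; the ES is the signed extremum
#' of the walk.  If every in-set score is zero the hits fall back to equal
#' weights.  Positions of the set absent from the ranking are ignored; an
#' empty intersection gives `NA`.
#'
#' @param ranked Output of [rank_positions()].
#' @param set Integer vector of concatenated positions (0-based).
#' @return The enrichment score (numeric scalar in `[-1, 1]`, `NA` when the
#'   set misses the ranked universe).
#' @export
enrichment_score <- function(ranked, set) {
  idx <- sort(match(unique(set), ranked$concat0))
  idx <- idx[!is.na(idx)]
  es_from_hits(ranked$rank_score, idx)
}

# core ES computation from hit indices (sorted, within 1..N)
es_from_hits <- function(scores, idx) {
  N <- length(scores)
  m <- length(idx)
  if (m == 0) return(NA_real_)
  if (m == N) return(1)
  w <- abs(scores[idx])
  nr <- sum(w)
  hit_cum <- if (nr > 0) cumsum(w) / nr else seq_len(m) / m
  miss_before <- (idx - seq_len(m)) / (N - m)
  top <- hit_cum - miss_before                 # just after each hit
  bot <- c(0, hit_cum[-m]) - miss_before       # just before each hit
  hi <- max(top)
  lo <- min(bot)
  if (hi >= -lo) hi else lo
}

# memoised null ES distributions, keyed by set size
es_null_cache <- function(ranked, n_perm) {
  cache <- new.env(parent = emptyenv())
  N <- nrow(ranked)
  scores <- ranked$rank_score
  function(m) {
    key <- as.character(m)
    if (is.null(cache[[key]])) {
      cache[[key]] <- vapply(seq_len(n_perm), function(i) {
        es_from_hits(scores, sort(sample.int(N, m)))
      }, numeric(1))
    }
    cache[[key]]
  }
}

#' Normalized enrichment score and permutation p-value
#'
#' Null ES values come from `n_perm` random position sets of the same size
#' drawn from the ranked universe.  The NES divides the observed ES by the
#' mean magnitude of same-sign null scores; the permutation p-value is the
#' same-sign tail probability with +1 smoothing.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of random sets (>= 100; default 1000).
#' @param seed Optional integer seed (the draw is local; the caller's RNG
#'   state is restored).
#' @param null_es Optional pre-computed numeric vector of null ES values for
#'   this set size (used internally to share one null across the background
#'   sets of an RP).
#' @return A list with `es`, `nes`, `p` and `null_es`.
#' @export
normalized_es <- function(ranked, set, n_perm = 1000, seed = NULL,
                          null_es = NULL) {
  if (is.null(null_es) && n_perm < 100) {
    stop_ribohet("n_perm must be at least 100", "ribohet_configuration_error")
  }
  es <- enrichment_score(ranked, set)
  if (is.na(es)) {
    return(list(es = NA_real_, nes = NA_real_, p = NA_real_,
                null_es = numeric(0)))
  }
  if (is.null(null_es)) {
    m <- sum(!is.na(match(unique(set), ranked$concat0)))
    null_es <- with_seed(seed, es_null_cache(ranked, n_perm)(m))
  }
  same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  if (length(same_sign) == 0 || mean(abs(same_sign)) == 0) {
    warn("no same-sign null mass; NES undefined for this set")
    return(list(es = es, nes = NA_real_, p = NA_real_, null_es = null_es))
  }
  nes <- es / mean(abs(same_sign))
  p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
  list(es = es, nes = nes, p = p, null_es = null_es)
}

#' z-score of an RP's NES against its background sets
#'
#' ES2 measures how far the RP contact set's normalized enrichment score sits
#' from the NES distribution of its own circular-shift background sets:
#' `(nes_rp - mean(nes_bg)) / sd(nes_bg)` (sample sd).  Missing background
#' NES values are dropped (their count is reported via `inform()`).
#'
#' @param nes_rp NES of the RP contact set.
#' @param nes_backgrounds Numeric vector of background NES values.
#' @return The z-score, or `NA` when fewer than two backgrounds are usable or
#'   their sd is zero.
#' @export
es2_zscore <- function(nes_rp, nes_backgrounds) {
  if (is.na(nes_rp)) return(NA_real_)
  n_missing <- sum(is.na(nes_backgrounds))
  bg <- nes_backgrounds[!is.na(nes_backgrounds)]
  if (n_missing > 0) {
    inform(sprintf("dropped %d background set(s) with missing NES", n_missing))
  }
  if (length(bg) < 2) {
    warn("fewer than two usable background NES values; ES2 undefined")
    return(NA_real_)
  }
  s <- sd(bg)
  if (s == 0) {
    warn("background NES values are constant; ES2 undefined")
    return(NA_real_)
  }
  (nes_rp - mean(bg)) / s
}

#' Hypergeometric overrepresentation test
#'
#' Tests whether significantly changed positions (`padj < padj_max` and
#' `abs(log2FC) > lfc_min`) are overrepresented in a contact set.  The
#' universe is the retained (tested) positions; the contact set is first
#' intersected with the universe.  The p-value is the upper hypergeometric
#' tail `P(X >= k)`.
#'
#' @param dt An `rrna_differential` or its tidy tibble.
#' @param set Integer vector of concatenated positions (0-based).
#' @param padj_max,lfc_min Significance rule (defaults 0.05 and 0.5).
#' @return A one-row tibble: `ora_p`, `overlap_k`, `set_size`,
#'   `universe_size`, `sig_size`.
#' @export
ora_test <- function(dt, set, padj_max = 0.05, lfc_min = 0.5) {
  if (inherits(dt, "rrna_differential")) dt <- dt$result
  if (nrow(dt) == 0) {
    stop_ribohet("empty universe", "ribohet_validation_error")
  }
  universe <- dt$concat0
  sig <- dt$concat0[!is.na(dt$padj) & dt$padj < padj_max &
                      abs(dt$log2FC) > lfc_min]
  set_u <- intersect(unique(set), universe)
  k <- length(intersect(set_u, sig))
  tibble::tibble(
    ora_p = phyper(k - 1, length(sig), length(universe) - length(sig),
                   length(set_u), lower.tail = FALSE),
    overlap_k = k,
    set_size = length(set_u),
    universe_size = length(universe),
    sig_size = length(sig)
  )
}

#' Predict differentially incorporated ribosomal proteins
#'
#' Runs, for every RP contact set, the three enrichment tests against the
#' differential positional-abundance table: the pre-ranked set-enrichment
#' walk (ES1 = NES with a permutation p-value), the z-score of that NES
#' against the RP's circular-shift background sets (ES2), and the
#' hypergeometric overrepresentation test.  Contact and background positions
#' absent from the tested universe are dropped before testing.  One null ES
#' distribution per set size is shared between an RP set and its backgrounds
#' (they are the same size by construction; sizes can drift slightly after
#' universe intersection, in which case nulls are drawn per distinct size).
#' GSEA and ORA p-values are BH-adjusted across the RP sets only - background
#' sets never enter multiple testing.  An RP is called a candidate when
#' `ES2 >= es2_threshold` (inclusive, default 1); ES1 and ORA are reported
#' for triage but do not gate the call.
#'
#' @param dt An `rrna_differential` or its tidy tibble (with `rank_score`).
#' @param contacts A `contact_set_collection`.
#' @param n_perm Random sets per null ES distribution (default 1000).
#' @param seed Optional integer seed making the permutation null reproducible.
#' @param es2_threshold Candidate threshold on ES2 (default 1).
#' @param padj_max,lfc_min Significance rule for the ORA test.
#' @return An object of class `rp_enrichment`: a tibble sorted by decreasing
#'   ES2 with columns `rp_id`, `es1` (NES), `es2`, `gsea_p`, `gsea_padj`,
#'   `ora_p`, `ora_padj`, `overlap_k`, `set_size`, `universe_size`,
#'   `sig_size`, `candidate`.
#' @export
predict_rp_incorporation <- function(dt, contacts, n_perm = 1000, seed = NULL,
                                     es2_threshold = 1, padj_max = 0.05,
                                     lfc_min = 0.5) {
  if (inherits(dt, "rrna_differential")) dt <- dt$result
  stopifnot(inherits(contacts, "contact_set_collection"))
  if (!"rank_score" %in% names(dt)) {
    stop_ribohet("differential table lacks rank_score; run ranking_scores()",
                 "ribohet_configuration_error")
  }
  ranked <- rank_positions(dt)
  rp_ids <- unique(contacts$sets$rp_id)
  contact_pos <- split(contacts$sets$concat0, contacts$sets$rp_id)[rp_ids]

  rows <- with_seed(seed, {
    null_of <- es_null_cache(ranked, n_perm)
    purrr::map(rp_ids, function(rp) {
      pos <- intersect(contact_pos[[rp]], ranked$concat0)
      ora <- ora_test(dt, contact_pos[[rp]],
                      padj_max = padj_max, lfc_min = lfc_min)
      if (length(pos) == 0) {
        return(dplyr::bind_cols(
          tibble::tibble(rp_id = rp, es1 = NA_real_, es2 = NA_real_,
                         gsea_p = NA_real_), ora))
      }
      rp_res <- normalized_es(ranked, pos, null_es = null_of(length(pos)))
      bg_nes <- vapply(contacts$backgrounds[[rp]], function(bg) {
        bpos <- intersect(bg, ranked$concat0)
        if (length(bpos) == 0) return(NA_real_)
        normalized_es(ranked, bpos, null_es = null_of(length(bpos)))$nes
      }, numeric(1))
      es2 <- suppressMessages(es2_zscore(rp_res$nes, bg_nes))
      dplyr::bind_cols(
        tibble::tibble(rp_id = rp, es1 = rp_res$nes, es2 = es2,
                       gsea_p = rp_res$p),
        ora
      )
    }) |> purrr::list_rbind()
  })

  out <- rows |>
    dplyr::mutate(
      gsea_padj = p.adjust(.data$gsea_p, method = "BH"),
      ora_padj = p.adjust(.data$ora_p, method = "BH"),
      candidate = !is.na(.data$es2) & .data$es2 >= es2_threshold
    ) |>
    dplyr::relocate("gsea_padj", .after = "gsea_p") |>
    dplyr::arrange(dplyr::desc(!is.na(.data$es2)), dplyr::desc(.data$es2))
  attr(out, "params") <- list(n_perm = n_perm, seed = seed,
                              es2_threshold = es2_threshold,
                              padj_max = padj_max, lfc_min = lfc_min)
  class(out) <- c("rp_enrichment", class(out))
  out
}

#' @export
print.rp_enrichment <- function(x, ...) {
  cat("# RP incorporation predictions (", sum(x$candidate), " candidate(s) at ES2 >= ",
      attr(x, "params")$es2_threshold, ")\n", sep = "")
  NextMethod()
}

#' @rdname predict_rp_incorporation
#' @param x An `rp_enrichment`.
#' @param ... Unused.
#' @export
glance.rp_enrichment <- function(x, ...) {
  tibble::tibble(
    n_rp = nrow(x),
    n_candidate = sum(x$candidate),
    top_rp = x$rp_id[1],
    top_es2 = x$es2[1],
    universe_size = x$universe_size[1]
  )
}

#' @rdname predict_rp_incorporation
#' @param object An `rp_enrichment`.
#' @param label_top Number of top RPs to label in the plot (default 5).
#' @export
autoplot.rp_enrichment <- function(object, label_top = 5, ...) {
  df <- dplyr::filter(object, !is.na(.data$es1), !is.na(.data$es2))
  lab <- utils::head(dplyr::arrange(df, dplyr::desc(.data$es2)), label_top)
  thr <- attr(object, "params")$es2_threshold %||% 1
  ggplot2::ggplot(df, ggplot2::aes(.data$es1, .data$es2)) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$ora_padj < 0.05,
                                     shape = .data$gsea_padj < 0.05),
                        size = 3) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$rp_id),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = "ES1 (normalized enrichment score)",
      y = "ES2 (z-score vs background sets)",
      colour = "ORA padj < 0.05", shape = "GSEA padj < 0.05",
      title = "RP contact-set enrichment",
      subtitle = "top candidates sit towards the top-right corner"
    ) +
    ggplot2::theme_minimal()
}

#' Write the enrichment report as TSV
#'
#' @param report An `rp_enrichment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
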
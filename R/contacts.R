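#' Global contact distance threshold
#'
#' A residue counts as an RP contact point when its distance to that RP is in
#' the lowest 5% of all RP-residue distances.  The threshold is the pooled
#' quantile over every present entry of the proximity matrix (all RPs, all
#' positions), so one Angstrom cutoff applies to every RP.  With the full
#' human 80S matrix this works out to roughly 27.4 Angstrom.  Quantiles use
#' linear interpolation between order statistics (R's default type 7).
#'
#' @param pm A `proximity_matrix`.
#' @param percentile Fraction of pooled distances below the threshold
#'   (default 0.05).
#' @param per_rp If `TRUE`, return a named vector of per-RP thresholds (the
#'   percentile within each RP's own distance distribution) instead of the
#'   single pooled value; provided for sensitivity analysis.
#' @return Numeric threshold in Angstrom (or named vector when `per_rp`).
#' @export
contact_threshold <- function(pm, percentile = 0.05, per_rp = FALSE) {
  stopifnot(inherits(pm, "proximity_matrix"),
            percentile > 0, percentile <= 1)
  d <- pm$distances
  if (all(is.na(d))) {
    stop_ribohet("proximity matrix has no present distances",
                 "ribohet_validation_error")
  }
  if (per_rp) {
    return(apply(d, 1, quantile, probs = percentile, na.rm = TRUE, type = 7))
  }
  unname(quantile(d[!is.na(d)], probs = percentile, type = 7))
}

#' Per-RP contact sets
#'
#' For each RP, every position with distance at or below `tau`, ordered
#' closest first and truncated to at most `cap` positions (the cap mirrors the
#' 5%-of-total-length rule; 360 for the human reference).  Ties in distance
#' break by ascending concatenated position, making the sets deterministic.
#'
#' @param pm A `proximity_matrix`.
#' @param tau Distance threshold in Angstrom (default: [contact_threshold()]).
#' @param cap Maximum set size (default: [default_contact_cap()] of the
#'   reference).
#' @return A tibble with columns `rp_id`, `rank`, `rrna_id`, `pos`, `concat0`
#'   and `distance`, `rank` running 1 = closest within each RP.
#' @export
build_contact_sets <- function(pm, tau = contact_threshold(pm),
                               cap = default_contact_cap(pm$reference)) {
  stopifnot(inherits(pm, "proximity_matrix"), tau > 0, cap >= 1)
  tidy(pm) |>
    dplyr::filter(.data$distance <= tau) |>
    dplyr::arrange(.data$rp_id, .data$distance, .data$concat0) |>
    dplyr::group_by(.data$rp_id) |>
    dplyr::slice_head(n = cap) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("rp_id", "rank", "rrna_id", "pos", "concat0", "distance")
}

#' Circular-shift background sets
#'
#' Backgrounds for the enrichment null are exact circular translations of a
#' contact set along the concatenated rRNA (the rRNAs are concatenated and
#' treated as circular): background `b` is `(p + b * shift) mod L` for every
#' contact position `p`.  Cardinality and the gap structure between positions
#' are preserved by construction.
#'
#' @param positions Integer vector of 0-based concatenated contact positions.
#' @param L Total concatenated length.
#' @param shift Shift step in nt (must be >= 1; see [default_shift()]).
#' @param n_background Number of background sets (default 100).
#' @return List of `n_background` integer vectors.
#' @examples
#' build_background_sets(c(0L, 1L, 2L), L = 10L, shift = 3L, n_background = 2)
#' @export
build_background_sets <- function(positions, L, shift, n_background = 100) {
  if (length(shift) != 1 || is.na(shift) || shift < 1) {
    stop_ribohet("shift must be a positive integer", "ribohet_configuration_error")
  }
  shift <- as.integer(shift)
  if (n_background * shift >= L) {
    warn(sprintf(
      "n_background * shift (%d) >= total length (%d): background sets wrap the full circle",
      n_background * shift, L
    ))
  }
  if (any((seq_len(n_background) * shift) %% L == 0)) {
    warn("some background shifts are multiples of the total length; those backgrounds equal the contact set itself")
  }
  lapply(seq_len(n_background), function(b) {
    sort((as.integer(positions) + b * shift) %% L)
  })
}

#' Contact sets plus backgrounds as one collection
#'
#' Convenience constructor running [contact_threshold()],
#' [build_contact_sets()] and [build_background_sets()] with the standard
#' defaults, producing the object the enrichment step consumes.
#'
#' @inheritParams build_contact_sets
#' @param percentile Pooled percentile defining `tau` when `tau` is `NULL`.
#' @param shift Circular shift step (default [default_shift()] of the
#'   reference).
#' @param n_background Number of background sets per RP (default 100).
#' @return An object of class `contact_set_collection`: list with `sets` (the
#'   [build_contact_sets()] tibble), `backgrounds` (named list: rp_id -> list
#'   of integer vectors), and the parameters `tau`, `cap`, `shift`,
#'   `n_background`, `total_length`.
#' @export
contact_set_collection <- function(pm, percentile = 0.05, tau = NULL,
                                   cap = NULL, shift = NULL,
                                   n_background = 100) {
  stopifnot(inherits(pm, "proximity_matrix"))
  tau <- tau %||% contact_threshold(pm, percentile)
  cap <- cap %||% default_contact_cap(pm$reference)
  shift <- shift %||% default_shift(pm$reference)
  L <- pm$reference$total_length
  sets <- build_contact_sets(pm, tau = tau, cap = cap)
  backgrounds <- lapply(split(sets$concat0, sets$rp_id), function(p) {
    build_background_sets(p, L = L, shift = shift, n_background = n_background)
  })
  structure(
    list(sets = sets, backgrounds = backgrounds, tau = tau,
         cap = as.integer(cap), shift = as.integer(shift),
         n_background = as.integer(n_background), total_length = L),
    class = "contact_set_collection"
  )
}

#' @export
print.contact_set_collection <- function(x, ...) {
  cat("<contact_set_collection> ", length(unique(x$sets$rp_id)),
      " RPs; tau = ", signif(x$tau, 4), " A, cap = ", x$cap,
      ", shift = ", x$shift, " nt, ", x$n_background,
      " backgrounds per RP\n", sep = "")
  invisible(x)
}

#' @rdname contact_set_collection
#' @param x A `contact_set_collection`.
#' @param ... Unused.
#' @export
tidy.contact_set_collection <- function(x, ...) x$sets

#' @rdname contact_set_collection
#' @export
glance.contact_set_collection <- function(x, ...) {
  tibble::tibble(
    n_rp = length(unique(x$sets$rp_id)),
    tau = x$tau, cap = x$cap, shift = x$shift,
    n_background = x$n_background,
    median_set_size = median(table(x$sets$rp_id)),
    total_length = x$total_length
  )
}

#' Export contact sets
#'
#' `write_contact_sets()` writes the per-RP contact table as TSV (`rp_id`,
#' `rank`, `rrna_id`, `pos`, `distance`).  `write_contact_bed()` writes a
#' BED-like file (0-based half-open, one record per contact position, name =
#' rp_id, score = distance) for genome-browser viewing against the individual
#' rRNA sequences.
#'
#' @param sets A contact-set tibble ([build_contact_sets()]) or a
#'   `contact_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_sets <- function(sets, path) {
  if (inherits(sets, "contact_set_collection")) sets <- sets$sets
  out <- dplyr::select(sets, "rp_id", "rank", "rrna_id", "pos", "distance")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_sets
#' @export
write_contact_bed <- function(sets, path) {
  if (inherits(sets, "contact_set_collection")) sets <- sets$sets
  bed <- dplyr::transmute(
    sets,
    chrom = .data$rrna_id, start = .data$pos - 1L, end = .data$pos,
    name = .data$rp_id, score = round(.data$distance, 2), strand = "+"
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
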
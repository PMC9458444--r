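#' Residue correspondence between two rRNA references
#'
#' Aligns each record of `source` to the record of `target` in the same
#' position of the concatenation order (28S to 28S, 18S to 18S, ...) with a
#' global pairwise nucleotide alignment, and records which residues pair up.
#' This is the map used to transfer a structure-derived proximity matrix from
#' the species with the solved structure (human) to another species (mouse):
#' aligned residues inherit distances directly, target-only residues
#' (insertions relative to the source) are later filled by interpolation.
#'
#' Scoring is the standard nucleotide default set: match +2, mismatch -1, gap
#' open -5, gap extend -1.  The output contract is the residue map, not a
#' particular optimal alignment among co-optimal ones.
#'
#' @param source,target `rrna_reference` objects with the same number of
#'   records, matched by order.
#' @return An object of class `rrna_alignment`: list with `pairs` (tibble
#'   `rrna_id` (target id), `source_pos`, `target_pos`, both 1-based within
#'   their record) and `unaligned_target` (tibble `rrna_id`, `target_pos`).
#' @examples
#' a <- rrna_reference(c(x = "ACGTACGTACGTACGTACGT"))
#' b <- rrna_reference(c(x = "ACGTACGTACTTGTACGTACGT"))
#' align_rrna_references(a, b)$unaligned_target
#' @export
align_rrna_references <- function(source, target) {
  stopifnot(inherits(source, "rrna_reference"), inherits(target, "rrna_reference"))
  if (nrow(source$records) != nrow(target$records)) {
    stop_ribohet("source and target must have the same number of records",
                 "ribohet_configuration_error")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = FALSE)
  res <- purrr::map2(
    seq_len(nrow(source$records)), target$records$rrna_id,
    function(i, tid) {
      s <- source$records$seq[i]
      t <- target$records$seq[i]
      al <- Biostrings::pairwiseAlignment(
        s, t, type = "global", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 1
      )
      # alignedPattern/alignedSubject keep end gaps, which pattern()/subject()
      # silently trim
      walk_alignment(as.character(Biostrings::alignedPattern(al)),
                     as.character(Biostrings::alignedSubject(al)), tid)
    }
  )
  structure(
    list(
      pairs = purrr::list_rbind(purrr::map(res, "pairs")),
      unaligned_target = purrr::list_rbind(purrr::map(res, "unaligned"))
    ),
    class = "rrna_alignment"
  )
}

# turn a pair of gapped alignment strings into residue pairs
walk_alignment <- function(gapped_source, gapped_target, rrna_id) {
  sc <- strsplit(gapped_source, "", fixed = TRUE)[[1]]
  tc <- strsplit(gapped_target, "", fixed = TRUE)[[1]]
  stopifnot(length(sc) == length(tc))
  s_gap <- sc == "-"
  t_gap <- tc == "-"
  s_pos <- cumsum(!s_gap)
  t_pos <- cumsum(!t_gap)
  both <- !s_gap & !t_gap
  list(
    pairs = tibble::tibble(
      rrna_id = rrna_id,
      source_pos = as.integer(s_pos[both]),
      target_pos = as.integer(t_pos[both])
    ),
    unaligned = tibble::tibble(
      rrna_id = rrna_id,
      target_pos = as.integer(t_pos[!t_gap & s_gap])
    )
  )
}

#' @export
print.rrna_alignment <- function(x, ...) {
  cat("<rrna_alignment> ", nrow(x$pairs), " aligned pairs, ",
      nrow(x$unaligned_target), " target-only residues\n", sep = "")
  invisible(x)
}

#' @rdname align_rrna_references
#' @param x An `rrna_alignment`.
#' @param ... Unused.
#' @export
tidy.rrna_alignment <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$pairs, status = "aligned"),
    dplyr::mutate(x$unaligned_target, source_pos = NA_integer_,
                  status = "target_only")
  ) |>
    dplyr::arrange(.data$rrna_id, .data$target_pos)
}
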
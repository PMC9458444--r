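#' Parse a ribosome structure into residue-level reference coordinates
#'
#' Reads an mmCIF (PDBx) model of the ribosome and reduces it to the two
#' coordinate sets the proximity matrix needs: one reference atom per rRNA
#' residue (the N1 base atom) and one per protein residue (the alpha carbon).
#' Every polypeptide chain that is not an rRNA chain and not on the deny-list
#' is treated as a ribosomal-protein (RP) chain.  rRNA residues without an N1
#' atom (unresolved bases) are kept as missing rather than dropped, so the
#' concatenated coordinate axis stays intact.
#'
#' @param cif_path Path to an mmCIF file.
#' @param rrna_chain_map Named character vector mapping `rrna_id` to the chain
#'   id (auth_asym_id) that carries it, e.g. `c("18S" = "A2")`.
#' @param rp_exclude Character vector of chain ids to exclude from the RP set
#'   (non-RP polypeptides such as bound factors or tags).
#' @return An object of class `ribosome_model`: list with `rna` (tibble
#'   `rrna_id`, `pos`, `base`, `x`, `y`, `z`; coordinates `NA` when the N1
#'   atom is unresolved) and `rp` (tibble `rp_id`, `x`, `y`, `z`, one row per
#'   alpha carbon).
#' @seealso [build_proximity_matrix()], [make_toy_structure()]
#' @export
read_ribosome_structure <- function(cif_path, rrna_chain_map,
                                    rp_exclude = character()) {
  stopifnot(is.character(rrna_chain_map), !is.null(names(rrna_chain_map)))
  if (!file.exists(cif_path)) {
    stop_ribohet(paste0("structure file not found: ", cif_path),
                 "ribohet_format_error")
  }
  cif <- tryCatch(
    suppressWarnings(bio3d::read.cif(cif_path)),
    error = function(e) {
      stop_ribohet(paste0("could not parse mmCIF file: ", conditionMessage(e)),
                   "ribohet_format_error")
    }
  )
  atoms <- tibble::as_tibble(cif$atom)
  atoms <- dplyr::filter(atoms, .data$type == "ATOM")

  missing_chains <- setdiff(unname(rrna_chain_map), unique(atoms$chain))
  if (length(missing_chains) > 0) {
    stop_ribohet(
      paste0("mapped rRNA chain(s) absent from structure: ",
             paste(missing_chains, collapse = ", ")),
      "ribohet_configuration_error"
    )
  }

  rna <- purrr::imap(rrna_chain_map, function(chain_id, rid) {
    ch <- dplyr::filter(atoms, .data$chain == chain_id)
    ch <- dplyr::filter(ch, .data$resid %in% c("A", "C", "G", "U", "T", "N"))
    res <- dplyr::distinct(ch, .data$resno, .data$resid)
    n1 <- dplyr::filter(ch, .data$elety == "N1") |>
      dplyr::distinct(.data$resno, .keep_all = TRUE)
    dplyr::left_join(res, dplyr::select(n1, "resno", "x", "y", "z"),
                     by = "resno") |>
      dplyr::transmute(
        rrna_id = rid, pos = as.integer(.data$resno),
        base = .data$resid, x = .data$x, y = .data$y, z = .data$z
      ) |>
      dplyr::arrange(.data$pos)
  }) |> purrr::list_rbind()

  rp_chains <- setdiff(unique(atoms$chain), c(unname(rrna_chain_map), rp_exclude))
  rp <- dplyr::filter(atoms, .data$chain %in% rp_chains, .data$elety == "CA") |>
    dplyr::transmute(rp_id = .data$chain, x = .data$x, y = .data$y, z = .data$z)
  # chains with no alpha carbon at all are not polypeptides (e.g. tRNA, mRNA)
  structure(
    list(rna = rna, rp = rp, source = cif_path),
    class = "ribosome_model"
  )
}

#' @export
print.ribosome_model <- function(x, ...) {
  cat("<ribosome_model> ", length(unique(x$rna$rrna_id)), " rRNA chain(s), ",
      nrow(x$rna), " residues (", sum(is.na(x$rna$x)), " unresolved); ",
      length(unique(x$rp$rp_id)), " RP chain(s)\n", sep = "")
  invisible(x)
}

#' Minimum RP-rRNA distances for every rRNA position
#'
#' For each rRNA residue the minimum Euclidean distance (in Angstrom) between
#' its N1 atom and any alpha carbon of each RP chain.  Rows are RPs, columns
#' are positions of the concatenated rRNA coordinate system; residues that are
#' unresolved in the structure (or absent from the model) are `NA` for every
#' RP.  Before computing, the structure-derived residue identities are checked
#' against the reference sequence (T/U-insensitive); a mismatch fraction above
#' `1 - identity_min` over resolved residues aborts.
#'
#' @param model A `ribosome_model` from [read_ribosome_structure()].
#' @param ref The `rrna_reference` the matrix is indexed against.
#' @param identity_min Minimum sequence identity between structure residues and
#'   the reference over resolved positions (default 0.99).  Mismatching
#'   positions are recorded in the `mismatches` attribute of the result.
#' @return An object of class `proximity_matrix`: list with `distances`
#'   (numeric matrix RP x total_length with dimnames) and `reference`.
#' @examples
#' \dontrun{
#' toy <- make_toy_structure(n_residues = 30, n_rps = 2, seed = 1)
#' ref <- read_rrna_reference(toy$fasta)
#' model <- read_ribosome_structure(toy$cif, c(rRNA = "R"))
#' pm <- build_proximity_matrix(model, ref)
#' }
#' @export
build_proximity_matrix <- function(model, ref, identity_min = 0.99) {
  stopifnot(inherits(model, "ribosome_model"), inherits(ref, "rrna_reference"))
  extra <- setdiff(unique(model$rna$rrna_id), ref$records$rrna_id)
  if (length(extra) > 0) {
    stop_ribohet(paste0("model rRNA id(s) not in reference: ",
                        paste(extra, collapse = ", ")),
                 "ribohet_configuration_error")
  }

  L <- ref$total_length
  rp_ids <- sort(unique(model$rp$rp_id))

  # place structure residues on the concatenated axis and check identity
  rna <- dplyr::inner_join(
    model$rna,
    dplyr::select(ref$records, "rrna_id", "length", "offset"),
    by = "rrna_id"
  )
  out_of_range <- rna$pos < 1L | rna$pos > rna$length
  if (any(out_of_range)) {
    rna <- rna[!out_of_range, , drop = FALSE]
  }
  ref_base <- substring(
    ref$records$seq[match(rna$rrna_id, ref$records$rrna_id)],
    rna$pos, rna$pos
  )
  struct_base <- gsub("U", "T", toupper(rna$base), fixed = TRUE)
  comparable <- struct_base %in% c("A", "C", "G", "T")
  mism <- comparable & struct_base != ref_base
  if (sum(comparable) > 0) {
    identity <- 1 - sum(mism) / sum(comparable)
    if (identity < identity_min) {
      stop_ribohet(
        sprintf("structure/reference sequence identity %.4f below %.4f (%d mismatches)",
                identity, identity_min, sum(mism)),
        "ribohet_validation_error"
      )
    }
  }

  resolved <- !is.na(rna$x)
  idx0 <- rna$offset + rna$pos - 1L

  dist <- matrix(NA_real_, nrow = length(rp_ids), ncol = L,
                 dimnames = list(rp_ids, concat_labels(ref)))
  if (any(resolved) && length(rp_ids) > 0) {
    P <- cbind(rna$x, rna$y, rna$z)[resolved, , drop = FALSE]
    cols <- idx0[resolved] + 1L
    for (rp in rp_ids) {
      A <- as.matrix(model$rp[model$rp$rp_id == rp, c("x", "y", "z")])
      d2 <- outer(rowSums(P^2), rowSums(A^2), "+") - 2 * P %*% t(A)
      dist[rp, cols] <- sqrt(pmax(apply(d2, 1, min), 0))
    }
  }
  res <- structure(list(distances = dist, reference = ref),
                   class = "proximity_matrix")
  attr(res, "mismatches") <- tibble::tibble(
    rrna_id = rna$rrna_id[mism], pos = rna$pos[mism],
    structure_base = struct_base[mism], reference_base = ref_base[mism]
  )
  res
}

#' @export
print.proximity_matrix <- function(x, ...) {
  d <- x$distances
  cat("<proximity_matrix> ", nrow(d), " RPs x ", ncol(d), " rRNA positions; ",
      sum(colSums(!is.na(d)) == 0), " unresolved column(s)\n", sep = "")
  invisible(x)
}

#' @rdname build_proximity_matrix
#' @param x A `proximity_matrix`.
#' @param ... Unused.
#' @return `tidy()` returns a long tibble (`rp_id`, `rrna_id`, `pos`,
#'   `concat0`, `distance`), missing distances omitted.
#' @export
tidy.proximity_matrix <- function(x, ...) {
  d <- x$distances
  loc <- from_concatenated(x$reference, seq_len(ncol(d)) - 1L)
  purrr::imap(
    setNames(seq_len(nrow(d)), rownames(d)),
    function(i, rp) {
      keep <- !is.na(d[i, ])
      tibble::tibble(
        rp_id = rp,
        rrna_id = loc$rrna_id[keep],
        pos = loc$pos_1based[keep],
        concat0 = unname(which(keep)) - 1L,
        distance = unname(d[i, keep])
      )
    }
  ) |> purrr::list_rbind()
}

#' Read/write a proximity matrix as TSV
#'
#' The TSV mirrors the matrix orientation: one row per RP, one column per
#' concatenated rRNA position labelled `rrna_id:pos` (1-based within each
#' rRNA), values in Angstrom with missing as `NA`.  A matrix read back without
#' an explicit reference gets a sequence-less skeleton reference (ids and
#' lengths inferred from the header, sequences set to `N`), which is
#' sufficient for all downstream set construction.
#'
#' @param pm A `proximity_matrix`.
#' @param path Output (input) TSV path.
#' @param ref Optional `rrna_reference` to index the matrix against; its
#'   labels must match the file header.
#' @return `read_proximity_matrix()` returns a `proximity_matrix`;
#'   `write_proximity_matrix()` returns `path` invisibly.
#' @export
write_proximity_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "proximity_matrix"))
  df <- data.frame(rp_id = rownames(pm$distances), pm$distances,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_proximity_matrix
#' @export
read_proximity_matrix <- function(path, ref = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "rp_id") {
    stop_ribohet("proximity TSV must start with an rp_id column",
                 "ribohet_format_error")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$rp_id
  labels <- colnames(m)
  parts <- strsplit(labels, ":", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1)
  pos <- as.integer(vapply(parts, `[`, "", 2))
  if (is.null(ref)) {
    lens <- tapply(pos, factor(ids, levels = unique(ids)), max)
    ref <- new_rrna_reference(names(lens), strrep("N", as.integer(lens)))
  }
  if (!identical(labels, concat_labels(ref))) {
    stop_ribohet("TSV columns do not match the reference coordinate system",
                 "ribohet_validation_error")
  }
  structure(list(distances = m, reference = ref), class = "proximity_matrix")
}

#' Transfer a proximity matrix to another species
#'
#' Projects a structure-derived proximity matrix onto the rRNA reference of a
#' second species using a residue alignment: each aligned target residue
#' inherits the distance of its source partner; target-only residues
#' (insertions) between two aligned flanks get per-RP linearly interpolated
#' distances; insertions beyond the outermost aligned residue, or adjacent to
#' a flank whose distance is missing, copy the value from the single resolved
#' side; when both flanks are missing the residue stays missing.
#'
#' @param pm Source `proximity_matrix`.
#' @param amap An `rrna_alignment` from [align_rrna_references()] mapping
#'   `pm$reference` (source) onto `target_ref`.
#' @param target_ref Target `rrna_reference`.
#' @return A `proximity_matrix` indexed against `target_ref`.
#' @export
transfer_proximity_matrix <- function(pm, amap, target_ref) {
  stopifnot(inherits(pm, "proximity_matrix"), inherits(amap, "rrna_alignment"),
            inherits(target_ref, "rrna_reference"))
  src_ref <- pm$reference
  if (nrow(src_ref$records) != nrow(target_ref$records)) {
    stop_ribohet("source and target references differ in record count",
                 "ribohet_configuration_error")
  }
  rp_ids <- rownames(pm$distances)
  out <- matrix(NA_real_, nrow = length(rp_ids), ncol = target_ref$total_length,
                dimnames = list(rp_ids, concat_labels(target_ref)))

  for (i in seq_len(nrow(target_ref$records))) {
    tid <- target_ref$records$rrna_id[i]
    t_len <- target_ref$records$length[i]
    t_off <- target_ref$records$offset[i]
    s_off <- src_ref$records$offset[i]
    pr <- amap$pairs[amap$pairs$rrna_id == tid, , drop = FALSE]
    if (nrow(pr) == 0) next
    ax <- pr$target_pos             # aligned target positions (sorted)
    ay_idx <- s_off + pr$source_pos # source concatenated index (1-based col)
    unal <- setdiff(seq_len(t_len), ax)
    # flanking aligned residues for every unaligned position
    li <- findInterval(unal, ax)                  # 0 = none to the left
    ri <- li + 1L                                 # > length(ax) = none right
    for (rp in rp_ids) {
      ay <- pm$distances[rp, ay_idx]
      out[rp, t_off + ax] <- ay
      if (length(unal) > 0) {
        lv <- ifelse(li >= 1L, ay[pmax(li, 1L)], NA_real_)
        lx <- ifelse(li >= 1L, ax[pmax(li, 1L)], NA_integer_)
        rv <- ifelse(ri <= length(ax), ay[pmin(ri, length(ax))], NA_real_)
        rx <- ifelse(ri <= length(ax), ax[pmin(ri, length(ax))], NA_integer_)
        val <- ifelse(
          !is.na(lv) & !is.na(rv),
          lv + (rv - lv) * (unal - lx) / (rx - lx),
          ifelse(!is.na(lv), lv, rv)   # one resolved side, or NA if neither
        )
        out[rp, t_off + unal] <- val
      }
    }
  }
  structure(list(distances = out, reference = target_ref),
            class = "proximity_matrix")
}
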
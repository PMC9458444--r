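#' Per-position rRNA fragment coverage from a BAM file
#'
#' Counts, for every position of the concatenated rRNA reference, how many
#' retained alignments cover it.  Each alignment contributes +1 to every
#' reference position under its aligned blocks (CIGAR `M/=/X`); deletions and
#' splice skips are not covered.  By default secondary, supplementary,
#' unmapped and QC-fail records are excluded, duplicates are kept (Ribo-seq
#' fragments are legitimately duplicated), and antisense alignments are
#' dropped (rRNA is single-stranded).
#'
#' @param bam_path Path to a BAM aligned to the rRNA reference sequences.  An
#'   index is created next to the file if absent.
#' @param ref An `rrna_reference`; every record must appear in the BAM header
#'   with an identical length.
#' @param include_antisense Keep minus-strand alignments (default `FALSE`).
#' @param include_duplicates Keep PCR/optical duplicates (default `TRUE`).
#' @param read_length Optional length window `c(min, max)` applied to the read
#'   (query) length, e.g. `c(19, 35)` to mimic the footprint size selection.
#' @return Integer vector of length `ref$total_length`.
#' @export
coverage_from_bam <- function(bam_path, ref, include_antisense = FALSE,
                              include_duplicates = TRUE, read_length = NULL) {
  stopifnot(inherits(ref, "rrna_reference"))
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path))) {
    Rsamtools::indexBam(bam_path)
  }
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  for (i in seq_len(nrow(ref$records))) {
    id <- ref$records$rrna_id[i]
    if (!id %in% names(hdr)) {
      stop_ribohet(paste0("BAM header lacks reference sequence: ", id),
                   "ribohet_validation_error")
    }
    if (hdr[[id]] != ref$records$length[i]) {
      stop_ribohet(sprintf("BAM length for %s (%d) differs from reference (%d)",
                           id, hdr[[id]], ref$records$length[i]),
                   "ribohet_validation_error")
    }
  }
  flag <- Rsamtools::scanBamFlag(
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isUnmappedQuery = FALSE,
    isNotPassingQualityControls = FALSE,
    isDuplicate = if (include_duplicates) NA else FALSE,
    isMinusStrand = if (include_antisense) NA else FALSE
  )
  gal <- GenomicAlignments::readGAlignments(
    bam_path, param = Rsamtools::ScanBamParam(flag = flag)
  )
  if (!is.null(read_length)) {
    qw <- GenomicAlignments::qwidth(gal)
    gal <- gal[qw >= read_length[1] & qw <= read_length[2]]
  }
  cov <- GenomicAlignments::coverage(gal, drop.D.ranges = TRUE)
  counts_from_rlelist(cov, ref)
}

# flatten an RleList of per-chromosome coverage onto the concatenated axis
counts_from_rlelist <- function(cov, ref) {
  out <- integer(ref$total_length)
  for (i in seq_len(nrow(ref$records))) {
    id <- ref$records$rrna_id[i]
    len <- ref$records$length[i]
    off <- ref$records$offset[i]
    if (id %in% names(cov)) {
      v <- as.integer(cov[[id]])
      n <- min(length(v), len)
      if (n > 0) out[off + seq_len(n)] <- v[seq_len(n)]
    }
  }
  out
}

#' Per-position counts from a bedGraph coverage track
#'
#' Expands 0-based half-open bedGraph intervals on the rRNA reference names to
#' per-position counts; overlapping intervals are summed.  Values must be
#' non-negative, and integral unless `strict = FALSE` (then rounded).
#'
#' @param bg_path Path to a bedGraph file (track lines and comments ignored).
#' @param ref An `rrna_reference`.
#' @param strict Require integral values (default `TRUE`).
#' @return Integer vector of length `ref$total_length`.
#' @export
coverage_from_bedgraph <- function(bg_path, ref, strict = TRUE) {
  stopifnot(inherits(ref, "rrna_reference"))
  lines <- readLines(bg_path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(integer(ref$total_length))
  parts <- strsplit(lines, "[\t ]+")
  bad_fmt <- vapply(parts, length, 1L) < 4
  if (any(bad_fmt)) {
    stop_ribohet("bedGraph line with fewer than 4 fields", "ribohet_format_error")
  }
  chrom <- vapply(parts, `[`, "", 1)
  start <- as.numeric(vapply(parts, `[`, "", 2))
  end <- as.numeric(vapply(parts, `[`, "", 3))
  value <- as.numeric(vapply(parts, `[`, "", 4))
  unknown <- setdiff(unique(chrom), ref$records$rrna_id)
  if (length(unknown) > 0) {
    stop_ribohet(paste0("bedGraph reference name(s) not in rRNA reference: ",
                        paste(unknown, collapse = ", ")),
                 "ribohet_validation_error")
  }
  if (any(is.na(value)) || any(value < 0)) {
    stop_ribohet("bedGraph values must be non-negative numbers",
                 "ribohet_format_error")
  }
  if (any(value != round(value))) {
    if (strict) {
      stop_ribohet("bedGraph values must be integers (use strict = FALSE to round)",
                   "ribohet_format_error")
    }
    value <- round(value)
  }
  i <- match(chrom, ref$records$rrna_id)
  if (any(start < 0) || any(end > ref$records$length[i]) || any(end <= start)) {
    stop_ribohet("bedGraph interval outside reference bounds",
                 "ribohet_validation_error")
  }
  out <- integer(ref$total_length)
  off <- ref$records$offset[i]
  for (k in seq_along(chrom)) {
    idx <- (off[k] + start[k] + 1L):(off[k] + end[k])
    out[idx] <- out[idx] + as.integer(value[k])
  }
  out
}

#' Write per-position counts as bedGraph
#'
#' Inverse of [coverage_from_bedgraph()]: non-zero runs of the count vector
#' become 0-based half-open intervals per rRNA record.
#'
#' @param counts Integer vector of length `ref$total_length`.
#' @param ref An `rrna_reference`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(counts, ref, path) {
  stopifnot(length(counts) == ref$total_length)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ref$records))) {
    id <- ref$records$rrna_id[i]
    v <- counts[ref$records$offset[i] + seq_len(ref$records$length[i])]
    r <- rle(as.integer(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0L
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%d", id, starts[keep], ends[keep],
                         r$values[keep]), con)
    }
  }
  invisible(path)
}

#' Assemble the sample x position count matrix
#'
#' Builds the `positional_counts` object from per-sample coverage vectors (or
#' from a sample sheet pointing at BAM/bedGraph files) and a two-condition
#' design.  Designs with a single replicate in a condition are accepted with a
#' warning; the differential stage then falls back to a fixed conservative
#' dispersion.
#'
#' @param x Either a named list of per-sample count vectors, or `NULL` to read
#'   the files named in `design$path` (type chosen by extension: `.bam` or
#'   bedGraph otherwise).
#' @param design A data frame with columns `sample_id` and `condition` (plus
#'   `path` when `x` is `NULL`).  Exactly two condition levels are required;
#'   the first level (factor order, or order of appearance) is the reference
#'   so log2 fold changes read "second vs first".
#' @param ref An `rrna_reference`.
#' @param ... Passed to [coverage_from_bam()] / [coverage_from_bedgraph()].
#' @return An object of class `positional_counts`: list with `counts` (integer
#'   matrix sample x position), `design` (tibble), `retained` (logical mask,
#'   initially all `TRUE`), `reference`.
#' @export
positional_counts <- function(x = NULL, design, ref, ...) {
  stopifnot(inherits(ref, "rrna_reference"), is.data.frame(design),
            all(c("sample_id", "condition") %in% names(design)))
  design <- tibble::as_tibble(design)
  if (anyDuplicated(design$sample_id)) {
    stop_ribohet("duplicate sample_id in design", "ribohet_configuration_error")
  }
  if (is.null(x)) {
    if (!"path" %in% names(design)) {
      stop_ribohet("design needs a 'path' column when no count vectors are given",
                   "ribohet_configuration_error")
    }
    x <- lapply(setNames(design$path, design$sample_id), function(p) {
      if (grepl("\\.bam$", p, ignore.case = TRUE)) {
        coverage_from_bam(p, ref, ...)
      } else {
        coverage_from_bedgraph(p, ref, ...)
      }
    })
  }
  missing_samples <- setdiff(design$sample_id, names(x))
  if (length(missing_samples) > 0) {
    stop_ribohet(paste0("no counts for sample(s): ",
                        paste(missing_samples, collapse = ", ")),
                 "ribohet_configuration_error")
  }
  x <- x[design$sample_id]
  lens <- vapply(x, length, 1L)
  if (any(lens != ref$total_length)) {
    stop_ribohet("count vector length does not match the reference",
                 "ribohet_validation_error")
  }
  counts <- do.call(rbind, lapply(x, as.integer))
  rownames(counts) <- design$sample_id
  colnames(counts) <- concat_labels(ref)
  if (any(counts < 0)) {
    stop_ribohet("negative counts", "ribohet_validation_error")
  }

  cond <- if (is.factor(design$condition)) design$condition else
    factor(design$condition, levels = unique(design$condition))
  if (nlevels(cond) != 2) {
    stop_ribohet(paste0("exactly two conditions required, got ",
                        nlevels(cond)),
                 "ribohet_configuration_error")
  }
  design$condition <- cond
  single_replicate <- any(table(cond) < 2)
  if (single_replicate) {
    warn("a condition has a single replicate; dispersion estimation will fall back to a fixed conservative value")
  }
  structure(
    list(counts = counts, design = design,
         retained = rep(TRUE, ref$total_length), reference = ref,
         single_replicate = single_replicate),
    class = "positional_counts"
  )
}

#' @export
print.positional_counts <- function(x, ...) {
  cat("<positional_counts> ", nrow(x$counts), " samples x ", ncol(x$counts),
      " positions (", sum(x$retained), " retained); conditions: ",
      paste(levels(x$design$condition), collapse = " vs "), "\n", sep = "")
  invisible(x)
}

#' @rdname positional_counts
#' @export
tidy.positional_counts <- function(x, ...) {
  loc <- from_concatenated(x$reference, seq_len(ncol(x$counts)) - 1L)
  purrr::imap(
    setNames(seq_len(nrow(x$counts)), rownames(x$counts)),
    function(i, sid) {
      tibble::tibble(
        sample_id = sid,
        condition = x$design$condition[x$design$sample_id == sid],
        rrna_id = loc$rrna_id, pos = loc$pos_1based,
        concat0 = seq_len(ncol(x$counts)) - 1L,
        count = x$counts[i, ], retained = x$retained
      )
    }
  ) |> purrr::list_rbind()
}

#' Low-count filtering
#'
#' Marks as retained the positions whose mean raw count across all samples is
#' at least `min_mean` (boundary inclusive).  Counts are kept unchanged; only
#' the `retained` mask is updated, and all downstream statistics run on
#' retained positions.
#'
#' @param pc A `positional_counts` object.
#' @param min_mean Minimum mean raw count (default 1).
#' @return The updated `positional_counts`.
#' @export
filter_low_counts <- function(pc, min_mean = 1.0) {
  stopifnot(inherits(pc, "positional_counts"))
  pc$retained <- colMeans(pc$counts) >= min_mean
  pc
}

#' Write the count matrix as TSV
#'
#' Positions (rows, labelled `rrna_id:pos`) by samples (columns).
#'
#' @param pc A `positional_counts`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(pc, path) {
  df <- data.frame(position = colnames(pc$counts), t(pc$counts),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
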
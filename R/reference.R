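#' Load an rRNA reference and define the concatenated coordinate system
#'
#' Reads the selected rRNA variants (typically 28S, 18S, 5.8S and 5S) from a
#' multi-record FASTA and concatenates them, in the requested order, into a
#' single 0-based coordinate space.  All downstream machinery - the proximity
#' matrix, contact sets and their circular-shift backgrounds, and the
#' positional count matrix - is indexed against this space.  `U` is normalized
#' to `T` at load time so RNA and DNA spellings of the same reference are
#' equivalent.
#'
#' @param fasta_path Path to a FASTA file containing all requested records.
#' @param order Character vector of record ids in the order they should be
#'   concatenated.  Ids are matched against the first whitespace-delimited
#'   token of each FASTA header.  Defaults to the file order.
#' @return An object of class `rrna_reference`: a list with `records` (a
#'   tibble with columns `rrna_id`, `length`, `offset` and `seq`) and
#'   `total_length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">18S", "ACGUACGUAC", ">5S", "GGGCC"), fa)
#' ref <- read_rrna_reference(fa)
#' ref$total_length
#' @seealso [to_concatenated()], [from_concatenated()], [align_rrna_references()]
#' @export
read_rrna_reference <- function(fasta_path, order = NULL) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop_ribohet(
      paste0("duplicate record id(s) in FASTA: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      "ribohet_reference_error"
    )
  }
  names(seqs) <- ids
  order <- order %||% ids
  missing <- setdiff(order, ids)
  if (length(missing) > 0) {
    stop_ribohet(
      paste0("rRNA id(s) not found in FASTA: ", paste(missing, collapse = ", ")),
      "ribohet_reference_error"
    )
  }
  seq_chr <- toupper(as.character(seqs[order]))
  seq_chr <- gsub("U", "T", seq_chr, fixed = TRUE)
  if (any(nchar(seq_chr) == 0)) {
    stop_ribohet(
      paste0("empty sequence for: ",
             paste(order[nchar(seq_chr) == 0], collapse = ", ")),
      "ribohet_format_error"
    )
  }
  bad <- !grepl("^[ACGTRYSWKMBDHVN]*$", seq_chr)
  if (any(bad)) {
    stop_ribohet(
      paste0("non-IUPAC characters in: ", paste(order[bad], collapse = ", ")),
      "ribohet_format_error"
    )
  }
  new_rrna_reference(order, seq_chr)
}

new_rrna_reference <- function(ids, seqs) {
  lens <- nchar(seqs)
  records <- tibble::tibble(
    rrna_id = ids,
    length = as.integer(lens),
    offset = as.integer(cumsum(c(0L, lens[-length(lens)]))),
    seq = unname(seqs)
  )
  structure(
    list(records = records, total_length = as.integer(sum(lens))),
    class = "rrna_reference"
  )
}

#' Build an rRNA reference directly from sequences
#'
#' Programmatic counterpart of [read_rrna_reference()], used by the synthetic
#' data generator and convenient in scripts.
#'
#' @param seqs Named character vector of nucleotide sequences (names are the
#'   rRNA ids; concatenation follows vector order).
#' @return An `rrna_reference`.
#' @export
rrna_reference <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  seqs2 <- gsub("U", "T", toupper(seqs), fixed = TRUE)
  if (any(nchar(seqs2) == 0)) {
    stop_ribohet("empty sequence", "ribohet_format_error")
  }
  new_rrna_reference(names(seqs), seqs2)
}

#' @export
print.rrna_reference <- function(x, ...) {
  cat("<rrna_reference> ", nrow(x$records), " records, ",
      x$total_length, " nt total\n", sep = "")
  print(dplyr::select(x$records, -"seq"))
  invisible(x)
}

#' @rdname read_rrna_reference
#' @param x An `rrna_reference`.
#' @param ... Unused.
#' @export
tidy.rrna_reference <- function(x, ...) {
  dplyr::select(x$records, -"seq")
}

#' Map a within-rRNA position to the concatenated coordinate
#'
#' Positions inside each rRNA are 1-based (as they appear in output tables and
#' genome browsers); the concatenated space is 0-based and used internally for
#' the circular-shift arithmetic of the background sets.
#'
#' @param ref An `rrna_reference`.
#' @param rrna_id Character vector of record ids.
#' @param pos_1based Integer vector of 1-based positions (recycled against
#'   `rrna_id`).
#' @return Integer vector of 0-based concatenated indices.
#' @examples
#' ref <- rrna_reference(c(a = "ACGTACGTAC", b = "GGGCC"))
#' to_concatenated(ref, "b", 2)  # 11
#' from_concatenated(ref, 11)
#' @export
to_concatenated <- function(ref, rrna_id, pos_1based) {
  stopifnot(inherits(ref, "rrna_reference"))
  n <- max(length(rrna_id), length(pos_1based))
  rrna_id <- rep_len(rrna_id, n)
  pos_1based <- rep_len(as.integer(pos_1based), n)
  i <- match(rrna_id, ref$records$rrna_id)
  if (anyNA(i)) {
    stop_ribohet(
      paste0("unknown rRNA id: ", paste(unique(rrna_id[is.na(i)]), collapse = ", ")),
      "ribohet_reference_error"
    )
  }
  bad <- pos_1based < 1L | pos_1based > ref$records$length[i]
  if (any(bad)) {
    stop_ribohet(
      paste0("position out of range for ", rrna_id[bad][1], ": ",
             pos_1based[bad][1]),
      "ribohet_coordinate_error"
    )
  }
  ref$records$offset[i] + pos_1based - 1L
}

#' @rdname to_concatenated
#' @param index0 Integer vector of 0-based concatenated indices.
#' @return `from_concatenated()` returns a tibble with columns `rrna_id` and
#'   `pos_1based`.
#' @export
from_concatenated <- function(ref, index0) {
  stopifnot(inherits(ref, "rrna_reference"))
  index0 <- as.integer(index0)
  if (any(index0 < 0L | index0 >= ref$total_length)) {
    stop_ribohet("concatenated index out of range", "ribohet_coordinate_error")
  }
  i <- findInterval(index0, ref$records$offset)
  tibble::tibble(
    rrna_id = ref$records$rrna_id[i],
    pos_1based = index0 - ref$records$offset[i] + 1L
  )
}

# labels like "18S:17" for the concatenated axis, used in file headers
concat_labels <- function(ref) {
  rec <- ref$records
  unlist(Map(function(id, len) paste0(id, ":", seq_len(len)),
             rec$rrna_id, rec$length), use.names = FALSE)
}

#' Bundled species presets
#'
#' Metadata for the single rRNA variant per species that the human and mouse
#' analyses use: accession ids, sequence lengths, and the circular-shift step
#' used when generating background sets (71 nt for human, 67 nt for mouse,
#' each roughly 1% of the summed rRNA length).  The 5S entry for human comes
#' from the 80S crystal structure chain rather than a RefSeq accession.
#'
#' Sequences themselves are not bundled; the preset carries enough to size the
#' coordinate system, derive the default contact-set cap, and pick the preset
#' shift when a matching reference is in use.
#'
#' @return A tibble with columns `species`, `rrna`, `accession`, `length` and
#'   `shift`.
#' @examples
#' rrna_species_presets()
#' @export
rrna_species_presets <- function() {
  path <- system.file("extdata", "species_presets.tsv", package = "ribohet",
                      mustWork = TRUE)
  tbl <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tibble::as_tibble(tbl)
}

#' Default circular shift for background sets
#'
#' The background sets for the enrichment null are circular translations of a
#' contact set along the concatenated rRNA; the step is roughly 1% of the
#' total rRNA length.  When the total length matches a bundled species preset
#' the preset's published shift (71 for human, 67 for mouse) is used; otherwise
#' `round(0.01 * L)` (at least 1).
#'
#' @param ref An `rrna_reference`.
#' @return Integer shift in nucleotides.
#' @export
default_shift <- function(ref) {
  stopifnot(inherits(ref, "rrna_reference"))
  presets <- rrna_species_presets()
  totals <- tapply(presets$length, presets$species, sum)
  hit <- names(totals)[totals == ref$total_length]
  if (length(hit) == 1) {
    return(as.integer(presets$shift[presets$species == hit][1]))
  }
  max(1L, as.integer(round(0.01 * ref$total_length)))
}

#' Default contact-set size cap
#'
#' Contact sets are capped at 5% of the total rRNA length (truncated to an
#' integer), the same fraction that defines the global contact distance
#' threshold.  For the bundled human reference (7217 nt summed over the four
#' selected rRNAs) this gives 360.
#'
#' @param total_length Total concatenated rRNA length in nt, or an
#'   `rrna_reference`.
#' @return Integer cap.
#' @export
default_contact_cap <- function(total_length) {
  if (inherits(total_length, "rrna_reference")) {
    total_length <- total_length$total_length
  }
  as.integer(floor(0.05 * total_length))
}
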
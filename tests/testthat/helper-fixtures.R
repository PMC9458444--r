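# Shared fixtures, built once per test run and cached.

fixture_cache <- new.env(parent = emptyenv())

# standard toy ribosome: 650-nt RNA helix, 8 RP chains, with the derived
# proximity matrix and contact-set collection
toy_fixture <- function() {
  if (is.null(fixture_cache$toy)) {
    toy <- make_toy_structure(650, 8, seed = 42)
    ref <- read_rrna_reference(toy$fasta)
    model <- read_ribosome_structure(toy$cif, toy$chain_map)
    pm <- build_proximity_matrix(model, ref)
    csc <- contact_set_collection(pm)
    fixture_cache$toy <- list(paths = toy, ref = ref, model = model,
                              pm = pm, csc = csc)
  }
  fixture_cache$toy
}

# four-record reference with lengths 100, 50, 10, 5 (L = 165)
four_rrna_ref <- function() {
  set.seed(165)
  mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  rrna_reference(c(`28S` = mk(100), `18S` = mk(50),
                   `5.8S` = mk(10), `5S` = mk(5)))
}

# write a SAM for `ref` with the given alignment records and convert to BAM;
# records are lists with qname, flag, rname, pos, cigar, seq
sam_to_bam <- function(records, ref, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "reads.sam")
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", ref$records$rrna_id, ref$records$length))
  body <- vapply(records, function(r) {
    paste(r$qname, r$flag, r$rname, r$pos, 60, r$cigar, "*", 0, 0, r$seq, "*",
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), sam)
  Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                   indexDestination = TRUE)
}

read_record <- function(qname, rname, pos, len, flag = 0, cigar = NULL) {
  list(qname = qname, flag = flag, rname = rname, pos = pos,
       cigar = cigar %||% paste0(len, "M"),
       seq = strrep("A", len))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force per-position coverage tally from explicit covered ranges
tally_coverage <- function(ranges, ref) {
  out <- integer(ref$total_length)
  for (r in ranges) {
    idx <- to_concatenated(ref, r$rname, r$start:r$end) + 1L
    out[idx] <- out[idx] + 1L
  }
  out
}

# step-by-step running-sum oracle for the enrichment walk (independent of
# the implementation's extremum shortcut)
es_walk_oracle <- function(scores, hit) {
  N <- length(scores)
  nr <- sum(abs(scores[hit]))
  running <- 0
  extremum <- 0
  n_miss <- N - length(hit)
  for (i in seq_len(N)) {
    if (i %in% hit) {
      running <- running +
        (if (nr > 0) abs(scores[i]) / nr else 1 / length(hit))
    } else {
      running <- running - 1 / n_miss
    }
    if (abs(running) > abs(extremum)) extremum <- running
  }
  extremum
}
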
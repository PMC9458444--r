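#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its default: the pooled
#' percentile defining the contact threshold (0.05), the contact-set cap
#' (5% of the total rRNA length when `NULL`), the number of background sets
#' (100), the circular shift (species preset or ~1% of total length when
#' `NULL`), the low-count filter on mean raw counts (1), the number of
#' permutations for the enrichment null (1000), the ES2 candidate threshold
#' (1), the ORA significance rule (padj < 0.05 and |log2FC| > 0.5), the
#' ranking-score mode, and the seed.
#'
#' @param percentile,cap,n_background,shift,min_mean,n_perm,es2_threshold
#'   See description.
#' @param padj_max,lfc_min ORA significance rule.
#' @param score_mode `"floor"` (as published) or `"cap"`; see
#'   [ranking_scores()].
#' @param seed Integer seed for the permutation null.
#' @return A named list of class `ribohet_config`.
#' @export
run_config <- function(percentile = 0.05, cap = NULL, n_background = 100,
                       shift = NULL, min_mean = 1, n_perm = 1000,
                       es2_threshold = 1, padj_max = 0.05, lfc_min = 0.5,
                       score_mode = "floor", seed = 1) {
  structure(
    list(percentile = percentile, cap = cap, n_background = n_background,
         shift = shift, min_mean = min_mean, n_perm = n_perm,
         es2_threshold = es2_threshold, padj_max = padj_max,
         lfc_min = lfc_min, score_mode = score_mode, seed = seed),
    class = "ribohet_config"
  )
}

#' Run the full analysis: counts to RP predictions
#'
#' Orchestrates the pipeline on quantified inputs: assemble the positional
#' count matrix from a sample sheet (BAM or bedGraph per sample), filter low
#' counts, normalize and test differential abundance, compute the sample PCA,
#' build contact and background sets from the proximity matrix, and run the
#' three enrichment tests.  When `out_dir` is given, all result tables plus a
#' machine-readable provenance file (configuration, seed, package version,
#' dropped-position counts) are written there.
#'
#' @param sample_sheet Data frame (or TSV path) with columns `sample_id`,
#'   `path`, `condition`.
#' @param proximity A `proximity_matrix` or path to its TSV.
#' @param ref Optional `rrna_reference`; defaults to the proximity matrix's
#'   reference (sequence-less references read back from TSV are fine for
#'   counting, which only needs ids and lengths).
#' @param config A [run_config()] list.
#' @param out_dir Optional output directory.
#' @return A list with `counts`, `differential`, `pca`, `contacts`,
#'   `enrichment`, `config`.
#' @export
run_rp_analysis <- function(sample_sheet, proximity, ref = NULL,
                            config = run_config(), out_dir = NULL) {
  if (is.character(sample_sheet)) {
    sample_sheet <- utils::read.table(sample_sheet, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE)
  }
  pm <- if (is.character(proximity)) read_proximity_matrix(proximity) else proximity
  ref <- ref %||% pm$reference

  contacts <- contact_set_collection(
    pm, percentile = config$percentile, cap = config$cap,
    shift = config$shift, n_background = config$n_background
  )
  pc <- positional_counts(NULL, design = sample_sheet, ref = ref) |>
    filter_low_counts(min_mean = config$min_mean)
  diff <- differential_abundance(pc, score_mode = config$score_mode)
  pca <- sample_pca(pc, diff$size_factors)
  enr <- predict_rp_incorporation(
    diff, contacts, n_perm = config$n_perm, seed = config$seed,
    es2_threshold = config$es2_threshold, padj_max = config$padj_max,
    lfc_min = config$lfc_min
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_count_matrix(pc, file.path(out_dir, "positional_counts.tsv"))
    write_differential(diff, file.path(out_dir, "differential.tsv"))
    write_enrichment(enr, file.path(out_dir, "enrichment.tsv"))
    utils::write.table(as.data.frame(pca),
                       file.path(out_dir, "pca.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_contact_sets(contacts, file.path(out_dir, "contact_sets.tsv"))
    write_provenance(file.path(out_dir, "provenance.yaml"), config, pc, contacts)
  }
  list(counts = pc, differential = diff, pca = pca, contacts = contacts,
       enrichment = enr, config = config)
}

write_provenance <- function(path, config, pc, contacts) {
  prov <- list(
    package = "ribohet",
    version = as.character(utils::packageVersion("ribohet")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = lapply(unclass(config), function(x) x %||% "auto"),
    resolved = list(
      tau = contacts$tau, cap = contacts$cap, shift = contacts$shift,
      n_background = contacts$n_background
    ),
    samples = as.character(pc$design$sample_id),
    conditions = as.character(pc$design$condition),
    n_positions = ncol(pc$counts),
    n_retained = sum(pc$retained),
    n_dropped_low_count = sum(!pc$retained)
  )
  yaml::write_yaml(prov, path)
  invisible(path)
}
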
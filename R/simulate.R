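#' Generate a toy ribosome structure
#'
#' Writes a minimal but valid mmCIF model for testing the structural stages
#' without any download: one RNA chain whose N1 atoms lie on a 3D helix
#' (adjacent residues ~6.7 Angstrom apart), and `n_rps` protein chains, each a
#' small cluster of alpha-carbon atoms placed just outside the helix near a
#' distinct residue range - so each toy RP has a known neighbourhood of
#' closest residues.  A matching FASTA of the RNA chain is written alongside.
#' Output is deterministic given `seed` (byte-identical files).
#'
#' @param n_residues Number of RNA residues (>= 3).
#' @param n_rps Number of protein chains (>= 1).
#' @param seed Integer seed.
#' @param dir Output directory (created if needed; default a fresh tempdir).
#' @param atoms_per_rp Alpha carbons per protein chain (default 8).
#' @param rrna_id Record/chain label for the RNA (default `"rRNA"`; the mmCIF
#'   chain id is `"R"`).
#' @return A list with `cif`, `fasta` (paths), `chain_map` (named vector for
#'   [read_ribosome_structure()]), `rp_ids`, and `rp_centers` (tibble of the
#'   residue index each RP was placed near).
#' @export
make_toy_structure <- function(n_residues, n_rps, seed = 1,
                               dir = tempfile("toy_structure"),
                               atoms_per_rp = 8, rrna_id = "rRNA") {
  stopifnot(n_residues >= 3, n_rps >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    t <- seq_len(n_residues)
    theta <- 0.2 * t
    rna <- cbind(x = 30 * cos(theta), y = 30 * sin(theta), z = 3 * t)
    bases <- sample(c("A", "C", "G", "U"), n_residues, replace = TRUE)

    centers <- round(seq(1, n_residues, length.out = n_rps + 2))[-c(1, n_rps + 2)]
    rp_ids <- paste0("RP", seq_len(n_rps))
    rp_atoms <- purrr::map2(centers, seq_len(n_rps), function(cen, j) {
      anchor <- rna[cen, ]
      outward <- anchor * c(1.3, 1.3, 1)           # radially outside the helix
      jitter <- matrix(rnorm(3 * atoms_per_rp, sd = 3), ncol = 3)
      tibble::tibble(
        rp_id = rp_ids[j],
        resno = seq_len(atoms_per_rp),
        x = outward[1] + jitter[, 1],
        y = outward[2] + jitter[, 2],
        z = outward[3] + jitter[, 3]
      )
    }) |> purrr::list_rbind()

    cif_path <- file.path(dir, "toy.cif")
    fasta_path <- file.path(dir, "toy.fa")
    lines <- c(
      "data_toy", "#", "loop_",
      paste0("_atom_site.", c(
        "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
        "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
        "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
        "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
        "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"
      ))
    )
    atom_id <- 0
    fmt <- function(elesy, elety, comp, asym, ent, resno, x, y, z) {
      atom_id <<- atom_id + 1
      sprintf("ATOM %d %s %s . %s %s %d %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
              atom_id, elesy, elety, comp, asym, ent, resno, x, y, z,
              resno, comp, asym, elety)
    }
    rna_lines <- vapply(t, function(i) {
      fmt("N", "N1", bases[i], "R", 1L, i, rna[i, 1], rna[i, 2], rna[i, 3])
    }, character(1))
    rp_lines <- vapply(seq_len(nrow(rp_atoms)), function(k) {
      a <- rp_atoms[k, ]
      fmt("C", "CA", "ALA", a$rp_id, 2L, a$resno, a$x, a$y, a$z)
    }, character(1))
    writeLines(c(lines, rna_lines, rp_lines, "#"), cif_path)
    writeLines(c(paste0(">", rrna_id), paste(bases, collapse = "")), fasta_path)

    list(
      cif = cif_path, fasta = fasta_path,
      chain_map = setNames("R", rrna_id),
      rp_ids = rp_ids,
      rp_centers = tibble::tibble(rp_id = rp_ids, center_residue = centers)
    )
  })
}

#' Simulate positional rRNA fragment counts with an RP-localised effect
#'
#' Emulates the protection-change model behind the pipeline: a
#' condition-dependent change in RP incorporation alters fragment abundance
#' specifically at rRNA positions near that RP.  Baseline per-position means
#' come from a log-normal profile with expectation `depth`; in the second
#' condition the mean is multiplied by `2^effect_log2fc` at a random subset
#' (`effect_fraction`) of the target RP's contact positions (only part of a
#' contact set responds in real data - changes concentrate in hotspots).
#' Counts are negative-binomial with the given dispersion (Poisson when 0).
#' With `target_rp = NULL` the two groups are exchangeable - the null used
#' for calibration checks.
#'
#' @param ref An `rrna_reference`.
#' @param contacts A `contact_set_collection` (required when `target_rp` is
#'   set).
#' @param n_per_group Replicates per condition (default 3).
#' @param depth Mean count per position (default 50).
#' @param dispersion NB dispersion (default 0.1; 0 = Poisson).
#' @param target_rp RP whose contact points carry the effect, or `NULL` for a
#'   null simulation.
#' @param effect_log2fc Log2 fold change applied at affected positions
#'   (default 1.5).
#' @param effect_fraction Fraction of the target RP's contact positions
#'   affected (default 0.6).
#' @param seed Integer seed.
#' @param conditions Two condition labels (default `c("A", "B")`; the effect
#'   is applied in the second).
#' @return A list with `pc` (a `positional_counts`) and `truth` (tibble
#'   `concat0`, `rrna_id`, `pos`, `true_log2fc` of affected positions; zero
#'   rows for a null simulation).
#' @export
simulate_positional_counts <- function(ref, contacts = NULL, n_per_group = 3,
                                       depth = 50, dispersion = 0.1,
                                       target_rp = NULL, effect_log2fc = 1.5,
                                       effect_fraction = 0.6, seed = 1,
                                       conditions = c("A", "B")) {
  stopifnot(inherits(ref, "rrna_reference"), depth > 0, dispersion >= 0,
            effect_fraction >= 0, effect_fraction <= 1)
  L <- ref$total_length
  with_seed(seed, {
    mu <- rlnorm(L, meanlog = log(depth) - 0.5, sdlog = 1)
    affected <- integer(0)
    if (!is.null(target_rp)) {
      stopifnot(inherits(contacts, "contact_set_collection"))
      pos <- contacts$sets$concat0[contacts$sets$rp_id == target_rp]
      if (length(pos) == 0) {
        stop_ribohet(paste0("target RP has no contact set: ", target_rp),
                     "ribohet_configuration_error")
      }
      n_aff <- round(effect_fraction * length(pos))
      affected <- sort(sample(pos, n_aff))
    }
    mu_b <- mu
    mu_b[affected + 1L] <- mu_b[affected + 1L] * 2^effect_log2fc

    draw <- function(mu_vec) {
      if (dispersion > 0) rnbinom(L, mu = mu_vec, size = 1 / dispersion)
      else rpois(L, mu_vec)
    }
    counts <- c(
      lapply(seq_len(n_per_group), function(i) draw(mu)),
      lapply(seq_len(n_per_group), function(i) draw(mu_b))
    )
    sample_ids <- paste0(rep(conditions, each = n_per_group), "_",
                         rep(seq_len(n_per_group), 2))
    names(counts) <- sample_ids
    design <- tibble::tibble(
      sample_id = sample_ids,
      condition = factor(rep(conditions, each = n_per_group),
                         levels = conditions)
    )
    pc <- positional_counts(counts, design, ref)
    truth <- if (length(affected) > 0) {
      loc <- from_concatenated(ref, affected)
      tibble::tibble(concat0 = affected, rrna_id = loc$rrna_id,
                     pos = loc$pos_1based, true_log2fc = effect_log2fc)
    } else {
      tibble::tibble(concat0 = integer(0), rrna_id = character(0),
                     pos = integer(0), true_log2fc = numeric(0))
    }
    list(pc = pc, truth = truth)
  })
}

#' Write a complete simulated input bundle
#'
#' Materialises a simulation as the on-disk inputs the pipeline (and its
#' command-line front end) consumes: the reference FASTA, one bedGraph per
#' sample, a sample sheet TSV (`sample_id`, `path`, `condition`) and the
#' truth TSV of affected positions.
#'
#' @param sim Output of [simulate_positional_counts()].
#' @param dir Output directory.
#' @return Named list of written paths (`fasta`, `sample_sheet`, `truth`,
#'   `bedgraphs`).
#' @export
write_simulation_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- sim$pc$reference
  fasta <- file.path(dir, "reference.fa")
  writeLines(
    unlist(Map(function(id, s) c(paste0(">", id), s),
               ref$records$rrna_id, ref$records$seq), use.names = FALSE),
    fasta
  )
  bgs <- vapply(seq_len(nrow(sim$pc$counts)), function(i) {
    p <- file.path(dir, paste0(rownames(sim$pc$counts)[i], ".bedGraph"))
    write_bedgraph(sim$pc$counts[i, ], ref, p)
    p
  }, character(1))
  sheet <- file.path(dir, "samples.tsv")
  utils::write.table(
    data.frame(sample_id = sim$pc$design$sample_id, path = bgs,
               condition = as.character(sim$pc$design$condition)),
    sheet, sep = "\t", quote = FALSE, row.names = FALSE
  )
  truth <- file.path(dir, "truth.tsv")
  utils::write.table(as.data.frame(sim$truth), truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(fasta = fasta, sample_sheet = sheet, truth = truth, bedgraphs = bgs)
}
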
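# minimal mmCIF writer for hand-built structural cases
write_test_cif <- function(atoms, path) {
  # atoms: data.frame with elesy, elety, comp, asym, ent, resno, x, y, z
  head <- c(
    "data_test", "#", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"
    ))
  )
  body <- sprintf(
    "ATOM %d %s %s . %s %s %d %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
    seq_len(nrow(atoms)), atoms$elesy, atoms$elety, atoms$comp, atoms$asym,
    atoms$ent, atoms$resno, atoms$x, atoms$y, atoms$z, atoms$resno,
    atoms$comp, atoms$asym, atoms$elety
  )
  writeLines(c(head, body, "#"), path)
  path
}

atom_row <- function(elety, comp, asym, resno, x, y, z) {
  data.frame(elesy = if (elety == "N1") "N" else "C", elety = elety,
             comp = comp, asym = asym, ent = if (elety == "N1") 1L else 2L,
             resno = resno, x = x, y = y, z = z)
}

test_that("structure parsing extracts N1 and CA reference atoms per chain", {
  atoms <- rbind(
    atom_row("N1", "A", "R", 1, 0, 0, 0),
    atom_row("N1", "C", "R", 2, 5, 0, 0),
    atom_row("N1", "G", "R", 3, 10, 0, 0),
    atom_row("CA", "ALA", "P1", 1, 0, 3, 0),
    atom_row("CA", "GLY", "P1", 2, 0, 6, 0),
    atom_row("CA", "ALA", "P2", 1, 10, 4, 0),
    atom_row("CA", "GLY", "P2", 2, 10, 8, 0)
  )
  cif <- write_test_cif(atoms, withr::local_tempfile(fileext = ".cif"))
  model <- read_ribosome_structure(cif, c(rna = "R"))
  expect_equal(nrow(model$rna), 3L)
  expect_equal(sort(unique(model$rp$rp_id)), c("P1", "P2"))
  expect_equal(sum(is.na(model$rna$x)), 0L)

  expect_error(read_ribosome_structure(cif, c(rna = "Z")),
               "Z", class = "ribohet_configuration_error")

  # deny-list removes a protein chain from the RP candidates
  model2 <- read_ribosome_structure(cif, c(rna = "R"), rp_exclude = "P2")
  expect_equal(unique(model2$rp$rp_id), "P1")
})

test_that("a residue without an N1 atom is missing, not an error", {
  atoms <- rbind(
    atom_row("N1", "A", "R", 1, 0, 0, 0),
    atom_row("P", "C", "R", 2, 5, 0, 0),   # unresolved base: no N1
    atom_row("N1", "G", "R", 3, 10, 0, 0),
    atom_row("CA", "ALA", "P1", 1, 0, 3, 0)
  )
  cif <- write_test_cif(atoms, withr::local_tempfile(fileext = ".cif"))
  model <- read_ribosome_structure(cif, c(rna = "R"))
  expect_equal(nrow(model$rna), 3L)
  expect_true(is.na(model$rna$x[model$rna$pos == 2]))

  ref <- rrna_reference(c(rna = "ACG"))
  pm <- build_proximity_matrix(model, ref)
  expect_true(all(is.na(pm$distances[, 2])))
  expect_false(anyNA(pm$distances[, c(1, 3)]))
})

test_that("minimum distances obey coincidence and the minimum rule", {
  atoms <- rbind(
    atom_row("N1", "A", "R", 1, 0, 0, 0),
    atom_row("CA", "ALA", "P1", 1, 0, 0, 0),   # coincident with residue 1
    atom_row("CA", "ALA", "P2", 1, 3, 4, 0),   # 5 away (3-4-5)
    atom_row("CA", "GLY", "P2", 2, 6, 8, 0)    # 10 away; min wins
  )
  cif <- write_test_cif(atoms, withr::local_tempfile(fileext = ".cif"))
  model <- read_ribosome_structure(cif, c(rna = "R"))
  pm <- build_proximity_matrix(model, rrna_reference(c(rna = "A")))
  expect_equal(pm$distances["P1", 1], 0)
  expect_equal(pm$distances["P2", 1], 5)
})

test_that("proximity matrix equals a brute-force atom-pair search", {
  fx <- make_toy_structure(10, 3, seed = 3, atoms_per_rp = 5)
  ref <- read_rrna_reference(fx$fasta)
  model <- read_ribosome_structure(fx$cif, fx$chain_map)
  pm <- build_proximity_matrix(model, ref)
  for (rp in unique(model$rp$rp_id)) {
    A <- model$rp[model$rp$rp_id == rp, ]
    for (i in seq_len(nrow(model$rna))) {
      r <- model$rna[i, ]
      d <- Inf
      for (k in seq_len(nrow(A))) {
        d <- min(d, sqrt((r$x - A$x[k])^2 + (r$y - A$y[k])^2 + (r$z - A$z[k])^2))
      }
      expect_equal(pm$distances[rp, r$pos], d, tolerance = 1e-10)
    }
  }
})

test_that("structure/reference sequence disagreement is a validation error", {
  atoms <- rbind(
    atom_row("N1", "A", "R", 1, 0, 0, 0),
    atom_row("N1", "C", "R", 2, 5, 0, 0),
    atom_row("N1", "G", "R", 3, 10, 0, 0),
    atom_row("CA", "ALA", "P1", 1, 0, 3, 0)
  )
  cif <- write_test_cif(atoms, withr::local_tempfile(fileext = ".cif"))
  model <- read_ribosome_structure(cif, c(rna = "R"))
  expect_error(build_proximity_matrix(model, rrna_reference(c(rna = "TTT"))),
               class = "ribohet_validation_error")
  # tolerance can be relaxed explicitly
  pm <- build_proximity_matrix(model, rrna_reference(c(rna = "ACT")),
                               identity_min = 0.6)
  expect_equal(nrow(attr(pm, "mismatches")), 1L)
})

test_that("proximity TSV round-trips and rebuilds a coordinate skeleton", {
  fx <- toy_fixture()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_proximity_matrix(fx$pm, tsv)
  back <- read_proximity_matrix(tsv)
  expect_equal(back$distances, fx$pm$distances)
  expect_equal(back$reference$total_length, fx$ref$total_length)
  back2 <- read_proximity_matrix(tsv, ref = fx$ref)
  expect_equal(back2$reference$records$seq, fx$ref$records$seq)
})

make_pm <- function(ref, dist_rows) {
  d <- do.call(rbind, dist_rows)
  dimnames(d) <- list(names(dist_rows), ribohet:::concat_labels(ref))
  structure(list(distances = d, reference = ref), class = "proximity_matrix")
}

make_amap <- function(rrna_id, source_pos, target_pos, unaligned) {
  structure(list(
    pairs = tibble::tibble(rrna_id = rrna_id, source_pos = source_pos,
                           target_pos = target_pos),
    unaligned_target = tibble::tibble(rrna_id = rrna_id, target_pos = unaligned)
  ), class = "rrna_alignment")
}

test_that("matrix transfer copies, interpolates, and respects missingness", {
  # identity alignment reproduces the matrix
  fx <- toy_fixture()
  n <- fx$ref$total_length
  ident <- make_amap("rRNA", seq_len(n), seq_len(n), integer(0))
  moved <- transfer_proximity_matrix(fx$pm, ident, fx$ref)
  expect_equal(moved$distances, fx$pm$distances)

  # 2-residue insertion between flanks 10 and 16 -> 12 and 14
  src <- rrna_reference(c(x = "AA"))
  tgt <- rrna_reference(c(x = "AANN"))
  pm <- make_pm(src, list(RP1 = c(10, 16)))
  am <- make_amap("x", c(1L, 2L), c(1L, 4L), c(2L, 3L))
  out <- transfer_proximity_matrix(pm, am, tgt)
  expect_equal(unname(out$distances["RP1", ]), c(10, 12, 14, 16))

  # insertion adjacent to a missing flank copies the resolved side;
  # both flanks missing stays missing (hand-worked 6-residue case)
  src6 <- rrna_reference(c(x = "AAAA"))
  tgt6 <- rrna_reference(c(x = "AANNAA"))
  am6 <- make_amap("x", 1:4, c(1L, 2L, 5L, 6L), c(3L, 4L))
  pm_a <- make_pm(src6, list(RP1 = c(10, 12, NA, 20)))
  out_a <- transfer_proximity_matrix(pm_a, am6, tgt6)
  expect_equal(unname(out_a$distances["RP1", ]), c(10, 12, 12, 12, NA, 20))
  pm_b <- make_pm(src6, list(RP1 = c(10, NA, NA, 20)))
  out_b <- transfer_proximity_matrix(pm_b, am6, tgt6)
  expect_equal(unname(out_b$distances["RP1", ]), c(10, NA, NA, NA, NA, 20))

  # insertions beyond the outermost aligned residue copy the nearest value
  tgt_e <- rrna_reference(c(x = "NAAN"))
  am_e <- make_amap("x", c(1L, 2L), c(2L, 3L), c(1L, 4L))
  pm_e <- make_pm(rrna_reference(c(x = "AA")), list(RP1 = c(7, 9)))
  out_e <- transfer_proximity_matrix(pm_e, am_e, tgt_e)
  expect_equal(unname(out_e$distances["RP1", ]), c(7, 7, 9, 9))
})

test_that("interpolated values stay within the flanking range (random maps)", {
  set.seed(21)
  for (rep in 1:10) {
    n_src <- 12
    src <- rrna_reference(c(x = strrep("A", n_src)))
    keep <- sort(sample(n_src, 7))
    n_tgt <- 7 + 5
    tpos <- sort(sample(n_tgt, 7))
    tgt <- rrna_reference(c(x = strrep("A", n_tgt)))
    am <- make_amap("x", keep, tpos, setdiff(seq_len(n_tgt), tpos))
    d <- runif(n_src, 5, 50)
    pm <- make_pm(src, list(RP1 = d))
    out <- transfer_proximity_matrix(pm, am, tgt)$distances["RP1", ]
    aligned_vals <- d[keep]
    for (u in setdiff(seq_len(n_tgt), tpos)) {
      lo_set <- aligned_vals[tpos < u]
      hi_set <- aligned_vals[tpos > u]
      flanks <- c(utils::tail(lo_set, 1), utils::head(hi_set, 1))
      expect_gte(out[u] + 1e-12, min(flanks))
      expect_lte(out[u] - 1e-12, max(flanks))
    }
  }
})
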
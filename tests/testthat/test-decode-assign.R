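test_that("spot aggregation groups per molecule and splits crowded sets", {
  asg <- assign_genes(default_cb(), c("a", "b"))
  cb <- asg$codebook
  mk_spots <- function(gene, x, y, id) {
    bits <- on_bits(cb, gene)
    data.frame(round = bits, x_um = x, y_um = y, intensity = 1,
               is_bead = FALSE, mol_id = id)
  }
  # two molecules 10 um apart: two candidates, word weight 6
  sp <- rbind(mk_spots("a", 5, 5, 1L), mk_spots("b", 15, 5, 2L))
  cand <- aggregate_rounds(sp, match_radius_um = 0.5)
  expect_identical(nrow(cand$words), 2L)
  expect_true(all(rowSums(cand$words) == 6L))

  # two same-gene molecules 0.1 um apart merge into one candidate but the
  # word weight stays 6 (per-round dedup)
  sp2 <- rbind(mk_spots("a", 5, 5, 1L), mk_spots("a", 5.1, 5, 2L))
  cand2 <- aggregate_rounds(sp2, match_radius_um = 0.5)
  expect_identical(nrow(cand2$words), 1L)
  expect_identical(sum(cand2$words), 6L)

  # beads never join molecules
  spb <- rbind(mk_spots("a", 5, 5, 1L),
               data.frame(round = 0L, x_um = 5, y_um = 5, intensity = 9,
                          is_bead = TRUE, mol_id = NA_integer_))
  expect_identical(nrow(aggregate_rounds(spb, 0.5)$words), 1L)
})

test_that("molecule decoding reports calls, no-calls and per-gene totals", {
  asg <- assign_genes(default_cb(), c("a", "b"))
  cb <- asg$codebook
  words <- rbind(cb$codes["a", ], cb$codes["b", ], rep(0L, 16L))
  cand <- list(words = words, x = c(1, 2, 3), y = c(1, 2, 3),
               n_spots = rowSums(words), members = list(1L, 2L, 3L))
  dec <- decode_molecules(cand, cb)
  expect_identical(nrow(dec$molecules), 2L)
  expect_identical(dec$n_nocall, 1L)
  expect_identical(unname(dec$per_label[c("a", "b")]), c(1L, 1L))
  expect_true(all(dec$molecules$bit_errors == 0))
})

test_that("blank rate is zero without errors and grows with bit gain", {
  prof <- example_profiles(20L, 4L)
  asg <- assign_genes(default_cb(), rownames(prof))
  # blank calls need combined dropout and gain (a gained-only word is a
  # superset of the true codeword, never within distance 1 of a blank)
  sc <- simulate_scene(example_profiles(20L, 4L, mean_total = 20),
                       n_cells = 150L, extent = c(700, 700),
                       ambient_rate = 8e-4, bead_density = 0, seed = 21L)
  rates <- vapply(c(0, 0.03, 0.1), function(pg) {
    cfg <- acquisition_config(p_dropout = if (pg > 0) 0.15 else 0,
                              p_gain = pg, seed = 22L)
    ro <- simulate_readout(sc, asg$codebook, cfg)
    cand <- aggregate_rounds(ro$spots, match_radius_um = 0.3)
    dec <- decode_molecules(cand, asg$codebook)
    blank_fpr(dec, asg$codebook)$mean
  }, numeric(1L))
  expect_identical(rates[1L], 0)
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3L], 0)

  # fixed-count arithmetic: 8 blanks, one call each, 8000 decoded
  fake <- list(molecules = data.frame(label = rep("x", 8000L)),
               per_label = stats::setNames(
                 rep(1L, 8L), sprintf("Blank-%d", 1:8)))
  cb8 <- assign_genes(default_cb(), sprintf("G%03d", seq_len(496L)))$codebook
  expect_identical(sum(startsWith(rownames(cb8$codes), "Blank-")), 8L)
  fr <- blank_fpr(fake, cb8)
  expect_equal(fr$mean, 1 / 8000)
  expect_equal(fr$sd, 0)

  no_blank <- assign_genes(generate_codebook(4L, 2L, 4L),
                           c("a", "b"))$codebook
  expect_error(blank_fpr(fake, no_blank), "no blank")
})

test_that("mask expansion grows 8 um without overlap or reassignment", {
  # one disk of radius 10 px at 1 um/px: grows to ~18 px radius
  lab <- disk_labels(c(100L, 100L), cbind(50, 50, 10))
  ex <- expand_masks(lab, distance_um = 8, pixel_size = 1)
  r_eff <- sqrt(sum(ex == 1L) / pi)
  expect_lt(abs(r_eff - 18), 1)
  expect_true(all(ex[lab == 1L] == 1L))

  # two disks whose edges are 14 um apart: expansion fronts meet without
  # overlap, original pixels are never reassigned
  lab2 <- disk_labels(c(120L, 120L), rbind(c(40, 60, 10), c(74, 60, 10)))
  ex2 <- expand_masks(lab2, distance_um = 8, pixel_size = 1)
  expect_true(all(ex2[lab2 > 0L] == lab2[lab2 > 0L]))
  expect_gt(sum(ex2 == 1L), sum(lab2 == 1L))
  expect_gt(sum(ex2 == 2L), sum(lab2 == 2L))
  # along the line through both centres the gap is fully closed and the
  # labels form two contiguous runs meeting near the equidistant front
  run <- ex2[60L, 45:70]
  expect_true(all(run > 0L))
  expect_true(all(diff(run) >= 0L))          # 1...1 then 2...2
  switch_at <- 44L + max(which(run == 1L))   # last column holding label 1
  expect_true(abs(switch_at - 57L) <= 1L)

  expect_identical(expand_masks(lab, distance_um = 0, pixel_size = 1), lab)
  expect_error(expand_masks(lab, 8, pixel_size = c(1, 2)), "anisotropic")
})

test_that("molecule assignment conserves counts and excludes blanks", {
  lab <- disk_labels(c(100L, 100L), rbind(c(30, 30, 12), c(70, 70, 12)))
  mols <- data.frame(
    label = c("g1", "g1", "g2", "Blank-1", "g2", "g1"),
    x_um = c(30, 32, 70, 30, 50, 98),
    y_um = c(30, 30, 70, 30, 50, 98))
  cm <- assign_to_cells(mols, lab, pixel_size = 1)
  n_blank_in_cells <- sum(!is.na(cm$cell_id) &
                            startsWith(mols$label, "Blank-"))
  expect_identical(as.integer(sum(cm$counts)) + cm$n_unassigned +
                     n_blank_in_cells, nrow(mols))
  expect_identical(as.integer(cm$counts["1", "g1"]), 2L)
  expect_identical(as.integer(cm$counts["2", "g2"]), 1L)
  expect_false("Blank-1" %in% colnames(cm$counts))
  # molecule in background and molecule outside any mask are unassigned
  expect_identical(cm$n_unassigned, 2L)

  # transform between stain and molecule frames is honoured
  tf <- similarity_transform(1, 0, 10, 0)   # stain -> molecule: +10 um in x
  cm2 <- assign_to_cells(data.frame(label = "g1", x_um = 40, y_um = 30),
                         lab, stain_to_mol = tf, pixel_size = 1)
  expect_identical(as.integer(cm2$counts["1", "g1"]), 1L)
})

test_that("cell quality control drops cells below thresholds", {
  m <- Matrix::sparseMatrix(i = c(1L, 1L, 2L, 3L), j = c(1L, 2L, 1L, 3L),
                            x = c(5, 3, 1, 2), dims = c(3L, 3L),
                            dimnames = list(c("c1", "c2", "c3"),
                                            c("g1", "g2", "g3")))
  qc0 <- qc_cells(m, 0, 0)
  expect_identical(qc0$n_dropped, 0L)
  qc <- qc_cells(m, min_counts = 2, min_genes = 2)
  expect_identical(rownames(qc$counts), "c1")
  expect_identical(qc$n_dropped, 2L)
})

test_that("end-to-end decoding recovers per-gene counts from drifted data", {
  prof <- example_profiles(20L, 4L)
  asg <- assign_genes(default_cb(), rownames(prof))
  sc <- simulate_scene(prof, n_cells = 150L, extent = c(520, 520),
                       ambient_rate = 8e-4, bead_density = 7.5e-4,
                       cell_radius_um = 6, seed = 31L)
  cfg <- acquisition_config(p_dropout = 0.05, p_gain = 0.002,
                            drift = make_drift(seed = 32L), seed = 33L)
  ro <- simulate_readout(sc, asg$codebook, cfg)
  tfs <- register_rounds(ro$spots, reference_round = 0L, match_radius = 3)
  reg <- apply_round_transforms(ro$spots, tfs)
  dec <- decode_molecules(aggregate_rounds(reg, match_radius_um = 0.3),
                          asg$codebook)
  truth_counts <- table(factor(ro$truth$gene, levels = rownames(prof)))
  r <- cor(as.numeric(truth_counts),
           as.numeric(dec$per_label[rownames(prof)]))
  expect_gt(r, 0.99)
  expect_gt(nrow(dec$molecules) / nrow(ro$truth), 0.9)
})
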
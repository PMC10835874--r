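# hand-built cell table: 6 patients, one lineage-A marker gene with patient
# means 5,6,7 in A cells against 1,2,3 elsewhere
toy_cells <- function() {
  vals <- matrix(0, nrow = 6, ncol = 2,
                 dimnames = list(sprintf("cell%d", 1:6), c("marker", "other")))
  vals[, "marker"] <- c(5, 6, 7, 1, 2, 3)
  vals[, "other"] <- c(2.1, 2, 1.9, 2, 2.05, 1.95)
  cell_table(vals, data.frame(
    cell_id = sprintf("cell%d", 1:6),
    patient_id = sprintf("p%d", 1:6),
    lineage = rep(c("A", "B"), each = 3)))
}

test_that("patient-averaged Wilcoxon matches exact enumeration on 3 vs 3", {
  res <- patient_averaged_dgea(toy_cells(), group_by = "lineage")
  # complete separation of three patient means per side: 2 of the 20
  # orderings are as extreme, two-sided exact p = 0.1
  pA <- res$p[res$group == "A" & res$gene_id == "marker"]
  expect_equal(pA, 0.1, tolerance = 1e-12)
  expect_gt(res$p[res$group == "A" & res$gene_id == "other"], 0.5)
  lfc <- res$lfc[res$group == "A" & res$gene_id == "marker"]
  expect_equal(lfc, 4)   # mean(5,6,7) - mean(1,2,3)
})

test_that("pseudobulk DGEA ignores cell duplication and cell order", {
  ct <- simulate_cell_table(8, 30, c("A", "B"), marker_strength = 3,
                            dropout = 0.2, seed = 70)
  base <- patient_averaged_dgea(ct)
  # duplicate every cell of one patient: patient means unchanged
  dup_rows <- which(ct$cells$patient_id == "pat01")
  vals2 <- rbind(ct$values, ct$values[dup_rows, , drop = FALSE])
  meta2 <- rbind(ct$cells, ct$cells[dup_rows, ])
  meta2$cell_id <- sprintf("cell%05d", seq_len(nrow(meta2)))
  rownames(vals2) <- meta2$cell_id
  dup <- patient_averaged_dgea(cell_table(vals2, meta2))
  expect_equal(dup$p, base$p, tolerance = 1e-12)
  expect_equal(dup$lfc, base$lfc, tolerance = 1e-12)

  perm <- sample(nrow(ct$values))
  shuf <- patient_averaged_dgea(
    cell_table(ct$values[perm, ], ct$cells[perm, ]))
  expect_equal(shuf$p, base$p, tolerance = 1e-12)
})

test_that("planted lineage markers top their own contrast and nulls stay flat", {
  ct <- simulate_cell_table(20, 40, c("A", "B"), marker_strength = 3,
                            dropout = 0.1, seed = 71)
  res <- patient_averaged_dgea(ct)
  resA <- res[res$group == "A", ]
  top <- resA$gene_id[order(-resA$lfc)][1:5]
  expect_true(all(grepl("^mk_A_", top)))
  expect_true(all(resA$significant[grepl("^mk_A_", resA$gene_id)]))

  # no markers, no dropout: raw p-values stay roughly calibrated
  ct0 <- simulate_cell_table(12, 40, c("A", "B"), marker_strength = 0,
                             dropout = 0, seed = 72)
  res0 <- patient_averaged_dgea(ct0)
  expect_lt(mean(res0$p < 0.05), 0.12)
  expect_equal(sum(res0$significant), 0)
})

test_that("DGEA needs two patients per side", {
  vals <- matrix(1:8, nrow = 4,
                 dimnames = list(sprintf("c%d", 1:4), c("g1", "g2")))
  meta <- data.frame(cell_id = sprintf("c%d", 1:4),
                     patient_id = c("p1", "p2", "p3", "p3"),
                     lineage = c("A", "A", "B", "B"))
  expect_error(suppressWarnings(patient_averaged_dgea(cell_table(vals, meta))),
               class = "invalid_input")
  w <- capture_warnings(
    tryCatch(patient_averaged_dgea(cell_table(vals, meta)),
             error = function(e) NULL))
  expect_true(any(grepl("fewer than 2 patients", w)))
})

test_that("DOR marker selection follows the corrected 2x2 odds ratio", {
  # 10 target and 10 background cells; marker detected 9/10 vs 1/10
  vals <- matrix(0, nrow = 20, ncol = 3,
                 dimnames = list(sprintf("c%d", 1:20),
                                 c("marker", "ubiquitous", "silent")))
  vals[1:9, "marker"] <- 5
  vals[11, "marker"] <- 5
  vals[, "ubiquitous"] <- 3
  ct <- cell_table(vals, data.frame(
    cell_id = sprintf("c%d", 1:20),
    patient_id = rep(sprintf("p%d", 1:4), each = 5),
    lineage = rep(c("T", "rest"), each = 10)))
  mk <- dor_markers(ct, "T", dor_cut = 2, lfc_cut = 1)
  tab <- attr(mk, "table")
  # Haldane-corrected: (9.5 * 9.5) / (1.5 * 1.5)
  expect_equal(tab$dor[tab$gene_id == "marker"], 9.5^2 / 1.5^2,
               tolerance = 1e-12)
  expect_identical(as.character(mk), "marker")
  expect_equal(tab$dor[tab$gene_id == "ubiquitous"], 1, tolerance = 1e-12)
  expect_equal(tab$dor[tab$gene_id == "silent"], 1, tolerance = 1e-12)

  # tightening the cut never grows the marker set
  m1 <- dor_markers(ct, "T", dor_cut = 1, lfc_cut = 0.5)
  m2 <- dor_markers(ct, "T", dor_cut = 10, lfc_cut = 0.5)
  expect_true(all(m2 %in% m1))
  expect_error(dor_markers(ct, "missing"), class = "unknown_label")
})

test_that("per-cell score contrasts behave symmetrically", {
  ct <- simulate_cell_table(10, 30, c("lumA", "lumB"), marker_strength = 0,
                            dropout = 0.2, seed = 73)
  sig <- signature_def(ct$gene_ids[11:20], rep(c(0.4, -0.4), 5))
  sc <- compute_cell_trs(ct, sig)
  same <- group_cell_trs(sc, ct, c("lumA", "lumA"))
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  ab <- group_cell_trs(sc, ct, c("lumA", "lumB"))
  ba <- group_cell_trs(sc, ct, c("lumB", "lumA"))
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p, ba$p)
  expect_error(group_cell_trs(sc, ct, c("lumA", "ghost")),
               class = "empty_group")
})

test_that("tumor cells with up-shifted risk genes score higher", {
  hits <- 0
  for (i in 1:5) {
    ct <- simulate_cell_table(10, 40, c("luminal", "T-luminal"),
                              marker_strength = 1.5, dropout = 0.2,
                              seed = 700 + i)
    risk <- sprintf("mk_T-luminal_%d", 1:5)       # up in T-luminal cells
    protective <- sprintf("mk_luminal_%d", 1:5)
    sig <- signature_def(c(risk, protective), c(rep(1, 5), rep(-1, 5)))
    sc <- compute_cell_trs(ct, sig)
    res <- group_cell_trs(sc, ct, c("T-luminal", "luminal"))
    hits <- hits + (res$delta > 0 && res$p < 0.05)
  }
  expect_gte(hits, 4)
})

test_that("module enrichment centers on its expression-matched background", {
  ct <- simulate_cell_table(6, 50, c("A", "B"), marker_strength = 0,
                            dropout = 0, seed = 74)
  all_score <- module_enrichment(ct, ct$gene_ids, seed = 3)
  expect_lt(abs(mean(all_score)), 0.05)

  # plant a high set in a subset of cells
  vals <- as.matrix(ct$values)
  set_genes <- ct$gene_ids[31:40]
  hot <- 1:60
  vals[hot, set_genes] <- vals[hot, set_genes] + 3
  ct2 <- cell_table(vals, ct$cells)
  sc <- module_enrichment(ct2, set_genes, seed = 3)
  ranked <- order(-sc)
  expect_gt(mean(ranked[1:60] %in% hot), 0.9)

  expect_identical(module_enrichment(ct2, set_genes, seed = 3), sc)
  expect_error(module_enrichment(ct, c("zz1", "zz2")), class = "no_overlap")
})
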
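#' Patient-averaged differential expression between cell groups
#'
#' Cells are not independent replicates - patients are. For each group
#' level (lineage or cell type), every gene's expression is first averaged
#' per patient within the group and per patient over all other cells of
#' the contrast background; a two-sided Wilcoxon rank-sum test then
#' compares the two sets of patient means (exact when free of ties), with
#' BH-FDR adjustment across genes within the contrast. The log fold change
#' is the difference of group means of the (log-scale) patient means.
#' For \code{group_by = "cell_type"} each contrast is restricted to cells
#' of the type's own lineage, so types are compared against their lineage
#' siblings rather than against unrelated compartments.
#'
#' @param cells a \code{cell_table} with normalized (log-scale) values.
#' @param group_by \code{"lineage"} or \code{"cell_type"}.
#' @param fdr_cut,lfc_cut significance thresholds (defaults 0.05 / 0.25)
#'   applied as \code{fdr < fdr_cut & lfc > lfc_cut}.
#' @return A \code{dgea_result} data.frame: \code{group}, \code{gene_id},
#'   \code{lfc}, \code{p}, \code{fdr}, \code{n_patients_in},
#'   \code{n_patients_out}, \code{significant}. Contrasts with fewer than
#'   2 patients on either side are skipped with a warning.
#' @export
patient_averaged_dgea <- function(cells, group_by = c("lineage", "cell_type"),
                                  fdr_cut = 0.05, lfc_cut = 0.25) {
  group_by <- match.arg(group_by)
  stopifnot(inherits(cells, "cell_table"))
  meta <- cells$cells
  if (group_by == "cell_type" && !"cell_type" %in% names(meta))
    abort("cell metadata lacks cell_type", "invalid_input")
  groups <- sort(unique(meta[[group_by]]))

  out <- list()
  for (g in groups) {
    in_grp <- meta[[group_by]] == g
    bg <- if (group_by == "cell_type") {
      lin <- unique(meta$lineage[in_grp])
      meta$lineage %in% lin & !in_grp
    } else !in_grp
    means_in <- patient_gene_means(cells, in_grp)
    means_out <- patient_gene_means(cells, bg)
    if (nrow(means_in) < 2 || nrow(means_out) < 2) {
      warn(sprintf("contrast '%s': fewer than 2 patients on one side; skipped", g),
           "contrast_skipped")
      next
    }
    # ties fall back to the normal approximation; the per-gene ties
    # warning is noise at transcriptome scale
    p <- vapply(seq_len(ncol(means_in)), function(j) {
      suppressWarnings(
        stats::wilcox.test(means_in[, j], means_out[, j])$p.value)
    }, numeric(1))
    lfc <- colMeans(means_in) - colMeans(means_out)
    fdr <- bh_adjust(p)
    out[[g]] <- data.frame(
      group = g, gene_id = cells$gene_ids, lfc = lfc, p = p, fdr = fdr,
      n_patients_in = nrow(means_in), n_patients_out = nrow(means_out),
      significant = fdr < fdr_cut & lfc > lfc_cut,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    abort("no testable contrast (need >= 2 patients per side)",
          "invalid_input")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("dgea_result", "data.frame")
  res
}

# patients x genes matrix of mean expression over a cell subset
patient_gene_means <- function(cells, which_cells) {
  sub <- cells$values[which_cells, , drop = FALSE]
  pats <- cells$cells$patient_id[which_cells]
  up <- sort(unique(pats))
  m <- t(vapply(up, function(p)
    as.numeric(Matrix::colMeans(sub[pats == p, , drop = FALSE])),
    numeric(ncol(sub))))
  rownames(m) <- up
  colnames(m) <- colnames(sub)
  m
}

#' Detection-based marker selection by diagnostic odds ratio
#'
#' A marker should be detected in the target population and silent
#' elsewhere. For each gene a 2x2 detection table (expression > 0 vs not,
#' target cells vs rest) is formed with the Haldane +0.5 correction, and
#' the diagnostic odds ratio \eqn{DOR = (a d)/(b c)} computed on the
#' corrected counts. Selected markers must exceed \code{dor_cut}, show a
#' log fold change above \code{lfc_cut}, and - when a
#' \code{\link{patient_averaged_dgea}} result is supplied - be
#' significantly overexpressed in the target group.
#'
#' @param cells a \code{cell_table}.
#' @param target group label (matched against \code{lineage}, or
#'   \code{cell_type} when \code{by = "cell_type"}).
#' @param dor_cut DOR threshold (e.g. 2 for lineage markers, 1 for
#'   tumor-specific luminal markers).
#' @param lfc_cut log fold-change threshold.
#' @param dgea optional \code{dgea_result} used to require significance.
#' @param by metadata column defining groups.
#' @return Character vector of marker gene ids; the full per-gene table in
#'   \code{attr(, "table")}.
#' @export
dor_markers <- function(cells, target, dor_cut = 2, lfc_cut = 1,
                        dgea = NULL, by = c("lineage", "cell_type")) {
  by <- match.arg(by)
  stopifnot(inherits(cells, "cell_table"))
  grp <- cells$cells[[by]]
  if (!target %in% grp)
    abort(sprintf("unknown %s label '%s'", by, target), "unknown_label")
  in_t <- grp == target
  det <- cells$values > 0
  a <- Matrix::colSums(det[in_t, , drop = FALSE]) + 0.5       # detected, target
  b <- sum(in_t) - a + 1                                      # silent, target (+0.5)
  cc <- Matrix::colSums(det[!in_t, , drop = FALSE]) + 0.5     # detected, rest
  d <- sum(!in_t) - cc + 1                                    # silent, rest (+0.5)
  dor <- (a * d) / (b * cc)
  lfc <- as.numeric(Matrix::colMeans(cells$values[in_t, , drop = FALSE]) -
                    Matrix::colMeans(cells$values[!in_t, , drop = FALSE]))
  tab <- data.frame(gene_id = cells$gene_ids, dor = as.numeric(dor),
                    lfc = lfc, stringsAsFactors = FALSE)
  pass <- tab$dor > dor_cut & tab$lfc > lfc_cut
  if (!is.null(dgea)) {
    sig_genes <- dgea$gene_id[dgea$group == target & dgea$significant]
    pass <- pass & tab$gene_id %in% sig_genes
  }
  structure(tab$gene_id[pass], table = tab)
}

#' Compare per-cell risk scores between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test of per-cell scores between two labeled
#' groups (e.g. tumor-specific luminal vs normal luminal cells), with the
#' difference of group medians as the effect size.
#'
#' @param cell_scores a \code{score_vector} from
#'   \code{\link{compute_cell_trs}}.
#' @param cells the matching \code{cell_table}.
#' @param contrast length-2 character vector \code{c(label_a, label_b)};
#'   labels are matched in \code{cell_type} first, then \code{lineage}.
#' @return List with \code{delta} (median_a - median_b), \code{p},
#'   \code{n_a}, \code{n_b}.
#' @export
group_cell_trs <- function(cell_scores, cells, contrast) {
  stopifnot(inherits(cells, "cell_table"), length(contrast) == 2)
  s <- score_values(cell_scores)[cells$cells$cell_id]
  lab <- cells$cells$cell_type %||% cells$cells$lineage
  pick <- function(l) {
    i <- lab == l
    if (!any(i)) i <- cells$cells$lineage == l
    if (!any(i)) abort(sprintf("empty group '%s'", l), "empty_group")
    i
  }
  ia <- pick(contrast[1]); ib <- pick(contrast[2])
  wt <- stats::wilcox.test(s[ia], s[ib], exact = FALSE, correct = TRUE)
  list(delta = stats::median(s[ia]) - stats::median(s[ib]),
       p = wt$p.value, n_a = sum(ia), n_b = sum(ib))
}

#' Expression-matched module enrichment score per cell or spot
#'
#' Scores each observation for a gene set against an expression-matched
#' background: genes are binned by their average expression across
#' observations (\code{n_bins} quantile bins), and for every set gene
#' \code{n_control} control genes are drawn (seeded, with replacement)
#' from its bin. The score is the observation's mean expression over the
#' set minus its mean over the pooled control draws, so a set that merely
#' sits at high average expression scores near zero.
#'
#' @param cells a \code{cell_table} of cells or spatial spots.
#' @param gene_set character vector of gene ids.
#' @param n_bins number of expression bins (default 24).
#' @param n_control control genes drawn per set gene (default 100).
#' @param seed RNG seed.
#' @return Named numeric vector, one score per observation.
#' @export
module_enrichment <- function(cells, gene_set, n_bins = 24,
                              n_control = 100, seed = 1) {
  stopifnot(inherits(cells, "cell_table"))
  set_genes <- intersect(gene_set, cells$gene_ids)
  if (length(set_genes) == 0)
    abort("gene set has no overlap with the matrix", "no_overlap")
  avg <- Matrix::colMeans(cells$values)
  n_bins <- max(2L, min(n_bins, length(avg) %/% 2L))
  breaks <- unique(stats::quantile(avg, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(avg, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  names(bin) <- cells$gene_ids

  set.seed(derive_seed(seed, 0L))
  ctrl <- unlist(lapply(set_genes, function(g) {
    cand <- setdiff(cells$gene_ids[bin == bin[g]], g)
    if (length(cand) == 0) cand <- setdiff(cells$gene_ids, g)
    cand[sample.int(length(cand), n_control, replace = TRUE)]
  }))
  set_mean <- Matrix::rowMeans(cells$values[, set_genes, drop = FALSE])
  ctrl_mean <- Matrix::rowMeans(cells$values[, ctrl, drop = FALSE])
  stats::setNames(as.numeric(set_mean - ctrl_mean), cells$cells$cell_id)
}

#' Read / write cell tables as MatrixMarket + metadata CSVs
#'
#' Plain-text trio: \code{matrix.mtx} (cells x genes sparse values),
#' \code{cells.csv} (cell metadata) and \code{genes.csv} (gene ids).
#'
#' @param dir directory containing (or receiving) the three files.
#' @export
read_cell_table_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "cells.csv", "genes.csv"))
  if (!all(file.exists(paths)))
    abort(sprintf("expected matrix.mtx, cells.csv, genes.csv in %s", dir),
          "file_not_found")
  m <- methods::as(Matrix::readMM(paths[1]), "CsparseMatrix")
  meta <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  genes <- utils::read.csv(paths[3], stringsAsFactors = FALSE)
  dimnames(m) <- list(meta$cell_id, genes$gene_id)
  cell_table(m, meta)
}

#' @rdname read_cell_table_mtx
#' @param cells a \code{cell_table}.
#' @export
write_cell_table_mtx <- function(cells, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cells$values, file.path(dir, "matrix.mtx"))
  utils::write.csv(cells$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(gene_id = cells$gene_ids),
                   file.path(dir, "genes.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
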
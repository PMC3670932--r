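#' Per-element Alu stabilities and iScores
#'
#' Each Alu element forms up to `2 * apsn_max` pairs with its flanking Alu
#' neighbours. The element's stability is the grand product of the square
#' roots of the predicted I:D ratios of those pairs; the stability of one
#' end (shared by both ends) is the grand product of the fourth roots; the
#' iScore is the reciprocal of the element stability. Direct pairs
#' contribute a factor of 1.
#'
#' @param elements sorted `retro_elements` (all families; non-Alu rows
#'   shape CLIQUEs only).
#' @param surface a calibrated `id_surface`.
#' @param apsn_max neighbour range (defaults to the surface's significant
#'   APSN range).
#' @param gap_bp CLIQUE gap (default 50).
#' @param pairs optional pre-enumerated `alu_pairs` for `elements`.
#' @return data.frame of class `alu_stability`: one row per Alu element
#'   with end_stability, element_stability, risk_end and iscore.
#' @export
alu_element_stability <- function(elements, surface,
                                  apsn_max = surface$apsn_max, gap_bp = 50,
                                  pairs = NULL) {
  alu_rows <- which(elements$family == "Alu")
  n <- nrow(elements)
  if (is.null(pairs)) {
    pairs <- enumerate_alu_pairs(elements, apsn_max = max(1L, apsn_max),
                                 cliques = detect_cliques(elements, gap_bp))
  }
  log_sum <- numeric(n)
  if (nrow(pairs) > 0L && apsn_max >= 1L) {
    pairs <- pairs[pairs$apsn <= apsn_max, ]
    if (nrow(pairs) > 0L) {
      lg <- log(predict(surface, pairs))
      acc <- rowsum(c(lg, lg), c(pairs$left, pairs$right))
      log_sum[as.integer(rownames(acc))] <- acc[, 1L]
    }
  }
  s_end <- exp(0.25 * log_sum[alu_rows])
  s_el <- exp(0.5 * log_sum[alu_rows])
  out <- data.frame(element = alu_rows,
                    chrom = elements$chrom[alu_rows],
                    start = elements$start[alu_rows],
                    end = elements$end[alu_rows],
                    midpoint = (elements$start[alu_rows] +
                                elements$end[alu_rows]) / 2,
                    strand = elements$strand[alu_rows],
                    end_stability = s_end,
                    element_stability = s_el,
                    risk_end = 1 - s_end,
                    iscore = 1 / s_el)
  class(out) <- c("alu_stability", "data.frame")
  out
}

# distance from a point coordinate to a half-open interval (0 inside)
.dist_to_interval <- function(x, lo, hi) {
  pmax(0, pmax(lo - x, x - hi))
}

# internal: risk-source Alu ends for a gene, with closest-exon distances
.gene_risk_ends <- function(gene, elements, surface, apsn_max, gap_bp) {
  span_lo <- min(gene$exons$start)
  span_hi <- max(gene$exons$end)
  win_lo <- span_lo - gene$flank_bp - gene$context_bp
  win_hi <- span_hi + gene$flank_bp + gene$context_bp
  on_chrom <- elements$chrom == gene$chrom
  if (!any(on_chrom)) {
    stop("no elements on chromosome ", gene$chrom, " for gene ",
         gene$gene_id)
  }
  sub <- elements[on_chrom & elements$end >= win_lo &
                  elements$start <= win_hi, , drop = FALSE]
  sub <- new_retro_elements(sub)
  stab <- alu_element_stability(sub, surface, apsn_max = apsn_max,
                                gap_bp = gap_bp)
  risk <- stab[stab$start <= span_hi + gene$flank_bp &
               stab$end >= span_lo - gene$flank_bp, , drop = FALSE]
  if (nrow(risk) == 0L) {
    return(list(stab = stab, risk = risk,
                ends = data.frame(element = integer(), end = character(),
                                  coord = numeric(), risk_end = numeric())))
  }
  ends <- data.frame(
    element = rep(seq_len(nrow(risk)), 2L),
    end = rep(c("5p", "3p"), each = nrow(risk)),
    coord = c(risk$start, risk$end),
    risk_end = rep(risk$risk_end, 2L))
  list(stab = stab, risk = risk, ends = ends)
}

#' Score the relative deletion stability of one gene
#'
#' Risk sources are the two ends of every Alu element within the gene's
#' coding span or within `flank_bp` of its ends (boundary inclusive); their
#' end stabilities are computed with full +/- APSN partner context drawn
#' from a window extended a further `context_bp`. For each exon, the
#' relative exon stability is the survival product over all risk ends of
#' `1 - Risk_End * P_Deletion(D_Min)`, with D_Min the distance from the end
#' coordinate to the exon's proximal boundary (0 inside the exon). The gene
#' stability uses, for each end, its closest coding exon (the highest-risk
#' target), so gene stability never exceeds any exon stability. Stabilities
#' are reported on a 0-100 scale; an Alu-free landscape scores 100.
#'
#' @param gene a `gene_model`.
#' @param elements sorted `retro_elements` covering the gene's chromosome.
#' @param surface a calibrated `id_surface`.
#' @param deletion_model a `deletion_size_model`.
#' @param apsn_max,gap_bp see [alu_element_stability()].
#' @return an object of class `gene_stability`.
#' @export
score_gene <- function(gene, elements, surface, deletion_model,
                       apsn_max = surface$apsn_max, gap_bp = 50) {
  ctx <- .gene_risk_ends(gene, elements, surface, apsn_max, gap_bp)
  ends <- ctx$ends
  ex <- gene$exons
  exon_rs <- numeric(nrow(ex))
  if (nrow(ends) == 0L) {
    exon_rs[] <- 1
    d_closest <- numeric(0)
    gene_rs <- 1
  } else {
    log_ex <- vapply(seq_len(nrow(ex)), function(e) {
      d <- .dist_to_interval(ends$coord, ex$start[e], ex$end[e])
      sum(log1p(-ends$risk_end * p_deletion(deletion_model, d)))
    }, 1.0)
    exon_rs <- exp(log_ex)
    d_all <- vapply(seq_len(nrow(ex)), function(e) {
      .dist_to_interval(ends$coord, ex$start[e], ex$end[e])
    }, numeric(nrow(ends)))
    d_closest <- if (nrow(ends) == 1L) min(d_all) else
      apply(matrix(d_all, nrow = nrow(ends)), 1L, min)
    gene_rs <- exp(sum(log1p(-ends$risk_end *
                             p_deletion(deletion_model, d_closest))))
  }
  span_lo <- min(ex$start); span_hi <- max(ex$end)
  land_mb <- (span_hi - span_lo + 2 * gene$flank_bp) / 1e6
  structure(list(
    gene_id = gene$gene_id, chrom = gene$chrom, group = gene$group,
    gene_rs = gene_rs, gene_instability = 1 - gene_rs,
    stability = 100 * gene_rs,
    exons = cbind(ex, exon_rs = exon_rs, exon_stability = 100 * exon_rs,
                  exon_instability = 1 - exon_rs),
    ends = if (nrow(ends)) cbind(ends, d_min_closest = d_closest) else ends,
    alu = ctx$risk,
    n_alu = nrow(ctx$risk),
    alu_density_per_mb = nrow(ctx$risk) / land_mb,
    flank_bp = gene$flank_bp, context_bp = gene$context_bp),
    class = "gene_stability")
}

#' @export
print.gene_stability <- function(x, ...) {
  cat(sprintf("Gene %s (%s): stability %.2f / 100\n",
              x$gene_id, x$chrom, x$stability))
  cat(sprintf("  %d coding exons (least stable: %.2f), %d landscape Alus (%.0f / Mb)\n",
              nrow(x$exons), min(x$exons$exon_stability), x$n_alu,
              x$alu_density_per_mb))
  invisible(x)
}

#' Score a cohort of genes
#'
#' @param genes list of `gene_model` objects.
#' @param elements sorted `retro_elements`.
#' @param surface a calibrated `id_surface`.
#' @param deletion_model a `deletion_size_model`.
#' @param ... passed to [score_gene()].
#' @return an object of class `stability_report`: a data.frame with one
#'   row per gene (stability on the 0-100 scale) carrying the per-gene
#'   `gene_stability` objects in `attr(, "details")`. Genes that fail to
#'   score (e.g. chromosome absent from the annotation) are recorded in
#'   `attr(, "errors")` and the run continues.
#' @export
score_genes <- function(genes, elements, surface, deletion_model, ...) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  details <- list()
  errors <- list()
  rows <- list()
  for (g in genes) {
    res <- tryCatch(score_gene(g, elements, surface, deletion_model, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[[g$gene_id]] <- conditionMessage(res)
      next
    }
    details[[g$gene_id]] <- res
    rows[[g$gene_id]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom, group = g$group,
      n_exons = nrow(res$exons), n_alu = res$n_alu,
      alu_density_per_mb = res$alu_density_per_mb,
      stability = res$stability, instability = 100 - res$stability)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), chrom = character(),
               group = character(), n_exons = integer(), n_alu = integer(),
               alu_density_per_mb = numeric(), stability = numeric(),
               instability = numeric())
  rownames(out) <- NULL
  attr(out, "details") <- details
  attr(out, "errors") <- errors
  class(out) <- c("stability_report", "data.frame")
  out
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Relative gene stability report (", nrow(x), " genes)\n", sep = "")
  print.data.frame(x, digits = 4)
  err <- attr(x, "errors")
  if (length(err)) {
    cat("failed genes:", paste(names(err), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.stability_report <- function(object, ...) {
  cat("Gene stability summary\n")
  cat(sprintf("  %d genes, mean stability %.2f (range %.2f-%.2f)\n",
              nrow(object), mean(object$stability), min(object$stability),
              max(object$stability)))
  grp <- object$group
  if (any(!is.na(grp)) && length(unique(grp[!is.na(grp)])) >= 2L) {
    means <- tapply(object$stability, grp, mean)
    instab <- tapply(object$instability, grp, mean)
    for (g in names(means)) {
      cat(sprintf("  group %-10s mean stability %.2f  mean instability %.2f\n",
                  g, means[g], instab[g]))
    }
    o <- order(instab, decreasing = TRUE)
    ratio <- instab[o[1L]] / instab[o[2L]]
    cat(sprintf("  excess instability of group '%s' over '%s': %.0f%%\n",
                names(instab)[o[1L]], names(instab)[o[2L]],
                100 * (ratio - 1)))
  }
  invisible(object)
}

#' Sensitivity of gene stabilities to the small-deletion fraction
#'
#' Rebuilds the deletion-size model for each value of the <=50 bp deletion
#' fraction (holding the tail slope fixed, see [vary_small_fraction()]) and
#' rescores every gene. Alu end stabilities do not depend on the deletion
#' model, so they are computed once per gene and only the survival products
#' are recomputed per fraction.
#'
#' @param genes list of `gene_model` objects.
#' @param elements,surface as in [score_genes()].
#' @param fracs grid of <=50 bp fractions (default 0.90..0.99 step 0.01).
#' @param deletion_model reference model (default the standard build).
#' @param ... passed to [score_gene()].
#' @return object of class `sensitivity_scan`: data.frame of gene
#'   stabilities (0-100) with one column per fraction, plus a rank-change
#'   summary in `attr(, "rank_change")` (TRUE where a gene's cohort rank
#'   varies across the sweep).
#' @export
sensitivity_scan <- function(genes, elements, surface,
                             fracs = seq(0.90, 0.99, by = 0.01),
                             deletion_model = deletion_size_model(), ...) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  base <- score_genes(genes, elements, surface, deletion_model, ...)
  details <- attr(base, "details")
  models <- lapply(fracs, function(f) vary_small_fraction(deletion_model, f))
  mat <- matrix(NA_real_, nrow = length(details), ncol = length(fracs),
                dimnames = list(names(details),
                                sprintf("frac_%.2f", fracs)))
  for (i in seq_along(details)) {
    ends <- details[[i]]$ends
    for (j in seq_along(models)) {
      mat[i, j] <- if (nrow(ends) == 0L) 100 else
        100 * exp(sum(log1p(-ends$risk_end *
                            p_deletion(models[[j]], ends$d_min_closest))))
    }
  }
  ranks <- apply(-mat, 2L, rank, ties.method = "first")
  if (is.null(dim(ranks))) {
    ranks <- matrix(ranks, nrow = nrow(mat), dimnames = dimnames(mat))
  }
  rank_change <- apply(ranks, 1L, function(r) max(r) - min(r)) > 0
  out <- data.frame(gene_id = rownames(mat), mat, row.names = NULL,
                    check.names = FALSE)
  attr(out, "fracs") <- fracs
  attr(out, "rank_change") <- rank_change
  attr(out, "ranks") <- ranks
  class(out) <- c("sensitivity_scan", "data.frame")
  out
}

#' @export
print.sensitivity_scan <- function(x, ...) {
  cat("Sensitivity scan over frac(<=50 bp) =",
      paste(range(attr(x, "fracs")), collapse = ".."), "\n")
  print.data.frame(x, digits = 4)
  rc <- attr(x, "rank_change")
  if (any(rc)) {
    cat("genes changing cohort rank:",
        paste(names(rc)[rc], collapse = ", "), "\n")
  } else cat("cohort ranking constant across the sweep\n")
  invisible(x)
}

#' iScore track across a gene's landscape
#'
#' Instability scores of every Alu element within a display window around
#' the gene, for landscape plots and BEDGRAPH export.
#'
#' @param gene a `gene_model`.
#' @param elements sorted `retro_elements`.
#' @param surface a calibrated `id_surface`.
#' @param window_bp display half-width around the coding span
#'   (default 500000).
#' @param apsn_max,gap_bp see [alu_element_stability()].
#' @return data.frame (chrom, midpoint, iscore), one row per Alu.
#' @export
landscape_track <- function(gene, elements, surface, window_bp = 500000,
                            apsn_max = surface$apsn_max, gap_bp = 50) {
  span_lo <- min(gene$exons$start)
  span_hi <- max(gene$exons$end)
  win_lo <- span_lo - window_bp - gene$context_bp
  win_hi <- span_hi + window_bp + gene$context_bp
  sub <- elements[elements$chrom == gene$chrom & elements$end >= win_lo &
                  elements$start <= win_hi, , drop = FALSE]
  sub <- new_retro_elements(sub)
  stab <- alu_element_stability(sub, surface, apsn_max = apsn_max,
                                gap_bp = gap_bp)
  stab <- stab[stab$midpoint >= span_lo - window_bp &
               stab$midpoint <= span_hi + window_bp, , drop = FALSE]
  data.frame(chrom = stab$chrom, midpoint = stab$midpoint,
             iscore = stab$iscore)
}

#' Write report tables
#'
#' `write_stability_report` writes the per-gene table and a combined
#' per-exon table as TSVs; `write_iscore_track` writes a BEDGRAPH-like
#' track (chrom, start, end, iscore); `write_sensitivity_matrix` writes
#' the per-gene x per-fraction stability matrix.
#'
#' @param report a `stability_report`.
#' @param dir output directory (created if missing).
#' @export
write_stability_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(as.data.frame(report), file.path(dir, "gene_stability.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  details <- attr(report, "details")
  exons <- do.call(rbind, lapply(names(details), function(g) {
    cbind(gene_id = g, details[[g]]$exons)
  }))
  if (!is.null(exons)) {
    write.table(exons, file.path(dir, "exon_stability.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_stability_report
#' @param track output of [landscape_track()].
#' @param file output path.
#' @export
write_iscore_track <- function(track, file) {
  out <- data.frame(chrom = track$chrom, start = floor(track$midpoint),
                    end = floor(track$midpoint) + 1L,
                    iscore = track$iscore)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' @rdname write_stability_report
#' @param scan a `sensitivity_scan`.
#' @export
write_sensitivity_matrix <- function(scan, file) {
  write.table(as.data.frame(scan), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
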
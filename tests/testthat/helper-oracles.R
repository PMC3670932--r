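# Shared fixtures and independent brute-force oracles.

# quick element-table constructor for hand-built landscapes
make_elements <- function(starts, strands, lengths = 300, chrom = "chr1",
                          family = "Alu") {
  retro_elements(chrom, starts, starts + lengths, strands, family)
}

# brute-force pair oracle: APSN from midpoint counting (never index
# arithmetic), double loop over every Alu pair
oracle_pairs <- function(elements, apsn_max) {
  alu <- which(elements$family == "Alu")
  mids <- (elements$start[alu] + elements$end[alu]) / 2
  out <- list()
  for (i in seq_along(alu)) {
    for (j in seq_along(alu)) {
      if (j <= i) next
      if (elements$chrom[alu[i]] != elements$chrom[alu[j]]) next
      lo <- elements$end[alu[i]]; hi <- elements$start[alu[j]]
      inside <- sum(mids > lo & mids < hi &
                    seq_along(alu) != i & seq_along(alu) != j &
                    elements$chrom[alu] == elements$chrom[alu[i]])
      apsn <- inside + 1L
      if (apsn > apsn_max) next
      out[[length(out) + 1L]] <- data.frame(
        left = alu[i], right = alu[j], apsn = apsn,
        spacer_bp = max(0, hi - lo),
        inverted = elements$strand[alu[i]] != elements$strand[alu[j]])
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(left = integer(), right = integer(), apsn = integer(),
               spacer_bp = numeric(), inverted = logical())
}

# brute-force stability oracle: explicit loops over every pair and every
# end-exon combination; prediction shared with the engine, aggregation not
oracle_element_stability <- function(elements, surface, apsn_max) {
  cl <- detect_cliques(elements)
  pairs <- enumerate_alu_pairs(elements, apsn_max = apsn_max, cliques = cl)
  pid_all <- predict(surface, pairs)
  alu <- which(elements$family == "Alu")
  res <- data.frame(element = alu, end_stability = NA_real_,
                    element_stability = NA_real_)
  for (k in seq_along(alu)) {
    s_end <- 1; s_el <- 1
    for (p in seq_len(nrow(pairs))) {
      if (pairs$left[p] == alu[k] || pairs$right[p] == alu[k]) {
        s_end <- s_end * pid_all[p]^(1 / 4)
        s_el <- s_el * pid_all[p]^(1 / 2)
      }
    }
    res$end_stability[k] <- s_end
    res$element_stability[k] <- s_el
  }
  res$risk_end <- 1 - res$end_stability
  res
}

oracle_score_gene <- function(gene, elements, surface, dmodel, apsn_max) {
  span_lo <- min(gene$exons$start); span_hi <- max(gene$exons$end)
  win_lo <- span_lo - gene$flank_bp - gene$context_bp
  win_hi <- span_hi + gene$flank_bp + gene$context_bp
  keep <- elements$chrom == gene$chrom & elements$end >= win_lo &
    elements$start <= win_hi
  sub <- retro_elements(elements$chrom[keep], elements$start[keep],
                        elements$end[keep], elements$strand[keep],
                        elements$family[keep], elements$subfamily[keep])
  stab <- oracle_element_stability(sub, surface, apsn_max)
  risk <- stab[sub$start[stab$element] <= span_hi + gene$flank_bp &
               sub$end[stab$element] >= span_lo - gene$flank_bp, ,
               drop = FALSE]
  exon_rs <- rep(1, nrow(gene$exons))
  gene_rs <- 1
  if (nrow(risk) > 0L) {
    for (e in seq_len(nrow(gene$exons))) {
      prod_e <- 1
      for (k in seq_len(nrow(risk))) {
        for (coord in c(sub$start[risk$element[k]],
                        sub$end[risk$element[k]])) {
          d <- if (coord < gene$exons$start[e]) {
            gene$exons$start[e] - coord
          } else if (coord > gene$exons$end[e]) {
            coord - gene$exons$end[e]
          } else 0
          prod_e <- prod_e * (1 - risk$risk_end[k] * p_deletion(dmodel, d))
        }
      }
      exon_rs[e] <- prod_e
    }
    for (k in seq_len(nrow(risk))) {
      for (coord in c(sub$start[risk$element[k]],
                      sub$end[risk$element[k]])) {
        d_best <- Inf
        for (e in seq_len(nrow(gene$exons))) {
          d <- if (coord < gene$exons$start[e]) {
            gene$exons$start[e] - coord
          } else if (coord > gene$exons$end[e]) {
            coord - gene$exons$end[e]
          } else 0
          d_best <- min(d_best, d)
        }
        gene_rs <- gene_rs * (1 - risk$risk_end[k] *
                              p_deletion(dmodel, d_best))
      }
    }
  }
  list(exon_rs = exon_rs, gene_rs = gene_rs,
       end_stability = risk$end_stability)
}

# hand-built surface with full control over anchors, for prediction and
# engine tests (10 anchors per (type, apsn) like a calibrated surface)
fake_surface <- function(values = 0.8, types = 1:3, apsns = 1:10,
                         medians = seq(100, 10000, length.out = 10),
                         p99 = 50000, cutoff = 0.995, epsilon = 1e-6,
                         type0_anchor = 0.8) {
  grid <- expand.grid(percentile = c(2.5, seq(10, 90, 10)),
                      apsn = apsns, pair_type = types)
  grid$median_spacer <- rep(medians, length.out = nrow(grid))
  grid$id_fitted <- rep_len(values, nrow(grid))
  grid$id_ratio <- grid$id_fitted
  grid$n_inverted <- 500L
  grid$n_direct <- 500L
  anchors <- data.table::as.data.table(
    grid[, c("pair_type", "apsn", "percentile", "median_spacer",
             "id_fitted", "id_ratio", "n_inverted", "n_direct")])
  p99_dt <- data.table::as.data.table(
    expand.grid(pair_type = types, apsn = apsns))
  p99_dt$p99_spacer <- p99
  structure(list(anchors = anchors, p99 = p99_dt, fits = list(),
                 pooled = NULL, apsn_max = max(apsns),
                 significance_cutoff = cutoff, min_n = 507000,
                 epsilon = epsilon,
                 type0 = list(strategy = "yeast_rescaled",
                              rel = c("12" = 0.60, "20" = 0.75,
                                      "30" = 0.85),
                              anchor = type0_anchor, anchor_spacer = 100,
                              anchor_source_type = 1L, homology = 0.85),
                 meta = list(schema_version = "1.0")),
            class = "id_surface")
}

# two-sided normal CI membership for an I:D ratio given stratum size
id_in_ci <- function(target, n, value, conf = 0.95) {
  p <- target / (1 + target)
  half <- qnorm(1 - (1 - conf) / 2) * sqrt(p * (1 - p) / n)
  lo <- (p - half) / (1 - p + half)
  hi <- (p + half) / (1 - p - half)
  value >= lo & value <= hi
}

# random small landscape + gene for oracle-equivalence checks; gaps mix
# clique-range (<50 bp) and larger separations
random_landscape <- function(n_alu, p_plus = 0.5, n_l1 = 0) {
  n <- n_alu + n_l1
  fam <- sample(c(rep("Alu", n_alu), rep("LINE1", n_l1)))
  lens <- sample(c(80, 200, 300, 310), n, replace = TRUE)
  lens[fam == "LINE1"] <- 1200
  gaps <- sample(c(0:45, 60:4000), n, replace = TRUE)
  starts <- cumsum(gaps) + cumsum(c(0, lens[-n]))
  retro_elements("chr1", starts, starts + lens,
                 sample(c("+", "-"), n, TRUE, c(p_plus, 1 - p_plus)), fam)
}

random_gene <- function(n_exons, lo, hi, flank = 5e4, context = 2e4) {
  bounds <- sort(sample(seq(lo, hi), 2 * n_exons))
  starts <- bounds[seq(1, length(bounds), 2)]
  ends <- pmax(bounds[seq(2, length(bounds), 2)], starts + 1)
  gene_model(paste0("g", sample.int(1e6, 1)), "chr1", starts, ends,
             flank_bp = flank, context_bp = context)
}
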
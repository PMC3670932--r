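#' Specify a synthetic retroelement landscape
#'
#' The generator emulates the statistical structure of genomic Alu
#' landscapes that the model consumes: overall placement density (the
#' genome-wide average is 381 Alu/Mb), random strand orientation, a
#' three-class element length mixture matching the small/medium/full-length
#' size bins, and CLIQUE clustering (bursts of elements with gaps <= 50 bp
#' separated from neighbours by > 50 bp). It does not emulate sequence
#' content, subfamily evolution or real spacer-size marginals.
#'
#' @param genome_length chromosome length in bp.
#' @param alu_density Alu elements per Mb (default 381).
#' @param orientation_p_plus probability of "+" strand (default 0.5).
#' @param clique_fraction fraction of elements placed inside CLIQUEs
#'   (default 0.45, matching the high clustered-pair share of genomic
#'   landscapes).
#' @param clique_size_p geometric parameter for clique sizes (size =
#'   2 + rgeom, default 0.5).
#' @param gap_bp maximum intra-clique gap (default 50); inter-unit gaps
#'   are always > `gap_bp` so cliques are exactly the constructed bursts.
#' @param size_weights mixture weights for small/medium/full_length
#'   element lengths.
#' @param line1_fraction fraction of additional LINE1 elements interleaved
#'   into cliques and landscape (default 0).
#' @param chrom chromosome name.
#' @param seed integer seed; identical seeds give identical landscapes.
#' @return object of class `landscape_spec`.
#' @export
landscape_spec <- function(genome_length, alu_density = 381,
                           orientation_p_plus = 0.5, clique_fraction = 0.45,
                           clique_size_p = 0.5, gap_bp = 50,
                           size_weights = c(small = 0.20, medium = 0.25,
                                            full_length = 0.55),
                           line1_fraction = 0, chrom = "chrS", seed = 1L) {
  stopifnot(genome_length > 0, alu_density > 0,
            orientation_p_plus >= 0, orientation_p_plus <= 1,
            clique_fraction >= 0, clique_fraction <= 1,
            line1_fraction >= 0, line1_fraction < 1,
            all(size_weights >= 0), sum(size_weights) > 0)
  structure(list(genome_length = genome_length, alu_density = alu_density,
                 orientation_p_plus = orientation_p_plus,
                 clique_fraction = clique_fraction,
                 clique_size_p = clique_size_p, gap_bp = gap_bp,
                 size_weights = size_weights / sum(size_weights),
                 line1_fraction = line1_fraction, chrom = chrom,
                 seed = as.integer(seed)),
            class = "landscape_spec")
}

.sample_lengths <- function(n, weights) {
  cls <- sample(names(weights), n, replace = TRUE, prob = weights)
  lo <- c(small = 30, medium = 136, full_length = 275)[cls]
  hi <- c(small = 135, medium = 274, full_length = 325)[cls]
  floor(runif(n, lo, hi + 1))
}

#' Generate a synthetic retroelement landscape
#'
#' Element counts are Poisson in the expected density; elements are grouped
#' into clique bursts and singletons, laid left to right with intra-clique
#' gaps uniform on 0..`gap_bp` and inter-unit gaps of at least
#' `gap_bp` + 1 plus a uniformly partitioned share of the remaining free
#' sequence. Errors if the requested density cannot be placed without
#' overlap.
#'
#' @param spec a `landscape_spec`.
#' @return a sorted `retro_elements` table.
#' @export
simulate_landscape <- function(spec) {
  set.seed(spec$seed)
  L <- spec$genome_length
  n_alu <- rpois(1L, spec$alu_density * L / 1e6)
  if (n_alu < 1L) return(empty_retro_elements())
  n_l1 <- if (spec$line1_fraction > 0)
    rpois(1L, n_alu * spec$line1_fraction / (1 - spec$line1_fraction))
    else 0L
  n <- n_alu + n_l1
  family <- sample(c(rep("Alu", n_alu), rep("LINE1", n_l1)))
  length_bp <- numeric(n)
  length_bp[family == "Alu"] <- .sample_lengths(n_alu, spec$size_weights)
  length_bp[family == "LINE1"] <- floor(runif(n_l1, 900, 6001))
  strand <- ifelse(runif(n) < spec$orientation_p_plus, "+", "-")
  subfam <- ifelse(family == "Alu", "AluY", "L1PA2")

  # group elements into clique bursts and singletons
  n_clustered <- round(spec$clique_fraction * n)
  unit_of <- integer(n)
  u <- 0L
  i <- 1L
  while (i <= n_clustered - 1L) {
    sz <- 2L + rgeom(1L, spec$clique_size_p)
    sz <- min(sz, n_clustered - i + 1L)
    if (sz < 2L) break
    u <- u + 1L
    unit_of[i:(i + sz - 1L)] <- u
    i <- i + sz
  }
  for (k in which(unit_of == 0L)) { u <- u + 1L; unit_of[k] <- u }
  n_units <- u
  # shuffle unit order so cliques and singletons interleave, then permute
  # per-element vectors into final chromosome order
  unit_order <- sample(n_units)
  perm <- order(match(unit_of, unit_order), seq_len(n))
  length_bp <- length_bp[perm]; strand <- strand[perm]
  family <- family[perm]; subfam <- subfam[perm]
  first <- !duplicated(unit_of[perm])
  # integer intra-clique gaps stay exact under the final floor()
  intra_gap <- ifelse(first, 0, floor(runif(n, 0, spec$gap_bp + 1)))
  occupied <- sum(length_bp) + sum(intra_gap)
  # +2 keeps inter-unit gaps > gap_bp even after flooring positions
  min_inter <- spec$gap_bp + 2
  free <- L - occupied - (n_units + 1L) * min_inter
  if (free < 0) {
    stop("element density too high to place without overlap at ",
         "genome_length = ", L)
  }
  # distribute the remaining free sequence over inter-unit gaps
  g <- runif(n_units + 1L)
  inter_gap <- min_inter + free * g / sum(g)
  gap_before <- intra_gap
  gap_before[first] <- inter_gap[seq_len(n_units)]
  raw_start <- cumsum(gap_before) + cumsum(c(0, length_bp))[seq_len(n)]
  start <- floor(raw_start)
  retro_elements(spec$chrom, start, start + length_bp, strand, family,
                 subfam)
}

#' Define an inverted-pair thinning rule
#'
#' The rule encodes the causal premise behind the genomic I:D imbalance:
#' inverted Alu pairs are lost by deletion. Each inverted pair matching the
#' rule loses one randomly chosen member with probability `q`.
#'
#' @param q removal probability in \[0, 1): a scalar or a function
#'   `q(pair_type, apsn, spacer_bp)` returning per-pair probabilities.
#' @param apsn APSN values the rule applies to (default 1).
#' @param pair_types pair types the rule applies to (default 0:3).
#' @param max_spacer largest spacer the rule applies to (default Inf).
#' @return object of class `thinning_rule`.
#' @export
thinning_rule <- function(q, apsn = 1L, pair_types = 0:3,
                          max_spacer = Inf) {
  if (!is.function(q)) {
    stopifnot(q >= 0, q < 1)
  }
  structure(list(q = q, apsn = as.integer(apsn),
                 pair_types = as.integer(pair_types),
                 max_spacer = max_spacer),
            class = "thinning_rule")
}

.rule_q <- function(rule, pairs) {
  qv <- if (is.function(rule$q)) {
    rule$q(pairs$pair_type, pairs$apsn, pairs$spacer_bp)
  } else rep(rule$q, nrow(pairs))
  qv[!(pairs$apsn %in% rule$apsn) |
     !(pairs$pair_type %in% rule$pair_types) |
     pairs$spacer_bp > rule$max_spacer] <- 0
  qv
}

#' Thin inverted Alu pairs from a landscape
#'
#' Applies the rule in sweeps until a fixed point: in each sweep all not
#' yet drawn inverted pairs currently matching the rule are drawn
#' simultaneously (each pair, keyed by its two member elements, is drawn at
#' most once over the whole process) and one random member of each
#' triggered pair is deleted. Deletions can only decrease a pair's APSN,
#' so pairs outside the rule's APSN range at the fixed point were never
#' eligible, while every surviving in-range inverted pair has survived
#' exactly one Bernoulli(1-q) draw -- the property the calibration
#' parameter-recovery experiments measure against.
#'
#' @param elements a sorted `retro_elements` table.
#' @param rule a `thinning_rule`.
#' @param seed integer seed.
#' @param max_sweeps safety bound on fixed-point iteration.
#' @return the thinned `retro_elements`, with the removal log (one row per
#'   drawn pair: sweep, member coordinates, apsn, spacer, type, q, whether
#'   a removal happened) in `attr(, "removal_log")`.
#' @export
apply_thinning <- function(elements, rule, seed = 1L, max_sweeps = 100L) {
  set.seed(seed)
  cur <- elements
  drawn <- character(0)
  logs <- list()
  apsn_max <- max(rule$apsn)
  for (sweep in seq_len(max_sweeps)) {
    if (nrow(cur) < 2L) break
    pairs <- enumerate_alu_pairs(cur, apsn_max = apsn_max)
    if (nrow(pairs) == 0L) break
    pairs <- pairs[pairs$inverted, ]
    if (nrow(pairs) == 0L) break
    qv <- .rule_q(rule, pairs)
    key <- paste(pairs$chrom, cur$start[pairs$left], cur$start[pairs$right])
    eligible <- qv > 0 & !(key %in% drawn)
    if (!any(eligible)) break
    pairs <- pairs[eligible, ]
    qv <- qv[eligible]
    key <- key[eligible]
    hit <- runif(nrow(pairs)) < qv
    side_left <- runif(nrow(pairs)) < 0.5
    removed_rows <- unique(c(pairs$left[hit & side_left],
                             pairs$right[hit & !side_left]))
    logs[[sweep]] <- data.frame(
      sweep = sweep, chrom = pairs$chrom,
      left_start = cur$start[pairs$left],
      right_start = cur$start[pairs$right],
      apsn = pairs$apsn, spacer_bp = pairs$spacer_bp,
      pair_type = pairs$pair_type, q = qv, removed = hit)
    drawn <- c(drawn, key)
    if (length(removed_rows)) {
      cur <- new_retro_elements(cur[-removed_rows, , drop = FALSE])
    } else if (sweep > 1L) {
      break                      # nothing removed and nothing new to draw
    }
  }
  attr(cur, "removal_log") <- if (length(logs)) do.call(rbind, logs) else
    data.frame(sweep = integer(), chrom = character(),
               left_start = numeric(), right_start = numeric(),
               apsn = integer(), spacer_bp = numeric(),
               pair_type = integer(), q = numeric(), removed = logical())
  cur
}

#' Write standard-format fixtures for a synthetic landscape
#'
#' Writes the element table in the UCSC rmsk dialect (read back identically
#' by [read_rmsk()]) and, when gene models are supplied, a coding-exon TSV
#' (read back by [read_gene_models()]).
#'
#' @param elements a `retro_elements` table.
#' @param genes optional list of `gene_model` objects.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_fixtures <- function(elements, genes = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep_class <- c(Alu = "SINE", LINE1 = "LINE", SVA = "Retroposon")
  rep_family <- c(Alu = "Alu", LINE1 = "L1", SVA = "SVA")
  rep_name <- ifelse(is.na(elements$subfamily),
                     c(Alu = "AluY", LINE1 = "L1PA2",
                       SVA = "SVA_D")[elements$family],
                     elements$subfamily)
  rmsk <- data.frame(genoName = elements$chrom,
                     genoStart = elements$start, genoEnd = elements$end,
                     strand = elements$strand, repName = rep_name,
                     repClass = rep_class[elements$family],
                     repFamily = rep_family[elements$family])
  rmsk_path <- file.path(dir, "rmsk.tsv")
  write.table(rmsk, rmsk_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- rmsk_path
  if (!is.null(genes)) {
    if (inherits(genes, "gene_model")) genes <- list(genes)
    ex <- do.call(rbind, lapply(genes, function(g) {
      data.frame(chrom = g$chrom, start = g$exons$start,
                 end = g$exons$end, gene_id = g$gene_id,
                 strand = g$strand, group = g$group)
    }))
    exon_path <- file.path(dir, "exons.tsv")
    write.table(ex, exon_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, exon_path)
  }
  invisible(paths)
}
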
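#' Detect CLIQUEs (clusters of retroelements)
#'
#' A CLIQUE is a maximal run of two or more Alu/LINE1/SVA elements in which
#' consecutive elements are separated by at most `gap_bp` (default 50 bp).
#' All three families participate in clustering; singletons form no clique.
#'
#' @param elements a `retro_elements` table sorted by (chrom, start).
#' @param gap_bp maximum inter-element gap within a clique.
#' @return an object of class `cliques`: a list with `membership` (integer
#'   clique id per element row, NA for unclustered elements) and `cliques`
#'   (one row per clique: clique_id, chrom, n_members, start, end).
#' @export
detect_cliques <- function(elements, gap_bp = 50) {
  n <- nrow(elements)
  membership <- rep(NA_integer_, n)
  if (n >= 2L) {
    o <- order(elements$chrom, elements$start, elements$end)
    if (!identical(o, seq_len(n))) {
      stop("elements must be sorted by (chrom, start)")
    }
    same_chrom <- elements$chrom[-1L] == elements$chrom[-n]
    gap <- elements$start[-1L] - elements$end[-n]
    linked <- same_chrom & gap <= gap_bp
    # run-length over the "linked to previous" indicator
    run_id <- cumsum(c(TRUE, !linked))
    sizes <- table(run_id)
    big <- as.integer(names(sizes))[sizes >= 2L]
    keep <- run_id %in% big
    membership[keep] <- match(run_id[keep], big)
  }
  cl <- NULL
  if (any(!is.na(membership))) {
    idx <- which(!is.na(membership))
    cl <- do.call(rbind, lapply(split(idx, membership[idx]), function(i) {
      data.frame(clique_id = membership[i[1L]], chrom = elements$chrom[i[1L]],
                 n_members = length(i), start = min(elements$start[i]),
                 end = max(elements$end[i]))
    }))
    rownames(cl) <- NULL
  } else {
    cl <- data.frame(clique_id = integer(), chrom = character(),
                     n_members = integer(), start = numeric(),
                     end = numeric())
  }
  structure(list(membership = membership, cliques = cl, gap_bp = gap_bp),
            class = "cliques")
}

#' @export
print.cliques <- function(x, ...) {
  cat("CLIQUEs:", nrow(x$cliques), "clusters covering",
      sum(!is.na(x$membership)), "elements (gap <=", x$gap_bp, "bp)\n")
  invisible(x)
}

#' Spacer size between two elements
#'
#' The spacer is the intervening sequence between two elements of a pair;
#' overlapping or adjacent annotations get spacer 0.
#'
#' @param a,b single-row element records (with chrom, start, end).
#' @return spacer size in bp.
#' @export
spacer_size <- function(a, b) {
  if (a$chrom != b$chrom) stop("spacer is undefined across chromosomes")
  if (a$start <= b$start) max(0, b$start - a$end) else max(0, a$start - b$end)
}

#' Classify an Alu pair by clustering state
#'
#' Type 0: both members in the same CLIQUE; Type 1: both clustered, in
#' different CLIQUEs; Type 2: exactly one member clustered; Type 3: neither.
#'
#' @param left_id,right_id clique membership of each member (NA when
#'   unclustered), e.g. `cliques$membership[i]`.
#' @return integer vector of pair types 0-3.
#' @export
classify_pair_type <- function(left_id, right_id) {
  lc <- !is.na(left_id); rc <- !is.na(right_id)
  type <- integer(length(lc))
  type[lc & rc] <- ifelse(left_id[lc & rc] == right_id[lc & rc], 0L, 1L)
  type[xor(lc, rc)] <- 2L
  type[!lc & !rc] <- 3L
  type
}

#' Enumerate Alu pairs with APSN, spacer, orientation and type
#'
#' For every pair of Alu elements on the same chromosome separated by at
#' most `apsn_max - 1` intervening Alus, one unordered pair record is
#' produced. The APSN (Alu pair sequence number) is the "n+1" count of Alu
#' elements strictly within the spacer, i.e. the rank distance of the two
#' members along the chromosome's Alu list. Signed APSNs arise from a focal
#' element's viewpoint (negative for 5' partners) and are symmetric, so the
#' pair table stores the unsigned value. Pairs of small-small or small-medium
#' members at APSN <= 10 are flagged (`tandem_flag`): these strata carry a
#' tandem-repeat annotation artifact and are excluded from calibration.
#'
#' @param elements a sorted `retro_elements` table (all families; LINE1/SVA
#'   rows participate in clustering only).
#' @param apsn_max largest APSN enumerated (default 110).
#' @param cliques optional `cliques` object (computed from `elements` if
#'   omitted).
#' @return a data.table of class `alu_pairs` with columns chrom, left,
#'   right (row indices into `elements`), apsn, spacer_bp, inverted,
#'   pair_type, left_size, right_size, tandem_flag.
#' @export
enumerate_alu_pairs <- function(elements, apsn_max = 110, cliques = NULL) {
  o <- order(elements$chrom, elements$start, elements$end)
  if (!identical(o, seq_len(nrow(elements)))) {
    stop("elements must be sorted by (chrom, start)")
  }
  if (is.null(cliques)) cliques <- detect_cliques(elements)
  alu_rows <- which(elements$family == "Alu")
  out <- vector("list", 0L)
  for (chr in unique(elements$chrom[alu_rows])) {
    rows <- alu_rows[elements$chrom[alu_rows] == chr]
    n <- length(rows)
    if (n < 2L) next
    start <- elements$start[rows]; end <- elements$end[rows]
    strand <- elements$strand[rows]
    memb <- cliques$membership[rows]
    size <- elements$size_class[rows]
    per_d <- vector("list", min(apsn_max, n - 1L))
    for (d in seq_len(min(apsn_max, n - 1L))) {
      i <- seq_len(n - d); j <- i + d
      per_d[[d]] <- data.table::data.table(
        chrom = chr, left = rows[i], right = rows[j], apsn = d,
        spacer_bp = pmax(0, start[j] - end[i]),
        inverted = strand[i] != strand[j],
        pair_type = classify_pair_type(memb[i], memb[j]),
        left_size = size[i], right_size = size[j])
    }
    out[[length(out) + 1L]] <- data.table::rbindlist(per_d)
  }
  pairs <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(chrom = character(), left = integer(),
                           right = integer(), apsn = integer(),
                           spacer_bp = numeric(), inverted = logical(),
                           pair_type = integer(), left_size = character(),
                           right_size = character())
  small <- c("small")
  sm <- c("small", "medium")
  pairs[, "tandem_flag" := apsn <= 10L &
          ((left_size %in% small & right_size %in% sm) |
           (right_size %in% small & left_size %in% sm))]
  data.table::setattr(pairs, "class", c("alu_pairs", class(pairs)))
  pairs[]
}

#' Write an Alu pair table as TSV
#'
#' @param pairs an `alu_pairs` table.
#' @param elements the element table the pair indices refer to.
#' @param file output path.
#' @export
write_pair_table <- function(pairs, elements, file) {
  out <- data.frame(chrom = pairs$chrom,
                    left_start = elements$start[pairs$left],
                    right_start = elements$start[pairs$right],
                    apsn = pairs$apsn, spacer_bp = pairs$spacer_bp,
                    orientation = ifelse(pairs$inverted, "inverted", "direct"),
                    pair_type = pairs$pair_type)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
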
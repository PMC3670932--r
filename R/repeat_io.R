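#' @import data.table
#' @importFrom stats approx binom.test lm.wfit median optim qnorm quantile
#'   runif rpois rbinom rgeom sd setNames splinefun uniroot
#' @importFrom utils head read.table tail write.table packageVersion
#' @importFrom graphics abline axis legend lines matplot par plot points
#' @importFrom grDevices dev.off
"_PACKAGE"

SIZE_CLASSES <- c("small", "medium", "full_length", "oversize")
FAMILIES <- c("Alu", "LINE1", "SVA")

#' Classify an Alu element by length
#'
#' Alu annotations fall into four size classes used throughout the model:
#' small (30-135 bp), medium (136-274 bp), full-length (275-325 bp) and
#' oversize (>325 bp). Fragments shorter than 30 bp are below model scope.
#'
#' @param length integer vector of element lengths in bp.
#' @return character vector of size classes.
#' @examples
#' classify_alu_size(c(135, 136, 300, 326))
#' @export
classify_alu_size <- function(length) {
  if (any(!is.finite(length)) || any(length < 1)) {
    stop("element lengths must be positive")
  }
  if (any(length < 30)) {
    stop("Alu fragments shorter than 30 bp are below model scope")
  }
  cut(length, breaks = c(29, 135, 274, 325, Inf),
      labels = SIZE_CLASSES, right = TRUE) |> as.character()
}

new_retro_elements <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("retro_elements", "data.frame")
  df
}

#' Construct a table of retroelement annotations
#'
#' Builds the canonical element table used by all downstream operations.
#' Coordinates are 0-based half-open. Alu elements shorter than 30 bp are
#' dropped (with a message); LINE1/SVA records are kept regardless of length
#' since they only participate in cluster (CLIQUE) detection.
#'
#' @param chrom,start,end,strand,family,subfamily element fields; `strand`
#'   must be "+" or "-" ("C" is accepted as an alias for "-"), `family` one
#'   of "Alu", "LINE1", "SVA".
#' @return a `retro_elements` data frame sorted by (chrom, start) with
#'   columns chrom, start, end, strand, family, subfamily, length,
#'   size_class (Alu only; NA otherwise).
#' @export
retro_elements <- function(chrom, start, end, strand, family,
                           subfamily = NA_character_) {
  n <- length(start)
  stopifnot(length(end) == n)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(strand, n)
  family <- rep_len(family, n)
  strand <- ifelse(strand == "C", "-", strand)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+', '-' or 'C'")
  if (!all(family %in% FAMILIES)) {
    stop("family must be one of: ", paste(FAMILIES, collapse = ", "))
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop("all elements must satisfy start < end")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   strand = strand, family = family,
                   subfamily = rep_len(as.character(subfamily), n),
                   stringsAsFactors = FALSE)
  df$length <- df$end - df$start
  short <- df$family == "Alu" & df$length < 30
  if (any(short)) {
    message("dropping ", sum(short), " Alu fragment(s) < 30 bp")
    df <- df[!short, , drop = FALSE]
  }
  df$size_class <- NA_character_
  is_alu <- df$family == "Alu"
  if (any(is_alu)) df$size_class[is_alu] <- classify_alu_size(df$length[is_alu])
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  new_retro_elements(df)
}

empty_retro_elements <- function() {
  new_retro_elements(data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    strand = character(), family = character(), subfamily = character(),
    length = numeric(), size_class = character(), stringsAsFactors = FALSE))
}

# map rmsk repName/repFamily text onto the three model families
.family_from_rep <- function(rep_class, rep_family, rep_name) {
  fam <- rep(NA_character_, length(rep_name))
  fam[rep_family == "Alu" | grepl("^Alu|^FLAM|^FRAM", rep_name)] <- "Alu"
  fam[rep_family == "L1" | grepl("^L1", rep_name)] <- "LINE1"
  fam[rep_class == "Retroposon" & grepl("^SVA", rep_name)] <- "SVA"
  fam[grepl("^SVA", rep_name)] <- "SVA"
  fam
}

#' Read repeat annotations (UCSC rmsk table or RepeatMasker .out)
#'
#' The dialect is auto-detected. A UCSC rmsk dump is a TSV with a header
#' naming genoName/genoStart/genoEnd (0-based half-open coordinates). A
#' RepeatMasker `.out` file has its characteristic two header lines and
#' whitespace-separated columns with 1-based inclusive coordinates, which are
#' converted to 0-based half-open on input. Only the requested model families
#' are retained.
#'
#' @param file path to the annotation file.
#' @param families subset of `c("Alu", "LINE1", "SVA")` to keep.
#' @return a `retro_elements` table sorted by (chrom, start).
#' @export
read_rmsk <- function(file, families = FAMILIES) {
  stopifnot(all(families %in% FAMILIES))
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_retro_elements())
  first <- lines[[1L]]
  if (grepl("genoName", first) && grepl("genoStart", first)) {
    df <- parse_rmsk_ucsc(lines, file)
  } else if (grepl("^\\s*SW\\s+", first) || grepl("score\\s+div", first) ||
             grepl("^\\s*\\d+\\s+\\d+\\.\\d", first)) {
    df <- parse_rmsk_out(lines, file)
  } else {
    stop("unknown repeat annotation dialect in ", file,
         ": expected a UCSC rmsk header or RepeatMasker .out layout")
  }
  if (nrow(df) == 0L) return(empty_retro_elements())
  fam <- .family_from_rep(df$rep_class, df$rep_family, df$rep_name)
  keep <- !is.na(fam) & fam %in% families
  if (!any(keep)) return(empty_retro_elements())
  retro_elements(df$chrom[keep], df$start[keep], df$end[keep],
                 df$strand[keep], fam[keep], df$rep_name[keep])
}

parse_rmsk_ucsc <- function(lines, file) {
  header <- strsplit(sub("^#", "", lines[[1L]]), "\t", fixed = TRUE)[[1L]]
  need <- c("genoName", "genoStart", "genoEnd", "strand", "repName",
            "repClass", "repFamily")
  idx <- match(need, header)
  if (anyNA(idx)) {
    stop("UCSC rmsk table in ", file, " is missing column(s): ",
         paste(need[is.na(idx)], collapse = ", "))
  }
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(vapply(rows, length, 1L) < max(idx))
  if (length(bad)) {
    stop("malformed rmsk row at line ", bad[1L] + 1L, " of ", file)
  }
  mat <- do.call(rbind, rows)
  start <- suppressWarnings(as.numeric(mat[, idx[2L]]))
  end <- suppressWarnings(as.numeric(mat[, idx[3L]]))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad)) {
    stop("malformed rmsk coordinates at line ", bad[1L] + 1L, " of ", file)
  }
  data.frame(chrom = mat[, idx[1L]], start = start, end = end,
             strand = mat[, idx[4L]], rep_name = mat[, idx[5L]],
             rep_class = mat[, idx[6L]], rep_family = mat[, idx[7L]],
             stringsAsFactors = FALSE)
}

parse_rmsk_out <- function(lines, file) {
  # skip the two header lines (and optional blank) of RepeatMasker output
  body_start <- grep("^\\s*\\d+\\s+\\d", lines)[1L]
  if (is.na(body_start)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      rep_name = character(), rep_class = character(),
                      rep_family = character(), stringsAsFactors = FALSE))
  }
  body <- lines[body_start:length(lines)]
  rows <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(rows, length, 1L) < 11L)
  if (length(bad)) {
    stop("malformed RepeatMasker .out row at line ",
         bad[1L] + body_start - 1L, " of ", file)
  }
  mat <- do.call(rbind, lapply(rows, `[`, 1:11))
  start1 <- suppressWarnings(as.numeric(mat[, 6L]))
  end1 <- suppressWarnings(as.numeric(mat[, 7L]))
  bad <- which(!is.finite(start1) | !is.finite(end1))
  if (length(bad)) {
    stop("malformed coordinates in RepeatMasker .out at line ",
         bad[1L] + body_start - 1L, " of ", file)
  }
  cf <- strsplit(mat[, 11L], "/", fixed = TRUE)
  data.frame(chrom = mat[, 5L],
             start = start1 - 1,          # 1-based inclusive -> 0-based
             end = end1,
             strand = mat[, 9L],
             rep_name = mat[, 10L],
             rep_class = vapply(cf, `[`, "", 1L),
             rep_family = vapply(cf, function(x) x[min(2L, length(x))], ""),
             stringsAsFactors = FALSE)
}

#' Write / read the canonical element table
#'
#' Plain TSV round-trip of a `retro_elements` table; used by the synthetic
#' landscape writer and the CLI.
#'
#' @param elements a `retro_elements` table.
#' @param file output (input) path.
#' @export
write_elements <- function(elements, file) {
  write.table(as.data.frame(elements), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname write_elements
#' @export
read_elements <- function(file) {
  df <- read.table(file, sep = "\t", header = TRUE,
                   colClasses = c(chrom = "character",
                                  subfamily = "character"))
  if (nrow(df) == 0L) return(empty_retro_elements())
  retro_elements(df$chrom, df$start, df$end, df$strand, df$family,
                 df$subfamily)
}

#' Construct a gene model from coding-exon intervals
#'
#' Coding exons are sorted and merged (overlapping or book-ended intervals
#' collapse into one). `flank_bp` is the half-width of the landscape that
#' poses direct deletion risk to the gene; `context_bp` is the extra span of
#' partner context consulted when computing the stability of risk-source Alu
#' elements near the landscape boundary.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome.
#' @param exon_start,exon_end parallel vectors of 0-based half-open coding
#'   exon intervals.
#' @param strand gene strand (informational).
#' @param flank_bp landscape half-width in bp (default 250000).
#' @param context_bp extra pair-partner context in bp (default 421000).
#' @param group optional group label (e.g. "cancer" / "random").
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, exon_start, exon_end, strand = "+",
                       flank_bp = 250000, context_bp = 421000,
                       group = NA_character_) {
  stopifnot(length(exon_start) == length(exon_end))
  if (length(exon_start) == 0L) stop("gene model requires at least one exon")
  if (length(chrom) != 1L) stop("gene model must reside on one chromosome")
  if (flank_bp <= 0) stop("flank_bp must be positive")
  if (context_bp < 0) stop("context_bp must be non-negative")
  if (any(exon_start >= exon_end)) stop("exons must satisfy start < end")
  ex <- merge_intervals(exon_start, exon_end)
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 strand = strand, exons = ex, flank_bp = flank_bp,
                 context_bp = context_bp, group = as.character(group)),
            class = "gene_model")
}

# merge sorted half-open intervals; book-ended intervals are joined
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(start) > 1L) {
    for (i in 2:length(start)) {
      if (start[i] <= me) {
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model:", x$gene_id, " (", x$chrom, x$strand, ")\n")
  cat("  coding exons:", nrow(x$exons), " span:",
      min(x$exons$start), "-", max(x$exons$end), "\n")
  cat("  flank:", x$flank_bp, "bp  partner context:", x$context_bp, "bp\n")
  invisible(x)
}

#' Read gene models from a coding-exon table
#'
#' Accepts a 4+ column TSV of coding exons (chrom, start, end, gene_id, with
#' optional strand and group columns; header optional) or a BED12 file whose
#' blocks are taken as coding exons and whose name field is the gene id.
#'
#' @param file exon table path.
#' @param gene_id optionally restrict to one gene.
#' @inheritParams gene_model
#' @return a list of `gene_model` objects (a single object if `gene_id`
#'   is given).
#' @export
read_gene_models <- function(file, gene_id = NULL, flank_bp = 250000,
                             context_bp = 421000) {
  first <- readLines(file, n = 1L, warn = FALSE)
  nfield <- length(strsplit(first, "\t", fixed = TRUE)[[1L]])
  if (nfield >= 12L) {
    df <- read.table(file, sep = "\t", header = FALSE,
                     colClasses = "character")
    ex <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      chromStart <- as.numeric(df[i, 2L])
      sizes <- as.numeric(strsplit(df[i, 11L], ",")[[1L]])
      offs <- as.numeric(strsplit(df[i, 12L], ",")[[1L]])
      data.frame(chrom = df[i, 1L], start = chromStart + offs,
                 end = chromStart + offs + sizes, gene_id = df[i, 4L],
                 strand = df[i, 6L], group = NA_character_)
    }))
  } else {
    has_header <- grepl("chrom|start|gene", first, ignore.case = TRUE)
    df <- tryCatch(read.table(file, sep = "\t", header = has_header,
                              colClasses = "character"),
                   error = function(e) stop("empty exon table: ", file))
    if (nrow(df) == 0L) stop("empty exon table: ", file)
    if (!has_header) {
      names(df)[1:4] <- c("chrom", "start", "end", "gene_id")
    }
    if (ncol(df) < 4L) stop("exon table needs chrom, start, end, gene_id")
    ex <- data.frame(chrom = df$chrom, start = as.numeric(df$start),
                     end = as.numeric(df$end), gene_id = df$gene_id,
                     strand = if ("strand" %in% names(df)) df$strand else "+",
                     group = if ("group" %in% names(df)) df$group
                             else NA_character_)
  }
  if (!is.null(gene_id)) {
    ex <- ex[ex$gene_id %in% gene_id, , drop = FALSE]
    if (nrow(ex) == 0L) stop("no exons found for gene ", gene_id)
  }
  if (nrow(ex) == 0L) stop("empty exon table: ", file)
  models <- lapply(split(ex, ex$gene_id), function(g) {
    if (length(unique(g$chrom)) > 1L) {
      stop("gene ", g$gene_id[1L], " has exons on multiple chromosomes")
    }
    gene_model(g$gene_id[1L], g$chrom[1L], g$start, g$end,
               strand = g$strand[1L], flank_bp = flank_bp,
               context_bp = context_bp, group = g$group[1L])
  })
  if (!is.null(gene_id) && length(gene_id) == 1L) models[[1L]] else models
}
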
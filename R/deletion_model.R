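#' Hybrid deletion-size probability model
#'
#' Builds the probability mass function over deletion sizes 1..`max_size` bp
#' used to convert Alu-end double-strand-break risk into exon-damage risk.
#' The pmf is piecewise log-log linear with two segments joined continuously
#' at `breakpoint_bp` (75 bp, reflecting the two source indel spectra the
#' hybrid is modelled on: one informative below ~75 bp, one above). The two
#' slopes and the normalising constant are solved so that the pmf sums to 1,
#' the cumulative mass at 50 bp equals `frac_le_50` and the cumulative mass
#' at 445 bp equals `frac_le_445`. With the defaults (95% of deletions
#' <= 50 bp, 99% <= 445 bp) the solved model also satisfies the tail bound
#' pmf(500000)/pmf(1) <= 1e-9, which is asserted after solving.
#'
#' @param frac_le_50 target cumulative mass at 50 bp (default 0.95).
#' @param frac_le_445 target cumulative mass at 445 bp (default 0.99).
#' @param max_size largest modelled deletion (default 500000 bp).
#' @param breakpoint_bp segment split (default 75 bp).
#' @return an object of class `deletion_size_model` with components `pmf`
#'   (length `max_size`), `tail` (upper cumulative sums, `tail[s]` =
#'   P(size >= s)), `slope_below`, `slope_above`, and the build parameters.
#' @examples
#' m <- deletion_size_model()
#' sum(m$pmf)                 # 1
#' sum(m$pmf[1:50])           # 0.95
#' p_deletion(m, c(0, 25, 250000))
#' @export
deletion_size_model <- function(frac_le_50 = 0.95, frac_le_445 = 0.99,
                                max_size = 500000, breakpoint_bp = 75) {
  if (!(frac_le_50 > 0 && frac_le_50 < frac_le_445 && frac_le_445 < 1)) {
    stop("need 0 < frac_le_50 < frac_le_445 < 1")
  }
  if (max_size <= 445 || breakpoint_bp <= 1 || breakpoint_bp >= 445) {
    stop("infeasible size range for the two-segment model")
  }
  ls <- log(seq_len(max_size))
  lbp <- log(breakpoint_bp)
  lo <- seq_len(breakpoint_bp)
  hi <- (breakpoint_bp + 1L):max_size
  unnorm <- function(a, b) {
    w <- numeric(max_size)
    w[lo] <- exp(a * ls[lo])
    w[hi] <- exp((a - b) * lbp + b * ls[hi])
    w
  }
  # inner solve: slope below the breakpoint fixes the 50 bp / 445 bp ratio
  ratio_target <- frac_le_50 / frac_le_445
  solve_a <- function(b) {
    uniroot(function(a) {
      w <- unnorm(a, b)
      sum(w[1:50]) / sum(w[1:445]) - ratio_target
    }, c(-8, -0.05), tol = 1e-13)$root
  }
  b <- uniroot(function(b) {
    w <- unnorm(solve_a(b), b)
    sum(w[1:445]) / sum(w) - frac_le_445
  }, c(-6, -1.001), tol = 1e-13)$root
  a <- solve_a(b)
  w <- unnorm(a, b)
  pmf <- w / sum(w)
  if (pmf[max_size] / pmf[1L] > 1e-9) {
    stop("solved model violates the extreme-tail bound ",
         "(pmf(max)/pmf(1) = ", signif(pmf[max_size] / pmf[1L], 3),
         "); the requested constraints are outside the model family")
  }
  structure(list(pmf = pmf, tail = rev(cumsum(rev(pmf))),
                 slope_below = a, slope_above = b,
                 frac_le_50 = frac_le_50, frac_le_445 = frac_le_445,
                 max_size = max_size, breakpoint_bp = breakpoint_bp),
            class = "deletion_size_model")
}

#' @export
print.deletion_size_model <- function(x, ...) {
  cat("Deletion-size model over 1..", x$max_size, " bp\n", sep = "")
  cat(sprintf("  log-log slopes: %.4f (<=%d bp), %.4f (>%d bp)\n",
              x$slope_below, x$breakpoint_bp, x$slope_above, x$breakpoint_bp))
  cat(sprintf("  cdf(50) = %.6f   cdf(445) = %.6f   sum = %.9f\n",
              sum(x$pmf[1:50]), sum(x$pmf[1:445]), sum(x$pmf)))
  invisible(x)
}

#' @export
plot.deletion_size_model <- function(x, ...) {
  s <- unique(round(10^seq(0, log10(x$max_size), length.out = 400)))
  plot(s, x$pmf[s], log = "xy", type = "l", xlab = "deletion size (bp)",
       ylab = "probability", main = "Deletion size frequency", ...)
  abline(v = c(50, 445), lty = 3)
  invisible(x)
}

#' Minimum-size-or-larger deletion probability
#'
#' Probability that a deletion initiated at an Alu end reaches a coding exon
#' `d_min` bp away. Deletions extend equidistant from the initiating
#' double-strand break, so the minimum required size is `2 * d_min`;
#' the returned value is the upper-tail mass of the deletion-size pmf at
#' that size (1 when `d_min` is 0; 0 when `2 * d_min` exceeds the modelled
#' range).
#'
#' @param model a `deletion_size_model`.
#' @param d_min distance(s) in bp from the Alu end to the proximal exon
#'   boundary.
#' @return vector of probabilities.
#' @export
p_deletion <- function(model, d_min) {
  if (any(d_min < 0)) stop("d_min must be non-negative")
  s_req <- pmax(1, ceiling(2 * d_min))
  out <- numeric(length(d_min))
  ok <- s_req <= model$max_size
  out[ok] <- model$tail[s_req[ok]]
  out
}

#' Rebuild the deletion-size model with a different small-deletion fraction
#'
#' Used by the sensitivity scan: the upper-segment (tail) slope of the
#' reference model is held fixed while the lower slope and normalisation are
#' re-solved so the cumulative mass at 50 bp equals `frac`. The 445 bp
#' checkpoint floats accordingly.
#'
#' @param model reference `deletion_size_model`.
#' @param frac new cumulative mass at 50 bp, in \[0.90, 0.99\].
#' @return a new `deletion_size_model`.
#' @export
vary_small_fraction <- function(model, frac) {
  if (frac < 0.90 || frac > 0.99) stop("frac must lie in [0.90, 0.99]")
  max_size <- model$max_size; bp <- model$breakpoint_bp
  b <- model$slope_above
  ls <- log(seq_len(max_size)); lbp <- log(bp)
  lo <- seq_len(bp); hi <- (bp + 1L):max_size
  unnorm <- function(a) {
    w <- numeric(max_size)
    w[lo] <- exp(a * ls[lo])
    w[hi] <- exp((a - b) * lbp + b * ls[hi])
    w
  }
  a <- uniroot(function(a) {
    w <- unnorm(a)
    sum(w[1:50]) / sum(w) - frac
  }, c(-10, -0.01), tol = 1e-13)$root
  w <- unnorm(a)
  pmf <- w / sum(w)
  out <- model
  out$pmf <- pmf
  out$tail <- rev(cumsum(rev(pmf)))
  out$slope_below <- a
  out$frac_le_50 <- frac
  out$frac_le_445 <- sum(pmf[1:445])
  out
}

#' Serialize / restore a deletion-size model
#'
#' The parameter header (the two solved slopes plus the size range) is
#' sufficient to rebuild the pmf exactly; the full (size, pmf) table is
#' written only on request.
#'
#' @param model a `deletion_size_model`.
#' @param file path.
#' @param full also write the per-size pmf table.
#' @export
write_deletion_model <- function(model, file, full = FALSE) {
  hdr <- sprintf(paste0(
    "# deletion_size_model slope_below=%.17g slope_above=%.17g",
    " max_size=%d breakpoint_bp=%d frac_le_50=%.17g frac_le_445=%.17g"),
    model$slope_below, model$slope_above, model$max_size,
    model$breakpoint_bp, model$frac_le_50, model$frac_le_445)
  con <- file(file, "w"); on.exit(close(con))
  writeLines(hdr, con)
  if (full) {
    writeLines("size\tpmf", con)
    writeLines(sprintf("%d\t%.17g", seq_len(model$max_size), model$pmf), con)
  }
  invisible(file)
}

#' @rdname write_deletion_model
#' @export
read_deletion_model <- function(file) {
  hdr <- readLines(file, n = 1L)
  if (!grepl("^# deletion_size_model ", hdr)) {
    stop("not a deletion_size_model file: ", file)
  }
  kv <- strsplit(strsplit(sub("^# deletion_size_model ", "", hdr),
                          " ")[[1L]], "=", fixed = TRUE)
  par <- setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                  vapply(kv, `[`, "", 1L))
  a <- par[["slope_below"]]; b <- par[["slope_above"]]
  max_size <- as.integer(par[["max_size"]])
  bp <- as.integer(par[["breakpoint_bp"]])
  ls <- log(seq_len(max_size))
  w <- numeric(max_size)
  lo <- seq_len(bp); hi <- (bp + 1L):max_size
  w[lo] <- exp(a * ls[lo])
  w[hi] <- exp((a - b) * log(bp) + b * ls[hi])
  pmf <- w / sum(w)
  structure(list(pmf = pmf, tail = rev(cumsum(rev(pmf))),
                 slope_below = a, slope_above = b,
                 frac_le_50 = par[["frac_le_50"]],
                 frac_le_445 = par[["frac_le_445"]],
                 max_size = max_size, breakpoint_bp = bp),
            class = "deletion_size_model")
}

#' Geometry constants of the deletion model
#'
#' `min_required_deletion_size` is the smallest deletion that can reach an
#' exon from a double-strand break `d_min` bp away under equidistant
#' extension (2 x d_min). `max_threat_distance` is the largest Alu-to-exon
#' distance at which an Alu can still contribute risk: an Alu beyond the
#' direct-risk flank can interact with a partner inside it across a spacer
#' of up to `spacer_cutoff_bp`, so the bound is `flank_bp +
#' spacer_cutoff_bp` (671,000 bp with the defaults).
#'
#' @param d_min distance from the DSB to the exon (bp).
#' @param flank_bp direct-risk landscape half-width (default 250000).
#' @param spacer_cutoff_bp largest spacer at which an inverted pair is below
#'   the significance cutoff (default 421000).
#' @export
min_required_deletion_size <- function(d_min) {
  if (any(d_min < 0)) stop("d_min must be non-negative")
  2 * d_min
}

#' @rdname min_required_deletion_size
#' @export
max_threat_distance <- function(flank_bp = 250000,
                                spacer_cutoff_bp = 421000) {
  flank_bp + spacer_cutoff_bp
}

#' Statistical confidence band on an I:D ratio
#'
#' For a stratum of `n` Alu pairs, the band of I:D ratios consistent with
#' unity at the given confidence level, via a two-sided test of the
#' inverted-pair fraction against 0.5. At n = 410 (the average Alu count in
#' a gene landscape) the band is approximately 0.82-1.22, which is why
#' gene-local pair counts cannot detect the imbalance and a genome-wide
#' calibration is required.
#'
#' @param n number of pairs in the stratum.
#' @param conf confidence level (default 0.95).
#' @param method "exact" (binomial test acceptance region) or "normal"
#'   (Wald interval on the proportion).
#' @return named vector c(lower, upper) of I:D bounds.
#' @export
id_confidence_band <- function(n, conf = 0.95, method = c("exact", "normal")) {
  method <- match.arg(method)
  alpha <- 1 - conf
  if (method == "normal") {
    z <- qnorm(1 - alpha / 2)
    half <- z * sqrt(0.25 / n)
    p <- c(0.5 - half, 0.5 + half)
  } else {
    ks <- 0:n
    pv <- vapply(ks, function(k) binom.test(k, n, 0.5)$p.value, 1.0)
    acc <- range(ks[pv >= alpha])
    p <- acc / n
  }
  c(lower = p[1L] / (1 - p[1L]), upper = p[2L] / (1 - p[2L]))
}
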
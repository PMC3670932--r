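PERCENTILE_LABELS <- c(2.5, seq(10, 90, by = 10))

# spacer -> regression abscissa; +1 guards the log at spacer 0
.xfun <- function(spacer) log10(spacer + 1)

#' Bin one (pair type, APSN) family of Alu pairs into spacer percentiles
#'
#' Pairs are sorted by spacer size (ties broken by enumeration order, which
#' is (chrom, left start)) and cut into ten groups: the smallest 5% of
#' spacers (the 2.5th-percentile group) followed by nine consecutive 10%
#' groups centred on the 10th..90th percentiles. The top 5% of spacers is
#' outside the binned range (it is used for the terminal prediction ramp).
#' Each group records inverted/direct counts, their ratio and the median
#' spacer.
#'
#' @param pairs an `alu_pairs` table (or any data frame with `spacer_bp`
#'   and `inverted`) belonging to a single (pair type, APSN) family.
#' @param min_pairs minimum family size (default 1000).
#' @return data.frame with one row per percentile group: percentile,
#'   spacer_lo, spacer_hi, median_spacer, n_inverted, n_direct, id_ratio.
#' @export
bin_spacer_percentiles <- function(pairs, min_pairs = 1000) {
  n <- nrow(pairs)
  if (n < min_pairs) {
    stop("only ", n, " pairs in this family (need >= ", min_pairs,
         "); pool across APSNs or lower min_pairs")
  }
  o <- order(pairs$spacer_bp)           # stable: ties keep enumeration order
  spacer <- pairs$spacer_bp[o]
  inv <- pairs$inverted[o]
  cuts <- floor(n * seq(0.05, 0.95, by = 0.10) + 1e-9)
  lo_i <- c(1L, cuts[-10L] + 1L)
  hi_i <- cuts
  out <- lapply(seq_along(PERCENTILE_LABELS), function(g) {
    idx <- lo_i[g]:hi_i[g]
    ni <- sum(inv[idx]); nd <- sum(!inv[idx])
    data.frame(percentile = PERCENTILE_LABELS[g],
               spacer_lo = spacer[lo_i[g]], spacer_hi = spacer[hi_i[g]],
               median_spacer = median(spacer[idx]),
               n_inverted = ni, n_direct = nd,
               id_ratio = if (nd > 0) ni / nd else ifelse(ni > 0, Inf, 0))
  })
  do.call(rbind, out)
}

#' Pool percentile groups across APSN families
#'
#' Step three of the calibration: for each percentile label the per-APSN
#' groups form one series of (apsn, median spacer, I:D) points, multiplying
#' the effective sample size by the number of APSN families. Pooled counts
#' are summed (never averaged as ratios), so the pooled I:D is the ratio of
#' total inverted to total direct counts.
#'
#' @param groups per-(type, apsn) percentile groups, i.e. the output of
#'   [bin_spacer_percentiles()] with `pair_type` and `apsn` columns added.
#' @return list with `series` (the input, ordered by type, percentile,
#'   apsn) and `pooled` (per type x percentile: summed counts and pooled
#'   I:D).
#' @export
pool_percentiles_across_apsns <- function(groups) {
  dt <- data.table::as.data.table(groups)
  data.table::setorderv(dt, c("pair_type", "percentile", "apsn"))
  pooled <- dt[, .(n_inverted = sum(n_inverted), n_direct = sum(n_direct)),
               by = c("pair_type", "percentile")]
  pooled[, "pooled_id" := ifelse(n_direct > 0, n_inverted / n_direct,
                                 ifelse(n_inverted > 0, Inf, 0))]
  list(series = dt[], pooled = pooled[])
}

#' Fit one percentile curve of I:D ratio versus spacer size
#'
#' Weighted segmented polynomial regression of the I:D ratio against
#' log10(spacer + 1). Breakpoints are chosen by exhaustive dynamic
#' programming over ordered points; the number of segments (up to
#' `max_segments`) is selected by BIC, so sharp regime changes (which the
#' underlying pair-loss process does produce) get their own segment while a
#' smooth series collapses to a single polynomial. Weights default to group
#' pair counts. Falls back to piecewise-linear interpolation, with a
#' warning, when the design is degenerate.
#'
#' @param series data.frame with `median_spacer`, `id_ratio` and optionally
#'   `n_inverted`/`n_direct` (weights).
#' @param degree polynomial degree per segment (default 2).
#' @param max_segments maximum number of segments (default 3).
#' @param min_seg minimum points per segment (default 5).
#' @return object of class `percentile_fit`; evaluate with
#'   [eval_percentile_fit()].
#' @export
fit_percentile_curve <- function(series, degree = 2, max_segments = 3,
                                 min_seg = 5) {
  y <- series$id_ratio
  x <- .xfun(series$median_spacer)
  w <- if (all(c("n_inverted", "n_direct") %in% names(series))) {
    series$n_inverted + series$n_direct
  } else rep(1, length(y))
  ok <- is.finite(y) & is.finite(x) & w > 0
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  o <- order(x)
  x <- x[o]; y <- y[o]; w <- w[o]
  m <- length(y)
  if (m == 0L) stop("no finite points to fit")
  if (m < max(2L, degree + 1L)) {
    return(.interp_fit(x, y, warn = FALSE))
  }
  seg_fit <- function(i, j) {
    xi <- x[i:j]; yi <- y[i:j]; wi <- w[i:j]
    d <- min(degree, length(unique(xi)) - 1L)
    X <- outer(xi, 0:d, `^`)
    fit <- tryCatch(lm.wfit(X, yi, wi), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      # collapse to weighted mean on singular designs
      cf <- c(sum(wi * yi) / sum(wi), rep(0, d))
      res <- yi - cf[1L]
      list(coef = cf, sse = sum(wi * res^2))
    } else {
      list(coef = fit$coefficients, sse = sum(wi * fit$residuals^2))
    }
  }
  kmax <- max(1L, min(max_segments, m %/% min_seg))
  # cost of fitting points i..j as one segment
  cost <- matrix(Inf, m, m)
  fits <- vector("list", m * m)
  for (i in 1:m) {
    for (j in i:m) {
      if (j - i + 1L >= min_seg || (i == 1L && j == m)) {
        f <- seg_fit(i, j)
        cost[i, j] <- f$sse
        fits[[(i - 1L) * m + j]] <- f
      }
    }
  }
  best <- matrix(Inf, kmax, m)   # best[k, j]: SSE of points 1..j in k segments
  back <- matrix(0L, kmax, m)
  best[1L, ] <- cost[1L, ]
  if (kmax > 1L) {
    for (k in 2:kmax) {
      for (j in k:m) {
        for (i in k:j) {
          v <- best[k - 1L, i - 1L] + cost[i, j]
          if (v < best[k, j]) { best[k, j] <- v; back[k, j] <- i }
        }
      }
    }
  }
  wtot <- m
  bic <- vapply(1:kmax, function(k) {
    sse <- best[k, m]
    if (!is.finite(sse)) return(Inf)
    wtot * log(max(sse / wtot, 1e-300)) + k * (degree + 1L) * log(wtot)
  }, 1.0)
  kbest <- which.min(bic)
  # recover breakpoints
  bounds <- integer(0)
  j <- m
  for (k in kbest:1) {
    i <- if (k == 1L) 1L else back[k, j]
    bounds <- c(i, bounds)
    j <- i - 1L
  }
  seg_idx <- cbind(bounds, c(bounds[-1L] - 1L, m))
  segments <- do.call(rbind, lapply(seq_len(nrow(seg_idx)), function(s) {
    i <- seg_idx[s, 1L]; j <- seg_idx[s, 2L]
    f <- fits[[(i - 1L) * m + j]]
    if (is.null(f)) f <- seg_fit(i, j)
    cf <- rep(0, degree + 1L)
    cf[seq_along(f$coef)] <- f$coef
    # segment domain: split halfway between adjacent points across bounds
    x_lo <- if (i == 1L) -Inf else (x[i - 1L] + x[i]) / 2
    x_hi <- if (j == m) Inf else (x[j] + x[j + 1L]) / 2
    data.frame(x_lo = x_lo, x_hi = x_hi, x_min = x[i], x_max = x[j],
               rbind(cf) |> as.data.frame() |>
                 stats::setNames(paste0("c", 0:degree)))
  }))
  rownames(segments) <- NULL
  res <- y - eval_segments(segments, x)
  structure(list(kind = "poly", degree = degree, segments = segments,
                 rms_residual = sqrt(sum(w * res^2) / sum(w)),
                 x_range = range(x)),
            class = "percentile_fit")
}

.interp_fit <- function(x, y, warn = TRUE) {
  if (warn) warning("degenerate design; falling back to interpolation")
  if (length(x) == 1L) {
    segments <- data.frame(x_lo = -Inf, x_hi = Inf, x_min = x, x_max = x,
                           c0 = y, c1 = 0)
  } else {
    segments <- do.call(rbind, lapply(seq_len(length(x) - 1L), function(i) {
      slope <- (y[i + 1L] - y[i]) / (x[i + 1L] - x[i])
      data.frame(x_lo = if (i == 1L) -Inf else x[i],
                 x_hi = if (i == length(x) - 1L) Inf else x[i + 1L],
                 x_min = x[i], x_max = x[i + 1L],
                 c0 = y[i] - slope * x[i], c1 = slope)
    }))
  }
  structure(list(kind = "interp", degree = 1L, segments = segments,
                 rms_residual = 0, x_range = range(x)),
            class = "percentile_fit")
}

eval_segments <- function(segments, x) {
  ncf <- sum(grepl("^c\\d+$", names(segments)))
  out <- numeric(length(x))
  seg_of <- findInterval(x, c(segments$x_lo[1L], segments$x_hi))
  seg_of[seg_of < 1L] <- 1L
  seg_of[seg_of > nrow(segments)] <- nrow(segments)
  for (s in unique(seg_of)) {
    sel <- seg_of == s
    # clamp to the segment's fitted span: flat extension, no extrapolation
    xs <- pmin(pmax(x[sel], segments$x_min[s]), segments$x_max[s])
    cf <- as.numeric(segments[s, paste0("c", 0:(ncf - 1L))])
    out[sel] <- drop(outer(xs, 0:(ncf - 1L), `^`) %*% cf)
  }
  out
}

#' Evaluate a fitted percentile curve at spacer sizes
#'
#' @param fit a `percentile_fit`.
#' @param spacer spacer sizes in bp.
#' @export
eval_percentile_fit <- function(fit, spacer) {
  eval_segments(fit$segments, .xfun(spacer))
}

#' @export
print.percentile_fit <- function(x, ...) {
  cat("Percentile curve fit (", x$kind, "): ", nrow(x$segments),
      " segment(s), RMS residual ", signif(x$rms_residual, 4), "\n", sep = "")
  invisible(x)
}

#' Extract per-APSN I:D anchors from the fitted percentile curves
#'
#' Step four of the calibration: for each (pair type, APSN) family the ten
#' fitted percentile curves are evaluated at that family's own median
#' spacers, yielding the ten (median spacer, regressed I:D) anchors of the
#' family's I:D-versus-spacer curve.
#'
#' @param fits named list of `percentile_fit` objects with names
#'   `"t<type>_p<percentile>"`.
#' @param groups the per-(type, apsn) percentile groups.
#' @param epsilon positive floor for fitted values.
#' @return the groups table with an `id_fitted` column (clamped to
#'   (epsilon, 1.25\]); raw ratios are retained in `id_ratio`.
#' @export
extract_apsn_curves <- function(fits, groups, epsilon = 1e-6) {
  dt <- data.table::as.data.table(groups)
  dt[, "id_fitted" := NA_real_]
  for (key in names(fits)) {
    tp <- as.integer(sub("^t(\\d+)_p.*$", "\\1", key))
    pc <- as.numeric(sub("^t\\d+_p", "", key))
    sel <- dt$pair_type == tp & dt$percentile == pc
    if (!any(sel)) next
    v <- eval_percentile_fit(fits[[key]], dt$median_spacer[sel])
    dt[sel, "id_fitted" := pmin(pmax(v, epsilon), 1.25)]
  }
  data.table::setorderv(dt, c("pair_type", "apsn", "percentile"))
  dt[]
}

#' Restrict an I:D surface to statistically significant APSNs
#'
#' An APSN family is informative only if at least one of its anchors lies
#' below the significance cutoff (the I:D value below which, at the paired
#' minimum sample size, the ratio is confidently below unity). The largest
#' such APSN becomes `apsn_max`; predicted I:D for pairs beyond it is 1.
#'
#' @param surface an `id_surface`.
#' @param cutoff significance cutoff (default 0.995).
#' @param min_n paired sample-size constant recorded as metadata
#'   (default 507000).
#' @return the surface with `apsn_max`, `significance_cutoff` and `min_n`
#'   set.
#' @export
apply_significance_filter <- function(surface, cutoff = 0.995,
                                      min_n = 507000) {
  sig <- surface$anchors[surface$anchors$id_fitted < cutoff, ]
  surface$apsn_max <- if (nrow(sig)) max(sig$apsn) else 0L
  surface$significance_cutoff <- cutoff
  surface$min_n <- min_n
  surface
}

#' Calibrate an I:D ratio surface from a repeat landscape
#'
#' Runs the five-step genome-wide calibration: (1) restrict to full-length
#' (275-325 bp) Alu pairs per APSN; (2) bin each (pair type, APSN) family
#' into ten spacer percentile groups; (3) pool groups across APSNs into ten
#' per-percentile series per pair type and fit each series against median
#' spacer with segmented weighted regression; (4) evaluate the fitted
#' percentile curves back at each APSN's own median spacers to obtain ten
#' anchors per (type, APSN); (5) keep the APSN range with statistical
#' support and record the 99th-percentile spacer per family for the
#' terminal prediction ramp. Type 0 pairs (same CLIQUE) are excluded from
#' calibration and handled by the yeast-anchored short-spacer rule at
#' prediction time, anchored at the fitted Type 1 2.5th-percentile APSN-1
#' value.
#'
#' @param elements a sorted `retro_elements` table (Alu/LINE1/SVA).
#' @param pairs optionally, a pre-enumerated `alu_pairs` table (skips
#'   enumeration; must have been built with `apsn_max >= apsn_cal_max`).
#' @param gap_bp CLIQUE gap (default 50).
#' @param apsn_cal_max largest APSN examined during calibration
#'   (default 115).
#' @param min_pairs minimum pairs per (type, APSN) family (default 1000;
#'   smaller families are skipped with a message).
#' @param cutoff,min_n significance constants (defaults 0.995 / 507000).
#' @param degree,max_segments,min_seg percentile-curve fit controls.
#' @param epsilon positive floor for fitted/predicted I:D.
#' @param type0_rel named rescaling of the Type 0 yeast anchors, see
#'   [predict_type0()].
#' @return an object of class `id_surface`.
#' @export
fit_id_surface <- function(elements = NULL, pairs = NULL, gap_bp = 50,
                           apsn_cal_max = 115, min_pairs = 1000,
                           cutoff = 0.995, min_n = 507000, degree = 2,
                           max_segments = 3, min_seg = 5, epsilon = 1e-6,
                           type0_rel = c("12" = 0.60, "20" = 0.75,
                                         "30" = 0.85)) {
  if (is.null(pairs)) {
    if (is.null(elements)) stop("supply elements or pairs")
    pairs <- enumerate_alu_pairs(elements, apsn_max = apsn_cal_max,
                                 cliques = detect_cliques(elements, gap_bp))
  }
  pairs <- data.table::as.data.table(pairs)
  cal <- pairs[pairs$left_size == "full_length" &
               pairs$right_size == "full_length" &
               !pairs$tandem_flag &
               pairs$pair_type %in% 1:3 &
               pairs$apsn <= apsn_cal_max, ]
  if (nrow(cal) == 0L) stop("no full-length pairs available for calibration")
  n_cal <- nrow(cal)
  # step two: percentile groups per (type, apsn) family
  fam <- split(seq_len(nrow(cal)),
               list(type = cal$pair_type, apsn = cal$apsn), drop = TRUE)
  groups <- vector("list", length(fam))
  skipped <- 0L
  for (k in seq_along(fam)) {
    idx <- fam[[k]]
    if (length(idx) < min_pairs) { skipped <- skipped + 1L; next }
    g <- bin_spacer_percentiles(cal[idx, ], min_pairs = min_pairs)
    g$pair_type <- cal$pair_type[idx[1L]]
    g$apsn <- cal$apsn[idx[1L]]
    groups[[k]] <- g
  }
  groups <- do.call(rbind, groups)
  if (is.null(groups)) {
    stop("every (type, APSN) family is below min_pairs = ", min_pairs)
  }
  if (skipped > 0L) {
    message("skipped ", skipped, " (type, APSN) families below min_pairs")
  }
  # step three: pool across APSNs and fit each percentile series
  pooled <- pool_percentiles_across_apsns(groups)
  fits <- list()
  for (tp in sort(unique(groups$pair_type))) {
    for (pc in PERCENTILE_LABELS) {
      ser <- pooled$series[pooled$series$pair_type == tp &
                           pooled$series$percentile == pc, ]
      if (nrow(ser) == 0L) next
      fits[[sprintf("t%d_p%s", tp, format(pc))]] <-
        fit_percentile_curve(ser, degree = degree,
                             max_segments = max_segments, min_seg = min_seg)
    }
  }
  # step four: anchors per (type, apsn)
  anchors <- extract_apsn_curves(fits, groups, epsilon = epsilon)
  # 99th-percentile spacer per family, for the terminal ramp
  p99 <- cal[, .(p99_spacer = as.numeric(quantile(spacer_bp, 0.99,
                                                  type = 1))),
             by = c("pair_type", "apsn")]
  data.table::setorderv(p99, c("pair_type", "apsn"))
  surface <- structure(
    list(anchors = anchors, p99 = p99, fits = fits,
         pooled = pooled$pooled, apsn_max = NA_integer_,
         significance_cutoff = cutoff, min_n = min_n, epsilon = epsilon,
         type0 = NULL,
         meta = list(schema_version = "1.0",
                     package_version = as.character(
                       utils::packageVersion("aluscape")),
                     n_pairs_calibrated = n_cal,
                     apsn_cal_max = apsn_cal_max, gap_bp = gap_bp,
                     degree = degree, max_segments = max_segments,
                     type0_note = paste(
                       "Type 0 rule is a monotone interpolant through",
                       "yeast anchor spacers (12/20/30/100 bp); the exact",
                       "functional form is a documented stand-in"))),
    class = "id_surface")
  # step five support: Type 0 anchor = fitted Type 1 (fallback 2, 3)
  # 2.5th-percentile value at APSN 1
  anchor <- NULL
  for (tp in 1:3) {
    row <- anchors[anchors$pair_type == tp & anchors$apsn == 1L &
                   anchors$percentile == 2.5, ]
    if (nrow(row) == 1L) {
      anchor <- list(value = min(1, max(epsilon, row$id_fitted)),
                     spacer = row$median_spacer, source_type = tp)
      break
    }
  }
  if (is.null(anchor)) anchor <- list(value = 1, spacer = 100,
                                      source_type = NA_integer_)
  surface$type0 <- list(strategy = "yeast_rescaled", rel = type0_rel,
                        anchor = anchor$value,
                        anchor_spacer = anchor$spacer,
                        anchor_source_type = anchor$source_type,
                        homology = 0.85)
  apply_significance_filter(surface, cutoff = cutoff, min_n = min_n)
}

#' @export
print.id_surface <- function(x, ...) {
  cat("I:D ratio surface\n")
  cat("  anchors:", nrow(x$anchors), "over pair types",
      paste(sort(unique(x$anchors$pair_type)), collapse = ", "),
      "and APSN 1..", max(x$anchors$apsn), "\n")
  cat("  apsn_max (significant):", x$apsn_max,
      "  cutoff:", x$significance_cutoff, "\n")
  cat("  calibrated from", x$meta$n_pairs_calibrated,
      "full-length pairs\n")
  cat("  Type 0 anchor:", signif(x$type0$anchor, 5), "at spacer",
      x$type0$anchor_spacer, "bp\n")
  invisible(x)
}

#' @export
summary.id_surface <- function(object, ...) {
  a <- object$anchors
  by_type <- split(a$id_fitted, a$pair_type)
  cat("I:D surface summary\n")
  for (tp in names(by_type)) {
    v <- by_type[[tp]]
    cat(sprintf("  Type %s: %d anchors, fitted I:D range %.4f-%.4f\n",
                tp, length(v), min(v), max(v)))
  }
  cat("  significant APSN range: 1..", object$apsn_max, "\n", sep = "")
  invisible(object)
}

#' Plot calibrated I:D curves for one pair type
#'
#' I:D anchors against median spacer size, one curve per APSN, on a log
#' spacer axis.
#'
#' @param x an `id_surface`.
#' @param pair_type which type to draw (default 1).
#' @param apsns which APSN curves to draw (default up to 10).
#' @param ... passed to [matplot()].
#' @export
plot.id_surface <- function(x, pair_type = 1,
                            apsns = head(sort(unique(x$anchors$apsn)), 10),
                            ...) {
  a <- x$anchors[x$anchors$pair_type == pair_type &
                 x$anchors$apsn %in% apsns, ]
  if (nrow(a) == 0L) stop("no anchors for pair type ", pair_type)
  plot(NA, xlim = range(a$median_spacer + 1), ylim = range(a$id_fitted, 1),
       log = "x", xlab = "median spacer (bp)", ylab = "I:D ratio",
       main = sprintf("Type %d I:D curves", pair_type), ...)
  for (ap in apsns) {
    s <- a[a$apsn == ap, ]
    lines(s$median_spacer + 1, s$id_fitted, col = "grey40")
  }
  abline(h = 1, lty = 3)
  invisible(x)
}

#' Write / read an I:D surface file
#'
#' Versioned JSON container: a metadata block (cutoffs, apsn_max,
#' calibration provenance, Type 0 rule), the anchor table, the fitted
#' percentile-curve segment table and the per-family 99th-percentile
#' spacers. Numbers are written at full precision so a round trip is exact.
#' Externally supplied surfaces that follow the same schema (an anchor
#' table with pair_type/apsn/percentile/median_spacer/id_fitted plus the
#' metadata block) are accepted by [read_id_surface()].
#'
#' @param surface an `id_surface`.
#' @param file path.
#' @export
write_id_surface <- function(surface, file) {
  ncf_max <- max(c(1L, vapply(surface$fits, function(f) {
    sum(grepl("^c\\d+$", names(f$segments)))
  }, 1L)))
  seg_tab <- do.call(rbind, lapply(names(surface$fits), function(key) {
    f <- surface$fits[[key]]
    seg <- f$segments
    for (ci in paste0("c", 0:(ncf_max - 1L))) {
      if (!ci %in% names(seg)) seg[[ci]] <- 0
    }
    # JSON has no +/-Inf: open segment bounds get finite sentinels
    seg$x_lo[!is.finite(seg$x_lo)] <- -1e300
    seg$x_hi[!is.finite(seg$x_hi)] <- 1e300
    cbind(data.frame(curve = key, kind = f$kind, degree = f$degree),
          seg[, c("x_lo", "x_hi", "x_min", "x_max",
                  paste0("c", 0:(ncf_max - 1L)))])
  }))
  payload <- list(
    meta = c(surface$meta,
             list(apsn_max = surface$apsn_max,
                  significance_cutoff = surface$significance_cutoff,
                  min_n = surface$min_n, epsilon = surface$epsilon)),
    type0 = c(surface$type0[setdiff(names(surface$type0), "rel")],
              list(rel = as.list(surface$type0$rel))),
    anchors = as.data.frame(surface$anchors),
    p99 = as.data.frame(surface$p99),
    segments = seg_tab)
  jsonlite::write_json(payload, file, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_id_surface
#' @export
read_id_surface <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = TRUE)
  meta <- payload$meta
  num_cols <- function(df, dbl, int = character(0)) {
    for (cc in intersect(dbl, names(df))) df[[cc]] <- as.numeric(df[[cc]])
    for (cc in intersect(int, names(df))) df[[cc]] <- as.integer(df[[cc]])
    df
  }
  segments <- payload$segments
  fits <- list()
  if (!is.null(segments) && nrow(segments)) {
    cf <- grep("^c\\d+$", names(segments), value = TRUE)
    segments <- num_cols(segments,
                         c("x_lo", "x_hi", "x_min", "x_max", cf))
    segments$x_lo[segments$x_lo <= -1e299] <- -Inf
    segments$x_hi[segments$x_hi >= 1e299] <- Inf
    for (key in unique(segments$curve)) {
      seg <- segments[segments$curve == key, , drop = FALSE]
      rownames(seg) <- NULL
      fits[[key]] <- structure(
        list(kind = seg$kind[1L], degree = as.integer(seg$degree[1L]),
             segments = seg[, c("x_lo", "x_hi", "x_min", "x_max", cf),
                            drop = FALSE],
             rms_residual = NA_real_,
             x_range = c(min(seg$x_min), max(seg$x_max))),
        class = "percentile_fit")
    }
  }
  anchors <- num_cols(payload$anchors,
                      c("percentile", "spacer_lo", "spacer_hi",
                        "median_spacer", "id_ratio", "id_fitted"),
                      c("pair_type", "apsn", "n_inverted", "n_direct"))
  p99 <- num_cols(payload$p99, "p99_spacer", c("pair_type", "apsn"))
  t0 <- payload$type0
  t0$rel <- unlist(t0$rel)
  for (cc in c("anchor", "anchor_spacer", "homology")) {
    t0[[cc]] <- as.numeric(t0[[cc]])
  }
  structure(
    list(anchors = data.table::as.data.table(anchors),
         p99 = data.table::as.data.table(p99),
         fits = fits, pooled = NULL,
         apsn_max = as.integer(meta$apsn_max),
         significance_cutoff = as.numeric(meta$significance_cutoff),
         min_n = as.numeric(meta$min_n),
         epsilon = as.numeric(meta$epsilon),
         type0 = t0,
         meta = meta[setdiff(names(meta),
                             c("apsn_max", "significance_cutoff", "min_n",
                               "epsilon"))]),
    class = "id_surface")
}
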
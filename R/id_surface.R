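#' Predicted I:D for Type 0 (same-CLIQUE) Alu pairs
#'
#' Type 0 pairs carry strong orientational insertion bias, so their
#' stability cannot be read off the genomic I:D ratio. Instead a
#' short-spacer rule is anchored on inverted-repeat instability measured in
#' a yeast experimental system at spacers of 12, 20, 30 and 100 bp, rescaled
#' to the typical 85% homology of human Alu pairs: the 100 bp point is
#' pinned to the fitted Type 1 2.5th-percentile I:D at APSN 1 (whose median
#' spacer is ~100 bp in genomic data), and the 12/20/30 bp points are fixed
#' fractions (`rel`) of that anchor. Prediction is a monotone
#' non-decreasing interpolant in spacer through these four points, clamped
#' to (epsilon, 1\]. The rule applies to spacers of at most 50 bp; larger
#' Type 0 spacers are routed to the Type 1 curves by [predict.id_surface()].
#'
#' @param spacer spacer sizes in bp.
#' @param type1_anchor the Type 1 2.5th-percentile APSN-1 I:D value.
#' @param rel named vector of rescaling fractions at spacers 12, 20, 30.
#' @param epsilon positive floor.
#' @param strict error on spacers > 50 bp (the rule's domain). Set to
#'   FALSE to evaluate the underlying interpolant anywhere up to 100 bp,
#'   e.g. to verify the anchor identity at spacer 100.
#' @return predicted I:D values in (epsilon, 1\].
#' @export
predict_type0 <- function(spacer, type1_anchor,
                          rel = c("12" = 0.60, "20" = 0.75, "30" = 0.85),
                          epsilon = 1e-6, strict = TRUE) {
  if (strict && any(spacer > 50)) {
    stop("Type 0 rule applies to spacers <= 50 bp; route larger spacers ",
         "to the Type 1 curves")
  }
  if (is.null(names(rel))) names(rel) <- c("12", "20", "30")
  xs <- c(12, 20, 30, 100)
  ys <- c(type1_anchor * rel[c("12", "20", "30")], type1_anchor)
  ys <- pmin(pmax(ys, epsilon), 1)
  ys <- cummax(ys)                       # enforce monotone anchors
  f <- splinefun(xs, ys, method = "monoH.FC")
  out <- f(pmin(pmax(spacer, 12), 100))  # flat below 12 bp
  pmin(pmax(out, epsilon), 1)
}

#' Predict the I:D ratio (pair stability) for Alu pairs
#'
#' The predicted I:D is the model's stability for an Alu pair. Direct
#' pairs are stable (1.0); inverted pairs beyond the significant APSN range
#' are 1.0; Type 0 inverted pairs with spacers <= 50 bp follow the
#' yeast-anchored rule and otherwise use the Type 1 curves. For the rest,
#' the pair's (type, APSN) anchor curve is interpolated linearly in spacer:
#' spacers below the 2.5th-percentile median take the 2.5th anchor value,
#' spacers above the 90th-percentile median ramp linearly to 1.0 at the
#' family's 99th-percentile spacer and are 1.0 beyond it. Any value above
#' the significance cutoff is assigned 1.0; everything is floored at the
#' surface epsilon so stability products stay positive.
#'
#' @param object an `id_surface`.
#' @param pairs an `alu_pairs` table (or any data frame with columns
#'   `apsn`, `spacer_bp`, `inverted`, `pair_type`; `apsn` may be signed).
#' @param ... unused.
#' @return numeric vector of predicted I:D in (0, 1\].
#' @export
predict.id_surface <- function(object, pairs, ...) {
  n <- nrow(pairs)
  apsn <- abs(pairs$apsn)
  type <- pairs$pair_type
  spacer <- pairs$spacer_bp
  if (any(!type %in% 0:3)) stop("unknown pair type")
  out <- rep(1, n)
  active <- pairs$inverted & apsn <= object$apsn_max
  if (!any(active)) return(out)
  # Type 0 short spacers: yeast-anchored rule
  t0 <- active & type == 0L & spacer <= 50
  if (any(t0)) {
    out[t0] <- predict_type0(spacer[t0], object$type0$anchor,
                             rel = object$type0$rel,
                             epsilon = object$epsilon)
  }
  # everything else: anchor-curve interpolation (Type 0 long spacers use
  # the Type 1 curves)
  rest <- active & !t0
  if (any(rest)) {
    type_eff <- ifelse(type[rest] == 0L, 1L, type[rest])
    out[rest] <- .predict_curves(object, type_eff, apsn[rest], spacer[rest])
  }
  out[out > object$significance_cutoff] <- 1
  pmin(pmax(out, object$epsilon), 1)
}

.predict_curves <- function(surface, type, apsn, spacer) {
  anchors <- surface$anchors
  p99 <- surface$p99
  res <- rep(1, length(type))
  key <- paste(type, apsn)
  have <- unique(paste(anchors$pair_type, anchors$apsn))
  # nearest-APSN fallback within type for families absent from calibration
  for (k in unique(key[!(key %in% have)])) {
    parts <- as.integer(strsplit(k, " ")[[1L]])
    cand <- anchors$apsn[anchors$pair_type == parts[1L]]
    if (length(cand) == 0L) next
    near <- cand[which.min(abs(cand - parts[2L]))]
    key[key == k] <- paste(parts[1L], near)
  }
  for (k in unique(key)) {
    if (!(k %in% have)) next
    parts <- as.integer(strsplit(k, " ")[[1L]])
    a <- anchors[anchors$pair_type == parts[1L] & anchors$apsn == parts[2L], ]
    a <- a[order(a$median_spacer), ]
    p99_s <- p99$p99_spacer[p99$pair_type == parts[1L] &
                            p99$apsn == parts[2L]]
    if (length(p99_s) == 0L) p99_s <- max(a$median_spacer) * 2
    sel <- key == k
    s <- spacer[sel]
    v <- numeric(length(s))
    lo <- s <= a$median_spacer[1L]
    hi <- s >= a$median_spacer[nrow(a)]
    mid <- !lo & !hi
    v[lo] <- a$id_fitted[1L]
    if (any(mid)) {
      v[mid] <- approx(a$median_spacer, a$id_fitted, xout = s[mid],
                       ties = "ordered")$y
    }
    if (any(hi)) {
      # linear ramp from the 90th-percentile anchor to 1.0 at the
      # 99th-percentile spacer, then unity
      s90 <- a$median_spacer[nrow(a)]
      v90 <- a$id_fitted[nrow(a)]
      if (p99_s <= s90) {
        v[hi] <- 1
      } else {
        frac <- pmin(1, (s[hi] - s90) / (p99_s - s90))
        v[hi] <- v90 + frac * (1 - v90)
      }
    }
    res[sel] <- v
  }
  res
}
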
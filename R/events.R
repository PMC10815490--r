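# Contraction-event machinery: threshold the map into a space-time
# constriction mask, extract 8-connected components as events, and
# classify them by extent and location.

#' Threshold a map into a space-time constriction mask
#'
#' A sample (position, time) is marked constricted when its diameter
#' falls below the position's resting diameter by more than
#' \code{depthThreshold} of that position's dynamic range (resting minus
#' constricted diameter, taken as upper/lower envelope quantiles of the
#' position's width trace).
#'
#' @param map a [SpatioTemporalMap-class].
#' @param depthThreshold fraction of the local dynamic range, in (0, 1);
#'   default 0.5 (half-depth).
#' @param hiQuantile,loQuantile envelope quantiles defining the resting
#'   and constricted diameter per position.
#' @return logical matrix of the same shape as the map. A map with zero
#'   dynamic range at every position (nothing ever contracts) yields an
#'   all-FALSE mask with a warning.
#' @seealso [extractEvents()]
#' @export
constrictionMask <- function(map, depthThreshold = 0.5,
                             hiQuantile = 0.95, loQuantile = 0.05) {
  stopifnot(is(map, "SpatioTemporalMap"))
  if (depthThreshold <= 0 || depthThreshold >= 1)
    stop("depthThreshold must lie in (0, 1)")
  d <- diameterMatrix(map)
  rest <- apply(d, 1, stats::quantile, hiQuantile)
  constr <- apply(d, 1, stats::quantile, loQuantile)
  rng <- rest - constr
  if (all(rng <= 0)) {
    warning("map has zero dynamic range at every position; empty mask")
    return(matrix(FALSE, nrow(d), ncol(d)))
  }
  d < rest - depthThreshold * rng
}

#' Extract contraction events from a constriction mask
#'
#' Events are the 8-connected components of the mask with at least
#' \code{minArea} samples. For each event the onset and end are the
#' first and last footprint times, the spatial extent is the span of
#' occupied positions, and the signed propagation velocity is the
#' least-squares slope of position on time over the event's leading edge
#' (the earliest occupied time at each position) - the way a front is
#' read off a heatmap. Positive velocity propagates oral to anal.
#'
#' @param mask logical matrix from [constrictionMask()].
#' @param map the [SpatioTemporalMap-class] the mask came from.
#' @param minArea minimum component area in samples (>= 1).
#' @return data.frame with one row per event: \code{event_id},
#'   \code{onset}, \code{end} (s), \code{pos_min}, \code{pos_max},
#'   \code{spatial_extent} (mm), \code{extent_fraction},
#'   \code{velocity} (mm/s, NA when the leading edge is degenerate),
#'   \code{fit_r2}, \code{n_samples}, and a \code{footprint} list column
#'   of data.frames with \code{position} (mm) and \code{time} (s).
#'   An empty list of events is a data.frame with zero rows.
#' @export
extractEvents <- function(mask, map, minArea = 1L) {
  stopifnot(is(map, "SpatioTemporalMap"),
            identical(dim(mask), dim(diameterMatrix(map))))
  if (minArea < 1L) stop("minArea must be >= 1")
  empty <- data.frame(event_id = integer(), onset = numeric(),
                      end = numeric(), pos_min = numeric(),
                      pos_max = numeric(), spatial_extent = numeric(),
                      extent_fraction = numeric(), velocity = numeric(),
                      fit_r2 = numeric(), n_samples = integer())
  empty$footprint <- list()
  if (!any(mask)) return(empty)
  lab <- labelComponents(mask)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  ri <- (idx - 1L) %% nrow(lab) + 1L
  ci <- (idx - 1L) %/% nrow(lab) + 1L
  pos <- (ri - 1) * spatialStep(map)
  tim <- (ci - 1) * temporalStep(map)
  L <- segmentLength(map)
  groups <- split(seq_along(comp), comp)
  rows <- lapply(seq_along(groups), function(k) {
    g <- groups[[k]]
    if (length(g) < minArea) return(NULL)
    p <- pos[g]; t <- tim[g]
    # leading edge: earliest time per occupied position
    leadT <- tapply(t, p, min)
    leadP <- as.numeric(names(leadT))
    leadT <- as.numeric(leadT)
    if (length(leadP) >= 2L && stats::var(leadT) > 0) {
      fit <- stats::lm(leadP ~ leadT)
      velocity <- unname(stats::coef(fit)[2])
      # R^2 computed directly: summary.lm warns on noiseless fits
      ssTot <- sum((leadP - mean(leadP))^2)
      r2 <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot
            else NA_real_
    } else {
      velocity <- NA_real_
      r2 <- NA_real_
    }
    out <- data.frame(event_id = k, onset = min(t), end = max(t),
                      pos_min = min(p), pos_max = max(p),
                      spatial_extent = max(p) - min(p),
                      extent_fraction = (max(p) - min(p)) / L,
                      velocity = velocity, fit_r2 = r2,
                      n_samples = length(g))
    out$footprint <- list(data.frame(position = p, time = t))
    out
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$onset), , drop = FALSE]
  out$event_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Classify contraction events by extent and location
#'
#' An event counts as a propagating contractile complex (PCC) when it
#' spans more than half the segment in a consistent direction
#' (\code{extent_fraction > 0.5} with leading-edge fit \code{fit_r2 >=
#' r2Min}). Classes: \code{full_length} when the extent fraction reaches
#' \code{fullLengthFraction}; otherwise \code{proximal_short} /
#' \code{distal_short} when the footprint is confined to the oral / anal
#' half of the segment; \code{non_propagating} for everything else
#' (including sub-full-length events straddling the midpoint).
#'
#' @param events data.frame from [extractEvents()].
#' @param segmentLength segment length, mm.
#' @param fullLengthFraction extent fraction at which an event counts as
#'   full length (default 0.9).
#' @param r2Min minimum leading-edge R^2 for a consistent direction
#'   (default 0.5).
#' @return \code{events} with logical column \code{is_pcc} and factor
#'   column \code{class} added.
#' @export
classifyEvents <- function(events, segmentLength,
                           fullLengthFraction = 0.9, r2Min = 0.5) {
  if (segmentLength <= 0) stop("segmentLength must be > 0")
  lvls <- c("full_length", "proximal_short", "distal_short",
            "non_propagating")
  if (!nrow(events)) {
    events$is_pcc <- logical()
    events$class <- factor(character(), levels = lvls)
    return(events)
  }
  half <- segmentLength / 2
  events$is_pcc <- events$extent_fraction > 0.5 &
    !is.na(events$fit_r2) & events$fit_r2 >= r2Min
  cls <- ifelse(events$extent_fraction >= fullLengthFraction,
                "full_length",
         ifelse(events$pos_max <= half, "proximal_short",
         ifelse(events$pos_min >= half, "distal_short",
                "non_propagating")))
  events$class <- factor(cls, levels = lvls)
  events
}

# PCC filter shared by the frequency / quiescence / velocity summaries:
# uses the classification when present, the raw criterion otherwise.
isPcc <- function(events, r2Min = 0.5) {
  if ("is_pcc" %in% names(events)) return(events$is_pcc)
  events$extent_fraction > 0.5 & !is.na(events$fit_r2) &
    events$fit_r2 >= r2Min
}
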
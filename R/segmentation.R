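#' Zone boundaries for stance subsegmentation
#'
#' Three anteroposterior cut positions partition `[0, foot_length]` into
#' four zones mapped rear-to-front onto the stance subphases ICP, FFCP, FFP,
#' FFPOP. Zones are half-open `[low, high)`: a CoP exactly on a cut belongs
#' to the later (more anterior) zone.
#'
#' @param cuts Strictly increasing numeric vector of 3 positions, mm.
#' @param foot_length Foot length, mm.
#' @return An object of class `zone_boundaries`.
#' @export
zone_boundaries <- function(cuts, foot_length = 260) {
  if (!is.finite(foot_length) || foot_length <= 0) {
    stop("foot_length must be positive", call. = FALSE)
  }
  cuts <- as.numeric(cuts)
  if (length(cuts) != 3L || is.unsorted(cuts, strictly = TRUE) ||
      cuts[1] <= 0 || cuts[3] >= foot_length) {
    stop("cuts must satisfy 0 < c1 < c2 < c3 < foot_length", call. = FALSE)
  }
  structure(list(cuts = cuts, foot_length = foot_length),
            class = "zone_boundaries")
}

#' Default zone boundaries
#'
#' Cuts at fractions 0.25, 0.45 and 0.70 of foot length. The four-zone
#' construction is defined for a normal EU 41 foot; the exact cut positions
#' are a package default placed between the heel, midfoot, metatarsal-head
#' and toe sensor bands of the default layout, and are fully configurable.
#'
#' @param foot_length Foot length, mm (default 260, EU 41).
#' @return A [zone_boundaries()] object.
#' @examples
#' default_zones(260)$cuts  # 65, 117, 182 mm
#' @export
default_zones <- function(foot_length = 260) {
  zone_boundaries(foot_length * c(0.25, 0.45, 0.70), foot_length)
}

#' Segment stance phases into subphases
#'
#' Labels every sample of each stance interval with one of the four stance
#' subphases (`ICP`, `FFCP`, `FFP`, `FFPOP`) according to the zone
#' containing its anteroposterior CoP position, then enforces subphase order
#' by forward-carrying the furthest zone reached within the stance (a
#' transient CoP dip across a cut can never revert the label, since the
#' subphases are strictly ordered events). Stance samples with no valid CoP
#' (e.g. the very first contact sample) inherit the first observed zone of
#' that stance. All non-stance samples are labeled `SWING`. A stance
#' interval containing no valid CoP sample at all is flagged, skipped with a
#' warning, and left as `SWING`.
#'
#' @param cop A `cop_trajectory` from [compute_cop()].
#' @param stance A [stance_intervals()] object.
#' @param zones A [zone_boundaries()] object.
#' @return An object of class `phase_annotation`: list with `foot_side`,
#'   per-sample factor `labels` (levels `SWING`, `ICP`, `FFCP`, `FFP`,
#'   `FFPOP`), an `intervals` data frame (`stance_id`, `subphase`,
#'   `start_s`, `end_s`) whose durations within each stance sum exactly to
#'   the stance duration, and `skipped` (ids of stances without valid CoP).
#' @export
segment_stance <- function(cop, stance, zones) {
  stopifnot(inherits(cop, "cop_trajectory"),
            inherits(stance, "stance_intervals"),
            inherits(zones, "zone_boundaries"))
  times <- cop$time_s
  labels <- factor(rep("SWING", length(times)), levels = .phase_levels)
  ivs <- list()
  skipped <- integer(0)
  subph <- .phase_levels[-1L]
  for (i in seq_len(nrow(stance$intervals))) {
    ic <- stance$intervals$ic_time[i]
    to <- stance$intervals$to_time[i]
    idx <- which(times >= ic & times < to)
    z <- rep(NA_integer_, length(idx))
    v <- cop$valid[idx]
    z[v] <- findInterval(cop$cop_y[idx][v], zones$cuts) + 1L
    if (!any(v)) {
      warning(sprintf("stance %d [%g, %g] s has no valid CoP sample; skipped",
                      i, ic, to))
      skipped <- c(skipped, i)
      next
    }
    # monotone forward-carry of the furthest zone reached; leading invalid
    # samples inherit the first observed zone
    zf <- z
    zf[is.na(zf)] <- 0L
    zc <- cummax(zf)
    zc[zc == 0L] <- zc[match(TRUE, zc > 0L)]
    labels[idx] <- subph[zc]
    # subphase intervals: boundaries at the stance edges and at the sample
    # times where the carried zone advances, so durations sum to to - ic
    trans <- which(diff(zc) > 0L) + 1L
    bounds <- c(ic, times[idx][trans], to)
    ivs[[length(ivs) + 1L]] <- data.frame(
      stance_id = i,
      subphase = subph[zc[c(1L, trans)]],
      start_s = bounds[-length(bounds)],
      end_s = bounds[-1L],
      stringsAsFactors = FALSE)
  }
  intervals <- if (length(ivs)) do.call(rbind, ivs) else
    data.frame(stance_id = integer(0), subphase = character(0),
               start_s = numeric(0), end_s = numeric(0))
  structure(list(foot_side = attr(cop, "foot_side"), times = times,
                 labels = labels, intervals = intervals, skipped = skipped),
            class = "phase_annotation")
}

#' Write a phase annotation as JSON
#'
#' Per-stance list of `{subphase, start_s, end_s}` records; schema in
#' `inst/schemas/annotation.schema.json`.
#'
#' @param ann A `phase_annotation`.
#' @param path File path.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "phase_annotation"))
  jsonlite::write_json(
    list(format = "gaitseg-annotation", version = "1.0",
         foot_side = ann$foot_side,
         stances = ann$intervals,
         skipped_stances = ann$skipped),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @export
print.phase_annotation <- function(x, ...) {
  n_st <- length(unique(x$intervals$stance_id))
  cat(sprintf("<phase_annotation> %s foot: %d segmented stances (%d skipped)\n",
              x$foot_side, n_st, length(x$skipped)))
  print(table(x$labels))
  invisible(x)
}
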
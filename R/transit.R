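# In vivo transit stage: serial-radiograph observation grid and
# whole / small-intestinal / colonic transit times.

#' Serial-imaging observation grid
#'
#' Radiographs are captured immediately after gavage (t = 0), every
#' 5 min for the first hour, every 10 min for the second hour, and every
#' 20 min afterwards. Event times scored from such a series can only
#' take values on this grid.
#'
#' @param tMax last time to include, min (> 0).
#' @return sorted numeric vector of observation times, min.
#' @examples
#' observationGrid(180)
#' @export
observationGrid <- function(tMax) {
  if (tMax <= 0) stop("tMax must be > 0")
  grid <- c(seq(0, 60, by = 5),
            seq(70, 120, by = 10),
            seq(140, max(140, 20 * ceiling(tMax / 20)), by = 20))
  grid[grid <= tMax]
}

#' Whole, small-intestinal and colonic transit times
#'
#' From each record of region-arrival times: SITT (small-intestinal
#' transit) is gavage to caecum arrival, CTT (colonic transit) is
#' proximal-colon arrival to first contrast-containing pellet, and WTT
#' (whole transit) is gavage to first pellet. Since the bolus dwells in
#' the caecum, WTT >= SITT + CTT for every valid record. Animals that
#' never produced a contrast-containing pellet are excluded (with a
#' message), mirroring standard practice.
#'
#' @param records data.frame with columns \code{animal_id},
#'   \code{group}, \code{gavage_time}, \code{caecum_arrival},
#'   \code{proximal_colon_arrival}, \code{first_pellet_time},
#'   \code{pellet_produced} (see [simulateTransitCohort()] or
#'   [readTransitRecords()]).
#' @return data.frame with columns \code{animal_id}, \code{group},
#'   \code{WTT}, \code{SITT}, \code{CTT} (min), one row per included
#'   animal. The number of excluded animals is attached as
#'   \code{attr(, "n_excluded")}.
#' @examples
#' rec <- data.frame(animal_id = "m1", group = "WT", gavage_time = 0,
#'   caecum_arrival = 80, proximal_colon_arrival = 90,
#'   first_pellet_time = 105, pellet_produced = TRUE)
#' transitTimes(rec)
#' @export
transitTimes <- function(records) {
  need <- c("animal_id", "group", "gavage_time", "caecum_arrival",
            "proximal_colon_arrival", "first_pellet_time",
            "pellet_produced")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records are missing columns: ", paste(missing, collapse = ", "))
  excluded <- !records$pellet_produced
  if (any(excluded))
    message(sum(excluded),
            " record(s) excluded: no contrast-containing pellet produced")
  rec <- records[!excluded, , drop = FALSE]
  out <- data.frame(
    animal_id = rec$animal_id, group = rec$group,
    WTT = rec$first_pellet_time - rec$gavage_time,
    SITT = rec$caecum_arrival - rec$gavage_time,
    CTT = rec$first_pellet_time - rec$proximal_colon_arrival)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(excluded)
  out
}

#' Read / write transit records as CSV
#'
#' \code{readTransitRecords} validates every record on load: arrival
#' times must be ordered (gavage <= caecum <= proximal colon <= first
#' pellet) and lie on the observation grid. Records violating the
#' ordering are rejected with a per-record diagnostic rather than
#' silently dropped.
#'
#' @param path CSV path.
#' @param records data.frame of transit records.
#' @return \code{readTransitRecords} returns the validated data.frame.
#' @export
readTransitRecords <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  rec$pellet_produced <- as.logical(rec$pellet_produced)
  need <- c("animal_id", "gavage_time", "caecum_arrival",
            "proximal_colon_arrival", "first_pellet_time",
            "pellet_produced")
  missing <- setdiff(need, names(rec))
  if (length(missing))
    stop("transit file is missing columns: ",
         paste(missing, collapse = ", "))
  bad <- with(rec, !(gavage_time <= caecum_arrival &
                     caecum_arrival <= proximal_colon_arrival &
                     proximal_colon_arrival <= first_pellet_time))
  bad[is.na(bad)] <- FALSE            # unscored times in failed animals
  bad <- bad & rec$pellet_produced
  if (any(bad))
    stop("record(s) with mis-ordered arrival times: ",
         paste(rec$animal_id[bad], collapse = ", "))
  grid <- observationGrid(max(rec$first_pellet_time, 140, na.rm = TRUE))
  offGrid <- !vapply(rec$first_pellet_time, function(t)
    is.na(t) || any(abs(grid - t) < 1e-9), logical(1))
  if (any(offGrid))
    warning("first_pellet_time off the observation grid for: ",
            paste(rec$animal_id[offGrid], collapse = ", "))
  rec
}

#' @rdname readTransitRecords
#' @export
writeTransitRecords <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
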
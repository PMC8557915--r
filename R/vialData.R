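#' Per-class fecundity from an 18-h pupae count
#'
#' Converts the pupae count of one egg-laying window into \code{f}, the
#' number of offspring per female for the full age class.  The count is
#' normalised to the females alive at the start of the window and, in the
#' default \code{"rate"} mode, extrapolated linearly from the laying window
#' to the full class length:
#' \deqn{f = \frac{pupae}{females} \times \frac{24 \cdot class\_days}{window\_hours}}
#' \code{"raw"} mode skips the extrapolation and uses the per-female window
#' count as the class value.
#'
#' @param pupaeCount nonnegative integer(s), pupae counted in the window.
#' @param femalesAtStart nonnegative integer(s), females alive at the start
#'   of the window.
#' @param layingWindowHours window length in hours (default 18).
#' @param classLengthDays age-class length in days (3 or 4 in the
#'   twice-weekly design).
#' @param extrapolation \code{"rate"} (default) or \code{"raw"}.
#' @return numeric, offspring per female per age class.
#' @examples
#' perClassFecundity(30, 20, 18, 3.5)   # 1.5 * (84/18) = 7
#' @export
perClassFecundity <- function(pupaeCount, femalesAtStart,
                              layingWindowHours = 18, classLengthDays,
                              extrapolation = c("rate", "raw")) {
  extrapolation <- match.arg(extrapolation)
  n <- max(length(pupaeCount), length(femalesAtStart))
  pupaeCount <- rep_len(pupaeCount, n)
  femalesAtStart <- rep_len(femalesAtStart, n)
  layingWindowHours <- rep_len(layingWindowHours, n)
  classLengthDays <- rep_len(classLengthDays, n)
  if (any(pupaeCount < 0) || any(femalesAtStart < 0))
    stop("counts must be nonnegative")
  if (any(layingWindowHours <= 0) || any(classLengthDays <= 0))
    stop("window and class lengths must be positive")
  if (any(layingWindowHours > 24 * classLengthDays))
    stop("'layingWindowHours' cannot exceed the class length")
  zero <- femalesAtStart == 0
  if (any(zero & pupaeCount > 0))
    stop("pupae counted with no females at the start of the window; ",
         "fecundity is undefined")
  if (any(zero))
    warning("females_at_start = 0 with no pupae: fecundity set to 0")
  scale <- if (extrapolation == "rate") 24 * classLengthDays / layingWindowHours else 1
  f <- ifelse(zero, 0, pupaeCount / pmax(femalesAtStart, 1) * scale)
  as.numeric(f)
}

#' Between-class survival fraction of one interval
#'
#' \code{s} is the fraction of females that survive from the start of one
#' age class to the start of the next.  Flies lost during vial transfers are
#' censored: by default (\code{censoring = "exclude"}) they are removed from
#' both numerator and denominator, treating loss as non-informative,
#' \deqn{s = \frac{n - deaths - censored}{n - censored}.}
#' \code{censoring = "deaths"} instead counts losses as deaths
#' (\eqn{s = (n - deaths - censored)/n}).
#'
#' @param femalesAtStart,femaleDeaths,femalesCensored nonnegative integers;
#'   deaths + censored must not exceed females at start.
#' @param censoring \code{"exclude"} (default) or \code{"deaths"}.
#' @return numeric in [0, 1]; \code{NA} when no females started the interval
#'   (the vial's schedule truncates there).
#' @export
intervalSurvival <- function(femalesAtStart, femaleDeaths, femalesCensored = 0,
                             censoring = c("exclude", "deaths")) {
  censoring <- match.arg(censoring)
  n <- max(length(femalesAtStart), length(femaleDeaths), length(femalesCensored))
  femalesAtStart <- rep_len(femalesAtStart, n)
  femaleDeaths <- rep_len(femaleDeaths, n)
  femalesCensored <- rep_len(femalesCensored, n)
  if (any(femaleDeaths < 0) || any(femalesCensored < 0) || any(femalesAtStart < 0))
    stop("counts must be nonnegative")
  if (any(femaleDeaths + femalesCensored > femalesAtStart))
    stop("deaths + censored exceed females_at_start")
  alive <- femalesAtStart - femaleDeaths - femalesCensored
  denom <- switch(censoring,
                  exclude = femalesAtStart - femalesCensored,
                  deaths = femalesAtStart)
  s <- ifelse(femalesAtStart == 0, NA_real_,
              ifelse(denom == 0, 0, alive / denom))
  as.numeric(s)
}

#' Read vial records from the tabular interchange format
#'
#' Two comma-separated, UTF-8, headered files describe a study:
#' \code{vials.csv} (\code{vial_id}, \code{treatment}, \code{experiment_day},
#' \code{replicate}) and \code{intervals.csv} (\code{vial_id},
#' \code{start_day}, \code{class_length_days}, \code{laying_window_hours},
#' \code{pupae_count}, \code{females_at_start}, \code{female_deaths},
#' \code{females_censored}).  Missing values are encoded as empty fields.
#' Malformed rows are reported with their line numbers.
#'
#' @param vialsFile,intervalsFile paths to the two CSV files.
#' @return a \linkS4class{VialRecordList} (empty, with a warning, when the
#'   vial table has no rows).
#' @seealso [writeVialTable()]
#' @export
readVialTable <- function(vialsFile, intervalsFile) {
  vt <- .readCsvChecked(vialsFile,
                        c("vial_id", "treatment", "experiment_day", "replicate"))
  it <- .readCsvChecked(intervalsFile, c("vial_id", .INTERVAL_COLS))
  if (nrow(vt) == 0L) {
    warning("empty vial table: ", vialsFile)
    return(VialRecordList(list()))
  }
  counts <- c("pupae_count", "females_at_start", "female_deaths", "females_censored")
  for (col in counts) {
    bad <- which(is.na(it[[col]]) | it[[col]] < 0 | it[[col]] != round(it[[col]]))
    if (length(bad))
      stop(sprintf("invalid '%s' in %s, line(s) %s (counts must be nonnegative integers)",
                   col, intervalsFile, paste(bad + 1L, collapse = ", ")))
  }
  bad <- which(it$female_deaths + it$females_censored > it$females_at_start)
  if (length(bad))
    stop(sprintf("deaths + censored exceed females_at_start in %s, line(s) %s",
                 intervalsFile, paste(bad + 1L, collapse = ", ")))
  orphan <- setdiff(it$vial_id, vt$vial_id)
  if (length(orphan))
    stop("interval rows reference unknown vial(s): ", paste(orphan, collapse = ", "))
  recs <- lapply(seq_len(nrow(vt)), function(i) {
    rows <- it[it$vial_id == vt$vial_id[i], .INTERVAL_COLS, drop = FALSE]
    if (nrow(rows) == 0L)
      stop("vial ", vt$vial_id[i], " has no interval rows")
    VialRecord(vt$vial_id[i], vt$treatment[i], vt$experiment_day[i],
               vt$replicate[i], rows)
  })
  VialRecordList(recs)
}

.readCsvChecked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s is missing mandatory column(s): %s", path,
                 paste(missing, collapse = ", ")))
  df
}

#' Write vial records to the tabular interchange format
#'
#' Inverse of [readVialTable()]; a written table re-reads field-for-field.
#'
#' @param vials a \linkS4class{VialRecordList}.
#' @param vialsFile,intervalsFile output CSV paths.
#' @return invisibly, the two paths.
#' @export
writeVialTable <- function(vials, vialsFile, intervalsFile) {
  vt <- do.call(rbind, lapply(vials, function(v)
    data.frame(vial_id = v@vialId, treatment = v@treatment,
               experiment_day = v@experimentDay, replicate = v@replicate)))
  it <- do.call(rbind, lapply(vials, function(v)
    cbind(data.frame(vial_id = v@vialId), v@intervals)))
  if (is.null(vt)) {
    vt <- data.frame(vial_id = character(0), treatment = character(0),
                     experiment_day = integer(0), replicate = integer(0))
    it <- cbind(data.frame(vial_id = character(0)),
                as.data.frame(stats::setNames(rep(list(numeric(0)),
                                                  length(.INTERVAL_COLS)),
                                              .INTERVAL_COLS)))
  }
  utils::write.csv(vt, vialsFile, row.names = FALSE, quote = FALSE)
  utils::write.csv(it, intervalsFile, row.names = FALSE, quote = FALSE)
  invisible(c(vialsFile, intervalsFile))
}

#' Read a contamination monitoring log
#'
#' @param path CSV with columns \code{vial_id}, \code{week},
#'   \code{cfu_per_fly}, \code{unexpected_morphology} (logical).
#' @return data.frame.
#' @export
readContaminationLog <- function(path) {
  df <- .readCsvChecked(path, c("vial_id", "week", "cfu_per_fly",
                                "unexpected_morphology"))
  df$unexpected_morphology <- as.logical(df$unexpected_morphology)
  df
}

#' Remove contaminated vials
#'
#' A vial is removed from all downstream analyses when its weekly F1
#' monitoring shows at least \code{thresholdCfu} CFU per fly of an
#' unexpected bacterial colony morphology in \code{consecutiveWeeks}
#' back-to-back weeks.
#'
#' @param vials a \linkS4class{VialRecordList}.
#' @param logs data.frame as returned by [readContaminationLog()]; every
#'   entry must reference a known vial.
#' @param thresholdCfu CFU-per-fly threshold (default 200); \code{Inf}
#'   disables the filter.
#' @param consecutiveWeeks number of back-to-back flagged weeks required
#'   (default 2).
#' @return list with elements \code{kept} (a VialRecordList) and
#'   \code{removed} (character vector of vial ids).
#' @export
contaminationFilter <- function(vials, logs, thresholdCfu = 200,
                                consecutiveWeeks = 2L) {
  ids <- names(vials)
  if (nrow(logs)) {
    unknown <- setdiff(logs$vial_id, ids)
    if (length(unknown))
      stop("contamination log references unknown vial(s): ",
           paste(unknown, collapse = ", "))
  }
  removed <- character(0)
  for (id in unique(logs$vial_id)) {
    lg <- logs[logs$vial_id == id, , drop = FALSE]
    lg <- lg[order(lg$week), , drop = FALSE]
    flagged <- lg$week[lg$unexpected_morphology & lg$cfu_per_fly >= thresholdCfu]
    if (.hasConsecutiveRun(flagged, consecutiveWeeks))
      removed <- c(removed, id)
  }
  keep <- setdiff(ids, removed)
  list(kept = VialRecordList(as.list(vials)[keep]), removed = removed)
}

# longest run of consecutive integers in 'weeks' reaches 'len'
.hasConsecutiveRun <- function(weeks, len) {
  if (len <= 1L) return(length(weeks) > 0L)
  if (length(weeks) < len) return(FALSE)
  weeks <- sort(unique(weeks))
  run <- 1L
  for (i in seq_along(weeks)[-1L]) {
    run <- if (weeks[i] == weeks[i - 1L] + 1L) run + 1L else 1L
    if (run >= len) return(TRUE)
  }
  FALSE
}

#' Expand vials into per-fly survival records
#'
#' Each female of the initial cohort contributes one record: deaths carry
#' event = 1 at the end of the interval in which they occurred, transfer
#' losses carry event = 0 at the interval end, and females still alive when
#' the experiment concludes carry event = 0 at the experiment end time.
#' Times are days since egg collection.
#'
#' @param vials a \linkS4class{VialRecordList}.
#' @param experimentEndDay day the experiment concluded; defaults per vial
#'   to the end of its last interval.
#' @return data.frame with columns \code{vial_id}, \code{treatment},
#'   \code{time_days}, \code{event} (1 = observed death, 0 = censored).
#' @export
toSurvivalRecords <- function(vials, experimentEndDay = NULL) {
  out <- lapply(vials, function(v) {
    iv <- v@intervals
    endTimes <- iv$start_day + iv$class_length_days
    endDay <- if (is.null(experimentEndDay)) endTimes[length(endTimes)] else experimentEndDay
    times <- c(rep(endTimes, iv$female_deaths),
               rep(endTimes, iv$females_censored))
    events <- c(rep(1L, sum(iv$female_deaths)),
                rep(0L, sum(iv$females_censored)))
    nAlive <- iv$females_at_start[nrow(iv)] - iv$female_deaths[nrow(iv)] -
      iv$females_censored[nrow(iv)]
    times <- c(times, rep(endDay, nAlive))
    events <- c(events, rep(0L, nAlive))
    data.frame(vial_id = v@vialId, treatment = v@treatment,
               time_days = times, event = events)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(vial_id = character(0), treatment = character(0),
                      time_days = numeric(0), event = integer(0))
  out
}
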
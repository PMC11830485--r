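#' Classify a glucose value into hypoglycemia levels
#'
#' Consensus levels: level 1 is 3.0-3.9 mmol/L (inclusive), level 2 is
#' below 3.0 mmol/L, level 3 is severe hypoglycemia requiring external
#' assistance — defined by the assistance flag and dominating any concurrent
#' glucose value.
#'
#' @param glucose Numeric vector, mmol/L. May be `NA` where `assisted` is
#'   `TRUE` (severe episodes need not have a strip value).
#' @param assisted Logical vector (recycled), external assistance required.
#' @return Factor with levels `none`, `level1`, `level2`, `level3`.
#' @examples
#' classifyHypo(c(3.5, 2.9, 4.0, 3.0))
#' classifyHypo(8, assisted = TRUE)
#' @export
classifyHypo <- function(glucose, assisted = FALSE) {
  n <- max(length(glucose), length(assisted))
  glucose <- rep_len(as.numeric(glucose), n)
  assisted <- rep_len(as.logical(assisted), n)
  assisted[is.na(assisted)] <- FALSE
  bad <- !assisted & (is.na(glucose) | glucose <= 0)
  if (any(bad)) {
    stop(sprintf("non-positive or missing glucose without assistance flag at position(s): %s",
                 paste(which(bad), collapse = ", ")))
  }
  out <- rep("none", n)
  out[glucose >= 3.0 & glucose <= 3.9] <- "level1"
  out[glucose < 3.0] <- "level2"
  out[assisted] <- "level3"
  factor(out, levels = c("none", "level1", "level2", "level3"))
}

# integer severity (0 = none)
hypo_level_int <- function(level) as.integer(level) - 1L

#' Extract hypoglycemia episodes from a reading stream
#'
#' One episode per qualifying reading (level 1-3), except that successive
#' qualifying readings of the same participant closer together than the
#' debounce gap — with no normal reading in between — merge into a single
#' episode recorded at the lowest glucose (repeated confirmatory strips within
#' the hour are one clinical event). Each episode is assigned to its 12-week
#' study period. Readings outside the study window are excluded with a
#' warning.
#'
#' @param readings Data frame with columns `participant_id`, `time` (POSIXct
#'   or Date), `glucose` (mmol/L); optional `assisted` (logical).
#' @param study_start Date (or POSIXct) of day 1 of the study.
#' @param config A [titrationConfig()] (supplies `debounce_gap_min`).
#' @param weeks Study length in weeks (default 24).
#' @return A tibble with columns `participant_id`, `time`, `level` (integer
#'   1-3), `glucose` (mmol/L, `NA` allowed for level 3), and `period` (factor
#'   `weeks_1_12` / `weeks_13_24`), sorted by participant and time.
#' @examples
#' rd <- data.frame(
#'   participant_id = "P01",
#'   time = as.POSIXct("2020-09-07 08:00", tz = "UTC") + c(0, 1800),
#'   glucose = c(3.4, 3.2)
#' )
#' extractEpisodes(rd, as.Date("2020-09-07"))
#' @export
extractEpisodes <- function(readings, study_start, config = titrationConfig(),
                            weeks = 24) {
  readings <- as.data.frame(readings)
  stopifnot(all(c("participant_id", "time", "glucose") %in% names(readings)))
  if (!("assisted" %in% names(readings))) readings$assisted <- logical(nrow(readings))
  readings$assisted[is.na(readings$assisted)] <- FALSE

  start <- as.POSIXct(paste(as.Date(study_start), "00:00:00"), tz = "UTC")
  tm <- as.POSIXct(readings$time, tz = "UTC")
  day <- as.numeric(difftime(tm, start, units = "days"))
  outside <- day < 0 | day >= weeks * 7
  if (any(outside)) {
    warning(sprintf("%d reading(s) outside the %d-week study window excluded", sum(outside), weeks))
    readings <- readings[!outside, , drop = FALSE]
    tm <- tm[!outside]
  }
  empty <- tibble::tibble(
    participant_id = character(), time = as.POSIXct(character(), tz = "UTC"),
    level = integer(), glucose = numeric(),
    period = factor(character(), levels = c("weeks_1_12", "weeks_13_24"))
  )
  if (nrow(readings) == 0) return(empty)

  level <- classifyHypo(readings$glucose, readings$assisted)
  res <- list()
  for (pid in sort(unique(as.character(readings$participant_id)))) {
    sel <- readings$participant_id == pid
    o <- order(tm[sel])
    t_p <- tm[sel][o]
    g_p <- as.numeric(readings$glucose[sel])[o]
    a_p <- readings$assisted[sel][o]
    l_p <- hypo_level_int(level[sel][o])
    qual <- which(l_p > 0)
    if (length(qual) == 0) next
    # episode id: a qualifying reading starts a new episode unless it follows
    # the previous qualifying reading within the debounce gap with no normal
    # reading in between
    ep <- integer(length(qual))
    ep[1] <- 1L
    if (length(qual) > 1) {
      for (k in 2:length(qual)) {
        i <- qual[k]; j <- qual[k - 1]
        gap_min <- as.numeric(difftime(t_p[i], t_p[j], units = "mins"))
        contiguous <- (i - j) == 1  # no intervening normal reading
        ep[k] <- ep[k - 1] + as.integer(!(contiguous && gap_min < config$debounce_gap_min))
      }
    }
    for (e in unique(ep)) {
      idx <- qual[ep == e]
      ass <- any(a_p[idx])
      gvals <- g_p[idx]
      if (all(is.na(gvals))) {
        gmin <- NA_real_; at <- idx[1]
      } else {
        at <- idx[which.min(gvals)]
        gmin <- g_p[at]
      }
      lvl <- if (ass) 3L else hypo_level_int(classifyHypo(gmin))
      res[[length(res) + 1]] <- tibble::tibble(
        participant_id = pid, time = t_p[at], level = lvl, glucose = gmin
      )
    }
  }
  if (length(res) == 0) return(empty)
  out <- dplyr::bind_rows(res)
  ep_day <- floor(as.numeric(difftime(out$time, start, units = "days")))
  out$period <- factor(ifelse(ep_day < 84, "weeks_1_12", "weeks_13_24"),
                       levels = c("weeks_1_12", "weeks_13_24"))
  out[order(out$participant_id, out$time), ]
}
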
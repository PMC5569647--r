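#' Convert ISO dates to decimal years
#'
#' Uses the package's fixed 365.25-day-year convention:
#' year + (days since January 1st) / 365.25.
#'
#' @param x `Date`s or ISO `"YYYY-MM-DD"` strings.
#' @return numeric decimal years.
#' @export
#' @examples
#' dec_year("1963-05-21")
dec_year <- function(x) {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (anyNA(d))
    .stop_demotime("unparseable date(s)", "demotime_format")
  yr <- as.integer(format(d, "%Y"))
  jan1 <- as.Date(sprintf("%d-01-01", yr))
  yr + as.numeric(d - jan1) / 365.25
}

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && grepl("\t", first, fixed = TRUE)) "\t" else ","
}

# Parse a character time column: decimal years pass through, ISO dates
# are converted (noted via message), empty strings become NA, anything
# else is flagged as bad.
.parse_time_col <- function(x, col) {
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  bad <- rep(FALSE, length(x))
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(iso)) {
    out[iso] <- dec_year(x[iso])
    message(sprintf("column '%s': %d ISO date(s) converted to decimal years (365.25-day year)",
                    col, sum(iso)))
  }
  num <- !iso & x != ""
  suppressWarnings(out[num] <- as.numeric(x[num]))
  bad[num & is.na(out)] <- TRUE
  list(values = out, bad = bad)
}

#' Read event-history files
#'
#' Lifelines come as delimited text (comma or tab, auto-detected) with
#' columns `id`, `birth`, and optionally `death` (empty = censored);
#' observations, if any, in a second long-format file with columns `id`,
#' `time`, and optionally `value`. Times are decimal years; ISO date
#' cells are converted via [dec_year()]. Malformed rows (missing or
#' unparseable times, death before birth) are rejected with a warning
#' listing ids and file line numbers, and returned in `rejected`.
#'
#' @param path lifeline file.
#' @param observations_path optional observation file.
#' @return list with elements `lifelines`, `observations` (zero-row if no
#'   file given), and `rejected` (data frame: `file`, `line`, `id`,
#'   `reason`).
#' @export
read_event_history <- function(path, observations_path = NULL) {
  ll <- .read_lifeline_file(path)
  if (!is.null(observations_path)) {
    obs <- .read_observation_file(observations_path)
  } else {
    obs <- list(observations = observations(character(0), numeric(0)),
                rejected = .no_rejects())
  }
  list(lifelines = ll$lifelines, observations = obs$observations,
       rejected = rbind(ll$rejected, obs$rejected))
}

.no_rejects <- function() {
  data.frame(file = character(0), line = integer(0), id = character(0),
             reason = character(0), stringsAsFactors = FALSE)
}

.read_delim_chars <- function(path) {
  if (!file.exists(path))
    .stop_demotime(sprintf("file not found: '%s'", path), "demotime_format")
  sep <- .detect_sep(path)
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
               colClasses = "character", strip.white = TRUE,
               check.names = FALSE),
    error = function(e) .stop_demotime(
      sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
      "demotime_format"))
  df
}

.read_lifeline_file <- function(path) {
  if (!file.exists(path))
    .stop_demotime(sprintf("file not found: '%s'", path), "demotime_format")
  if (all(!nzchar(trimws(readLines(path, warn = FALSE))))) {
    warning(sprintf("'%s' holds no lifeline records", path), call. = FALSE)
    return(list(lifelines = lifelines(character(0), numeric(0)),
                rejected = .no_rejects()))
  }
  df <- .read_delim_chars(path)
  names(df) <- tolower(names(df))
  if (!all(c("id", "birth") %in% names(df)))
    .stop_demotime(sprintf("'%s' must have columns id and birth", path),
                   "demotime_format")
  if (nrow(df) == 0L) {
    warning(sprintf("'%s' holds no lifeline records", path), call. = FALSE)
    return(list(lifelines = lifelines(character(0), numeric(0)),
                rejected = .no_rejects()))
  }
  birth <- .parse_time_col(df$birth, "birth")
  death <- if ("death" %in% names(df)) .parse_time_col(df$death, "death")
           else list(values = rep(NA_real_, nrow(df)), bad = rep(FALSE, nrow(df)))
  reason <- rep(NA_character_, nrow(df))
  reason[death$bad] <- "unparseable death"
  reason[birth$bad | is.na(birth$values)] <- "missing or unparseable birth"
  ok_times <- is.na(reason)
  before <- ok_times & !is.na(death$values) & death$values < birth$values
  reason[before] <- "death before birth"
  keep <- is.na(reason)
  rejected <- data.frame(file = rep(path, sum(!keep)),
                         line = which(!keep) + 1L,
                         id = df$id[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(rejected))
    warning(sprintf("'%s': rejected %d row(s) [%s]", path, nrow(rejected),
                    paste(sprintf("line %d id %s: %s", rejected$line,
                                  rejected$id, rejected$reason),
                          collapse = "; ")),
            call. = FALSE)
  list(lifelines = lifelines(df$id[keep], birth$values[keep],
                             death$values[keep]),
       rejected = rejected)
}

.read_observation_file <- function(path) {
  df <- .read_delim_chars(path)
  names(df) <- tolower(names(df))
  if (!all(c("id", "time") %in% names(df)))
    .stop_demotime(sprintf("'%s' must have columns id and time", path),
                   "demotime_format")
  tm <- .parse_time_col(df$time, "time")
  value <- if ("value" %in% names(df)) {
    suppressWarnings(as.numeric(df$value))
  } else rep(NA_real_, nrow(df))
  keep <- !is.na(tm$values)
  rejected <- data.frame(file = rep(path, sum(!keep)),
                         line = which(!keep) + 1L,
                         id = df$id[!keep],
                         reason = rep("missing or unparseable time", sum(!keep)),
                         stringsAsFactors = FALSE)
  if (nrow(rejected))
    warning(sprintf("'%s': rejected %d observation row(s)", path,
                    nrow(rejected)), call. = FALSE)
  list(observations = observations(df$id[keep], tm$values[keep], value[keep]),
       rejected = rejected)
}

#' Write lifelines / observations as delimited text
#'
#' @param x a [lifelines()] or [observations()] data frame.
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_event_history <- function(x, path, sep = ",") {
  write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
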
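#' Vigilance-state labels used throughout the package
#'
#' The five states: `W` wake, `NR` NREM sleep, `R` REM sleep, `C` cataplexy,
#' `D` DT sleep.
#' @export
VIGILANCE_STATES <- c("W", "NR", "R", "C", "D")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a clock time to seconds from midnight
#'
#' Accepts `"HH:MM"`, `"HH:MM:SS"` or a numeric number of seconds. Clock
#' times are stored internally as seconds from midnight.
#'
#' @param x clock time
#' @return integer seconds in `[0, 86400)`
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) {
    return(as.integer(round(x)) %% 86400L)
  }
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (!length(parts) %in% 2:3 || anyNA(suppressWarnings(as.numeric(parts)))) {
    stop("cannot parse clock time: ", x)
  }
  parts <- as.numeric(parts)
  sec <- parts[1] * 3600 + parts[2] * 60 + if (length(parts) == 3) parts[3] else 0
  as.integer(round(sec)) %% 86400L
}

#' Format seconds from midnight as HH:MM:SS
#' @param sec seconds from midnight
#' @return character
#' @export
format_clock <- function(sec) {
  sec <- as.integer(round(sec)) %% 86400L
  sprintf("%02d:%02d:%02d", sec %/% 3600L, (sec %% 3600L) %/% 60L, sec %% 60L)
}

#' Is a clock time within the light phase?
#'
#' Handles schedules that wrap midnight (lights on later than lights off).
#'
#' @param sec seconds from midnight (vectorised)
#' @param lights_on,lights_off clock times (any form accepted by
#'   [parse_clock()])
#' @return logical vector; `TRUE` = light phase
#' @export
in_light_phase <- function(sec, lights_on, lights_off) {
  on <- parse_clock(lights_on)
  off <- parse_clock(lights_off)
  if (on == off) stop("lights_on and lights_off must differ")
  sec <- as.integer(round(sec)) %% 86400L
  if (on < off) sec >= on & sec < off else sec >= on | sec < off
}

# Maximal runs of TRUE in a logical vector -> data.frame(start, end), 1-based.
runs_of <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Atomic-ish write: write to a temp file in the same directory, then rename.
write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}
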
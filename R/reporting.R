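#' Resolve a clock-time interval against a recording's start
#'
#' `"HH:MM"`/`"HH:MM:SS"` strings are anchored to the date of `anchor`; an
#' interval whose end precedes its start, or that ends before the anchor,
#' is shifted across midnight. Long recordings are reported in wall-clock
#' time, so named analysis windows are most naturally given this way.
#'
#' @param start,end clock-time strings.
#' @param anchor POSIXct anchor (first window time).
#' @return POSIXct vector `c(start, end)`.
#' @export
resolve_interval <- function(start, end, anchor) {
  parse1 <- function(s) {
    if (!grepl(":", s)) stop("clock time must look like HH:MM", call. = FALSE)
    if (length(strsplit(s, ":")[[1]]) == 2L) s <- paste0(s, ":00")
    as.POSIXct(paste(format(anchor, "%Y-%m-%d"), s), tz = attr(anchor, "tzone") %||% "UTC")
  }
  a <- parse1(start); b <- parse1(end)
  if (b <= a) b <- b + 86400
  if (b <= anchor) { a <- a + 86400; b <- b + 86400 }
  c(a, b)
}

#' Summarise a consciousness trace over named intervals
#'
#' Mean trace value per named clock-time interval, plus day (08:00-20:00)
#' and night means. An interval capturing no window is reported as `NA`,
#' never as zero.
#'
#' @param trace a `consciousness_trace`.
#' @param intervals named list of `c(start, end)` clock-time strings, e.g.
#'   `list(experiment = c("14:50", "17:00"))`.
#' @param day_hours numeric `c(start_hour, end_hour)` defining "day".
#' @return A data frame with columns `interval`, `n_windows`, `mean`.
#' @export
summarize_trace <- function(trace, intervals = list(), day_hours = c(8, 20)) {
  anchor <- trace$times[1]
  rows <- lapply(names(intervals), function(nm) {
    iv <- resolve_interval(intervals[[nm]][1], intervals[[nm]][2], anchor)
    inside <- trace$times >= iv[1] & trace$times < iv[2]
    data.frame(interval = nm, n_windows = sum(inside),
               mean = if (any(inside)) mean(trace$values[inside]) else NA_real_)
  })
  hr <- as.numeric(format(trace$times, "%H")) +
    as.numeric(format(trace$times, "%M")) / 60
  is_day <- hr >= day_hours[1] & hr < day_hours[2]
  rows <- c(rows, list(
    data.frame(interval = "day", n_windows = sum(is_day),
               mean = if (any(is_day)) mean(trace$values[is_day]) else NA_real_),
    data.frame(interval = "night", n_windows = sum(!is_day),
               mean = if (any(!is_day)) mean(trace$values[!is_day]) else NA_real_)))
  do.call(rbind, rows)
}

#' Percentage of clear answers
#'
#' Auxiliary behavioural summary: `100 * clear / total`.
#'
#' @param clear number of clearly answered questions.
#' @param total number of questions asked.
#' @return Percentage (0-100).
#' @export
answer_rate <- function(clear, total) {
  if (total <= 0 || clear < 0 || clear > total) {
    stop("need 0 <= clear <= total with total > 0", call. = FALSE)
  }
  100 * clear / total
}

#' Spearman correlation between features and consciousness traces
#'
#' Rank correlation of each feature column against each supplied trace,
#' with p-values (asymptotic, tie-tolerant). A constant column yields `NA`
#' and is flagged with a warning.
#'
#' @param feats an `ecog_features` (raw columns are used; Spearman is
#'   invariant to the monotone min-max rescaling).
#' @param traces named list of `consciousness_trace`s (e.g. `fcm`, `gmm`,
#'   `ensemble`).
#' @return Data frame: `feature`, then `rho_<name>` and `p_<name>` per trace.
#' @export
feature_correlations <- function(feats, traces) {
  out <- data.frame(feature = feats$names)
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    stopifnot(length(tr$values) == nrow(feats$raw))
    rho <- p <- rep(NA_real_, length(feats$names))
    for (j in seq_along(feats$names)) {
      col <- feats$raw[, j]
      if (stats::sd(col) == 0 || stats::sd(tr$values) == 0) {
        warning("constant column: correlation undefined for ", feats$names[j])
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(col, tr$values, method = "spearman", exact = FALSE))
      rho[j] <- unname(ct$estimate)
      p[j] <- ct$p.value
    }
    out[[paste0("rho_", nm)]] <- rho
    out[[paste0("p_", nm)]] <- p
  }
  out
}

#' Write trace CSV (timestamp, fcm, gmm, ensemble)
#' @param traces list with `trace_fcm`, `trace_gmm`, `trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  df <- data.frame(timestamp = format(traces$trace$times, "%Y-%m-%dT%H:%M:%OS3"),
                   fcm = traces$trace_fcm$values,
                   gmm = traces$trace_gmm$values,
                   ensemble = traces$trace$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
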
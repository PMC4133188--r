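#' Click trains
#'
#' A click train is the raw observable of the method: the ordered times at
#' which the pen clicked, each click marking delivery of one fixed volume
#' increment (`volume_per_click`, nominally 10 uL).
#'
#' @param times numeric, click times in seconds, strictly increasing.
#' @param volume_per_click volume delivered per click in m^3 (default 10 uL).
#' @param subject_id subject label.
#' @param medium `"air"` or `"tissue"`.
#' @return An object of class `click_train`.
#' @examples
#' click_train(seq(0, 2.3, by = 0.1), subject_id = "S1", medium = "air")
#' @export
click_train <- function(times, volume_per_click = uL_to_m3(10),
                        subject_id = "unknown", medium = c("air", "tissue")) {
  medium <- match.arg(medium)
  times <- as.numeric(times)
  if (any(!is.finite(times)))
    pp_stop("invalid_input", "click times must be finite")
  if (length(times) >= 2 && any(diff(times) <= 0))
    pp_stop("invalid_input", "click times must be strictly increasing")
  if (!is.numeric(volume_per_click) || length(volume_per_click) != 1 ||
      volume_per_click <= 0)
    pp_stop("invalid_input", "volume_per_click must be a positive scalar")
  structure(
    list(times = times, volume_per_click = volume_per_click,
         subject_id = as.character(subject_id), medium = medium),
    class = "click_train"
  )
}

#' @export
print.click_train <- function(x, ...) {
  cat(sprintf("<click_train> %s (%s): %d clicks, %.1f uL/click",
              x$subject_id, x$medium, length(x$times),
              m3_to_uL(x$volume_per_click)))
  if (length(x$times) >= 2)
    cat(sprintf(", span %.2f..%.2f s", x$times[1], x$times[length(x$times)]))
  cat("\n")
  invisible(x)
}

#' @export
length.click_train <- function(x) length(x$times)

#' Convert a click train to a flow-rate series
#'
#' Each inter-click interval delivers exactly one volume increment, so the
#' flow over interval i is `Q_i = volume_per_click / (t_{i+1} - t_i)`,
#' assigned to the interval midpoint.  Click i marks completion of the i-th
#' increment, so the cumulative delivered volume at the midpoint of
#' interval i is `(i + 1/2) * volume_per_click`.  The device deliberately
#' reduces the spring force near the end of the injection, so the last
#' intervals are excluded by `truncate_tail` (the mechanism itself is not
#' modelled; see [suggest_truncation()] for a diagnostic).
#'
#' @param train a [click_train()].
#' @param truncate_tail number of trailing intervals to drop (default 2).
#' @return A `flow_series`: data frame with columns `t_mid` (s), `Q` (m^3/s),
#'   `V_mid` (m^3), plus attributes `volume_per_click`, `truncated_tail`,
#'   `subject_id`, `medium`.
#' @examples
#' tr <- click_train(c(0, 0.1, 0.2, 0.3))
#' flow_from_clicks(tr, truncate_tail = 0)$Q  # 1e-7 m^3/s = 100 uL/s each
#' @export
flow_from_clicks <- function(train, truncate_tail = 2L) {
  stopifnot(inherits(train, "click_train"))
  truncate_tail <- as.integer(truncate_tail)
  if (truncate_tail < 0)
    pp_stop("invalid_input", "truncate_tail must be >= 0")
  n <- length(train$times)
  if (n < 2L + truncate_tail)
    pp_stop("insufficient_data", sprintf(
      "need at least %d clicks, got %d", 2L + truncate_tail, n))
  dt <- diff(train$times)
  keep <- seq_len(length(dt) - truncate_tail)
  vpc <- train$volume_per_click
  out <- data.frame(
    t_mid = (train$times[keep] + train$times[keep + 1L]) / 2,
    Q = vpc / dt[keep],
    V_mid = (keep + 0.5) * vpc
  )
  structure(out,
            class = c("flow_series", "data.frame"),
            volume_per_click = vpc,
            truncated_tail = truncate_tail,
            subject_id = train$subject_id,
            medium = train$medium)
}

#' Flag a suspicious end-of-injection flow drop
#'
#' The pen's end-of-injection mechanism shows up as a sudden slow-down of
#' the final clicks.  This diagnostic reports how many trailing intervals
#' sit after a flow drop larger than `drop_frac` between consecutive
#' intervals; it only suggests a truncation, it never applies one.
#'
#' @param train a [click_train()].
#' @param drop_frac relative flow drop that triggers the flag (default 0.3).
#' @return integer, suggested number of trailing intervals to truncate
#'   (0 if no drop is found).
#' @export
suggest_truncation <- function(train, drop_frac = 0.3) {
  stopifnot(inherits(train, "click_train"))
  if (length(train$times) < 3) return(0L)
  Q <- train$volume_per_click / diff(train$times)
  m <- length(Q)
  rel <- (Q[-m] - Q[-1]) / Q[-m]
  # look in the final third of the injection only
  from <- max(1L, ceiling(2 * m / 3))
  hits <- which(rel >= drop_frac)
  hits <- hits[hits >= from]
  if (length(hits) == 0) 0L else as.integer(m - min(hits))
}

#' Perturb click times with Gaussian jitter
#'
#' Models microphone/detection timing error.  Times are re-sorted after
#' jittering so the result is still a valid train.
#'
#' @param train a [click_train()].
#' @param sd jitter standard deviation in seconds.
#' @return a jittered [click_train()].
#' @export
jitter_click_train <- function(train, sd) {
  stopifnot(inherits(train, "click_train"))
  if (sd <= 0) return(train)
  t2 <- sort(train$times + rnorm(length(train$times), sd = sd))
  # enforce strict monotonicity against rare coincident draws
  eps <- 1e-9
  t2 <- t2 + cumsum(c(0, as.numeric(diff(t2) <= 0))) * eps
  click_train(t2, train$volume_per_click, train$subject_id, train$medium)
}

#' Read and write click tables
#'
#' Click tables are plain CSV with columns `subject_id`, `medium`
#' (`air`/`tissue`), `click_index`, `time_s`.  Rows are sorted by time and
#' re-indexed on read; an unknown medium label is a format error.
#'
#' @param path file path.
#' @param volume_per_click volume increment in m^3 (a device constant, not
#'   stored in the table).
#' @return `read_click_table()` returns a [click_train()];
#'   `write_click_table()` returns `path` invisibly.
#' @examples
#' # synthetic example recordings shipped with the package
#' path <- system.file("extdata", "example_air_clicks_synthetic.csv",
#'                     package = "penpress")
#' flow_from_clicks(read_click_table(path), truncate_tail = 0)
#' @export
read_click_table <- function(path, volume_per_click = uL_to_m3(10)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "medium", "click_index", "time_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    pp_stop("format_error", paste("missing column(s):",
                                  paste(miss, collapse = ", ")))
  med <- unique(df$medium)
  if (length(med) != 1 || !med %in% c("air", "tissue"))
    pp_stop("format_error", paste("medium must be one of 'air','tissue', got:",
                                  paste(med, collapse = ", ")))
  df <- df[order(df$time_s), , drop = FALSE]
  click_train(df$time_s, volume_per_click,
              subject_id = unique(df$subject_id)[1], medium = med)
}

#' @rdname read_click_table
#' @param train a [click_train()].
#' @export
write_click_table <- function(train, path) {
  stopifnot(inherits(train, "click_train"))
  df <- data.frame(
    subject_id = train$subject_id,
    medium = train$medium,
    click_index = seq_along(train$times),
    time_s = train$times
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a flow series as CSV
#'
#' Columns: `subject_id`, `medium`, `t_mid_s`, `Q_uL_per_s`, `V_mid_uL`.
#'
#' @param flow a `flow_series` from [flow_from_clicks()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_flow_table <- function(flow, path) {
  stopifnot(inherits(flow, "flow_series"))
  df <- data.frame(
    subject_id = attr(flow, "subject_id"),
    medium = attr(flow, "medium"),
    t_mid_s = flow$t_mid,
    Q_uL_per_s = m3_to_uL(flow$Q),
    V_mid_uL = m3_to_uL(flow$V_mid)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Internal: rebuild a flow_series from bare vectors (SI units).
as_flow_series <- function(t_mid, Q, V_mid, volume_per_click,
                           subject_id = "unknown", medium = "air",
                           truncated_tail = 0L) {
  structure(data.frame(t_mid = t_mid, Q = Q, V_mid = V_mid),
            class = c("flow_series", "data.frame"),
            volume_per_click = volume_per_click,
            truncated_tail = truncated_tail,
            subject_id = subject_id, medium = medium)
}
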
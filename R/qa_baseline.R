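#' @title Longitudinal QA baselines and pass/warn/fail decisions
#' @description
#' A baseline is the set of previous *accepted* measurements of one metric
#' for one coil set and series condition.  A new value warns when it
#' diverges more than 2 sample SDs (or 5% of the baseline mean) and fails
#' beyond 3 SDs (or 10%); the percent criterion is the default for short
#' baselines.  Measurements are stored append-only as one CSV per
#' coil/condition with a JSON index, and failed measurements are kept but
#' flagged not-accepted so they never pollute later baselines.
#' @name qa-baseline
NULL

#' Open (or create) a QA baseline store
#' @param dir directory holding the store (created if missing).
#' @return a `qa_store` object.
#' @export
qa_store <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  structure(list(path = normalizePath(dir)), class = "qa_store")
}

.series_file <- function(store, coil_id, condition) {
  safe <- function(x) gsub("[^A-Za-z0-9._+-]+", "-", x)
  file.path(store$path, paste0(safe(coil_id), "__", safe(condition), ".csv"))
}

.empty_history <- function() {
  data.frame(date = character(0), key = character(0),
             value = numeric(0), accepted = logical(0))
}

#' Read the measurement history of one coil/condition series
#' @param store a [qa_store()].
#' @param coil_id coil identifier (type + serial numbers, e.g.
#'   `"torso:B1142_T1141"`).
#' @param condition series condition (`"unfiltered"`, `"prescan"`, `"sos"`,
#'   `"elements"`, ...).
#' @param accepted_only drop entries flagged not-accepted.
#' @return data.frame with columns `date`, `key`, `value`, `accepted`.
#' @export
qa_history <- function(store, coil_id, condition, accepted_only = FALSE) {
  f <- .series_file(store, coil_id, condition)
  if (!file.exists(f)) return(.empty_history())
  h <- utils::read.csv(f, stringsAsFactors = FALSE,
                       colClasses = c(date = "character", key = "character",
                                      value = "numeric",
                                      accepted = "logical"))
  if (accepted_only) h <- h[h$accepted, , drop = FALSE]
  h
}

#' Append a dated measurement to the store
#' @inheritParams qa_history
#' @param date measurement date (text, e.g. `"2021-05-27"`); must be new
#'   within the series.
#' @param values named numeric vector, one entry per metric key (e.g.
#'   `"snr@+110"`, `"piu@-30"`, `"peak_snr@VAS1"`).
#' @param accepted whether the measurement may enter future baselines.
#' @return the store, invisibly.
#' @export
qa_append <- function(store, coil_id, condition, date, values,
                      accepted = TRUE) {
  stopifnot(inherits(store, "qa_store"), length(values) >= 1,
            !is.null(names(values)))
  h <- qa_history(store, coil_id, condition)
  if (date %in% h$date)
    stop("date ", date, " already recorded for ", coil_id, " / ", condition)
  add <- data.frame(date = date, key = names(values),
                    value = as.numeric(values), accepted = accepted)
  utils::write.csv(rbind(h, add), .series_file(store, coil_id, condition),
                   row.names = FALSE)
  .update_index(store)
  invisible(store)
}

.update_index <- function(store) {
  files <- list.files(store$path, pattern = "__.*\\.csv$")
  entries <- lapply(files, function(f) {
    parts <- strsplit(sub("\\.csv$", "", f), "__", fixed = TRUE)[[1]]
    h <- utils::read.csv(file.path(store$path, f), stringsAsFactors = FALSE)
    list(file = f, coil_id = parts[1], condition = parts[2],
         dates = sort(unique(h$date)), n_accepted_dates =
           length(unique(h$date[h$accepted])))
  })
  jsonlite::write_json(entries, file.path(store$path, "index.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(store)
}

#' Pass/warn/fail decision for one value against a baseline
#'
#' Criteria: `"sd"` warns when |x - mean| > 2 sample SDs and fails beyond
#' 3 (two-sided); `"percent"` warns beyond 5% of the baseline mean and
#' fails beyond 10%; `"auto"` selects percent for baselines shorter than
#' `auto_n` values and sd otherwise.  With an insufficient baseline
#' (< 2 values for sd, < 1 for percent) the status is `"not-evaluable"`,
#' distinct from a pass.
#'
#' @param current_value new measurement.
#' @param baseline_values numeric vector of previous accepted values.
#' @param criterion `"auto"`, `"sd"` or `"percent"`.
#' @param warn_sd,fail_sd sd-criterion thresholds (in SDs).
#' @param warn_pct,fail_pct percent-criterion thresholds (% of mean).
#' @param auto_n baseline length below which `"auto"` picks percent.
#' @return a `qa_decision` list: `status` (`"pass"`, `"warn"`, `"fail"`,
#'   `"not-evaluable"`), `criterion`, `deviation` (signed, in SD units or
#'   percent of mean), `baseline_n`, `baseline_mean`, `baseline_sd`.
#' @export
qa_decide <- function(current_value, baseline_values,
                      criterion = c("auto", "sd", "percent"),
                      warn_sd = 2, fail_sd = 3, warn_pct = 5, fail_pct = 10,
                      auto_n = 10) {
  criterion <- match.arg(criterion)
  b <- baseline_values[is.finite(baseline_values)]
  n <- length(b)
  if (criterion == "auto") criterion <- if (n < auto_n) "percent" else "sd"
  mk <- function(status, dev, bm, bs) {
    structure(list(status = status, criterion = criterion, deviation = dev,
                   baseline_n = n, baseline_mean = bm, baseline_sd = bs),
              class = "qa_decision")
  }
  if ((criterion == "sd" && n < 2) || (criterion == "percent" && n < 1))
    return(mk("not-evaluable", NA_real_, NA_real_, NA_real_))
  mu <- mean(b)
  if (criterion == "sd") {
    s <- stats::sd(b)
    if (s == 0) {
      dev <- if (current_value == mu) 0 else Inf * sign(current_value - mu)
    } else dev <- (current_value - mu) / s
    status <- if (abs(dev) > fail_sd) "fail"
              else if (abs(dev) > warn_sd) "warn" else "pass"
    return(mk(status, dev, mu, s))
  }
  if (mu == 0) return(mk("not-evaluable", NA_real_, mu, NA_real_))
  dev <- 100 * (current_value - mu) / abs(mu)
  status <- if (abs(dev) > fail_pct) "fail"
            else if (abs(dev) > warn_pct) "warn" else "pass"
  mk(status, dev, mu, if (n >= 2) stats::sd(b) else NA_real_)
}

# named metric vectors for the store -----------------------------------------

#' Flatten combined-series metrics to baseline keys
#' @param metrics a `slice_metrics` data.frame.
#' @return named numeric vector with keys `snr@<loc>` and `piu@<loc>`.
#' @export
combined_baseline_values <- function(metrics) {
  loc <- sprintf("%+g", metrics$slice_location)
  stats::setNames(c(metrics$snr, metrics$piu),
                  c(paste0("snr@", loc), paste0("piu@", loc)))
}

#' Flatten element summaries to baseline keys
#' @param summary an `element_summary` data.frame.
#' @return named numeric vector with keys `peak_snr@<element>`.
#' @export
element_baseline_values <- function(summary) {
  stats::setNames(summary$peak_snr_mean,
                  paste0("peak_snr@", summary$element))
}

#' Evaluate a new measurement against its stored baseline
#'
#' Applies [qa_decide()] to every metric key, derives an overall verdict,
#' and (optionally) appends the measurement to the store — flagged
#' not-accepted when the overall verdict is a fail, so failed runs never
#' enter later baselines.
#'
#' Overall rule (documented configuration, not a published prescription):
#' for element conditions any failing element fails the measurement; for
#' combined conditions a metric with more than half of its slices failing
#' fails the measurement, any other warn/fail yields a warning; otherwise
#' the worst per-metric status is reported.
#'
#' @param values named numeric vector (see [combined_baseline_values()] /
#'   [element_baseline_values()]).
#' @param store a [qa_store()].
#' @inheritParams qa_history
#' @param date measurement date; required when `record = TRUE`.
#' @param criteria `"auto"`, `"sd"` or `"percent"`.
#' @param record append the measurement to the store.
#' @param accept explicit acceptance override; default accepts unless the
#'   overall verdict is `"fail"`.
#' @param ... passed to [qa_decide()] (thresholds, `auto_n`).
#' @return list: `decisions` (data.frame: key, value, status, criterion,
#'   deviation, baseline_n), `summary` (status counts), `overall`.
#' @export
evaluate_measurement <- function(values, store, coil_id, condition,
                                 date = NULL, criteria = "auto",
                                 record = FALSE, accept = NULL, ...) {
  stopifnot(length(values) >= 1, !is.null(names(values)))
  hist <- qa_history(store, coil_id, condition, accepted_only = TRUE)
  decisions <- do.call(rbind, lapply(names(values), function(k) {
    d <- qa_decide(values[[k]], hist$value[hist$key == k],
                   criterion = criteria, ...)
    data.frame(key = k, value = values[[k]], status = d$status,
               criterion = d$criterion, deviation = d$deviation,
               baseline_n = d$baseline_n)
  }))
  overall <- .overall_status(decisions)
  if (record) {
    if (is.null(date)) stop("date is required to record a measurement")
    if (is.null(accept)) accept <- overall != "fail"
    qa_append(store, coil_id, condition, date, values, accepted = accept)
  }
  counts <- table(factor(decisions$status,
                         levels = c("pass", "warn", "fail",
                                    "not-evaluable")))
  list(decisions = decisions, summary = as.list(counts), overall = overall)
}

.overall_status <- function(decisions) {
  st <- decisions$status
  evaluable <- st != "not-evaluable"
  if (!any(evaluable)) return("not-evaluable")
  st <- st[evaluable]
  key <- decisions$key[evaluable]
  metric <- sub("@.*$", "", key)
  slicewise <- grepl("@[+-]?[0-9.]+$", key)  # per-slice combined metrics
  if (any(st == "fail" & !slicewise)) return("fail")
  for (m in unique(metric[slicewise])) {
    sel <- slicewise & metric == m
    if (mean(st[sel] == "fail") > 0.5) return("fail")
  }
  if (any(st %in% c("fail", "warn"))) return("warn")
  "pass"
}

#' Compare a candidate coil against a reference coil's history
#'
#' Per metric key, the candidate value minus the minimum past accepted
#' value of the reference coil; negative margins are flagged (a value equal
#' to the reference minimum passes).
#'
#' @param values named numeric vector for the candidate coil.
#' @param store a [qa_store()].
#' @param reference_coil_id coil whose accepted history provides the
#'   reference minima; must be of the same coil type (identical prefix
#'   before `":"`) as `candidate_coil_id`.
#' @param candidate_coil_id candidate coil identifier.
#' @param condition series condition (must match the reference series).
#' @return data.frame: `key`, `value`, `reference_min`, `margin`,
#'   `flagged`.
#' @export
compare_coils <- function(values, store, reference_coil_id,
                          candidate_coil_id, condition) {
  type_of <- function(x) sub(":.*$", "", x)
  if (type_of(reference_coil_id) != type_of(candidate_coil_id))
    stop("coil type mismatch: ", candidate_coil_id, " vs ",
         reference_coil_id)
  hist <- qa_history(store, reference_coil_id, condition,
                     accepted_only = TRUE)
  if (nrow(hist) == 0)
    stop("no accepted reference history for ", reference_coil_id, " / ",
         condition)
  out <- do.call(rbind, lapply(names(values), function(k) {
    ref <- hist$value[hist$key == k]
    rmin <- if (length(ref)) min(ref) else NA_real_
    data.frame(key = k, value = values[[k]], reference_min = rmin,
               margin = values[[k]] - rmin, flagged = isTRUE(values[[k]] < rmin))
  }))
  rownames(out) <- NULL
  out
}
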
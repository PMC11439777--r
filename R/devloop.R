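# Development-loop bookkeeping: per-iteration cost records split into four
# components (evaluation and modeling are human hours; rendering and
# training are compute hours), the total-cost objective, and the stopping
# rule "latest achieved quality >= q_min".

#' Per-iteration cost record (hours)
#'
#' @param c_eval evaluation cost: expert hours spent analyzing the previous
#'   iteration and deciding the next changes.
#' @param c_model modeling cost: expert hours improving the generators.
#' @param c_render rendering cost: compute hours for the new dataset.
#' @param c_train training cost: compute hours for retraining.
#' @return a `phyto_cost`.
#' @export
cost_record <- function(c_eval = 0, c_model = 0, c_render = 0, c_train = 0) {
  for (f in c("c_eval", "c_model", "c_render", "c_train"))
    check_range(get(f), f, 0, Inf)
  structure(list(c_eval = c_eval, c_model = c_model,
                 c_render = c_render, c_train = c_train),
            class = "phyto_cost")
}

#' One development-iteration record
#'
#' @param k iteration index (>= 1; must increase within a ledger).
#' @param cost a [cost_record()].
#' @param achieved_q evaluation-set quality reached, fraction in `[0, 1]`.
#' @param preset dataset preset name used in this iteration.
#' @param hyperparameters optional [hyperparameters()] object; stored as a
#'   digest.
#' @return a `phyto_iteration`.
#' @export
iteration_record <- function(k, cost, achieved_q, preset = "",
                             hyperparameters = NULL) {
  check_range(k, "k", 1, Inf, integer = TRUE)
  check_range(achieved_q, "achieved_q", 0, 1)
  if (!inherits(cost, "phyto_cost")) stop_validation("cost must be a cost_record()")
  structure(list(k = as.integer(k), cost = cost, achieved_q = achieved_q,
                 preset = preset,
                 h_digest = if (is.null(hyperparameters)) ""
                            else digest::digest(hyperparameters)),
            class = "phyto_iteration")
}

#' Development ledger
#'
#' @param q_min target quality in `(0, 1]` that terminates development
#'   (default 0.9).
#' @param records optional list of [iteration_record()]s, k strictly
#'   increasing.
#' @return a `phyto_ledger`.
#' @export
dev_ledger <- function(q_min = 0.9, records = list()) {
  check_range(q_min, "q_min", 0, 1, lo_open = TRUE)
  led <- structure(list(q_min = q_min, records = list()),
                   class = "phyto_ledger")
  for (r in records) led <- add_iteration(led, r)
  led
}

#' Append an iteration record to a ledger
#'
#' @param ledger a [dev_ledger()].
#' @param record an [iteration_record()] with `k` greater than the last one.
#' @return the updated ledger.
#' @export
add_iteration <- function(ledger, record) {
  if (!inherits(record, "phyto_iteration"))
    stop_validation("record must be an iteration_record()")
  n <- length(ledger$records)
  if (n > 0 && record$k <= ledger$records[[n]]$k)
    stop_validation(sprintf("iteration k = %d does not increase on %d",
                            record$k, ledger$records[[n]]$k))
  ledger$records[[n + 1]] <- record
  ledger
}

#' Total cost of one iteration: exact sum of the four components
#'
#' @param record an [iteration_record()] or bare [cost_record()].
#' @return hours.
#' @export
iteration_cost <- function(record) {
  cost <- if (inherits(record, "phyto_iteration")) record$cost else record
  cost$c_eval + cost$c_model + cost$c_render + cost$c_train
}

#' Total cost over all ledger iterations
#'
#' @param ledger a non-empty [dev_ledger()].
#' @return hours.
#' @export
total_cost <- function(ledger) {
  if (length(ledger$records) == 0) stop_validation("ledger is empty")
  sum(vapply(ledger$records, iteration_cost, 1.0))
}

#' Human/compute cost split
#'
#' Human share = evaluation + modeling hours; compute share = rendering +
#' training hours. The two shares sum exactly to [total_cost()].
#'
#' @param ledger a non-empty [dev_ledger()].
#' @return named numeric vector `c(human =, compute =)`.
#' @export
human_compute_split <- function(ledger) {
  if (length(ledger$records) == 0) stop_validation("ledger is empty")
  human <- sum(vapply(ledger$records,
                      function(r) r$cost$c_eval + r$cost$c_model, 1.0))
  compute <- sum(vapply(ledger$records,
                        function(r) r$cost$c_render + r$cost$c_train, 1.0))
  c(human = human, compute = compute)
}

#' Stopping rule: has the latest iteration reached the target quality?
#'
#' @param ledger a non-empty [dev_ledger()].
#' @return `TRUE` iff the latest `achieved_q >= q_min` (boundary inclusive;
#'   the comparison is strict on the stored values, no rounding).
#' @export
stop_rule_met <- function(ledger) {
  if (length(ledger$records) == 0) stop_validation("ledger is empty")
  ledger$records[[length(ledger$records)]]$achieved_q >= ledger$q_min
}

#' Write per-iteration cost/quality report files
#'
#' @param ledger a non-empty [dev_ledger()].
#' @param out_dir output directory; writes `iterations.csv` (absolute and
#'   relative cost components plus achieved quality per iteration) and
#'   `summary.json` (totals, human/compute split, stop status).
#' @return paths of the written files, invisibly.
#' @export
summary_report <- function(ledger, out_dir) {
  if (length(ledger$records) == 0) stop_validation("ledger is empty")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_io(sprintf("cannot create %s", out_dir))
  rows <- lapply(ledger$records, function(r) {
    tot <- iteration_cost(r)
    data.frame(k = r$k, preset = r$preset,
               c_eval = r$cost$c_eval, c_model = r$cost$c_model,
               c_render = r$cost$c_render, c_train = r$cost$c_train,
               cost_total = tot,
               rel_eval = r$cost$c_eval / tot, rel_model = r$cost$c_model / tot,
               rel_render = r$cost$c_render / tot,
               rel_train = r$cost$c_train / tot,
               achieved_q = r$achieved_q)
  })
  df <- do.call(rbind, rows)
  csv <- file.path(out_dir, "iterations.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  split <- human_compute_split(ledger)
  js <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(
    q_min = ledger$q_min, n_iterations = length(ledger$records),
    total_cost = total_cost(ledger),
    human_cost = unname(split["human"]), compute_cost = unname(split["compute"]),
    stop = stop_rule_met(ledger),
    final_q = ledger$records[[length(ledger$records)]]$achieved_q
  ), js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}

#' Persist a ledger as JSON
#' @param ledger a [dev_ledger()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  jsonlite::write_json(list(
    q_min = ledger$q_min,
    records = lapply(ledger$records, function(r)
      list(k = r$k, preset = r$preset, h_digest = r$h_digest,
           achieved_q = r$achieved_q, cost = unclass(r$cost)))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a ledger from JSON
#' @param path JSON path written by [write_ledger()].
#' @return a [dev_ledger()].
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no ledger at %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  dev_ledger(
    q_min = raw$q_min,
    records = lapply(raw$records, function(r)
      iteration_record(r$k, do.call(cost_record, r$cost), r$achieved_q,
                       preset = r$preset %||% ""))
  )
}
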
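#' RACE chip layout
#'
#' Well layout of a Raman-activated cell ejection chip. A 12-well chip
#' reserves at least two control wells: one negative control that must
#' remain cell-free throughout, and one positive control that receives a
#' bulk cell suspension before amplification. Control wells are allocated
#' first and are never ejection destinations for sorted cells.
#'
#' @param n_wells Number of wells (default 12).
#' @param n_negative,n_positive Reserved control wells (each >= 1).
#' @return An object of class `scrs_chip_layout` with `wells`, `controls`
#'   (data frame well/role) and `target_wells`.
#' @export
chip_layout <- function(n_wells = 12, n_negative = 1, n_positive = 1) {
  n_wells <- as.integer(n_wells)
  if (n_wells < n_negative + n_positive + 1)
    stop("chip needs at least one non-control well", call. = FALSE)
  if (n_negative < 1 || n_positive < 1)
    stop("at least one negative and one positive control well are required",
         call. = FALSE)
  wells <- sprintf("W%02d", seq_len(n_wells))
  controls <- data.frame(
    well = wells[seq_len(n_negative + n_positive)],
    role = c(rep("negative_control", n_negative),
             rep("positive_control", n_positive)),
    stringsAsFactors = FALSE)
  structure(list(n_wells = n_wells, wells = wells, controls = controls,
                 target_wells = setdiff(wells, controls$well)),
            class = "scrs_chip_layout")
}

#' Build a sort plan from phenotype calls
#'
#' Selects target cells by a query over the call table, orders them by
#' ascending `cell_id`, and assigns them to non-control wells. With a
#' scalar `cells_per_well` (maximum occupancy, 1--8) cells are dealt
#' round-robin over the minimum number of wells that respects the
#' occupancy; with a vector, well k receives exactly `cells_per_well[k]`
#' cells in order, so multi-cell wells (e.g. 1/1/1/3/5/8/8) can be
#' composed explicitly. Plan building is a pure function of its inputs.
#'
#' @param calls An `scrs_calls` object or its `calls` data frame (must
#'   carry `x`/`y` coordinates).
#' @param query Either a one-argument function on the call table returning
#'   a logical vector, or a character expression evaluated in it, e.g.
#'   `"label == 'carotenoid'"`.
#' @param layout A [chip_layout()].
#' @param cells_per_well Scalar maximum cells per well, or an explicit
#'   per-well count vector; all values must lie in 1--8.
#' @return An object of class `scrs_sort_plan` with `targets` (cell_id, x,
#'   y, well), `controls`, `layout`, `query`.
#' @export
build_sort_plan <- function(calls, query = "label == 'carotenoid'",
                            layout = chip_layout(), cells_per_well = 1) {
  df <- if (inherits(calls, "scrs_calls")) calls$calls else calls
  stopifnot(inherits(layout, "scrs_chip_layout"))
  cpw <- as.integer(cells_per_well)
  if (any(is.na(cpw)) || any(cpw < 1) || any(cpw > 8))
    stop("config error: cells_per_well must lie in [1, 8]", call. = FALSE)
  sel <- if (is.function(query)) query(df)
         else eval(parse(text = query), df, baseenv())
  sel[is.na(sel)] <- FALSE
  targets <- df[sel, , drop = FALSE]
  targets <- targets[order(targets$cell_id), , drop = FALSE]
  avail <- layout$target_wells
  if (length(cpw) > 1) {
    if (length(cpw) > length(avail))
      stop(sprintf("capacity error: plan needs %d wells but only %d non-control wells are available (short %d)",
                   length(cpw), length(avail), length(cpw) - length(avail)),
           call. = FALSE)
    take <- min(nrow(targets), sum(cpw))
    targets <- targets[seq_len(take), , drop = FALSE]
    well <- rep(avail[seq_along(cpw)], cpw)[seq_len(take)]
  } else if (nrow(targets) == 0) {
    well <- character()
  } else {
    wells_needed <- ceiling(nrow(targets) / cpw)
    if (wells_needed > length(avail))
      stop(sprintf("capacity error: %d cells need %d wells at <=%d cells/well but only %d non-control wells are available (short %d)",
                   nrow(targets), wells_needed, cpw, length(avail),
                   wells_needed - length(avail)), call. = FALSE)
    well <- avail[(seq_len(nrow(targets)) - 1) %% wells_needed + 1]
  }
  plan_targets <- data.frame(cell_id = targets$cell_id,
                             x = targets$x, y = targets$y, well = well,
                             stringsAsFactors = FALSE)
  rownames(plan_targets) <- NULL
  structure(list(targets = plan_targets, controls = layout$controls,
                 layout = layout,
                 query = if (is.function(query)) "<function>" else query,
                 cells_per_well = cpw),
            class = "scrs_sort_plan")
}

#' @export
print.scrs_sort_plan <- function(x, ...) {
  cat(sprintf("<scrs_sort_plan> %d target cell(s) in %d well(s); query: %s\n",
              nrow(x$targets), length(unique(x$targets$well)), x$query))
  print(x$controls, row.names = FALSE)
  invisible(x)
}

#' Simulate a RACE ejection session
#'
#' Walks the sort plan in order and simulates one laser ejection per target
#' cell. Ejection timestamps are spaced by the per-cell acquisition time
#' (default 5 s); each outcome is an independent Bernoulli draw with
#' `success_prob` (default 1; the published ejection + whole-genome-
#' amplification success rate of 7/30 can be plugged in here). Control
#' wells receive no ejections; in particular the negative-control well
#' stays cell-free.
#'
#' @param plan An `scrs_sort_plan`.
#' @param seed Integer seed for the outcome draws.
#' @param success_prob Per-ejection success probability in `[0, 1]`.
#' @param acquisition_time Seconds between consecutive ejections
#'   (default 5).
#' @return An object of class `scrs_sort_manifest`: `records` (cell_id,
#'   well, x, y, t_offset, outcome), `well_counts` (collected cells per
#'   well, zero for controls) and session `totals`.
#' @export
simulate_session <- function(plan, seed = 1, success_prob = 1,
                             acquisition_time = 5) {
  stopifnot(inherits(plan, "scrs_sort_plan"))
  if (!is.finite(success_prob) || success_prob < 0 || success_prob > 1)
    stop("`success_prob` must lie in [0, 1]", call. = FALSE)
  n <- nrow(plan$targets)
  outcome <- character(0)
  if (n > 0)
    outcome <- with_seed(seed, ifelse(stats::runif(n) < success_prob,
                                      "collected", "failed"))
  records <- data.frame(cell_id = plan$targets$cell_id,
                        well = plan$targets$well,
                        x = plan$targets$x, y = plan$targets$y,
                        t_offset = (seq_len(n) - 1) * acquisition_time,
                        outcome = outcome, stringsAsFactors = FALSE)
  wc <- vapply(plan$layout$wells, function(w)
    sum(records$well == w & records$outcome == "collected"), integer(1))
  structure(list(records = records, well_counts = wc,
                 totals = c(attempted = n,
                            collected = sum(outcome == "collected"),
                            failed = sum(outcome == "failed")),
                 seed = seed, success_prob = success_prob,
                 acquisition_time = acquisition_time, plan = plan),
            class = "scrs_sort_manifest")
}

#' @export
print.scrs_sort_manifest <- function(x, ...) {
  cat(sprintf("<scrs_sort_manifest> %d attempted, %d collected, %d failed (p = %g)\n",
              x$totals["attempted"], x$totals["collected"], x$totals["failed"],
              x$success_prob))
  invisible(x)
}

#' Write a sort manifest as tab-delimited text
#' @param manifest An `scrs_sort_manifest`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_manifest_tsv <- function(manifest, path) {
  stopifnot(inherits(manifest, "scrs_sort_manifest"))
  utils::write.table(manifest$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
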
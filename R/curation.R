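#' Energy-window curation configuration
#'
#' Conformers more than `threshold_kcal` above the lowest-energy conformer
#' of the same molecule are moved to the high-energy partition; the default
#' window is 275 kcal/mol. The boundary is inclusive by default: a conformer
#' exactly at the threshold stays in the low-energy set (only energies
#' strictly greater are removed).
#'
#' @param threshold_kcal Window width, kcal/mol (converted to Hartree
#'   internally).
#' @param inclusive_boundary If `TRUE` (default) `E - E_min == threshold`
#'   is classified low.
#' @param include_equilibrium If `TRUE` (default) the equilibrium structure's
#'   energy participates in the minimum-energy reference.
#' @param constants Physical constants (for the unit conversion).
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(threshold_kcal = 275, inclusive_boundary = TRUE,
                            include_equilibrium = TRUE,
                            constants = physical_constants()) {
  stopifnot(threshold_kcal > 0)
  structure(list(threshold_kcal = threshold_kcal,
                 threshold_ha = threshold_kcal / constants$hartree_to_kcalmol,
                 inclusive_boundary = isTRUE(inclusive_boundary),
                 include_equilibrium = isTRUE(include_equilibrium)),
            class = "curation_config")
}

#' Split a conformer set at the energy window
#'
#' Partitions the `ok` conformers of a set into a low-energy and a
#' high-energy subset relative to the minimum energy over the set (by
#' default including the equilibrium structure, which is itself a conformer
#' of the set). Failed conformers belong to neither partition. The window is
#' relative, so adding a constant to every energy leaves the split
#' unchanged.
#'
#' @param x A `conformer_set` or an `ani_record`.
#' @param config A [curation_config()].
#' @param ... Method arguments.
#' @return For a `conformer_set`: list with elements `low` and `high`, both
#'   `conformer_set`s, plus `e_min` (Hartree). For an `ani_record`: a new
#'   record with the main/HE arrays repartitioned (see
#'   [energy_window_split.ani_record()]).
#' @export
energy_window_split <- function(x, config = curation_config(), ...) {
  UseMethod("energy_window_split")
}

#' @export
energy_window_split.conformer_set <- function(x, config = curation_config(),
                                              ...) {
  ok <- which(x$status == "ok")
  pool <- x$energies[ok]
  if (config$include_equilibrium) pool <- c(pool, x$equilibrium_energy)
  pool <- pool[is.finite(pool)]
  if (length(pool) == 0L)
    stop("no usable energies in conformer set ", x$molecule$id)
  e_min <- min(pool)
  rel <- x$energies[ok] - e_min
  low_mask <- if (config$inclusive_boundary) rel <= config$threshold_ha
              else rel < config$threshold_ha
  subset_cs <- function(idx) {
    out <- x
    out$coordinates <- x$coordinates[idx, , , drop = FALSE]
    out$energies <- x$energies[idx]
    out$status <- x$status[idx]
    out$weight_sums <- x$weight_sums[idx]
    out$temperatures <- x$temperatures[idx]
    out
  }
  list(low = subset_cs(ok[low_mask]), high = subset_cs(ok[!low_mask]),
       e_min = e_min)
}

#' Dataset summary table
#'
#' Builds the per-size bookkeeping table of a curated dataset: one row per
#' heavy-atom count with molecule count, schedule parameters, low-energy and
#' high-energy conformer counts and their total, plus a grand-total row.
#'
#' @param counts A `data.frame` with columns `heavy_atoms`, `molecules`,
#'   `t_max`, `S`, `low`, `high` (one row per size group).
#' @return A `data.frame` of class `nms_summary` with an added `total`
#'   column and a final `Total` row summing `molecules`, `low`, `high` and
#'   `total`.
#' @seealso [summarize_dataset()] to build `counts` from curated conformer
#'   sets.
#' @export
dataset_summary <- function(counts) {
  need <- c("heavy_atoms", "molecules", "t_max", "S", "low", "high")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "))
  counts <- counts[order(counts$heavy_atoms), need, drop = FALSE]
  counts$total <- counts$low + counts$high
  grand <- data.frame(heavy_atoms = NA_integer_,
                      molecules = sum(counts$molecules),
                      t_max = NA_real_, S = NA_integer_,
                      low = sum(counts$low), high = sum(counts$high),
                      total = sum(counts$total))
  out <- rbind(counts, grand)
  rownames(out) <- c(as.character(counts$heavy_atoms), "Total")
  class(out) <- c("nms_summary", "data.frame")
  out
}

#' Summarize curated conformer sets
#'
#' Groups curated sets by heavy-atom count and tabulates low/high conformer
#' counts into the bookkeeping table produced by [dataset_summary()].
#'
#' @param splits List of results of [energy_window_split()] applied to
#'   `conformer_set`s (each a list with `low` and `high`).
#' @param schedule The `nms_schedule` the sets were sampled under (provides
#'   the `S` and `t_max` columns).
#' @return An `nms_summary`.
#' @export
summarize_dataset <- function(splits, schedule = default_schedule()) {
  if (length(splits) == 0L)
    return(dataset_summary(data.frame(heavy_atoms = integer(),
                                      molecules = integer(), t_max = numeric(),
                                      S = integer(), low = integer(),
                                      high = integer())))
  ha <- vapply(splits, function(s) heavy_atom_count(s$low$molecule), 0L)
  lo <- vapply(splits, function(s) length(s$low$energies), 0L)
  hi <- vapply(splits, function(s) length(s$high$energies), 0L)
  sizes <- sort(unique(ha))
  rows <- lapply(sizes, function(h) {
    sched <- schedule_lookup(schedule, h)
    data.frame(heavy_atoms = h, molecules = sum(ha == h),
               t_max = sched$t_max, S = sched$S,
               low = sum(lo[ha == h]), high = sum(hi[ha == h]))
  })
  dataset_summary(do.call(rbind, rows))
}

#' @export
print.nms_summary <- function(x, ...) {
  df <- as.data.frame(x)
  df$heavy_atoms <- ifelse(is.na(df$heavy_atoms), "Total", df$heavy_atoms)
  for (col in c("molecules", "low", "high", "total"))
    df[[col]] <- format(df[[col]], big.mark = ",")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Published bookkeeping rows of the reference dataset
#'
#' The per-size molecule counts, schedule parameters and low/high
#' conformer counts of the published 57k-molecule normal-mode-sampling
#' dataset, as printed in its data descriptor. Shipped so the summary
#' arithmetic (row totals and the grand-total row) can be recomputed and
#' checked against the published grand totals.
#'
#' @return A `data.frame` in the column layout [dataset_summary()] expects.
#' @examples
#' dataset_summary(published_schedule_counts())
#' @export
published_schedule_counts <- function() {
  data.frame(
    heavy_atoms = 1:8,
    molecules = c(3L, 13L, 20L, 61L, 267L, 1406L, 7760L, 47932L),
    t_max = c(2000, 1500, 1000, 600, 600, 600, 600, 450),
    S = c(500L, 450L, 425L, 400L, 200L, 30L, 20L, 5L),
    low  = c(10800L, 50962L, 151200L, 651936L, 1813151L, 1682245L,
             6460162L, 11236918L),
    high = c(0L, 398L, 0L, 6144L, 9889L, 29963L, 869222L, 1714819L)
  )
}

#' Exclusion accounting
#'
#' Bookkeeping for structures dropped from a pipeline stage (failed geometry
#' optimizations or failed single-point energies): retained count and the
#' failure rate as a percentage rounded to two decimals (half-even).
#'
#' @param failures Either a single non-negative count or a vector/list whose
#'   length is the number of failures (e.g. a log of failed ids).
#' @param n_started Number of structures entering the stage.
#' @return List with `n_started`, `n_failed`, `n_retained`,
#'   `failure_rate_percent`.
#' @examples
#' exclusion_report(485, 57947)  # 57462 retained, 0.84 percent
#' @export
exclusion_report <- function(failures, n_started) {
  n_failed <- if (length(failures) == 1L && is.numeric(failures))
    as.integer(failures) else length(failures)
  n_started <- as.integer(n_started)
  if (n_failed < 0L || n_started < 1L) stop("invalid counts")
  if (n_failed > n_started)
    stop("more failures (", n_failed, ") than structures started (",
         n_started, ")")
  list(n_started = n_started, n_failed = n_failed,
       n_retained = n_started - n_failed,
       failure_rate_percent = round(100 * n_failed / n_started, 2L))
}
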
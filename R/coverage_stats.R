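#' Histogram container for coverage statistics
#'
#' All coverage statistics return this container: fixed bin edges, raw
#' per-bin counts, and the base-10 logarithm of the counts normalized over
#' the full domain. Empty bins are `NA` in the log series (omitted, not
#' clamped to a floor).
#'
#' @param values Numeric observations.
#' @param breaks Strictly increasing numeric vector of bin edges.
#' @return An object of class `nms_histogram`: `breaks`, `mids`, `counts`,
#'   `total` (observations tallied inside the edges), `n_out_of_range`,
#'   `log10_norm`.
#' @keywords internal
nms_histogram <- function(values, breaks) {
  breaks <- as.numeric(breaks)
  if (length(breaks) < 2L || is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing")
  values <- values[is.finite(values)]
  inside <- values >= breaks[1L] & values <= breaks[length(breaks)]
  counts <- graphics::hist(values[inside], breaks = breaks, plot = FALSE,
                           right = TRUE, include.lowest = TRUE)$counts
  total <- sum(counts)
  lg <- rep(NA_real_, length(counts))
  if (total > 0L) {
    nz <- counts > 0L
    lg[nz] <- log10(counts[nz] / total)
  }
  structure(list(breaks = breaks,
                 mids = (breaks[-1L] + breaks[-length(breaks)]) / 2,
                 counts = counts, total = total,
                 n_out_of_range = sum(!inside), log10_norm = lg),
            class = "nms_histogram")
}

#' @export
print.nms_histogram <- function(x, ...) {
  occ <- sum(x$counts > 0L)
  cat(sprintf("<histogram: %d observations in %d bins (%d occupied) on [%g, %g]%s>\n",
              x$total, length(x$counts), occ, min(x$breaks), max(x$breaks),
              if (x$n_out_of_range > 0L)
                sprintf(", %d out of range", x$n_out_of_range) else ""))
  invisible(x)
}

#' @export
plot.nms_histogram <- function(x, log = TRUE, xlab = "value",
                               ylab = if (log) "log10 normalized count"
                                      else "count", ...) {
  y <- if (log) x$log10_norm else x$counts
  keep <- !is.na(y)
  graphics::plot(x$mids[keep], y[keep], type = "s", xlab = xlab,
                 ylab = ylab, ...)
  invisible(x)
}

#' Export a histogram as a TSV table
#'
#' Columns `bin_left`, `bin_right`, `count`, `log10_norm`; empty bins keep
#' an empty `log10_norm` field.
#'
#' @param x An `nms_histogram`.
#' @param path Output path (or `""` for stdout).
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(x, path = "") {
  df <- data.frame(bin_left = x$breaks[-length(x$breaks)],
                   bin_right = x$breaks[-1L], count = x$counts,
                   log10_norm = x$log10_norm)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

record_list <- function(records) {
  if (inherits(records, "ani_record")) list(records) else records
}

# distances between the requested element pair in one conformer
conformer_pair_distances <- function(species, coords, pair) {
  a <- which(species == pair[1L])
  b <- which(species == pair[2L])
  if (pair[1L] == pair[2L]) {
    if (length(a) < 2L) return(numeric())
    idx <- utils::combn(a, 2L)
  } else {
    if (length(a) == 0L || length(b) == 0L) return(numeric())
    idx <- rbind(rep(a, each = length(b)), rep(b, times = length(a)))
  }
  sqrt(rowSums((coords[idx[1L, ], , drop = FALSE] -
                  coords[idx[2L, ], , drop = FALSE])^2))
}

#' Pair-distance distribution normalized by a reference bond length
#'
#' Tallies, over every conformer of every record, the distances between all
#' unordered atom pairs of the requested element pair, expressed as `r/r0`
#' with `r0` a reference single-bond equilibrium distance. Pairs can be
#' Bernoulli-subsampled (a production-size dataset is far too dense to
#' tally fully; the reference analysis subsampled at 1%).
#'
#' @param records An `ani_record` or list of them.
#' @param pair Length-2 character vector of element symbols, e.g.
#'   `c("C", "H")` (order irrelevant).
#' @param r0 Reference distance, Angstrom.
#' @param breaks Bin edges on the `r/r0` axis; defaults to 100 bins
#'   spanning the tallied values.
#' @param subsample_rate Bernoulli keep probability in `(0, 1]`.
#' @param seed Integer seed for the subsampling draw.
#' @param include_he If `TRUE` the HE block's conformers are tallied too.
#' @return An `nms_histogram`.
#' @export
pair_distance_histogram <- function(records, pair, r0, breaks = NULL,
                                    subsample_rate = 1, seed = 1L,
                                    include_he = FALSE) {
  stopifnot(length(pair) == 2L, r0 > 0,
            subsample_rate > 0, subsample_rate <= 1)
  records <- record_list(records)
  vals <- numeric()
  for (rec in records) {
    blocks <- list(rec$coordinates)
    if (include_he) blocks <- c(blocks, list(rec$coordinatesHE))
    for (coords in blocks) {
      n <- dim(coords)[1L]
      for (k in seq_len(n))
        vals <- c(vals, conformer_pair_distances(rec$species,
                                                 coords[k, , ], pair))
    }
  }
  if (length(vals) == 0L)
    stop("no ", pair[1L], "-", pair[2L], " pairs in the dataset")
  if (subsample_rate < 1) {
    vals <- with_seed(derive_seed(seed, paste(pair, collapse = "-")),
                      vals[stats::runif(length(vals)) < subsample_rate])
    if (length(vals) == 0L)
      stop("subsampling removed every pair; raise subsample_rate")
  }
  vals <- vals / r0
  if (is.null(breaks))
    breaks <- seq(0, max(vals) * 1.001, length.out = 101L)
  nms_histogram(vals, breaks)
}

# triples (i, j, k) with j central, matching the element triple
conformer_triples <- function(species, triple) {
  ctr <- which(species == triple[2L])
  out <- NULL
  for (j in ctr) {
    a <- setdiff(which(species == triple[1L]), j)
    b <- setdiff(which(species == triple[3L]), j)
    for (i in a) for (k in b) {
      if (i == k) next
      if (triple[1L] == triple[3L] && i > k) next  # unordered ends
      out <- rbind(out, c(i, j, k))
    }
  }
  out
}

internal_angle_deg <- function(coords, i, j, k) {
  u <- coords[i, ] - coords[j, ]
  v <- coords[k, ] - coords[j, ]
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Angle distribution for an element triple
#'
#' Tallies the internal angle (degrees, `[0, 180]`) at the central atom of
#' every matching triple in every conformer. By default only "bonded"
#' triples are counted: both flanking atoms must lie within a distance
#' cutoff of the central atom (`cutoff_factor` times the pair's reference
#' bond length); `mode = "all"` counts every triple.
#'
#' @param records An `ani_record` or list of them.
#' @param triple Length-3 character vector `(end, center, end)`, e.g.
#'   `c("H", "O", "H")`.
#' @param breaks Bin edges in degrees (default 2-degree bins on
#'   `[0, 180]`).
#' @param mode `"bonded"` or `"all"`.
#' @param r0_table Named numeric vector of reference bond lengths keyed by
#'   sorted element pairs (`"H-O"`), required for `mode = "bonded"`.
#' @param cutoff_factor Multiplier on `r0` defining "bonded".
#' @param include_he Tally the HE block too.
#' @return An `nms_histogram`.
#' @export
angle_histogram <- function(records, triple, breaks = seq(0, 180, by = 2),
                            mode = c("bonded", "all"), r0_table = NULL,
                            cutoff_factor = 1.6, include_he = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(triple) == 3L)
  if (mode == "bonded" && is.null(r0_table))
    stop("mode = 'bonded' needs an r0_table of reference bond lengths")
  records <- record_list(records)
  vals <- numeric()
  for (rec in records) {
    trip <- conformer_triples(rec$species, triple)
    if (is.null(trip)) next
    blocks <- list(rec$coordinates)
    if (include_he) blocks <- c(blocks, list(rec$coordinatesHE))
    for (coords in blocks) {
      for (kk in seq_len(dim(coords)[1L])) {
        cf <- coords[kk, , ]
        for (t in seq_len(nrow(trip))) {
          i <- trip[t, 1L]; j <- trip[t, 2L]; k <- trip[t, 3L]
          if (mode == "bonded") {
            cut_ij <- cutoff_factor * pair_r0(r0_table, rec$species[i],
                                              rec$species[j])
            cut_kj <- cutoff_factor * pair_r0(r0_table, rec$species[k],
                                              rec$species[j])
            if (sqrt(sum((cf[i, ] - cf[j, ])^2)) > cut_ij ||
                sqrt(sum((cf[k, ] - cf[j, ])^2)) > cut_kj) next
          }
          vals <- c(vals, internal_angle_deg(cf, i, j, k))
        }
      }
    }
  }
  if (length(vals) == 0L)
    stop("no matching ", paste(triple, collapse = "-"), " triples")
  nms_histogram(vals, breaks)
}

#' Energy-per-electron distribution by molecule size
#'
#' For every conformer, tallies the total energy divided by the molecule's
#' electron count, grouped by heavy-atom count. Each group's histogram is
#' normalized over the full domain, so groups of very different size are
#' comparable (equal unit area).
#'
#' @param records An `ani_record` or list of them.
#' @param table Element table (for electron counts).
#' @param breaks Shared bin edges; defaults to 100 bins spanning all
#'   groups.
#' @param include_he Tally the HE block too.
#' @return Named list of `nms_histogram`s keyed by heavy-atom count
#'   (names like `"gdb03"`).
#' @export
energy_per_electron_distribution <- function(records,
                                             table = element_table(),
                                             breaks = NULL,
                                             include_he = FALSE) {
  records <- record_list(records)
  vals_by_group <- list()
  for (rec in records) {
    mol <- molecule(rec$species, matrix(0, length(rec$species), 3L))
    ne <- electron_count(mol, table)
    key <- sprintf("gdb%02d", heavy_atom_count(mol))
    e <- rec$energies
    if (include_he) e <- c(e, rec$energiesHE)
    vals_by_group[[key]] <- c(vals_by_group[[key]], e / ne)
  }
  if (length(vals_by_group) == 0L) stop("no records")
  if (is.null(breaks)) {
    all_vals <- unlist(vals_by_group)
    breaks <- seq(min(all_vals) - 1e-9, max(all_vals) + 1e-9,
                  length.out = 101L)
  }
  lapply(vals_by_group[order(names(vals_by_group))], nms_histogram,
         breaks = breaks)
}

#' Atomization-energy distribution
#'
#' Tallies `E_total - sum of atomic reference energies` per conformer. The
#' returned histogram carries the maximum tallied value in `max_value`, the
#' quantity that must stay at or below 0 Hartree for a curated low-energy
#' set built from bound conformers.
#'
#' @param records An `ani_record` or list of them.
#' @param table Named atomic-energy vector (Hartree), see
#'   [read_atomic_energy_table()].
#' @param breaks Bin edges; default 100 bins spanning the values.
#' @param include_he Tally the HE block too.
#' @return An `nms_histogram` with extra field `max_value`.
#' @export
atomization_energy_distribution <- function(records, table, breaks = NULL,
                                            include_he = FALSE) {
  records <- record_list(records)
  vals <- numeric()
  for (rec in records) {
    e <- rec$energies
    if (include_he) e <- c(e, rec$energiesHE)
    if (length(e) > 0L)
      vals <- c(vals, atomization_energy(e, rec$species, table))
  }
  if (length(vals) == 0L) stop("no conformers to tally")
  if (is.null(breaks))
    breaks <- seq(min(vals) - 1e-9, max(vals) + 1e-9, length.out = 101L)
  h <- nms_histogram(vals, breaks)
  h$max_value <- max(vals)
  h
}

#' Occupied support of a histogram
#'
#' Indices of bins with nonzero counts; used to compare the conformational
#' coverage of two datasets tallied on the same edges.
#'
#' @param x An `nms_histogram`.
#' @return Integer vector of occupied bin indices.
#' @export
histogram_support <- function(x) which(x$counts > 0L)
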
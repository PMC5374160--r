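#' Default mechanism settings of the factorial design
#'
#' The positive effect, the negative effect, and the mixed effect at
#' `alpha = 0, 0.1, ..., 1` (eleven values; the endpoints deliberately
#' duplicate the pure mechanisms, matching the design arithmetic
#' `9 x 8 x (1 + 1 + 11) x 50 = 46,800`).
#'
#' @return a list of [mechanism()] objects (length 13).
#' @export
default_mechanisms <- function() {
  c(list(mechanism("positive"), mechanism("negative")),
    lapply(seq(0, 1, by = 0.1), function(a) mechanism("mixed", alpha = a)))
}

#' Factorial sweep specification
#'
#' Describes the full simulation design: culture-A counts (`ratios`), alter
#' tie counts, mechanism settings, replicates per cell, the per-run
#' [sim_config()], and a base seed from which every run derives its own
#' stream via [derive_seed()]. The defaults reproduce the model's stated
#' design: 8 alters, ratios 0:8..8:0, tie counts 0, 4, ..., 28, the 13
#' default mechanism settings, and 50 replicates -- 936 cells and 46,800
#' simulated outcome pairs.
#'
#' @param n_alters roster size (default 8).
#' @param ratios integer vector of culture-A counts, each in `[0, n_alters]`.
#' @param tie_counts integer vector, each in `[0, n_alters(n_alters-1)/2]`.
#' @param mechanisms list of [mechanism()] objects.
#' @param replicates positive integer runs per cell.
#' @param config a [sim_config()].
#' @param base_seed integer base seed.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_alters = 8L, ratios = 0:8,
                      tie_counts = seq(0L, 28L, by = 4L),
                      mechanisms = default_mechanisms(),
                      replicates = 50L, config = sim_config(),
                      base_seed = 20260909L) {
  n_alters <- as.integer(n_alters)
  stopifnot(inherits(config, "sim_config"))
  if (length(ratios) == 0L || length(tie_counts) == 0L ||
      length(mechanisms) == 0L) {
    stop("ratios, tie_counts and mechanisms must be non-empty", call. = FALSE)
  }
  if (any(ratios < 0 | ratios > n_alters)) {
    stop(sprintf("ratios must lie in [0, %d]", n_alters), call. = FALSE)
  }
  max_ties <- n_alters * (n_alters - 1L) / 2L
  if (any(tie_counts < 0 | tie_counts > max_ties)) {
    stop(sprintf("tie_counts must lie in [0, %d]", max_ties), call. = FALSE)
  }
  if (!all(vapply(mechanisms, inherits, logical(1), "mechanism"))) {
    stop("mechanisms must be a list of mechanism() objects", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("replicates must be a positive integer", call. = FALSE)
  }
  structure(
    list(n_alters = n_alters, ratios = as.integer(ratios),
         tie_counts = as.integer(tie_counts), mechanisms = mechanisms,
         replicates = replicates, config = config,
         base_seed = as.integer(base_seed)),
    class = "grid_spec"
  )
}

#' Enumerate the design cells of a sweep
#'
#' Deterministic (mechanism, ratio, ties) ordering. The default
#' single-mechanism grid has `9 x 8 = 72` cells per mechanism setting; the
#' mixed grid over 11 alpha values has 792.
#'
#' @param grid a [grid_spec()].
#' @return a data frame with columns `mechanism_index`, `mechanism_kind`,
#'   `alpha` (`NA` unless mixed), `ratio`, `ties`; one row per cell.
#' @export
enumerate_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  kinds <- vapply(grid$mechanisms, function(m) m$kind, character(1))
  alphas <- vapply(grid$mechanisms, function(m) m$alpha, numeric(1))
  cells <- expand.grid(
    ties = grid$tie_counts,
    ratio = grid$ratios,
    mechanism_index = seq_along(grid$mechanisms),
    KEEP.OUT.ATTRS = FALSE
  )
  data.frame(
    mechanism_index = cells$mechanism_index,
    mechanism_kind = kinds[cells$mechanism_index],
    alpha = alphas[cells$mechanism_index],
    ratio = cells$ratio,
    ties = cells$ties,
    stringsAsFactors = FALSE
  )
}

run_seed_for <- function(base_seed, kind, alpha, ratio, ties, replicate) {
  kind_code <- match(kind, c("positive", "negative", "mixed"))
  alpha_code <- if (is.na(alpha)) -1 else round(alpha * 100)
  derive_seed(base_seed, kind_code, alpha_code, ratio, ties, replicate)
}

# Tight inner simulation returning only the outcome pair. Must stay
# arithmetic-identical to simulate_identity(): same RNG consumption
# (one sample.int for ties at generation, one for interactions), same
# update and clamping order.
sim_finals <- function(n, is_a, delta, w, steps, init, lo, up) {
  draws <- sample.int(n, steps, replace = TRUE)
  a <- init
  b <- init
  for (t in seq_len(steps)) {
    i <- draws[t]
    d <- delta[i]
    if (is_a[i]) {
      a <- a + w * d
      b <- b - (1 - w) * d
    } else {
      b <- b + w * d
      a <- a - (1 - w) * d
    }
    if (a > up) a <- up else if (a < lo) a <- lo
    if (b > up) b <- up else if (b < lo) b <- lo
  }
  c(a, b)
}

#' Run the factorial sweep
#'
#' For every design cell and replicate: derive the per-run seed with
#' [derive_seed()] from the base seed, the mechanism (kind and alpha), the
#' ratio, the tie count and the replicate index; draw a fresh uniformly
#' random tie placement (ties are redrawn for every replicate); simulate the
#' 50-step trajectory; and record the outcome identification pair.
#' Re-running with the same `base_seed` is bit-identical, and per-run streams
#' are independent of cell execution order.
#'
#' @param grid a [grid_spec()].
#' @param progress logical: emit a [message()] per cell.
#' @return a data frame of run records with columns `ratio`, `ties`,
#'   `mechanism_kind`, `alpha`, `replicate`, `seed`, `final_id_a`,
#'   `final_id_b`; `cells x replicates` rows in [enumerate_cells()] order.
#' @export
run_sweep <- function(grid, progress = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  cells <- enumerate_cells(grid)
  reps <- grid$replicates
  n <- grid$n_alters
  cfg <- grid$config
  pairs <- all_pairs(n)
  npairs <- nrow(pairs)
  p1 <- pairs[, 1] + 1L
  p2 <- pairs[, 2] + 1L
  total <- nrow(cells) * reps
  out_a <- numeric(total)
  out_b <- numeric(total)
  seeds <- integer(total)
  row <- 0L
  for (ci in seq_len(nrow(cells))) {
    kind <- cells$mechanism_kind[ci]
    alpha <- cells$alpha[ci]
    ratio <- cells$ratio[ci]
    ties <- cells$ties[ci]
    w <- switch(kind, positive = 1, negative = 0, mixed = alpha)
    is_a <- seq_len(n) <= ratio
    if (progress) {
      message(sprintf("cell %d/%d: %s%s ratio=%d ties=%d",
                      ci, nrow(cells), kind,
                      if (is.na(alpha)) "" else sprintf("(alpha=%.1f)", alpha),
                      ratio, ties))
    }
    for (r in seq_len(reps)) {
      seed <- run_seed_for(grid$base_seed, kind, alpha, ratio, ties, r)
      set.seed(seed)
      idx <- if (ties > 0L) sample.int(npairs, ties) else integer(0)
      if (length(idx)) {
        same <- is_a[p1[idx]] == is_a[p2[idx]]
        deg <- tabulate(c(p1[idx][same], p2[idx][same]), nbins = n)
      } else {
        deg <- integer(n)
      }
      fin <- tryCatch(
        sim_finals(n, is_a, cfg$base_increment * (1 + deg), w,
                   cfg$n_steps, cfg$initial_identification,
                   cfg$lower_bound, cfg$upper_bound),
        error = function(e) {
          stop(sprintf("sweep failure in cell (%s, alpha=%s, ratio=%d, ties=%d), replicate %d: %s",
                       kind, format(alpha), ratio, ties, r,
                       conditionMessage(e)), call. = FALSE)
        }
      )
      row <- row + 1L
      out_a[row] <- fin[1]
      out_b[row] <- fin[2]
      seeds[row] <- seed
    }
  }
  data.frame(
    ratio = rep(cells$ratio, each = reps),
    ties = rep(cells$ties, each = reps),
    mechanism_kind = rep(cells$mechanism_kind, each = reps),
    alpha = rep(cells$alpha, each = reps),
    replicate = rep(seq_len(reps), times = nrow(cells)),
    seed = seeds,
    final_id_a = out_a,
    final_id_b = out_b,
    stringsAsFactors = FALSE
  )
}

#' Summarize sweep records per design cell
#'
#' Groups run records by (mechanism, alpha, ratio, ties) and reports the mean
#' and sample standard deviation (n - 1 denominator) of both outcome
#' identifications. A single-replicate cell reports `NA` standard deviations
#' (undefined).
#'
#' @param records run records from [run_sweep()].
#' @return a data frame with one row per cell, in first-appearance order,
#'   with columns `ratio`, `ties`, `mechanism_kind`, `alpha`, `mean_id_a`,
#'   `sd_id_a`, `mean_id_b`, `sd_id_b`, `n_replicates`.
#' @export
summarize_runs <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty data frame of run records", call. = FALSE)
  }
  key <- paste(records$mechanism_kind,
               ifelse(is.na(records$alpha), "-", format(records$alpha)),
               records$ratio, records$ties, sep = "|")
  key <- factor(key, levels = unique(key))
  groups <- split(seq_len(nrow(records)), key)
  rows <- lapply(groups, function(ix) {
    r <- records[ix, , drop = FALSE]
    data.frame(
      ratio = r$ratio[1], ties = r$ties[1],
      mechanism_kind = r$mechanism_kind[1], alpha = r$alpha[1],
      mean_id_a = mean(r$final_id_a),
      sd_id_a = if (nrow(r) > 1L) sd(r$final_id_a) else NA_real_,
      mean_id_b = mean(r$final_id_b),
      sd_id_b = if (nrow(r) > 1L) sd(r$final_id_b) else NA_real_,
      n_replicates = nrow(r),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fmt6 <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))

#' Write run records to `runs.csv`
#'
#' One row per run record; numeric identifications fixed at 6 decimal places
#' for byte-reproducible output; `alpha` empty for non-mixed mechanisms.
#'
#' @param records run records from [run_sweep()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_runs <- function(records, path) {
  out <- data.frame(
    ratio = records$ratio,
    ties = records$ties,
    mechanism_kind = records$mechanism_kind,
    alpha = ifelse(is.na(records$alpha), "", sprintf("%.1f", records$alpha)),
    replicate = records$replicate,
    seed = records$seed,
    final_id_a = fmt6(records$final_id_a),
    final_id_b = fmt6(records$final_id_b)
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-cell summaries to `summary.csv`
#'
#' @param summary_rows output of [summarize_runs()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary_rows, path) {
  out <- data.frame(
    ratio = summary_rows$ratio,
    ties = summary_rows$ties,
    mechanism_kind = summary_rows$mechanism_kind,
    alpha = ifelse(is.na(summary_rows$alpha), "",
                   sprintf("%.1f", summary_rows$alpha)),
    mean_id_a = fmt6(summary_rows$mean_id_a),
    sd_id_a = fmt6(summary_rows$sd_id_a),
    mean_id_b = fmt6(summary_rows$mean_id_b),
    sd_id_b = fmt6(summary_rows$sd_id_b),
    n_replicates = summary_rows$n_replicates
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
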
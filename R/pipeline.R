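# High-level entry points wiring the pipeline: simulate a dataset to
# disk, analyze a dataset directory, and run the self-contained
# validation experiment. A thin command-line wrapper lives in
# inst/cli/icalternans.

.write_manifest <- function(dir, seed, config) {
  writeLines(c(
    sprintf("# seed: %d", seed),
    sprintf("# config_digest: %s",
            paste(format(unlist(config), digits = 10), collapse = ",")),
    sprintf("# package: icalternans %s",
            as.character(utils::packageVersion("icalternans")))
  ), file.path(dir, "MANIFEST.txt"))
}

#' Simulate a dataset and write it to disk
#'
#' Generates a mixed uniform/alternant dataset with
#' [generate_dataset()], writes each cell in the package's ASCII sweep
#' dialect plus a per-cell ground-truth sidecar CSV, and a manifest
#' recording the seed. Byte-identical across runs with the same seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_uniform,n_alternant Cell counts.
#' @param seed Integer seed.
#' @param ... Passed to [generate_dataset()] (e.g. `depth`, `protocol`).
#' @return Invisibly, the vector of recording file paths.
#' @export
run_simulate <- function(out_dir, n_uniform = 13L, n_alternant = 11L,
                         seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cells <- generate_dataset(n_uniform, n_alternant, seed = seed, ...)
  paths <- vapply(cells, function(rec) {
    p <- file.path(out_dir, paste0(rec$cell_id, ".asc"))
    write_recording_ascii(rec, p)
    truth <- attr(rec, "truth")
    if (!is.null(truth)) {
      write_features_csv(truth, file.path(out_dir, paste0(rec$cell_id, "_truth.csv")))
    }
    p
  }, character(1))
  .write_manifest(out_dir, seed,
                  list(n_uniform = n_uniform, n_alternant = n_alternant, ...))
  invisible(paths)
}

#' Analyze a dataset directory
#'
#' Loads every recording, extracts the per-sweep feature matrices,
#' computes the alternation index of every feature per cell, and (when
#' both regime labels are present) the uniform-vs-alternant group
#' comparison of the indices. Writes one feature CSV per cell, a
#' dataset-level alternation-index CSV, and a group-comparison CSV.
#'
#' @param in_dir Directory of `.asc` recordings.
#' @param out_dir Output directory (default `in_dir`).
#' @param features Feature subset passed to
#'   [extract_recording_features()].
#' @param plots Emit a quick-look PNG per cell (default `FALSE`).
#' @param ... Extraction configuration overrides (`peak_cfg`, `area_cfg`,
#'   `fspec`, `lut`).
#' @return Invisibly, a list with `features` (per-cell matrices),
#'   `cidx` (dataset index table) and `comparison` (or `NULL`).
#' @export
run_analyze <- function(in_dir, out_dir = in_dir,
                        features = .feature_names, plots = FALSE, ...) {
  cells <- load_dataset(in_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fms <- lapply(cells, function(rec) {
    fm <- extract_recording_features(rec, features = features, ...)
    write_features_csv(fm, file.path(out_dir, paste0(rec$cell_id, "_features.csv")))
    if (plots) {
      grDevices::png(file.path(out_dir, paste0(rec$cell_id, "_sweep1.png")),
                     width = 900, height = 600)
      plot_sweep(rec$sweeps[[1L]])
      grDevices::dev.off()
    }
    fm
  })
  cidx <- do.call(rbind, lapply(seq_along(cells), function(i) {
    ix <- index_over_features(fms[[i]])
    wide <- stats::setNames(as.list(ix$cidx), paste0("cidx_", ix$feature))
    cbind(data.frame(cell_id = cells[[i]]$cell_id,
                     regime_label = cells[[i]]$regime_label), wide)
  }))
  write_features_csv(cidx, file.path(out_dir, "alternation_index.csv"))
  comparison <- NULL
  if (length(unique(cidx$regime_label[cidx$regime_label != "unknown"])) == 2L) {
    known <- cidx[cidx$regime_label != "unknown", ]
    # only indices with data in both regimes are comparable (features that
    # were not extracted leave all-NA index columns)
    usable <- vapply(names(known), function(cn) {
      is.numeric(known[[cn]]) &&
        all(tapply(!is.na(known[[cn]]), known$regime_label, any))
    }, logical(1))
    if (any(usable)) {
      comparison <- compare_groups(known, group_col = "regime_label",
                                   value_cols = names(known)[usable])
      write_features_csv(comparison, file.path(out_dir, "group_comparison.csv"))
    }
  }
  invisible(list(features = fms, cidx = cidx, comparison = comparison))
}

#' Run the self-contained validation experiment
#'
#' Regenerates the two desk-scale validation studies on purely synthetic
#' data: (1) automatic-vs-ground-truth extraction accuracy on a noisy
#' depolarization pulse (median relative errors of the charge area, the
#' peak amplitude and the inactivation time constant over `reps` noise
#' seeds); (2) discrimination of uniform vs alternant cells by the
#' alternation index of Q_Ca (Wilcoxon rank-sum p-value on one simulated
#' dataset). Prints a small report including the seed.
#'
#' @param seed Integer seed.
#' @param reps Number of noise seeds for the extraction study.
#' @param error_bounds Pass/fail bounds (%) for area, peak and tau.
#' @param quiet Suppress printing.
#' @return Invisibly, a list `errors` (data.frame) and `discrimination`
#'   (list with the p-value).
#' @export
run_validate <- function(seed = 1L, reps = 20L,
                         error_bounds = c(area = 0.86, peak = 0.32, tau = 1.27),
                         quiet = FALSE) {
  errs <- pulse_recovery_errors(seeds = seed * 1000L + seq_len(reps))
  med <- apply(errs, 2, stats::median)
  tab <- data.frame(
    feature = c("area", "peak", "tau"),
    median_rel_error_pct = as.numeric(med[c("area", "peak", "tau")]),
    bound_pct = as.numeric(error_bounds[c("area", "peak", "tau")])
  )
  tab$pass <- tab$median_rel_error_pct <= tab$bound_pct

  p <- cidx_discrimination_p(seed = seed)
  if (!quiet) {
    cat(sprintf("validation seed = %d, reps = %d\n", seed, reps))
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %-5s median rel. error = %6.3f %% (bound %.2f %%) %s\n",
                  tab$feature[i], tab$median_rel_error_pct[i], tab$bound_pct[i],
                  if (tab$pass[i]) "PASS" else "FAIL"))
    }
    cat(sprintf("  CIdx(Q_Ca) rank-sum p = %.3g (%s at 0.01)\n",
                p, if (p <= 0.01) "PASS" else "FAIL"))
  }
  invisible(list(errors = tab, discrimination = list(p_value = p)))
}

#' Extraction errors on the synthetic depolarization pulse
#'
#' For each seed: simulate one sweep at the default circuit, protocol
#' and ionic parameters with calibrated noise, run the automatic
#' extraction, and report the relative errors (%) of Q_Ca, the calcium
#' peak amplitude and the inactivation time constant against the
#' generator's ground truth.
#'
#' @param seeds Integer vector of noise seeds.
#' @param ... Overrides passed to [simulate_sweep()].
#' @return A data.frame with columns `area`, `peak`, `tau` (one row per
#'   seed, values in percent).
#' @export
pulse_recovery_errors <- function(seeds, ...) {
  rows <- lapply(seeds, function(s) {
    sim <- simulate_sweep(noise = noise_model(seed = s), ...)
    f <- extract_sweep_features(sim$sweep,
                                features = c("peak_cap", "peak_ca", "q_ca", "tau"))
    tr <- sim$truth
    data.frame(
      area = 100 * abs(f$q_ca_pAms - tr$q_ca) / abs(tr$q_ca),
      peak = 100 * abs(f$peak_ca_pA - tr$peak_ca) / abs(tr$peak_ca),
      tau = 100 * abs(f$tau_ms - tr$tau) / abs(tr$tau)
    )
  })
  do.call(rbind, rows)
}

#' Uniform-vs-alternant discrimination p-value on one synthetic dataset
#'
#' Simulates the canonical 13 uniform + 11 alternant cell dataset,
#' extracts Q_Ca per sweep, computes the alternation index per cell, and
#' returns the two-sided Wilcoxon rank-sum p-value between regimes.
#'
#' @param seed Integer seed.
#' @param depth Alternation depth of the alternant cells.
#' @param ... Overrides passed to [generate_dataset()].
#' @return The p-value.
#' @export
cidx_discrimination_p <- function(seed, depth = 0.3, ...) {
  cells <- generate_dataset(seed = seed, depth = depth, ...)
  cidx <- vapply(cells, function(rec) {
    fm <- extract_recording_features(rec, features = c("peak_cap", "q_ca"))
    alternation_index(fm$q_ca_pAms)$cidx
  }, numeric(1))
  regime <- vapply(cells, `[[`, character(1), "regime_label")
  wilcoxon_rank_sum(cidx[regime == "uniform"], cidx[regime == "alternant"])$p_value
}

#' Quick-look plot of one sweep
#'
#' Two stacked base-graphics panels: command voltage and recorded
#' current.
#'
#' @param sweep A [sweep_trace()].
#' @param main Title.
#' @return Invisibly, `NULL`.
#' @export
plot_sweep <- function(sweep, main = "voltage-clamp sweep") {
  stopifnot(inherits(sweep, "sweep_trace"))
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4.5, 2, 1))
  on.exit(graphics::par(op))
  t_ms <- sweep$time * 1e3
  graphics::plot(t_ms, sweep$voltage_cmd, type = "l", xlab = "",
                 ylab = "command (mV)", main = main)
  graphics::plot(t_ms, sweep$current, type = "l", xlab = "time (ms)",
                 ylab = "current (pA)")
  invisible(NULL)
}
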
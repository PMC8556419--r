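#' Run one simulated scenario end to end
#'
#' Simulates a panel, scans it, and optionally matches segments and
#' reconstructs the wave model of the dominant archaic lineage.  This is
#' the workhorse of the benchmark suite.
#'
#' @param cfg a [scenario_config()].
#' @param match run the lineage matcher on the decoded segments.
#' @param history reconstruct the wave model (implies `match`).
#' @param seek_args list of extra arguments for [seek()].
#' @param min_bp history tract-length filter.
#' @param B_screen bootstrap resamples for the small-wave screen.
#' @return list: `sim` (panel + truth), `scan` (`"archaic_scan"`),
#'   `matched` (when matched), `model` (when history), `truth_waves`.
#' @export
run_scenario <- function(cfg, match = FALSE, history = FALSE,
                         seek_args = list(), min_bp = 15000,
                         B_screen = 50L) {
  sim <- simulate_panel(cfg)
  scan <- do.call(seek, c(list(panel = sim$panel), seek_args))
  out <- list(sim = sim, scan = scan,
              truth_waves = data.frame(
                t = vapply(cfg$waves, `[[`, 0, "t"),
                m = vapply(cfg$waves, `[[`, 0, "m"),
                lineage = vapply(cfg$waves, `[[`, "", "lineage")))
  if (match || history) {
    out$matched <- match_segments(scan$segments, sim$panel)
    if (history) {
      arch <- out$matched[out$matched$lineage_class == "archaic", ,
                          drop = FALSE]
      if (nrow(arch)) {
        # dominant lineage bucket by total called length; single-lineage
        # histories pool the whole archaic class (label noise must not
        # distort the tract-length distribution)
        mass <- tapply(arch$end - arch$start, arch$label, sum)
        out$dominant <- names(mass)[which.max(mass)]
        one_lineage <-
          length(unique(out$truth_waves$lineage)) <= 1L
        out$model <- tryCatch(
          reconstruct_history(out$matched,
                              if (one_lineage) "archaic" else
                                out$dominant,
                              genome_bp = cfg$chrom_len,
                              n_hap = cfg$n_test, min_bp = min_bp,
                              B_screen = B_screen, seed = cfg$seed),
          error = function(e) NULL)
      }
    }
  }
  out
}

#' Score detection concordance over seeded replicates of one scenario
#'
#' @param base_cfg a [scenario_config()]; replicate i reuses it with seed
#'   `seeds[i]`.
#' @param seeds integer vector of replicate seeds.
#' @param bases concordance bases to report.
#' @return data frame: one row per replicate and basis with pooled
#'   precision/TPR/FPR.
#' @export
replicate_concordance <- function(base_cfg, seeds = 1:20,
                                  bases = c("length", "aim")) {
  rows <- list()
  for (s in seeds) {
    cfg <- base_cfg; cfg$seed <- as.integer(s)
    r <- run_scenario(cfg)
    for (b in bases) {
      cc <- concordance(r$scan$segments, r$sim$truth, r$sim$panel,
                        basis = b, genome_bp = cfg$chrom_len)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, basis = b, precision = cc$pooled[["precision"]],
        tpr = cc$pooled[["tpr"]], fpr = cc$pooled[["fpr"]])
    }
  }
  do.call(rbind, rows)
}
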
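# Pipeline driver: simulate -> steadiness -> firing -> coherence -> cluster
# -> stats, with every table written as delimited text plus a run log.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the configured stages over a synthetic cohort (simulated in
#' place, or read from an existing cohort manifest) and writes tidy tables,
#' a JSON/YAML record of the configuration, and a run log into the report
#' directory. Identical configuration and seed reproduce identical tables.
#'
#' @param config a list, or the path to a YAML file, with entries:
#'   `seed` (integer), `out_dir` (report directory), `stages` (character
#'   subset of `simulate`, `steadiness`, `firing`, `coherence`, `cluster`,
#'   `stats`), `cohort` (list: `n_per_group`, `strength`), `protocol`
#'   (argument overrides for [protocol_spec()]), `manifest` (path to an
#'   existing cohort manifest.json, used when `simulate` is not run) and
#'   `plots` (logical).
#' @return Invisibly, a `pipeline_report`: stage results and table paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out <- config$out_dir %||% stop_invalid("config must name `out_dir`")
  stages <- config$stages %||%
    c("simulate", "steadiness", "firing", "coherence", "cluster", "stats")
  protocol <- do.call(protocol_spec, config$protocol %||% list())
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_path <- file.path(out, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)), file = log_path, append = TRUE)
  }
  put <- function(df, name) {
    df$seed <- seed
    df$config_hash <- cfg_hash
    p <- file.path(out, name)
    data.table::fwrite(df, p)
    p
  }
  logf("pipeline start, seed %d, config %s, stages: %s", seed, cfg_hash,
       paste(stages, collapse = ", "))
  report <- list(out_dir = out, seed = seed, config_hash = cfg_hash,
                 tables = character(0))

  # ---- cohort ---------------------------------------------------------
  if ("simulate" %in% stages) {
    co <- config$cohort %||% list()
    manifest <- generate_cohort(
      group_specs = default_group_specs(strength = co$strength %||% 0.3),
      protocol = protocol, n_per_group = co$n_per_group %||% 10,
      seed = seed, dir = file.path(out, "cohort"))
    trials <- attr(manifest, "trials")
    logf("simulated %d trials (%d participants)", nrow(manifest),
         length(unique(manifest$participant)))
  } else {
    mpath <- config$manifest %||%
      stop_invalid("stage `simulate` skipped but no `manifest` given")
    mj <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    manifest <- mj$trials
    trials <- NULL
    logf("loaded manifest %s (%d trials)", mpath, nrow(manifest))
  }
  get_trial <- function(i) {
    if (!is.null(trials)) trials[[i]] else
      read_trial_bundle(manifest[i, ], protocol)
  }
  report$manifest <- manifest

  # ---- steadiness -----------------------------------------------------
  if (any(c("steadiness", "firing", "coherence") %in% stages)) {
    fm <- lapply(seq_len(nrow(manifest)), function(i) {
      tr <- get_trial(i)
      win <- find_steadiest_window(tr$force)
      data.frame(manifest[i, c("participant", "group", "level", "rep", "mvc")],
                 cov_center6_pct = steadiness_cov(tr$force),
                 win_start_s = win$start, win_width_s = win$width,
                 win_cov_pct = win$cov)
    })
    force_metrics <- do.call(rbind, fm)
    if ("steadiness" %in% stages) {
      report$tables["force_metrics"] <- put(force_metrics, "force_metrics.csv")
      reg <- do.call(rbind, lapply(split(force_metrics, force_metrics$level),
        function(d) {
          pp <- stats::aggregate(cov_center6_pct ~ participant + mvc,
                                 data = d, FUN = mean)
          r <- regress_peak_vs_cov(data.frame(peak = pp$mvc,
                                              cov = pp$cov_center6_pct))
          data.frame(level = d$level[1], intercept = r$intercept,
                     slope = r$slope, slope_lo = r$slope_ci[1],
                     slope_hi = r$slope_ci[2],
                     adj_r_squared = r$adj_r_squared)
        }))
      report$tables["regression"] <- put(reg, "cov_regression.csv")
      report$force_metrics <- force_metrics
      logf("steadiness: %d trials", nrow(force_metrics))
    }
  }

  # ---- firing ---------------------------------------------------------
  if ("firing" %in% stages) {
    recs <- lapply(seq_len(nrow(manifest)), function(i) {
      tr <- get_trial(i)
      win <- list(start = force_metrics$win_start_s[i],
                  width = force_metrics$win_width_s[i])
      rows <- lapply(unlist(tr$spikes, recursive = FALSE), function(st) {
        kept <- length(filter_trains(list(st), win)) == 1L
        if (!kept) return(NULL)
        data.frame(manifest[i, c("participant", "group", "level", "rep")],
                   muscle = st$muscle, unit_id = st$unit_id,
                   rate = mean_firing_rate(st, win),
                   threshold = firing_threshold(st, tr$force,
                                                manifest$mvc[i]))
      })
      do.call(rbind, rows)
    })
    firing <- do.call(rbind, recs)
    report$firing <- firing
    report$tables["mu_firing"] <- put(firing, "mu_firing.csv")
    lmm_in <- firing[!is.na(firing$threshold), ]
    lmm_in$level <- 100 * lmm_in$level
    report$lmm <- tryCatch(
      fit_firing_lmm(lmm_in),
      error = function(e) {
        logf("firing LMM not fitted: %s", conditionMessage(e)); NULL
      })
    if (!is.null(report$lmm)) {
      report$tables["lmm_contrasts"] <- put(report$lmm$contrasts,
                                            "lmm_contrasts.csv")
      sink(file.path(out, "lmm_summary.txt")); print(report$lmm); sink()
    }
    logf("firing: %d retained motor-unit records", nrow(firing))
  }

  # ---- coherence ------------------------------------------------------
  if ("coherence" %in% stages) {
    specs <- vector("list", nrow(manifest))
    qc <- logical(nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      tr <- get_trial(i)
      win <- list(start = force_metrics$win_start_s[i],
                  width = force_metrics$win_width_s[i])
      ex <- preprocess_envelope(tr$emg$APB[, 1], win, protocol$emg_fs)
      ey <- preprocess_envelope(tr$emg$FDS[, 1], win, protocol$emg_fs)
      specs[[i]] <- estimate_spectra(ex, ey)
      qc[i] <- crosstalk_qc(coherence(specs[[i]]))
    }
    report$crosstalk_flagged <- manifest[qc, c("participant", "level", "rep")]
    key <- interaction(manifest$group, manifest$level, drop = TRUE)
    pooled_tab <- list(); band_tab <- list(); pct_tab <- list()
    pooled_by <- list()
    for (kk in levels(key)) {
      sel <- which(key == kk)
      pc <- pool_coherence(specs[sel])
      pooled_by[[kk]] <- pc
      g <- manifest$group[sel[1]]; lv <- manifest$level[sel[1]]
      pooled_tab[[kk]] <- data.frame(
        group = g, level = lv, freq = pc$freqs, R2 = pc$R2, CL = pc$CL,
        significant = pc$significant,
        heterogeneous = if (!is.null(pc$heterogeneity))
          pc$heterogeneity$flag else FALSE,
        low_freq_unreliable = pc$freqs < 8)
      band_tab[[kk]] <- data.frame(group = g, level = lv, band_average(pc))
      pct_tab[[kk]] <- data.frame(group = g, level = lv,
                                  percent_significant_trials(
                                    lapply(specs[sel], coherence)))
    }
    report$pooled <- pooled_by
    report$tables["coherence_pooled"] <- put(do.call(rbind, pooled_tab),
                                             "coherence_pooled.csv")
    report$tables["coherence_bands"] <- put(do.call(rbind, band_tab),
                                            "coherence_bands.csv")
    report$tables["coherence_trial_pct"] <- put(do.call(rbind, pct_tab),
                                                "coherence_trial_pct.csv")
    groups <- unique(manifest$group)
    if (length(groups) == 2L) {
      diff_tab <- lapply(unique(manifest$level), function(lv) {
        a <- pooled_by[[paste(groups[1], lv, sep = ".")]]
        b <- pooled_by[[paste(groups[2], lv, sep = ".")]]
        dt <- between_group_difference(a, b)
        data.frame(level = lv, freq = dt$freqs, statistic = dt$statistic,
                   ci_half_width = dt$ci_half_width,
                   direction = dt$direction)
      })
      report$tables["coherence_diff"] <- put(do.call(rbind, diff_tab),
                                             "coherence_diff.csv")
    }
    logf("coherence: pooled %d group x level cells", length(pooled_by))
  }

  # ---- cluster --------------------------------------------------------
  if ("cluster" %in% stages) {
    diag_tab <- list(); assign_tab <- list()
    report$clusters <- list()
    for (m in MUSCLES) for (lv in unique(manifest$level)) {
      sel <- which(manifest$level == lv)
      env_by_p <- lapply(split(sel, manifest$participant[sel]), function(ii) {
        envs <- lapply(ii, function(i) {
          tr <- get_trial(i)
          smoothed_power(tr$emg[[m]][, 1], protocol$emg_fs)
        })
        decimate_envelope(participant_average(envs))
      })
      X <- do.call(rbind, env_by_p)
      if (nrow(X) < 6L) { logf("cluster %s %g: skipped (n < 6)", m, lv); next }
      kk <- sprintf("%s_L%02.0f", m, 100 * lv)
      diag <- choose_k(X, seed = derive_seed(seed, match(m, MUSCLES),
                                             round(100 * lv)))
      attr(diag, "envelopes") <- X
      report$clusters[[kk]] <- diag
      diag_tab[[kk]] <- data.frame(
        muscle = m, level = lv, k = as.integer(names(diag$wcss)),
        wcss = diag$wcss,
        silhouette = c(NA, diag$silhouette)[seq_along(diag$wcss)],
        chosen_k = diag$chosen_k, supported = diag$supported)
      if (diag$supported) {
        model <- diag$models[[diag$chosen_k]]
        assign_tab[[kk]] <- data.frame(
          muscle = m, level = lv, participant = rownames(X),
          cluster = unname(model$assignments))
      }
    }
    if (length(diag_tab)) {
      report$tables["cluster_diagnostics"] <- put(do.call(rbind, diag_tab),
                                                  "cluster_diagnostics.csv")
    }
    if (length(assign_tab)) {
      report$tables["cluster_assignments"] <- put(do.call(rbind, assign_tab),
                                                  "cluster_assignments.csv")
    }
    logf("cluster: %d muscle x level cells analyzed", length(diag_tab))
  }

  # ---- stats ----------------------------------------------------------
  if ("stats" %in% stages) {
    pp <- unique(manifest[, c("participant", "group", "mvc")])
    groups <- unique(pp$group)
    cmp <- list()
    if (length(groups) == 2L && all(table(pp$group) >= 2)) {
      a <- pp$mvc[pp$group == groups[1]]
      b <- pp$mvc[pp$group == groups[2]]
      bd <- boot_mean_diff(a, b, seed = derive_seed(seed, 900))
      es <- boot_cohens_d(a, b, seed = derive_seed(seed, 901))
      cmp[["mvc"]] <- data.frame(
        measure = "mvc_n", level = NA_real_,
        groups = paste(groups, collapse = " - "),
        estimate = bd$estimate, lo = bd$ci[1], hi = bd$ci[2],
        significant = bd$significant, d = es$d, d_label = es$label)
      if (exists("force_metrics", inherits = FALSE)) {
        for (lv in unique(force_metrics$level)) {
          d <- force_metrics[force_metrics$level == lv, ]
          pm <- stats::aggregate(cov_center6_pct ~ participant + group,
                                 data = d, FUN = mean)
          a <- pm$cov_center6_pct[pm$group == groups[1]]
          b <- pm$cov_center6_pct[pm$group == groups[2]]
          if (length(a) < 2 || length(b) < 2) next
          bd <- boot_mean_diff(a, b, seed = derive_seed(seed, 910,
                                                        round(100 * lv)))
          es <- boot_cohens_d(a, b, seed = derive_seed(seed, 911,
                                                       round(100 * lv)))
          cmp[[paste0("cov", lv)]] <- data.frame(
            measure = "force_cov_pct", level = lv,
            groups = paste(groups, collapse = " - "),
            estimate = bd$estimate, lo = bd$ci[1], hi = bd$ci[2],
            significant = bd$significant, d = es$d, d_label = es$label)
        }
      }
      comparisons <- do.call(rbind, cmp)
      report$comparisons <- comparisons
      report$tables["group_comparisons"] <- put(comparisons,
                                                "group_comparisons.csv")
      logf("stats: %d bootstrap comparisons", nrow(comparisons))
    } else {
      logf("stats: skipped (need two groups with >= 2 participants)")
    }
  }

  # ---- plots ----------------------------------------------------------
  if (isTRUE(config$plots)) {
    if (!is.null(report$pooled)) {
      grDevices::pdf(file.path(out, "coherence_pooled.pdf"), width = 10,
                     height = 4)
      plot_pooled_coherence(report$pooled)
      grDevices::dev.off()
    }
    for (kk in names(report$clusters)) {
      diag <- report$clusters[[kk]]
      if (!diag$supported) next
      grDevices::pdf(file.path(out, sprintf("clusters_%s.pdf", kk)),
                     width = 8, height = 4)
      plot_clusters(diag$models[[diag$chosen_k]], attr(diag, "envelopes"),
                    fs = 20)
      grDevices::dev.off()
    }
  }

  logf("pipeline done")
  class(report) <- "pipeline_report"
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report in %s (seed %d)\n", x$out_dir, x$seed))
  cat("  tables:", paste(basename(x$tables), collapse = ", "), "\n")
  invisible(x)
}

#' Plot pooled coherence spectra
#'
#' One panel per group x level cell: pooled squared coherence against
#' frequency with the confidence limit as a dashed line and the canonical
#' alpha/beta/gamma bands shaded.
#'
#' @param pooled named list of [pool_coherence()] results (names
#'   `group.level`).
#' @param fmax largest frequency displayed, Hz.
#' @export
plot_pooled_coherence <- function(pooled, fmax = 80) {
  old <- graphics::par(mfrow = c(1, length(pooled)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in names(pooled)) {
    pc <- pooled[[nm]]
    sel <- pc$freqs <= fmax
    graphics::plot(pc$freqs[sel], pc$R2[sel], type = "l",
                   xlab = "frequency (Hz)", ylab = "pooled coherence",
                   main = nm)
    for (bd in COHERENCE_BANDS) {
      graphics::rect(bd[1], 0, bd[2], max(pc$R2[sel]),
                     col = grDevices::adjustcolor("grey", 0.2), border = NA)
    }
    graphics::abline(h = pc$CL, lty = 2)
  }
  invisible(NULL)
}
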
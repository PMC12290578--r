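#' Run the full simulation-to-reliability pipeline
#'
#' Orchestrates the stages of the reliability analysis on a synthetic
#' two-session study: data generation, autonomic response extraction,
#' physiological-noise modeling, first-level GLMs, ROI amplitude metrics,
#' group permutation inference with spatial overlap, and ICC(3,1)
#' reliability of every response measure. All randomness derives from
#' `config$seed` (overridable via `seed`), so identical calls reproduce
#' identical results.
#'
#' @param config a [study_config()]; desk-scale settings (e.g., 12
#'   participants on a 16 x 16 x 8 grid) keep the run in the minutes range.
#' @param stages character vector of stages to run: any of `"simulate"`,
#'   `"physio"`, `"noise"`, `"glm"`, `"roi"`, `"reliability"`,
#'   `"splithalf"`, or `"all"` (everything except `"splithalf"` is implied
#'   by downstream stages).
#' @param seed master seed; defaults to `config$seed`.
#' @param n_permutations permutations for the group tests.
#' @param smooth_fwhm spatial smoothing FWHM in mm (0 disables).
#' @param contralateral add the contralateral dorsal-horn regressor to the
#'   first-level designs.
#' @param out_dir optional directory; when given, [make_report()] is
#'   called on the result.
#' @return A `pipeline_result` list; see the individual elements
#'   (`physio_runs`, `tonic`, `qc`, `roi_metrics`, `reliability`,
#'   `session_diffs`, `correlations`, `dice_individual`, `dice_group`,
#'   `specificity`, `group`, `splithalf`, `manifest`).
#' @export
run_pipeline <- function(config, stages = "all", seed = NULL,
                         n_permutations = 1000, smooth_fwhm = 0,
                         contralateral = FALSE, out_dir = NULL) {
  t0 <- Sys.time()
  if (!is.null(seed)) config$seed <- as.integer(seed)
  all_stages <- c("simulate", "physio", "noise", "glm", "roi",
                  "reliability", "splithalf")
  if ("all" %in% stages) stages <- setdiff(all_stages, "splithalf")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  # dependency closure
  deps <- list(simulate = character(), physio = "simulate",
               noise = "simulate", glm = c("simulate", "noise"),
               roi = c("simulate", "glm"),
               reliability = c("simulate", "physio", "noise", "glm", "roi"),
               splithalf = c("simulate", "noise"))
  repeat {
    need <- unique(unlist(deps[stages]))
    if (all(need %in% stages)) break
    stages <- union(stages, need)
  }

  masks <- build_masks(config$grid_shape)
  roi_dl <- mask_on_segment(masks$horns$DL, masks, "C6")
  roi_vr <- mask_on_segment(masks$horns$VR, masks, "C6")
  quad_dl <- mask_on_segment(masks$dilated$DL, masks, "C6")
  quad_vr <- mask_on_segment(masks$dilated$VR, masks, "C6")
  mask_list <- list(horn_DL = roi_dl, quadrant_DL = quad_dl,
                    horn_VR = roi_vr, quadrant_VR = quad_vr)
  cord_all <- masks$cord
  analysis_mask <- Reduce(`|`, masks$dilated)

  study <- generate_study(config, bold = any(
    c("noise", "glm", "roi", "reliability", "splithalf") %in% stages))
  n <- config$n_participants; k <- config$n_sessions

  res <- list(config = config, masks = masks,
              ground_truth = study$ground_truth)
  physio_runs <- tonic_tbl <- qc_tbl <- metrics_tbl <- NULL
  statmaps <- vector("list", n)
  split_rows <- list()

  for (p in seq_len(n)) {
    statmaps[[p]] <- vector("list", k)
    for (s in seq_len(k)) {
      sess <- study$sessions[[p]][[s]]
      if ("physio" %in% stages) {
        ph <- sess$physio
        hpr <- extract_hpr(bandpass_ibi(ibi_from_rpeaks(ph$rpeaks)),
                           sess$schedule)
        scr <- extract_scr(ph$sc, ph$fs, sess$schedule)
        pdr <- extract_pdr(ph$pupil, ph$fs, ph$blinks, sess$schedule)
        trials <- dplyr::bind_rows(hpr, scr, pdr)
        trials$participant <- p; trials$session <- s
        physio_runs <- dplyr::bind_rows(
          physio_runs,
          dplyr::summarise(dplyr::group_by(trials, .data$measure),
                           value = mean(.data$value), .groups = "drop") |>
            dplyr::mutate(participant = p, session = s))
        ton <- tonic_state(ph$rpeaks, ph$sc, ph$fs, sess$schedule,
                           config$scr_shape, config$scr_rate)
        ton$participant <- p; ton$session <- s
        tonic_tbl <- dplyr::bind_rows(tonic_tbl, ton)
      }
      if (any(c("noise", "glm", "splithalf") %in% stages)) {
        bold <- sess$bold
        if (smooth_fwhm > 0) bold <- smooth_spatial(bold, smooth_fwhm)
        nz <- config$grid_shape[3]
        tv <- (seq_len(config$n_volumes) - 1) * config$tr
        ph <- sess$physio
        phc <- vapply(seq_len(nz), function(z) {
          cardiac_phase(ph$rpeaks, tv + bold$slice_offsets[z])
        }, numeric(config$n_volumes))
        phr <- vapply(seq_len(nz), function(z) {
          respiratory_phase(ph$resp, ph$fs, tv + bold$slice_offsets[z])
        }, numeric(config$n_volumes))
        csf <- csf_regressor(bold, masks$csf_ring)
        nuis <- pnm_regressors(phc, phr, csf)
        flags <- detect_outlier_volumes(bold, analysis_mask)
        qc <- qc_report(bold, cord_all)
        qc$participant <- p; qc$session <- s
        qc$n_outliers <- length(flags$volumes)
        qc_tbl <- dplyr::bind_rows(qc_tbl, qc)

        if ("glm" %in% stages) {
          des <- build_design(sess$schedule, config$n_volumes, config$tr,
                              nuisance = nuis, flags = flags)
          if (contralateral) {
            des <- add_contralateral_regressor(des, bold, masks$horns$DR)
          }
          sm <- fit_glm(bold, des)
          statmaps[[p]][[s]] <- sm
          for (mn in names(mask_list)) {
            for (st in c("beta", "z")) {
              mt <- extract_metrics(sm, mask_list[[mn]], what = st)
              metrics_tbl <- dplyr::bind_rows(
                metrics_tbl,
                tidyr::pivot_longer(mt[, c("mean", "peak", "top10_mean")],
                                    dplyr::everything(),
                                    names_to = "metric") |>
                  dplyr::mutate(participant = p, session = s,
                                mask = mn, stat = st))
            }
          }
        }
        if ("splithalf" %in% stages) {
          for (scheme in c("odd_even", "early_late")) {
            subs <- split_trials(sess$schedule, scheme)
            scheds <- lapply(subs, function(tr) {
              sess$schedule[sess$schedule$trial %in% tr, ]
            })
            names(scheds) <- c("first", "second")
            dsub <- build_design(scheds, config$n_volumes, config$tr,
                                 nuisance = nuis, flags = flags)
            msub <- fit_glm(bold, dsub)
            for (j in 1:2) {
              mt <- extract_metrics(msub[[j]], roi_dl, what = "beta")
              split_rows[[length(split_rows) + 1]] <- tibble::tibble(
                scheme = scheme, participant = p, day = s, subset = j,
                source = "bold",
                metric = c("mean", "peak", "top10_mean"),
                value = c(mt$mean, mt$peak, mt$top10_mean))
            }
            if ("physio" %in% stages) {
              for (ms in c("hpr", "scr", "pdr")) {
                tv2 <- trials[trials$measure == ms, ]
                for (j in 1:2) {
                  vv <- tv2$value[tv2$trial %in% subs[[j]]]
                  split_rows[[length(split_rows) + 1]] <- tibble::tibble(
                    scheme = scheme, participant = p, day = s, subset = j,
                    source = ms, metric = "run_mean", value = mean(vv))
                }
              }
            }
          }
        }
      }
    }
  }
  res$physio_runs <- physio_runs
  res$tonic <- tonic_tbl
  res$qc <- qc_tbl
  res$roi_metrics <- metrics_tbl
  res$statmaps <- statmaps

  if ("roi" %in% stages) {
    # group-level inference: per-day and day-averaged maps
    betas_day <- lapply(seq_len(k), function(s) {
      lapply(seq_len(n), function(p) statmaps[[p]][[s]]$beta)
    })
    beta_avg <- lapply(seq_len(n), function(p) {
      Reduce(`+`, lapply(seq_len(k), function(s) statmaps[[p]][[s]]$beta)) / k
    })
    res$group <- list(
      average = group_onesample_perm(beta_avg, roi_dl, n_permutations,
                                     seed = derive_seed(config$seed,
                                                        stream = 10L)),
      days = lapply(seq_len(k), function(s) {
        group_onesample_perm(betas_day[[s]], roi_dl, n_permutations,
                             seed = derive_seed(config$seed, session = s,
                                                stream = 11L))
      })
    )
    if (k >= 2) {
      res$conjunction <- conjunction(res$group$days[[1]]$sig_fwe05,
                                     res$group$days[[2]]$sig_fwe05)
      # group-level spatial overlap at liberal uncorrected thresholds
      gd <- lapply(1:2, function(s) {
        group_onesample_perm(betas_day[[s]], quad_dl, n_permutations,
                             seed = derive_seed(config$seed, session = s,
                                                stream = 12L))
      })
      res$dice_group <- dplyr::bind_rows(lapply(c(0.01, 0.05), function(th) {
        d <- dice(!is.na(gd[[1]]$p_unc) & gd[[1]]$p_unc < th,
                  !is.na(gd[[2]]$p_unc) & gd[[2]]$p_unc < th)
        d$threshold <- th
        d
      }))
      res$dice_individual <- dplyr::bind_rows(lapply(seq_len(n), function(p) {
        d <- individual_overlap(statmaps[[p]][[1]], statmaps[[p]][[2]],
                                roi_dl)
        d$participant <- p
        d
      }))
    }
    spec_group <- group_onesample_perm(
      beta_avg, analysis_mask, n_permutations,
      seed = derive_seed(config$seed, stream = 13L))
    res$specificity <- count_suprathreshold(spec_group$p_unc, 0.001, masks)
    res$group$specificity_map <- spec_group
  }

  if ("reliability" %in% stages && k >= 2) {
    rel_rows <- list()
    add_icc <- function(df, measure, mask = NA, stat = NA, metric = NA) {
      fit <- tryCatch(icc31(df), error = function(e) NULL)
      if (is.null(fit)) return()
      row <- tidy.icc_fit(fit)
      row$measure <- measure; row$mask <- mask
      row$stat <- stat; row$metric <- metric
      rel_rows[[length(rel_rows) + 1]] <<- row
    }
    for (ms in unique(physio_runs$measure)) {
      dd <- physio_runs[physio_runs$measure == ms, ]
      add_icc(data.frame(participant = dd$participant,
                         session = dd$session, value = dd$value), ms)
    }
    for (ms in c("heart_rate", "rmssd", "scf_auc")) {
      add_icc(data.frame(participant = tonic_tbl$participant,
                         session = tonic_tbl$session,
                         value = tonic_tbl[[ms]]), ms)
    }
    for (mn in names(mask_list)) {
      for (st in c("beta", "z")) {
        for (me in c("mean", "peak", "top10_mean")) {
          dd <- metrics_tbl[metrics_tbl$mask == mn &
                              metrics_tbl$stat == st &
                              metrics_tbl$metric == me, ]
          add_icc(data.frame(participant = dd$participant,
                             session = dd$session, value = dd$value),
                  "bold", mask = mn, stat = st, metric = me)
        }
      }
    }
    res$reliability <- dplyr::bind_rows(rel_rows)

    # day differences of the autonomic responses
    res$session_diffs <- dplyr::bind_rows(lapply(
      unique(physio_runs$measure), function(ms) {
        dd <- physio_runs[physio_runs$measure == ms, ]
        out <- session_difference_test(
          data.frame(participant = dd$participant,
                     session = dd$session, value = dd$value))
        out$measure <- ms
        out
      }))

    # cross-measure correlations: day-averaged top-10% BOLD vs autonomic
    bold_avg <- function(st) {
      dd <- metrics_tbl[metrics_tbl$mask == "horn_DL" &
                          metrics_tbl$stat == st &
                          metrics_tbl$metric == "top10_mean", ]
      tapply(dd$value, dd$participant, mean)
    }
    phys_avg <- function(ms) {
      dd <- physio_runs[physio_runs$measure == ms, ]
      tapply(dd$value, dd$participant, mean)
    }
    corr_rows <- list()
    for (st in c("beta", "z")) {
      bv <- bold_avg(st)
      for (ms in c("scr", "pdr", "hpr")) {
        sgn <- if (ms == "hpr") -1 else 1
        cc <- correlate_measures(bv, phys_avg(ms)[names(bv)], sgn)
        cc$stat <- st; cc$measure <- ms
        corr_rows[[length(corr_rows) + 1]] <- cc
      }
    }
    res$correlations <- dplyr::bind_rows(corr_rows)

    # QC-difference correlations (absolute day differences)
    qc_diff <- function(col) {
      w <- tidyr::pivot_wider(qc_tbl[, c("participant", "session", col)],
                              names_from = "session",
                              values_from = dplyr::all_of(col))
      abs(w[[2]] - w[[3]])
    }
    bold_diff <- function(st) {
      dd <- metrics_tbl[metrics_tbl$mask == "horn_DL" &
                          metrics_tbl$stat == st &
                          metrics_tbl$metric == "top10_mean", ]
      w <- tidyr::pivot_wider(dd[, c("participant", "session", "value")],
                              names_from = "session",
                              values_from = "value")
      abs(w[[2]] - w[[3]])
    }
    qcc_rows <- list()
    for (st in c("beta", "z")) {
      bd <- bold_diff(st)
      for (qcm in c("refrms_mean", "tsnr_mean")) {
        cc <- qc_difference_correlation(qc_diff(qcm), bd)
        cc$stat <- st; cc$qc_metric <- qcm
        qcc_rows[[length(qcc_rows) + 1]] <- cc
      }
    }
    res$qc_correlations <- dplyr::bind_rows(qcc_rows)
  }

  if ("splithalf" %in% stages && length(split_rows) > 0) {
    sh <- dplyr::bind_rows(split_rows)
    combos <- unique(sh[, c("scheme", "source", "metric")])
    res$splithalf <- dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
      dd <- dplyr::semi_join(sh, combos[i, ],
                             by = c("scheme", "source", "metric"))
      fit <- split_half_icc(dd)
      tibble::tibble(scheme = combos$scheme[i], source = combos$source[i],
                     metric = combos$metric[i], icc = fit$icc,
                     category = categorize_icc(fit$icc))
    }))
  }

  res$manifest <- list(
    package_version = as.character(utils::packageVersion("spinalrel")),
    seed = config$seed, stages = stages,
    n_permutations = n_permutations,
    smooth_fwhm = smooth_fwhm, contralateral = contralateral,
    config = unclass(config),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z")
  )
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) make_report(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  stages:", paste(x$manifest$stages, collapse = ", "), "\n")
  if (!is.null(x$reliability)) {
    cat("  reliability rows:", nrow(x$reliability), "\n")
  }
  invisible(x)
}

#' Write the report files for a pipeline result
#'
#' Serializes the result tables: ICC summary (one row per measure, mask,
#' statistic and metric, mirroring a measure-by-metric reliability table),
#' Dice overlap summaries, the spatial-specificity table, QC and run-level
#' tables, a JSON reliability report, and the run manifest.
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the named vector of written file paths (also stored
#'   with md5 checksums in the manifest JSON).
#' @export
make_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(as.data.frame(df), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files[[name]] <<- path
  }
  empty <- tibble::tibble()
  wr(result$reliability %||% empty, "reliability_summary.tsv")
  wr(result$dice_individual %||% empty, "dice_individual.tsv")
  wr(result$dice_group %||% empty, "dice_group.tsv")
  wr(result$specificity %||% empty, "specificity.tsv")
  wr(result$roi_metrics %||% empty, "roi_metrics.tsv")
  wr(result$physio_runs %||% empty, "physio_runs.tsv")
  wr(result$qc %||% empty, "qc.tsv")
  if (!is.null(result$splithalf)) wr(result$splithalf, "splithalf.tsv")

  json_path <- file.path(out_dir, "reliability.json")
  jsonlite::write_json(
    list(reliability = result$reliability %||% list(),
         session_diffs = result$session_diffs %||% list(),
         correlations = result$correlations %||% list(),
         qc_correlations = result$qc_correlations %||% list()),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  files[["reliability.json"]] <- json_path

  manifest <- result$manifest
  manifest$files <- lapply(files, function(f) {
    list(path = basename(f), md5 = unname(tools::md5sum(f)))
  })
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  files[["manifest.json"]] <- man_path
  invisible(unlist(files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
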
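# End-to-end study driver: generate trials, run the marker-subset
# experiment under every condition, and emit the summary tables, plots and
# a JSON report.

#' Full study configuration
#'
#' Defaults mirror the study conditions at a desk-feasible scale: four
#' porcine-like trials, five annotating clinicians, registration subsets
#' of 3-10 marks.  Frame and repeat counts are scaled down by default
#' (20 frames, 5 repeats); `paper_scale = TRUE` restores the full counts
#' (100 frames, 10 repeats), which is slower but changes nothing
#' methodologically.
#'
#' @param seed master integer seed (mandatory; every random stream in the
#'   study derives from it).
#' @param n_trials number of synthetic trials (default 4).
#' @param n_users number of annotating clinicians (default 5).
#' @param frames_per_trial camera frames evaluated per trial (default 20).
#' @param repeats random marker subsets per (condition, user, N)
#'   (default 5).
#' @param n_markers registration subset sizes (default 3:10).
#' @param conditions experiment conditions (default all three).
#' @param sigma_intraop intraoperative annotation sigma, mm (default 10.5,
#'   targeting a mean FLE of ~16.8 mm).
#' @param preop_ratio preoperative/intraoperative sigma ratio (default
#'   1.45).
#' @param deformation_magnitude mean pneumoperitoneum mark displacement,
#'   mm (default 25).
#' @param tracking a [tracking_model()].
#' @param intrinsics `camera_intrinsics` (default [default_intrinsics()]).
#' @param centroid_noise_px 2D centroid annotation noise, pixels
#'   (default 2).
#' @param paper_scale if `TRUE`, use 100 frames and 10 repeats.
#' @param output_dir directory for the report bundle, or `NULL` to skip
#'   writing files.
#' @return a list of class `study_config`.
#' @export
study_config <- function(seed, n_trials = 4L, n_users = 5L,
                         frames_per_trial = 20L, repeats = 5L,
                         n_markers = 3:10,
                         conditions = c("intraop-user", "preop-user",
                                        "fiducial"),
                         sigma_intraop = 10.5, preop_ratio = 1.45,
                         deformation_magnitude = 25,
                         tracking = tracking_model(),
                         intrinsics = default_intrinsics(),
                         centroid_noise_px = 2,
                         paper_scale = FALSE,
                         output_dir = NULL) {
  if (missing(seed)) stop("a master seed is mandatory for a study run")
  if (paper_scale) { frames_per_trial <- 100L; repeats <- 10L }
  structure(list(seed = as.integer(seed), n_trials = as.integer(n_trials),
                 n_users = as.integer(n_users),
                 frames_per_trial = as.integer(frames_per_trial),
                 repeats = as.integer(repeats),
                 n_markers = as.integer(n_markers),
                 conditions = conditions,
                 sigma_intraop = sigma_intraop, preop_ratio = preop_ratio,
                 deformation_magnitude = deformation_magnitude,
                 tracking = tracking, intrinsics = intrinsics,
                 centroid_noise_px = centroid_noise_px,
                 output_dir = output_dir),
            class = "study_config")
}

#' Run the full simulated study
#'
#' Generates `n_trials` synthetic trials, runs the marker-subset
#' experiment on each under every condition, computes FLE and inter-user
#' variability from the annotations, and summarizes TRE by condition and
#' subset size with per-N deltas and pairwise condition comparisons.
#' With an `output_dir` set, writes `results.csv`,
#' `tre_by_condition_n.csv`, `tre_deltas.csv`, `fle_by_user.csv`,
#' `summary.json` and two PNG figures.  CSV and JSON outputs are
#' byte-reproducible given the seed; a trial that fails is recorded in the
#' report and the study continues.
#'
#' @param cfg a [study_config()].
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) a list: `results` (long TRE table), `tre_summary`,
#'   `tre_deltas`, `fle`, `fle_by_user`, `inter_user`, `comparisons`,
#'   `failed_trials`, `timings_s`, `config`.
#' @export
run_study <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  users <- default_users(cfg$n_users, cfg$sigma_intraop, cfg$preop_ratio)
  results <- list(); fle <- list(); iuv <- list()
  failed <- character(0); timings <- c()
  for (i in seq_len(cfg$n_trials)) {
    tid <- paste0("trial", i)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      trial <- generate_trial(
        trial_id = tid, users = users,
        deformation = deformation_model(magnitude = cfg$deformation_magnitude,
                                        seed = derive_seed(cfg$seed, i, 2L)),
        tracking = cfg$tracking, intrinsics = cfg$intrinsics,
        n_frames = cfg$frames_per_trial,
        centroid_noise_px = cfg$centroid_noise_px,
        seed = derive_seed(cfg$seed, i))
      ecfg <- experiment_config(n_markers = cfg$n_markers,
                                repeats = cfg$repeats,
                                conditions = cfg$conditions,
                                seed = derive_seed(cfg$seed, i, 3L))
      tab <- run_marker_subset_experiment(trial, ecfg)
      intra <- trial$annotations[trial$annotations$variant == "intraop", ]
      f <- do.call(rbind, lapply(unique(intra$user), function(u) {
        fu <- compute_fle(intra[intra$user == u, ], trial$fiducials)
        fu$trial <- tid
        fu
      }))
      v <- inter_user_variability(intra)
      list(tab = tab, fle = f, iuv = v$mean_mm)
    }, error = function(e) e)
    timings[tid] <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      failed <- c(failed, paste0(tid, ": ", conditionMessage(res)))
      say("%s FAILED (%s)", tid, conditionMessage(res))
      next
    }
    results[[tid]] <- res$tab
    fle[[tid]] <- res$fle
    iuv[[tid]] <- res$iuv
    say("%s done in %.1f s (%d TRE records)", tid, timings[tid],
        nrow(res$tab))
  }
  if (length(results) == 0L) stop("every trial failed: ",
                                  paste(failed, collapse = "; "))
  all_res <- do.call(rbind, results)
  rownames(all_res) <- NULL
  fle_all <- do.call(rbind, fle)
  rownames(fle_all) <- NULL
  s <- summarize_tre(all_res, "condition_n")
  fle_by_user <- summarize_fle(fle_all, "user")
  comparisons <- list()
  have <- intersect(cfg$conditions, unique(all_res$condition))
  cmb <- utils::combn(have, 2, simplify = FALSE)
  for (p in cmb) {
    comparisons[[paste(p[1], "vs", p[2])]] <-
      compare_conditions(all_res, p[1], p[2])
  }
  out <- list(results = all_res, tre_summary = s$summary,
              tre_deltas = s$deltas, fle = fle_all,
              fle_by_user = fle_by_user,
              inter_user = unlist(iuv), comparisons = comparisons,
              failed_trials = failed, timings_s = timings, config = cfg)
  if (!is.null(cfg$output_dir)) write_study_bundle(out, cfg$output_dir, quiet)
  invisible(out)
}

write_study_bundle <- function(study, dir, quiet = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE)
  w(study$results, "results.csv")
  w(study$tre_summary, "tre_by_condition_n.csv")
  w(study$tre_deltas, "tre_deltas.csv")
  w(study$fle_by_user, "fle_by_user.csv")
  cond_means <- summarize_tre(study$results, "condition")
  summary <- list(
    seed = study$config$seed,
    n_trials = study$config$n_trials,
    failed_trials = study$failed_trials,
    tre_mean_mm = stats::setNames(as.list(cond_means$mean_mm),
                                  cond_means$condition),
    tre_sd_mm = stats::setNames(as.list(cond_means$sd_mm),
                                cond_means$condition),
    fle_mean_mm = mean(study$fle$fle_mm),
    inter_user_mean_mm = mean(study$inter_user),
    deltas = study$tre_deltas,
    comparisons = lapply(study$comparisons, function(x)
      x[c("mean_difference", "pooled_sd", "welch_t", "p_value")]))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  plot_study(study, dir)
  if (!quiet) message("report bundle written to ", dir)
  invisible(dir)
}

plot_study <- function(study, dir) {
  s <- study$tre_summary
  grDevices::png(file.path(dir, "tre_vs_n.png"), width = 900, height = 600)
  on.exit(grDevices::dev.off(), add = TRUE)
  conds <- unique(s$condition)
  cols <- stats::setNames(grDevices::hcl.colors(max(3, length(conds)),
                                                "Dark 3")[seq_along(conds)],
                          conds)
  graphics::plot(NA, xlim = range(s$n_markers),
                 ylim = c(0, max(s$mean_mm + s$sd_mm)),
                 xlab = "registration markers (N)", ylab = "TRE [mm]",
                 main = "Mean TRE vs number of registration markers")
  for (cc in conds) {
    sc <- s[s$condition == cc, ]
    graphics::lines(sc$n_markers, sc$mean_mm, col = cols[cc], lwd = 2)
    graphics::points(sc$n_markers, sc$mean_mm, col = cols[cc], pch = 19)
    graphics::arrows(sc$n_markers, sc$mean_mm - sc$sd_mm, sc$n_markers,
                     sc$mean_mm + sc$sd_mm, angle = 90, code = 3,
                     length = 0.03, col = cols[cc])
  }
  graphics::legend("topright", legend = conds, col = cols[conds], lwd = 2)
  grDevices::dev.off()
  grDevices::png(file.path(dir, "fle_by_user.png"), width = 700, height = 500)
  graphics::boxplot(fle_mm ~ user, data = study$fle,
                    xlab = "clinician", ylab = "FLE [mm]",
                    main = "Fiducial localization error by clinician")
  invisible(NULL)
}

#' Render report tables from a written study bundle
#'
#' Reads the CSV outputs of [run_study()] back in and renders the per-N
#' mean (+/- sd) TRE table per condition, the per-N delta table and the
#' per-user FLE table, with presentation rounding (half-up).  Conditions
#' without records are omitted with a notice.
#'
#' @param results_dir directory written by [run_study()].
#' @param digits decimals for presentation rounding (default 1; deltas
#'   use 2).
#' @return list of data.frames: `tre_by_n` (one column per condition),
#'   `deltas`, `fle_by_user`; also a `markdown` character vector with the
#'   rendered tables.
#' @export
report_tables <- function(results_dir, digits = 1) {
  need <- c("tre_by_condition_n.csv", "tre_deltas.csv", "fle_by_user.csv")
  missing_files <- need[!file.exists(file.path(results_dir, need))]
  if (length(missing_files))
    stop("missing study outputs in ", results_dir, ": ",
         paste(missing_files, collapse = ", "))
  s <- utils::read.csv(file.path(results_dir, "tre_by_condition_n.csv"))
  d <- utils::read.csv(file.path(results_dir, "tre_deltas.csv"))
  f <- utils::read.csv(file.path(results_dir, "fle_by_user.csv"))
  conds <- unique(s$condition)
  empty <- conds[vapply(conds, function(cc)
    all(is.na(s$mean_mm[s$condition == cc])), logical(1))]
  if (length(empty)) {
    message("omitting condition(s) without records: ",
            paste(empty, collapse = ", "))
    conds <- setdiff(conds, empty)
  }
  ns <- sort(unique(s$n_markers))
  tre_by_n <- data.frame(N = ns)
  for (cc in conds) {
    sc <- s[s$condition == cc, ]
    i <- match(ns, sc$n_markers)
    tre_by_n[[cc]] <- sprintf("%.*f ± %.*f", digits,
                              round_half_up(sc$mean_mm[i], digits), digits,
                              round_half_up(sc$sd_mm[i], digits))
  }
  d$delta_mm <- round_half_up(d$delta_mm, 2)
  f$mean_mm <- round_half_up(f$mean_mm, digits)
  f$sd_mm <- round_half_up(f$sd_mm, digits)
  md <- c("## Mean TRE [mm] by number of registration markers", "",
          md_table(tre_by_n), "",
          "## Decrease of TRE [mm] per added marker", "",
          md_table(d), "",
          "## FLE [mm] by clinician", "",
          md_table(f[, c("user", "mean_mm", "sd_mm", "n")]))
  list(tre_by_n = tre_by_n, deltas = d,
       fle_by_user = f, markdown = md)
}

md_table <- function(df) {
  hdr <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(hdr, sep, rows)
}
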
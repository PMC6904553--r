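# TRE / FLE evaluation and the marker-subset resampling experiment.
#
# FLE (fiducial localization error) is the distance between a clinician's
# annotation of a mark on the CT model and the mark's ground-truth
# position.  TRE (target registration error) is measured on marks *not*
# used to compute the registration: each held-out mark is reprojected
# through the AR chain, compared with its manually annotated 2D centroid,
# and the pixel discrepancy is converted to millimetres at the reprojected
# depth through the inverse calibration matrix.

#' Compute per-mark fiducial localization error
#'
#' Euclidean distance in mm between annotated and true positions, per
#' shared label.
#'
#' @param annotations labeled points (annotated positions), mm.
#' @param truth labeled points (ground truth), mm.
#' @return data.frame with columns `label`, `fle_mm` (plus `user` if the
#'   annotations carried one).
#' @export
compute_fle <- function(annotations, truth) {
  stopifnot(is.data.frame(annotations), is.data.frame(truth))
  shared <- intersect(annotations$label, truth$label)
  if (length(shared) == 0L)
    stop("no shared labels between annotations and truth")
  a <- points_matrix(annotations[match(shared, annotations$label), ])
  t <- points_matrix(truth[match(shared, truth$label), ])
  out <- data.frame(label = shared, fle_mm = sqrt(rowSums((a - t)^2)))
  if ("user" %in% names(annotations)) {
    out$user <- annotations$user[match(shared, annotations$label)]
  }
  out
}

#' Summarize FLE (or any per-record error) by group
#'
#' Arithmetic mean and sample standard deviation per group.  Groups with a
#' single record get `sd = 0` and are flagged (`sd_defined = FALSE`).
#' Values are reported unrounded; presentation rounding (half-up, one
#' decimal) is applied only by the table renderers.
#'
#' @param results data.frame containing the error column and the grouping
#'   column.
#' @param group_by name of the grouping column (e.g. `"user"`, `"trial"`,
#'   `"label"`, `"subject"`).
#' @param value name of the error column (default `"fle_mm"`).
#' @return data.frame: group, `mean_mm`, `sd_mm`, `n`, `sd_defined`.
#' @export
summarize_fle <- function(results, group_by = "user", value = "fle_mm") {
  stopifnot(is.data.frame(results), nrow(results) > 0,
            group_by %in% names(results), value %in% names(results))
  g <- factor(results[[group_by]], levels = unique(results[[group_by]]))
  v <- results[[value]]
  mean_mm <- tapply(v, g, mean)
  sd_mm <- tapply(v, g, stats::sd)
  n <- as.integer(tapply(v, g, length))
  out <- data.frame(group = names(mean_mm), mean_mm = as.numeric(mean_mm),
                    sd_mm = as.numeric(sd_mm), n = n,
                    sd_defined = n > 1L, stringsAsFactors = FALSE)
  out$sd_mm[!out$sd_defined] <- 0
  names(out)[1] <- group_by
  rownames(out) <- NULL
  out
}

#' Inter-user annotation variability
#'
#' For every mark, the Euclidean distances between the annotations of all
#' unordered user pairs; summarized as mean and sample standard deviation
#' over all (mark, pair) combinations.  This pairwise-distance definition
#' is one reasonable reading of "inter-user variability"; no formula is
#' standard.
#'
#' @param annotations data.frame of labeled points with a `user` column
#'   (annotations of the same marks by >= 2 users).
#' @return list: `mean_mm`, `sd_mm`, `n`, and `pairs` (data.frame with
#'   label, user_i, user_j, distance_mm).
#' @export
inter_user_variability <- function(annotations) {
  stopifnot(is.data.frame(annotations), "user" %in% names(annotations))
  users <- unique(annotations$user)
  if (length(users) < 2L)
    stop("inter-user variability needs at least 2 users, got ",
         length(users))
  labels <- unique(annotations$label)
  recs <- list()
  for (lab in labels) {
    sub <- annotations[annotations$label == lab, ]
    present <- intersect(users, sub$user)
    if (length(present) < 2L) next
    m <- points_matrix(sub[match(present, sub$user), ])
    for (i in seq_len(length(present) - 1L)) {
      for (j in seq.int(i + 1L, length(present))) {
        recs[[length(recs) + 1L]] <- data.frame(
          label = lab, user_i = present[i], user_j = present[j],
          distance_mm = sqrt(sum((m[i, ] - m[j, ])^2)))
      }
    }
  }
  pairs <- do.call(rbind, recs)
  list(mean_mm = mean(pairs$distance_mm),
       sd_mm = stats::sd(pairs$distance_mm),
       n = nrow(pairs), pairs = pairs)
}

# fast core: TRE for one frame.  marks_mat / mark_labels describe the 3D
# marks of the registered model (image frame); obs_* the annotated 2D
# centroids; exclude the registration subset.  Returns label/tre vectors
# (marks behind the camera get NA and behind = TRUE).
tre_frame_core <- function(chain, marks_mat, mark_labels, obs_u, obs_v,
                           obs_labels, exclude) {
  eval_labels <- setdiff(intersect(obs_labels, mark_labels), exclude)
  if (length(eval_labels) == 0L) {
    return(list(label = character(0), tre_mm = numeric(0),
                behind = logical(0)))
  }
  mi <- match(eval_labels, mark_labels)
  oi <- match(eval_labels, obs_labels)
  pc <- transform_points(chain$t_ic, marks_mat[mi, , drop = FALSE])
  k <- chain$intrinsics
  z <- pc[, 3]
  behind <- z <= 0
  tre <- rep(NA_real_, length(z))
  if (any(!behind)) {
    zz <- z[!behind]
    ru <- k$fx * pc[!behind, 1] / zz + k$cx
    rv <- k$fy * pc[!behind, 2] / zz + k$cy
    du <- (obs_u[oi][!behind] - ru) / k$fx
    dv <- (obs_v[oi][!behind] - rv) / k$fy
    tre[!behind] <- zz * sqrt(du^2 + dv^2)
  }
  list(label = eval_labels, tre_mm = tre, behind = behind)
}

#' TRE of one AR frame
#'
#' Reprojects the (registered) model marks through the AR chain, compares
#' each with its observed 2D centroid, and converts the pixel discrepancy
#' to millimetres at the reprojected mark's camera depth (see
#' [pixel_error_to_mm()]).  Marks used for the registration are excluded;
#' marks behind the camera are flagged, not fatal.
#'
#' @param chain an [build_ar_chain()] operator.
#' @param marks_image labeled 3D points of the model's marks (image
#'   frame, mm).
#' @param observed data.frame `label,u,v`: annotated centroids in pixels.
#' @param exclude character vector of registration-mark labels to exclude
#'   from TRE.
#' @return data.frame `label`, `tre_mm`, `behind`.
#' @export
compute_tre_frame <- function(chain, marks_image, observed,
                              exclude = character(0)) {
  stopifnot(inherits(chain, "ar_chain"), is.data.frame(marks_image),
            is.data.frame(observed),
            all(c("label", "u", "v") %in% names(observed)))
  res <- tre_frame_core(chain, points_matrix(marks_image),
                        as.character(marks_image$label),
                        observed$u, observed$v,
                        as.character(observed$label), exclude)
  data.frame(label = res$label, tre_mm = res$tre_mm, behind = res$behind)
}

#' Experiment configuration for marker-subset resampling
#'
#' @param n_markers integer vector of registration-subset sizes (default
#'   3:10; at least one mark must remain for TRE, so the maximum must be
#'   below the number of marks).
#' @param repeats random subsets drawn per (condition, user, N) (default
#'   10).
#' @param frames number of trial frames evaluated (default `NULL` = all).
#' @param conditions subset of `"intraop-user"`, `"preop-user"`,
#'   `"fiducial"`.
#' @param seed master integer seed; one reproducible sub-stream is derived
#'   per (condition, user, N).
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(n_markers = 3:10, repeats = 10L, frames = NULL,
                              conditions = c("intraop-user", "preop-user",
                                             "fiducial"),
                              seed = 1L) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (min(n_markers) < 3L)
    stop("registration needs at least 3 markers (n_markers >= 3)")
  structure(list(n_markers = as.integer(sort(unique(n_markers))),
                 repeats = as.integer(repeats),
                 frames = if (is.null(frames)) NULL else as.integer(frames),
                 conditions = conditions, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the marker-subset resampling experiment on one trial
#'
#' For every condition x user x subset size N x repeat: draw N marks
#' uniformly without replacement, compute the rigid image-to-patient
#' registration from the condition's image-side points (the user's
#' annotations on the intraoperative model, the user's annotations on the
#' preoperative model, or the fiducial ground truth) against the
#' tool-sampled patient points of the same marks, assemble the AR chain
#' with the trial's hand-eye and tracked poses, and evaluate TRE on every
#' frame over the marks not used for registration.  Fully reproducible
#' from the configuration seed.
#'
#' For the preoperative condition both the registration points and the
#' reprojected model marks come from the deformed preoperative model, as
#' they would in a navigation system fed only preoperative imaging.
#'
#' @param trial a [generate_trial()] object.
#' @param cfg an [experiment_config()].
#' @return data.frame of class `results_table`, long format, one row per
#'   (condition, user, n_markers, repeat, frame, mark): columns `trial`,
#'   `condition`, `user`, `n_markers`, `rep`, `frame`, `mark`, `tre_mm`,
#'   `registration_marks` (comma-separated subset, for auditing the
#'   exclusion rule).
#' @export
run_marker_subset_experiment <- function(trial, cfg = experiment_config()) {
  stopifnot(inherits(trial, "trial_data"), inherits(cfg, "experiment_config"))
  n_marks_total <- nrow(trial$phantom$marks)
  if (max(cfg$n_markers) > n_marks_total - 1L)
    stop("largest registration subset (", max(cfg$n_markers),
         ") must leave at least one mark for TRE (trial has ",
         n_marks_total, " marks)")
  frame_idx <- seq_along(trial$frames)
  if (!is.null(cfg$frames)) frame_idx <- frame_idx[seq_len(
    min(cfg$frames, length(frame_idx)))]
  mark_labels <- as.character(trial$phantom$marks$label)
  marks_intra <- points_matrix(trial$phantom$marks)
  marks_preop <- points_matrix(trial$preop$marks)
  user_ids <- vapply(trial$users, function(u) u$id, character(1))
  acc <- list(); ai <- 0L
  push <- function(rec) { ai <<- ai + 1L; acc[[ai]] <<- rec }
  for (ci in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[ci]
    cond_users <- if (cond == "fiducial") "fiducial" else user_ids
    preop <- cond == "preop-user"
    marks_model <- if (preop) marks_preop else marks_intra
    model_lp <- labeled_points(mark_labels, marks_model)
    for (ui in seq_along(cond_users)) {
      uid <- cond_users[ui]
      image_side <- if (cond == "fiducial") {
        trial$fiducials
      } else {
        trial$annotations[trial$annotations$user == uid &
                          trial$annotations$variant ==
                            (if (preop) "preop" else "intraop"), ]
      }
      for (n in cfg$n_markers) {
        withr::with_seed(derive_seed(cfg$seed, ci, ui, n), {
          for (r in seq_len(cfg$repeats)) {
            subset <- sample(mark_labels, n)
            cs <- correspondence_set(
              image_side[image_side$label %in% subset, ],
              trial$tool_points[trial$tool_points$label %in% subset, ])
            reg <- rigid_register_svd(cs)
            sub_str <- paste(sort(subset), collapse = ",")
            for (f in frame_idx) {
              fr <- trial$frames[[f]]
              chain <- build_ar_chain(trial$intrinsics, trial$t_cm,
                                      fr$t_mo, trial$t_po, reg$t_ip)
              res <- tre_frame_core(chain, marks_model, mark_labels,
                                    fr$centroids$u, fr$centroids$v,
                                    as.character(fr$centroids$label),
                                    exclude = subset)
              if (length(res$label)) {
                push(list(cond = cond, user = uid, n = n, rep = r,
                          frame = f, label = res$label, tre = res$tre_mm,
                          subset = sub_str))
              }
            }
          }
        })
      }
    }
  }
  len <- vapply(acc, function(a) length(a$label), integer(1))
  out <- data.frame(
    trial = trial$trial_id,
    condition = rep(vapply(acc, `[[`, character(1), "cond"), len),
    user = rep(vapply(acc, `[[`, character(1), "user"), len),
    n_markers = rep(vapply(acc, function(a) a$n, integer(1)), len),
    rep = rep(vapply(acc, function(a) a$rep, integer(1)), len),
    frame = rep(vapply(acc, function(a) a$frame, integer(1)), len),
    mark = unlist(lapply(acc, `[[`, "label")),
    tre_mm = unlist(lapply(acc, `[[`, "tre")),
    registration_marks = rep(vapply(acc, `[[`, character(1), "subset"), len),
    stringsAsFactors = FALSE)
  class(out) <- c("results_table", class(out))
  out
}

#' Summarize TRE
#'
#' Grouped mean and sample standard deviation of TRE records, and (for the
#' condition-by-N grouping) the per-N deltas `mean(N) - mean(N+1)` for
#' consecutive subset sizes — the decrease of TRE when one more
#' registration marker is used.
#'
#' @param table a results table from [run_marker_subset_experiment()].
#' @param group_by `"condition_n"` (default), `"user"` or `"condition"`.
#' @return for `"condition_n"`: list with `summary` (condition, n_markers,
#'   mean_mm, sd_mm, n, sd_defined) and `deltas` (condition, from_n, to_n,
#'   delta_mm); otherwise the summary data.frame alone.
#' @export
summarize_tre <- function(table,
                          group_by = c("condition_n", "user", "condition")) {
  group_by <- match.arg(group_by)
  stopifnot(is.data.frame(table), nrow(table) > 0)
  tab <- table[!is.na(table$tre_mm), ]
  if (group_by != "condition_n") {
    return(summarize_fle(tab, group_by = group_by, value = "tre_mm"))
  }
  key <- interaction(tab$condition, tab$n_markers, drop = TRUE)
  agg <- data.frame(
    condition = tapply(as.character(tab$condition), key, `[`, 1),
    n_markers = as.integer(tapply(tab$n_markers, key, `[`, 1)),
    mean_mm = as.numeric(tapply(tab$tre_mm, key, mean)),
    sd_mm = as.numeric(tapply(tab$tre_mm, key, stats::sd)),
    n = as.integer(tapply(tab$tre_mm, key, length)),
    stringsAsFactors = FALSE)
  agg$sd_defined <- agg$n > 1L
  agg$sd_mm[!agg$sd_defined] <- 0
  agg <- agg[order(agg$condition, agg$n_markers), ]
  rownames(agg) <- NULL
  deltas <- do.call(rbind, lapply(split(agg, agg$condition), function(s) {
    s <- s[order(s$n_markers), ]
    if (nrow(s) < 2L) return(NULL)
    data.frame(condition = s$condition[-nrow(s)],
               from_n = s$n_markers[-nrow(s)], to_n = s$n_markers[-1],
               delta_mm = s$mean_mm[-nrow(s)] - s$mean_mm[-1],
               stringsAsFactors = FALSE)
  }))
  rownames(deltas) <- NULL
  list(summary = agg, deltas = deltas)
}

#' Compare TRE between two conditions
#'
#' Descriptive two-sample comparison: difference of means, pooled standard
#' deviation, and a Welch two-sample t statistic.  Deliberately plain — no
#' repeated-measures modelling or multiple-testing machinery.
#'
#' @param table a results table.
#' @param a,b condition names present in the table.
#' @return list: `mean_a`, `mean_b`, `mean_difference` (a - b),
#'   `pooled_sd`, `welch_t`, `df`, `p_value`, `n_a`, `n_b`.
#' @export
compare_conditions <- function(table, a, b) {
  stopifnot(is.data.frame(table))
  for (cond in c(a, b)) {
    if (!cond %in% table$condition)
      stop("condition not present in results: ", cond)
  }
  va <- table$tre_mm[table$condition == a & !is.na(table$tre_mm)]
  vb <- table$tre_mm[table$condition == b & !is.na(table$tre_mm)]
  tt <- stats::t.test(va, vb)
  na <- length(va); nb <- length(vb)
  pooled <- sqrt(((na - 1) * stats::var(va) + (nb - 1) * stats::var(vb)) /
                   (na + nb - 2))
  list(mean_a = mean(va), mean_b = mean(vb),
       mean_difference = mean(va) - mean(vb), pooled_sd = pooled,
       welch_t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n_a = na, n_b = nb)
}

#' Audit the registration-mark exclusion rule
#'
#' Scans a results table and counts records whose evaluated mark appears
#' in its own registration subset (there must be none).
#'
#' @param table a results table with a `registration_marks` column.
#' @return number of violating records (0 when the rule holds).
#' @export
audit_exclusion_rule <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("mark", "registration_marks") %in% names(table)))
  subsets <- strsplit(table$registration_marks, ",", fixed = TRUE)
  sum(mapply(function(m, s) m %in% s, table$mark, subsets))
}
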
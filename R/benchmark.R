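# End-to-end benchmark: simulate a multi-group cohort on synthetic scenes,
# run the gaze-distribution analyses (entropy, agreement, center bias) and
# evaluate the three saliency models per group. All CSV outputs are
# deterministic given the seed and carry the seed and a config hash in
# comment headers.

#' Default age-group profiles
#'
#' Four profiles emulating the qualitative developmental pattern: the
#' youngest group is the least explorative (low temperature), has the
#' strongest center bias and consequently the highest within-group
#' agreement; the adult profile is the most explorative with the weakest
#' center bias. All groups share the scene-driven attention maps
#' (`full_conspicuity`).
#'
#' @param n_observers,fixations_per_observer Cohort size per group.
#' @return Named list of [group_profile()]s.
#' @export
default_group_profiles <- function(n_observers = 20,
                                   fixations_per_observer = 30) {
  labels <- c("4y", "6y", "8y", "adult")
  tau <- c(0.35, 0.55, 0.85, 1.30)
  lambda <- c(0.70, 0.50, 0.30, 0.15)
  out <- lapply(seq_along(labels), function(i)
    group_profile(labels[i], n_observers = n_observers,
                  fixations_per_observer = fixations_per_observer,
                  lambda_cb = lambda[i], tau = tau[i],
                  source_mode = "full_conspicuity"))
  stats::setNames(out, labels)
}

#' Benchmark run configuration
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Master seed; every random stage derives its seed from it.
#' @param profiles List of [group_profile()]s.
#' @param n_stimuli,stimulus_dims Synthetic scenes to generate
#'   (`c(height, width)`) when no stimuli are supplied.
#' @param stimuli Optional named list of RGB arrays to use instead.
#' @param sigma Human-map smoothing sigma (`NULL` = width-scaled default).
#' @param bins Entropy histogram bins.
#' @param agreement An [agreement_config()].
#' @param models Subset of `c("S", "SIC", "P")` to evaluate.
#' @param s_values Scale subsets scanned for the "S"/"S+I+C" models.
#' @param patch_scales List of patch scale-index subsets (see
#'   [patch_scale_subset()]).
#' @param P Training samples per class for "S+I+C".
#' @param n_train Training images for "S+I+C" (the study used 20 of its
#'   stimuli; scaled to the synthetic set size).
#' @param w_k Per-group center-bias strengths used at prediction time,
#'   named by group label (defaults 0.6/0.5/0.35/0.3 youngest to adult).
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1,
                       profiles = default_group_profiles(),
                       n_stimuli = 6, stimulus_dims = c(256, 256),
                       stimuli = NULL, sigma = NULL, bins = 256,
                       agreement = agreement_config(),
                       models = c("S", "SIC", "P"),
                       s_values = 1:6,
                       patch_scales = list(1:4, 2:4, 3:4, 4),
                       P = 10, n_train = NULL, w_k = NULL) {
  labels <- vapply(profiles, `[[`, "", "label")
  if (is.null(w_k))
    w_k <- stats::setNames(
      c(0.6, 0.5, 0.35, 0.3, rep(0.3, max(0, length(labels) - 4)))[
        seq_along(labels)], labels)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 profiles = profiles, n_stimuli = n_stimuli,
                 stimulus_dims = stimulus_dims, stimuli = stimuli,
                 sigma = sigma, bins = bins, agreement = agreement,
                 models = match.arg(models, several.ok = TRUE),
                 s_values = s_values, patch_scales = patch_scales,
                 P = P, n_train = n_train, w_k = w_k),
            class = "run_config")
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(cfg[setdiff(names(cfg), c("out_dir", "stimuli"))], file = tf)
  unname(tools::md5sum(tf))
}

write_report_csv <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# agesal report", paste0("# seed: ", seed),
               paste0("# config: ", hash)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a benchmark report CSV
#'
#' Skips the comment header emitted by [run_full_benchmark()].
#' @param path CSV path.
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Run the full simulation / analysis / model benchmark
#'
#' Stages: (1) generate or take the stimuli and simulate the multi-group
#' cohort; (2) gaze-distribution analysis: per-image entropy per group, the
#' source-by-target agreement matrix, and the per-group center-bias summary
#' (centroid distance and center-map prediction AUC); (3) model
#' evaluation: AUC-by-scale-subset tables for "S" (and, when selected, the
#' trained "S+I+C" model and the patch model over its size subsets) plus a
#' model-comparison table on held-out images. Outputs are CSV files plus
#' PNG heat maps under `cfg$out_dir`; a failing stage keeps the outputs of
#' the earlier stages and signals an error naming the stage.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory results (`stimuli` ids,
#'   `cohort`, `entropy`, `agreement`, `center_bias`, `models`).
#' @export
run_full_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  seed <- cfg$seed
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  stage <- "simulate"
  res <- tryCatch({
    ## stage 1: stimuli + cohort ------------------------------------------
    logf("stage simulate: generating stimuli and cohort (seed ", seed, ")")
    stimuli <- cfg$stimuli
    if (is.null(stimuli)) {
      stimuli <- lapply(seq_len(cfg$n_stimuli), function(i)
        make_layered_scene(width = cfg$stimulus_dims[2],
                           height = cfg$stimulus_dims[1],
                           seed = derive_seed(seed, 100 + i))$image)
      names(stimuli) <- sprintf("scene%02d", seq_len(cfg$n_stimuli))
    }
    ids <- names(stimuli)
    needs_stack <- any(vapply(cfg$profiles, function(p)
      p$source_mode %in% c("coarse_conspicuity", "full_conspicuity"),
      logical(1))) || length(cfg$models) > 0
    stacks <- if (needs_stack)
      stats::setNames(lapply(stimuli, conspicuity_stack), ids) else NULL
    cohort <- simulate_cohort(stimuli, cfg$profiles, seed,
                              stack_cache = stacks)
    write_report_csv(cohort$records, file.path(cfg$out_dir, "cohort.csv"),
                     seed, hash)
    groups <- cohort$groups
    labels <- vapply(cfg$profiles, `[[`, "", "label")

    ## stage 2: analysis ---------------------------------------------------
    stage <- "analyze"
    logf("stage analyze: entropy, agreement, center bias")
    fmaps <- smaps <- list()
    for (g in labels) for (id in ids) {
      fm <- build_fixation_map(cohort, g, id)
      fmaps[[g]][[id]] <- fm
      smaps[[g]][[id]] <- build_human_saliency_map(fm, sigma = cfg$sigma)
    }
    entropy <- do.call(rbind, lapply(labels, function(g)
      data.frame(group = g, image = ids,
                 H = vapply(ids, function(id)
                   explorativeness_entropy(smaps[[g]][[id]],
                                           bins = cfg$bins)$H, 0),
                 row.names = NULL)))
    write_report_csv(entropy, file.path(cfg$out_dir, "entropy.csv"),
                     seed, hash)
    agg <- agreement_matrix(cohort, groups = labels, images = ids,
                            sigma = cfg$sigma, cfg = cfg$agreement)
    agg_df <- data.frame(source = rownames(agg),
                         as.data.frame(unclass(agg)), row.names = NULL,
                         check.names = FALSE)
    write_report_csv(agg_df, file.path(cfg$out_dir, "agreement_matrix.csv"),
                     seed, hash)
    cbres <- lapply(labels, function(g) compute_center_map(smaps[[g]]))
    names(cbres) <- labels
    center <- do.call(rbind, lapply(labels, function(g) {
      auc <- mean(vapply(ids, function(id)
        center_map_prediction_auc(cbres[[g]], fmaps[[g]][[id]],
                                  cfg$agreement), 0))
      data.frame(group = g,
                 centroid_x = cbres[[g]]$centroid[1],
                 centroid_y = cbres[[g]]$centroid[2],
                 distance_px = cbres[[g]]$distance_px,
                 center_auc = auc, row.names = NULL)
    }))
    write_report_csv(center, file.path(cfg$out_dir, "center_bias.csv"),
                     seed, hash)
    for (g in labels)
      write_map_png(cbres[[g]]$center_map,
                    file.path(cfg$out_dir, paste0("center_map_", g, ".png")))
    write_map_png(smaps[[labels[1]]][[ids[1]]],
                  file.path(cfg$out_dir,
                            paste0("human_map_", labels[1], "_", ids[1],
                                   ".png")))

    ## stage 3: models ------------------------------------------------------
    stage <- "models"
    models_out <- list()
    n_train <- cfg$n_train %||% max(2, ceiling(2 * length(ids) / 3))
    train_ids <- ids[seq_len(min(n_train, length(ids) - 1))]
    test_ids <- setdiff(ids, train_ids)
    comparison <- data.frame(group = labels)
    if ("S" %in% cfg$models) {
      logf("stage models: scale-subset scan (S)")
      scanS <- do.call(rbind, lapply(labels, function(g) {
        sc <- scan_scale_subsets(stacks, cohort, g,
                                 s_values = cfg$s_values,
                                 w_k = cfg$w_k[[g]], cfg = cfg$agreement)
        cbind(group = g, sc, s_star = attr(sc, "s_star"))
      }))
      write_report_csv(scanS, file.path(cfg$out_dir, "scan_S.csv"),
                       seed, hash)
      models_out$scan_S <- scanS
      comparison$S <- vapply(labels, function(g) {
        st <- scanS[scanS$group == g, ]
        s_best <- st$s_star[1]
        mean(vapply(test_ids, function(id)
          agreement_auc(saliency_S(stacks[[id]], s = s_best,
                                   w_k = cfg$w_k[[g]],
                                   dims = dim(fmaps[[g]][[id]]$grid)),
                        fmaps[[g]][[id]], cfg$agreement)$auc, 0))
      }, 0)
    }
    if ("SIC" %in% cfg$models && length(train_ids) < 2) {
      logf("skipping S+I+C: fewer than 2 training images available")
      cfg$models <- setdiff(cfg$models, "SIC")
    }
    if ("SIC" %in% cfg$models) {
      logf("stage models: training S+I+C per group")
      sic <- lapply(labels, function(g) {
        gm <- train_group_model(stacks[train_ids], cohort, g,
                                s = 1, P = cfg$P, sigma = cfg$sigma,
                                w_k = cfg$w_k[[g]], cfg = cfg$agreement)
        auc <- mean(vapply(test_ids, function(id)
          agreement_auc(predict_saliency_SIC(stacks[[id]], gm),
                        fmaps[[g]][[id]], cfg$agreement)$auc, 0))
        data.frame(group = g, w_intensity = gm$w[1], w_color = gm$w[2],
                   w_orientation = gm$w[3], b = gm$b, s = gm$s,
                   w_k = gm$w_k, test_auc = auc, row.names = NULL)
      })
      sic <- do.call(rbind, sic)
      write_report_csv(sic, file.path(cfg$out_dir, "model_SIC.csv"),
                       seed, hash)
      models_out$SIC <- sic
      comparison$SIC <- sic$test_auc
    }
    if ("P" %in% cfg$models) {
      logf("stage models: patch-size subsets (P)")
      # per-subset maps are group-independent except for w_k: compute the
      # unbiased map once per (subset, image), bias per group on the fly
      base_maps <- lapply(cfg$patch_scales, function(scales)
        lapply(stimuli, function(im)
          multiscale_patch_saliency(im, patch_scale_subset(scales))))
      scanP <- do.call(rbind, lapply(seq_along(cfg$patch_scales),
                                     function(sc_i) {
        scales <- cfg$patch_scales[[sc_i]]
        do.call(rbind, lapply(labels, function(g) {
          auc <- mean(vapply(ids, function(id)
            agreement_auc(apply_center_bias(base_maps[[sc_i]][[id]],
                                            cfg$w_k[[g]]),
                          fmaps[[g]][[id]], cfg$agreement)$auc, 0))
          data.frame(group = g,
                     scales = paste(range(scales), collapse = "~"),
                     mean_auc = auc, row.names = NULL)
        }))
      }))
      write_report_csv(scanP, file.path(cfg$out_dir, "model_P.csv"),
                       seed, hash)
      models_out$P <- scanP
      comparison$P <- vapply(labels, function(g)
        mean(vapply(test_ids, function(id)
          agreement_auc(apply_center_bias(base_maps[[1]][[id]],
                                          cfg$w_k[[g]]),
                        fmaps[[g]][[id]], cfg$agreement)$auc, 0)), 0)
    }
    if (ncol(comparison) > 1)
      write_report_csv(comparison,
                       file.path(cfg$out_dir, "model_comparison.csv"),
                       seed, hash)
    jsonlite::write_json(
      list(seed = seed, hash = hash,
           groups = labels, images = ids,
           models = cfg$models,
           profiles = lapply(cfg$profiles, function(p)
             p[c("label", "n_observers", "fixations_per_observer",
                 "lambda_cb", "tau", "source_mode")])),
      file.path(cfg$out_dir, "config.json"), auto_unbox = TRUE)
    logf("benchmark complete")
    list(stimuli = ids, cohort = cohort, entropy = entropy,
         agreement = agg, center_bias = center, models = models_out,
         comparison = if (ncol(comparison) > 1) comparison else NULL)
  }, error = function(e) {
    logf("FAILED at stage '", stage, "': ", conditionMessage(e))
    stop("benchmark stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
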
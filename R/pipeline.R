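#' Run the full STN parcellation pipeline
#'
#' Orchestrates the per-subject stages — binarize profiles, build the
#' cross-correlation matrix, Ward cluster sweep with elbow detection —
#' then takes the modal elbow K across subjects as the working cluster
#' number, names clusters along the anterior-posterior axis (when the
#' modal K is 3), consolidates the subject parcellations into a group
#' parcellation, re-estimates per-sub-region connectivity and, when
#' target labels are supplied, hard-segments the targets and derives the
#' seven-class overlap labelling with per-region composition.
#'
#' Any stage failure aborts with the stage name and subject id. The run
#' is deterministic given (`cfg$random_seed`, manifest).
#'
#' @param cfg A [run_config()].
#' @param manifest A `phantom_set` (from [generate_profiles()]) or a
#'   list with element `subjects`, each subject a list holding a
#'   `profiles` [voxel_profiles()] entry.
#' @param target_labels Optional [label_volume()] of target regions on
#'   the profile target grid.
#' @param out_dir Optional directory (must exist) where volumes, tables
#'   and the JSON report are written.
#' @return A `pipeline_report` list: `subject_elbows`, `modal_K`,
#'   `sweeps`, `parcellations`, `group_labels`, `subregions`,
#'   `hard_segmentation`, `overlap`, `composition`, `outputs` (paths,
#'   when written) and the configuration used.
#' @export
run_pipeline <- function(cfg, manifest, target_labels = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  subjects <- manifest$subjects
  if (is.null(subjects) || length(subjects) == 0L) stop("no subjects")
  withr_seed(cfg$random_seed)
  n_sub <- length(subjects)

  stage <- function(name, s, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for subject %d: %s",
                   name, s, conditionMessage(e)), call. = FALSE))
  }

  sweeps <- vector("list", n_sub)
  elbows <- integer(n_sub)
  for (s in seq_len(n_sub)) {
    p <- subjects[[s]]$profiles
    bin <- stage("binarize", s,
                 binarize_profiles(p, cfg$pico_threshold_fraction))
    C <- stage("correlate", s, correlation_matrix(bin))
    k_max <- min(cfg$k_max, nrow(C$C) - 1L)
    sw <- stage("sweep", s, ward_sweep(C, cfg$k_min, k_max))
    sweeps[[s]] <- sw
    elbows[s] <- sw$elbow_K
  }
  modal_K <- modal_value(elbows)

  parcellations <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    sw <- sweeps[[s]]
    memb <- sw$membership[, match(modal_K, sw$K)]
    p <- subjects[[s]]$profiles
    parcellations[[s]] <- stage("name_clusters", s,
      name_clusters_by_axis(memb, p$seed_coords, p$seed_affine,
                            p$seed_dim))
  }
  group_labels <- group_consolidate(parcellations,
                                    cfg$group_presence_threshold)

  profs <- lapply(subjects, `[[`, "profiles")
  subreg <- subregion_connectivity(profs, parcellations, cfg)

  hard <- overlap <- comp <- NULL
  if (!is.null(target_labels)) {
    hard <- hard_segment_targets(subreg, target_labels,
                                 cfg$group_presence_threshold)
    if (length(subreg$distributions) == 3L) {
      overlap <- overlap_classes(subreg, target_labels,
                                 cfg$group_presence_threshold)
      comp <- region_composition(overlap, target_labels)
    }
  }

  outputs <- list()
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) stop("output directory does not exist: ",
                                   out_dir)
    outputs$group_labels <- file.path(out_dir, "group_parcellation.nii.gz")
    write_volume(group_labels, outputs$group_labels)
    for (nm in names(subreg$distributions)) {
      f <- file.path(out_dir, sprintf("subregion_%s.nii.gz", nm))
      write_volume(subreg$distributions[[nm]], f)
      outputs[[paste0("subregion_", nm)]] <- f
    }
    if (!is.null(hard)) {
      outputs$hard_segmentation <- file.path(out_dir,
                                             "hard_segmentation.nii.gz")
      write_volume(hard, outputs$hard_segmentation)
    }
    if (!is.null(overlap)) {
      outputs$overlap <- file.path(out_dir, "overlap_classes.nii.gz")
      write_volume(overlap, outputs$overlap)
    }
    if (!is.null(comp)) {
      outputs$composition <- file.path(out_dir, "region_composition.csv")
      utils::write.csv(comp, outputs$composition, row.names = FALSE)
    }
    sweep_tab <- do.call(rbind, lapply(seq_len(n_sub), function(s)
      data.frame(subject = s, K = sweeps[[s]]$K,
                 w_sse = sweeps[[s]]$w_sse,
                 variance_explained = sweeps[[s]]$variance_explained)))
    outputs$sweep_table <- file.path(out_dir, "cluster_sweep.csv")
    utils::write.csv(sweep_tab, outputs$sweep_table, row.names = FALSE)
    report <- list(n_subjects = n_sub,
                   subject_elbows = elbows, modal_K = modal_K,
                   config = unclass(cfg), outputs = outputs)
    outputs$report <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, outputs$report, auto_unbox = TRUE,
                         digits = NA)
  }

  structure(list(subject_elbows = elbows, modal_K = modal_K,
                 sweeps = sweeps, parcellations = parcellations,
                 group_labels = group_labels, subregions = subreg,
                 hard_segmentation = hard, overlap = overlap,
                 composition = comp, outputs = outputs,
                 config = cfg),
            class = "pipeline_report")
}

modal_value <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d subjects, modal K = %d (elbows: %s)\n",
              length(x$subject_elbows), x$modal_K,
              paste(x$subject_elbows, collapse = " ")))
  invisible(x)
}
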
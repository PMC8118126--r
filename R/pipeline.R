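# End-to-end entry points over the module functions; these back the thin
# command-line script in inst/cli/fissura.R.

#' Run the midline pipeline on one volume
#'
#' Loads (or accepts) a volume, estimates the mid-sagittal surface, and
#' writes hemisphere masks, the midline CSV/JSON and, when ground truth is
#' supplied, a metrics report.
#'
#' @param volume a [flair_volume()], or a NIfTI path.
#' @param mask_path brain-mask NIfTI path (when `volume` is a path).
#' @param out_dir output directory; `NULL` to skip writing.
#' @param truth optional `phantom_truth` or midline CSV path for validation.
#' @param config a [default_config()] list.
#' @param stem output file stem.
#' @return invisibly, list with `result` (a `midline_result`), `metrics`
#'   (tibble or `NULL`) and `paths`.
#' @export
run_volume <- function(volume, mask_path = NULL, out_dir = NULL,
                       truth = NULL, config = default_config(),
                       stem = "subject") {
  vol <- if (inherits(volume, "flair_volume")) volume else load_volume(volume, mask_path)
  res <- estimate_volume_midline(vol, config)
  metrics <- NULL
  if (inherits(truth, "phantom_truth")) {
    metrics <- evaluate_midline(res, truth, vol$spacing)
  }
  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- write_midline_result(res, vol, out_dir, stem)
    if (!is.null(metrics)) {
      mp <- file.path(out_dir, paste0(stem, "_metrics.csv"))
      write.csv(as.data.frame(metrics), mp, row.names = FALSE)
      paths <- c(paths, metrics = mp)
    }
  }
  invisible(list(result = res, metrics = metrics, paths = paths))
}

#' Run the cohort pipeline: asymmetry QC and optional biomarkers
#'
#' Takes a manifest (CSV path or data frame) with columns `subject_id`,
#' `volume_path`, `mask_path` and optionally `diagnosis`, `age`, `sex`.
#' Estimates the midline per subject, computes hemispheric volumes and
#' asymmetry-index outlier flags, and — when a diagnosis column is present
#' and `biomarkers = TRUE` — the hemispheric texture biomarker table plus
#' ANOVA/Tukey group tests for each asymmetry feature. Subjects whose
#' pipeline fails are skipped with a warning and summarized at the end.
#'
#' @param manifest CSV path or data frame.
#' @param out_dir optional output directory for the report CSVs.
#' @param config a [default_config()] list.
#' @param biomarkers compute texture biomarkers when diagnosis is available.
#' @return list with `ai` (QC tibble), `biomarkers` (tibble or `NULL`) and
#'   `tests` (list of `fissura_grouptest` or `NULL`).
#' @export
run_cohort <- function(manifest, out_dir = NULL, config = default_config(),
                       biomarkers = FALSE) {
  mf <- if (is.character(manifest)) read.csv(manifest, stringsAsFactors = FALSE) else as.data.frame(manifest)
  need <- c("subject_id", "volume_path", "mask_path")
  miss <- setdiff(need, names(mf))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(mf)
  rows <- vector("list", n)
  bio <- vector("list", n)
  failed <- character(0)
  for (i in seq_len(n)) {
    rec <- tryCatch({
      vol <- load_volume(mf$volume_path[i], mf$mask_path[i])
      res <- estimate_volume_midline(vol, config)
      vv <- hemisphere_volumes(res$hemispheres, vol$spacing)
      if (biomarkers && "diagnosis" %in% names(mf)) {
        bio[[i]] <- hemispheric_biomarkers(vol, res$hemispheres, config)
      }
      tibble(subject_id = as.character(mf$subject_id[i]),
             v_left = vv[["v_left"]], v_right = vv[["v_right"]])
    }, error = function(e) {
      warning(sprintf("subject %s failed: %s", mf$subject_id[i], conditionMessage(e)))
      NULL
    })
    rows[[i]] <- rec
    if (is.null(rec)) failed <- c(failed, as.character(mf$subject_id[i]))
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (length(failed)) {
    warning(sprintf("%d of %d subjects failed: %s", length(failed), n,
                    paste(failed, collapse = ", ")))
  }
  ai <- flag_outliers(dplyr::bind_rows(rows[ok]), z_cut = config$z_cut)
  bio_tbl <- NULL; tests <- NULL
  if (biomarkers && "diagnosis" %in% names(mf) && any(ok)) {
    bio_tbl <- dplyr::bind_cols(
      tibble(subject_id = as.character(mf$subject_id[ok]),
             diagnosis = mf$diagnosis[ok]),
      dplyr::bind_rows(bio[ok]))
    if ("age" %in% names(mf)) bio_tbl$age <- mf$age[ok]
    if ("sex" %in% names(mf)) bio_tbl$sex <- mf$sex[ok]
    feats <- grep("^delta_", names(bio_tbl), value = TRUE)
    tests <- lapply(feats, function(f) {
      tryCatch(group_tests(bio_tbl, f, group = "diagnosis"),
               error = function(e) NULL)
    })
    names(tests) <- feats
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(as.data.frame(ai), file.path(out_dir, "cohort_qc.csv"), row.names = FALSE)
    if (!is.null(bio_tbl)) {
      write.csv(as.data.frame(bio_tbl), file.path(out_dir, "biomarkers.csv"),
                row.names = FALSE)
    }
    if (!is.null(tests)) {
      st <- dplyr::bind_rows(lapply(Filter(Negate(is.null), tests), glance))
      write.csv(as.data.frame(st), file.path(out_dir, "group_tests.csv"),
                row.names = FALSE)
    }
  }
  list(ai = ai, biomarkers = bio_tbl, tests = tests)
}
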
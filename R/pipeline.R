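#' Assemble a pipeline configuration
#'
#' Collects every knob of the curation workflow in one serializable
#' object. The resolved configuration is written next to the outputs of
#' every run so any result can be audited and reproduced.
#'
#' @param manifest path to the dataset manifest CSV (see
#'   [load_manifest()]); image paths inside it are resolved relative to
#'   its directory.
#' @param output_dir directory for all artifacts (created if needed).
#' @param annotations_dir directory of VOC XMLs, keyed `<image_id>.xml`;
#'   defaults to `annotations/` next to the manifest.
#' @param base_source_tag source tag of the base (web-image) pool.
#' @param infusion_source_tag source tag of the camera-trap pool used for
#'   infusion; `NULL` disables infusion planning.
#' @param negative_source_tag source tag of negative samples.
#' @param infusion_percents infusion levels; default 5% to 20% in 5%
#'   steps.
#' @param train_fraction training share of each split.
#' @param n_negatives_train,n_negatives_test negatives appended to train
#'   and test sets; scaled to the pool at hand (the published experiment
#'   used 800 and 200).
#' @param dedup_threshold SSIM above which images are duplicates.
#' @param cluster_threshold SSIM at/above which images share a cluster.
#' @param ssim an [ssim_params()].
#' @param detections optional detections CSV to score against the
#'   manifest's annotations.
#' @param eval_thresholds confidence thresholds for the evaluation sweep.
#' @param iou_threshold IoU cutoff for a true positive.
#' @param ap_mode `"all_points"` or `"eleven_point"`.
#' @param seed global seed; per-stage seeds are derived from it with
#'   [derive_seed()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, output_dir,
                            annotations_dir = NULL,
                            base_source_tag = "FiN",
                            infusion_source_tag = NULL,
                            negative_source_tag = "NEG",
                            infusion_percents = c(0.05, 0.10, 0.15, 0.20),
                            train_fraction = 0.9,
                            n_negatives_train = 800,
                            n_negatives_test = 200,
                            dedup_threshold = 0.8,
                            cluster_threshold = 0.4,
                            ssim = ssim_params(),
                            detections = NULL,
                            eval_thresholds = c(0.05, 0.30, 0.50),
                            iou_threshold = 0.5,
                            ap_mode = "all_points",
                            seed = 1) {
  structure(list(
    manifest = manifest, output_dir = output_dir,
    annotations_dir = annotations_dir,
    base_source_tag = base_source_tag,
    infusion_source_tag = infusion_source_tag,
    negative_source_tag = negative_source_tag,
    infusion_percents = infusion_percents,
    train_fraction = train_fraction,
    n_negatives_train = n_negatives_train,
    n_negatives_test = n_negatives_test,
    dedup_threshold = dedup_threshold,
    cluster_threshold = cluster_threshold,
    ssim = ssim, detections = detections,
    eval_thresholds = eval_thresholds,
    iou_threshold = iou_threshold, ap_mode = ap_mode,
    seed = as.integer(seed)), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Every [pipeline_config()] argument may appear as a top-level YAML key;
#' `ssim` takes a mapping of [ssim_params()] fields. Keyword lists or
#' other download metadata present in the file are carried through to the
#' resolved-config copy but not executed.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  if (!is.null(args$ssim)) args$ssim <- do.call(ssim_params, args$ssim)
  cfg <- do.call(pipeline_config, args)
  cfg$extra <- y[setdiff(names(y), names(formals(pipeline_config)))]
  cfg
}

write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$ssim <- unclass(out$ssim)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full curation pipeline
#'
#' Executes, in order: near-duplicate removal on the base pool,
#' capture-event clustering + representative selection on the infusion
#' pool, the base train/validation split, one infusion split per
#' configured infusion level (selected one-frame-per-cluster), negative
#' supplementation of every split, and (when a detections file is
#' configured) a confidence-threshold evaluation sweep against the
#' manifest's annotations. Every intermediate artifact (similarity
#' matrices, removal list, cluster assignments, split CSVs, evaluation
#' JSON) is written under `output_dir` together with the resolved
#' configuration and a run summary; with a fixed seed, re-running
#' reproduces every artifact byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return the run summary (named list of per-stage counts), invisibly
#'   identical to `summary.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      fail("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  manifest_dir <- dirname(config$manifest)
  ann_dir <- if (is.null(config$annotations_dir))
    file.path(manifest_dir, "annotations") else config$annotations_dir
  manifest <- stage("load_manifest",
                    load_manifest(config$manifest, annotations_dir = ann_dir))
  manifest$abs_path <- ifelse(
    grepl("^(/|[A-Za-z]:)", manifest$path), manifest$path,
    file.path(manifest_dir, manifest$path))
  tags <- stats::setNames(manifest$source_tag, manifest$image_id)
  summary <- list(seed = config$seed,
                  images_total = nrow(manifest),
                  images_negative = sum(manifest$is_negative))

  base <- manifest[manifest$source_tag == config$base_source_tag &
                     !manifest$is_negative, ]
  if (!nrow(base)) fail("no positive records with base_source_tag '%s'",
                        config$base_source_tag)

  # -- duplicate removal on the base pool -------------------------------
  message(sprintf("[%s] dedup: %d base images", format(Sys.time()),
                  nrow(base)))
  base_matrix <- stage("ssim_matrix", ssim_matrix(
    stats::setNames(base$abs_path, base$image_id), config$ssim))
  write_similarity_csv(base_matrix, file.path(out, "ssim_base.csv"))
  dd <- stage("dedup", dedup(base_matrix, config$dedup_threshold,
                             derive_seed(config$seed, "dedup")))
  utils::write.csv(data.frame(image_id = dd$removed),
                   file.path(out, "removed.csv"), row.names = FALSE,
                   quote = FALSE)
  summary$dedup <- list(input = nrow(base), kept = length(dd$kept),
                        removed = length(dd$removed),
                        threshold = config$dedup_threshold)
  base_pool <- dd$kept

  # -- capture-event clustering on the infusion pool --------------------
  clusters <- NULL
  infusion_pool <- character()
  if (!is.null(config$infusion_source_tag)) {
    infu <- manifest[manifest$source_tag == config$infusion_source_tag &
                       !manifest$is_negative, ]
    if (!nrow(infu)) fail("no positive records with infusion_source_tag '%s'",
                          config$infusion_source_tag)
    message(sprintf("[%s] cluster: %d infusion-pool images",
                    format(Sys.time()), nrow(infu)))
    infusion_matrix <- stage("ssim_matrix", ssim_matrix(
      stats::setNames(infu$abs_path, infu$image_id), config$ssim))
    write_similarity_csv(infusion_matrix,
                         file.path(out, "ssim_infusion.csv"))
    clusters <- stage("cluster", cluster_events(infusion_matrix,
                                                config$cluster_threshold))
    write_cluster_csv(clusters, file.path(out, "clusters.csv"))
    reps <- select_representatives(clusters,
                                   derive_seed(config$seed, "representatives"))
    utils::write.csv(data.frame(image_id = reps),
                     file.path(out, "representatives.csv"),
                     row.names = FALSE, quote = FALSE)
    infusion_pool <- infu$image_id
    summary$clustering <- list(
      input = nrow(infu), clusters = length(clusters$clusters),
      sizes = lengths(clusters$clusters),
      threshold = config$cluster_threshold)
  }

  # -- splits -----------------------------------------------------------
  negatives <- manifest$image_id[manifest$is_negative]
  finalize <- function(split, name) {
    if (config$n_negatives_train + config$n_negatives_test > 0)
      split <- supplement_negatives(
        split, negatives, config$n_negatives_train,
        config$n_negatives_test,
        derive_seed(config$seed, paste0("negatives-", name)), tags)
    write_split_csv(split, file.path(out, paste0(name, ".csv")))
    split_summary(split)
  }
  splits <- list()
  bs <- stage("base_split", base_split(base_pool, config$train_fraction,
                                       derive_seed(config$seed, "split"),
                                       tags))
  splits$base <- finalize(bs, "split_base")
  for (p in config$infusion_percents) {
    if (!length(infusion_pool)) break
    name <- sprintf("split_inf_%02.0f", 100 * p)
    inf <- stage(name, build_infusion_split(
      base_pool, infusion_pool, p, config$train_fraction,
      seed = derive_seed(config$seed, name),
      infusion_seed = derive_seed(config$seed, paste0(name, "-select")),
      clusters = clusters, source_tags = tags))
    splits[[sprintf("infusion_%02.0f", 100 * p)]] <- finalize(inf, name)
  }
  summary$splits <- splits

  # -- evaluation -------------------------------------------------------
  if (!is.null(config$detections)) {
    message(sprintf("[%s] evaluate: %s", format(Sys.time()),
                    config$detections))
    dets <- read_detections_csv(config$detections)
    gts <- read_voc_dir(ann_dir, ids = manifest$image_id)
    reports <- stage("evaluate", evaluate_at_thresholds(
      dets, gts, config$eval_thresholds, config$iou_threshold,
      config$ap_mode))
    summary$evaluation <- lapply(reports, eval_report_summary)
    jsonlite::write_json(summary$evaluation,
                         file.path(out, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  write_pipeline_config(config, file.path(out, "config_resolved.yaml"))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("[%s] done in %.1f s", format(Sys.time()),
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(summary)
}
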
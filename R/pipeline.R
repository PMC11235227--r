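#' Configuration of a full synthetic experiment
#'
#' Bundles the per-stage settings of the end-to-end run (synthesise
#' slides and stacks, fuse and extract instances, compute features,
#' train the attention model, evaluate, render overlays) with one global
#' seed. Stage seeds are derived from the global seed by a stable hash
#' ([derive_seed()]), so every stage is independently reproducible. The
#' config round-trips through YAML unchanged.
#'
#' @param n_slides Number of synthetic slides.
#' @param slide Arguments for [slide_config()].
#' @param stack Arguments for [synth_stack()] (`n_models`,
#'   `disagreement`, ...).
#' @param fusion List with `A`, `min_area_px`, `smoothness`.
#' @param features List with `stain_profile`.
#' @param mil Arguments for [mil_config()].
#' @param eval List with `weight_col`.
#' @param seed Global integer seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_slides = 8L,
                              slide = list(width = 192L, height = 192L,
                                           min_canvas = 128L,
                                           n_tubule = 2L, n_glomerulus = 1L,
                                           n_vessel = 1L),
                              stack = list(n_models = 4L, disagreement = 0.1),
                              fusion = list(A = 1, min_area_px = 32L,
                                            smoothness = 0.5),
                              features = list(stain_profile = "PAS"),
                              mil = list(max_epochs = 60L, patience = 15L),
                              eval = list(weight_col = "n_instances"),
                              seed = 1L) {
  structure(list(n_slides = n_slides, slide = slide, stack = stack,
                 fusion = fusion, features = features, mil = mil,
                 eval = eval, seed = seed),
            class = "experiment_config")
}

#' Read / write an experiment config as YAML
#'
#' @param config An `experiment_config`.
#' @param path File path.
#' @return `write_experiment_config()` invisibly returns `path`;
#'   `read_experiment_config()` returns the config.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  obj <- yaml::read_yaml(path)
  structure(obj, class = "experiment_config")
}

# Stable content hash of a stage config (order-independent via
# canonical serialisation).
.stage_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  derive_seed(0L, as.character(s))
}

#' Run the full synthetic experiment pipeline
#'
#' Executes the stages in dependency order — `synth` (slides and
#' probability stacks), `fuse` (fusion, instance extraction, quality
#' weights, crops), `features` (handcrafted per-instance features,
#' imputation/normalisation), `mil` (slide-label task keyed to the
#' glomeruli count, attention model training), `eval` (weighted ROC
#' report), `viz` (attention overlay PNG for the first slide) — and
#' writes a manifest with per-stage config hashes and seeds. Re-runs
#' skip stages whose config hash matches the manifest unless `force`;
#' changing one stage's config re-runs that stage and its descendants.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory.
#' @param force Re-run everything.
#' @return Invisibly, the manifest (list), with stage results attached
#'   as the `results` attribute.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path) && !force) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list(stages = list())
  results <- list()
  dirty <- force
  stage_names <- c("synth", "fuse", "features", "mil", "eval", "viz")

  run_stage <- function(name, cfg, fn) {
    h <- .stage_hash(cfg)
    cache <- file.path(out_dir, paste0(name, ".rds.json"))
    prev <- manifest$stages[[name]]
    if (!dirty && !is.null(prev) && identical(prev$hash, h) &&
        file.exists(file.path(out_dir, paste0(name, ".done")))) {
      results[[name]] <<- attr(manifest, paste0("mem_", name))
      return(FALSE)  # skipped
    }
    dirty <<- TRUE
    res <- fn()
    results[[name]] <<- res
    manifest$stages[[name]] <<- list(
      hash = h, seed = derive_seed(config$seed, name),
      ran_at = format(Sys.time(), tz = "UTC"))
    writeLines(as.character(h), file.path(out_dir, paste0(name, ".done")))
    TRUE
  }

  ran <- c()
  # results of skipped stages must still exist for descendants, so any
  # skipped prefix is recomputed lazily on first need: we keep all stage
  # outputs in memory within one call and recompute a skipped stage only
  # if a descendant runs.
  need_data <- function(name) is.null(results[[name]])

  synth_fn <- function() {
    seed <- derive_seed(config$seed, "synth")
    slides <- lapply(seq_len(config$n_slides), function(i) {
      synth_slide(do.call(slide_config, config$slide),
                  seed = derive_seed(seed, paste0("slide", i)))
    })
    stacks <- lapply(seq_along(slides), function(i) {
      do.call(synth_stack, c(list(slide = slides[[i]],
                                  seed = derive_seed(seed, paste0("stack", i))),
                             config$stack))
    })
    write_slide(slides[[1L]], out_dir, "slide_example")
    list(slides = slides, stacks = stacks)
  }
  fuse_fn <- function() {
    if (need_data("synth")) results$synth <<- synth_fn()
    syn <- results$synth
    lapply(seq_along(syn$slides), function(i) {
      fused <- fuse_ensemble(syn$stacks[[i]], config$fusion$A)
      per_class <- list()
      for (cl in c("tubule", "glomerulus", "vessel")) {
        ci <- match(cl, fused$class_names)
        inst <- extract_instances(fused, cl,
                                  min_area_px = config$fusion$min_area_px,
                                  smoothness = config$fusion$smoothness)
        if (length(inst) > 0L) {
          inst <- compute_quality_weights(inst, fused$p_sigma[ci, , ])
          inst <- lapply(inst, function(z) {
            crop_instance(syn$slides[[i]]$image, z, mpp = fused$mpp)
          })
        }
        per_class[[cl]] <- inst
      }
      list(fused = fused, instances = per_class)
    })
  }
  features_fn <- function() {
    if (need_data("fuse")) results$fuse <<- fuse_fn()
    syn <- results$synth
    schema <- feature_schema(config$features$stain_profile)
    rows <- list()
    for (i in seq_along(results$fuse)) {
      slide <- syn$slides[[i]]
      total_area <- sum(vapply(results$fuse[[i]]$instances, function(cl) {
        sum(vapply(cl, function(z) sum(z$mask), numeric(1)))
      }, numeric(1))) * slide$mpp^2
      iid <- 0L
      for (cl in names(results$fuse[[i]]$instances)) {
        for (ins in results$fuse[[i]]$instances[[cl]]) {
          iid <- iid + 1L
          # nuclei ground truth restricted to this instance's crop frame
          nmasks <- list()
          if (config$features$stain_profile == "PAS") {
            bb <- ins$bbox
            for (gt in slide$instances) {
              if (gt$class_label != "nucleus") next
              sub <- gt$mask[(bb[1L] + 1L):bb[2L], (bb[3L] + 1L):bb[4L]]
              if (any(sub & ins$crop_mask)) nmasks[[length(nmasks) + 1L]] <- sub
            }
          }
          hc <- handcrafted_features(
            ins$crop, ins$crop_mask, nmasks,
            slide_context = list(total_area_um2 = total_area),
            mpp = slide$mpp, schema = schema)
          rows[[length(rows) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(bag_id = i, instance_id = iid,
                           class_label = ins$class_label, g = ins$g,
                           sigma2 = ins$s2),
            hc)
        }
      }
    }
    dplyr::bind_rows(rows)
  }
  mil_fn <- function() {
    if (need_data("features")) results$features <<- features_fn()
    ft <- results$features
    syn <- results$synth
    # slide label: tissue-adequacy analogue — does the slide carry at
    # least the median number of extracted compartments?
    n_inst <- as.integer(table(factor(ft$bag_id, levels = seq_along(syn$slides))))
    labels <- as.integer(n_inst >= stats::median(n_inst))
    if (length(unique(labels)) < 2L) labels[which.min(n_inst)] <- 0L
    if (length(unique(labels)) < 2L) labels[1L] <- 1L - labels[1L]
    feat_cols <- setdiff(names(ft)[vapply(ft, is.numeric, logical(1))],
                         c("bag_id", "instance_id", "g", "sigma2"))
    stats_f <- fit_feature_stats(ft[, c("bag_id", "instance_id", feat_cols)])
    ftn <- apply_feature_stats(stats_f, ft)
    names(ftn)[match(feat_cols, names(ftn))] <- paste0("f_", seq_along(feat_cols))
    bags <- tibble::tibble(
      bag_id = seq_along(syn$slides),
      donor_id = paste0("donor_", rep_len(seq_len(max(2L, length(syn$slides) %/% 2L)),
                                          length(syn$slides))),
      label = labels,
      n_instances = as.integer(table(factor(ftn$bag_id,
                                            levels = seq_along(syn$slides)))))
    bs <- structure(list(instances = ftn, bags = bags, config = NULL),
                    class = "bag_set")
    cfg <- do.call(mil_config, c(config$mil,
                                 list(seed = derive_seed(config$seed, "mil"))))
    ids <- bags$bag_id
    split <- list(train = ids[seq_along(ids) %% 2L == 1L],
                  val = ids[seq_along(ids) %% 2L == 0L])
    model <- tryCatch(mil_train(bs, cfg, split),
                      error = function(e) NULL)
    list(bag_set = bs, model = model, split = split)
  }
  eval_fn <- function() {
    if (need_data("mil")) results$mil <<- mil_fn()
    m <- results$mil
    if (is.null(m$model)) return(NULL)
    preds <- mil_predict(m$model, m$bag_set)
    roc <- tryCatch(
      weighted_roc(dplyr::left_join(preds, m$bag_set$bags[, c("bag_id", "n_instances")],
                                    by = "bag_id"),
                   .data$label, .data$.pred_1, .data$n_instances),
      error = function(e) NULL)
    if (!is.null(roc)) {
      jsonlite::write_json(list(auc = roc$auc),
                           file.path(out_dir, "eval.json"), auto_unbox = TRUE)
    }
    list(predictions = preds, roc = roc)
  }
  viz_fn <- function() {
    if (need_data("eval")) results$eval <<- eval_fn()
    if (need_data("fuse")) results$fuse <<- fuse_fn()
    syn <- results$synth
    inst <- unlist(results$fuse[[1L]]$instances, recursive = FALSE)
    if (length(inst) == 0L) return(NULL)
    attn <- results$eval$predictions
    a <- rep(1 / length(inst), length(inst))
    if (!is.null(attr(attn, "attention"))) {
      at <- attr(attn, "attention")
      at1 <- at[at$bag_id == 1L, ]
      if (nrow(at1) == length(inst)) a <- at1$attention
    }
    fig <- attention_overlay(syn$slides[[1L]]$image, inst, a)
    write_overlay(fig, file.path(out_dir, "overlay.png"))
    fig
  }

  fns <- list(synth = synth_fn, fuse = fuse_fn, features = features_fn,
              mil = mil_fn, eval = eval_fn, viz = viz_fn)
  cfgs <- list(synth = c(config["n_slides"], config["slide"], config["stack"],
                         config["seed"]),
               fuse = config["fusion"], features = config["features"],
               mil = config["mil"], eval = config["eval"], viz = list())
  # descendants inherit ancestor hashes so upstream changes propagate
  acc <- list()
  for (nm in stage_names) {
    acc <- c(acc, cfgs[[nm]])
    ran[nm] <- run_stage(nm, acc, fns[[nm]])
  }
  manifest$seed <- config$seed
  manifest$stages_run <- names(ran)[ran]
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  out <- manifest
  attr(out, "results") <- results
  attr(out, "ran") <- ran
  invisible(out)
}
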
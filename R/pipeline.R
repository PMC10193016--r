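# End-to-end orchestration: augment -> featurize -> split/train ->
# evaluate/gap -> screen/filter -> (optional) dose-response, with a
# manifest that makes a whole run reproducible from one integer seed.

#' Assemble a run configuration
#'
#' All stage parameters with their study defaults (augmentation k = 20 at
#' radius 3; 75/25 stratified split; 5-fold CV on seeds, 10-fold on
#' augmented data; probability band 0.6-0.9; >= 3 neighbors; HBA 0-10,
#' HBD 0-5, cLogP 0-5, MW 300-1000; R^2 threshold 0.18; the 10-point
#' concentration ladder). Every stage derives its own RNG stream from
#' `rng_seed` (stage seed = `rng_seed * 100` + a fixed stage offset), so a
#' single integer reproduces the entire run.
#'
#' @param out_dir run directory (created if needed).
#' @param seeds_path,library_path,assay_path optional input files; when
#'   `NULL` and `demo = TRUE` the synthetic generator supplies them.
#' @param demo all-synthetic demo mode (default TRUE when no inputs given).
#' @param n_active,n_inactive,n_library,n_reference synthetic sizes.
#' @param augment an [augment_config()].
#' @param split a [split_spec()].
#' @param train a [train_config()] (`cv_folds` is overridden to 10 when
#'   training on augmented data unless set explicitly).
#' @param criteria a [hit_criteria()].
#' @param edge_threshold similarity-network edge threshold.
#' @param paper_mode augment the full seed set first and stratified-split
#'   the augmented records afterwards (the literal protocol, in which
#'   analog families straddle the split and test metrics are flattered by
#'   near-duplicates); default FALSE = parent-grouped seed split first,
#'   then each side augmented independently (leakage-safe).
#' @param with_embedding compute the 2-D map (default TRUE).
#' @param with_assay fit demo dose-response curves for top hits.
#' @param rng_seed master integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = "molscreen_run", seeds_path = NULL,
                       library_path = NULL, assay_path = NULL, demo = TRUE,
                       n_active = 30L, n_inactive = 20L, n_library = 120L,
                       n_reference = 300L,
                       augment = augment_config(),
                       split = split_spec(),
                       train = train_config(),
                       criteria = hit_criteria(),
                       edge_threshold = 0.4,
                       paper_mode = FALSE, with_embedding = TRUE,
                       with_assay = TRUE, rng_seed = 1L) {
  structure(list(out_dir = out_dir, seeds_path = seeds_path,
                 library_path = library_path, assay_path = assay_path,
                 demo = demo, n_active = as.integer(n_active),
                 n_inactive = as.integer(n_inactive),
                 n_library = as.integer(n_library),
                 n_reference = as.integer(n_reference),
                 augment = augment, split = split, train = train,
                 criteria = criteria, edge_threshold = edge_threshold,
                 paper_mode = isTRUE(paper_mode),
                 with_embedding = isTRUE(with_embedding),
                 with_assay = isTRUE(with_assay),
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

# documented stage-seed derivation: one master integer -> per-stage streams
.stage_seed <- function(cfg, offset) cfg$rng_seed * 100L + offset

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full screening pipeline
#'
#' Executes the stages in order (augment, featurize, split/train,
#' evaluate/gap, screen/filter, optional dose-response) and writes every
#' artifact plus a manifest into `cfg$out_dir`. A stage failure halts the
#' run naming the stage; artifacts written before the failure are kept.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the in-memory artifacts (seed records,
#'   model bundle, metrics, gap, screen audit, hits, fits, manifest).
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- function(f) file.path(cfg$out_dir, f)

  seeds <- .stage("seeds", {
    if (!is.null(cfg$seeds_path)) read_molecule_table(cfg$seeds_path)
    else if (cfg$demo)
      generate_sar_dataset(sar_config(n_active = cfg$n_active,
                                      n_inactive = cfg$n_inactive,
                                      rng_seed = .stage_seed(cfg, 1L)))
    else stop("no seeds_path given and demo = FALSE")
  })
  write_molecule_table(seeds, paths("seeds.csv"))

  lib <- .stage("fragment_library", {
    ref <- reference_fragment_collection(n = cfg$n_reference)
    build_fragment_library(ref, radius = cfg$augment$radius)
  })

  split0 <- cfg$split
  split0$rng_seed <- .stage_seed(cfg, 2L)
  aug_cfg <- cfg$augment
  aug_cfg$rng_seed <- .stage_seed(cfg, 3L)
  if (cfg$paper_mode) {
    all_aug <- .stage("augment",
                      suppressWarnings(augment_dataset(seeds, lib, aug_cfg)))
    split0$group_by_parent <- FALSE
    parts <- .stage("split", stratified_split(all_aug, split0))
    aug <- list(train = parts$train, test = parts$test)
  } else {
    parts <- .stage("split", stratified_split(seeds, split0))
    aug_cfg2 <- aug_cfg
    aug_cfg2$rng_seed <- .stage_seed(cfg, 4L)
    aug <- .stage("augment", list(
      train = suppressWarnings(augment_dataset(parts$train, lib, aug_cfg)),
      test = suppressWarnings(augment_dataset(parts$test, lib, aug_cfg2))))
  }
  write_molecule_table(aug$train, paths("train_set.csv"))
  write_molecule_table(aug$test, paths("test_set.csv"))

  feats <- .stage("featurize", {
    ftr <- featurize(aug$train)
    fte <- featurize(aug$test, scaler = ftr$scaler, config = ftr$config)
    list(train = ftr, test = fte)
  })
  write_feature_matrix(feats$train, paths("train_features.csv"))

  bundle <- .stage("train", {
    train_model(feats$train$features, aug$train$label, cfg$train,
                rng_seed = .stage_seed(cfg, 5L),
                scaler = feats$train$scaler,
                feat_config = feats$train$config)
  })

  reports <- .stage("evaluate", {
    tr <- evaluate(bundle, feats$train$features, aug$train$label)
    te <- evaluate(bundle, feats$test$features, aug$test$label)
    list(train = tr, test = te, gap = generalization_gap(tr, te))
  })
  .write_metrics(reports, paths("metrics.csv"))

  screen <- .stage("screen", {
    library_rec <-
      if (!is.null(cfg$library_path)) read_molecule_table(cfg$library_path)
      else if (cfg$demo)
        generate_screening_library(cfg$n_library,
                                   rng_seed = .stage_seed(cfg, 6L),
                                   seeds = seeds)
      else stop("no library_path given and demo = FALSE")
    flib <- featurize(library_rec, scaler = feats$train$scaler,
                      config = feats$train$config)
    prob <- predict_proba(bundle, flib$features)
    net <- build_similarity_network(library_rec, cfg$edge_threshold)
    emb <- if (cfg$with_embedding)
      embed_2d(flib$features, perplexity = min(30, nrow(library_rec) / 4),
               rng_seed = .stage_seed(cfg, 7L)) else NULL
    recs <- screen_records(library_rec, prob, net, flib$properties, emb)
    res <- filter_hits(recs, cfg$criteria)
    list(library = library_rec, records = recs, hits = res$hits,
         audit = res$audit, network = net)
  })
  write.csv(screen$audit, paths("screen_audit.csv"), row.names = FALSE)
  write.csv(screen$hits, paths("hits.csv"), row.names = FALSE)
  write.csv(screen$network$edges, paths("network_edges.csv"),
            row.names = FALSE)

  fits <- NULL
  if (cfg$with_assay || !is.null(cfg$assay_path)) {
    fits <- .stage("dose_response", {
      assay <- if (!is.null(cfg$assay_path)) read_assay_table(cfg$assay_path)
        else .demo_assay(screen$hits, .stage_seed(cfg, 8L))
      .fit_assay_table(assay)
    })
    if (!is.null(fits))
      write.csv(fits, paths("dose_response_fits.csv"), row.names = FALSE)
  }

  manifest <- .stage("manifest", {
    cfg_json <- paths("config.json")
    jsonlite::write_json(.config_as_list(cfg), cfg_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    list(config_md5 = unname(tools::md5sum(cfg_json)),
         rng_seed = cfg$rng_seed,
         stage_seeds = setNames(as.list(cfg$rng_seed * 100L + 1:8),
                                c("seeds", "split", "augment_train",
                                  "augment_test", "train", "library",
                                  "embedding", "assay")),
         n_train = nrow(aug$train), n_test = nrow(aug$test),
         n_library = nrow(screen$library), n_hits = nrow(screen$hits),
         package_version = as.character(utils::packageVersion("molscreen")))
  })
  jsonlite::write_json(manifest, paths("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(seeds = seeds, split = parts, augmented = aug,
                 bundle = bundle, reports = reports, screen = screen,
                 fits = fits, manifest = manifest))
}

# strip S3 classes recursively so the config serializes to plain JSON
.config_as_list <- function(cfg) {
  if (is.list(cfg)) lapply(unclass(cfg), .config_as_list) else cfg
}

.write_metrics <- function(reports, path) {
  row <- function(nm, r) data.frame(
    set = nm, accuracy = r$accuracy, mcc = r$mcc, f1 = r$f1,
    roc_auc = r$roc_auc, tn = r$confusion["TN"], fp = r$confusion["FP"],
    fn = r$confusion["FN"], tp = r$confusion["TP"], row.names = NULL)
  df <- rbind(row("training", reports$train), row("test", reports$test),
              data.frame(set = "delta_train_minus_test",
                         accuracy = reports$gap$delta_accuracy,
                         mcc = reports$gap$delta_mcc,
                         f1 = reports$gap$delta_f1,
                         roc_auc = NA, tn = NA, fp = NA, fn = NA, tp = NA))
  write.csv(df, path, row.names = FALSE)
}

# demo-mode validation: synthesize an assay for up to 3 nominated hits
# (arbitrary generating truths spanning inhibitor and inactive behavior)
.demo_assay <- function(hits, rng_seed) {
  if (nrow(hits) == 0) return(NULL)
  truths <- list(fourpl_params(40, 100, 10, 1),
                 fourpl_params(30, 100, 22.7, 1),
                 fourpl_params(97, 100, 50, 1))  # last: essentially flat
  ids <- head(hits$id, 3)
  do.call(rbind, lapply(seq_along(ids), function(i)
    generate_dose_response(assay_config(truths[[i]], compound = ids[i],
                                        rng_seed = rng_seed + i))))
}

# fit every (compound, form) group of an assay table
.fit_assay_table <- function(assay) {
  if (is.null(assay)) return(NULL)
  if (is.null(assay$form)) assay$form <- "unknown"
  groups <- unique(assay[, c("compound", "form")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- assay[assay$compound == groups$compound[i] &
                   assay$form == groups$form[i], , drop = FALSE]
    norm <- normalize_activity(sub)
    fit <- fit_4pl(norm)
    data.frame(compound = groups$compound[i], form = groups$form[i],
               ic50_uM = fit$ic50,
               max_inhibition_pct = fit$max_inhibition,
               hill = if (is.null(fit$params)) NA else fit$params$hill,
               r_squared = fit$r_squared, reliable = fit$reliable,
               activity_call = classify_activity(fit),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
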
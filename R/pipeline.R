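# End-to-end pipeline plumbing: volume loading with optional resampling,
# per-patient graph construction, cohort-scale feature extraction with a
# leakage-safe reducer fit, and the command-line entry points.

#' Load a CT volume from NIfTI
#'
#' @param path `.nii` / `.nii.gz` file.
#' @param slice_mm optional target slice thickness; when given, the volume
#'   is resampled so the z spacing equals `slice_mm`.
#' @param matrix_size optional in-plane matrix (e.g. 512): y/x are resampled
#'   to `matrix_size x matrix_size`.
#' @return a [ct_volume].
#' @export
load_volume <- function(path, slice_mm = NULL, matrix_size = NULL) {
  vol <- read_nifti(path)
  if (!is.null(slice_mm))
    vol <- resample_volume(vol, c(slice_mm, NA, NA))
  if (!is.null(matrix_size)) {
    d <- dim(vol$data)
    sp <- vol$spacing_mm
    target <- c(sp[1], d[2] * sp[2] / matrix_size, d[3] * sp[3] / matrix_size)
    vol <- resample_volume(vol, target)
  }
  vol
}

#' Save a CT volume as NIfTI
#' @param vol a [ct_volume].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) write_nifti(vol, path)

#' Box-filter smoothing of a CT volume
#'
#' Separable-equivalent 3x3x3 mean filter (edge-replicated); takes the
#' noise SD down ~5x before thresholding-based segmentation.
#'
#' @param vol a [ct_volume].
#' @return a smoothed [ct_volume] of identical shape.
#' @export
smooth_volume <- function(vol) {
  d <- dim(vol$data)
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vol$data
  padded[1, , ] <- padded[2, , ];   padded[d[1] + 2, , ] <- padded[d[1] + 1, , ]
  padded[, 1, ] <- padded[, 2, ];   padded[, d[2] + 2, ] <- padded[, d[2] + 1, ]
  padded[, , 1] <- padded[, , 2];   padded[, , d[3] + 2] <- padded[, , d[3] + 1]
  out <- .conv3d_valid(as.numeric(padded), c(1L, dim(padded)),
                       rep(1 / 27, 27), c(1L, 1L, 3L), 0, 1L, FALSE)
  ct_volume(array(out$values, d), vol$spacing_mm)
}

#' Segment the airway and locate the four landmarks
#'
#' Convenience wrapper: box-filter denoising, seed selection, region
#' growing, skeletonization, landmark extraction.
#'
#' @param ct a [ct_volume].
#' @param smooth denoise before thresholding (recommended on noisy input).
#' @return list: `mask` (`binary_mask`), `skeleton`, `landmarks`.
#' @export
segment_airway <- function(ct, smooth = TRUE) {
  work <- if (smooth) smooth_volume(ct) else ct
  seed <- select_seed(work)
  mask <- region_grow(work, seed)
  skel <- skeletonize(mask)
  lm <- extract_landmarks(skel)
  list(mask = mask, skeleton = skel, landmarks = lm)
}

#' Raw (pre-reduction) features for one patient
#'
#' Extracts the ten patches and encodes each to a 1024-d vector.
#'
#' @param sample a `phantom_sample` (or a list with the same fields).
#' @param enc a `patch_encoder`.
#' @param landmark_mode `"segment"` runs the airway pipeline on the CT;
#'   `"truth"` uses the phantom's designed landmarks (cohort-scale runs).
#' @return `10 x channels` matrix with role rownames.
#' @export
patient_raw_features <- function(sample, enc = default_encoder(),
                                 landmark_mode = c("segment", "truth")) {
  landmark_mode <- match.arg(landmark_mode)
  lm <- if (landmark_mode == "truth") {
    structure(sample$landmarks_truth, class = "landmark_set")
  } else {
    segment_airway(sample$ct)$landmarks
  }
  patches <- patient_patches(sample$ct, lm, sample$lobe_labels,
                             sample$tumor_annotation)
  raw <- t(vapply(patches, encode_patch, numeric(enc$channels), enc = enc))
  rownames(raw) <- names(patches)
  raw
}

#' Cohort-scale raw feature extraction
#'
#' Materializes each patient in turn (volumes are discarded after
#' encoding), returning the stacked `10 n x channels` raw feature matrix.
#'
#' @param cohort a `phantom_cohort`.
#' @param enc a `patch_encoder`.
#' @param landmark_mode see [patient_raw_features].
#' @param verbose print progress every 50 patients.
#' @return list: `raw` (matrix), `patient` (id per row), `role` (role per
#'   row), `tumor_lobes` (named list per patient).
#' @export
cohort_raw_features <- function(cohort, enc = default_encoder(),
                                landmark_mode = "truth", verbose = FALSE) {
  n <- nrow(cohort$table)
  roles <- node_roles()
  raw <- matrix(NA_real_, n * length(roles), enc$channels)
  tumor_lobes <- vector("list", n)
  for (i in seq_len(n)) {
    s <- cohort_sample(cohort, i)
    raw[(i - 1) * length(roles) + seq_along(roles), ] <-
      patient_raw_features(s, enc, landmark_mode)
    tumor_lobes[[i]] <- s$tumor_annotation$lobes
    if (verbose && i %% 50 == 0) message(sprintf("  encoded %d/%d patients", i, n))
  }
  list(raw = raw,
       patient = rep(cohort$table$id, each = length(roles)),
       role = rep(roles, n),
       tumor_lobes = stats::setNames(tumor_lobes, cohort$table$id))
}

#' Build labeled lung graphs for a whole cohort
#'
#' Fits the ridge reducer on the training patients' raw features only
#' (leakage guard), then reduces and assembles one graph per patient.
#'
#' @param cohort a `phantom_cohort`.
#' @param feats output of [cohort_raw_features].
#' @param split a `split_assignment` over the cohort ids.
#' @param lambda ridge penalty for [fit_reducer].
#' @return list: `graphs` (named by id), `reducer`.
#' @export
build_cohort_graphs <- function(cohort, feats, split, lambda = 1) {
  train_rows <- feats$patient %in% split$train
  reducer <- fit_reducer(feats$raw[train_rows, , drop = FALSE], lambda = lambda,
                         fitted_on = split$train)
  reduced <- apply_reducer(reducer, feats$raw)
  graphs <- lapply(seq_len(nrow(cohort$table)), function(i) {
    id <- cohort$table$id[i]
    rows <- which(feats$patient == id)
    feat <- reduced[rows, , drop = FALSE]
    rownames(feat) <- feats$role[rows]
    build_graph(feat, feats$tumor_lobes[[id]], id,
                label = cohort$table$label_5yr[i])
  })
  names(graphs) <- cohort$table$id
  list(graphs = graphs, reducer = reducer)
}

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param n_patients synthetic cohort size.
#' @param seed global seed; every stochastic stage derives a child seed.
#' @param landmark_mode `"segment"` (full airway pipeline per patient) or
#'   `"truth"` (phantom ground-truth landmarks).
#' @param hidden_dim,n_blocks,dropout_p model hyperparameters.
#' @param epochs,batch_size training hyperparameters.
#' @param lambda ridge penalty of the feature reducer.
#' @param cohort overrides for [cohort_spec] fields (list).
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, n_patients = 20L, seed = 1L,
                            landmark_mode = "segment",
                            hidden_dim = 32L, n_blocks = 2L, dropout_p = 0.3,
                            epochs = 30L, batch_size = 32L, lambda = 1,
                            cohort = list()) {
  structure(list(out_dir = out_dir, n_patients = as.integer(n_patients),
                 seed = as.integer(seed), landmark_mode = landmark_mode,
                 hidden_dim = as.integer(hidden_dim),
                 n_blocks = as.integer(n_blocks), dropout_p = dropout_p,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lambda = lambda, cohort = cohort),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic pipeline
#'
#' Generates a phantom cohort, builds per-patient graphs (reducer fitted on
#' the training split only), trains the GCN, and writes the evaluation
#' report: cohort table, serialized graphs, model checkpoint, metrics JSON
#' (classification + KM/log-rank/Cox on median risk groups), KM curve CSV.
#' Every artifact embeds the config hash; a rerun with the same config is
#' deterministic.
#'
#' @param config a [pipeline_config].
#' @param verbose print stage progress.
#' @return list: `metrics`, `model`, `split`, `graphs`, `config_hash`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  say <- function(...) if (verbose) message(sprintf(...))

  say("[1/5] generating cohort (n = %d)", config$n_patients)
  cs_args <- utils::modifyList(list(n_patients = config$n_patients,
                                    seed = child_seed(config$seed, 1)),
                               config$cohort)
  cohort <- generate_cohort(do.call(cohort_spec, cs_args))
  write_cohort_table(cohort, file.path(config$out_dir, "cohort.csv"))

  say("[2/5] encoding patches (%s landmarks)", config$landmark_mode)
  enc <- default_encoder()
  feats <- cohort_raw_features(cohort, enc, config$landmark_mode, verbose)

  say("[3/5] splitting and building graphs")
  labels <- stats::setNames(cohort$table$label_5yr, cohort$table$id)
  split <- stratified_split(labels, seed = child_seed(config$seed, 2))
  built <- build_cohort_graphs(cohort, feats, split, lambda = config$lambda)
  gdir <- file.path(config$out_dir, "graphs")
  dir.create(gdir, showWarnings = FALSE)
  for (id in names(built$graphs))
    serialize_graph(built$graphs[[id]], file.path(gdir, id))

  say("[4/5] training GCN")
  mc <- model_config(n_blocks = config$n_blocks, hidden_dim = config$hidden_dim,
                     dropout_p = config$dropout_p)
  tc <- train_config(epochs = config$epochs, batch_size = config$batch_size,
                     seed = child_seed(config$seed, 3))
  model <- train_gcn(built$graphs[split$train], built$graphs[split$val], mc, tc)
  save_model(model, file.path(config$out_dir, "model"))

  say("[5/5] evaluating on the test split")
  test_graphs <- built$graphs[split$test]
  scores <- predict_risk(model, test_graphs)
  test_tab <- cohort$table[match(split$test, cohort$table$id), ]
  cm <- if (length(unique(test_tab$label_5yr)) < 2) {
    # tiny smoke cohorts can land a single-class test split
    list(auc = NA, auc_ci = NA, sensitivity = NA, specificity = NA,
         precision = NA, f2 = NA, threshold = 0.5)
  } else {
    classifier_metrics(scores, test_tab$label_5yr,
                       seed = child_seed(config$seed, 4))
  }
  grp <- stratify_risk(scores)
  records <- survival_records(test_tab$id, test_tab$os_months, test_tab$os_event)
  km_low <- kaplan_meier(records[grp == "low", ])
  km_high <- kaplan_meier(records[grp == "high", ])
  surv_stats <- if (all(table(grp) > 0) &&
                    all(tapply(records$event, grp, sum) > 0)) {
    lr <- log_rank(grp, records)
    cox <- cox_hr(as.integer(grp) - 1L, records)
    list(log_rank_chisq = lr$chisq, log_rank_p = lr$p,
         hr = cox$hr, hr_ci = cox$ci, hr_p = cox$p)
  } else list(log_rank_chisq = NA, log_rank_p = NA, hr = NA, hr_ci = NA, hr_p = NA)

  metrics <- c(list(config_hash = hash, n_test = length(scores)),
               unclass(cm)[c("auc", "auc_ci", "sensitivity", "specificity",
                             "precision", "f2", "threshold")],
               surv_stats)
  jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  km_bind <- function(gname, km) {
    if (nrow(km) == 0) return(NULL)
    cbind(group = gname, km)
  }
  km_out <- rbind(km_bind("low", km_low), km_bind("high", km_high))
  if (is.null(km_out))
    km_out <- data.frame(group = character(0), time = numeric(0),
                         n_risk = integer(0), n_event = integer(0),
                         surv = numeric(0))
  write.csv(km_out, file.path(config$out_dir, "km_curve.csv"), row.names = FALSE)

  list(metrics = metrics, model = model, split = split,
       graphs = built$graphs, config_hash = hash)
}

#' Command-line interface
#'
#' Subcommands: `phantom` (write a synthetic cohort), `segment-airway`
#' (airway mask + landmarks for one CT), `run-all` (full synthetic
#' pipeline).  See `lungraph_cli(c("<cmd>", "--help"))`.
#'
#' @param args character vector (default: the process command line).
#' @return exit status 0, invisibly.
#' @export
lungraph_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: lungraph <phantom|segment-airway|run-all> [options]"
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; rest <- args[-1]
  if (cmd == "phantom") {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
      optparse::make_option("--n", type = "integer", default = 10L),
      optparse::make_option("--seed", type = "integer", default = 7L),
      optparse::make_option("--out", type = "character", default = "phantom_out"),
      optparse::make_option("--volumes", action = "store_true", default = FALSE,
                            help = "also write per-patient NIfTI volumes"))),
      args = rest)
    cohort <- generate_cohort(cohort_spec(opts$n, seed = opts$seed))
    dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
    write_cohort_table(cohort, file.path(opts$out, "cohort.csv"))
    if (opts$volumes) {
      for (i in seq_len(opts$n))
        write_phantom_sample(cohort_sample(cohort, i), opts$out,
                             cohort$table$id[i])
    }
    message("cohort written to ", opts$out)
  } else if (cmd == "segment-airway") {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
      optparse::make_option("--ct", type = "character"),
      optparse::make_option("--out", type = "character", default = "airway_out"))),
      args = rest)
    if (is.null(opts$ct) || !file.exists(opts$ct)) stop("--ct file not found")
    ct <- load_volume(opts$ct)
    seg <- segment_airway(ct)
    dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
    write_nifti(array(as.integer(seg$mask$voxels), dim(seg$mask$voxels)),
                file.path(opts$out, "airway_mask.nii.gz"),
                spacing_mm = ct$spacing_mm, datatype = "uint8")
    write_landmarks(seg$landmarks, file.path(opts$out, "landmarks.json"))
    message("airway mask and landmarks written to ", opts$out)
  } else if (cmd == "run-all") {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
      optparse::make_option("--n", type = "integer", default = 20L),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--out", type = "character", default = "pipeline_out"),
      optparse::make_option("--landmarks", type = "character", default = "segment"),
      optparse::make_option("--epochs", type = "integer", default = 30L),
      optparse::make_option("--hidden", type = "integer", default = 32L))),
      args = rest)
    res <- run_pipeline(pipeline_config(opts$out, n_patients = opts$n,
                                        seed = opts$seed,
                                        landmark_mode = opts$landmarks,
                                        epochs = opts$epochs,
                                        hidden_dim = opts$hidden),
                        verbose = TRUE)
    message("metrics written to ", file.path(opts$out, "metrics.json"))
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
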
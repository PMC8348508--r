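#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end QSAR workflow. All seeds are
#' explicit; no stage seeds itself from the clock.
#'
#' @param input path to an activity CSV (`id,smiles,ki_nM`) or `.smi` file.
#' @param outdir run directory (created; outputs are written here).
#' @param specs descriptor specs (default [named_descriptor_set()]).
#' @param corr_cut,near_const_tol objective-feature-selection parameters.
#' @param train_fraction training-set fraction.
#' @param m_max largest model size scanned by the GA.
#' @param ga a [ga_config()].
#' @param delta breaking-point threshold on Q2_LOO gains.
#' @param lmo_fraction,lmo_iterations,yscr_iterations,resid_cut validation
#'   parameters.
#' @param seed global seed (controls the split and validation resampling).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, outdir, specs = named_descriptor_set(),
                            corr_cut = 0.90, near_const_tol = 0.05,
                            train_fraction = 0.8, m_max = 8L,
                            ga = ga_config(), delta = 0.02,
                            lmo_fraction = 0.3, lmo_iterations = 200L,
                            yscr_iterations = 200L, resid_cut = 2.5,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

.config_hash <- function(config) {
  stripped <- config[setdiff(names(config), c("specs"))]
  stripped$spec_names <- names(config$specs)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(stripped, tmp, auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full QSAR pipeline
#'
#' Executes, in order: curation, descriptor calculation, objective feature
#' selection, train/external split, GA-MLR search per model size, breaking
#' point selection, final OLS fit and the complete validation suite.
#' Writes into the run directory: `curated.csv`, `descriptors.csv`,
#' `split.csv`, `sizes.json`, `scores.csv`, `validation.json`,
#' `williams.csv`, `yscrambling.csv`, and `run_log.txt` with the config
#' hash. Rerunning with an identical config reproduces identical numeric
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `curated`, `X`, `split`, `scan`,
#'   `m_best`, `report`, `outdir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run_log.txt")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  say("config hash: ", .config_hash(config))

  say("stage curate")
  raw <- if (grepl("\\.smi$", config$input)) read_smi(config$input) else
    read_activity_csv(config$input)
  curated <- curate(raw)
  write_curated_csv(curated, file.path(config$outdir, "curated.csv"))
  say("  ", nrow(curated), " molecules survive curation")

  say("stage descriptors")
  mols <- parse_molecules(curated$canonical_smiles, curated$id)
  X_all <- compute_matrix(mols, config$specs)
  write_descriptor_csv(X_all, file.path(config$outdir, "descriptors.csv"))

  say("stage ofs")
  X <- ofs_filter(X_all, y = curated$pki, corr_cut = config$corr_cut,
                  near_const_tol = config$near_const_tol)
  say("  ", ncol(X), " of ", ncol(X_all), " descriptors retained")

  say("stage split")
  split <- split_dataset(nrow(X), config$train_fraction, seed = config$seed)
  write_split_csv(curated$id, split, file.path(config$outdir, "split.csv"))
  tab <- modeling_table(curated, X, split, seed = config$seed)
  tr <- split == "train"

  say("stage ga-mlr scan (m = 1..", config$m_max, ")")
  ga <- config$ga
  ga$seed <- config$seed
  m_cap <- min(config$m_max, ncol(X), floor(sum(tr) / 5) - 1L)
  scan <- model_size_scan(X[tr, , drop = FALSE], tab$y[tr], m_cap, ga)
  write.csv(scan$scores, file.path(config$outdir, "scores.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    lapply(names(scan$best), function(m) list(
      m = as.integer(m),
      best_subsets = lapply(seq_len(nrow(scan$best[[m]])), function(i) list(
        names = strsplit(scan$best[[m]]$names[i], ",")[[1L]],
        q2_loo = scan$best[[m]]$q2_loo[i],
        r2_tr = scan$best[[m]]$r2_tr[i]))
    )),
    file.path(config$outdir, "sizes.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  m_best <- breaking_point(scan$scores, delta = config$delta)
  say("  breaking point at m = ", m_best)
  chosen <- strsplit(scan$best[[as.character(m_best)]]$names[1L], ",")[[1L]]
  say("  descriptors: ", paste(chosen, collapse = ", "))

  say("stage validation")
  report <- validate_model(
    X[tr, , drop = FALSE], tab$y[tr],
    X[!tr, , drop = FALSE], tab$y[!tr],
    names = chosen, lmo_fraction = config$lmo_fraction,
    lmo_iterations = config$lmo_iterations,
    yscr_iterations = config$yscr_iterations,
    resid_cut = config$resid_cut, seed = config$seed)
  write_validation_report(report, file.path(config$outdir, "validation.json"))
  write.csv(report$ad$table, file.path(config$outdir, "williams.csv"),
            row.names = FALSE)
  write.csv(report$yscr$table, file.path(config$outdir, "yscrambling.csv"),
            row.names = FALSE)
  say("done: R2_tr = ", round(report$training$R2_tr, 3),
      ", Q2_LOO = ", round(report$cv$Q2_LOO, 3))

  invisible(list(curated = curated, X = X, split = split, scan = scan,
                 m_best = m_best, report = report, outdir = config$outdir))
}

#' Predict activities with a stored or published model
#'
#' @param input activity CSV or `.smi` file with SMILES to predict.
#' @param model an `mlr_model`, or `"published"` for [published_model()].
#' @param output optional CSV path for the predictions.
#' @return data.frame with `id` and predicted `pki`.
#' @export
run_predict <- function(input, model = "published", output = NULL) {
  if (identical(model, "published")) model <- published_model()
  stopifnot(inherits(model, "mlr_model"))
  raw <- if (grepl("\\.smi$", input)) read_smi(input) else
    read_activity_csv(input)
  mols <- parse_molecules(raw$smiles, raw$id)
  X <- compute_matrix(mols, named_descriptor_set())
  out <- data.frame(id = raw$id, pki_pred = predict(model, X),
                    stringsAsFactors = FALSE)
  if (!is.null(output)) write.csv(out, output, row.names = FALSE, quote = FALSE)
  out
}
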
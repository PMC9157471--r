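#' Run the full splice-site pipeline from a configuration
#'
#' Executes the chain simulate/read -> (ORF scan) -> dataset build -> train ->
#' predict -> evaluate, writing each stage's artifacts plus a JSON run
#' manifest (resolved parameters, seeds, input digests, output paths,
#' wall-clock start/end) sufficient to re-run the pipeline identically.
#'
#' The configuration is a YAML file (or an equivalent named list) with keys:
#' \describe{
#'   \item{outdir}{Output directory (required).}
#'   \item{seed}{Master seed; stage seeds default to it (default 1).}
#'   \item{input}{Path to a FASTA genome. Exactly one of `input` or
#'     `simulate` is required.}
#'   \item{simulate}{List of [simulate_genome()] arguments.}
#'   \item{dataset}{`source` (`"truth"` needs a simulated genome with ground
#'     truth; `"orf"` runs the ORF-based Algorithm-1 builder),
#'     `train_fraction` (default 0.8), `min_orf_length` (default 150),
#'     `stop_set` (`"standard"`/`"code4"`).}
#'   \item{train}{[splice_config()] overrides.}
#'   \item{predict}{`min_intron`/`max_intron` (defaults 70/100), `spans`
#'     (`"orf"` or `"truth"`), `aggregate`.}
#'   \item{evaluate}{Compare calls against ground truth (default TRUE when
#'     simulated).}
#' }
#'
#' @param config Path to a YAML configuration file, or a named list.
#' @return Invisibly, a list with the fitted model, the splice-structure
#'   result, the evaluation metrics (or NULL) and the manifest.
#' @export
run_pipeline <- function(config) {
  started <- Sys.time()
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file or a named list")
  need <- function(key) {
    if (is.null(config[[key]])) stop("missing config key: ", key)
    config[[key]]
  }
  outdir <- need("outdir")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (is.null(config$input) && is.null(config$simulate)) {
    stop("missing config key: input or simulate")
  }
  outputs <- character()
  digests <- character()
  out_path <- function(name) {
    p <- file.path(outdir, name)
    outputs[[name]] <<- p
    p
  }

  # -- stage 1: genome ------------------------------------------------------
  sim <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    sim <- do.call(simulate_genome, sim_args)
    genome <- sim$genome
    write_fasta(genome, out_path("genome.fasta"))
    write_truth_gff3(sim, out_path("truth.gff3"))
  } else {
    if (!file.exists(config$input)) {
      stop("input FASTA not found: ", config$input)
    }
    digests[config$input] <- unname(tools::md5sum(config$input))
    genome <- read_fasta(config$input)
  }
  message("genome: ", length(genome), " sequence(s), ",
          sum(nchar(genome)), " nt")

  # -- stage 2: dataset -----------------------------------------------------
  ds <- config$dataset
  if (is.null(ds)) ds <- list()
  source <- if (is.null(ds$source)) {
    if (is.null(sim)) "orf" else "truth"
  } else ds$source
  train_fraction <- if (is.null(ds$train_fraction)) 0.8 else ds$train_fraction
  if (source == "truth") {
    if (is.null(sim)) stop("dataset source 'truth' needs a simulated genome")
    windows <- truth_windows(sim, seed = seed)
  } else {
    stop_set <- orf_stop_set(if (is.null(ds$stop_set)) "standard"
                             else ds$stop_set)
    min_len <- if (is.null(ds$min_orf_length)) 150L
               else as.integer(ds$min_orf_length)
    orfs <- scan_orfs_genome(genome, min_orf_length = min_len,
                             stop_set = stop_set)
    message("ORFs: ", nrow(orfs))
    orf_seqs <- extract_orf_residues(genome, orfs)
    write_fasta(orf_seqs, out_path("orfs.fasta"))
    windows <- build_dataset(orf_seqs)
  }
  message("windows: ", nrow(windows), " (", nrow(windows) %/% 3L,
          " per class)")
  utils::write.table(windows, out_path("windows.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  split <- split_dataset(windows, train_fraction = train_fraction,
                         seed = seed)

  # -- stage 3: train -------------------------------------------------------
  train_args <- config$train
  if (is.null(train_args)) train_args <- list()
  if (is.null(train_args$seed)) train_args$seed <- seed
  cfg <- do.call(splice_config, train_args)
  model <- splice_rnn(split, cfg)
  message(sprintf("trained %d epochs; held-out accuracy %.4f",
                  nrow(model$history),
                  model$history$test_acc[nrow(model$history)]))
  save_model(model, out_path("model.rds"))
  utils::write.table(
    model$history[, c("epoch", "train_loss", "train_acc", "test_loss",
                      "test_acc")],
    out_path("history.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)

  # -- stage 4: predict -----------------------------------------------------
  pr <- config$predict
  if (is.null(pr)) pr <- list()
  min_intron <- if (is.null(pr$min_intron)) 70L else as.integer(pr$min_intron)
  max_intron <- if (is.null(pr$max_intron)) 100L
                else as.integer(pr$max_intron)
  spans <- NULL
  if (identical(pr$spans, "truth")) {
    if (is.null(sim)) stop("predict spans 'truth' needs a simulated genome")
    spans <- sim$truth$genes[, c("start", "end")]
  }
  target <- genome[1L]
  structure_call <- call_splice_structure(
    model, target, spans = spans, min_intron = min_intron,
    max_intron = max_intron, aggregate = isTRUE(pr$aggregate))
  feats <- rbind(
    if (nrow(structure_call$exons) > 0L)
      data.frame(type = "exon", start = structure_call$exons$start,
                 end = structure_call$exons$end)
    else NULL,
    if (nrow(structure_call$introns) > 0L)
      data.frame(type = "intron", start = structure_call$introns$start,
                 end = structure_call$introns$end)
    else NULL)
  if (is.null(feats)) feats <- data.frame(type = character(),
                                          start = integer(),
                                          end = integer())
  write_gff3(feats, names(target), out_path("calls.gff3"))
  summ <- structure_call$summary
  utils::write.table(
    data.frame(n_exons = summ$n_exons, n_introns = summ$n_introns,
               mean_exon_len = summ$mean_exon_length,
               mean_intron_len = summ$mean_intron_length),
    out_path("summary.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  message(sprintf("called %d introns, %d exons", summ$n_introns,
                  summ$n_exons))

  # -- stage 5: evaluate ----------------------------------------------------
  metrics <- NULL
  do_eval <- if (is.null(config$evaluate)) !is.null(sim)
             else isTRUE(config$evaluate)
  if (do_eval) {
    if (is.null(sim)) stop("evaluate needs a simulated genome with truth")
    metrics <- evaluate_against_truth(structure_call$calls, sim,
                                      exons = structure_call$exons,
                                      seq_length = nchar(target))
    utils::write.table(metrics, out_path("metrics.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("spliceRNN")),
    parameters = list(seed = seed, dataset_source = source,
                      train_fraction = train_fraction,
                      model_config = unclass(cfg),
                      min_intron = min_intron, max_intron = max_intron,
                      simulate = if (is.null(sim)) NULL else sim$params,
                      input = config$input),
    input_digests = as.list(digests),
    outputs = as.list(outputs),
    started = format(started, "%Y-%m-%d %H:%M:%S %Z"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(model = model, structure = structure_call,
                 metrics = metrics, manifest = manifest))
}
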
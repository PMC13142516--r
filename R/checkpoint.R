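# Checkpoints: a serialized parameter container plus a JSON sidecar carrying
# the full model configuration and a model tag.

configToList <- function(config) {
  list(embedDim = config@embedDim, numHeads = config@numHeads,
       headDim = config@headDim, mlpHidden = config@mlpHidden,
       dropoutRate = config@dropoutRate,
       attentionScaleMode = config@attentionScaleMode,
       useResidual = config@useResidual,
       outputBiasInit = config@outputBiasInit)
}

configFromList <- function(x) {
  modelConfig(embedDim = x$embedDim, numHeads = x$numHeads,
              mlpHidden = x$mlpHidden, dropoutRate = x$dropoutRate,
              attentionScaleMode = x$attentionScaleMode,
              useResidual = x$useResidual, outputBiasInit = x$outputBiasInit)
}

#' Save / load a model checkpoint
#'
#' `saveCheckpoint` writes the parameter container to `<path>` (RDS) and a
#' JSON sidecar `<path>.json` with the full configuration and the model tag
#' (`receptor_centric`, `peptide_centric`, or `custom`). `loadCheckpoint`
#' reads both back and re-validates the configuration.
#'
#' @param params `ModelParams`.
#' @param path Checkpoint file path.
#' @param modelTag Tag recorded in the sidecar.
#' @return `saveCheckpoint`: `path`, invisibly. `loadCheckpoint`: list with
#'   `params`, `config`, `modelTag`.
#' @export
saveCheckpoint <- function(params, path,
                           modelTag = c("custom", "receptor_centric",
                                        "peptide_centric")) {
  modelTag <- match.arg(modelTag)
  saveRDS(params[paramNames()], path)
  jsonlite::write_json(
    list(model_tag = modelTag, trained = isTRUE(params$trained),
         config = configToList(params$config)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  config <- configFromList(side$config)
  params <- readRDS(path)
  params$config <- config
  params$trained <- isTRUE(side$trained)
  class(params) <- "ModelParams"
  for (nm in paramNames())
    if (is.null(params[[nm]]))
      stop("checkpoint missing parameter ", nm, call. = FALSE)
  list(params = params, config = config, modelTag = side$model_tag)
}

#' Write a reproducibility manifest for a run
#'
#' Records package version, R version, the seed, and SHA-agnostic digests
#' (file sizes and modification-free content hashes via [tools::md5sum()])
#' of the declared inputs.
#'
#' @param path Output JSON path.
#' @param seed Seed used for the run.
#' @param inputs Character vector of input file paths.
#' @param extra Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(path, seed, inputs = character(0), extra = list()) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- c(list(
    package = "crossPPI",
    version = as.character(utils::packageVersion("crossPPI")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = lapply(stats::setNames(inputs, basename(inputs)), function(f)
      list(path = f, bytes = file.size(f),
           md5 = unname(tools::md5sum(f))))),
    extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
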
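#' Run configuration
#'
#' One object (serializable to YAML) that fixes every knob of a pipeline
#' run: phantom generation, augmentation, training, segmentation mode
#' and post-processing, the output directory and the single global seed
#' from which every stage seed is derived via [stage_seed()].
#'
#' @param seed global integer seed.
#' @param out_dir output directory for all artifacts.
#' @param manifest optional dataset manifest path.
#' @param phantom a [phantom_spec()].
#' @param augment an [augment_config()] or `NULL` to skip augmentation.
#' @param train a [train_config()].
#' @param postprocess a [postprocess_config()].
#' @param seg_mode `"fixed"` or `"sweep"`.
#' @param tau fixed segmentation threshold.
#' @param overlay_alpha overlay weight.
#' @param n_phantoms phantom count for `simulate`.
#' @param scale network scale divisor.
#' @param log_level `"quiet"` or `"verbose"`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = "flairseg_out",
                       manifest = NULL,
                       phantom = phantom_spec(),
                       augment = NULL,
                       train = train_config(),
                       postprocess = postprocess_config(),
                       seg_mode = c("fixed", "sweep"), tau = 0.5,
                       overlay_alpha = 0.4, n_phantoms = 100L,
                       scale = 8L, log_level = c("quiet", "verbose")) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 manifest = manifest, phantom = phantom, augment = augment,
                 train = train, postprocess = postprocess,
                 seg_mode = match.arg(seg_mode), tau = tau,
                 overlay_alpha = overlay_alpha,
                 n_phantoms = as.integer(n_phantoms),
                 scale = as.integer(scale),
                 log_level = match.arg(log_level)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The round trip is lossless: `read_run_config(write_run_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  plain <- lapply(unclass(cfg), function(x) {
    if (is.object(x)) unclass(x) else x
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config not found: %s", path), call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  bad_field <- function(section, e) {
    stop(sprintf("invalid config section `%s`: %s", section,
                 conditionMessage(e)), call. = FALSE)
  }
  mk <- function(section, ctor) {
    if (is.null(y[[section]])) return(NULL)
    tryCatch(do.call(ctor, y[[section]]),
             error = function(e) bad_field(section, e))
  }
  run_config(seed = y$seed %||% 1L,
             out_dir = y$out_dir %||% "flairseg_out",
             manifest = y$manifest,
             phantom = mk("phantom", phantom_spec) %||% phantom_spec(),
             augment = mk("augment", augment_config),
             train = mk("train", train_config) %||% train_config(),
             postprocess = mk("postprocess", postprocess_config) %||%
               postprocess_config(),
             seg_mode = y$seg_mode %||% "fixed",
             tau = y$tau %||% 0.5,
             overlay_alpha = y$overlay_alpha %||% 0.4,
             n_phantoms = y$n_phantoms %||% 100L,
             scale = y$scale %||% 8L,
             log_level = y$log_level %||% "quiet")
}
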
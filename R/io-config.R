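# Run configuration: one object tying together optics, phantom,
# reconstruction and QC settings, serialisable to YAML.

#' End-to-end run configuration
#'
#' @slot optics an [OpticalConfig-class].
#' @slot cc a [CCModel-class].
#' @slot phantom a [PhantomSpec-class].
#' @slot reconstruction list: `voxel_um` (3-vector), `interpolation`
#'   (`"cubic"`/`"trilinear"`), `registration` (`"similarity"`/`"affine"`),
#'   `fuse_mode` (`"mean"`/`"max"`), `match_radius_um`, `crop_to_extent`.
#' @slot qc list: `min_sep_um`, `threshold_rel`, `half_size_um` (3-vector),
#'   `r2_min`, `bin_um` (3-vector).
#' @slot seed integer(1). Master seed; all pipeline randomness derives from
#'   it.
#' @slot output_dir character(1).
#' @export
setClass("RunConfig",
  representation(optics = "OpticalConfig", cc = "CCModel",
                 phantom = "PhantomSpec", reconstruction = "list",
                 qc = "list", seed = "integer", output_dir = "character"))

.recon_defaults <- function() {
  list(voxel_um = c(0.205, 0.205, 0.25), interpolation = "cubic",
       registration = "similarity", fuse_mode = "mean",
       match_radius_um = 1, crop_to_extent = TRUE)
}

.qc_defaults <- function() {
  list(min_sep_um = 3, threshold_rel = 0.2, half_size_um = c(4, 4, 5),
       r2_min = 0.9, bin_um = c(32, 32, 60))
}

#' Construct a RunConfig
#'
#' @param optics an [OpticalConfig-class].
#' @param cc a [CCModel-class].
#' @param phantom a [PhantomSpec-class].
#' @param reconstruction named list overriding reconstruction defaults.
#' @param qc named list overriding QC defaults.
#' @param seed master seed.
#' @param output_dir output directory for [runPipeline()].
#' @return A [RunConfig-class].
#' @export
RunConfig <- function(optics = OpticalConfig(), cc = CCModel(),
                      phantom = PhantomSpec(), reconstruction = list(),
                      qc = list(), seed = 1L, output_dir = tempfile("dopm")) {
  rec <- .merge_known(.recon_defaults(), reconstruction, "reconstruction")
  qcl <- .merge_known(.qc_defaults(), qc, "qc")
  new("RunConfig", optics = optics, cc = cc, phantom = phantom,
      reconstruction = rec, qc = qcl, seed = as.integer(seed),
      output_dir = output_dir)
}

.merge_known <- function(defaults, override, where) {
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    .validation_error(sprintf("unknown key(s) in '%s': %s", where,
                              paste(unknown, collapse = ", ")))
  defaults[names(override)] <- override
  defaults
}

.slots_to_list <- function(obj) {
  out <- lapply(slotNames(obj), function(nm) slot(obj, nm))
  names(out) <- slotNames(obj)
  out
}

.list_to_s4 <- function(lst, constructor, allowed, where) {
  unknown <- setdiff(names(lst), allowed)
  if (length(unknown))
    .validation_error(sprintf("unknown key(s) in '%s': %s", where,
                              paste(unknown, collapse = ", ")))
  do.call(constructor, lst)
}

#' Write / read a run configuration as YAML
#'
#' The YAML mirrors the object structure (`optics:`, `cc:`, `phantom:`,
#' `reconstruction:`, `qc:`, `seed:`, `output_dir:`). Reading rejects
#' unknown keys with a named validation error and round-trips losslessly.
#'
#' @param config a [RunConfig-class].
#' @param path YAML file path.
#' @return `readRunConfig` returns a [RunConfig-class].
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(is(config, "RunConfig"))
  yaml::write_yaml(list(
    optics = .slots_to_list(config@optics),
    cc = .slots_to_list(config@cc),
    phantom = .slots_to_list(config@phantom),
    reconstruction = config@reconstruction,
    qc = config@qc,
    seed = config@seed,
    output_dir = config@output_dir), path, precision = 15)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  top <- c("optics", "cc", "phantom", "reconstruction", "qc", "seed",
           "output_dir")
  unknown <- setdiff(names(lst), top)
  if (length(unknown))
    .validation_error(sprintf("unknown top-level key(s): %s",
                              paste(unknown, collapse = ", ")))
  optics <- .list_to_s4(lst$optics %||% list(), OpticalConfig,
                        slotNames("OpticalConfig"), "optics")
  cc <- .list_to_s4(lst$cc %||% list(), CCModel, slotNames("CCModel"), "cc")
  phantom <- .list_to_s4(lst$phantom %||% list(), PhantomSpec,
                         slotNames("PhantomSpec"), "phantom")
  RunConfig(optics = optics, cc = cc, phantom = phantom,
            reconstruction = lst$reconstruction %||% list(),
            qc = lst$qc %||% list(),
            seed = lst$seed %||% 1L,
            output_dir = lst$output_dir %||% tempfile("dopm"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
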
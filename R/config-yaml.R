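#' Read a pipeline configuration from YAML
#'
#' Loads a cohort/acquisition/measurement configuration and merges it over
#' the [pipeline_config()] defaults: any field omitted from the file keeps
#' its default, nested blocks (`mri`, `patho`, `measurement`, ...) are
#' merged field by field, and the result is validated by
#' [pipeline_config()]. The `measurement$observer_bias` block may be given
#' as a list of per-observer named vectors and is converted to the matrix
#' form the pipeline uses. A documented example ships with the package:
#' `system.file("extdata", "cohort-example.yaml", package = "rflesion")`.
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  known <- setdiff(names(defaults), NULL)
  unknown <- setdiff(names(user), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  merged <- unclass(defaults)
  for (nm in names(user)) {
    merged[[nm]] <- if (is.list(merged[[nm]]) && is.list(user[[nm]]))
      utils::modifyList(merged[[nm]], user[[nm]]) else user[[nm]]
  }
  if (!is.null(user$mri$contrast))
    merged$mri$contrast <- unlist(user$mri$contrast)
  if (!is.null(user$measurement$repeat_sd))
    merged$measurement$repeat_sd <- unlist(user$measurement$repeat_sd)
  ob <- merged$measurement$observer_bias
  if (is.list(ob))
    merged$measurement$observer_bias <- do.call(rbind, lapply(ob, unlist))
  if (is.list(merged$dims))
    merged$dims <- lapply(merged$dims, unlist)
  do.call(pipeline_config, merged)
}
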